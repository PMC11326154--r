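#' Reflection sets
#'
#' A \code{reflection_set} stores structure-factor amplitudes on a common
#' lattice: a data frame with columns \code{h, k, l} (Miller indices in
#' the Friedel-unique half sphere), \code{F} (amplitude, electrons on the
#' absolute scale for simulated data, arbitrary experimental scale
#' otherwise), \code{SIGF} (amplitude uncertainty) and, when known,
#' \code{phi} (phase in degrees). Cell and space group ride along.
#'
#' @param refl reflection data frame (h, k, l, F, SIGF, optionally phi).
#' @param cell unit cell vector.
#' @param space_group space-group symbol.
#' @return an object of class \code{reflection_set}.
#' @export
reflection_set <- function(refl, cell, space_group = "P 1") {
  check_cell(cell)
  need <- c("h", "k", "l", "F", "SIGF")
  miss <- setdiff(need, names(refl))
  if (length(miss)) stop("reflection table missing columns: ", paste(miss, collapse = ", "))
  if (any(refl$F < 0)) stop("amplitudes must be non-negative")
  if (any(refl$SIGF < 0)) stop("sigmas must be non-negative")
  key <- paste(refl$h, refl$k, refl$l)
  if (anyDuplicated(key)) stop("duplicate Miller indices after ASU mapping")
  structure(list(refl = as.data.frame(refl), cell = as.numeric(cell),
                 space_group = space_group),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  d <- 1 / sqrt(pmax(inv_d2(x$refl[, c("h", "k", "l")], x$cell), 1e-12))
  cat(sprintf("reflection_set: %d reflections, d range %.2f - %.2f A, %s\n",
              nrow(x$refl), max(d[is.finite(d)]), min(d), x$space_group))
  invisible(x)
}

# single-Gaussian scattering factors: f(s) = Z_eff * exp(-b_el * s^2 / 4).
# Effective electron counts with crude per-element widths; adequate for
# difference-signal simulation, not for refinement.
.scatter_tab <- list(H = c(z = 1, b = 25), C = c(z = 6, b = 13),
                     N = c(z = 7, b = 11), O = c(z = 8, b = 9),
                     S = c(z = 16, b = 14), P = c(z = 15, b = 14))

scatter_params <- function(element) {
  el <- toupper(element)
  unknown <- setdiff(unique(el), names(.scatter_tab))
  if (length(unknown)) stop("no scattering factor for element(s): ",
                            paste(unknown, collapse = ", "))
  z <- vapply(el, function(e) .scatter_tab[[e]]["z"], numeric(1))
  b <- vapply(el, function(e) .scatter_tab[[e]]["b"], numeric(1))
  list(z = unname(z), b = unname(b))
}

# Friedel-unique half sphere (plus F000) for a P1 cell at d >= d_min
hkl_half_sphere <- function(cell, d_min) {
  Minv <- cart_to_frac(cell)
  # conservative per-axis bounds from the reciprocal cell
  astar <- sqrt(rowSums(Minv^2))
  hmax <- ceiling(1 / (d_min * astar[1]))
  kmax <- ceiling(1 / (d_min * astar[2]))
  lmax <- ceiling(1 / (d_min * astar[3]))
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  keep <- inv_d2(g, cell) <= 1 / d_min^2 + 1e-12
  g <- g[keep, ]
  plus <- g$h > 0 | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l >= 0)
  g <- g[plus, ]
  g[order(g$h, g$k, g$l), ]
}

# complex structure factors by direct summation over non-water atoms
direct_structure_factors <- function(model, hkl) {
  a <- model$atoms[!model$atoms$is_water, , drop = FALSE]
  if (nrow(a) == 0) stop("model contains no scattering atoms")
  sp <- scatter_params(a$element)
  xf <- as.matrix(a[, c("x", "y", "z")]) %*% t(cart_to_frac(model$cell))
  H <- as.matrix(hkl[, c("h", "k", "l")])
  s2 <- inv_d2(H, model$cell)
  # per (reflection, atom) weight: occ * Z * exp(-(b_el + B) s^2 / 4)
  W <- exp(outer(-s2 / 4, sp$b + a$b)) *
    matrix(a$occ * sp$z, nrow(H), nrow(a), byrow = TRUE)
  ph <- 2 * pi * (H %*% t(xf))
  as.vector(rowSums(W * exp(1i * ph)))
}

#' Simulate structure-factor amplitudes for a model
#'
#' Computes F(h) by direct summation over all non-water atoms of the
#' model, F(h) = sum_j occ_j f_j(s) exp(-B_j s^2/4) exp(2 pi i h.x_j),
#' with single-Gaussian per-element scattering factors, complete in the
#' Friedel-unique half sphere to \code{d_min} (F000 included). Phases are
#' retained in the \code{phi} column; sigmas are initialized to zero.
#'
#' @param model an \code{xtal_model} in a P1 cell.
#' @param d_min high-resolution limit in Angstrom (> 0.8).
#' @return a \code{reflection_set} on the absolute electron scale.
#' @export
simulate_structure_factors <- function(model, d_min = 1.8) {
  stopifnot(inherits(model, "xtal_model"))
  if (d_min <= 0.8) stop("d_min must exceed 0.8 Angstrom")
  if (model$space_group != "P 1") stop("synthetic structure factors require P1")
  hkl <- hkl_half_sphere(model$cell, d_min)
  Fc <- direct_structure_factors(model, hkl)
  refl <- data.frame(h = hkl$h, k = hkl$k, l = hkl$l,
                     F = Mod(Fc), SIGF = 0,
                     phi = Arg(Fc) * 180 / pi)
  reflection_set(refl, model$cell, "P 1")
}

#' Add proportional Gaussian measurement noise to amplitudes
#'
#' F' = F + N(0, (rel_sigma * F)^2), with SIGF recording rel_sigma * F.
#' Phases, if present, are dropped: measured amplitudes carry no phase.
#'
#' @param refl a \code{reflection_set}.
#' @param rel_sigma relative noise level (>= 0), e.g. 0.05 for 5\%.
#' @param seed integer seed.
#' @return a \code{reflection_set} with noisy F and populated SIGF.
#' @export
add_measurement_noise <- function(refl, rel_sigma, seed = 1) {
  stopifnot(inherits(refl, "reflection_set"))
  if (rel_sigma < 0) stop("rel_sigma must be >= 0")
  r <- refl$refl
  if (rel_sigma > 0) {
    set.seed(as.integer(seed))
    sig <- rel_sigma * r$F
    r$F <- pmax(r$F + stats::rnorm(nrow(r), sd = sig), 0)
    r$SIGF <- sig
  } else {
    r$SIGF <- 0
  }
  r$phi <- NULL
  reflection_set(r, refl$cell, refl$space_group)
}
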