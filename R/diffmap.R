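#' Isomorphous difference map pipeline
#'
#' Functions to place a mutant reflection set on the scale of a wild-type
#' reference, form error-weighted Fo-Fo difference coefficients, attach
#' reference-model phases, and synthesize a real-space difference density
#' map by FFT.
#'
#' @name diffmap
NULL

# join two reflection sets on common Miller indices
common_reflections <- function(a, b) {
  ka <- paste(a$refl$h, a$refl$k, a$refl$l)
  kb <- paste(b$refl$h, b$refl$k, b$refl$l)
  ia <- match(intersect(ka, kb), ka)
  ib <- match(ka[ia], kb)
  list(a = a$refl[ia, , drop = FALSE], b = b$refl[ib, , drop = FALSE])
}

#' Scale a reflection set to a reference
#'
#' Fits an isotropic scale/relative-B model by least squares on
#' amplitudes over the common reflections, minimizing
#' sum (k exp(+B s^2/4) F_mut - F_ref)^2, and applies the per-reflection
#' factor to both F and SIGF. B is the fitted relative isotropic
#' B-factor of the mutant data (positive when the mutant is more smeared
#' than the reference; the applied correction exp(+B s^2/4) undoes it).
#' Reflections present in only one set are untouched by the fit but
#' still rescaled.
#'
#' @param mut reflection set to be scaled.
#' @param ref reference reflection set (same cell within 1\%, same space
#'   group, at least 50 common reflections).
#' @return the scaled \code{reflection_set}, with the fitted scale stored
#'   in attribute \code{"scale"} as \code{c(k =, B =)}.
#' @export
scale_to_reference <- function(mut, ref) {
  stopifnot(inherits(mut, "reflection_set"), inherits(ref, "reflection_set"))
  if (mut$space_group != ref$space_group) stop("space groups do not match")
  if (any(abs(mut$cell - ref$cell) / ref$cell > 0.01)) {
    stop("unit cells differ by more than 1%")
  }
  cm <- common_reflections(mut, ref)
  if (nrow(cm$a) < 50) stop("fewer than 50 common reflections")
  s2 <- inv_d2(cm$a[, c("h", "k", "l")], ref$cell)
  dat <- data.frame(Fm = cm$a$F, Fr = cm$b$F, s2 = s2)
  # log-linear start (Wilson-style), then Levenberg-Marquardt refit with
  # an analytic Jacobian (robust to exact-fit and near-collinear cases)
  ok <- dat$Fm > 0 & dat$Fr > 0
  init <- stats::lm(log(Fr / Fm) ~ s2, data = dat[ok, ])
  st <- c(k = exp(unname(stats::coef(init)[1])),
          B = 4 * unname(stats::coef(init)[2]))
  resid_fn <- function(p) p["k"] * exp(p["B"] * dat$s2 / 4) * dat$Fm - dat$Fr
  jac_fn <- function(p) {
    e <- exp(p["B"] * dat$s2 / 4)
    cbind(k = e * dat$Fm, B = p["k"] * dat$s2 / 4 * e * dat$Fm)
  }
  fit <- minpack.lm::nls.lm(par = st, fn = resid_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  kB <- fit$par
  out <- mut
  s2all <- inv_d2(mut$refl[, c("h", "k", "l")], mut$cell)
  fac <- kB["k"] * exp(kB["B"] * s2all / 4)
  out$refl$F <- fac * mut$refl$F
  out$refl$SIGF <- fac * mut$refl$SIGF
  attr(out, "scale") <- c(k = unname(kB["k"]), B = unname(kB["B"]))
  out
}

#' Error-weighted isomorphous difference coefficients
#'
#' For each reflection common to both inputs forms
#' dF = F_mut - F_ref and sigma_dF = sqrt(sig_mut^2 + sig_ref^2), and the
#' weight w = 1 / (1 + sigma_dF^2/<sigma_dF^2> + alpha * dF^2/<dF^2>),
#' the standard error/outlier down-weighting for Fo-Fo difference maps.
#' Means <.> are taken globally by default or within resolution bins.
#'
#' @param mut_scaled mutant reflections already on the reference scale.
#' @param ref reference reflections.
#' @param alpha outlier-weighting strength (dimensionless, default 0.05).
#' @param n_bins number of equal-population resolution bins for the
#'   normalizing means; 1 (default) uses global means.
#' @return a data frame of class \code{diff_coeffs} with columns h, k, l,
#'   dF, sig, w and attributes cell/space_group/alpha; phases are absent
#'   until \code{\link{phase_from_model}} is applied.
#' @export
weighted_differences <- function(mut_scaled, ref, alpha = 0.05, n_bins = 1) {
  stopifnot(inherits(mut_scaled, "reflection_set"), inherits(ref, "reflection_set"))
  cm <- common_reflections(mut_scaled, ref)
  if (nrow(cm$a) == 0) stop("no common reflections")
  dF <- cm$a$F - cm$b$F
  sig2 <- cm$a$SIGF^2 + cm$b$SIGF^2
  s2 <- inv_d2(cm$a[, c("h", "k", "l")], ref$cell)
  # exclude F000 from the difference coefficients (carries no map contrast)
  keep <- !(cm$a$h == 0 & cm$a$k == 0 & cm$a$l == 0)
  dF <- dF[keep]; sig2 <- sig2[keep]; s2 <- s2[keep]
  hkl <- cm$a[keep, c("h", "k", "l")]

  bin <- if (n_bins > 1) {
    cut(rank(s2, ties.method = "first"), breaks = n_bins, labels = FALSE)
  } else rep(1L, length(dF))
  msig <- stats::ave(sig2, bin)
  mdF2 <- stats::ave(dF^2, bin)
  denom <- 1 + ifelse(msig > 0, sig2 / msig, 0) +
    alpha * ifelse(mdF2 > 0, dF^2 / mdF2, 0)
  w <- 1 / denom

  out <- data.frame(h = hkl$h, k = hkl$k, l = hkl$l, dF = dF,
                    sig = sqrt(sig2), w = w)
  structure(out, class = c("diff_coeffs", "data.frame"),
            cell = ref$cell, space_group = ref$space_group, alpha = alpha)
}

#' Attach reference-model phases to difference coefficients
#'
#' Computes the reference model's structure factors at each difference
#' coefficient's Miller index by direct summation and stores the
#' calculated phase (degrees) in column \code{phi}.
#'
#' @param coeffs a \code{diff_coeffs} object.
#' @param model the reference \code{xtal_model} (cell consistent with the
#'   reflections within 1\%).
#' @return the coefficients with a \code{phi} column.
#' @export
phase_from_model <- function(coeffs, model) {
  stopifnot(inherits(coeffs, "diff_coeffs"))
  if (!inherits(model, "xtal_model")) stop("a reference model is required")
  cell <- attr(coeffs, "cell")
  if (any(abs(model$cell - cell) / cell > 0.01)) {
    stop("model cell inconsistent with reflection cell")
  }
  Fc <- direct_structure_factors(model, coeffs[, c("h", "k", "l")])
  coeffs$phi <- Arg(Fc) * 180 / pi
  coeffs
}

# grid dimensions satisfying both the spacing target and Nyquist sampling
map_grid_dims <- function(cell, d_min, grid_spacing) {
  Minv <- cart_to_frac(cell)
  astar <- sqrt(rowSums(Minv^2))
  hmax <- ceiling(1 / (d_min * astar))
  n <- pmax(ceiling(cell[1:3] / grid_spacing), 2 * hmax + 2)
  as.integer(n)
}

#' Synthesize a real-space difference density map
#'
#' Evaluates dRho(x) = (1/V) sum_h w dF exp(i phi) exp(-2 pi i h.x) on a
#' grid by FFT, expanding the Friedel-unique coefficients to the full
#' sphere so the map is real. F000 is excluded; the map mean is zero.
#'
#' @param coeffs phased \code{diff_coeffs}.
#' @param grid_spacing target grid spacing in Angstrom; must satisfy the
#'   sampling condition grid_spacing <= d_min / 2.
#' @return an object of class \code{real_space_map}: list with the 3-D
#'   array \code{rho} (electrons/Angstrom^3), \code{cell} and \code{dims}.
#' @export
synthesize_map <- function(coeffs, grid_spacing = 0.5) {
  stopifnot(inherits(coeffs, "diff_coeffs"))
  if (is.null(coeffs$phi)) stop("coefficients are unphased; run phase_from_model first")
  cell <- attr(coeffs, "cell")
  s2 <- inv_d2(coeffs[, c("h", "k", "l")], cell)
  d_min <- 1 / sqrt(max(s2))
  if (grid_spacing > d_min / 2 + 1e-9) {
    stop(sprintf("grid too coarse: spacing %.3f exceeds d_min/2 = %.3f",
                 grid_spacing, d_min / 2))
  }
  n <- map_grid_dims(cell, d_min, grid_spacing)
  V <- cell_volume(cell)
  Fc <- coeffs$w * coeffs$dF * exp(1i * coeffs$phi * pi / 180)

  arr <- array(0 + 0i, dim = n)
  idx <- function(h, k, l) cbind(h %% n[1] + 1L, k %% n[2] + 1L, l %% n[3] + 1L)
  arr[idx(coeffs$h, coeffs$k, coeffs$l)] <- Fc
  arr[idx(-coeffs$h, -coeffs$k, -coeffs$l)] <- Conj(Fc)
  # forward DFT: sum_h F(h) exp(-2 pi i h.k/n) evaluated at x = k/n
  rho <- Re(stats::fft(arr)) / V
  structure(list(rho = rho, cell = cell, dims = n,
                 grid_spacing = grid_spacing, d_min = d_min),
            class = "real_space_map")
}

#' @export
print.real_space_map <- function(x, ...) {
  cat(sprintf("real_space_map: %s grid, cell %s, rms %.4g e-/A^3\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$cell, 4), collapse = " "), stats::sd(x$rho)))
  invisible(x)
}

#' Evaluate the difference density at arbitrary fractional coordinates
#'
#' Direct Fourier summation over the stored coefficients; the slow exact
#' counterpart of \code{\link{synthesize_map}}, used for verification.
#'
#' @param coeffs phased \code{diff_coeffs}.
#' @param xf n x 3 matrix of fractional coordinates.
#' @return density values in electrons/Angstrom^3.
#' @export
map_value_direct <- function(coeffs, xf) {
  stopifnot(inherits(coeffs, "diff_coeffs"))
  if (is.null(coeffs$phi)) stop("coefficients are unphased")
  xf <- matrix(xf, ncol = 3)
  V <- cell_volume(attr(coeffs, "cell"))
  Fc <- coeffs$w * coeffs$dF * exp(1i * coeffs$phi * pi / 180)
  H <- as.matrix(coeffs[, c("h", "k", "l")])
  ph <- -2 * pi * (xf %*% t(H))
  # Friedel mates contribute the conjugate term: total is 2 Re(.)
  as.vector(2 * Re(exp(1i * ph) %*% Fc)) / V
}
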