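#' Generate a toy poly-alanine crystal structure
#'
#' Builds an idealized helical poly-alanine chain (N, CA, C, O, CB per
#' residue) inside a P1 cell sized to leave at least a 5 Angstrom solvent
#' margin on every side. A small seeded coordinate jitter (0.05 Angstrom)
#' breaks the exact helical symmetry so that different seeds give distinct
#' but equally realistic models; a fixed seed is bit-reproducible.
#'
#' @param n_residues number of residues, between 5 and 100.
#' @param seed integer seed for the coordinate jitter.
#' @param b_factor isotropic B applied to every atom (Angstrom^2).
#' @param margin solvent margin around the chain (Angstrom).
#' @return an \code{xtal_model} with \code{5 * n_residues} atoms.
#' @export
#' @examples
#' m <- make_toy_structure(10, seed = 1)
#' nrow(m$atoms)  # 50
make_toy_structure <- function(n_residues, seed = 1, b_factor = 15, margin = 5) {
  if (!is.numeric(n_residues) || n_residues < 5 || n_residues > 100) {
    stop("n_residues must be between 5 and 100")
  }
  n_residues <- as.integer(n_residues)
  set.seed(as.integer(seed))

  # alpha-helical CA trace: 100 degrees twist, 1.5 A rise, 2.3 A radius
  i <- seq_len(n_residues)
  th <- (i - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1))

  # rigid local offsets, rotated with the helix twist
  offs <- rbind(N  = c(-0.95, -1.10, -0.50),
                CA = c( 0.00,  0.00,  0.00),
                C  = c( 1.20,  0.70,  0.55),
                O  = c( 1.25,  1.90,  0.70),
                CB = c( 0.55, -0.55,  1.40))
  elem <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

  rows <- vector("list", n_residues)
  for (r in i) {
    rot <- matrix(c(cos(th[r]), -sin(th[r]), 0,
                    sin(th[r]),  cos(th[r]), 0,
                    0, 0, 1), 3, 3, byrow = TRUE)
    xyz <- sweep(offs %*% t(rot), 2, ca[r, ], "+")
    rows[[r]] <- data.frame(elety = rownames(offs), element = unname(elem),
                            resno = r, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  jit <- matrix(stats::rnorm(nrow(at) * 3, sd = 0.05), ncol = 3)
  at$x <- at$x + jit[, 1]; at$y <- at$y + jit[, 2]; at$z <- at$z + jit[, 3]

  # shift into the positive octant and box with the solvent margin
  for (cc in c("x", "y", "z")) at[[cc]] <- at[[cc]] - min(at[[cc]]) + margin
  cell <- c(max(at$x) + margin, max(at$y) + margin, max(at$z) + margin, 90, 90, 90)

  atoms <- data.frame(atom_id = seq_len(nrow(at)), element = at$element,
                      resno = at$resno, resid = "ALA", chain = "A",
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      occ = 1, b = b_factor, is_water = FALSE,
                      stringsAsFactors = FALSE)
  xtal_model(atoms, cell, "P 1")
}

#' Displace selected residues of a model
#'
#' Emulates the local rearrangement around a point mutation: the CB atom
#' (and optionally the backbone) of each listed residue is translated by
#' \code{displacement} along a seeded random unit direction (one direction
#' per residue). All other atoms are bit-identical to the input.
#'
#' @param model an \code{xtal_model}.
#' @param residues integer vector of residue numbers to displace.
#' @param displacement shift magnitude in Angstrom (>= 0).
#' @param seed integer seed for the directions.
#' @param backbone also displace N, CA, C, O of the listed residues?
#' @return the perturbed \code{xtal_model}.
#' @export
perturb_structure <- function(model, residues, displacement, seed = 1,
                              backbone = FALSE) {
  stopifnot(inherits(model, "xtal_model"))
  if (displacement < 0) stop("displacement must be >= 0")
  residues <- as.integer(residues)
  known <- unique(model$atoms$resno)
  if (!all(residues %in% known)) {
    stop("unknown residue index: ", paste(setdiff(residues, known), collapse = ", "))
  }
  if (displacement == 0) return(model)
  set.seed(as.integer(seed))
  at <- model$atoms
  target_ety <- if (backbone) c("N", "CA", "C", "O", "CB") else "CB"
  for (r in residues) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    sel <- at$resno == r & at$elety %in% target_ety & !at$is_water
    at$x[sel] <- at$x[sel] + displacement * u[1]
    at$y[sel] <- at$y[sel] + displacement * u[2]
    at$z[sel] <- at$z[sel] + displacement * u[3]
  }
  out <- model
  out$atoms <- at
  out
}
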