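#' Unit-cell geometry helpers
#'
#' A unit cell is the numeric vector \code{c(a, b, c, alpha, beta, gamma)}
#' with lengths in Angstrom and angles in degrees. All synthetic crystals
#' are P1; the geometry below is general triclinic so that real P1 cells
#' with non-orthogonal axes are handled identically.
#'
#' @param cell numeric length-6 vector (a, b, c, alpha, beta, gamma).
#' @return \code{cell_volume}: volume in cubic Angstrom.
#'   \code{frac_to_cart}: 3x3 matrix M with x_cart = M %*% x_frac.
#'   \code{cart_to_frac}: the inverse of M.
#' @keywords internal
#' @name cell-geometry
NULL

check_cell <- function(cell) {
  if (!is.numeric(cell) || length(cell) != 6L || any(!is.finite(cell))) {
    stop("cell must be a numeric vector (a, b, c, alpha, beta, gamma)")
  }
  if (any(cell[1:3] <= 0) || any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
    stop("cell lengths must be positive and angles in (0, 180) degrees")
  }
  invisible(cell)
}

#' @rdname cell-geometry
frac_to_cart <- function(cell) {
  check_cell(cell)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  # standard PDB convention: a along x, b in the xy plane
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  matrix(c(a, b * cos(ga), cx,
           0, b * sin(ga), cy,
           0, 0,           cz), nrow = 3, byrow = TRUE)
}

#' @rdname cell-geometry
cart_to_frac <- function(cell) solve(frac_to_cart(cell))

#' @rdname cell-geometry
cell_volume <- function(cell) {
  det(frac_to_cart(cell))
}

#' Inverse resolution squared for Miller indices
#'
#' Computes s^2 = 1/d^2 for each (h, k, l) row using the reciprocal metric
#' of the cell.
#'
#' @param hkl integer matrix with columns h, k, l.
#' @param cell unit cell vector.
#' @return numeric vector of 1/d^2 values (1/Angstrom^2).
#' @keywords internal
inv_d2 <- function(hkl, cell) {
  hkl <- as.matrix(hkl)
  Minv <- cart_to_frac(cell)        # rows of Minv are the reciprocal axes
  svec <- hkl %*% Minv              # s = h a* + k b* + l c*
  rowSums(svec^2)
}

#' Minimum-image distances between grid points and atoms
#'
#' Distances under periodic boundary conditions, computed in fractional
#' space by checking the 27 neighbouring cell translations (exact for any
#' displacement shorter than half the shortest cell extent, which holds
#' for the sub-2 Angstrom radii used in difference-density integration).
#'
#' @param pf n x 3 matrix of fractional coordinates (points).
#' @param af m x 3 matrix of fractional coordinates (atoms).
#' @param cell unit cell vector.
#' @return n x m matrix of Cartesian distances in Angstrom.
#' @keywords internal
min_image_dist <- function(pf, af, cell) {
  M <- frac_to_cart(cell)
  pf <- as.matrix(pf); af <- as.matrix(af)
  n <- nrow(pf); m <- nrow(af)
  d2 <- matrix(Inf, n, m)
  if (all(abs(cell[4:6] - 90) < 1e-9)) {
    # orthogonal cell: per-axis wrapping is the exact minimum image
    for (j in seq_len(m)) {
      df <- sweep(pf, 2, af[j, ])
      df <- df - round(df)
      d2[, j] <- (df[, 1] * cell[1])^2 + (df[, 2] * cell[2])^2 +
        (df[, 3] * cell[3])^2
    }
  } else {
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (j in seq_len(m)) {
      df <- sweep(pf, 2, af[j, ])            # fractional difference
      df <- df - round(df)                   # wrap to [-0.5, 0.5)
      best <- rep(Inf, n)
      for (s in seq_len(nrow(shifts))) {
        dc <- (df + matrix(shifts[s, ], n, 3, byrow = TRUE)) %*% t(M)
        best <- pmin(best, rowSums(dc^2))
      }
      d2[, j] <- best
    }
  }
  sqrt(d2)
}
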