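#' Structure models
#'
#' An \code{xtal_model} is a light-weight container for a crystallographic
#' coordinate model: a data frame of atoms plus a P1-compatible unit cell.
#' Atom table columns: \code{atom_id} (integer), \code{element},
#' \code{resno} (1-based author numbering), \code{resid} (residue name),
#' \code{chain}, \code{elety} (atom name), \code{x,y,z} (Angstrom,
#' Cartesian), \code{occ} (0-1), \code{b} (Angstrom^2), \code{is_water}.
#'
#' @param atoms atom data frame as described above.
#' @param cell unit cell \code{c(a, b, c, alpha, beta, gamma)}.
#' @param space_group space-group symbol; synthetic generation is P1 only.
#' @return an object of class \code{xtal_model}.
#' @export
xtal_model <- function(atoms, cell, space_group = "P 1") {
  check_cell(cell)
  need <- c("atom_id", "element", "resno", "resid", "chain", "elety",
            "x", "y", "z", "occ", "b", "is_water")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (any(atoms$resno < 1)) stop("residue numbers must be strictly positive")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0, 1]")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 cell = as.numeric(cell),
                 space_group = space_group),
            class = "xtal_model")
}

#' @export
print.xtal_model <- function(x, ...) {
  cat(sprintf("xtal_model: %d atoms, %d residues, cell %s, %s\n",
              nrow(x$atoms), length(unique(x$atoms$resno[!x$atoms$is_water])),
              paste(signif(x$cell, 4), collapse = " "), x$space_group))
  invisible(x)
}

#' Fractional coordinates of a model's atoms
#' @param model an \code{xtal_model}.
#' @param wrap wrap into [0, 1)?
#' @return n x 3 matrix of fractional coordinates.
#' @keywords internal
model_frac <- function(model, wrap = TRUE) {
  xf <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(cart_to_frac(model$cell))
  if (wrap) xf <- xf - floor(xf)
  xf
}

#' Protein heavy atoms of a model
#'
#' Waters and hydrogens are excluded; these are the assignment targets for
#' difference-density integration.
#' @param model an \code{xtal_model}.
#' @return the atom data frame subset.
#' @keywords internal
heavy_atoms <- function(model) {
  a <- model$atoms
  a[!a$is_water & toupper(a$element) != "H", , drop = FALSE]
}
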