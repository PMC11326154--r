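#' Integrate absolute difference density above a noise threshold (IADDAT)
#'
#' For every map grid point whose |density| strictly exceeds
#' \code{threshold}, the nearest non-water heavy atom within \code{radius}
#' (minimum-image periodic distances) receives that |density|; each
#' residue's accumulated total is then divided by its number of non-water
#' heavy atoms, so that small and large residues are comparable. Grid
#' points with no atom within the radius contribute nothing. Ties in the
#' nearest-atom assignment resolve to the lowest (chain, residue, atom id).
#'
#' @param map a \code{real_space_map} (difference density, e-/Angstrom^3).
#' @param model the \code{xtal_model} sharing the map's cell (within 1\%).
#' @param threshold absolute density threshold, e-/Angstrom^3 (> 0);
#'   default 0.04.
#' @param radius assignment radius in Angstrom (> 0); default 1.5.
#' @param per_grid_point average over contributing grid points instead of
#'   over residue heavy atoms (alternative normalization; default FALSE).
#' @return an \code{iaddat_profile}: data frame with columns \code{resno},
#'   \code{chain}, \code{score}, \code{n_atoms}, plus attributes recording
#'   threshold and radius.
#' @export
compute_iaddat <- function(map, model, threshold = 0.04, radius = 1.5,
                           per_grid_point = FALSE) {
  stopifnot(inherits(map, "real_space_map"), inherits(model, "xtal_model"))
  if (threshold <= 0) stop("threshold must be > 0")
  if (radius <= 0) stop("radius must be > 0")
  if (any(abs(map$cell - model$cell) / model$cell > 0.01)) {
    stop("map and model cells disagree")
  }
  atoms <- heavy_atoms(model)
  if (nrow(atoms) == 0) stop("model has no protein heavy atoms")
  # deterministic tie-break order: (chain, resno, atom_id)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$atom_id), , drop = FALSE]

  res_tab <- unique(atoms[, c("chain", "resno")])
  res_tab <- res_tab[order(res_tab$chain, res_tab$resno), , drop = FALSE]
  res_key <- paste(res_tab$chain, res_tab$resno)
  n_heavy <- as.integer(table(factor(paste(atoms$chain, atoms$resno),
                                     levels = res_key)))

  n <- map$dims
  hot <- which(abs(map$rho) > threshold, arr.ind = TRUE)
  acc <- numeric(nrow(res_tab))
  npt <- integer(nrow(res_tab))
  if (nrow(hot) > 0) {
    pf <- sweep(hot - 1, 2, n, "/")                     # fractional coords
    af <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(cart_to_frac(model$cell))
    vals <- abs(map$rho[hot])
    D <- min_image_dist(pf, af, model$cell)
    nearest <- max.col(-D, ties.method = "first")       # first = lowest order
    dmin <- D[cbind(seq_len(nrow(D)), nearest)]
    ok <- dmin <= radius
    if (any(ok)) {
      ridx <- match(paste(atoms$chain, atoms$resno)[nearest[ok]], res_key)
      for (i in seq_along(ridx)) {
        acc[ridx[i]] <- acc[ridx[i]] + vals[ok][i]
        npt[ridx[i]] <- npt[ridx[i]] + 1L
      }
    }
  }
  score <- if (per_grid_point) ifelse(npt > 0, acc / pmax(npt, 1L), 0)
           else acc / n_heavy
  out <- data.frame(resno = res_tab$resno, chain = res_tab$chain,
                    score = score, n_atoms = n_heavy,
                    stringsAsFactors = FALSE)
  structure(out, class = c("iaddat_profile", "data.frame"),
            threshold = threshold, radius = radius,
            normalization = if (per_grid_point) "per-grid-point" else "per-atom",
            cap = NA_real_)
}

#' Cap an IADDAT profile for display
#'
#' Returns a display copy with scores truncated at \code{cap}; the raw
#' profile is never modified.
#'
#' @param profile an \code{iaddat_profile}.
#' @param cap maximum displayed score (> 0); default 0.3.
#' @return the capped display copy, with attribute \code{cap} set.
#' @export
cap_for_display <- function(profile, cap = 0.3) {
  stopifnot(inherits(profile, "iaddat_profile"))
  if (!is.numeric(cap) || cap <= 0) stop("cap must be > 0")
  out <- profile
  out$score <- pmin(profile$score, cap)
  attr(out, "cap") <- cap
  out
}

#' Write per-residue scores as CSV and B-factor-annotated PDB
#'
#' Writes a two-column CSV (\code{resno,score}) and a PDB copy of the
#' model in which every atom's B-factor column carries its residue's
#' score (fixed 2-decimal PDB format), the convention used to color
#' structures by per-residue response in molecular viewers.
#'
#' @param profile per-residue scores: an \code{iaddat_profile} or any data
#'   frame with columns \code{resno} and \code{score}.
#' @param model the \code{xtal_model} the scores refer to.
#' @param csv_path output CSV path (NULL to skip).
#' @param pdb_path output PDB path (NULL to skip).
#' @return invisibly, the per-atom B-factor vector used.
#' @export
write_residue_scores <- function(profile, model, csv_path = NULL,
                                 pdb_path = NULL) {
  stopifnot(inherits(model, "xtal_model"))
  if (!all(c("resno", "score") %in% names(profile))) {
    stop("profile must have columns resno and score")
  }
  prot <- unique(model$atoms$resno[!model$atoms$is_water])
  if (!all(profile$resno %in% prot)) stop("profile residues not all present in model")
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(resno = profile$resno,
                                score = profile$score),
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  b <- profile$score[match(model$atoms$resno, profile$resno)]
  b[is.na(b)] <- 0
  if (!is.null(pdb_path)) {
    annotated <- model
    annotated$atoms$b <- round(b, 2)
    write_model_pdb(annotated, pdb_path)
  }
  invisible(b)
}
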