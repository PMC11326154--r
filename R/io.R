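#' Write a structure model as PDB
#'
#' ATOM/HETATM records are written through bio3d; the CRYST1 cell record
#' (which bio3d does not emit) is prepended so the cell survives a
#' round-trip. Waters become HETATM/HOH.
#'
#' @param model an \code{xtal_model}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_model_pdb <- function(model, path) {
  stopifnot(inherits(model, "xtal_model"))
  a <- model$atoms
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$is_water, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, eleno = a$atom_id,
                   o = a$occ, b = a$b, elesy = a$element)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   model$cell[1], model$cell[2], model$cell[3],
                   model$cell[4], model$cell[5], model$cell[6],
                   model$space_group, 1L)
  writeLines(c(cryst, readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}

#' Read a structure model from PDB
#'
#' Parses ATOM/HETATM records with bio3d, preserving 1-based author
#' residue numbering; waters (HOH/WAT/DOD) are flagged, hydrogens are
#' retained but carry element "H" so downstream heavy-atom selections
#' skip them. The CRYST1 record is required (difference-map work is
#' meaningless without the cell).
#'
#' @param path PDB file path.
#' @return an \code{xtal_model}.
#' @export
read_model_pdb <- function(path) {
  lines <- readLines(path)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) stop("PDB file has no CRYST1 record: ", path)
  cell <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                       substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                       substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  sg <- trimws(substr(cl[1], 56, 66))
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  element <- a$elesy
  fallback <- gsub("[0-9 ]", "", a$elety)
  element[is.na(element) | element == ""] <-
    substr(fallback[is.na(element) | element == ""], 1, 1)
  atoms <- data.frame(atom_id = a$eleno, element = toupper(element),
                      resno = a$resno, resid = a$resid, chain = a$chain,
                      elety = a$elety, x = a$x, y = a$y, z = a$z,
                      occ = a$o, b = a$b,
                      is_water = a$resid %in% c("HOH", "WAT", "DOD"),
                      stringsAsFactors = FALSE)
  xtal_model(atoms, cell, if (nzchar(sg)) sg else "P 1")
}

# canonical Friedel-unique index for P1: negate when in the minus half
asu_map_p1 <- function(h, k, l) {
  plus <- h > 0 | (h == 0 & k > 0) | (h == 0 & k == 0 & l >= 0)
  s <- ifelse(plus, 1L, -1L)
  data.frame(h = s * h, k = s * k, l = s * l)
}

#' Write reflections as CSV
#'
#' Plain-text reflection exchange format: comment header lines carrying
#' the cell and space group, then columns h,k,l,F,SIGF (and phi when
#' present).
#'
#' @param refl a \code{reflection_set}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_reflections_csv <- function(refl, path) {
  stopifnot(inherits(refl, "reflection_set"))
  hdr <- c(sprintf("# cell: %s", paste(format(refl$cell, digits = 10), collapse = " ")),
           sprintf("# space_group: %s", refl$space_group))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(refl$refl, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Read reflections from CSV
#'
#' Expects columns h,k,l,F,SIGF (extra columns such as phi are kept).
#' Indices are mapped to the Friedel-unique half sphere; duplicate
#' indices after mapping are merged by inverse-variance weighted mean
#' (plain mean when sigmas are zero or equal), with the merge count
#' reported via a message.
#'
#' @param path CSV path; header comments written by
#'   \code{\link{write_reflections_csv}} supply the cell.
#' @param cell unit cell, required when the file carries no cell header.
#' @param space_group space group, default from header or "P 1".
#' @return a \code{reflection_set}.
#' @export
read_reflections_csv <- function(path, cell = NULL, space_group = NULL) {
  lines <- readLines(path, n = 10)
  hl <- grep("^# cell:", lines, value = TRUE)
  if (length(hl) > 0) cell <- as.numeric(strsplit(trimws(sub("^# cell:", "", hl[1])), "\\s+")[[1]])
  sl <- grep("^# space_group:", lines, value = TRUE)
  if (is.null(space_group)) {
    space_group <- if (length(sl) > 0) trimws(sub("^# space_group:", "", sl[1])) else "P 1"
  }
  if (is.null(cell)) stop("no cell in file header; supply cell=")
  d <- utils::read.csv(path, comment.char = "#")
  if (nrow(d) == 0) stop("reflection file is empty: ", path)
  need <- c("h", "k", "l", "F", "SIGF")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("missing reflection columns ", paste(miss, collapse = ", "),
         "; available: ", paste(names(d), collapse = ", "))
  }
  m <- asu_map_p1(d$h, d$k, d$l)
  d$h <- m$h; d$k <- m$k; d$l <- m$l
  key <- paste(d$h, d$k, d$l)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    message("merged ", n_dup, " duplicate reflection(s)")
    w <- ifelse(d$SIGF > 0, 1 / d$SIGF^2, 1)
    agg <- function(v) vapply(split(seq_along(key), key), function(i)
      sum(v[i] * w[i]) / sum(w[i]), numeric(1))
    idx <- !duplicated(key)
    ord <- match(unique(key), names(split(seq_along(key), key)))
    d2 <- d[idx, , drop = FALSE]
    Fm <- agg(d$F); Sm <- agg(d$SIGF)
    d2$F <- Fm[paste(d2$h, d2$k, d2$l)]
    d2$SIGF <- Sm[paste(d2$h, d2$k, d2$l)]
    d <- d2
  }
  reflection_set(d, cell, space_group)
}

#' Write / read peptide uptake tables as CSV
#'
#' Long format with documented headers
#' (sequence,start,end,timepoint,replicate,centroid_mass) plus
#' undeuterated reference masses as extra rows with timepoint "M0".
#'
#' @param table an \code{uptake_table}.
#' @param path CSV path.
#' @return invisibly the path, or the \code{uptake_table} on read.
#' @export
write_uptake_csv <- function(table, path) {
  stopifnot(inherits(table, "uptake_table"))
  d <- table$data
  keys <- unique(d[, c("sequence", "start", "end")])
  m0rows <- data.frame(sequence = keys$sequence, start = keys$start,
                       end = keys$end, timepoint = "M0", replicate = 0,
                       centroid_mass = unlist(table$m0[paste(keys$sequence,
                                                             keys$start, keys$end)]),
                       stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines(sprintf("# d_frac: %.6f", table$d_frac), con)
  utils::write.csv(rbind(m0rows, d), con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_uptake_csv
#' @export
read_uptake_csv <- function(path) {
  lines <- readLines(path, n = 3)
  hl <- grep("^# d_frac:", lines, value = TRUE)
  d_frac <- if (length(hl)) as.numeric(sub("^# d_frac:", "", hl[1])) else 0.9
  d <- utils::read.csv(path, comment.char = "#",
                       colClasses = c(timepoint = "character"))
  m0rows <- d$timepoint == "M0"
  m0 <- stats::setNames(as.list(d$centroid_mass[m0rows]),
                        paste(d$sequence[m0rows], d$start[m0rows], d$end[m0rows]))
  uptake_table(d[!m0rows, , drop = FALSE], m0, d_frac = d_frac)
}

#' Read a residue set from CSV
#'
#' One column \code{residue_index}; the universe is supplied separately
#' (it materially affects overlap p-values and is echoed in reports).
#'
#' @param path CSV with a residue_index column.
#' @param universe integer vector defining the universe.
#' @param label set label (defaults to the file name).
#' @return a \code{residue_set}.
#' @export
read_residue_set_csv <- function(path, universe,
                                 label = tools::file_path_sans_ext(basename(path))) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!"residue_index" %in% names(d)) stop("CSV needs a residue_index column")
  residue_set(d$residue_index, universe, label)
}

#' Write a residue set to CSV
#' @param set a \code{residue_set}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_residue_set_csv <- function(set, path) {
  stopifnot(inherits(set, "residue_set"))
  utils::write.csv(data.frame(residue_index = set$members), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
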