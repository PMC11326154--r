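#' Exchangeable backbone amides of a peptic peptide
#'
#' A peptide of length L has L - 1 backbone amide positions (2..L).
#' Prolines carry no amide hydrogen, and the amide adjacent to the
#' N-terminal residue (position 2) back-exchanges too rapidly to retain
#' label, so it is discounted whether or not it is proline. The count is
#' therefore N_ex = L - 2 - (# prolines at positions 3..L). An equivalent
#' accounting — (L - 1 amides) minus prolines at positions 2..L minus the
#' position-2 amide when residue 2 is not proline — is evaluated
#' alongside and asserted to agree.
#'
#' @param sequence peptide string, standard one-letter codes, length >= 2.
#' @return integer number of exchangeable amides (error if <= 0: such a
#'   peptide carries no usable exchange information).
#' @export
#' @examples
#' count_exchangeable_amides("AAAA")  # 2
#' count_exchangeable_amides("AAPA")  # 1
count_exchangeable_amides <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2) stop("peptide must have length >= 2")
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("non-standard residue code in peptide: ", sequence)
  }
  n1 <- L - 2L - if (L >= 3) sum(aa[3:L] == "P") else 0L
  n2 <- (L - 1L) - sum(aa[2:L] == "P") - as.integer(aa[2] != "P")
  stopifnot(n1 == n2)
  if (n1 <= 0) stop("peptide has no exchangeable amides: ", sequence)
  n1
}

# per-peptide positions (global residue numbering) whose amides can retain
# deuterium: peptide positions 3..L, excluding prolines
exchangeable_positions <- function(sequence, start) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  pos <- if (L >= 3) 3:L else integer(0)
  pos <- pos[aa[pos] != "P"]
  start + pos - 1L
}

# monoisotopic residue masses (Da); peptide m0 = sum + water
.res_mass <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
               C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
               H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
               M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
               T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)

peptide_mass <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  sum(.res_mass[aa]) + 18.010565
}

# mass difference D - H
M_DEUTERIUM <- 1.00628

#' Percent deuteration of a peptide measurement
#'
#' With a fully-deuterated (FD) control the back-exchange-corrected value
#' is 100 (m_t - m0) / (mFD - m0). Without one, the theoretical maximum
#' N_ex * d_frac * m_D is used as the denominator. Values are clipped to
#' [-5, 110]; out-of-range inputs are flagged via attribute
#' \code{"out_of_range"}.
#'
#' @param m_t centroid mass at the timepoint (Da).
#' @param m0 undeuterated reference mass (Da).
#' @param mFD fully-deuterated control mass (Da), or NULL.
#' @param n_ex exchangeable amide count (needed when mFD is NULL).
#' @param d_frac labeling D2O fraction (default 0.90).
#' @return percent deuteration (vectorized over m_t).
#' @export
percent_deuteration <- function(m_t, m0, mFD = NULL, n_ex = NULL,
                                d_frac = 0.9) {
  if (!is.null(mFD)) {
    if (mFD <= m0) stop("FD control mass must exceed the undeuterated mass")
    pd <- 100 * (m_t - m0) / (mFD - m0)
  } else {
    if (is.null(n_ex)) stop("n_ex required when no FD control is supplied")
    pd <- 100 * (m_t - m0) / (n_ex * d_frac * M_DEUTERIUM)
  }
  oor <- pd < -5 | pd > 110
  pd <- pmin(pmax(pd, -5), 110)
  attr(pd, "out_of_range") <- oor
  pd
}

# replicate-averaged %D per peptide at one timepoint, FD-corrected when
# FD rows are present
peptide_percentD <- function(table, timepoint, d_frac = 0.9) {
  stopifnot(inherits(table, "uptake_table"))
  tab <- table$data
  key <- paste(tab$sequence, tab$start, tab$end)
  peps <- unique(tab[, c("sequence", "start", "end")])
  pkey <- paste(peps$sequence, peps$start, peps$end)
  out <- data.frame(peps, pD = NA_real_, n_rep = 0L, n_ex = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peps))) {
    sel <- key == pkey[i]
    m0 <- table$m0[[pkey[i]]]
    if (is.null(m0)) next
    fd_rows <- sel & tab$timepoint == "FD"
    mFD <- if (any(fd_rows)) mean(tab$centroid_mass[fd_rows]) else NULL
    tnum <- suppressWarnings(as.numeric(tab$timepoint))
    t_rows <- sel & !is.na(tnum) & abs(tnum - timepoint) < 1e-9
    if (!any(t_rows)) next
    n_ex <- count_exchangeable_amides(peps$sequence[i])
    m_t <- mean(tab$centroid_mass[t_rows])
    out$pD[i] <- as.numeric(percent_deuteration(m_t, m0, mFD,
                                                n_ex = n_ex, d_frac = d_frac))
    out$n_rep[i] <- sum(t_rows)
    out$n_ex[i] <- n_ex
  }
  out[!is.na(out$pD), , drop = FALSE]
}

#' Mutant-minus-WT peptide difference table (Woods-plot data)
#'
#' Replicates are averaged within each condition, peptides are matched by
#' (sequence, start, end), and each matched peptide receives
#' delta %D = %D_mut - %D_WT with a classification against the no-change
#' band: protected if delta < -band, deprotected if delta > +band,
#' otherwise no-change (strict inequalities; default band 5 percentage
#' points). Unmatched peptides are dropped with a message.
#'
#' @param mut,wt \code{uptake_table} objects (see
#'   \code{\link{uptake_table}}).
#' @param timepoint labeling time in seconds.
#' @param band half-width of the no-change band in percentage points.
#' @param d_frac labeling D2O fraction.
#' @return data frame of class \code{woods_table}: sequence, start, end,
#'   n_ex, pD_mut, pD_wt, delta_pD, classification.
#' @export
difference_table <- function(mut, wt, timepoint, band = 5, d_frac = 0.9) {
  pm <- peptide_percentD(mut, timepoint, d_frac)
  pw <- peptide_percentD(wt, timepoint, d_frac)
  km <- paste(pm$sequence, pm$start, pm$end)
  kw <- paste(pw$sequence, pw$start, pw$end)
  shared <- intersect(km, kw)
  if (length(shared) == 0) stop("no matched peptides between conditions")
  dropped <- length(km) + length(kw) - 2 * length(shared)
  if (dropped > 0) message(dropped, " unmatched peptide(s) dropped")
  im <- match(shared, km); iw <- match(shared, kw)
  delta <- pm$pD[im] - pw$pD[iw]
  cls <- ifelse(delta < -band, "protected",
                ifelse(delta > band, "deprotected", "no-change"))
  out <- data.frame(sequence = pm$sequence[im], start = pm$start[im],
                    end = pm$end[im], n_ex = pm$n_ex[im],
                    pD_mut = pm$pD[im], pD_wt = pw$pD[iw],
                    delta_pD = delta, classification = cls,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  structure(out, class = c("woods_table", "data.frame"),
            timepoint = timepoint, band = band)
}

# greedy minimal-length set cover: repeatedly take the shortest peptide
# covering the leftmost uncovered position (ties -> smaller start)
greedy_peptide_cover <- function(rows) {
  len <- rows$end - rows$start + 1L
  covered <- logical(max(rows$end))
  chosen <- integer(0)
  repeat {
    pos <- which(!covered & seq_along(covered) >= min(rows$start))
    pos <- pos[vapply(pos, function(p) any(rows$start <= p & rows$end >= p),
                      logical(1))]
    if (length(pos) == 0) break
    p <- pos[1]
    cand <- which(rows$start <= p & rows$end >= p)
    cand <- cand[order(len[cand], rows$start[cand])]
    pick <- cand[1]
    chosen <- c(chosen, pick)
    covered[rows$start[pick]:rows$end[pick]] <- TRUE
  }
  sort(unique(chosen))
}

#' Residue-level interpolation of peptide difference values
#'
#' Maps peptide-level delta %D onto single residues as a weighted mean of
#' the covering peptides, weight 1 / N_ex(peptide), so short
#' high-resolution peptides dominate. Scheme \code{"short-peptides"}
#' first restricts to a greedy minimal-length set cover of the sequence
#' (shortest peptide covering each yet-uncovered position, ties broken by
#' smaller start) — the single-residue-oriented selection used for
#' structure mapping; \code{"all-peptides"} uses every row. Residues
#' covered by no peptide are flagged no-data, never imputed as zero.
#'
#' @param rows a \code{woods_table} (or data frame with columns start,
#'   end, n_ex, delta_pD).
#' @param scheme \code{"all-peptides"} or \code{"short-peptides"}.
#' @param n_residues sequence length; defaults to max(end).
#' @param band classification band in percentage points (default 5).
#' @return data frame of class \code{residue_hdx_profile}: resno,
#'   delta_pD, coverage, no_data, classification.
#' @export
residue_interpolation <- function(rows, scheme = c("all-peptides", "short-peptides"),
                                  n_residues = NULL, band = 5) {
  scheme <- match.arg(scheme)
  if (nrow(rows) == 0) stop("empty peptide table")
  if (is.null(n_residues)) n_residues <- max(rows$end)
  sel <- if (scheme == "short-peptides") greedy_peptide_cover(rows) else seq_len(nrow(rows))
  use <- rows[sel, , drop = FALSE]
  val <- rep(NA_real_, n_residues)
  cov <- integer(n_residues)
  wsum <- numeric(n_residues)
  vsum <- numeric(n_residues)
  for (i in seq_len(nrow(use))) {
    rr <- use$start[i]:use$end[i]
    rr <- rr[rr <= n_residues]
    w <- 1 / use$n_ex[i]
    vsum[rr] <- vsum[rr] + w * use$delta_pD[i]
    wsum[rr] <- wsum[rr] + w
    cov[rr] <- cov[rr] + 1L
  }
  has <- wsum > 0
  val[has] <- vsum[has] / wsum[has]
  cls <- rep(NA_character_, n_residues)
  cls[has] <- ifelse(val[has] < -band, "protected",
                     ifelse(val[has] > band, "deprotected", "no-change"))
  structure(data.frame(resno = seq_len(n_residues), delta_pD = val,
                       coverage = cov, no_data = !has,
                       classification = cls, stringsAsFactors = FALSE),
            class = c("residue_hdx_profile", "data.frame"),
            scheme = scheme, band = band)
}

#' Deuteration buildup curve for one peptide
#'
#' Per-timepoint mean percent deuteration with replicate spread, ordered
#' by time. The standard deviation is reported only when n >= 2 (a single
#' replicate has no spread, reported as NA rather than 0).
#'
#' @param table an \code{uptake_table}.
#' @param sequence,start,end peptide identity.
#' @param d_frac labeling D2O fraction.
#' @return data frame: timepoint, mean_pD, sd_pD, n.
#' @export
uptake_curves <- function(table, sequence, start, end, d_frac = 0.9) {
  stopifnot(inherits(table, "uptake_table"))
  tab <- table$data
  sel <- tab$sequence == sequence & tab$start == start & tab$end == end
  if (!any(sel)) stop("unknown peptide: ", sequence, " ", start, "-", end)
  key <- paste(sequence, start, end)
  m0 <- table$m0[[key]]
  fd_rows <- sel & tab$timepoint == "FD"
  mFD <- if (any(fd_rows)) mean(tab$centroid_mass[fd_rows]) else NULL
  n_ex <- count_exchangeable_amides(sequence)
  tsel <- sel & tab$timepoint != "FD"
  tp <- as.numeric(tab$timepoint[tsel])
  pd <- as.numeric(percent_deuteration(tab$centroid_mass[tsel], m0, mFD,
                                       n_ex = n_ex, d_frac = d_frac))
  agg <- split(pd, tp)
  tt <- as.numeric(names(agg))
  out <- data.frame(timepoint = tt,
                    mean_pD = vapply(agg, mean, numeric(1)),
                    sd_pD = vapply(agg, function(v)
                      if (length(v) >= 2) stats::sd(v) else NA_real_, numeric(1)),
                    n = lengths(agg))
  out <- out[order(out$timepoint), ]
  rownames(out) <- NULL
  out
}
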