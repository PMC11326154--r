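#' Peptide uptake tables
#'
#' Container for peptide-level HDX-MS measurements: a long data frame
#' with columns \code{sequence}, \code{start}, \code{end} (1-based,
#' inclusive), \code{timepoint} (seconds, or the sentinel string
#' \code{"FD"} for fully-deuterated controls), \code{replicate} and
#' \code{centroid_mass} (Da), plus a named list \code{m0} of undeuterated
#' reference masses keyed by \code{"sequence start end"} and the labeling
#' D2O fraction.
#'
#' @param data measurement data frame as above.
#' @param m0 named list / vector of undeuterated masses.
#' @param d_frac labeling D2O fraction (default 0.90).
#' @return an object of class \code{uptake_table}.
#' @export
uptake_table <- function(data, m0, d_frac = 0.9) {
  need <- c("sequence", "start", "end", "timepoint", "replicate", "centroid_mass")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("uptake table missing columns: ", paste(miss, collapse = ", "))
  if (any(data$end < data$start)) stop("peptide end before start")
  if (any(nchar(data$sequence) != data$end - data$start + 1)) {
    stop("sequence length inconsistent with start/end")
  }
  keys <- unique(paste(data$sequence, data$start, data$end))
  if (!all(keys %in% names(m0))) stop("every peptide needs an m0 reference mass")
  structure(list(data = as.data.frame(data), m0 = as.list(m0), d_frac = d_frac),
            class = "uptake_table")
}

#' @export
print.uptake_table <- function(x, ...) {
  k <- unique(paste(x$data$sequence, x$data$start, x$data$end))
  cat(sprintf("uptake_table: %d peptides, %d rows, d_frac %.2f\n",
              length(k), nrow(x$data), x$d_frac))
  invisible(x)
}

#' Protection profile for HDX simulation
#'
#' Ground-truth per-residue protection factors PF_i >= 1 and intrinsic
#' exchange rates k_int,i > 0 (s^-1). The default intrinsic rate is a
#' single constant (1 s^-1) rather than sequence-dependent chemistry:
#' recovery tests need controllable, not chemically exact, rates; supply
#' per-residue rates for anything more realistic.
#'
#' @param pf per-residue protection factors (>= 1).
#' @param k_int per-residue intrinsic rates (s^-1); recycled if scalar.
#' @return an object of class \code{protection_profile}.
#' @export
protection_profile <- function(pf, k_int = 1) {
  if (any(pf < 1)) stop("protection factors must be >= 1")
  k_int <- rep_len(k_int, length(pf))
  if (any(k_int <= 0)) stop("intrinsic rates must be positive")
  structure(list(pf = as.numeric(pf), k_int = as.numeric(k_int)),
            class = "protection_profile")
}

#' Simulate peptide-level HDX-MS uptake data
#'
#' Per-residue deuterium uptake follows single-exponential exchange
#' D_i(t) = d_frac (1 - exp(-(k_int,i / PF_i) t)) at exchangeable amide
#' positions (peptide positions 3..L, excluding prolines). The peptide
#' mass increase is (1 - backexchange) sum_i D_i(t) m_D with
#' m_D = 1.00628 Da; fully-deuterated (FD) controls carry
#' (1 - backexchange) d_frac N_ex m_D. Gaussian noise of scale
#' \code{noise_da} is added to every centroid.
#'
#' @param sequence protein sequence (one-letter codes).
#' @param profile a \code{\link{protection_profile}} of the same length.
#' @param peptides data frame or 2-column matrix of (start, end).
#' @param timepoints labeling times in seconds (defaults to the standard
#'   30/100/300/1000/3000/10000 s series).
#' @param d_frac labeling D2O fraction (default 0.90).
#' @param backexchange back-exchange loss fraction in [0, 1).
#' @param noise_da centroid mass noise, Da.
#' @param n_reps replicates per timepoint (default 2).
#' @param seed integer seed.
#' @return an \code{\link{uptake_table}} including FD rows.
#' @export
simulate_hdx_peptides <- function(sequence, profile, peptides,
                                  timepoints = c(30, 100, 300, 1000, 3000, 10000),
                                  d_frac = 0.9, backexchange = 0.1,
                                  noise_da = 0.05, n_reps = 2, seed = 1) {
  stopifnot(inherits(profile, "protection_profile"))
  L <- nchar(sequence)
  if (length(profile$pf) != L) stop("profile length must equal sequence length")
  if (d_frac <= 0 || d_frac > 1) stop("d_frac must be in (0, 1]")
  if (backexchange < 0 || backexchange >= 1) stop("backexchange must be in [0, 1)")
  peptides <- as.data.frame(peptides)
  names(peptides)[1:2] <- c("start", "end")
  if (any(peptides$start < 1 | peptides$end > L)) {
    stop("peptide bounds outside the sequence")
  }
  set.seed(as.integer(seed))
  k_obs <- profile$k_int / profile$pf

  rows <- list(); m0 <- list()
  for (i in seq_len(nrow(peptides))) {
    st <- peptides$start[i]; en <- peptides$end[i]
    pep <- substr(sequence, st, en)
    n_ex <- count_exchangeable_amides(pep)
    pos <- exchangeable_positions(pep, st)
    key <- paste(pep, st, en)
    m0[[key]] <- peptide_mass(pep)
    for (tp in timepoints) {
      Dsum <- sum(d_frac * (1 - exp(-k_obs[pos] * tp)))
      mass <- m0[[key]] + (1 - backexchange) * Dsum * M_DEUTERIUM
      for (rep in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = pep, start = st, end = en, timepoint = as.character(tp),
          replicate = rep,
          centroid_mass = mass + stats::rnorm(1, sd = noise_da),
          stringsAsFactors = FALSE)
      }
    }
    fd_mass <- m0[[key]] + (1 - backexchange) * d_frac * n_ex * M_DEUTERIUM
    for (rep in seq_len(n_reps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, start = st, end = en, timepoint = "FD",
        replicate = rep,
        centroid_mass = fd_mass + stats::rnorm(1, sd = noise_da),
        stringsAsFactors = FALSE)
    }
  }
  uptake_table(do.call(rbind, rows), m0, d_frac = d_frac)
}

#' Overlapping peptide tiling of a sequence
#'
#' Regular tiling used by the synthetic HDX fixtures: peptides of a fixed
#' length advancing by a fixed step, with a final peptide pinned to the
#' C-terminus so coverage is complete.
#'
#' @param n_residues sequence length.
#' @param len peptide length (default 9).
#' @param step start-to-start spacing (default 3).
#' @return data frame with columns start, end.
#' @export
tile_peptides <- function(n_residues, len = 9, step = 3) {
  starts <- seq(1, max(n_residues - len + 1, 1), by = step)
  if (starts[length(starts)] + len - 1 < n_residues) {
    starts <- c(starts, n_residues - len + 1)
  }
  data.frame(start = starts, end = pmin(starts + len - 1, n_residues))
}
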