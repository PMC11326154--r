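#' Residue sets over an explicit universe
#'
#' @param members integer residue numbers in the set.
#' @param universe integer residue numbers over which membership is
#'   defined; members must be a subset.
#' @param label short set name.
#' @return an object of class \code{residue_set}.
#' @export
residue_set <- function(members, universe, label = "") {
  members <- sort(unique(as.integer(members)))
  universe <- sort(unique(as.integer(universe)))
  if (length(universe) == 0) stop("universe must be non-empty")
  if (!all(members %in% universe)) stop("members must lie within the universe")
  structure(list(label = label, members = members, universe = universe),
            class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("residue_set '%s': %d of %d residues\n", x$label,
              length(x$members), length(x$universe)))
  invisible(x)
}

#' Draw two residue sets with a prescribed overlap
#'
#' Samples from 1..universe_size two sets of the requested sizes sharing
#' exactly \code{overlap} members — controlled fixtures for overlap
#' statistics.
#'
#' @param universe_size size of the universe.
#' @param size_a,size_b set sizes.
#' @param overlap exact intersection size.
#' @param seed integer seed.
#' @return list of two \code{residue_set}s (A, B).
#' @export
make_residue_sets <- function(universe_size, size_a, size_b, overlap, seed = 1) {
  if (overlap > min(size_a, size_b)) stop("overlap exceeds a set size")
  if (size_a + size_b - overlap > universe_size) stop("sets do not fit the universe")
  set.seed(as.integer(seed))
  uni <- seq_len(universe_size)
  pick <- sample(uni, size_a + size_b - overlap)
  shared <- pick[seq_len(overlap)]
  only_a <- pick[seq_len(size_a - overlap) + overlap]
  only_b <- pick[seq_len(size_b - overlap) + size_a]
  list(A = residue_set(c(shared, only_a), uni, "A"),
       B = residue_set(c(shared, only_b), uni, "B"))
}

#' Threshold a per-residue profile into a residue set
#'
#' Members are the residues whose value strictly exceeds the cutoff
#' (absolute value when \code{absolute = TRUE}, as for signed HDX
#' differences). No-data residues are never members; they are part of the
#' universe only when \code{include_no_data_in_universe} is set.
#'
#' @param profile an \code{iaddat_profile}, \code{residue_hdx_profile},
#'   or data frame with \code{resno} and a value column.
#' @param cutoff strictly positive cutoff, same units as the profile.
#' @param absolute threshold |value| instead of value.
#' @param value_col value column name; guessed from the class by default.
#' @param include_no_data_in_universe keep residues with no data in the
#'   universe (default FALSE: the universe is the residues with data).
#' @param label set label.
#' @return a \code{residue_set}.
#' @export
threshold_residues <- function(profile, cutoff, absolute = FALSE,
                               value_col = NULL,
                               include_no_data_in_universe = FALSE,
                               label = "") {
  if (nrow(profile) == 0) stop("empty profile")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(value_col)) {
    value_col <- if ("score" %in% names(profile)) "score" else "delta_pD"
  }
  v <- profile[[value_col]]
  has <- !is.na(v)
  if ("no_data" %in% names(profile)) has <- has & !profile$no_data
  x <- if (absolute) abs(v) else v
  members <- profile$resno[has & x > cutoff]
  universe <- if (include_no_data_in_universe) profile$resno else profile$resno[has]
  residue_set(members, universe, label)
}

#' Pool residue sets by union
#'
#' Union of members across mutants and techniques, over the intersection
#' of the input universes. An intersection mode exists for sensitivity
#' analysis.
#'
#' @param sets list of \code{residue_set}s.
#' @param mode \code{"union"} (default) or \code{"intersection"}.
#' @param label pooled set label.
#' @return a \code{residue_set}.
#' @export
pool_sets <- function(sets, mode = c("union", "intersection"), label = "pooled") {
  mode <- match.arg(mode)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1), "residue_set")))
  uni <- Reduce(intersect, lapply(sets, `[[`, "universe"))
  if (length(uni) == 0) stop("input universes are disjoint")
  mem <- Reduce(if (mode == "union") union else intersect,
                lapply(sets, `[[`, "members"))
  residue_set(intersect(mem, uni), uni, label)
}

#' Jaccard ratio of two residue sets
#'
#' J(X, Y) = |X intersect Y| / |X union Y|, defined as 0 when both sets
#' are empty.
#'
#' @param x,y \code{residue_set}s on a shared universe.
#' @return the Jaccard ratio in [0, 1].
#' @export
jaccard_index <- function(x, y) {
  stopifnot(inherits(x, "residue_set"), inherits(y, "residue_set"))
  u <- length(union(x$members, y$members))
  if (u == 0) return(0)
  length(intersect(x$members, y$members)) / u
}

#' Hypergeometric overlap test
#'
#' Upper-tail (inclusive) probability of observing at least the given
#' overlap between a network of size n and a sector of size K drawn from
#' a universe of size N: P(X >= k), evaluated in log space via the
#' hypergeometric distribution for numerical stability.
#'
#' @param network,sector \code{residue_set}s sharing a universe.
#' @return the p-value in (0, 1].
#' @export
hypergeometric_overlap <- function(network, sector) {
  stopifnot(inherits(network, "residue_set"), inherits(sector, "residue_set"))
  uni <- intersect(network$universe, sector$universe)
  N <- length(uni)
  n <- length(intersect(network$members, uni))
  K <- length(intersect(sector$members, uni))
  if (N < n || N < K) stop("universe smaller than a set")
  k <- length(intersect(network$members, sector$members))
  # P(X >= k); log-space tail from phyper, exponentiated once
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Overlap summary of a network against residue sectors
#'
#' One row per sector: sizes, intersection, union, Jaccard ratio and the
#' hypergeometric upper-tail p-value, plus a one-line human summary
#' naming the sector with the larger Jaccard. The effective universe
#' (intersection of the inputs') is echoed since it materially changes
#' the p-values.
#'
#' @param network pooled \code{residue_set}.
#' @param sectors named list of \code{residue_set}s.
#' @return data frame of class \code{overlap_summary} with attribute
#'   \code{"message"} and \code{"universe_size"}.
#' @export
summarize_overlaps <- function(network, sectors) {
  stopifnot(length(sectors) >= 1)
  rows <- lapply(seq_along(sectors), function(i) {
    s <- sectors[[i]]
    lab <- if (nzchar(s$label)) s$label else names(sectors)[i]
    uni <- intersect(network$universe, s$universe)
    data.frame(sector = lab,
               network_size = length(intersect(network$members, uni)),
               sector_size = length(intersect(s$members, uni)),
               intersection = length(intersect(network$members, s$members)),
               union = length(union(network$members, s$members)),
               jaccard = jaccard_index(network, s),
               p_hypergeometric = hypergeometric_overlap(network, s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  best <- out$sector[which.max(out$jaccard)]
  msg <- sprintf("largest Jaccard overlap with sector '%s' (J = %.3f, P = %.3g)",
                 best, max(out$jaccard), out$p_hypergeometric[which.max(out$jaccard)])
  structure(out, class = c("overlap_summary", "data.frame"),
            message = msg,
            universe_size = length(Reduce(intersect,
                                          c(list(network$universe),
                                            lapply(sectors, `[[`, "universe")))))
}
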