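# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# small toy crystal reused across diffmap/iaddat tests
toy_pair <- function(n_residues = 10, perturbed = 4, displacement = 1.5,
                     seed = 1, d_min = 1.8, rel_sigma = 0) {
  wt <- make_toy_structure(n_residues, seed = seed)
  mut <- perturb_structure(wt, perturbed, displacement, seed = seed + 1)
  fw <- simulate_structure_factors(wt, d_min)
  fm <- simulate_structure_factors(mut, d_min)
  if (rel_sigma > 0) {
    fw <- add_measurement_noise(fw, rel_sigma, seed = seed + 100)
    fm <- add_measurement_noise(fm, rel_sigma, seed = seed + 200)
  }
  list(wt = wt, mut = mut, fw = fw, fm = fm)
}

# full diffmap branch on a toy pair -> (map, model)
toy_diffmap <- function(pair, alpha = 0.05, grid_spacing = 0.5) {
  scaled <- scale_to_reference(pair$fm, pair$fw)
  co <- phase_from_model(weighted_differences(scaled, pair$fw, alpha = alpha),
                         pair$wt)
  synthesize_map(co, grid_spacing = grid_spacing)
}

# exhaustive grid-scan IADDAT oracle: scalar triple loop over all grid
# points in column-major order, nearest-atom search with explicit
# minimum-image arithmetic; independent of compute_iaddat's vectorized path
iaddat_oracle <- function(map, model, threshold = 0.04, radius = 1.5) {
  atoms <- model$atoms[!model$atoms$is_water &
                         toupper(model$atoms$element) != "H", ]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$atom_id), ]
  cell <- model$cell
  af <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(solve(allomap:::frac_to_cart(cell)))
  res <- sort(unique(atoms$resno))
  acc <- setNames(numeric(length(res)), res)
  n_heavy <- sapply(res, function(r) sum(atoms$resno == r))
  n <- map$dims
  for (iz in seq_len(n[3])) for (iy in seq_len(n[2])) for (ix in seq_len(n[1])) {
    v <- map$rho[ix, iy, iz]
    if (abs(v) <= threshold) next
    p <- c((ix - 1) / n[1], (iy - 1) / n[2], (iz - 1) / n[3])
    best_d <- Inf; best_a <- NA
    for (a in seq_len(nrow(af))) {
      df <- p - af[a, ]
      df <- df - round(df)
      d <- sqrt(sum((df * cell[1:3])^2))   # orthogonal toy cells
      if (d < best_d) { best_d <- d; best_a <- a }
    }
    if (best_d <= radius) {
      r <- as.character(atoms$resno[best_a])
      acc[r] <- acc[r] + abs(v)
    }
  }
  data.frame(resno = res, score = unname(acc) / n_heavy)
}

# exact P(X >= k) by dynamic programming over the universe elements:
# counts subsets of size n with i sector members via the running
# polynomial ways[i+1][j+1], no hypergeometric distribution involved
hyper_tail_dp <- function(N, K, n, k) {
  # W[i+1, j+1] = number of j-subsets of the elements seen so far that
  # contain exactly i sector members (elements 1..K form the sector)
  W <- matrix(0, nrow = K + 1, ncol = n + 1)
  W[1, 1] <- 1
  for (e in seq_len(N)) {
    if (e <= K) {
      W[2:(K + 1), 2:(n + 1)] <- W[2:(K + 1), 2:(n + 1)] + W[1:K, 1:n]
    } else {
      W[, 2:(n + 1)] <- W[, 2:(n + 1)] + W[, 1:n]
    }
  }
  total <- sum(W[, n + 1])
  sum(W[seq(k + 1, K + 1), n + 1]) / total
}

# direct enumeration oracle: count amide positions 3..L that are not proline
amide_count_oracle <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  L <- length(aa)
  if (L < 3) return(0L)
  sum(aa[3:L] != "P")
}

# random peptide strings over the 20 standard residues
random_peptides <- function(n, min_len = 3, max_len = 20, seed = 1) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  replicate(n, paste(sample(aas, sample(min_len:max_len, 1), replace = TRUE),
                     collapse = ""))
}
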