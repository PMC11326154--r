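test_that("exchangeable-amide counting follows the N-terminal and proline rules", {
  expect_equal(count_exchangeable_amides("AAAA"), 2)
  expect_equal(count_exchangeable_amides("APAA"), 2)
  expect_equal(count_exchangeable_amides("AAPA"), 1)
  expect_error(count_exchangeable_amides("A"), "length")
  expect_error(count_exchangeable_amides("AP"), "no exchangeable")
  expect_error(count_exchangeable_amides("AB"), "non-standard")

  # property: agrees with direct enumeration on random peptides (the two
  # internal algebraic formulations are asserted equal on every call)
  for (pep in random_peptides(500, seed = 3)) {
    n <- amide_count_oracle(pep)
    if (n <= 0) {
      expect_error(count_exchangeable_amides(pep))
    } else {
      expect_equal(count_exchangeable_amides(pep), n)
    }
  }
})

test_that("percent deuteration handles FD correction, closed forms and clipping", {
  expect_equal(as.numeric(percent_deuteration(1005, 1000, 1010)), 50)
  expect_equal(as.numeric(percent_deuteration(1000, 1000, 1010)), 0)
  # no FD control: theoretical-maximum denominator
  m_up <- 4 * 0.9 * 1.00628
  expect_equal(as.numeric(percent_deuteration(1000 + m_up, 1000, n_ex = 4)), 100)
  # FD row scored against itself is 100% by construction
  expect_equal(as.numeric(percent_deuteration(1010, 1000, 1010)), 100)
  # clipping and flagging
  v <- percent_deuteration(c(990, 1030), 1000, 1010)
  expect_equal(as.numeric(v), c(-5, 110))
  expect_equal(attr(v, "out_of_range"), c(TRUE, TRUE))
  expect_error(percent_deuteration(1005, 1000, 999), "FD control")
})

test_that("simulated uptake obeys saturation, protection and closed-form limits", {
  seq4 <- "AAAA"
  peps <- data.frame(start = 1, end = 4)

  # t -> infinity equals the FD control (noiseless)
  tab <- simulate_hdx_peptides(seq4, protection_profile(rep(1, 4)), peps,
                               timepoints = c(1e9), noise_da = 0, n_reps = 1)
  m_inf <- tab$data$centroid_mass[tab$data$timepoint == "1e+09"]
  m_fd <- tab$data$centroid_mass[tab$data$timepoint == "FD"]
  expect_equal(m_inf, m_fd, tolerance = 1e-9)

  # full protection: no uptake at any finite time
  tabp <- simulate_hdx_peptides(seq4, protection_profile(rep(1e12, 4)), peps,
                                timepoints = c(30, 1e5), noise_da = 0, n_reps = 1)
  mt <- tabp$data[tabp$data$timepoint != "FD", "centroid_mass"]
  expect_equal(mt, rep(tabp$m0[[paste(seq4, 1, 4)]], 2), tolerance = 1e-6)

  # one amide, saturated exchange, d_frac 0.9, backexchange 0.1:
  # mass increase = 0.9 * 0.9 * 1.00628 Da
  seq3 <- "AAA"   # one exchangeable amide
  tab1 <- simulate_hdx_peptides(seq3, protection_profile(rep(1, 3), k_int = 1e9),
                                data.frame(start = 1, end = 3),
                                timepoints = 100, d_frac = 0.9,
                                backexchange = 0.1, noise_da = 0, n_reps = 1)
  up <- tab1$data$centroid_mass[tab1$data$timepoint == "100"] -
    tab1$m0[[paste(seq3, 1, 3)]]
  expect_equal(up, 0.9 * 0.9 * 1.00628, tolerance = 1e-9)

  # uptake is monotone non-decreasing in time; FD is the ceiling
  tabm <- simulate_hdx_peptides(paste(rep("A", 12), collapse = ""),
                                protection_profile(rep(50, 12)),
                                data.frame(start = 1, end = 12),
                                noise_da = 0, n_reps = 1)
  mseries <- tabm$data[tabm$data$timepoint != "FD", ]
  mseries <- mseries[order(as.numeric(mseries$timepoint)), "centroid_mass"]
  expect_true(all(diff(mseries) >= -1e-12))
  expect_true(all(mseries <= tabm$data$centroid_mass[tabm$data$timepoint == "FD"] + 1e-12))

  expect_error(simulate_hdx_peptides(seq4, protection_profile(rep(1, 4)),
                                     data.frame(start = 1, end = 9)),
               "outside")
})

test_that("difference tables classify against the +/-5 band with strict inequalities", {
  seq_aa <- paste(rep("A", 30), collapse = "")
  peps <- tile_peptides(30)
  wt <- simulate_hdx_peptides(seq_aa, protection_profile(rep(700, 30)), peps,
                              noise_da = 0, seed = 1)

  # identity: everything zero / no-change
  wd0 <- difference_table(wt, wt, 300)
  expect_true(all(wd0$delta_pD == 0))
  expect_true(all(wd0$classification == "no-change"))

  # exact boundary at the peptide level: delta of exactly -5 is no-change
  mk_tab <- function(m_t) uptake_table(
    data.frame(sequence = "AAAAA", start = 1, end = 5,
               timepoint = c("300", "FD"), replicate = 1,
               centroid_mass = c(m_t, 510)),
    m0 = list("AAAAA 1 5" = 500))
  wt5 <- mk_tab(505)                                 # 50 %D
  expect_equal(difference_table(mk_tab(504.5), wt5, 300)$classification,
               "no-change")                          # exactly -5
  expect_equal(difference_table(mk_tab(504.4), wt5, 300)$classification,
               "protected")
  expect_equal(difference_table(mk_tab(505.6), wt5, 300)$classification,
               "deprotected")

  # same strictness at the residue level
  mk <- function(delta) {
    structure(data.frame(start = 1, end = 9, n_ex = 7, delta_pD = delta),
              class = c("woods_table", "data.frame"))
  }
  prof <- residue_interpolation(mk(-5), n_residues = 9)
  expect_equal(unique(prof$classification[!prof$no_data]), "no-change")
  prof2 <- residue_interpolation(mk(-5.0001), n_residues = 9)
  expect_equal(unique(prof2$classification[!prof2$no_data]), "protected")

  # synthetic protection PF x10 on 20-25: peptides inside the block are
  # protected, peptides disjoint from it are no-change
  pf <- rep(700, 30); pf[20:25] <- 7000
  mut <- simulate_hdx_peptides(seq_aa, protection_profile(pf), peps,
                               noise_da = 0, seed = 2)
  wd <- difference_table(mut, wt, 300)
  inside <- wd$start >= 20 & wd$end <= 25
  disjoint <- wd$end < 20 | wd$start > 25
  if (any(inside)) expect_true(all(wd$classification[inside] == "protected"))
  expect_true(all(wd$classification[disjoint] == "no-change"))
  # overlap fraction drives the magnitude: fully-contained exchangeable
  # stretches see the full protection signal
  expect_true(min(wd$delta_pD) < -15)
})

test_that("greedy short-peptide cover picks minimal peptides and matches brute force", {
  rows <- data.frame(start = c(1, 1, 5, 11), end = c(20, 6, 12, 20))
  sel <- allomap:::greedy_peptide_cover(rows)
  expect_equal(sel, c(2, 3, 4))            # 1-6, 5-12, 11-20; never 1-20

  # brute force over all covering subsets: prioritizing short peptides
  # means minimizing the longest peptide used, then the total length
  all_subsets <- unlist(lapply(1:4, function(k)
    combn(4, k, simplify = FALSE)), recursive = FALSE)
  covers <- Filter(function(s) {
    cov <- rep(FALSE, 20)
    for (i in s) cov[rows$start[i]:rows$end[i]] <- TRUE
    all(cov)
  }, all_subsets)
  plen <- rows$end - rows$start + 1
  score <- vapply(covers, function(s) max(plen[s]) * 1000 + sum(plen[s]),
                  numeric(1))
  best <- covers[[which.min(score)]]
  expect_equal(sel, sort(best))
})

test_that("residue interpolation weights by inverse amide count and flags gaps", {
  # single peptide: constant value over its span, no-data elsewhere
  one <- structure(data.frame(start = 1, end = 10, n_ex = 8, delta_pD = -8),
                   class = c("woods_table", "data.frame"))
  prof <- residue_interpolation(one, n_residues = 15)
  expect_equal(prof$delta_pD[1:10], rep(-8, 10))
  expect_true(all(prof$no_data[11:15]))
  expect_true(all(is.na(prof$delta_pD[11:15])))     # never imputed zero

  # two equal-length peptides covering a residue: plain average
  two <- structure(data.frame(start = c(1, 3), end = c(8, 10),
                              n_ex = c(6, 6), delta_pD = c(-10, 0)),
                   class = c("woods_table", "data.frame"))
  prof2 <- residue_interpolation(two, n_residues = 10)
  expect_equal(prof2$delta_pD[4], -5)

  # inverse-amide-count weighting: shorter peptide dominates
  uneq <- structure(data.frame(start = c(1, 1), end = c(4, 13),
                               n_ex = c(2, 11), delta_pD = c(-13, 0)),
                    class = c("woods_table", "data.frame"))
  prof3 <- residue_interpolation(uneq, n_residues = 13)
  expect_equal(prof3$delta_pD[2], -13 * (1/2) / (1/2 + 1/11), tolerance = 1e-12)

  # exactness: all covering peptides agree -> flat recovery
  flat <- structure(data.frame(start = c(1, 4, 8), end = c(6, 10, 14),
                               n_ex = c(4, 5, 5), delta_pD = c(-7, -7, -7)),
                    class = c("woods_table", "data.frame"))
  prof4 <- residue_interpolation(flat, n_residues = 14)
  expect_equal(prof4$delta_pD, rep(-7, 14))
})

test_that("uptake curves aggregate replicates and stay monotone for simulated data", {
  # FD span of 10 Da makes %D replicates exactly (50, 52)
  tab <- uptake_table(
    data.frame(sequence = "AAAAA", start = 1, end = 5,
               timepoint = c("30", "30", "300", "FD"), replicate = c(1, 2, 1, 1),
               centroid_mass = c(505.0, 505.2, 506.0, 510.0)),
    m0 = list("AAAAA 1 5" = 500), d_frac = 0.9)
  cv <- uptake_curves(tab, "AAAAA", 1, 5)
  expect_equal(cv$timepoint, c(30, 300))
  expect_equal(cv$mean_pD[1], 51)
  expect_equal(cv$sd_pD[1], sqrt(2), tolerance = 1e-9)
  expect_true(is.na(cv$sd_pD[2]))                   # single replicate: NA, not 0

  sim <- simulate_hdx_peptides(paste(rep("A", 10), collapse = ""),
                               protection_profile(rep(100, 10)),
                               data.frame(start = 1, end = 10),
                               noise_da = 0, n_reps = 2, seed = 5)
  cv2 <- uptake_curves(sim, paste(rep("A", 10), collapse = ""), 1, 10)
  expect_true(all(diff(cv2$mean_pD) >= -1e-9))
  expect_error(uptake_curves(sim, "GGG", 1, 3), "unknown peptide")
})
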