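test_that("thresholding uses strict inequalities and respects no-data flags", {
  prof <- structure(data.frame(resno = 1:5, chain = "A",
                               score = c(0, 0.3, 0.31, 0.29, 1), n_atoms = 5),
                    class = c("iaddat_profile", "data.frame"))
  s <- threshold_residues(prof, 0.3)
  expect_equal(s$members, c(3, 5))          # 0.3 exactly is excluded

  zero <- prof; zero$score <- 0
  expect_length(threshold_residues(zero, 0.3)$members, 0)

  hdxp <- structure(data.frame(resno = 1:3, delta_pD = c(8, -8, 6),
                               coverage = 1, no_data = FALSE,
                               classification = "x"),
                    class = c("residue_hdx_profile", "data.frame"))
  expect_equal(threshold_residues(hdxp, 7, absolute = TRUE)$members, c(1, 2))
  # signed mode keeps only the positive exceedance
  expect_equal(threshold_residues(hdxp, 7)$members, 1)

  nd <- hdxp; nd$no_data <- c(FALSE, TRUE, FALSE); nd$delta_pD[2] <- NA
  s2 <- threshold_residues(nd, 7, absolute = TRUE)
  expect_equal(s2$members, 1)
  expect_equal(s2$universe, c(1, 3))        # no-data out of the universe...
  s3 <- threshold_residues(nd, 7, absolute = TRUE,
                           include_no_data_in_universe = TRUE)
  expect_equal(s3$universe, 1:3)            # ...unless asked for

  expect_error(threshold_residues(prof[0, ], 0.3), "empty")
  expect_error(threshold_residues(prof, 0), "cutoff")
})

test_that("pooling takes order-invariant unions over the shared universe", {
  u <- 1:20
  a <- residue_set(c(1, 2), u); b <- residue_set(c(2, 3), u)
  expect_equal(pool_sets(list(a))$members, a$members)
  expect_equal(pool_sets(list(a, b))$members, c(1, 2, 3))
  expect_equal(pool_sets(list(b, a))$members, pool_sets(list(a, b))$members)
  expect_equal(pool_sets(list(a, b), mode = "intersection")$members, 2)
  c_other <- residue_set(105, 101:110)
  expect_error(pool_sets(list(a, c_other)), "disjoint")
})

test_that("Jaccard ratio matches its definition", {
  u <- 1:10
  x <- residue_set(1:3, u); y <- residue_set(2:4, u)
  expect_equal(jaccard_index(x, y), 0.5)
  expect_equal(jaccard_index(y, x), 0.5)                    # symmetry
  expect_equal(jaccard_index(x, x), 1)
  expect_equal(jaccard_index(x, residue_set(5:6, u)), 0)
  e <- residue_set(integer(0), u)
  expect_equal(jaccard_index(e, e), 0)                      # empty convention
})

test_that("hypergeometric tail matches closed forms and exhaustive enumeration", {
  u10 <- 1:10
  p <- hypergeometric_overlap(residue_set(1:5, u10), residue_set(1:5, u10))
  expect_equal(p, 1 / choose(10, 5), tolerance = 1e-12)     # 1/252

  # zero overlap is a certain event
  expect_equal(hypergeometric_overlap(residue_set(1:3, u10),
                                      residue_set(4:6, u10)), 1)

  # dynamic-programming enumeration oracle over all draws, N <= 50
  cases <- list(c(50, 12, 15, 7), c(30, 10, 10, 5), c(20, 6, 9, 2),
                c(45, 20, 10, 8), c(50, 25, 25, 13))
  for (cs in cases) {
    N <- cs[1]; K <- cs[2]; n <- cs[3]; k <- cs[4]
    net <- residue_set(c(seq_len(k), seq(K + 1, K + n - k)), seq_len(N))
    sec <- residue_set(seq_len(K), seq_len(N))
    expect_equal(hypergeometric_overlap(net, sec), hyper_tail_dp(N, K, n, k),
                 tolerance = 1e-10)
  }

  # monotone non-increasing in the observed overlap at fixed (N, K, n)
  ps <- vapply(0:6, function(k) {
    outside <- if (k < 6) seq(13, 13 + (6 - k) - 1) else integer(0)
    mem <- c(seq_len(k), outside)
    hypergeometric_overlap(residue_set(mem, 1:40), residue_set(1:12, 1:40))
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_equal(ps[1], 1)
})

test_that("overlap summaries report sizes, Jaccard and enrichment correctly", {
  u <- 1:40
  net <- residue_set(1:10, u)
  res <- summarize_overlaps(net, list(self = residue_set(1:10, u),
                                      off = residue_set(21:30, u)))
  expect_equal(res$jaccard, c(1, 0))
  expect_equal(res$p_hypergeometric[2], 1)
  expect_equal(res$p_hypergeometric[1],
               hypergeometric_overlap(net, residue_set(1:10, u)))
  expect_match(attr(res, "message"), "self")

  # constructed overlap is reported exactly
  sets <- make_residue_sets(60, 20, 15, 9, seed = 4)
  res2 <- summarize_overlaps(sets$A, list(B = sets$B))
  expect_equal(res2$intersection, 9)
  expect_equal(res2$union, 20 + 15 - 9)

  # enriched overlap is significant; a typical random one is not
  enr <- make_residue_sets(200, 30, 30, 20, seed = 5)
  expect_lt(summarize_overlaps(enr$A, list(s = enr$B))$p_hypergeometric, 1e-6)
})

test_that("null draws give calibrated type-I error and monotone behaviour", {
  # design chosen for near-nominal attainable size of the discrete test
  N <- 321; K <- 100; n <- 70
  uni <- seq_len(N)
  sector <- residue_set(seq_len(K), uni)
  set.seed(20)
  rejections <- 0
  for (i in 1:300) {
    net <- residue_set(sample(uni, n), uni)
    if (hypergeometric_overlap(net, sector) < 0.05) rejections <- rejections + 1
  }
  # quick-turnaround version of the 1000-draw calibration (binomial 3 sd)
  expect_lt(abs(rejections / 300 - 0.05), 0.05)
})
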