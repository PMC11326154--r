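test_that("isotropic scaling recovers constructed scale and B-factor offsets", {
  m <- make_toy_structure(10, seed = 1)
  ref <- simulate_structure_factors(m, d_min = 1.8)

  double <- ref
  double$refl$F <- 2 * ref$refl$F
  sc <- scale_to_reference(double, ref)
  kB <- attr(sc, "scale")
  expect_equal(unname(kB["k"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(kB["B"]), 0, tolerance = 1e-6)
  expect_equal(sc$refl$F, ref$refl$F, tolerance = 1e-8)

  ident <- scale_to_reference(ref, ref)
  expect_equal(unname(attr(ident, "scale")), c(1, 0), tolerance = 1e-7)

  # mut = ref * exp(-5 s^2 / 4): refit must recover B = +5
  s2 <- allomap:::inv_d2(ref$refl[, c("h", "k", "l")], ref$cell)
  damped <- ref
  damped$refl$F <- ref$refl$F * exp(-5 * s2 / 4)
  sc2 <- scale_to_reference(damped, ref)
  expect_equal(unname(attr(sc2, "scale")["B"]), 5, tolerance = 1e-6)
  expect_equal(unname(attr(sc2, "scale")["k"]), 1, tolerance = 1e-6)

  # guards
  other <- ref
  other$cell <- ref$cell * 1.2
  expect_error(scale_to_reference(other, ref), "cells differ")
  few <- ref
  few$refl <- few$refl[1:10, ]
  expect_error(scale_to_reference(few, ref), "50 common")
})

test_that("difference weighting matches its closed forms and is monotone", {
  m <- make_toy_structure(8, seed = 2)
  ref <- simulate_structure_factors(m, d_min = 2.0)

  # identical datasets: all differences and weighted coefficients zero
  co0 <- weighted_differences(ref, ref)
  expect_true(all(co0$dF == 0))
  expect_true(all(co0$w * co0$dF == 0))

  # constructed inputs exercising the weight formula directly
  set.seed(1)
  base <- data.frame(h = 1:100, k = 0, l = 0, F = 100, SIGF = 1)
  cell <- c(500, 500, 500, 90, 90, 90)   # keep all indices low-resolution
  a <- reflection_set(base, cell)
  b <- base; b$F <- b$F + rnorm(100, sd = 1e-3)
  b <- reflection_set(b, cell)
  # alpha = 0, equal sigmas: sigma_d^2 equals its mean for every reflection
  co <- weighted_differences(b, a, alpha = 0)
  expect_equal(co$w, rep(0.5, 100), tolerance = 1e-12)

  # one outlier with dF^2 = 100 <dF^2> and negligible sigma (zero, against
  # a nonzero sigma mean) -> w = 1/(1 + 0 + 0.05 * 100) = 1/6; with n unit
  # differences plus one outlier x, solving x^2 = 100 (n - 1 + x^2) / n
  # gives x^2 = 100 (n - 1) / (n - 100)
  n <- 1000
  bigb <- data.frame(h = 1:n, k = 0, l = 0, F = 100, SIGF = c(0, rep(1, n - 1)))
  x2 <- 100 * (n - 1) / (n - 100)
  bb <- bigb; bb$F <- bb$F + c(sqrt(x2), rep(1, n - 1))
  co2 <- weighted_differences(reflection_set(bb, cell),
                              reflection_set(bigb, cell), alpha = 0.05)
  expect_equal(co2$w[1], 1 / 6, tolerance = 1e-6)

  # monotonicity: w decreases with sigma at fixed dF, and with |dF| at alpha>0
  sig_sweep <- seq(0.1, 5, length.out = 20)
  w_of_sigma <- vapply(sig_sweep, function(s) {
    aa <- data.frame(h = 1:200, k = 0, l = 0, F = 100, SIGF = 1)
    bb <- aa; bb$F <- bb$F + 1; bb$SIGF[1] <- s
    weighted_differences(reflection_set(bb, cell),
                         reflection_set(aa, cell), alpha = 0.05)$w[1]
  }, numeric(1))
  expect_true(all(diff(w_of_sigma) < 0))

  df_sweep <- seq(1, 20, length.out = 20)
  w_of_df <- vapply(df_sweep, function(d) {
    aa <- data.frame(h = 1:200, k = 0, l = 0, F = 100, SIGF = 1)
    bb <- aa; bb$F <- bb$F + 1; bb$F[1] <- aa$F[1] + d
    weighted_differences(reflection_set(bb, cell),
                         reflection_set(aa, cell), alpha = 0.05)$w[1]
  }, numeric(1))
  expect_true(all(diff(w_of_df) < 0))
})

test_that("model phases obey the origin and shift theorems", {
  one <- xtal_model(data.frame(atom_id = 1, element = "C", resno = 1,
                               resid = "ALA", chain = "A", elety = "CA",
                               x = 0, y = 0, z = 0, occ = 1, b = 10,
                               is_water = FALSE),
                    c(10, 12, 14, 90, 90, 90))
  f <- simulate_structure_factors(one, d_min = 2.0)
  noisy <- add_measurement_noise(f, 0.02, seed = 1)
  co <- weighted_differences(noisy, f)
  co <- phase_from_model(co, one)
  expect_equal(max(abs(co$phi)), 0, tolerance = 1e-8)

  # translation by fractional (1/2, 0, 0) shifts phi(h00) by 180 h
  shifted <- one
  shifted$atoms$x <- shifted$atoms$x + one$cell[1] / 2
  co2 <- phase_from_model(co, shifted)
  h00 <- co2[co2$k == 0 & co2$l == 0, ]
  expected <- (180 * h00$h) %% 360
  got <- h00$phi %% 360
  expect_equal(cos(got * pi / 180), cos(expected * pi / 180), tolerance = 1e-8)
  expect_equal(sin(got * pi / 180), sin(expected * pi / 180), tolerance = 1e-8)

  co3 <- phase_from_model(co, one)
  expect_identical(co3$phi, co$phi)
})

test_that("FFT synthesis matches direct summation and Parseval's identity", {
  pair <- toy_pair(10, perturbed = 4, seed = 3)
  scaled <- scale_to_reference(pair$fm, pair$fw)
  co <- phase_from_model(weighted_differences(scaled, pair$fw), pair$wt)
  map <- synthesize_map(co, grid_spacing = 0.5)

  # map mean is zero (no F000 term)
  expect_lt(abs(mean(map$rho)), 1e-9)

  # direct summation at 5 random grid points
  set.seed(7)
  ijk <- cbind(sample.int(map$dims[1], 5), sample.int(map$dims[2], 5),
               sample.int(map$dims[3], 5))
  direct <- map_value_direct(co, sweep(ijk - 1, 2, map$dims, "/"))
  grid <- map$rho[ijk]
  expect_equal(grid, direct, tolerance = 1e-6)

  # Parseval: sum rho^2 V/N = sum |w dF|^2 / V over the full sphere
  V <- allomap:::cell_volume(map$cell)
  lhs <- sum(map$rho^2) * V / prod(map$dims)
  rhs <- 2 * sum((co$w * co$dF)^2) / V
  expect_equal(lhs, rhs, tolerance = 1e-6)

  # all-zero coefficients give an all-zero map
  co0 <- co
  co0$dF <- 0
  map0 <- synthesize_map(co0, grid_spacing = 0.5)
  expect_true(all(map0$rho == 0))

  # guards
  expect_error(synthesize_map(co, grid_spacing = 5), "grid too coarse")
  conp <- weighted_differences(scaled, pair$fw)
  expect_error(synthesize_map(conp, 0.5), "unphased")
})

test_that("a real perturbation produces more difference density than a null comparison", {
  wt <- make_toy_structure(10, seed = 5)
  mut <- perturb_structure(wt, 6, 1.5, seed = 6)
  fw <- simulate_structure_factors(wt, 1.8)
  fm <- simulate_structure_factors(mut, 1.8)
  fw1 <- add_measurement_noise(fw, 0.05, seed = 11)
  fw2 <- add_measurement_noise(fw, 0.05, seed = 12)   # independent WT draw
  fmn <- add_measurement_noise(fm, 0.05, seed = 13)

  null_map <- toy_diffmap(list(wt = wt, fw = fw1, fm = fw2))
  sig_map <- toy_diffmap(list(wt = wt, fw = fw1, fm = fmn))
  expect_lt(sd(null_map$rho), sd(sig_map$rho))
})
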