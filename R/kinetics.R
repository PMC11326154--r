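#' Kinetics datasets
#'
#' Initial-velocity data for Michaelis-Menten analysis: a data frame with
#' columns \code{substrate_mM}, \code{replicate} and
#' \code{slope_mAU_per_min}, plus the assay constants needed to convert
#' absorbance slopes to turnover: enzyme concentration \code{e0_nM},
#' molar absorptivity \code{epsilon} (AU mM^-1 cm^-1) and \code{path_cm}.
#'
#' @param data velocity data frame as above.
#' @param e0_nM enzyme concentration, nM.
#' @param epsilon product molar absorptivity at the read wavelength,
#'   AU mM^-1 cm^-1 (buffer/pH dependent; must be supplied for k_cat).
#' @param path_cm optical path length, cm.
#' @return an object of class \code{kinetics_dataset}.
#' @export
kinetics_dataset <- function(data, e0_nM, epsilon = NA_real_, path_cm = NA_real_) {
  need <- c("substrate_mM", "replicate", "slope_mAU_per_min")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("kinetics data missing columns: ", paste(miss, collapse = ", "))
  if (any(data$substrate_mM <= 0)) stop("substrate concentrations must be positive")
  if (length(unique(data$substrate_mM)) < 3) {
    stop("at least 3 distinct substrate concentrations are required")
  }
  structure(list(data = as.data.frame(data), e0_nM = e0_nM,
                 epsilon = epsilon, path_cm = path_cm),
            class = "kinetics_dataset")
}

#' Simulate Michaelis-Menten plate-reader velocities
#'
#' v(S) = k_cat E0 S / (K_m + S), converted to an absorbance slope via
#' the molar absorptivity and path length; replicate slopes are perturbed
#' multiplicatively by N(1, rel_noise). The default substrate series is
#' 12 concentrations spanning 40 mM down to 3.9 uM geometrically.
#'
#' @param k_cat turnover number, s^-1.
#' @param K_m Michaelis constant, mM.
#' @param E0 enzyme concentration, nM.
#' @param substrate_mM substrate series, mM.
#' @param n_reps replicates per concentration (default 4).
#' @param rel_noise relative multiplicative noise on slopes.
#' @param epsilon molar absorptivity, AU mM^-1 cm^-1 (default 18, the
#'   typical scale for para-nitrophenolate at 405 nm near neutral pH).
#' @param path_cm optical path, cm (default 0.5, a 100 uL well).
#' @param seed integer seed.
#' @return a \code{\link{kinetics_dataset}}.
#' @export
simulate_kinetics <- function(k_cat, K_m, E0,
                              substrate_mM = pnpp_series(),
                              n_reps = 4, rel_noise = 0, epsilon = 18,
                              path_cm = 0.5, seed = 1) {
  if (any(c(k_cat, K_m, E0) <= 0)) stop("kinetic parameters must be positive")
  if (length(substrate_mM) == 0) stop("substrate series is empty")
  if (any(substrate_mM <= 0)) stop("substrate concentrations must be positive")
  set.seed(as.integer(seed))
  rows <- expand.grid(replicate = seq_len(n_reps), substrate_mM = substrate_mM)
  S <- rows$substrate_mM
  v_mM_per_s <- k_cat * (E0 * 1e-6) * S / (K_m + S)   # E0 nM -> mM
  slope <- v_mM_per_s * epsilon * path_cm * 1000 * 60 # AU/s -> mAU/min
  if (rel_noise > 0) slope <- slope * stats::rnorm(length(slope), 1, rel_noise)
  kinetics_dataset(data.frame(substrate_mM = S, replicate = rows$replicate,
                              slope_mAU_per_min = slope),
                   e0_nM = E0, epsilon = epsilon, path_cm = path_cm)
}

#' Standard 12-point pNPP dilution series
#'
#' Geometric series of 12 substrate concentrations from 40 mM down to
#' 3.9 uM (dilution factor about 2.3), covering both sides of typical
#' phosphatase K_m values.
#'
#' @return numeric vector of concentrations in mM.
#' @export
pnpp_series <- function() {
  exp(seq(log(40), log(0.0039), length.out = 12))
}

#' Initial-velocity slope from a plate-reader trace
#'
#' Ordinary least-squares slope of absorbance against time over the
#' fitting window, returned in mAU per minute.
#'
#' @param time_s time points, seconds.
#' @param absorbance_AU absorbance readings, AU.
#' @param window_s fitting window \code{c(min, max)} in seconds (default
#'   the full 6-minute read).
#' @return slope in mAU/min.
#' @export
slopes_from_traces <- function(time_s, absorbance_AU, window_s = c(0, 360)) {
  keep <- time_s >= window_s[1] & time_s <= window_s[2]
  if (sum(keep) < 5) stop("fewer than 5 time points in the fitting window")
  fit <- stats::lm(absorbance_AU[keep] ~ time_s[keep])
  unname(stats::coef(fit)[2]) * 1000 * 60
}

#' Fit Michaelis-Menten parameters
#'
#' Nonlinear least squares of v = V_max S / (K_m + S) on replicate-level
#' velocities (pooled residuals, preserving degrees of freedom), with
#' starting values V_max = max(v) and K_m = S at half-max. 95\% confidence
#' intervals come from the parameter covariance with a t quantile on
#' n - 2 degrees of freedom. k_cat = V_max / (epsilon * path * E0) in
#' s^-1 is reported only when absorptivity and path length are known;
#' otherwise V_max is left in slope units with an explicit unit tag.
#'
#' @param dataset a \code{\link{kinetics_dataset}}.
#' @return an object of class \code{mm_fit}: list with elements Vmax, Km,
#'   kcat (possibly NA), their 95\% CIs, units, residual summary and the
#'   underlying \code{nls} fit.
#' @export
fit_michaelis_menten <- function(dataset) {
  stopifnot(inherits(dataset, "kinetics_dataset"))
  d <- dataset$data
  if (any(d$slope_mAU_per_min < 0)) warning("negative velocities present")
  v <- d$slope_mAU_per_min; S <- d$substrate_mM
  Vmax0 <- max(v)
  Km0 <- S[which.min(abs(v - Vmax0 / 2))]
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                           start = list(Vmax = Vmax0, Km = max(Km0, 1e-6)),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  if (any(est <= 0)) stop("non-positive parameter estimate; fit failed")
  if (est["Km"] > max(S) || est["Km"] < min(S)) {
    warning("fitted K_m outside the substrate range; design does not bracket K_m")
  }
  n <- length(v)
  se <- summary(fit)$coefficients[, "Std. Error"]
  tq <- stats::qt(0.975, df = n - 2)
  ci <- rbind(Vmax = est["Vmax"] + c(-1, 1) * tq * se["Vmax"],
              Km = est["Km"] + c(-1, 1) * tq * se["Km"])
  colnames(ci) <- c("lo", "hi")

  kcat <- kcat_ci <- kcat_se <- NA_real_
  if (is.finite(dataset$epsilon) && is.finite(dataset$path_cm)) {
    # slope mAU/min -> rate mM/s -> turnover s^-1
    conv <- 1 / (1000 * 60 * dataset$epsilon * dataset$path_cm *
                   (dataset$e0_nM * 1e-6))
    kcat <- est["Vmax"] * conv
    kcat_se <- se["Vmax"] * conv
    kcat_ci <- ci["Vmax", ] * conv
  }
  structure(list(Vmax = unname(est["Vmax"]), Km = unname(est["Km"]),
                 kcat = unname(kcat), Vmax_ci = ci["Vmax", ],
                 Km_ci = ci["Km", ], kcat_ci = kcat_ci,
                 Vmax_se = unname(se["Vmax"]), Km_se = unname(se["Km"]),
                 kcat_se = unname(kcat_se),
                 vmax_units = "mAU/min", kcat_units = "1/s",
                 rss = sum(stats::resid(fit)^2), n = n,
                 e0_nM = dataset$e0_nM, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d)\n", x$n))
  cat(sprintf("  Vmax = %.4g %s  [%.4g, %.4g]\n", x$Vmax, x$vmax_units,
              x$Vmax_ci[1], x$Vmax_ci[2]))
  cat(sprintf("  Km   = %.4g mM  [%.4g, %.4g]\n", x$Km, x$Km_ci[1], x$Km_ci[2]))
  if (is.finite(x$kcat)) {
    cat(sprintf("  kcat = %.4g %s  [%.4g, %.4g]\n", x$kcat, x$kcat_units,
                x$kcat_ci[1], x$kcat_ci[2]))
  }
  invisible(x)
}

# per-replicate parameter estimates, for replicate-level inference
replicate_params <- function(dataset) {
  stopifnot(inherits(dataset, "kinetics_dataset"))
  reps <- unique(dataset$data$replicate)
  out <- vapply(reps, function(r) {
    sub <- dataset
    sub$data <- dataset$data[dataset$data$replicate == r, , drop = FALSE]
    f <- fit_michaelis_menten(sub)
    c(activity = if (is.finite(f$kcat)) f$kcat else f$Vmax, Km = f$Km)
  }, numeric(2))
  t(out)
}

replicate_kcat <- function(dataset) replicate_params(dataset)[, "activity"]

#' Compare mutant kinetics to wild type
#'
#' For each parameter (k_cat when available, else V_max; and K_m) reports
#' the mutant/WT ratio of the pooled-fit point estimates with a 95\% CI.
#' When both conditions carry at least two replicates the CI comes from
#' the replicate-level parameter estimates (Welch interval on the log
#' scale) — the pooled-fit covariance understates uncertainty under the
#' proportional noise typical of plate readers, while replicate spread
#' captures it directly. With single-replicate data the CI falls back to
#' the delta method on the pooled-fit standard errors. A parameter is
#' flagged "unchanged" when the ratio CI contains 1. A two-tailed
#' one-sample t-test of the mutant's replicate-level activity estimates
#' against the WT mean is also reported.
#'
#' @param mut_data,wt_data \code{kinetics_dataset} objects.
#' @return data frame of class \code{kinetics_comparison}: one row per
#'   parameter with ratio, CI, unchanged flag and t-test p-value.
#' @export
compare_fits <- function(mut_data, wt_data) {
  fm <- fit_michaelis_menten(mut_data)
  fw <- fit_michaelis_menten(wt_data)
  if (fm$vmax_units != fw$vmax_units) stop("fits are in different units")
  use_kcat <- is.finite(fm$kcat) && is.finite(fw$kcat)

  rm_ <- replicate_params(mut_data)
  rw_ <- replicate_params(wt_data)
  have_reps <- nrow(rm_) >= 2 && nrow(rw_) >= 2

  ratio_ci <- function(m, m_se, w, w_se, col) {
    ratio <- m / w
    if (have_reps) {
      lm_ <- log(rm_[, col]); lw_ <- log(rw_[, col])
      vm <- stats::var(lm_) / length(lm_); vw <- stats::var(lw_) / length(lw_)
      se <- sqrt(vm + vw)
      if (se == 0) return(c(ratio, ratio, ratio))
      df <- (vm + vw)^2 /
        (vm^2 / (length(lm_) - 1) + vw^2 / (length(lw_) - 1))
      half <- stats::qt(0.975, df) * se
      ratio * exp(c(0, -half, half))
    } else {
      se_log <- sqrt((m_se / m)^2 + (w_se / w)^2)
      ratio * exp(c(0, -1.96 * se_log, 1.96 * se_log))
    }
  }
  one <- function(param, m, m_se, w, w_se, col) {
    rc <- ratio_ci(m, m_se, w, w_se, col)
    data.frame(parameter = param, mutant = m, wt = w, ratio = rc[1],
               ratio_lo = rc[2], ratio_hi = rc[3],
               unchanged = rc[2] <= 1 && rc[3] >= 1,
               stringsAsFactors = FALSE)
  }
  act <- if (use_kcat) one("kcat", fm$kcat, fm$kcat_se, fw$kcat, fw$kcat_se, "activity")
         else one("Vmax", fm$Vmax, fm$Vmax_se, fw$Vmax, fw$Vmax_se, "activity")
  km <- one("Km", fm$Km, fm$Km_se, fw$Km, fw$Km_se, "Km")

  km_mut <- rm_[, "activity"]
  wt_mean <- mean(rw_[, "activity"])
  pval <- if (length(km_mut) >= 2 && stats::sd(km_mut) > 0) {
    stats::t.test(km_mut, mu = wt_mean)$p.value
  } else NA_real_
  act$t_test_p <- pval
  km$t_test_p <- NA_real_
  out <- rbind(act, km)
  rownames(out) <- NULL
  structure(out, class = c("kinetics_comparison", "data.frame"))
}
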