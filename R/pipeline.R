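#' Pipeline configuration
#'
#' Collects the stage parameters and file paths for a full run. Defaults
#' are the analysis constants used throughout the package: alpha = 0.05
#' difference-map weighting, 0.04 e-/A^3 integration threshold within
#' 1.5 A, display cap 0.3, the +/-5 percentage-point HDX no-change band,
#' and network cutoffs of 0.3 (IADDAT) and 7 (|delta %D|). The fully
#' resolved configuration is written alongside every run's outputs.
#'
#' @param ref_reflections path to the reference (WT) reflection CSV.
#' @param mutant_reflections named list of mutant reflection CSV paths.
#' @param model path to the reference model PDB.
#' @param hdx_wt path to the WT uptake CSV (NULL to skip the HDX branch).
#' @param hdx_mut named list of mutant uptake CSV paths.
#' @param sectors named list of sector residue-set CSV paths.
#' @param out_dir output directory.
#' @param alpha difference-map weighting strength.
#' @param threshold IADDAT density threshold, e-/A^3.
#' @param radius IADDAT assignment radius, A.
#' @param cap IADDAT display cap.
#' @param grid_spacing map grid spacing, A.
#' @param hdx_timepoint HDX labeling time for the difference analysis, s.
#' @param hdx_band no-change band half-width, percentage points.
#' @param hdx_scheme residue interpolation scheme.
#' @param iaddat_cut network cutoff on IADDAT scores.
#' @param hdx_cut network cutoff on |delta %D|.
#' @param universe residue universe for overlap tests; NULL uses the
#'   model's protein residues.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(ref_reflections, mutant_reflections, model,
                            hdx_wt = NULL, hdx_mut = NULL, sectors = NULL,
                            out_dir = ".",
                            alpha = 0.05, threshold = 0.04, radius = 1.5,
                            cap = 0.3, grid_spacing = 0.5,
                            hdx_timepoint = 300, hdx_band = 5,
                            hdx_scheme = "short-peptides",
                            iaddat_cut = 0.3, hdx_cut = 7,
                            universe = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full difference-map / HDX / network pipeline
#'
#' Per mutant: scale to the reference, form alpha-weighted difference
#' coefficients, phase against the reference model, synthesize the
#' difference map and integrate IADDAT per residue (CSV out). When HDX
#' inputs are present, compute the peptide difference table at the
#' configured timepoint and its residue-level interpolation (CSV out).
#' Threshold and pool everything into a combined network, test it
#' against each sector (hypergeometric, Jaccard), and write a combined
#' JSON report plus the resolved configuration. Progress goes to stderr;
#' outputs are deterministic for identical inputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the report list, invisibly (also written as report.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[allomap] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  model <- stage("read-model", read_model_pdb(config$model))
  ref <- stage("read-reference", read_reflections_csv(config$ref_reflections))
  prot_res <- sort(unique(model$atoms$resno[!model$atoms$is_water]))
  universe <- if (is.null(config$universe)) prot_res else config$universe

  iaddat_profiles <- list()
  for (mname in names(config$mutant_reflections)) {
    iaddat_profiles[[mname]] <- stage(paste0("diffmap/iaddat:", mname), {
      mut <- read_reflections_csv(config$mutant_reflections[[mname]])
      scaled <- scale_to_reference(mut, ref)
      co <- weighted_differences(scaled, ref, alpha = config$alpha)
      co <- phase_from_model(co, model)
      map <- synthesize_map(co, grid_spacing = config$grid_spacing)
      prof <- compute_iaddat(map, model, threshold = config$threshold,
                             radius = config$radius)
      write_residue_scores(cap_for_display(prof, config$cap), model,
                           csv_path = file.path(config$out_dir,
                                                paste0("iaddat_", mname, ".csv")),
                           pdb_path = file.path(config$out_dir,
                                                paste0("iaddat_", mname, ".pdb")))
      prof
    })
  }

  hdx_profiles <- list()
  if (!is.null(config$hdx_wt) && length(config$hdx_mut)) {
    wt_tab <- stage("read-hdx-wt", read_uptake_csv(config$hdx_wt))
    for (mname in names(config$hdx_mut)) {
      hdx_profiles[[mname]] <- stage(paste0("hdx:", mname), {
        mt <- read_uptake_csv(config$hdx_mut[[mname]])
        woods <- difference_table(mt, wt_tab, timepoint = config$hdx_timepoint,
                                  band = config$hdx_band)
        prof <- residue_interpolation(woods, scheme = config$hdx_scheme,
                                      n_residues = max(prot_res),
                                      band = config$hdx_band)
        utils::write.csv(woods, file.path(config$out_dir,
                                          paste0("woods_", mname, ".csv")),
                         row.names = FALSE, quote = FALSE)
        utils::write.csv(prof, file.path(config$out_dir,
                                         paste0("hdx_residue_", mname, ".csv")),
                         row.names = FALSE, quote = FALSE)
        prof
      })
    }
  }

  network <- stage("network", {
    sets <- lapply(names(iaddat_profiles), function(m) {
      p <- iaddat_profiles[[m]]
      p_uni <- p[p$resno %in% universe, , drop = FALSE]
      threshold_residues(p_uni, cutoff = config$iaddat_cut,
                         label = paste0("iaddat:", m))
    })
    for (m in names(hdx_profiles)) {
      p <- hdx_profiles[[m]]
      p_uni <- p[p$resno %in% universe, , drop = FALSE]
      sets <- c(sets, list(threshold_residues(
        p_uni, cutoff = config$hdx_cut, absolute = TRUE,
        include_no_data_in_universe = TRUE, label = paste0("hdx:", m))))
    }
    pool_sets(sets, label = "combined-network")
  })
  write_residue_set_csv(network, file.path(config$out_dir, "network.csv"))

  overlaps <- NULL
  if (length(config$sectors)) {
    overlaps <- stage("overlaps", {
      secs <- lapply(names(config$sectors), function(s)
        read_residue_set_csv(config$sectors[[s]], universe = network$universe,
                             label = s))
      names(secs) <- names(config$sectors)
      summarize_overlaps(network, secs)
    })
  }

  report <- list(
    parameters = config[!vapply(config, is.null, logical(1))],
    universe_size = length(network$universe),
    network = network$members,
    network_size = length(network$members),
    hdx_included = length(hdx_profiles) > 0,
    overlaps = if (!is.null(overlaps)) as.data.frame(overlaps) else NULL,
    overlap_note = if (!is.null(overlaps)) attr(overlaps, "message") else NULL)
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$parameters,
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Generate the bundled synthetic study fixture
#'
#' Writes a complete synthetic input bundle with known ground truth to
#' \code{dir}: a 60-residue toy crystal (WT) with three well-separated
#' single-residue CB perturbations standing in for point mutants, noisy
#' structure-factor CSVs for all four crystals, WT and mutant HDX uptake
#' tables with a short protected block around each mutation site, and
#' two sector residue sets — one built to overlap the
#' perturbed/protected residues, one random. The geometry keeps the
#' pooled network a minority of the chain (as in real catalytic
#' domains), so overlap statistics remain informative.
#'
#' @param dir output directory.
#' @param seed master seed; all sub-seeds derive from it.
#' @param n_residues toy chain length (default 30).
#' @param perturbed named integer vector of perturbed residues, one per
#'   synthetic mutant.
#' @param displacement perturbation size in Angstrom (default 1.5).
#' @param rel_sigma relative amplitude noise (default 0.05).
#' @param d_min resolution limit, A.
#' @return named list of the file paths written, plus the ground truth.
#' @export
make_synthetic_fixture <- function(dir, seed = 1, n_residues = 60,
                                   perturbed = c(mutA = 12L, mutB = 30L, mutC = 48L),
                                   displacement = 1.5, rel_sigma = 0.05,
                                   d_min = 1.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  wt <- make_toy_structure(n_residues, seed = seed)
  model_path <- file.path(dir, "wt.pdb")
  write_model_pdb(wt, model_path)
  fwt <- simulate_structure_factors(wt, d_min = d_min)
  fwt_noisy <- add_measurement_noise(fwt, rel_sigma, seed = seed + 1000L)
  ref_path <- file.path(dir, "wt_reflections.csv")
  write_reflections_csv(fwt_noisy, ref_path)

  mut_paths <- list()
  for (i in seq_along(perturbed)) {
    mname <- names(perturbed)[i]
    mut <- perturb_structure(wt, perturbed[i], displacement, seed = seed + i)
    fm <- simulate_structure_factors(mut, d_min = d_min)
    fm <- add_measurement_noise(fm, rel_sigma, seed = seed + 2000L + i)
    mut_paths[[mname]] <- file.path(dir, paste0(mname, "_reflections.csv"))
    write_reflections_csv(fm, mut_paths[[mname]])
  }

  # HDX: mid-curve baseline exchange (PF 700 at k_int 1/s puts 300 s
  # mid-transition) with a 10x protected block of 3 residues around each
  # mutation site; short 6-mer peptides limit positional smearing
  seq_aa <- paste(rep("A", n_residues), collapse = "")
  peptides <- tile_peptides(n_residues, len = 6, step = 2)
  base_pf <- rep(700, n_residues)
  wt_prof <- protection_profile(base_pf)
  hdx_wt_path <- file.path(dir, "hdx_wt.csv")
  write_uptake_csv(simulate_hdx_peptides(seq_aa, wt_prof, peptides,
                                         seed = seed + 10L), hdx_wt_path)
  hdx_mut_paths <- list(); protected <- list()
  for (i in seq_along(perturbed)) {
    mname <- names(perturbed)[i]
    block <- perturbed[i] + (-1:1)
    block <- block[block >= 1 & block <= n_residues]
    protected[[mname]] <- block
    pf <- base_pf; pf[block] <- pf[block] * 10
    tabm <- simulate_hdx_peptides(seq_aa, protection_profile(pf), peptides,
                                  seed = seed + 20L + i)
    hdx_mut_paths[[mname]] <- file.path(dir, paste0("hdx_", mname, ".csv"))
    write_uptake_csv(tabm, hdx_mut_paths[[mname]])
  }

  # sectors: one enriched in the perturbed/protected residues, one random
  set.seed(seed + 99L)
  truth_res <- sort(unique(c(unlist(protected), unname(perturbed))))
  uni <- seq_len(n_residues)
  sec_size <- length(truth_res) + 3L
  sec_a <- sort(sample(uni, sec_size))                          # random
  sec_b <- sort(c(truth_res, sample(setdiff(uni, truth_res), 3L)))
  sector_paths <- list(sectorA = file.path(dir, "sectorA.csv"),
                       sectorB = file.path(dir, "sectorB.csv"))
  write_residue_set_csv(residue_set(sec_a, uni, "sectorA"), sector_paths$sectorA)
  write_residue_set_csv(residue_set(sec_b, uni, "sectorB"), sector_paths$sectorB)

  list(model = model_path, ref_reflections = ref_path,
       mutant_reflections = mut_paths, hdx_wt = hdx_wt_path,
       hdx_mut = hdx_mut_paths, sectors = sector_paths,
       truth = list(perturbed = perturbed, protected = protected,
                    displacement = displacement, rel_sigma = rel_sigma,
                    seed = seed))
}
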