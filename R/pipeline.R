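# End-to-end pipeline: simulate -> sample -> genotype matrix -> (optional
# mask / group restriction) -> LD binning -> Ne trajectory -> windowed
# report, with a machine-readable run manifest.

#' Simulate a scenario and build the genotyped cohort
#'
#' Runs [run_scenario()], [draw_sample()] and [build_genotype_matrix()].
#'
#' @param scenario A [scenario_config()] (or a YAML path/string for
#'   [parse_scenario()]).
#' @param seed Master seed (defaults to the scenario's).
#' @param maf_min MAF filter for the genotype matrix.
#' @param n_chromosomes Optional override of the pooled chromosome count.
#' @return A list with `run` (`sim_run`), `cohort` and `gm`
#'   (`genotype_matrix`).
#' @export
simulate_cohort <- function(scenario, seed = NULL, maf_min = 0.05,
                            n_chromosomes = NULL) {
  if (!inherits(scenario, "scenario_config"))
    scenario <- parse_scenario(scenario)
  if (is.null(seed)) seed <- scenario$seed
  if (is.null(n_chromosomes))
    n_chromosomes <- scenario$genome$n_chromosomes
  run <- run_scenario(scenario, seed = seed, n_chromosomes = n_chromosomes)
  cohort <- draw_sample(run, seed = seed + 1L)
  gm <- build_genotype_matrix(cohort, maf_min = maf_min)
  list(run = run, cohort = cohort, gm = gm)
}

#' Simulate and write PED/MAP (and optionally VCF) files
#'
#' @param scenario A [scenario_config()] or YAML path.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param scale Desk-scale factor applied with [rescale_scenario()] before
#'   simulating (1 = no rescaling).
#' @param maf_min MAF filter.
#' @param mask_inversion Discard SNPs inside the scenario's inversion
#'   interval before writing.
#' @param vcf Also write a VCF file.
#' @param prefix Output file prefix (default `"cohort"`).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
simulate_to_files <- function(scenario, out_dir, seed = NULL, scale = 1,
                              maf_min = 0.05, mask_inversion = FALSE,
                              vcf = FALSE, prefix = "cohort") {
  if (!inherits(scenario, "scenario_config"))
    scenario <- parse_scenario(scenario)
  if (scale > 1) scenario <- rescale_scenario(scenario, scale)
  if (is.null(seed)) seed <- scenario$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(scenario, seed = seed, maf_min = maf_min)
  gm <- sim$gm
  if (mask_inversion) {
    if (is.null(scenario$inversion))
      stop("mask_inversion requested but the scenario has no inversion")
    gm <- mask_region(gm, c(scenario$inversion$start_bp,
                            scenario$inversion$end_bp))
  }
  paths <- write_ped_map(gm, file.path(out_dir, prefix))
  if (vcf) {
    vp <- file.path(out_dir, paste0(prefix, ".vcf"))
    write_vcf(gm, vp, contig_length_bp = scenario$genome$sequence_length_bp)
    paths <- c(paths, vcf = vp)
  }
  man <- write_manifest(out_dir, scenario, seed, as.list(paths),
                        stage = "simulate")
  invisible(man)
}

#' Estimate an Ne trajectory from genotype files
#'
#' @param input Path prefix of a PED/MAP pair, or a `.vcf` path, or a
#'   `genotype_matrix`.
#' @param cfg An [estimator_config()].
#' @param out Optional output TSV path for the trajectory.
#' @param reference Optional `nevk_reference`.
#' @param map_rate Morgan/bp used when reading a VCF.
#' @return An `ne_trajectory`.
#' @export
estimate_from_files <- function(input, cfg = estimator_config(), out = NULL,
                                reference = NULL, map_rate = 1e-8) {
  gm <- if (inherits(input, "genotype_matrix")) input
  else if (grepl("\\.vcf$", input)) read_vcf(input, map_rate = map_rate)
  else read_ped_map(input)
  traj <- estimate_ne(gm, cfg, reference = reference)
  if (!is.null(out)) write_trajectory(traj, out)
  traj
}

#' Windowed comparison of a trajectory against its NeVk baseline
#'
#' Summarizes the trajectory over the recent (t <= 20), mid
#' (20 < t <= 100) and ancestral (t > 100) windows: median estimated Ne,
#' the expected NeVk lines, and their log-ratios.
#'
#' @param traj An `ne_trajectory`.
#' @param reference An `nevk_reference` (may be omitted if the trajectory
#'   already carries `expected_nevk` columns).
#' @return A data frame with one row per non-empty window.
#' @export
report_windows <- function(traj, reference = NULL) {
  if (!nrow(traj)) stop("empty trajectory")
  if (is.null(traj$expected_nevk)) {
    if (is.null(reference))
      stop("no NeVk reference available for the report")
    traj$expected_nevk <- nevk_at(reference, traj$t, "total")
    traj$expected_nevk_focal <- nevk_at(reference, traj$t, "focal")
  }
  wins <- list(recent = c(0, 20), mid = c(20, 100),
               ancestral = c(100, Inf))
  rows <- lapply(names(wins), function(w) {
    lim <- wins[[w]]
    sel <- traj$t > lim[1] & traj$t <= lim[2]
    if (!any(sel)) return(NULL)
    med <- stats::median(traj$Ne_hat[sel])
    nev_t <- stats::median(traj$expected_nevk[sel], na.rm = TRUE)
    nev_f <- stats::median(traj$expected_nevk_focal[sel], na.rm = TRUE)
    data.frame(window = w, t_min = min(traj$t[sel]),
               t_max = max(traj$t[sel]), n_bins = sum(sel),
               median_ne_hat = med,
               nevk_total = nev_t, nevk_focal = nev_f,
               log_ratio_total = log(med / nev_t),
               log_ratio_focal = log(med / nev_f))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline for a scenario
#'
#' Simulates, samples, estimates, optionally applies the two remedies
#' (inversion masking, structure-restricted estimation), writes the
#' trajectory, report and manifest, and returns everything in memory.
#'
#' @param scenario A [scenario_config()] or YAML path.
#' @param out_dir Optional output directory; when given, the trajectory
#'   TSV, PCA TSV, report TSV and `manifest.json` are written there.
#' @param seed Master seed.
#' @param scale Desk-scale factor applied before simulating.
#' @param cfg An [estimator_config()].
#' @param maf_min MAF filter.
#' @param mask_inversion Apply [mask_region()] over the inversion interval.
#' @param restrict_group If non-`NULL`, run [genotype_pca()] +
#'   [assign_groups()] and restrict estimation to this group label.
#' @return A list with `scenario`, `gm`, `trajectory`, `report`,
#'   `reference`, and (when computed) `pca`, `labels`.
#' @export
run_pipeline <- function(scenario, out_dir = NULL, seed = NULL, scale = 1,
                         cfg = estimator_config(), maf_min = 0.05,
                         mask_inversion = FALSE, restrict_group = NULL) {
  if (!inherits(scenario, "scenario_config"))
    scenario <- parse_scenario(scenario)
  if (scale > 1) scenario <- rescale_scenario(scenario, scale)
  if (is.null(seed)) seed <- scenario$seed
  sim <- simulate_cohort(scenario, seed = seed, maf_min = maf_min)
  gm <- sim$gm
  if (mask_inversion) {
    if (is.null(scenario$inversion))
      stop("mask_inversion requested but the scenario has no inversion")
    gm <- mask_region(gm, c(scenario$inversion$start_bp,
                            scenario$inversion$end_bp))
  }
  reference <- expected_nevk(scenario)
  res <- list(scenario = scenario, gm = gm, reference = reference)
  if (!is.null(restrict_group)) {
    res$pca <- genotype_pca(gm, k = 4L)
    res$labels <- assign_groups(res$pca, n_groups = 2L, seed = seed)
    res$trajectory <- restrict_and_reestimate(
      gm, res$labels, restrict_group, cfg, maf_min = maf_min,
      reference = reference)
  } else {
    res$trajectory <- estimate_ne(gm, cfg, reference = reference)
  }
  res$report <- report_windows(res$trajectory, reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(trajectory = file.path(out_dir, "trajectory.tsv"),
                  report = file.path(out_dir, "report.tsv"))
    write_trajectory(res$trajectory, paths$trajectory)
    utils::write.table(res$report, paths$report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(res$pca)) {
      paths$pca <- file.path(out_dir, "pca.tsv")
      write_pca(res$pca, res$labels, paths$pca)
    }
    res$manifest <- write_manifest(out_dir, scenario, seed, paths,
                                   stage = "pipeline")
  }
  res
}

# ---------------------------------------------------------------------------
# Manifest

# canonical JSON (keys sorted recursively) -> md5, so the hash is stable
# under key reordering
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && any(nzchar(names(v))))
        v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon(rapply(list(x), unclass, how = "replace")[[1]]),
                       tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records the resolved scenario (and its canonical-JSON md5 hash, stable
#' under key reordering), the master seed, the output paths, the package
#' version and a timestamp as `manifest.json` in `out_dir`.
#'
#' @param out_dir Output directory.
#' @param scenario The resolved `scenario_config`.
#' @param seed Master seed used.
#' @param paths Named list of files the run wrote.
#' @param stage Pipeline stage name.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(out_dir, scenario, seed, paths,
                           stage = "pipeline") {
  man <- list(stage = stage,
              scenario_family = scenario$family,
              config_hash = config_hash(scenario),
              seed = seed,
              outputs = lapply(paths, normalizePath, mustWork = FALSE),
              package_version =
                as.character(utils::packageVersion("ldnesim")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
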