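RUN_CONFIG_KEYS <- c("seed", "outdir", "stacks_dir", "layout_csv", "simulate",
                     "analysis", "simulation")
ANALYSIS_KEYS <- c("responsiveness_threshold", "hit_cutoff", "zprime_variant",
                   "min_responsive_cells", "artifact_k_sd", "artifact_f_count",
                   "background_policy", "max_radius_px", "min_area_px",
                   "smoothing_sigma")

#' Build and validate a run configuration
#'
#' A `run_config` holds paths, analysis parameters and (optionally) a
#' simulation block. Unknown keys are rejected; the seed is mandatory. The
#' configuration round-trips losslessly through YAML ([read_run_config] /
#' [write_run_config]).
#'
#' @param seed integer seed (mandatory).
#' @param outdir output directory.
#' @param stacks_dir directory of per-well TIFF stacks (NULL when simulating).
#' @param layout_csv layout path (NULL when simulating, the simulated layout
#'   is used).
#' @param simulate logical: generate the plate instead of reading stacks.
#' @param analysis named list of analysis parameters (subset of:
#'   responsiveness_threshold, hit_cutoff, zprime_variant,
#'   min_responsive_cells, artifact_k_sd, artifact_f_count,
#'   background_policy, max_radius_px, min_area_px, smoothing_sigma).
#' @param simulation named list passed to [sim_params], plus optional
#'   `n_compounds`, `replicates`, `suppression` (named vector or list).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed, outdir = tempfile("fretscreen_run_"),
                       stacks_dir = NULL, layout_csv = NULL, simulate = TRUE,
                       analysis = list(), simulation = list()) {
  if (missing(seed) || is.null(seed)) stop("config is missing `seed`")
  unknown <- setdiff(names(analysis), ANALYSIS_KEYS)
  if (length(unknown)) stop("unknown analysis key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(responsiveness_threshold = 0.1, hit_cutoff = 0.9,
                   zprime_variant = "canonical", min_responsive_cells = 20L,
                   artifact_k_sd = 5, artifact_f_count = 0.3,
                   background_policy = "field", max_radius_px = 10,
                   min_area_px = 20, smoothing_sigma = 1)
  analysis <- utils::modifyList(defaults, analysis)
  if (analysis$responsiveness_threshold <= 0 || analysis$hit_cutoff <= 0)
    stop("thresholds must be positive")
  structure(list(seed = as.integer(seed), outdir = outdir,
                 stacks_dir = stacks_dir, layout_csv = layout_csv,
                 simulate = isTRUE(simulate), analysis = analysis,
                 simulation = simulation),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output YAML file.
#' @return `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full screening pipeline on one plate
#'
#' Executes simulate (optional) -> segmentation -> trace analysis -> plate
#' normalization -> replicate aggregation -> artifact filtering -> hit
#' calling -> Z'-factor QC, writes the result CSVs and a JSON run manifest
#' (config hash, seed, package version, per-plate Z', hit list) to
#' `config$outdir`, and returns the tables. Re-running the same config and
#' seed reproduces the outputs. Any stage failure aborts with the stage
#' name (and well context where applicable).
#'
#' @param config a `run_config` (or path to a YAML config).
#' @return list: `well_results`, `normalized`, `screen_table`, `plate_qc`,
#'   `hits`, `manifest_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  an <- config$analysis
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (config$simulate) {
    sim <- config$simulation
    n_compounds <- sim$n_compounds %||% 8L
    replicates <- sim$replicates %||% 4L
    supp <- sim$suppression
    if (is.list(supp)) supp <- unlist(supp)
    sp_args <- sim[setdiff(names(sim), c("n_compounds", "replicates", "suppression",
                                         "n_dmso", "n_tp", "n_untreated"))]
    params <- stage("simulate", do.call(sim_params, sp_args))
    compound_ids <- names(supp) %||% sprintf("CPD%03d", seq_len(n_compounds))
    layout <- stage("simulate", plate_layout(
      compound_ids, replicates = replicates,
      n_dmso = sim$n_dmso %||% 8L, n_tp = sim$n_tp %||% 8L,
      n_untreated = sim$n_untreated %||% 2L, n_cpa = 0L, n_tmb8 = 0L))
    well_rows <- list()
    stage("simulate/analyze", simulate_plate(
      layout, params, seed = config$seed, compound_suppression = supp,
      keep_stacks = FALSE, sink = function(st) {
        well_rows[[st$well_id]] <<- analyze_well(
          st, threshold = an$responsiveness_threshold,
          min_responsive_cells = an$min_responsive_cells,
          background_policy = an$background_policy,
          min_area_px = an$min_area_px, smoothing_sigma = an$smoothing_sigma,
          max_radius_px = an$max_radius_px)
      }))
    well_results <- do.call(rbind, well_rows[layout$well_id])
  } else {
    if (is.null(config$layout_csv) || is.null(config$stacks_dir))
      stop("stage 'input' failed: need `layout_csv` and `stacks_dir` when simulate = FALSE")
    layout <- stage("input", read_layout(config$layout_csv))
    well_results <- do.call(rbind, lapply(layout$well_id, function(wid) {
      st <- stage(paste0("read/", wid),
                  read_stack(file.path(config$stacks_dir, paste0(wid, ".tif"))))
      stage(paste0("analyze/", wid), analyze_well(
        st, threshold = an$responsiveness_threshold,
        min_responsive_cells = an$min_responsive_cells,
        background_policy = an$background_policy,
        min_area_px = an$min_area_px, smoothing_sigma = an$smoothing_sigma,
        max_radius_px = an$max_radius_px))
    }))
  }

  normalized <- stage("normalize", normalize_to_dmso(well_results, layout))
  screen_table <- stage("aggregate", aggregate_replicates(normalized))
  if (nrow(screen_table)) {
    screen_table <- stage("artifacts", flag_artifacts(
      normalized, screen_table, k_sd = an$artifact_k_sd,
      f_count = an$artifact_f_count))
    screen_table <- stage("hits", call_hits(screen_table, cutoff = an$hit_cutoff))
  }
  # plate QC uses the all-cell mean peak (suppressed positive-control wells
  # rarely clear the responsive-cell QC floor), normalized to the DMSO mean
  dmso_all <- normalized$mean_peak_all[normalized$role == "DMSO"]
  ref_all <- mean(dmso_all, na.rm = TRUE)
  tp_vals <- normalized$mean_peak_all[normalized$role == "TP"] / ref_all
  dmso_vals <- dmso_all / ref_all
  qc <- stage("qc", zprime(tp_vals[!is.na(tp_vals)], dmso_vals[!is.na(dmso_vals)],
                           plate_id = "plate1"))

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_results(list(well_results = well_results, screen_table = screen_table,
                     plate_qc = qc), config$outdir, config_hash = hash)
  hits <- if (nrow(screen_table)) screen_table$compound_id[screen_table$hit] else character(0)
  manifest <- list(
    config_hash = hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("fretscreen")),
    n_wells = nrow(well_results),
    zprime = if (identical(an$zprime_variant, "as_printed"))
      qc$zprime_as_printed else qc$zprime_canonical,
    zprime_variant = an$zprime_variant,
    hits = hits)
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  list(well_results = well_results, normalized = normalized,
       screen_table = screen_table, plate_qc = qc, hits = hits,
       manifest_path = manifest_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
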