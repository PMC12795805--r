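#' Run one of the two standard experiments end to end
#'
#' Orchestrates enumerate grid -> baseline sweep -> perturbation
#' experiment -> EI-ratio analysis, and writes a CSV/JSON result bundle
#' plus a manifest. `"stn-gpe-sweep"` perturbs with a 600 spikes/s
#' inhibitory drive onto GPe; `"cortex-sweep"` raises the inhibition ratio
#' from g = 4 to 8 and 12.
#'
#' The `"mini"` preset is the desk-scale protocol (3 values per swept
#' parameter, 3 trials, reduced populations); `"full"` is the full
#' protocol (5 values per STN-GPe parameter, 625 configurations, 25
#' trials, full populations).
#'
#' @param name `"stn-gpe-sweep"` or `"cortex-sweep"`
#' @param preset `"mini"` or `"full"`
#' @param master_seed integer master seed
#' @param out_dir output directory (created if absent); `NULL` to skip
#'   writing
#' @param n_trials trials per configuration (default from the preset)
#' @param verbose print progress?
#' @return list with `baseline`, `perturbation` (records, histogram,
#'   perturbed summaries), `ei` (EI-ratio analysis), `manifest`
#' @export
run_experiment <- function(name = c("stn-gpe-sweep", "cortex-sweep"),
                           preset = c("mini", "full"), master_seed = 1,
                           out_dir = NULL, n_trials = NULL, verbose = FALSE) {
  name <- match.arg(name)
  preset <- match.arg(preset)
  motif <- if (name == "stn-gpe-sweep") "stn_gpe" else "cortex"
  if (is.null(n_trials)) n_trials <- if (preset == "mini") 3 else 25
  sizes <- preset_sizes(motif, preset)
  t0 <- Sys.time()

  if (motif == "stn_gpe") {
    grid_df <- enumerate_grid(stn_gpe_grid(preset))
    baseline <- run_sweep(grid_df, motif, sizes, n_trials = n_trials,
                          master_seed = master_seed, verbose = verbose)
    baseline$condition <- "baseline"
    pe <- perturbation_experiment(baseline, grid_df, motif, sizes,
                                  perturb_rate = 600, n_trials = n_trials,
                                  master_seed = master_seed)
  } else {
    grid <- cortex_grid(preset)
    grid$g <- 4   # baseline condition; perturbation raises g
    grid_df <- enumerate_grid(grid)
    baseline <- run_sweep(grid_df, motif, sizes, n_trials = n_trials,
                          master_seed = master_seed, verbose = verbose)
    baseline$condition <- "baseline"
    pe <- perturbation_experiment(baseline, grid_df, motif, sizes,
                                  g_to = c(8, 12), n_trials = n_trials,
                                  master_seed = master_seed)
  }
  ei <- ei_ratio_analysis(rbind(baseline, pe$perturbed))

  manifest <- list(
    experiment = name, preset = preset, motif = motif,
    master_seed = master_seed, n_trials = n_trials,
    n_configurations = nrow(grid_df),
    sizes = as.list(sizes),
    package_version = as.character(utils::packageVersion("eislope")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = list())

  res <- list(baseline = baseline, perturbation = pe, ei = ei,
              manifest = manifest)
  if (!is.null(out_dir)) write_result_bundle(res, out_dir)
  res
}

#' Write an experiment result bundle
#'
#' Plain CSV for the summary tables and transition records, JSON for the
#' angle histogram, correlations and the manifest. Every output file is
#' listed in the manifest.
#'
#' @param res result of [run_experiment]
#' @param out_dir directory
#' @export
write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(baseline = "baseline_summaries.csv",
             perturbed = "perturbed_summaries.csv",
             transitions = "transition_records.csv",
             histogram = "angle_histogram.json",
             ei = "ei_ratio_table.csv",
             correlations = "ei_correlations.json",
             manifest = "manifest.json")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write.csv(res$baseline, paths["baseline"], row.names = FALSE)
  write.csv(res$perturbation$perturbed, paths["perturbed"], row.names = FALSE)
  write.csv(res$perturbation$records, paths["transitions"], row.names = FALSE)
  jsonlite::write_json(res$perturbation$histogram, paths["histogram"],
                       digits = NA)
  write.csv(res$ei$table, paths["ei"], row.names = FALSE)
  jsonlite::write_json(res$ei$correlations, paths["correlations"],
                       digits = NA)
  res$manifest$outputs <- as.list(setNames(unname(files), names(files)))
  jsonlite::write_json(res$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a result-bundle manifest
#' @param out_dir bundle directory
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"), simplifyVector = TRUE)
}
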