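#' Trial-averaged summary of one network configuration
#'
#' Simulates `n_trials` trials of the configuration (default protocol:
#' 1700 ms per trial, analysis on the last 1000 ms), analyzes each trial's
#' spectrum, and averages the oscillation index, the aperiodic exponent,
#' the fit quality and the mean conductances across valid trials. Wiring
#' is held fixed across trials (one wiring stream per configuration);
#' trial k varies the initial-condition and drive streams.
#'
#' Trials whose aperiodic fit did not converge or had R-squared below
#' `min_r2` are excluded from the averages; their count is reported.
#'
#' @param config a [network_config]
#' @param n_trials number of trials (25 in the full protocol)
#' @param master_seed integer master seed for [seed_streams]
#' @param duration_ms trial length (ms)
#' @param skip_ms initial transient discarded from analysis (ms)
#' @param min_r2 fit-quality floor below which a trial is excluded
#' @param ... further arguments to [analyze_trial]
#' @return one-row data.frame (class `state_summary`): grid coordinates,
#'   `OI_avg`, `gamma_avg`, `gamma_sd`, `mean_R2`, `G_ex`, `G_in`,
#'   `EI_ratio`, per-population mean rates, `n_valid_trials`,
#'   `n_excluded`, `flagged`
#' @export
run_configuration <- function(config, n_trials = 25, master_seed = 1,
                              duration_ms = 1700, skip_ms = 700, min_r2 = 0.5,
                              ...) {
  stopifnot(n_trials >= 1)
  wiring <- wire_network(config, seed_streams(master_seed)$wiring)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    trials[[k]] <- tryCatch({
      sim <- simulate_network(config, duration_ms = duration_ms,
                              seeds = seed_streams(master_seed, k),
                              wiring = wiring)
      analyze_trial(sim, skip_ms = skip_ms, ...)
    }, error = function(e) NULL)
  }
  ok <- !vapply(trials, is.null, TRUE)
  valid <- vapply(trials, function(tr)
    !is.null(tr) && isTRUE(tr$converged) && is.finite(tr$fit_R2) &&
      tr$fit_R2 >= min_r2, TRUE)
  use <- trials[valid]
  avg <- function(field) if (length(use)) mean(vapply(use, `[[`, 0, field)) else NA_real_
  rates <- if (length(use))
    colMeans(do.call(rbind, lapply(use, `[[`, "rates"))) else
    setNames(rep(NA_real_, length(config$populations)), names(config$populations))
  coords <- as.data.frame(config$meta$coords %||% list())
  out <- cbind(coords, data.frame(
    OI_avg = avg("OI"), gamma_avg = avg("gamma"),
    gamma_sd = if (length(use) > 1)
      sd(vapply(use, `[[`, 0, "gamma")) else NA_real_,
    mean_R2 = avg("fit_R2"),
    G_ex = avg("G_ex"), G_in = avg("G_in"), EI_ratio = avg("EI_ratio"),
    n_valid_trials = sum(valid), n_excluded = sum(ok) - sum(valid),
    flagged = sum(valid) == 0))
  for (p in names(rates)) out[[paste0("rate_", p)]] <- rates[[p]]
  class(out) <- c("state_summary", class(out))
  out
}

#' Classify a network state into activity regimes
#'
#' Oscillation regime: low for `OI_avg <= 0.4`, high for `OI_avg > 0.6`,
#' intermediate in the gap (excluded from regime-conditioned analyses).
#' Exponent regime: high for `gamma_avg >= 3`, low otherwise.
#'
#' @param OI_avg trial-averaged oscillation index (or a `state_summary`)
#' @param gamma_avg trial-averaged aperiodic exponent
#' @return list with `oscillation` in `{"low","intermediate","high"}` and
#'   `exponent` in `{"low","high"}`
#' @export
classify_state <- function(OI_avg, gamma_avg = NULL) {
  if (inherits(OI_avg, "state_summary")) {
    gamma_avg <- OI_avg$gamma_avg
    OI_avg <- OI_avg$OI_avg
  }
  osc <- if (is.na(OI_avg)) NA_character_
         else if (OI_avg <= 0.4) "low"
         else if (OI_avg > 0.6) "high"
         else "intermediate"
  expn <- if (is.null(gamma_avg) || is.na(gamma_avg)) NA_character_
          else if (gamma_avg >= 3) "high" else "low"
  list(oscillation = osc, exponent = expn)
}

#' Transition record between a baseline and a perturbed state
#'
#' Direction of the displacement of the `(OI_avg, gamma_avg)` state under
#' a perturbation: the angle of the line joining the two states, with
#' `delta OI` on the abscissa and `delta gamma` on the ordinate, mapped to
#' `[0, 360)` degrees. An increase in both lands in (0, 90); an increase
#' in OI with a decrease in gamma lands in (270, 360).
#'
#' @param base,pert `state_summary` rows with identical grid coordinates
#' @param normalized also compute the angle after min-max normalization of
#'   the two axes over a cohort? Supply `oi_range` / `gamma_range` for
#'   that; raw-unit angle is always reported.
#' @param oi_range,gamma_range optional `c(min, max)` cohort ranges
#' @return one-row data.frame (class `transition_record`): coordinates,
#'   baseline and perturbed `(OI, gamma)`, `dOI`, `dgamma`, `angle`
#'   (degrees), `angle_norm` (or NA), `quadrant`, `undefined`
#' @export
transition_angle <- function(base, pert, oi_range = NULL, gamma_range = NULL) {
  coord_cols <- setdiff(names(base),
                        c("OI_avg", "gamma_avg", "gamma_sd", "mean_R2", "G_ex",
                          "G_in", "EI_ratio", "n_valid_trials", "n_excluded",
                          "flagged", grep("^rate_", names(base), value = TRUE)))
  bc <- base[coord_cols]; rownames(bc) <- NULL
  pc <- pert[coord_cols]; rownames(pc) <- NULL
  if (!isTRUE(all.equal(bc, pc, check.attributes = FALSE)))
    stop("baseline and perturbed summaries have different coordinates")
  doi <- pert$OI_avg - base$OI_avg
  dg <- pert$gamma_avg - base$gamma_avg
  undefined <- (doi == 0 && dg == 0) || is.na(doi) || is.na(dg)
  ang <- if (undefined) NA_real_ else (atan2(dg, doi) * 180 / pi) %% 360
  ang_norm <- NA_real_
  if (!undefined && !is.null(oi_range) && !is.null(gamma_range)) {
    ndoi <- doi / diff(oi_range)
    ndg <- dg / diff(gamma_range)
    ang_norm <- (atan2(ndg, ndoi) * 180 / pi) %% 360
  }
  quad <- if (undefined) NA_character_ else
    paste0("dOI", if (doi >= 0) "+" else "-", "_dg", if (dg >= 0) "+" else "-")
  out <- cbind(base[coord_cols],
               data.frame(OI_base = base$OI_avg, gamma_base = base$gamma_avg,
                          OI_pert = pert$OI_avg, gamma_pert = pert$gamma_avg,
                          dOI = doi, dgamma = dg, angle = ang,
                          angle_norm = ang_norm, quadrant = quad,
                          undefined = undefined))
  class(out) <- c("transition_record", class(out))
  out
}

#' Binned histogram of transition directions
#'
#' Radar-plot data: counts of transition angles in `n_bins` equal bins of
#' `[0, 360)` degrees (default 16 bins of 22.5 degrees). Undefined
#' transitions are dropped; counts over defined records are conserved.
#'
#' @param records data.frame of [transition_angle] rows
#' @param n_bins number of angular bins
#' @return data.frame with `bin_lo`, `bin_hi`, `count`
#' @export
angle_histogram <- function(records, n_bins = 16) {
  a <- records$angle[!records$undefined & !is.na(records$angle)]
  edges <- seq(0, 360, length.out = n_bins + 1)
  counts <- tabulate(findInterval(a, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1], count = counts)
}

#' Run a sweep of configurations
#'
#' Summarizes every row of an enumerated grid with [run_configuration].
#' `modify` (optional) transforms each configuration before simulation —
#' this is how perturbed conditions reuse the same grid and seeds.
#'
#' @param grid_df output of [enumerate_grid]
#' @param motif `"stn_gpe"` or `"cortex"`
#' @param sizes population sizes
#' @param n_trials trials per configuration
#' @param master_seed master seed; configuration i uses
#'   `master_seed + i - 1` so the same grid row gets the same seeds in
#'   every condition
#' @param modify optional function `config -> config`
#' @param builder_args list of extra arguments for the config builder
#' @param verbose print progress?
#' @param ... passed to [run_configuration]
#' @return data.frame of `state_summary` rows (one per configuration)
#' @export
run_sweep <- function(grid_df, motif, sizes, n_trials = 3, master_seed = 1,
                      modify = NULL, builder_args = list(), verbose = FALSE,
                      ...) {
  rows <- lapply(seq_len(nrow(grid_df)), function(i) {
    row <- grid_df[i, ]
    cfg <- do.call(config_from_row,
                   c(list(row = row, motif = motif, sizes = sizes),
                     builder_args))
    if (!is.null(modify)) cfg <- modify(cfg)
    s <- run_configuration(cfg, n_trials = n_trials,
                           master_seed = master_seed + i - 1, ...)
    s$config_id <- row$config_id
    if (verbose && i %% 10 == 0) message("  config ", i, "/", nrow(grid_df))
    s
  })
  do.call(rbind, rows)
}

#' Perturbation experiment over a summarized grid
#'
#' For the STN-GPe motif, re-runs every configuration with an additional
#' inhibitory Poisson drive onto GPe (default 600 spikes/s); for the
#' cortex motif, re-runs with the inhibition ratio raised from the
#' baseline `g = 4` to each value in `g_to`. Baseline and perturbed runs
#' of a configuration share seeds, so differences are due to the
#' perturbation alone. Emits transition records and the binned direction
#' histogram.
#'
#' @param baseline data.frame of baseline `state_summary` rows (from
#'   [run_sweep])
#' @param grid_df the enumerated grid the baseline was run on
#' @param motif `"stn_gpe"` or `"cortex"`
#' @param sizes population sizes
#' @param perturb_rate inhibitory drive onto GPe (spikes/s; STN-GPe motif)
#' @param g_to vector of perturbed `g` values (cortex motif)
#' @param n_trials,master_seed,... as in [run_sweep] (must match the
#'   baseline run)
#' @return list with `records` (transition data.frame), `histogram`,
#'   `perturbed` (summaries)
#' @export
perturbation_experiment <- function(baseline, grid_df, motif, sizes,
                                    perturb_rate = 600, g_to = c(8, 12),
                                    n_trials = 3, master_seed = 1, ...) {
  records <- NULL
  perturbed_all <- NULL
  if (motif == "stn_gpe") {
    pert <- run_sweep(grid_df, motif, sizes, n_trials = n_trials,
                      master_seed = master_seed,
                      builder_args = list(perturb_rate = perturb_rate), ...)
    pert$condition <- paste0("inh", perturb_rate)
    perturbed_all <- pert
    for (i in seq_len(nrow(grid_df))) {
      rec <- transition_angle(baseline[i, setdiff(names(baseline), "condition")],
                              pert[i, setdiff(names(pert), "condition")])
      rec$condition <- pert$condition[1]
      records <- rbind(records, rec)
    }
  } else if (motif == "cortex") {
    if (!all(baseline$g == 4)) stop("cortex baseline must be the g = 4 state")
    for (gv in g_to) {
      gdf <- grid_df
      gdf$g <- gv
      pert <- run_sweep(gdf, motif, sizes, n_trials = n_trials,
                        master_seed = master_seed, ...)
      pert$condition <- paste0("g", gv)
      perturbed_all <- rbind(perturbed_all, pert)
      for (i in seq_len(nrow(gdf))) {
        b <- baseline[i, setdiff(names(baseline), "condition")]
        p <- pert[i, setdiff(names(pert), "condition")]
        p$g <- 4   # transitions are indexed by the baseline coordinates
        rec <- transition_angle(b, p)
        rec$condition <- paste0("g", gv)
        records <- rbind(records, rec)
      }
    }
  } else stop("unknown motif: ", motif)
  list(records = records, histogram = angle_histogram(records),
       perturbed = perturbed_all)
}

#' Min-max normalization over a cohort
#'
#' `(x - min) / (max - min)`: the cohort minimum maps to 0, the maximum to
#' 1, affine in between.
#' @param x value(s) to normalize
#' @param cohort values defining the range (defaults to `x`)
#' @export
normalize_param <- function(x, cohort = x) {
  rng <- range(cohort, na.rm = TRUE)
  if (diff(rng) == 0) stop("constant cohort: min equals max")
  (x - rng[1]) / diff(rng)
}

#' EI-conductance-ratio analysis
#'
#' Scatter-ready table of `(EI_ratio, gamma_avg)` per condition, plus the
#' Spearman rank correlation between the two, per condition and pooled.
#' Summaries with non-finite EI ratio (zero inhibitory conductance) are
#' flagged and excluded from the correlations.
#'
#' @param summaries data.frame of `state_summary` rows; a `condition`
#'   column distinguishes baseline from perturbed states (rows without one
#'   are labelled "baseline")
#' @return list with `table` (EI_ratio, gamma_avg, condition, excluded)
#'   and `correlations` (condition, rho, p, n)
#' @export
ei_ratio_analysis <- function(summaries) {
  if (is.null(summaries$condition)) summaries$condition <- "baseline"
  tab <- data.frame(EI_ratio = summaries$EI_ratio,
                    gamma_avg = summaries$gamma_avg,
                    condition = summaries$condition)
  tab$excluded <- !is.finite(tab$EI_ratio) | !is.finite(tab$gamma_avg)
  ok <- tab[!tab$excluded, ]
  corr_one <- function(d, label) {
    if (nrow(d) < 3)
      return(data.frame(condition = label, rho = NA_real_, p = NA_real_,
                        n = nrow(d)))
    ct <- suppressWarnings(cor.test(d$EI_ratio, d$gamma_avg,
                                    method = "spearman"))
    data.frame(condition = label, rho = unname(ct$estimate),
               p = ct$p.value, n = nrow(d))
  }
  cors <- do.call(rbind, c(
    lapply(split(ok, ok$condition), function(d) corr_one(d, d$condition[1])),
    list(corr_one(ok, "pooled"))))
  rownames(cors) <- NULL
  list(table = tab, correlations = cors)
}
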