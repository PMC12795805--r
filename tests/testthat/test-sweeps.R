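fake_summary <- function(oi, gamma, id = 1) {
  data.frame(config_id = id, OI_avg = oi, gamma_avg = gamma)
}

test_that("single-trial configuration summaries equal the trial analysis", {
  cfg <- build_stn_gpe(sizes = preset_sizes("stn_gpe", "mini"))
  s <- run_configuration(cfg, n_trials = 1, master_seed = 5)
  wiring <- wire_network(cfg, seed_streams(5)$wiring)
  sim <- simulate_network(cfg, seeds = seed_streams(5, 1), wiring = wiring)
  a <- analyze_trial(sim)
  expect_equal(s$OI_avg, a$OI)
  expect_equal(s$gamma_avg, a$gamma)
  expect_equal(s$mean_R2, a$fit_R2)
  expect_equal(s$EI_ratio, a$EI_ratio)
  expect_equal(s$n_valid_trials, 1)

  s2 <- run_configuration(cfg, n_trials = 1, master_seed = 5)
  expect_identical(s, s2)
})

test_that("trial-to-trial exponent variability is finite and reported", {
  cfg <- build_stn_gpe(sizes = preset_sizes("stn_gpe", "mini"))
  s <- run_configuration(cfg, n_trials = 3, master_seed = 2)
  expect_true(is.finite(s$gamma_sd))
  expect_gt(s$gamma_sd, 0)
  expect_equal(s$n_valid_trials + s$n_excluded, 3)
})

test_that("regime classification follows the published thresholds", {
  # the example non-oscillatory state: OI 0.32, gamma 3.49
  cl <- classify_state(0.32, 3.49)
  expect_equal(cl$oscillation, "low")
  expect_equal(cl$exponent, "high")
  expect_equal(classify_state(0.5, 2)$oscillation, "intermediate")
  expect_equal(classify_state(0.7, 2.9)$oscillation, "high")
  expect_equal(classify_state(0.7, 2.9)$exponent, "low")
  expect_equal(classify_state(0.4, 3)$oscillation, "low")      # boundary
  expect_equal(classify_state(0.4, 3)$exponent, "high")
  expect_equal(classify_state(0.6, 1)$oscillation, "intermediate")
})

test_that("transition angles land in the quadrant their deltas dictate", {
  r1 <- transition_angle(fake_summary(0.2, 3.0), fake_summary(0.5, 3.4))
  expect_gt(r1$angle, 0); expect_lt(r1$angle, 90)
  expect_equal(r1$quadrant, "dOI+_dg+")

  r2 <- transition_angle(fake_summary(0.2, 3.0), fake_summary(0.5, 2.5))
  expect_gt(r2$angle, 270); expect_lt(r2$angle, 360)

  r3 <- transition_angle(fake_summary(0, 3), fake_summary(1, 3))
  expect_equal(r3$angle, 0)

  r4 <- transition_angle(fake_summary(0.3, 3), fake_summary(0.3, 3))
  expect_true(r4$undefined)
  expect_true(is.na(r4$angle))

  expect_error(transition_angle(fake_summary(0.2, 3, id = 1),
                                fake_summary(0.3, 3, id = 2)),
               "coordinates")

  # normalized-axis variant
  r5 <- transition_angle(fake_summary(0.2, 3.0), fake_summary(0.5, 3.4),
                         oi_range = c(0, 1), gamma_range = c(2, 5))
  expect_false(is.na(r5$angle_norm))
})

test_that("the angle histogram conserves defined records", {
  recs <- rbind(
    transition_angle(fake_summary(0.2, 3.0), fake_summary(0.5, 3.4)),
    transition_angle(fake_summary(0.2, 3.0), fake_summary(0.1, 2.4)),
    transition_angle(fake_summary(0.2, 3.0), fake_summary(0.2, 3.0)))
  h <- angle_histogram(recs)
  expect_equal(nrow(h), 16)
  expect_equal(sum(h$count), 2)   # the undefined record is dropped
})

test_that("a null perturbation with identical seeds yields zero deltas", {
  grid <- cortex_grid("mini", g = 4, eta = 1, zeta = 400)
  gdf <- enumerate_grid(grid)
  base <- run_sweep(gdf, "cortex", preset_sizes("cortex", "mini"),
                    n_trials = 1, master_seed = 3)
  pe <- perturbation_experiment(base, gdf, "cortex",
                                preset_sizes("cortex", "mini"),
                                g_to = 4, n_trials = 1, master_seed = 3)
  expect_equal(pe$records$dOI, 0)
  expect_equal(pe$records$dgamma, 0)
})

test_that("min-max normalization maps the cohort onto the unit interval", {
  cohort <- c(0.8, 1.2, 1.5, 1.6, 1.8)
  expect_equal(normalize_param(0.8, cohort), 0)
  expect_equal(normalize_param(1.8, cohort), 1)
  expect_equal(normalize_param(1.3, cohort), 0.5)
  expect_equal(normalize_param(cohort, cohort),
               (cohort - 0.8) / 1)
  expect_error(normalize_param(1, c(2, 2, 2)), "constant")
})

test_that("EI-ratio bookkeeping: trivial ratios, scaling invariance, exclusions", {
  fake <- structure(list(
    t = 1:10 * 100, V = matrix(-60, 10, 2),
    G_ex = matrix(2, 10, 2), G_in = matrix(2, 10, 2),
    record_pop = "N", E_rev = list(N = list(ex = 0, inh = -80))),
    class = "sim_result")
  mc <- mean_conductances(fake, skip_ms = 0)
  expect_equal(mc$EI_ratio, 1)
  fake2 <- fake; fake2$G_ex <- fake$G_ex * 2; fake2$G_in <- fake$G_in * 2
  expect_equal(mean_conductances(fake2, skip_ms = 0)$EI_ratio, 1)

  summ <- data.frame(EI_ratio = c(1, 2, 3, Inf), gamma_avg = c(3, 2, 4, 3),
                     condition = "baseline")
  ei <- ei_ratio_analysis(summ)
  expect_equal(sum(ei$table$excluded), 1)
  expect_equal(ei$correlations$n[ei$correlations$condition == "pooled"], 3)
  expect_true(all(abs(ei$correlations$rho) <= 1, na.rm = TRUE))
})

test_that("a micro-sweep reruns byte-identically from the same master seed", {
  grid <- structure(list(STN_bg = 1900, GPe_bg = 1200, w_STN_GPe = 1.5,
                         w_GPe_STN = -1.3),
                    class = "sweep_grid", motif = "stn_gpe", preset = "micro")
  gdf <- enumerate_grid(grid)
  out <- replicate(2, {
    res <- run_sweep(gdf, "stn_gpe", preset_sizes("stn_gpe", "mini"),
                     n_trials = 2, master_seed = 77)
    p <- tempfile(fileext = ".csv")
    write.csv(res, p, row.names = FALSE)
    md5 <- unname(tools::md5sum(p))
    unlink(p)
    md5
  })
  expect_identical(out[1], out[2])
})
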