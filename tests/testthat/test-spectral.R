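test_that("welch_psd locates a pure tone and is flat for white noise", {
  t <- seq_len(10000) / 1000
  set.seed(1)
  x <- sin(2 * pi * 20 * t) + rnorm(10000, sd = 1e-3)
  ps <- welch_psd(x, fs = 1000)
  expect_equal(ps$freq[which.max(ps$psd)], 19.53125, tolerance = 2)
  expect_equal(diff(ps$freq[1:2]), 1000 / 256)

  set.seed(2)
  w <- rnorm(10000)
  pw <- welch_psd(w, fs = 1000)
  band <- pw$psd[pw$freq >= 5 & pw$freq <= 150]
  expect_lt(max(10 * log10(band / mean(band))), 3)
  expect_gt(min(10 * log10(band / mean(band))), -3)

  expect_error(welch_psd(rnorm(100), fs = 1000), "shorter")
})

test_that("welch_psd conserves power (Parseval over the one-sided density)", {
  set.seed(3)
  x <- rnorm(4096)
  ps <- welch_psd(x, fs = 1000)
  df <- diff(ps$freq[1:2])
  # integral of the density ~ signal variance (detrended segments)
  expect_equal(sum(ps$psd) * df, var(x), tolerance = 0.05)
})

test_that("oscillation index has its exact limits and hand-computed value", {
  freq <- c(10, 20, 30, 40)
  expect_equal(oscillation_index(rep(0.25, 4), band = c(5, 50), freq = freq), 0)
  expect_equal(oscillation_index(c(0, 1, 0, 0), band = c(5, 50), freq = freq), 1)
  # P = (0.5, 0.5, 0, 0): H_s = 0.5, OI = 0.5
  expect_equal(oscillation_index(c(0.5, 0.5, 0, 0), band = c(5, 50),
                                 freq = freq), 0.5)
  expect_error(oscillation_index(rep(0, 4), band = c(5, 50), freq = freq),
               "zero total power")
  expect_error(oscillation_index(c(1, 2), band = c(5, 50), freq = c(10, NA)))
})

test_that("oscillation index stays in [0,1] and grows with peak prominence", {
  set.seed(7)
  freq <- seq(0, 500, by = 1000 / 256)
  for (i in 1:20) {
    p <- runif(length(freq))^2
    oi <- oscillation_index(p, band = c(5, 150), freq = freq)
    expect_gte(oi, 0); expect_lte(oi, 1)
    # adding power to the single largest bin never decreases OI
    idx <- which(freq >= 5 & freq <= 150)
    j <- idx[which.max(p[idx])]
    p2 <- p; p2[j] <- p2[j] * 3
    expect_gte(oscillation_index(p2, band = c(5, 150), freq = freq), oi - 1e-12)
  }
})

test_that("the aperiodic fit is exact on a pure power law and flat noise", {
  freq <- seq(0, 500, by = 1000 / 256)
  p2 <- c(0, 1 / freq[-1]^2)
  ft <- fit_aperiodic(p2, band = c(50, 150), freq = freq)
  expect_equal(ft$gamma, 2, tolerance = 0.01)
  expect_gt(ft$r_squared, 0.999)

  set.seed(4)
  w <- rnorm(60000)
  fw <- fit_aperiodic(welch_psd(w, fs = 1000))
  expect_lt(abs(fw$gamma), 0.1)

  expect_error(fit_aperiodic(p2, band = c(50, 60), freq = freq), "fewer than 8")
})

test_that("an in-band peak is absorbed by the periodic component", {
  x0 <- generate_powerlaw_signal(3, 20000, seed = 21)
  xp <- generate_powerlaw_signal(3, 20000, seed = 21,
                                 peaks = data.frame(center = 80, height = 1,
                                                    width = 3))
  g0 <- fit_aperiodic(welch_psd(x0))$gamma
  gp <- fit_aperiodic(welch_psd(xp))$gamma
  expect_lt(abs(gp - 3), 0.2)
  expect_lt(abs(gp - g0), 0.2)
})

test_that("the LFP proxy implements the conductance-to-current conversion", {
  fake <- structure(list(
    t = 1:4, V = matrix(-60, 4, 1), G_ex = matrix(1, 4, 1),
    G_in = matrix(0, 4, 1), record_pop = "N",
    E_rev = list(N = list(ex = 0, inh = -80))), class = "sim_result")
  lfp <- make_lfp(fake)
  expect_equal(lfp$samples, rep(1 * (-60 - 0), 4))   # G_ex (V - E_ex)
  fake$G_in <- matrix(2, 4, 1)
  lfp2 <- make_lfp(fake)
  expect_equal(lfp2$samples, rep(-60 + 2 * (-60 + 80), 4))
  # zero conductances -> identically zero LFP
  fake$G_ex <- fake$G_in <- matrix(0, 4, 1)
  expect_true(all(make_lfp(fake)$samples == 0))
  expect_error(make_lfp(fake, neuron_ids = 2), "not recorded")
})

test_that("10 recorded neurons give the same spectral slope as a large sample", {
  # sampling homogeneity holds at the published population size, where
  # shared-input correlations are weak; 200 recorded neurons already
  # average the independent noise 20-fold below the 10-neuron proxy
  cfg <- build_stn_gpe(sizes = preset_sizes("stn_gpe", "full"), n_record = 200)
  sim <- simulate_network(cfg, duration_ms = 3700, seeds = seed_streams(12))
  g10 <- fit_aperiodic(welch_psd(trim_lfp(make_lfp(sim, 1:10))))$gamma
  gall <- fit_aperiodic(welch_psd(trim_lfp(make_lfp(sim, 1:200))))$gamma
  expect_lt(abs(g10 - gall), 0.3)
})

test_that("analyze_trial is deterministic and rejects a silent network", {
  cfg <- build_stn_gpe(sizes = preset_sizes("stn_gpe", "mini"))
  sim <- simulate_network(cfg, seeds = seed_streams(8))
  a1 <- analyze_trial(sim)
  a2 <- analyze_trial(sim)
  expect_identical(a1[c("OI", "gamma", "fit_R2")], a2[c("OI", "gamma", "fit_R2")])
  expect_true(a1$OI >= 0 && a1$OI <= 1)

  silent <- toy_config(n = 10)
  sims <- simulate_network(silent, seeds = seed_streams(1))
  expect_error(analyze_trial(sims))
})

test_that("traces and spectra round-trip through their file formats", {
  x <- generate_powerlaw_signal(2, 2048, seed = 5)
  p <- tempfile(fileext = ".csv")
  write_trace_csv(x, p)
  back <- read_trace_csv(p)
  expect_equal(back$samples, x$samples)
  expect_equal(back$fs, x$fs)
  unlink(p)

  ps <- welch_psd(x)
  sr <- structure(list(freq = ps$freq, psd = ps$psd, OI = 0.2, gamma = 2,
                       fit_R2 = 0.99, G_ex = 1, G_in = 2, EI_ratio = 0.5,
                       fit_band = c(50, 150), oi_band = c(5, 150)),
                  class = "spectrum_result")
  pj <- tempfile(fileext = ".json")
  write_spectrum_json(sr, pj)
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(j$metrics$gamma, 2)
  expect_equal(length(j$psd), length(ps$psd))
  unlink(pj)
})
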