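test_that("alpha kernel starts at zero, peaks at tau with g_max/e", {
  expect_equal(alpha_kernel(0, 5), 0)
  expect_equal(alpha_kernel(-3, 5), 0)
  expect_equal(alpha_kernel(5, 5, g_max = 2), 2 * exp(-1))
  # the peak really is at t = tau
  tt <- seq(0, 50, by = 0.01)
  expect_equal(tt[which.max(alpha_kernel(tt, 7))], 7, tolerance = 0.02)
  expect_error(alpha_kernel(1, 0), "tau_syn")
})

test_that("discrete propagation superposes spikes exactly", {
  tau <- 5; gmax <- 1.3
  spikes <- c(10, 17.5)   # multiples of the step so binning is exact
  tr <- alpha_trace(spikes, tau, gmax, duration_ms = 100, step_ms = 0.1)
  closed <- alpha_kernel(tr$t - spikes[1], tau, gmax) +
    alpha_kernel(tr$t - spikes[2], tau, gmax)
  expect_lt(max(abs(tr$g - closed)), 1e-9 * gmax)
})

test_that("fixed in-degree wiring gives exact in-degree, binomial out-degree", {
  set.seed(11)
  adj <- wire_fixed_indegree(2000, 1000, 40)
  expect_true(all(lengths(adj) == 40))
  expect_true(all(vapply(adj, function(a) length(unique(a)), 0L) == 40))
  # mean out-degree ~ in_degree * n_target / n_source within 3 binomial SDs
  out_deg <- tabulate(unlist(adj), nbins = 2000)
  mu <- 40 * 1000 / 2000
  sd3 <- 3 * sqrt(1000 * (40 / 2000) * (1 - 40 / 2000)) / sqrt(2000)
  expect_lt(abs(mean(out_deg) - mu), sd3 + 1e-9)

  expect_length(wire_fixed_indegree(10, 5, 0)[[1]], 0)
  expect_error(wire_fixed_indegree(10, 5, 11), "exceeds")
  # no self-connections within a population
  adj2 <- wire_fixed_indegree(50, 50, 49, same_pop = TRUE)
  expect_true(all(vapply(seq_along(adj2), function(j) !j %in% adj2[[j]], TRUE)))
})

test_that("undriven membrane relaxes to V_rest with tau_m = C_m/g_L", {
  cfg <- toy_config(n = 1)
  sim <- simulate_network(cfg, duration_ms = 200, seeds = seed_streams(42))
  expect_equal(nrow(sim$spikes), 0)
  v <- sim$V[, 1]
  fit <- lm(log(v + 70) ~ sim$t, subset = (v + 70) > 0.5)
  expect_equal(-1 / unname(coef(fit)[2]), 20, tolerance = 0.01)
  expect_equal(v[length(v)], -70, tolerance = 0.01)
})

test_that("constant-current firing matches the closed-form LIF rate", {
  np <- neuron_params(-70, -54, -70, 200, 10, 5, I_ext = 250)
  cfg <- toy_config(n = 1, params = np)
  sim <- simulate_network(cfg, duration_ms = 5000, seeds = seed_streams(1))
  taum <- np$C_m / np$g_L
  isi <- np$t_ref + taum * log((np$I_ext / np$g_L + np$V_rest - np$V_reset) /
                                 (np$I_ext / np$g_L + np$V_rest - np$V_th))
  expect_equal(nrow(sim$spikes) / 5, 1000 / isi, tolerance = 0.01)
})

test_that("identical seed bundle and config give a bit-identical raster", {
  cfg <- build_stn_gpe(sizes = c(STN = 50, GPe = 100))
  s1 <- simulate_network(cfg, duration_ms = 500, seeds = seed_streams(9))
  s2 <- simulate_network(cfg, duration_ms = 500, seeds = seed_streams(9))
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$G_ex, s2$G_ex)
  s3 <- simulate_network(cfg, duration_ms = 500, seeds = seed_streams(10))
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("refractoriness and conductance positivity hold in a driven net", {
  cfg <- build_stn_gpe(sizes = preset_sizes("stn_gpe", "mini"))
  sim <- simulate_network(cfg, duration_ms = 800, seeds = seed_streams(3))
  expect_gt(nrow(sim$spikes), 100)   # actually active
  expect_true(check_sim_result(sim))
  # explicit minimum-ISI check for the busiest neuron
  tab <- table(sim$spikes$id)
  busiest <- as.integer(names(tab)[which.max(tab)])
  tt <- sort(sim$spikes$time[sim$spikes$id == busiest])
  expect_gte(min(diff(tt)), 5)
})

test_that("halving the step shifts single-neuron spike times by < 0.2 ms", {
  np <- neuron_params(-70, -54, -70, 200, 10, 5, I_ext = 300)
  cfg <- toy_config(n = 1, params = np)
  s1 <- simulate_network(cfg, duration_ms = 200, step_ms = 0.1,
                         seeds = seed_streams(1))
  s2 <- simulate_network(cfg, duration_ms = 200, step_ms = 0.05,
                         seeds = seed_streams(1))
  expect_equal(nrow(s1$spikes), nrow(s2$spikes))
  expect_lt(max(abs(s1$spikes$time - s2$spikes$time)), 0.2)
})

test_that("output rate is non-decreasing in excitatory drive rate", {
  rates_in <- c(500, 1000, 2000, 4000, 8000)
  mean_out <- vapply(rates_in, function(r) {
    mean(vapply(1:5, function(s) {
      cfg <- toy_config(n = 1, drives = toy_drive(rate = r, weight = 1))
      sim <- simulate_network(cfg, duration_ms = 1000,
                              seeds = seed_streams(100 + s))
      nrow(sim$spikes)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_out) >= 0))
})

test_that("shot-noise conductance mean follows Campbell's theorem", {
  # unconnected neuron, Poisson 1000/s through a 1 nS alpha synapse (tau 5 ms)
  cfg <- toy_config(n = 1, drives = toy_drive(rate = 1000, weight = 1))
  sim <- simulate_network(cfg, duration_ms = 10000, seeds = seed_streams(5))
  expect_equal(mean(sim$G_ex), 1000 * 1 * 5e-3, tolerance = 0.05)
  expect_true(all(sim$G_ex >= 0))
})

test_that("rk4 agrees with euler on a quiet trajectory", {
  np <- neuron_params(-70, -54, -70, 200, 10, 5, I_ext = 120)
  cfg <- toy_config(n = 1, params = np)
  se <- simulate_network(cfg, duration_ms = 300, seeds = seed_streams(1),
                         method = "euler")
  sr <- simulate_network(cfg, duration_ms = 300, seeds = seed_streams(1),
                         method = "rk4")
  expect_lt(max(abs(se$V - sr$V)), 0.05)
})

test_that("raster round-trips through text and csv", {
  df <- data.frame(time = c(1.2, 5.3, 9.9), id = c(3L, 1L, 2L))
  for (fmt in c("txt", "csv")) {
    p <- tempfile()
    write_raster(df, p, format = fmt)
    back <- read_raster(p, format = fmt)
    expect_equal(back$time, df$time)
    expect_equal(back$id, df$id)
    unlink(p)
  }
})
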