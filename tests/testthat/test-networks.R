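test_that("the STN-GPe builder reproduces the published projection table", {
  cfg <- build_stn_gpe(sizes = c(STN = 1000, GPe = 2000))
  pr <- cfg$projections
  key <- paste(pr$src, pr$tgt)
  expect_setequal(key, c("STN GPe", "GPe STN", "GPe GPe"))  # no STN->STN
  sg <- pr[key == "STN GPe", ]; gs <- pr[key == "GPe STN", ]
  gg <- pr[key == "GPe GPe", ]
  expect_equal(c(sg$in_degree, gs$in_degree, gg$in_degree), c(20, 40, 40))
  expect_equal(c(sg$delay_min, gs$delay_min, gg$delay_min), c(5, 5, 2))
  expect_equal(c(sg$weight, gs$weight, gg$weight), c(1.5, 1.3, 0.725))
  # sign carried by the receptor: GPe projections land on the channel
  # whose reversal is below threshold
  chans <- cfg$populations$STN$channels
  expect_lt(chans$E_rev[match(gs$channel, chans$name)],
            cfg$populations$STN$params$V_th)
  expect_gt(chans$E_rev[match(sg$channel, chans$name)],
            cfg$populations$GPe$params$V_th)
})

test_that("the 600 Hz perturbation adds an inhibitory drive onto GPe only", {
  base <- build_stn_gpe()
  pert <- build_stn_gpe(perturb_rate = 600)
  expect_equal(nrow(base$drives), 2)
  added <- pert$drives[pert$drives$role == "perturbation", ]
  expect_equal(nrow(added), 1)
  expect_equal(added$target, "GPe")
  expect_equal(added$channel, "inh")
  expect_equal(added$rate, 600)
})

test_that("in-degree constraints hold at published and mini sizes", {
  for (preset in c("full", "mini")) {
    cfg <- build_stn_gpe(sizes = preset_sizes("stn_gpe", preset))
    ns <- vapply(cfg$populations, `[[`, 0, "n")
    expect_true(all(cfg$projections$in_degree <= ns[cfg$projections$src]))
  }
  expect_error(build_stn_gpe(sizes = c(STN = 10, GPe = 20)), "in_degree")
})

test_that("zeta splits the 800 excitatory afferents between NMDA and AMPA", {
  c0 <- build_cortex(zeta = 0, sizes = preset_sizes("cortex", "mini"))
  ee <- c0$projections[c0$projections$src == "E" & c0$projections$tgt == "E", ]
  expect_equal(ee$channel, "AMPA")
  expect_equal(ee$in_degree, 800)

  c4 <- build_cortex(zeta = 400, sizes = preset_sizes("cortex", "mini"))
  pr <- c4$projections
  get <- function(s, t, ch, col) pr[pr$src == s & pr$tgt == t & pr$channel == ch, col]
  expect_equal(get("E", "E", "NMDA", "in_degree"), 400)
  expect_equal(get("E", "E", "AMPA", "in_degree"), 400)
  expect_equal(get("E", "I", "NMDA", "in_degree"), 400)
  expect_equal(get("E", "E", "NMDA", "weight"), 0.15)
  expect_equal(get("E", "E", "AMPA", "weight"), 0.13)
  expect_equal(get("E", "I", "NMDA", "weight"), 0.16)
  expect_equal(get("E", "I", "AMPA", "weight"), 0.14)
  expect_equal(get("I", "E", "GABA", "weight"), 0.547)
  expect_equal(get("I", "I", "GABA", "weight"), 0.3)
  expect_equal(get("I", "I", "GABA", "delay_min"), 1)
  expect_equal(get("I", "I", "GABA", "delay_max"), 5)
  expect_warning(build_cortex(zeta = 33, sizes = preset_sizes("cortex", "mini")),
                 "multiple of 50")
})

test_that("g rescales inhibitory weights relative to the g = 4 baseline", {
  c4 <- build_cortex(g = 4, sizes = preset_sizes("cortex", "mini"))
  c8 <- build_cortex(g = 8, sizes = preset_sizes("cortex", "mini"))
  w <- function(cfg, s, t) {
    pr <- cfg$projections
    pr[pr$src == s & pr$tgt == t, "weight"]
  }
  expect_equal(w(c8, "I", "E"), 2 * w(c4, "I", "E"))
  expect_equal(w(c8, "I", "I"), 2 * w(c4, "I", "I"))
  expect_equal(w(c8, "E", "E"), w(c4, "E", "E"))   # excitation untouched
})

test_that("AMPA is faster than NMDA in every built cortex configuration", {
  for (z in c(0, 250, 500)) {
    cfg <- build_cortex(zeta = z, sizes = preset_sizes("cortex", "mini"))
    for (p in cfg$populations) {
      tau <- setNames(p$channels$tau_syn, p$channels$name)
      expect_lt(tau["AMPA"], tau["NMDA"])
    }
  }
})

test_that("grid enumeration is the lexicographic Cartesian product", {
  expect_equal(nrow(enumerate_grid(stn_gpe_grid("full"))), 625)
  expect_equal(nrow(enumerate_grid(stn_gpe_grid("mini"))), 81)

  g1 <- structure(list(a = 1, b = 2, c = 3, d = 4), class = "sweep_grid",
                  motif = "stn_gpe")
  expect_equal(nrow(enumerate_grid(g1)), 1)

  g2 <- structure(list(a = c(1, 2), b = c(10, 20), c = 5, d = 6),
                  class = "sweep_grid", motif = "stn_gpe")
  df <- enumerate_grid(g2)
  expect_equal(nrow(df), 4)
  expect_equal(df$a, c(1, 1, 2, 2))     # first parameter most significant
  expect_equal(df$b, c(10, 20, 10, 20))

  g3 <- structure(list(a = numeric(0), b = 1), class = "sweep_grid",
                  motif = "stn_gpe")
  expect_error(enumerate_grid(g3), "empty")
})

test_that("a configuration round-trips through its YAML serialization", {
  cfg <- build_stn_gpe(stn_bg = 1800, w_stn_gpe = 1.2, perturb_rate = 600,
                       sizes = c(STN = 100, GPe = 200))
  p <- tempfile(fileext = ".yaml")
  write_network_config(cfg, p)
  back <- read_network_config(p)
  expect_equal(back$projections, cfg$projections)
  expect_equal(back$drives, cfg$drives)
  expect_equal(vapply(back$populations, `[[`, 0, "n"),
               vapply(cfg$populations, `[[`, 0, "n"))
  expect_equal(back$populations$STN$params$C_m, 200)
  unlink(p)
})

test_that("the threshold background rate matches its defining balance", {
  nu <- cortex_nu_thr(w = 0.13, E_ex = -10)
  np <- cortex_neuron()
  g_mean <- nu * 0.13 * 3e-3
  v_inf <- (np$g_L * np$V_rest + g_mean * (-10)) / (np$g_L + g_mean)
  expect_equal(v_inf, np$V_th, tolerance = 1e-10)
})
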