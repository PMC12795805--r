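# Shared fixtures: tiny configurations and cached sweep results.
# Expensive sweeps are computed once per test run and reused across tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one-population configuration with STN-like channels (ex tau 5 / inh tau 10)
toy_config <- function(n = 1, params = stn_gpe_neuron(), drives = NULL,
                       n_record = min(n, 10)) {
  chans <- data.frame(name = c("ex", "inh"), tau_syn = c(5, 10),
                      E_rev = c(0, -80), stringsAsFactors = FALSE)
  pops <- list(N = list(n = n, params = params, channels = chans))
  proj <- data.frame(src = character(0), tgt = character(0),
                     channel = character(0), in_degree = integer(0),
                     weight = numeric(0), delay_min = numeric(0),
                     delay_max = numeric(0), stringsAsFactors = FALSE)
  if (is.null(drives))
    drives <- data.frame(target = character(0), channel = character(0),
                         rate = numeric(0), weight = numeric(0),
                         role = character(0), stringsAsFactors = FALSE)
  network_config(pops, proj, drives,
                 record = list(population = "N", n = n_record),
                 meta = list(motif = "toy"))
}

toy_drive <- function(rate, weight = 1, channel = "ex") {
  data.frame(target = "N", channel = channel, rate = rate, weight = weight,
             role = "background", stringsAsFactors = FALSE)
}

# desk-scale STN-GPe experiment shared by the acceptance tests
mini_stn_gpe <- function() {
  cached("mini_stn_gpe",
         run_experiment("stn-gpe-sweep", "mini", master_seed = 42))
}

# desk-scale cortex experiment shared by the acceptance tests
mini_cortex <- function() {
  cached("mini_cortex",
         run_experiment("cortex-sweep", "mini", master_seed = 42))
}
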