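#' Calibrate the cortical background drive to a target pyramidal rate
#'
#' The neocortical base state (g = 4, zeta = 400) is tuned so that the
#' pyramidal population fires at about 0.68 spikes/s. This function
#' searches the background level `eta` (units of the threshold rate, see
#' [cortex_nu_thr]) by bisection on the measured mean E rate, then
#' re-measures the rate at the calibrated level over `n_trials`
#' full-length trials. On the default asynchronous branch the E rate is
#' monotone decreasing in `eta` (recurrent inhibition grows faster than
#' the direct drive); the bisection handles either monotone direction.
#'
#' Search trials use a shorter probe (`probe_ms`) with the same 700 ms
#' settling window; the final measurement uses the standard 1700 ms
#' protocol with the last 1000 ms analyzed.
#'
#' @param target_rate target mean pyramidal rate (spikes/s)
#' @param g,zeta base-state parameters
#' @param sizes population sizes
#' @param eta_range bracketing interval for the bisection
#' @param tol_rate stop when the probe rate is within this of the target
#' @param max_iter maximum bisection steps
#' @param n_trials trials for the final measurement
#' @param probe_ms probe trial length (ms)
#' @param master_seed master seed
#' @param bg_weight unitary background conductance (nS)
#' @param ... extra arguments to [build_cortex]
#' @return list with `eta` (calibrated level), `bg_rate` (spikes/s),
#'   `rate` (final mean E rate), `rate_sd` (across trials), `trace`
#'   (data.frame of the search path), `n_trials`
#' @export
calibrate_cortex_background <- function(target_rate = 0.68, g = 4, zeta = 400,
                                        sizes = preset_sizes("cortex", "mini"),
                                        eta_range = c(0.45, 1.4),
                                        tol_rate = 0.02, max_iter = 12,
                                        n_trials = 5, probe_ms = 1700,
                                        master_seed = 1, bg_weight = 2.0,
                                        ...) {
  measure <- function(eta, trial, duration_ms) {
    cfg <- build_cortex(g = g, eta = eta, zeta = zeta, sizes = sizes,
                        bg_weight = bg_weight, ...)
    sim <- simulate_network(cfg, duration_ms = duration_ms,
                            seeds = seed_streams(master_seed, trial))
    unname(firing_rates(sim, c(700, duration_ms))["E"])
  }
  lo <- eta_range[1]; hi <- eta_range[2]
  r_lo <- measure(lo, 1, probe_ms)
  r_hi <- measure(hi, 1, probe_ms)
  if ((r_lo - target_rate) * (r_hi - target_rate) > 0)
    stop("target rate not bracketed by eta_range (rates ",
         signif(r_lo, 3), " .. ", signif(r_hi, 3), ")")
  increasing <- r_hi > r_lo
  trace <- data.frame(eta = c(lo, hi), rate = c(r_lo, r_hi))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- measure(mid, 1, probe_ms)
    trace <- rbind(trace, data.frame(eta = mid, rate = r_mid))
    if (abs(r_mid - target_rate) <= tol_rate) { lo <- hi <- mid; break }
    if ((r_mid < target_rate) == increasing) lo <- mid else hi <- mid
  }
  eta_star <- (lo + hi) / 2
  rates <- vapply(seq_len(n_trials), function(k) measure(eta_star, k, 1700), 0)
  list(eta = eta_star,
       bg_rate = eta_star * cortex_nu_thr(bg_weight),
       rate = mean(rates), rate_sd = sd(rates), rates = rates,
       trace = trace, n_trials = n_trials, target = target_rate)
}
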