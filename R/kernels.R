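#' Alpha-function conductance kernel
#'
#' Conductance transient elicited by one presynaptic spike arriving at
#' t = 0: \eqn{G(t) = g_{max} (t/\tau) e^{-t/\tau}} for t >= 0 and 0
#' before the spike. The kernel peaks at \eqn{t = \tau} with value
#' \eqn{g_{max}/e} and integrates to \eqn{g_{max}\tau}.
#'
#' The simulator does not evaluate this closed form directly; it propagates
#' the equivalent two-state linear system exactly per step so that
#' superposition over spike trains is exact. This function is the reference
#' against which that scheme is checked.
#'
#' @param t time since the spike (ms); vectorized
#' @param tau_syn kernel time constant (ms), > 0
#' @param g_max peak-defining synaptic weight (nS)
#' @return conductance values (nS), same length as `t`
#' @export
alpha_kernel <- function(t, tau_syn, g_max = 1) {
  if (!is.numeric(tau_syn) || length(tau_syn) != 1 || tau_syn <= 0)
    stop("tau_syn must be a single positive number")
  ifelse(t < 0, 0, g_max * (t / tau_syn) * exp(-t / tau_syn))
}

#' Exact discrete propagation of the alpha-synapse state
#'
#' Advances the two-state system (x, g) over a regular grid with impulses
#' `x <- x + g_max/tau` at given spike times (binned to the grid), returning
#' the conductance trace. Used by tests to verify linear superposition and
#' by the shot-noise generator.
#'
#' @param spike_times spike arrival times (ms)
#' @param tau_syn kernel time constant (ms)
#' @param g_max synaptic weight (nS)
#' @param duration_ms trace length (ms)
#' @param step_ms integration step (ms)
#' @return data.frame with columns `t` (ms) and `g` (nS)
#' @export
alpha_trace <- function(spike_times, tau_syn, g_max, duration_ms, step_ms = 0.1) {
  stopifnot(tau_syn > 0, step_ms > 0)
  nsteps <- round(duration_ms / step_ms)
  bins <- tabulate(pmin(floor(spike_times / step_ms) + 1L, nsteps), nbins = nsteps)
  E1 <- exp(-step_ms / tau_syn)
  amp <- g_max / tau_syn
  g <- numeric(nsteps)
  gs <- 0
  xs <- 0
  for (n in seq_len(nsteps)) {
    xs <- xs + bins[n] * amp
    gs <- (gs + step_ms * xs) * E1
    xs <- xs * E1
    g[n] <- gs
  }
  data.frame(t = seq_len(nsteps) * step_ms, g = g)
}
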