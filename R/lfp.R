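#' LFP proxy from recorded synaptic conductances
#'
#' Converts the recorded excitatory and inhibitory conductances of the
#' sampled neurons into synaptic currents,
#' \eqn{I_{syn}(t) = G_{ex}(t)(V_m(t) - E_{ex}) + G_{in}(t)(V_m(t) - E_{in})},
#' and sums them over neurons and channels. The default (`mode =
#' "signed"`) sums the signed currents; `mode = "abs"` sums their absolute
#' values, since the conductance-to-current conversion convention is not
#' uniquely determined.
#'
#' @param sim a `sim_result` with recorded traces
#' @param neuron_ids which of the recorded neurons to use (indices into the
#'   recorded set); defaults to all of them
#' @param mode `"signed"` or `"abs"`
#' @return object of class `lfp_trace`: list with `samples` (current-like,
#'   pA scale, arbitrary sign), `fs` (Hz), `t` (ms),
#'   `n_contributing_neurons`
#' @export
make_lfp <- function(sim, neuron_ids = NULL, mode = c("signed", "abs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "sim_result"))
  nrec <- ncol(sim$V)
  if (is.null(neuron_ids)) neuron_ids <- seq_len(nrec)
  if (max(neuron_ids) > nrec || length(neuron_ids) < 1)
    stop("requested neurons were not recorded (", nrec, " available)")
  erev <- sim$E_rev[[sim$record_pop]]
  V <- sim$V[, neuron_ids, drop = FALSE]
  Iex <- sim$G_ex[, neuron_ids, drop = FALSE] * (V - erev$ex)
  Iin <- sim$G_in[, neuron_ids, drop = FALSE] * (V - erev$inh)
  samples <- if (mode == "signed") rowSums(Iex + Iin) else rowSums(abs(Iex) + abs(Iin))
  structure(list(samples = samples, fs = 1000 / diff(sim$t[1:2]),
                 t = sim$t, n_contributing_neurons = length(neuron_ids)),
            class = "lfp_trace")
}

#' Restrict a trace to an analysis window
#'
#' Drops the initial transient (default: everything up to 700 ms) so that
#' spectra are computed on the stationary part of the run.
#' @param lfp an `lfp_trace`
#' @param skip_ms initial interval to discard (ms)
#' @export
trim_lfp <- function(lfp, skip_ms = 700) {
  keep <- lfp$t > skip_ms
  lfp$samples <- lfp$samples[keep]
  lfp$t <- lfp$t[keep]
  lfp
}

#' Mean recorded conductances
#'
#' Time-averaged excitatory and inhibitory conductance over the recorded
#' neurons in an analysis window; the EI conductance ratio is
#' `mean G_ex / mean G_in`.
#' @param sim a `sim_result`
#' @param skip_ms initial interval to discard (ms)
#' @return list with `G_ex`, `G_in` (nS) and `EI_ratio`
#' @export
mean_conductances <- function(sim, skip_ms = 700) {
  keep <- sim$t > skip_ms
  ge <- mean(sim$G_ex[keep, , drop = FALSE])
  gi <- mean(sim$G_in[keep, , drop = FALSE])
  list(G_ex = ge, G_in = gi,
       EI_ratio = if (gi > 0) ge / gi else Inf)
}

#' Write / read a 1 kHz signal trace
#'
#' Two-column CSV `(time_ms, value)`; the format accepted by the spectral
#' pipeline for externally supplied signals.
#' @param lfp an `lfp_trace` (or list with `t`, `samples`)
#' @param path file path
#' @export
write_trace_csv <- function(lfp, path) {
  write.csv(data.frame(time_ms = lfp$t, value = lfp$samples), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  dt <- diff(df[[1]][1:2])
  structure(list(samples = df[[2]], fs = 1000 / dt, t = df[[1]],
                 n_contributing_neurons = NA_integer_),
            class = "lfp_trace")
}
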