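#' Surrogate signal with known aperiodic exponent
#'
#' Generates an LFP-like signal by inverse-FFT spectral synthesis: the
#' amplitude spectrum is set to \eqn{f^{-\gamma/2}} (so the power spectrum
#' is exactly \eqn{1/f^{\gamma}}), optional oscillatory peaks are added as
#' Gaussian bumps in log10 power, phases are drawn uniformly, and the
#' real-valued signal is recovered. The ground-truth exponent is therefore
#' bit-defined, which makes these signals the validation harness for the
#' spectral pipeline.
#'
#' The power law is applied above `lowcut_hz` only; below it the spectrum
#' plateaus. A pure power law has divergent power at DC, which no
#' physical signal has and which would leak through the analysis window's
#' sidelobes into the measurement band for steep exponents; the plateau
#' sits far below both analysis bands, so the in-band ground truth is
#' still exactly \eqn{1/f^{\gamma}}.
#'
#' @param gamma_true target aperiodic exponent, >= 0
#' @param duration_ms signal length (ms), >= 1024
#' @param fs sampling rate (Hz)
#' @param peaks optional data.frame with columns `center` (Hz, below
#'   Nyquist), `height` (log10 power units), `width` (Hz, Gaussian sd)
#' @param seed integer seed
#' @param lowcut_hz plateau frequency (Hz)
#' @return an `lfp_trace`
#' @export
generate_powerlaw_signal <- function(gamma_true, duration_ms = 10000,
                                     fs = 1000, peaks = NULL, seed = 1,
                                     lowcut_hz = 1) {
  if (gamma_true < 0) stop("gamma_true must be >= 0")
  if (duration_ms < 1024) stop("duration must be at least 1024 ms")
  n <- round(duration_ms * fs / 1000)
  freq <- seq(0, fs / 2, by = fs / n)
  if (!is.null(peaks) && any(peaks$center >= fs / 2))
    stop("peak center at or above Nyquist")
  amp <- c(0, pmax(freq[-1], lowcut_hz)^(-gamma_true / 2))
  if (!is.null(peaks)) {
    bump <- numeric(length(freq))
    for (k in seq_len(nrow(peaks)))
      bump <- bump + peaks$height[k] *
        exp(-(freq - peaks$center[k])^2 / (2 * peaks$width[k]^2))
    amp <- amp * 10^(bump / 2)
  }
  set.seed(seed)
  nhalf <- length(freq)
  phase <- runif(nhalf, 0, 2 * pi)
  spec_half <- amp * exp(1i * phase)
  spec_half[1] <- 0
  if (n %% 2 == 0) spec_half[nhalf] <- Re(spec_half[nhalf])
  spec <- c(spec_half, Conj(rev(spec_half[2:(nhalf - (n %% 2 == 0))])))
  x <- Re(fft(spec, inverse = TRUE)) / n
  structure(list(samples = x, fs = fs, t = seq_len(n) * 1000 / fs,
                 n_contributing_neurons = NA_integer_),
            class = "lfp_trace")
}

#' Shot-noise conductance trace
#'
#' A Poisson spike train at `rate` convolved with the alpha kernel
#' \eqn{g_{max}(t/\tau)e^{-t/\tau}}. By Campbell's theorem the mean of the
#' resulting conductance is `rate * g_max * tau` (the kernel integral times
#' the rate) and the high-frequency power falls as \eqn{f^{-4}}, the
#' squared magnitude of the alpha kernel's Fourier transform.
#'
#' @param rate spikes/s, >= 0
#' @param tau_syn kernel time constant (ms)
#' @param g_max synaptic weight (nS)
#' @param duration_ms trace length (ms)
#' @param step_ms integration step (ms)
#' @param fs output sampling rate (Hz)
#' @param seed integer seed
#' @return an `lfp_trace` whose samples are conductance (nS)
#' @export
generate_shot_noise <- function(rate, tau_syn, g_max, duration_ms,
                                step_ms = 0.1, fs = 1000, seed = 1) {
  stopifnot(rate >= 0)
  set.seed(seed)
  nsteps <- round(duration_ms / step_ms)
  counts <- rpois(nsteps, rate * step_ms * 1e-3)
  E1 <- exp(-step_ms / tau_syn)
  amp <- g_max / tau_syn
  every <- round(1000 / fs / step_ms)
  g <- numeric(nsteps %/% every)
  gs <- 0; xs <- 0
  for (n in seq_len(nsteps)) {
    xs <- xs + counts[n] * amp
    gs <- (gs + step_ms * xs) * E1
    xs <- xs * E1
    if (n %% every == 0) g[n %/% every] <- gs
  }
  structure(list(samples = g, fs = fs, t = seq_along(g) * 1000 / fs,
                 n_contributing_neurons = 1L),
            class = "lfp_trace")
}
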