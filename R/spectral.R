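#' Welch power spectral density
#'
#' Averaged-periodogram PSD: the signal is cut into segments of
#' `seg_len` samples with 50% overlap, each segment is mean-detrended,
#' multiplied by a Hann window and Fourier transformed; squared magnitudes
#' are averaged across segments and scaled to power density (one-sided,
#' power per Hz). With `fs = 1000` and `seg_len = 256` the frequency
#' resolution is 1000/256 = 3.90625 Hz.
#'
#' @param x an `lfp_trace` or numeric vector
#' @param fs sampling rate (Hz); taken from the trace when available
#' @param seg_len segment length M in samples
#' @param overlap fractional segment overlap
#' @return object of class `psd`: list with `freq` (Hz), `psd`
#'   (power/Hz), `fs`, `seg_len`, `n_segments`
#' @export
welch_psd <- function(x, fs = 1000, seg_len = 256, overlap = 0.5) {
  if (inherits(x, "lfp_trace")) { fs <- x$fs; x <- x$samples }
  n <- length(x)
  if (n < seg_len)
    stop("signal (", n, " samples) shorter than one segment (", seg_len, ")")
  step <- round(seg_len * (1 - overlap))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / seg_len)   # periodic Hann
  norm <- fs * sum(w^2)
  nfreq <- seg_len %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[1:nfreq])^2 / norm
    acc <- acc + sp
  }
  pxx <- acc / length(starts)
  pxx[2:(nfreq - 1)] <- 2 * pxx[2:(nfreq - 1)]   # one-sided
  structure(list(freq = (0:(nfreq - 1)) * fs / seg_len, psd = pxx,
                 fs = fs, seg_len = seg_len, n_segments = length(starts)),
            class = "psd")
}

band_index <- function(freq, band) {
  which(freq >= band[1] & freq <= band[2] & freq > 0)
}

#' Oscillation index
#'
#' Entropy-based oscillation strength of a PSD. The spectrum (restricted
#' to `band`) is normalized to unit sum and its Shannon entropy taken
#' relative to the maximal (uniform) entropy,
#' \deqn{H_s = -\sum_i P(f_i) \log_2 P(f_i) / \log_2 N, \quad OI = 1 - H_s.}
#' A flat spectrum gives OI = 0, a single-frequency spectrum OI = 1.
#'
#' @param psd a `psd` object, or a numeric vector of spectral powers (then
#'   `freq` must be given)
#' @param band analysis band `c(lo, hi)` in Hz
#' @param freq frequency grid when `psd` is a bare vector
#' @return OI in `[0, 1]`
#' @export
oscillation_index <- function(psd, band = c(5, 150), freq = NULL) {
  if (inherits(psd, "psd")) { freq <- psd$freq; psd <- psd$psd }
  idx <- band_index(freq, band)
  if (length(idx) < 2) stop("band contains fewer than 2 frequency bins")
  p <- psd[idx]
  if (any(p < 0)) stop("negative spectral power")
  tot <- sum(p)
  if (tot <= 0) stop("zero total power in band")
  p <- p / tot
  nz <- p > 0
  hs <- -sum(p[nz] * log2(p[nz])) / log2(length(p))
  1 - hs
}

#' Aperiodic (1/f) exponent by spectral parameterization
#'
#' Decomposes a log-power spectrum into an aperiodic power-law component
#' plus Gaussian oscillatory peaks, in the style of the FOOOF / specparam
#' algorithm with the aperiodic mode fixed (no knee):
#' \eqn{\log_{10} P(f) = b - \gamma \log_{10} f + \sum_k a_k
#' e^{-(f-c_k)^2 / 2 s_k^2}}.
#'
#' The fit proceeds as: robust linear fit of log-power on log-frequency;
#' iterative extraction of up to `max_n_peaks` Gaussian peaks from the
#' flattened spectrum (a candidate must exceed both `min_peak_height` and
#' `peak_threshold` standard deviations of the flattened spectrum); joint
#' bounded refinement of all peaks; re-fit of the aperiodic component on
#' the peak-removed spectrum. R-squared is the squared correlation between
#' the log-spectrum and the full model.
#'
#' @param psd a `psd` object, or numeric powers with `freq` supplied
#' @param band fit band in Hz (default 50-150, chosen to avoid
#'   low-frequency oscillations below and spectral plateaus above)
#' @param freq frequency grid when `psd` is a bare vector
#' @param max_n_peaks maximum number of Gaussian peaks
#' @param min_peak_height minimum peak height (log10 power units)
#' @param peak_threshold peak detection threshold in standard deviations of
#'   the flattened spectrum
#' @param peak_width_limits allowed full peak widths `c(lo, hi)` in Hz
#' @return list with `gamma` (aperiodic exponent), `offset`, `r_squared`,
#'   `peaks` (data.frame `center`, `height`, `sd`), `converged`, `band`,
#'   and `model` (fitted log10 power on the band grid)
#' @export
fit_aperiodic <- function(psd, band = c(50, 150), freq = NULL,
                          max_n_peaks = 16, min_peak_height = 0.01,
                          peak_threshold = 2, peak_width_limits = c(0.5, 12)) {
  if (inherits(psd, "psd")) { freq <- psd$freq; psd <- psd$psd }
  idx <- band_index(freq, band)
  if (length(idx) < 8) stop("fewer than 8 frequency bins in the fit band")
  f <- freq[idx]
  p <- psd[idx]
  if (any(p <= 0)) return(list(gamma = NA_real_, offset = NA_real_,
                               r_squared = NA_real_, peaks = NULL,
                               converged = FALSE, band = band, model = NULL))
  lf <- log10(f)
  lp <- log10(p)

  ap_fit <- function(y, robust = FALSE) {
    fit <- lm(y ~ lf)
    if (robust) {
      # refit through the lower envelope: clip positive residuals to zero
      # and keep the points at or below the initial line, so oscillatory
      # peaks do not drag the aperiodic component upward
      r <- pmax(y - fitted(fit), 0)
      keep <- r <= quantile(r, 0.025)
      if (sum(keep) >= 4) fit <- lm(y[keep] ~ lf[keep])
    }
    coef(fit)
  }
  gauss <- function(pars) {   # pars: c(center, height, sd) x k
    m <- numeric(length(f))
    for (k in seq_len(length(pars) / 3)) {
      c0 <- pars[3 * k - 2]; h <- pars[3 * k - 1]; s <- pars[3 * k]
      m <- m + h * exp(-(f - c0)^2 / (2 * s^2))
    }
    m
  }

  ab <- ap_fit(lp, robust = TRUE)
  flat <- lp - (ab[1] + ab[2] * lf)
  sd_limits <- peak_width_limits / 2              # width limits -> gaussian sd
  guesses <- NULL
  for (k in seq_len(max_n_peaks)) {
    i <- which.max(flat)
    h <- flat[i]
    thr <- peak_threshold * sd(flat)
    if (!is.finite(h) || h <= max(min_peak_height, thr)) break
    # width guess from half-height crossing
    half <- h / 2
    li <- i; while (li > 1 && flat[li] > half) li <- li - 1
    ri <- i; while (ri < length(f) && flat[ri] > half) ri <- ri + 1
    fwhm <- max(f[ri] - f[li], diff(f[1:2]))
    s <- min(max(fwhm / 2.355, sd_limits[1]), sd_limits[2])
    guesses <- rbind(guesses, c(f[i], h, s))
    flat <- flat - h * exp(-(f - f[i])^2 / (2 * s^2))
  }
  # drop guesses hugging the band edge, and the smaller of overlapping pairs
  if (!is.null(guesses)) {
    keep <- guesses[, 1] - band[1] > guesses[, 3] &
            band[2] - guesses[, 1] > guesses[, 3]
    guesses <- guesses[keep, , drop = FALSE]
    if (nrow(guesses) > 1) {
      ord <- order(guesses[, 1])
      g2 <- guesses[ord, , drop = FALSE]
      drop <- rep(FALSE, nrow(g2))
      for (k in seq_len(nrow(g2) - 1)) {
        if (g2[k + 1, 1] - g2[k, 1] < 0.75 * (g2[k, 3] + g2[k + 1, 3])) {
          smaller <- if (g2[k, 2] < g2[k + 1, 2]) k else k + 1
          drop[smaller] <- TRUE
        }
      }
      guesses <- g2[!drop, , drop = FALSE]
    }
    if (nrow(guesses) == 0) guesses <- NULL
  }

  converged <- TRUE
  peaks <- NULL
  periodic <- numeric(length(f))
  if (!is.null(guesses)) {
    target <- lp - (ab[1] + ab[2] * lf)
    par0 <- as.vector(t(guesses))
    npk <- nrow(guesses)
    lower <- as.vector(t(cbind(guesses[, 1] - 2 * guesses[, 3],
                               rep(0, npk), rep(sd_limits[1], npk))))
    upper <- as.vector(t(cbind(guesses[, 1] + 2 * guesses[, 3],
                               rep(Inf, npk), rep(sd_limits[2], npk))))
    obj <- function(pars) sum((target - gauss(pars))^2)
    opt <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) {
      converged <- FALSE
      pars <- par0
    } else pars <- opt$par
    periodic <- gauss(pars)
    peaks <- data.frame(center = pars[seq(1, length(pars), 3)],
                        height = pars[seq(2, length(pars), 3)],
                        sd = pars[seq(3, length(pars), 3)])
  }

  ab2 <- ap_fit(lp - periodic, robust = FALSE)
  model <- ab2[1] + ab2[2] * lf + periodic
  r2 <- suppressWarnings(cor(lp, model)^2)
  if (!is.finite(r2)) r2 <- NA_real_
  list(gamma = unname(-ab2[2]), offset = unname(ab2[1]),
       r_squared = unname(r2), peaks = peaks, converged = converged,
       band = band, model = model, freq = f)
}

#' Full spectral analysis of one simulated trial
#'
#' Pipeline composition: LFP proxy from the recorded neurons, analysis
#' window (default: discard the first 700 ms), Welch PSD, oscillation
#' index and aperiodic-exponent fit.
#'
#' @param sim a `sim_result`
#' @param skip_ms initial transient to discard (ms)
#' @param oi_band band for the oscillation index (Hz)
#' @param fit_band band for the aperiodic fit (Hz)
#' @param mode LFP sign convention, see [make_lfp]
#' @param ... further arguments to [fit_aperiodic]
#' @return object of class `spectrum_result`: list with `freq`, `psd`,
#'   `OI`, `gamma`, `fit_R2`, `fit_band`, `oi_band`, `converged`,
#'   `G_ex`, `G_in`, `EI_ratio`, `rates`
#' @export
analyze_trial <- function(sim, skip_ms = 700, oi_band = c(5, 150),
                          fit_band = c(50, 150), mode = "signed", ...) {
  lfp <- trim_lfp(make_lfp(sim, mode = mode), skip_ms)
  ps <- welch_psd(lfp)
  oi <- oscillation_index(ps, band = oi_band)
  fit <- fit_aperiodic(ps, band = fit_band, ...)
  gc <- mean_conductances(sim, skip_ms)
  structure(list(freq = ps$freq, psd = ps$psd, OI = oi,
                 gamma = fit$gamma, fit_R2 = fit$r_squared,
                 peaks = fit$peaks, converged = fit$converged,
                 fit_band = fit_band, oi_band = oi_band,
                 G_ex = gc$G_ex, G_in = gc$G_in, EI_ratio = gc$EI_ratio,
                 rates = firing_rates(sim, c(skip_ms, sim$duration_ms))),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum_result: OI=%.3f gamma=%.2f R2=%.3f EI=%.2f\n",
              x$OI, x$gamma, x$fit_R2, x$EI_ratio))
  invisible(x)
}

#' Write a spectrum result to JSON
#'
#' Frequencies and PSD as arrays, scalar metrics as metadata.
#' @param x a `spectrum_result`
#' @param path output path
#' @export
write_spectrum_json <- function(x, path) {
  jsonlite::write_json(
    list(freq = x$freq, psd = x$psd,
         metrics = list(OI = x$OI, gamma = x$gamma, fit_R2 = x$fit_R2,
                        G_ex = x$G_ex, G_in = x$G_in, EI_ratio = x$EI_ratio),
         fit_band = x$fit_band, oi_band = x$oi_band),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
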