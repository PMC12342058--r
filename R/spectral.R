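# Per-epoch power spectra and slow-wave metrics.
#
# All band powers run through the same estimator: a rectangular-window FFT of
# each raw 10 s segment, which natively yields 0.1 Hz resolution. Power is
# stored as a one-sided density (uV^2/Hz) so that sum(power) * 0.1 Hz
# reproduces the segment mean square (Parseval).

.DELTA_BAND <- c(0.5, 4)
.THETA_BAND <- c(6, 10)
.TOTAL_BAND <- c(0.5, 30)

#' Power spectrum of one 10 s epoch
#'
#' One-sided power spectral density of a single scoring epoch via FFT of the
#' raw segment (rectangular window by default), at the native 0.1 Hz
#' resolution of a 10 s window. `sum(power) * 0.1` over any band equals that
#' band's contribution to the segment mean square.
#'
#' @param segment Numeric vector, exactly 10 s of samples (`10 * fs`).
#' @param fs Sampling rate in Hz; must be at least 60 so the spectrum covers
#'   the 0.5-30 Hz analysis range.
#' @param window `"rectangular"` (default, raw FFT) or `"hann"`.
#' @return A list with `freqs` (Hz, 0.1 Hz spacing from 0 to `fs/2`) and
#'   `power` (uV^2/Hz).
#' @examples
#' sp <- epochSpectrum(sin(2 * pi * 2 * seq(0, 10, by = 0.01)[-1]), fs = 100)
#' sp$freqs[which.max(sp$power)]  # 2 Hz
#' @export
epochSpectrum <- function(segment, fs, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (fs < 60) stop("fs must be >= 60 Hz for 0.5-30 Hz analysis")
  n <- length(segment)
  if (n != round(10 * fs)) stop("segment must be exactly 10 s of samples")
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  } else rep(1, n)
  # window power correction keeps Parseval agreement
  x <- segment * w / sqrt(mean(w^2))
  X <- stats::fft(x)
  half <- floor(n / 2)
  df <- fs / n                      # 0.1 Hz for a 10 s window
  p <- Mod(X[seq_len(half + 1)])^2 / (n^2 * df)
  scale <- rep(2, half + 1)
  scale[1] <- 1
  if (n %% 2 == 0) scale[half + 1] <- 1
  list(freqs = (0:half) * df, power = p * scale)
}

#' Band power from a spectrum
#'
#' Sums the power density over the half-open frequency band `[lo, hi)` and
#' multiplies by the bin width, so disjoint bands are additive:
#' `bandPower(s, 0.5, 4) + bandPower(s, 4, 30) == bandPower(s, 0.5, 30)`.
#'
#' @param spec A spectrum as returned by [epochSpectrum()].
#' @param lo,hi Band edges in Hz (`lo` inclusive, `hi` exclusive).
#' @param closed If `TRUE`, include the `hi` bin as well (closed interval).
#' @return Band power in uV^2.
#' @export
bandPower <- function(spec, lo, hi, closed = FALSE) {
  if (lo >= hi) stop("band must satisfy lo < hi")
  f <- spec$freqs
  if (lo < f[1] - 1e-9 || hi > f[length(f)] + 0.1 + 1e-9)
    stop("band outside spectrum range")
  df <- f[2] - f[1]
  sel <- f >= lo - 1e-9 & (if (closed) f <= hi + 1e-9 else f < hi - 1e-9)
  sum(spec$power[sel]) * df
}

#' Normalized slow-wave activity
#'
#' Expresses each epoch's delta power as a percentage of the subject's own
#' baseline-day mean delta power, following the convention of dividing by the
#' first (undisturbed) recording day's average in the same band. By default
#' the baseline mean is taken over NREM epochs only, because slow-wave
#' activity is defined during NREM sleep; set `baselineStates = NULL` to use
#' all baseline epochs instead.
#'
#' @param delta Numeric vector of per-epoch delta power (uV^2).
#' @param baselineDelta Per-epoch delta power of the baseline day (uV^2).
#' @param baselineStates Optional character vector of baseline epoch labels;
#'   when given, the divisor averages over `"NREM"` epochs only.
#' @return Percent series, 100 at the baseline mean. The self-normalized
#'   baseline series has mean exactly 100.
#' @export
normalizedSwa <- function(delta, baselineDelta, baselineStates = NULL) {
  if (!is.null(baselineStates)) {
    if (length(baselineStates) != length(baselineDelta))
      stop("baselineStates must match baselineDelta in length")
    baselineDelta <- baselineDelta[baselineStates == "NREM"]
  }
  if (length(baselineDelta) == 0L)
    stop("empty baseline NREM set: cannot normalize")
  m <- mean(baselineDelta)
  if (!is.finite(m) || m <= 0) stop("baseline mean delta power must be positive")
  100 * delta / m
}

#' Relative slow-wave activity
#'
#' Delta power (0.5-4 Hz) as a percentage of total power (0.5-30 Hz) in the
#' same epoch.
#'
#' @param delta Delta-band power (uV^2).
#' @param total Total-band power (uV^2); must be positive and at least `delta`.
#' @return Percentage in `[0, 100]`.
#' @export
relativeSwa <- function(delta, total) {
  if (any(total <= 0)) stop("total power must be positive")
  if (any(delta > total * (1 + 1e-8))) stop("delta power cannot exceed total")
  100 * delta / total
}

#' Cumulative slow-wave energy
#'
#' Accumulates delta power x epoch duration over NREM epochs:
#' `energy = sum(power_i * t_i)`. Non-NREM (and artifact) epochs contribute
#' zero and carry the running total forward, so the series is non-decreasing.
#'
#' @param delta Per-epoch delta power (uV^2).
#' @param stateMask Logical vector (TRUE for NREM epochs) or character state
#'   labels, same length as `delta`.
#' @param t Epoch duration in seconds (10).
#' @return Numeric vector of cumulative energy (uV^2 s), one value per epoch.
#' @examples
#' slowWaveEnergy(rep(100, 6), rep(TRUE, 6))  # ends at 6000
#' @export
slowWaveEnergy <- function(delta, stateMask, t = 10) {
  if (is.character(stateMask)) stateMask <- stateMask == "NREM"
  if (length(delta) != length(stateMask))
    stop("delta and stateMask must have equal length")
  cumsum(ifelse(stateMask, delta, 0) * t)
}

#' Binned SWA time course
#'
#' Mean and SEM of a per-epoch series in ZT bins, restricted to NREM epochs.
#' Bins containing no NREM epochs are reported as missing (`NA`), never zero.
#'
#' @param values Per-epoch values (e.g. normalized SWA).
#' @param ztHours ZT hour at each epoch start.
#' @param states Epoch labels; only `"NREM"` epochs enter the bins.
#' @param bin Bin width in hours; must divide 24.
#' @return Data.frame with `zt_bin` (bin start, ZT h within the day), `mean`,
#'   `sem` and `n` (number of contributing epochs).
#' @export
swaTimecourse <- function(values, ztHours, states = rep("NREM", length(values)),
                          bin = 1) {
  if (24 %% bin != 0) stop("bin must divide 24 hours")
  if (length(values) != length(ztHours) || length(values) != length(states))
    stop("values, ztHours and states must have equal length")
  keep <- states == "NREM"
  starts <- seq(0, 24 - bin, by = bin)
  zt <- ztHours %% 24
  idx <- floor(zt / bin) + 1L
  out <- data.frame(zt_bin = starts, mean = NA_real_, sem = NA_real_,
                    n = 0L)
  for (b in seq_along(starts)) {
    v <- values[keep & idx == b]
    out$n[b] <- length(v)
    if (length(v)) {
      out$mean[b] <- mean(v)
      out$sem[b] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }
  }
  out
}

#' Per-epoch spectral table for a recording day
#'
#' Convenience wrapper producing the standard spectral table: per-epoch delta,
#' theta and total band power from [epochSpectrum()] plus relative SWA, and
#' cumulative slow-wave energy over NREM epochs. Artifact epochs are excluded
#' from all aggregates (their band powers are reported but their SWE
#' contribution is zero and they are dropped by [swaTimecourse()]).
#'
#' @param rec A [recording()] with the EEG channel to analyse.
#' @param hyp The matching [hypnogram()].
#' @param channel EEG channel name (default `"eeg_frontal"`).
#' @return Data.frame: `epoch`, `zt_s`, `state`, `delta`, `theta`, `total`,
#'   `rel_swa_pct`, `swe_cum`.
#' @export
spectralTable <- function(rec, hyp, channel = "eeg_frontal") {
  ef <- extractFeatures(rec, channel = channel)
  tb <- featureTable(ef)
  st <- states(hyp)
  n <- min(nrow(tb), length(st))
  tb <- tb[seq_len(n), ]
  st <- st[seq_len(n)]
  nrem <- st == "NREM"
  data.frame(epoch = tb$epoch, zt_s = tb$zt_s, state = st,
             delta = tb$delta, theta = tb$theta, total = tb$total,
             rel_swa_pct = 100 * tb$delta / tb$total,
             swe_cum = slowWaveEnergy(tb$delta, nrem, t = 10))
}
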