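# Frequency-domain EEG/EMG synthesis.
#
# Each epoch's EEG is a sum of band-limited Gaussian noise components (delta
# 0.5-4 Hz, theta 6-10 Hz, broadband 0.5-30 Hz) whose time-domain standard
# deviations are set by state: delta-dominant NREM (scaled by sqrt(S) of the
# homeostat), theta-dominant REM, low-voltage broadband wake. Synthesis
# happens directly on the 0.1 Hz FFT grid of each 10 s epoch, so the analysis
# bands recover the planted powers exactly in expectation.

# positive-frequency bin indices (1-based into 1..N-1) for [lo, hi)
.bandBins <- function(fs, n, lo, hi) {
  df <- fs / n
  k <- seq_len(floor(n / 2) - 1L)   # strictly positive, below Nyquist
  f <- k * df
  k[f >= lo - 1e-9 & f < hi - 1e-9]
}

# per-epoch band amplitude matrix (epochs x 3 bands) for one EEG lead
.epochBandAmps <- function(st, sTraj, params, deltaScale = 1) {
  amps <- params@bandAmps
  stEff <- ifelse(st == "ARTIFACT", "WAKE", st)  # artifact = wake background
  A <- amps[stEff, , drop = FALSE]
  sHi <- params@sBounds[2]
  nrem <- stEff == "NREM"
  A[, "delta"] <- A[, "delta"] *
    ifelse(nrem, sqrt(pmax(sTraj, 0) / sHi), 1) * deltaScale
  A
}

# synthesize one EEG channel for all epochs (chunked over epochs)
.synthEeg <- function(st, sTraj, params, deltaScale) {
  fs <- params@eegFs
  n <- as.integer(round(params@epochS * fs))
  nEp <- length(st)
  bins <- list(delta = .bandBins(fs, n, 0.5, 4),
               theta = .bandBins(fs, n, 6, 10),
               broad = .bandBins(fs, n, 0.5, 30))
  A <- .epochBandAmps(st, sTraj, params, deltaScale)
  out <- numeric(n * nEp)
  chunk <- 1440L
  for (s0 in seq(1L, nEp, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, nEp)
    m <- s1 - s0 + 1L
    S2 <- matrix(0, n, m)          # per-bin variance
    for (b in names(bins)) {
      kb <- bins[[b]]
      S2[kb + 1L, ] <- S2[kb + 1L, ] +
        rep(A[s0:s1, b]^2 / length(kb), each = length(kb))
    }
    Z <- sqrt(S2) * matrix(complex(real = stats::rnorm(n * m),
                                   imaginary = stats::rnorm(n * m)), n, m)
    x <- Re(stats::mvfft(Z, inverse = TRUE))
    out[((s0 - 1L) * n + 1L):(s1 * n)] <- as.vector(x)
  }
  out
}

.artifactPulse <- function(fs, epochS, amplitude = 500) {
  # 1 s clipping transient at epoch start: 2 Hz square wave at full amplitude
  n <- as.integer(round(epochS * fs))
  pulse <- numeric(n)
  t <- seq_len(fs) / fs
  pulse[seq_len(fs)] <- amplitude * sign(sin(2 * pi * 2 * t))
  pulse
}

#' Synthesize EEG/EMG signals for a hypnogram
#'
#' Produces a two-lead EEG (frontal, parietal) plus EMG [recording()] matching
#' the given hypnogram epoch for epoch. NREM delta amplitude scales
#' monotonically with the homeostat value; REM epochs carry a dominant
#' 6-10 Hz theta component; EMG is zero-mean noise with state-ordered scale
#' wake > NREM > REM. The parietal lead's delta amplitude is the frontal one
#' times `params@deltaLeadRatio`. Epochs already labelled ARTIFACT receive a
#' wake-like background plus a clipping transient. Deterministic given `seed`.
#'
#' @param hyp A [hypnogram()].
#' @param sTraj Homeostat values, one per epoch (see [homeostatTrajectory()]).
#' @param params A [simParams()].
#' @param seed Seed for the synthesis noise; defaults to `params@seed`.
#' @return A [recording()] with channels `eeg_frontal`, `eeg_parietal`, `emg`.
#' @export
synthesizeSignals <- function(hyp, sTraj, params, seed = params@seed) {
  st <- states(hyp)
  if (length(sTraj) != length(st))
    stop("sTraj and hypnogram must have the same epoch count")
  set.seed(.childSeed(seed, 1))
  fs <- params@eegFs
  n <- as.integer(round(params@epochS * fs))
  frontal <- .synthEeg(st, sTraj, params, deltaScale = 1)
  parietal <- .synthEeg(st, sTraj, params, deltaScale = params@deltaLeadRatio)
  emg <- stats::rnorm(n * length(st)) *
    rep(params@emgSigma[st], each = n)
  art <- which(st == "ARTIFACT")
  if (length(art)) {
    pulse <- .artifactPulse(fs, params@epochS)
    for (e in art) {
      idx <- ((e - 1L) * n + 1L):(e * n)
      frontal[idx] <- frontal[idx] + pulse
      parietal[idx] <- parietal[idx] + pulse
    }
  }
  recording(list(eeg_frontal = frontal, eeg_parietal = parietal, emg = emg),
            fs = fs, ztStartS = hyp@ztStartS)
}

#' Inject artifact epochs into a recording
#'
#' Relabels exactly `round(fraction * nEpochs)` epochs as ARTIFACT and writes
#' high-amplitude clipping transients into both EEG leads at those epochs.
#' Positions are reproducible from `seed`; `fraction = 0` returns the inputs
#' unchanged.
#'
#' @param rec A [recording()].
#' @param hyp The matching [hypnogram()].
#' @param fraction Proportion of epochs to corrupt, in `[0, 1]`.
#' @param seed Integer seed selecting the positions.
#' @return List with elements `recording` and `hypnogram`.
#' @export
injectArtifacts <- function(rec, hyp, fraction, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  nEp <- nEpochs(hyp)
  k <- round(fraction * nEp)
  if (k == 0) return(list(recording = rec, hypnogram = hyp))
  set.seed(.childSeed(seed, 2))
  sel <- sort(sample.int(nEp, k))
  st <- states(hyp)
  st[sel] <- "ARTIFACT"
  n <- as.integer(round(hyp@epochS * samplingRate(rec)))
  pulse <- .artifactPulse(samplingRate(rec), hyp@epochS)
  ch <- rec@channels
  for (nm in intersect(c("eeg_frontal", "eeg_parietal"), names(ch))) {
    for (e in sel) {
      idx <- ((e - 1L) * n + 1L):(e * n)
      ch[[nm]][idx] <- ch[[nm]][idx] + pulse
    }
  }
  list(recording = recording(ch, fs = samplingRate(rec),
                             ztStartS = rec@ztStartS),
       hypnogram = hypnogram(st, epochS = hyp@epochS, ztStartS = hyp@ztStartS))
}

#' Simulate one synthetic recording day
#'
#' Convenience wrapper chaining [simulateHypnogram()], [homeostatTrajectory()],
#' [synthesizeSignals()] and [injectArtifacts()] (at
#' `params@artifactFraction`) for a single protocol day.
#'
#' @param params A [simParams()]; its seed drives everything.
#' @param kind Day kind (see [protocolSchedule()]).
#' @param s0 Homeostat starting value.
#' @return List with `recording`, `hypnogram` (artifact labels injected),
#'   `truth` (pre-injection hypnogram) and `s` (homeostat trajectory).
#' @export
simulateRecordingDay <- function(params, kind = "baseline",
                                 s0 = mean(params@sBounds)) {
  hyp <- simulateHypnogram(params, protocolSchedule(kind))
  s <- homeostatTrajectory(hyp, params, s0 = s0)
  rec <- synthesizeSignals(hyp, s, params)
  inj <- injectArtifacts(rec, hyp, params@artifactFraction,
                         seed = params@seed)
  list(recording = inj$recording, hypnogram = inj$hypnogram, truth = hyp,
       s = s)
}
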