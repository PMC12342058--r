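# Rule-based sleep staging in 10 s epochs.
#
# The decision rule operationalizes the classical manual criteria:
#   WAKE: low-voltage EEG, high-amplitude EMG
#   NREM: high-voltage (delta-dominant) EEG, low-amplitude EMG
#   REM:  low-voltage EEG with dominant 6-10 Hz theta, very low EMG
# Thresholds default to per-recording quantiles of the epoch feature
# distributions, which makes staging invariant to overall amplitude scale.

#' Per-epoch staging features
#'
#' Splits a recording into 10 s epochs and computes, per epoch, the delta
#' (0.5-4 Hz), theta (6-10 Hz) and total (0.5-30 Hz) band powers of the
#' chosen EEG channel via [epochSpectrum()]/[bandPower()], the EMG RMS, and
#' the peak absolute EEG amplitude (for artifact screening). A trailing
#' partial epoch is dropped with a warning, never padded.
#'
#' @param rec A [recording()] with the chosen EEG channel and an `emg`
#'   channel.
#' @param channel EEG channel to analyse (default `"eeg_frontal"`, the
#'   staging lead; the parietal lead is used for lead-specific SWA analyses).
#' @param epochS Epoch length in seconds (10).
#' @return An `EpochFeatures` object; see [featureTable()].
#' @export
extractFeatures <- function(rec, channel = "eeg_frontal", epochS = 10) {
  if (!"emg" %in% channelNames(rec)) stop("recording has no 'emg' channel")
  if (!channel %in% channelNames(rec))
    stop("recording has no '", channel, "' channel")
  fs <- samplingRate(rec)
  if (fs < 60) stop("fs too low for 0.5-30 Hz analysis (need >= 60 Hz)")
  n <- as.integer(round(epochS * fs))
  eeg <- channelSignal(rec, channel)
  emg <- channelSignal(rec, "emg")
  nEp <- length(eeg) %/% n
  if (nEp < 1L) stop("recording shorter than one epoch")
  if (length(eeg) %% n != 0L)
    warning("trailing partial epoch dropped (", length(eeg) %% n, " samples)")
  df <- fs / n
  kAll <- seq_len(floor(n / 2) - 1L)
  fPos <- kAll * df
  selD <- fPos >= 0.5 - 1e-9 & fPos < 4 - 1e-9
  selT <- fPos >= 6 - 1e-9 & fPos < 10 - 1e-9
  selTot <- fPos >= 0.5 - 1e-9 & fPos < 30 - 1e-9
  delta <- theta <- total <- peak <- numeric(nEp)
  chunk <- 1440L
  for (s0 in seq(1L, nEp, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, nEp)
    seg <- matrix(eeg[((s0 - 1L) * n + 1L):(s1 * n)], nrow = n)
    X <- stats::mvfft(seg)
    # one-sided density on positive bins: 2|X|^2 / (N^2 df)
    P <- 2 * Mod(X[kAll + 1L, , drop = FALSE])^2 / (n^2 * df)
    delta[s0:s1] <- colSums(P[selD, , drop = FALSE]) * df
    theta[s0:s1] <- colSums(P[selT, , drop = FALSE]) * df
    total[s0:s1] <- colSums(P[selTot, , drop = FALSE]) * df
    peak[s0:s1] <- apply(abs(seg), 2, max)
  }
  emgM <- matrix(emg[seq_len(nEp * n)], nrow = n)
  emgRms <- sqrt(colMeans(emgM^2))
  tb <- data.frame(epoch = seq_len(nEp),
                   zt_s = rec@ztStartS + (seq_len(nEp) - 1) * epochS,
                   delta = delta, theta = theta, total = total,
                   emg_rms = emgRms, peak_uv = peak)
  new("EpochFeatures", table = tb, fs = fs, epochS = epochS,
      channel = channel)
}

#' Calibrate staging thresholds
#'
#' Default mode sets both decision thresholds from per-recording quantiles of
#' the epoch feature distributions, which makes the downstream staging
#' decisions invariant to multiplying the recording by any positive constant.
#' The EMG wake threshold is the 0.60 quantile of the epoch EMG-RMS
#' distribution. The delta NREM threshold is placed in the gap between the
#' low-delta (wake/REM) and high-delta (NREM) clusters as the geometric
#' midpoint of a quantile bracket (defaults 0.30 and 0.97): a single delta
#' quantile would have to equal the recording's actual non-NREM fraction,
#' which shifts with sleep restriction and phenotype, whereas the bracket
#' midpoint lands between the clusters for any NREM fraction from roughly 5%
#' to 65%. The theta/delta REM ratio (1.5) and the artifact screens (absolute
#' amplitude 400 uV, total-power z-score 6) are absolute defaults.
#'
#' @param features An `EpochFeatures` object (>= 360 epochs recommended; a
#'   warning is issued below that).
#' @param mode `"per-recording-quantile"` (default) or `"absolute"` (supply
#'   `emgThreshold`/`deltaThreshold` directly).
#' @param emgWakeQuantile EMG calibration quantile in (0, 1).
#' @param deltaQuantiles Length-2 delta-power quantile bracket; the threshold
#'   is the geometric mean of the two quantile values.
#' @param thetaDeltaRemRatio REM rule ratio threshold.
#' @param artifactAmplitudeUv,artifactPowerZscore Artifact screen settings.
#' @param emgThreshold,deltaThreshold Absolute thresholds (mode
#'   `"absolute"` only).
#' @return A `StagerThresholds` object.
#' @export
calibrateThresholds <- function(features, mode = "per-recording-quantile",
                                emgWakeQuantile = 0.60,
                                deltaQuantiles = c(0.30, 0.97),
                                thetaDeltaRemRatio = 1.5,
                                artifactAmplitudeUv = 400,
                                artifactPowerZscore = 6,
                                emgThreshold = NULL, deltaThreshold = NULL) {
  tb <- featureTable(features)
  if (nrow(tb) < 360)
    warning("fewer than 360 epochs; quantile calibration may be unstable")
  if (mode == "per-recording-quantile") {
    for (col in c("emg_rms", "delta")) {
      if (stats::sd(tb[[col]]) == 0)
        stop("degenerate (constant) feature channel: ", col)
    }
    emgThr <- unname(stats::quantile(tb$emg_rms, emgWakeQuantile))
    dq <- unname(stats::quantile(tb$delta, deltaQuantiles))
    deltaThr <- sqrt(prod(dq))
  } else if (mode == "absolute") {
    if (is.null(emgThreshold) || is.null(deltaThreshold))
      stop("absolute mode requires emgThreshold and deltaThreshold")
    emgThr <- emgThreshold
    deltaThr <- deltaThreshold
  } else stop("unknown calibration mode: ", mode)
  new("StagerThresholds", mode = if (mode == "absolute") "absolute"
        else "per-recording-quantile",
      emgWakeQuantile = emgWakeQuantile,
      deltaQuantiles = deltaQuantiles,
      thetaDeltaRemRatio = thetaDeltaRemRatio,
      artifactAmplitudeUv = artifactAmplitudeUv,
      artifactPowerZscore = artifactPowerZscore,
      emgThreshold = emgThr, deltaThreshold = deltaThr)
}

#' Artifact detection
#'
#' Flags an epoch if its peak absolute EEG amplitude exceeds the artifact
#' amplitude threshold, or if its total-power z-score (relative to the
#' recording's epoch distribution) exceeds the z threshold.
#'
#' @param features An `EpochFeatures` object.
#' @param thr A `StagerThresholds` object.
#' @return Logical vector, one flag per epoch.
#' @export
detectArtifacts <- function(features, thr) {
  tb <- featureTable(features)
  sdP <- stats::sd(tb$total)
  if (!is.finite(sdP) || sdP == 0)
    stop("total-power z-score undefined: constant (or degenerate) signal")
  z <- (tb$total - mean(tb$total)) / sdP
  tb$peak_uv > thr@artifactAmplitudeUv | z > thr@artifactPowerZscore
}

#' Classify epochs into a hypnogram
#'
#' Deterministic per-epoch decision rule, applied in order: (1) artifact
#' screens ([detectArtifacts()]); (2) EMG RMS above the wake threshold ->
#' WAKE; (3) else theta/delta ratio above the REM ratio AND delta below the
#' NREM threshold -> REM; (4) else delta above the NREM threshold -> NREM;
#' (5) else WAKE. An optional 3-epoch majority filter (off by default, since
#' scoring is epoch-wise) can smooth isolated single-epoch states.
#'
#' @param features An `EpochFeatures` object.
#' @param thr A calibrated `StagerThresholds`.
#' @param smooth If `TRUE`, apply a 3-epoch majority filter to the non-artifact
#'   labels.
#' @return A [hypnogram()].
#' @export
classifyEpochs <- function(features, thr, smooth = FALSE) {
  tb <- featureTable(features)
  art <- detectArtifacts(features, thr)
  ratio <- ifelse(tb$delta > 0, tb$theta / tb$delta, Inf)
  lab <- ifelse(tb$emg_rms > thr@emgThreshold, "WAKE",
           ifelse(ratio > thr@thetaDeltaRemRatio &
                    tb$delta < thr@deltaThreshold, "REM",
             ifelse(tb$delta > thr@deltaThreshold, "NREM", "WAKE")))
  lab[art] <- "ARTIFACT"
  if (smooth && length(lab) >= 3) {
    sm <- lab
    for (i in 2:(length(lab) - 1)) {
      if (lab[i] != "ARTIFACT" && lab[i - 1] == lab[i + 1] &&
          lab[i] != lab[i - 1] && lab[i - 1] != "ARTIFACT")
        sm[i] <- lab[i - 1]
    }
    lab <- sm
  }
  hypnogram(lab, epochS = features@epochS,
            ztStartS = tb$zt_s[1])
}

#' Artifact exclusion rule
#'
#' A recording is excluded from all analyses when strictly more than 5% of
#' its epochs are artifact; a file at exactly 5% is included.
#'
#' @param hyp A [hypnogram()].
#' @param maxFraction Exclusion threshold (0.05).
#' @return List with `included` (logical) and `artifact_fraction`.
#' @examples
#' exclusionCheck(hypnogram(c(rep("NREM", 94), rep("ARTIFACT", 6))))
#' @export
exclusionCheck <- function(hyp, maxFraction = 0.05) {
  f <- artifactFraction(hyp)
  list(included = !(f > maxFraction), artifact_fraction = f)
}

#' Inter-scorer epoch agreement
#'
#' Percent of epochs with identical labels between two hypnograms of equal
#' length; ARTIFACT counts as a class. Symmetric in its arguments.
#'
#' @param h1,h2 [hypnogram()] objects with equal length and epoch size.
#' @param exclude Optional state label(s): epochs carrying one of these in
#'   *either* hypnogram are dropped from the comparison (e.g.
#'   `exclude = "ARTIFACT"` scores agreement over artifact-free epochs only).
#' @return Agreement in percent.
#' @export
agreement <- function(h1, h2, exclude = NULL) {
  if (nEpochs(h1) != nEpochs(h2) || h1@epochS != h2@epochS)
    stop("hypnograms must have equal length and epoch size")
  a <- states(h1); b <- states(h2)
  if (!is.null(exclude)) {
    keep <- !(a %in% exclude) & !(b %in% exclude)
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) == 0L) stop("no epochs left to compare")
  100 * mean(a == b)
}
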