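# Shared fixture builders: everything is generated in code at test time.

# tiny recording with known sinusoidal/noise content
toneRecording <- function(freqHz, nEpochs = 1, fs = 100, amp = 1,
                          emgSd = 1, seed = 1) {
  set.seed(seed)
  n <- nEpochs * 10 * fs
  t <- seq_len(n) / fs
  recording(list(eeg_frontal = amp * sin(2 * pi * freqHz * t),
                 eeg_parietal = amp * sin(2 * pi * freqHz * t),
                 emg = rnorm(n, sd = emgSd)), fs = fs)
}

# EpochFeatures built directly from a table (for deterministic rule tests)
featuresFromTable <- function(tb, fs = 100, epochS = 10) {
  if (is.null(tb$zt_s)) tb$zt_s <- (tb$epoch - 1) * epochS
  if (is.null(tb$peak_uv)) tb$peak_uv <- 50
  new("EpochFeatures", table = tb, fs = fs, epochS = epochS,
      channel = "eeg_frontal")
}

absThresholds <- function(emg = 20, delta = 450, ratio = 1.5,
                          amp = 400, z = 6) {
  suppressWarnings(calibrateThresholds(
    featuresFromTable(data.frame(epoch = 1:2, delta = c(1, 2),
                                 theta = c(1, 1), total = c(3, 4),
                                 emg_rms = c(1, 2))),
    mode = "absolute", emgThreshold = emg, deltaThreshold = delta,
    thetaDeltaRemRatio = ratio, artifactAmplitudeUv = amp,
    artifactPowerZscore = z))
}

randomHypnogram <- function(n, seed, states = c("WAKE", "NREM", "REM"),
                            prob = NULL) {
  set.seed(seed)
  hypnogram(sample(states, n, replace = TRUE, prob = prob))
}

# keep only epochs whose *truth* label is not ARTIFACT, then score agreement;
# false artifact calls by the stager on clean epochs still count as misses
agreementOnCleanTruth <- function(staged, truth) {
  keep <- states(truth) != "ARTIFACT"
  agreement(hypnogram(states(staged)[keep]), hypnogram(states(truth)[keep]))
}

# independent classical balanced mixed-ANOVA oracle (cell-mean formulas):
# between factors A, B (2 levels each), within factor time; n per cell equal.
balancedMixedAnovaOracle <- function(d) {
  # d: subject_id, A, B, time, value; balanced
  ybar <- mean(d$value)
  tlev <- unique(d$time); a <- unique(d$A); b <- unique(d$B)
  nt <- length(tlev)
  subj <- unique(d[, c("subject_id", "A", "B")])
  nPerCell <- nrow(subj) / (length(a) * length(b))
  cellMean <- function(...) {
    sel <- rep(TRUE, nrow(d))
    args <- list(...)
    for (nm in names(args)) sel <- sel & d[[nm]] == args[[nm]]
    mean(d$value[sel])
  }
  SS_A <- nt * nPerCell * length(b) *
    sum(sapply(a, function(ai) (cellMean(A = ai) - ybar)^2))
  SS_B <- nt * nPerCell * length(a) *
    sum(sapply(b, function(bi) (cellMean(B = bi) - ybar)^2))
  SS_AB <- nt * nPerCell *
    sum(sapply(a, function(ai) sapply(b, function(bi)
      (cellMean(A = ai, B = bi) - cellMean(A = ai) - cellMean(B = bi) +
         ybar)^2)))
  SS_T <- nrow(subj) *
    sum(sapply(tlev, function(ti) (cellMean(time = ti) - ybar)^2))
  SS_AT <- nPerCell * length(b) *
    sum(sapply(a, function(ai) sapply(tlev, function(ti)
      (cellMean(A = ai, time = ti) - cellMean(A = ai) - cellMean(time = ti) +
         ybar)^2)))
  SS_BT <- nPerCell * length(a) *
    sum(sapply(b, function(bi) sapply(tlev, function(ti)
      (cellMean(B = bi, time = ti) - cellMean(B = bi) - cellMean(time = ti) +
         ybar)^2)))
  SS_ABT <- nPerCell *
    sum(sapply(a, function(ai) sapply(b, function(bi) sapply(tlev,
      function(ti)
        (cellMean(A = ai, B = bi, time = ti) - cellMean(A = ai, B = bi) -
           cellMean(A = ai, time = ti) - cellMean(B = bi, time = ti) +
           cellMean(A = ai) + cellMean(B = bi) + cellMean(time = ti) -
           ybar)^2))))
  # subjects-within-groups stratum
  SS_subj <- nt * sum(sapply(seq_len(nrow(subj)), function(i) {
    sm <- mean(d$value[d$subject_id == subj$subject_id[i]])
    (sm - cellMean(A = subj$A[i], B = subj$B[i]))^2
  }))
  SS_total <- sum((d$value - ybar)^2)
  SS_err_w <- SS_total - SS_A - SS_B - SS_AB - SS_subj - SS_T - SS_AT -
    SS_BT - SS_ABT
  dfSubj <- nrow(subj) - length(a) * length(b)
  dfW <- dfSubj * (nt - 1)
  mk <- function(ss, df) (ss / df)
  list(
    F_A = mk(SS_A, 1) / mk(SS_subj, dfSubj),
    F_B = mk(SS_B, 1) / mk(SS_subj, dfSubj),
    F_AB = mk(SS_AB, 1) / mk(SS_subj, dfSubj),
    F_T = mk(SS_T, nt - 1) / mk(SS_err_w, dfW),
    F_AT = mk(SS_AT, nt - 1) / mk(SS_err_w, dfW),
    F_BT = mk(SS_BT, nt - 1) / mk(SS_err_w, dfW),
    F_ABT = mk(SS_ABT, nt - 1) / mk(SS_err_w, dfW),
    SS = c(A = SS_A, B = SS_B, AB = SS_AB, subj = SS_subj, T = SS_T,
           AT = SS_AT, BT = SS_BT, ABT = SS_ABT, errW = SS_err_w,
           total = SS_total))
}
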