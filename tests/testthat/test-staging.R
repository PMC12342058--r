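test_that("feature extraction yields one row per epoch with tone powers in band", {
  rec <- toneRecording(2, nEpochs = 6)
  ef <- extractFeatures(rec)
  tb <- featureTable(ef)
  expect_equal(nrow(tb), 6)
  expect_true(all(tb$delta / tb$total > 0.999))
  expect_true(all(tb$delta <= tb$total))
  # trailing partial epoch dropped with a warning
  short <- recording(list(eeg_frontal = rnorm(1500), eeg_parietal = rnorm(1500),
                          emg = rnorm(1500)), fs = 100)
  expect_warning(ef2 <- extractFeatures(short), "partial epoch")
  expect_equal(nrow(featureTable(ef2)), 1)
  expect_error(extractFeatures(recording(list(eeg_frontal = rnorm(1000)),
                                         fs = 100)), "emg")
})

test_that("quantile calibration is scale and order invariant; degenerate input errors", {
  p <- simParams(seed = 8, artifactFraction = 0)
  h <- simulateHypnogram(p)
  h1 <- hypnogram(states(h)[1:720])
  s <- homeostatTrajectory(h1, p)
  rec <- synthesizeSignals(h1, s, p)
  ef <- extractFeatures(rec)
  thr <- calibrateThresholds(ef)
  hyp1 <- classifyEpochs(ef, thr)
  # multiply every channel by 10: identical staging decisions
  rec10 <- recording(lapply(rec@channels, function(x) 10 * x), fs = 100)
  ef10 <- extractFeatures(rec10)
  thr10 <- calibrateThresholds(ef10, artifactAmplitudeUv = 4000)
  hyp10 <- classifyEpochs(ef10, thr10)
  expect_identical(states(hyp1), states(hyp10))
  # shuffling epochs leaves the thresholds unchanged (quantiles are order-free)
  tb <- featureTable(ef)
  set.seed(1)
  efShuf <- featuresFromTable(tb[sample(nrow(tb)), ])
  thrShuf <- calibrateThresholds(efShuf)
  expect_equal(thrShuf@emgThreshold, thr@emgThreshold)
  expect_equal(thrShuf@deltaThreshold, thr@deltaThreshold)
  # constant EMG errors, naming the flat channel
  tbc <- tb; tbc$emg_rms <- 5
  expect_error(calibrateThresholds(featuresFromTable(tbc)), "emg_rms")
})

test_that("the decision rules fire in the specified order", {
  thr <- absThresholds(emg = 20, delta = 450, ratio = 1.5)
  tb <- data.frame(
    epoch = 1:5,
    delta = c(100, 600, 100, 600, 100),
    theta = c(300, 100, 50, 1200, 100),
    total = c(1000, 1000, 1000, 2000, 1000),
    emg_rms = c(5, 5, 5, 50, 5),
    peak_uv = c(50, 50, 50, 50, 900))
  h <- classifyEpochs(featuresFromTable(tb), thr)
  # 1: low EMG, low delta, ratio 3 -> REM; 2: high delta -> NREM;
  # 3: nothing fires -> WAKE; 4: high EMG wins despite high delta -> WAKE;
  # 5: amplitude artifact screen first
  expect_equal(states(h), c("REM", "NREM", "WAKE", "WAKE", "ARTIFACT"))
  # determinism
  expect_identical(states(classifyEpochs(featuresFromTable(tb), thr)),
                   states(h))
})

test_that("artifact screens catch injected transients and reject degenerate input", {
  p <- simParams(seed = 2, artifactFraction = 0)
  hits <- total <- 0
  for (sd in 1:20) {
    p2 <- simParams(seed = sd, artifactFraction = 0)
    h <- simulateHypnogram(p2)
    h1 <- hypnogram(states(h)[1:360])
    rec <- synthesizeSignals(h1, homeostatTrajectory(h1, p2), p2)
    ef <- extractFeatures(rec)
    thr <- calibrateThresholds(ef)
    if (sd == 1) expect_equal(sum(detectArtifacts(ef, thr)), 0)  # clean file
    inj <- injectArtifacts(rec, h1, 0.05, seed = sd)
    efI <- extractFeatures(inj$recording)
    thrI <- calibrateThresholds(efI)
    flag <- detectArtifacts(efI, thrI)
    injected <- states(inj$hypnogram) == "ARTIFACT"
    hits <- hits + sum(flag[injected])
    total <- total + sum(injected)
  }
  expect_gte(hits / total, 0.9)
  zero <- recording(list(eeg_frontal = numeric(3000),
                         eeg_parietal = numeric(3000),
                         emg = numeric(3000)), fs = 100)
  suppressWarnings(efZ <- extractFeatures(zero))
  expect_error(detectArtifacts(efZ, absThresholds()), "undefined")
})

test_that("the 5% artifact exclusion rule uses a strict inequality", {
  h6 <- hypnogram(c(rep("ARTIFACT", 518), rep("NREM", 8640 - 518)))
  expect_false(exclusionCheck(h6)$included)
  h5 <- hypnogram(c(rep("ARTIFACT", 432), rep("NREM", 8640 - 432)))
  expect_true(exclusionCheck(h5)$included)
  expect_equal(exclusionCheck(h5)$artifact_fraction, 0.05)
  expect_true(exclusionCheck(hypnogram(rep("WAKE", 100)))$included)
})

test_that("epoch agreement is a symmetric percentage with ARTIFACT as a class", {
  h <- randomHypnogram(8640, 1, states = epochStates())
  expect_equal(agreement(h, h), 100)
  st2 <- states(h)
  flip <- 1:864
  st2[flip] <- ifelse(st2[flip] == "WAKE", "NREM", "WAKE")
  h2 <- hypnogram(st2)
  expect_equal(agreement(h, h2), 90)
  expect_equal(agreement(h, h2), agreement(h2, h))
  expect_error(agreement(h, hypnogram(rep("WAKE", 10))), "equal length")
})

test_that("the stager recovers generating truth per state on synthetic days", {
  recall <- matrix(NA_real_, 3, 3,
                   dimnames = list(NULL, c("WAKE", "NREM", "REM")))
  for (sd in 1:3) {
    day <- simulateRecordingDay(simParams(seed = sd))
    half <- 4320
    truth <- hypnogram(states(day$hypnogram)[1:half])
    rec <- recording(lapply(day$recording@channels, function(x)
      x[1:(half * 1000)]), fs = 100)
    ef <- extractFeatures(rec)
    staged <- classifyEpochs(ef, calibrateThresholds(ef))
    for (s in colnames(recall)) {
      sel <- states(truth) == s
      recall[sd, s] <- mean(states(staged)[sel] == s)
    }
  }
  expect_true(all(recall[, "WAKE"] >= 0.9))
  expect_true(all(recall[, "NREM"] >= 0.9))
  expect_true(all(recall[, "REM"] >= 0.8))
})
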