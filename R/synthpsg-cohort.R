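# Cohort-level simulation: one male-female pair per cage, a 13-day protocol
# (baseline, sleep restriction, ten defeat days, post-defeat), and pre/post
# arena trials.

# label-level artifact injection for days without synthesized signals
.injectArtifactLabels <- function(hyp, fraction, seed) {
  nEp <- nEpochs(hyp)
  k <- round(fraction * nEp)
  if (k == 0) return(hyp)
  set.seed(.childSeed(seed, 2))
  st <- states(hyp)
  st[sort(sample.int(nEp, k))] <- "ARTIFACT"
  hypnogram(st, epochS = hyp@epochS, ztStartS = hyp@ztStartS)
}

#' Default per-subject preset table
#'
#' One male and one female per pair; phenotypes drawn with the susceptibility
#' rates of the emulated study design (50% of males, 60% of females
#' susceptible). Post-defeat arena bias is +2.5 (approach) for resilient and
#' -2.5 (avoidance) for susceptible subjects; pre-defeat bias is 0.
#'
#' @param nPairs Number of male-female pairs.
#' @param seed Integer seed for the phenotype draw.
#' @return Data.frame with `subject_id`, `pair`, `sex`, `preset`,
#'   `artifact_fraction`, `pre_bias`, `post_bias`.
#' @export
defaultPresetTable <- function(nPairs, seed = 1) {
  set.seed(.childSeed(seed, 4))
  rows <- do.call(rbind, lapply(seq_len(nPairs), function(i) {
    data.frame(pair = i, sex = c("male", "female"),
               susceptible = stats::runif(2) < c(0.5, 0.6))
  }))
  phen <- ifelse(rows$susceptible, "susceptible", "resilient")
  data.frame(
    subject_id = sprintf("s%02d_%s", rows$pair, substr(rows$sex, 1, 1)),
    pair = rows$pair, sex = rows$sex,
    preset = paste(rows$sex, phen, sep = "_"),
    artifact_fraction = 0.02,
    pre_bias = 0,
    post_bias = ifelse(phen == "resilient", 2.5, -2.5),
    stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' For every subject: the complete protocol hypnogram (one day per protocol
#' row), the homeostat trajectory, EEG/EMG recordings for the requested day
#' kinds (with artifact injection at the subject's artifact fraction), label
#' level artifact injection on the remaining days, and pre/post arena trial
#' pairs. Everything is a pure function of the master seed: per-subject and
#' per-day child seeds are derived by a fixed splitting rule.
#'
#' @param nPairs Number of male-female pairs (>= 1).
#' @param seed Master seed.
#' @param presetTable Per-subject table as from [defaultPresetTable()]
#'   (which is the default); must have one row per subject (2 x `nPairs`).
#' @param schedule A [protocolSchedule()]; default [defaultProtocol()].
#' @param signalDays Day kinds for which raw signals are synthesized; use
#'   `character(0)` for a (much faster) hypnogram-level cohort.
#' @return A list (class `CohortBundle`) with `subjects` (named list; each
#'   has `params`, `hyps` truth hypnograms per day, `hypsObserved` with
#'   artifacts injected, `recordings` by day index, `arena` with `pre`/`post`
#'   trial pairs) and `manifest` (design table: subject, day, kind, seeds).
#' @export
simulateCohort <- function(nPairs, seed = 1, presetTable = NULL,
                           schedule = defaultProtocol(),
                           signalDays = c("baseline", "sleep_restriction",
                                          "post_defeat")) {
  if (nPairs < 1) stop("nPairs must be >= 1")
  if (is.null(presetTable)) presetTable <- defaultPresetTable(nPairs, seed)
  if (nrow(presetTable) != 2 * nPairs)
    stop("presetTable must have one row per subject (2 * nPairs)")
  days <- protocolDays(schedule)
  epd <- as.integer(24 * 3600 / 10)
  subjects <- list()
  manifest <- NULL
  for (si in seq_len(nrow(presetTable))) {
    row <- presetTable[si, ]
    subjSeed <- .childSeed(seed, si)
    params <- simParams(row$preset, seed = subjSeed,
                        artifactFraction = row$artifact_fraction)
    full <- simulateHypnogram(params, schedule)
    s <- homeostatTrajectory(full, params)
    hyps <- hypsObs <- vector("list", nrow(days))
    recordings <- list()
    for (di in seq_len(nrow(days))) {
      idx <- ((di - 1L) * epd + 1L):(di * epd)
      h <- hypnogram(states(full)[idx], ztStartS = 0)
      hyps[[di]] <- h
      daySeed <- .childSeed(subjSeed, 100 + di)
      if (days$kind[di] %in% signalDays) {
        rec <- synthesizeSignals(h, s[idx], params, seed = daySeed)
        inj <- injectArtifacts(rec, h, row$artifact_fraction, seed = daySeed)
        recordings[[as.character(di)]] <- inj$recording
        hypsObs[[di]] <- inj$hypnogram
      } else {
        hypsObs[[di]] <- .injectArtifactLabels(h, row$artifact_fraction,
                                               daySeed)
      }
    }
    arena <- list(
      pre = simulateArena(attractionBias = row$pre_bias,
                          seed = .childSeed(subjSeed, 201)),
      post = simulateArena(attractionBias = row$post_bias,
                           seed = .childSeed(subjSeed, 202)))
    subjects[[row$subject_id]] <- list(
      id = row$subject_id, sex = row$sex, preset = row$preset,
      params = params, hyps = hyps, hypsObserved = hypsObs,
      recordings = recordings, arena = arena, s = s)
    manifest <- rbind(manifest, data.frame(
      subject_id = row$subject_id, pair = row$pair, sex = row$sex,
      preset = row$preset, day_index = days$day_index, kind = days$kind,
      has_signals = days$kind %in% signalDays,
      day_seed = vapply(days$day_index,
                        function(di) .childSeed(subjSeed, 100 + di),
                        integer(1)),
      stringsAsFactors = FALSE))
  }
  structure(list(subjects = subjects, manifest = manifest,
                 presetTable = presetTable, seed = seed,
                 schedule = schedule),
            class = "CohortBundle")
}

#' @export
print.CohortBundle <- function(x, ...) {
  cat(sprintf("CohortBundle: %d subjects x %d days (master seed %g)\n",
              length(x$subjects), nrow(protocolDays(x$schedule)), x$seed))
  invisible(x)
}
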