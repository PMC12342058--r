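# End-to-end study orchestration on a synthetic cohort:
# generate -> stage -> spectral -> architecture -> behavior -> stats.

#' Study configuration
#'
#' Collects the knobs of [runStudy()]. All seeds are explicit: nothing is
#' seeded from the wall clock.
#'
#' @param nPairs Number of male-female pairs.
#' @param seed Master seed.
#' @param presetTable Optional per-subject table (see [defaultPresetTable()]).
#' @param signalDays Day kinds with raw-signal synthesis and automatic
#'   staging; `character(0)` runs the (fast) hypnogram-level pipeline in
#'   which true hypnograms feed the architecture stages directly.
#' @param swaBin Time-course bin width in hours.
#' @return A list of class `StudyConfig`.
#' @export
studyConfig <- function(nPairs = 15, seed = 1, presetTable = NULL,
                        signalDays = c("baseline", "sleep_restriction",
                                       "post_defeat"),
                        swaBin = 1) {
  structure(list(nPairs = nPairs, seed = seed, presetTable = presetTable,
                 signalDays = signalDays, swaBin = swaBin),
            class = "StudyConfig")
}

# exclusion bookkeeping shared by runStudy and the tests: behavioral rows are
# never excluded; sleep analyses drop artifact>5% files and SIR in [0.9, 1.1].
applyExclusionRules <- function(behaviorTable, artifactTable) {
  excl <- NULL
  if (!is.null(artifactTable) && nrow(artifactTable)) {
    bad <- artifactTable[artifactTable$artifact_fraction > 0.05, ,
                         drop = FALSE]
    if (nrow(bad))
      excl <- rbind(excl, data.frame(subject_id = unique(bad$subject_id),
                                     reason = "artifact>5%",
                                     stringsAsFactors = FALSE))
  }
  post <- behaviorTable[behaviorTable$day == "post", , drop = FALSE]
  band <- post$subject_id[post$phenotype == "excluded"]
  if (length(band))
    excl <- rbind(excl, data.frame(subject_id = band,
                                   reason = "SIR in [0.9, 1.1]",
                                   stringsAsFactors = FALSE))
  if (is.null(excl))
    excl <- data.frame(subject_id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  excl
}

#' Run the full synthetic study
#'
#' Executes every pipeline stage in order on a simulated cohort and returns
#' the analysis tables: social-interaction scores pre/post, baseline sleep
#' and SWA time courses, bout statistics, relative SWA by EEG lead,
#' sleep lost and recovery after restriction with slow-wave energy, and the
#' pre/post-defeat sleep change, each with its ANOVA block where the design
#' permits. Exclusion rules are applied throughout: recordings with more than
#' 5% artifact epochs and subjects with a post-defeat interaction ratio in
#' [0.9, 1.1] are dropped from sleep analyses (the latter stay in the
#' behavioral tables). The report is a pure function of the configuration.
#'
#' @param config A [studyConfig()].
#' @return A list of class `StudyReport`; see Details. Fields: `behavior`,
#'   `baseline_timecourse`, `bouts`, `relative_swa`, `sleep_lost`,
#'   `recovery`, `swe`, `pre_post`, `anova` (named list of ANOVA tables),
#'   `exclusions`, `staging_agreement`, `provenance`.
#' @export
runStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "StudyConfig"))
  cohort <- simulateCohort(config$nPairs, seed = config$seed,
                           presetTable = config$presetTable,
                           signalDays = config$signalDays)
  days <- protocolDays(cohort$schedule)
  dBase <- which(days$kind == "baseline")[1]
  dSr <- which(days$kind == "sleep_restriction")[1]
  dPost <- which(days$kind == "post_defeat")[1]

  # --- behavior ------------------------------------------------------------
  behavior <- NULL
  for (s in cohort$subjects) {
    for (day in c("pre", "post")) {
      sc <- scoreInteraction(s$arena[[day]])
      behavior <- rbind(behavior,
                        cbind(data.frame(subject_id = s$id, sex = s$sex,
                                         day = day,
                                         stringsAsFactors = FALSE), sc))
    }
  }

  # --- staging (signal days) ----------------------------------------------
  useSignals <- length(config$signalDays) > 0
  stagedHyp <- list()   # stagedHyp[[subject]][[dayIndex]]
  artifactTable <- NULL
  agree <- NULL
  for (s in cohort$subjects) {
    stagedHyp[[s$id]] <- s$hypsObserved
    for (di in names(s$recordings)) {
      dii <- as.integer(di)
      ef <- extractFeatures(s$recordings[[di]])
      thr <- calibrateThresholds(ef)
      h <- classifyEpochs(ef, thr)
      stagedHyp[[s$id]][[dii]] <- h
      artifactTable <- rbind(artifactTable, data.frame(
        subject_id = s$id, day_index = dii,
        artifact_fraction = artifactFraction(h), stringsAsFactors = FALSE))
      agree <- c(agree, agreement(h, s$hypsObserved[[dii]],
                                  exclude = "ARTIFACT"))
    }
    if (!useSignals) {
      for (di in c(dBase, dSr, dPost)) {
        artifactTable <- rbind(artifactTable, data.frame(
          subject_id = s$id, day_index = di,
          artifact_fraction = artifactFraction(s$hypsObserved[[di]]),
          stringsAsFactors = FALSE))
      }
    }
  }

  # --- exclusions ----------------------------------------------------------
  exclusions <- applyExclusionRules(behavior, artifactTable)
  post <- behavior[behavior$day == "post", ]
  phenotype <- stats::setNames(post$phenotype, post$subject_id)
  sleepIds <- setdiff(names(cohort$subjects), exclusions$subject_id)

  # --- architecture + spectral tables -------------------------------------
  baselineTc <- bouts <- relSwa <- lostTab <- recTab <- sweTab <-
    prePost <- NULL
  for (id in sleepIds) {
    s <- cohort$subjects[[id]]
    phen <- phenotype[[id]]
    hB <- stagedHyp[[id]][[dBase]]
    hS <- stagedHyp[[id]][[dSr]]
    hP <- stagedHyp[[id]][[dPost]]
    meta <- data.frame(subject_id = id, sex = s$sex, phenotype = phen,
                       stringsAsFactors = FALSE)
    # baseline NREM minutes per 6 h bin (time course for the mixed ANOVA)
    for (b in seq(0, 18, by = 6)) {
      baselineTc <- rbind(baselineTc, cbind(meta, data.frame(
        time = sprintf("zt%02d", b),
        nrem_min = unname(stateMinutes(hB, c(b, b + 6))$minutes["NREM"]),
        rem_min = unname(stateMinutes(hB, c(b, b + 6))$minutes["REM"]))))
    }
    bs <- boutStats(segmentBouts(hB))
    bouts <- rbind(bouts, cbind(meta[rep(1, nrow(bs)), ], bs))
    lost <- sleepLost(hB, hS)$lost
    lostTab <- rbind(lostTab, cbind(meta, data.frame(
      nrem_lost_min = unname(lost["NREM"]),
      rem_lost_min = unname(lost["REM"]))))
    rec <- recoverySleep(hB, hS, window = c(6, 24))
    recTab <- rbind(recTab, cbind(meta, data.frame(
      nrem_recovered_min = rec$cum_gain_min[nrow(rec)])))
    ppBase <- stateMinutes(hB, c(0, 24))$minutes["NREM"]
    ppPost <- stateMinutes(hP, c(0, 24))$minutes["NREM"]
    prePost <- rbind(prePost, cbind(meta, data.frame(
      pre_nrem_min = unname(ppBase), post_nrem_min = unname(ppPost),
      delta_nrem_min = unname(ppPost - ppBase))))
    if (useSignals) {
      recB <- s$recordings[[as.character(dBase)]]
      recS <- s$recordings[[as.character(dSr)]]
      for (lead in c("eeg_frontal", "eeg_parietal")) {
        stB <- spectralTable(recB, hB, channel = lead)
        nrem <- stB$state == "NREM"
        relSwa <- rbind(relSwa, cbind(meta, data.frame(
          lead = lead,
          rel_swa_pct = mean(stB$rel_swa_pct[nrem]))))
      }
      stS <- spectralTable(recS, hS)
      stB <- spectralTable(recB, hB)
      base <- stB$delta[stB$state == "NREM"]
      norm <- normalizedSwa(stS$delta, base)
      recovery <- stS$zt_s / 3600 >= 6
      sweTab <- rbind(sweTab, cbind(meta, data.frame(
        swe_final = max(slowWaveEnergy(stS$delta[recovery],
                                       stS$state[recovery] == "NREM")),
        swa_mean_norm_pct = mean(norm[recovery & stS$state == "NREM"]))))
    }
  }

  # --- stats blocks --------------------------------------------------------
  anova <- list()
  runAov <- function(tab, valueCol, between) {
    tab$value <- tab[[valueCol]]
    ok <- tryCatch({
      for (b in between)
        if (length(unique(tab[[b]])) < 2) stop("single level")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) return(NULL)
    tryCatch(mixedAnova(tab, between = between, within = "time"),
             error = function(e) NULL)
  }
  if (!is.null(baselineTc)) {
    anova$baseline_nrem <- runAov(baselineTc, "nrem_min",
                                  c("sex", "phenotype"))
    anova$baseline_rem <- runAov(baselineTc, "rem_min", c("sex", "phenotype"))
  }
  if (!is.null(prePost)) {
    pp <- prePost
    long <- rbind(
      data.frame(pp[c("subject_id", "sex", "phenotype")], time = "pre",
                 value = pp$pre_nrem_min),
      data.frame(pp[c("subject_id", "sex", "phenotype")], time = "post",
                 value = pp$post_nrem_min))
    anova$pre_post_nrem <- tryCatch(
      mixedAnova(long, between = c("sex", "phenotype"), within = "time"),
      error = function(e) NULL)
  }

  structure(list(
    behavior = behavior, baseline_timecourse = baselineTc, bouts = bouts,
    relative_swa = relSwa, sleep_lost = lostTab, recovery = recTab,
    swe = sweTab, pre_post = prePost, anova = anova,
    exclusions = exclusions,
    staging_agreement = if (is.null(agree)) NA_real_ else mean(agree),
    provenance = list(seed = config$seed, nPairs = config$nPairs,
                      signalDays = config$signalDays,
                      config = config)),
    class = "StudyReport")
}

#' @export
print.StudyReport <- function(x, ...) {
  cat(sprintf("StudyReport: %d subjects, seed %g\n",
              length(unique(x$behavior$subject_id)), x$provenance$seed))
  cat(sprintf("  exclusions: %d; mean staging agreement: %s\n",
              nrow(x$exclusions),
              if (is.na(x$staging_agreement)) "n/a (hypnogram-level run)"
              else sprintf("%.1f%%", x$staging_agreement)))
  invisible(x)
}

#' Exclusion audit
#'
#' Table of subjects excluded from sleep analyses with the rule that removed
#' them (`artifact>5%` or `SIR in [0.9, 1.1]`). Excluded subjects still
#' appear in the report's behavioral tables.
#'
#' @param report A `StudyReport` from [runStudy()].
#' @return Data.frame with `subject_id` and `reason` (empty when nothing was
#'   excluded).
#' @export
exclusionAudit <- function(report) {
  stopifnot(inherits(report, "StudyReport"))
  report$exclusions
}
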