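#' @import methods
NULL

## Canonical epoch labels. ARTIFACT is a first-class scoring category:
## epochs carrying it are excluded from every spectral/architecture aggregate.
.STATES <- c("WAKE", "NREM", "REM", "ARTIFACT")
.SLEEP_STATES <- c("NREM", "REM")

#' Epoch state labels
#'
#' Canonical label set used throughout the package: `WAKE`, `NREM`, `REM`,
#' `ARTIFACT`.
#'
#' @return Character vector of the four epoch labels.
#' @export
epochStates <- function() .STATES

# ---------------------------------------------------------------------------
# Light schedule
# ---------------------------------------------------------------------------

#' @rdname lightSchedule
#' @export
setClass("LightSchedule",
  representation(lightsOnZt = "numeric", period = "numeric",
                 lightHours = "numeric"),
  prototype(lightsOnZt = 0, period = 24, lightHours = 12))

setValidity("LightSchedule", function(object) {
  if (length(object@period) != 1L || object@period <= 0)
    return("period must be a single positive number of hours")
  if (length(object@lightHours) != 1L ||
      object@lightHours <= 0 || object@lightHours >= object@period)
    return("lightHours must satisfy 0 < lightHours < period")
  TRUE
})

#' Light:dark schedule
#'
#' Describes the Zeitgeber frame of the recording. ZT0 is lights-on by
#' definition; the default is the standard 12:12 light:dark cycle.
#'
#' @param lightsOnZt ZT hour of lights-on (0 by convention).
#' @param period Cycle period in hours (24).
#' @param lightHours Duration of the light phase in hours (12).
#' @return A `LightSchedule` object.
#' @examples
#' ls12 <- lightSchedule()
#' isLight(ls12, c(0, 6, 12, 18))
#' @export
lightSchedule <- function(lightsOnZt = 0, period = 24, lightHours = 12) {
  new("LightSchedule", lightsOnZt = lightsOnZt, period = period,
      lightHours = lightHours)
}

#' @describeIn lightSchedule TRUE for ZT hours falling in the light phase.
#' @param object A `LightSchedule`.
#' @param zt Numeric vector of ZT hours.
#' @export
isLight <- function(object, zt) {
  ((zt - object@lightsOnZt) %% object@period) < object@lightHours
}

setMethod("show", "LightSchedule", function(object) {
  cat(sprintf("LightSchedule: %g:%g L:D, lights on at ZT%g\n",
              object@lightHours, object@period - object@lightHours,
              object@lightsOnZt))
})

# ---------------------------------------------------------------------------
# Protocol schedule
# ---------------------------------------------------------------------------

.DAY_KINDS <- c("baseline", "sleep_restriction", "defeat", "recovery",
                "post_defeat")

#' @rdname protocolSchedule
#' @export
setClass("ProtocolSchedule", representation(days = "data.frame"))

setValidity("ProtocolSchedule", function(object) {
  d <- object@days
  need <- c("day_index", "kind", "fw_start", "fw_end", "defeat_start",
            "defeat_end")
  if (!all(need %in% names(d)))
    return(paste("days must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) == 0L) return("schedule must contain at least one day")
  if (any(diff(d$day_index) <= 0))
    return("day indices must be strictly increasing")
  if (!all(d$kind %in% .DAY_KINDS))
    return(paste("unknown day kind; allowed:", paste(.DAY_KINDS, collapse = ", ")))
  sr <- d$kind == "sleep_restriction"
  if (any(sr) && (any(is.na(d$fw_start[sr])) ||
                  any(d$fw_start[sr] != 0 | d$fw_end[sr] != 6)))
    return("sleep_restriction days must have forced-wake window [ZT0, ZT6)")
  df <- d$kind == "defeat"
  if (any(df) && (any(is.na(d$defeat_start[df])) ||
                  any(d$defeat_start[df] < 12 | d$defeat_end[df] > 14)))
    return("defeat windows must lie within [ZT12, ZT14)")
  TRUE
})

#' Study protocol schedule
#'
#' Ordered day records for a simulated subject. `sleep_restriction` days carry
#' a forced-wake window over the first six light hours (ZT0-ZT6);
#' `defeat` days carry a defeat window inside the first two dark hours
#' (ZT12-ZT14).
#'
#' @param kinds Character vector of day kinds, one per day, each one of
#'   `"baseline"`, `"sleep_restriction"`, `"defeat"`, `"recovery"`,
#'   `"post_defeat"`.
#' @return A `ProtocolSchedule`.
#' @examples
#' protocolSchedule(c("baseline", "sleep_restriction"))
#' @export
protocolSchedule <- function(kinds) {
  n <- length(kinds)
  d <- data.frame(
    day_index = seq_len(n), kind = kinds,
    fw_start = ifelse(kinds == "sleep_restriction", 0, NA_real_),
    fw_end = ifelse(kinds == "sleep_restriction", 6, NA_real_),
    defeat_start = ifelse(kinds == "defeat", 12, NA_real_),
    defeat_end = ifelse(kinds == "defeat", 14, NA_real_),
    stringsAsFactors = FALSE)
  new("ProtocolSchedule", days = d)
}

#' @describeIn protocolSchedule The full study protocol: one baseline day, one
#'   sleep-restriction day, ten consecutive defeat days, one post-defeat day.
#' @export
defaultProtocol <- function() {
  protocolSchedule(c("baseline", "sleep_restriction", rep("defeat", 10),
                     "post_defeat"))
}

#' @describeIn protocolSchedule Day records as a data.frame.
#' @param object A `ProtocolSchedule`.
#' @export
protocolDays <- function(object) object@days

setMethod("show", "ProtocolSchedule", function(object) {
  k <- table(factor(object@days$kind, levels = .DAY_KINDS))
  cat(sprintf("ProtocolSchedule: %d days (%s)\n", nrow(object@days),
              paste(sprintf("%s=%d", names(k)[k > 0], k[k > 0]),
                    collapse = ", ")))
})

# ---------------------------------------------------------------------------
# Simulation parameters
# ---------------------------------------------------------------------------

#' @rdname simParams
#' @export
setClass("SimParams",
  representation(
    epochS = "numeric",
    stateDwell = "matrix",       # 3 states x {light, dark}, mean dwell (epochs)
    nremToRem = "numeric",       # P(next = REM | leaving NREM), light/dark
    remToWake = "numeric",       # P(next = WAKE | leaving REM), light/dark
    sTauRise = "numeric",        # Process-S rise constant in wake (h)
    sTauFall = "numeric",        # Process-S fall constant in NREM (h)
    sBounds = "numeric",
    remThetaHz = "numeric",
    eegFs = "numeric",
    emgSigma = "numeric",        # per-state EMG noise scale (uV)
    bandAmps = "matrix",         # state x {delta, theta, broad} amplitude (uV)
    deltaLeadRatio = "numeric",  # parietal/frontal delta amplitude ratio
    artifactFraction = "numeric",
    postDefeatDwellScale = "matrix",  # state x phase dwell multipliers
    phenotypePreset = "character",
    seed = "numeric"))

setValidity("SimParams", function(object) {
  if (object@epochS <= 0) return("epochS must be positive")
  if (!identical(dim(object@stateDwell), c(3L, 2L)))
    return("stateDwell must be a 3x2 matrix (WAKE/NREM/REM x light/dark)")
  if (any(object@stateDwell < 1))
    return("all mean dwell times must be >= 1 epoch")
  if (any(object@nremToRem < 0 | object@nremToRem > 1) ||
      any(object@remToWake < 0 | object@remToWake > 1))
    return("transition weights must be probabilities in [0, 1]")
  if (object@sBounds[1] >= object@sBounds[2])
    return("sBounds must satisfy low < high")
  if (object@eegFs < 60)
    return("eegFs must be >= 60 Hz (2x the 30 Hz analysis ceiling)")
  if (object@artifactFraction < 0 || object@artifactFraction > 1)
    return("artifactFraction must be in [0, 1]")
  TRUE
})

.PRESETS <- c("male_resilient", "male_susceptible", "female_resilient",
              "female_susceptible")

#' Synthetic-cohort simulation parameters
#'
#' Bundles everything the generator needs: per-state mean dwell times by light
#' phase (a semi-Markov chain with geometric per-epoch dwell), the
#' NREM-to-REM and REM-to-WAKE branch probabilities (REM is entered only from
#' NREM), the two-process homeostat constants, EEG/EMG synthesis amplitudes,
#' and the phenotype preset.
#'
#' Presets modify the base architecture: males have shorter dark-phase NREM
#' dwell (more NREM bouts in the dark), females have longer REM bouts, and
#' susceptible animals have longer light-phase REM bouts. On post-defeat days
#' NREM dwell is scaled up for susceptible females and for resilient males
#' (wake dwell down), emulating the post-stress NREM increase of those groups.
#'
#' @param phenotypePreset One of `"male_resilient"`, `"male_susceptible"`,
#'   `"female_resilient"`, `"female_susceptible"`.
#' @param seed Integer seed driving every random draw of the generator.
#' @param epochS Scoring epoch length in seconds (10).
#' @param eegFs EEG/EMG sampling rate in Hz (default 100; the analysis ceiling
#'   is 30 Hz).
#' @param artifactFraction Fraction of epochs relabelled ARTIFACT with
#'   injected transients when a day is synthesized (default 0.02).
#' @param sTauRise,sTauFall Process-S exponential time constants (hours) for
#'   the rise in wake and discharge in NREM.
#' @param sBounds Lower/upper asymptotes of Process S (dimensionless).
#' @param deltaLeadRatio Parietal/frontal delta amplitude ratio.
#' @param stateDwell,nremToRem,remToWake Optional overrides of the preset
#'   architecture: a 3 x 2 dwell matrix (WAKE/NREM/REM x light/dark, epochs)
#'   and length-2 (light, dark) branch probabilities.
#' @return A `SimParams` object.
#' @examples
#' p <- simParams("female_susceptible", seed = 1)
#' p
#' @export
simParams <- function(phenotypePreset = "male_resilient", seed = 1,
                      epochS = 10, eegFs = 100, artifactFraction = 0.02,
                      sTauRise = 8.6, sTauFall = 1.8,
                      sBounds = c(0.2, 1), deltaLeadRatio = 1.2,
                      stateDwell = NULL, nremToRem = NULL, remToWake = NULL) {
  phenotypePreset <- match.arg(phenotypePreset, .PRESETS)
  userDwell <- stateDwell
  userN2R <- nremToRem
  userR2W <- remToWake
  # Base architecture: mean dwell (epochs of 10 s) by state and phase, chosen
  # to give ~42% NREM / ~6% REM in the light phase and ~25% NREM in the dark.
  dwell <- matrix(c(22, 31,   # WAKE  light, dark
                    15, 10,   # NREM
                    6,  5),   # REM
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("WAKE", "NREM", "REM"),
                                  c("light", "dark")))
  nremToRem <- c(light = 0.35, dark = 0.25)
  remToWake <- c(light = 0.60, dark = 0.70)
  sex <- if (grepl("^male", phenotypePreset)) "male" else "female"
  phen <- if (grepl("resilient$", phenotypePreset)) "resilient" else "susceptible"
  if (sex == "male") {           # more, shorter NREM bouts in the dark
    dwell["NREM", "dark"] <- dwell["NREM", "dark"] * 0.7
    dwell["WAKE", "dark"] <- dwell["WAKE", "dark"] * 0.8
  } else {                        # longer REM bouts in females
    dwell["REM", ] <- dwell["REM", ] * 1.4
  }
  if (phen == "susceptible")      # longer light-phase REM bouts
    dwell["REM", "light"] <- dwell["REM", "light"] * 1.3
  dwell <- pmax(dwell, 1)
  if (!is.null(userDwell)) {
    dwell <- userDwell
    dimnames(dwell) <- list(c("WAKE", "NREM", "REM"), c("light", "dark"))
  }
  if (!is.null(userN2R)) nremToRem <- stats::setNames(userN2R, c("light", "dark"))
  if (!is.null(userR2W)) remToWake <- stats::setNames(userR2W, c("light", "dark"))
  # Post-defeat NREM gain: susceptible females and resilient males.
  pd <- matrix(1, 3, 2, dimnames = dimnames(dwell))
  if (phenotypePreset == "female_susceptible") {
    pd["NREM", ] <- 1.5
  } else if (phenotypePreset == "male_resilient") {
    pd["NREM", ] <- 1.25
    pd["WAKE", ] <- 0.75
  }
  # Per-state band amplitudes (time-domain standard deviation, uV) for the
  # three synthesis components: delta (0.5-4 Hz), theta (6-10 Hz) and
  # broadband (0.5-30 Hz). NREM delta is additionally scaled by sqrt(S).
  amps <- matrix(c(12, 10, 20,    # WAKE: low-voltage, broadband
                   42, 12, 15,    # NREM: delta-dominant (x sqrt(S))
                   8, 32, 8),     # REM: theta-dominant
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("WAKE", "NREM", "REM"),
                                 c("delta", "theta", "broad")))
  new("SimParams", epochS = epochS, stateDwell = dwell,
      nremToRem = nremToRem, remToWake = remToWake,
      sTauRise = sTauRise, sTauFall = sTauFall, sBounds = sBounds,
      remThetaHz = c(6, 10), eegFs = eegFs,
      emgSigma = c(WAKE = 30, NREM = 10, REM = 4, ARTIFACT = 30),
      bandAmps = amps, deltaLeadRatio = deltaLeadRatio,
      artifactFraction = artifactFraction, postDefeatDwellScale = pd,
      phenotypePreset = phenotypePreset, seed = seed)
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: preset %s, seed %g\n", object@phenotypePreset,
              object@seed))
  cat(sprintf("  epoch %g s, eegFs %g Hz, artifact fraction %.3f\n",
              object@epochS, object@eegFs, object@artifactFraction))
  cat(sprintf("  Process S: tau rise %g h, fall %g h, bounds [%g, %g]\n",
              object@sTauRise, object@sTauFall, object@sBounds[1],
              object@sBounds[2]))
})

# ---------------------------------------------------------------------------
# Arena
# ---------------------------------------------------------------------------

#' @rdname arenaSpec
#' @export
setClass("ArenaSpec",
  representation(side = "numeric", cageCenter = "numeric",
                 cageSide = "numeric", interactionRadius = "numeric",
                 trialS = "numeric", sampleHz = "numeric", stepSd = "numeric"))

setValidity("ArenaSpec", function(object) {
  if (object@interactionRadius <= 0)
    return("interactionRadius must be positive")
  if (object@trialS <= 0) return("trial duration must be positive")
  half <- object@cageSide / 2
  if (any(object@cageCenter - half < 0) ||
      any(object@cageCenter + half > object@side))
    return("cage must fit inside the arena")
  TRUE
})

#' Social-interaction arena geometry
#'
#' The 30 x 30 cm open arena with a 9 x 9 cm mesh cage (holding the novel
#' aggressor in the target trial) against the middle of one wall. The
#' interaction zone is all points within `interactionRadius` (15 cm) of the
#' cage boundary; see [zoneTime()] for the distance convention.
#'
#' @param side Arena side length (cm).
#' @param cageCenter Cage centre `(x, y)` in cm.
#' @param cageSide Cage side length (cm).
#' @param interactionRadius Interaction-zone radius from the cage boundary (cm).
#' @param trialS Trial duration in seconds (180 = three minutes).
#' @param sampleHz Tracking/simulation sample rate (Hz).
#' @param stepSd Random-walk per-axis step standard deviation (cm per sample).
#' @return An `ArenaSpec`.
#' @export
arenaSpec <- function(side = 30, cageCenter = c(15, 4.5), cageSide = 9,
                      interactionRadius = 15, trialS = 180, sampleHz = 10,
                      stepSd = 0.8) {
  new("ArenaSpec", side = side, cageCenter = cageCenter, cageSide = cageSide,
      interactionRadius = interactionRadius, trialS = trialS,
      sampleHz = sampleHz, stepSd = stepSd)
}

setMethod("show", "ArenaSpec", function(object) {
  cat(sprintf(
    "ArenaSpec: %gx%g cm arena, %gx%g cm cage at (%g, %g), zone %g cm, trial %g s\n",
    object@side, object@side, object@cageSide, object@cageSide,
    object@cageCenter[1], object@cageCenter[2], object@interactionRadius,
    object@trialS))
})

# ---------------------------------------------------------------------------
# Recording
# ---------------------------------------------------------------------------

#' @rdname recording
#' @export
setClass("Recording",
  representation(channels = "list", fs = "numeric", ztStartS = "numeric"))

setValidity("Recording", function(object) {
  if (length(object@channels) == 0L) return("at least one channel required")
  ns <- vapply(object@channels, length, integer(1))
  if (length(unique(ns)) != 1L)
    return("all channels must have equal sample counts")
  if (is.null(names(object@channels)) || any(names(object@channels) == ""))
    return("channels must be named")
  if (object@fs <= 0) return("fs must be positive")
  TRUE
})

#' Multi-channel EEG/EMG recording
#'
#' In-memory polysomnography block: named signal vectors in microvolts at a
#' common sampling rate, with the recording start expressed in seconds from
#' lights-on (Zeitgeber time). Standard channel names are `eeg_frontal`,
#' `eeg_parietal` and `emg`.
#'
#' @param channels Named list of equal-length numeric vectors (uV).
#' @param fs Sampling rate in Hz.
#' @param ztStartS Recording start, seconds after ZT0.
#' @return A `Recording`.
#' @export
recording <- function(channels, fs, ztStartS = 0) {
  new("Recording", channels = lapply(channels, as.numeric), fs = fs,
      ztStartS = ztStartS)
}

#' @describeIn recording Channel names.
#' @param object A `Recording`.
#' @export
channelNames <- function(object) names(object@channels)

#' @describeIn recording One channel as a numeric vector.
#' @param name Channel name.
#' @export
channelSignal <- function(object, name) {
  if (!name %in% names(object@channels))
    stop("no channel named '", name, "'")
  object@channels[[name]]
}

#' @describeIn recording Sampling rate in Hz.
#' @export
samplingRate <- function(object) object@fs

#' @describeIn recording Duration in seconds.
#' @export
recordingDuration <- function(object) {
  length(object@channels[[1]]) / object@fs
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) [%s], fs %g Hz, %.1f s from ZT %.2f h\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "), object@fs,
              recordingDuration(object), object@ztStartS / 3600))
})

# ---------------------------------------------------------------------------
# Hypnogram
# ---------------------------------------------------------------------------

#' @rdname hypnogram
#' @export
setClass("Hypnogram",
  representation(states = "character", epochS = "numeric",
                 ztStartS = "numeric"))

setValidity("Hypnogram", function(object) {
  if (length(object@states) < 1L) return("hypnogram must have >= 1 epoch")
  bad <- setdiff(unique(object@states), .STATES)
  if (length(bad))
    return(paste("invalid state labels:", paste(bad, collapse = ", ")))
  if (object@epochS != 10) return("epochS must be 10 s")
  TRUE
})

#' Epoch-by-epoch hypnogram
#'
#' The scored state sequence: one label per 10 s epoch over
#' `WAKE`/`NREM`/`REM`/`ARTIFACT`, aligned to Zeitgeber time.
#'
#' @param states Character vector of epoch labels.
#' @param epochS Epoch length in seconds (must be 10).
#' @param ztStartS Start of the first epoch, seconds after ZT0.
#' @return A `Hypnogram`.
#' @examples
#' h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "REM"))
#' states(h)
#' artifactFraction(h)
#' @export
hypnogram <- function(states, epochS = 10, ztStartS = 0) {
  new("Hypnogram", states = as.character(states), epochS = epochS,
      ztStartS = ztStartS)
}

#' @describeIn hypnogram Epoch labels as a character vector.
#' @param object A `Hypnogram`.
#' @export
states <- function(object) object@states

#' @describeIn hypnogram Number of epochs.
#' @export
nEpochs <- function(object) length(object@states)

#' @describeIn hypnogram ZT hour at the start of each epoch.
#' @export
epochZtHours <- function(object) {
  (object@ztStartS + (seq_along(object@states) - 1) * object@epochS) / 3600
}

#' @describeIn hypnogram Fraction of epochs labelled ARTIFACT.
#' @export
artifactFraction <- function(object) mean(object@states == "ARTIFACT")

setMethod("show", "Hypnogram", function(object) {
  tb <- table(factor(object@states, levels = .STATES))
  cat(sprintf("Hypnogram: %d epochs x %g s (%.1f h) from ZT %.2f h\n",
              length(object@states), object@epochS,
              length(object@states) * object@epochS / 3600,
              object@ztStartS / 3600))
  cat(sprintf("  %s\n", paste(sprintf("%s %d", names(tb), tb),
                              collapse = ", ")))
})

# ---------------------------------------------------------------------------
# Epoch features
# ---------------------------------------------------------------------------

#' @rdname extractFeatures
#' @export
setClass("EpochFeatures",
  representation(table = "data.frame", fs = "numeric", epochS = "numeric",
                 channel = "character"))

setValidity("EpochFeatures", function(object) {
  need <- c("epoch", "zt_s", "delta", "theta", "total", "emg_rms", "peak_uv")
  if (!all(need %in% names(object@table)))
    return(paste("feature table must have columns:",
                 paste(need, collapse = ", ")))
  tb <- object@table
  if (any(tb$delta < 0) || any(tb$theta < 0) || any(tb$emg_rms < 0))
    return("band powers and EMG RMS must be nonnegative")
  if (any(tb$delta > tb$total * (1 + 1e-8)))
    return("delta power cannot exceed total power")
  TRUE
})

#' @describeIn extractFeatures Feature table as a data.frame (one row per
#'   epoch: `epoch`, `zt_s`, `delta`, `theta`, `total`, `emg_rms`, `peak_uv`).
#' @export
featureTable <- function(object) object@table

setMethod("show", "EpochFeatures", function(object) {
  cat(sprintf("EpochFeatures: %d epochs x %g s, channel %s, fs %g Hz\n",
              nrow(object@table), object@epochS, object@channel, object@fs))
})

# ---------------------------------------------------------------------------
# Stager thresholds
# ---------------------------------------------------------------------------

#' @rdname calibrateThresholds
#' @export
setClass("StagerThresholds",
  representation(mode = "character",
                 emgWakeQuantile = "numeric", deltaQuantiles = "numeric",
                 thetaDeltaRemRatio = "numeric",
                 artifactAmplitudeUv = "numeric",
                 artifactPowerZscore = "numeric",
                 emgThreshold = "numeric", deltaThreshold = "numeric"))

setValidity("StagerThresholds", function(object) {
  if (!object@mode %in% c("per-recording-quantile", "absolute"))
    return("mode must be 'per-recording-quantile' or 'absolute'")
  q <- c(object@emgWakeQuantile, object@deltaQuantiles)
  if (any(q <= 0 | q >= 1)) return("quantiles must lie in (0, 1)")
  if (object@thetaDeltaRemRatio <= 0) return("REM ratio must be positive")
  TRUE
})

setMethod("show", "StagerThresholds", function(object) {
  cat(sprintf("StagerThresholds (%s):\n", object@mode))
  cat(sprintf("  EMG wake q%.2f -> %.3g uV; delta bracket q%.2f/q%.2f -> %.3g uV^2\n",
              object@emgWakeQuantile, object@emgThreshold,
              object@deltaQuantiles[1], object@deltaQuantiles[2],
              object@deltaThreshold))
  cat(sprintf("  theta/delta REM ratio %.2f; artifact: |x| > %g uV or power z > %g\n",
              object@thetaDeltaRemRatio, object@artifactAmplitudeUv,
              object@artifactPowerZscore))
})
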