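# Semi-Markov hypnogram simulation and the two-process homeostat.

# Stable master-seed -> child-seed splitting (documented contract): children
# are spread over the 31-bit integer range by a fixed affine map, so the same
# master seed always yields the same per-subject / per-day streams.
.childSeed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(index) * 7919 + 1) %%
               2147483647)
}

.dayDwell <- function(params, kind) {
  d <- params@stateDwell
  if (kind == "post_defeat") d <- pmax(d * params@postDefeatDwellScale, 1)
  d
}

#' Simulate a hypnogram for a protocol
#'
#' Generates one 24 h hypnogram per protocol day and concatenates them. States
#' follow a semi-Markov chain: dwell in the current state is geometric per
#' epoch with the phase-specific mean from `params`, and on leaving, WAKE
#' always enters NREM, NREM branches to REM or WAKE, and REM to WAKE or NREM
#' (REM is never entered from WAKE, the standard rodent staging constraint).
#' During the forced-wake window of sleep-restriction days every epoch is
#' WAKE. On post-defeat days the preset's dwell modifiers apply.
#'
#' @param params A [simParams()] object (its `seed` drives the simulation).
#' @param schedule A [protocolSchedule()]; default a single baseline day.
#' @param light A [lightSchedule()].
#' @return A [hypnogram()] of `8640 * nDays` epochs starting at ZT0.
#' @examples
#' h <- simulateHypnogram(simParams(seed = 1))
#' nEpochs(h)  # 8640
#' @export
simulateHypnogram <- function(params, schedule = protocolSchedule("baseline"),
                              light = lightSchedule()) {
  set.seed(.childSeed(params@seed, 0))
  epd <- as.integer(round(24 * 3600 / params@epochS))  # epochs per day
  days <- protocolDays(schedule)
  out <- character(epd * nrow(days))
  state <- "WAKE"
  for (di in seq_len(nrow(days))) {
    kind <- days$kind[di]
    dwell <- .dayDwell(params, kind)
    lab <- character(epd)
    i <- 1L
    while (i <= epd) {
      ztH <- (i - 1L) * params@epochS / 3600
      phase <- if (isLight(light, ztH)) "light" else "dark"
      # geometric dwell: run length >= 1 with continuation prob 1 - 1/mean
      m <- dwell[state, phase]
      len <- 1L + stats::rgeom(1, prob = min(1, 1 / m))
      len <- min(len, epd - i + 1L)
      lab[i:(i + len - 1L)] <- state
      i <- i + len
      state <- switch(state,
        WAKE = "NREM",
        NREM = if (stats::runif(1) < params@nremToRem[[phase]]) "REM" else "WAKE",
        REM  = if (stats::runif(1) < params@remToWake[[phase]]) "WAKE" else "NREM")
    }
    if (kind == "sleep_restriction" && !is.na(days$fw_start[di])) {
      ztH <- (seq_len(epd) - 1L) * params@epochS / 3600
      fw <- ztH >= days$fw_start[di] & ztH < days$fw_end[di]
      lab[fw] <- "WAKE"
      if (any(fw) && max(which(fw)) < epd) state <- lab[max(which(fw)) + 1L]
    }
    out[((di - 1L) * epd + 1L):(di * epd)] <- lab
  }
  hypnogram(out, epochS = params@epochS, ztStartS = 0)
}

#' Single homeostat update
#'
#' One 10 s step of the Process-S sleep-pressure variable: exponential
#' saturating rise toward the upper bound during WAKE (time constant
#' `sTauRise`), exponential decay toward the lower bound during NREM
#' (`sTauFall`), unchanged during REM and ARTIFACT epochs. The output always
#' stays within `sBounds`.
#'
#' @param s Current S value (within `params@sBounds`).
#' @param epochState Epoch label (`"WAKE"`, `"NREM"`, `"REM"`, `"ARTIFACT"`).
#' @param params A [simParams()].
#' @return Updated S value.
#' @export
updateHomeostat <- function(s, epochState, params) {
  lo <- params@sBounds[1]; hi <- params@sBounds[2]
  dtH <- params@epochS / 3600
  s2 <- switch(epochState,
    WAKE = hi - (hi - s) * exp(-dtH / params@sTauRise),
    NREM = lo + (s - lo) * exp(-dtH / params@sTauFall),
    s)
  min(max(s2, lo), hi)
}

#' Homeostat trajectory over a hypnogram
#'
#' Applies [updateHomeostat()] across a full hypnogram (vectorized within runs
#' of constant state using the closed-form exponential), returning S at the
#' end of every epoch.
#'
#' @param hyp A [hypnogram()].
#' @param params A [simParams()].
#' @param s0 Starting S value; defaults to the midpoint of `sBounds`.
#' @return Numeric vector, one S value per epoch.
#' @export
homeostatTrajectory <- function(hyp, params, s0 = mean(params@sBounds)) {
  lo <- params@sBounds[1]; hi <- params@sBounds[2]
  dtH <- params@epochS / 3600
  r <- rle(states(hyp))
  s <- numeric(nEpochs(hyp))
  cur <- min(max(s0, lo), hi)
  pos <- 0L
  for (k in seq_along(r$lengths)) {
    L <- r$lengths[k]
    st <- r$values[k]
    if (st == "WAKE") {
      f <- exp(-(seq_len(L)) * dtH / params@sTauRise)
      seg <- hi - (hi - cur) * f
    } else if (st == "NREM") {
      f <- exp(-(seq_len(L)) * dtH / params@sTauFall)
      seg <- lo + (cur - lo) * f
    } else {
      seg <- rep(cur, L)
    }
    s[(pos + 1L):(pos + L)] <- seg
    cur <- seg[L]
    pos <- pos + L
  }
  s
}
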