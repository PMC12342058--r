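# Bout segmentation and state-time accounting.

#' Segment a hypnogram into bouts
#'
#' Maximal runs of identical state. ARTIFACT epochs terminate bouts; artifact
#' runs appear as their own rows (state `ARTIFACT`) so that concatenating the
#' table reproduces the hypnogram exactly, but they are excluded from
#' [boutStats()] by default. A bout spanning the light/dark boundary is
#' assigned to the phase containing its onset.
#'
#' @param hyp A [hypnogram()].
#' @param light A [lightSchedule()].
#' @return Data.frame with `state`, `start_epoch`, `n_epochs`, `duration_s`,
#'   `phase` (`"light"`/`"dark"` at bout onset).
#' @examples
#' segmentBouts(hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM", "REM", "WAKE")))
#' @export
segmentBouts <- function(hyp, light = lightSchedule()) {
  if (nEpochs(hyp) == 0L) stop("empty hypnogram")
  r <- rle(states(hyp))
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  ztH <- (hyp@ztStartS + (start - 1L) * hyp@epochS) / 3600
  data.frame(state = r$values, start_epoch = start, n_epochs = r$lengths,
             duration_s = r$lengths * hyp@epochS,
             phase = ifelse(isLight(light, ztH), "light", "dark"),
             stringsAsFactors = FALSE)
}

#' Bout statistics by state and phase
#'
#' Counts and mean durations of bouts grouped by state and (optionally)
#' light/dark phase. Empty groups are reported with `n_bouts = 0` and a
#' missing mean, never zero. ARTIFACT bouts are dropped unless requested.
#'
#' @param bouts A bout table from [segmentBouts()].
#' @param by Grouping columns, subset of `c("state", "phase")`.
#' @param includeArtifact Keep ARTIFACT bouts (default `FALSE`).
#' @return Data.frame with the grouping columns plus `n_bouts`,
#'   `mean_duration_s`, `total_duration_s`.
#' @export
boutStats <- function(bouts, by = c("state", "phase"),
                      includeArtifact = FALSE) {
  by <- match.arg(by, c("state", "phase"), several.ok = TRUE)
  if (!includeArtifact) bouts <- bouts[bouts$state != "ARTIFACT", ]
  lev <- list(state = setdiff(.STATES, if (includeArtifact) NULL else "ARTIFACT"),
              phase = c("light", "dark"))
  grid <- expand.grid(lev[by], stringsAsFactors = FALSE)
  out <- grid
  out$n_bouts <- 0L
  out$mean_duration_s <- NA_real_
  out$total_duration_s <- 0
  for (i in seq_len(nrow(grid))) {
    sel <- rep(TRUE, nrow(bouts))
    for (g in by) sel <- sel & bouts[[g]] == grid[[g]][i]
    d <- bouts$duration_s[sel]
    out$n_bouts[i] <- length(d)
    if (length(d)) {
      out$mean_duration_s[i] <- mean(d)
      out$total_duration_s[i] <- sum(d)
    }
  }
  out
}

#' State minutes in a ZT window
#'
#' Minutes per state over the half-open window `[start, end)` (ZT hours from
#' the start of the recording's first day). An epoch belongs to the window
#' containing its start time. Artifact minutes are reported separately and
#' excluded from the state totals, so
#' `WAKE + NREM + REM + artifact = window length`.
#'
#' @param hyp A [hypnogram()].
#' @param window Numeric `c(start, end)` in ZT hours (may span days, e.g.
#'   `c(6, 24)`).
#' @return List with `minutes` (named: WAKE, NREM, REM), `artifact_minutes`,
#'   `total_sleep_minutes` (NREM + REM) and `window`.
#' @export
stateMinutes <- function(hyp, window = c(0, 24)) {
  ztH <- (hyp@ztStartS + (seq_len(nEpochs(hyp)) - 1L) * hyp@epochS) / 3600
  if (window[1] < ztH[1] - 1e-9 ||
      window[2] > ztH[length(ztH)] + hyp@epochS / 3600 + 1e-9)
    stop("window outside recording")
  sel <- ztH >= window[1] - 1e-9 & ztH < window[2] - 1e-9
  st <- states(hyp)[sel]
  perMin <- hyp@epochS / 60
  m <- vapply(c("WAKE", "NREM", "REM"),
              function(s) sum(st == s) * perMin, numeric(1))
  list(minutes = m, artifact_minutes = sum(st == "ARTIFACT") * perMin,
       total_sleep_minutes = unname(m["NREM"] + m["REM"]), window = window)
}

#' Sleep lost during restriction
#'
#' Difference between sleep amount in the forced-wake window on the baseline
#' (undisturbed) day and the same window on the sleep-restriction day:
#' `lost = baseline - restriction`, per state and total. A negative loss is
#' possible in principle and triggers a warning.
#'
#' @param baselineHyp Baseline-day [hypnogram()].
#' @param srHyp Sleep-restriction-day [hypnogram()].
#' @param window ZT window of the restriction (default `c(0, 6)`).
#' @return List with `lost` (named: NREM, REM, total) and the per-day minute
#'   accounts.
#' @export
sleepLost <- function(baselineHyp, srHyp, window = c(0, 6)) {
  b <- stateMinutes(baselineHyp, window)
  s <- stateMinutes(srHyp, window)
  lost <- c(NREM = unname(b$minutes["NREM"] - s$minutes["NREM"]),
            REM = unname(b$minutes["REM"] - s$minutes["REM"]))
  lost <- c(lost, total = unname(lost["NREM"] + lost["REM"]))
  if (any(lost < 0))
    warning("negative sleep lost: restriction day had more sleep than baseline")
  list(lost = lost, baseline = b, restriction = s)
}

#' Cumulative recovery-sleep curve
#'
#' Hourly cumulative gain in state minutes on the post-restriction day
#' relative to baseline over the recovery window (default the 18 h from ZT6).
#' The curve endpoint equals the [stateMinutes()] difference over the full
#' window.
#'
#' @param baselineHyp,postHyp Baseline and recovery-day hypnograms.
#' @param window Recovery ZT window (default `c(6, 24)`).
#' @param state State to track (default `"NREM"`).
#' @return Data.frame with `zt_end` (bin end, ZT h), `gain_min` (that hour's
#'   difference) and `cum_gain_min`.
#' @export
recoverySleep <- function(baselineHyp, postHyp, window = c(6, 24),
                          state = "NREM") {
  edges <- seq(window[1], window[2], by = 1)
  gain <- numeric(length(edges) - 1L)
  for (i in seq_along(gain)) {
    w <- c(edges[i], edges[i + 1])
    gain[i] <- stateMinutes(postHyp, w)$minutes[state] -
      stateMinutes(baselineHyp, w)$minutes[state]
  }
  data.frame(zt_end = edges[-1], gain_min = gain, cum_gain_min = cumsum(gain))
}

#' Paired pre/post change table
#'
#' Per-subject paired differences of a sleep metric between pre- and
#' post-stress days, in the long format the stats module consumes.
#' `metric` is a function mapping a hypnogram to a single number.
#'
#' @param preHyps,postHyps Named lists of hypnograms (same subject names).
#' @param metric Function `hypnogram -> numeric(1)`; default NREM minutes over
#'   the full day.
#' @return Data.frame with `subject_id`, `pre`, `post`, `delta`.
#' @export
prePostChange <- function(preHyps, postHyps,
                          metric = function(h)
                            stateMinutes(h, c(0, 24))$minutes["NREM"]) {
  if (!setequal(names(preHyps), names(postHyps)) ||
      is.null(names(preHyps)))
    stop("pre and post hypnogram lists must carry matching subject names")
  ids <- names(preHyps)
  pre <- vapply(preHyps[ids], function(h) unname(metric(h)), numeric(1))
  post <- vapply(postHyps[ids], function(h) unname(metric(h)), numeric(1))
  data.frame(subject_id = ids, pre = pre, post = post, delta = post - pre,
             row.names = NULL, stringsAsFactors = FALSE)
}
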