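# Social-interaction test scoring from arena trajectories.
#
# A trajectory is a data.frame with columns t (s), x, y (cm) plus a "trial"
# attribute-style column when written to CSV. The interaction zone is the set
# of points within `interactionRadius` of the *boundary* of the cage
# rectangle (a 15 cm radius from the centre of a 9 cm cage would barely clear
# the cage itself); a centre-distance mode is available by argument.

# Euclidean distance from points to the cage rectangle boundary (0 inside).
.cageDistance <- function(x, y, spec, from = c("boundary", "center")) {
  from <- match.arg(from)
  cx <- spec@cageCenter[1]; cy <- spec@cageCenter[2]
  if (from == "center") return(sqrt((x - cx)^2 + (y - cy)^2))
  half <- spec@cageSide / 2
  dx <- pmax(abs(x - cx) - half, 0)
  dy <- pmax(abs(y - cy) - half, 0)
  sqrt(dx^2 + dy^2)
}

# resample a trajectory to a uniform grid by linear interpolation
.resampleTraj <- function(traj, hz) {
  t0 <- traj$t[1]; t1 <- traj$t[nrow(traj)]
  tt <- seq(t0, t1, by = 1 / hz)
  data.frame(t = tt,
             x = stats::approx(traj$t, traj$x, tt)$y,
             y = stats::approx(traj$t, traj$y, tt)$y)
}

#' Time in the interaction zone
#'
#' Total time the animal spends within `interactionRadius` (15 cm) of the
#' cage boundary. The trajectory is resampled to a uniform grid (10 Hz) by
#' linear interpolation and time is integrated by sample-interval weighting.
#'
#' @param traj Data.frame with columns `t` (s), `x`, `y` (cm).
#' @param spec An [arenaSpec()].
#' @param from Measure the 15 cm from the cage `"boundary"` (default) or
#'   `"center"`.
#' @return Zone time in seconds (never more than the trial duration).
#' @export
zoneTime <- function(traj, spec, from = "boundary") {
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 samples")
  u <- .resampleTraj(traj, spec@sampleHz)
  d <- .cageDistance(u$x, u$y, spec, from = from)
  sum(d <= spec@interactionRadius) / spec@sampleHz
}

#' Social interaction ratio
#'
#' `SIR = t_f / t_e`: time near the caged novel aggressor over time near the
#' empty cage.
#'
#' @param tF Seconds near the occupied cage (target trial).
#' @param tE Seconds near the empty cage (empty trial); must be positive.
#' @return The ratio.
#' @export
interactionRatio <- function(tF, tE) {
  if (tE <= 0)
    stop("undefined interaction ratio: zero empty-cage time (flag subject ",
         "for manual review)")
  tF / tE
}

#' Resilience classification from the interaction ratio
#'
#' A ratio above 1.1 confirms resilience; below 0.9, susceptibility. Ratios
#' in the closed band `[0.9, 1.1]` are excluded (from sleep analyses; such
#' animals remain in behavioral tables).
#'
#' @param sir Finite nonnegative interaction ratio(s).
#' @return Character vector over `"resilient"`, `"susceptible"`, `"excluded"`.
#' @examples
#' classifyPhenotype(c(1.2, 0.85, 1.0))
#' @export
classifyPhenotype <- function(sir) {
  if (any(!is.finite(sir)) || any(sir < 0))
    stop("interaction ratio must be finite and nonnegative")
  ifelse(sir > 1.1, "resilient", ifelse(sir < 0.9, "susceptible", "excluded"))
}

#' Distance traveled
#'
#' Sum of consecutive Euclidean step lengths along the trajectory.
#'
#' @param traj Data.frame with `x`, `y` in cm (>= 2 samples).
#' @return Path length in cm.
#' @export
distanceTraveled <- function(traj) {
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 samples")
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Occupancy grid
#'
#' Dwell time per square cell of the arena; the grid sum equals the trial
#' duration represented by the (resampled) samples.
#'
#' @param traj Data.frame with `t`, `x`, `y`.
#' @param spec An [arenaSpec()].
#' @param cellCm Cell side in cm; must divide the arena side.
#' @return Matrix of dwell seconds (rows = x bins, cols = y bins).
#' @export
occupancyGrid <- function(traj, spec, cellCm = 5) {
  if (spec@side %% cellCm != 0) stop("cellCm must divide the arena side")
  u <- .resampleTraj(traj, spec@sampleHz)
  k <- as.integer(spec@side / cellCm)
  ix <- pmin(pmax(floor(u$x / cellCm), 0), k - 1) + 1L
  iy <- pmin(pmax(floor(u$y / cellCm), 0), k - 1) + 1L
  g <- matrix(0, k, k)
  dt <- 1 / spec@sampleHz
  for (i in seq_along(ix)) g[ix[i], iy[i]] <- g[ix[i], iy[i]] + dt
  g
}

# one biased-random-walk trial; bias > 0 drifts toward the cage, < 0 away
.walkTrial <- function(spec, bias, nSteps) {
  cx <- spec@cageCenter[1]; cy <- spec@cageCenter[2]
  half <- spec@cageSide / 2
  x <- numeric(nSteps); y <- numeric(nSteps)
  px <- spec@side / 2; py <- spec@side / 2
  driftScale <- bias * spec@stepSd / 20
  dxs <- stats::rnorm(nSteps, sd = spec@stepSd)
  dys <- stats::rnorm(nSteps, sd = spec@stepSd)
  for (i in seq_len(nSteps)) {
    dx <- dxs[i]
    dy <- dys[i]
    if (bias != 0) {
      vx <- cx - px; vy <- cy - py
      nv <- sqrt(vx^2 + vy^2)
      if (nv > 1e-9) {
        dx <- dx + driftScale * vx / nv
        dy <- dy + driftScale * vy / nv
      }
    }
    nx <- px + dx; ny <- py + dy
    # reflect at walls
    if (nx < 0) nx <- -nx
    if (nx > spec@side) nx <- 2 * spec@side - nx
    if (ny < 0) ny <- -ny
    if (ny > spec@side) ny <- 2 * spec@side - ny
    nx <- min(max(nx, 0), spec@side)
    ny <- min(max(ny, 0), spec@side)
    # the cage is solid: reject steps into it
    if (abs(nx - cx) < half && abs(ny - cy) < half) {
      nx <- px; ny <- py
    }
    px <- nx; py <- ny
    x[i] <- px; y[i] <- py
  }
  data.frame(t = (seq_len(nSteps) - 1) / spec@sampleHz, x = x, y = y)
}

#' Simulate a pair of social-interaction trials
#'
#' Biased random walk inside the arena: two consecutive 180 s trials with
#' identical geometry, the empty-cage trial unbiased and the target trial
#' drifting toward (bias > 0) or away from (bias < 0) the cage. The expected
#' interaction ratio increases with `attractionBias`; bias 0 gives symmetric
#' occupancy in expectation (mean SIR near 1).
#'
#' @param spec An [arenaSpec()].
#' @param attractionBias Dimensionless drift strength in the target trial.
#' @param seed Integer seed.
#' @return List with `empty` and `target` trajectory data.frames.
#' @export
simulateArena <- function(spec = arenaSpec(), attractionBias = 0, seed = 1) {
  if (spec@trialS <= 0) stop("trial duration must be positive")
  set.seed(.childSeed(seed, 3))
  nSteps <- as.integer(round(spec@trialS * spec@sampleHz))
  list(empty = .walkTrial(spec, 0, nSteps),
       target = .walkTrial(spec, attractionBias, nSteps))
}

#' Score one social-interaction test
#'
#' Applies [zoneTime()] to both trials, forms the interaction ratio and the
#' phenotype call, and reports distance traveled per trial.
#'
#' @param trials List with `empty` and `target` trajectories (e.g. from
#'   [simulateArena()]).
#' @param spec An [arenaSpec()].
#' @return Data.frame row: `t_f`, `t_e`, `sir`, `phenotype`,
#'   `distance_empty_cm`, `distance_target_cm`.
#' @export
scoreInteraction <- function(trials, spec = arenaSpec()) {
  tE <- zoneTime(trials$empty, spec)
  tF <- zoneTime(trials$target, spec)
  sir <- interactionRatio(tF, tE)
  data.frame(t_f = tF, t_e = tE, sir = sir,
             phenotype = classifyPhenotype(sir),
             distance_empty_cm = distanceTraveled(trials$empty),
             distance_target_cm = distanceTraveled(trials$target),
             stringsAsFactors = FALSE)
}
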