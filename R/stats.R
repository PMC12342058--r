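# Statistical toolkit: mixed repeated-measures ANOVA, Holm-Sidak step-down,
# Mann-Whitney U, Shapiro-Wilk gate, t-tests and the power-based sample-size
# calculation.

#' Mixed repeated-measures ANOVA
#'
#' Between x within ANOVA on a long-format design table with one value per
#' (subject, time) cell. Between-subject factors (e.g. sex, phenotype) are
#' tested against the subjects-within-groups stratum and the within factor
#' (time) and its interactions against the subject-by-time residual. The fit
#' uses sum-to-zero contrasts with Type-III sums of squares (an
#' unweighted-means solution), so unbalanced between-cells (e.g. 12 females
#' vs 8 males) are handled. No sphericity correction is applied by default
#' (flagged in the output); Greenhouse-Geisser adjusted p-values are added
#' with `sphericity = "GG"`.
#'
#' @param data Data.frame with columns `subject_id`, the between factors, a
#'   within (time) column and `value`.
#' @param between Character vector of between-subject factor columns (may be
#'   empty for a one-way repeated-measures design).
#' @param within Name of the within-subject (time) column.
#' @param value Name of the value column.
#' @param sphericity `"none"` (default) or `"GG"`.
#' @return Data.frame with one row per effect: `effect`, `df_num`, `df_den`,
#'   `F`, `p` (plus `p_gg` when requested); attribute `sphericity_correction`
#'   records the setting.
#' @export
mixedAnova <- function(data, between = character(), within = "time",
                       value = "value", sphericity = c("none", "GG")) {
  sphericity <- match.arg(sphericity)
  need <- c("subject_id", between, within, value)
  if (!all(need %in% names(data)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  data[[within]] <- factor(data[[within]])
  tlev <- levels(data[[within]])
  if (length(tlev) < 2) stop("within factor needs >= 2 levels")
  # one value per (subject, time); complete series required
  wide <- stats::reshape(
    data[, c("subject_id", between, within, value)],
    idvar = c("subject_id", between), timevar = within,
    direction = "wide")
  ycols <- paste(value, tlev, sep = ".")
  if (!all(ycols %in% names(wide)) || anyNA(wide[, ycols]))
    stop("incomplete within-subject series: every subject needs one value ",
         "per time level")
  for (b in between) {
    wide[[b]] <- factor(wide[[b]])
    if (any(table(wide[[b]]) < 2))
      stop("singleton between-group cell in factor ", b)
  }
  if (length(between)) {
    cells <- interaction(wide[, between, drop = FALSE], drop = FALSE)
    if (any(table(cells) == 0)) stop("missing between-factor cell")
    if (any(table(cells) < 2)) stop("singleton between-factor cell")
  }
  Y <- as.matrix(wide[, ycols])
  rhs <- if (length(between)) paste(between, collapse = " * ") else "1"
  contr <- as.list(stats::setNames(rep("contr.sum", length(between)), between))
  mlm <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = wide,
                   contrasts = if (length(between)) contr else NULL)
  idata <- data.frame(time = factor(tlev, levels = tlev))
  av <- car::Anova(mlm, idata = idata, idesign = ~time, type = 3)
  su <- suppressWarnings(summary(av, multivariate = FALSE))
  tab <- su$univariate.tests
  keep <- setdiff(rownames(tab), "(Intercept)")
  res <- data.frame(effect = gsub("\\btime\\b", within, keep),
                    df_num = tab[keep, "num Df"],
                    df_den = tab[keep, "den Df"],
                    F = tab[keep, "F value"],
                    p = tab[keep, "Pr(>F)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  # degenerate all-equal data: zero effect and zero residual -> F = 0, p = 1
  zero <- tab[keep, "Sum Sq"] <= .Machine$double.eps * 100 *
    max(1, sum(Y^2))
  res$F[zero | !is.finite(res$F)] <- 0
  res$p[zero | !is.finite(res$p)] <- 1
  if (sphericity == "GG" && !is.null(su$pval.adjustments) &&
      nrow(su$pval.adjustments)) {
    adj <- su$pval.adjustments
    res$p_gg <- res$p
    hit <- match(rownames(adj), keep)
    res$p_gg[hit[!is.na(hit)]] <- adj[!is.na(hit), "Pr(>F[GG])"]
  }
  attr(res, "sphericity_correction") <- sphericity
  attr(res, "n_subjects") <- nrow(wide)
  res
}

#' Holm-Sidak step-down multiple comparisons
#'
#' Orders the p-values ascending and compares step `i` of `k` against
#' `1 - (1 - alpha)^(1/(k - i + 1))`; rejection stops at the first failure.
#' Controls the family-wise error rate at `alpha`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param alpha Family-wise error rate (0.05).
#' @return Data.frame in the input order: `p`, `adjusted_alpha` (the
#'   threshold each p was compared against), `reject`.
#' @examples
#' holmSidak(c(0.001, 0.02, 0.04))
#' @export
holmSidak <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value list")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  k <- length(pvals)
  ord <- order(pvals)
  thr <- 1 - (1 - alpha)^(1 / (k - seq_len(k) + 1))
  rejSorted <- logical(k)
  for (i in seq_len(k)) {
    if (pvals[ord[i]] <= thr[i]) rejSorted[i] <- TRUE else break
  }
  out <- data.frame(p = pvals, adjusted_alpha = NA_real_, reject = FALSE)
  out$adjusted_alpha[ord] <- thr
  out$reject[ord] <- rejSorted
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. For combined sample sizes of at
#' most 8 the two-sided p-value is exact, by full enumeration of the
#' `choose(n_x + n_y, n_x)` group assignments of the observed values; larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `U` (for `x`), `p`, and `method` (`"exact"` or
#'   `"normal"`).
#' @export
mannWhitneyU <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= 8) {
    idx <- utils::combn(nx + ny, nx)
    Us <- apply(idx, 2, function(ii) sum(r[ii])) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    # two-sided: as or more extreme in |U - mean|
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- nx * ny / 2
    nt <- nx + ny
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sig2)
    list(U = U, p = min(1, 2 * stats::pnorm(-max(z, 0))), method = "normal")
  }
}

#' Power-based sample size per group
#'
#' Smallest integer n satisfying the two-sample, two-sided normal
#' approximation `n >= (z_{1-alpha/2} + z_{1-beta})^2 * 2 sd^2 / diff^2`,
#' with a floor of 2. With `sd = 14.6`, `diff = 25`, `alpha = 0.05` and power
#' 0.8 this yields 6. The exact noncentral-t iteration
#' (`method = "t"`, via [stats::power.t.test()]) is slightly more
#' conservative and yields 7 for the same inputs.
#'
#' @param sd Common standard deviation (positive).
#' @param diff Mean difference to detect (nonzero).
#' @param alpha Type-I error rate (two-sided).
#' @param power Target power (1 - type-II error rate).
#' @param method `"normal"` (default) or `"t"`.
#' @return Integer sample size per group.
#' @examples
#' sampleSize(sd = 14.6, diff = 25)  # 6
#' @export
sampleSize <- function(sd, diff, alpha = 0.05, power = 0.8,
                       method = c("normal", "t")) {
  method <- match.arg(method)
  if (sd <= 0) stop("sd must be positive")
  if (diff == 0) stop("diff must be nonzero")
  if (method == "t") {
    n <- stats::power.t.test(delta = abs(diff), sd = sd, sig.level = alpha,
                             power = power)$n
    return(max(2L, as.integer(ceiling(n - 1e-9))))
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- z^2 * 2 * sd^2 / diff^2
  max(2L, as.integer(ceiling(n - 1e-9)))
}

#' Shapiro-Wilk normality gate
#'
#' Wraps [stats::shapiro.test()]; the gate passes (`normal = TRUE`) when
#' p > 0.05. A constant sample cannot be tested and returns `normal = FALSE`
#' with `p = NA` (documented degenerate case).
#'
#' @param values Numeric sample, n >= 3.
#' @param alpha Gate level (0.05).
#' @return List with `normal` (logical) and `p`.
#' @export
shapiroWilkGate <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("Shapiro-Wilk requires n >= 3")
  if (stats::sd(values) == 0) return(list(normal = FALSE, p = NA_real_))
  p <- stats::shapiro.test(values)$p.value
  list(normal = p > alpha, p = p)
}

#' Student's t-tests
#'
#' Two-sided paired and two-sample (Welch by default off: classical pooled)
#' t-tests via [stats::t.test()]. A paired comparison of identical series
#' returns `t = 0, p = 1` rather than erroring on zero-variance differences.
#'
#' @param x,y Numeric samples (paired: equal length).
#' @return List with `t`, `df`, `p`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1))
    stop("zero variance with nonzero mean difference: t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' @rdname pairedT
#' @param var.equal Pooled-variance test if `TRUE` (classical Student), Welch
#'   otherwise.
#' @export
twoSampleT <- function(x, y, var.equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(x, y, var.equal = var.equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
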