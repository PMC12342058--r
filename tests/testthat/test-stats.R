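test_that("mixed ANOVA matches the classical balanced-design oracle", {
  set.seed(21)
  d <- expand.grid(subject_id = 1:16, time = c("t1", "t2", "t3"),
                   stringsAsFactors = FALSE)
  d$A <- ifelse(d$subject_id %% 2 == 0, "a1", "a2")
  d$B <- ifelse(d$subject_id <= 8, "b1", "b2")
  d$value <- rnorm(nrow(d)) + 2 * (d$A == "a1") + 1.5 * (d$B == "b1") +
    0.8 * (d$A == "a1") * (d$time == "t2")
  res <- mixedAnova(d, between = c("A", "B"))
  oracle <- balancedMixedAnovaOracle(d)
  getF <- function(eff) res$F[res$effect == eff]
  expect_equal(getF("A"), oracle$F_A, tolerance = 1e-8)
  expect_equal(getF("B"), oracle$F_B, tolerance = 1e-8)
  expect_equal(getF("A:B"), oracle$F_AB, tolerance = 1e-8)
  expect_equal(getF("time"), oracle$F_T, tolerance = 1e-8)
  expect_equal(getF("A:time"), oracle$F_AT, tolerance = 1e-8)
  expect_equal(getF("B:time"), oracle$F_BT, tolerance = 1e-8)
  expect_equal(getF("A:B:time"), oracle$F_ABT, tolerance = 1e-8)
  # SS components partition the total SS exactly (balanced design)
  expect_equal(sum(oracle$SS[c("A", "B", "AB", "subj", "T", "AT", "BT",
                               "ABT", "errW")]),
               oracle$SS[["total"]], tolerance = 1e-8)
})

test_that("mixed ANOVA is invariant to subject relabeling and flags degeneracy", {
  set.seed(22)
  d <- expand.grid(subject_id = 1:12, time = c("t1", "t2"),
                   stringsAsFactors = FALSE)
  d$sex <- ifelse(d$subject_id <= 6, "M", "F")
  d$value <- rnorm(nrow(d)) + (d$sex == "M")
  r1 <- mixedAnova(d, between = "sex")
  # permute subject labels within groups
  perm <- c(sample(1:6), sample(7:12))
  d2 <- d; d2$subject_id <- perm[d$subject_id]
  r2 <- mixedAnova(d2, between = "sex")
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  # all values equal: every F is 0 with p = 1
  d$value <- 3
  r0 <- mixedAnova(d, between = "sex")
  expect_true(all(r0$F == 0))
  expect_true(all(r0$p == 1))
  # incomplete series and singleton cells error
  expect_error(mixedAnova(d[-1, ], between = "sex"), "incomplete")
  d$sex[d$subject_id == 1] <- "X"
  expect_error(mixedAnova(d, between = "sex"), "singleton")
})

test_that("unbalanced groups are handled by the unweighted-means solution", {
  set.seed(23)
  d <- expand.grid(subject_id = 1:20, time = c("t1", "t2"),
                   stringsAsFactors = FALSE)
  d$sex <- ifelse(d$subject_id <= 12, "F", "M")  # 12 vs 8
  d$value <- rnorm(nrow(d)) + 1.2 * (d$sex == "M")
  r <- mixedAnova(d, between = "sex")
  expect_equal(r$df_den[r$effect == "sex"], 18)
  expect_gt(r$F[r$effect == "sex"], 1)
  expect_true(all(r$p > 0 & r$p <= 1))
})

test_that("Holm-Sidak thresholds follow the closed form and stop at first failure", {
  one <- holmSidak(0.04, alpha = 0.05)
  expect_equal(one$adjusted_alpha, 0.05)
  expect_true(one$reject)
  r <- holmSidak(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_equal(sort(r$adjusted_alpha),
               c(1 - 0.95^(1 / 3), 1 - 0.95^(1 / 2), 0.05),
               tolerance = 1e-9)
  expect_equal(round(sort(r$adjusted_alpha)[1:2], 6), c(0.016952, 0.025321))
  expect_true(all(r$reject))
  expect_false(any(holmSidak(rep(1, 5))$reject))
  # step-down stops: a failing first step blocks later small thresholds
  r2 <- holmSidak(c(0.03, 0.049))
  expect_false(r2$reject[1])   # 0.03 > 1-0.95^(1/2) = 0.0253
  expect_false(r2$reject[2])
  expect_error(holmSidak(numeric(0)), "empty")
})

test_that("Holm-Sidak rejections nest between single-step Sidak and unadjusted alpha", {
  for (sd in 1:20) {
    set.seed(sd)
    p <- runif(sample(2:8, 1))^2
    k <- length(p)
    hs <- holmSidak(p)$reject
    singleStep <- p <= 1 - 0.95^(1 / k)
    unadjusted <- p <= 0.05
    expect_true(all(hs[singleStep]))       # superset of single-step Sidak
    expect_true(all(unadjusted[hs]))       # subset of unadjusted rejections
  }
})

test_that("Mann-Whitney U agrees with enumeration and the base implementation", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  wt <- suppressWarnings(wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE))
  expect_equal(r$p, wt$p.value)
  # identical samples: U = n^2/2 under midranks
  same <- mannWhitneyU(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$U, 9 / 2)
  # U_x + U_y = n_x n_y without ties; exact p matches wilcox.test
  for (sd in 1:10) {
    set.seed(sd)
    x <- rnorm(4); y <- rnorm(4)
    ux <- mannWhitneyU(x, y); uy <- mannWhitneyU(y, x)
    expect_equal(ux$U + uy$U, 16)
    expect_equal(ux$p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    # independent brute-force U: pairwise comparisons
    expect_equal(ux$U, sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "==")))
  }
  # large-sample branch stays close to the base normal approximation
  set.seed(99)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  big <- mannWhitneyU(x, y)
  expect_equal(big$method, "normal")
  expect_equal(big$p,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("the sample-size formula reproduces n = 6 and behaves monotonically", {
  expect_identical(sampleSize(sd = 14.6, diff = 25), 6L)
  expect_identical(sampleSize(sd = 14.6, diff = 1e6), 2L)
  expect_identical(sampleSize(sd = 14.6, diff = 25, method = "t"), 7L)
  # non-increasing in |diff|, non-decreasing in sd
  diffs <- c(5, 10, 20, 40)
  expect_true(all(diff(sapply(diffs, function(d) sampleSize(14.6, d))) <= 0))
  sds <- c(5, 10, 20, 40)
  expect_true(all(diff(sapply(sds, function(s) sampleSize(s, 25))) >= 0))
  expect_error(sampleSize(-1, 25), "positive")
  expect_error(sampleSize(10, 0), "nonzero")
  # the returned n achieves >= 80% power under the stated normal model
  n <- sampleSize(14.6, 25)
  set.seed(31)
  reps <- 10000
  m1 <- matrix(rnorm(n * reps, 0, 14.6), n)
  m2 <- matrix(rnorm(n * reps, 25, 14.6), n)
  z <- (colMeans(m2) - colMeans(m1)) / (14.6 * sqrt(2 / n))
  expect_gte(mean(abs(z) > qnorm(0.975)), 0.8)
})

test_that("the Shapiro-Wilk gate accepts normal data and rejects discrete data", {
  hits <- vapply(1:100, function(sd) {
    set.seed(sd)
    shapiroWilkGate(rnorm(500))$normal
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  set.seed(7)
  twoPoint <- sample(c(0, 1), 500, replace = TRUE)
  expect_false(shapiroWilkGate(twoPoint)$normal)
  expect_false(shapiroWilkGate(rep(3, 10))$normal)
  expect_error(shapiroWilkGate(c(1, 2)), "n >= 3")
})

test_that("t-tests follow their textbook definitions", {
  x <- c(5.1, 4.9, 5.6, 4.7)
  expect_equal(pairedT(x, x), list(t = 0, df = 3, p = 1))
  y <- c(4.2, 4.4, 4.9, 4.1)
  pt <- pairedT(x, y)
  d <- x - y
  tHand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(pt$t, tHand)
  expect_equal(pairedT(y, x)$t, -pt$t)
  # two-sample hand computation (pooled)
  a <- c(10, 12, 9, 11); b <- c(14, 15, 13, 16)
  ts <- twoSampleT(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  expect_equal(ts$t, (mean(a) - mean(b)) / sqrt(sp2 * (2 / 4)))
  expect_equal(ts$df, 6)
  expect_error(twoSampleT(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("the ANOVA gate plus Holm-Sidak pipeline controls type-I error", {
  set.seed(41)
  reps <- 2000
  falsePos <- logical(reps)
  tlev <- c("t1", "t2", "t3")
  base <- expand.grid(subject_id = 1:12, time = tlev,
                      stringsAsFactors = FALSE)
  base$sex <- ifelse(base$subject_id <= 6, "M", "F")
  for (r in seq_len(reps)) {
    base$value <- rnorm(nrow(base))
    av <- mixedAnova(base, between = "sex")
    gate <- av$p[av$effect == "sex"] < 0.05
    if (gate) {
      ps <- vapply(tlev, function(tl) {
        twoSampleT(base$value[base$sex == "M" & base$time == tl],
                   base$value[base$sex == "F" & base$time == tl])$p
      }, numeric(1))
      falsePos[r] <- any(holmSidak(ps)$reject)
    }
  }
  expect_lte(mean(falsePos), 0.06)
})
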