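test_that("youden cutoff separates perfectly separable classes", {
  res <- youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$threshold, 10)
  expect_equal(res$youden_j, 1)
  expect_equal(res$youden_j, res$sensitivity + res$specificity - 1,
               tolerance = 1e-12)
})

test_that("youden cutoff matches a brute-force scan with smallest-threshold ties", {
  values <- c(1, 4, 6, 5, 7, 9)
  labels <- c(0, 0, 0, 1, 1, 1)
  # independent brute force over all observed thresholds
  best_j <- -Inf
  best_t <- NA
  for (t in sort(unique(values))) {
    sens <- mean(values[labels == 1] >= t)
    spec <- mean(values[labels == 0] < t)
    if (sens + spec - 1 > best_j + 1e-12) {
      best_j <- sens + spec - 1
      best_t <- t
    }
  }
  res <- youden_cutoff(values, labels)
  expect_equal(res$threshold, best_t)
  expect_equal(res$threshold, 5)
  expect_equal(res$youden_j, 2 / 3, tolerance = 1e-12)
  # permutation invariance under joint shuffles
  set.seed(1)
  for (r in 1:5) {
    idx <- sample(length(values))
    expect_equal(youden_cutoff(values[idx], labels[idx]), res)
  }
})

test_that("youden cutoff agrees with an ROC-package cross-check", {
  skip_if_not_installed("pROC")
  set.seed(5)
  x <- c(rnorm(60, 0), rnorm(60, 1.2))
  y <- rep(0:1, each = 60)
  res <- youden_cutoff(x, y)
  roc <- pROC::roc(y, x, quiet = TRUE, direction = "<")
  best <- pROC::coords(roc, "best", best.method = "youden", transpose = FALSE)
  j_ref <- max(best$sensitivity + best$specificity - 1)
  expect_equal(res$youden_j, j_ref, tolerance = 1e-9)
})

test_that("single-class labels are rejected", {
  expect_error(youden_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("standard cutoffs dichotomize clinical values as configured", {
  ch <- toy_cohort(zones_from_sets(list(11)))
  ch$ca125 <- 300
  ch$he4 <- 130
  ch$menopause <- 0L
  d <- discretize_clinical(ch)
  expect_equal(as.character(d$ca125), "1")  # 300 is above the 264.5 cutoff
  expect_equal(as.character(d$he4), "1")    # premenopausal cutoff 122.2
  ch$menopause <- 1L
  expect_equal(as.character(discretize_clinical(ch)$he4), "0")  # below 148.5
})

test_that("odds ratio and Woolf interval reproduce the lateralization table", {
  res <- odds_ratio_2x2(table2x2(254, 110, 109, 181))
  expect_equal(round(res$or, 2), 3.83)
  expect_equal(round(res$ci_low, 2), 2.77)
  expect_equal(round(res$ci_high, 2), 5.31)
  expect_false(res$corrected)
})

test_that("symmetric tables give OR 1 and zero cells are handled", {
  expect_equal(odds_ratio_2x2(table2x2(10, 10, 10, 10))$or, 1)
  # Haldane-Anscombe by hand: (5.5*5.5)/(5.5*0.5) = 11
  res <- odds_ratio_2x2(table2x2(5, 0, 5, 5), correction = TRUE)
  expect_equal(res$or, 11)
  expect_true(res$corrected)
  expect_error(odds_ratio_2x2(table2x2(5, 0, 5, 5)), "n01")
})

test_that("Woolf interval brackets the OR and tightens with sample size", {
  set.seed(11)
  for (r in 1:50) {
    cells <- rpois(4, 30) + 1
    res <- odds_ratio_2x2(table2x2(cells[1], cells[2], cells[3], cells[4]))
    expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
    res4 <- odds_ratio_2x2(table2x2(4 * cells[1], 4 * cells[2],
                                    4 * cells[3], 4 * cells[4]))
    expect_lt(log(res4$ci_high) - log(res4$ci_low),
              log(res$ci_high) - log(res$ci_low))
  }
})

test_that("chi-square matches the closed 2x2 formula", {
  # n(ad - bc)^2 / (r1 r2 c1 c2) = 60 * 300^2 / 810000
  res <- chi_square_2x2(table2x2(10, 20, 20, 10))
  expect_equal(res$statistic, 60 * (10 * 10 - 20 * 20)^2 /
                 (30 * 30 * 30 * 30), tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_equal(chi_square_2x2(table2x2(10, 10, 20, 20))$statistic, 0,
               tolerance = 1e-12)
  set.seed(2)
  for (r in 1:100) {
    cells <- rpois(4, 20) + 1
    res <- chi_square_2x2(table2x2(cells[1], cells[2], cells[3], cells[4]))
    a <- cells[1]; b <- cells[2]; c2 <- cells[3]; d <- cells[4]
    n <- sum(cells)
    expect_equal(res$statistic,
                 n * (a * d - b * c2)^2 /
                   ((a + b) * (c2 + d) * (a + c2) * (b + d)),
                 tolerance = 1e-9)
  }
  # invariant under swapping exposure/outcome roles
  expect_equal(chi_square_2x2(table2x2(7, 13, 21, 5))$statistic,
               chi_square_2x2(table2x2(7, 21, 13, 5))$statistic,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(table2x2(0, 0, 5, 5)), "marginal")
})

test_that("Mann-Whitney U counts pairs and conserves U_a + U_b", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$u), 0)
  expect_equal(unname(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$u), 9)
  set.seed(3)
  for (r in 1:20) {
    a <- rnorm(sample(3:15, 1))
    b <- rnorm(sample(3:15, 1))
    ua <- mann_whitney_u(a, b)$u
    ub <- mann_whitney_u(b, a)$u
    expect_equal(unname(ua + ub), length(a) * length(b))
  }
  x <- c(1, 2, 3, 4)
  expect_equal(unname(mann_whitney_u(x, x)$u), length(x)^2 / 2)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("logistic fit on aggregated 2x2 counts recovers the odds ratio", {
  d <- data.frame(x = c(0, 0, 1, 1))
  y <- c(0, 1, 0, 1)
  f <- fit_logistic(d, y, weights = c(254, 110, 109, 181))
  expect_equal(round(exp(f$coefficients[["x"]]), 2), 3.83)
  expect_true(f$converged)
  expect_false(f$separation_flag)
})

test_that("logistic MLE equals the closed-form odds ratio on random tables", {
  set.seed(17)
  for (r in 1:200) {
    cells <- rpois(4, 25) + 1
    orr <- odds_ratio_2x2(table2x2(cells[1], cells[2], cells[3], cells[4]))$or
    f <- fit_logistic(data.frame(x = c(0, 0, 1, 1)), c(0, 1, 0, 1),
                      weights = cells)
    expect_equal(exp(f$coefficients[["x"]]), orr, tolerance = 1e-6)
  }
})

test_that("balanced independent data give a zero slope", {
  d <- data.frame(x = rep(c(0, 1), each = 20))
  y <- rep(c(0, 1, 0, 1), each = 10)
  f <- fit_logistic(d, y)
  expect_lt(abs(f$coefficients[["x"]]), 1e-6)
})

test_that("separation is flagged rather than reported as convergence failure", {
  d <- data.frame(x = c(rep(0, 10), rep(1, 10)))
  y <- c(rep(0, 10), rep(1, 10))
  f <- fit_logistic(d, y)
  expect_true(f$separation_flag)
})

test_that("forward stepwise selects exactly the planted predictor", {
  set.seed(101)
  n <- 1000
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)
  x3 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.75 + 1.5 * x1))
  res <- forward_stepwise(data.frame(planted = x1, noise_a = x2,
                                     noise_b = x3), y)
  expect_equal(res$selected, "planted")
})

test_that("stepwise type-I error is controlled under the global null", {
  set.seed(202)
  n <- 1000
  picks <- vapply(1:100, function(r) {
    x <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, 0.4)
    length(forward_stepwise(x, y)$selected)
  }, numeric(1))
  expect_gte(mean(picks == 0), 0.90)
})

test_that("alpha_in = 0 always returns the intercept-only model", {
  set.seed(5)
  x <- data.frame(a = rbinom(50, 1, 0.5))
  y <- c(rep(0, 25), rep(1, 25))
  expect_equal(forward_stepwise(x, y, alpha_in = 0)$selected, character(0))
})
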