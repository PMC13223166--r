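# Cohort-level statistics: Youden-index dichotomization, 2x2 odds ratios
# with Woolf intervals, group comparison tests, and logistic regression
# with forward stepwise selection.

#' Optimal dichotomization cutoff by the Youden index
#'
#' Scans all observed values as candidate thresholds under the rule
#' "positive iff value >= threshold" and returns the threshold maximizing
#' J = sensitivity + specificity - 1; ties are broken toward the smallest
#' threshold.
#'
#' @param values Numeric vector.
#' @param labels Binary outcome vector (0/1 or logical), same length.
#' @return List of class `cutoff_result`: `threshold`, `youden_j`,
#'   `sensitivity`, `specificity`.
#' @examples
#' youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' @export
youden_cutoff <- function(values, labels) {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels), length(values) >= 2)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes must be present: sensitivity/specificity undefined")
  }
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  cand <- sort(unique(values))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- vapply(cand, function(t) sum(values >= t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(values < t & labels == 0) / n_neg,
                 numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # first maximum = smallest threshold
  structure(list(threshold = cand[best], youden_j = j[best],
                 sensitivity = sens[best], specificity = spec[best]),
            class = "cutoff_result")
}

#' 2x2 contingency table constructor
#'
#' First index is the exposure (0/1), second the outcome (0/1).
#'
#' @param n00,n01,n10,n11 Non-negative counts (`n10` = exposed without the
#'   outcome, `n11` = exposed with the outcome).
#' @return Object of class `table2x2`.
#' @export
table2x2 <- function(n00, n01, n10, n11) {
  cells <- c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  if (any(cells < 0) || sum(cells) <= 0) {
    stop("counts must be non-negative with a positive total")
  }
  structure(as.list(cells), class = "table2x2")
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (n11 * n00) / (n10 * n01)`; the interval is
#' `exp(log OR +/- 1.96 * sqrt(sum 1/cell))` (log-normal / Woolf).  With a
#' zero cell and `correction = TRUE`, 0.5 is added to every cell
#' (Haldane-Anscombe) and the result is flagged.
#'
#' @param table A [table2x2()].
#' @param correction Apply the Haldane-Anscombe correction when a cell is
#'   zero (default FALSE).
#' @return List: `or`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio_2x2(table2x2(254, 110, 109, 181))  # OR 3.83, CI 2.77-5.31
#' @export
odds_ratio_2x2 <- function(table, correction = FALSE) {
  stopifnot(inherits(table, "table2x2"))
  cells <- unlist(table)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction) {
      stop("zero cell (", paste(names(cells)[cells == 0], collapse = ", "),
           "): odds ratio undefined without the Haldane-Anscombe correction")
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells[["n11"]] * cells[["n00"]]) / (cells[["n10"]] * cells[["n01"]])
  se <- sqrt(sum(1 / cells))
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       corrected = corrected)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default; a flag exposes the Yates
#' variant.  Thin wrapper over [stats::chisq.test()] on the 2x2 matrix.
#'
#' @param table A [table2x2()].
#' @param correct Continuity correction (default FALSE).
#' @return List: `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "table2x2"))
  m <- matrix(unlist(table), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal: chi-square test undefined")
  }
  ht <- stats::chisq.test(m, correct = correct)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Mann-Whitney U test
#'
#' Rank-sum with midrank tie handling via [stats::wilcox.test()]; exact
#' enumeration for small samples (both groups <= 8, no ties), normal
#' approximation with tie correction otherwise.  The reported `u` is the
#' U statistic for `sample_a`.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List: `u`, `p_value`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  exact <- length(sample_a) <= 8 && length(sample_b) <= 8 &&
    !anyDuplicated(c(sample_a, sample_b))
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = FALSE)
  )
  list(u = unname(ht$statistic), p_value = ht$p.value)
}

#' Maximum-likelihood logistic regression
#'
#' Fit by iteratively reweighted least squares ([stats::glm()], binomial
#' family, convergence tolerance 1e-8, at most 100 iterations).  Monotone
#' likelihood (complete or quasi-complete separation) is detected by
#' diverging coefficients (`|beta| > 15` on standardized binary designs)
#' and flagged rather than treated as convergence failure.
#'
#' @param design Data.frame or matrix of covariates (no intercept column;
#'   one is added).
#' @param outcome Binary vector, length matching `design` rows.
#' @param weights Optional case weights (for aggregated 2x2 data).
#' @return List of class `logistic_fit`: `coefficients`, `standard_errors`,
#'   `converged`, `n_iterations`, `separation_flag`, `deviance`, `fit`
#'   (the underlying `glm` object).
#' @examples
#' # single binary predictor from aggregated 2x2 counts
#' d <- data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
#' f <- fit_logistic(d["x"], d$y, weights = c(254, 110, 109, 181))
#' exp(f$coefficients[["x"]])  # 3.83
#' @export
fit_logistic <- function(design, outcome, weights = NULL) {
  design <- as.data.frame(design)
  stopifnot(nrow(design) == length(outcome))
  df <- cbind(design, .y = as.integer(outcome))
  fit <- suppressWarnings(stats::glm(
    .y ~ ., data = df, family = stats::binomial(),
    weights = weights,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  beta <- stats::coef(fit)
  separation <- any(abs(beta[-1]) > 15, na.rm = TRUE)
  if (!fit$converged && !separation) {
    stop("logistic fit failed to converge after ", fit$iter,
         " iterations (deviance ", format(fit$deviance), ")")
  }
  structure(list(coefficients = beta,
                 standard_errors = summary(fit)$coefficients[, 2],
                 converged = fit$converged,
                 n_iterations = fit$iter,
                 separation_flag = separation,
                 deviance = fit$deviance,
                 fit = fit),
            class = "logistic_fit")
}

#' Forward stepwise logistic selection by likelihood-ratio test
#'
#' Starts from the intercept-only model; at each step the candidate with
#' the smallest likelihood-ratio-test p-value enters if below `alpha_in`;
#' stops when no candidate qualifies.  Entry only (no removal).  A
#' candidate whose fit shows separation is assessed by a
#' Haldane-Anscombe-corrected 2x2 odds ratio when it is binary, and
#' otherwise skipped with a warning.
#'
#' @param candidates Data.frame of candidate covariates.
#' @param outcome Binary vector.
#' @param alpha_in Entry significance level (default 0.05).
#' @return List: `selected` (names in entry order), `fit` (final
#'   [fit_logistic()] result), `trace` (data.frame of steps with p-values).
#' @export
forward_stepwise <- function(candidates, outcome, alpha_in = 0.05) {
  candidates <- as.data.frame(candidates)
  stopifnot(ncol(candidates) >= 1)
  selected <- character(0)
  trace <- list()
  repeat {
    pool <- setdiff(names(candidates), selected)
    if (!length(pool)) break
    base_fit <- fit_logistic(candidates[selected], outcome)
    pvals <- vapply(pool, function(v) {
      fit1 <- tryCatch(fit_logistic(candidates[c(selected, v)], outcome),
                       error = function(e) NULL)
      if (is.null(fit1)) return(NA_real_)
      if (fit1$separation_flag) {
        x <- candidates[[v]]
        if (length(unique(x)) == 2 && !length(selected)) {
          # binary fallback: corrected 2x2 chi-square style LRT surrogate
          xb <- as.integer(x == sort(unique(x))[2])
          tab <- table2x2(sum(xb == 0 & outcome == 0),
                          sum(xb == 0 & outcome == 1),
                          sum(xb == 1 & outcome == 0),
                          sum(xb == 1 & outcome == 1))
          orr <- odds_ratio_2x2(tab, correction = TRUE)
          z <- abs(log(orr$or)) / ((log(orr$ci_high) - log(orr$ci_low)) / (2 * 1.96))
          return(2 * stats::pnorm(-z))
        }
        warning("candidate '", v, "' shows separation and is not binary; skipped")
        return(NA_real_)
      }
      lr <- base_fit$deviance - fit1$deviance
      df <- length(fit1$coefficients) - length(base_fit$coefficients)
      stats::pchisq(lr, df, lower.tail = FALSE)
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- names(pvals)[which.min(pvals)]
    if (is.na(min(pvals, na.rm = TRUE)) || min(pvals, na.rm = TRUE) >= alpha_in) break
    selected <- c(selected, best)
    trace[[length(trace) + 1L]] <- data.frame(step = length(selected),
                                              variable = best,
                                              p_value = min(pvals, na.rm = TRUE))
  }
  final <- fit_logistic(candidates[selected], outcome)
  list(selected = selected,
       fit = final,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), variable = character(0),
                    p_value = numeric(0)))
}
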