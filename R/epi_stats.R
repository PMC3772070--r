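#' Cross-tabulate current smoking by a categorical factor
#'
#' One row per factor category with the number of patients, the number
#' currently smoking, and the percentage. Complete-case: rows with `NA` or
#' `"unknown"` in the factor are dropped; categories with zero patients are
#' omitted with a warning.
#'
#' @param data data frame with one row per patient carrying a resolved
#'   `status` column (`current`/`past`/`never`) and the factor column.
#' @param factor name of the factor column. For ordinal factors pass the
#'   column as an ordered factor (or a factor with levels in order).
#' @return data frame `category`, `n`, `n_current`, `pct_current`.
#' @export
crosstab <- function(data, factor) {
  stopifnot(is.data.frame(data), "status" %in% names(data),
            factor %in% names(data))
  f <- data[[factor]]
  keep <- !is.na(f) & f != "unknown"
  f <- droplevels(as.factor(f[keep]))
  cur <- data$status[keep] == "current"
  n <- as.integer(table(f))
  k <- as.integer(tapply(cur, f, sum, default = 0L))
  empty <- n == 0L
  if (any(empty)) {
    warning("categories with no patients omitted: ",
            paste(levels(f)[empty], collapse = ", "), call. = FALSE)
  }
  data.frame(category = levels(f)[!empty], n = n[!empty],
             n_current = k[!empty],
             pct_current = round(100 * k[!empty] / n[!empty], 1),
             stringsAsFactors = FALSE)
}

as_count_matrix <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  m
}

#' Pearson chi-squared test for heterogeneity
#'
#' Standard Pearson X-squared on an r x c count table, (r-1)(c-1) degrees of
#' freedom, no continuity correction.
#'
#' @param table matrix-like of non-negative integer counts.
#' @return list `statistic`, `df`, `p.value`.
#' @export
pearson_chi2 <- function(table) {
  m <- as_count_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero row or column marginal: expected counts undefined",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

#' Cochran-Armitage test for linear trend in proportions
#'
#' One-degree-of-freedom chi-squared test for a linear trend in the success
#' proportion across k >= 3 ordered categories. With successes \eqn{r_i},
#' totals \eqn{n_i}, scores \eqn{s_i} and pooled proportion \eqn{\bar p}:
#' \deqn{X^2 = \frac{\left[\sum_i s_i (r_i - n_i \bar p)\right]^2}
#'   {\bar p (1-\bar p) \left[\sum_i n_i s_i^2 - (\sum_i n_i s_i)^2 / N\right]}}
#' The statistic is invariant under affine transformations of the scores.
#'
#' @param table a 2 x k matrix (row 1 = successes, row 2 = failures) with
#'   columns in ordinal order, or a k x 2 matrix with ordered rows.
#' @param scores numeric scores for the ordered categories; default
#'   consecutive integers from 0.
#' @return list `statistic`, `df` (always 1), `p.value`.
#' @export
cochran_armitage <- function(table, scores = NULL) {
  m <- as_count_matrix(table)
  if (nrow(m) != 2L && ncol(m) == 2L) m <- t(m)
  if (nrow(m) != 2L) stop("need a 2 x k table", call. = FALSE)
  k <- ncol(m)
  if (k < 3L) {
    stop("trend test needs at least 3 ordered categories", call. = FALSE)
  }
  if (is.null(scores)) scores <- seq_len(k) - 1
  stopifnot(length(scores) == k)
  r <- m[1L, ]; n <- colSums(m); N <- sum(n)
  pbar <- sum(r) / N
  num <- sum(scores * (r - n * pbar))^2
  den <- pbar * (1 - pbar) * (sum(n * scores^2) - sum(n * scores)^2 / N)
  stat <- if (den <= 0) 0 else num / den
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2 x 2 table with the Woolf (log-normal)
#' interval \eqn{\exp(\log OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. The table
#' is laid out with the exposure of interest in row 1, the reference exposure
#' in row 2, events (e.g. current smokers) in column 1.
#'
#' @param table 2 x 2 count matrix, or four counts `c(a, b, c, d)` read
#'   row-wise.
#' @param conf.level confidence level (default 0.95).
#' @param continuity add 0.5 to every cell (Haldane-Anscombe); default off.
#'   With `continuity = FALSE` any zero cell is an error suggesting it.
#' @return object of class `or_result`: `estimate`, `ci_low`, `ci_high`,
#'   `log_se`, `conf.level`.
#' @export
odds_ratio <- function(table, conf.level = 0.95, continuity = FALSE) {
  m <- if (is.matrix(table)) table else matrix(table, 2L, 2L, byrow = TRUE)
  m <- as_count_matrix(m)
  stopifnot(nrow(m) == 2L, ncol(m) == 2L)
  if (any(m == 0)) {
    if (!continuity) {
      stop("zero cell: odds ratio undefined; consider continuity = TRUE ",
           "(adds 0.5 to every cell)", call. = FALSE)
    }
    m <- m + 0.5
  }
  est <- unname((m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  structure(list(estimate = est,
                 ci_low = exp(log(est) - z * se),
                 ci_high = exp(log(est) + z * se),
                 log_se = se, conf.level = conf.level),
            class = "or_result")
}

#' @export
print.or_result <- function(x, digits = 2, ...) {
  cat(sprintf("OR %.*f (%.0f%% CI %.*f-%.*f)\n", digits, x$estimate,
              100 * x$conf.level, digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' Logistic regression with odds-ratio reporting
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (via [stats::glm()], convergence tolerance 1e-8, at most 50
#' iterations), accepting either individual-level binary outcomes or grouped
#' binomial counts; the two parameterisations give identical fits. Reports
#' exponentiated coefficients with Wald confidence intervals. Estimates are
#' withheld when the fit does not converge or shows signs of separation.
#'
#' @param formula model formula. For grouped data use
#'   `cbind(successes, failures) ~ ...`; for individual data a binary (0/1 or
#'   logical) response.
#' @param data data frame.
#' @param conf.level Wald CI level (default 0.95).
#' @return object of class `logistic_fit` with elements `coefficients`,
#'   `vcov`, `or_table` (OR, CI bounds, p per term), `converged`, `n`
#'   (individuals, i.e. total trials), `glm` (the underlying fit).
#' @export
fit_logistic <- function(formula, data, conf.level = 0.95) {
  fit <- stats::glm(formula, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separated <- any(abs(co) > 15) || any(se > 100)
  converged <- fit$converged && !separated
  n <- sum(fit$prior.weights)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  or_table <- if (converged) {
    data.frame(term = names(co), or = exp(co),
               ci_low = exp(co - z * se), ci_high = exp(co + z * se),
               p = 2 * stats::pnorm(-abs(co / se)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else NULL
  structure(list(coefficients = if (converged) co else NULL,
                 vcov = if (converged) stats::vcov(fit) else NULL,
                 or_table = or_table, converged = converged,
                 n = n, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 2, ...) {
  if (!x$converged) {
    cat("<logistic_fit> did NOT converge (or separation detected); ",
        "no estimates reported\n", sep = "")
    return(invisible(x))
  }
  cat("<logistic_fit> n =", x$n, "\n")
  tab <- x$or_table
  tab$or <- round(tab$or, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p <- format_pvalue(tab$p)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  if (object$converged) print(summary(object$glm))
  invisible(object)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

# Two-decimal p-value convention with a "<0.001" floor.
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.2f", p))
}

#' Missingness of smoking information by patient factors
#'
#' For each factor: per-category cohort size and number/percentage of
#' patients with *no* resolved smoking status, with a Pearson heterogeneity
#' p-value and (for ordinal factors) a Cochran-Armitage trend p-value.
#'
#' @param cohort patient table.
#' @param resolved output of [resolve_patient_status()].
#' @param factors character vector of factor column names in `cohort`.
#' @param ordinal subset of `factors` to additionally trend-test, in the
#'   order of their factor levels.
#' @return named list, one element per factor: list(`table`, `p_heterogeneity`,
#'   `p_trend` (`NA` unless ordinal with >= 3 categories)).
#' @export
missingness_table <- function(cohort, resolved, factors,
                              ordinal = character(0)) {
  stopifnot(is.data.frame(cohort), all(factors %in% names(cohort)))
  missing <- !(as.character(cohort$patient_id) %in%
                 as.character(resolved$patient_id))
  out <- list()
  for (fac in factors) {
    f <- cohort[[fac]]
    keep <- !is.na(f) & f != "unknown"
    fk <- droplevels(as.factor(f[keep]))
    mk <- missing[keep]
    n <- as.integer(table(fk))
    k <- as.integer(tapply(mk, fk, sum, default = 0L))
    tab <- data.frame(category = levels(fk), n = n, n_missing = k,
                      pct_missing = round(100 * k / n, 1),
                      stringsAsFactors = FALSE)
    counts <- rbind(missing = k, present = n - k)
    degenerate <- sum(k) == 0L || sum(k) == sum(n)
    # no variation anywhere: statistic is 0 by convention, p = 1
    p_het <- if (degenerate) 1 else pearson_chi2(counts)$p.value
    p_trend <- if (fac %in% ordinal && ncol(counts) >= 3L) {
      if (degenerate) 1 else cochran_armitage(counts)$p.value
    } else NA_real_
    out[[fac]] <- list(table = tab, p_heterogeneity = p_het,
                       p_trend = p_trend)
  }
  out
}
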