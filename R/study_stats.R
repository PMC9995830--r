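#' Arcsine square-root transform for percentage scores
#'
#' The variance-stabilizing transform `asin(sqrt(p / 100))` applied to
#' percentage data before normality testing and linear modelling. Maps
#' `[0, 100]` onto `[0, pi/2]` and is strictly monotone.
#'
#' @param p Percentages in `[0, 100]`; `NA`s pass through.
#' @return Transformed values in `[0, pi/2]`.
#' @examples
#' arcsine_sqrt(c(0, 50, 100))
#' @export
arcsine_sqrt <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 100)
  if (any(bad)) {
    stop("arcsine_sqrt: values outside [0, 100]: ",
         paste(utils::head(p[bad], 3), collapse = ", "), call. = FALSE)
  }
  asin(sqrt(p / 100))
}

#' D'Agostino's skewness test
#'
#' Tests the null hypothesis that a sample comes from a normally distributed
#' population against skewed alternatives, using D'Agostino's (1970)
#' transformation of the sample skewness: the moment coefficient
#' `g1 = m3 / m2^(3/2)` is standardized by its exact small-sample moments and
#' mapped through a Johnson SU transformation to an approximately standard
#' normal `z`; the p-value is two-sided. Valid for `8 < n < 46340`.
#'
#' @param x Numeric sample (NAs dropped).
#' @return An object of class `skew_test` with fields `skewness` (g1),
#'   `z_stat`, `p_value` and `n`.
#' @examples
#' dagostino_skew_test(rexp(40))
#' @export
dagostino_skew_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n <= 8 || n >= 46340) {
    stop("dagostino_skew_test: sample size ", n,
         " outside the supported range 8 < n < 46340", call. = FALSE)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  if (m2 == 0) {
    stop("dagostino_skew_test: sample is constant", call. = FALSE)
  }
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  structure(
    list(skewness = g1, z_stat = z,
         p_value = 2 * stats::pnorm(-abs(z)), n = n),
    class = "skew_test"
  )
}

#' @export
print.skew_test <- function(x, ...) {
  cat(sprintf(
    "D'Agostino skewness test: skew = %.3f, z = %.3f, p = %.4g (n = %d)\n",
    x$skewness, x$z_stat, x$p_value, x$n))
  invisible(x)
}

#' Power of the linear-model F test for a given Cohen's f-squared
#'
#' Uses the noncentral-F distribution with noncentrality
#' `ncp = f2 * (u + v + 1)` (the convention of Cohen's regression power
#' tables, and of standard f-squared power calculators).
#'
#' @param f2 Cohen's f-squared effect size.
#' @param u,v Numerator and denominator degrees of freedom.
#' @param alpha Significance level.
#' @return Power in `[0, 1]`.
#' @export
f2_power <- function(f2, u, v, alpha = 0.05) {
  fcrit <- stats::qf(1 - alpha, u, v)
  1 - stats::pf(fcrit, u, v, ncp = f2 * (u + v + 1))
}

#' Detectable effect size for a linear-model F test
#'
#' Solves for the Cohen's f-squared at which the F test with `u` on `v`
#' degrees of freedom attains the target power at significance `alpha` — the
#' post-hoc power analysis used to decide how complex a model a cohort can
#' support. Root-finding brackets on `(0, 1000)` to a power error below 1e-8.
#'
#' @inheritParams f2_power
#' @param power Target power, with `alpha < power < 1`.
#' @return The effect size f-squared (dimensionless).
#' @examples
#' solve_f2(u = 1, v = 61, alpha = 0.05, power = 0.95)  # ~0.21
#' @export
solve_f2 <- function(u, v, alpha = 0.05, power = 0.95) {
  if (u < 1 || v < 1) stop("solve_f2: u and v must be >= 1", call. = FALSE)
  if (!(alpha > 0 && alpha < power && power < 1)) {
    stop("solve_f2: need 0 < alpha < power < 1", call. = FALSE)
  }
  g <- function(f2) f2_power(f2, u, v, alpha) - power
  if (g(1000) < 0) {
    stop("solve_f2: no root in (0, 1000)", call. = FALSE)
  }
  stats::uniroot(g, lower = 1e-12, upper = 1000, tol = 1e-12)$root
}

#' Fit one single-predictor linear model of a score
#'
#' Ordinary least squares of the (optionally arcsine-square-root transformed)
#' outcome on a single continuous or categorical predictor, returning the
#' model-level statistics used by the sequential testing plan: adjusted R²,
#' the overall F statistic with its degrees of freedom, and the raw p-value.
#' Rows with missing outcome or predictor are dropped listwise with a
#' message.
#'
#' @param cohort A cohort data frame (see [cohort_columns()]).
#' @param outcome Name of a continuous column; a percentage when
#'   `transform = TRUE`.
#' @param predictor Name of the explanatory column.
#' @param transform Apply [arcsine_sqrt()] to the outcome first?
#' @return An object of class `model_result` with fields `predictor_name`,
#'   `r2_adj`, `F`, `df` (numerator, denominator), `p_raw`, `n`, and
#'   placeholders `p_corrected`/`test_index` filled by
#'   [run_study_pipeline()].
#' @export
fit_single_predictor <- function(cohort, outcome, predictor,
                                 transform = TRUE) {
  for (col in c(outcome, predictor)) {
    if (!col %in% names(cohort)) {
      stop("fit_single_predictor: column '", col, "' not found", call. = FALSE)
    }
  }
  y <- cohort[[outcome]]
  x <- cohort[[predictor]]
  keep <- !is.na(y) & !is.na(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("fit_single_predictor: dropped ", n_dropped,
            " row(s) with missing '", outcome, "' or '", predictor, "'")
  }
  y <- y[keep]
  x <- x[keep]
  if (is.character(x) || is.logical(x)) x <- factor(x)
  if ((is.factor(x) && nlevels(droplevels(x)) < 2) ||
      (!is.factor(x) && stats::var(x) == 0)) {
    stop("fit_single_predictor: predictor '", predictor,
         "' is constant (degenerate design)", call. = FALSE)
  }
  if (transform) y <- arcsine_sqrt(y)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  fs <- s$fstatistic
  structure(
    list(
      predictor_name = predictor,
      r2_adj = s$adj.r.squared,
      F = unname(fs[1]),
      df = unname(c(fs[2], fs[3])),
      p_raw = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
      p_corrected = NA_real_,
      test_index = NA_integer_,
      n = length(y)
    ),
    class = "model_result"
  )
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf(
    "lm(score ~ %s): R2_adj = %.3f, F(%g, %g) = %.3f, p = %.4g%s\n",
    x$predictor_name, x$r2_adj, x$df[1], x$df[2], x$F, x$p_raw,
    if (!is.na(x$p_corrected))
      sprintf(" (corrected %.4g, test %d)", x$p_corrected, x$test_index)
    else ""))
  invisible(x)
}

#' Sequential Bonferroni correction
#'
#' Corrects an ordered sequence of p-values from models tested one at a time:
#' the k-th p-value is multiplied by the number of models tested up to and
#' including it (`multiplier = "inclusive"`, the default) and capped at 1.
#' `multiplier = "planned"` instead multiplies every p-value by the total
#' number of planned models (ordinary Bonferroni), which — unlike the
#' sequential multiplier — controls the familywise error rate at `alpha`
#' under a stop-at-first-success rule.
#'
#' @param p_raw Ordered raw p-values (testing order).
#' @param multiplier `"inclusive"` (k) or `"planned"` (length of the plan).
#' @param n_planned Total planned models for `multiplier = "planned"`;
#'   defaults to `length(p_raw)`.
#' @return Corrected p-values, same length as `p_raw`.
#' @examples
#' bonferroni_sequential(c(0.03, 0.03, 0.03))  # 0.03 0.06 0.09
#' @export
bonferroni_sequential <- function(p_raw,
                                  multiplier = c("inclusive", "planned"),
                                  n_planned = length(p_raw)) {
  multiplier <- match.arg(multiplier)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("bonferroni_sequential: p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- switch(multiplier,
              inclusive = seq_along(p_raw),
              planned = rep(n_planned, length(p_raw)))
  pmin(1, p_raw * m)
}

#' Pearson chi-squared test of independence
#'
#' Pearson's chi-squared without continuity correction on an r x c
#' contingency table, `df = (r - 1)(c - 1)` — as applied to the 9 x 2
#' lameness-signs-by-experience table.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2, with no
#'   all-zero row or column margin.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) {
    stop("chisq_independence: counts must be non-negative", call. = FALSE)
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("chisq_independence: table must be at least 2 x 2", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chisq_independence: degenerate table (all-zero margin)",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Group summary with the estimate-quality flag
#'
#' Per-group summary used under the categorical-predictor plots: mean,
#' quartiles (linear interpolation between order statistics) and the
#' Student-t 95% confidence interval of the mean. The group is flagged as a
#' poor estimate when either quartile lies strictly outside the confidence
#' limits of the mean — i.e. when within-group spread dwarfs the precision
#' of the mean.
#'
#' @param values Numeric sample, `n >= 2` after dropping NAs.
#' @param label Group label carried into the result.
#' @return An object of class `group_summary` with fields `group_label`,
#'   `n`, `mean`, `lower_quartile`, `upper_quartile`, `ci95_low`,
#'   `ci95_high`, `poor_estimate`.
#' @export
group_summary <- function(values, label = "") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    stop("group_summary: need at least 2 values (got ", n, ")", call. = FALSE)
  }
  m <- mean(values)
  qs <- unname(stats::quantile(values, c(0.25, 0.75), type = 7))
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  ci <- c(m - half, m + half)
  structure(
    list(
      group_label = label,
      n = n,
      mean = m,
      lower_quartile = qs[1],
      upper_quartile = qs[2],
      ci95_low = ci[1],
      ci95_high = ci[2],
      poor_estimate = (qs[1] < ci[1]) || (qs[2] > ci[2])
    ),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "group '%s' (n = %d): mean %.2f [95%% CI %.2f, %.2f], IQR [%.2f, %.2f]%s\n",
    x$group_label, x$n, x$mean, x$ci95_low, x$ci95_high,
    x$lower_quartile, x$upper_quartile,
    if (x$poor_estimate) " — poor estimate" else ""))
  invisible(x)
}

#' Likert response summary
#'
#' Row-normalizes per-statement counts of negative / neutral / positive
#' responses into percentages.
#'
#' @param counts Matrix or data frame, one row per statement, three columns
#'   of non-negative counts.
#' @return Matrix of percentages (rows sum to 100); all-zero rows are dropped
#'   with a warning.
#' @export
likert_summary <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 3) {
    stop("likert_summary: expected 3 columns (negative, neutral, positive)",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("likert_summary: counts must be non-negative", call. = FALSE)
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("likert_summary: dropped ", sum(empty), " empty row(s)",
            call. = FALSE)
    counts <- counts[!empty, , drop = FALSE]
  }
  pct <- 100 * counts / rowSums(counts)
  colnames(pct) <- c("negative", "neutral", "positive")
  pct
}

#' Run the full cohort evaluation pipeline
#'
#' Executes the study's analysis plan in order: D'Agostino skewness tests on
#' the (arcsine-transformed) accuracy and recall scores; the post-hoc power
#' report for the cohort's sample size via [solve_f2()]; then each planned
#' single-predictor model via [fit_single_predictor()] with sequential
#' Bonferroni correction, stopping after the first model whose corrected
#' p-value falls below `alpha` (a "feasible" model). Group summaries are
#' produced for every categorical predictor in the plan.
#'
#' @param cohort Cohort data frame (see [cohort_columns()]).
#' @param plan Ordered list of `c(outcome, predictor)` character pairs, or a
#'   two-column data frame/matrix.
#' @param alpha Feasibility threshold on the corrected p-value.
#' @param power Target power of the effect-size report.
#' @param multiplier Passed to [bonferroni_sequential()].
#' @return An object of class `study_report`: `skew_tests` (accuracy,
#'   recall), `power` (a list u, v, alpha, power, f2), `models` (the
#'   `model_result`s actually fitted, with `p_corrected` and `test_index`
#'   filled), `feasible_model` (name or `NA`), `stopped_at` (index or `NA`)
#'   and `group_summaries`.
#' @export
run_study_pipeline <- function(cohort, plan, alpha = 0.05, power = 0.95,
                               multiplier = c("inclusive", "planned")) {
  multiplier <- match.arg(multiplier)
  plan <- normalize_plan(plan)
  if (!nrow(plan)) stop("run_study_pipeline: empty plan", call. = FALSE)

  skew_tests <- list()
  for (score in c("accuracy", "recall")) {
    if (score %in% names(cohort)) {
      vals <- cohort[[score]][!is.na(cohort[[score]])]
      skew_tests[[score]] <- dagostino_skew_test(arcsine_sqrt(vals))
    }
  }

  n <- sum(!is.na(cohort$recall))
  u <- 1
  v <- n - 2
  pwr <- list(u = u, v = v, alpha = alpha, power = power,
              f2 = solve_f2(u, v, alpha = alpha, power = power))

  models <- list()
  p_raw <- numeric(0)
  stopped_at <- NA_integer_
  for (k in seq_len(nrow(plan))) {
    res <- tryCatch(
      fit_single_predictor(cohort, plan$outcome[k], plan$predictor[k],
                           transform = TRUE),
      error = function(e) {
        stop("run_study_pipeline: model ", k, " (", plan$predictor[k], "): ",
             conditionMessage(e), call. = FALSE)
      })
    p_raw <- c(p_raw, res$p_raw)
    p_corr <- bonferroni_sequential(p_raw, multiplier = multiplier,
                                    n_planned = nrow(plan))
    res$p_corrected <- p_corr[k]
    res$test_index <- k
    models[[k]] <- res
    if (p_corr[k] < alpha) {
      stopped_at <- k
      break
    }
  }
  # refresh corrected values on the fitted models (cap-consistent)
  p_corr <- bonferroni_sequential(p_raw, multiplier = multiplier,
                                  n_planned = nrow(plan))
  for (k in seq_along(models)) models[[k]]$p_corrected <- p_corr[k]
  names(models) <- plan$predictor[seq_along(models)]

  group_summaries <- list()
  for (k in seq_len(nrow(plan))) {
    pred <- plan$predictor[k]
    x <- cohort[[pred]]
    if (is.character(x) || is.logical(x) || is.factor(x)) {
      y <- cohort[[plan$outcome[k]]]
      keep <- !is.na(x) & !is.na(y)
      gs <- lapply(split(y[keep], as.character(x[keep])), function(vals) {
        if (length(vals) >= 2) group_summary(vals) else NULL
      })
      for (lbl in names(gs)) {
        if (!is.null(gs[[lbl]])) gs[[lbl]]$group_label <- lbl
      }
      group_summaries[[pred]] <- Filter(Negate(is.null), gs)
    }
  }

  structure(
    list(
      skew_tests = skew_tests,
      power = pwr,
      models = models,
      p_raw = p_raw,
      p_corrected = p_corr,
      feasible_model = if (is.na(stopped_at)) NA_character_ else
        plan$predictor[stopped_at],
      stopped_at = stopped_at,
      group_summaries = group_summaries,
      n = n,
      alpha = alpha,
      multiplier = multiplier
    ),
    class = "study_report"
  )
}

normalize_plan <- function(plan) {
  if (is.data.frame(plan) || is.matrix(plan)) {
    plan <- as.data.frame(plan, stringsAsFactors = FALSE)
    names(plan) <- c("outcome", "predictor")
  } else if (is.list(plan)) {
    plan <- data.frame(
      outcome = vapply(plan, `[`, character(1), 1),
      predictor = vapply(plan, `[`, character(1), 2),
      stringsAsFactors = FALSE
    )
  } else {
    stop("run_study_pipeline: plan must be a list of (outcome, predictor) ",
         "pairs or a two-column table", call. = FALSE)
  }
  plan
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in names(x$skew_tests)) {
    s <- x$skew_tests[[nm]]
    cat(sprintf("  %s: skew %.2f, z %.2f, p %.3g (n %d)\n",
                nm, s$skewness, s$z_stat, s$p_value, s$n))
  }
  cat(sprintf("  power: f2 = %.4f detectable at %d on %d df (alpha %.2f, power %.2f)\n",
              x$power$f2, x$power$u, x$power$v, x$power$alpha, x$power$power))
  for (m in x$models) print(m)
  if (is.na(x$stopped_at)) {
    cat("  no feasible model found\n")
  } else {
    cat(sprintf("  stopped at model %d ('%s')\n", x$stopped_at,
                x$feasible_model))
  }
  invisible(x)
}
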