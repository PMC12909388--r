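#' Per-group summary of a cohort table
#'
#' Descriptive statistics (mean, sample SD, n) of one measured variable per
#' grouping cell, e.g. percent growth modulation by (level, side).
#'
#' @param records cohort `data.frame` (see [cohort_record()]).
#' @param group_by character vector of grouping columns.
#' @param value name of the numeric column to summarise.
#' @return `data.frame` with the grouping columns plus `mean`, `sd` (NA when
#'   n < 2), `n`.
#' @export
aggregate_levels <- function(records, group_by = c("level", "side"),
                             value = "pct_growth_modulation") {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  bad <- setdiff(c(group_by, value), names(records))
  if (length(bad)) {
    stop(sprintf("unknown column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  key <- interaction(records[group_by], drop = TRUE, lex.order = TRUE)
  cells <- split(records[[value]], key)
  keys <- do.call(rbind, strsplit(names(cells), ".", fixed = TRUE))
  out <- as.data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- group_by
  out$mean <- vapply(cells, function(v) mean(v, na.rm = TRUE), numeric(1))
  out$sd <- vapply(cells, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, numeric(1))
  out$n <- vapply(cells, function(v) sum(!is.na(v)), integer(1))
  rownames(out) <- NULL
  out
}

#' Grubbs' single-outlier test
#'
#' Computes `G`, the maximum absolute deviation from the sample mean
#' normalised by the sample (n-1) standard deviation, and compares it with
#' the critical value derived from the Student t distribution with n-2
#' degrees of freedom:
#'
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}} \sqrt{\frac{t^2}{n-2+t^2}}}
#'
#' where `t` is the upper quantile at `alpha/(2n)` (two-sided, the default:
#' the suspect value may lie on either side) or `alpha/n` (one-sided). The
#' value is flagged as an outlier when `G > G_crit`.
#'
#' @param values numeric vector, n >= 3, nonzero variance.
#' @param alpha significance level.
#' @param sidedness `"two_sided"` or `"one_sided"`.
#' @return An object of class `grubbs_result` with fields `G`, `G_crit`, `n`,
#'   `alpha`, `sidedness`, `is_outlier`, `suspect` (the extreme value).
#' @examples
#' grubbs_test(c(1, 1, 1, 1, 1, 10))
#' @export
grubbs_test <- function(values, alpha = 0.05,
                        sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Grubbs' test needs at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("Grubbs' test is undefined for zero-variance data", call. = FALSE)
  }
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  G_crit <- grubbs_critical(n, alpha, sidedness)
  structure(list(G = G, G_crit = G_crit, n = n, alpha = alpha,
                 sidedness = sidedness, is_outlier = G > G_crit,
                 suspect = values[which.max(dev)]),
            class = "grubbs_result")
}

#' @rdname grubbs_test
#' @param n sample size (>= 3).
#' @export
grubbs_critical <- function(n, alpha = 0.05,
                            sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  p <- if (sidedness == "two_sided") alpha / (2 * n) else alpha / n
  t <- stats::qt(1 - p, df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("Grubbs' test (%s): G = %.3f, G crit(n = %d, alpha = %g) = %.3f -> %s\n",
              x$sidedness, x$G, x$n, x$alpha, x$G_crit,
              if (x$is_outlier) "outlier" else "not an outlier"))
  invisible(x)
}

#' Recover a value excluded from a leave-one-out mean
#'
#' Given the mean of all n values and the mean after excluding one of them,
#' the excluded value is `n * mean_all - (n - 1) * mean_excluding_one`. This
#' reconstructs individual data points from published whole-sample and
#' leave-one-out descriptive statistics (sensitivity analyses).
#'
#' @param mean_all mean of the full sample.
#' @param n full sample size (>= 2).
#' @param mean_excluding_one mean of the remaining n - 1 values.
#' @return the excluded value.
#' @examples
#' infer_excluded_value(22.7, 6, 23.9)  # 16.7
#' @export
infer_excluded_value <- function(mean_all, n, mean_excluding_one) {
  stopifnot(is.numeric(mean_all), is.numeric(mean_excluding_one),
            n >= 2, n == round(n))
  n * mean_all - (n - 1) * mean_excluding_one
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha nominal family-wise level.
#' @param kappa number of comparisons in the family (>= 1). It is supplied by
#'   the caller, never inferred from the table, because the comparison family
#'   is an analysis decision.
#' @return `alpha / kappa`.
#' @export
bonferroni_alpha <- function(alpha, kappa) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.numeric(kappa) || kappa < 1) {
    stop("kappa must be a count >= 1", call. = FALSE)
  }
  alpha / kappa
}

#' Pairwise one-tailed t tests across groups
#'
#' Every unordered pair of groups is compared with a two-sample t test
#' (Welch's unequal-variance test by default) and a one-tailed p value taken
#' in the direction of the observed difference (`p = P(T >= |t|)`, so equal
#' sample means give p = 0.5). Significance is flagged at the
#' Bonferroni-adjusted level `alpha / kappa`.
#'
#' @param groups named list of numeric vectors.
#' @param alpha nominal level.
#' @param kappa number of comparisons for the Bonferroni family.
#' @param welch use Welch's unequal-variance test (default) or the
#'   pooled-variance test.
#' @return `data.frame` with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p_one_tailed`, `significant` (NA throughout when a group has n < 2).
#' @export
pairwise_one_tailed_t <- function(groups, alpha = 0.05, kappa = 1,
                                  welch = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  adj <- bonferroni_alpha(alpha, kappa)
  nm <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- groups[[i]][!is.na(groups[[i]])]
    b <- groups[[j]][!is.na(groups[[j]])]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(group1 = nm[i], group2 = nm[j], t = NA_real_,
                        df = NA_real_, p_one_tailed = NA_real_,
                        significant = NA))
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    tval <- unname(tt$statistic); df <- unname(tt$parameter)
    p1 <- stats::pt(-abs(tval), df)
    data.frame(group1 = nm[i], group2 = nm[j], t = tval, df = df,
               p_one_tailed = p1, significant = p1 < adj)
  })
  out <- do.call(rbind, rows)
  attr(out, "adjusted_alpha") <- adj
  out
}

# Power of the two-sample t test at effect size d and n per group, from the
# noncentral t distribution with 2n - 2 df and ncp = d * sqrt(n / 2).
t_test_power <- function(d, n, alpha = 0.05,
                         sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(n >= 2)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (sidedness == "two_sided") {
    crit <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(crit, df, ncp)) + stats::pt(-crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  }
}

#' Per-group sample size for a target power
#'
#' Smallest integer n per group for which a two-sample t test at effect size
#' `d` (Cohen's d) reaches the target power. The search starts from the
#' normal approximation `2 (z_{1-alpha/2} + z_{1-beta})^2 / d^2` and iterates
#' n against the exact noncentral t power.
#'
#' @param d Cohen's d (> 0).
#' @param alpha significance level.
#' @param power target power in (0, 1).
#' @param sidedness `"two_sided"` or `"one_sided"`.
#' @return integer n per group (minimum 2).
#' @examples
#' required_sample_size(d = 1.0)  # 17
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  if (!is.numeric(d) || d <= 0) {
    stop("effect size d must be > 0 (power unachievable at d = 0)", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha) return(2L)  # the test's size already meets the target
  za <- if (sidedness == "two_sided") stats::qnorm(1 - alpha / 2)
        else stats::qnorm(1 - alpha)
  n <- max(2L, floor(2 * (za + stats::qnorm(power))^2 / d^2) - 5L)
  while (t_test_power(d, n, alpha, sidedness) < power) n <- n + 1L
  while (n > 2L && t_test_power(d, n - 1L, alpha, sidedness) >= power) n <- n - 1L
  as.integer(n)
}

#' Post hoc power of a two-group comparison
#'
#' Cohen's d is computed from the two group means and the pooled (equal-n)
#' standard deviation, and power is evaluated from the noncentral t
#' distribution with 2n - 2 degrees of freedom.
#'
#' @param mean1,sd1,mean2,sd2 group summaries.
#' @param n_per_group per-group sample size (>= 2).
#' @param alpha significance level.
#' @param sidedness `"two_sided"` or `"one_sided"`.
#' @return list with `d` and `power`.
#' @export
post_hoc_power <- function(mean1, sd1, mean2, sd2, n_per_group, alpha = 0.05,
                           sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(n_per_group >= 2)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (!is.finite(pooled) || pooled <= 0) {
    stop("pooled standard deviation must be positive", call. = FALSE)
  }
  d <- abs(mean1 - mean2) / pooled
  list(d = d, power = t_test_power(d, n_per_group, alpha, sidedness))
}

#' One-way ANOVA across groups
#'
#' @param groups named list of numeric vectors, >= 2 groups of n >= 2 each.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- vapply(groups, function(v) sum(!is.na(v)), integer(1))
  if (any(sizes < 2)) stop("every group needs n >= 2", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(seq_along(groups), lengths(groups))))
  df <- df[!is.na(df$value), ]
  if (stats::var(df$value) == 0) {
    stop("ANOVA is undefined for zero-variance data", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"])
}
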