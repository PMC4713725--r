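# Group-comparison statistics: nested line fits (extra sum-of-squares F
# test), one-way ANOVA with the Newman-Keuls Studentized-range post test,
# two-tailed Student t tests, and mean +/- SEM summaries. Tests operate on
# mouse-level values by convention (N = number of mice).

new_test_report <- function(test_name, statistic, df, p_value, groups,
                            note = NA_character_) {
  structure(
    list(test_name = test_name, statistic = statistic, df = df,
         p_value = p_value, groups_compared = groups,
         significant_05 = !is.na(p_value) && p_value < 0.05,
         significant_01 = !is.na(p_value) && p_value < 0.01,
         note = note),
    class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  stars <- if (isTRUE(x$significant_01)) "**"
  else if (isTRUE(x$significant_05)) "*" else "ns"
  cat(sprintf("<test_report> %s [%s]\n", x$test_name,
              paste(x$groups_compared, collapse = " vs ")))
  cat(sprintf("  statistic = %s, df = (%s), p = %s %s\n",
              format(x$statistic, digits = 4),
              paste(format(x$df, digits = 4), collapse = ", "),
              format.pval(x$p_value, digits = 3), stars))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` by least squares and records the
#' residual sum of squares and residual degrees of freedom needed for
#' nested-model F tests.
#'
#' @param x,y numeric vectors of equal length (at least 3 points).
#' @return object of class `line_fit`: `slope`, `intercept`,
#'   `residual_sum_squares`, `df_residual` (`n - 2`), `n_points`.
#' @export
#' @examples
#' fit_line(1:5, 2 * (1:5) + 1)
fit_line <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("fit_line needs at least 3 points", call. = FALSE)
  if (length(unique(x)) < 2) stop("all x values identical", call. = FALSE)
  fit <- lm(y ~ x)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         residual_sum_squares = sum(fit$residuals^2),
         df_residual = fit$df.residual, n_points = length(x)),
    class = "line_fit")
}

#' Extra sum-of-squares F test between nested line models
#'
#' Compares a full model (separate lines, e.g. one per group) with a nested
#' reduced model (one shared line) via the reduction in residual sum of
#' squares:
#' `F = ((RSS_red - RSS_full) / (df_red - df_full)) / (RSS_full / df_full)`,
#' referred to the F distribution with `(df_red - df_full, df_full)` degrees
#' of freedom.
#'
#' @param full list of [fit_line()] objects (one per group), or a single
#'   one; their RSS and df are summed.
#' @param reduced a single [fit_line()] on the pooled points.
#' @param groups labels for the report.
#' @return [`test_report`][one_way_anova] with `statistic = F`,
#'   `df = c(df_num, df_den)`. Degenerate inputs (no residual degrees of
#'   freedom, or both models fitting exactly) yield `p_value = NA` with an
#'   explanatory note.
#' @export
extra_ss_f_test <- function(full, reduced, groups = NULL) {
  if (inherits(full, "line_fit")) full <- list(full)
  stopifnot(all(vapply(full, inherits, logical(1), "line_fit")),
            inherits(reduced, "line_fit"))
  rss_full <- sum(vapply(full, function(f) f$residual_sum_squares, numeric(1)))
  df_full <- sum(vapply(full, function(f) f$df_residual, numeric(1)))
  rss_red <- reduced$residual_sum_squares
  df_red <- reduced$df_residual
  if (df_red <= df_full) {
    stop("reduced model must have more residual degrees of freedom than the full model",
         call. = FALSE)
  }
  groups <- groups %||% paste("group", seq_along(full))
  if (df_full <= 0 || (rss_full == 0 && rss_red == rss_full)) {
    return(new_test_report("extra_ss_F", NA_real_, c(df_red - df_full, df_full),
                           NA_real_, groups,
                           note = "degenerate: no residual variation"))
  }
  Fstat <- ((rss_red - rss_full) / (df_red - df_full)) / (rss_full / df_full)
  p <- pf(Fstat, df_red - df_full, df_full, lower.tail = FALSE)
  new_test_report("extra_ss_F", Fstat, c(df_red - df_full, df_full), p, groups)
}

#' Compare time trends between groups
#'
#' Convenience wrapper around [extra_ss_f_test()] for long-format data: fits
#' a line to `value ~ day` in each group (the full model) and one line to
#' the pooled points (the reduced model), then tests whether separate lines
#' explain the data significantly better. With `nesting = "slope"` the full
#' model instead allows separate slopes around a shared intercept; the
#' report names the nesting used.
#'
#' @param data data frame with columns named by `day`, `value`, `group`.
#' @param day,value,group column names.
#' @param nesting `"lines"` (separate slopes and intercepts, default) or
#'   `"slope"` (separate slopes, shared intercept).
#' @return a `test_report`.
#' @export
trend_f_test <- function(data, day = "session_day", value = "value",
                         group = "group", nesting = c("lines", "slope")) {
  nesting <- match.arg(nesting)
  d <- data.frame(x = data[[day]], y = data[[value]],
                  g = factor(data[[group]]))
  d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$g)) < 2) stop("need at least 2 groups", call. = FALSE)
  d$g <- droplevels(d$g)
  reduced_fit <- lm(y ~ x, data = d)
  full_fit <- if (nesting == "lines") lm(y ~ g * x, data = d) else
    lm(y ~ x:g, data = d)
  rss <- function(f) sum(f$residuals^2)
  as_line <- function(f) structure(
    list(slope = NA_real_, intercept = NA_real_,
         residual_sum_squares = rss(f), df_residual = f$df.residual,
         n_points = length(f$residuals)),
    class = "line_fit")
  rep <- extra_ss_f_test(as_line(full_fit), as_line(reduced_fit),
                         groups = levels(d$g))
  rep$test_name <- paste0("extra_ss_F(", nesting, ")")
  rep
}

#' One-way analysis of variance
#'
#' Standard between/within sums-of-squares decomposition across two or more
#' independent groups.
#'
#' @param groups list of numeric samples (each of size >= 2); names are used
#'   as group labels.
#' @return a `test_report` with `statistic = F` and `df = c(between,
#'   within)`, plus fields `ms_within` and `group_n` consumed by
#'   [newman_keuls()]. Zero variance everywhere with equal means gives
#'   `p_value = NA` and a note.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labels
  d <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(labels, vapply(groups, length, integer(1))), levels = labels))
  fit <- aov(y ~ g, data = d)
  tab <- anova(fit)
  ss_within <- tab$`Sum Sq`[2]
  ss_between <- tab$`Sum Sq`[1]
  df <- c(tab$Df[1], tab$Df[2])
  if (ss_within == 0 && ss_between == 0) {
    rep <- new_test_report("one_way_anova", NA_real_, df, NA_real_, labels,
                           note = "degenerate: zero variance in all groups")
  } else if (ss_within == 0) {
    rep <- new_test_report("one_way_anova", Inf, df, 0, labels,
                           note = "zero within-group variance")
  } else {
    rep <- new_test_report("one_way_anova", tab$`F value`[1], df,
                           tab$`Pr(>F)`[1], labels)
  }
  rep$ms_within <- ss_within / df[2]
  rep$df_within <- df[2]
  rep$group_means <- vapply(groups, mean, numeric(1))
  rep$group_n <- vapply(groups, length, integer(1))
  rep
}

#' Studentized-range critical value
#'
#' Upper critical value `q(alpha, r, df)` of the Studentized range for `r`
#' ordered means and `df` error degrees of freedom, computed numerically
#' from the distribution function.
#'
#' @param alpha significance level.
#' @param r number of means spanned.
#' @param df error degrees of freedom.
#' @export
#' @examples
#' nk_critical_value(0.05, 3, 20) # 3.578
nk_critical_value <- function(alpha, r, df) {
  qtukey(1 - alpha, nmeans = r, df = df)
}

#' Newman-Keuls post test
#'
#' Step-down pairwise comparisons after a one-way ANOVA using
#' Studentized-range critical values. Group means are ordered; the pair
#' spanning `r` ordered means is tested with
#' `q = |mean_i - mean_j| / sqrt(MS_within / n_h)` (with `n_h` the harmonic
#' mean of the two group sizes) against `q(alpha, r, df_within)`. Testing is
#' step-down: whenever a span is non-significant, every pair nested inside
#' it is sealed as non-significant without further testing.
#'
#' @param groups list of numeric samples (named), as in [one_way_anova()].
#' @param alpha significance level for the critical values.
#' @param anova optionally a precomputed [one_way_anova()] report for the
#'   same groups (source of `MS_within` and `df_within`).
#' @return tibble of pairwise rows: `group_a`, `group_b` (in ascending order
#'   of group mean), `mean_diff`, `r`, `q`, `q_crit`, `p_value` (Studentized
#'   range tail probability, reported for tested pairs only), `significant`,
#'   `sealed` (TRUE when the decision was forced by an enclosing
#'   non-significant span).
#' @export
newman_keuls <- function(groups, alpha = 0.05, anova = NULL) {
  if (is.null(anova)) anova <- one_way_anova(groups)
  k <- length(anova$group_means)
  if (anova$df_within < 2) stop("Newman-Keuls needs df_within >= 2", call. = FALSE)
  ms_within <- anova$ms_within
  ord <- order(anova$group_means)
  means <- anova$group_means[ord]
  ns <- anova$group_n[ord]
  labels <- names(anova$group_means)[ord]

  sig <- matrix(NA, k, k)      # significance decision per ordered pair
  sealed <- matrix(FALSE, k, k)
  rows <- list()
  for (r in k:2) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      enclosing_ns <- FALSE
      # any wider span containing (i, j) already declared non-significant?
      for (i2 in seq_len(i)) {
        for (j2 in j:k) {
          if ((j2 - i2) > (j - i) && isFALSE(sig[i2, j2])) enclosing_ns <- TRUE
        }
      }
      n_h <- 2 / (1 / ns[i] + 1 / ns[j])
      q_obs <- unname(abs(means[j] - means[i]) / sqrt(ms_within / n_h))
      q_crit <- nk_critical_value(alpha, r, anova$df_within)
      if (enclosing_ns) {
        sig[i, j] <- FALSE
        sealed[i, j] <- TRUE
        p <- NA_real_
      } else {
        sig[i, j] <- q_obs > q_crit
        p <- ptukey(q_obs, nmeans = r, df = anova$df_within, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_a = labels[i], group_b = labels[j],
        mean_diff = unname(means[j] - means[i]), r = r, q = q_obs,
        q_crit = q_crit,
        p_value = p, significant = sig[i, j], sealed = sealed[i, j])
    }
  }
  dplyr::bind_rows(rows)
}

#' Two-tailed Student t test
#'
#' Pooled-variance two-sample t test (the classical Student test); Welch's
#' unequal-variance form is available behind `var_equal = FALSE`.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param var_equal pool the variances (default TRUE).
#' @param labels group labels for the report.
#' @return a `test_report` with `statistic = t` and a single `df`. If both
#'   samples have zero variance and equal means the result is degenerate
#'   (`p_value = NA`, note set).
#' @export
two_tailed_t_test <- function(a, b, var_equal = TRUE, labels = c("a", "b")) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_test_report("t_test", NA_real_, length(a) + length(b) - 2,
                             NA_real_, labels,
                             note = "degenerate: zero variance, equal means"))
    }
    return(new_test_report("t_test", Inf, length(a) + length(b) - 2, 0, labels,
                           note = "zero variance, unequal means"))
  }
  ht <- t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  rep <- new_test_report(if (var_equal) "t_test" else "t_test_welch",
                         unname(ht$statistic), unname(ht$parameter),
                         ht$p.value, labels)
  rep
}

#' Mean, SEM and n
#'
#' @param x numeric sample (in the study convention, one value per mouse).
#' @return tibble with `mean`, `sem` (`NA` when `n = 1`; sample SD over
#'   `sqrt(n)`), `n`.
#' @export
#' @examples
#' summarize_mean_sem(c(1, 3))
summarize_mean_sem <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1)
  n <- length(x)
  tibble::tibble(mean = mean(x),
                 sem = if (n > 1) sd(x) / sqrt(n) else NA_real_,
                 n = n)
}
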