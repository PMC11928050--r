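song_test_result <- function(statistic, df, p_value, effect_direction,
                             method_name, transform_applied = "none",
                             note = NULL) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         effect_direction = effect_direction, method_name = method_name,
         transform_applied = transform_applied, note = note),
    class = "song_test"
  )
}

#' @export
print.song_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, df = %s, p = %.4g\n",
              x$method_name, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_value))
  if (!identical(x$transform_applied, "none")) {
    cat("  transform:", x$transform_applied, "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, used for the overall full-data comparison of mean
#' chirp duration between groups. Degenerate inputs (zero variance in both
#' groups) follow the convention p = 1 for equal means and p = 0 (flagged)
#' otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `song_test` result. `effect_direction` is the sign of
#'   `mean(a) - mean(b)`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  dir <- sign(mean(a) - mean(b))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(song_test_result(0, length(a) + length(b) - 2, 1, 0,
                              "Welch two-sample t-test",
                              note = "zero variance in both groups"))
    }
    return(song_test_result(dir * Inf, length(a) + length(b) - 2, 0, dir,
                            "Welch two-sample t-test",
                            note = "degenerate: zero variance, unequal means"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  song_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                   dir, "Welch two-sample t-test")
}

#' F-test for equality of variances
#'
#' The ratio of the larger to the smaller sample variance, with degrees of
#' freedom ordered accordingly and a two-sided p-value
#' (2 x upper tail, capped at 1). By construction the result is invariant to
#' argument order.
#'
#' @param a,b Numeric vectors, each of length >= 2; at least one group must
#'   have nonzero variance.
#' @return A `song_test` result with `df` a length-2 vector (numerator,
#'   denominator). `effect_direction` is the sign of `var(a) - var(b)`.
#' @export
variance_f_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    stop("F-test undefined: both groups have zero variance")
  }
  if (va >= vb) {
    f <- va / vb; df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    f <- vb / va; df <- c(length(b) - 1L, length(a) - 1L)
  }
  p <- min(1, 2 * stats::pf(f, df[1L], df[2L], lower.tail = FALSE))
  song_test_result(f, df, p, sign(va - vb), "F-test of equality of variances")
}

#' Apply a recorded normality transform
#'
#' @param values Numeric vector.
#' @param transform A transform name recorded by
#'   [check_normality_and_transform()] (`"none"`, `"log"`, `"sqrt"`,
#'   `"failed"`).
#' @return The transformed values (`"none"`/`"failed"` are identity).
#' @export
apply_song_transform <- function(values, transform) {
  switch(transform,
         none = ,
         failed = values,
         log = log(values),
         sqrt = sqrt(values),
         stop("Unknown transform: ", transform))
}

#' Normality check with transform ladder
#'
#' Shapiro-Wilk test at `alpha`; if normality is rejected, a log transform is
#' tried (strictly positive data only), then a square-root transform
#' (non-negative data only), keeping the first transform under which the
#' Shapiro-Wilk test no longer rejects. When comparing two groups the same
#' transform must be applied to both; use the recorded `transform` with
#' `apply_song_transform()` on the second group.
#'
#' @param values Numeric vector, length >= 3. Samples larger than 5000 are
#'   checked on 5000 evenly spaced order statistics (Shapiro-Wilk limit).
#' @param alpha Rejection level of the normality check (default 0.05).
#' @return A list with `values` (possibly transformed), `transform` (one of
#'   `"none"`, `"log"`, `"sqrt"`, `"failed"`), and `shapiro_p` (named vector
#'   of the p-values examined).
#' @export
check_normality_and_transform <- function(values, alpha = 0.05) {
  stopifnot(length(values) >= 3L, all(is.finite(values)))
  shapiro_p_of <- function(v) {
    if (length(unique(v)) < 3L) return(NA_real_)
    if (length(v) > 5000L) {
      v <- sort(v)[as.integer(round(seq(1, length(v), length.out = 5000L)))]
    }
    stats::shapiro.test(v)$p.value
  }
  ps <- c(none = shapiro_p_of(values))
  if (is.na(ps["none"])) {
    return(list(values = values, transform = "failed", shapiro_p = ps))
  }
  if (ps["none"] >= alpha) {
    return(list(values = values, transform = "none", shapiro_p = ps))
  }
  if (all(values > 0)) {
    ps["log"] <- shapiro_p_of(log(values))
    if (!is.na(ps["log"]) && ps["log"] >= alpha) {
      return(list(values = log(values), transform = "log", shapiro_p = ps))
    }
  }
  if (all(values >= 0)) {
    ps["sqrt"] <- shapiro_p_of(sqrt(values))
    if (!is.na(ps["sqrt"]) && ps["sqrt"] >= alpha) {
      return(list(values = sqrt(values), transform = "sqrt", shapiro_p = ps))
    }
  }
  list(values = values, transform = "failed", shapiro_p = ps)
}

as_individual_values <- function(g) {
  if (is.data.frame(g)) {
    stopifnot(all(c("value", "individual") %in% names(g)))
    g <- split(g$value, g$individual)
  }
  stopifnot(is.list(g), all(vapply(g, is.numeric, logical(1))),
            all(lengths(g) >= 1L))
  g
}

#' Nested t-test on individual means
#'
#' Recordings (subsamples) are nested within individuals (biological
#' replicates): each individual's recordings are first collapsed to their
#' mean, and the treatments are compared by an equal-variance two-sample t
#' on the individual means, with `n1 + n2 - 2` degrees of freedom. For
#' balanced designs this equals the t derived from a nested ANOVA testing
#' treatment over individuals-within-treatment, and it is immune to
#' pseudoreplication: duplicating recordings within an individual does not
#' change the result.
#'
#' @param g1,g2 Either a list of numeric vectors (one vector of per-recording
#'   values per individual) or a data frame with columns `value` and
#'   `individual`. Each group needs >= 2 individuals.
#' @return A `song_test` result. `effect_direction` is the sign of the
#'   group-1 minus group-2 difference of means of individual means.
#' @export
nested_t_test <- function(g1, g2) {
  g1 <- as_individual_values(g1)
  g2 <- as_individual_values(g2)
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("Nested t-test needs at least 2 individuals per treatment")
  }
  m1 <- vapply(g1, mean, numeric(1))
  m2 <- vapply(g2, mean, numeric(1))
  dir <- sign(mean(m1) - mean(m2))
  if (stats::var(m1) == 0 && stats::var(m2) == 0) {
    if (mean(m1) == mean(m2)) {
      return(song_test_result(0, length(m1) + length(m2) - 2, 1, 0,
                              "Nested t-test (individual means)",
                              note = "zero variance in both groups"))
    }
    return(song_test_result(dir * Inf, length(m1) + length(m2) - 2, 0, dir,
                            "Nested t-test (individual means)",
                            note = "degenerate: zero variance, unequal means"))
  }
  tt <- stats::t.test(m1, m2, var.equal = TRUE)
  song_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                   dir, "Nested t-test (individual means)")
}

#' Chi-square goodness of fit on observed vs expected proportions
#'
#' `X2 = sum((O - E)^2 / E)` with `E = p * sum(O)`, `df = k - 1`, upper-tail
#' p-value. Expected proportions are normalized internally, so any uniform
#' scaling of `expected_proportions` gives the same result. Non-integer
#' "counts" are accepted: the statistic is well defined on non-negative
#' reals, which is needed when counts are reconstructed from printed
#' percentages.
#'
#' @param observed Non-negative numeric vector of observed counts (sum > 0).
#' @param expected_proportions Positive weights, same length as `observed`
#'   (normalized to proportions internally). Defaults to a uniform split.
#' @return A `song_test` result.
#' @export
chisq_gof <- function(observed,
                      expected_proportions = rep(1, length(observed))) {
  stopifnot(length(observed) == length(expected_proportions),
            all(observed >= 0), sum(observed) > 0,
            all(expected_proportions >= 0))
  p <- expected_proportions / sum(expected_proportions)
  if (any(p == 0 & observed > 0)) {
    stop("Chi-square undefined: zero expected proportion with nonzero count")
  }
  e <- p * sum(observed)
  use <- e > 0
  stat <- sum((observed[use] - e[use])^2 / e[use])
  df <- length(observed) - 1L
  song_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                   NA_real_, "Chi-square goodness of fit")
}
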