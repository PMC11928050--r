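# Brute-force reference implementations of the test battery, written from
# the textbook formulas and kept independent of the package's code paths.

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

oracle_f <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  if (va >= vb) {
    f <- va / vb; d1 <- length(a) - 1; d2 <- length(b) - 1
  } else {
    f <- vb / va; d1 <- length(b) - 1; d2 <- length(a) - 1
  }
  # upper-tail probability by numerical integration of the F density
  upper <- stats::integrate(function(x) stats::df(x, d1, d2), f, Inf,
                            rel.tol = 1e-12, abs.tol = 1e-14)$value
  list(statistic = f, df = c(d1, d2), p_value = min(1, 2 * upper))
}

# Nested ANOVA for a balanced two-treatment design: F of treatment over
# individuals-within-treatment, reported as a signed t.
oracle_nested_anova_t <- function(g1, g2) {
  r <- unique(c(lengths(g1), lengths(g2)))
  stopifnot(length(r) == 1L)                 # balanced only
  y <- c(unlist(g1), unlist(g2))
  n1 <- length(g1); n2 <- length(g2)
  ind_mean <- c(vapply(g1, mean, numeric(1)), vapply(g2, mean, numeric(1)))
  trt_of_ind <- rep(1:2, c(n1, n2))
  trt_mean <- tapply(ind_mean, trt_of_ind, mean)
  grand <- mean(ind_mean)                    # balanced: mean of means
  ss_treat <- r * sum(c(n1, n2) * (trt_mean - grand)^2)
  ss_ind <- r * sum((ind_mean - trt_mean[trt_of_ind])^2)
  df_ind <- n1 + n2 - 2
  f <- (ss_treat / 1) / (ss_ind / df_ind)
  t <- sign(trt_mean[1] - trt_mean[2]) * sqrt(f)
  list(statistic = unname(t), df = df_ind,
       p_value = 2 * stats::pt(-abs(t), df_ind))
}

oracle_chisq <- function(observed, props) {
  p <- props / sum(props)
  e <- p * sum(observed)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
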