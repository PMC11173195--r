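#' Paired t test with effect size and Bayes factor
#'
#' Classical paired t on `d = x - y` with `t = mean(d) / (sd(d)/sqrt(n))`,
#' `df = n - 1`, and the within-subject effect size `d_z = mean(d)/sd(d)
#' = t/sqrt(n)`; evidence is summarized by the natural-log JZS Bayes
#' factor ([jzs_lnbf()]).
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return list of class `social_test_result`: `statistic`, `df`,
#'   `effect_size`, `ln_bf10`, `p_value`, `method`.
#' @export
paired_t <- function(x, y, rscale = sqrt(2) / 2) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) < 1e-12) stop("zero-variance differences: t undefined")
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  res <- list(statistic = t, df = n - 1, effect_size = t / sqrt(n),
              ln_bf10 = jzs_lnbf(t, n, rscale = rscale),
              p_value = 2 * pt(-abs(t), n - 1),
              method = "paired t")
  class(res) <- "social_test_result"
  res
}

#' Two-sample pooled-variance t test
#'
#' Student t with pooled variance, `df = n_a + n_b - 2`, Cohen's d on the
#' pooled SD, and the two-sample JZS Bayes factor (effective sample size
#' `n_a n_b / (n_a + n_b)`).
#'
#' @param a,b numeric vectors (each >= 2).
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return a `social_test_result`.
#' @export
two_sample_t <- function(a, b, rscale = sqrt(2) / 2) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 < 1e-24) stop("zero pooled variance: t undefined")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  res <- list(statistic = t, df = na + nb - 2,
              effect_size = (mean(a) - mean(b)) / sqrt(sp2),
              ln_bf10 = jzs_lnbf(t, na, n2 = nb, rscale = rscale),
              p_value = 2 * pt(-abs(t), na + nb - 2),
              method = "two-sample t (pooled)")
  class(res) <- "social_test_result"
  res
}

#' @export
print.social_test_result <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.3f, p = %.3g, d = %.3f, lnBF10 = %.2f\n",
              x$method, x$df, x$statistic, x$p_value, x$effect_size,
              x$ln_bf10))
  invisible(x)
}

#' Within-subject effect size from a paired t statistic
#'
#' For a paired design, `d_z = mean(d)/sd(d) = t / sqrt(n)` exactly, so
#' the effect size can be recovered from a reported t statistic and
#' sample size.
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Cohen's d_z.
#' @export
effect_size_dz <- function(t, n) {
  stopifnot(n >= 1)
  t / sqrt(n)
}

#' Natural-log JZS Bayes factor for a t statistic
#'
#' Default Bayesian t test with a Jeffreys-Zellner-Siow prior: a Cauchy
#' prior with scale `rscale` on the standardized effect, equivalently an
#' inverse-gamma(1/2, rscale^2/2) mixing prior on `g`. The Bayes factor
#' is
#' `BF10 = integral_0^inf (1+Ng)^(-1/2) (1 + t^2/((1+Ng) nu))^(-(nu+1)/2)
#'  pi(g) dg / (1 + t^2/nu)^(-(nu+1)/2)`
#' with `N` the (effective) sample size and `nu` the degrees of freedom,
#' evaluated by adaptive quadrature on the log scale. For a one-sample or
#' paired design `N = n`, `nu = n - 1`; supplying `n2` switches to the
#' two-sample form `N = n n2/(n + n2)`, `nu = n + n2 - 2`.
#'
#' @param t observed t statistic.
#' @param n sample size (first group for two-sample).
#' @param n2 optional second-group size.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return natural logarithm of BF10.
#' @export
jzs_lnbf <- function(t, n, n2 = NULL, rscale = sqrt(2) / 2) {
  stopifnot(n >= 2, rscale > 0)
  if (is.null(n2)) {
    N <- n; nu <- n - 1
  } else {
    stopifnot(n2 >= 2)
    N <- n * n2 / (n + n2); nu <- n + n2 - 2
  }
  r2 <- rscale^2
  log_integrand <- function(g)
    -0.5 * log1p(N * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) +
    0.5 * log(r2 / 2) - lgamma(0.5) - 1.5 * log(g) - r2 / (2 * g)
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  peak <- optimize(log_integrand, c(1e-8, 1e4), maximum = TRUE)
  M <- peak$objective
  int <- tryCatch(
    integrate(function(g) exp(log_integrand(g) - M), 0, Inf,
              rel.tol = 1e-10, abs.tol = 0),
    error = function(e) stop("JZS quadrature failed: ",
                             conditionMessage(e)))
  if (int$message != "OK" || !is.finite(int$value) || int$value <= 0)
    stop("JZS quadrature did not converge: ", int$message)
  M + log(int$value) - log_null
}

#' Test-retest intraclass correlation (two-way random, absolute agreement)
#'
#' Single-measure ICC from the two-way (items x sessions) mean squares,
#' the ICC(A,1) / ICC(2,1) form:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with an F-based 95% confidence interval (Satterthwaite degrees of
#' freedom for the lower/upper bounds).
#'
#' @param session1,session2 matched numeric vectors (>= 3 items).
#' @param conf_level confidence level (default 0.95).
#' @return list of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `variant`, `ms` (mean squares).
#' @export
icc_testretest <- function(session1, session2, conf_level = 0.95) {
  stopifnot(length(session1) == length(session2), length(session1) >= 3)
  n <- length(session1); k <- 2
  Y <- cbind(session1, session2)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((Y - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-24 && mse < 1e-24) stop("degenerate ratings: no variance")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based CI (Shrout-Fleiss form for the agreement ICC)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  res <- list(icc = icc, ci_lower = min(lower, icc),
              ci_upper = max(upper, icc),
              variant = "ICC(A,1): two-way random, absolute agreement, single measure",
              ms = c(msr = msr, msc = msc, mse = mse))
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f, %s CI [%.3f, %.3f] (%s)\n", x$icc, "95%",
              x$ci_lower, x$ci_upper, x$variant))
  invisible(x)
}

#' Behavioral analysis of a ratings table
#'
#' Runs the standard battery on a long ratings table (see
#' [simulate_ratings()]): for each dimension, a paired t test comparing
#' each subject's mean rating of concepts labelled high vs low on that
#' dimension (pre-scan session), and the test-retest ICC across all
#' subject-by-concept ratings.
#'
#' @param ratings long `data.frame(subject_id, concept_id, dimension,
#'   session, rating)`.
#' @param concept_set the concept set giving each concept's labels.
#' @return named list per dimension with `contrast`
#'   (`social_test_result`) and `retest` (`icc_result`).
#' @export
behavioral_report <- function(ratings, concept_set) {
  out <- list()
  for (d in unique(ratings$dimension)) {
    sub <- ratings[ratings$dimension == d, ]
    lab <- concept_set[[d]][match(sub$concept_id, concept_set$concept_id)]
    pre <- sub[sub$session == "pre", ]
    lab_pre <- lab[sub$session == "pre"]
    hi <- aggregate(rating ~ subject_id, data = pre[lab_pre == "high", ],
                    FUN = mean)
    lo <- aggregate(rating ~ subject_id, data = pre[lab_pre == "low", ],
                    FUN = mean)
    stopifnot(all(hi$subject_id == lo$subject_id))
    contrast <- paired_t(hi$rating, lo$rating)
    wide <- merge(sub[sub$session == "pre",
                      c("subject_id", "concept_id", "rating")],
                  sub[sub$session == "post",
                      c("subject_id", "concept_id", "rating")],
                  by = c("subject_id", "concept_id"),
                  suffixes = c("_pre", "_post"))
    retest <- icc_testretest(wide$rating_pre, wide$rating_post)
    out[[d]] <- list(contrast = contrast, retest = retest)
  }
  out
}
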