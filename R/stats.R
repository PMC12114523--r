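new_test_result <- function(method, statistic_name, statistic, p_value = NA,
                            effect_size = NA, ci_low = NA, ci_high = NA,
                            n, exact = NA, degenerate = FALSE) {
  structure(list(method = method, statistic_name = statistic_name,
                 statistic = statistic, p_value = p_value,
                 effect_size = effect_size, ci_low = ci_low,
                 ci_high = ci_high, n = n, exact = exact,
                 degenerate = degenerate),
            class = "caliber_test")
}

#' @export
print.caliber_test <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4g", x$method, x$statistic_name, x$statistic))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$ci_low)) {
    cat(sprintf(", 95%% CI (%.4g, %.4g)", x$ci_low, x$ci_high))
  }
  cat(sprintf(", n = %d", x$n))
  if (isTRUE(x$exact)) cat(" [exact]")
  if (x$degenerate) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

#' Paired sign-flip permutation test
#'
#' Tests whether the mean of paired differences is zero. Under the null each
#' difference's sign is exchangeable, so the null distribution is generated
#' by independent sign flips. All `2^n` assignments are enumerated when
#' `n <= exact_max_n` (default 20); otherwise a seeded Monte Carlo draw of
#' `reps` assignments is used, with the observed assignment included in both
#' numerator and denominator (`(b + 1) / (B + 1)`, so p is never 0). The
#' two-sided p-value is the proportion of assignments whose `|mean|` reaches
#' the observed `|mean|`.
#'
#' @param differences Numeric vector of paired differences (n >= 2).
#' @param reps Monte Carlo resamples (default 10000).
#' @param seed Seed for the Monte Carlo mode.
#' @param exact_max_n Largest n for exhaustive enumeration.
#' @return A `caliber_test` with `statistic` = mean difference.
#' @export
#' @examples
#' paired_permutation_test(c(1, 1, 1))$p_value  # 2/8 = 0.25
paired_permutation_test <- function(differences, reps = 10000L, seed = 1L,
                                    exact_max_n = 20L) {
  d <- differences
  stopifnot(is.numeric(d), all(is.finite(d)), length(d) >= 2)
  n <- length(d)
  obs <- mean(d)
  if (all(d == 0)) {
    return(new_test_result("paired_permutation", "mean_difference", obs,
                           p_value = 1.0, effect_size = obs, n = n,
                           exact = TRUE, degenerate = TRUE))
  }
  tol <- 1e-9 * max(abs(d))
  if (n <= exact_max_n) {
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    p <- mean(abs(sums / n) >= abs(obs) - tol)
    exact <- TRUE
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), reps * n, replace = TRUE), reps, n)
    means <- as.vector(signs %*% d) / n
    p <- (sum(abs(means) >= abs(obs) - tol) + 1) / (reps + 1)
    exact <- FALSE
  }
  new_test_result("paired_permutation", "mean_difference", obs, p_value = p,
                  effect_size = obs, n = n, exact = exact)
}

# U statistics of every n-vs-m labeling of the pooled midranks
mw_enumerate_u <- function(r, n) {
  combs <- utils::combn(length(r), n)
  colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties:
#' `U = sum(rank(x in pooled)) - n(n+1)/2`. For `n + m <= exact_max` the
#' two-sided p-value is exact, by enumerating all `choose(n+m, n)` labelings
#' of the pooled (tie-aware) midranks and counting those whose `|U - nm/2|`
#' reaches the observed one. Larger samples use the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples (each n, m >= 1).
#' @param exact_max Largest `n + m` for exact enumeration (default 14).
#' @return A `caliber_test` with `statistic` = U (for `x`).
#' @export
#' @examples
#' mann_whitney_u(c(3, 4), c(1, 2))$p_value  # 1/3, exact
mann_whitney_u <- function(x, y, exact_max = 14L) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (N <= exact_max) {
    u_all <- mw_enumerate_u(r, n)
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(new_test_result("mann_whitney_u", "U", U, p_value = 1.0,
                             n = N, exact = FALSE, degenerate = TRUE))
    }
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
    exact <- FALSE
  }
  new_test_result("mann_whitney_u", "U", U, p_value = p, n = N,
                  exact = exact)
}

#' Paired mean difference with bootstrap confidence interval
#'
#' Estimation-statistics style effect size: the mean of the paired
#' differences with a 95 percent bootstrap CI from seeded resampling of the
#' pairs. The interval is bias-corrected-and-accelerated (BCa, jackknife
#' acceleration); when the bias correction or acceleration is undefined
#' (degenerate resamples) the percentile interval is used and recorded in
#' `method`.
#'
#' @param differences Paired differences (n >= 3).
#' @param reps Bootstrap resamples (default 5000).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return A `caliber_test` with `effect_size`, `ci_low`, `ci_high`.
#' @export
paired_mean_difference_ci <- function(differences, reps = 5000L, seed = 1L,
                                      conf = 0.95) {
  d <- differences
  stopifnot(is.numeric(d), all(is.finite(d)), length(d) >= 3)
  n <- length(d)
  obs <- mean(d)
  if (max(d) == min(d)) {
    return(new_test_result("bootstrap_degenerate", "mean_difference", obs,
                           effect_size = obs, ci_low = obs, ci_high = obs,
                           n = n, degenerate = TRUE))
  }
  set.seed(seed)
  idx <- matrix(sample.int(n, reps * n, replace = TRUE), reps, n)
  th <- rowMeans(matrix(d[idx], reps, n))
  alpha <- (1 - conf) / 2
  # BCa: bias correction from the bootstrap distribution, acceleration from
  # the jackknife
  prop_less <- (sum(th < obs) + 0.5 * sum(th == obs)) / reps
  jk <- (sum(d) - d) / (n - 1)
  jm <- mean(jk)
  denom <- 6 * sum((jm - jk)^2)^1.5
  method <- "bootstrap_bca"
  if (prop_less <= 0 || prop_less >= 1 || denom == 0) {
    lo <- stats::quantile(th, alpha, names = FALSE)
    hi <- stats::quantile(th, 1 - alpha, names = FALSE)
    method <- "bootstrap_percentile"
  } else {
    z0 <- stats::qnorm(prop_less)
    a <- sum((jm - jk)^3) / denom
    adj <- function(q) {
      zq <- stats::qnorm(q)
      stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    }
    lo <- stats::quantile(th, adj(alpha), names = FALSE)
    hi <- stats::quantile(th, adj(1 - alpha), names = FALSE)
  }
  new_test_result(method, "mean_difference", obs, effect_size = obs,
                  ci_low = lo, ci_high = hi, n = n)
}

#' Ordinary least squares slope, intercept and R^2
#'
#' Thin wrapper around [stats::lm()]; `r2 = 1 - SS_res / SS_tot`. A constant
#' response gives `r2 = 0` with a degenerate flag.
#'
#' @param x,y Numeric vectors (n >= 3, `var(x) > 0`).
#' @return List: `slope`, `intercept`, `r2`, `n`, `degenerate`.
#' @export
linregress_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0) stop("x has zero variance")
  if (stats::var(y) == 0) {
    fit <- stats::lm(y ~ x)
    return(list(slope = 0, intercept = y[1], r2 = 0, n = length(x),
                degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r2 = summary(fit)$r.squared, n = length(x), degenerate = FALSE)
}

#' Collect test results into a statistical summary table
#'
#' @param results Named list of `caliber_test` objects (names become the
#'   `comparison` column).
#' @return Data frame in the layout of a statistical methods table:
#'   comparison, test, statistic, p, effect size, CI bounds, n, method.
#' @export
stats_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(comparison = nm, test = r$method,
               statistic = r$statistic, p_value = r$p_value,
               effect_size = r$effect_size, ci_low = r$ci_low,
               ci_high = r$ci_high, n = r$n,
               method = if (isTRUE(r$exact)) paste0(r$method, "_exact")
                        else r$method)
  }))
}
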