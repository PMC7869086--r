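new_nq_test <- function(statistic, p_value, method, exact, n, extra = list()) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   method = method, exact = exact, n = n), extra),
            class = "nq_test")
}

#' @export
print.nq_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.6g, p = %.4g (%s; n = %s)\n",
              x$method, x$statistic, x$p_value,
              if (isTRUE(x$exact)) "exact" else "approximate",
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Grubbs test for a single outlier
#'
#' Tests the most extreme studentized deviate `G = max |x - mean| / sd`
#' against the critical value
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))`, where `t` is the
#' upper `alpha/(2n)` (two-sided) or `alpha/n` (one-sided) critical value of
#' Student's t with `n - 2` degrees of freedom. With zero variance no
#' outlier can be flagged. G is location- and scale-invariant.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param two_sided Two-sided test (default TRUE).
#' @return An `nq_test` with `statistic` (G), `critical` (G_crit), and
#'   `outlier_index` (index of the flagged value, or `NA` if none).
#' @export
#' @examples
#' grubbs_test(c(1, 1, 1, 1, 1, 1, 1, 100))$outlier_index  # 8
grubbs_test <- function(values, alpha = 0.05, two_sided = TRUE) {
  n <- length(values)
  if (n < 3) abort("Grubbs test needs at least 3 values.")
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  s <- sd(values)
  if (s == 0) {
    res <- new_nq_test(0, 1, "Grubbs test for one outlier", TRUE, n,
                       list(critical = NA_real_, outlier_index = NA_integer_))
    return(res)
  }
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  a <- if (two_sided) alpha / (2 * n) else alpha / n
  tcrit <- qt(1 - a, df = n - 2)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  idx <- if (g > gcrit) which.max(dev) else NA_integer_
  # approximate p: smallest alpha at which G would be flagged
  denom <- (n - 1)^2 - g^2 * n
  pt_arg <- if (denom > 0) g^2 * n * (n - 2) / denom else Inf
  p <- if (!is.finite(pt_arg)) 0 else {
    pp <- n * (if (two_sided) 2 else 1) * pt(sqrt(pt_arg), df = n - 2, lower.tail = FALSE)
    min(1, pp)
  }
  new_nq_test(g, p, "Grubbs test for one outlier", TRUE, n,
              list(critical = gcrit, outlier_index = idx))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with average ranks for ties. The p-value is exact by full
#' enumeration of all group labelings when `n_x + n_y <= exact_limit`
#' (default 12) and there are no ties; otherwise it uses the normal
#' approximation with tie and continuity corrections. `exact` in the result
#' reports which branch ran.
#'
#' @param x,y Non-empty numeric samples.
#' @param two_sided Two-sided alternative (default TRUE).
#' @param exact_limit Largest `n_x + n_y` for the enumeration branch.
#' @return An `nq_test`; `statistic` is `U` for the first sample.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 2/20 = 0.1
mann_whitney_u <- function(x, y, two_sided = TRUE, exact_limit = 12) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) abort("Both groups must be non-empty.")
  all_v <- c(x, y)
  rk <- rank(all_v)
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(all_v) > 0
  n <- nx + ny
  if (!ties && n <= exact_limit) {
    # full enumeration of all C(n, nx) labelings
    combos <- utils::combn(n, nx)
    rks <- rank(all_v)
    us <- apply(combos, 2, function(ix) sum(rks[ix])) - nx * (nx + 1) / 2
    mid <- nx * ny / 2
    p <- if (two_sided) {
      mean(abs(us - mid) >= abs(u - mid) - 1e-9)
    } else {
      mean(us >= u - 1e-9)
    }
    return(new_nq_test(u, p, "Mann-Whitney U test", TRUE, c(nx, ny)))
  }
  mu <- nx * ny / 2
  tie_tab <- table(all_v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
  if (sigma == 0) return(new_nq_test(u, 1, "Mann-Whitney U test", FALSE, c(nx, ny)))
  z <- u - mu
  cc <- sign(z) * 0.5
  z <- (z - cc) / sigma
  p <- if (two_sided) 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
  new_nq_test(u, min(1, p), "Mann-Whitney U test (normal approximation)",
              FALSE, c(nx, ny))
}

#' Kruskal-Wallis rank test across groups
#'
#' The H statistic with tie correction and a chi-square reference with
#' `k - 1` degrees of freedom (via [stats::kruskal.test()]); flagged
#' approximate whenever any group has fewer than 5 observations, where the
#' chi-square reference is rough.
#'
#' @param groups A list of (>= 2) non-empty numeric vectors.
#' @return An `nq_test` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("Kruskal-Wallis needs a list of at least 2 groups.")
  }
  if (any(lengths(groups) == 0)) abort("All groups must be non-empty.")
  kt <- stats::kruskal.test(groups)
  small <- any(lengths(groups) < 5)
  new_nq_test(kt$statistic, kt$p.value,
              if (small) "Kruskal-Wallis test (chi-square approximation, small groups)"
              else "Kruskal-Wallis test",
              FALSE, lengths(groups),
              list(df = unname(kt$parameter)))
}

#' Kolmogorov-Smirnov normality test (fitted parameters)
#'
#' One-sample KS distance against a normal with the sample mean and SD.
#' The default asymptotic p-value ignores that the parameters were
#' estimated and is therefore anti-conservative (flagged in the method
#' string); `lilliefors = TRUE` calibrates the null by Monte-Carlo
#' simulation of normal samples with re-fitted parameters instead.
#'
#' @param values Numeric vector, n >= 5, with positive SD.
#' @param lilliefors Use the Monte-Carlo Lilliefors calibration.
#' @param n_mc Number of Monte-Carlo null replicates (default 2000).
#' @return An `nq_test` with the KS distance D.
#' @export
ks_normality <- function(values, lilliefors = FALSE, n_mc = 2000) {
  n <- length(values)
  if (n < 5) abort("KS normality test needs at least 5 values.")
  s <- sd(values)
  if (s == 0) abort("Constant data: SD is 0, the fitted-normal KS distance is degenerate.")
  ks_d <- function(v) {
    m <- mean(v); sdv <- sd(v)
    z <- sort(pnorm(v, m, sdv))
    i <- seq_along(z)
    max(i / length(z) - z, z - (i - 1) / length(z))
  }
  d <- ks_d(values)
  if (lilliefors) {
    d_null <- vapply(seq_len(n_mc), function(i) ks_d(rnorm(n)), numeric(1))
    p <- (1 + sum(d_null >= d)) / (n_mc + 1)
    return(new_nq_test(d, p, "Lilliefors normality test (Monte-Carlo null)",
                       FALSE, n))
  }
  # asymptotic Kolmogorov tail: 2 * sum (-1)^{k-1} exp(-2 k^2 n D^2)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * n * d^2))
  p <- min(1, max(0, p))
  new_nq_test(d, p,
              "Kolmogorov-Smirnov normality test (fitted parameters; asymptotic p is anti-conservative)",
              FALSE, n)
}
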