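#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' Computes the exact two-sided p-value for the 2x2 table
#' `rbind(c(a, b), c(c, d))` by summing the conditional hypergeometric
#' point probabilities of all tables (with the same margins) whose
#' probability does not exceed that of the observed table. This is the
#' classical two-sided Fisher definition; the comparison uses the standard
#' `1 + 1e-7` relative tolerance so that ties at the observed probability
#' are included despite floating-point rounding.
#'
#' The function is vectorised over tables, and its cost per table is
#' proportional to the smallest margin, so it remains fast even when the
#' column totals are whole-repertoire template counts.
#'
#' @param a,b,c,d Non-negative integer vectors (recycled) giving the cell
#'   counts; `a` and `b` form the first row.
#' @return Numeric vector of two-sided p-values in `[0, 1]`.
#' @examples
#' fisher_exact_p(10, 1, 90, 99)
#' stats::fisher.test(matrix(c(10, 90, 1, 99), 2))$p.value
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    stop_config("fisher_exact_p() requires non-negative integer cell counts")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 total (white balls)
    nn <- c[i] + d[i]         # row 2 total (black balls)
    k <- a[i] + c[i]          # column 1 total (balls drawn)
    if (k == 0 || k == m + nn || m == 0 || nn == 0) return(1)
    support <- max(0, k - nn):min(k, m)
    dens <- dhyper(support, m, nn, k)
    obs <- dhyper(a[i], m, nn, k)
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Odds ratio for 2x2 tables with Haldane-Anscombe correction
#'
#' `odds_ratio_2x2()` returns `(a * d) / (b * c)`; whenever any cell of a
#' table is zero, 0.5 is added to all four cells of that table so that the
#' ratio (and its log) stays finite.
#'
#' @inheritParams fisher_exact_p
#' @return Numeric vector of odds ratios.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  d <- rep_len(as.numeric(d), n)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a[zero] <- a[zero] + 0.5
  b[zero] <- b[zero] + 0.5
  c[zero] <- c[zero] + 0.5
  d[zero] <- d[zero] + 0.5
  (a * d) / (b * c)
}

#' Exact two-rate Poisson comparison (conditional binomial test)
#'
#' Tests the null hypothesis of equal event rates for two Poisson counts
#' `x1` and `x2` observed over exposures `t1` and `t2`. Conditional on
#' `n = x1 + x2`, `x1` is Binomial(n, t1 / (t1 + t2)) under the null; the
#' two-sided p-value sums the binomial point probabilities not exceeding
#' that of the observed `x1` (with the standard `1 + 1e-7` relative
#' tolerance). This is the classical exact comparison of two Poisson
#' rates, here used as the "Poisson test" for motif enrichment between
#' compartments.
#'
#' @param x1,x2 Non-negative integer counts (vectorised, recycled).
#' @param t1,t2 Positive exposures (e.g. total template counts).
#' @return Numeric vector of two-sided p-values. When `x1 + x2 == 0` the
#'   p-value is 1 (degenerate comparison).
#' @examples
#' poisson_rate_p(12, 0, 1e4, 1e4)  # 2 * 0.5^12
#' @export
poisson_rate_p <- function(x1, x2, t1, t2) {
  n <- max(length(x1), length(x2), length(t1), length(t2))
  x1 <- rep_len(as.numeric(x1), n)
  x2 <- rep_len(as.numeric(x2), n)
  t1 <- rep_len(as.numeric(t1), n)
  t2 <- rep_len(as.numeric(t2), n)
  if (any(t1 <= 0) || any(t2 <= 0)) {
    stop_config("poisson_rate_p() requires positive exposures")
  }
  vapply(seq_len(n), function(i) {
    tot <- x1[i] + x2[i]
    if (tot == 0) return(1)
    p0 <- t1[i] / (t1[i] + t2[i])
    dens <- dbinom(0:tot, tot, p0)
    obs <- dens[x1[i] + 1]
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

# Round a positive number up to 3 significant digits.
round_up_sig3 <- function(x) {
  stopifnot(x > 0)
  e <- floor(log10(x))
  scale <- 10^(2 - e)
  up <- ceiling(x * scale - 1e-9) / scale
  up
}
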