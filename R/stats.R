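#' Agresti-Coull binomial confidence interval
#'
#' Adjusted-count interval for a proportion: with `x` successes in `n`
#' trials and normal quantile `z`, the adjusted proportion is
#' `p~ = (x + z^2/2) / (n + z^2)` and the half-width
#' `z * sqrt(p~ (1 - p~) / (n + z^2))`.  This is the interval used for
#' spark fidelity.
#'
#' @param x number of successes (successful sparks).
#' @param n number of trials (simulations).
#' @param z normal quantile (default 1.96 for 95%).
#' @return a `proportion_ci` list: `x`, `n`, `z`, `p_tilde`, `half_width`,
#'   `lower`, `upper`, and percent renderings rounded to one decimal
#'   (`percent`, `percent_half_width`).
#' @examples
#' agresti_coull(63, 200)  # 31.8% +/- 6.4%
#' @export
agresti_coull <- function(x, n, z = 1.96) {
  stopifnot(n >= 1, x >= 0)
  if (x > n) stop("successes exceed trials")
  n_t <- n + z^2
  p_t <- (x + z^2 / 2) / n_t
  hw <- z * sqrt(p_t * (1 - p_t) / n_t)
  structure(list(x = x, n = n, z = z, p_tilde = p_t, half_width = hw,
                 lower = max(0, p_t - hw), upper = min(1, p_t + hw),
                 percent = round(100 * p_t, 1),
                 percent_half_width = round(100 * hw, 1)),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.1f%% +/- %.1f%% (Agresti-Coull, %d/%d)\n",
              100 * x$p_tilde, 100 * x$half_width, x$x, x$n))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger
#' than the observed table's (the standard definition); used to compare
#' spark fidelities between configurations (binary outcomes).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero")
  stats::fisher.test(table)$p.value
}

#' Group comparison with Welch's t-test
#'
#' Mean and standard error per group plus a two-sample unequal-variance
#' t-test (two-sided); used for amplitude/TTP/duration contrasts against
#' the unphosphorylated case.  Two constant samples with equal means give
#' p = 1 by convention.
#'
#' @param a,b numeric samples (length >= 2 each).
#' @return list with `mean_a`, `se_a`, `mean_b`, `se_b`, `t`, `p`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(mean_a = mean(a), se_a = 0, mean_b = mean(b), se_b = 0,
                t = if (same) 0 else Inf, p = if (same) 1 else 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(mean_a = mean(a), se_a = se(a), mean_b = mean(b), se_b = se(b),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Kernel density estimate of spark amplitudes
#'
#' Gaussian kernel with Scott's rule-of-thumb bandwidth by default.
#'
#' @param values numeric sample (length >= 2).
#' @param bw bandwidth: `"scott"`, or a positive number.
#' @param n grid size.
#' @return list with `x`, `y` (density curve) and `bw`.
#' @export
kde <- function(values, bw = "scott", n = 512) {
  stopifnot(length(values) >= 2)
  if (identical(bw, "scott")) {
    if (stats::sd(values) == 0)
      stop("zero variance; supply an explicit bandwidth")
    bw <- stats::bw.nrd(values)
  }
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = n, cut = 5)
  list(x = d$x, y = d$y, bw = d$bw)
}
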