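# Comparative statistics: urea-N fractions, rank-sum tests and boxplot
# summaries used to contrast nutrient regimes and rate distributions
# between regions.

#' Fraction of urea-N in the combined ammonium-N + urea-N pool
#'
#' Below-detection values are substituted before the ratio is formed,
#' according to `lod_policy`: the analytical LOD (`"lod"`, conservative —
#' biases the fraction downward when the other analyte is quantified),
#' half the LOD (`"half_lod"`) or zero (`"zero"`). When both analytes are
#' below detection the fraction is undefined (`NA`).
#'
#' @param urea_nM,ammonium_nM Concentrations (nM-N); vectorized.
#' @param urea_below_lod,ammonium_below_lod Logical below-detection flags.
#' @param urea_lod,ammonium_lod Analytical LODs (nM-N) used for
#'   substitution.
#' @param lod_policy `"lod"`, `"half_lod"` or `"zero"`.
#' @return Fraction urea / (urea + ammonium) in `[0, 1]`, `NA` where
#'   undefined.
#' @export
urea_fraction <- function(urea_nM, ammonium_nM,
                          urea_below_lod = FALSE,
                          ammonium_below_lod = FALSE,
                          urea_lod = 0, ammonium_lod = 0,
                          lod_policy = c("lod", "half_lod", "zero")) {
  lod_policy <- match.arg(lod_policy)
  n <- max(length(urea_nM), length(ammonium_nM))
  u <- rep_len(as.numeric(urea_nM), n)
  a <- rep_len(as.numeric(ammonium_nM), n)
  ubd <- rep_len(as.logical(urea_below_lod), n)
  abd <- rep_len(as.logical(ammonium_below_lod), n)
  ul <- rep_len(as.numeric(urea_lod), n)
  al <- rep_len(as.numeric(ammonium_lod), n)
  sub <- function(lod) switch(lod_policy, lod = lod, half_lod = lod / 2,
                              zero = 0 * lod)
  u[ubd] <- sub(ul)[ubd]
  a[abd] <- sub(al)[abd]
  out <- ifelse(u + a > 0, u / (u + a), NA_real_)
  out[ubd & abd] <- NA_real_
  out
}

# Null distribution of the Mann-Whitney U statistic: counts[u + 1] is the
# number of the choose(n1 + n2, n1) equally likely rank assignments with
# statistic u, by the classic recursion
# c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1).
u_null_counts <- function(n1, n2) {
  dp <- lapply(0:n1, function(m) 1)  # n = 0: U is always 0
  for (nn in seq_len(n2)) {
    new <- vector("list", n1 + 1L)
    new[[1]] <- 1
    for (m in seq_len(n1)) {
      umax <- m * nn
      v <- numeric(umax + 1L)
      for (u in 0:umax) {
        a <- if (u - nn >= 0 && u - nn <= (m - 1) * nn) {
          new[[m]][u - nn + 1L]
        } else 0
        b <- if (u <= m * (nn - 1)) dp[[m + 1L]][u + 1L] else 0
        v[u + 1L] <- a + b
      }
      new[[m + 1L]] <- v
    }
    dp <- new
  }
  dp[[n1 + 1L]]
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' The statistic is the rank-sum-minus-minimum form
#' `W = sum(rank(x in pooled ranking)) - n1 (n1 + 1) / 2`, ranging over
#' `[0, n1 n2]`. The p value is exact (full enumeration of the null rank
#' distribution) when there are no ties and `n1 + n2 <= exact_limit`;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_limit Largest pooled sample size for the exact p value.
#' @return An object of class `rank_test` with `W`, `p_value`, `n1`, `n2`
#'   and `method` (`"exact"` or `"normal_approx_cc"`).
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "greater", "less"),
                         exact_limit = 20L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stopf("both samples must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)

  if (!has_ties && n1 + n2 <= exact_limit) {
    counts <- u_null_counts(n1, n2)
    total <- sum(counts)
    p_le <- sum(counts[seq_len(w + 1L)]) / total
    p_ge <- sum(counts[(w + 1L):length(counts)]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- w - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- (z - cc) / sigma
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pnorm(z),
                                           pnorm(z, lower.tail = FALSE))),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
    method <- "normal_approx_cc"
  }
  structure(list(W = w, p_value = p, n1 = n1, n2 = n2, method = method,
                 alternative = alternative),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> W = %g, p = %.4g (%s, %s; n = %d, %d)\n",
              x$W, x$p_value, x$alternative, x$method, x$n1, x$n2))
  invisible(x)
}

#' Boxplot summary with selectable whisker convention
#'
#' Quartiles use the linear-interpolation (type 7) quantile definition.
#' Whiskers either span the 10th to 90th percentile (`"pct10_90"`) or
#' extend to the most extreme data points within 1.5 times the
#' interquartile range of the quartiles (`"iqr1_5"`, the Tukey rule).
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @param whisker_mode `"pct10_90"` or `"iqr1_5"`.
#' @return List with `q25`, `median`, `q75`, `whisker_low`,
#'   `whisker_high`, `outliers` (points outside the whiskers) and `n`.
#' @export
box_summary <- function(values, whisker_mode = c("pct10_90", "iqr1_5")) {
  whisker_mode <- match.arg(whisker_mode)
  values <- values[!is.na(values)]
  if (length(values) < 1L) stopf("empty input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (whisker_mode == "pct10_90") {
    wl <- unname(quantile(values, 0.10, type = 7))
    wh <- unname(quantile(values, 0.90, type = 7))
  } else {
    iqr <- q[3] - q[1]
    inside <- values[values >= q[1] - 1.5 * iqr &
                     values <= q[3] + 1.5 * iqr]
    wl <- min(inside); wh <- max(inside)
  }
  list(q25 = q[1], median = q[2], q75 = q[3], whisker_low = wl,
       whisker_high = wh,
       outliers = sort(values[values < wl | values > wh]),
       n = length(values))
}

#' Arithmetic mean with its standard error
#'
#' @param values Numeric vector (NAs dropped); SE requires n >= 2.
#' @return List with `mean`, `se` (`NA` for n < 2) and `n`.
#' @export
mean_with_se <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stopf("empty input")
  list(mean = mean(values),
       se = if (n >= 2) sd(values) / sqrt(n) else NA_real_, n = n)
}
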