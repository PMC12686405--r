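# Shared fixture builders; everything is generated in code at test time.

# A rate_estimate with just the fields the censoring/reconciliation rules
# look at, for rule-level tests that don't need a fitted series.
make_estimate <- function(rate, significant, lod = 0.04,
                          treatment = "UREA_15N") {
  structure(list(slope = rate, slope_se = NA_real_, t_statistic = NA_real_,
                 p_one_sided = if (significant) 0.01 else 0.5, rate = rate,
                 lod = lod, significant = significant, censored = FALSE,
                 n_points = 5L, treatment = treatment, region = "test",
                 station = "t1", depth_m = 100, replicate = 1L),
            class = "rate_estimate")
}

# Closed-form OLS oracle (normal equations), independent of lm().
ols_oracle <- function(t_h, y) {
  n <- length(t_h)
  sxx <- sum((t_h - mean(t_h))^2)
  slope <- sum((t_h - mean(t_h)) * (y - mean(y))) / sxx
  res <- y - mean(y) - slope * (t_h - mean(t_h))
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  list(slope = slope * 24, se = se * 24)
}

# Brute-force three-threshold filter, the BSR classifier oracle.
bsr_oracle <- function(reads, min_score = 100, min_identity = 90,
                       min_bsr = 0.9, missing_global_ok = TRUE) {
  out <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s_ok <- reads$custom_score[i] >= min_score
    i_ok <- reads$custom_identity[i] >= min_identity
    b_ok <- if (is.na(reads$global_score[i])) missing_global_ok
            else reads$custom_score[i] / reads$global_score[i] >= min_bsr
    out[i] <- s_ok && i_ok && b_ok
  }
  out
}

# Exact two-sided Mann-Whitney p by explicit enumeration of all
# choose(n1 + n2, n1) rank assignments (tie-free data only).
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ws <- apply(utils::combn(N, n1), 2,
              function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
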