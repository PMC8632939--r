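# Independent oracles and fixture builders shared across the suite.

# JZS Bayes factor oracle: marginalise the noncentral-t density over the
# Cauchy effect-size prior by a fine midpoint rule on the Cauchy quantile
# scale. Deliberately a different parametrisation (delta-space, stats::dt
# with ncp) and a different quadrature than the package's g-integral.
bf_oracle <- function(t, df, neff, scale = sqrt(2) / 2, K = 50001) {
  u <- seq(1 / (2 * K), 1 - 1 / (2 * K), length.out = K)
  delta <- scale * tan(pi * (u - 0.5))
  ld <- suppressWarnings(dt(t, df, ncp = delta * sqrt(neff), log = TRUE))
  mx <- max(ld)
  log_m1 <- mx + log(mean(exp(ld - mx)))
  log_m0 <- dt(t, df, log = TRUE)
  exp(log_m1 - log_m0)
}

# Tie-free matched-pairs rank-biserial correlation, computed the textbook
# way from plain ranks of the absolute nonzero differences.
rank_biserial_oracle <- function(x1, x2) {
  d <- x2 - x1
  d <- d[d != 0]
  stopifnot(length(d) > 0, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  (sum(rk[d > 0]) - sum(rk[d < 0])) / sum(rk)
}

# Deterministic 24-hex participant ids.
valid_ids <- function(n, offset = 0) sprintf("%024x", seq_len(n) + offset)

# Texts that pass / fail the stopword-based English heuristic.
english_text <- function(n = 1) {
  base <- paste(
    "i was at home with my family and we were talking about how the",
    "situation had changed over the year and what we could do next")
  rep(base, n)
}

non_english_text <- function(n = 1) {
  rep(paste(rep(c("zzz", "qqq", "xxy", "bzzt", "grfm"), 5), collapse = " "), n)
}

punct_heavy_text <- function(n = 1) {
  rep("ok !!! ??? ... !!?? ((()))) ::: ;;; !!!", n)
}

emotion_cols_tibble <- function(n, value = 5L) {
  out <- tibble::as_tibble(setNames(
    rep(list(rep(as.integer(value), n)), 9), emotion_names()))
  out
}

# One-wave roster of n fully valid records.
valid_wave <- function(n, phase = 2L, offset = 0, score = 5L) {
  dplyr::bind_cols(
    tibble::tibble(participant_id = valid_ids(n, offset), phase = phase),
    emotion_cols_tibble(n, score),
    tibble::tibble(text_long = english_text(n), text_short = english_text(n),
                   age = rep(35L, n), gender = rep("female", n)))
}

# The planted exclusion roster: `n_valid` clean records plus disjoint
# blocks violating exactly one rule each, and `n_dup` trailing duplicates
# of clean ids.
exclusion_roster <- function(n_valid = 1716, n_noneng = 67, n_punct = 6,
                             n_badid = 33, n_dup = 17) {
  clean <- valid_wave(n_valid, offset = 0)
  noneng <- valid_wave(n_noneng, offset = n_valid)
  noneng$text_long <- non_english_text(n_noneng)
  punct <- valid_wave(n_punct, offset = n_valid + n_noneng)
  punct$text_long <- punct_heavy_text(n_punct)
  badid <- valid_wave(n_badid, offset = n_valid + n_noneng + n_punct)
  badid$participant_id <- paste0("BAD-", seq_len(n_badid))
  dup <- clean[seq_len(n_dup), ]
  dplyr::bind_rows(clean, noneng, punct, badid, dup)
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
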