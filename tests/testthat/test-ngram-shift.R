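# n-gram preprocessing, document-frequency filtering and the
# randomized-tie Wilcoxon shift statistic.

mini_docs <- function(texts1, texts2) {
  n <- length(texts1)
  preprocess_for_ngrams(tibble::tibble(
    participant_id = rep(as.character(seq_len(n)), 2),
    phase = rep(1:2, each = n),
    text_long = c(texts1, texts2)))
}

test_that("preprocessing lower-cases, removes stopwords and stems in order", {
  df <- tibble::tibble(participant_id = "a", phase = 1L,
                       text_long = "We are staying at home!")
  expect_equal(preprocess_for_ngrams(df)$tokens[[1]], c("stay", "home"))
  df2 <- tibble::tibble(participant_id = "a", phase = 1L,
                        text_long = "Vaccines vaccinated")
  expect_equal(preprocess_for_ngrams(df2)$tokens[[1]], c("vaccin", "vaccin"))
  df3 <- tibble::tibble(participant_id = "a", phase = 1L, text_long = "")
  expect_equal(preprocess_for_ngrams(df3)$tokens[[1]], character(0))
})

test_that("n-gram matrix forms post-removal adjacency and filters by docfreq", {
  docs <- mini_docs(
    rep("we are staying at home today", 10),
    rep("the vaccine gives hope today", 10))
  mat <- build_ngram_matrix(docs, orders = 1:3, min_docfreq = 0.05)
  expect_true("stay_home" %in% mat$vocab$ngram)
  expect_true("stay_home_today" %in% mat$vocab$ngram)
  expect_true(all(mat$vocab$docfreq >= 0.05))
  # docfreq of phase-1-only trigram is 10/20
  expect_equal(mat$vocab$docfreq[mat$vocab$ngram == "stay_home_today"], 0.5)

  # an n-gram in 4 of 100 documents is dropped at the 5% threshold
  texts1 <- c(rep("rare term here today", 2), rep("common words here today", 48))
  texts2 <- c(rep("rare term here today", 2), rep("common words here today", 48))
  mat2 <- build_ngram_matrix(mini_docs(texts1, texts2), orders = 1,
                             min_docfreq = 0.05)
  expect_false("rare" %in% mat2$vocab$ngram)
  expect_true("common" %in% mat2$vocab$ngram)
})

test_that("per-phase count totals are conserved and thresholds are monotone", {
  set.seed(77)
  co <- generate_cohort(synth_config(n_participants = 40, seed = 10))
  resp <- co$responses
  docs <- preprocess_for_ngrams(resp)
  mat <- build_ngram_matrix(docs, orders = 1, min_docfreq = 0.05)
  # conservation for a unigram: matrix column sum equals token tally
  g <- mat$vocab$ngram[1]
  tally <- sum(vapply(seq_len(nrow(docs)), function(i)
    if (docs$phase[i] == 1) sum(docs$tokens[[i]] == g) else 0L, integer(1)))
  expect_equal(sum(mat$counts_1[, g]), tally)
  # raising the threshold never adds vocabulary
  mat2 <- build_ngram_matrix(docs, orders = 1, min_docfreq = 0.2)
  expect_true(all(mat2$vocab$ngram %in% mat$vocab$ngram))
  expect_error(build_ngram_matrix(docs[0, ]), "empty")
})

test_that("all-positive differences give r = 1 with zero spread", {
  st <- randomized_tie_wilcoxon_r(rep(0, 10), rep(1, 10), iterations = 50,
                                  seed = 3)
  expect_equal(st$mean_r, 1)
  expect_equal(st$spread, 0)
  expect_equal(st$direction, "+")
})

test_that("swapping phases negates mean r exactly under the same seed", {
  set.seed(9)
  x1 <- rpois(60, 1)
  x2 <- rpois(60, 1.5)
  a <- randomized_tie_wilcoxon_r(x1, x2, iterations = 100, seed = 21)
  b <- randomized_tie_wilcoxon_r(x2, x1, iterations = 100, seed = 21)
  expect_equal(a$mean_r, -b$mean_r)
  expect_equal(a$spread, b$spread)
})

test_that("tie-free case equals the exhaustive rank-biserial oracle, every iteration", {
  x1 <- c(0, 0, 0, 0, 0, 0, 0, 0)
  x2 <- c(5, -3, 2, -1, 7, 4, -6, 8) # distinct magnitudes, no zeros
  st <- randomized_tie_wilcoxon_r(x1, x2, iterations = 200, seed = 5)
  expect_equal(st$mean_r, rank_biserial_oracle(x1, x2))
  expect_equal(st$spread, 0) # no ties -> identical every iteration
})

test_that("degenerate all-zero differences are flagged, determinism holds", {
  st <- randomized_tie_wilcoxon_r(c(1, 2, 3), c(1, 2, 3), iterations = 10)
  expect_true(st$degenerate)
  expect_true(is.na(st$mean_r))
  set.seed(1); x1 <- rpois(30, 1); x2 <- rpois(30, 1)
  a <- randomized_tie_wilcoxon_r(x1, x2, iterations = 50, seed = 8)
  b <- randomized_tie_wilcoxon_r(x1, x2, iterations = 50, seed = 8)
  expect_identical(a, b)
})

test_that("per-iteration r stays within [-1, 1] under heavy ties", {
  set.seed(14)
  for (i in 1:20) {
    x1 <- rpois(40, 0.5)
    x2 <- rpois(40, 0.5)
    st <- randomized_tie_wilcoxon_r(x1, x2, iterations = 40, seed = i)
    if (!st$degenerate) {
      expect_gte(st$mean_r, -1)
      expect_lte(st$mean_r, 1)
      # |mean| + spread cannot exceed the bound by construction
      expect_lte(abs(st$mean_r), 1)
    }
  }
})

test_that("random tie ranks are unbiased: expected rank equals the midrank", {
  # three tied magnitudes occupying ranks 1..3 plus a distinct magnitude
  x1 <- c(0, 0, 0, 0)
  x2 <- c(1, 1, 1, 5)
  iters <- 10000
  set.seed(2)
  ranks1 <- replicate(iters, rank(abs(x2 - x1), ties.method = "random")[1])
  se <- sd(ranks1) / sqrt(iters)
  expect_lt(abs(mean(ranks1) - 2), 3 * se)
})

test_that("exchangeable null: mean r centred on zero across replicates", {
  set.seed(300)
  reps <- 200
  means <- vapply(seq_len(reps), function(i) {
    x1 <- rpois(200, 1)
    x2 <- sample(x1) # same marginal, paired at random
    st <- randomized_tie_wilcoxon_r(x1, x2, iterations = 100, seed = i)
    st$mean_r
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(reps))
})

test_that("shift tables rank planted phase-specific terms at the extremes", {
  n <- 30
  t1 <- rep(paste("still worried and staying at home with the family",
                  "watching the news"), n)
  t2 <- rep(paste("the vaccine brings hope and we look forward to",
                  "normal life again"), n)
  docs <- mini_docs(t1, t2)
  mat <- build_ngram_matrix(docs, orders = 1, min_docfreq = 0.05)
  st <- shift_table(mat, iterations = 50, seed = 4)
  expect_equal(st$increased$ngram[1], sort(st$increased$ngram[st$increased$mean_r == 1])[1])
  expect_true("vaccin" %in% st$increased$ngram[st$increased$mean_r == 1])
  expect_true(all(c("worri", "news") %in%
                    st$decreased$ngram[st$decreased$mean_r == -1]))
  # ranked by |mean_r| within each list
  expect_true(all(diff(abs(st$increased$mean_r)) <= 1e-12))
  expect_true(all(diff(abs(st$decreased$mean_r)) <= 1e-12))
})

test_that("symmetric null corpora produce no strong shifts in most seeds", {
  ok <- 0L
  for (s in 1:10) {
    set.seed(s)
    pool <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
    mk <- function(n) vapply(seq_len(n), function(i)
      paste(sample(pool, 12, replace = TRUE), collapse = " "), character(1))
    docs <- mini_docs(mk(300), mk(300))
    mat <- build_ngram_matrix(docs, orders = 1, min_docfreq = 0.05)
    st <- shift_table(mat, iterations = 50, seed = s)
    top <- max(abs(c(st$increased$mean_r, st$decreased$mean_r, 0)))
    if (top <= 0.3) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("the Z-based effect variant and relative frequencies are available", {
  # all-positive differences: Z/sqrt(n) caps below 1 (about 0.87 for large n)
  st <- randomized_tie_wilcoxon_r(rep(0, 30), rep(1, 30), iterations = 20,
                                  seed = 2, method = "z_over_sqrt_n")
  expect_lt(st$mean_r, 0.9)
  expect_gt(st$mean_r, 0.8)
  # cross-check against stats::wilcox.test's normal approximation
  set.seed(17)
  x2 <- rnorm(40) # continuous: no ties, no zeros
  stz <- randomized_tie_wilcoxon_r(rep(0, 40), x2, iterations = 5,
                                   seed = 1, method = "z_over_sqrt_n")
  w <- sum(rank(abs(x2))[x2 > 0])
  z <- (w - 40 * 41 / 4) / sqrt(40 * 41 * 81 / 24)
  expect_equal(stz$mean_r, z / sqrt(40))
  expect_equal(stz$spread, 0)

  # relative counts: same ranking signs, counts scaled by document length
  docs <- mini_docs(rep("worried still worried now", 20),
                    rep("the vaccine brings hope now", 20))
  m_rel <- build_ngram_matrix(docs, orders = 1, relative = TRUE)
  expect_true(all(m_rel$counts_1 <= 1))
  st_rel <- shift_table(m_rel, iterations = 20, seed = 3)
  expect_true("vaccin" %in% st_rel$increased$ngram[st_rel$increased$mean_r == 1])
})
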