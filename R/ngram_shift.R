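# Within-subject n-gram differentiation between phases.
#
# Texts of both phases form one joint corpus: lower-cased, tokenized,
# stopword-filtered and stemmed; n-grams (default unigrams, bigrams,
# trigrams) are formed over the surviving token sequence (post-removal
# adjacency, so "we are staying at home" yields "stay_home"), without
# sentence-boundary blocking. Only n-grams present in at least
# `min_docfreq` of all documents (both phases jointly) are retained.
#
# Per retained n-gram, the paired per-participant counts are compared with
# a Wilcoxon signed-rank statistic: zero differences are dropped, the
# absolute differences are ranked with ties resolved by *random* ranks
# within each tied block, and the matched-pairs rank-biserial correlation
# r = (W+ - W-)/(W+ + W-) is computed; the procedure is repeated over
# seeded iterations and the mean and spread (SD across iterations,
# reported as the "SE" column of shift tables) are returned. r ranges over
# [-1, 1] with r > 0 meaning higher counts in phase 2.

#' Preprocess texts for n-gram analysis
#'
#' Lower-cases, tokenizes ([tokenize_basic()]), removes stopwords and
#' Porter-stems each participant-phase text, preserving token order.
#'
#' @param data Data frame with columns `participant_id`, `phase`, and the
#'   text column.
#' @param text Column (tidy-eval) holding the text (default `text_long`).
#' @param stopwords Stopword list (default [stopwords_en()]).
#' @return A tibble `participant_id`, `phase`, `tokens` (list-column of
#'   character vectors, possibly empty).
#' @export
#' @examples
#' df <- tibble::tibble(participant_id = "a", phase = 1,
#'                      text_long = "We are staying at home!")
#' preprocess_for_ngrams(df)$tokens[[1]] # "stay" "home"
preprocess_for_ngrams <- function(data, text = text_long,
                                  stopwords = stopwords_en()) {
  txt <- dplyr::pull(data, {{ text }})
  toks <- tokenize_basic(txt)
  toks <- lapply(toks, function(tk) porter_stem(tk[!(tk %in% stopwords)]))
  tibble::tibble(participant_id = as.character(data$participant_id),
                 phase = as.integer(data$phase),
                 tokens = toks)
}

make_ngrams <- function(tokens, orders) {
  n <- length(tokens)
  out <- list()
  for (ord in orders) {
    if (n >= ord) {
      if (ord == 1) {
        out[[length(out) + 1]] <- tokens
      } else {
        m <- vapply(seq_len(n - ord + 1), function(i)
          paste(tokens[i:(i + ord - 1)], collapse = "_"), character(1))
        out[[length(out) + 1]] <- m
      }
    }
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

#' Build a participant x n-gram count matrix for both phases
#'
#' @param docs Preprocessed corpus from [preprocess_for_ngrams()], both
#'   phases, nonempty.
#' @param orders n-gram orders to include (default `1:3`).
#' @param min_docfreq Minimum document frequency, as a fraction of all
#'   documents in the joint corpus, for an n-gram to be retained (default
#'   0.05).
#' @param relative Divide each document's counts by its surviving token
#'   total (default FALSE: raw counts; documents of similar length make
#'   the distinction immaterial).
#' @return An `ngram_matrix`: `vocab` (tibble of `ngram`, `docfreq`),
#'   `counts_1` and `counts_2` (matrices over participants present in
#'   both phases, aligned rows), `n_docs`, `min_docfreq`, `orders`.
#' @export
build_ngram_matrix <- function(docs, orders = 1:3, min_docfreq = 0.05,
                               relative = FALSE) {
  if (nrow(docs) == 0) abort("`docs` is empty.")
  check_number(min_docfreq, "min_docfreq", lower = 0, upper = 1)
  if (min_docfreq <= 0) abort("`min_docfreq` must be in (0, 1].")
  grams <- lapply(docs$tokens, make_ngrams, orders = orders)
  n_docs <- length(grams)
  df_tab <- table(unlist(lapply(grams, unique), use.names = FALSE))
  docfreq <- as.numeric(df_tab) / n_docs
  keep <- docfreq >= min_docfreq
  vocab <- sort(names(df_tab)[keep])
  if (length(vocab) == 0)
    abort("No n-gram meets the document-frequency threshold.")
  docfreq <- docfreq[keep][match(vocab, names(df_tab)[keep])]

  ids1 <- docs$participant_id[docs$phase == 1L]
  ids2 <- docs$participant_id[docs$phase == 2L]
  ids <- intersect(ids1, ids2)
  count_phase <- function(phase) {
    m <- matrix(0, length(ids), length(vocab),
                dimnames = list(ids, vocab))
    rows <- which(docs$phase == phase & docs$participant_id %in% ids)
    for (i in rows) {
      tab <- table(grams[[i]][grams[[i]] %in% vocab])
      if (length(tab)) {
        cnt <- as.numeric(tab)
        if (relative) cnt <- cnt / max(length(docs$tokens[[i]]), 1L)
        m[docs$participant_id[i], names(tab)] <- cnt
      }
    }
    if (!relative) storage.mode(m) <- "integer"
    m
  }
  structure(
    list(vocab = tibble::tibble(ngram = vocab, docfreq = docfreq),
         counts_1 = count_phase(1L), counts_2 = count_phase(2L),
         n_docs = n_docs, min_docfreq = min_docfreq, orders = orders),
    class = "ngram_matrix")
}

#' @export
print.ngram_matrix <- function(x, ...) {
  cat(sprintf("n-gram matrix: %d retained n-grams (orders %s, docfreq >= %g) over %d paired participants\n",
              nrow(x$vocab), paste(x$orders, collapse = ","), x$min_docfreq,
              nrow(x$counts_1)))
  invisible(x)
}

#' Randomized-tie Wilcoxon rank-biserial shift statistic
#'
#' For paired count vectors, computes per iteration the matched-pairs
#' rank-biserial correlation `(W+ - W-)/(W+ + W-)` on the nonzero
#' differences `x2 - x1`, with tied absolute differences ranked by a
#' random permutation within each tied block; returns the mean and SD of r
#' across iterations. Deterministic under the master seed; swapping the
#' inputs negates the mean exactly.
#'
#' @param x1,x2 Paired nonnegative count vectors (phase 1, phase 2).
#' @param iterations Number of random-rank iterations (default 500).
#' @param seed Master seed.
#' @param method Effect-size form: `"rank_biserial"` (default; range
#'   exactly `[-1, 1]`) or `"z_over_sqrt_n"`, the normal-approximation
#'   `Z/sqrt(n)` variant (bounded near 0.87).
#' @return A one-row tibble: `mean_r`, `spread` (SD over iterations),
#'   `direction` (`"+"`/`"-"`), `n_nonzero`, `iterations`, `degenerate`
#'   (TRUE when all differences are zero, in which case `mean_r` is `NA`).
#' @export
randomized_tie_wilcoxon_r <- function(x1, x2, iterations = 500, seed = 1,
                                      method = c("rank_biserial",
                                                 "z_over_sqrt_n")) {
  method <- rlang::arg_match(method)
  if (length(x1) != length(x2)) abort("`x1` and `x2` must be paired.")
  if (iterations < 1) abort("`iterations` must be at least 1.")
  d <- as.numeric(x2) - as.numeric(x1)
  d <- d[d != 0]
  if (length(d) == 0) {
    return(tibble::tibble(mean_r = NA_real_, spread = NA_real_,
                          direction = NA_character_, n_nonzero = 0L,
                          iterations = as.integer(iterations),
                          degenerate = TRUE))
  }
  ad <- abs(d)
  pos <- d > 0
  n <- length(d)
  set.seed(as.integer(seed %% 2147483647))
  rs <- vapply(seq_len(iterations), function(i) {
    rk <- rank(ad, ties.method = "random")
    wp <- sum(rk[pos])
    wm <- sum(rk[!pos])
    if (method == "rank_biserial") {
      (wp - wm) / (wp + wm)
    } else {
      z <- (wp - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
      z / sqrt(n)
    }
  }, numeric(1))
  m <- mean(rs)
  tibble::tibble(mean_r = m,
                 spread = if (iterations > 1) sd(rs) else 0,
                 direction = ifelse(m >= 0, "+", "-"),
                 n_nonzero = length(d),
                 iterations = as.integer(iterations),
                 degenerate = FALSE)
}

#' Ranked n-gram shift table
#'
#' Applies [randomized_tie_wilcoxon_r()] to every retained n-gram and
#' returns the entries ranked by absolute mean r, split into increased
#' (`mean_r > 0`, higher in phase 2) and decreased lists. Ties in |r|
#' break by vocabulary order; degenerate n-grams (all paired differences
#' zero) are excluded. Per-n-gram seeds are split deterministically from
#' the master seed, so results do not depend on evaluation order.
#'
#' @param matrix An [build_ngram_matrix()] result.
#' @param iterations Iterations per n-gram (default 500).
#' @param seed Master seed.
#' @param top_k Entries to keep per list (default 20).
#' @param method Effect-size form, passed to
#'   [randomized_tie_wilcoxon_r()].
#' @return A `shift_table`: tibbles `increased` and `decreased` with
#'   columns `ngram`, `mean_r`, `spread`, `direction`, `docfreq`.
#' @export
shift_table <- function(matrix, iterations = 500, seed = 1, top_k = 20,
                        method = c("rank_biserial", "z_over_sqrt_n")) {
  method <- rlang::arg_match(method)
  if (!inherits(matrix, "ngram_matrix")) abort("`matrix` must be an ngram_matrix.")
  vocab <- matrix$vocab$ngram
  seeds <- derive_seeds(seed, length(vocab))
  rows <- lapply(seq_along(vocab), function(j) {
    st <- randomized_tie_wilcoxon_r(matrix$counts_1[, j], matrix$counts_2[, j],
                                    iterations = iterations, seed = seeds[j],
                                    method = method)
    dplyr::bind_cols(tibble::tibble(ngram = vocab[j],
                                    docfreq = matrix$vocab$docfreq[j]), st)
  })
  tab <- dplyr::bind_rows(rows)
  tab <- tab[!tab$degenerate, , drop = FALSE]
  tab <- tab[order(-abs(tab$mean_r), tab$ngram), , drop = FALSE]
  cols <- c("ngram", "mean_r", "spread", "direction", "docfreq")
  structure(
    list(increased = utils::head(tab[tab$mean_r > 0, cols], top_k),
         decreased = utils::head(tab[tab$mean_r < 0, cols], top_k),
         all = tab[, c(cols, "n_nonzero")],
         iterations = as.integer(iterations), seed = seed),
    class = "shift_table")
}

#' @export
print.shift_table <- function(x, n = 10, ...) {
  cat(sprintf("n-gram shift table (%d iterations)\n", x$iterations))
  cat("Top increased (phase 2 > phase 1):\n")
  print(utils::head(x$increased, n))
  cat("Top decreased (phase 2 < phase 1):\n")
  print(utils::head(x$decreased, n))
  invisible(x)
}
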