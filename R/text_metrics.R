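# Corpus descriptives, dictionary-based category scoring and term-variant
# counting.
#
# Word tokens are maximal lower-cased alphanumeric runs, with apostrophes
# kept when internal to a token ("don't"). Sentences are maximal segments
# terminated by '.', '!' or '?'; a trailing segment without terminator
# counts as one sentence.

#' Tokenize text into lower-cased word tokens
#'
#' @param text Character vector.
#' @return A list of character vectors, one per input element (empty vector
#'   for empty text).
#' @export
#' @examples
#' tokenize_basic("Don't panic!")[[1]]
tokenize_basic <- function(text) {
  if (!is.character(text)) abort("`text` must be a character vector.")
  text <- tolower(text)
  text <- gsub("’", "'", text)
  stringr::str_extract_all(text, "[a-z0-9]+(?:'[a-z0-9]+)*")
}

#' Count sentences in text
#'
#' @param text Character vector.
#' @return Integer vector: number of terminator-delimited segments, with a
#'   minimum of one for any text containing a non-space character.
#' @export
count_sentences <- function(text) {
  if (!is.character(text)) abort("`text` must be a character vector.")
  vapply(text, function(x) {
    if (is.na(x) || !grepl("[^[:space:]]", x)) return(0L)
    pieces <- strsplit(x, "[.!?]+")[[1]]
    max(1L, sum(grepl("[^[:space:]]", pieces)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Corpus descriptive statistics
#'
#' Per-document token counts, sentence counts and type-token ratio (TTR =
#' distinct tokens / total tokens), aggregated as across-document means and
#' sample SDs, optionally within groups (typically the collection phase).
#' Documents with zero tokens are excluded from the TTR aggregate with a
#' warning.
#'
#' @param data Data frame of documents.
#' @param text Column (tidy-eval) holding the text.
#' @param by Optional grouping column (tidy-eval), e.g. `phase`.
#' @return A tibble with one row per group: `n_docs`, `tokens_mean`,
#'   `tokens_sd`, `sentences_mean`, `sentences_sd`, `ttr_mean`, `ttr_sd`.
#' @export
corpus_descriptives <- function(data, text, by = NULL) {
  txt <- dplyr::pull(data, {{ text }})
  if (length(txt) == 0) abort("`data` must contain at least one document.")
  toks <- tokenize_basic(txt)
  n_tokens <- lengths(toks)
  n_types <- vapply(toks, function(x) length(unique(x)), integer(1))
  stats_df <- tibble::tibble(
    .tokens = n_tokens,
    .sentences = count_sentences(txt),
    .ttr = ifelse(n_tokens > 0, n_types / n_tokens, NA_real_)
  )
  if (any(n_tokens == 0))
    warn(sprintf("%d document(s) with zero tokens excluded from TTR.",
                 sum(n_tokens == 0)))
  grouped <- dplyr::bind_cols(dplyr::select(data, {{ by }}), stats_df)
  dplyr::summarise(
    dplyr::group_by(grouped, dplyr::across(!dplyr::starts_with("."))),
    n_docs = dplyr::n(),
    tokens_mean = mean(.data$.tokens), tokens_sd = sd(.data$.tokens),
    sentences_mean = mean(.data$.sentences), sentences_sd = sd(.data$.sentences),
    ttr_mean = mean(.data$.ttr, na.rm = TRUE),
    ttr_sd = sd(.data$.ttr, na.rm = TRUE),
    .groups = "drop"
  )
}

# ---- category dictionaries -------------------------------------------------

#' Build or read a category dictionary
#'
#' A category dictionary maps category names to lists of patterns; a
#' pattern is either a literal lower-case token or a prefix wildcard with a
#' trailing `*` (so `fear*` matches `fear`, `fearful`, ...). Categories may
#' overlap. Two file formats are supported: the de-facto `.dic` layout
#' (`%`-delimited header mapping numeric category ids to names, then one
#' pattern per line with tab-separated category ids) and a JSON object
#' mapping category names to pattern arrays.
#'
#' @param x For `category_dictionary()`: a named list of character pattern
#'   vectors. For `read_dictionary()`: a file path ending in `.dic` or
#'   `.json`.
#' @return A `category_dictionary` object.
#' @export
category_dictionary <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    abort("`x` must be a named list of pattern vectors.")
  x <- lapply(x, function(p) {
    p <- tolower(as.character(p))
    if (length(p) == 0 || any(!nzchar(sub("\\*$", "", p))))
      abort("Every category needs nonempty lower-case patterns.")
    p
  })
  structure(x, class = "category_dictionary")
}

#' @rdname category_dictionary
#' @export
read_dictionary <- function(x) {
  if (grepl("\\.json$", x, ignore.case = TRUE)) {
    return(category_dictionary(jsonlite::read_json(x, simplifyVector = TRUE)))
  }
  lines <- readr::read_lines(x, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2) abort("Malformed .dic file: missing %% header block.")
  header <- lines[(pct[1] + 1):(pct[2] - 1)]
  body <- lines[-seq_len(pct[2])]
  hp <- strsplit(trimws(header), "[\t ]+")
  ids <- vapply(hp, `[`, character(1), 1)
  cat_names <- vapply(hp, `[`, character(1), 2)
  pats <- setNames(vector("list", length(cat_names)), cat_names)
  for (ln in body) {
    fields <- strsplit(trimws(ln), "\t")[[1]]
    fields <- fields[nzchar(fields)]
    token <- tolower(fields[1])
    for (id in fields[-1]) {
      nm <- cat_names[match(id, ids)]
      if (is.na(nm)) abort(sprintf("Pattern '%s' references unknown category id '%s'.",
                                   token, id))
      pats[[nm]] <- c(pats[[nm]], token)
    }
  }
  category_dictionary(pats[lengths(pats) > 0])
}

#' @export
print.category_dictionary <- function(x, ...) {
  cat(sprintf("Category dictionary: %d categories, %d patterns\n",
              length(x), sum(lengths(x))))
  for (nm in names(x))
    cat(sprintf("  %-14s %d patterns (%s%s)\n", nm, length(x[[nm]]),
                paste(head(x[[nm]], 4), collapse = ", "),
                if (length(x[[nm]]) > 4) ", ..." else ""))
  invisible(x)
}

#' The packaged demonstration dictionary
#'
#' A small open dictionary (8 categories, ~120 patterns) shipped for tests,
#' examples and the synthetic corpus generator. It is a demonstration
#' artefact in the `.dic` format, not a reproduction of any proprietary
#' word list.
#'
#' @return A `category_dictionary`.
#' @export
demo_dictionary <- function() {
  read_dictionary(system.file("extdata", "demo_categories.dic",
                              package = "emoshift", mustWork = TRUE))
}

match_patterns <- function(tokens, patterns) {
  if (length(tokens) == 0) return(logical(0))
  is_prefix <- grepl("\\*$", patterns)
  literals <- patterns[!is_prefix]
  prefixes <- sub("\\*$", "", patterns[is_prefix])
  hit <- tokens %in% literals
  for (p in prefixes) hit <- hit | startsWith(tokens, p)
  hit
}

#' Score documents against a category dictionary
#'
#' The score of a category in a document is the percentage of word tokens
#' matching any of the category's patterns (0-100), the usual output
#' convention of dictionary-based text scorers. Documents without tokens
#' score 0 in every category and are flagged in the `empty_doc` column.
#'
#' @param data Data frame of documents.
#' @param text Column (tidy-eval) holding the text.
#' @param dictionary A [category_dictionary()].
#' @return `data`'s non-text columns plus one numeric column per category
#'   and a logical `empty_doc` column.
#' @export
score_dictionary <- function(data, text, dictionary) {
  if (!inherits(dictionary, "category_dictionary"))
    abort("`dictionary` must be a category_dictionary.")
  txt <- dplyr::pull(data, {{ text }})
  toks <- tokenize_basic(txt)
  n_tok <- lengths(toks)
  scores <- lapply(names(dictionary), function(nm) {
    hits <- vapply(toks, function(tk) sum(match_patterns(tk, dictionary[[nm]])),
                   numeric(1))
    ifelse(n_tok > 0, 100 * hits / n_tok, 0)
  })
  names(scores) <- names(dictionary)
  dplyr::bind_cols(
    dplyr::select(data, -{{ text }}),
    tibble::as_tibble(scores),
    tibble::tibble(empty_doc = n_tok == 0)
  )
}

#' Rank dictionary-category shifts between phases
#'
#' For each category, takes the paired per-participant score differences
#' (phase 2 minus phase 1), computes the paired effect size and the JZS
#' Bayes factor, and returns the table sorted by descending Bayes factor.
#' All categories are tested exploratorily; no multiplicity correction is
#' applied. Categories whose score differences have zero variance are
#' excluded with a warning.
#'
#' @param phase1_scores,phase2_scores Data frames from [score_dictionary()]
#'   for the two phases, with a shared `participant_id` column and
#'   identical category columns.
#' @param categories Character vector of category columns; default all
#'   columns shared by both frames apart from id/flag columns.
#' @param level Confidence level for the d interval (default 0.99).
#' @param prior_scale Cauchy prior scale for the Bayes factor (default
#'   `sqrt(2)/2`).
#' @return A tibble with one row per category: `category`, `mean_diff`,
#'   `sd_diff`, `d`, `ci_low`, `ci_high`, `t`, `p`, `log10_bf10`, `bf10`,
#'   `direction` (`"+"` if higher in phase 2).
#' @export
rank_category_shifts <- function(phase1_scores, phase2_scores,
                                 categories = NULL,
                                 level = 0.99, prior_scale = sqrt(2) / 2) {
  by_id <- dplyr::inner_join(phase1_scores, phase2_scores,
                             by = "participant_id", suffix = c("_1", "_2"))
  if (is.null(categories)) {
    categories <- setdiff(intersect(names(phase1_scores), names(phase2_scores)),
                          c("participant_id", "phase", "empty_doc"))
  }
  rows <- list()
  dropped <- character()
  for (cat_nm in categories) {
    diffs <- by_id[[paste0(cat_nm, "_2")]] - by_id[[paste0(cat_nm, "_1")]]
    if (sd(diffs) == 0) {
      dropped <- c(dropped, cat_nm)
      next
    }
    eff <- paired_effect(diffs, level = level)
    bf <- jzs_bf_one_sample(eff$t, eff$n, prior_scale = prior_scale)
    rows[[cat_nm]] <- tibble::tibble(
      category = cat_nm,
      mean_diff = eff$mean_diff, sd_diff = eff$sd_diff,
      d = eff$d, ci_low = eff$ci_low, ci_high = eff$ci_high,
      t = eff$t, p = eff$p,
      log10_bf10 = bf$log10_bf10, bf10 = bf$bf10,
      direction = ifelse(eff$mean_diff >= 0, "+", "-")
    )
  }
  if (length(dropped) > 0)
    warn(sprintf("Excluded categories with zero-variance differences: %s.",
                 paste(dropped, collapse = ", ")))
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$log10_bf10))
}

#' Count stem-variant occurrences of a term
#'
#' Counts the tokens of a text whose stemmed form begins with
#' `stem_prefix`. The default prefix `"vaccin"` captures `vaccine`,
#' `vaccines`, `vaccinated`, `vaccination`, ... while rejecting
#' near-misses such as `vacation` (stem `vacat`).
#'
#' @param text Character vector of raw texts.
#' @param stem_prefix Lower-case stem prefix (nonempty).
#' @param stem Match on Porter-stemmed tokens (default) or on surface
#'   forms.
#' @return Integer vector of counts.
#' @export
count_term_variants <- function(text, stem_prefix = "vaccin", stem = TRUE) {
  if (!is.character(stem_prefix) || length(stem_prefix) != 1 ||
      !nzchar(stem_prefix) || stem_prefix != tolower(stem_prefix))
    abort("`stem_prefix` must be a single nonempty lower-case string.")
  toks <- tokenize_basic(text)
  vapply(toks, function(tk) {
    if (length(tk) == 0) return(0L)
    forms <- if (stem) porter_stem(tk) else tk
    sum(startsWith(forms, stem_prefix))
  }, integer(1))
}
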