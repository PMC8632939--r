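# Reading, cleaning and pairing two-wave survey records.
#
# A wave is a tibble with one row per participant containing:
#   participant_id, phase (1 or 2), the nine emotion scores (1-9),
#   chosen_emotion, text_long, text_short, age, gender, plus pass-through
#   columns. The paired cohort is the inner join of the two waves with
#   per-emotion change scores delta_<emotion> = phase2 - phase1.

.ascii_punct_class <- "[!-/:-@\\[-`{-~]"

#' Fraction of punctuation characters in a text
#'
#' Punctuation is the fixed 32-character ASCII set
#' `` !"#$%&'()*+,-./:;<=>?@[\]^_`{|}~ ``; the denominator is the number of
#' non-whitespace characters, so that whitespace-padded texts are not
#' diluted. Records whose long text exceeds a punctuation share of 0.20 are
#' excluded by the default cleaning rules.
#'
#' @param text Character vector. Every element must contain at least one
#'   non-whitespace character.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' punctuation_ratio("Hello, world!") # 2/12
punctuation_ratio <- function(text) {
  if (!is.character(text)) abort("`text` must be a character vector.")
  non_ws <- nchar(gsub("[[:space:]]", "", text))
  if (any(is.na(text)) || any(non_ws == 0))
    abort("`text` contains empty or whitespace-only elements.")
  punct <- stringr::str_count(text, .ascii_punct_class)
  punct / non_ws
}

#' Heuristic English-language check
#'
#' A text is taken to be English when at least `threshold` of its word
#' tokens appear in the packaged English stopword list. Texts shorter than
#' `min_tokens` tokens carry too little evidence and are passed through as
#' English. The check is a pluggable predicate: [apply_exclusions()] accepts
#' any function with this signature, and fixture data can carry an explicit
#' override column.
#'
#' @param text Character vector.
#' @param min_tokens Minimum token count for the heuristic to apply.
#' @param threshold Minimum stopword fraction for an English verdict.
#' @param stopwords Reference word list, default [stopwords_en()].
#' @return Logical vector.
#' @export
is_english <- function(text, min_tokens = 20, threshold = 0.05,
                       stopwords = stopwords_en()) {
  toks <- tokenize_basic(text)
  vapply(toks, function(tk) {
    if (length(tk) < min_tokens) return(TRUE)
    mean(tk %in% stopwords) >= threshold
  }, logical(1))
}

.exclusion_rule_names <- c("non_english", "punctuation", "invalid_id", "duplicate")

#' Apply sequential exclusion rules to one wave of survey records
#'
#' Records are screened rule by rule in a fixed order (non-English text,
#' punctuation share above `max_punct`, invalid participant id, duplicated
#' participant id within the phase); each excluded record is tagged with the
#' first rule it violates, so the rule counts partition the exclusions and
#' `initial = retained + sum(counts)` always holds.
#'
#' @param records Tibble of one-wave survey records (see [read_cohort()]).
#' @param rules Character vector naming the rules to apply, in order.
#' @param text Which text column the language and punctuation rules read:
#'   `"long"` (default) or `"short"`.
#' @param max_punct Maximum allowed punctuation fraction (default 0.20).
#' @param id_pattern Regular expression a valid participant id must match;
#'   the default is the 24-hexadecimal-character crowdsourcing-platform id.
#' @param english Predicate `function(text) -> logical` used by the
#'   `non_english` rule; default [is_english()].
#' @param override_col Optional logical column name; where present and
#'   non-NA it replaces the English predicate's verdict (fixture support).
#' @return A list with elements `retained` (tibble of surviving records)
#'   and `report` (an `exclusion_report`; see [tidy.exclusion_report()]).
#' @export
apply_exclusions <- function(records,
                             rules = .exclusion_rule_names,
                             text = c("long", "short"),
                             max_punct = 0.2,
                             id_pattern = "^[0-9a-f]{24}$",
                             english = is_english,
                             override_col = "english_override") {
  text <- rlang::arg_match(text)
  unknown <- setdiff(rules, .exclusion_rule_names)
  if (length(unknown) > 0)
    abort(sprintf("Unknown exclusion rule(s): %s.", paste(unknown, collapse = ", ")))
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  if (n == 0) {
    report <- new_exclusion_report(0L, setNames(integer(length(rules)), rules),
                                   0L, tibble::tibble(participant_id = character(),
                                                      rule = character()))
    return(list(retained = records, report = report))
  }
  text_col <- paste0("text_", text)
  txt <- as.character(records[[text_col]])
  txt[is.na(txt)] <- ""
  ids <- as.character(records$participant_id)
  phase <- if ("phase" %in% names(records)) records$phase else rep(1L, n)

  violated <- rep(NA_character_, n)
  for (rule in rules) {
    fails <- switch(
      rule,
      non_english = {
        blank <- !grepl("[^[:space:]]", txt)
        verdict <- rep(FALSE, n)
        verdict[!blank] <- english(txt[!blank])
        if (override_col %in% names(records)) {
          ov <- records[[override_col]]
          verdict[!is.na(ov)] <- ov[!is.na(ov)]
        }
        !verdict
      },
      punctuation = {
        blank <- !grepl("[^[:space:]]", txt)
        ratio <- rep(0, n)
        ratio[!blank] <- punctuation_ratio(txt[!blank])
        ratio > max_punct
      },
      invalid_id = is.na(ids) | !grepl(id_pattern, ids),
      duplicate = duplicated(paste(phase, ids, sep = "\r"))
    )
    violated[is.na(violated) & fails] <- rule
  }
  keep <- is.na(violated)
  counts <- vapply(rules, function(r) sum(violated == r, na.rm = TRUE), integer(1))
  assignments <- tibble::tibble(
    participant_id = ids[!keep],
    rule = violated[!keep]
  )
  report <- new_exclusion_report(n, counts, sum(keep), assignments)
  list(retained = records[keep, , drop = FALSE], report = report)
}

new_exclusion_report <- function(initial, counts, retained, assignments) {
  structure(
    list(initial_count = as.integer(initial),
         rule_counts = counts,
         retained_count = as.integer(retained),
         assignments = assignments),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat("  initial records: ", x$initial_count, "\n", sep = "")
  for (r in names(x$rule_counts))
    cat(sprintf("  excluded (%s): %d\n", r, x$rule_counts[[r]]))
  cat("  retained: ", x$retained_count, "\n", sep = "")
  invisible(x)
}

#' Merge two waves into a paired cohort
#'
#' Keeps exactly the participants present (with complete emotion scores) in
#' both waves and computes, for each emotion, the change score
#' `delta_<emotion> = phase-2 score - phase-1 score`. Records with missing
#' emotion scores are dropped with a warning, never silently; the number of
#' phase-2 ids without a phase-1 record is reported as a message.
#'
#' Demographics (`age`, `gender`) and the texts of each wave are carried
#' with `_1`/`_2` suffixes; `age` and `gender` without suffix refer to the
#' phase-2 record.
#'
#' @param phase1,phase2 One-wave record tibbles, deduplicated by id.
#' @return A `paired_cohort` tibble with one row per paired participant.
#' @export
merge_phases <- function(phase1, phase2) {
  phase1 <- tibble::as_tibble(phase1)
  phase2 <- tibble::as_tibble(phase2)
  emo <- emotion_names()
  for (df_name in c("phase1", "phase2")) {
    df <- get(df_name)
    missing_cols <- setdiff(c("participant_id", emo), names(df))
    if (length(missing_cols) > 0)
      abort(sprintf("`%s` lacks column(s): %s.", df_name,
                    paste(missing_cols, collapse = ", ")))
  }
  drop_incomplete <- function(df, label) {
    ok <- complete.cases(df[, emo])
    if (any(!ok))
      warn(sprintf("Dropped %d %s record(s) with missing emotion scores.",
                   sum(!ok), label))
    df[ok, , drop = FALSE]
  }
  phase1 <- drop_incomplete(phase1, "phase-1")
  phase2 <- drop_incomplete(phase2, "phase-2")
  dedupe <- function(df, label) {
    dup <- duplicated(df$participant_id)
    if (any(dup))
      warn(sprintf("Dropped %d duplicated %s id(s); first occurrence kept.",
                   sum(dup), label))
    df[!dup, , drop = FALSE]
  }
  phase1 <- dedupe(phase1, "phase-1")
  phase2 <- dedupe(phase2, "phase-2")

  unmatched <- sum(!(phase2$participant_id %in% phase1$participant_id))
  inform(sprintf("%d phase-2 id(s) have no phase-1 record.", unmatched))

  drop_cols <- function(df) df[, setdiff(names(df), "phase"), drop = FALSE]
  paired <- dplyr::inner_join(drop_cols(phase1), drop_cols(phase2),
                              by = "participant_id", suffix = c("_1", "_2"))
  for (e in emo)
    paired[[paste0("delta_", e)]] <-
      paired[[paste0(e, "_2")]] - paired[[paste0(e, "_1")]]
  if ("age_2" %in% names(paired)) paired$age <- paired$age_2
  if ("gender_2" %in% names(paired)) paired$gender <- paired$gender_2
  class(paired) <- c("paired_cohort", class(paired))
  paired
}

#' Extract the emotion-change matrix from a paired cohort
#'
#' @param cohort A `paired_cohort` from [merge_phases()].
#' @return Numeric matrix with one row per participant and one column per
#'   emotion (change scores, phase 2 minus phase 1).
#' @export
change_scores <- function(cohort) {
  cols <- paste0("delta_", emotion_names())
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0)
    abort("`cohort` is not a paired cohort (missing delta_* columns).")
  m <- as.matrix(cohort[, cols])
  colnames(m) <- emotion_names()
  rownames(m) <- cohort$participant_id
  m
}

#' Read or write one-wave survey records
#'
#' Comma-separated UTF-8 text with a header row and quoted multi-line text
#' fields; columns as described in [apply_exclusions()] and
#' [merge_phases()].
#'
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("phase" %in% names(df)) df$phase <- as.integer(df$phase)
  df
}

#' @param records Tibble of survey records.
#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
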