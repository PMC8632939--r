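# End-to-end orchestration: clean -> pair -> paired battery -> clustering
# -> corpus descriptives -> category shifts -> n-gram shifts -> term-split
# comparison, under one configuration and one master seed.
#
# Defaults are pinned to the study settings: 99% intervals, Cauchy prior
# scale sqrt(2)/2, k sweep 1..20 with 25 restarts, 5% document-frequency
# threshold, 500 tie-randomisation iterations, alpha 0.01, term prefix
# "vaccin", long texts. Text-stage failures are isolated: an error in a
# text analysis is logged and leaves the emotion-stage outputs intact.

#' Configuration for the full analysis pipeline
#'
#' @param phase1,phase2 One-wave record tibbles, or paths readable by
#'   [read_cohort()]. Alternatively supply `synth` to simulate them.
#' @param synth A [synth_config()] used when `phase1`/`phase2` are absent.
#' @param apply_exclusions Run the exclusion rules on each wave before
#'   pairing (default TRUE).
#' @param level Confidence level (default 0.99).
#' @param prior_scale Bayes-factor Cauchy prior scale (default `sqrt(2)/2`).
#' @param k_max,restarts Clustering sweep bound (default 20) and restarts
#'   (default 25).
#' @param dictionary A [category_dictionary()]; default the packaged
#'   demonstration dictionary.
#' @param ngram_orders,min_docfreq,iterations n-gram settings (defaults
#'   `1:3`, 0.05, 500).
#' @param stem_prefix Term-split stem prefix (default `"vaccin"`).
#' @param alpha Significance level for cluster profiling (default 0.01).
#' @param texts Which texts the text analyses use: `"long"` (default) or
#'   `"short"`.
#' @param seed Master seed for all stochastic stages.
#' @param out_dir Optional directory; when set, every table is written as
#'   delimited text with a config-hash header.
#' @return A `run_config` list.
#' @export
run_config <- function(phase1 = NULL, phase2 = NULL, synth = NULL,
                       apply_exclusions = TRUE,
                       level = 0.99, prior_scale = sqrt(2) / 2,
                       k_max = 20, restarts = 25,
                       dictionary = NULL,
                       ngram_orders = 1:3, min_docfreq = 0.05,
                       iterations = 500,
                       stem_prefix = "vaccin", alpha = 0.01,
                       texts = c("long", "short"),
                       seed = 1, out_dir = NULL) {
  texts <- rlang::arg_match(texts)
  check_prob_level(level)
  check_number(min_docfreq, "min_docfreq", lower = 0, upper = 1)
  if (is.null(phase1) != is.null(phase2))
    abort("Supply both `phase1` and `phase2`, or neither plus `synth`.")
  if (is.null(phase1) && is.null(synth)) synth <- synth_config(seed = seed)
  structure(
    list(phase1 = phase1, phase2 = phase2, synth = synth,
         apply_exclusions = apply_exclusions,
         level = level, prior_scale = prior_scale,
         k_max = k_max, restarts = restarts,
         dictionary = dictionary,
         ngram_orders = ngram_orders, min_docfreq = min_docfreq,
         iterations = iterations,
         stem_prefix = stem_prefix, alpha = alpha, texts = texts,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

load_wave <- function(x) {
  if (is.character(x)) read_cohort(x) else tibble::as_tibble(x)
}

#' Run the full two-wave analysis
#'
#' Executes every stage in order with a shared seed discipline and stage
#' isolation for the text analyses, and returns all result tables in one
#' bundle. With `config$out_dir` set, each table is also written as a
#' tab-separated file whose first line records the configuration hash.
#'
#' @param config A [run_config()].
#' @return A `report_bundle`: `exclusions` (per phase), `cohort`
#'   (`paired_cohort`), `paired_summary`, `k_selection`, `kmeans`,
#'   `cluster_profile`, `demographics`, `descriptives`,
#'   `category_shifts`, `ngram_shifts`, `term_split`, `log` (tibble of
#'   stage records), `config_hash`, `seed`.
#' @export
run_full_analysis <- function(config = run_config()) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  log_rows <- list()
  note <- function(stage, message) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, message = message)
  }
  isolate <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, paste("ERROR:", conditionMessage(e)))
      NULL
    })
  }
  seeds <- derive_seeds(config$seed, 4)

  # --- load or simulate ---
  if (!is.null(config$phase1)) {
    w1 <- load_wave(config$phase1)
    w2 <- load_wave(config$phase2)
    note("input", sprintf("loaded waves: %d + %d records", nrow(w1), nrow(w2)))
  } else {
    synth <- config$synth
    cohort_synth <- generate_cohort(synth)
    resp <- cohort_synth$responses
    w1 <- resp[resp$phase == 1L, ]
    w2 <- resp[resp$phase == 2L, ]
    note("input", sprintf("simulated cohort: n = %d (seed %d)",
                          synth$n_participants, synth$seed))
  }

  # --- exclusions ---
  excl <- NULL
  if (isTRUE(config$apply_exclusions)) {
    e1 <- apply_exclusions(w1, text = config$texts)
    e2 <- apply_exclusions(w2, text = config$texts)
    w1 <- e1$retained
    w2 <- e2$retained
    excl <- list(phase1 = e1$report, phase2 = e2$report)
    note("exclusions", sprintf("retained %d / %d (phase 1), %d / %d (phase 2)",
                               e1$report$retained_count, e1$report$initial_count,
                               e2$report$retained_count, e2$report$initial_count))
  }

  # --- pair ---
  cohort <- suppressMessages(merge_phases(w1, w2))
  note("merge", sprintf("paired cohort: n = %d", nrow(cohort)))

  # --- paired battery ---
  summary_tab <- paired_summary(cohort, level = config$level,
                                prior_scale = config$prior_scale)
  note("paired_summary", "nine-emotion change battery computed")

  # --- clustering ---
  X <- change_scores(cohort)
  ksel <- select_k(X, k_max = config$k_max, restarts = config$restarts,
                   seed = seeds[1])
  km <- ksel$models[[ksel$selected_k]]
  profile <- profile_clusters(cohort, km$labels, alpha = config$alpha)
  demo <- if (ksel$selected_k == 2)
    compare_demographics(cohort, km$labels, level = config$level)
  else NULL
  note("clustering", sprintf("selected k = %d (silhouette %.3f)",
                             ksel$selected_k,
                             ksel$curve$silhouette[ksel$selected_k]))

  # --- text stages (isolated) ---
  text_col <- paste0("text_", config$texts)
  long_df <- dplyr::bind_rows(
    tibble::tibble(participant_id = cohort$participant_id, phase = 1L,
                   text = cohort[[paste0(text_col, "_1")]]),
    tibble::tibble(participant_id = cohort$participant_id, phase = 2L,
                   text = cohort[[paste0(text_col, "_2")]]))

  descr <- isolate("descriptives", {
    out <- corpus_descriptives(long_df, text, by = phase)
    note("descriptives", "corpus descriptives computed")
    out
  })

  cat_shifts <- isolate("category_shifts", {
    dict <- config$dictionary %||% demo_dictionary()
    sc <- score_dictionary(long_df, text, dict)
    out <- rank_category_shifts(sc[sc$phase == 1L, ], sc[sc$phase == 2L, ],
                                level = config$level,
                                prior_scale = config$prior_scale)
    note("category_shifts", sprintf("%d categories ranked", nrow(out)))
    out
  })

  ngrams <- isolate("ngram_shifts", {
    docs <- preprocess_for_ngrams(long_df, text)
    mat <- build_ngram_matrix(docs, orders = config$ngram_orders,
                              min_docfreq = config$min_docfreq)
    out <- shift_table(mat, iterations = config$iterations, seed = seeds[2])
    note("ngram_shifts", sprintf("%d retained n-grams ranked", nrow(mat$vocab)))
    out
  })

  split_tab <- isolate("term_split", {
    out <- term_split_analysis(cohort, stem_prefix = config$stem_prefix,
                               level = config$level,
                               prior_scale = config$prior_scale,
                               text = config$texts)
    note("term_split", sprintf("term-split comparison on prefix '%s'",
                               config$stem_prefix))
    out
  })

  bundle <- structure(
    list(exclusions = excl, cohort = cohort, paired_summary = summary_tab,
         k_selection = ksel, kmeans = km, cluster_profile = profile,
         demographics = demo, descriptives = descr,
         category_shifts = cat_shifts, ngram_shifts = ngrams,
         term_split = split_tab,
         log = dplyr::bind_rows(log_rows),
         config_hash = hash, seed = config$seed),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Two-wave analysis bundle (n = %d, config %s)\n",
              nrow(x$cohort), substr(x$config_hash, 1, 8)))
  print(x$log, n = Inf)
  invisible(x)
}

#' Write every bundle table as delimited text
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    path <- file.path(dir, paste0(name, ".tsv"))
    readr::write_lines(sprintf("# config_hash: %s seed: %d",
                               bundle$config_hash, bundle$seed), path)
    suppressMessages(readr::write_tsv(df, path, append = TRUE,
                                      col_names = TRUE, progress = FALSE))
    invisible(NULL)
  }
  if (!is.null(bundle$exclusions)) {
    emit(tidy(bundle$exclusions$phase1), "exclusions_phase1")
    emit(tidy(bundle$exclusions$phase2), "exclusions_phase2")
  }
  emit(tibble::as_tibble(bundle$paired_summary), "paired_summary")
  emit(bundle$k_selection$curve, "k_selection")
  emit(tibble::tibble(participant_id = bundle$cohort$participant_id,
                      cluster = bundle$kmeans$labels), "cluster_assignments")
  emit(bundle$cluster_profile$emotions, "cluster_profile_emotions")
  emit(bundle$cluster_profile$clusters, "cluster_profile_clusters")
  emit(bundle$descriptives, "corpus_descriptives")
  emit(bundle$category_shifts, "category_shifts")
  if (!is.null(bundle$ngram_shifts)) {
    emit(bundle$ngram_shifts$increased, "ngram_increased")
    emit(bundle$ngram_shifts$decreased, "ngram_decreased")
  }
  emit(bundle$term_split, "term_split")
  emit(bundle$log, "run_log")
  invisible(dir)
}

#' Compare emotion change between term mentioners and non-mentioners
#'
#' Splits the cohort by whether the phase-2 text contains at least one
#' token whose stem begins with `stem_prefix` (see
#' [count_term_variants()]), then compares the per-emotion change scores
#' between the two groups with the pooled two-group effect size and the
#' two-sample JZS Bayes factor.
#'
#' @param cohort A `paired_cohort` with phase-2 texts.
#' @param stem_prefix Stem prefix defining a mention (default `"vaccin"`).
#' @param level Confidence level (default 0.99).
#' @param prior_scale Bayes-factor prior scale (default `sqrt(2)/2`).
#' @param text Which text column to scan: `"long"` (default) or `"short"`.
#' @param stem Stemmed matching (default) or surface prefix matching.
#' @return A tibble with one row per emotion: group means/SDs of change,
#'   `d`, `ci_low`, `ci_high`, `t`, `p`, `log10_bf10`, `bf10`,
#'   `n_mention`, `n_no_mention`.
#' @export
term_split_analysis <- function(cohort, stem_prefix = "vaccin",
                                level = 0.99, prior_scale = sqrt(2) / 2,
                                text = c("long", "short"), stem = TRUE) {
  text <- rlang::arg_match(text)
  col <- paste0("text_", text, "_2")
  if (!col %in% names(cohort))
    abort(sprintf("`cohort` lacks phase-2 texts (column %s).", col))
  mention <- count_term_variants(cohort[[col]], stem_prefix, stem = stem) > 0
  if (sum(mention) < 3 || sum(!mention) < 3)
    abort("Both mention groups need at least 3 participants.")
  rows <- lapply(emotion_names(), function(e) {
    x1 <- cohort[[paste0("delta_", e)]][mention]
    x2 <- cohort[[paste0("delta_", e)]][!mention]
    eff <- two_sample_effect(mean(x1), sd(x1), length(x1),
                             mean(x2), sd(x2), length(x2), level = level)
    bf <- jzs_bf_two_sample(eff$t, length(x1), length(x2),
                            prior_scale = prior_scale)
    tibble::tibble(
      emotion = e,
      mean_mention = mean(x1), sd_mention = sd(x1),
      mean_no_mention = mean(x2), sd_no_mention = sd(x2),
      d = eff$d, ci_low = eff$ci_low, ci_high = eff$ci_high,
      t = eff$t, p = eff$p,
      log10_bf10 = bf$log10_bf10, bf10 = bf$bf10,
      n_mention = length(x1), n_no_mention = length(x2))
  })
  dplyr::bind_rows(rows)
}
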