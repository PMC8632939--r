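# Synthetic two-wave cohort generator.
#
# Emotion scores: each participant is assigned a latent change-cluster;
# phase-1 scores are round-then-clip draws from per-emotion normals;
# phase-2 scores are clip(round(phase1 + change)) with the change drawn
# from the participant's cluster. The additive construction induces a
# positive phase-1/phase-2 correlation of approximately
# SD1 / sqrt(SD1^2 + SDchange^2) before discretisation.
#
# Texts: bag-of-tokens draws from a phase-specific vocabulary (token rates
# per phase). A token with phase-1 rate 0 never appears in phase-1 texts;
# a token with per-token rate p in a document of length L is present with
# probability 1 - (1 - p)^L. Tokens are emitted sequentially, so bigram
# and trigram adjacency arises naturally; sentences are chunks of
# Poisson-distributed length terminated by ".".
#
# Randomness: one master seed, split into per-stage substream seeds
# (cluster assignment / phase-1 scores / changes / texts / demographics),
# so regenerating texts does not disturb scores.

default_cluster_spec <- function() {
  list(
    list(proportion = 0.4358,
         mean_change = c(anger = -1.74, anxiety = -3.06, desire = 1.21,
                         disgust = -1.36, fear = -3.52, happiness = 1.88,
                         relaxation = 2.16, sadness = -2.70, worry = -2.48),
         sd_change = c(anger = 2.08, anxiety = 2.13, desire = 2.44,
                       disgust = 2.14, fear = 1.94, happiness = 2.10,
                       relaxation = 2.24, sadness = 2.37, worry = 1.85)),
    list(proportion = 0.5642,
         mean_change = c(anger = 0.88, anxiety = -0.09, desire = 0.33,
                         disgust = 0.61, fear = -0.53, happiness = -0.19,
                         relaxation = -0.53, sadness = 0.55, worry = -0.97),
         sd_change = c(anger = 2.19, anxiety = 1.96, desire = 2.27,
                       disgust = 2.28, fear = 1.94, happiness = 1.90,
                       relaxation = 2.01, sadness = 2.07, worry = 1.66))
  )
}

default_phase1_means <- function() {
  c(anger = 3.81, anxiety = 6.46, desire = 2.86, disgust = 3.12, fear = 5.60,
    happiness = 3.60, relaxation = 3.89, sadness = 5.55, worry = 6.57)
}

default_phase1_sds <- function() {
  c(anger = 2.21, anxiety = 2.31, desire = 1.98, disgust = 2.12, fear = 2.28,
    happiness = 1.87, relaxation = 2.11, sadness = 2.33, worry = 1.75)
}

#' Default synthetic vocabulary specification
#'
#' A tibble of `(token, rate_1, rate_2)` per-token sampling rates: common
#' function words (so generated texts look English to the stopword
#' heuristic), neutral content fillers, pandemic-vocabulary terms whose
#' rates shift between phases — including a `vaccin`-stem family that is
#' absent in phase 1 — and emotion words aligned with the demonstration
#' dictionary so category shifts are plantable.
#'
#' @return A tibble with columns `token`, `rate_1`, `rate_2` (rates are
#'   normalised at sampling time).
#' @export
default_vocab_spec <- function() {
  fw <- c("the", "and", "i", "to", "of", "a", "is", "that", "it", "for",
          "my", "we", "be", "are", "have", "not", "this", "but", "at", "so",
          "was", "had")
  fill <- c("day", "week", "work", "life", "world", "country", "job",
            "school", "shop", "food", "house", "garden", "walk", "road",
            "town", "child", "parent", "neighbour", "weather", "summer",
            "winter", "morning", "evening", "money", "plan", "music",
            "book", "game", "dog", "cat")
  up <- c(vaccine = 0.000, vaccinated = 0.000, vaccination = 0.000,
          forward = 0.002, looking = 0.003, open = 0.002, normal = 0.003,
          hope = 0.004, return = 0.002, happy = 0.003, relaxed = 0.002,
          relief = 0.001, calm = 0.002, tomorrow = 0.002, easing = 0.001)
  up2 <- c(vaccine = 0.0035, vaccinated = 0.0012, vaccination = 0.0008,
           forward = 0.006, looking = 0.007, open = 0.006, normal = 0.008,
           hope = 0.008, return = 0.005, happy = 0.006, relaxed = 0.004,
           relief = 0.003, calm = 0.004, tomorrow = 0.003, easing = 0.003)
  down <- c(worried = 0.008, worry = 0.006, anxious = 0.008, fear = 0.005,
            scared = 0.005, staying = 0.006, home = 0.010, isolating = 0.003,
            news = 0.005, nhs = 0.003, stress = 0.004, sad = 0.005,
            afraid = 0.003, panic = 0.003, yesterday = 0.002, virus = 0.008,
            family = 0.008, friends = 0.007)
  down2 <- c(worried = 0.004, worry = 0.003, anxious = 0.004, fear = 0.002,
             scared = 0.002, staying = 0.002, home = 0.005, isolating = 0.001,
             news = 0.002, nhs = 0.001, stress = 0.002, sad = 0.003,
             afraid = 0.001, panic = 0.001, yesterday = 0.002, virus = 0.005,
             family = 0.006, friends = 0.005)
  tibble::tibble(
    token = c(fw, fill, names(up), names(down)),
    rate_1 = c(rep(0.022, length(fw)), rep(0.0045, length(fill)),
               unname(up), unname(down)),
    rate_2 = c(rep(0.022, length(fw)), rep(0.0045, length(fill)),
               unname(up2), unname(down2))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_participants Number of participants (>= 0).
#' @param cluster_spec List of clusters, each `list(proportion,
#'   mean_change, sd_change)` with nine-dimensional named vectors;
#'   proportions must sum to 1 (tolerance 1e-9). Defaults to the two
#'   planted change-clusters (a well-coping and a resignation pattern).
#' @param phase1_means,phase1_sds Nine-dimensional named vectors for the
#'   phase-1 score distribution.
#' @param vocab_spec Tibble `(token, rate_1, rate_2)`; see
#'   [default_vocab_spec()].
#' @param text_length_mean,text_length_sd Token-count distribution of long
#'   texts (defaults 125 and 32).
#' @param short_length_mean,short_length_sd Token-count distribution of
#'   short texts (defaults 25 and 15).
#' @param sentence_length_mean Mean tokens per sentence (default 22).
#' @param seed Master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_participants = 200,
                         cluster_spec = default_cluster_spec(),
                         phase1_means = default_phase1_means(),
                         phase1_sds = default_phase1_sds(),
                         vocab_spec = default_vocab_spec(),
                         text_length_mean = 125, text_length_sd = 32,
                         short_length_mean = 25, short_length_sd = 15,
                         sentence_length_mean = 22,
                         seed = 1) {
  check_number(n_participants, "n_participants", lower = 0)
  props <- vapply(cluster_spec, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    abort("Cluster proportions must sum to 1 (tolerance 1e-9).")
  emo <- emotion_names()
  for (cl in cluster_spec) {
    if (!all(emo %in% names(cl$mean_change)) || !all(emo %in% names(cl$sd_change)))
      abort("Each cluster needs named nine-dimensional mean_change and sd_change.")
    if (any(cl$sd_change < 0)) abort("Change SDs must be nonnegative.")
  }
  vocab_spec <- tibble::as_tibble(vocab_spec)
  if (!all(c("token", "rate_1", "rate_2") %in% names(vocab_spec)))
    abort("`vocab_spec` needs columns token, rate_1, rate_2.")
  if (any(vocab_spec$rate_1 < 0) || any(vocab_spec$rate_2 < 0))
    abort("Vocabulary rates must be nonnegative.")
  cfg <- list(n_participants = as.integer(n_participants),
              cluster_spec = cluster_spec,
              phase1_means = phase1_means[emo], phase1_sds = phase1_sds[emo],
              vocab_spec = vocab_spec,
              text_length_mean = text_length_mean, text_length_sd = text_length_sd,
              short_length_mean = short_length_mean, short_length_sd = short_length_sd,
              sentence_length_mean = sentence_length_mean,
              seed = as.integer(seed))
  structure(cfg, class = "synth_config")
}

#' Serialise or restore a synthetic-cohort configuration
#'
#' @param config A `synth_config`.
#' @param path JSON file path.
#' @return `write_synth_config()` returns `path` invisibly;
#'   `read_synth_config()` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  out <- unclass(config)
  # named vectors must become objects, not bare arrays, to keep names
  out$phase1_means <- as.list(out$phase1_means)
  out$phase1_sds <- as.list(out$phase1_sds)
  out$cluster_spec <- lapply(out$cluster_spec, function(cl)
    list(proportion = cl$proportion,
         mean_change = as.list(cl$mean_change),
         sd_change = as.list(cl$sd_change)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cluster_spec <- lapply(raw$cluster_spec, function(cl) {
    list(proportion = cl$proportion,
         mean_change = unlist(cl$mean_change),
         sd_change = unlist(cl$sd_change))
  })
  vocab_spec <- tibble::tibble(
    token = unlist(raw$vocab_spec$token),
    rate_1 = unlist(raw$vocab_spec$rate_1),
    rate_2 = unlist(raw$vocab_spec$rate_2))
  synth_config(n_participants = raw$n_participants,
               cluster_spec = cluster_spec,
               phase1_means = unlist(raw$phase1_means),
               phase1_sds = unlist(raw$phase1_sds),
               vocab_spec = vocab_spec,
               text_length_mean = raw$text_length_mean,
               text_length_sd = raw$text_length_sd,
               short_length_mean = raw$short_length_mean,
               short_length_sd = raw$short_length_sd,
               sentence_length_mean = raw$sentence_length_mean,
               seed = raw$seed)
}

clip_likert <- function(x) pmin(pmax(round(x), .likert_min), .likert_max)

random_hex_ids <- function(n) {
  chars <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i)
    paste(sample(chars, 24, replace = TRUE), collapse = ""), character(1))
}

#' Generate a synthetic two-wave cohort
#'
#' @param config A [synth_config()].
#' @param texts Also generate texts via [generate_text_corpus()] (default
#'   TRUE).
#' @return A `synth_cohort`: `responses` (long tibble, one row per
#'   participant per phase), `clusters` (tibble of true cluster labels),
#'   `seed`, and `config_hash`. Identical config and seed reproduce the
#'   cohort exactly.
#' @export
generate_cohort <- function(config = synth_config(), texts = TRUE) {
  if (!inherits(config, "synth_config")) abort("`config` must be a synth_config.")
  n <- config$n_participants
  emo <- emotion_names()
  seeds <- derive_seeds(config$seed, 5)
  if (n == 0) {
    empty <- tibble::tibble(participant_id = character(), phase = integer())
    return(structure(list(responses = empty,
                          clusters = tibble::tibble(participant_id = character(),
                                                    cluster = integer()),
                          seed = config$seed,
                          config_hash = config_hash(unclass(config))),
                     class = "synth_cohort"))
  }

  set.seed(seeds[1])
  ids <- random_hex_ids(n)
  props <- vapply(config$cluster_spec, `[[`, numeric(1), "proportion")
  cl <- sample.int(length(props), n, replace = TRUE, prob = props)

  set.seed(seeds[2])
  p1 <- matrix(rnorm(n * 9, mean = rep(config$phase1_means, each = n),
                     sd = rep(config$phase1_sds, each = n)), n, 9)
  p1 <- clip_likert(p1)

  set.seed(seeds[3])
  mu <- do.call(rbind, lapply(config$cluster_spec, function(c_) c_$mean_change[emo]))
  sg <- do.call(rbind, lapply(config$cluster_spec, function(c_) c_$sd_change[emo]))
  change <- matrix(rnorm(n * 9), n, 9) * sg[cl, , drop = FALSE] + mu[cl, , drop = FALSE]
  p2 <- clip_likert(p1 + change)

  set.seed(seeds[4])
  age <- pmin(pmax(round(rnorm(n, 36.22, 11.66)), 18), 83)
  gender <- sample(c("female", "male", "missing"), n, replace = TRUE,
                   prob = c(0.6737, 0.3133, 0.0130))
  gender[gender == "missing"] <- NA_character_

  colnames(p1) <- colnames(p2) <- emo
  # forced choice: the emotion (worry excluded) with the highest score,
  # ties broken at random
  choose_emotion <- function(scores) {
    choices <- setdiff(emo, "worry")
    apply(scores[, choices, drop = FALSE], 1, function(s)
      choices[sample(which(s == max(s)), 1)])
  }
  responses <- dplyr::bind_rows(
    tibble::tibble(participant_id = ids, phase = 1L,
                   tibble::as_tibble(p1),
                   chosen_emotion = choose_emotion(p1),
                   age = age, gender = gender),
    tibble::tibble(participant_id = ids, phase = 2L,
                   tibble::as_tibble(p2),
                   chosen_emotion = choose_emotion(p2),
                   age = age, gender = gender)
  )
  cohort <- structure(
    list(responses = responses,
         clusters = tibble::tibble(participant_id = ids, cluster = cl),
         seed = config$seed,
         config_hash = config_hash(unclass(config))),
    class = "synth_cohort")
  if (texts) cohort <- generate_text_corpus(cohort, config)
  cohort
}

#' Attach synthetic texts to a cohort
#'
#' Draws, for every participant and phase, a long and a short text from
#' the phase-specific token rates of `config$vocab_spec` (lengths are
#' rounded normals truncated at one token; sentences are Poisson-length
#' chunks terminated by "."). Uses its own substream of the master seed,
#' so calling it again on the same cohort reproduces the same texts.
#'
#' @param cohort A `synth_cohort`.
#' @param config The [synth_config()] that generated it.
#' @return The cohort with `text_long` and `text_short` columns filled.
#' @export
generate_text_corpus <- function(cohort, config = synth_config()) {
  if (!inherits(cohort, "synth_cohort")) abort("`cohort` must be a synth_cohort.")
  vs <- config$vocab_spec
  if (nrow(vs) == 0) abort("`vocab_spec` must be nonempty.")
  if (sum(vs$rate_1) <= 0 || sum(vs$rate_2) <= 0)
    abort("Each phase needs positive total token rate.")
  resp <- cohort$responses
  if (nrow(resp) == 0) return(cohort)
  seeds <- derive_seeds(config$seed, 5)
  set.seed(seeds[5])
  make_text <- function(rate, len_mean, len_sd) {
    len <- max(1L, as.integer(round(rnorm(1, len_mean, len_sd))))
    toks <- sample(vs$token, len, replace = TRUE, prob = rate)
    out <- character(0)
    i <- 1L
    while (i <= len) {
      sl <- max(1L, rpois(1, config$sentence_length_mean - 1) + 1L)
      j <- min(len, i + sl - 1L)
      out <- c(out, paste0(paste(toks[i:j], collapse = " "), "."))
      i <- j + 1L
    }
    paste(out, collapse = " ")
  }
  rates <- list(`1` = vs$rate_1, `2` = vs$rate_2)
  resp$text_long <- vapply(seq_len(nrow(resp)), function(i)
    make_text(rates[[as.character(resp$phase[i])]],
              config$text_length_mean, config$text_length_sd), character(1))
  resp$text_short <- vapply(seq_len(nrow(resp)), function(i)
    make_text(rates[[as.character(resp$phase[i])]],
              config$short_length_mean, config$short_length_sd), character(1))
  cohort$responses <- resp
  cohort
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic two-wave cohort: %d participants, %d clusters (seed %d, config %s)\n",
              nrow(x$clusters), length(unique(x$clusters$cluster)),
              x$seed, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Pair the two waves of a synthetic cohort
#'
#' Convenience wrapper: splits the generated responses by phase and runs
#' [merge_phases()].
#'
#' @param cohort A `synth_cohort`.
#' @return A `paired_cohort` tibble.
#' @export
pair_synth_cohort <- function(cohort) {
  resp <- cohort$responses
  suppressMessages(merge_phases(resp[resp$phase == 1L, ], resp[resp$phase == 2L, ]))
}
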