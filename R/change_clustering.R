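# Subgroup discovery on emotion-change vectors.
#
# k-means is Lloyd's algorithm with k-means++ seeding, best of `restarts`
# initialisations, an empty-cluster rescue (re-seed from the farthest
# point), and determinism under a fixed seed. Change scores are clustered
# raw: all nine dimensions share the Likert-difference scale, so no
# standardisation is applied. The selection sweep additionally warm-starts
# each k from the best (k-1)-model plus its farthest point, which
# guarantees a non-increasing within-cluster sum of squares across k.

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  centers <- X[idx, , drop = FALSE]
  if (k == 1) return(centers)
  mind2 <- rowSums((X - rep(X[idx, ], each = n))^2)
  for (j in seq_len(k - 1)) {
    if (all(mind2 <= 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = pmax(mind2, 0))
    centers <- rbind(centers, X[idx, ])
    mind2 <- pmin(mind2, rowSums((X - rep(X[idx, ], each = n))^2))
  }
  centers
}

lloyd_iterate <- function(X, centers, max_iter = 300) {
  n <- nrow(X)
  k <- nrow(centers)
  xs <- rowSums(X^2)
  labels_old <- integer(n)
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    d2 <- outer(xs, rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    # empty-cluster rescue: re-seed from the point farthest from its center
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        far <- which.max(d2[cbind(seq_len(n), labels)])
        labels[far] <- j
      }
    }
    if (identical(labels, labels_old)) break
    labels_old <- labels
    sizes <- tabulate(labels, nbins = k)
    centers <- rowsum(X, labels, reorder = TRUE) / sizes
  }
  d2 <- outer(xs, rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  wcss <- sum(pmax(d2[cbind(seq_len(n), labels)], 0))
  list(centers = centers, labels = labels, wcss = wcss, iterations = iter)
}

new_kmeans_model <- function(fit, k, restarts, seed) {
  structure(
    list(k = k, centers = fit$centers, labels = fit$labels, wcss = fit$wcss,
         iterations = fit$iterations, restarts = restarts, seed = seed),
    class = "emoshift_kmeans"
  )
}

#' @export
print.emoshift_kmeans <- function(x, ...) {
  cat(sprintf("k-means model: k = %d, n = %d, wcss = %.2f (%d restarts, seed %s)\n",
              x$k, length(x$labels), x$wcss, x$restarts, format(x$seed)))
  invisible(x)
}

#' Fit k-means to an emotion-change matrix
#'
#' @param X Numeric matrix (participants x dimensions), e.g. from
#'   [change_scores()].
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param restarts Number of k-means++ initialisations; the best (lowest
#'   within-cluster sum of squares) fit is kept.
#' @param seed Integer seed making the fit deterministic.
#' @param max_iter Iteration cap per start.
#' @param extra_inits Optional list of center matrices to try in addition
#'   to the random restarts (used by [select_k()] for warm starts).
#' @return An `emoshift_kmeans` model: `k`, `centers` (k x d), `labels`
#'   (in `1..k`), `wcss`, `iterations`, `restarts`, `seed`.
#' @export
fit_kmeans <- function(X, k, restarts = 25, seed = 1, max_iter = 300,
                       extra_inits = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) abort("`X` must be a complete numeric matrix.")
  if (k < 1 || k > nrow(X)) abort("`k` must satisfy 1 <= k <= nrow(X).")
  set.seed(as.integer(seed %% 2147483647))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd_iterate(X, kmeanspp_init(X, k), max_iter = max_iter)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  for (init in extra_inits %||% list()) {
    fit <- lloyd_iterate(X, as.matrix(init), max_iter = max_iter)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  new_kmeans_model(best, k, restarts, seed)
}

#' Mean silhouette width of a clustering
#'
#' The silhouette of point i is `(b_i - a_i)/max(a_i, b_i)` where `a_i` is
#' its mean Euclidean distance to its own cluster and `b_i` the smallest
#' mean distance to another cluster; singleton clusters contribute 0, and a
#' point at zero distance from its own cluster scores 1 when `b_i > 0`.
#'
#' @param X Numeric matrix of observations.
#' @param labels Integer cluster assignment with at least two nonempty
#'   clusters.
#' @param dist_x Optional precomputed [stats::dist()] object for `X`.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_avg <- function(X, labels, dist_x = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    abort("Silhouette needs at least two clusters.")
  if (!is.null(X) && length(labels) != nrow(as.matrix(X)))
    abort("`labels` must match rows of `X`.")
  d <- dist_x %||% dist(as.matrix(X))
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by elbow and silhouette
#'
#' Fits k-means for `k = 1..k_max` (best of `restarts` k-means++ starts per
#' k, plus a warm start from the previous k's best model so the
#' within-cluster sum of squares never increases with k). The operative
#' selector is the largest mean silhouette over `k >= 2` (ties broken
#' towards smaller k); the elbow k (largest curvature of the wcss curve,
#' i.e. maximum second difference) is reported alongside. When even the
#' best silhouette is below 0.2 the data show little cluster structure and
#' `low_structure` is set.
#'
#' @inheritParams fit_kmeans
#' @param k_max Upper end of the sweep (default 20), `2 <= k_max < nrow(X)`.
#' @return A `k_selection_curve`: `curve` (tibble of k, wcss, silhouette),
#'   `selected_k`, `elbow_k`, `low_structure`, and `models` (fitted
#'   `emoshift_kmeans` per k).
#' @export
select_k <- function(X, k_max = 20, restarts = 25, seed = 1) {
  X <- as.matrix(X)
  if (k_max < 2) abort("`k_max` must be at least 2.")
  if (nrow(X) <= k_max) abort("Need more observations than `k_max`.")
  seeds <- derive_seeds(seed, k_max)
  dist_x <- dist(X)
  models <- vector("list", k_max)
  wcss <- numeric(k_max)
  sil <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    warm <- NULL
    if (k > 1) {
      prev <- models[[k - 1]]
      d2p <- rowSums((X - prev$centers[prev$labels, , drop = FALSE])^2)
      warm <- list(rbind(prev$centers, X[which.max(d2p), ]))
    }
    models[[k]] <- fit_kmeans(X, k, restarts = restarts, seed = seeds[k],
                              extra_inits = warm)
    wcss[k] <- models[[k]]$wcss
    if (k >= 2) sil[k] <- silhouette_avg(NULL, models[[k]]$labels, dist_x = dist_x)
  }
  selected_k <- which.max(sil) # NA for k = 1; ties -> smallest k
  elbow_k <- if (k_max >= 3) {
    ks <- 2:(k_max - 1)
    ks[which.max(wcss[ks - 1] - 2 * wcss[ks] + wcss[ks + 1])]
  } else NA_integer_
  structure(
    list(curve = tibble::tibble(k = seq_len(k_max), wcss = wcss, silhouette = sil),
         selected_k = as.integer(selected_k),
         elbow_k = as.integer(elbow_k),
         low_structure = max(sil, na.rm = TRUE) < 0.2,
         models = models),
    class = "k_selection_curve"
  )
}

#' @export
print.k_selection_curve <- function(x, ...) {
  cat(sprintf("k selection over k = 1..%d: selected k = %d (silhouette %.3f), elbow k = %s%s\n",
              nrow(x$curve), x$selected_k,
              x$curve$silhouette[x$selected_k],
              format(x$elbow_k),
              if (x$low_structure) "; low cluster structure" else ""))
  invisible(x)
}

#' Profile clusters of emotion change
#'
#' Per-cluster, per-emotion mean change with SD and a deviation-from-zero
#' test ([one_sample_profile()] at `alpha`), plus cluster-level size,
#' prevalence, mean age with SD (participants with `age <= age_bound`
#' only; implausible ages stay in all other analyses) and % female among
#' gender-reporting members.
#'
#' @param cohort A `paired_cohort`.
#' @param labels Cluster assignment aligned with `cohort` rows.
#' @param alpha Significance level for the zero-change test (default 0.01).
#' @param age_bound Upper bound for plausible ages (default 110).
#' @return A `cluster_profile`: `emotions` tibble (cluster x emotion) and
#'   `clusters` tibble (one row per cluster).
#' @export
profile_clusters <- function(cohort, labels, alpha = 0.01, age_bound = 110) {
  if (length(labels) != nrow(cohort))
    abort("`labels` must have one entry per cohort row.")
  labels <- as.integer(labels)
  emo <- emotion_names()
  n_total <- nrow(cohort)
  ks <- sort(unique(labels))
  emotions <- dplyr::bind_rows(lapply(ks, function(kk) {
    rows <- labels == kk
    dplyr::bind_rows(lapply(emo, function(e) {
      x <- cohort[[paste0("delta_", e)]][rows]
      prof <- one_sample_profile(mean(x), sd(x), length(x), alpha = alpha)
      tibble::tibble(cluster = kk, emotion = e,
                     mean_change = mean(x), sd_change = sd(x),
                     d = prof$d, t = prof$t, p = prof$p,
                     significant = prof$significant)
    }))
  }))
  clusters <- dplyr::bind_rows(lapply(ks, function(kk) {
    rows <- labels == kk
    age <- cohort$age[rows]
    age <- age[!is.na(age) & age <= age_bound]
    gender <- cohort$gender[rows]
    gender <- gender[!is.na(gender) & gender %in% c("female", "male")]
    tibble::tibble(
      cluster = kk,
      size = sum(rows),
      prevalence = 100 * sum(rows) / n_total,
      age_mean = if (length(age)) mean(age) else NA_real_,
      age_sd = if (length(age) > 1) sd(age) else NA_real_,
      pct_female = if (length(gender)) 100 * mean(gender == "female") else NA_real_
    )
  }))
  structure(list(emotions = emotions, clusters = clusters, alpha = alpha),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Cluster profile\n")
  print(x$clusters)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$emotions,
                  cell = sprintf("%.2f (%.2f)%s", .data$mean_change,
                                 .data$sd_change,
                                 ifelse(.data$significant, "", " ns"))),
    id_cols = "emotion", names_from = "cluster", values_from = "cell",
    names_prefix = "cluster_")
  print(wide)
  invisible(x)
}

#' Compare demographics between two clusters
#'
#' Age is compared with the pooled two-group effect size
#' ([two_sample_effect()]) on plausible ages; gender with a 2x2 chi-square
#' test (continuity-corrected by default) on female/male counts among
#' gender-reporting members.
#'
#' @inheritParams profile_clusters
#' @param level Confidence level for the age effect (default 0.99).
#' @param correct Apply the 2x2 continuity correction (default TRUE).
#' @return A list: `age` (`effect_estimate`), `gender` (list with
#'   `statistic`, `df`, `p_value`, `table`).
#' @export
compare_demographics <- function(cohort, labels, level = 0.99,
                                 age_bound = 110, correct = TRUE) {
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) != 2) abort("Demographic comparison needs exactly two clusters.")
  ok_age <- !is.na(cohort$age) & cohort$age <= age_bound
  a1 <- cohort$age[ok_age & labels == ks[1]]
  a2 <- cohort$age[ok_age & labels == ks[2]]
  age_eff <- two_sample_effect(mean(a1), sd(a1), length(a1),
                               mean(a2), sd(a2), length(a2), level = level)
  ok_g <- !is.na(cohort$gender) & cohort$gender %in% c("female", "male")
  tab <- table(factor(cohort$gender[ok_g], levels = c("female", "male")),
               factor(labels[ok_g], levels = ks))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("Gender table has a zero marginal; chi-square test undefined.")
  cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(age = age_eff,
       gender = list(statistic = unname(cs$statistic), df = unname(cs$parameter),
                     p_value = cs$p.value, table = tab))
}
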