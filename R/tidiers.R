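# broom-style tidiers for the package's result objects.

#' Tidy an effect estimate
#'
#' @param x An `effect_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the effect size, interval, test statistic
#'   and sample sizes.
#' @method tidy effect_estimate
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble::tibble(
    design = x$design, d = x$d, ci_low = x$ci_low, ci_high = x$ci_high,
    t = x$t, df = x$df, p = x$p, level = x$level,
    mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    n = x$n %||% NA_integer_, n1 = x$n1 %||% NA_integer_,
    n2 = x$n2 %||% NA_integer_)
}

#' Tidy a Bayes factor result
#'
#' @param x A `bf_result`.
#' @param ... Unused.
#' @return A one-row tibble: `bf10`, `log10_bf10`, `prior_scale`,
#'   `design`.
#' @method tidy bf_result
#' @export
tidy.bf_result <- function(x, ...) {
  tibble::tibble(bf10 = x$bf10, log10_bf10 = x$log10_bf10,
                 prior_scale = x$prior_scale, design = x$design)
}

#' Tidy an exclusion report
#'
#' @param x An `exclusion_report`.
#' @param ... Unused.
#' @return A tibble with one row per rule plus `initial` and `retained`
#'   rows, columns `rule` and `count`.
#' @method tidy exclusion_report
#' @export
tidy.exclusion_report <- function(x, ...) {
  tibble::tibble(
    rule = c("initial", names(x$rule_counts), "retained"),
    count = c(x$initial_count, unname(x$rule_counts), x$retained_count))
}

#' Tidy a k-means model
#'
#' @param x An `emoshift_kmeans`.
#' @param ... Unused.
#' @return A tibble with one row per cluster and dimension:
#'   `cluster`, `dimension`, `center`, `size`.
#' @method tidy emoshift_kmeans
#' @export
tidy.emoshift_kmeans <- function(x, ...) {
  centers <- x$centers
  dims <- colnames(centers) %||% paste0("dim_", seq_len(ncol(centers)))
  sizes <- tabulate(x$labels, nbins = x$k)
  tibble::tibble(
    cluster = rep(seq_len(x$k), each = ncol(centers)),
    dimension = rep(dims, times = x$k),
    center = as.vector(t(centers)),
    size = rep(sizes, each = ncol(centers)))
}

#' Glance at a k-means model
#'
#' @param x An `emoshift_kmeans`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `wcss`, `iterations`, `restarts`,
#'   `seed`.
#' @method glance emoshift_kmeans
#' @export
glance.emoshift_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels), wcss = x$wcss,
                 iterations = x$iterations, restarts = x$restarts,
                 seed = x$seed)
}

#' Tidy a k-selection curve
#'
#' @param x A `k_selection_curve`.
#' @param ... Unused.
#' @return The per-k tibble of `wcss` and mean `silhouette`.
#' @method tidy k_selection_curve
#' @export
tidy.k_selection_curve <- function(x, ...) x$curve

#' Glance at a k-selection curve
#'
#' @param x A `k_selection_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `selected_k`, `elbow_k`, `best_silhouette`,
#'   `low_structure`.
#' @method glance k_selection_curve
#' @export
glance.k_selection_curve <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k, elbow_k = x$elbow_k,
                 best_silhouette = max(x$curve$silhouette, na.rm = TRUE),
                 low_structure = x$low_structure)
}

#' Tidy a cluster profile
#'
#' @param x A `cluster_profile`.
#' @param ... Unused.
#' @return The cluster-by-emotion tibble of mean changes, SDs and
#'   deviation-from-zero tests.
#' @method tidy cluster_profile
#' @export
tidy.cluster_profile <- function(x, ...) x$emotions

#' Glance at a cluster profile
#'
#' @param x A `cluster_profile`.
#' @param ... Unused.
#' @return The per-cluster tibble (size, prevalence, age, % female).
#' @method glance cluster_profile
#' @export
glance.cluster_profile <- function(x, ...) x$clusters

#' Tidy a shift table
#'
#' @param x A `shift_table`.
#' @param ... Unused.
#' @return All non-degenerate entries ranked by absolute mean r.
#' @method tidy shift_table
#' @export
tidy.shift_table <- function(x, ...) x$all
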