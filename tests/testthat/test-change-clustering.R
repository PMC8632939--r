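# k-means, silhouette, k selection, cluster profiling and demographics.

two_blob_data <- function(n_per = 6, sep = 10, d = 2, seed = 5) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * d, 0, 0.2), n_per, d),
        matrix(rnorm(n_per * d, sep, 0.2), n_per, d))
}

test_that("k = 1 returns the mean and the total sum of squares", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  m <- fit_kmeans(X, 1, restarts = 2, seed = 1)
  expect_equal(as.vector(m$centers), colMeans(X))
  expect_equal(m$wcss, sum(sweep(X, 2, colMeans(X))^2))
})

test_that("two separated blobs are partitioned exactly and deterministically", {
  X <- two_blob_data()
  m <- fit_kmeans(X, 2, restarts = 5, seed = 9)
  expect_equal(length(unique(m$labels[1:6])), 1L)
  expect_equal(length(unique(m$labels[7:12])), 1L)
  expect_false(m$labels[1] == m$labels[7])
  m2 <- fit_kmeans(X, 2, restarts = 5, seed = 9)
  expect_identical(m, m2)
  expect_error(fit_kmeans(X, 13), "k")
})

test_that("wcss equals the sum of squared distances to assigned centers", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  m <- fit_kmeans(X, 3, restarts = 5, seed = 4)
  manual <- sum((X - m$centers[m$labels, ])^2)
  expect_equal(m$wcss, manual)
})

test_that("silhouette matches the hand-computed two-pair configuration", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c(1, 1, 2, 2)
  # a = 1, b = (10 + sqrt(101))/2 for every point
  b <- (10 + sqrt(101)) / 2
  expect_equal(silhouette_avg(X, labels), (b - 1) / b, tolerance = 1e-12)
  expect_error(silhouette_avg(X, rep(1, 4)), "two clusters")
})

test_that("silhouette conventions: duplicated points score 1, permutation invariance", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(silhouette_avg(X, c(1, 1, 2, 2)), 1)
  set.seed(6)
  Y <- matrix(rnorm(80), 40, 2)
  lab <- rep(1:4, each = 10)
  perm <- c(3, 1, 4, 2)
  expect_equal(silhouette_avg(Y, lab), silhouette_avg(Y, perm[lab]))
})

test_that("k selection picks 2 for two far pairs and flags unstructured data", {
  X <- rbind(c(0, 0), c(0, 1), c(50, 0), c(50, 1),
             c(0, 0.5), c(50, 0.5), c(0.5, 0), c(49.5, 1))
  ks <- select_k(X, k_max = 3, restarts = 5, seed = 2)
  expect_equal(ks$selected_k, 2L)
  expect_false(ks$low_structure)

  set.seed(12)
  G <- matrix(rnorm(500 * 9, 0, 2.1), 500, 9)
  ksg <- select_k(G, k_max = 8, restarts = 5, seed = 3)
  expect_true(ksg$low_structure)
})

test_that("wcss is non-increasing across the selection sweep", {
  set.seed(44)
  X <- matrix(rnorm(300 * 9), 300, 9)
  ks <- select_k(X, k_max = 10, restarts = 3, seed = 7)
  expect_true(all(diff(ks$curve$wcss) <= 1e-8))
  expect_error(select_k(X, k_max = 1), "at least 2")
})

test_that("planted labels are recovered at the published cluster separations", {
  skip_if_not_installed("mclust")
  spec <- default_cluster_spec()
  mu <- rbind(spec[[1]]$mean_change, spec[[2]]$mean_change)
  sg <- rbind(spec[[1]]$sd_change, spec[[2]]$sd_change)
  ari_cont <- ari_disc <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 1000
    cl <- 1 + (runif(n) > spec[[1]]$proportion)
    Xc <- matrix(rnorm(n * 9), n, 9) * sg[cl, ] + mu[cl, ]
    m <- fit_kmeans(Xc, 2, restarts = 10, seed = s)
    ari_cont[s] <- mclust::adjustedRandIndex(m$labels, cl)
    # the same changes pushed through the Likert round/clip discretisation
    base <- pmin(pmax(round(matrix(rnorm(n * 9, rep(default_phase1_means(), each = n),
                                         rep(default_phase1_sds(), each = n)),
                                   n, 9)), 1), 9)
    Xd <- pmin(pmax(round(base + Xc), 1), 9) - base
    md <- fit_kmeans(Xd, 2, restarts = 10, seed = s)
    ari_disc[s] <- mclust::adjustedRandIndex(md$labels, cl)
  }
  expect_gt(mean(ari_cont), 0.8)   # continuous change vectors
  expect_gt(mean(ari_disc), 0.7)   # after Likert discretisation
})

test_that("cluster profiles recover planted means and calibrate the zero test", {
  emo <- emotion_names()
  spec <- list(
    list(proportion = 0.5,
         mean_change = setNames(c(-1.5, 0, 1, -1, -1.5, 1.5, 1, -1, -1), emo),
         sd_change = setNames(rep(1.3, 9), emo)),
    list(proportion = 0.5,
         mean_change = setNames(c(1.2, 0, 0.3, 0.6, -0.5, -0.2, -0.5, 0.5, -0.9), emo),
         sd_change = setNames(rep(1.3, 9), emo)))
  cfg <- synth_config(n_participants = 5000, cluster_spec = spec,
                      phase1_means = setNames(rep(5, 9), emo),
                      phase1_sds = setNames(rep(1, 9), emo), seed = 15)
  co <- generate_cohort(cfg, texts = FALSE)
  pc <- pair_synth_cohort(co)
  labels <- co$clusters$cluster[match(pc$participant_id,
                                      co$clusters$participant_id)]
  prof <- profile_clusters(pc, labels)
  expect_equal(sum(glance(prof)$prevalence), 100, tolerance = 1e-9)
  expect_equal(sum(glance(prof)$size), nrow(pc))
  emos <- tidy(prof)
  for (k in 1:2) {
    got <- emos$mean_change[emos$cluster == k]
    want <- unname(spec[[k]]$mean_change)
    se <- sqrt((1.3^2 + 1 / 6) / sum(labels == k))
    expect_true(all(abs(got - want) < 3 * se + 0.02))
  }
  # anxiety planted at zero change in both clusters: usually flagged ns
  anx <- emos[emos$emotion == "anxiety", ]
  expect_false(any(anx$significant))
})

test_that("profile statistics are invariant to cluster relabelling", {
  co <- generate_cohort(synth_config(n_participants = 120, seed = 33),
                        texts = FALSE)
  pc <- pair_synth_cohort(co)
  labels <- co$clusters$cluster[match(pc$participant_id,
                                      co$clusters$participant_id)]
  p1 <- profile_clusters(pc, labels)
  p2 <- profile_clusters(pc, 3 - labels) # swap 1 <-> 2
  a <- dplyr::arrange(tidy(p1), .data$emotion, .data$cluster)
  b <- dplyr::arrange(dplyr::mutate(tidy(p2), cluster = 3 - .data$cluster),
                      .data$emotion, .data$cluster)
  expect_equal(a$mean_change, b$mean_change)
  expect_equal(a$d, b$d)
  expect_error(profile_clusters(pc, labels[-1]), "one entry per")
})

test_that("demographic comparison: chi-square hand values and published age d", {
  # balanced table: no association
  set.seed(71)
  cohort <- tibble::tibble(
    age = rnorm(40, 35, 5),
    gender = rep(c("female", "male"), 20))
  labels <- rep(1:2, each = 20)
  res <- compare_demographics(cohort, labels)
  expect_equal(res$gender$statistic, 0)
  expect_equal(res$gender$p_value, 1)

  # 20/10 vs 10/20: continuity-corrected chi-square = 5.4 by hand
  cohort2 <- tibble::tibble(
    age = rnorm(60, 35, 5),
    gender = c(rep("female", 20), rep("male", 10),
               rep("female", 10), rep("male", 20)))
  labels2 <- rep(1:2, each = 30)
  res2 <- compare_demographics(cohort2, labels2)
  expect_equal(res2$gender$statistic, 5.4, tolerance = 1e-12)
  expect_equal(res2$gender$df, 1)

  # zero marginal -> informative error
  cohort3 <- tibble::tibble(age = rnorm(20, 35, 5), gender = rep("female", 20))
  expect_error(compare_demographics(cohort3, rep(1:2, each = 10)),
               "zero marginal")
})

test_that("implausible ages are excluded from age statistics only", {
  co <- generate_cohort(synth_config(n_participants = 60, seed = 51),
                        texts = FALSE)
  pc <- pair_synth_cohort(co)
  pc$age[1] <- 961L
  labels <- rep(1:2, length.out = nrow(pc))
  prof <- profile_clusters(pc, labels)
  expect_equal(sum(glance(prof)$size), nrow(pc)) # record kept
  expect_true(all(glance(prof)$age_mean < 100))  # age stat unaffected
})
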