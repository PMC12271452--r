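test_that("stratified sampling allocates equally and reproducibly", {
  strata <- rep(1:10, each = 100)
  idx <- stratified_sample(strata, 0.1, seed = 4)
  expect_length(idx, 100)
  expect_true(all(table(strata[idx]) == 10))
  expect_identical(idx, stratified_sample(strata, 0.1, seed = 4))
  # 1% of 100,000 over 1000 strata is one point per stratum
  strata2 <- rep(1:1000, each = 100)
  idx2 <- stratified_sample(strata2, 0.01, seed = 1)
  expect_length(idx2, 1000)
  expect_true(all(table(strata2[idx2]) == 1))
})

test_that("preclustering rejects more strata than points and labels every point", {
  g <- gaussian_embeddings(300, 3, dim = 4, seed = 2)
  expect_error(precluster_for_sampling(g$x, k = 301), "strata")
  lab <- precluster_for_sampling(g$x, k = 20, seed = 5)
  expect_length(lab, 300)
  expect_lte(length(unique(lab)), 20)
})

test_that("clustering indices match reference values on a frozen fixture", {
  # fixture values computed independently with scikit-learn 1.9
  x <- matrix(c(
    1.690526, -0.465937, 0.03282, 0.407516, -0.788923, 0.002066,
    -0.00089, -1.754724, 1.017658, 0.600499, -0.625429, -0.171548,
    0.505299, -0.261356, -0.242749, -1.453241, 0.55458, 0.123881,
    0.27446, -1.526525, 1.6507, 0.154336, -0.38714, 2.029072,
    -0.045386, -1.450679, -0.405228, -2.288315, 1.049397, -0.416474,
    -0.742554, 1.07247, -1.651076, 0.535429, -2.064415, -0.662159),
    12, 3, byrow = TRUE)
  lab <- rep(1:3, each = 4)
  expect_equal(davies_bouldin(x, lab), 1.9115081476924527, tolerance = 1e-9)
  expect_equal(calinski_harabasz(x, lab), 1.7572118402294943, tolerance = 1e-9)
})

test_that("bootstrapped silhouette selection recovers a planted component count", {
  g <- gaussian_embeddings(1500, 3, dim = 8, sep = 5, seed = 6)
  rep_ <- select_optimal_k(g$x, k_range = 2:6, replicates = 10,
                           fraction = 0.2, precluster_k = 50, seed = 8)
  expect_equal(rep_$chosen_k, 3)
  expect_equal(rep_$metrics$k, 2:6)
  expect_true(all(c("sil_mean", "sil_sd", "db_mean", "db_sd",
                    "ch_mean", "ch_sd") %in% names(rep_$metrics)))
  expect_true(all(rep_$metrics$sil_mean >= -1 & rep_$metrics$sil_mean <= 1))
  # on two-mass data the silhouette at the true k dominates a k too large
  g2 <- gaussian_embeddings(200, 2, dim = 4, sep = 6, seed = 9)
  r2 <- select_optimal_k(g2$x, k_range = c(2, 5), replicates = 3,
                         fraction = 0.5, precluster_k = 10, seed = 3)
  m <- r2$metrics
  expect_gt(m$sil_mean[m$k == 2], m$sil_mean[m$k == 5])
})

test_that("final K-Means is validated, deterministic and finds mass centers", {
  g <- gaussian_embeddings(400, 2, dim = 4, sep = 8, seed = 10)
  expect_error(fit_final_kmeans(g$x, k = 1), "at least 2")
  expect_error(fit_final_kmeans(g$x[1:3, ], k = 5), "exceed")
  m1 <- fit_final_kmeans(g$x, 2, seed = 12)
  m2 <- fit_final_kmeans(g$x, 2, seed = 12)
  expect_identical(m1$centers, m2$centers)
  # centroids sit at the component means
  perm <- hungarian_match(m1$centers, g$centers)$permutation
  for (i in 1:2) {
    mass_mean <- colMeans(g$x[g$labels == perm[i], ])
    expect_lt(sqrt(sum((m1$centers[i, ] - mass_mean)^2)), 0.2)
  }
})

test_that("Hungarian matching recovers permutations and the brute-force optimum", {
  withr::with_seed(15, {
    a <- matrix(rnorm(5 * 8), 5, 8)
    self <- hungarian_match(a, a)
    expect_equal(self$permutation, 1:5)
    expect_equal(self$distances, rep(0, 5), tolerance = 1e-12)
    p <- sample(5)
    perm_rec <- hungarian_match(a, a[p, ])$permutation
    expect_equal(p[perm_rec], 1:5)
    expect_error(hungarian_match(a, a[1:3, ]), "equal size")
    for (i in 1:30) {
      k <- sample(2:6, 1)
      b1 <- matrix(rnorm(k * 6), k, 6)
      b2 <- matrix(rnorm(k * 6), k, 6)
      hm <- hungarian_match(b1, b2)
      bf <- brute_force_assignment(1 - cosine_similarity(b1, b2))
      expect_equal(hm$total, bf$total, tolerance = 1e-10)
    }
  })
})

test_that("bootstrap stability reports small matched distances for separated clusters", {
  g <- gaussian_embeddings(1000, 4, dim = 8, sep = 6, seed = 20)
  model <- fit_final_kmeans(g$x, 4, seed = 21)
  rep_ <- bootstrap_stability(g$x, model, replicates = 10, fraction = 0.25,
                              seed = 22)
  expect_equal(nrow(rep_$per_cluster), 4)
  # within-cluster spread in cosine distance to own centroid
  spread <- median(vapply(seq_len(nrow(g$x)), function(i) {
    1 - cosine_similarity(g$x[i, ], model$centers[model$cluster[i], ])
  }, numeric(1)))
  expect_true(all(rep_$per_cluster$median_cosine_distance < spread))
  # a single replicate on the full data self-matches almost exactly
  r1 <- bootstrap_stability(g$x, model, replicates = 1, fraction = 1,
                            seed = 21)
  expect_lt(max(r1$per_cluster$median_cosine_distance), 1e-6)
})

test_that("K-Means recovers planted archetype components", {
  g <- gaussian_embeddings(2000, 5, dim = 16, sep = 5, seed = 30)
  model <- fit_final_kmeans(g$x, 5, seed = 31)
  expect_gte(mclust::adjustedRandIndex(model$cluster, g$labels), 0.9)
})

test_that("record splicing honours the eligibility rule", {
  mk <- function(yob, years) {
    demo <- data.frame(patient_id = "p1", gender = "female",
                       year_of_birth = yob,
                       ethnicity = NA, imd_quintile = NA,
                       registration_start = as.Date("1990-01-01"),
                       registration_end = as.Date("2020-12-31"))
    ev <- data.frame(patient_id = "p1",
                     date = as.Date(sprintf("%d-06-01", yob + years)),
                     source = "diagnosis", code = "I10")
    structure(list(demographics = demo, events = data.table::as.data.table(ev),
                   truth = data.frame(patient_id = "p1", gender = "female",
                                      archetype = "x")),
              class = "ehr_cohort")
  }
  # records only up to age 64: excluded from the age-65 cohort
  co <- mk(1940, c(55, 60, 64))
  out <- splice_records(co, 65)
  expect_equal(nrow(out$demographics), 0)
  expect_equal(attr(out, "ineligible"), "p1")
  # records beyond the cutoff: retained with truncated events
  co2 <- mk(1940, c(55, 60, 64, 70))
  out2 <- splice_records(co2, 65)
  expect_equal(nrow(out2$demographics), 1)
  expect_equal(nrow(out2$events), 3)
  # cutoff before the first event: ineligible (empty spliced sequence)
  out3 <- splice_records(co2, 50)
  expect_equal(nrow(out3$demographics), 0)
})

test_that("temporal cohesion is zero when age-spliced embeddings equal the final ones", {
  g <- gaussian_embeddings(600, 3, dim = 8, sep = 6, seed = 40)
  model <- fit_final_kmeans(g$x, 3, seed = 41)
  rep_ <- temporal_cohesion(list(`60` = g$x, `70` = g$x), model, g$x)
  expect_equal(rep_$average_difference, 0, tolerance = 1e-10)
  expect_setequal(unique(rep_$by_age$age), c(60, 70))
  # stationary components: per-age cohesion within noise of the final one
  sub <- g$x[sample(nrow(g$x), 300), ]
  rep2 <- temporal_cohesion(list(`60` = sub), model, g$x)
  expect_lt(rep2$average_difference, 0.05)
})
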