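# Gender-stratified clustering of patient embeddings: bootstrapped
# agglomerative k-selection on stratified subsamples, final K-Means,
# Hungarian-matched bootstrap centroid stability, and temporal cohesion of
# clusters under age-spliced histories.

#' Pre-cluster for representative subsampling
#'
#' Before subsampling, the cohort is clustered into `k` K-Means strata;
#' stratified sampling then draws equally from each stratum so subsamples
#' represent the whole embedding space.
#'
#' @param embeddings Numeric matrix, one row per patient.
#' @param k Number of sampling strata (default 1000; must not exceed the
#'   number of rows).
#' @param seed Seed for the K-Means initialisation.
#' @return Integer vector of stratum labels, one per row.
#' @export
precluster_for_sampling <- function(embeddings, k = 1000, seed = 1L) {
  n <- nrow(embeddings)
  assert_that(k <= n, "cannot form more sampling strata than points")
  with_seed(seed, {
    km <- suppressWarnings(kmeans(embeddings, centers = k, iter.max = 20,
                                  nstart = 1))
    as.integer(km$cluster)
  })
}

#' Stratified equal-allocation subsample
#'
#' Draws `floor(fraction * n)` points, allocated equally across strata
#' (floor division; the remainder is assigned round-robin in stratum-label
#' order). Strata smaller than their quota contribute all their points.
#'
#' @param strata Integer/character stratum labels, one per point.
#' @param fraction Sampling fraction of the total.
#' @param seed Seed.
#' @return Integer vector of sampled row indices.
#' @export
stratified_sample <- function(strata, fraction, seed = NULL) {
  n <- length(strata)
  m <- max(1L, floor(fraction * n))
  labs <- sort(unique(strata))
  S <- length(labs)
  quota <- rep(m %/% S, S)
  rem <- m %% S
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  with_seed(seed, {
    idx <- unlist(lapply(seq_len(S), function(i) {
      members <- which(strata == labs[i])
      take <- min(quota[i], length(members))
      if (take == 0) return(integer())
      members[sample.int(length(members), take)]
    }), use.names = FALSE)
    sort(idx)
  })
}

# Davies-Bouldin index (Euclidean); lower is better.
davies_bouldin <- function(x, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- t(vapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_len(k), function(i) {
    m <- x[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((m - matrix(cent[i, ], nrow(m), ncol(x),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(dist(cent))
  mean(vapply(seq_len(k), function(i) {
    r <- (s[i] + s[-i]) / M[i, -i]
    max(r)
  }, numeric(1)))
}

# Calinski-Harabasz index (variance-ratio criterion); higher is better.
calinski_harabasz <- function(x, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  n <- nrow(x)
  gmean <- colMeans(x)
  B <- 0; W <- 0
  for (l in labs) {
    m <- x[labels == l, , drop = FALSE]
    cm <- colMeans(m)
    B <- B + nrow(m) * sum((cm - gmean)^2)
    W <- W + sum(sweep(m, 2, cm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Bootstrapped selection of the number of clusters
#'
#' Repeatedly draws stratified subsamples, runs agglomerative hierarchical
#' clustering (Ward linkage on Euclidean distances of length-normalised
#' embeddings) cut at every candidate k, and records silhouette,
#' Davies-Bouldin and Calinski-Harabasz scores. The chosen k maximises the
#' mean silhouette across replicates (ties broken towards the smaller k);
#' the other two indices are reported for corroboration.
#'
#' @param embeddings Numeric matrix of patient embeddings.
#' @param k_range Candidate cluster numbers (default 2:30).
#' @param replicates Number of bootstrap replicates (reference setting 500).
#' @param fraction Subsample fraction per replicate (reference setting 0.01).
#' @param strata Optional precomputed sampling strata; computed with
#'   [precluster_for_sampling()] when `NULL`.
#' @param precluster_k Number of sampling strata if computed here.
#' @param seed Seed driving preclustering and all replicates.
#' @return An object of class `k_selection_report` with `metrics` (per-k
#'   mean/sd of each index), `chosen_k`, and bookkeeping fields.
#' @export
select_optimal_k <- function(embeddings, k_range = 2:30, replicates = 500,
                             fraction = 0.01, strata = NULL,
                             precluster_k = 1000, seed = 1L) {
  n <- nrow(embeddings)
  if (is.null(strata)) {
    strata <- precluster_for_sampling(embeddings, k = min(precluster_k, n),
                                      seed = seed)
  }
  sub_n <- max(1L, floor(fraction * n))
  assert_that(min(k_range) >= 2 && max(k_range) < sub_n,
              "k_range must lie within [2, subsample size)")
  Xn <- l2_normalize(embeddings)
  seeds <- derive_seeds(seed, replicates)
  res <- vector("list", replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    idx <- stratified_sample(strata, fraction, seed = seeds[r])
    sub <- Xn[idx, , drop = FALSE]
    if (nrow(unique(sub)) <= max(k_range)) {
      skipped <- skipped + 1L
      message(sprintf("replicate %d skipped: degenerate subsample", r))
      next
    }
    d <- dist(sub)
    hc <- hclust(d, method = "ward.D2")
    res[[r]] <- do.call(rbind, lapply(k_range, function(k) {
      ct <- cutree(hc, k)
      sil <- mean(cluster::silhouette(ct, d)[, "sil_width"])
      data.frame(replicate = r, k = k, silhouette = sil,
                 davies_bouldin = davies_bouldin(sub, ct),
                 calinski_harabasz = calinski_harabasz(sub, ct))
    }))
  }
  per <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  assert_that(nrow(per) > 0, "all replicates were degenerate")
  metrics <- per[, list(
    sil_mean = mean(silhouette), sil_sd = sd(silhouette),
    db_mean = mean(davies_bouldin), db_sd = sd(davies_bouldin),
    ch_mean = mean(calinski_harabasz), ch_sd = sd(calinski_harabasz)),
    by = "k"]
  metrics <- metrics[order(metrics$k), ]
  best <- metrics$k[metrics$sil_mean == max(metrics$sil_mean)]
  structure(list(metrics = as.data.frame(metrics),
                 chosen_k = min(best),
                 replicates = replicates, fraction = fraction,
                 skipped = skipped),
            class = "k_selection_report")
}

#' @export
print.k_selection_report <- function(x, ...) {
  cat(sprintf("<k_selection_report> chosen k = %d (%d replicates, %.3g fraction)\n",
              x$chosen_k, x$replicates, x$fraction))
  invisible(x)
}

#' Final K-Means model
#'
#' Standard K-Means with multiple restarts and a fixed seed.
#'
#' @param embeddings Numeric matrix of patient embeddings.
#' @param k Number of clusters (>= 2, from [select_optimal_k()]).
#' @param seed Seed (fixed seed gives identical centroids).
#' @param stratum Optional stratum label ("female"/"male") carried in the
#'   model.
#' @param nstart,iter_max K-Means restarts and iteration cap.
#' @return An object of class `cluster_model` with `k`, `centers`,
#'   `cluster` (training assignments), `stratum`, `seed`.
#' @export
fit_final_kmeans <- function(embeddings, k, seed = 1L, stratum = NULL,
                             nstart = 10, iter_max = 100) {
  assert_that(k >= 2, "k must be at least 2")
  assert_that(k <= nrow(embeddings), "k may not exceed the number of points")
  with_seed(seed, {
    km <- suppressWarnings(kmeans(embeddings, centers = k, nstart = nstart,
                                  iter.max = iter_max))
    structure(list(k = as.integer(k), centers = km$centers,
                   cluster = km$cluster, size = km$size,
                   tot_withinss = km$tot.withinss,
                   stratum = stratum, seed = seed),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d%s, sizes %s\n", x$k,
              if (!is.null(x$stratum)) paste0(" (", x$stratum, ")") else "",
              paste(x$size, collapse = "/")))
  invisible(x)
}

#' Assign points to the nearest centroid
#'
#' @param model A `cluster_model`.
#' @param embeddings Points to assign.
#' @param metric "euclidean" (K-Means geometry) or "cosine" (used for
#'   temporal cohesion, consistent with the cohesion metric).
#' @return Integer cluster labels.
#' @export
assign_clusters <- function(model, embeddings, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  C <- model$centers
  if (metric == "euclidean") {
    d2 <- outer(rowSums(embeddings^2), rep(1, nrow(C))) -
      2 * embeddings %*% t(C) + outer(rep(1, nrow(embeddings)), rowSums(C^2))
    max.col(-d2, ties.method = "first")
  } else {
    s <- cosine_similarity(embeddings, C)
    max.col(s, ties.method = "first")
  }
}

#' Hungarian matching of centroid sets
#'
#' Finds the one-to-one assignment between two equal-sized centroid sets
#' minimising total cosine distance.
#'
#' @param centroids_a,centroids_b Matrices with the same number of rows.
#' @return List with `permutation` (row i of `a` matches row
#'   `permutation[i]` of `b`), `distances` (matched cosine distances) and
#'   `total` cost.
#' @export
hungarian_match <- function(centroids_a, centroids_b) {
  assert_that(nrow(centroids_a) == nrow(centroids_b),
              "centroid sets must have equal size")
  cost <- pmax(1 - cosine_similarity(centroids_a, centroids_b), 0)
  perm <- as.integer(clue::solve_LSAP(cost))
  d <- cost[cbind(seq_len(nrow(cost)), perm)]
  list(permutation = perm, distances = d, total = sum(d))
}

#' Bootstrap stability of the final clusters
#'
#' Refits K-Means at the final k on repeated subsamples, matches each
#' replicate's centroids to the final centroids with the Hungarian
#' algorithm on cosine distances, and reports the median matched distance
#' per final cluster.
#'
#' @param embeddings Full-stratum embedding matrix.
#' @param model The final `cluster_model`.
#' @param replicates Number of replicates (reference setting 100).
#' @param fraction Subsample fraction (reference setting 0.25).
#' @param strata Optional sampling strata for stratified subsampling;
#'   simple random subsampling when `NULL`.
#' @param seed Seed.
#' @return An object of class `stability_report`: data frame `per_cluster`
#'   (cluster, median matched cosine distance) plus the full replicate x
#'   cluster distance matrix.
#' @export
bootstrap_stability <- function(embeddings, model, replicates = 100,
                                fraction = 0.25, strata = NULL, seed = 1L) {
  n <- nrow(embeddings)
  seeds <- derive_seeds(seed, replicates)
  D <- matrix(NA_real_, replicates, model$k)
  for (r in seq_len(replicates)) {
    idx <- if (is.null(strata)) {
      with_seed(seeds[r], sample.int(n, max(model$k, floor(fraction * n))))
    } else {
      stratified_sample(strata, fraction, seed = seeds[r])
    }
    km <- with_seed(seeds[r] + 1L,
                    suppressWarnings(kmeans(embeddings[idx, , drop = FALSE],
                                            centers = model$k, nstart = 5,
                                            iter.max = 50)))
    hm <- hungarian_match(model$centers, km$centers)
    D[r, ] <- hm$distances
  }
  per <- data.frame(cluster = seq_len(model$k),
                    median_cosine_distance = apply(D, 2, median))
  structure(list(per_cluster = per, distances = D,
                 replicates = replicates, fraction = fraction),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d replicates at %.0f%%: median matched distance %.4f (mean over clusters)\n",
              x$replicates, 100 * x$fraction,
              mean(x$per_cluster$median_cosine_distance)))
  invisible(x)
}

#' Splice medical records at an age cutoff
#'
#' Retains events up to and including the cutoff age. A patient is eligible
#' for the cutoff cohort only if they have at least one retained event and
#' at least one record after the cutoff age (a patient whose records stop
#' at age 64 is excluded from the age-65 cohort).
#'
#' @param cohort An `ehr_cohort`.
#' @param age_cutoff Age in completed years.
#' @return An `ehr_cohort` restricted to eligible patients with truncated
#'   events; the excluded patient ids are in `attr(, "ineligible")`.
#' @export
splice_records <- function(cohort, age_cutoff) {
  ev <- merge(cohort$events,
              cohort$demographics[, c("patient_id", "year_of_birth")],
              by = "patient_id")
  ev$age <- as.integer(format(ev$date, "%Y")) - ev$year_of_birth
  byp <- ev[, list(has_before = any(age <= age_cutoff),
                   has_after = any(age > age_cutoff)), by = "patient_id"]
  eligible <- byp$patient_id[byp$has_before & byp$has_after]
  out <- cohort
  keep <- ev$patient_id %in% eligible & ev$age <= age_cutoff
  out$events <- cohort$events[which(keep), ]
  out$demographics <- cohort$demographics[
    cohort$demographics$patient_id %in% eligible, ]
  out$truth <- cohort$truth[cohort$truth$patient_id %in% eligible, ]
  attr(out, "ineligible") <- setdiff(cohort$demographics$patient_id, eligible)
  attr(out, "age_cutoff") <- age_cutoff
  out
}

#' Temporal cohesion of clusters
#'
#' Assigns age-spliced embeddings to the nearest final centroid by cosine
#' distance and compares the per-cluster median cohesion (cosine distance
#' to centroid) with the cohesion of the final clusters.
#'
#' @param age_embeddings Named list (age -> embedding matrix) of embeddings
#'   computed from age-spliced histories.
#' @param model The final `cluster_model`.
#' @param final_embeddings Embeddings of the full histories (cohesion
#'   baseline), rows aligned with `model$cluster`.
#' @return An object of class `temporal_cohesion_report` with `by_age`
#'   (age, cluster, n, median cohesion), `final` (per-cluster baseline),
#'   `difference` (per-cluster mean difference across ages) and the overall
#'   `average_difference`.
#' @export
temporal_cohesion <- function(age_embeddings, model, final_embeddings) {
  cohesion <- function(X, lab) {
    vapply(seq_len(model$k), function(c) {
      m <- X[lab == c, , drop = FALSE]
      if (nrow(m) == 0) return(NA_real_)
      median(1 - as.vector(cosine_similarity(m, rbind(model$centers[c, ]))))
    }, numeric(1))
  }
  fin <- cohesion(final_embeddings, model$cluster)
  final_df <- data.frame(cluster = seq_len(model$k),
                         n = as.vector(table(factor(model$cluster,
                                                    seq_len(model$k)))),
                         median_cohesion = fin)
  rows <- list()
  for (a in names(age_embeddings)) {
    X <- age_embeddings[[a]]
    if (is.null(X) || nrow(X) == 0) {
      message(sprintf("age %s skipped: empty cohort", a))
      next
    }
    lab <- assign_clusters(model, X, metric = "cosine")
    coh <- cohesion(X, lab)
    rows[[a]] <- data.frame(age = as.integer(a), cluster = seq_len(model$k),
                            n = as.vector(table(factor(lab, seq_len(model$k)))),
                            median_cohesion = coh)
  }
  by_age <- do.call(rbind, rows)
  rownames(by_age) <- NULL
  diff_df <- do.call(rbind, lapply(seq_len(model$k), function(c) {
    v <- by_age$median_cohesion[by_age$cluster == c]
    data.frame(cluster = c,
               mean_difference = mean(v - fin[c], na.rm = TRUE))
  }))
  structure(list(by_age = by_age, final = final_df, difference = diff_df,
                 average_difference = mean(abs(diff_df$mean_difference),
                                           na.rm = TRUE)),
            class = "temporal_cohesion_report")
}

#' @export
print.temporal_cohesion_report <- function(x, ...) {
  cat(sprintf("<temporal_cohesion_report> %d ages, average cohesion difference %.4f\n",
              length(unique(x$by_age$age)), x$average_difference))
  invisible(x)
}
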