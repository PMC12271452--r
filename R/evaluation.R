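# Cluster characterisation: disease-frequency--inverse-patient-frequency
# weights (a TF-IDF adaptation), cluster-averaged c-DF-IPF, one-vs-all
# association tests with the signed-Z symbol scheme, observed/expected
# ratios and exclusivity, comorbidity-pair embedding validation and
# cross-gender cluster profile correlation.

#' Build a binary disease matrix
#'
#' Patients x conditions presence matrix over the configured long-term
#' condition list (54 chronic conditions + 3 risk factors by default).
#'
#' @param events Events table (`patient_id`, `code`, diagnosis rows are
#'   used).
#' @param patient_ids Patients to include as rows (default: all in events).
#' @param ltc Condition list (data frame with `code`), default
#'   [default_ltc_list()].
#' @return Binary matrix with patient ids as rownames, condition codes as
#'   colnames.
#' @export
disease_matrix <- function(events, patient_ids = NULL, ltc = default_ltc_list()) {
  ev <- data.table::as.data.table(events)
  code_col <- if ("token" %in% names(ev)) "token" else "code"
  if (is.null(patient_ids)) patient_ids <- sort(unique(ev$patient_id))
  X <- matrix(0L, length(patient_ids), nrow(ltc),
              dimnames = list(patient_ids, ltc$code))
  sel <- ev[[code_col]] %in% ltc$code & ev$patient_id %in% patient_ids
  if (any(sel)) {
    pr <- unique(data.frame(p = ev$patient_id[sel], d = ev[[code_col]][sel]))
    X[cbind(match(pr$p, patient_ids), match(pr$d, ltc$code))] <- 1L
  }
  X
}

#' Disease-frequency--inverse-patient-frequency weights
#'
#' For patient p and disease d:
#' `DF-IPF(d, p) = n_dp / sum_d' n_d'p * log(|P| / |{p in P : d in p}|)`
#' with the natural logarithm; `n_dp` is the 0/1 presence of d in p's
#' record. Entries for absent diseases are zero. Diseases present in no
#' patient are excluded (reported via `attr(, "excluded")`); patients with
#' no diseases get all-zero rows.
#'
#' @param x Binary patients x conditions matrix.
#' @return Numeric matrix of the same shape (minus excluded columns).
#' @export
dfipf <- function(x) {
  assert_that(nrow(x) >= 1, "need at least one patient")
  assert_that(all(x %in% c(0, 1)), "disease matrix must be binary")
  colsum <- colSums(x)
  excluded <- colnames(x)[colsum == 0]
  if (length(excluded)) {
    message(sprintf("excluding %d condition(s) with zero patients: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
    x <- x[, colsum > 0, drop = FALSE]
    colsum <- colsum[colsum > 0]
  }
  rowsum_ <- rowSums(x)
  ipf <- log(nrow(x) / colsum)
  tf <- x / ifelse(rowsum_ == 0, 1, rowsum_)
  out <- sweep(tf, 2, ipf, "*")
  attr(out, "excluded") <- excluded
  attr(out, "presence") <- x == 1
  out
}

#' Cluster-averaged c-DF-IPF weights
#'
#' Averages patient DF-IPF weights within each cluster and scales by the
#' cluster-specific inverse patient frequency
#' `log(|K| / |{clusters containing d}|)` (natural log). A condition
#' present in every cluster gets weight zero everywhere; a condition absent
#' from all clusters is excluded with a message.
#'
#' @param w Patient x condition DF-IPF matrix (from [dfipf()]).
#' @param assignments Cluster label per patient (row).
#' @param K Number of clusters (default: number of distinct labels).
#' @param presence Optional binary patients x conditions presence matrix
#'   used to count the clusters containing each condition; defaults to the
#'   presence recorded by [dfipf()] (a ubiquitous condition has weight zero
#'   but is still present in every cluster).
#' @return `cdfipf_matrix`: clusters x conditions weight matrix.
#' @export
cdfipf <- function(w, assignments, K = NULL, presence = NULL) {
  assert_that(nrow(w) == length(assignments),
              "one assignment per patient row required")
  if (is.null(presence)) presence <- attr(w, "presence")
  if (is.null(presence)) presence <- w > 0
  labs <- sort(unique(assignments))
  if (is.null(K)) K <- length(labs)
  means <- t(vapply(labs, function(l) {
    colMeans(w[assignments == l, , drop = FALSE])
  }, numeric(ncol(w))))
  present <- t(vapply(labs, function(l) {
    colSums(presence[assignments == l, , drop = FALSE]) > 0
  }, logical(ncol(w))))
  if (ncol(w) == 1) {            # vapply collapses single-column matrices
    means <- matrix(means, ncol = 1, dimnames = list(labs, colnames(w)))
    present <- matrix(present, ncol = 1, dimnames = list(labs, colnames(w)))
  }
  n_with <- colSums(present)
  absent <- colnames(w)[n_with == 0]
  if (length(absent)) {
    message(sprintf("excluding %d condition(s) absent from all clusters: %s",
                    length(absent), paste(absent, collapse = ", ")))
    keep <- n_with > 0
    means <- means[, keep, drop = FALSE]
    n_with <- n_with[keep]
  }
  out <- sweep(means, 2, log(K / n_with), "*")
  rownames(out) <- labs
  structure(out, class = c("cdfipf_matrix", "matrix", "array"),
            K = K, excluded = absent)
}

#' Symbol for a signed association Z-score
#'
#' Thresholds: `++` for z >= 50, `+` for 10 <= z < 50, `-` for
#' -50 < z <= -10, `--` for z <= -50, empty otherwise.
#'
#' @param z Numeric vector of signed Z-scores.
#' @return Character vector of symbols.
#' @export
association_symbol <- function(z) {
  ifelse(z >= 50, "++",
         ifelse(z >= 10, "+",
                ifelse(z <= -50, "--",
                       ifelse(z <= -10, "-", ""))))
}

#' One-vs-all chi-squared association tests
#'
#' For each cluster, tests the 2x2 table (in cluster vs rest x variable
#' present/absent) with a 1-df chi-squared test (no continuity correction)
#' and reports the signed Z-score `sign(observed - expected) * sqrt(chi2)`,
#' where the expected in-cluster count comes from the pooled prevalence.
#'
#' @param variable Binary (0/1 or logical) vector, one value per patient.
#' @param assignments Cluster label per patient (>= 2 clusters).
#' @return Data frame per cluster: observed, expected, chi-squared
#'   statistic, signed z, symbol. Zero-margin tables are flagged with
#'   z = 0.
#' @export
chi2_one_vs_all <- function(variable, assignments) {
  v <- as.numeric(variable)
  assert_that(all(v %in% c(0, 1)), "variable must be binary")
  labs <- sort(unique(assignments))
  assert_that(length(labs) >= 2, "need at least two clusters")
  n <- length(v)
  prev <- mean(v)
  out <- do.call(rbind, lapply(labs, function(l) {
    inc <- assignments == l
    obs <- sum(v[inc])
    expct <- prev * sum(inc)
    tab <- matrix(c(obs, sum(inc) - obs,
                    sum(v) - obs, sum(!inc) - (sum(v) - obs)), 2, 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      chi2 <- 0; z <- 0
    } else {
      chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
      z <- sign(obs - expct) * sqrt(unname(chi2))
    }
    data.frame(cluster = l, n = sum(inc), observed = obs, expected = expct,
               chi2 = unname(chi2), z = z, symbol = association_symbol(z),
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-vs-all Welch t-tests
#'
#' Welch two-sample t-test of a continuous variable for each cluster
#' against all other patients.
#'
#' @param variable Numeric vector, one value per patient.
#' @param assignments Cluster label per patient.
#' @return Data frame per cluster: mean in/out, t statistic, p value.
#'   Clusters where both sides have zero variance are flagged with NA
#'   statistics.
#' @export
ttest_one_vs_all <- function(variable, assignments) {
  labs <- sort(unique(assignments))
  out <- do.call(rbind, lapply(labs, function(l) {
    a <- variable[assignments == l]; b <- variable[assignments != l]
    if (length(a) < 2 || length(b) < 2 ||
        (stats::var(a) == 0 && stats::var(b) == 0)) {
      return(data.frame(cluster = l, mean_in = mean(a), mean_out = mean(b),
                        t = NA_real_, p_value = NA_real_, degenerate = TRUE))
    }
    tt <- t.test(a, b)
    data.frame(cluster = l, mean_in = mean(a), mean_out = mean(b),
               t = unname(tt$statistic), p_value = tt$p.value,
               degenerate = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Observed/expected ratios and exclusivity
#'
#' O/E is the in-cluster prevalence of a condition divided by its overall
#' prevalence; exclusivity is the fraction of all carriers of the condition
#' who belong to the cluster (so exclusivity sums to 1 over clusters).
#' Conditions with zero overall prevalence are excluded.
#'
#' @param x Binary patients x conditions matrix.
#' @param assignments Cluster label per patient.
#' @return Long data frame: cluster, condition, observed, expected,
#'   oe_ratio, exclusivity.
#' @export
observed_expected_exclusivity <- function(x, assignments) {
  tot <- colSums(x)
  excl_cols <- colnames(x)[tot == 0]
  if (length(excl_cols)) {
    message(sprintf("excluding %d condition(s) with zero prevalence",
                    length(excl_cols)))
    x <- x[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  prev <- tot / nrow(x)
  labs <- sort(unique(assignments))
  out <- do.call(rbind, lapply(labs, function(l) {
    m <- x[assignments == l, , drop = FALSE]
    obs <- colSums(m)
    data.frame(cluster = l, condition = colnames(x),
               observed = as.integer(obs),
               expected = prev * nrow(m),
               oe_ratio = (obs / nrow(m)) / prev,
               exclusivity = obs / tot, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Comorbidity-pair embedding similarity
#'
#' Cosine similarity between the token input embeddings of established
#' comorbidity pairs, with a comparison distribution over random non-pair
#' couples.
#'
#' @param emb Token embedding matrix (rownames = tokens), from
#'   [token_embeddings()].
#' @param pairs Data frame with columns `a`, `b`.
#' @param n_random Number of random non-pair couples (default 1000).
#' @param seed Seed for the random couples.
#' @return List with `per_pair` (a, b, cosine), `median_pair`,
#'   `random_similarities`, `median_random`; pairs with a missing token are
#'   skipped with a message.
#' @export
comorbidity_similarity <- function(emb, pairs, n_random = 1000, seed = 1L) {
  have <- pairs$a %in% rownames(emb) & pairs$b %in% rownames(emb)
  if (any(!have)) {
    message(sprintf("skipping %d pair(s) with missing embeddings", sum(!have)))
  }
  pr <- pairs[have, , drop = FALSE]
  assert_that(nrow(pr) > 0, "no pairs with embeddings available")
  sims <- vapply(seq_len(nrow(pr)), function(i) {
    cosine_similarity(emb[pr$a[i], ], emb[pr$b[i], ])
  }, numeric(1))
  per_pair <- data.frame(a = pr$a, b = pr$b, cosine = sims,
                         stringsAsFactors = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pair_keys <- key(pr$a, pr$b)
  toks <- rownames(emb)
  rand <- with_seed(seed, {
    out <- numeric(0)
    guard <- 0
    while (length(out) < n_random && guard < 50) {
      i <- sample.int(length(toks), n_random, replace = TRUE)
      j <- sample.int(length(toks), n_random, replace = TRUE)
      ok <- i != j & !(key(toks[i], toks[j]) %in% pair_keys)
      ii <- i[ok]; jj <- j[ok]
      out <- c(out, vapply(seq_along(ii), function(q) {
        cosine_similarity(emb[ii[q], ], emb[jj[q], ])
      }, numeric(1)))
      guard <- guard + 1
    }
    out[seq_len(min(length(out), n_random))]
  })
  list(per_pair = per_pair, median_pair = median(sims),
       random_similarities = rand, median_random = median(rand))
}

#' Cross-gender cluster profile correlation
#'
#' Pearson correlation between every female cluster's c-DF-IPF condition
#' profile and every male cluster's profile, over the shared condition
#' columns.
#'
#' @param cdfipf_female,cdfipf_male `cdfipf_matrix` objects.
#' @return Matrix (female clusters x male clusters) of correlations;
#'   constant profiles give NA with a message.
#' @export
crossgender_similarity <- function(cdfipf_female, cdfipf_male) {
  shared <- intersect(colnames(cdfipf_female), colnames(cdfipf_male))
  assert_that(length(shared) >= 3, "need at least three shared conditions")
  Fm <- cdfipf_female[, shared, drop = FALSE]
  Mm <- cdfipf_male[, shared, drop = FALSE]
  out <- matrix(NA_real_, nrow(Fm), nrow(Mm),
                dimnames = list(rownames(Fm), rownames(Mm)))
  for (i in seq_len(nrow(Fm))) {
    for (j in seq_len(nrow(Mm))) {
      if (sd(Fm[i, ]) == 0 || sd(Mm[j, ]) == 0) {
        message(sprintf("constant profile: female %s / male %s", i, j))
        next
      }
      out[i, j] <- cor(Fm[i, ], Mm[j, ])
    }
  }
  out
}
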