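# Shared fixtures and independent oracles, built in code at test time.

# Desk-scale trained encoder fixture: a 500-patient single-stratum cohort,
# replaced-token-detection pretraining at the desk defaults and contrastive
# fine-tuning. Trained once per test run and memoised (several tests share
# it).
.fixtures <- new.env(parent = emptyenv())
trained_fixture <- function() {
  if (is.null(.fixtures$trained)) {
    co <- generate_cohort(cohort_config(n_patients = 500, prop_female = 1,
                                        seed = 21))
    sq <- cohort_to_sequences(co, min_patient_count = 5)
    cfg <- desk_model_config()
    pt <- rtd_pretrain(sq$sequences, sq$vocab, cfg, seed = 11)
    ft <- diffcse_finetune(pt$generator, sq$sequences, sq$vocab, seed = 5)
    emb <- embed_patients(ft$encoder, sq$sequences, sq$vocab)
    .fixtures$trained <- list(cohort = co, seqdata = sq, pretrained = pt,
                              finetuned = ft, embeddings = emb)
  }
  .fixtures$trained
}

# Small hand vocabulary for encoder tests.
tiny_vocab <- function(tokens = c("a", "b", "c", "d")) {
  special <- c("[PAD]", "[MASK]", "[CLS]", "[SEP]", "[UNK]")
  all <- c(special, tokens)
  structure(list(tokens = all,
                 index = setNames(seq_along(all), all),
                 special = setNames(seq_along(special), special),
                 patient_counts = setNames(rep(1000L, length(tokens)), tokens),
                 min_patient_count = 1L),
            class = "ehr_vocabulary")
}

# Hand-built sequence for encoder tests.
tiny_sequence <- function(ids, gender = "female") {
  n <- length(ids)
  list(patient_id = "p1", token_ids = as.integer(ids),
       tokens = rep("x", n),
       age_years = as.integer(seq(50, length.out = n)),
       calendar_year = as.integer(seq(2000, length.out = n)),
       visit_number = seq_len(n), gender = gender)
}

# Random length-64 synthetic sequences over a tiny vocabulary.
random_sequences <- function(n, len = 64, vocab = tiny_vocab(), seed = 1) {
  ns <- length(vocab$special)
  V <- length(vocab$tokens)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- tiny_sequence(sample((ns + 1):V, len, replace = TRUE))
      s$patient_id <- sprintf("p%05d", i)
      s
    })
  })
}

# Brute-force DF-IPF oracle: literal evaluation of the weight definition,
# element by element, independent of the vectorised implementation.
dfipf_oracle <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x), dimnames = dimnames(x))
  for (p in seq_len(n)) {
    total <- sum(x[p, ])
    for (d in seq_len(ncol(x))) {
      if (x[p, d] == 1) {
        carriers <- sum(x[, d])
        out[p, d] <- (1 / total) * log(n / carriers)
      }
    }
  }
  out
}

# Brute-force c-DF-IPF oracle over cluster assignments; condition presence
# per cluster is taken literally from the binary disease matrix.
cdfipf_oracle <- function(w, assignments, x) {
  labs <- sort(unique(assignments))
  K <- length(labs)
  out <- matrix(0, K, ncol(w), dimnames = list(labs, colnames(w)))
  for (d in seq_len(ncol(w))) {
    in_k <- vapply(labs, function(l) any(x[assignments == l, d] == 1),
                   logical(1))
    if (!any(in_k)) next
    for (ki in seq_len(K)) {
      m <- mean(w[assignments == labs[ki], d])
      out[ki, d] <- m * log(K / sum(in_k))
    }
  }
  out
}

# Exhaustive assignment oracle for small k.
brute_force_assignment <- function(cost) {
  k <- nrow(cost)
  perms <- gtools_permutations(k)
  best <- NULL; best_cost <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    tc <- sum(cost[cbind(seq_len(k), p)])
    if (tc < best_cost) {
      best_cost <- tc; best <- p
    }
  }
  list(permutation = best, total = best_cost)
}

# All permutations of 1..k (k <= 7), without extra packages.
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Gaussian mixture embeddings with planted component labels. Components
# have per-coordinate sd `sd_within`; centers are resampled until every
# pairwise centroid distance is at least `sep` times the within-component
# spread (sd_within * sqrt(dim)), i.e. well separated.
gaussian_embeddings <- function(n, G, dim = 16, sep = 5, sd_within = 1,
                                seed = 1) {
  withr::with_seed(seed, {
    spread <- sd_within * sqrt(dim)
    centers <- matrix(0, G, dim)
    for (g in seq_len(G)) {
      repeat {
        cand <- rnorm(dim, sd = sep * spread / sqrt(dim))
        if (g == 1) { centers[g, ] <- cand; break }
        dmin <- min(sqrt(rowSums(sweep(centers[seq_len(g - 1), , drop = FALSE],
                                       2, cand)^2)))
        if (dmin >= sep * spread) { centers[g, ] <- cand; break }
      }
    }
    lab <- sample.int(G, n, replace = TRUE)
    X <- centers[lab, ] + matrix(rnorm(n * dim, sd = sd_within), n, dim)
    list(x = X, labels = lab, centers = centers)
  })
}
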