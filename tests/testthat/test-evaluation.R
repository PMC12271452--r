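test_that("DF-IPF matches hand evaluation of the weight definition", {
  # 4 patients; disease d1 only in patient 1, who has two diseases
  x <- matrix(0, 4, 3, dimnames = list(paste0("p", 1:4), c("d1", "d2", "d3")))
  x["p1", c("d1", "d2")] <- 1
  x["p2", "d2"] <- 1; x["p3", "d2"] <- 1; x["p4", "d3"] <- 1
  w <- dfipf(x)
  expect_equal(w["p1", "d1"], 0.5 * log(4), tolerance = 1e-12)
  # a patient with a single disease carried by exactly 1 of |P| patients
  expect_equal(w["p4", "d3"], log(4), tolerance = 1e-12)
  # ubiquitous disease weighs zero for everyone
  xu <- cbind(x, all = 1)
  wu <- dfipf(xu)
  expect_true(all(wu[, "all"] == 0))
})

test_that("DF-IPF and c-DF-IPF equal brute-force evaluation on random matrices", {
  withr::with_seed(19, {
    for (i in 1:100) {
      x <- matrix(rbinom(20 * 10, 1, 0.35), 20, 10,
                  dimnames = list(paste0("p", 1:20), paste0("d", 1:10)))
      x[1, ] <- pmax(x[1, ], 1)            # avoid all-zero columns quirk
      keep <- colSums(x) > 0
      x <- x[, keep, drop = FALSE]
      w <- dfipf(x)
      expect_equal(unclass(w)[, ], dfipf_oracle(x)[, ], tolerance = 1e-12)
      cl <- sample(1:3, 20, replace = TRUE)
      cl[1:3] <- 1:3
      cw <- suppressMessages(cdfipf(w, cl))
      orc <- cdfipf_oracle(w, cl, x)
      expect_equal(unclass(cw)[, colnames(cw)], orc[, colnames(cw)],
                   tolerance = 1e-12)
    }
  })
})

test_that("c-DF-IPF limits behave as the definition requires", {
  x <- matrix(1, 5, 2, dimnames = list(paste0("p", 1:5), c("d1", "d2")))
  x[1:2, "d2"] <- 0
  w <- dfipf(x)
  # a single cluster gives log(1/1) = 0 everywhere
  cw1 <- cdfipf(w, rep(1, 5))
  expect_true(all(cw1 == 0))
  # condition in all clusters weighs zero in every cluster
  cl <- c(1, 1, 2, 2, 2)
  cw <- cdfipf(w, cl)
  expect_true(all(cw[, "d1"] == 0))
  # K=2, condition only in cluster 2: weight = mean DF-IPF * ln 2
  m2 <- mean(w[cl == 2, "d2"])
  expect_equal(unname(cw["2", "d2"]), m2 * log(2), tolerance = 1e-12)
  expect_equal(unname(cw["1", "d2"]), 0)
})

test_that("one-vs-all chi-squared agrees with the contingency-table oracle", {
  # cluster of 100 with 30 cases vs rest of 900 with 90 cases
  assignments <- rep(c(1, 2), c(100, 900))
  v <- c(rep(1, 30), rep(0, 70), rep(1, 90), rep(0, 810))
  res <- chi2_one_vs_all(v, assignments)
  tab <- matrix(c(30, 70, 90, 810), 2, byrow = TRUE)
  ref <- chisq.test(tab, correct = FALSE)
  r1 <- res[res$cluster == 1, ]
  expect_equal(r1$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r1$z, sqrt(unname(ref$statistic)) * sign(30 - 100 * 0.12),
               tolerance = 1e-10)
  # z^2 equals the 1-df statistic on random tables
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- 400
      cl <- sample(1:3, n, replace = TRUE)
      vv <- rbinom(n, 1, 0.3)
      rr <- chi2_one_vs_all(vv, cl)
      expect_equal(rr$z^2, rr$chi2, tolerance = 1e-10)
    }
  })
})

test_that("observed equal to expected gives z = 0 and no symbol", {
  v <- rep(c(1, 0, 0, 1), 25)
  cl <- rep(1:2, 50)          # both clusters have exactly half the cases
  res <- chi2_one_vs_all(v, cl)
  expect_equal(res$z, c(0, 0))
  expect_equal(res$symbol, c("", ""))
})

test_that("association symbols switch exactly at the published thresholds", {
  z <- c(50, 49.999, 10, 9.999, 0, -9.999, -10, -49.999, -50)
  expect_equal(association_symbol(z),
               c("++", "+", "+", "", "", "", "-", "-", "--"))
})

test_that("one-vs-all Welch t-tests match the direct computation", {
  a <- c(5.1, 4.8, 5.6, 5.0, 4.9)
  b <- c(4.0, 4.2, 3.9, 4.4, 4.1)
  res <- ttest_one_vs_all(c(a, b), rep(1:2, each = 5))
  # Welch statistic computed from first principles
  tref <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(res$t[res$cluster == 1], tref, tolerance = 1e-12)
  expect_equal(res$t[res$cluster == 2], -tref, tolerance = 1e-12)
  # identical distributions give t near zero
  same <- rep(c(1, 2, 3, 4), 20)
  r0 <- ttest_one_vs_all(same, rep(1:2, each = 40))
  expect_lt(abs(r0$t[1]), 1e-10)
  # a location shift grows the statistic with sample size
  withr::with_seed(3, {
    t_small <- abs(ttest_one_vs_all(c(rnorm(20) + 1, rnorm(20)),
                                    rep(1:2, each = 20))$t[1])
    t_large <- abs(ttest_one_vs_all(c(rnorm(500) + 1, rnorm(500)),
                                    rep(1:2, each = 500))$t[1])
    expect_gt(t_large, t_small)
  })
})

test_that("observed/expected ratios and exclusivity follow the counting rules", {
  x <- matrix(0, 12, 2, dimnames = list(paste0("p", 1:12), c("d1", "d2")))
  cl <- rep(1:3, each = 4)
  x[c(1, 5, 9), "d1"] <- 1           # uniform prevalence across clusters
  x[1:4, "d2"] <- 1                  # concentrated in cluster 1
  res <- observed_expected_exclusivity(x, cl)
  d1 <- res[res$condition == "d1", ]
  expect_equal(d1$oe_ratio, rep(1, 3), tolerance = 1e-12)
  d2 <- res[res$condition == "d2", ]
  expect_equal(d2$exclusivity[d2$cluster == 1], 1)
  expect_equal(d2$exclusivity[d2$cluster != 1], c(0, 0))
  # exclusivity sums to 1 per condition; size-weighted O/E averages to 1
  withr::with_seed(5, {
    xr <- matrix(rbinom(60 * 4, 1, 0.4), 60, 4,
                 dimnames = list(NULL, paste0("c", 1:4)))
    clr <- sample(1:3, 60, replace = TRUE)
    rr <- observed_expected_exclusivity(xr, clr)
    for (cc in unique(rr$condition)) {
      sub <- rr[rr$condition == cc, ]
      expect_equal(sum(sub$exclusivity), 1, tolerance = 1e-12)
      wts <- table(clr)[as.character(sub$cluster)] / length(clr)
      expect_equal(sum(sub$oe_ratio * wts), 1, tolerance = 1e-12)
    }
  })
})

test_that("comorbidity-pair similarity behaves on trivial geometry", {
  emb <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(1, 0, 0))
  same <- comorbidity_similarity(emb, data.frame(a = "a", b = "a"),
                                 n_random = 10, seed = 1)
  expect_equal(same$per_pair$cosine, 1)
  orth <- comorbidity_similarity(emb, data.frame(a = "a", b = "b"),
                                 n_random = 10, seed = 1)
  expect_equal(orth$per_pair$cosine, 0)
  expect_message(
    comorbidity_similarity(emb, data.frame(a = c("a", "zz"), b = c("c", "a")),
                           n_random = 10, seed = 1),
    "missing")
})

test_that("cross-gender profile correlation is Pearson over shared conditions", {
  f <- matrix(c(1, 2, 3, 4, 5,
                0, 0.5, 1, 1.5, 2), 2, 5, byrow = TRUE,
              dimnames = list(1:2, paste0("d", 1:5)))
  m <- matrix(c(1, 2, 3, 4, 5,
                -1, -2, -3, -4, -5), 2, 5, byrow = TRUE,
              dimnames = list(1:2, paste0("d", 1:5)))
  cc <- crossgender_similarity(f, m)
  expect_equal(cc[1, 1], 1, tolerance = 1e-12)
  expect_equal(cc[1, 2], -1, tolerance = 1e-12)
  v1 <- c(0.2, 0.9, 0.1, 0.5, 0.4); v2 <- c(0.3, 0.1, 0.8, 0.2, 0.6)
  f2 <- rbind(`1` = v1); colnames(f2) <- paste0("d", 1:5)
  m2 <- rbind(`1` = v2); colnames(m2) <- paste0("d", 1:5)
  expect_equal(crossgender_similarity(f2, m2)[1, 1], cor(v1, v2),
               tolerance = 1e-12)
})

test_that("disease matrix restricts to the condition list", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 31))
  X <- disease_matrix(co$events, patient_ids = co$demographics$patient_id)
  expect_equal(ncol(X), nrow(default_ltc_list()))
  expect_true(all(X %in% 0:1))
  expect_setequal(rownames(X), co$demographics$patient_id)
  # medication and symptom codes never enter the disease matrix
  expect_false(any(c("statins", "R05") %in% colnames(X)))
})
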