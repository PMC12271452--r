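small_cfg <- function(...) {
  model_config(hidden_size = 8, discriminator_layers = 2, generator_layers = 2,
               attention_heads = 2, ffn_size = 12, max_len = 8,
               dropout = 0, batch_size = 4, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(model_config(hidden_size = 10, attention_heads = 4),
               "divisible")
  expect_error(model_config(mask_rate = 0), "\\(0, 1\\)")
  expect_error(model_config(mask_rate = 1), "\\(0, 1\\)")
  expect_error(model_config(generator_layers = 7, discriminator_layers = 6),
               "deeper")
})

test_that("initialisation is deterministic and the forward pass has the contracted shape", {
  v <- tiny_vocab()
  cfg <- small_cfg(seed = 5)
  m1 <- init_model(cfg, v)
  m2 <- init_model(cfg, v)
  expect_identical(m1$generator$params, m2$generator$params)
  expect_identical(m1$discriminator$params, m2$discriminator$params)
  s <- tiny_sequence(c(6, 7, 8, 9, 6, 7, 8, 9))
  inp <- make_model_input(s, v, m1$config)
  fw <- nn_forward(m1$generator, inp)
  expect_equal(dim(fw$H), c(9, 8))     # 8 events + CLS, hidden 8
  expect_true(all(is.finite(fw$H)))
})

test_that("analytic gradients match finite differences", {
  v <- tiny_vocab()
  cfg <- small_cfg(seed = 3)
  withr::with_seed(2, {
    mod <- init_model(cfg, v)
    gen <- mod$generator
    s <- tiny_sequence(c(6, 7, 8, 9, 6))
    inp <- make_model_input(s, v, cfg)
    pos <- c(2L, 4L); targets <- c(7L, 9L)
    loss_fn <- function(enc) {
      fw <- nn_forward(enc, inp, training = FALSE)
      mlm_head(enc, fw$H, pos, targets)$loss
    }
    gr <- new_grad_env()
    fw <- nn_forward(gen, inp, training = FALSE)
    ml <- mlm_head(gen, fw$H, pos, targets, gr = gr)
    nn_backward(gen, fw$cache, ml$dH, gr)
    h <- 1e-5
    for (nm in ls(gr)) {
      g <- gr[[nm]]
      idx <- if (length(g) <= 2) seq_along(g) else sample.int(length(g), 2)
      for (i in idx) {
        e1 <- gen; e1$params[[nm]][i] <- e1$params[[nm]][i] + h
        e2 <- gen; e2$params[[nm]][i] <- e2$params[[nm]][i] - h
        num <- (loss_fn(e1) - loss_fn(e2)) / (2 * h)
        expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-4), 1e-3,
                  label = sprintf("gradient of %s[%d]", nm, i))
      }
    }
  })
})

test_that("discriminator gradients flow into the delta table, not the shared one", {
  v <- tiny_vocab()
  cfg <- small_cfg(seed = 9)
  mod <- init_model(cfg, v)
  s <- tiny_sequence(c(6, 7, 8))
  inp <- make_model_input(s, v, cfg)
  gr <- new_grad_env()
  fw <- nn_forward(mod$discriminator, inp, training = FALSE,
                   shared_E = mod$generator$params$E_tok)
  rl <- rtd_head_weighted(mod$discriminator, fw$H, c(0, 1, 0, 0), gr)
  nn_backward(mod$discriminator, fw$cache, rl$dH, gr)
  expect_true(!is.null(gr$E_delta))
  expect_null(gr$E_tok)
})

test_that("dynamic masking hits the configured rate and never touches special tokens", {
  v <- tiny_vocab(letters)
  seqs <- random_sequences(2000, len = 64, vocab = v, seed = 4)
  expect_error(dynamic_mask(seqs, v, rate = 0), "\\(0, 1\\)")
  mk <- dynamic_mask(seqs, v, rate = 0.15, seed = 8)
  fracs <- vapply(seq_along(seqs), function(i) {
    length(mk[[i]]$positions) / length(seqs[[i]]$token_ids)
  }, numeric(1))
  se <- sqrt(0.15 * 0.85 / (2000 * 64))
  expect_lt(abs(mean(fracs) - 0.15), 3 * se)
  # masked ids only at the selected positions, and MASK substituted there
  i <- 1
  expect_true(all(mk[[i]]$masked_ids[mk[[i]]$positions] == v$special[["[MASK]"]]))
  expect_equal(mk[[i]]$masked_ids[-mk[[i]]$positions],
               seqs[[i]]$token_ids[-mk[[i]]$positions])
  # a length-1 sequence always has its single position masked
  one <- list(tiny_sequence(7))
  mk1 <- dynamic_mask(one, v, rate = 0.15, seed = 2)
  expect_equal(mk1[[1]]$positions, 1L)
  # UNK (a special token) is never masked when real tokens are present
  su <- tiny_sequence(c(5, 6, 5, 7))
  mku <- dynamic_mask(list(su), v, rate = 0.9, seed = 3)
  expect_false(any(mku[[1]]$positions %in% c(1, 3)))
})

test_that("embeddings are deterministic in evaluation mode and channel-sensitive", {
  v <- tiny_vocab()
  cfg <- small_cfg(seed = 7)
  mod <- init_model(cfg, v)
  s1 <- tiny_sequence(c(6, 7, 8, 9), gender = "female")
  s2 <- tiny_sequence(c(6, 7, 8, 9), gender = "male")
  s2$patient_id <- "p2"
  e1 <- embed_patients(mod$generator, structure(list(s1, s2),
                                                class = "sequence_set"), v)
  e2 <- embed_patients(mod$generator, structure(list(s1, s2),
                                                class = "sequence_set"), v)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 2)
  # same events, different gender: the gender channel changes the embedding
  expect_gt(sqrt(sum((e1["p1", ] - e1["p2", ])^2)), 1e-6)
})

test_that("token embeddings cover the non-special vocabulary", {
  v <- tiny_vocab(c("x", "y", "z"))
  cfg <- small_cfg(seed = 1)
  mod <- init_model(cfg, v)
  te <- token_embeddings(mod$generator, v)
  expect_equal(rownames(te), c("x", "y", "z"))
  expect_equal(cosine_similarity(te["x", ], te["x", ]), 1, tolerance = 1e-12)
})

test_that("short replaced-token-detection training reduces both losses", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 33))
  sq <- cohort_to_sequences(co, min_patient_count = 3)
  cfg <- desk_model_config(pretrain_epochs = 4, pretrain_lr = 2e-3)
  pt <- rtd_pretrain(sq$sequences, sq$vocab, cfg, seed = 13)
  expect_equal(nrow(pt$history), 4)
  expect_lt(pt$history$combined_loss[4], pt$history$combined_loss[1])
  expect_true(all(is.finite(pt$history$combined_loss)))
  expect_error(rtd_pretrain(list(), sq$vocab, cfg), "empty corpus")

  # an uncorrupted batch is all-original: detection loss equals the BCE
  # against the all-original labels
  s <- sq$sequences[[1]]
  inp <- make_model_input(s, sq$vocab, cfg)
  fw <- nn_forward(pt$discriminator, inp, training = FALSE,
                   shared_E = pt$generator$params$E_tok)
  lab0 <- rep(0, inp$L)
  rl <- rtd_head_weighted(pt$discriminator, fw$H, lab0, new_grad_env())
  pr <- rl$probs
  expect_equal(rl$loss, -mean(log(1 - pr)), tolerance = 1e-10)

  # contrastive fine-tuning: invalid lambda rejected; lambda = 0 reduces to
  # the pure contrastive objective; the loss does not increase over epochs
  expect_error(diffcse_finetune(pt$generator, sq$sequences, sq$vocab,
                                lambda = -1), "non-negative")
  ft0 <- diffcse_finetune(pt$generator, sq$sequences, sq$vocab,
                          lambda = 0, epochs = 2, seed = 3)
  expect_equal(ft0$history$crtd_loss, c(0, 0))
  expect_equal(ft0$history$total_loss, ft0$history$contrastive_loss,
               tolerance = 1e-12)
  ft <- diffcse_finetune(pt$generator, sq$sequences, sq$vocab,
                         epochs = 3, seed = 4)
  expect_lte(tail(ft$history$total_loss, 1), ft$history$total_loss[1])
})

test_that("generator prediction on a two-token vocabulary reaches the majority baseline", {
  v <- tiny_vocab(c("maj", "min"))
  # 80/20 mixture of the two tokens
  withr::with_seed(6, {
    seqs <- lapply(1:60, function(i) {
      s <- tiny_sequence(ifelse(runif(16) < 0.8, 6L, 7L))
      s$patient_id <- sprintf("p%03d", i)
      s
    })
  })
  cfg <- model_config(hidden_size = 16, discriminator_layers = 2,
                      generator_layers = 1, attention_heads = 2,
                      ffn_size = 32, max_len = 16, pretrain_epochs = 6,
                      pretrain_lr = 2e-3, batch_size = 16, dropout = 0,
                      seed = 2)
  pt <- rtd_pretrain(structure(seqs, class = "sequence_set"), v, cfg, seed = 2)
  mk <- dynamic_mask(seqs, v, 0.15, seed = 9)
  correct <- 0; total <- 0
  for (i in seq_along(seqs)) {
    sm <- seqs[[i]]; sm$token_ids <- mk[[i]]$masked_ids
    inp <- make_model_input(sm, v, cfg)
    fw <- nn_forward(pt$generator, inp, training = FALSE)
    pos <- mk[[i]]$positions + 1L
    ml <- mlm_head(pt$generator, fw$H, pos, seqs[[i]]$token_ids[mk[[i]]$positions])
    pred <- max.col(ml$probs)
    correct <- correct + sum(pred == seqs[[i]]$token_ids[mk[[i]]$positions])
    total <- total + length(pos)
  }
  maj <- mean(unlist(lapply(seqs, `[[`, "token_ids")) == 6L)
  expect_gte(correct / total, maj - 0.05)
})
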