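# Training procedures for the encoder: replaced-token-detection pretraining
# (generator + discriminator trained simultaneously, shared token embeddings
# with gradient-disentangled sharing) and contrastive fine-tuning that makes
# patient embeddings invariant to dropout-noise views while staying
# sensitive to generator-made event edits.

#' Dynamic masking
#'
#' Independently selects each non-special position of every sequence with
#' probability `rate`, redrawing the selection at every call (dynamic
#' masking); at least one position is always selected per non-empty
#' sequence.
#'
#' @param sequences A `sequence_set` (or list with `token_ids` elements).
#' @param vocab The vocabulary (to identify special tokens and the MASK id).
#' @param rate Masking rate, strictly inside (0, 1).
#' @param seed Optional seed for reproducibility.
#' @return A list per sequence with `positions` (1-based, into the event
#'   sequence) and `masked_ids` (token ids with MASK substituted).
#' @export
dynamic_mask <- function(sequences, vocab, rate = 0.15, seed = NULL) {
  assert_that(rate > 0 && rate < 1, "masking rate must be in (0, 1)")
  mask_id <- vocab$special[["[MASK]"]]
  n_special <- length(vocab$special)
  with_seed(seed, {
    lapply(sequences, function(s) {
      ids <- s$token_ids
      n <- length(ids)
      if (n == 0) return(list(positions = integer(), masked_ids = ids))
      cand <- which(ids > n_special)
      if (!length(cand)) cand <- seq_len(n)
      sel <- cand[runif(length(cand)) < rate]
      if (!length(sel)) sel <- cand[sample.int(length(cand), 1L)]
      m <- ids; m[sel] <- mask_id
      list(positions = sort(sel), masked_ids = m)
    })
  })
}

# Sample replacement tokens from the generator's predictive distribution at
# the masked positions (special tokens excluded from sampling).
sample_replacements <- function(probs, vocab) {
  ns <- length(vocab$special)
  V <- ncol(probs)
  vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    p[seq_len(ns)] <- 0
    if (sum(p) <= 0) p[(ns + 1L):V] <- 1
    sample.int(V, 1L, prob = p)
  }, integer(1))
}

batch_indices <- function(n, batch_size) {
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  # fold a trailing singleton into the previous batch (contrastive terms
  # need at least two sequences)
  if (length(idx) > 1 && length(idx[[length(idx)]]) == 1) {
    idx[[length(idx) - 1]] <- c(idx[[length(idx) - 1]], idx[[length(idx)]])
    idx[[length(idx)]] <- NULL
  }
  idx
}

#' Replaced-token-detection pretraining
#'
#' Trains the generator on masked-token prediction and the discriminator on
#' per-position original/replaced labels over generator-corrupted
#' sequences; both models update simultaneously. The discriminator reads
#' the generator's token embedding table plus its own delta table, and its
#' gradients flow only into the delta (gradient-disentangled embedding
#' sharing).
#'
#' @param sequences A non-empty `sequence_set`.
#' @param vocab The vocabulary.
#' @param config A [model_config()].
#' @param seed Optional override of `config$seed`.
#' @param init Optional result of a previous [rtd_pretrain()] call to
#'   resume training from (its generator/discriminator replace the fresh
#'   initialisation).
#' @param verbose Print per-epoch losses.
#' @return List with `generator`, `discriminator`, `config`, `vocab` and
#'   `history` (per-epoch masked-prediction, detection and combined loss).
#' @export
rtd_pretrain <- function(sequences, vocab, config, seed = NULL,
                         init = NULL, verbose = FALSE) {
  assert_that(length(sequences) > 0, "cannot pretrain on an empty corpus")
  sequences <- Filter(function(s) length(s$token_ids) > 0, sequences)
  assert_that(length(sequences) > 0, "cannot pretrain on an empty corpus")
  model <- if (is.null(init)) init_model(config, vocab, seed = seed) else {
    cfg0 <- config
    cfg0$vocab_size <- vocab_size(vocab)
    list(generator = init$generator, discriminator = init$discriminator,
         config = cfg0)
  }
  gen <- model$generator; dis <- model$discriminator
  cfg <- model$config
  st_gen <- adam_state(); st_dis <- adam_state()
  hist <- data.frame(epoch = integer(), mlm_loss = numeric(),
                     rtd_loss = numeric(), combined_loss = numeric())
  with_seed((seed %||% cfg$seed) + 1L, {
    for (ep in seq_len(cfg$pretrain_epochs)) {
      ord <- sample.int(length(sequences))
      ep_mlm <- 0; ep_rtd <- 0; nb <- 0
      for (bi in batch_indices(length(ord), cfg$batch_size)) {
        gr_gen <- new_grad_env(); gr_dis <- new_grad_env()
        b_mlm <- 0; b_rtd <- 0
        masks <- dynamic_mask(sequences[ord[bi]], vocab, cfg$mask_rate)
        for (k in seq_along(bi)) {
          s <- sequences[[ord[bi[k]]]]
          mk <- masks[[k]]
          sm <- s; sm$token_ids <- mk$masked_ids
          inp_g <- make_model_input(sm, vocab, cfg)
          fw_g <- nn_forward(gen, inp_g, training = TRUE)
          pos <- mk$positions + 1L            # offset for CLS
          targets <- s$token_ids[mk$positions]
          ml <- mlm_head(gen, fw_g$H, pos, targets, gr = gr_gen)
          nn_backward(gen, fw_g$cache, ml$dH, gr_gen)
          b_mlm <- b_mlm + ml$loss

          repl <- sample_replacements(ml$probs, vocab)
          sc <- s
          sc$token_ids[mk$positions] <- repl
          labels <- rep(0, length(sc$token_ids) + 1L)
          labels[pos] <- as.numeric(repl != targets)
          inp_d <- make_model_input(sc, vocab, cfg)
          fw_d <- nn_forward(dis, inp_d, training = TRUE,
                             shared_E = gen$params$E_tok)
          rl <- rtd_head_weighted(dis, fw_d$H, labels, gr_dis,
                                  weight = cfg$rtd_loss_weight)
          nn_backward(dis, fw_d$cache, rl$dH, gr_dis)
          b_rtd <- b_rtd + rl$loss
        }
        nbk <- length(bi)
        gen$params <- adam_step(gen$params, gr_gen, st_gen,
                                lr = cfg$pretrain_lr, scale = 1 / nbk)
        dis$params <- adam_step(dis$params, gr_dis, st_dis,
                                lr = cfg$pretrain_lr, scale = 1 / nbk)
        ep_mlm <- ep_mlm + b_mlm / nbk
        ep_rtd <- ep_rtd + b_rtd / nbk
        nb <- nb + 1
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, mlm_loss = ep_mlm / nb, rtd_loss = ep_rtd / nb,
        combined_loss = ep_mlm / nb + cfg$rtd_loss_weight * ep_rtd / nb))
      if (verbose) {
        message(sprintf("epoch %d: mlm %.4f rtd %.4f", ep,
                        ep_mlm / nb, ep_rtd / nb))
      }
    }
  })
  list(generator = gen, discriminator = dis, config = cfg, vocab = vocab,
       history = hist)
}

# RTD head with loss weighting applied to the gradients (reported loss is
# the unweighted binary cross-entropy).
rtd_head_weighted <- function(enc, Hmat, labels, gr, weight = 1) {
  p <- enc$params
  s <- as.vector(Hmat %*% p$w_rtd) + p$b_rtd
  pr <- 1 / (1 + exp(-s))
  loss <- -mean(labels * log(pmax(pr, 1e-12)) +
                (1 - labels) * log(pmax(1 - pr, 1e-12)))
  ds <- weight * (pr - labels) / length(labels)
  gw <- as.vector(t(Hmat) %*% ds)
  gr$w_rtd <- if (is.null(gr$w_rtd)) gw else gr$w_rtd + gw
  gr$b_rtd <- if (is.null(gr$b_rtd)) sum(ds) else gr$b_rtd + sum(ds)
  list(loss = loss, probs = pr, dH = outer(ds, p$w_rtd))
}

#' Contrastive fine-tuning of the pretrained encoder
#'
#' Fine-tunes the pretrained generator encoder so that the pooled
#' patient embedding is invariant to dropout-noise views (temperature-scaled
#' cosine contrastive term over in-batch negatives) while remaining
#' sensitive to generator-made event edits (a conditional replaced-token
#' detection term weighted by `lambda`, whose gradient reaches the encoder
#' only through the conditioning embedding). The edit generator is frozen.
#'
#' @param encoder The pretrained generator encoder (role "generator").
#' @param sequences A `sequence_set`.
#' @param vocab The vocabulary.
#' @param generator Frozen edit generator (defaults to a copy of `encoder`
#'   before fine-tuning).
#' @param temperature,lambda,epochs,lr Override the corresponding
#'   `diffcse_*` configuration entries.
#' @param seed Optional seed.
#' @param verbose Print per-epoch losses.
#' @return List with the fine-tuned `encoder` and a per-epoch `history`.
#' @export
diffcse_finetune <- function(encoder, sequences, vocab, generator = NULL,
                             temperature = NULL, lambda = NULL,
                             epochs = NULL, lr = NULL, seed = NULL,
                             verbose = FALSE) {
  cfg <- encoder$cfg
  temperature <- temperature %||% cfg$diffcse_temperature
  lambda <- lambda %||% cfg$diffcse_lambda
  epochs <- epochs %||% cfg$diffcse_epochs
  lr <- lr %||% cfg$diffcse_lr
  assert_that(lambda >= 0, "lambda must be non-negative")
  assert_that(temperature > 0, "temperature must be positive")
  sequences <- Filter(function(s) length(s$token_ids) > 0, sequences)
  assert_that(length(sequences) > 1, "need at least two non-empty sequences")
  if (is.null(generator)) generator <- encoder   # frozen copy for edits
  H <- cfg$hidden_size
  with_seed(seed %||% (cfg$seed + 17L), {
    # conditional-detection probe parameters live alongside the encoder's
    E0 <- encoder$params$E_tok                  # frozen lookup for the probe
    encoder$params$cd_W1 <- nn_mat(2L * H, H)
    encoder$params$cd_b1 <- rep(0, H)
    encoder$params$cd_w2 <- rep(0, H)
    encoder$params$cd_b2 <- 0
    st <- adam_state()
    hist <- data.frame(epoch = integer(), contrastive_loss = numeric(),
                       crtd_loss = numeric(), total_loss = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(sequences))
      ep_c <- 0; ep_r <- 0; nb <- 0
      for (bi in batch_indices(length(ord), cfg$batch_size)) {
        B <- length(bi)
        gr <- new_grad_env()
        fw1 <- vector("list", B); fw2 <- vector("list", B)
        Z1 <- matrix(0, B, H); Z2 <- matrix(0, B, H)
        for (k in seq_len(B)) {
          s <- sequences[[ord[bi[k]]]]
          inp <- make_model_input(s, vocab, cfg)
          fw1[[k]] <- nn_forward(encoder, inp, training = TRUE)
          fw2[[k]] <- nn_forward(encoder, inp, training = TRUE)
          Z1[k, ] <- pool_hidden(fw1[[k]]$H, cfg$pooling)
          Z2[k, ] <- pool_hidden(fw2[[k]]$H, cfg$pooling)
        }
        n1 <- sqrt(rowSums(Z1^2)); n2 <- sqrt(rowSums(Z2^2))
        Zn1 <- Z1 / pmax(n1, 1e-12); Zn2 <- Z2 / pmax(n2, 1e-12)
        S <- (Zn1 %*% t(Zn2)) / temperature
        P <- softmax_rows(S)
        loss_c <- -mean(log(pmax(P[cbind(1:B, 1:B)], 1e-12)))
        dS <- P; dS[cbind(1:B, 1:B)] <- dS[cbind(1:B, 1:B)] - 1
        dS <- dS / B
        dZn1 <- (dS %*% Zn2) / temperature
        dZn2 <- (t(dS) %*% Zn1) / temperature
        unnorm <- function(dZn, Zn, nrm) {
          (dZn - Zn * rowSums(dZn * Zn)) / pmax(nrm, 1e-12)
        }
        dZ1 <- unnorm(dZn1, Zn1, n1)
        dZ2 <- unnorm(dZn2, Zn2, n2)

        loss_r <- 0
        if (lambda > 0) {
          masks <- dynamic_mask(sequences[ord[bi]], vocab, cfg$mask_rate)
          for (k in seq_len(B)) {
            s <- sequences[[ord[bi[k]]]]
            mk <- masks[[k]]
            sm <- s; sm$token_ids <- mk$masked_ids
            inp_g <- make_model_input(sm, vocab, cfg)
            fg <- nn_forward(generator, inp_g, training = FALSE)
            pos <- mk$positions + 1L
            targets <- s$token_ids[mk$positions]
            ml <- mlm_head(generator, fg$H, pos, targets)
            repl <- sample_replacements(ml$probs, vocab)
            ide <- c(vocab$special[["[CLS]"]], s$token_ids)
            ide[pos] <- repl
            labels <- rep(0, length(ide)); labels[pos] <- as.numeric(repl != targets)
            Lp <- length(ide)
            z <- Z1[k, ]
            feat <- cbind(E0[ide, , drop = FALSE],
                          matrix(z, Lp, H, byrow = TRUE))
            U0 <- feat %*% encoder$params$cd_W1 +
              matrix(encoder$params$cd_b1, Lp, H, byrow = TRUE)
            U <- gelu(U0)
            sc <- as.vector(U %*% encoder$params$cd_w2) + encoder$params$cd_b2
            pr <- 1 / (1 + exp(-sc))
            loss_r <- loss_r +
              -mean(labels * log(pmax(pr, 1e-12)) +
                    (1 - labels) * log(pmax(1 - pr, 1e-12)))
            dsc <- lambda * (pr - labels) / Lp
            gw2 <- as.vector(t(U) %*% dsc)
            gr$cd_w2 <- (gr$cd_w2 %||% 0) + gw2
            gr$cd_b2 <- (gr$cd_b2 %||% 0) + sum(dsc)
            dU <- outer(dsc, encoder$params$cd_w2) * gelu_grad(U0)
            gr$cd_W1 <- (gr$cd_W1 %||% 0) + t(feat) %*% dU
            gr$cd_b1 <- (gr$cd_b1 %||% 0) + colSums(dU)
            dfeat <- dU %*% t(encoder$params$cd_W1)
            dZ1[k, ] <- dZ1[k, ] + colSums(dfeat[, (H + 1):(2 * H), drop = FALSE])
          }
        }
        for (k in seq_len(B)) {
          dH1 <- pool_backward(dZ1[k, ], fw1[[k]]$cache$L, cfg$pooling)
          nn_backward(encoder, fw1[[k]]$cache, dH1, gr)
          dH2 <- pool_backward(dZ2[k, ], fw2[[k]]$cache$L, cfg$pooling)
          nn_backward(encoder, fw2[[k]]$cache, dH2, gr)
        }
        encoder$params <- adam_step(encoder$params, gr, st, lr = lr,
                                    scale = 1)
        ep_c <- ep_c + loss_c
        ep_r <- ep_r + loss_r / B
        nb <- nb + 1
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, contrastive_loss = ep_c / nb, crtd_loss = ep_r / nb,
        total_loss = ep_c / nb + lambda * ep_r / nb))
      if (verbose) {
        message(sprintf("epoch %d: contrastive %.4f crtd %.4f", ep,
                        ep_c / nb, ep_r / nb))
      }
    }
    list(encoder = encoder, history = hist)
  })
}

#' Extract patient embeddings
#'
#' One deterministic vector per patient: the pooled final hidden state of
#' the fine-tuned encoder in evaluation mode (no dropout). Pooling follows
#' the model configuration (mean over event positions by default).
#'
#' @param encoder A (fine-tuned) generator-role encoder.
#' @param sequences A `sequence_set`.
#' @param vocab The vocabulary.
#' @return An embedding matrix, one row per patient, rownames = patient ids.
#' @export
embed_patients <- function(encoder, sequences, vocab) {
  keep <- vapply(sequences, function(s) length(s$token_ids) > 0, logical(1))
  if (any(!keep)) {
    message(sprintf("skipping %d empty sequence(s)", sum(!keep)))
  }
  sequences <- sequences[keep]
  out <- matrix(0, length(sequences), encoder$cfg$hidden_size)
  ids <- character(length(sequences))
  for (i in seq_along(sequences)) {
    inp <- make_model_input(sequences[[i]], vocab, encoder$cfg)
    out[i, ] <- pool_hidden(nn_forward(encoder, inp, training = FALSE)$H,
                            encoder$cfg$pooling)
    ids[i] <- sequences[[i]]$patient_id
  }
  rownames(out) <- ids
  out
}

#' Token input embeddings
#'
#' The input embedding table rows for all non-special tokens, used for
#' comorbidity-pair embedding validation.
#'
#' @param encoder A generator-role encoder.
#' @param vocab The vocabulary.
#' @return Matrix with one row per non-special token, rownames = tokens.
#' @export
token_embeddings <- function(encoder, vocab) {
  ns <- length(vocab$special)
  E <- encoder$params$E_tok
  idx <- (ns + 1L):vocab_size(vocab)
  out <- E[idx, , drop = FALSE]
  rownames(out) <- vocab$tokens[idx]
  out
}
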