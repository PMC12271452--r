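# Covariate-aware disentangled-attention encoder ("EHR-DeBERTa").
#
# The encoder reads a chronological token sequence with parallel age,
# calendar-year, gender and visit channels. Input embeddings are the sum of
# token, age, year, gender, visit and absolute-position embeddings; attention
# scores combine content-to-content, content-to-relative-position and
# relative-position-to-content terms, scaled by 1/sqrt(3 d_head).
#
# Forward and backward passes are written directly in dense matrix algebra
# (one sequence at a time, gradients accumulated over a batch) with an Adam
# optimizer; correctness of the backward pass is established by finite-
# difference gradient checks in the test suite.

#' Encoder / training configuration
#'
#' Defaults follow the reference setup of the method: hidden size 768, 6
#' discriminator and 3 generator layers, maximum sequence length 64, 15%
#' dynamic masking, 100 pretraining epochs, contrastive fine-tuning with
#' temperature 0.05 and lambda 0.005 for 5 epochs. [desk_model_config()]
#' gives a small configuration suitable for laptop-scale corpora, which is
#' what the tests and examples exercise.
#'
#' @param hidden_size Embedding/hidden dimension; must be divisible by
#'   `attention_heads`.
#' @param discriminator_layers,generator_layers Encoder depths; the
#'   generator may not be deeper than the discriminator.
#' @param attention_heads Number of attention heads.
#' @param ffn_size Feed-forward inner dimension (default 4x hidden).
#' @param max_len Maximum number of events per sequence (a leading CLS
#'   position is added internally).
#' @param vocab_size Vocabulary size (set from the vocabulary at init).
#' @param age_cap Ages are clamped to 0..`age_cap` years.
#' @param year_min,year_max Calendar-year embedding range (clamped).
#' @param visit_cap Visit numbers clamped to this cap.
#' @param mask_rate Dynamic masking rate, in (0, 1).
#' @param pretrain_epochs,pretrain_lr,batch_size Pretraining schedule.
#' @param rtd_loss_weight Weight of the replaced-token-detection loss
#'   relative to the masked-prediction loss.
#' @param diffcse_temperature,diffcse_lambda,diffcse_epochs,diffcse_lr
#'   Contrastive fine-tuning parameters.
#' @param dropout Dropout rate used in training and as the stochastic view
#'   augmentation during contrastive fine-tuning.
#' @param pooling Patient-embedding pooling: "mean" (average of the final
#'   hidden states over event positions; default) or "cls" (leading CLS
#'   position). The contrastive fine-tuning objective operates on the same
#'   pooled representation.
#' @param seed Integer seed for initialization and training randomness.
#' @return An object of class `model_config`.
#' @export
model_config <- function(hidden_size = 768,
                         discriminator_layers = 6,
                         generator_layers = 3,
                         attention_heads = 12,
                         ffn_size = NULL,
                         max_len = 64,
                         vocab_size = NULL,
                         age_cap = 110,
                         year_min = 1900,
                         year_max = 2030,
                         visit_cap = 512,
                         mask_rate = 0.15,
                         pretrain_epochs = 100,
                         pretrain_lr = 1e-3,
                         batch_size = 32,
                         rtd_loss_weight = 50,
                         diffcse_temperature = 0.05,
                         diffcse_lambda = 0.005,
                         diffcse_epochs = 5,
                         diffcse_lr = 1e-4,
                         dropout = 0.1,
                         pooling = c("mean", "cls"),
                         seed = 1L) {
  pooling <- match.arg(pooling)
  assert_that(mask_rate > 0 && mask_rate < 1, "mask_rate must be in (0, 1)")
  assert_that(generator_layers <= discriminator_layers,
              "generator may not be deeper than the discriminator")
  assert_that(hidden_size %% attention_heads == 0,
              "hidden_size must be divisible by attention_heads")
  if (is.null(ffn_size)) ffn_size <- 4L * hidden_size
  structure(list(
    hidden_size = as.integer(hidden_size),
    discriminator_layers = as.integer(discriminator_layers),
    generator_layers = as.integer(generator_layers),
    attention_heads = as.integer(attention_heads),
    ffn_size = as.integer(ffn_size),
    max_len = as.integer(max_len), vocab_size = vocab_size,
    age_cap = as.integer(age_cap),
    year_min = as.integer(year_min), year_max = as.integer(year_max),
    visit_cap = as.integer(visit_cap),
    mask_rate = mask_rate,
    pretrain_epochs = as.integer(pretrain_epochs),
    pretrain_lr = pretrain_lr, batch_size = as.integer(batch_size),
    rtd_loss_weight = rtd_loss_weight,
    diffcse_temperature = diffcse_temperature,
    diffcse_lambda = diffcse_lambda,
    diffcse_epochs = as.integer(diffcse_epochs),
    diffcse_lr = diffcse_lr,
    dropout = dropout, pooling = pooling,
    seed = as.integer(seed)), class = "model_config")
}

#' @rdname model_config
#' @param ... Overrides passed on to [model_config()].
#' @export
desk_model_config <- function(...) {
  args <- list(hidden_size = 64L, discriminator_layers = 2L,
               generator_layers = 1L, attention_heads = 2L,
               ffn_size = 128L, pretrain_epochs = 30L,
               pretrain_lr = 2e-3, batch_size = 32L)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

# ---- parameter initialization -------------------------------------------

nn_mat <- function(nr, nc, scale = 0.02) {
  matrix(rnorm(nr * nc, sd = scale), nr, nc)
}

init_encoder_params <- function(cfg, n_layers, role) {
  H <- cfg$hidden_size; F <- cfg$ffn_size; V <- cfg$vocab_size
  P <- cfg$max_len + 1L                     # event positions + CLS
  ny <- cfg$year_max - cfg$year_min + 1L
  p <- list()
  if (role == "generator") {
    p$E_tok <- nn_mat(V, H)
  } else {
    p$E_delta <- matrix(0, V, H)            # gradient-disentangled sharing
  }
  p$E_age <- nn_mat(cfg$age_cap + 1L, H)
  p$E_year <- nn_mat(ny, H)
  p$E_gen <- nn_mat(2L, H)
  p$E_visit <- nn_mat(cfg$visit_cap, H)
  p$E_pos <- nn_mat(P, H)
  p$R_rel <- nn_mat(2L * P - 1L, H)
  p$ln_emb_g <- rep(1, H); p$ln_emb_b <- rep(0, H)
  for (l in seq_len(n_layers)) {
    p[[paste0("Wq_", l)]] <- nn_mat(H, H); p[[paste0("bq_", l)]] <- rep(0, H)
    p[[paste0("Wk_", l)]] <- nn_mat(H, H); p[[paste0("bk_", l)]] <- rep(0, H)
    p[[paste0("Wv_", l)]] <- nn_mat(H, H); p[[paste0("bv_", l)]] <- rep(0, H)
    p[[paste0("Wo_", l)]] <- nn_mat(H, H); p[[paste0("bo_", l)]] <- rep(0, H)
    p[[paste0("ln1_g_", l)]] <- rep(1, H); p[[paste0("ln1_b_", l)]] <- rep(0, H)
    p[[paste0("W1_", l)]] <- nn_mat(H, F); p[[paste0("b1_", l)]] <- rep(0, F)
    p[[paste0("W2_", l)]] <- nn_mat(F, H); p[[paste0("b2_", l)]] <- rep(0, H)
    p[[paste0("ln2_g_", l)]] <- rep(1, H); p[[paste0("ln2_b_", l)]] <- rep(0, H)
  }
  if (role == "generator") {
    p$b_mlm <- rep(0, V)                    # output projection tied to E_tok
  } else {
    p$w_rtd <- rep(0, H); p$b_rtd <- 0      # per-position original/replaced
  }
  p
}

#' Initialise the generator/discriminator pair
#'
#' Both encoders share the token embedding table with gradient-disentangled
#' sharing: the discriminator sees the generator's table plus its own delta
#' table, and its gradients flow only into the delta.
#'
#' @param config A [model_config()] (with `vocab_size` unset).
#' @param vocab An `ehr_vocabulary`.
#' @param seed Optional override of `config$seed`.
#' @return A list with `generator`, `discriminator` and `config`.
#' @export
init_model <- function(config, vocab, seed = NULL) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  config$vocab_size <- vocab_size(vocab)
  with_seed(seed %||% config$seed, {
    gen <- structure(list(cfg = config, n_layers = config$generator_layers,
                          role = "generator",
                          params = init_encoder_params(config,
                                                       config$generator_layers,
                                                       "generator")),
                     class = "ehr_encoder")
    dis <- structure(list(cfg = config, n_layers = config$discriminator_layers,
                          role = "discriminator",
                          params = init_encoder_params(config,
                                                       config$discriminator_layers,
                                                       "discriminator")),
                     class = "ehr_encoder")
    list(generator = gen, discriminator = dis, config = config)
  })
}

#' @export
print.ehr_encoder <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<ehr_encoder:%s> %d layers, hidden %d, %s parameters\n",
              x$role, x$n_layers, x$cfg$hidden_size, format(np, big.mark = ",")))
  invisible(x)
}

# ---- model input construction -------------------------------------------

# A sequence (token ids + channels) becomes model input by prepending a CLS
# position that inherits the first event's covariates.
make_model_input <- function(s, vocab, cfg) {
  stopifnot(length(s$token_ids) > 0)
  cls <- vocab$special[["[CLS]"]]
  ids <- c(cls, s$token_ids)
  age <- pmin(pmax(c(s$age_years[1], s$age_years), 0L), cfg$age_cap) + 1L
  yr <- pmin(pmax(c(s$calendar_year[1], s$calendar_year), cfg$year_min),
             cfg$year_max) - cfg$year_min + 1L
  vis <- pmin(c(1L, s$visit_number), cfg$visit_cap)
  g <- if (identical(s$gender, "male")) 2L else 1L
  list(ids = ids, age = age, year = yr, visit = vis, gender = g,
       L = length(ids))
}

# ---- primitive layers ----------------------------------------------------

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  invsd <- 1 / sqrt(rowMeans(xc^2) + 1e-6)
  xhat <- xc * invsd
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(x), ncol(x), byrow = TRUE),
       xhat = xhat, invsd = invsd)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$invsd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

scatter_add_mat <- function(rows, cols, values, nr, nc) {
  lin <- (cols - 1L) * nr + rows
  acc <- rowsum(values, lin)
  out <- numeric(nr * nc)
  out[as.integer(rownames(acc))] <- acc
  matrix(out, nr, nc)
}

# ---- encoder forward -----------------------------------------------------

# Returns list(H = L x hidden final states, cache) for one sequence.
# `shared_E` supplies the generator's token table when running the
# discriminator (gradient-disentangled sharing).
nn_forward <- function(enc, inp, training = FALSE, shared_E = NULL) {
  cfg <- enc$cfg; p <- enc$params
  H <- cfg$hidden_size; A <- cfg$attention_heads; Dh <- H %/% A
  L <- inp$L; P <- cfg$max_len + 1L
  drop_p <- if (training) cfg$dropout else 0

  E_eff <- if (enc$role == "generator") p$E_tok else shared_E + p$E_delta
  X0 <- E_eff[inp$ids, , drop = FALSE] +
    p$E_age[inp$age, , drop = FALSE] +
    p$E_year[inp$year, , drop = FALSE] +
    matrix(p$E_gen[inp$gender, ], L, H, byrow = TRUE) +
    p$E_visit[inp$visit, , drop = FALSE] +
    p$E_pos[seq_len(L), , drop = FALSE]
  lnc <- ln_forward(X0, p$ln_emb_g, p$ln_emb_b)
  dm0 <- drop_mask(L, H, drop_p)
  X <- if (is.null(dm0)) lnc$y else lnc$y * dm0

  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  IDXv <- ii - jj + P                      # column-major (i,j) -> i - j + P
  IDXtv <- jj - ii + P                     # column-major (i,j) -> j - i + P
  scale <- 1 / sqrt(3 * Dh)

  layers <- vector("list", enc$n_layers)
  for (l in seq_len(enc$n_layers)) {
    Wq <- p[[paste0("Wq_", l)]]; Wk <- p[[paste0("Wk_", l)]]
    Wv <- p[[paste0("Wv_", l)]]
    Q <- X %*% Wq + matrix(p[[paste0("bq_", l)]], L, H, byrow = TRUE)
    K <- X %*% Wk + matrix(p[[paste0("bk_", l)]], L, H, byrow = TRUE)
    Vm <- X %*% Wv + matrix(p[[paste0("bv_", l)]], L, H, byrow = TRUE)
    Qr <- p$R_rel %*% Wq                   # relative projections share Wq/Wk
    Kr <- p$R_rel %*% Wk
    Aheads <- vector("list", A)
    Oc <- matrix(0, L, H)
    for (h in seq_len(A)) {
      hs <- ((h - 1L) * Dh + 1L):(h * Dh)
      Qh <- Q[, hs, drop = FALSE]; Kh <- K[, hs, drop = FALSE]
      C <- Qh %*% t(Kr[, hs, drop = FALSE])         # L x (2P-1), c2p
      D <- Kh %*% t(Qr[, hs, drop = FALSE])         # L x (2P-1), p2c
      S <- Qh %*% t(Kh) +
        matrix(C[cbind(ii, IDXv)], L, L) +
        matrix(D[cbind(jj, IDXtv)], L, L)
      Am <- softmax_rows(S * scale)
      Aheads[[h]] <- Am
      Oc[, hs] <- Am %*% Vm[, hs, drop = FALSE]
    }
    O <- Oc %*% p[[paste0("Wo_", l)]] +
      matrix(p[[paste0("bo_", l)]], L, H, byrow = TRUE)
    dm1 <- drop_mask(L, H, drop_p)
    Od <- if (is.null(dm1)) O else O * dm1
    ln1 <- ln_forward(X + Od, p[[paste0("ln1_g_", l)]], p[[paste0("ln1_b_", l)]])
    X1 <- ln1$y
    U0 <- X1 %*% p[[paste0("W1_", l)]] +
      matrix(p[[paste0("b1_", l)]], L, cfg$ffn_size, byrow = TRUE)
    U <- gelu(U0)
    Fo <- U %*% p[[paste0("W2_", l)]] +
      matrix(p[[paste0("b2_", l)]], L, H, byrow = TRUE)
    dm2 <- drop_mask(L, H, drop_p)
    Fd <- if (is.null(dm2)) Fo else Fo * dm2
    ln2 <- ln_forward(X1 + Fd, p[[paste0("ln2_g_", l)]], p[[paste0("ln2_b_", l)]])
    layers[[l]] <- list(X = X, Q = Q, K = K, V = Vm, Qr = Qr, Kr = Kr,
                        Aheads = Aheads, Oc = Oc, dm1 = dm1, ln1 = ln1,
                        X1 = X1, U0 = U0, U = U, dm2 = dm2, ln2 = ln2)
    X <- ln2$y
  }
  list(H = X,
       cache = list(inp = inp, L = L, lnc = lnc, dm0 = dm0, layers = layers,
                    ii = ii, jj = jj, IDXv = IDXv, IDXtv = IDXtv,
                    scale = scale))
}

# ---- encoder backward ----------------------------------------------------

# dH: L x hidden gradient of the loss w.r.t. the final hidden states.
# Accumulates parameter gradients into environment `gr` (name -> array).
nn_backward <- function(enc, cache, dH, gr) {
  cfg <- enc$cfg; p <- enc$params
  H <- cfg$hidden_size; A <- cfg$attention_heads; Dh <- H %/% A
  L <- cache$L; P <- cfg$max_len + 1L; M <- 2L * P - 1L
  ii <- cache$ii; jj <- cache$jj
  IDXv <- cache$IDXv; IDXtv <- cache$IDXtv; scale <- cache$scale
  add <- function(nm, v) {
    gr[[nm]] <- if (is.null(gr[[nm]])) v else gr[[nm]] + v
  }
  dX <- dH
  for (l in rev(seq_len(enc$n_layers))) {
    lc <- cache$layers[[l]]
    g2 <- p[[paste0("ln2_g_", l)]]
    lb2 <- ln_backward(dX, lc$ln2, g2)
    add(paste0("ln2_g_", l), lb2$dg); add(paste0("ln2_b_", l), lb2$db)
    dres <- lb2$dx                       # grad w.r.t. X1 + dropout(Fo)
    dFd <- dres
    dFo <- if (is.null(lc$dm2)) dFd else dFd * lc$dm2
    add(paste0("b2_", l), colSums(dFo))
    add(paste0("W2_", l), t(lc$U) %*% dFo)
    dU <- dFo %*% t(p[[paste0("W2_", l)]])
    dU0 <- dU * gelu_grad(lc$U0)
    add(paste0("b1_", l), colSums(dU0))
    add(paste0("W1_", l), t(lc$X1) %*% dU0)
    dX1 <- dres + dU0 %*% t(p[[paste0("W1_", l)]])

    g1 <- p[[paste0("ln1_g_", l)]]
    lb1 <- ln_backward(dX1, lc$ln1, g1)
    add(paste0("ln1_g_", l), lb1$dg); add(paste0("ln1_b_", l), lb1$db)
    dres1 <- lb1$dx                      # grad w.r.t. X + dropout(O)
    dOd <- dres1
    dO <- if (is.null(lc$dm1)) dOd else dOd * lc$dm1
    add(paste0("bo_", l), colSums(dO))
    add(paste0("Wo_", l), t(lc$Oc) %*% dO)
    dOc <- dO %*% t(p[[paste0("Wo_", l)]])

    dQ <- matrix(0, L, H); dK <- matrix(0, L, H); dV <- matrix(0, L, H)
    dQr <- matrix(0, M, H); dKr <- matrix(0, M, H)
    for (h in seq_len(A)) {
      hs <- ((h - 1L) * Dh + 1L):(h * Dh)
      Am <- lc$Aheads[[h]]
      Qh <- lc$Q[, hs, drop = FALSE]; Kh <- lc$K[, hs, drop = FALSE]
      Vh <- lc$V[, hs, drop = FALSE]
      Qrh <- lc$Qr[, hs, drop = FALSE]; Krh <- lc$Kr[, hs, drop = FALSE]
      dOh <- dOc[, hs, drop = FALSE]
      dAm <- dOh %*% t(Vh)
      dV[, hs] <- t(Am) %*% dOh
      dSsc <- Am * (dAm - rowSums(Am * dAm))   # softmax rows backward
      dS <- dSsc * scale
      dQ[, hs] <- dQ[, hs] + dS %*% Kh
      dK[, hs] <- dK[, hs] + t(dS) %*% Qh
      dC <- scatter_add_mat(ii, IDXv, as.vector(dS), L, M)
      dQ[, hs] <- dQ[, hs] + dC %*% Krh
      dKr[, hs] <- dKr[, hs] + t(dC) %*% Qh
      dD <- scatter_add_mat(jj, IDXtv, as.vector(dS), L, M)
      dK[, hs] <- dK[, hs] + dD %*% Qrh
      dQr[, hs] <- dQr[, hs] + t(dD) %*% Kh
    }
    X <- lc$X
    add(paste0("bq_", l), colSums(dQ))
    add(paste0("bk_", l), colSums(dK))
    add(paste0("bv_", l), colSums(dV))
    add(paste0("Wq_", l), t(X) %*% dQ + t(p$R_rel) %*% dQr)
    add(paste0("Wk_", l), t(X) %*% dK + t(p$R_rel) %*% dKr)
    add(paste0("Wv_", l), t(X) %*% dV)
    add("R_rel", dQr %*% t(p[[paste0("Wq_", l)]]) +
                 dKr %*% t(p[[paste0("Wk_", l)]]))
    dX <- dres1 + dQ %*% t(p[[paste0("Wq_", l)]]) +
      dK %*% t(p[[paste0("Wk_", l)]]) + dV %*% t(p[[paste0("Wv_", l)]])
  }
  if (!is.null(cache$dm0)) dX <- dX * cache$dm0
  lbe <- ln_backward(dX, cache$lnc, p$ln_emb_g)
  add("ln_emb_g", lbe$dg); add("ln_emb_b", lbe$db)
  dX0 <- lbe$dx
  inp <- cache$inp
  tok_target <- if (enc$role == "generator") "E_tok" else "E_delta"
  add_scatter <- function(nm, idx, nr) {
    acc <- rowsum(dX0, idx)
    g <- matrix(0, nr, H)
    g[as.integer(rownames(acc)), ] <- acc
    add(nm, g)
  }
  add_scatter(tok_target, inp$ids, cfg$vocab_size)
  add_scatter("E_age", inp$age, cfg$age_cap + 1L)
  add_scatter("E_year", inp$year, cfg$year_max - cfg$year_min + 1L)
  add_scatter("E_visit", inp$visit, cfg$visit_cap)
  gg <- matrix(0, 2L, H); gg[inp$gender, ] <- colSums(dX0)
  add("E_gen", gg)
  gp <- matrix(0, P, H); gp[seq_len(L), ] <- dX0
  add("E_pos", gp)
  invisible(NULL)
}

# ---- heads ---------------------------------------------------------------

# Masked-token prediction at positions `pos` (indices into the model input,
# i.e. offset by the CLS position). Returns loss and, when `gr` is given,
# adds gradients (tied output projection: gradients flow into E_tok) and
# returns dH.
mlm_head <- function(enc, Hmat, pos, targets, gr = NULL) {
  p <- enc$params
  logits <- Hmat[pos, , drop = FALSE] %*% t(p$E_tok) +
    matrix(p$b_mlm, length(pos), length(p$b_mlm), byrow = TRUE)
  pr <- softmax_rows(logits)
  n <- length(pos)
  loss <- -mean(log(pmax(pr[cbind(seq_len(n), targets)], 1e-12)))
  out <- list(loss = loss, probs = pr)
  if (!is.null(gr)) {
    dlog <- pr
    dlog[cbind(seq_len(n), targets)] <- dlog[cbind(seq_len(n), targets)] - 1
    dlog <- dlog / n
    dH <- matrix(0, nrow(Hmat), ncol(Hmat))
    dH[pos, ] <- dlog %*% p$E_tok
    gE <- t(dlog) %*% Hmat[pos, , drop = FALSE]
    gr$E_tok <- if (is.null(gr$E_tok)) gE else gr$E_tok + gE
    gb <- colSums(dlog)
    gr$b_mlm <- if (is.null(gr$b_mlm)) gb else gr$b_mlm + gb
    out$dH <- dH
  }
  out
}

# Per-position original/replaced head (binary logistic probe).
rtd_head <- function(enc, Hmat, labels, gr = NULL) {
  p <- enc$params
  s <- as.vector(Hmat %*% p$w_rtd) + p$b_rtd
  pr <- 1 / (1 + exp(-s))
  loss <- -mean(labels * log(pmax(pr, 1e-12)) +
                (1 - labels) * log(pmax(1 - pr, 1e-12)))
  out <- list(loss = loss, probs = pr)
  if (!is.null(gr)) {
    ds <- (pr - labels) / length(labels)
    out$dH <- outer(ds, p$w_rtd)
    gw <- as.vector(t(Hmat) %*% ds)
    gr$w_rtd <- if (is.null(gr$w_rtd)) gw else gr$w_rtd + gw
    gr$b_rtd <- if (is.null(gr$b_rtd)) sum(ds) else gr$b_rtd + sum(ds)
  }
  out
}

# ---- Adam optimizer ------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(params, gr, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, scale = 1) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in ls(gr)) {
    g <- gr[[nm]] * scale
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- g * 0; st$v[[nm]] <- g * 0
    }
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  params
}

new_grad_env <- function() new.env(parent = emptyenv())

# Pool final hidden states into one patient vector. "mean" averages the
# event positions (excluding CLS); "cls" takes the leading position.
pool_hidden <- function(Hmat, pooling) {
  if (pooling == "cls" || nrow(Hmat) == 1) return(Hmat[1, ])
  colMeans(Hmat[-1, , drop = FALSE])
}

# Gradient of the pooled vector w.r.t. the hidden states.
pool_backward <- function(dz, L, pooling) {
  dH <- matrix(0, L, length(dz))
  if (pooling == "cls" || L == 1) {
    dH[1, ] <- dz
  } else {
    dH[-1, ] <- matrix(dz / (L - 1), L - 1, length(dz), byrow = TRUE)
  }
  dH
}
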