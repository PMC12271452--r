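# Latent class analysis baseline: EM for a finite mixture of independent
# Bernoulli item profiles over the binary disease matrix, with AIC/BIC
# class-number selection and class profiling.

lca_loglik <- function(x, pi_, rho, eps = 1e-12) {
  # log f(x_i) = logsumexp_c [ log pi_c + sum_d x log rho + (1-x) log(1-rho) ]
  lr <- log(rho); lr1 <- log(1 - rho)
  ll_ic <- x %*% t(lr) + (1 - x) %*% t(lr1)          # n x C
  ll_ic <- sweep(ll_ic, 2, log(pi_), "+")
  m <- apply(ll_ic, 1, max)
  lse <- m + log(rowSums(exp(ll_ic - m)))
  list(ll = sum(lse), log_resp = ll_ic - lse)
}

#' Fit a latent class model by EM
#'
#' Mixture of `C` classes with conditionally independent Bernoulli items.
#' The E-step computes responsibilities proportional to
#' `pi_c * prod_d rho_cd^x (1-rho_cd)^(1-x)`; the M-step updates mixing
#' weights and item probabilities in closed form. The best of `n_starts`
#' jittered initialisations (by log-likelihood) is returned; item
#' probabilities are clipped to `[eps, 1-eps]`.
#'
#' @param x Binary patients x items matrix.
#' @param C Number of classes (1 <= C <= n).
#' @param n_starts Random restarts (default 10).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Iteration cap per start.
#' @param seed Seed.
#' @param eps Clipping bound for item probabilities.
#' @return An object of class `lca_model` with `C`, `pi` (mixing weights),
#'   `rho` (C x D item probabilities), `loglik`, `n_parameters`, `AIC`,
#'   `BIC`, `posterior` (responsibilities), `assignments` (MAP classes),
#'   `converged`, `loglik_trace` (best start).
#' @export
fit_lca <- function(x, C, n_starts = 10, tol = 1e-6, max_iter = 500,
                    seed = 1L, eps = 1e-6) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 1 && ncol(x) >= 1, "matrix must be nonempty")
  assert_that(all(x %in% c(0, 1)), "matrix must be binary")
  assert_that(C >= 1 && C <= nrow(x), "C must be in [1, n]")
  n <- nrow(x); D <- ncol(x)
  prev <- colMeans(x)
  best <- NULL
  seeds <- derive_seeds(seed, n_starts)
  for (s in seq_len(n_starts)) {
    with_seed(seeds[s], {
      rho <- matrix(pmin(pmax(
        rep(prev, each = C) + runif(C * D, -0.15, 0.15), eps), 1 - eps), C, D)
      pi_ <- rep(1 / C, C)
      trace <- numeric(0)
      converged <- FALSE
      ll_prev <- -Inf
      for (it in seq_len(max_iter)) {
        e <- lca_loglik(x, pi_, rho)
        trace <- c(trace, e$ll)
        if (is.finite(ll_prev) && abs(e$ll - ll_prev) < tol) {
          converged <- TRUE
          break
        }
        ll_prev <- e$ll
        resp <- exp(e$log_resp)                       # n x C
        nk <- colSums(resp)
        pi_ <- nk / n
        rho <- pmin(pmax((t(resp) %*% x) / nk, eps), 1 - eps)
      }
      e <- lca_loglik(x, pi_, rho)
      if (is.null(best) || e$ll > best$loglik) {
        best <- list(pi = pi_, rho = rho, loglik = e$ll,
                      log_resp = e$log_resp, converged = converged,
                      trace = trace)
      }
    })
  }
  m <- (C - 1) + C * D
  structure(list(C = as.integer(C), pi = best$pi, rho = best$rho,
                 loglik = best$loglik, n_parameters = m,
                 AIC = -2 * best$loglik + 2 * m,
                 BIC = -2 * best$loglik + m * log(n),
                 posterior = exp(best$log_resp),
                 assignments = max.col(best$log_resp, ties.method = "first"),
                 converged = best$converged,
                 loglik_trace = best$trace,
                 item_names = colnames(x), seed = seed),
            class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("<lca_model> C = %d, loglik = %.2f, AIC = %.1f, BIC = %.1f%s\n",
              x$C, x$loglik, x$AIC, x$BIC,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Select the number of latent classes
#'
#' Fits the model over a range of class counts and reports AIC and BIC;
#' the chosen count minimises BIC (ties towards fewer classes). A
#' disagreement between the AIC and BIC optima is reported with a message.
#'
#' @param x Binary matrix.
#' @param C_range Candidate class counts.
#' @param ... Passed to [fit_lca()].
#' @param seed Seed (each C gets a derived seed).
#' @return List with `table` (C, loglik, AIC, BIC), `chosen_C`, `models`.
#' @export
select_classes <- function(x, C_range = 1:10, seed = 1L, ...) {
  seeds <- derive_seeds(seed, length(C_range))
  models <- lapply(seq_along(C_range), function(i) {
    fit_lca(x, C_range[i], seed = seeds[i], ...)
  })
  tab <- data.frame(C = C_range,
                    loglik = vapply(models, `[[`, numeric(1), "loglik"),
                    n_parameters = vapply(models, `[[`, numeric(1), "n_parameters"),
                    AIC = vapply(models, `[[`, numeric(1), "AIC"),
                    BIC = vapply(models, `[[`, numeric(1), "BIC"))
  chosen <- C_range[which.min(tab$BIC)]
  aic_best <- C_range[which.min(tab$AIC)]
  if (aic_best != chosen) {
    message(sprintf("AIC prefers C = %d, BIC prefers C = %d; using BIC",
                    aic_best, chosen))
  }
  list(table = tab, chosen_C = chosen, models = models)
}

#' Class profiles
#'
#' Top conditions per class by item probability (lexicographic tie-break)
#' together with the class share.
#'
#' @param model An `lca_model`.
#' @param top_n Number of top conditions (default 3).
#' @return Data frame: class, share, rank, condition, rho.
#' @export
class_profiles <- function(model, top_n = 3) {
  items <- model$item_names %||% paste0("item", seq_len(ncol(model$rho)))
  do.call(rbind, lapply(seq_len(model$C), function(c) {
    r <- model$rho[c, ]
    ord <- order(-r, items)
    sel <- ord[seq_len(min(top_n, length(ord)))]
    data.frame(class = c, share = model$pi[c],
               rank = seq_along(sel), condition = items[sel],
               rho = r[sel], stringsAsFactors = FALSE)
  }))
}
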