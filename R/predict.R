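# Dynamic individual prediction: conditional survival and expected
# biomarker trajectory given an individual's observation history, updated
# whenever a new measurement arrives by simply re-predicting from it.

# moment state after assimilating the history up to age s
.state_at <- function(params, individual, s, h_max = 0.1, sigma_me = 0) {
  obs <- individual$obs[individual$obs$age <= s + 1e-12, , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("prediction age precedes the first observation", call. = FALSE)
  ad <- .cov_adjust(params, individual$x)
  J <- params$dim
  m <- params$m0
  g <- params$gamma0
  t <- individual$t0
  ycols <- paste0("y", seq_len(J))
  for (r in seq_len(nrow(obs))) {
    ta <- obs$age[r]
    st <- cpp_propagate_interval(.par_clist(params), ad$f1i, ad$f0i, ad$lmu,
                                 t, ta, m, as.matrix(g), 0, h_max)
    m <- as.numeric(st$m); g <- st$gamma
    y <- as.numeric(obs[r, ycols])
    if (sigma_me > 0) {
      S <- g + diag(sigma_me^2, J)
      Kg <- g %*% solve(S)
      m <- m + drop(Kg %*% (y - m))
      g <- (diag(J) - Kg) %*% g
    } else {
      m <- y
      g <- matrix(0, J, J)
    }
    t <- ta
  }
  if (s > t) {
    st <- cpp_propagate_interval(.par_clist(params), ad$f1i, ad$f0i, ad$lmu,
                                 t, s, m, as.matrix(g), 0, h_max)
    m <- as.numeric(st$m); g <- st$gamma
  }
  list(m = m, g = as.matrix(g), ad = ad)
}

#' Conditional survival and biomarker forecast for one individual
#'
#' Assimilates the individual's measurements up to `at_age` (exact reset,
#' or filter update when `sigma_me > 0`), then integrates the moment
#' equations and the averaged hazard forward:
#' \eqn{S(u \mid s) = \exp(-\int_s^u \bar\mu)}.  When a new measurement
#' arrives, call the function again with the extended history — that is
#' the dynamic update path.
#'
#' @inheritParams indiv_logliks
#' @param individual record as returned by [cohort_individual()] (needs at
#'   least one observation at or before `at_age`).
#' @param at_age conditioning age s.
#' @param horizon last age of the forecast grid.
#' @param grid_n number of grid ages between `at_age` and `horizon`.
#' @param sigma_me measurement-error SD used in the state update.
#' @return Object of class `"spm_prediction"`: data frame with `age`,
#'   `survival` (1 at `at_age`, non-increasing), predicted mean `m1..mJ`
#'   and variance `v1..vJ` (conditional-Gaussian band, an approximation).
#' @export
predict_individual <- function(params, individual, at_age, horizon,
                               grid_n = 51L, h_max = 0.1, sigma_me = 0) {
  stopifnot(horizon > at_age)
  st <- .state_at(params, individual, at_age, h_max, sigma_me)
  grid <- seq(at_age, horizon, length.out = grid_n)
  J <- params$dim
  out <- data.frame(age = grid, survival = NA_real_)
  M <- matrix(NA_real_, grid_n, J)
  V <- matrix(NA_real_, grid_n, J)
  m <- st$m; g <- st$g; H <- 0
  M[1, ] <- m; V[1, ] <- diag(as.matrix(g)); out$survival[1] <- 1
  for (i in 2:grid_n) {
    r <- cpp_propagate_interval(.par_clist(params), st$ad$f1i, st$ad$f0i,
                                st$ad$lmu, grid[i - 1L], grid[i], m,
                                as.matrix(g), H, h_max)
    m <- as.numeric(r$m); g <- r$gamma; H <- r$H
    M[i, ] <- m
    V[i, ] <- diag(as.matrix(g))
    out$survival[i] <- exp(-H)
  }
  for (j in seq_len(J)) {
    out[[paste0("m", j)]] <- M[, j]
    out[[paste0("v", j)]] <- V[, j]
  }
  structure(out, class = c("spm_prediction", "data.frame"),
            at_age = at_age, id = individual$id)
}

#' Mixture prediction under a latent-class or genetic model
#'
#' Posterior-weighted mixture of the per-regime predictions:
#' \eqn{S(u|s) = \sum_k \pi_k S_k(u|s)} with \eqn{\pi_k} the posterior
#' membership given the history up to `at_age` (degenerate at the observed
#' genotype when the individual is genotyped under a genetic model).
#'
#' @inheritParams predict_individual
#' @param model a [latent_class_model()] or [genetic_model()].
#' @return An `"spm_prediction"` with attribute `posterior`.
#' @export
predict_latent <- function(model, individual, at_age, horizon, grid_n = 51L,
                           h_max = 0.1, sigma_me = 0) {
  stopifnot(inherits(model, "spm_mixture"))
  K <- model$K
  geno <- individual$genotype
  use_geno <- inherits(model, "genetic_model") && !is.na(geno)
  if (use_geno) {
    post <- replace(numeric(K), geno, 1)
  } else if (K == 1L) {
    post <- 1
  } else {
    # posterior from the history: prior x likelihood of (obs <= s, survival to s)
    hist_ind <- individual
    hist_ind$obs <- individual$obs[individual$obs$age <= at_age + 1e-12, ,
                                   drop = FALSE]
    hist_ind$tau <- at_age
    hist_ind$delta <- 0
    lk <- vapply(model$components, function(p)
      individual_loglik(p, hist_ind, h_max = h_max, sigma_me = sigma_me),
      numeric(1))
    x0 <- if (is.null(model$x0_names)) NULL else
      individual$x0 %||% individual$x
    lp <- log(.multilogit_p(model$beta0, model$beta1, x0))
    w <- lk + lp
    post <- exp(w - .logsumexp(w))
  }
  preds <- lapply(seq_len(K), function(k)
    predict_individual(model$components[[k]], individual, at_age, horizon,
                       grid_n = grid_n, h_max = h_max, sigma_me = sigma_me))
  out <- preds[[1]]
  num_cols <- setdiff(names(out), "age")
  for (cc in num_cols) {
    acc <- 0
    for (k in seq_len(K)) acc <- acc + post[k] * preds[[k]][[cc]]
    out[[cc]] <- acc
  }
  attr(out, "posterior") <- post
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
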