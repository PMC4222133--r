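# Latent-class extension: a finite mixture of model regimes with
# multinomial-logistic class membership on baseline covariates.  Class K is
# the reference category (linear predictor 0).

#' Latent-class model: K regimes plus a membership model
#'
#' @param components list of K [spm_params()] objects (all with the same
#'   number of biomarkers), one per latent class.
#' @param beta0 membership intercepts for classes 1..K-1 (class K is the
#'   reference).
#' @param beta1 optional (K-1) x p matrix of membership coefficients on the
#'   baseline covariates `x0_names`.
#' @param x0_names names of the membership covariates (columns of the
#'   cohort's survival table); may overlap the dynamics covariates.
#' @return Object of class `c("latent_class_model", "spm_mixture")`.
#' @export
latent_class_model <- function(components, beta0 = numeric(length(components) - 1L),
                               beta1 = NULL, x0_names = NULL) {
  .new_mixture(components, beta0, beta1, x0_names, "latent_class_model")
}

.new_mixture <- function(components, beta0, beta1, x0_names, cls) {
  stopifnot(is.list(components), length(components) >= 1L)
  K <- length(components)
  Js <- vapply(components, function(p) p$dim, integer(1))
  if (length(unique(Js)) != 1L)
    stop("all regimes must share the number of biomarkers", call. = FALSE)
  if (length(beta0) != K - 1L)
    stop(sprintf("`beta0` must have length K-1 = %d", K - 1L), call. = FALSE)
  if (!is.null(beta1)) {
    beta1 <- matrix(beta1, nrow = K - 1L)
    if (is.null(x0_names) || ncol(beta1) != length(x0_names))
      stop("`beta1` columns must match `x0_names`", call. = FALSE)
  }
  structure(list(components = components, K = K, beta0 = as.numeric(beta0),
                 beta1 = beta1, x0_names = x0_names),
            class = c(cls, "spm_mixture"))
}

#' @export
print.spm_mixture <- function(x, ...) {
  cat(sprintf("<%s> K = %d regimes, J = %d\n", class(x)[1], x$K,
              x$components[[1]]$dim))
  p <- class_probabilities(x, if (is.null(x$x0_names)) NULL else
    numeric(length(x$x0_names)))
  cat("  membership at x0 = 0:", paste(signif(p, 4), collapse = " "), "\n")
  invisible(x)
}

#' Class-membership probabilities
#'
#' \eqn{p_k = e^{\eta_k} / \sum_c e^{\eta_c}} with
#' \eqn{\eta_k = \beta_{0k} + \beta_{1k}^\top x^0} for k < K and
#' \eqn{\eta_K = 0}.
#'
#' @param model a [latent_class_model()] or [genetic_model()].
#' @param x0 baseline covariate vector, or a matrix/data frame with one row
#'   per individual.
#' @return Probability vector of length K (or an n x K matrix), each row
#'   summing to one.
#' @export
class_probabilities <- function(model, x0 = NULL) {
  stopifnot(inherits(model, "spm_mixture"))
  if (is.null(x0) || is.null(dim(x0)))
    return(.multilogit_p(model$beta0, model$beta1, x0))
  t(apply(as.matrix(x0), 1, function(r)
    .multilogit_p(model$beta0, model$beta1, r)))
}

# n x K matrix of log membership probabilities for a cohort
.log_membership <- function(model, cohort) {
  n <- nrow(cohort$surv)
  if (is.null(model$x0_names)) {
    lp <- log(.multilogit_p(model$beta0, model$beta1, NULL))
    matrix(lp, n, model$K, byrow = TRUE)
  } else {
    X0 <- as.matrix(cohort$surv[, model$x0_names, drop = FALSE])
    eta <- cbind(matrix(model$beta0, n, model$K - 1L, byrow = TRUE) +
                   (if (is.null(model$beta1)) 0 else X0 %*% t(model$beta1)),
                 0)
    eta - apply(eta, 1, .logsumexp)
  }
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# n x K matrix of per-class individual log-likelihood contributions
.class_logliks <- function(model, cohort, h_max = 0.1, sigma_me = NULL) {
  vapply(model$components, function(p)
    as.numeric(indiv_logliks(p, cohort, h_max = h_max, sigma_me = sigma_me)),
    numeric(nrow(cohort$surv)))
}

#' Observed-data log-likelihood of the latent-class model
#'
#' \eqn{\sum_i \log \sum_k p_k(x^0_i)\, e^{\ell_i^{(k)}}} with
#' \eqn{\ell_i^{(k)}} the individual contribution under the class-k
#' parameters, computed with log-sum-exp stabilisation.  Any recorded
#' genotype labels are ignored: classes are treated as latent (use
#' [genetic_loglik()] when labels are observed for a sub-sample).
#'
#' @param model a [latent_class_model()].
#' @inheritParams indiv_logliks
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(model, cohort, h_max = 0.1, sigma_me = NULL) {
  ll <- .class_logliks(model, cohort, h_max, sigma_me)
  lp <- .log_membership(model, cohort)
  sum(apply(ll + lp, 1, .logsumexp))
}

#' Posterior class-membership probabilities
#'
#' Bayes update of the prior membership with each class's likelihood of the
#' individual's full record:
#' \eqn{P(Z = k \mid \mathrm{data}_i) \propto p_k(x^0_i) e^{\ell_i^{(k)}}}.
#'
#' @inheritParams mixture_loglik
#' @return n x K matrix of posterior probabilities (rows sum to one).
#' @export
posterior_class <- function(model, cohort, h_max = 0.1, sigma_me = NULL) {
  ll <- .class_logliks(model, cohort, h_max, sigma_me)
  lp <- .log_membership(model, cohort)
  w <- ll + lp
  post <- exp(w - apply(w, 1, .logsumexp))
  post / rowSums(post)
}

# ---- mixture codec ---------------------------------------------------------
# u = [ shared coords | class-1 coords | ... | class-K coords | beta ]
.mix_pack <- function(model, free_shared, free_class, free_beta) {
  u <- numeric(0)
  if (length(free_shared)) {
    v <- spm_pack(model$components[[1]], free_shared)
    names(v) <- paste0("shared.", names(v))
    u <- c(u, v)
  }
  if (length(free_class)) for (k in seq_len(model$K)) {
    v <- spm_pack(model$components[[k]], free_class)
    names(v) <- paste0("k", k, ".", names(v))
    u <- c(u, v)
  }
  if (free_beta && model$K > 1L) {
    b <- stats::setNames(model$beta0, paste0("beta0.", seq_len(model$K - 1L)))
    u <- c(u, b)
    if (!is.null(model$beta1)) {
      b1 <- as.numeric(model$beta1)
      names(b1) <- paste0("beta1.", seq_along(b1))
      u <- c(u, b1)
    }
  }
  u
}

.mix_unpack <- function(u, model, free_shared, free_class, free_beta) {
  k0 <- 0L
  take <- function(n) { k0 <<- k0 + n; u[(k0 - n + 1L):k0] }
  comps <- model$components
  if (length(free_shared)) {
    ns <- length(spm_pack(comps[[1]], free_shared))
    vs <- take(ns)
    comps <- lapply(comps, function(p) spm_unpack(vs, p, free_shared))
  }
  if (length(free_class)) for (k in seq_len(model$K)) {
    nk <- length(spm_pack(comps[[k]], free_class))
    comps[[k]] <- spm_unpack(take(nk), comps[[k]], free_class)
  }
  beta0 <- model$beta0
  beta1 <- model$beta1
  if (free_beta && model$K > 1L) {
    beta0 <- take(model$K - 1L)
    if (!is.null(beta1)) beta1[] <- take(length(beta1))
  }
  .new_mixture(comps, beta0, beta1, model$x0_names, class(model)[1])
}

#' Canonical class ordering
#'
#' Reorders the regimes by ascending allostatic-target intercept (first
#' biomarker) and re-expresses the membership coefficients relative to the
#' new reference class, resolving the label-switching indeterminacy of
#' mixture fits.
#'
#' @param model an `"spm_mixture"`.
#' @return The same model with classes in canonical order.
#' @export
canonicalize_classes <- function(model) {
  stopifnot(inherits(model, "spm_mixture"))
  K <- model$K
  ord <- order(vapply(model$components, function(p) p$f1_0[1], numeric(1)))
  if (all(ord == seq_len(K))) return(model)
  eta0 <- c(model$beta0, 0)[ord]
  beta0 <- eta0[-K] - eta0[K]
  beta1 <- model$beta1
  if (!is.null(beta1)) {
    eta1 <- rbind(beta1, 0)[ord, , drop = FALSE]
    beta1 <- sweep(eta1[-K, , drop = FALSE], 2, eta1[K, ], "-")
  }
  .new_mixture(model$components[ord], beta0, beta1, model$x0_names,
               class(model)[1])
}

#' Fit the latent-class model
#'
#' Direct maximization of the observed-data mixture likelihood
#' ([mixture_loglik()]) over the free regime coefficients and membership
#' coefficients, with multi-start optimization; the fitted classes are
#' returned in canonical order (ascending allostatic-target intercept).
#'
#' @inheritParams spm_fit
#' @param K number of latent classes.
#' @param template starting model: a single [spm_params()] (replicated with
#'   the class allostatic-target intercepts spread by one empirical
#'   biomarker SD), a list of K [spm_params()], or a full
#'   [latent_class_model()].
#' @param free_class regime coefficient names estimated separately in every
#'   class.
#' @param free_shared regime coefficient names estimated once, shared by
#'   all classes.
#' @param free_beta estimate the membership coefficients.
#' @param x0_names membership covariates (when `template` is not already a
#'   mixture model).
#' @return An `"spm_fit"` whose `model` element is the fitted
#'   [latent_class_model()]; `empty_classes` flags classes whose prior mass
#'   drops below `1/(10 n)`.
#' @export
fit_latent <- function(cohort, K, template, free_class = "f1_0",
                       free_shared = character(), free_beta = TRUE,
                       x0_names = NULL, options = fit_options()) {
  model0 <- .as_start_mixture(template, K, cohort, x0_names,
                              "latent_class_model")
  u0 <- .mix_pack(model0, free_shared, free_class, free_beta && K > 1L)
  if (length(u0) == 0L) stop("no free parameters", call. = FALSE)
  hmax <- options$h_max
  negll <- function(u) {
    m <- .mix_unpack(u, model0, free_shared, free_class, free_beta && K > 1L)
    -mixture_loglik(m, cohort, h_max = hmax)
  }
  eng <- .mle_multistart(negll, u0, options)
  fit <- .make_fit(eng, function(u)
    canonicalize_classes(.mix_unpack(u, model0, free_shared, free_class,
                                     free_beta && K > 1L)),
    names(u0), options, cohort, negll, kind = "latent")
  fit$model <- fit$params
  fit$params <- NULL
  fit$K <- K
  pbar <- if (is.null(fit$model$x0_names))
    class_probabilities(fit$model)
  else colMeans(class_probabilities(
    fit$model, cohort$surv[, fit$model$x0_names, drop = FALSE]))
  fit$empty_classes <- which(pbar < 1 / (10 * nrow(cohort$surv)))
  fit$BIC <- fit$n_free * log(nrow(cohort$surv)) - 2 * fit$logLik
  fit
}

.as_start_mixture <- function(template, K, cohort, x0_names, cls) {
  if (inherits(template, "spm_mixture")) {
    stopifnot(template$K == K)
    return(.new_mixture(template$components, template$beta0, template$beta1,
                        template$x0_names, cls))
  }
  if (inherits(template, "spm_params")) {
    comps <- replicate(K, template, simplify = FALSE)
    if (K > 1L) {
      sdy <- stats::sd(cohort$long$y1)
      shift <- seq(-1, 1, length.out = K) * sdy
      for (k in seq_len(K)) {
        comps[[k]]$f1_0[1] <- comps[[k]]$f1_0[1] + shift[k]
        comps[[k]]$f0_0[1] <- comps[[k]]$f0_0[1] + shift[k]
        comps[[k]]$m0[1] <- comps[[k]]$m0[1] + shift[k]
      }
    }
  } else if (is.list(template) && length(template) == K) {
    comps <- template
  } else stop("`template` must be spm_params, a list of K spm_params, or a mixture model", # nolint
              call. = FALSE)
  beta1 <- if (is.null(x0_names)) NULL else
    matrix(0, K - 1L, length(x0_names))
  .new_mixture(comps, numeric(K - 1L), beta1, x0_names, cls)
}

#' Sensitivity analysis over the number of classes
#'
#' Fits the latent-class model for each K in `K_list` and reports the
#' comparison table; the row with the lowest BIC is flagged as the
#' recommendation, but no model is selected silently.  A likelihood-ratio
#' test across different K is deliberately not offered: the null hypothesis
#' sits on the boundary of the parameter space and the chi-square reference
#' does not apply.
#'
#' @inheritParams fit_latent
#' @param K_list numbers of classes to try.
#' @return Data frame with one row per K (`logLik`, `k`, `AIC`, `BIC`,
#'   `recommended`), with the fits attached as attribute `"fits"`.
#' @export
select_K <- function(cohort, K_list, template, free_class = "f1_0",
                     free_shared = character(), free_beta = TRUE,
                     x0_names = NULL, options = fit_options()) {
  stopifnot(length(K_list) >= 1L)
  fits <- lapply(K_list, function(K)
    fit_latent(cohort, K, template, free_class = free_class,
               free_shared = free_shared,
               free_beta = free_beta, x0_names = x0_names,
               options = options))
  tab <- data.frame(K = K_list,
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    k = vapply(fits, function(f) f$n_free, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    BIC = vapply(fits, function(f) f$BIC, numeric(1)))
  tab$recommended <- tab$BIC == min(tab$BIC)
  attr(tab, "fits") <- fits
  tab
}
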