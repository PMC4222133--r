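# Maximum-likelihood estimation: multi-start quasi-Newton on the
# unconstrained scale with a Nelder-Mead fallback, numerical-Hessian
# standard errors, likelihood-ratio test for nested models and AIC for
# non-nested ones.

#' Optimizer settings
#'
#' @param starts number of starts: the template values plus `starts - 1`
#'   random log-scale perturbations (each unconstrained coordinate scaled
#'   by an independent factor in `start_dispersion`), guarding against
#'   local maxima of the likelihood.
#' @param optimizer `"BFGS"` (quasi-Newton with numerical gradients) or
#'   `"Nelder-Mead"`; a failed BFGS start is retried with Nelder-Mead.
#' @param maxit maximum iterations per start.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @param start_dispersion range of the multiplicative start perturbation.
#' @param h_max maximum moment-ODE integration step (years) used inside the
#'   likelihood.
#' @param hessian compute the numerical Hessian (central differences) at
#'   the optimum for Wald standard errors.
#' @param hessian_step central-difference step on the unconstrained scale.
#' @param seed optional seed governing the start perturbations.
#' @return List of class `"fit_options"`.
#' @export
fit_options <- function(starts = 5L, optimizer = c("BFGS", "Nelder-Mead"),
                        maxit = 300L, reltol = 1e-10,
                        start_dispersion = c(0.5, 2), h_max = 0.1,
                        hessian = TRUE, hessian_step = 1e-4, seed = NULL) {
  stopifnot(starts >= 1L, maxit >= 1L, reltol > 0, hessian_step > 0)
  structure(list(starts = as.integer(starts),
                 optimizer = match.arg(optimizer), maxit = as.integer(maxit),
                 reltol = reltol, start_dispersion = start_dispersion,
                 h_max = h_max, hessian = hessian,
                 hessian_step = hessian_step, seed = seed),
            class = "fit_options")
}

# central-difference Hessian of f at x
.num_hessian <- function(f, x, h) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# Multi-start minimisation of negll from u0.  Start 1 is u0 itself; the
# others scale each coordinate by an independent factor in `disp` (a zero
# coordinate is nudged by log(factor) so it is perturbed too).
.mle_multistart <- function(negll, u0, options) {
  if (!is.null(options$seed)) set.seed(options$seed)
  safe <- function(u) {
    v <- tryCatch(negll(u), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(u0)
  for (s in seq_len(options$starts - 1L)) {
    f <- stats::runif(length(u0), options$start_dispersion[1],
                      options$start_dispersion[2])
    u <- ifelse(u0 == 0, log(f), u0 * f)
    starts[[s + 1L]] <- u
  }
  recs <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    r <- tryCatch(
      stats::optim(starts[[s]], safe, method = options$optimizer,
                   control = list(maxit = options$maxit,
                                  reltol = options$reltol)),
      error = function(e) NULL)
    if ((is.null(r) || r$convergence > 1) &&
        options$optimizer != "Nelder-Mead") {
      r <- tryCatch(
        stats::optim(starts[[s]], safe, method = "Nelder-Mead",
                     control = list(maxit = 5L * options$maxit,
                                    reltol = options$reltol)),
        error = function(e) NULL)
    }
    recs[[s]] <- if (is.null(r))
      list(start = starts[[s]], value = Inf, par = starts[[s]],
           convergence = 99L, counts = NA_integer_)
    else list(start = starts[[s]], value = r$value, par = r$par,
              convergence = r$convergence,
              counts = unname(r$counts[1]))
  }
  vals <- vapply(recs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals)))
    stop("all optimization starts failed; per-start diagnostics attached",
         call. = FALSE)
  # highest log-likelihood; within 1e-6, fewest function evaluations
  best <- order(vals, vapply(recs, function(r)
    ifelse(is.na(r$counts), Inf, r$counts), numeric(1)))[1]
  near <- which(vals <= vals[best] + 1e-6)
  if (length(near) > 1L) {
    cnt <- vapply(recs[near], function(r)
      ifelse(is.na(r$counts), Inf, r$counts), numeric(1))
    best <- near[which.min(cnt)]
  }
  list(par = recs[[best]]$par, value = vals[best], starts = recs,
       converged = recs[[best]]$convergence == 0L)
}

# Shared assembly of a fit object from the engine result
.make_fit <- function(eng, unpack_fn, coef_names, options, cohort,
                      negll, kind) {
  k <- length(eng$par)
  logL <- -eng$value
  fit <- list(kind = kind, par_u = stats::setNames(eng$par, coef_names),
              logLik = logL, n_free = k, AIC = 2 * k - 2 * logL,
              converged = eng$converged,
              starts = data.frame(
                start = seq_along(eng$starts),
                value = vapply(eng$starts, function(r) -r$value, numeric(1)),
                convergence = vapply(eng$starts, function(r)
                  as.integer(r$convergence), integer(1))),
              options = options,
              n = nrow(cohort$surv),
              data_id = c(nrow(cohort$surv), sum(cohort$surv$tau),
                          sum(cohort$surv$delta)))
  fit$params <- unpack_fn(eng$par)
  if (isTRUE(options$hessian)) {
    H <- .num_hessian(function(u) {
      v <- tryCatch(negll(u), error = function(e) NA_real_)
      if (!is.finite(v)) NA_real_ else v
    }, eng$par, options$hessian_step)
    fit$hessian <- H
    ok <- all(is.finite(H))
    ev <- if (ok) eigen(H, symmetric = TRUE, only.values = TRUE)$values else -1
    if (ok && min(ev) > 0) {
      V <- solve(H)
      fit$vcov_u <- V
      fit$se_u <- stats::setNames(sqrt(diag(V)), coef_names)
      fit$hessian_pd <- TRUE
    } else {
      fit$hessian_pd <- FALSE
      fit$se_u <- stats::setNames(rep(NA_real_, k), coef_names)
    }
  }
  class(fit) <- "spm_fit"
  fit
}

#' @export
print.spm_fit <- function(x, ...) {
  cat(sprintf("<spm_fit:%s> logLik = %.4f, k = %d, AIC = %.2f%s\n",
              x$kind, x$logLik, x$n_free, x$AIC,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- data.frame(estimate_u = round(x$par_u, 6))
  if (!is.null(x$se_u)) est$se_u <- round(x$se_u, 6)
  print(est)
  invisible(x)
}

#' @export
logLik.spm_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_free, class = "logLik")
}

#' Fit the basic stochastic process model by maximum likelihood
#'
#' Maximizes [cohort_loglik()] over the free coefficients (on the
#' unconstrained codec scale) with multi-start optimization; standard
#' errors come from the inverse numerical Hessian, mapped to the natural
#' scale by the delta method.
#'
#' @param cohort an [spm_cohort()].
#' @param template an [spm_params()] supplying starting values for free
#'   coefficients and the values of fixed ones.
#' @param free character vector of free component names (see [spm_pack()]).
#' @param options a [fit_options()] list.
#' @return An object of class `"spm_fit"`: best-fit `params`, `logLik`,
#'   `AIC`, per-start records, unconstrained estimates `par_u` with
#'   standard errors `se_u`, natural-scale `coef` table, and provenance.
#' @examples
#' \donttest{
#' truth <- spm_params(f1_0 = 100, a0 = -0.2, B = 4, Q0 = 1e-4,
#'                     c0 = -11, theta = 0.09, m0 = 100, gamma0 = 25,
#'                     age_range = c(40, 100))
#' sch <- observation_scheme(seq(40, 90, by = 2), censor_age = 90)
#' co <- simulate_cohort(truth, 300, sch, seed = 1)
#' fit <- spm_fit(co, truth, free = c("Q0", "c0", "theta"),
#'                options = fit_options(starts = 2, seed = 1))
#' }
#' @export
spm_fit <- function(cohort, template, free, options = fit_options()) {
  stopifnot(inherits(cohort, "spm_cohort"), inherits(template, "spm_params"),
            length(free) >= 1L)
  u0 <- spm_pack(template, free)
  arr <- .cohort_arrays(cohort, template)
  sme <- cohort$sigma_me
  hmax <- options$h_max
  negll <- function(u) {
    p <- spm_unpack(u, template, free)
    arr2 <- if (is.null(p$covariates) ||
                !any(c("cov_f1", "cov_f0") %in% free)) {
      # intercept adjustments do not depend on free coords beyond f1_0/f0_0
      a <- arr
      a$F1I <- a$F1I - template$f1_0 + p$f1_0
      a$F0I <- a$F0I - template$f0_0 + p$f0_0
      a
    } else .cohort_arrays(cohort, p)
    ll <- cpp_indiv_logliks(.par_clist(p), arr2$F1I, arr2$F0I, arr2$LMU,
                            arr2$obs_age, arr2$obs_y, arr2$obs_ptr,
                            arr2$t0, arr2$tau, arr2$delta, hmax, sme)
    -sum(ll)
  }
  eng <- .mle_multistart(negll, u0, options)
  fit <- .make_fit(eng, function(u) spm_unpack(u, template, free),
                   names(u0), options, cohort, negll, kind = "basic")
  fit$free <- free
  fit$coef <- .natural_coef(fit, template, free)
  fit
}

# delta-method map of unconstrained SEs to the natural coefficient scale
.natural_coef <- function(fit, template, free) {
  u <- fit$par_u
  val <- function(uu) {
    p <- spm_unpack(uu, template, free)
    unlist(lapply(free, function(f) switch(f,
      B = diag(as.matrix(p$B)),
      Q0 = p$Q0[lower.tri(p$Q0, diag = TRUE)],
      gamma0 = p$gamma0[lower.tri(p$gamma0, diag = TRUE)],
      cov_f1 = as.numeric(p$covariates$f1),
      cov_f0 = as.numeric(p$covariates$f0),
      cov_mu0 = as.numeric(p$covariates$mu0),
      as.numeric(p[[f]]))))
  }
  est <- val(u)
  out <- data.frame(coef = names(u), estimate = unname(est))
  if (!is.null(fit$vcov_u) && all(is.finite(fit$vcov_u))) {
    h <- 1e-6
    Jm <- matrix(0, length(est), length(u))
    for (i in seq_along(u)) {
      e <- replace(numeric(length(u)), i, h)
      Jm[, i] <- (val(u + e) - val(u - e)) / (2 * h)
    }
    V <- Jm %*% fit$vcov_u %*% t(Jm)
    out$se <- sqrt(pmax(diag(V), 0))
    out$lower95 <- out$estimate - 1.96 * out$se
    out$upper95 <- out$estimate + 1.96 * out$se
  }
  out
}

#' Likelihood-ratio test for nested models
#'
#' Fits with different numbers of latent classes are refused: that null
#' hypothesis sits on the boundary of the parameter space, the chi-square
#' reference distribution does not apply, and AIC/BIC comparison should be
#' used instead.
#'
#' @param null_fit,alt_fit `"spm_fit"` objects on the same cohort; the null
#'   model's free-parameter set must be a subset of the alternative's.
#' @param check set `FALSE` to skip the nestedness check (e.g. when nesting
#'   holds structurally but the coefficient names differ).
#' @return List with `statistic` (\eqn{2(\ell_1 - \ell_0)}, floored at 0),
#'   `df` (difference in free-parameter counts) and `p.value` from the
#'   chi-square reference distribution.
#' @export
lr_test <- function(null_fit, alt_fit, check = TRUE) {
  stopifnot(inherits(null_fit, "spm_fit"), inherits(alt_fit, "spm_fit"))
  if (!isTRUE(all.equal(null_fit$data_id, alt_fit$data_id)))
    stop("fits are not on the same cohort", call. = FALSE)
  if (!is.null(null_fit$K) && !is.null(alt_fit$K) &&
      null_fit$K != alt_fit$K)
    stop("likelihood-ratio tests across different numbers of latent classes ",
         "are not offered (the null lies on the boundary of the parameter ",
         "space and the chi-square reference fails); compare AIC/BIC instead",
         call. = FALSE)
  if (check) {
    n0 <- names(null_fit$par_u); n1 <- names(alt_fit$par_u)
    if (!all(n0 %in% n1))
      stop("models are not nested: null has free parameters absent from ",
           "the alternative (", paste(setdiff(n0, n1), collapse = ", "), ")",
           call. = FALSE)
  }
  df <- alt_fit$n_free - null_fit$n_free
  if (df < 1L)
    stop("alternative must have more free parameters than the null",
         call. = FALSE)
  stat <- max(0, 2 * (alt_fit$logLik - null_fit$logLik))
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2k - 2 logL`; for comparing non-nested models on the same cohort.
#' @param fit an `"spm_fit"`.
#' @return Scalar AIC.
#' @export
spm_aic <- function(fit) {
  stopifnot(inherits(fit, "spm_fit"))
  2 * fit$n_free - 2 * fit$logLik
}

#' Rank fits by AIC
#'
#' @param ... named `"spm_fit"` objects fitted to the same cohort.
#' @return Data frame sorted by ascending AIC (ties broken by fewer free
#'   parameters), with `dAIC` relative to the best model.
#' @export
compare_aic <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  ids <- lapply(fits, function(f) f$data_id)
  if (length(fits) > 1L &&
      !all(vapply(ids[-1], function(d) isTRUE(all.equal(d, ids[[1]])),
                  logical(1))))
    stop("fits compare different cohorts", call. = FALSE)
  tab <- data.frame(model = names(fits),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    k = vapply(fits, function(f) f$n_free, numeric(1)),
                    AIC = vapply(fits, spm_aic, numeric(1)))
  tab <- tab[order(tab$AIC, tab$k), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}
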