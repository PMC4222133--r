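# Synthetic-cohort generator: Euler-Maruyama trajectories from the
# diffusion, event times from the quadratic hazard, sparse examination
# schedules, latent-class membership, partial genotyping.  Doubles as the
# Monte-Carlo oracle for the moment-equation likelihood.  All randomness
# flows through R's RNG, so set.seed() makes every output reproducible.

#' Examination schedule for a simulated cohort
#'
#' @param ages strictly increasing examination ages shared by all
#'   individuals (per-individual jitter optional).
#' @param censor_age administrative censoring age (> first examination).
#' @param miss_prob per-visit probability that an examination is missed.
#' @param sigma_me measurement-error SD added to each recorded biomarker
#'   (0 = process observed exactly, the model's default reading).
#' @param jitter_sd SD of Gaussian jitter applied per individual per visit
#'   (truncated so ages stay increasing).
#' @return An object of class `"observation_scheme"`.
#' @export
observation_scheme <- function(ages, censor_age, miss_prob = 0,
                               sigma_me = 0, jitter_sd = 0) {
  stopifnot(all(diff(ages) > 0), censor_age > ages[1],
            miss_prob >= 0, miss_prob <= 1, sigma_me >= 0, jitter_sd >= 0)
  structure(list(ages = as.numeric(ages), censor_age = censor_age,
                 miss_prob = miss_prob, sigma_me = sigma_me,
                 jitter_sd = jitter_sd), class = "observation_scheme")
}

#' Simulate one biomarker trajectory and its event time
#'
#' Euler-Maruyama on a fine grid:
#' \eqn{y_{k+1} = y_k + a(t_k)(y_k - f_1(t_k))\,dt + B\sqrt{dt}\,z_k}.
#' At every step the event fires with probability
#' \eqn{1 - \exp(-\mu(t_k, y_k)\,dt)}; the event age is reported at the
#' step midpoint.
#'
#' @inheritParams marginal_survival
#' @param y0 starting biomarker vector, or `"draw"` to sample from the
#'   initial law \eqn{N(m_0, \gamma_0)}.
#' @param dt step in years.
#' @param horizon administrative censoring age.
#' @param keep_path return the full fine-grid trajectory (set `FALSE` when
#'   only the event time is needed).
#' @return List with `event` (logical), `age_end` (event or censoring age),
#'   and, when kept, `time` and `y` (J x steps matrix).
#' @export
simulate_path <- function(params, t0, horizon, y0 = "draw", x = NULL,
                          dt = 0.05, keep_path = TRUE) {
  stopifnot(dt > 0, horizon > t0)
  ad <- .cov_adjust(params, x)
  if (identical(y0, "draw")) {
    L <- .chol_psd(params$gamma0)
    y0 <- params$m0 + drop(L %*% stats::rnorm(params$dim))
  }
  cpp_simulate_path(.par_clist(params), ad$f1i, ad$f0i, ad$lmu,
                    t0, as.numeric(y0), dt, horizon, keep_path)
}

.chol_psd <- function(M) {
  M <- as.matrix(M)
  if (max(abs(M)) == 0) return(M * 0)
  t(chol(M))
}

# multinomial-logit probabilities; beta0 length K-1, beta1 (K-1) x p,
# class K is the reference with linear predictor 0
.multilogit_p <- function(beta0, beta1 = NULL, x0 = NULL) {
  eta <- beta0
  if (!is.null(beta1) && length(beta1) > 0 && !is.null(x0))
    eta <- eta + drop(as.matrix(beta1) %*% as.numeric(x0))
  e <- exp(c(eta, 0))
  e / sum(e)
}

#' Draw a latent-class / genotype label
#'
#' Multinomial-logistic membership with class K as the reference category
#' (linear predictor fixed at 0), so the probabilities are
#' \eqn{p_k = e^{\beta_{0k} + \beta_{1k}^\top x^0} / (1 + \sum_c e^{\beta_{0c} + \beta_{1c}^\top x^0})}.
#'
#' @param beta0 intercepts for classes 1..K-1.
#' @param beta1 optional (K-1) x p coefficient matrix on the baseline
#'   covariates.
#' @param x0 baseline covariate vector.
#' @return List with `class` (integer in 1..K) and the probability vector
#'   `p` (sums to one).
#' @export
sample_class <- function(beta0, beta1 = NULL, x0 = NULL) {
  p <- .multilogit_p(beta0, beta1, x0)
  list(class = sample.int(length(p), 1L, prob = p), p = p)
}

#' Simulate a cohort
#'
#' For each individual: a class label is drawn from the membership model
#' (single-regime models have one class), the trajectory and event time are
#' simulated under that regime, examinations are recorded at the scheme
#' ages that precede the terminal age (with optional missed visits and
#' measurement noise), and the label is retained as the `genotype` column
#' with probability `genotyped_fraction` (else recorded missing).
#'
#' @param model an [spm_params()] (single regime) or a
#'   [latent_class_model()] / [genetic_model()] (K regimes + membership).
#' @param n number of individuals.
#' @param scheme an [observation_scheme()].
#' @param genotyped_fraction probability that an individual's true label is
#'   recorded; use 0 for purely latent classes.
#' @param t0 entry age, a scalar or length-n vector (default: first
#'   scheme age).
#' @param covariates optional data frame (n rows) of baseline covariates;
#'   its columns must cover both the dynamics covariates and the
#'   membership covariates of the model.
#' @param dt Euler step in years.
#' @param seed optional seed set before any draw.
#' @return An [spm_cohort()] with attributes `truth` (the generating
#'   model), `truth_class` (true labels) and `seed`.
#' @export
simulate_cohort <- function(model, n, scheme, genotyped_fraction = 1,
                            t0 = NULL, covariates = NULL, dt = 0.05,
                            seed = NULL) {
  stopifnot(inherits(scheme, "observation_scheme"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(model, "spm_params")) {
    comps <- list(model)
    beta0 <- numeric(0)
    beta1 <- NULL
    x0_names <- NULL
  } else if (inherits(model, "spm_mixture")) {
    comps <- model$components
    beta0 <- model$beta0
    beta1 <- model$beta1
    x0_names <- model$x0_names
  } else stop("`model` must be spm_params, latent_class_model or genetic_model",
              call. = FALSE)
  K <- length(comps)
  J <- comps[[1]]$dim
  if (is.null(t0)) t0 <- scheme$ages[1]
  t0 <- rep_len(as.numeric(t0), n)

  # membership draws
  if (K == 1L) {
    cls <- rep(1L, n)
  } else {
    cls <- integer(n)
    for (i in seq_len(n)) {
      x0 <- if (is.null(x0_names)) NULL else
        as.numeric(covariates[i, x0_names])
      cls[i] <- sample_class(beta0, beta1, x0)$class
    }
  }

  # per-individual covariate-adjusted intercepts under the assigned regime
  F1I <- matrix(0, J, n); F0I <- matrix(0, J, n); LMU <- numeric(n)
  for (i in seq_len(n)) {
    pk <- comps[[cls[i]]]
    xi <- if (is.null(pk$covariates)) NULL else
      as.numeric(covariates[i, pk$covariates$names])
    ad <- .cov_adjust(pk, xi)
    F1I[, i] <- ad$f1i; F0I[, i] <- ad$f0i; LMU[i] <- ad$lmu
  }

  # examination schedule (shared grid, optional per-individual jitter)
  exam <- vector("list", n)
  for (i in seq_len(n)) {
    a <- scheme$ages[scheme$ages >= t0[i] - 1e-9]
    if (scheme$jitter_sd > 0 && length(a) > 1) {
      a <- a + c(0, stats::rnorm(length(a) - 1L, 0, scheme$jitter_sd))
      a <- sort(a)
      a <- a[a >= t0[i]]
    }
    exam[[i]] <- a
  }
  exam_age <- unlist(exam)
  exam_ptr <- c(0L, cumsum(lengths(exam)))

  sim <- cpp_simulate_cohort(lapply(comps, .par_clist), cls, F1I, F0I, LMU,
                             t0, exam_age, exam_ptr,
                             rep(scheme$censor_age, n), dt,
                             scheme$sigma_me, scheme$miss_prob)
  nobs <- diff(sim$obs_ptr)
  long <- data.frame(id = rep(seq_len(n), nobs), age = sim$obs_age)
  for (j in seq_len(J)) long[[paste0("y", j)]] <- sim$obs_y[j, ]
  surv <- data.frame(id = seq_len(n), t0 = t0, tau = as.numeric(sim$tau),
                     delta = as.integer(sim$delta))
  if (!is.null(covariates)) surv <- cbind(surv, covariates)
  observed <- stats::runif(n) < genotyped_fraction
  surv$genotype <- ifelse(observed, cls, NA_integer_)
  cvn <- unique(c(
    if (!is.null(comps[[1]]$covariates)) comps[[1]]$covariates$names,
    x0_names))
  out <- spm_cohort(long, surv, dim = J,
                    covariate_names = if (length(cvn)) cvn else NULL,
                    sigma_me = scheme$sigma_me)
  attr(out, "truth") <- model
  attr(out, "truth_class") <- cls
  attr(out, "seed") <- seed
  out
}

#' Monte-Carlo marginal survival
#'
#' Fraction of simulated trajectories (initial value drawn from the initial
#' law) surviving past each age; the simulation oracle against which the
#' moment-equation survival is validated.
#'
#' @inheritParams marginal_survival
#' @param n_paths number of simulated trajectories.
#' @param dt Euler step in years.
#' @return Data frame with `age`, `survival` and the binomial Monte-Carlo
#'   standard error `se`.
#' @export
mc_survival <- function(params, t0, ages, n_paths = 1e5, x = NULL,
                        dt = 0.05) {
  stopifnot(all(diff(ages) > 0), all(ages >= t0))
  ad <- .cov_adjust(params, x)
  S <- as.numeric(cpp_mc_survival(.par_clist(params), ad$f1i, ad$f0i,
                                  ad$lmu, t0, dt, ages, as.integer(n_paths)))
  data.frame(age = ages, survival = S,
             se = sqrt(pmax(S * (1 - S), 1e-12) / n_paths))
}
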