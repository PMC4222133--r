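# Continuous-time likelihood via conditional-Gaussian moment equations.
# Between examinations the conditional mean m(t) and covariance gamma(t) of
# the biomarker given survival and past observations obey
#   dm/dt     = a (m - f1) - 2 gamma Q (m - f0)
#   dgamma/dt = a gamma + gamma a' + BB' - 2 gamma Q gamma,
# and the population-averaged hazard is
#   mu_bar(t) = mu0 + (m - f0)' Q (m - f0) + tr(Q gamma).
# Survival conditioning pulls m toward the norm f0 and shrinks gamma; with
# Q = 0 these reduce to the unconditional Ornstein-Uhlenbeck moment
# equations.  The survival integral rides along as an extra coordinate of
# the same fixed-step Runge-Kutta integration.

#' Moment-equation derivatives at one state
#'
#' Pure-R reference implementation of the right-hand side used by the
#' compiled integrator; useful for diagnostics and cross-checks.
#'
#' @inheritParams evaluate_components
#' @param m conditional mean (length J).
#' @param gamma conditional covariance (J x J).
#' @return List with `dm` (length J) and `dgamma` (J x J).
#' @export
moment_derivatives <- function(params, t, m, gamma, x = NULL) {
  cmp <- evaluate_components(params, t, x)
  m <- as.numeric(m)
  gamma <- as.matrix(gamma)
  dm <- drop(cmp$a %*% (m - cmp$f1)) - 2 * drop(gamma %*% cmp$Q %*% (m - cmp$f0))
  dg <- cmp$a %*% gamma + gamma %*% t(cmp$a) + cmp$B %*% t(cmp$B) -
    2 * gamma %*% cmp$Q %*% gamma
  list(dm = dm, dgamma = dg)
}

#' Hazard averaged over the conditional Gaussian law
#'
#' \eqn{\bar\mu(t) = \mu_0 + (m - f_0)^\top Q (m - f_0) + tr(Q\gamma)};
#' always at least the baseline hazard.
#'
#' @inheritParams moment_derivatives
#' @return Non-negative scalar.
#' @export
conditional_hazard <- function(params, t, m, gamma, x = NULL) {
  cmp <- evaluate_components(params, t, x)
  d <- as.numeric(m) - cmp$f0
  as.numeric(cmp$mu0 + t(d) %*% cmp$Q %*% d + sum(diag(cmp$Q %*% as.matrix(gamma))))
}

.check_clip <- function(ll) {
  nc <- attr(ll, "nclip")
  if (!is.null(nc) && nc > 0)
    warning(sprintf("conditional covariance clipped below -1e-10 at %d step(s)",
                    nc), call. = FALSE)
  ll
}

#' Per-individual log-likelihood contributions
#'
#' For each individual: Gaussian one-step-ahead densities of the
#' examinations after the first, minus the integrated conditional hazard
#' from entry to the terminal age, plus the log conditional hazard at the
#' event age for individuals with the event.  The first examination
#' initialises the state (exact reset `m <- y`, `gamma <- 0` when
#' `sigma_me = 0`; a linear-Gaussian filter update otherwise) and is not
#' scored.  Individuals without examinations contribute the survival part
#' propagated from the initial law.
#'
#' @param params an [spm_params()] object.
#' @param cohort an [spm_cohort()].
#' @param h_max maximum integration step in years.
#' @param sigma_me measurement-error SD; defaults to the value the cohort
#'   carries.
#' @return Numeric vector of contributions, one per row of `cohort$surv`.
#' @export
indiv_logliks <- function(params, cohort, h_max = 0.1, sigma_me = NULL) {
  arr <- .cohort_arrays(cohort, params)
  if (is.null(sigma_me)) sigma_me <- cohort$sigma_me
  ll <- cpp_indiv_logliks(.par_clist(params), arr$F1I, arr$F0I, arr$LMU,
                          arr$obs_age, arr$obs_y, arr$obs_ptr,
                          arr$t0, arr$tau, arr$delta, h_max, sigma_me)
  .check_clip(ll)
}

#' Log-likelihood of one individual
#'
#' @param params an [spm_params()] object.
#' @param individual a record as returned by [cohort_individual()], or any
#'   list with `t0`, `tau`, `delta`, optional `x`, and an `obs` data frame.
#' @inheritParams indiv_logliks
#' @return Scalar log-likelihood contribution.
#' @export
individual_loglik <- function(params, individual, h_max = 0.1, sigma_me = 0) {
  obs <- individual$obs
  J <- params$dim
  long <- data.frame(id = 1L, age = obs$age)
  for (j in seq_len(J)) long[[paste0("y", j)]] <- obs[[paste0("y", j)]]
  surv <- data.frame(id = 1L, t0 = individual$t0, tau = individual$tau,
                     delta = individual$delta)
  cvn <- NULL
  if (!is.null(params$covariates)) {
    cvn <- params$covariates$names
    for (k in seq_along(cvn)) surv[[cvn[k]]] <- individual$x[k]
  }
  co <- spm_cohort(long, surv, dim = J, covariate_names = cvn,
                   sigma_me = sigma_me)
  as.numeric(indiv_logliks(params, co, h_max = h_max, sigma_me = sigma_me))
}

#' Total log-likelihood of a cohort
#'
#' Sum of [indiv_logliks()]; invariant to the ordering of individuals.
#'
#' @inheritParams indiv_logliks
#' @return Scalar log-likelihood with attribute `n` (number of individuals).
#' @export
cohort_loglik <- function(params, cohort, h_max = 0.1, sigma_me = NULL) {
  ll <- indiv_logliks(params, cohort, h_max = h_max, sigma_me = sigma_me)
  structure(sum(ll), n = length(ll))
}

#' Marginal survival implied by the model
#'
#' \eqn{S(t) = \exp(-\int_{t_0}^t \bar\mu(s)\,ds)} with the moments
#' propagated from the initial law and no observation resets.
#'
#' @inheritParams indiv_logliks
#' @param x covariate vector (omit for covariate-free models).
#' @param t0 entry age.
#' @param ages increasing vector of ages (> = `t0`) at which to report.
#' @return Data frame with columns `age` and `survival` (non-increasing,
#'   `survival = 1` at `t0`).
#' @export
marginal_survival <- function(params, t0, ages, x = NULL, h_max = 0.1) {
  stopifnot(all(diff(ages) > 0), all(ages >= t0))
  ad <- .cov_adjust(params, x)
  S <- cpp_marginal_survival(.par_clist(params), ad$f1i, ad$f0i, ad$lmu,
                             t0, ages, h_max)
  data.frame(age = ages, survival = as.numeric(S))
}

#' Discrete-time version of the likelihood
#'
#' Treats the biomarker as a discrete-time Gaussian autoregression on a
#' fixed step grid: transition factors
#' \eqn{N(y_{j+1};\; y_j + a(t_j)(y_j - f_1(t_j))\Delta,\; BB^\top\Delta)},
#' per-step survival factors \eqn{\exp(-\mu(t_j, y_j)\Delta)} with the last
#' observed value held fixed after the final examination, and the event
#' factor \eqn{1 - \exp(-\mu\Delta)} at the event step.
#'
#' @inheritParams indiv_logliks
#' @param step grid step \eqn{\Delta} in years; every gap between
#'   consecutive examinations must equal it (within `tol`) unless
#'   `bin = TRUE`.
#' @param bin snap examination ages to the nearest grid point (keeping the
#'   first observation per bin) instead of erroring on off-grid ages.
#' @param tol tolerance for the on-grid check.
#' @return Scalar total log-likelihood.
#' @export
discrete_time_loglik <- function(params, cohort, step, bin = FALSE,
                                 tol = 1e-6) {
  if (bin) {
    long <- cohort$long
    t0_of <- cohort$surv$t0[match(long$id, cohort$surv$id)]
    long$age <- t0_of + round((long$age - t0_of) / step) * step
    keep <- !duplicated(long[, c("id", "age")])
    cohort <- spm_cohort(long[keep, , drop = FALSE], cohort$surv,
                         dim = cohort$dim,
                         covariate_names = cohort$covariate_names,
                         sigma_me = cohort$sigma_me)
  }
  arr <- .cohort_arrays(cohort, params)
  ll <- cpp_discrete_logliks(.par_clist(params), arr$F1I, arr$F0I, arr$LMU,
                             arr$obs_age, arr$obs_y, arr$obs_ptr,
                             arr$t0, arr$tau, arr$delta, step, tol)
  sum(ll)
}
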