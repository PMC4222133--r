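#' Parameters of a stochastic process model of aging
#'
#' Bundles every parametric component of one model regime.  The biomarker
#' vector \eqn{Y_t} (dimension `dim` = J) follows the mean-reverting diffusion
#' \deqn{dY_t = a(t,X)\,(Y_t - f_1(t,X))\,dt + B\,dW_t,}
#' and the event hazard is the quadratic form
#' \deqn{\mu(t, Y_t, X) = \mu_0(t,X) + (Y_t - f_0(t,X))^\top Q(t)\,(Y_t - f_0(t,X)).}
#'
#' Parametric forms (all pluggable coefficients, linear in age by default):
#' \itemize{
#'   \item feedback (adaptive capacity): \eqn{a(t) = a_0 + a_1 t} (J x J);
#'   \item allostatic target: \eqn{f_1(t) = f_{1,0} + f_{1,1} t} plus additive
#'     covariate shifts on the intercept;
#'   \item physiological norm: \eqn{f_0(t) = f_{0,0} + f_{0,1} t} plus shifts;
#'   \item diffusion: constant matrix `B` (default diagonal);
#'   \item hazard curvature (stress resistance): \eqn{Q(t) = Q_0 \max(1 + q_1 t, 0)},
#'     `Q0` symmetric non-negative-definite;
#'   \item baseline hazard: Gompertz \eqn{\mu_0(t) = \exp(c_0 + \theta t)},
#'     multiplied by \eqn{\exp(x^\top \beta_{\mu})} for covariates;
#'   \item initial law: \eqn{Y_{t_0} \sim N(m_0, \gamma_0)}.
#' }
#'
#' @param dim number of biomarkers J.
#' @param a0,a1 feedback intercept and age slope; scalars (expanded to
#'   diagonal J x J) or J x J matrices.  Negative eigenvalues of `a(t)` give
#'   the mean-reverting (homeostatic) regime.
#' @param f1_0,f1_1 allostatic-target intercept and slope (length-J).
#' @param f0_0,f0_1 physiological-norm intercept and slope (length-J).
#'   Defaults to the allostatic target when omitted.
#' @param B diffusion matrix; scalar/vector expanded to `diag(B, J)`.
#' @param Q0 hazard-curvature matrix at `1 + q1 t = 1`; scalar or J x J
#'   symmetric non-negative-definite.
#' @param q1 relative age slope of Q; `Q(t)` is clipped at zero.
#' @param c0,theta Gompertz log-baseline-hazard intercept and slope
#'   (`theta` unconstrained in sign; `theta = 0` gives a constant hazard).
#' @param m0,gamma0 mean and covariance of the biomarker at entry.
#' @param covariates optional [spm_covariates()] specification.
#' @param age_range ages (years) over which the model is declared valid.
#'
#' @return An object of class `"spm_params"`.
#' @seealso [evaluate_components()], [validate_model()], [spm_pack()]
#' @examples
#' p <- spm_params(f1_0 = 100, f1_1 = 0.5, a0 = -0.2, B = 4,
#'                 Q0 = 5e-5, c0 = -10.5, theta = 0.085,
#'                 m0 = 120, gamma0 = 25, age_range = c(40, 110))
#' evaluate_components(p, t = 60)
#' @export
spm_params <- function(dim = 1L,
                       a0 = -0.2, a1 = 0,
                       f1_0, f1_1 = 0,
                       f0_0 = f1_0, f0_1 = f1_1,
                       B = 1,
                       Q0 = 0, q1 = 0,
                       c0 = -10, theta = 0.08,
                       m0 = f1_0, gamma0 = 0,
                       covariates = NULL,
                       age_range = c(30, 110)) {
  J <- as.integer(dim)
  if (J < 1L) stop("`dim` must be a positive integer", call. = FALSE)
  as_sqmat <- function(v, what) {
    if (is.matrix(v)) {
      if (!all(dim(v) == c(J, J)))
        stop(sprintf("`%s` must be %d x %d", what, J, J), call. = FALSE)
      v
    } else if (length(v) %in% c(1L, J)) {
      diag(as.numeric(v), J, J)
    } else stop(sprintf("`%s` has incompatible length", what), call. = FALSE)
  }
  as_vec <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- rep(v, J)
    if (length(v) != J)
      stop(sprintf("`%s` must have length %d", what, J), call. = FALSE)
    v
  }
  p <- structure(list(
    dim = J,
    a0 = as_sqmat(a0, "a0"), a1 = as_sqmat(a1, "a1"),
    f1_0 = as_vec(f1_0, "f1_0"), f1_1 = as_vec(f1_1, "f1_1"),
    f0_0 = as_vec(f0_0, "f0_0"), f0_1 = as_vec(f0_1, "f0_1"),
    B = as_sqmat(B, "B"),
    Q0 = as_sqmat(Q0, "Q0"), q1 = as.numeric(q1),
    c0 = as.numeric(c0), theta = as.numeric(theta),
    m0 = as_vec(m0, "m0"), gamma0 = as_sqmat(gamma0, "gamma0"),
    covariates = covariates,
    age_range = as.numeric(age_range)
  ), class = "spm_params")
  if (length(p$age_range) != 2L || diff(p$age_range) <= 0)
    stop("`age_range` must be c(t_min, t_max) with t_min < t_max", call. = FALSE)
  if (!is.null(covariates)) {
    stopifnot(inherits(covariates, "spm_covariates"))
    if (nrow(covariates$f1) != J)
      stop("covariate effect matrices must have `dim` rows", call. = FALSE)
  }
  if (max(abs(p$Q0 - t(p$Q0))) > 1e-12)
    stop("`Q0` must be symmetric", call. = FALSE)
  if (max(abs(p$gamma0 - t(p$gamma0))) > 1e-12)
    stop("`gamma0` must be symmetric", call. = FALSE)
  p
}

#' Baseline-covariate specification for a model regime
#'
#' Covariates enter as additive shifts on the intercepts of the allostatic
#' target and the physiological norm, and log-linearly (proportional-hazards
#' style) on the Gompertz baseline hazard.  The feedback, diffusion and
#' hazard-curvature components are covariate-free; regime-specific versions
#' of those are available through the latent-class and genetic models.
#'
#' @param names character vector of covariate names (columns of the
#'   individual-level table).
#' @param f1,f0 J x p matrices (or length-p vectors for J = 1) of intercept
#'   shifts per unit covariate.
#' @param mu0 length-p vector of log hazard ratios.
#' @return An object of class `"spm_covariates"`.
#' @export
spm_covariates <- function(names, f1 = 0, f0 = 0, mu0 = 0) {
  p <- length(names)
  fix <- function(v) {
    if (is.matrix(v)) v else matrix(rep_len(as.numeric(v), p), nrow = 1)
  }
  structure(list(names = names, f1 = fix(f1), f0 = fix(f0),
                 mu0 = rep_len(as.numeric(mu0), p)),
            class = "spm_covariates")
}

#' @export
print.spm_params <- function(x, ...) {
  cat(sprintf("<spm_params> J = %d biomarker(s), ages [%g, %g]\n",
              x$dim, x$age_range[1], x$age_range[2]))
  fmt <- function(m) paste(signif(m, 4), collapse = " ")
  cat(sprintf("  feedback a(t):   a0 = %s, a1 = %s\n", fmt(x$a0), fmt(x$a1)))
  cat(sprintf("  target f1(t):    %s + %s t\n", fmt(x$f1_0), fmt(x$f1_1)))
  cat(sprintf("  norm f0(t):      %s + %s t\n", fmt(x$f0_0), fmt(x$f0_1)))
  cat(sprintf("  diffusion B:     %s\n", fmt(x$B)))
  cat(sprintf("  curvature Q(t):  %s * max(1 + %g t, 0)\n", fmt(x$Q0), x$q1))
  cat(sprintf("  baseline mu0(t): exp(%g + %g t)\n", x$c0, x$theta))
  cat(sprintf("  initial law:     N(%s; %s)\n", fmt(x$m0), fmt(x$gamma0)))
  if (!is.null(x$covariates))
    cat("  covariates:      ", paste(x$covariates$names, collapse = ", "), "\n")
  invisible(x)
}

# covariate vector for an individual -> adjusted intercepts and log-mu shift
.cov_adjust <- function(params, x = NULL) {
  J <- params$dim
  f1i <- params$f1_0
  f0i <- params$f0_0
  lmu <- 0
  cv <- params$covariates
  if (!is.null(cv)) {
    if (is.null(x)) x <- numeric(length(cv$names))
    if (length(x) != length(cv$names))
      stop(sprintf("covariate vector has length %d, expected %d (%s)",
                   length(x), length(cv$names),
                   paste(cv$names, collapse = ", ")), call. = FALSE)
    x <- as.numeric(x)
    f1i <- f1i + drop(cv$f1 %*% x)
    f0i <- f0i + drop(cv$f0 %*% x)
    lmu <- sum(cv$mu0 * x)
  } else if (!is.null(x) && length(x) > 0) {
    stop("covariates supplied but the model declares none", call. = FALSE)
  }
  list(f1i = f1i, f0i = f0i, lmu = lmu)
}

# parameter list handed to the C++ kernels
.par_clist <- function(params) {
  list(J = params$dim, a0 = params$a0, a1 = params$a1,
       f1_1 = params$f1_1, f0_1 = params$f0_1,
       BBt = params$B %*% t(params$B),
       Q0 = params$Q0, q1 = params$q1,
       c0 = params$c0, theta = params$theta,
       m0 = params$m0, gamma0 = params$gamma0)
}

#' Evaluate every model component at one age
#'
#' @param params an [spm_params()] object.
#' @param t age in years, within the declared `age_range`.
#' @param x covariate vector conforming to the model's covariate
#'   specification (omit for covariate-free models).
#' @return List with elements `a`, `f1`, `f0`, `B`, `Q`, `mu0` evaluated at
#'   `(t, x)`; `Q` is symmetric non-negative-definite and `mu0 >= 0` by
#'   construction.
#' @export
evaluate_components <- function(params, t, x = NULL) {
  stopifnot(inherits(params, "spm_params"), length(t) == 1L)
  if (t < params$age_range[1] || t > params$age_range[2])
    stop(sprintf("age %g outside declared range [%g, %g]", t,
                 params$age_range[1], params$age_range[2]), call. = FALSE)
  ad <- .cov_adjust(params, x)
  list(a = params$a0 + params$a1 * t,
       f1 = ad$f1i + params$f1_1 * t,
       f0 = ad$f0i + params$f0_1 * t,
       B = params$B,
       Q = params$Q0 * max(1 + params$q1 * t, 0),
       mu0 = exp(params$c0 + params$theta * t + ad$lmu))
}

#' Full hazard at a biomarker value
#'
#' The quadratic hazard \eqn{\mu_0(t,x) + (y - f_0)^\top Q(t) (y - f_0)}; its
#' minimum over `y` is `mu0` and is attained at `y = f0(t, x)`.
#' @inheritParams evaluate_components
#' @param y biomarker vector (length J).
#' @return Non-negative scalar hazard (per year).
#' @export
hazard_at <- function(params, t, y, x = NULL) {
  cmp <- evaluate_components(params, t, x)
  d <- as.numeric(y) - cmp$f0
  as.numeric(cmp$mu0 + t(d) %*% cmp$Q %*% d)
}

#' Check model invariants over the declared age range
#'
#' Evaluates the components on a grid (101 ages by default) and reports
#' violations (non-symmetric or indefinite `Q`, negative baseline hazard,
#' indefinite initial covariance, non-finite diffusion) and warnings
#' (positive real part of a feedback eigenvalue anywhere on the range, which
#' makes the dynamics diverge from the allostatic target).
#'
#' @inheritParams evaluate_components
#' @param age_range optional override of the declared range.
#' @param grid_n number of grid ages.
#' @return Data frame with columns `type` ("violation" or "warning"),
#'   `component` and `message`; zero rows when every invariant holds.
#' @export
validate_model <- function(params, age_range = NULL, grid_n = 101L) {
  stopifnot(inherits(params, "spm_params"))
  rng <- if (is.null(age_range)) params$age_range else as.numeric(age_range)
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  out <- list()
  add <- function(type, component, message)
    out[[length(out) + 1L]] <<- data.frame(type = type, component = component,
                                           message = message)
  if (max(abs(params$Q0 - t(params$Q0))) > 1e-10)
    add("violation", "Q", "Q0 is not symmetric")
  if (any(!is.finite(params$B)))
    add("violation", "B", "diffusion entries must be finite")
  evg0 <- eigen(params$gamma0, symmetric = TRUE, only.values = TRUE)$values
  if (min(evg0) < -1e-10)
    add("violation", "gamma0",
        sprintf("initial covariance not non-negative-definite (eigenvalue %.3g)",
                min(evg0)))
  qmin <- Inf; amax <- -Inf; mumin <- Inf
  for (t in grid) {
    Qt <- params$Q0 * max(1 + params$q1 * t, 0)
    qmin <- min(qmin, eigen(Qt, symmetric = TRUE, only.values = TRUE)$values)
    at <- params$a0 + params$a1 * t
    amax <- max(amax, max(Re(eigen(at, only.values = TRUE)$values)))
    mumin <- min(mumin, exp(params$c0 + params$theta * t))
  }
  if (qmin < -1e-10)
    add("violation", "Q",
        sprintf("Q not non-negative-definite on the age range (eigenvalue %.3g)",
                qmin))
  if (mumin < 0)
    add("violation", "mu0", "baseline hazard negative on the age range")
  if (amax > 1e-12)
    add("warning", "a",
        sprintf(paste0("feedback eigenvalue with positive real part (%.3g): ",
                       "dynamics diverge from the allostatic target"), amax))
  if (length(out) == 0)
    data.frame(type = character(), component = character(),
               message = character())
  else do.call(rbind, out)
}
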