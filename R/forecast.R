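# Population-level microsimulation forecasting under "what-if" scenarios:
# aggregate many simulated life histories per arm, with common random
# numbers across arms so scenario contrasts are paired.

#' Intervention scenario
#'
#' Named modifications applied to the model components, e.g. a reduction
#' of the hazard curvature (`Q_scale < 1`: improved stress resistance), a
#' proportional change of the baseline hazard, or shifts of the
#' physiological norm / allostatic target.  `from_age` delays the
#' modification: life histories evolve under the baseline model until that
#' age and under the modified model afterwards.
#'
#' @param Q_scale multiplier on the hazard curvature `Q0`.
#' @param mu0_scale multiplier on the Gompertz baseline hazard.
#' @param B_scale multiplier on the diffusion matrix.
#' @param f0_shift,f1_shift additive shifts (length J or scalar) on the
#'   norm and allostatic-target intercepts.
#' @param a_scale multiplier on the feedback matrix (values > 1 strengthen
#'   homeostatic regulation).
#' @param from_age age at which the modification switches on (default:
#'   from entry).
#' @param label scenario name used in output tables.
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(Q_scale = 1, mu0_scale = 1, B_scale = 1,
                          f0_shift = 0, f1_shift = 0, a_scale = 1,
                          from_age = NULL, label = "scenario") {
  stopifnot(Q_scale >= 0, mu0_scale >= 0, B_scale >= 0, a_scale >= 0)
  structure(list(Q_scale = Q_scale, mu0_scale = mu0_scale,
                 B_scale = B_scale, f0_shift = f0_shift,
                 f1_shift = f1_shift, a_scale = a_scale,
                 from_age = from_age, label = label),
            class = "scenario_spec")
}

#' Apply a scenario to a parameter set
#'
#' @param params an [spm_params()].
#' @param scenario a [scenario_spec()].
#' @return Modified [spm_params()]; errors if the result violates the
#'   model invariants ([validate_model()]).
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- params
  p$Q0 <- p$Q0 * scenario$Q_scale
  p$c0 <- p$c0 + log(max(scenario$mu0_scale, 1e-300))
  p$B <- p$B * scenario$B_scale
  p$f0_0 <- p$f0_0 + scenario$f0_shift
  p$f1_0 <- p$f1_0 + scenario$f1_shift
  p$a0 <- p$a0 * scenario$a_scale
  p$a1 <- p$a1 * scenario$a_scale
  v <- validate_model(p)
  if (any(v$type == "violation"))
    stop("scenario produces an invalid model: ",
         paste(v$message[v$type == "violation"], collapse = "; "),
         call. = FALSE)
  p
}

# one microsimulation arm; returns per-path event ages and biomarker values
# on the grid (NA after death)
.simulate_arm <- function(params, scen_params, from_age, n_sim, t0, grid,
                          x = NULL, dt = 0.05) {
  ad <- .cov_adjust(params, x)
  two_stage <- !is.null(from_age) && from_age > t0
  horizon <- max(grid)
  tau <- numeric(n_sim)
  delta <- logical(n_sim)
  Y <- matrix(NA_real_, n_sim, length(grid))
  cl1 <- .par_clist(params)
  cl2 <- if (!is.null(scen_params)) .par_clist(scen_params)
  ad2 <- if (!is.null(scen_params)) .cov_adjust(scen_params, x)
  L0 <- .chol_psd(params$gamma0)
  J <- params$dim
  for (i in seq_len(n_sim)) {
    y0 <- params$m0 + drop(L0 %*% stats::rnorm(J))
    if (!two_stage) {
      cl <- if (is.null(scen_params)) cl1 else cl2
      adu <- if (is.null(scen_params)) ad else ad2
      r <- cpp_simulate_path(cl, adu$f1i, adu$f0i, adu$lmu, t0, y0, dt,
                             horizon, TRUE)
    } else {
      r1 <- cpp_simulate_path(cl1, ad$f1i, ad$f0i, ad$lmu, t0, y0, dt,
                              from_age, TRUE)
      if (r1$event) {
        r <- r1
      } else {
        ylast <- r1$y[, ncol(r1$y)]
        r2 <- cpp_simulate_path(cl2, ad2$f1i, ad2$f0i, ad2$lmu, from_age,
                                ylast, dt, horizon, TRUE)
        r <- list(event = r2$event, age_end = r2$age_end,
                  time = c(r1$time, r2$time[-1]),
                  y = cbind(r1$y, r2$y[, -1, drop = FALSE]))
      }
    }
    tau[i] <- r$age_end
    delta[i] <- r$event
    alive <- grid <= r$age_end
    if (any(alive)) {
      idx <- pmin(findInterval(grid[alive], r$time), length(r$time))
      Y[i, alive] <- r$y[1, idx]
    }
  }
  list(tau = tau, delta = delta, Y = Y)
}

#' Microsimulation population forecast under a what-if scenario
#'
#' Simulates `n_sim` life histories under the fitted (baseline) model and,
#' when a scenario is given, `n_sim` histories under the modified model
#' using the same random-number stream (common random numbers: with a null
#' scenario both arms are identical, and contrasts are paired).  Reports
#' age-specific survival with Monte-Carlo standard errors, mean biomarker
#' level among survivors, and cumulative event counts, baseline and
#' scenario side by side.
#'
#' @param params baseline [spm_params()].
#' @param t0 entry age of the synthetic population.
#' @param ages increasing grid of projection ages (> = `t0`).
#' @param n_sim simulated life histories per arm (>= 1000 recommended).
#' @param scenario optional [scenario_spec()].
#' @param x covariate vector shared by the population (heterogeneity
#'   beyond the initial law and covariates is out of scope).
#' @param dt Euler step in years.
#' @param seed seed set before each arm (drives the common random
#'   numbers).
#' @return Object of class `"spm_forecast"`: data frame with per-age
#'   baseline columns (`survival`, `se`, `mean_y`, `events`) and, with a
#'   scenario, the matching `*_scen` columns.
#' @export
forecast_population <- function(params, t0, ages, n_sim = 1000L,
                                scenario = NULL, x = NULL, dt = 0.05,
                                seed = 1L) {
  stopifnot(all(diff(ages) > 0), all(ages >= t0), n_sim >= 1L)
  scen_params <- if (!is.null(scenario)) apply_scenario(params, scenario)
  set.seed(seed)
  base <- .simulate_arm(params, NULL, NULL, n_sim, t0, ages, x, dt)
  out <- data.frame(age = ages)
  summarize <- function(arm) {
    S <- vapply(ages, function(a) mean(!(arm$delta & arm$tau <= a)),
                numeric(1))
    list(S = S,
         se = sqrt(pmax(S * (1 - S), 1e-12) / n_sim),
         ybar = colMeans(arm$Y, na.rm = TRUE),
         events = vapply(ages, function(a) sum(arm$delta & arm$tau <= a),
                         numeric(1)))
  }
  b <- summarize(base)
  out$survival <- b$S; out$se <- b$se; out$mean_y <- b$ybar
  out$events <- b$events
  if (!is.null(scenario)) {
    set.seed(seed)  # common random numbers across arms
    scen <- .simulate_arm(params, scen_params,
                          scenario$from_age, n_sim, t0, ages, x, dt)
    s <- summarize(scen)
    out$survival_scen <- s$S; out$se_scen <- s$se
    out$mean_y_scen <- s$ybar; out$events_scen <- s$events
  }
  structure(out, class = c("spm_forecast", "data.frame"),
            n_sim = n_sim, seed = seed,
            scenario = if (!is.null(scenario)) scenario$label)
}
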