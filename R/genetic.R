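# Genetic extension: regime label (genotype) observed for a sub-sample,
# latent for the rest.  Genotyped and non-genotyped parts of the likelihood
# share the same parameters, which is the source of the power gain over a
# genotyped-only analysis.  Genotype missingness is assumed independent of
# the outcome given the baseline covariates (missing at random).

#' Genetic model: genotype-specific regimes plus genotype probabilities
#'
#' Same structure as [latent_class_model()] (genotype probabilities follow
#' the multinomial-logistic form with category K as reference; the default
#' intercept-only model encodes population genotype frequencies), but the
#' likelihood treats recorded genotype labels as observed.
#'
#' @inheritParams latent_class_model
#' @return Object of class `c("genetic_model", "spm_mixture")`.
#' @export
genetic_model <- function(components, beta0 = numeric(length(components) - 1L),
                          beta1 = NULL, x0_names = NULL) {
  .new_mixture(components, beta0, beta1, x0_names, "genetic_model")
}

#' Joint log-likelihood for genotyped and non-genotyped individuals
#'
#' Genotyped individual i with label k: \eqn{\log p_k(x^0_i) + \ell_i^{(k)}}.
#' Non-genotyped: \eqn{\log \sum_k p_k(x^0_i) e^{\ell_i^{(k)}}}.  With no
#' genotyped individuals this is exactly the latent-class
#' [mixture_loglik()]; with everyone genotyped and K = 1 it reduces to
#' [cohort_loglik()].
#'
#' @param model a [genetic_model()] (or any `"spm_mixture"`).
#' @inheritParams indiv_logliks
#' @return Scalar log-likelihood.
#' @export
genetic_loglik <- function(model, cohort, h_max = 0.1, sigma_me = NULL) {
  g <- if ("genotype" %in% names(cohort$surv)) cohort$surv$genotype else
    rep(NA_integer_, nrow(cohort$surv))
  if (any(!is.na(g) & (g < 1 | g > model$K)))
    stop("genotype label outside 1..K", call. = FALSE)
  ll <- .class_logliks(model, cohort, h_max, sigma_me)
  lp <- .log_membership(model, cohort)
  w <- ll + lp
  obs <- !is.na(g)
  tot <- 0
  if (any(obs))
    tot <- tot + sum(w[cbind(which(obs), g[obs])])
  if (any(!obs))
    tot <- tot + sum(apply(w[!obs, , drop = FALSE], 1, .logsumexp))
  tot
}

# effect-design vectors: one column per free effect parameter, K rows
.action_design <- function(mode, K) {
  if (K == 2L) {
    switch(mode,
      shared = matrix(0, 2, 0),
      free = , dominant = , recessive = , additive = matrix(c(0, 1), 2, 1),
      stop("unknown action mode: ", mode, call. = FALSE))
  } else if (K == 3L) {
    switch(mode,
      shared = matrix(0, 3, 0),
      dominant = matrix(c(0, 1, 1), 3, 1),
      recessive = matrix(c(0, 0, 1), 3, 1),
      # heterozygote effect = mean of homozygote effects (unconstrained scale)
      additive = matrix(c(0, 0.5, 1), 3, 1),
      free = cbind(c(0, 1, 0), c(0, 0, 1)),
      stop("unknown action mode: ", mode, call. = FALSE))
  } else stop("action modes are defined for K = 2 or 3 genotype categories",
              call. = FALSE)
}

# genotype-k parameters: base params with `delta` added to the unconstrained
# coordinates of `component`, scaled by the design row e_k
.apply_effect <- function(base, component, delta_mat, e_row) {
  if (length(e_row) == 0L || all(e_row == 0)) return(base)
  u <- spm_pack(base, component)
  u <- u + as.numeric(delta_mat %*% e_row)
  spm_unpack(u, base, component)
}

.genetic_build <- function(base, component, delta, design, K) {
  ncoord <- length(spm_pack(base, component))
  nmode <- ncol(design)
  delta_mat <- matrix(delta, ncoord, nmode)
  lapply(seq_len(K), function(k)
    .apply_effect(base, component, delta_mat, design[k, ]))
}

#' Fit the genetic model
#'
#' Maximizes [genetic_loglik()] over (i) the base regime coefficients in
#' `free`, (ii) the genetic-effect parameters on the declared `component`
#' under the chosen mode of action of the minor allele, and (iii) the
#' genotype-probability intercepts.  The effect acts additively on the
#' unconstrained (codec) scale of the component, so e.g. an effect on `Q0`
#' is a multiplicative change of the hazard curvature.
#'
#' Modes (K = 3 genotype categories of a biallelic marker; category 1 =
#' major-allele homozygote, 3 = minor-allele homozygote): `"shared"` no
#' effect; `"dominant"` categories 2 and 3 share one effect; `"recessive"`
#' only category 3; `"additive"` heterozygote effect equal to half the
#' homozygote effect on the unconstrained scale; `"free"` separate effects
#' for categories 2 and 3.  With K = 2 (carrier / non-carrier) all
#' non-shared modes coincide with one carrier effect.
#'
#' @inheritParams spm_fit
#' @param template base-regime [spm_params()] starting values.
#' @param component regime component carrying the genetic effect
#'   (a codec name, e.g. `"Q0"`, `"a0"`, `"f1_0"`).
#' @param mode mode of action (see Details).
#' @param K number of genotype categories.
#' @param free base coefficients estimated jointly (shared across
#'   genotypes).
#' @param free_beta estimate the genotype-probability intercepts.
#' @param beta0 starting genotype-probability intercepts.
#' @return An `"spm_fit"` with elements `model` (fitted [genetic_model()]),
#'   `mode`, `component`, and `effect` (estimates, SEs and coordinate names
#'   of the genetic-effect parameters).
#' @export
fit_genetic <- function(cohort, template, component = "Q0",
                        mode = c("free", "dominant", "recessive", "additive",
                                 "shared"),
                        K = 3L, free = c("c0"), free_beta = TRUE,
                        beta0 = numeric(K - 1L), options = fit_options()) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "spm_params"))
  if (component %in% free)
    stop("`component` cannot also be in `free`: its base value is already ",
         "estimated with the effect", call. = FALSE)
  g <- cohort$surv$genotype
  if (is.null(g) || all(is.na(g)))
    warning("no genotyped individuals: the fit degenerates to a latent-class ",
            "mixture", call. = FALSE)
  design <- .action_design(mode, K)
  ncoord <- length(spm_pack(template, component))
  ndelta <- ncoord * ncol(design)
  base_free <- unique(c(free, component))
  u_base <- spm_pack(template, base_free)
  u0 <- c(u_base,
          if (ndelta) stats::setNames(numeric(ndelta),
                                      paste0("effect.", seq_len(ndelta))),
          if (free_beta && K > 1L)
            stats::setNames(beta0, paste0("beta0.", seq_len(K - 1L))))
  nb <- length(u_base)
  hmax <- options$h_max
  build <- function(u) {
    base <- spm_unpack(u[seq_len(nb)], template, base_free)
    delta <- if (ndelta) u[nb + seq_len(ndelta)] else numeric(0)
    b0 <- if (free_beta && K > 1L) u[nb + ndelta + seq_len(K - 1L)] else beta0
    comps <- .genetic_build(base, component, delta, design, K)
    genetic_model(comps, beta0 = b0)
  }
  negll <- function(u) -genetic_loglik(build(u), cohort, h_max = hmax)
  eng <- .mle_multistart(negll, u0, options)
  fit <- .make_fit(eng, build, names(u0), options, cohort, negll,
                   kind = "genetic")
  fit$model <- fit$params
  fit$params <- NULL
  fit$mode <- mode
  fit$component <- component
  if (ndelta) {
    idx <- nb + seq_len(ndelta)
    fit$effect <- data.frame(
      coef = names(u0)[idx],
      estimate = unname(fit$par_u[idx]),
      se = if (!is.null(fit$se_u)) unname(fit$se_u[idx]) else NA_real_)
  } else {
    fit$effect <- data.frame(coef = character(), estimate = numeric(),
                             se = numeric())
  }
  fit
}

#' Compare modes of genetic action on a component
#'
#' Fits the declared modes and reports log-likelihood, parameter count and
#' AIC per mode, plus likelihood-ratio tests for the nested pairs
#' (`shared` within every other mode; `dominant`/`recessive`/`additive`
#' within `free`).  Non-nested pairs (e.g. dominant vs recessive) are
#' compared by AIC only.  Trying all modes is the recommended practice:
#' the form of genetic action is not known a priori.
#'
#' @inheritParams fit_genetic
#' @param modes modes to fit and compare.
#' @return List with `table` (per-mode fit summary), `lrt` (nested-pair
#'   tests) and `fits`.
#' @export
test_genetic_effect <- function(cohort, template, component = "Q0",
                                modes = c("shared", "dominant", "recessive",
                                          "additive", "free"),
                                K = 3L, free = c("c0"), free_beta = TRUE,
                                options = fit_options()) {
  fits <- lapply(modes, function(m)
    fit_genetic(cohort, template, component = component, mode = m, K = K,
                free = free, free_beta = free_beta, options = options))
  names(fits) <- modes
  tab <- data.frame(mode = modes,
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    k = vapply(fits, function(f) f$n_free, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)))
  nested <- list()
  add_lrt <- function(null, alt) {
    if (null %in% modes && alt %in% modes &&
        fits[[alt]]$n_free > fits[[null]]$n_free) {
      lt <- lr_test(fits[[null]], fits[[alt]], check = FALSE)
      nested[[length(nested) + 1L]] <<- data.frame(
        null = null, alt = alt, statistic = lt$statistic, df = lt$df,
        p.value = lt$p.value)
    }
  }
  for (m in setdiff(modes, "shared")) add_lrt("shared", m)
  for (m in intersect(modes, c("dominant", "recessive", "additive")))
    add_lrt(m, "free")
  lrt <- if (length(nested)) do.call(rbind, nested) else
    data.frame(null = character(), alt = character(), statistic = numeric(),
               df = numeric(), p.value = numeric())
  list(table = tab[order(tab$AIC), ], lrt = lrt, fits = fits)
}
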