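# Structured-text (YAML) model configuration shared by the command-line
# wrapper.  Schema:
#   model:   arguments of spm_params() (scalars or lists for matrices);
#            covariates: {names: [...], f1: [...], f0: [...], mu0: [...]}
#   scheme:  ages: [..] or {from, to, by}; censor_age; miss_prob; sigma_me;
#            jitter_sd
#   free:    [component names]    (starting values come from `model`)
#   latent:  {K, beta0: [...], x0_names: [...]}
#   genetic: {K, component, mode, beta0: [...]}

#' Read a model configuration file
#'
#' @param path YAML file following the schema documented above.
#' @return List with `params` ([spm_params()]), optional `scheme`
#'   ([observation_scheme()]), `free` (character vector) and the raw
#'   `latent` / `genetic` sections.
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config has no `model` section", call. = FALSE)
  m <- cfg$model
  J <- m$dim %||% 1L
  msq <- function(v) if (is.list(v) || (length(v) > 1 && !is.null(m$dim) &&
                                        length(v) == J * J))
    matrix(unlist(v), J, J) else unlist(v)
  args <- list(dim = J)
  for (nm in c("a0", "a1", "B", "Q0", "gamma0"))
    if (!is.null(m[[nm]])) args[[nm]] <- msq(m[[nm]])
  for (nm in c("f1_0", "f1_1", "f0_0", "f0_1", "q1", "c0", "theta", "m0",
               "age_range"))
    if (!is.null(m[[nm]])) args[[nm]] <- unlist(m[[nm]])
  if (!is.null(m$covariates))
    args$covariates <- do.call(spm_covariates, lapply(m$covariates, unlist))
  params <- do.call(spm_params, args)
  scheme <- NULL
  if (!is.null(cfg$scheme)) {
    s <- cfg$scheme
    ages <- if (!is.null(s$ages$from))
      seq(s$ages$from, s$ages$to, by = s$ages$by) else unlist(s$ages)
    scheme <- observation_scheme(ages, censor_age = s$censor_age,
                                 miss_prob = s$miss_prob %||% 0,
                                 sigma_me = s$sigma_me %||% 0,
                                 jitter_sd = s$jitter_sd %||% 0)
  }
  list(params = params, scheme = scheme,
       free = unlist(cfg$free) %||% character(),
       latent = cfg$latent, genetic = cfg$genetic, raw = cfg)
}
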