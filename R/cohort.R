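# Cohort container: long-format examination table + one-row-per-individual
# survival table, the layout longitudinal studies of aging distribute.

#' Assemble a cohort from its two tables
#'
#' @param long data frame with columns `id`, `age`, and `y1 ... yJ`
#'   (one row per individual per examination).
#' @param surv data frame with columns `id`, `t0` (entry age), `tau`
#'   (event or censoring age), `delta` (1 = event, 0 = censored), optional
#'   baseline covariate columns, and an optional `genotype` column
#'   (integer regime label, `NA` = not genotyped).
#' @param dim number of biomarkers J.
#' @param covariate_names names of the covariate columns in `surv` used by
#'   the model (may be `NULL`).
#' @param sigma_me measurement-error standard deviation the observations
#'   carry (0 = biomarkers observed exactly).
#' @return An object of class `"spm_cohort"`.
#' @export
spm_cohort <- function(long, surv, dim = 1L, covariate_names = NULL,
                       sigma_me = 0) {
  J <- as.integer(dim)
  ycols <- paste0("y", seq_len(J))
  stopifnot(all(c("id", "age", ycols) %in% names(long)),
            all(c("id", "t0", "tau", "delta") %in% names(surv)))
  if (anyDuplicated(surv$id))
    stop("duplicated ids in the survival table", call. = FALSE)
  if (!all(long$id %in% surv$id))
    stop("longitudinal rows with ids missing from the survival table",
         call. = FALSE)
  if (!all(surv$delta %in% c(0, 1)))
    stop("`delta` must be 0 or 1", call. = FALSE)
  long <- long[order(match(long$id, surv$id), long$age), , drop = FALSE]
  tau_of <- surv$tau[match(long$id, surv$id)]
  late <- long$age > tau_of + 1e-9
  if (any(late))
    stop("observation after terminal age for id(s): ",
         paste(unique(long$id[late]), collapse = ", "), call. = FALSE)
  dup <- stats::ave(long$age, long$id,
                    FUN = function(a) c(FALSE, diff(a) <= 0))
  if (any(dup > 0))
    stop("examination ages not strictly increasing for id(s): ",
         paste(unique(long$id[dup > 0]), collapse = ", "), call. = FALSE)
  if (!is.null(covariate_names) && !all(covariate_names %in% names(surv)))
    stop("covariate column(s) missing from the survival table: ",
         paste(setdiff(covariate_names, names(surv)), collapse = ", "),
         call. = FALSE)
  structure(list(long = long, surv = surv, dim = J,
                 covariate_names = covariate_names, sigma_me = sigma_me),
            class = "spm_cohort")
}

#' @export
print.spm_cohort <- function(x, ...) {
  cat(sprintf("<spm_cohort> %d individuals, %d examinations, J = %d\n",
              nrow(x$surv), nrow(x$long), x$dim))
  cat(sprintf("  events: %d (%.1f%%); entry %g-%g, follow-up to %g\n",
              sum(x$surv$delta), 100 * mean(x$surv$delta),
              min(x$surv$t0), max(x$surv$t0), max(x$surv$tau)))
  if (!is.null(x$covariate_names))
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  if ("genotype" %in% names(x$surv))
    cat(sprintf("  genotyped: %d / %d\n", sum(!is.na(x$surv$genotype)),
                nrow(x$surv)))
  invisible(x)
}

#' @export
`[.spm_cohort` <- function(x, i) {
  surv <- x$surv[i, , drop = FALSE]
  long <- x$long[x$long$id %in% surv$id, , drop = FALSE]
  spm_cohort(long, surv, dim = x$dim, covariate_names = x$covariate_names,
             sigma_me = x$sigma_me)
}

#' Extract one individual's record
#'
#' @param cohort an [spm_cohort()].
#' @param id individual identifier.
#' @return List with `t0`, `tau`, `delta`, covariate vector `x`, `genotype`,
#'   and the observation data frame `obs` (age + biomarker columns).
#' @export
cohort_individual <- function(cohort, id) {
  i <- match(id, cohort$surv$id)
  if (is.na(i)) stop("unknown id: ", id, call. = FALSE)
  s <- cohort$surv[i, ]
  x <- if (is.null(cohort$covariate_names)) NULL else
    as.numeric(s[1, cohort$covariate_names])
  list(id = id, t0 = s$t0, tau = s$tau, delta = s$delta, x = x,
       genotype = if ("genotype" %in% names(s)) s$genotype else NA,
       obs = cohort$long[cohort$long$id == id,
                         c("age", paste0("y", seq_len(cohort$dim)))])
}

# CSR arrays + per-individual covariate-adjusted intercepts for the C++ side
.cohort_arrays <- function(cohort, params) {
  J <- cohort$dim
  if (J != params$dim)
    stop("cohort and model disagree on the number of biomarkers",
         call. = FALSE)
  surv <- cohort$surv
  long <- cohort$long
  n <- nrow(surv)
  idx <- match(long$id, surv$id)
  ord <- order(idx, long$age)
  long <- long[ord, , drop = FALSE]
  idx <- idx[ord]
  counts <- tabulate(idx, nbins = n)
  ptr <- c(0L, cumsum(counts))
  Y <- t(as.matrix(long[, paste0("y", seq_len(J)), drop = FALSE]))
  cv <- params$covariates
  if (is.null(cv)) {
    F1I <- matrix(params$f1_0, J, n)
    F0I <- matrix(params$f0_0, J, n)
    LMU <- numeric(n)
  } else {
    X <- as.matrix(surv[, cv$names, drop = FALSE])
    F1I <- matrix(params$f1_0, J, n) + cv$f1 %*% t(X)
    F0I <- matrix(params$f0_0, J, n) + cv$f0 %*% t(X)
    LMU <- as.numeric(X %*% cv$mu0)
  }
  list(F1I = F1I, F0I = F0I, LMU = LMU,
       obs_age = long$age, obs_y = Y, obs_ptr = ptr,
       t0 = surv$t0, tau = surv$tau, delta = as.integer(surv$delta))
}
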