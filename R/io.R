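# Delimited-text readers/writers.  Two-file layout: a long-format
# examination table (id, age, y1..yJ) and a one-row-per-individual survival
# table (id, t0, tau, delta, covariates..., genotype).  Numbers are written
# with 17 significant digits so write -> read round-trips at full double
# precision.

.write_precise <- function(df, path, sep = ",") {
  out <- df
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Write a cohort to delimited text
#'
#' @param cohort an [spm_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are
#'   `<prefix>_long.csv` and `<prefix>_surv.csv`.
#' @param sep field delimiter.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort", sep = ",") {
  stopifnot(inherits(cohort, "spm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- file.path(dir, paste0(prefix, "_long.csv"))
  sp <- file.path(dir, paste0(prefix, "_surv.csv"))
  .write_precise(cohort$long, lp, sep)
  .write_precise(cohort$surv, sp, sep)
  invisible(c(long = lp, surv = sp))
}

#' Read a cohort from delimited text
#'
#' Expects the two-file layout written by [write_cohort()].  Validation is
#' run on load: examination ages strictly increasing per individual and
#' not later than the terminal age, `delta` in {0, 1}; empty genotype
#' fields become missing (not category 0).
#'
#' @param long_path path of the longitudinal table (`id`, `age`,
#'   `y1..yJ`).
#' @param surv_path path of the survival table (`id`, `t0`, `tau`,
#'   `delta`, covariates, optional `genotype`).
#' @param covariate_names covariate columns the model will use.
#' @param sigma_me measurement-error SD the observations carry.
#' @param sep field delimiter.
#' @return An [spm_cohort()].
#' @export
read_cohort <- function(long_path, surv_path, covariate_names = NULL,
                        sigma_me = 0, sep = ",") {
  for (p in c(long_path, surv_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  long <- utils::read.table(long_path, header = TRUE, sep = sep,
                            na.strings = "")
  surv <- utils::read.table(surv_path, header = TRUE, sep = sep,
                            na.strings = "")
  need_l <- c("id", "age")
  need_s <- c("id", "t0", "tau", "delta")
  if (!all(need_l %in% names(long)))
    stop("longitudinal table must have columns ",
         paste(need_l, collapse = ", "), call. = FALSE)
  if (!all(need_s %in% names(surv)))
    stop("survival table must have columns ",
         paste(need_s, collapse = ", "), call. = FALSE)
  ycols <- grep("^y[0-9]+$", names(long), value = TRUE)
  if (length(ycols) == 0L)
    stop("no biomarker columns (y1, y2, ...) in the longitudinal table",
         call. = FALSE)
  if ("genotype" %in% names(surv))
    surv$genotype <- as.integer(surv$genotype)
  spm_cohort(long, surv, dim = length(ycols),
             covariate_names = covariate_names, sigma_me = sigma_me)
}
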