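# Codec between spm_params and a flat unconstrained parameter vector.
# Constrained quantities go through smooth bijections: positivity via log
# (diffusion diagonal), non-negative-definiteness via the Cholesky factor
# with log-transformed diagonal (Q0, gamma0).  Everything else is identity.

.codec_fields <- c("a0", "a1", "f1_0", "f1_1", "f0_0", "f0_1", "B",
                   "Q0", "q1", "c0", "theta", "m0", "gamma0",
                   "cov_f1", "cov_f0", "cov_mu0")

# lower-triangular log-chol packing of a symmetric PD matrix
.pack_logchol <- function(M, what) {
  L <- tryCatch(t(chol(M)), error = function(e)
    stop(sprintf("`%s` must be positive-definite to be a free parameter; give a positive starting value", # nolint
                 what), call. = FALSE))
  J <- nrow(L)
  v <- numeric(0)
  for (j in seq_len(J)) for (i in j:J)
    v <- c(v, if (i == j) log(L[i, j]) else L[i, j])
  v
}

.unpack_logchol <- function(v, J) {
  L <- matrix(0, J, J)
  k <- 1L
  for (j in seq_len(J)) for (i in j:J) {
    L[i, j] <- if (i == j) exp(v[k]) else v[k]
    k <- k + 1L
  }
  L %*% t(L)
}

.codec_coords <- function(params, field) {
  J <- params$dim
  switch(field,
    a0 = , a1 = , m0 = , f1_0 = , f1_1 = , f0_0 = , f0_1 =
      as.numeric(params[[field]]),
    q1 = , c0 = , theta = params[[field]],
    B = log(diag(as.matrix(params$B))),
    Q0 = .pack_logchol(params$Q0, "Q0"),
    gamma0 = .pack_logchol(params$gamma0, "gamma0"),
    cov_f1 = as.numeric(params$covariates$f1),
    cov_f0 = as.numeric(params$covariates$f0),
    cov_mu0 = as.numeric(params$covariates$mu0),
    stop(sprintf("unknown free-parameter name '%s'", field), call. = FALSE)
  )
}

.codec_nchol <- function(J) (J * (J + 1L)) %/% 2L

#' Pack free coefficients into an unconstrained vector
#'
#' The optimizer works on this scale: diffusion diagonals are
#' log-transformed, `Q0` and `gamma0` are stored as Cholesky factors with
#' log diagonal, and all other coefficients pass through unchanged.
#' `spm_unpack(spm_pack(p, free), p, free)` reproduces every free
#' coefficient exactly.
#'
#' @param params an [spm_params()] object supplying the coefficient values.
#' @param free character vector of free component names, a subset of
#'   `c("a0","a1","f1_0","f1_1","f0_0","f0_1","B","Q0","q1","c0","theta",
#'   "m0","gamma0","cov_f1","cov_f0","cov_mu0")`.
#' @return Named numeric vector on the unconstrained scale.
#' @export
spm_pack <- function(params, free) {
  stopifnot(inherits(params, "spm_params"))
  bad <- setdiff(free, .codec_fields)
  if (length(bad))
    stop("unknown free-parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  free <- intersect(.codec_fields, free)  # canonical order
  out <- numeric(0)
  for (f in free) {
    v <- .codec_coords(params, f)
    names(v) <- if (length(v) == 1L) f else paste0(f, ".", seq_along(v))
    out <- c(out, v)
  }
  out
}

#' Rebuild parameters from an unconstrained vector
#'
#' @param v numeric vector as produced by [spm_pack()] (same `free`, same
#'   order); length must match exactly.
#' @param template an [spm_params()] object supplying every fixed
#'   coefficient and the dimensions.
#' @inheritParams spm_pack
#' @return An [spm_params()] object with the free coefficients replaced.
#' @export
spm_unpack <- function(v, template, free) {
  stopifnot(inherits(template, "spm_params"))
  free <- intersect(.codec_fields, free)
  p <- template
  J <- p$dim
  need <- function(f) {
    switch(f,
      a0 = , a1 = J * J,
      f1_0 = , f1_1 = , f0_0 = , f0_1 = , m0 = , B = J,
      Q0 = , gamma0 = .codec_nchol(J),
      q1 = , c0 = , theta = 1L,
      cov_f1 = , cov_f0 = length(p$covariates$f1),
      cov_mu0 = length(p$covariates$mu0))
  }
  total <- sum(vapply(free, function(f) as.integer(need(f)), integer(1)))
  if (length(v) != total)
    stop(sprintf("parameter vector has length %d, codec expects %d",
                 length(v), total), call. = FALSE)
  k <- 0L
  take <- function(n) { k <<- k + n; v[(k - n + 1L):k] }
  for (f in free) {
    n <- need(f)
    w <- unname(take(n))
    switch(f,
      a0 = { p$a0 <- matrix(w, J, J) },
      a1 = { p$a1 <- matrix(w, J, J) },
      f1_0 = { p$f1_0 <- w }, f1_1 = { p$f1_1 <- w },
      f0_0 = { p$f0_0 <- w }, f0_1 = { p$f0_1 <- w },
      m0 = { p$m0 <- w },
      B = { d <- as.matrix(p$B); diag(d) <- exp(w); p$B <- d },
      Q0 = { p$Q0 <- .unpack_logchol(w, J) },
      gamma0 = { p$gamma0 <- .unpack_logchol(w, J) },
      q1 = { p$q1 <- w }, c0 = { p$c0 <- w }, theta = { p$theta <- w },
      cov_f1 = { p$covariates$f1[] <- w },
      cov_f0 = { p$covariates$f0[] <- w },
      cov_mu0 = { p$covariates$mu0[] <- w })
  }
  p
}
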