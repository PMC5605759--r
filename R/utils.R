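# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw `n` sub-seeds below 2^31 deterministically from a master seed.
.spawn_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Cholesky factor of a symmetric matrix expected to be p.d.; NULL on failure.
.chol_or_null <- function(M) {
  tryCatch(chol((M + t(M)) / 2), error = function(e) NULL)
}

# log|M| for symmetric p.d. M via its Cholesky factor.
.logdet_pd <- function(M, label = "matrix") {
  R <- .chol_or_null(M)
  if (is.null(R)) {
    stop(sprintf("%s is not positive-definite", label), call. = FALSE)
  }
  2 * sum(log(diag(R)))
}

# Symmetric p.d. inverse via Cholesky; errors with `label` if indefinite.
.inv_pd <- function(M, label = "matrix") {
  R <- .chol_or_null(M)
  if (is.null(R)) {
    stop(sprintf("%s is not positive-definite", label), call. = FALSE)
  }
  V <- chol2inv(R)
  (V + t(V)) / 2
}

.is_square_matrix <- function(M) {
  is.matrix(M) && is.numeric(M) && nrow(M) == ncol(M)
}

.is_symmetric <- function(M, tol = 1e-8) {
  .is_square_matrix(M) && max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

.quad_form <- function(v, Minv) {
  drop(crossprod(v, Minv %*% v))
}

.stopifnot_numeric_vector <- function(x, len, name) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop(sprintf("`%s` must be a numeric vector of length %d", name, len),
         call. = FALSE)
  }
}
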