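#' Covariance basis for the AR(1)-plus-white-noise approximation
#'
#' Builds the two-component covariance basis used in first-level fMRI
#' time-series modelling: an identity matrix capturing independent noise and
#' an exponentially decaying Toeplitz matrix capturing serial correlations,
#' \eqn{(Q_2)_{ij} = \exp(-|i-j|/\tau)}. With the default decay constant of
#' 5 scans (lag-1 correlation \eqn{e^{-0.2}}) this is the widely used
#' approximation to the AR(1)+white-noise error model of fMRI analysis.
#'
#' @param n Number of observations (scans); positive integer.
#' @param tau Decay constant of the serial-correlation basis, in scan units;
#'   must be positive. The default of 5 scans (10 s at TR = 2 s) gives a
#'   lag-1 correlation of exp(-0.2), the decay rate of the standard
#'   approximation.
#' @return A list of two symmetric \code{n x n} matrices \code{list(Q1, Q2)}
#'   with \code{Q1} the identity and \code{Q2} the exponential-decay basis;
#'   both have unit diagonal.
#' @examples
#' Q <- build_covariance_basis(5)
#' Q[[2]][1, 2]  # exp(-1/5)
#' @export
build_covariance_basis <- function(n, tau = 5) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a positive scalar", call. = FALSE)
  }
  idx <- seq_len(n)
  Q2 <- exp(-abs(outer(idx, idx, "-")) / tau)
  list(diag(n), Q2)
}

#' Assemble the error covariance from its components
#'
#' Computes \eqn{V_\lambda = \sum_i \exp(\lambda_i) Q_i}. The exponential map
#' guarantees positive component scalings; positive-definiteness of the sum
#' is nevertheless verified by an attempted Cholesky factorization and
#' reported via the \code{"positive_definite"} attribute so that callers can
#' decide how to react to indefinite assemblies.
#'
#' @param lam Numeric vector of log scaling parameters, one per basis matrix.
#' @param Q List of symmetric covariance basis matrices of common dimension.
#' @return The symmetric matrix \eqn{V_\lambda} with a logical attribute
#'   \code{"positive_definite"}.
#' @export
assemble_covariance <- function(lam, Q) {
  if (!is.list(Q) || length(Q) < 1L) {
    stop("`Q` must be a non-empty list of matrices", call. = FALSE)
  }
  k <- length(Q)
  .stopifnot_numeric_vector(lam, k, "lam")
  n <- nrow(Q[[1]])
  V <- matrix(0, n, n)
  for (i in seq_len(k)) {
    if (!.is_square_matrix(Q[[i]]) || nrow(Q[[i]]) != n) {
      stop("all basis matrices must be square and share one dimension",
           call. = FALSE)
    }
    V <- V + exp(lam[i]) * Q[[i]]
  }
  V <- (V + t(V)) / 2
  attr(V, "positive_definite") <- !is.null(.chol_or_null(V))
  V
}

#' GLM specification with linearly decomposable error covariance
#'
#' Bundles a design matrix \code{X} and a covariance basis set
#' \code{Q_1, ..., Q_k} into the model \eqn{y = X\beta + \varepsilon},
#' \eqn{\varepsilon \sim N(0, V_\lambda)} with
#' \eqn{V_\lambda = \sum_i \exp(\lambda_i) Q_i}. When \code{Q} is omitted the
#' default AR(1)+white-noise basis \code{build_covariance_basis(n, tau)} is
#' used (so \code{Q[[1]]} is the identity).
#'
#' When the basis matrices are simultaneously diagonalizable (the default
#' basis, or a single component), their joint eigendecomposition is cached in
#' the returned object; all estimators then evaluate log-determinants,
#' quadratic forms and derivatives in that basis in O(n) per lambda value.
#'
#' @param X Design matrix (\code{n x p}, full column rank).
#' @param Q Optional list of symmetric \code{n x n} basis matrices.
#' @param tau Decay constant for the default basis (ignored if \code{Q}
#'   given).
#' @return An object of class \code{"glm_spec"} with fields \code{X},
#'   \code{Q}, \code{n}, \code{p}, \code{k} and a cached derivative kernel.
#' @export
glm_spec <- function(X, Q = NULL, tau = 5) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("`X` must be numeric", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  if (p > n) stop("design has more columns than rows (p > n)", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("design matrix is rank-deficient", call. = FALSE)
  }
  if (is.null(Q)) Q <- build_covariance_basis(n, tau)
  if (!is.list(Q) || length(Q) < 1L) {
    stop("`Q` must be a non-empty list", call. = FALSE)
  }
  for (Qi in Q) {
    if (!.is_square_matrix(Qi) || nrow(Qi) != n) {
      stop("each basis matrix must be n x n", call. = FALSE)
    }
    if (!.is_symmetric(Qi)) stop("basis matrices must be symmetric",
                                 call. = FALSE)
  }
  spec <- structure(
    list(X = X, Q = Q, n = n, p = p, k = length(Q)),
    class = "glm_spec"
  )
  spec$kernel <- .kernel_build(spec)
  spec
}

#' @export
print.glm_spec <- function(x, ...) {
  cat(sprintf(
    "GLM specification: n = %d observations, p = %d regressors, k = %d covariance components\n",
    x$n, x$p, x$k))
  cat(sprintf("derivative kernel: %s\n",
              if (x$kernel$type == "eig") "joint eigenbasis (fast path)"
              else "dense Cholesky"))
  invisible(x)
}

#' Configuration of a synthetic event-related fMRI design
#'
#' @param n_scans Number of volumes acquired. Default 400.
#' @param TR Repetition time in seconds. Default 2.
#' @param conditions Character vector of condition labels. Default two
#'   conditions.
#' @param iti_mean,iti_sd Mean and standard deviation (seconds) of the
#'   Gaussian inter-trial intervals; gaps are truncated below at 1 s.
#'   Defaults 6 and 1.
#' @param microtime_bins Micro-time bins per TR used for convolution with the
#'   hemodynamic response. Default 16.
#' @param hrf_params Parameters of the canonical double-gamma response, see
#'   \code{\link{canonical_hrf}}.
#' @param include_offset Add a constant offset column to the design. Default
#'   \code{FALSE} (the demonstration model does not model a signal offset).
#' @return An object of class \code{"design_config"}.
#' @export
design_config <- function(n_scans = 400, TR = 2,
                          conditions = c("cond1", "cond2"),
                          iti_mean = 6, iti_sd = 1,
                          microtime_bins = 16,
                          hrf_params = hrf_default(),
                          include_offset = FALSE) {
  if (n_scans < 1 || n_scans != round(n_scans)) {
    stop("`n_scans` must be a positive integer", call. = FALSE)
  }
  if (TR <= 0) stop("`TR` must be positive", call. = FALSE)
  if (!(iti_mean > iti_sd && iti_sd >= 0)) {
    stop("need iti_mean > iti_sd >= 0", call. = FALSE)
  }
  if (microtime_bins < 1 || microtime_bins != round(microtime_bins)) {
    stop("`microtime_bins` must be a positive integer", call. = FALSE)
  }
  structure(
    list(n_scans = as.integer(n_scans), TR = TR,
         conditions = as.character(conditions),
         iti_mean = iti_mean, iti_sd = iti_sd,
         microtime_bins = as.integer(microtime_bins),
         hrf_params = hrf_params,
         include_offset = isTRUE(include_offset)),
    class = "design_config"
  )
}

#' Canonical double-gamma hemodynamic response parameters
#'
#' Response peak at 6 s and undershoot peak at 16 s (gamma shape parameters
#' with unit dispersion), undershoot-to-response ratio 1/6, 32 s kernel
#' length. The kernel is scaled to unit peak amplitude.
#'
#' @return A list of HRF parameters.
#' @export
hrf_default <- function() {
  list(peak1 = 6, peak2 = 16, disp1 = 1, disp2 = 1,
       ratio = 1 / 6, length = 32)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, scaled to unit peak amplitude (the
#' scaling constant is computed once on a fine fixed grid, so regressor
#' amplitudes do not depend on the micro-time resolution).
#'
#' @param t Time points in seconds (non-negative; negative times return 0).
#' @param params HRF parameters, see \code{\link{hrf_default}}.
#' @return Numeric vector of response amplitudes.
#' @export
canonical_hrf <- function(t, params = hrf_default()) {
  raw <- function(tt) {
    out <- numeric(length(tt))
    pos <- tt >= 0
    out[pos] <- stats::dgamma(tt[pos], shape = params$peak1 / params$disp1,
                              scale = params$disp1) -
      params$ratio * stats::dgamma(tt[pos], shape = params$peak2 / params$disp2,
                                   scale = params$disp2)
    out
  }
  peak <- max(raw(seq(0, params$length, by = 1e-3)))
  raw(t) / peak
}

#' Build an event-related design matrix by micro-time convolution
#'
#' For each condition, event onsets are drawn with Gaussian inter-trial gaps
#' (mean \code{iti_mean}, sd \code{iti_sd}, truncated below at 1 s, redrawn
#' on truncation) and rounded to the default TR/16 micro-time grid. Unit
#' stick functions at micro-time resolution \code{TR/microtime_bins} are
#' convolved with the canonical double-gamma response and downsampled to one
#' value per scan (scan times 0, TR, 2 TR, ...). Condition columns come
#' first, followed by an optional constant offset column.
#'
#' @param config A \code{\link{design_config}}.
#' @param seed Integer seed controlling the onset draws.
#' @return A list with the design matrix \code{X} (\code{n_scans} rows, one
#'   column per condition plus optional offset) and the onset table
#'   \code{onsets} (columns \code{condition}, \code{onset_s},
#'   \code{duration_s}).
#' @export
build_design_matrix <- function(config, seed) {
  stopifnot(inherits(config, "design_config"))
  n <- config$n_scans
  bins <- config$microtime_bins
  dt <- config$TR / bins
  duration <- n * config$TR
  # onsets are committed to the reference TR/16 grid once; finer micro-time
  # resolutions then only refine the convolution, not the event times
  grid <- config$TR / 16
  onset_list <- .with_seed(seed, {
    lapply(config$conditions, function(cond) {
      onsets <- numeric(0)
      t_cur <- 0
      repeat {
        gap <- stats::rnorm(1, config$iti_mean, config$iti_sd)
        while (gap < 1) gap <- stats::rnorm(1, config$iti_mean, config$iti_sd)
        t_cur <- t_cur + gap
        if (t_cur >= duration) break
        onsets <- c(onsets, round(t_cur / grid) * grid)
      }
      onsets
    })
  })
  n_micro <- n * bins
  hrf <- canonical_hrf(seq(0, config$hrf_params$length, by = dt),
                       config$hrf_params)
  cols <- lapply(onset_list, function(onsets) {
    x <- numeric(n_micro)
    for (on in onsets) {
      i0 <- round(on / dt) + 1
      if (i0 > n_micro) next
      idx <- i0:min(n_micro, i0 + length(hrf) - 1L)
      x[idx] <- x[idx] + hrf[seq_along(idx)]
    }
    x[seq(1, by = bins, length.out = n)]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- config$conditions
  if (config$include_offset) {
    X <- cbind(X, offset = 1)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("constructed design matrix is rank-deficient (a condition may have no onsets)",
         call. = FALSE)
  }
  onsets <- data.frame(
    condition = rep(config$conditions, vapply(onset_list, length, 1L)),
    onset_s = unlist(onset_list),
    duration_s = 0
  )
  list(X = X, onsets = onsets)
}

#' True generating parameters of the GLM
#'
#' @param beta Effect-size vector (length p).
#' @param lam Log covariance scaling vector (length k).
#' @return A list of class \code{"true_params"}.
#' @export
true_params <- function(beta, lam) {
  structure(list(beta = as.numeric(beta), lam = as.numeric(lam)),
            class = "true_params")
}

#' Simulate data realizations from the GLM
#'
#' Draws \eqn{y = X\beta + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, V_\lambda)} through a Cholesky factorization of
#' the assembled covariance. Identical seeds give identical output.
#'
#' @param spec A \code{\link{glm_spec}}.
#' @param params A \code{\link{true_params}} (or list with \code{beta},
#'   \code{lam}).
#' @param seed Integer seed.
#' @param n_series Number of independent series to draw. Default 1.
#' @return A numeric vector of length \code{n} (or an \code{n x n_series}
#'   matrix for \code{n_series > 1}).
#' @export
simulate_glm <- function(spec, params, seed, n_series = 1) {
  stopifnot(inherits(spec, "glm_spec"))
  .stopifnot_numeric_vector(params$beta, spec$p, "params$beta")
  .stopifnot_numeric_vector(params$lam, spec$k, "params$lam")
  V <- assemble_covariance(params$lam, spec$Q)
  if (!attr(V, "positive_definite")) {
    stop("assembled covariance is not positive-definite", call. = FALSE)
  }
  R <- chol(V)
  mu <- drop(spec$X %*% params$beta)
  Z <- .with_seed(seed, matrix(stats::rnorm(spec$n * n_series),
                               spec$n, n_series))
  Y <- mu + crossprod(R, Z)
  if (n_series == 1) drop(Y) else Y
}
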