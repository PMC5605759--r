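# Shared fixtures and numerical oracles for the test suite. The
# demonstration model (400 scans, two conditions, AR(1)+white-noise basis)
# is built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

demo_design <- function() {
  if (is.null(.fixture_cache$design)) {
    .fixture_cache$design <- build_design_matrix(design_config(), seed = 11)
  }
  .fixture_cache$design
}

demo_spec <- function() {
  if (is.null(.fixture_cache$spec)) {
    .fixture_cache$spec <- glm_spec(demo_design()$X)
  }
  .fixture_cache$spec
}

demo_params <- function() true_params(c(2, -1), c(-0.5, -2))

# small, fast spec for unit tests: short event-related design on the
# default basis
small_spec <- function(n = 48, seed = 5) {
  des <- build_design_matrix(
    design_config(n_scans = n, TR = 2, conditions = c("a", "b")), seed = seed)
  glm_spec(des$X)
}

# spec with a general (not simultaneously diagonalizable) basis: exercises
# the dense Cholesky path
dense_spec <- function(n = 10, p = 2, k = 3, seed = 3) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  Q <- lapply(seq_len(k), function(i) {
    A <- matrix(rnorm(n * n), n)
    S <- crossprod(A) / n
    (S + t(S)) / 2
  })
  glm_spec(X, Q)
}

# central finite-difference gradient and Hessian oracles
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

fd_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    H[j, ] <- (fd_gradient(f, xp, h) - fd_gradient(f, xm, h)) / (2 * h)
  }
  (H + t(H)) / 2
}

# independent multivariate Gaussian log density (generic solve/determinant
# route, deliberately different from the package's kernel evaluations)
oracle_mvn_logpdf <- function(y, mu, V) {
  n <- length(y)
  -n / 2 * log(2 * pi) - as.numeric(determinant(V, logarithm = TRUE)$modulus) / 2 -
    drop(crossprod(y - mu, solve(V, y - mu))) / 2
}
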