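test_that("covariance basis has the stated analytic entries", {
  Q <- build_covariance_basis(3, tau = 0.2)
  expect_identical(Q[[1]], diag(3))
  expect_equal(Q[[2]][1, 2], exp(-5), tolerance = 1e-12)
  expect_equal(Q[[2]][1, 3], exp(-10), tolerance = 1e-12)
  Qd <- build_covariance_basis(7)
  expect_equal(diag(Qd[[2]]), rep(1, 7))
  expect_equal(Qd[[2]][2, 3], exp(-1 / 5))
  expect_error(build_covariance_basis(0), "positive")
  expect_error(build_covariance_basis(4, tau = -1), "positive")
})

test_that("serial-correlation basis is Toeplitz (function of |i-j| only)", {
  Q2 <- build_covariance_basis(30, tau = 3)[[2]]
  set.seed(1)
  for (rep in 1:20) {
    ij <- sample(30, 2)
    kl <- sort(sample(30 - abs(diff(ij)), 1) + c(0, abs(diff(ij))))
    expect_equal(Q2[ij[1], ij[2]], Q2[kl[1], kl[2]])
  }
  expect_equal(Q2, t(Q2))
})

test_that("assembled covariance matches its definition and flags definiteness", {
  Q <- build_covariance_basis(4, tau = 2)
  V0 <- assemble_covariance(c(0, 0), Q)
  expect_equal(unname(V0[,]), Q[[1]] + Q[[2]], ignore_attr = TRUE)
  expect_true(attr(V0, "positive_definite"))

  V2 <- assemble_covariance(c(log(2), -50), list(diag(4), Q[[2]]))
  expect_lt(max(abs(V2 - 2 * diag(4))), 1e-15)

  V1 <- assemble_covariance(-0.5, list(diag(4)))
  expect_equal(diag(V1), rep(exp(-0.5), 4))

  expect_error(assemble_covariance(c(0, 0, 0), Q), "length")
  # an indefinite combination is flagged, not silently repaired
  Qi <- list(diag(3), -2 * diag(3))
  expect_false(attr(assemble_covariance(c(-2, 0), Qi), "positive_definite"))
})

test_that("covariance assembly is linear in exp(lambda)", {
  Q <- build_covariance_basis(6, tau = 4)
  lam <- c(-0.5, -2)
  V <- assemble_covariance(lam, Q)
  for (j in 1:2) {
    for (cc in c(0.3, -1)) {
      lam2 <- lam
      lam2[j] <- lam2[j] + cc
      expect_equal(
        unname(assemble_covariance(lam2, Q)[,]),
        unname(V[,] + exp(lam[j]) * (exp(cc) - 1) * Q[[j]]),
        tolerance = 1e-12)
    }
  }
})

test_that("design matrix has the demo shape, full rank, and reproducible onsets", {
  des <- demo_design()
  expect_equal(dim(des$X), c(400, 2))
  expect_equal(qr(des$X)$rank, 2)
  expect_setequal(unique(des$onsets$condition), c("cond1", "cond2"))
  # inter-trial gaps realize the configured mean/sd
  on1 <- des$onsets$onset_s[des$onsets$condition == "cond1"]
  gaps <- diff(sort(on1))
  expect_gt(mean(gaps), 5)
  expect_lt(mean(gaps), 7)
  # identical seed reproduces the bundle exactly
  des2 <- build_design_matrix(design_config(), seed = 11)
  expect_identical(des$X, des2$X)
  expect_identical(des$onsets, des2$onsets)
})

test_that("degenerate designs are refused", {
  # session too short for any onset of a condition -> zero column
  expect_error(
    build_design_matrix(design_config(n_scans = 2, TR = 2), seed = 1),
    "rank-deficient")
})

test_that("constant offset column is a vector of ones", {
  des <- build_design_matrix(
    design_config(n_scans = 60, include_offset = TRUE), seed = 2)
  expect_equal(ncol(des$X), 3)
  expect_equal(unname(des$X[, 3]), rep(1, 60))
})

test_that("design is invariant to micro-time refinement beyond 16 bins", {
  base <- build_design_matrix(design_config(n_scans = 80), seed = 4)$X
  for (bins in c(32, 48, 64)) {
    ref <- build_design_matrix(
      design_config(n_scans = 80, microtime_bins = bins), seed = 4)$X
    expect_lt(max(abs(base - ref)), 1e-3)
  }
})

test_that("simulation is deterministic, honours the noiseless limit, and fails on indefinite V", {
  spec <- small_spec()
  params <- true_params(c(2, -1), c(-0.5, -2))
  y1 <- simulate_glm(spec, params, seed = 9)
  y2 <- simulate_glm(spec, params, seed = 9)
  expect_identical(y1, y2)
  expect_false(identical(y1, simulate_glm(spec, params, seed = 10)))

  y0 <- simulate_glm(spec, true_params(c(2, -1), c(-50, -50)), seed = 9)
  expect_lt(max(abs(y0 - drop(spec$X %*% c(2, -1)))), 1e-10)

  spec_bad <- glm_spec(spec$X, list(diag(spec$n), -2 * diag(spec$n)))
  expect_error(simulate_glm(spec_bad, true_params(c(1, 1), c(-3, 0)), 1),
               "positive-definite")
})

test_that("simulated moments converge to (X beta, V_lambda)", {
  set.seed(2)
  X <- cbind(1, rnorm(8))
  spec <- glm_spec(X, tau = 2)
  params <- true_params(c(1, 0.5), c(-0.5, -1))
  V <- assemble_covariance(params$lam, spec$Q)
  mu <- drop(X %*% params$beta)
  N <- 20000
  Y <- simulate_glm(spec, params, seed = 123, n_series = N)
  # means within 5 standard errors
  se_mu <- sqrt(diag(V) / N)
  expect_true(all(abs(rowMeans(Y) - mu) < 5 * se_mu))
  # covariance entries within 5 standard errors of a Gaussian 4th-moment bound
  S <- tcrossprod(Y - mu) / N
  se_S <- sqrt((outer(diag(V), diag(V)) + V^2) / N)
  expect_true(all(abs(S - V) < 5 * se_S))
})

test_that("the cached eigen kernel agrees with the dense path", {
  spec <- small_spec(n = 24)
  spec_dense <- spec
  spec_dense$kernel <- list(type = "dense")
  lam <- c(-0.4, -1.5)
  set.seed(7)
  r <- rnorm(spec$n)
  Sb <- diag(c(0.5, 2))
  pf <- vbglm:::.lam_parts(spec, lam, r = r, Sb = Sb)
  pd <- vbglm:::.lam_parts(spec_dense, lam, r = r, Sb = Sb)
  for (part in c("ld", "quad", "tr")) {
    expect_equal(pf[[part]]$val, pd[[part]]$val, tolerance = 1e-10)
    expect_equal(pf[[part]]$grad, pd[[part]]$grad, tolerance = 1e-10)
    expect_equal(pf[[part]]$hess, pd[[part]]$hess, tolerance = 1e-8)
  }
  gf <- vbglm:::.gls_quantities(spec, lam, r)
  gd <- vbglm:::.gls_quantities(spec_dense, lam, r)
  expect_equal(gf$XtViX, gd$XtViX, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(gf$XtViy, gd$XtViy, tolerance = 1e-10, ignore_attr = TRUE)
})
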