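# Unit tests of the free-energy objectives, their derivatives, the Newton
# lambda solver, and the four iterative fits.

test_that("ML free energy equals the Gaussian log density", {
  spec <- small_spec()
  n <- spec$n
  # zero residual, spherical unit covariance
  spec_sph <- glm_spec(spec$X, list(diag(n)))
  beta <- c(1, -2)
  y <- drop(spec$X %*% beta)
  expect_equal(ml_free_energy(beta, 0, y, spec_sph), -n / 2 * log(2 * pi))
  # scalar case: n = 1, X = 1, beta = 0, V = 1, y = 1
  sc <- glm_spec(matrix(1, 1, 1), list(diag(1)))
  expect_equal(ml_free_energy(0, 0, 1, sc), -log(2 * pi) / 2 - 1 / 2,
               tolerance = 1e-12)
  # random points against an independent density evaluation
  set.seed(21)
  for (i in 1:20) {
    beta <- rnorm(2)
    lam <- rnorm(2) * 0.5
    y <- rnorm(spec$n)
    V <- assemble_covariance(lam, spec$Q)
    expect_equal(ml_free_energy(beta, lam, y, spec),
                 oracle_mvn_logpdf(y, drop(spec$X %*% beta), V[,]),
                 tolerance = 1e-10)
  }
})

test_that("analytic lambda-gradients and Hessians match finite differences", {
  for (spec in list(small_spec(n = 24), dense_spec())) {
    set.seed(31)
    k <- spec$k
    r <- rnorm(spec$n)
    Sb <- diag(runif(spec$p, 0.2, 2))
    maps <- list(
      ld = function(l) vbglm:::.lam_parts(spec, l)$ld$val,
      quad = function(l) vbglm:::.lam_parts(spec, l, r = r)$quad$val,
      tr = function(l) vbglm:::.lam_parts(spec, l, Sb = Sb)$tr$val
    )
    for (i in 1:10) {
      lam <- rnorm(k) * 0.4
      parts <- vbglm:::.lam_parts(spec, lam, r = r, Sb = Sb)
      for (nm in names(maps)) {
        expect_lt(max(abs(parts[[nm]]$grad - fd_gradient(maps[[nm]], lam))),
                  1e-4)
        expect_lt(max(abs(parts[[nm]]$hess - fd_hessian(maps[[nm]], lam))),
                  1e-4)
      }
    }
  }
})

test_that("B is the summed Hessian: finite-difference oracle, symmetry, degenerate case", {
  spec <- small_spec(n = 24)
  set.seed(41)
  y <- rnorm(spec$n)
  for (i in 1:10) {
    m_beta <- rnorm(2)
    Sb <- crossprod(matrix(rnorm(4), 2)) / 2 + diag(0.3, 2)
    m_lam <- rnorm(2) * 0.4
    B <- compute_B(m_beta, Sb, m_lam, y, spec)
    expect_lt(max(abs(B - t(B))), 1e-12)
    r <- y - drop(spec$X %*% m_beta)
    ftot <- function(l) {
      p <- vbglm:::.lam_parts(spec, l, r = r, Sb = Sb)
      p$ld$val + p$quad$val + p$tr$val
    }
    expect_lt(max(abs(B - fd_hessian(ftot, m_lam))), 1e-4)
  }
  # k = 1, Q = I, S_beta = 0, zero residual: ln|V| = n*lambda is linear, the
  # trace and residual terms vanish, so B = 0
  sph <- glm_spec(spec$X, list(diag(spec$n)))
  B0 <- compute_B(c(1, 2), matrix(0, 2, 2), 0.3,
                  drop(spec$X %*% c(1, 2)), sph)
  expect_lt(max(abs(B0)), 1e-10)
})

test_that("Newton solver is exact on quadratics and closed-form 1-D problems", {
  M <- matrix(c(2, 0.5, 0.5, 1), 2)
  a <- c(1, -2)
  obj <- function(l) -0.5 * drop(crossprod(l - a, M %*% (l - a)))
  gr <- function(l) -drop(M %*% (l - a))
  he <- function(l) -M
  res <- lambda_stationary_solve(obj, gr, he, c(5, 5))
  expect_lt(max(abs(res$lambda - a)), 1e-10)
  expect_equal(res$steps, 1L)
  expect_false(res$no_progress)

  # starting at the optimum: no steps taken
  res0 <- lambda_stationary_solve(obj, gr, he, a)
  expect_equal(res0$steps, 0L)
  expect_identical(res0$lambda, a)

  # concave non-quadratic: f(l) = -e^l + 2l has stationary point ln 2
  res1 <- lambda_stationary_solve(function(l) -exp(l) + 2 * l,
                                  function(l) -exp(l) + 2,
                                  function(l) matrix(-exp(l)), 0)
  expect_equal(res1$lambda, log(2), tolerance = 1e-6)

  # the returned point never has a lower objective than the start
  expect_gte(res$objective, obj(c(5, 5)))
})

test_that("GLS estimator reduces to OLS, identity, and matches direct minimization", {
  spec <- small_spec(n = 24)
  set.seed(51)
  y <- rnorm(spec$n)
  sph <- glm_spec(spec$X, list(diag(spec$n)))
  ols <- unname(drop(solve(crossprod(spec$X), crossprod(spec$X, y))))
  for (s2 in c(0.3, 1, 4)) {
    expect_equal(gls_estimator(log(s2), y, sph), ols, tolerance = 1e-10)
  }
  eye <- glm_spec(diag(6), list(diag(6)))
  expect_equal(gls_estimator(-0.2, y[1:6], eye), y[1:6])
  # brute-force quadratic minimization oracle on a small instance
  ds <- dense_spec(n = 6, p = 2, k = 2)
  lam <- c(-0.3, 0.2)
  yy <- rnorm(6)
  V <- assemble_covariance(lam, ds$Q)
  fn <- function(b) drop(crossprod(yy - ds$X %*% b, solve(V[,], yy - ds$X %*% b)))
  opt <- optim(c(0, 0), fn, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(gls_estimator(lam, yy, ds), opt$par, tolerance = 1e-6)
})

test_that("ReML objective: hand-computed value, column-space invariance, identity with the free energy", {
  # n = 2, p = 1, X = (1,1)', V = I, y = (1,1)': zero residual, X'X = 2
  sc <- glm_spec(matrix(1, 2, 1), list(diag(2)))
  expect_equal(reml_objective(0, c(1, 1), sc), -0.5 * log(2),
               tolerance = 1e-12)
  spec <- small_spec(n = 24)
  set.seed(61)
  y <- rnorm(spec$n)
  lam <- c(-0.2, -1)
  # adding a column-space vector only shifts the absorbed GLS fit
  shift <- drop(spec$X %*% c(3, -1))
  expect_equal(reml_objective(lam, y + shift, spec),
               reml_objective(lam, y, spec), tolerance = 1e-8)
  # F^ReML at the exact posterior equals l_ReML + c, c = -(n/2)ln 2pi + (p/2)ln 2pi
  cst <- -spec$n / 2 * log(2 * pi) + spec$p / 2 * log(2 * pi)
  for (i in 1:10) {
    l <- rnorm(2) * 0.5
    b <- gls_estimator(l, y, spec)
    S <- solve(vbglm:::.gls_quantities(spec, l, y)$XtViX)
    expect_equal(reml_free_energy(b, S, l, y, spec) - reml_objective(l, y, spec),
                 cst, tolerance = 1e-10)
  }
})

test_that("free energies are nested: VML strips lambda terms from VB, ReML strips the beta prior", {
  spec <- small_spec(n = 24)
  prior <- prior_spec(c(0, 0), diag(10, 2), c(0, 0), diag(10, 2))
  set.seed(71)
  y <- rnorm(spec$n) + drop(spec$X %*% c(2, -1))
  st <- variational_state(c(1.5, -0.5), diag(c(0.2, 0.3)), c(-0.3, -1),
                          diag(c(0.4, 0.5)))
  fvb <- vb_free_energy(st, y, spec, prior)
  fvml <- vml_free_energy(st$m_beta, st$S_beta, st$m_lam, y, spec, prior)
  B <- compute_B(st$m_beta, st$S_beta, st$m_lam, y, spec)
  Sli <- solve(prior$Sigma_lam)
  lam_terms <- -sum(B * st$S_lam) / 4 -
    1 * log(2 * pi) - 0.5 * determinant(prior$Sigma_lam)$modulus[1] -
    0.5 * drop(crossprod(st$m_lam - prior$mu_lam,
                         Sli %*% (st$m_lam - prior$mu_lam))) -
    0.5 * sum(Sli * st$S_lam) +
    1 * log(2 * pi * exp(1)) + 0.5 * determinant(st$S_lam)$modulus[1]
  expect_equal(fvb, fvml + lam_terms, tolerance = 1e-10)
  # VML minus ReML = Gaussian prior complexity terms for beta
  frml <- reml_free_energy(st$m_beta, st$S_beta, st$m_lam, y, spec)
  Sbi <- solve(prior$Sigma_beta)
  beta_terms <- -1 * log(2 * pi) - 0.5 * determinant(prior$Sigma_beta)$modulus[1] -
    0.5 * drop(crossprod(st$m_beta, Sbi %*% st$m_beta)) -
    0.5 * sum(Sbi * st$S_beta)
  expect_equal(fvml, frml + beta_terms, tolerance = 1e-10)
  expect_true(is.finite(fvb) && is.finite(fvml) && is.finite(frml))
})

test_that("spherical fits recover the closed-form ML and ReML estimators", {
  opts <- fit_options(delta = 1e-12, max_iter = 200, newton_tol = 1e-10)
  set.seed(81)
  for (i in 1:5) {
    n <- sample(15:40, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n))
    y <- drop(X %*% rnorm(3)) + rnorm(n, sd = runif(1, 0.5, 2))
    spec <- glm_spec(X, list(diag(n)))
    ml <- ml_fit(y, spec, options = opts)
    ref <- spherical_ml(y, X)
    expect_equal(ml$state$beta, ref$beta_hat, tolerance = 1e-6)
    expect_equal(exp(ml$state$lam), ref$sigma2_hat, tolerance = 1e-6)
    rm_ <- reml_fit(y, spec, variational_state(rep(0, 3), diag(10, 3)),
                    options = opts)
    expect_equal(exp(rm_$state$m_lam), spherical_reml_sigma2(y, X),
                 tolerance = 1e-6)
  }
})

test_that("fits on the demonstration model converge quickly with monotone traces", {
  spec <- demo_spec()
  y <- simulate_glm(spec, demo_params(), seed = 7)
  setup <- recovery_setup(2, 2)
  fits <- list(
    vb = vb_fit(y, spec, setup$vb_prior),
    vml = vml_fit(y, spec, setup$vml_prior),
    reml = reml_fit(y, spec),
    ml = ml_fit(y, spec)
  )
  for (f in fits) {
    expect_true(f$converged)
    expect_lte(f$n_iter, 8)
    expect_gte(min(diff(f$free_energy_trace)), -1e-8)
    expect_lt(max(abs(vbglm:::.est_beta(f) - c(2, -1))), 0.5)
  }
  # converged ReML lambda is a stationary point of the ReML objective
  tight <- reml_fit(y, spec, options = fit_options(delta = 1e-10,
                                                   newton_tol = 1e-8,
                                                   max_iter = 200))
  g <- fd_gradient(function(l) reml_objective(l, y, spec),
                   tight$state$m_lam, h = 1e-6)
  expect_lt(sqrt(sum(g^2)), 1e-4)
})

test_that("noise-free data are recovered exactly by VB under imprecise priors", {
  spec <- small_spec(n = 40)
  beta <- c(2, -1)
  y <- simulate_glm(spec, true_params(beta, c(-50, -50)), seed = 3)
  f <- vb_fit(y, spec, prior_spec(c(0, 0), diag(1e4, 2), c(0, 0), diag(10, 2)))
  expect_lt(max(abs(f$state$m_beta - beta)), 1e-3)
})

test_that("VML with a vague beta prior matches GLS; ReML/VB nest into it", {
  spec <- demo_spec()
  y <- simulate_glm(spec, demo_params(), seed = 19)
  opts <- fit_options(delta = 1e-8, max_iter = 200)
  vague <- prior_spec(c(0, 0), diag(1e8, 2))
  fv <- vml_fit(y, spec, vague, options = opts)
  bgls <- gls_estimator(fv$state$m_lam, y, spec)
  expect_equal(fv$state$m_beta, bgls, tolerance = 1e-4)
  # VML -> ReML in the vague-prior limit
  fr <- reml_fit(y, spec, options = opts)
  expect_lt(max(abs(fv$state$m_beta - fr$state$m_beta)), 1e-3)
  expect_lt(max(abs(fv$state$m_lam - fr$state$m_lam)), 1e-3)
  # VB -> VML with additionally vague lambda prior
  fvb <- vb_fit(y, spec, prior_spec(c(0, 0), diag(1e8, 2),
                                    c(0, 0), diag(1e8, 2)), options = opts)
  expect_lt(max(abs(fvb$state$m_beta - fv$state$m_beta)), 1e-2)
  expect_lt(max(abs(fvb$state$m_lam - fv$state$m_lam)), 1e-2)
})

test_that("ML fit attains a local maximum of the likelihood", {
  spec <- small_spec(n = 40)
  y <- simulate_glm(spec, true_params(c(2, -1), c(-0.5, -2)), seed = 13)
  f <- ml_fit(y, spec, options = fit_options(delta = 1e-10, max_iter = 200,
                                             newton_tol = 1e-9))
  f0 <- ml_free_energy(f$state$beta, f$state$lam, y, spec)
  set.seed(99)
  for (i in 1:100) {
    db <- rnorm(2) * 0.05
    dl <- rnorm(2) * 0.05
    expect_lte(ml_free_energy(f$state$beta + db, f$state$lam + dl, y, spec),
               f0 + 1e-8)
  }
})

test_that("exceedance probabilities follow the Gaussian tail", {
  expect_equal(exceedance_probability(1.3, 2, 1.3), 0.5)
  expect_equal(exceedance_probability(2, 1, 4), 1 - pnorm(2),
               tolerance = 1e-12)
  etas <- seq(-3, 3, by = 0.5)
  p <- exceedance_probability(0, 1, etas)
  expect_true(all(diff(p) < 0))
  expect_error(exceedance_probability(0, -1, 0), "positive")
})

test_that("indefinite covariance states signal errors instead of clamping", {
  spec <- small_spec(n = 24)
  y <- rnorm(24)
  ds <- glm_spec(spec$X, list(diag(24), -diag(24)))
  expect_error(ml_free_energy(c(0, 0), c(-1, 0), y, ds), "positive-definite")
})
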