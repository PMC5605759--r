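# Derivative engine for the covariance map V(lambda) = sum_i exp(lambda_i) Q_i.
#
# All estimators need, per lambda value, the three scalar maps
#   f_ld(lambda)   = ln|V|
#   f_quad(lambda) = r' V^-1 r
#   f_tr(lambda)   = tr(V^-1 X S_b X')
# together with their gradients and Hessians. Two computational paths:
#
# * "eig": when the basis is simultaneously diagonalizable (k = 1, or the
#   default {I, Q2} AR(1)+WN basis), V = U diag(d) U' with
#   d_i = sum_j exp(lambda_j) q_{ji}, and every quantity reduces to O(n)
#   weighted sums of the eigenvalue rows. The decomposition is cached once
#   per glm_spec.
# * "dense": generic Cholesky-based evaluation for arbitrary bases.

.kernel_build <- function(spec) {
  n <- spec$n
  k <- spec$k
  if (k == 1L) {
    eg <- eigen((spec$Q[[1]] + t(spec$Q[[1]])) / 2, symmetric = TRUE)
    return(list(type = "eig", U = eg$vectors,
                q = matrix(eg$values, nrow = 1),
                Xt = crossprod(eg$vectors, spec$X)))
  }
  if (k == 2L && max(abs(spec$Q[[1]] - diag(n))) < 1e-12) {
    eg <- eigen((spec$Q[[2]] + t(spec$Q[[2]])) / 2, symmetric = TRUE)
    return(list(type = "eig", U = eg$vectors,
                q = rbind(rep(1, n), eg$values),
                Xt = crossprod(eg$vectors, spec$X)))
  }
  list(type = "dense")
}

# value/grad/hess of f(lambda) = sum_i w_i / d_i in the eigenbasis;
# `ud` is the k x n matrix u_{ji}/d_i with u_{ji} = exp(lambda_j) q_{ji}.
.fp_wparts <- function(ud, d, w) {
  k <- nrow(ud)
  wd <- w / d
  val <- sum(wd)
  W2 <- drop(ud %*% wd)
  wrow <- matrix(wd, k, length(d), byrow = TRUE)
  W3 <- tcrossprod(ud, ud * wrow)
  grad <- -W2
  H <- 2 * W3
  diag(H) <- diag(H) - W2
  list(val = val, grad = grad, hess = (H + t(H)) / 2)
}

# value/grad/hess of f_ld(lambda) = sum_i log d_i in the eigenbasis.
.fp_ldparts <- function(ud, d) {
  k <- nrow(ud)
  S1 <- rowSums(ud)
  S2 <- tcrossprod(ud)
  H <- -S2
  diag(H) <- diag(H) + S1
  list(val = sum(log(d)), grad = S1, hess = (H + t(H)) / 2)
}

# Evaluate the scalar maps and their lambda-derivatives at `lam`.
# `r` enables the quadratic-form part, `Sb` the trace part. Signals an error
# if V(lam) is indefinite.
.lam_parts <- function(spec, lam, r = NULL, Sb = NULL) {
  kern <- spec$kernel
  k <- spec$k
  .stopifnot_numeric_vector(lam, k, "lam")
  if (kern$type == "eig") {
    u <- exp(lam) * kern$q
    d <- colSums(u)
    if (any(d <= 0) || any(!is.finite(d))) {
      stop("V_lambda is not positive-definite", call. = FALSE)
    }
    ud <- sweep(u, 2, d, "/")
    out <- list(ld = .fp_ldparts(ud, d))
    if (!is.null(r)) {
      rt <- drop(crossprod(kern$U, r))
      out$quad <- .fp_wparts(ud, d, rt^2)
    }
    if (!is.null(Sb)) {
      ad <- rowSums((kern$Xt %*% Sb) * kern$Xt)
      out$tr <- .fp_wparts(ud, d, ad)
    }
    return(out)
  }
  .lam_parts_dense(spec, lam, r, Sb)
}

.lam_parts_dense <- function(spec, lam, r = NULL, Sb = NULL) {
  k <- spec$k
  e <- exp(lam)
  V <- assemble_covariance(lam, spec$Q)
  if (!attr(V, "positive_definite")) {
    stop("V_lambda is not positive-definite", call. = FALSE)
  }
  R <- chol(V)
  Vi <- chol2inv(R)
  P <- lapply(seq_len(k), function(j) Vi %*% spec$Q[[j]])
  g_ld <- vapply(seq_len(k), function(j) e[j] * sum(Vi * spec$Q[[j]]), 0)
  H_ld <- matrix(0, k, k)
  for (j in seq_len(k)) {
    for (l in j:k) {
      H_ld[j, l] <- H_ld[l, j] <- -e[j] * e[l] * sum(P[[j]] * t(P[[l]]))
    }
  }
  diag(H_ld) <- diag(H_ld) + g_ld
  out <- list(ld = list(val = 2 * sum(log(diag(R))), grad = g_ld,
                        hess = (H_ld + t(H_ld)) / 2))
  if (!is.null(r)) {
    rho <- drop(Vi %*% r)
    w <- lapply(seq_len(k), function(j) drop(spec$Q[[j]] %*% rho))
    g <- vapply(seq_len(k), function(j) -e[j] * sum(rho * w[[j]]), 0)
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      for (l in j:k) {
        H[j, l] <- H[l, j] <- 2 * e[j] * e[l] * drop(crossprod(w[[j]], Vi %*% w[[l]]))
      }
    }
    diag(H) <- diag(H) + g
    out$quad <- list(val = sum(r * rho), grad = g, hess = (H + t(H)) / 2)
  }
  if (!is.null(Sb)) {
    A <- spec$X %*% Sb %*% t(spec$X)
    AV <- Vi %*% A
    PA <- lapply(seq_len(k), function(j) P[[j]] %*% AV)
    g <- vapply(seq_len(k), function(j) -e[j] * sum(P[[j]] * t(AV)), 0)
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      for (l in j:k) {
        H[j, l] <- H[l, j] <- e[j] * e[l] *
          (sum(P[[l]] * t(PA[[j]])) + sum(P[[j]] * t(PA[[l]])))
      }
    }
    diag(H) <- diag(H) + g
    out$tr <- list(val = sum(Vi * A), grad = g, hess = (H + t(H)) / 2)
  }
  out
}

# Weighted design quantities X' V^-1 X and X' V^-1 y at a lambda value.
.gls_quantities <- function(spec, lam, y) {
  kern <- spec$kernel
  if (kern$type == "eig") {
    u <- exp(lam) * kern$q
    d <- colSums(u)
    if (any(d <= 0)) stop("V_lambda is not positive-definite", call. = FALSE)
    w <- 1 / d
    yt <- drop(crossprod(kern$U, y))
    XtViX <- crossprod(kern$Xt, kern$Xt * w)
    XtViy <- drop(crossprod(kern$Xt, yt * w))
  } else {
    V <- assemble_covariance(lam, spec$Q)
    if (!attr(V, "positive_definite")) {
      stop("V_lambda is not positive-definite", call. = FALSE)
    }
    R <- chol(V)
    ViX <- backsolve(R, forwardsolve(t(R), spec$X))
    XtViX <- crossprod(spec$X, ViX)
    XtViy <- drop(crossprod(ViX, y))
  }
  list(XtViX = (XtViX + t(XtViX)) / 2, XtViy = XtViy)
}
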