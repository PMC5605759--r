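# Simulation experiments: parameter recovery with outlier screening, model
# recovery by free-energy comparison, and estimation-quality divergences
# under regularizing priors.

.est_beta <- function(fit) {
  if (!is.null(fit$state$m_beta)) fit$state$m_beta else fit$state$beta
}

.est_lam <- function(fit) {
  if (!is.null(fit$state$m_lam)) fit$state$m_lam else fit$state$lam
}

.final_F <- function(fit) fit$free_energy_trace[fit$n_iter]

#' Iterative two-sided Grubbs outlier screen
#'
#' Repeatedly computes the Grubbs statistic
#' \eqn{G = \max_i |x_i - \bar x| / s}, compares it against the critical
#' value at significance level \code{alpha} (derived from the t
#' distribution), removes the most extreme point while the test rejects, and
#' returns the removal mask. Applying the screen to the retained values again
#' flags nothing (idempotence). With fewer than 3 values no test is possible
#' and an empty mask is returned (attribute \code{tested = FALSE}); zero
#' spread stops the iteration without rejections.
#'
#' @param values Numeric vector.
#' @param alpha Two-sided significance level in (0, 1). Default 0.05.
#' @return Logical mask, \code{TRUE} for removed (outlying) values.
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  n_all <- length(values)
  mask <- rep(FALSE, n_all)
  if (n_all < 3L) {
    attr(mask, "tested") <- FALSE
    return(mask)
  }
  active <- which(!mask)
  repeat {
    x <- values[active]
    N <- length(x)
    if (N < 3L) break
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    tq <- stats::qt(1 - alpha / (2 * N), df = N - 2)
    crit <- (N - 1) / sqrt(N) * sqrt(tq^2 / (N - 2 + tq^2))
    if (G > crit) {
      worst <- active[which.max(dev)]
      mask[worst] <- TRUE
      active <- setdiff(active, worst)
    } else {
      break
    }
  }
  attr(mask, "tested") <- TRUE
  mask
}

#' Average Euclidean error and per-component bias of an estimate table
#'
#' Reports the Monte-Carlo estimate of the root-mean-square error defined as
#' the average Euclidean error norm
#' \eqn{\hat E(\|\hat\theta - \theta\|_2)} (the mean of per-realization
#' norms, not the root of the mean squared norm) and the per-component biases
#' \eqn{\hat E(\hat\theta_j - \theta_j)}.
#'
#' @param estimates Matrix of estimates, one realization per row.
#' @param truth True parameter vector (length \code{ncol(estimates)}).
#' @return A list with scalar \code{rmse} and vector \code{bias}.
#' @export
summarize_rmse_bias <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  truth <- as.numeric(truth)
  if (ncol(estimates) != length(truth)) {
    stop("`truth` length must match the estimate dimension", call. = FALSE)
  }
  err <- sweep(estimates, 2, truth)
  list(rmse = mean(sqrt(rowSums(err^2))), bias = colMeans(err))
}

#' Imprecise default priors and initial values for recovery simulations
#'
#' The objective-Bayes setup of the recovery experiments: zero-mean priors
#' with covariance \code{10 I} for both \eqn{\beta} (VB/VML) and
#' \eqn{\lambda} (VB), ReML initial state \eqn{m_\beta = 0},
#' \eqn{S_\beta = 10 I}, and zero initial values for all point estimates.
#'
#' @param p,k Effect-size and covariance-component dimensions.
#' @return A named list with the per-method priors and initial values.
#' @export
recovery_setup <- function(p, k) {
  list(
    vb_prior = prior_spec(rep(0, p), diag(10, p), rep(0, k), diag(10, k)),
    vml_prior = prior_spec(rep(0, p), diag(10, p)),
    vml_lam_init = rep(0, k),
    reml_init_state = variational_state(rep(0, p), diag(10, p)),
    reml_lam_init = rep(0, k),
    ml_beta_init = rep(0, p),
    ml_lam_init = rep(0, k)
  )
}

.fit_all_methods <- function(y, spec, setup, options) {
  list(
    VB = vb_fit(y, spec, setup$vb_prior, options),
    VML = vml_fit(y, spec, setup$vml_prior, setup$vml_lam_init, options),
    ReML = reml_fit(y, spec, setup$reml_init_state, setup$reml_lam_init,
                    options),
    ML = ml_fit(y, spec, setup$ml_beta_init, setup$ml_lam_init, options)
  )
}

.cumstats <- function(x) {
  r <- seq_along(x)
  avg <- cumsum(x) / r
  v <- c(NA_real_, vapply(r[-1], function(i) stats::var(x[seq_len(i)]), 0))
  data.frame(index = r, cum_avg = avg, cum_var = v)
}

#' Parameter recovery experiment
#'
#' Draws \code{n_real} realizations from the generating model, fits each with
#' VB, VML, ReML, and ML, and summarizes the converged effect-size and
#' covariance-component estimates by cumulative averages and variances.
#' Covariance-component estimates are screened per component with the
#' iterative Grubbs test; a realization is masked for a method when any of
#' its lambda components is flagged or when the fit did not converge
#' (non-converged fits are also reported separately).
#'
#' @param spec Generating \code{\link{glm_spec}}.
#' @param params Generating \code{\link{true_params}}.
#' @param n_real Number of data realizations. Default 100.
#' @param seed Master seed; per-realization seeds are derived from it.
#' @param options \code{\link{fit_options}} shared by all fits.
#' @param setup Per-method priors and inits; default
#'   \code{\link{recovery_setup}}.
#' @param alpha Grubbs significance level. Default 0.05.
#' @return An object of class \code{"recovery_report"}: long estimate table,
#'   per-method lambda outlier masks and rates, cumulative statistics, and
#'   convergence bookkeeping.
#' @export
parameter_recovery <- function(spec, params, n_real = 100, seed,
                               options = fit_options(),
                               setup = recovery_setup(spec$p, spec$k),
                               alpha = 0.05) {
  seeds <- .spawn_seeds(seed, n_real)
  methods <- c("VB", "VML", "ReML", "ML")
  p <- spec$p
  k <- spec$k
  beta_est <- lapply(methods, function(m) matrix(NA_real_, n_real, p))
  lam_est <- lapply(methods, function(m) matrix(NA_real_, n_real, k))
  names(beta_est) <- names(lam_est) <- methods
  conv <- matrix(TRUE, n_real, 4, dimnames = list(NULL, methods))
  for (r in seq_len(n_real)) {
    y <- simulate_glm(spec, params, seeds[r])
    fits <- .fit_all_methods(y, spec, setup, options)
    for (m in methods) {
      beta_est[[m]][r, ] <- .est_beta(fits[[m]])
      lam_est[[m]][r, ] <- .est_lam(fits[[m]])
      conv[r, m] <- fits[[m]]$converged
    }
  }
  masks <- lapply(methods, function(m) {
    comp <- vapply(seq_len(k),
                   function(j) grubbs_outliers(lam_est[[m]][, j], alpha),
                   logical(n_real))
    union_mask <- apply(comp, 1, any) | !conv[, m]
    list(per_component = comp, union = union_mask)
  })
  names(masks) <- methods
  cumulative <- do.call(rbind, lapply(methods, function(m) {
    rows <- list()
    for (j in seq_len(p)) {
      cs <- .cumstats(beta_est[[m]][, j])
      rows[[length(rows) + 1L]] <-
        cbind(method = m, parameter = paste0("beta", j), cs)
    }
    for (j in seq_len(k)) {
      keep <- !masks[[m]]$union
      cs <- .cumstats(lam_est[[m]][keep, j])
      rows[[length(rows) + 1L]] <-
        cbind(method = m, parameter = paste0("lam", j), cs)
    }
    do.call(rbind, rows)
  }))
  estimates <- do.call(rbind, lapply(methods, function(m) {
    data.frame(
      realization = rep(seq_len(n_real), p + k),
      method = m,
      parameter = rep(c(paste0("beta", seq_len(p)), paste0("lam", seq_len(k))),
                      each = n_real),
      value = c(beta_est[[m]], lam_est[[m]]),
      converged = rep(conv[, m], p + k)
    )
  }))
  structure(list(
    estimates = estimates,
    beta_estimates = beta_est,
    lam_estimates = lam_est,
    masks = masks,
    outlier_rate = vapply(masks, function(m) mean(m$union), 0),
    component_outlier_rate = vapply(masks, function(m) colMeans(m$per_component),
                                    numeric(k)),
    converged = conv,
    cumulative = cumulative,
    truth = params,
    n_real = n_real
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d realizations\n", x$n_real))
  for (m in names(x$beta_estimates)) {
    cat(sprintf(
      "  %-4s beta mean: %s | lambda mean (screened): %s | outlier rate %.0f%%\n",
      m, paste(sprintf("%.3f", colMeans(x$beta_estimates[[m]])), collapse = ", "),
      paste(sprintf("%.3f",
                    colMeans(x$lam_estimates[[m]][!x$masks[[m]]$union, ,
                                                  drop = FALSE])),
            collapse = ", "),
      100 * x$outlier_rate[m]))
  }
  invisible(x)
}

#' Model recovery experiment
#'
#' Crossover design comparing a one-regressor generating/analysis model
#' (first design column; MG1/MA1) against the full two-regressor model
#' (MG2/MA2). For each generator, \code{n_real} realizations are drawn and
#' analysed under both analysis models with all four estimation techniques;
#' the converged free energy serves as the (marginal) log-likelihood
#' approximation. Lambda-outlier realizations (Grubbs union over analysis
#' models and components, plus non-converged fits) are excluded per
#' generator and method, so each cell pair is averaged over an identical
#' realization set.
#'
#' @param spec Full two-column \code{\link{glm_spec}}.
#' @param params Generating parameters of the full model; MG1 uses the first
#'   effect-size entry only.
#' @inheritParams parameter_recovery
#' @return An object of class \code{"model_recovery_report"} with the
#'   per-realization free energies, cell means, matched-model margins, and
#'   win counts.
#' @export
model_recovery <- function(spec, params, n_real = 100, seed,
                           options = fit_options(), alpha = 0.05) {
  if (spec$p < 2) stop("model recovery needs a two-column design",
                       call. = FALSE)
  spec1 <- glm_spec(spec$X[, 1, drop = FALSE], spec$Q)
  specs <- list(MA1 = spec1, MA2 = spec)
  gens <- list(
    MG1 = list(spec = spec1,
               params = true_params(params$beta[1], params$lam)),
    MG2 = list(spec = spec, params = params)
  )
  methods <- c("VB", "VML", "ReML", "ML")
  setups <- lapply(specs, function(s) recovery_setup(s$p, s$k))
  rows <- list()
  lam_store <- list()
  for (g in names(gens)) {
    seeds <- .spawn_seeds(seed + match(g, names(gens)) - 1L, n_real)
    for (r in seq_len(n_real)) {
      y <- simulate_glm(gens[[g]]$spec, gens[[g]]$params, seeds[r])
      for (a in names(specs)) {
        fits <- .fit_all_methods(y, specs[[a]], setups[[a]], options)
        for (m in methods) {
          rows[[length(rows) + 1L]] <- data.frame(
            generator = g, analyzer = a, method = m, realization = r,
            free_energy = .final_F(fits[[m]]),
            converged = fits[[m]]$converged
          )
          lam_store[[paste(g, a, m, sep = ".")]] <-
            rbind(lam_store[[paste(g, a, m, sep = ".")]],
                  .est_lam(fits[[m]]))
        }
      }
    }
  }
  fe <- do.call(rbind, rows)
  masks <- list()
  for (g in names(gens)) {
    for (m in methods) {
      mask <- rep(FALSE, n_real)
      for (a in names(specs)) {
        lam <- lam_store[[paste(g, a, m, sep = ".")]]
        for (j in seq_len(ncol(lam))) {
          mask <- mask | grubbs_outliers(lam[, j], alpha)
        }
        mask <- mask | !fe$converged[fe$generator == g & fe$analyzer == a &
                                       fe$method == m]
      }
      masks[[paste(g, m, sep = ".")]] <- mask
    }
  }
  cells <- expand.grid(generator = names(gens), analyzer = names(specs),
                       method = methods, stringsAsFactors = FALSE)
  cells$mean_free_energy <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- fe$generator == cells$generator[i] &
      fe$analyzer == cells$analyzer[i] & fe$method == cells$method[i]
    keep <- !masks[[paste(cells$generator[i], cells$method[i], sep = ".")]]
    cells$mean_free_energy[i] <- mean(fe$free_energy[sel][keep])
  }
  margins <- do.call(rbind, lapply(names(gens), function(g) {
    matched <- if (g == "MG1") "MA1" else "MA2"
    other <- setdiff(names(specs), matched)
    do.call(rbind, lapply(methods, function(m) {
      fm <- cells$mean_free_energy[cells$generator == g &
                                     cells$analyzer == matched &
                                     cells$method == m]
      fo <- cells$mean_free_energy[cells$generator == g &
                                     cells$analyzer == other &
                                     cells$method == m]
      selm <- fe$generator == g & fe$analyzer == matched & fe$method == m
      selo <- fe$generator == g & fe$analyzer == other & fe$method == m
      keep <- !masks[[paste(g, m, sep = ".")]]
      wins <- sum(fe$free_energy[selm][keep] > fe$free_energy[selo][keep])
      data.frame(generator = g, method = m, matched = matched,
                 margin = fm - fo, wins = wins, n_kept = sum(keep))
    }))
  }))
  structure(list(free_energies = fe, cell_means = cells, margins = margins,
                 masks = masks, n_real = n_real),
            class = "model_recovery_report")
}

#' @export
print.model_recovery_report <- function(x, ...) {
  cat(sprintf("Model recovery over %d realizations per generator\n",
              x$n_real))
  print(x$margins, row.names = FALSE)
  invisible(x)
}

#' Prior/initialization sets of the divergence simulations
#'
#' Named initialization sets for the estimation-quality divergence
#' simulations. Set \code{"8A"} (effect-size focus) pins the first effect
#' size with a precise prior variance of 1e-2 while leaving the second
#' imprecise (1e1), with expectations initialized at (1, 0) and lambda at
#' (-1, -1). Set \code{"8B"} (covariance focus) uses imprecise isotropic
#' priors (10 I) with zero effect-size initialization and lambda at (-1,
#' -1); only VB carries a lambda prior (covariance 10 I).
#'
#' @param name \code{"8A"} or \code{"8B"}.
#' @return A setup list as consumed by the internal four-method fitter.
#' @export
table1_init <- function(name = c("8A", "8B")) {
  name <- match.arg(name)
  lam0 <- c(-1, -1)
  if (name == "8A") {
    mb <- c(1, 0)
    Sb <- diag(c(1e-2, 1e1))
  } else {
    mb <- c(0, 0)
    Sb <- diag(10, 2)
  }
  list(
    vb_prior = prior_spec(mb, Sb, lam0, diag(10, 2)),
    vml_prior = prior_spec(mb, Sb),
    vml_lam_init = lam0,
    reml_init_state = variational_state(mb, diag(10, 2)),
    reml_lam_init = lam0,
    ml_beta_init = mb,
    ml_lam_init = lam0
  )
}

#' Estimation-quality divergence experiment
#'
#' Sweeps the first covariance component parameter over a noise grid with
#' true effect sizes \eqn{\beta = (1, 1)^T} and \eqn{\lambda_2 = -2}, fits
#' every realization with all four techniques, and reports the average
#' Euclidean error (\code{\link{summarize_rmse_bias}}) and per-component
#' biases of the focus parameter block. Scenario \code{"effect"} (grid on
#' high noise levels, initialization set 8A) focuses on \eqn{\beta};
#' scenario \code{"covariance"} (grid around zero, set 8B) focuses on
#' \eqn{\lambda}. No outlier screening is applied.
#'
#' @param spec Two-column \code{\link{glm_spec}}.
#' @param grid Numeric vector of \eqn{\lambda_1} values; defaults to 7
#'   points on [6, 12] for \code{"effect"} and on [-1, 1] for
#'   \code{"covariance"}.
#' @param scenario \code{"effect"} or \code{"covariance"}.
#' @inheritParams parameter_recovery
#' @return An object of class \code{"divergence_report"}: a summary data
#'   frame (grid point, method, rmse, biases) and the raw estimate arrays.
#' @export
divergence_experiment <- function(spec, grid = NULL,
                                  scenario = c("effect", "covariance"),
                                  n_real = 100, seed,
                                  options = fit_options()) {
  scenario <- match.arg(scenario)
  if (is.null(grid)) {
    grid <- if (scenario == "effect") seq(6, 12, by = 1) else
      seq(-1, 1, length.out = 7)
  }
  setup <- table1_init(if (scenario == "effect") "8A" else "8B")
  beta_true <- c(1, 1)
  methods <- c("VB", "VML", "ReML", "ML")
  seeds <- matrix(.spawn_seeds(seed, length(grid) * n_real),
                  nrow = n_real)
  summary_rows <- list()
  raw <- list()
  for (gi in seq_along(grid)) {
    params <- true_params(beta_true, c(grid[gi], -2))
    est_b <- lapply(methods, function(m) matrix(NA_real_, n_real, 2))
    est_l <- lapply(methods, function(m) matrix(NA_real_, n_real, 2))
    names(est_b) <- names(est_l) <- methods
    for (r in seq_len(n_real)) {
      y <- simulate_glm(spec, params, seeds[r, gi])
      fits <- .fit_all_methods(y, spec, setup, options)
      for (m in methods) {
        est_b[[m]][r, ] <- .est_beta(fits[[m]])
        est_l[[m]][r, ] <- .est_lam(fits[[m]])
      }
    }
    for (m in methods) {
      est <- if (scenario == "effect") est_b[[m]] else est_l[[m]]
      truth <- if (scenario == "effect") beta_true else c(grid[gi], -2)
      s <- summarize_rmse_bias(est, truth)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        lam1 = grid[gi], method = m, rmse = s$rmse,
        bias1 = s$bias[1], bias2 = s$bias[2]
      )
    }
    raw[[gi]] <- list(lam1 = grid[gi], beta = est_b, lam = est_l)
  }
  structure(list(summary = do.call(rbind, summary_rows), raw = raw,
                 scenario = scenario, grid = grid, n_real = n_real),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("Estimation-quality divergence (%s scenario, %d realizations per grid point)\n",
              x$scenario, x$n_real))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
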