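# Delimited-matrix and configuration I/O, the mass-univariate runner and
# exceedance maps, and fixture generation. Matrices travel as comma-separated
# text without header (rows = scans); numbers are serialized with 17
# significant digits so that write/read round-trips are bit-exact.

#' Write a numeric matrix as headerless CSV
#'
#' @param x Numeric matrix or vector (written as one column).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  x <- as.matrix(x)
  txt <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  utils::write.table(txt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a headerless CSV numeric matrix
#'
#' @param path Input file path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path),
                               call. = FALSE)
  M <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(M) <- NULL
  M
}

#' Write / read an onset table
#'
#' Onset tables are CSV files with header columns \code{condition},
#' \code{onset_s}, \code{duration_s}.
#'
#' @param onsets Data frame with the three onset columns.
#' @param path File path.
#' @return \code{path} (writer) or the onset data frame (reader).
#' @export
write_onsets_csv <- function(onsets, path) {
  stopifnot(all(c("condition", "onset_s", "duration_s") %in% names(onsets)))
  utils::write.csv(onsets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_onsets_csv
#' @export
read_onsets_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a run configuration
#'
#' Configurations are YAML documents with keys \code{method} (one of
#' \code{vb}, \code{vml}, \code{reml}, \code{ml}), \code{data},
#' \code{design}, \code{basis} (either a list of basis-matrix paths or
#' \code{\{tau: ...\}} for the default AR(1)+white-noise basis),
#' \code{prior} (\code{mu_beta}, \code{Sigma_beta}, \code{mu_lam},
#' \code{Sigma_lam}; scalar covariances are expanded to multiples of the
#' identity), \code{init} (\code{beta}, \code{lam}, \code{m_beta},
#' \code{S_beta}), \code{options} (\code{delta}, \code{max_iter}),
#' \code{seed}, and command-specific extras such as \code{eta} and
#' \code{component} for exceedance maps.
#'
#' @param path Path to a YAML configuration file.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  config <- yaml::read_yaml(path)
  # relative input paths are resolved against the config file's directory
  config$.dir <- dirname(normalizePath(path))
  config
}

.cfg_path <- function(config, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p) || is.null(config$.dir)) return(p)
  file.path(config$.dir, p)
}

.cfg_matrix <- function(x, dim, what) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1L && !is.list(x)) return(diag(as.numeric(x), dim))
  M <- if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else as.matrix(x)
  if (nrow(M) != dim || ncol(M) != dim) {
    stop(sprintf("config key `%s` must be %d x %d", what, dim, dim),
         call. = FALSE)
  }
  M
}

.cfg_spec <- function(config) {
  X <- read_matrix_csv(.cfg_path(config, config$design))
  n <- nrow(X)
  if (!is.null(config$basis$tau)) {
    Q <- build_covariance_basis(n, config$basis$tau)
  } else if (is.character(config$basis) || is.list(config$basis)) {
    Q <- lapply(unlist(config$basis),
                function(p) read_matrix_csv(.cfg_path(config, p)))
  } else {
    Q <- build_covariance_basis(n)
  }
  glm_spec(X, Q)
}

.cfg_prior <- function(config, spec, need_lam) {
  pr <- config$prior
  if (is.null(pr) || is.null(pr$mu_beta)) {
    stop("config is missing key `prior.mu_beta`", call. = FALSE)
  }
  mu_b <- as.numeric(unlist(pr$mu_beta))
  if (length(mu_b) != spec$p) {
    stop("config key `prior.mu_beta` has the wrong length", call. = FALSE)
  }
  Sb <- .cfg_matrix(pr$Sigma_beta, spec$p, "prior.Sigma_beta")
  if (is.null(Sb)) stop("config is missing key `prior.Sigma_beta`",
                        call. = FALSE)
  if (need_lam) {
    if (is.null(pr$mu_lam)) {
      stop("config is missing key `prior.mu_lam` (required for vb)",
           call. = FALSE)
    }
    prior_spec(mu_b, Sb, as.numeric(unlist(pr$mu_lam)),
               .cfg_matrix(pr$Sigma_lam, spec$k, "prior.Sigma_lam"))
  } else {
    prior_spec(mu_b, Sb)
  }
}

.cfg_options <- function(config) {
  op <- config$options
  fit_options(
    delta = if (!is.null(op$delta)) op$delta else 1e-3,
    max_iter = if (!is.null(op$max_iter)) op$max_iter else 64
  )
}

.fit_one_series <- function(y, spec, method, config, options) {
  init_lam <- if (!is.null(config$init$lam)) {
    as.numeric(unlist(config$init$lam))
  } else {
    rep(0, spec$k)
  }
  switch(
    method,
    vb = vb_fit(y, spec, .cfg_prior(config, spec, TRUE), options),
    vml = vml_fit(y, spec, .cfg_prior(config, spec, FALSE), init_lam,
                  options),
    reml = {
      st <- variational_state(
        if (!is.null(config$init$m_beta)) {
          as.numeric(unlist(config$init$m_beta))
        } else {
          rep(0, spec$p)
        },
        if (!is.null(config$init$S_beta)) {
          .cfg_matrix(config$init$S_beta, spec$p, "init.S_beta")
        } else {
          diag(10, spec$p)
        })
      reml_fit(y, spec, st, init_lam, options)
    },
    ml = ml_fit(
      y, spec,
      if (!is.null(config$init$beta)) {
        as.numeric(unlist(config$init$beta))
      } else {
        rep(0, spec$p)
      },
      init_lam, options),
    stop(sprintf("unknown method `%s` (expected vb, vml, reml or ml)",
                 method), call. = FALSE)
  )
}

#' Fit a (multi-)series dataset from a run configuration
#'
#' Reads the response matrix (one column per series/voxel), design, and
#' covariance basis named in the configuration, fits every series with the
#' configured estimation technique, and (when \code{config$out} is set)
#' writes a per-series estimate table \code{estimates.csv}, the free-energy
#' traces \code{free_energy_trace.csv} (one row per series, NA-padded), and
#' for vb/vml/reml the posterior variance table \code{uncertainty.csv}.
#'
#' @param config Configuration list (see \code{\link{read_run_config}}) or
#'   path to a YAML file.
#' @return Invisibly, a list with the per-series fits and the estimate
#'   table.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  method <- tolower(config$method)
  spec <- .cfg_spec(config)
  Y <- read_matrix_csv(.cfg_path(config, config$data))
  if (nrow(Y) != spec$n) {
    stop("config: `data` and `design` row counts differ", call. = FALSE)
  }
  options <- .cfg_options(config)
  fits <- lapply(seq_len(ncol(Y)),
                 function(j) .fit_one_series(Y[, j], spec, method, config,
                                             options))
  est <- do.call(rbind, lapply(seq_along(fits), function(j) {
    f <- fits[[j]]
    data.frame(series = j,
               t(stats::setNames(.est_beta(f), paste0("beta", seq_len(spec$p)))),
               t(stats::setNames(.est_lam(f), paste0("lam", seq_len(spec$k)))),
               free_energy = .final_F(f), n_iter = f$n_iter,
               converged = f$converged)
  }))
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(est, file.path(config$out, "estimates.csv"),
                     row.names = FALSE)
    maxlen <- max(vapply(fits, function(f) f$n_iter, 1L))
    traces <- t(vapply(fits, function(f) {
      c(f$free_energy_trace, rep(NA_real_, maxlen - f$n_iter))
    }, numeric(maxlen)))
    write_matrix_csv(traces, file.path(config$out, "free_energy_trace.csv"))
    if (method %in% c("vb", "vml", "reml")) {
      unc <- do.call(rbind, lapply(seq_along(fits), function(j) {
        f <- fits[[j]]
        row <- data.frame(series = j,
                          t(stats::setNames(diag(f$state$S_beta),
                                            paste0("var_beta", seq_len(spec$p)))))
        if (method == "vb") {
          row <- cbind(row, t(stats::setNames(diag(f$state$S_lam),
                                              paste0("var_lam",
                                                     seq_len(spec$k)))))
        }
        row
      }))
      utils::write.csv(unc, file.path(config$out, "uncertainty.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(fits = fits, estimates = est, spec = spec))
}

#' Posterior exceedance-probability maps over a series set
#'
#' Fits every series as in \code{\link{run_fit}} and tabulates, for the
#' requested parameter component, the posterior expectation, variance, and
#' exceedance probability \eqn{p(\theta > \eta)}. Effect-size maps require a
#' technique that quantifies posterior uncertainty over \eqn{\beta} (vb,
#' vml, reml); covariance-component maps are available under vb only, since
#' the other techniques provide no posterior over \eqn{\lambda}. Requests
#' without the needed uncertainty are refused.
#'
#' @param config Configuration list or YAML path; additional keys
#'   \code{eta} (threshold), \code{component} (e.g. \code{"beta1"} or
#'   \code{"lam1"}).
#' @return The exceedance table (one row per series); also written to
#'   \code{config$out} as \code{exceedance.csv} when set.
#' @export
run_maps <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  method <- tolower(config$method)
  comp <- config$component
  if (is.null(comp) || is.null(config$eta)) {
    stop("maps config requires keys `component` and `eta`", call. = FALSE)
  }
  block <- sub("[0-9]+$", "", comp)
  idx <- as.integer(sub("^[a-z_]+", "", comp))
  if (block == "beta" && method == "ml") {
    stop("beta exceedance maps are not available under method=ml (no posterior uncertainty over beta)",
         call. = FALSE)
  }
  if (block == "lam" && method != "vb") {
    stop(sprintf("lambda exceedance maps are not available under method=%s (only vb quantifies lambda uncertainty)",
                 method), call. = FALSE)
  }
  if (!block %in% c("beta", "lam")) {
    stop("`component` must name a beta or lam entry, e.g. beta1", call. = FALSE)
  }
  res <- run_fit(config)
  tab <- do.call(rbind, lapply(seq_along(res$fits), function(j) {
    f <- res$fits[[j]]
    if (block == "beta") {
      m <- .est_beta(f)[idx]
      s <- diag(f$state$S_beta)[idx]
    } else {
      m <- f$state$m_lam[idx]
      s <- diag(f$state$S_lam)[idx]
    }
    data.frame(series = j, component = comp, expectation = m, variance = s,
               eta = config$eta,
               exceedance = exceedance_probability(m, s, config$eta))
  }))
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(config$out, "exceedance.csv"),
                     row.names = FALSE)
  }
  tab
}

#' Generate the demonstration fixture bundle
#'
#' Writes the demonstration model to \code{dir}: the 400-scan two-condition
#' design (TR 2 s, expected inter-trial interval 6 s, sd 1 s), the
#' AR(1)+white-noise covariance basis (decay constant 5 scans), one
#' simulated series with \eqn{\beta = (2, -1)^T} and
#' \eqn{\lambda = (-0.5, -2)^T},
#' and one YAML configuration per estimation technique with the imprecise
#' priors/initial values of the demonstration analyses (zero-mean, 10 I) and
#' convergence criterion \eqn{\delta = 10^{-3}}.
#'
#' @param dir Output directory (created if needed). Default a fresh
#'   temporary directory.
#' @param seed Integer seed for the design onsets and the noise draw.
#' @return The directory path, invisibly.
#' @export
make_fixtures <- function(dir = tempfile("vbglm-fixtures-"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .spawn_seeds(seed, 2)
  cfg <- design_config()
  des <- build_design_matrix(cfg, seeds[1])
  spec <- glm_spec(des$X)
  params <- true_params(c(2, -1), c(-0.5, -2))
  y <- simulate_glm(spec, params, seeds[2])
  write_matrix_csv(des$X, file.path(dir, "X.csv"))
  write_onsets_csv(des$onsets, file.path(dir, "onsets.csv"))
  write_matrix_csv(spec$Q[[1]], file.path(dir, "Q1.csv"))
  write_matrix_csv(spec$Q[[2]], file.path(dir, "Q2.csv"))
  write_matrix_csv(y, file.path(dir, "y.csv"))
  base <- list(
    data = "y.csv",
    design = "X.csv",
    basis = list(tau = 5),
    options = list(delta = 1e-3, max_iter = 64),
    seed = as.integer(seed)
  )
  prior_beta <- list(mu_beta = c(0, 0), Sigma_beta = 10)
  cfgs <- list(
    vb = c(base, list(method = "vb",
                      prior = c(prior_beta,
                                list(mu_lam = c(0, 0), Sigma_lam = 10)))),
    vml = c(base, list(method = "vml", prior = prior_beta,
                       init = list(lam = c(0, 0)))),
    reml = c(base, list(method = "reml",
                        init = list(m_beta = c(0, 0), S_beta = 10,
                                    lam = c(0, 0)))),
    ml = c(base, list(method = "ml",
                      init = list(beta = c(0, 0), lam = c(0, 0))))
  )
  for (m in names(cfgs)) {
    yaml::write_yaml(cfgs[[m]], file.path(dir, sprintf("config_%s.yaml", m)))
  }
  invisible(dir)
}
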