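#' Prior specification for BYM and non-spatial Poisson models
#'
#' Fixed effects get independent N(0, `beta_sd`^2) priors (default SD 31.62,
#' i.e. precision 0.001); the intercept is improper flat; both random-effect
#' precisions \eqn{1/\sigma_u^2, 1/\sigma_v^2} get Gamma(`prec_shape`,
#' `prec_rate`) priors (default Gamma(1, 5e-5)). These are the package's
#' documented vague defaults in the spirit of standard disease-mapping
#' software.
#'
#' @param beta_sd Prior SD of each regression coefficient.
#' @param prec_shape,prec_rate Gamma prior on the two precisions.
#' @return A `bym_priors` list.
#' @export
bym_priors <- function(beta_sd = 31.62, prec_shape = 1, prec_rate = 5e-5) {
  stopifnot(beta_sd > 0, prec_shape > 0, prec_rate > 0)
  structure(list(beta_sd = beta_sd, prec_shape = prec_shape,
                 prec_rate = prec_rate), class = "bym_priors")
}

#' MCMC run configuration
#'
#' @param n_chains Number of independent chains (>= 2 for convergence
#'   diagnostics).
#' @param n_iter Total iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain (< `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain `c` runs under `set.seed(seed + c - 1)`.
#' @param target_accept Target acceptance rate of the adaptive random-walk
#'   proposals (0.44, the scalar-update optimum).
#' @param adapt_until Iteration after which proposal SDs are frozen
#'   (defaults to the end of burn-in; adaptation never continues past
#'   burn-in, preserving the stationary distribution).
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(n_chains = 4, n_iter = 20000, n_burnin = 10000,
                         thin = 5, seed = 1L, target_accept = 0.44,
                         adapt_until = n_burnin) {
  stopifnot(n_chains >= 1, n_burnin < n_iter, thin >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept,
                 adapt_until = as.integer(adapt_until)),
            class = "mcmc_control")
}

# Impute (column mean) or drop rows with missing covariates; optionally
# standardize to zero mean / unit SD. Returns list(X, scaled_center/scale,
# keep) for downstream use.
prepare_covariates <- function(data, covariates, impute = c("mean", "drop"),
                               standardize = TRUE) {
  impute <- match.arg(impute)
  if (!length(covariates)) {
    return(list(X = matrix(0, nrow(data), 0), keep = rep(TRUE, nrow(data))))
  }
  miss_cols <- setdiff(covariates, names(data))
  if (length(miss_cols)) {
    abort(paste0("covariate column(s) not in data: ",
                 paste(miss_cols, collapse = ", ")))
  }
  X <- as.matrix(data[covariates])
  keep <- rep(TRUE, nrow(data))
  if (anyNA(X)) {
    if (impute == "mean") {
      n_imp <- sum(is.na(X))
      for (k in seq_len(ncol(X))) {
        nas <- is.na(X[, k])
        X[nas, k] <- mean(X[, k], na.rm = TRUE)
      }
      warn(paste0(n_imp, " missing covariate value(s) imputed by column mean"))
    } else {
      keep <- stats::complete.cases(X)
      warn(paste0(sum(!keep), " row(s) with missing covariates dropped"))
      X <- X[keep, , drop = FALSE]
    }
  }
  ctr <- NULL; scl <- NULL
  if (standardize && ncol(X) > 0) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    if (any(scl == 0)) abort("constant covariate cannot be standardized")
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  list(X = X, center = ctr, scale = scl, keep = keep)
}

#' Fit a non-spatial or BYM Poisson model by MCMC
#'
#' Poisson likelihood \eqn{Y_i \sim \mathrm{Poisson}(E_i \theta_i)} with
#' \eqn{\log\theta_i = \beta_0 + x_i'\beta} (non-spatial) or
#' \eqn{\log\theta_i = \beta_0 + x_i'\beta + u_i + v_i} (BYM), where `u` has
#' an intrinsic CAR prior on `graph` and `v` is i.i.d. Gaussian. Sampling is
#' Metropolis-within-Gibbs: adaptive random-walk updates for \eqn{\beta_0},
#' each \eqn{\beta_k}, each \eqn{u_i}, \eqn{v_i}; conjugate Gibbs draws for
#' the two precisions; `u` is re-centered to per-component mean zero after
#' every sweep (the ICAR sum-to-zero constraint). Missing covariate values
#' are mean-imputed with a warning (see `impute`); covariates are
#' standardized by default so effects are per-SD.
#'
#' The classic BYM decomposition is only sum-identified: `theta` (and
#' `u + v`) are well identified, individual `u`, `v` summaries are weakly
#' identified and should be read with care.
#'
#' @param data A `county_table`; `expected` is filled via
#'   [compute_expected_counts()] if absent.
#' @param graph An [adjacency_graph()] (required when `spatial = TRUE`).
#' @param covariates Character vector of covariate columns (may be empty).
#' @param spatial Fit the BYM model (`TRUE`) or the fixed-effects-only
#'   non-spatial model (`FALSE`).
#' @param priors A [bym_priors()].
#' @param control An [mcmc_control()].
#' @param impute `"mean"` (default) or `"drop"` for missing covariates.
#' @param standardize_covariates Standardize covariates before fitting.
#' @return A `bym_fit` object: retained draws for all parameters
#'   (`$draws` tibble with `.chain`/`.iteration`, plus `u`, `v`, `theta`
#'   matrices), acceptance rates, the model data echo, and configuration.
#' @export
fit_bym <- function(data, graph = NULL, covariates = character(),
                    spatial = !is.null(graph), priors = bym_priors(),
                    control = mcmc_control(), impute = c("mean", "drop"),
                    standardize_covariates = TRUE) {
  impute <- match.arg(impute)
  if (spatial && is.null(graph)) {
    abort("spatial = TRUE requires an adjacency graph")
  }
  if (!"expected" %in% names(data)) data <- compute_expected_counts(data)
  prep <- prepare_covariates(data, covariates, impute, standardize_covariates)
  data <- data[prep$keep, , drop = FALSE]
  if (spatial && graph$n != nrow(data)) {
    abort("graph size does not match number of areas")
  }
  count_col <- if ("cases_period" %in% names(data)) "cases_period" else "cases"
  y <- as.integer(data[[count_col]])
  E <- as.numeric(data$expected)
  X <- prep$X
  n <- length(y)

  nbr0 <- if (spatial) lapply(graph$neighbors, function(v) v - 1L) else
    rep(list(integer()), n)
  comp <- if (spatial) graph$component else rep(1L, n)

  chains <- purrr::map(seq_len(control$n_chains), function(ch) {
    set.seed(control$seed + ch - 1L)
    bym_mcmc_chain(y, E, X, nbr0, comp, spatial,
                   priors$beta_sd, priors$prec_shape, priors$prec_rate,
                   control$n_iter, control$n_burnin, control$thin,
                   control$target_accept, control$adapt_until)
  })

  n_keep <- length(chains[[1]]$beta0)
  bnames <- if (ncol(X) > 0) colnames(X) else character()
  draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    cc <- chains[[ch]]
    d <- tibble::tibble(.chain = ch, .iteration = seq_len(n_keep),
                        beta0 = as.numeric(cc$beta0))
    if (length(bnames)) {
      B <- cc$beta
      colnames(B) <- bnames
      d <- dplyr::bind_cols(d, tibble::as_tibble(B))
    }
    if (spatial) {
      d$sigma_u2 <- as.numeric(cc$sigma_u2)
      d$sigma_v2 <- as.numeric(cc$sigma_v2)
    }
    d
  })
  U <- if (spatial) do.call(rbind, purrr::map(chains, "u")) else NULL
  V <- if (spatial) do.call(rbind, purrr::map(chains, "v")) else NULL
  B0 <- draws$beta0
  ETA <- matrix(B0, nrow = length(B0), ncol = n)
  if (length(bnames)) {
    ETA <- ETA + as.matrix(draws[bnames]) %*% t(X)
  }
  if (spatial) ETA <- ETA + U + V
  theta <- exp(ETA)
  colnames(theta) <- data$area_id

  accept <- purrr::map_dfr(seq_along(chains), function(ch) {
    a <- chains[[ch]]$accept
    tibble::tibble(.chain = ch, block = names(a), rate = as.numeric(a))
  })

  structure(list(
    draws = draws, u = U, v = V, theta = theta,
    data = tibble::tibble(area_id = data$area_id, y = y, expected = E,
                          smr = y / E),
    X = X, covariates = bnames, spatial = spatial,
    covariate_center = prep$center, covariate_scale = prep$scale,
    priors = priors, control = control, accept = accept,
    graph = if (spatial) graph else NULL
  ), class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("# bym_fit: %s model, %d areas, %d covariate(s)\n",
              if (x$spatial) "BYM (ICAR + iid)" else "non-spatial",
              nrow(x$data), length(x$covariates)))
  cat(sprintf("#   %d chain(s) x %d retained draws\n",
              max(x$draws$.chain), sum(x$draws$.chain == 1)))
  invisible(x)
}

#' Joint log-posterior of the BYM / non-spatial model
#'
#' Poisson log-likelihood \eqn{\sum_i [Y_i \log(E_i\theta_i) - E_i\theta_i]}
#' (constants dropped), Gaussian log-priors on the coefficients (flat
#' intercept), the ICAR log-density
#' \eqn{-(n-G)/2 \log\sigma_u^2 - \mathrm{QF}(u)/(2\sigma_u^2)} with `G` the
#' number of graph components, an i.i.d. Normal log-density for `v`, and
#' Gamma log-priors on the precisions -- all up to additive constants fixed
#' across calls. Used mainly for testing and diagnostics; sampling happens in
#' compiled code.
#'
#' @param params List with `beta0`, and optionally `beta` (named as the
#'   covariates), `u`, `v`, `sigma_u2`, `sigma_v2`.
#' @param data County table with `expected` filled.
#' @param graph [adjacency_graph()] or `NULL` for the non-spatial model.
#' @param covariates Covariate columns (standardized internally to match
#'   [fit_bym()]'s default).
#' @param priors A [bym_priors()].
#' @param spatial Include the BYM random-effect terms.
#' @param standardize_covariates As in [fit_bym()].
#' @return Scalar log-posterior (up to a constant).
#' @export
log_posterior <- function(params, data, graph = NULL,
                          covariates = character(), priors = bym_priors(),
                          spatial = !is.null(graph),
                          standardize_covariates = TRUE) {
  if (!"expected" %in% names(data)) data <- compute_expected_counts(data)
  count_col <- if ("cases_period" %in% names(data)) "cases_period" else "cases"
  y <- data[[count_col]]
  E <- data$expected
  n <- length(y)
  prep <- prepare_covariates(data, covariates,
                             standardize = standardize_covariates)
  eta <- rep(params$beta0, n)
  if (length(covariates)) {
    eta <- eta + as.numeric(prep$X %*% params$beta[covariates])
  }
  if (spatial) eta <- eta + params$u + params$v
  if (any(!is.finite(eta))) abort("non-finite linear predictor")
  lp <- sum(y * (log(E) + eta) - E * exp(eta))
  if (length(covariates)) {
    lp <- lp - sum(params$beta[covariates]^2) / (2 * priors$beta_sd^2)
  }
  if (spatial) {
    G <- max(graph$component)
    qf <- icar_quadratic_form(graph, params$u)
    lp <- lp - (n - G) / 2 * log(params$sigma_u2) - qf / (2 * params$sigma_u2)
    lp <- lp - n / 2 * log(params$sigma_v2) -
      sum(params$v^2) / (2 * params$sigma_v2)
    for (s2 in c(params$sigma_u2, params$sigma_v2)) {
      prec <- 1 / s2
      lp <- lp + (priors$prec_shape - 1) * log(prec) - priors$prec_rate * prec
    }
  }
  lp
}

#' Maximum-likelihood fit of the non-spatial Poisson model
#'
#' Fits \eqn{Y_i \sim \mathrm{Poisson}(E_i e^{\beta_0 + x_i'\beta})} by
#' iteratively reweighted least squares (`stats::glm` with a `log(E)`
#' offset), the Newton-type maximizer of the Poisson log-likelihood. Serves
#' as the frequentist cross-check of the Bayesian non-spatial fit.
#'
#' @inheritParams fit_bym
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`; the `glm` object is attached as attribute `"fit"`.
#' @export
fit_nonspatial_mle <- function(data, covariates = character(),
                               impute = c("mean", "drop"),
                               standardize_covariates = TRUE) {
  impute <- match.arg(impute)
  if (!"expected" %in% names(data)) data <- compute_expected_counts(data)
  prep <- prepare_covariates(data, covariates, impute, standardize_covariates)
  data <- data[prep$keep, , drop = FALSE]
  count_col <- if ("cases_period" %in% names(data)) "cases_period" else "cases"
  df <- data.frame(y = data[[count_col]])
  form <- if (ncol(prep$X) > 0) {
    df <- cbind(df, as.data.frame(prep$X))
    stats::as.formula(paste("y ~", paste(colnames(prep$X), collapse = " + ")))
  } else stats::as.formula("y ~ 1")
  fit <- glm(form, family = poisson(), data = df,
             offset = log(data$expected),
             control = list(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) abort("Poisson MLE did not converge in 100 iterations")
  cf <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = ifelse(rownames(cf) == "(Intercept)", "beta0", rownames(cf)),
    estimate = cf[, 1], std.error = cf[, 2],
    statistic = cf[, 3], p.value = cf[, 4])
  attr(out, "fit") <- fit
  out
}
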