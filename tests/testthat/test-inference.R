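# Oracles: independent reimplementations and closed forms that the MCMC and
# log-posterior code must agree with.

test_that("log-posterior matches a term-by-term reimplementation", {
  g <- path3_graph()
  d <- toy_table(cases = c(4, 7, 2), pop = c(100, 150, 80),
                 x1 = c(0.2, -0.5, 1.1))
  d <- compute_expected_counts(d)
  pr <- bym_priors()
  set.seed(21)
  for (rep in 1:5) {
    params <- list(beta0 = rnorm(1), beta = c(x1 = rnorm(1)),
                   u = rnorm(3), v = rnorm(3),
                   sigma_u2 = runif(1, 0.1, 2), sigma_v2 = runif(1, 0.1, 2))
    got <- log_posterior(params, d, g, covariates = "x1", priors = pr)
    # oracle: every density written out explicitly
    x <- scale(d$x1)[, 1]
    eta <- params$beta0 + x * params$beta + params$u + params$v
    lp <- sum(d$cases * (log(d$expected) + eta) - d$expected * exp(eta))
    lp <- lp - params$beta^2 / (2 * pr$beta_sd^2)
    qf <- (params$u[1] - params$u[2])^2 + (params$u[2] - params$u[3])^2
    lp <- lp - (3 - 1) / 2 * log(params$sigma_u2) - qf / (2 * params$sigma_u2)
    lp <- lp - 3 / 2 * log(params$sigma_v2) -
      sum(params$v^2) / (2 * params$sigma_v2)
    for (s2 in c(params$sigma_u2, params$sigma_v2)) {
      lp <- lp + (pr$prec_shape - 1) * log(1 / s2) - pr$prec_rate / s2
    }
    expect_equal(got, as.numeric(lp))
  }
})

test_that("likelihood is maximized at the Poisson rate = mean", {
  d1 <- toy_table(cases = 3, pop = 10)
  d1$expected <- 1
  f <- function(b0) log_posterior(list(beta0 = b0), d1, spatial = FALSE)
  opt <- stats::optimize(f, c(-3, 4), maximum = TRUE)
  expect_equal(opt$maximum, log(3), tolerance = 1e-4)
  # with Y = E, theta = 1 beats any scaled alternative
  d2 <- compute_expected_counts(toy_table(cases = c(5, 9), pop = c(50, 90)))
  for (t in c(0.5, 0.9, 1.3, 2)) {
    expect_gt(log_posterior(list(beta0 = 0), d2, spatial = FALSE),
              log_posterior(list(beta0 = log(t)), d2, spatial = FALSE))
  }
})

test_that("Gibbs precision full conditional matches grid evaluation", {
  g <- path3_graph()
  u <- c(-0.4, 0.1, 0.3)
  pr <- bym_priors(prec_shape = 1, prec_rate = 5e-5)
  qf <- icar_quadratic_form(g, u)
  n <- 3; G <- 1
  # package's conjugate update: Gamma(shape + (n - G)/2, rate + qf/2)
  shape <- pr$prec_shape + (n - G) / 2
  rate <- pr$prec_rate + qf / 2
  # brute-force grid: prior x ICAR likelihood of u given the precision
  grid <- seq(0.01, 400, length.out = 40000)
  logd <- (pr$prec_shape - 1) * log(grid) - pr$prec_rate * grid +
    (n - G) / 2 * log(grid) - grid * qf / 2
  w <- exp(logd - max(logd)); w <- w / sum(w)
  expect_equal(sum(w * grid), shape / rate, tolerance = 1e-3)
  expect_equal(sum(w * grid^2) - sum(w * grid)^2, shape / rate^2,
               tolerance = 1e-2)
  # and the iid-effect analogue on v
  v <- c(0.2, -0.3, 0.05)
  shape_v <- pr$prec_shape + n / 2
  rate_v <- pr$prec_rate + sum(v^2) / 2
  logd <- (pr$prec_shape - 1) * log(grid) - pr$prec_rate * grid +
    n / 2 * log(grid) - grid * sum(v^2) / 2
  w <- exp(logd - max(logd)); w <- w / sum(w)
  expect_equal(sum(w * grid), shape_v / rate_v, tolerance = 1e-3)
})

test_that("single-area posterior matches the Gamma-Poisson conjugate oracle", {
  # Y = 3, E = 1, flat intercept prior: theta | Y ~ Gamma(3, 1)
  d <- toy_table(cases = 3, pop = 10)
  d$expected <- 1
  fit <- fit_bym(d, spatial = FALSE,
                 control = mcmc_control(n_chains = 2, n_iter = 24000,
                                        n_burnin = 4000, thin = 2, seed = 2))
  theta <- as.numeric(fit$theta)
  mcse <- sd(theta) / sqrt(length(theta) / 20)  # conservative ESS
  expect_lt(abs(mean(theta) - 3), 3 * mcse)
  expect_equal(var(theta), 3, tolerance = 0.4)
})

test_that("Poisson MLE behaves at its closed-form cases", {
  d <- toy_table(cases = c(5, 9), pop = c(50, 90))
  d <- compute_expected_counts(d)
  m <- fit_nonspatial_mle(d)
  expect_equal(m$estimate[m$term == "beta0"], 0, tolerance = 1e-10)
  # null covariate at large n: estimate near 0, |z| unremarkable
  sim <- simulate_bym_data(lattice_graph(20, 20), beta0 = 0,
                           beta = c(x1 = 0), sigma_u = 0, sigma_v = 0,
                           seed = 31)
  m <- fit_nonspatial_mle(sim$data, "x1")
  expect_lt(abs(m$estimate[m$term == "x1"]), 0.05)
})

test_that("non-spatial Bayesian means agree with the MLE under vague priors", {
  sim <- simulate_bym_data(lattice_graph(20, 20), beta0 = 0.1,
                           beta = c(x1 = 0.3), sigma_u = 0, sigma_v = 0,
                           seed = 17)
  mle <- fit_nonspatial_mle(sim$data, "x1")
  fit <- fit_bym(sim$data, covariates = "x1", spatial = FALSE,
                 control = mcmc_control(n_chains = 2, n_iter = 6000,
                                        n_burnin = 2000, thin = 2, seed = 5))
  td <- tidy(fit)
  for (tm in c("beta0", "x1")) {
    b <- fit$draws[[if (tm == "beta0") "beta0" else tm]]
    mcse <- sd(b) / sqrt(length(b) / 20)
    expect_lt(abs(td$estimate[td$term == tm] -
                    mle$estimate[mle$term == tm]), 3 * mcse + 1e-3)
  }
})

test_that("spatial fit shrinks the structured field when there is none", {
  sim <- simulate_bym_data(lattice_graph(8, 8), beta0 = 0, sigma_u = 0,
                           sigma_v = 0, population_range = c(30000L, 30000L),
                           seed = 12)
  fit <- fit_bym(sim$data, graph = sim$graph,
                 control = mcmc_control(n_chains = 2, n_iter = 4000,
                                        n_burnin = 2000, thin = 2, seed = 3))
  expect_lt(mean(fit$draws$sigma_u2), 0.05)
  expect_lt(max(abs(colMeans(fit$u))), 0.25)
})

test_that("posterior draws satisfy their structural invariants", {
  sim <- simulate_bym_data(lattice_graph(4, 4), beta = c(x1 = 0.2), seed = 9)
  fit <- fit_bym(sim$data, graph = sim$graph, covariates = "x1",
                 control = mcmc_control(n_chains = 2, n_iter = 1000,
                                        n_burnin = 500, thin = 1, seed = 4))
  # theta recomputable from the component draws to machine precision
  eta <- matrix(fit$draws$beta0, nrow(fit$u), 16) +
    as.matrix(fit$draws["x1"]) %*% t(fit$X) + fit$u + fit$v
  expect_equal(unname(fit$theta), exp(unname(eta)), tolerance = 1e-12)
  expect_true(all(fit$theta > 0))
  # per-draw sum-to-zero constraint on u (connected graph: one component)
  expect_lt(max(abs(rowSums(fit$u))), 1e-8)
  expect_error(fit_bym(sim$data, spatial = TRUE), "graph")
})

test_that("theta is invariant to rescaling the expected counts", {
  sim <- simulate_bym_data(lattice_graph(6, 6), beta0 = 0.2, sigma_u = 0.3,
                           sigma_v = 0.1, seed = 14)
  d1 <- compute_expected_counts(sim$data)
  d2 <- d1
  d2$expected <- d1$expected * exp(1)
  ctl <- mcmc_control(n_chains = 2, n_iter = 6000, n_burnin = 3000,
                      thin = 3, seed = 6)
  f1 <- fit_bym(d1, graph = sim$graph, control = ctl)
  f2 <- fit_bym(d2, graph = sim$graph, control = ctl)
  expect_equal(mean(f2$draws$beta0) - mean(f1$draws$beta0), -1,
               tolerance = 0.05)
  ey1 <- colMeans(f1$theta) * d1$expected
  ey2 <- colMeans(f2$theta) * d2$expected
  expect_equal(ey1, ey2, tolerance = 0.05)
})

test_that("prior-only spatial sampling reproduces the exact ICAR law", {
  # likelihood switched off, precisions fixed: the u-updates + recentering
  # must target the constrained ICAR distribution simulate_icar_field draws
  # from exactly.
  g <- lattice_graph(4, 4)
  sigma <- 0.7
  set.seed(77)
  res <- bymrisk:::bym_mcmc_chain(
    rep(0L, 16), rep(1, 16), matrix(0, 16, 0),
    lapply(g$neighbors, function(v) v - 1L), g$component, TRUE,
    31.62, 1, 5e-5, 42000L, 2000L, 20L, 0.44, 2000L,
    0, 1 / sigma^2, 100)
  exact <- t(replicate(2000, simulate_icar_field(g, sigma)))
  for (node in c(1, 6, 16)) {
    ks <- suppressWarnings(stats::ks.test(res$u[, node], exact[, node]))
    expect_gt(ks$p.value, 0.01)
  }
  expect_equal(apply(res$u, 2, sd), apply(exact, 2, sd), tolerance = 0.12)
})

test_that("split R-hat flags stuck chains and passes iid ones", {
  set.seed(123)
  m <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(m), 1.01)
  expect_equal(split_rhat(matrix(c(rep(1, 100), rep(5, 100)), ncol = 2)), Inf)
  expect_equal(split_rhat(matrix(2, 100, 2)), 1)
  expect_error(split_rhat(matrix(1:10, ncol = 1)), "chains")
})

test_that("R-hat matches an independent textbook implementation", {
  # oracle: rank-normalize, split, then the classic between/within formula,
  # written with different primitives than the package's
  oracle <- function(x) {
    z <- array(qnorm((rank(x) - 0.375) / (length(x) + 0.25)), dim(x))
    h <- floor(nrow(z) / 2)
    chains <- c(lapply(seq_len(ncol(z)), function(j) z[1:h, j]),
                lapply(seq_len(ncol(z)), function(j)
                  z[(nrow(z) - h + 1):nrow(z), j]))
    m <- length(chains); nn <- h
    means <- vapply(chains, mean, numeric(1))
    vars <- vapply(chains, var, numeric(1))
    W <- sum(vars) / m
    B <- nn / (m - 1) * sum((means - mean(means))^2)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  set.seed(55)
  for (rho in c(0, 0.6, 0.95)) {
    x <- matrix(0, 500, 4)
    for (j in 1:4) {
      e <- rnorm(500)
      for (t in 2:500) e[t] <- rho * e[t - 1] + sqrt(1 - rho^2) * e[t]
      x[, j] <- e + (j - 2) * 0.05   # mild chain offsets
    }
    expect_equal(split_rhat(x), oracle(x), tolerance = 1e-12)
  }
  # and close to the classic coda diagnostic on well-behaved normal chains
  set.seed(56)
  x <- matrix(rnorm(8000), ncol = 4)
  cd <- coda::gelman.diag(coda::as.mcmc.list(
    lapply(1:4, function(j) coda::as.mcmc(x[, j]))))$psrf[1, 1]
  expect_equal(split_rhat(x), unname(cd), tolerance = 0.02)
})

test_that("gelman_rubin monitors all scalar parameters and warns", {
  sim <- simulate_bym_data(lattice_graph(5, 5), beta = c(x1 = 0.3), seed = 19)
  fit <- fit_bym(sim$data, graph = sim$graph, covariates = "x1",
                 control = mcmc_control(n_chains = 2, n_iter = 3000,
                                        n_burnin = 1500, thin = 2, seed = 8))
  gr <- suppressWarnings(gelman_rubin(fit))
  expect_setequal(gr$parameter, c("beta0", "x1", "sigma_u2", "sigma_v2"))
  expect_true(all(is.finite(gr$rhat)))
  # a deliberately stuck pair of chains must warn
  bad <- fit
  bad$draws$beta0 <- rep(c(0, 10), each = nrow(bad$draws) / 2)
  expect_warning(gelman_rubin(bad), "R-hat")
})
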