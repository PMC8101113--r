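test_that("relative-risk summaries match hand-enumerable draw sets", {
  # all draws equal to 2
  f <- fake_fit(matrix(2, 40, 3))
  s <- summarize_relative_risk(f, thresholds = c(1.5, 2))
  expect_equal(s$rr_mean, rep(2, 3))
  expect_equal(s$rr_lo, rep(2, 3))
  expect_equal(s$rr_hi, rep(2, 3))
  expect_equal(s$p_exceed_1.5, rep(1, 3))
  expect_equal(s$p_exceed_2, rep(0, 3))       # strict inequality
  # half at 0.5, half at 1.5
  f <- fake_fit(matrix(rep(c(0.5, 1.5), 50), ncol = 1))
  s <- summarize_relative_risk(f, thresholds = 1)
  expect_equal(s$p_exceed_1, 0.5)
  # three areas, small draw set: quantiles vs a sorted-array oracle
  set.seed(41)
  th <- matrix(rexp(60, 1), 20, 3)
  s <- summarize_relative_risk(fake_fit(th), thresholds = 1.2)
  for (j in 1:3) {
    srt <- sort(th[, j])
    # type-7 quantile by hand: interpolate at 1 + (n-1)p
    q <- function(p) {
      h <- 1 + (20 - 1) * p
      srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
    }
    expect_equal(s$rr_mean[j], mean(th[, j]))
    expect_equal(s$rr_lo[j], q(0.025))
    expect_equal(s$rr_hi[j], q(0.975))
    expect_equal(s$p_exceed_1.2[j], sum(th[, j] > 1.2) / 20)
    expect_true(s$rr_mean[j] >= min(th[, j]) && s$rr_mean[j] <= max(th[, j]))
  }
  g <- attr(s, "global")
  expect_equal(g$mean_rr, mean(colMeans(th)))
  expect_error(summarize_relative_risk(fake_fit(matrix(1, 0, 2))), "draws")
  expect_error(summarize_relative_risk(f, thresholds = -1), ">= 0")
})

test_that("exceedance probabilities are monotone non-increasing in c", {
  set.seed(42)
  f <- fake_fit(matrix(rlnorm(500, 0, 0.5), 100, 5))
  cs <- c(0.5, 1, 1.5, 2, 3)
  s <- summarize_relative_risk(f, thresholds = cs)
  p <- as.matrix(s[paste0("p_exceed_", cs)])
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(t(p)) <= 0))
})

test_that("effect summaries flag significance by the credible interval", {
  f <- fake_fit(matrix(1, 30, 1))
  f$covariates <- "x1"
  f$draws$x1 <- rep(0.3, 30)
  e <- summarize_effects(f)
  expect_equal(e$conf.low, 0.3)
  expect_equal(e$conf.high, 0.3)
  expect_true(e$significant)
  f$draws$x1 <- rep(c(-1, 1), 15)   # symmetric around 0
  e <- summarize_effects(f)
  expect_false(e$significant)
  expect_equal(e$p_positive, 0.5)
  expect_equal(nrow(e$density[[1]]), 512)
  expect_error(summarize_effects(fake_fit(matrix(1, 5, 1))), "covariates")
})

test_that("a moderate effect is detected in most simulated fits", {
  hits <- vapply(1:10, function(r) {
    sim <- simulate_bym_data(lattice_graph(10, 10), beta0 = 0.1,
                             beta = c(x1 = 0.3), sigma_u = 0.3,
                             sigma_v = 0.1, seed = 200 + r)
    fit <- fit_bym(sim$data, graph = sim$graph, covariates = "x1",
                   control = mcmc_control(n_chains = 2, n_iter = 2000,
                                          n_burnin = 1000, thin = 2,
                                          seed = 300 + r))
    summarize_effects(fit)$significant
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("area ranking is stable, descending, tie-broken alphabetically", {
  s <- tibble::tibble(area_id = c("b", "a", "c"),
                      rr_mean = c(1, 2, 1),
                      smr = c(3, 1, 2),
                      p_exceed_1.5 = c(0.2, 0.9, 0.2))
  r <- rank_areas(s, "rr_mean")
  expect_equal(r$area_id, c("a", "b", "c"))   # tie at 1: b before c
  expect_equal(r$rank, 1:3)
  expect_equal(rank_areas(s, "exceedance@1.5")$area_id[1], "a")
  expect_equal(rank_areas(s, "smr")$area_id, c("b", "c", "a"))
  expect_error(rank_areas(s, "exceedance@2"), "unknown")
  expect_error(rank_areas(s, "population"), "unknown")
})

test_that("tidy/glance/augment expose the fit the broom way", {
  sim <- simulate_bym_data(lattice_graph(4, 4), beta = c(x1 = 0.2), seed = 51)
  fit <- fit_bym(sim$data, graph = sim$graph, covariates = "x1",
                 control = mcmc_control(n_chains = 2, n_iter = 1200,
                                        n_burnin = 600, thin = 2, seed = 52))
  td <- tidy(fit)
  expect_setequal(td$term, c("beta0", "x1", "sigma_u2", "sigma_v2"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_areas, 16)
  expect_equal(gl$n_chains, 2)
  expect_true(gl$min_rr <= gl$mean_rr & gl$mean_rr <= gl$max_rr)
  ag <- augment(fit)
  expect_equal(nrow(ag), 16)
  expect_true(all(c("rr_mean", "rr_lo", "rr_hi", "smr") %in% names(ag)))
  # autoplot builds without error
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_risk(ag), "ggplot")
})
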