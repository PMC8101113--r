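#' Posterior relative-risk summaries and exceedance probabilities
#'
#' Per area: posterior mean of \eqn{\theta_i}, equal-tailed 95% credible
#' interval (2.5% and 97.5% quantiles), exceedance probabilities
#' \eqn{P(\theta_i > c)} (strict inequality) for each threshold, and the raw
#' SMR for reference. The attached `"global"` attribute (also surfaced by
#' [glance()]) holds the mean over areas of the posterior-mean RRs and the
#' extremes with their intervals.
#'
#' @param fit A `bym_fit`.
#' @param thresholds Exceedance thresholds `c` (default `c(1, 1.5, 2)`).
#' @return Tibble with `area_id`, `rr_mean`, `rr_lo`, `rr_hi`,
#'   `p_exceed_<c>` columns, and `smr`.
#' @export
summarize_relative_risk <- function(fit, thresholds = c(1, 1.5, 2)) {
  theta <- fit$theta
  if (is.null(theta) || nrow(theta) == 0) abort("fit contains no draws")
  if (any(thresholds < 0)) abort("thresholds must be >= 0")
  out <- tibble::tibble(
    area_id = fit$data$area_id,
    rr_mean = unname(colMeans(theta)),
    rr_lo = unname(apply(theta, 2, quantile, 0.025, names = FALSE)),
    rr_hi = unname(apply(theta, 2, quantile, 0.975, names = FALSE)),
    smr = fit$data$smr)
  for (c in thresholds) {
    out[[paste0("p_exceed_", c)]] <- unname(colMeans(theta > c))
  }
  i_min <- which.min(out$rr_mean); i_max <- which.max(out$rr_mean)
  attr(out, "global") <- list(
    mean_rr = mean(out$rr_mean),
    min_rr = out$rr_mean[i_min], min_area = out$area_id[i_min],
    min_ci = c(out$rr_lo[i_min], out$rr_hi[i_min]),
    max_rr = out$rr_mean[i_max], max_area = out$area_id[i_max],
    max_ci = c(out$rr_lo[i_max], out$rr_hi[i_max]))
  out
}

#' Posterior covariate-effect summaries
#'
#' Per covariate: posterior mean, equal-tailed 95% credible interval, the
#' tail probability \eqn{P(\beta_k > 0)}, a significance flag (interval
#' excludes 0, the usual credible-interval criterion), and a 512-point
#' kernel density estimate for plotting.
#'
#' @param fit A `bym_fit` with at least one covariate.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p_positive`, `significant`, and a `density` list-column of
#'   `tibble(x, y)` grids.
#' @export
summarize_effects <- function(fit) {
  if (!length(fit$covariates)) abort("fit has no covariates")
  purrr::map_dfr(fit$covariates, function(cn) {
    b <- fit$draws[[cn]]
    lo <- quantile(b, 0.025, names = FALSE)
    hi <- quantile(b, 0.975, names = FALSE)
    den <- if (sd(b) > 0) density(b, n = 512) else
      list(x = rep(b[1], 512), y = rep(1, 512))  # degenerate point mass
    tibble::tibble(term = cn, estimate = mean(b),
                   conf.low = lo, conf.high = hi,
                   p_positive = mean(b > 0),
                   significant = (lo > 0) | (hi < 0),
                   density = list(tibble::tibble(x = den$x, y = den$y)))
  })
}

#' Rank areas by posterior risk
#'
#' Stable descending sort by posterior-mean RR, an exceedance probability, or
#' the raw SMR; ties broken by `area_id` lexicographic order.
#'
#' @param summaries Result of [summarize_relative_risk()].
#' @param by `"rr_mean"`, `"smr"`, or `"exceedance@c"` (e.g.
#'   `"exceedance@1.5"`, requiring that threshold in the summaries).
#' @return `summaries` reordered, with a `rank` column.
#' @export
rank_areas <- function(summaries, by = "rr_mean") {
  col <- if (grepl("^exceedance@", by)) {
    paste0("p_exceed_", sub("^exceedance@", "", by))
  } else by
  if (!col %in% names(summaries) || !col %in%
      c("rr_mean", "smr", grep("^p_exceed_", names(summaries), value = TRUE))) {
    abort(paste0("unknown ranking key: ", by))
  }
  out <- dplyr::arrange(summaries, dplyr::desc(.data[[col]]), .data$area_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' @describeIn fit_bym Tidy posterior summaries of the scalar parameters
#'   (intercept, covariate effects, variance parameters): posterior mean, SD
#'   and equal-tailed 95% interval.
#' @param x A `bym_fit`.
#' @param ... Unused.
#' @export
tidy.bym_fit <- function(x, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".iteration"))
  purrr::map_dfr(pars, function(pn) {
    b <- x$draws[[pn]]
    tibble::tibble(term = pn, estimate = mean(b), std.error = sd(b),
                   conf.low = quantile(b, 0.025, names = FALSE),
                   conf.high = quantile(b, 0.975, names = FALSE))
  })
}

#' @describeIn fit_bym One-row model overview: areas, chains, retained
#'   draws, max monitored R-hat, global mean/range of posterior-mean RR.
#' @export
glance.bym_fit <- function(x, ...) {
  rs <- summarize_relative_risk(x, thresholds = numeric())
  g <- attr(rs, "global")
  rh <- suppressWarnings(gelman_rubin(x))
  tibble::tibble(n_areas = nrow(x$data),
                 n_chains = max(x$draws$.chain),
                 n_draws = nrow(x$draws),
                 max_rhat = max(rh$rhat),
                 mean_rr = g$mean_rr, min_rr = g$min_rr, max_rr = g$max_rr)
}

#' @describeIn fit_bym Per-area posterior summaries joined to the model
#'   data (equivalent to [summarize_relative_risk()]).
#' @param data Ignored (the fit carries its data echo).
#' @export
augment.bym_fit <- function(x, data = NULL, ...) {
  summarize_relative_risk(x)
}
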