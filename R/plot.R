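#' Posterior density plot of covariate effects
#'
#' One panel per covariate showing the posterior density of its effect (per
#' standardized covariate unit, under the default standardization), with a
#' dashed zero line; panel strips flag credible-interval significance.
#'
#' @param effects Result of [summarize_effects()] (or a `bym_fit`).
#' @return A ggplot object.
#' @export
plot_effects <- function(effects) {
  if (inherits(effects, "bym_fit")) effects <- summarize_effects(effects)
  dd <- tidyr::unnest(
    dplyr::mutate(effects, label = paste0(
      .data$term, ifelse(.data$significant, " *", ""))),
    "density")
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_area(fill = "#88aacc", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(x = "effect (log relative risk per SD)",
                  y = "posterior density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bym_fit <- function(object, ...) plot_effects(object)

#' Caterpillar plot of per-area posterior relative risks
#'
#' Areas ordered by posterior-mean RR with 95% credible intervals and the
#' raw SMR overplotted.
#'
#' @param summaries Result of [summarize_relative_risk()].
#' @param max_areas Show at most this many top/bottom areas (default all).
#' @return A ggplot object.
#' @export
plot_risk <- function(summaries, max_areas = Inf) {
  s <- rank_areas(summaries, "rr_mean")
  if (is.finite(max_areas) && nrow(s) > max_areas) {
    k <- ceiling(max_areas / 2)
    s <- dplyr::bind_rows(utils::head(s, k), utils::tail(s, k))
  }
  s$area_id <- factor(s$area_id, levels = rev(s$area_id))
  ggplot2::ggplot(s, ggplot2::aes(y = .data$area_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(x = .data$rr_mean,
                                          xmin = .data$rr_lo,
                                          xmax = .data$rr_hi), size = 0.2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$smr), shape = 4,
                        colour = "#bb4444") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "posterior relative risk (x = raw SMR)", y = NULL) +
    ggplot2::theme_minimal()
}
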