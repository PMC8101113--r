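#' Run the full disease-mapping pipeline
#'
#' Load (or accept) a county table, fill expected counts and SMRs, fit the
#' non-spatial and BYM models, summarize covariate effects and per-area
#' relative risks with exceedance probabilities, check convergence, and
#' write all artifacts (CSV/JSON summaries, effect-density SVGs, and -- when
#' geometry is supplied -- static and interactive choropleths) to an output
#' directory. Fully reproducible given the seed in `control`.
#'
#' @param data A `county_table`, a CSV path, or the fixture token accepted by
#'   [load_county_table()].
#' @param graph An [adjacency_graph()], or a neighbor-list file path (read
#'   against the table's `area_id`s), or `NULL` to derive queen contiguity
#'   from `geojson`.
#' @param covariates Covariate columns for both models.
#' @param out_dir Output directory (created).
#' @param thresholds Exceedance thresholds.
#' @param priors,control Passed to [fit_bym()].
#' @param geojson Optional polygon geometry (path or
#'   [read_geojson_polygons()] tibble) for contiguity and maps.
#' @param id_property GeoJSON property holding area ids.
#' @param strict_convergence Error (default) when any monitored R-hat
#'   exceeds 1.05; otherwise warn.
#' @return Invisibly, a run report: fitted objects, summaries, the R-hat
#'   table and the paths written.
#' @export
run_pipeline <- function(data, graph = NULL, covariates = county_covariates(),
                         out_dir, thresholds = c(1, 1.5, 2),
                         priors = bym_priors(), control = mcmc_control(),
                         geojson = NULL, id_property = "name",
                         strict_convergence = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(data)) data <- load_county_table(data)
  data <- add_smr(compute_expected_counts(data))
  geo <- NULL
  if (!is.null(geojson)) {
    geo <- if (is.data.frame(geojson)) geojson else
      read_geojson_polygons(geojson, id_property)
  }
  if (is.character(graph)) graph <- read_neighbor_list(graph, data$area_id)
  if (is.null(graph)) {
    if (is.null(geo)) abort("supply a graph or polygon geometry")
    graph <- queen_contiguity(geo, id_property)
  }
  paths <- character()
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  emit("county_summary.json", function(p) {
    jsonlite::write_json(summarize_table(data), p, digits = NA)
  })

  fits <- list(
    nonspatial = fit_bym(data, covariates = covariates, spatial = FALSE,
                         priors = priors, control = control),
    spatial = fit_bym(data, graph = graph, covariates = covariates,
                      spatial = TRUE, priors = priors, control = control))

  effects <- if (!length(covariates)) list() else
    purrr::imap(fits, function(f, nm) {
    e <- summarize_effects(f)
    emit(paste0("effects_", nm, ".csv"), function(p) {
      readr::write_csv(dplyr::select(e, -"density"), p)
    })
    emit(paste0("effects_", nm, ".svg"), function(p) {
      grDevices::svg(p, width = 8, height = 6)
      print(plot_effects(e))
      grDevices::dev.off()
    })
    e
    })

  risk <- summarize_relative_risk(fits$spatial, thresholds)
  emit("risk_summary.csv", function(p) readr::write_csv(risk, p))

  rhat <- dplyr::bind_rows(
    purrr::imap(fits, ~ dplyr::mutate(suppressWarnings(gelman_rubin(.x)),
                                      model = .y)))
  emit("convergence.csv", function(p) readr::write_csv(rhat, p))
  if (any(rhat$rhat > 1.05)) {
    msg <- paste0("R-hat > 1.05 for: ",
                  paste(rhat$parameter[rhat$rhat > 1.05], collapse = ", "))
    if (strict_convergence) abort(msg) else warn(msg)
  }

  if (!is.null(geo)) {
    md <- join_geometry(risk, geo, id_property)
    emit("map_rr.svg", function(p) render_static(md, "rr_mean", p))
    for (c in setdiff(thresholds, 1)) {
      key <- paste0("exceedance@", c)
      emit(paste0("map_exceed_", c, ".svg"),
           function(p) render_static(md, key, p))
    }
    emit("map_interactive.html", function(p) {
      render_interactive(
        md, layers = c("rr_mean",
                       paste0("exceedance@", setdiff(thresholds, 1))),
        out = p)
    })
  }

  invisible(list(fits = fits, effects = effects, risk = risk,
                 global = attr(risk, "global"), rhat = rhat, graph = graph,
                 paths = paths))
}

#' Simulation study: parameter recovery of the BYM sampler
#'
#' For each replicate: simulate a dataset from the model
#' ([simulate_bym_data()]), fit it with [fit_bym()] (internal-standardization
#' expected counts, as with real data), and record bias, 95% interval
#' coverage and squared error for each covariate effect and both variance
#' parameters. The aggregate table (mean bias, coverage rate, RMSE) is
#' attached as attribute `"aggregate"` and optionally written to CSV.
#'
#' @param n_reps Number of replicates (>= 2).
#' @param graph Simulation geography (default 20 x 20 lattice).
#' @param beta0,beta,sigma_u,sigma_v Generating parameters.
#' @param control MCMC settings per replicate fit (reduced lengths are
#'   appropriate here).
#' @param priors Passed to [fit_bym()].
#' @param seed Master seed; replicate `r` simulates under `seed + r`.
#' @param out_csv Optional path for the aggregate table.
#' @return Tibble with one row per replicate x parameter: `replicate`,
#'   `parameter`, `truth`, `estimate`, `lo`, `hi`, `bias`, `covered`.
#' @export
run_recovery_study <- function(n_reps = 50, graph = lattice_graph(20, 20),
                               beta0 = 0.1, beta = c(x1 = 0.3),
                               sigma_u = 0.5, sigma_v = 0.1,
                               control = mcmc_control(n_chains = 2,
                                                      n_iter = 6000,
                                                      n_burnin = 3000,
                                                      thin = 3),
                               priors = bym_priors(), seed = 1L,
                               out_csv = NULL) {
  if (n_reps < 2) abort("n_reps must be >= 2")
  truth_tab <- c(as.list(beta),
                 list(sigma_u2 = sigma_u^2, sigma_v2 = sigma_v^2))
  rows <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- simulate_bym_data(graph, beta0 = beta0, beta = beta,
                             sigma_u = sigma_u, sigma_v = sigma_v,
                             seed = seed + r)
    ctl <- control
    ctl$seed <- as.integer(seed + 100000L + r)
    fit <- fit_bym(sim$data, graph = graph, covariates = names(beta),
                   priors = priors, control = ctl)
    td <- tidy(fit)
    purrr::map_dfr(names(truth_tab), function(pn) {
      row <- td[td$term == pn, ]
      # covariate effects back on the raw (generating) scale
      if (pn %in% names(fit$covariate_scale)) {
        sc <- fit$covariate_scale[[pn]]
        row$estimate <- row$estimate / sc
        row$conf.low <- row$conf.low / sc
        row$conf.high <- row$conf.high / sc
      }
      tibble::tibble(replicate = r, parameter = pn,
                     truth = truth_tab[[pn]], estimate = row$estimate,
                     lo = row$conf.low, hi = row$conf.high,
                     bias = row$estimate - truth_tab[[pn]],
                     covered = row$conf.low <= truth_tab[[pn]] &
                       truth_tab[[pn]] <= row$conf.high)
    })
  })
  agg <- rows %>%
    dplyr::group_by(.data$parameter) %>%
    dplyr::summarise(truth = .data$truth[1],
                     mean_bias = mean(.data$bias),
                     coverage = mean(.data$covered),
                     rmse = sqrt(mean(.data$bias^2)), .groups = "drop")
  attr(rows, "aggregate") <- agg
  if (!is.null(out_csv)) readr::write_csv(agg, out_csv)
  rows
}
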