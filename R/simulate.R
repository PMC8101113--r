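#' Draw an intrinsic CAR (ICAR) spatial field
#'
#' Exact draw from the intrinsic conditional autoregressive distribution with
#' variance parameter `sigma_u^2` on the given graph, via the spectral
#' decomposition of the structure matrix \eqn{Q = \mathrm{diag}(n_\delta) -
#' A}: zero-eigenvalue modes (one per connected component) are removed, so
#' each draw sums to zero within every component and has covariance
#' \eqn{\sigma_u^2 Q^{+}} (Moore-Penrose pseudoinverse). Island areas
#' (degree 0) get exactly 0.
#'
#' @param graph An [adjacency_graph()].
#' @param sigma_u Standard-deviation parameter of the ICAR conditionals
#'   (`>= 0`; 0 returns the zero vector).
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @return Numeric vector of length `graph$n`.
#' @export
simulate_icar_field <- function(graph, sigma_u, seed = NULL) {
  if (sigma_u < 0) abort("sigma_u must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (sigma_u == 0) return(numeric(graph$n))
  if (all(graph$n_delta == 0)) {
    abort("ICAR field undefined on an all-isolated graph")
  }
  Q <- icar_precision(graph)
  e <- eigen(Q, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  V <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  z <- rnorm(length(lam))
  as.numeric(V %*% (z / sqrt(lam))) * sigma_u
}

#' Simulate an areal disease-mapping dataset with known truth
#'
#' Generates data with exactly the structure the BYM model assumes:
#' independent Gaussian covariates per area, a zero-centered ICAR field `u`,
#' i.i.d. Gaussian `v`, populations uniform over a range, explicit expected
#' counts \eqn{E_i = \mathrm{pop}_i \times} `baseline_rate`, and
#' \eqn{Y_i \sim \mathrm{Poisson}(E_i \exp(\beta_0 + x_i'\beta + u_i + v_i))}.
#' The generating parameters are returned so inference can be validated by
#' parameter recovery. `E_i` here is the *generating* expectation; fitting
#' still applies internal standardization to the realized counts, as with
#' real data.
#'
#' @param graph An [adjacency_graph()] (e.g. [lattice_graph()]).
#' @param beta0 Intercept (log baseline relative risk).
#' @param beta Named numeric vector of covariate effects (names become
#'   covariate columns); `NULL` for none.
#' @param sigma_u,sigma_v SDs of the structured (ICAR) and unstructured
#'   fields.
#' @param baseline_rate Reference rate used for the generating expected
#'   counts (default 150 per 100,000).
#' @param population_range Integer range populations are drawn from,
#'   uniformly.
#' @param covariate_mean,covariate_sd Mean/SD of the independent Gaussian
#'   covariate draws (recycled over covariates).
#' @param seed Optional integer seed; the full dataset is reproducible given
#'   it.
#' @return List with `data` (a `county_table` whose `cases` are the simulated
#'   period counts), `graph`, and `truth` (list of all generating parameters
#'   and latent fields, including `theta` and `expected`).
#' @export
simulate_bym_data <- function(graph, beta0 = 0, beta = NULL,
                              sigma_u = 0.5, sigma_v = 0.1,
                              baseline_rate = 150 / 1e5,
                              population_range = c(5000L, 50000L),
                              covariate_mean = 0, covariate_sd = 1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n
  p <- length(beta)
  if (p > 0 && is.null(names(beta))) names(beta) <- paste0("x", seq_len(p))
  cm <- rep_len(covariate_mean, p)
  cs <- rep_len(covariate_sd, p)
  X <- if (p > 0) {
    vapply(seq_len(p), function(k) rnorm(n, cm[k], cs[k]), numeric(n))
  } else matrix(0, n, 0)
  if (p > 0) colnames(X) <- names(beta)
  u <- if (sigma_u > 0) simulate_icar_field(graph, sigma_u) else numeric(n)
  v <- rnorm(n, 0, sigma_v)
  pop <- as.integer(round(runif(n, population_range[1], population_range[2])))
  expected <- pop * baseline_rate
  eta <- beta0 + (if (p > 0) as.numeric(X %*% beta) else 0) + u + v
  if (any(!is.finite(eta))) abort("non-finite linear predictor in simulation")
  y <- rpois(n, expected * exp(eta))
  d <- tibble::tibble(area_id = graph$area_ids, cases = y, population = pop)
  if (p > 0) d <- dplyr::bind_cols(d, tibble::as_tibble(X))
  data <- new_county_table(d, period_years = 1, source_label = "simulated")
  truth <- list(beta0 = beta0, beta = beta, u = u, v = v,
                sigma_u = sigma_u, sigma_v = sigma_v,
                theta = exp(eta), expected = expected,
                baseline_rate = baseline_rate)
  list(data = data, graph = graph, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes the same CSV schema [load_county_table()] reads, a `truth.json`
#' with the generating parameters, and an edge-list file for the graph.
#'
#' @param sim Result of [simulate_bym_data()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(data = file.path(dir, "data.csv"),
             truth = file.path(dir, "truth.json"),
             graph = file.path(dir, "edges.txt"))
  write_county_table(sim$data, paths[["data"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE)
  write_edge_list(sim$graph, paths[["graph"]])
  invisible(paths)
}

#' Write a graph as a plain edge list
#'
#' Two whitespace-separated area labels per line, each unordered pair once;
#' readable by [read_neighbor_list()].
#'
#' @param graph An [adjacency_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  lines <- character()
  for (i in seq_len(graph$n)) {
    j <- graph$neighbors[[i]][graph$neighbors[[i]] > i]
    if (length(j)) {
      lines <- c(lines, paste(graph$area_ids[i], graph$area_ids[j]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
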