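# Shared in-code fixtures for the test suite.

# Small county table built directly from values.
toy_table <- function(cases = c(10, 0, 5), pop = c(100, 100, 50),
                      ids = LETTERS[seq_along(cases)], ...) {
  new_county_table(tibble::tibble(area_id = ids, cases = cases,
                                  population = pop, ...))
}

# 3-node path A - B - C as an adjacency graph.
path3_graph <- function() {
  adjacency_graph(list(2L, c(1L, 3L), 2L), c("A", "B", "C"))
}

# Dense ICAR structure matrix built by explicit loops, independent of
# icar_precision().
dense_Q <- function(graph) {
  n <- graph$n
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in graph$neighbors[[i]]) {
      Q[i, j] <- -1
    }
    Q[i, i] <- length(graph$neighbors[[i]])
  }
  Q
}

# Minimal bym_fit-shaped object for summary-layer tests: theta draws only.
fake_fit <- function(theta, smr = rep(1, ncol(theta)),
                     ids = paste0("A", seq_len(ncol(theta)))) {
  colnames(theta) <- ids
  structure(list(theta = theta,
                 data = tibble::tibble(area_id = ids,
                                       y = NA_real_, expected = NA_real_,
                                       smr = smr),
                 draws = tibble::tibble(.chain = 1,
                                        .iteration = seq_len(nrow(theta))),
                 covariates = character(), spatial = FALSE),
            class = "bym_fit")
}

# GeoJSON FeatureCollection of unit squares on an integer grid.
# squares: named list of c(x0, y0) lower-left corners.
grid_geojson <- function(squares, id_property = "name") {
  feats <- vapply(names(squares), function(nm) {
    p <- squares[[nm]]
    ring <- sprintf("[[%s]]", paste(sprintf(
      "[%d,%d]",
      p[1] + c(0L, 1L, 1L, 0L, 0L), p[2] + c(0L, 0L, 1L, 1L, 0L)),
      collapse = ","))
    sprintf(paste0('{"type":"Feature","properties":{"%s":"%s"},',
                   '"geometry":{"type":"Polygon","coordinates":%s}}'),
            id_property, nm, ring)
  }, character(1))
  sprintf('{"type":"FeatureCollection","features":[%s]}',
          paste(feats, collapse = ","))
}
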