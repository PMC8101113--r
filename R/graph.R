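#' Build a spatial adjacency graph
#'
#' Container for the symmetric neighbor structure the intrinsic CAR prior
#' needs: per-area neighbor index lists, neighbor counts \eqn{n_{\delta_i}},
#' and connected-component labels. Asymmetric input is symmetrized with a
#' warning; self-loops are dropped.
#'
#' @param neighbors List of integer vectors, one per area, giving neighbor
#'   indices (1-based).
#' @param area_ids Character labels, one per area, aligned with the rows of
#'   the county table the graph will be used with.
#' @return An `adjacency_graph`: list with elements `n`, `neighbors` (sorted
#'   integer vectors), `n_delta`, `component` (integer labels), `area_ids`.
#' @export
adjacency_graph <- function(neighbors, area_ids = NULL) {
  n <- length(neighbors)
  if (n == 0L) abort("empty graph")
  area_ids <- area_ids %||% as.character(seq_len(n))
  if (length(area_ids) != n) abort("area_ids length must equal n")
  nb <- lapply(seq_len(n), function(i) {
    v <- unique(as.integer(neighbors[[i]]))
    v <- v[v != i]                       # no self-loops
    if (length(v) && (min(v) < 1L || max(v) > n)) {
      abort(paste0("neighbor index out of range for area ", area_ids[i]))
    }
    sort(v)
  })
  # symmetrize
  asym <- FALSE
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]])) {
        nb[[j]] <- sort(c(nb[[j]], i))
        asym <- TRUE
      }
    }
  }
  if (asym) warn("asymmetric neighbor structure symmetrized")
  comp <- graph_components(nb)
  structure(list(n = n, neighbors = nb,
                 n_delta = vapply(nb, length, integer(1)),
                 component = comp, area_ids = area_ids),
            class = "adjacency_graph")
}

graph_components <- function(nb) {
  n <- length(nb)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- nb[[i]][nb[[i]] > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  as.integer(igraph::components(g)$membership)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf(
    "# adjacency_graph: %d areas, %d edges, %d component(s), %d island(s)\n",
    x$n, sum(x$n_delta) / 2, max(x$component), sum(x$n_delta == 0)))
  invisible(x)
}

#' Read a neighbor structure from a GAL or edge-list file
#'
#' GAL files (`n` header, then `id k` / neighbor-id line pairs) and plain
#' edge lists (two whitespace-separated area labels per line; `#` comments
#' allowed) are supported. Areas named in the file must appear in
#' `area_ids`; areas absent from the file become islands (degree 0).
#'
#' @param path File path.
#' @param area_ids Ordered area labels defining the graph's node order.
#' @return An [adjacency_graph()].
#' @export
read_neighbor_list <- function(path, area_ids) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (!length(lines)) abort("empty neighbor file")
  idx <- stats::setNames(seq_along(area_ids), area_ids)
  first <- strsplit(lines[[1]], "\\s+")[[1]]
  is_gal <- all(grepl("^[0-9]+$", first)) && length(first) %in% c(1L, 4L)
  pairs <- list()
  if (is_gal) {
    i <- 2L
    while (i <= length(lines)) {
      hdr <- strsplit(lines[[i]], "\\s+")[[1]]
      if (length(hdr) != 2L) abort(paste0("malformed GAL record: ", lines[[i]]))
      a <- hdr[[1]]; k <- as.integer(hdr[[2]])
      nbrs <- if (k > 0L) strsplit(lines[[i + 1L]], "\\s+")[[1]] else character()
      if (length(nbrs) != k) abort(paste0("GAL record for ", a,
                                          " promises ", k, " neighbors"))
      for (b in nbrs) pairs[[length(pairs) + 1L]] <- c(a, b)
      i <- i + (if (k > 0L) 2L else 1L)
    }
  } else {
    for (ln in lines) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) != 2L) abort(paste0("malformed edge-list line: ", ln))
      pairs[[length(pairs) + 1L]] <- tok
    }
  }
  named <- unique(unlist(pairs))
  unknown <- setdiff(named, area_ids)
  if (length(unknown)) {
    abort(paste0("unknown area name(s) in neighbor file: ",
                 paste(unknown, collapse = ", ")))
  }
  nb <- rep(list(integer()), length(area_ids))
  for (p in pairs) {
    a <- idx[[p[[1]]]]; b <- idx[[p[[2]]]]
    if (a != b) {
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  adjacency_graph(nb, area_ids)
}

#' Rectangular lattice graph (rook adjacency)
#'
#' Regular `nrow` x `ncol` grid with horizontal/vertical neighbors; interior
#' nodes have degree 4, corners degree 2. The standard synthetic geography
#' for validating areal models.
#'
#' @param nrow,ncol Grid dimensions.
#' @return An [adjacency_graph()] over `nrow * ncol` areas labelled
#'   `"r<i>c<j>"`, in row-major order.
#' @export
lattice_graph <- function(nrow, ncol) {
  id <- function(i, j) (i - 1L) * ncol + j
  nb <- vector("list", nrow * ncol)
  ids <- character(nrow * ncol)
  for (i in seq_len(nrow)) {
    for (j in seq_len(ncol)) {
      k <- id(i, j)
      ids[k] <- paste0("r", i, "c", j)
      v <- integer()
      if (i > 1L) v <- c(v, id(i - 1L, j))
      if (i < nrow) v <- c(v, id(i + 1L, j))
      if (j > 1L) v <- c(v, id(i, j - 1L))
      if (j < ncol) v <- c(v, id(i, j + 1L))
      nb[[k]] <- v
    }
  }
  adjacency_graph(nb, ids)
}

#' Ring-lattice graph over ordered areas
#'
#' Connects each area to its `k` nearest neighbors on either side of a ring
#' in the given order (degree `2k`, connected, planar-like sparsity). A
#' synthetic stand-in adjacency for when true geographic contiguity is
#' unavailable; results driven by it are sensitivity checks, not geography.
#'
#' @param area_ids Ordered area labels.
#' @param k Neighbors on each side (default 2).
#' @return An [adjacency_graph()].
#' @export
ring_graph <- function(area_ids, k = 2L) {
  n <- length(area_ids)
  if (n < 2L * k + 1L) abort("too few areas for this k")
  nb <- lapply(seq_len(n), function(i) {
    off <- c(-seq_len(k), seq_len(k))
    sort(((i - 1L + off) %% n) + 1L)
  })
  adjacency_graph(nb, area_ids)
}

#' ICAR pairwise-difference quadratic form
#'
#' \eqn{\sum_{i \sim j} (u_i - u_j)^2} over unordered neighbor pairs; equals
#' \eqn{u' Q u} with \eqn{Q = \mathrm{diag}(n_\delta) - A}. Zero iff `u` is
#' constant on every connected component.
#'
#' @param graph An [adjacency_graph()].
#' @param u Numeric vector of length `graph$n`.
#' @return Scalar quadratic form.
#' @export
icar_quadratic_form <- function(graph, u) {
  if (length(u) != graph$n) abort("length(u) must equal graph$n")
  s <- 0
  for (i in seq_len(graph$n)) {
    j <- graph$neighbors[[i]][graph$neighbors[[i]] > i]
    if (length(j)) s <- s + sum((u[i] - u[j])^2)
  }
  s
}

#' ICAR precision (structure) matrix
#'
#' @param graph An [adjacency_graph()].
#' @return Dense matrix `Q = diag(n_delta) - A`.
#' @export
icar_precision <- function(graph) {
  n <- graph$n
  Q <- matrix(0, n, n, dimnames = list(graph$area_ids, graph$area_ids))
  for (i in seq_len(n)) {
    Q[i, graph$neighbors[[i]]] <- -1
    Q[i, i] <- graph$n_delta[i]
  }
  Q
}
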