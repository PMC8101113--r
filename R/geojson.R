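#' Read polygon features from a GeoJSON file
#'
#' Minimal reader for RFC 7946 FeatureCollections of Polygon/MultiPolygon
#' features, keyed by an id property. Coordinates are returned as a tidy
#' nested tibble; no planar-geometry library is required.
#'
#' @param path GeoJSON file path (or a single JSON string).
#' @param id_property Name of the feature property holding the area id.
#' @return A tibble with one row per area: `area_id` and `rings`, a
#'   list-column of two-column coordinate matrices (outer + hole rings of all
#'   polygons, in feature order).
#' @export
read_geojson_polygons <- function(path, id_property = "name") {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "\n") else path
  gj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  if (!length(feats)) abort("GeoJSON contains no features")
  rows <- purrr::map(seq_along(feats), function(k) {
    f <- feats[[k]]
    id <- f$properties[[id_property]]
    if (is.null(id)) {
      abort(paste0("feature ", k, " lacks property '", id_property, "'"))
    }
    geom <- f$geometry
    rings <- switch(
      geom$type %||% "missing",
      Polygon = geom$coordinates,
      MultiPolygon = purrr::flatten(geom$coordinates),
      abort(paste0("feature '", id, "': unsupported geometry type '",
                   geom$type %||% "missing", "'"))
    )
    mats <- purrr::map(rings, function(r) {
      m <- do.call(rbind, purrr::map(r, ~ as.numeric(.x[1:2])))
      if (!is.matrix(m) || nrow(m) < 4 || any(!is.finite(m))) {
        abort(paste0("feature '", id, "': invalid polygon ring"))
      }
      colnames(m) <- c("x", "y")
      m
    })
    tibble::tibble(area_id = as.character(id), rings = list(mats))
  })
  dplyr::bind_rows(rows)
}

#' Queen-contiguity adjacency from polygons
#'
#' Two areas are neighbors when their boundaries share any point (edge or
#' corner) -- the usual default for US county CAR models. Contact is detected
#' by shared ring vertices after rounding coordinates to `digits` decimal
#' places, which is exact for topologically clean polygon layers (shared
#' boundaries represented by identical vertices); boundaries that touch only
#' along the interior of an edge with no common vertex are not detected.
#' Islands (degree 0) are allowed and reported.
#'
#' @param geojson Path/string accepted by [read_geojson_polygons()], or its
#'   tibble result.
#' @param id_property Feature property holding the area id.
#' @param digits Coordinate rounding used for vertex matching.
#' @return An [adjacency_graph()] over the features, in feature order.
#' @export
queen_contiguity <- function(geojson, id_property = "name", digits = 7) {
  geo <- if (is.data.frame(geojson)) geojson else
    read_geojson_polygons(geojson, id_property)
  if (anyDuplicated(geo$area_id)) abort("duplicate area ids in geometry")
  n <- nrow(geo)
  keys <- purrr::map(geo$rings, function(mats) {
    m <- do.call(rbind, mats)
    unique(paste(round(m[, 1], digits), round(m[, 2], digits), sep = "|"))
  })
  vert <- tibble::tibble(area = rep(seq_len(n), lengths(keys)),
                         key = unlist(keys))
  nb <- rep(list(integer()), n)
  shared <- vert %>%
    dplyr::group_by(.data$key) %>%
    dplyr::filter(dplyr::n() > 1) %>%
    dplyr::summarise(areas = list(unique(.data$area)), .groups = "drop")
  for (as_ in shared$areas) {
    for (i in as_) nb[[i]] <- union(nb[[i]], setdiff(as_, i))
  }
  g <- adjacency_graph(nb, geo$area_id)
  isl <- sum(g$n_delta == 0)
  if (isl > 0) inform(paste0(isl, " island area(s) with no neighbors"))
  g
}

#' Join posterior risk summaries onto polygon geometry
#'
#' Matches summary areas to features by id after trimming whitespace and
#' case-folding. In strict mode any unmatched summary area is an error
#' listing the offenders; in lenient mode they are dropped with a warning.
#'
#' @param summaries Risk-summary tibble from [summarize_relative_risk()]
#'   (needs `area_id`; value columns are carried along).
#' @param geojson Geometry accepted by [queen_contiguity()].
#' @param id_property Feature property holding the area id.
#' @param strict Error (default) or warn on unmatched summary areas.
#' @return A `map_data` tibble: one row per matched area with `rings` plus
#'   all summary columns.
#' @export
join_geometry <- function(summaries, geojson, id_property = "name",
                          strict = TRUE) {
  geo <- if (is.data.frame(geojson)) geojson else
    read_geojson_polygons(geojson, id_property)
  norm <- function(x) tolower(trimws(x))
  geo$.key <- norm(geo$area_id)
  s <- summaries
  s$.key <- norm(s$area_id)
  unmatched <- s$area_id[!s$.key %in% geo$.key]
  if (length(unmatched)) {
    msg <- paste0("unmatched summary area(s): ",
                  paste(unmatched, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  out <- dplyr::inner_join(geo, dplyr::select(s, -"area_id"), by = ".key") %>%
    dplyr::select(-".key")
  class(out) <- c("map_data", class(out))
  out
}
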