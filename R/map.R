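# Choropleth rendering: static SVG via ggplot2/cairo, interactive maps as
# self-contained HTML with inline SVG layers written by the package itself
# (no external web-mapping dependency).

resolve_value_key <- function(key, data) {
  col <- if (grepl("^exceedance@", key)) {
    paste0("p_exceed_", sub("^exceedance@", "", key))
  } else key
  if (!col %in% names(data)) abort(paste0("value key not found: ", key))
  col
}

default_breaks <- function(key) {
  if (grepl("^exceedance@", key)) c(0.2, 0.5, 0.8, 0.95)
  else c(0.5, 0.75, 1, 1.25, 1.5, 2, 3)
}

#' Assign values to choropleth bins
#'
#' Bin `k` collects values in `(breaks[k-1], breaks[k]]`, with open-ended
#' extreme bins; `length(breaks) + 1` bins in total.
#'
#' @param values Numeric vector.
#' @param breaks Strictly increasing bin edges.
#' @return Integer bin indices in `1:(length(breaks) + 1)`.
#' @export
bin_values <- function(values, breaks) {
  if (any(diff(breaks) <= 0)) abort("breaks must be strictly increasing")
  findInterval(values, breaks, left.open = TRUE) + 1L
}

map_colours <- function(key, n) {
  pal <- if (grepl("^exceedance@", key)) {
    # sequential reds: highest bin = deepest red
    c("#fff5f0", "#fcbba1", "#fb6a4a", "#cb181d", "#67000d")
  } else {
    # diverging blue-white-red around RR = 1
    c("#2166ac", "#92c5de", "#f7f7f7", "#f4a582", "#d6604d", "#b2182b",
      "#67001f")
  }
  grDevices::colorRampPalette(pal)(n)
}

bin_labels <- function(breaks) {
  k <- length(breaks) + 1L
  c(paste0("<= ", breaks[1]),
    if (k > 2) paste0(breaks[-length(breaks)], " - ", breaks[-1]),
    paste0("> ", breaks[length(breaks)]))
}

unnest_rings <- function(map_data) {
  purrr::map_dfr(seq_len(nrow(map_data)), function(i) {
    rings <- map_data$rings[[i]]
    purrr::map_dfr(seq_along(rings), function(r) {
      tibble::tibble(area_id = map_data$area_id[i],
                     ring = paste0(map_data$area_id[i], ".", r),
                     x = rings[[r]][, 1], y = rings[[r]][, 2])
    })
  })
}

#' Render a static choropleth map
#'
#' Draws the joined geometry filled by binned values of `value_key` and
#' writes a deterministic SVG (same input, byte-identical output).
#'
#' @param map_data Result of [join_geometry()].
#' @param value_key `"rr_mean"`, `"smr"`, or `"exceedance@c"`.
#' @param out Output `.svg` path.
#' @param breaks Bin edges (defaults: RR/SMR `c(0.5, 0.75, 1, 1.25, 1.5, 2,
#'   3)`, exceedance `c(0.2, 0.5, 0.8, 0.95)`).
#' @param palette Optional vector of fill colours, one per bin.
#' @param legend_title,title Legend and plot titles.
#' @param width,height Device size in inches.
#' @return `out`, invisibly.
#' @export
render_static <- function(map_data, value_key = "rr_mean", out,
                          breaks = NULL, palette = NULL,
                          legend_title = value_key, title = NULL,
                          width = 7, height = 6) {
  if (nrow(map_data) == 0) abort("empty feature collection")
  col <- resolve_value_key(value_key, map_data)
  breaks <- breaks %||% default_breaks(value_key)
  k <- length(breaks) + 1L
  palette <- palette %||% map_colours(value_key, k)
  if (length(palette) != k) abort("palette length must equal bin count")
  labs <- bin_labels(breaks)
  bins <- bin_values(map_data[[col]], breaks)
  map_data$.bin <- factor(labs[bins], levels = labs)
  dd <- dplyr::left_join(unnest_rings(map_data),
                         dplyr::select(tibble::as_tibble(map_data),
                                       "area_id", ".bin"),
                         by = "area_id")
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$ring,
                                        fill = .data$.bin)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.15) +
    ggplot2::scale_fill_manual(values = stats::setNames(palette, labs),
                               drop = FALSE, name = legend_title) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title) +
    ggplot2::theme_void()
  grDevices::svg(out, width = width, height = height)
  print(p)
  grDevices::dev.off()
  invisible(out)
}

# Project lon/lat rings to a y-down SVG pixel viewport.
svg_project <- function(coords, width, height, pad = 10) {
  xr <- range(coords$x); yr <- range(coords$y)
  sc <- min((width - 2 * pad) / diff(xr), (height - 2 * pad) / diff(yr))
  list(px = function(x) pad + (x - xr[1]) * sc,
       py = function(y) height - pad - (y - yr[1]) * sc)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render an interactive choropleth map
#'
#' Writes a single self-contained HTML file with one toggleable layer per
#' value key (radio buttons, no external assets) and a hover tooltip per
#' area showing its id, posterior RR with 95% interval, SMR and exceedance
#' probabilities. Deterministic given its inputs.
#'
#' @param map_data Result of [join_geometry()].
#' @param layers Character vector of value keys (see [render_static()]);
#'   default RR plus the 1.5 and 2 exceedance layers.
#' @param out Output `.html` path.
#' @param title Page title.
#' @param width,height Map viewport in pixels.
#' @return `out`, invisibly.
#' @export
render_interactive <- function(map_data,
                               layers = c("rr_mean", "exceedance@1.5",
                                          "exceedance@2"),
                               out, title = "Posterior relative risk",
                               width = 800, height = 640) {
  if (nrow(map_data) == 0) abort("empty feature collection")
  for (ly in layers) resolve_value_key(ly, map_data)
  coords <- unnest_rings(map_data)
  pr <- svg_project(coords, width, height)
  ex_cols <- grep("^p_exceed_", names(map_data), value = TRUE)
  tooltips <- vapply(seq_len(nrow(map_data)), function(i) {
    s <- sprintf("%s: RR %.2f [%.2f, %.2f], SMR %.2f",
                 map_data$area_id[i], map_data$rr_mean[i],
                 map_data$rr_lo[i], map_data$rr_hi[i], map_data$smr[i])
    if (length(ex_cols)) {
      s <- paste0(s, ", ", paste(sprintf(
        "P(RR>%s)=%.2f", sub("^p_exceed_", "", ex_cols),
        as.numeric(map_data[i, ex_cols])), collapse = ", "))
    }
    s
  }, character(1))

  layer_svgs <- vapply(seq_along(layers), function(li) {
    ly <- layers[li]
    col <- resolve_value_key(ly, map_data)
    breaks <- default_breaks(ly)
    cols <- map_colours(ly, length(breaks) + 1L)
    bins <- bin_values(map_data[[col]], breaks)
    polys <- vapply(seq_len(nrow(map_data)), function(i) {
      rings <- map_data$rings[[i]]
      d <- paste(vapply(rings, function(m) {
        pts <- paste0(sprintf("%.2f", pr$px(m[, 1])), ",",
                      sprintf("%.2f", pr$py(m[, 2])), collapse = " L")
        paste0("M", pts, " Z")
      }, character(1)), collapse = " ")
      sprintf(paste0('<path d="%s" fill="%s" stroke="#444" ',
                     'stroke-width="0.5"><title>%s</title></path>'),
              d, cols[bins[i]], html_escape(tooltips[i]))
    }, character(1))
    legend <- paste(vapply(seq_along(cols), function(b) {
      sprintf(paste0('<rect x="%d" y="%d" width="14" height="14" ',
                     'fill="%s"/><text x="%d" y="%d" font-size="11">%s</text>'),
              width - 150, 20 + 18 * (b - 1), cols[b],
              width - 130, 32 + 18 * (b - 1),
              html_escape(bin_labels(breaks)[b]))
    }, character(1)), collapse = "\n")
    sprintf('<g id="layer%d" class="maplayer"%s>\n%s\n%s\n</g>',
            li, if (li == 1) "" else ' style="display:none"',
            paste(polys, collapse = "\n"), legend)
  }, character(1))

  controls <- paste(vapply(seq_along(layers), function(li) {
    sprintf(paste0('<label><input type="radio" name="layer" value="layer%d"',
                   '%s onchange="showLayer(this.value)"> %s</label>'),
            li, if (li == 1) " checked" else "", html_escape(layers[li]))
  }, character(1)), collapse = "\n")

  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>",
    html_escape(title), "</title>\n",
    "<script>function showLayer(id){",
    "var ls=document.getElementsByClassName('maplayer');",
    "for(var i=0;i<ls.length;i++){ls[i].style.display=",
    "(ls[i].id===id)?'':'none';}}</script>\n",
    "</head><body>\n<h2>", html_escape(title), "</h2>\n",
    "<div>", controls, "</div>\n",
    sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
            width, height), "\n",
    paste(layer_svgs, collapse = "\n"), "\n</svg>\n</body></html>\n")
  writeLines(html, out)
  invisible(out)
}
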