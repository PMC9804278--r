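#' In-memory single-band raster
#'
#' A minimal georeferenced grid in a projected, metre-unit coordinate
#' system: a numeric matrix plus origin and cell size. Row 1 is the southern
#' row; cell centres sit at `xmin + (col - 0.5) * cell`,
#' `ymin + (row - 0.5) * cell`.
#'
#' @param values numeric matrix (rows = south-to-north, cols = west-to-east).
#' @param xmin,ymin coordinates of the lower-left corner (m).
#' @param cell cell size (m).
#' @return a `land_raster` object.
#' @export
land_raster <- function(values, xmin = 0, ymin = 0, cell = 30) {
  assert_that(is.matrix(values), "values must be a matrix")
  assert_that(cell > 0, "cell size must be positive")
  structure(list(values = values, xmin = xmin, ymin = ymin, cell = cell),
            class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster> %d x %d cells, %gm resolution, extent [%g,%g]x[%g,%g]\n",
              nrow(x$values), ncol(x$values), x$cell,
              x$xmin, x$xmin + ncol(x$values) * x$cell,
              x$ymin, x$ymin + nrow(x$values) * x$cell))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + ncol(r$values) * r$cell,
    ymin = r$ymin, ymax = r$ymin + nrow(r$values) * r$cell)
}

#' Sample a raster at point coordinates
#'
#' @param r a [land_raster()].
#' @param x,y coordinate vectors (m).
#' @return cell values at the points; points outside the extent give `NA`.
#' @export
raster_value_at <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cell) + 1
  row <- floor((y - r$ymin) / r$cell) + 1
  ok <- col >= 1 & col <= ncol(r$values) & row >= 1 & row <= nrow(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Generate a stack of spatially autocorrelated landscape covariates
#'
#' For each named covariate, builds a grid as a linear spatial trend plus
#' smoothed Gaussian noise: `value = trend_x * x/extent + trend_y * y/extent
#' + smooth(noise) + offset`. Smoothing is a square moving-average filter,
#' which produces the short-range autocorrelation typical of topographic and
#' climatic surfaces. Identical configuration (including seed) yields
#' bit-identical rasters.
#'
#' @param config a [sim_config()]; uses `landscape_extent`, `cell_size`,
#'   `env_gradients` and `seed`.
#' @return a named list of [land_raster()] objects.
#' @export
make_landscape <- function(config) {
  assert_that(config$landscape_extent > 0 && config$cell_size > 0,
              "landscape extent and cell size must be positive")
  n_cells <- max(2L, ceiling(config$landscape_extent / config$cell_size))
  out <- list()
  for (nm in names(config$env_gradients)) {
    g <- config$env_gradients[[nm]]
    set.seed(sub_seed(config$seed, paste0("landscape_", nm)))
    xs <- (seq_len(n_cells) - 0.5) / n_cells
    trend <- outer(xs * (g$trend_y %||% 0), xs * (g$trend_x %||% 0), "+")
    noise_sd <- g$noise_sd %||% 0
    if (noise_sd > 0) {
      smooth_cells <- max(1L, as.integer(g$smooth %||% 5L))
      z <- matrix(rnorm(n_cells^2), n_cells, n_cells)
      z <- smooth_matrix(z, smooth_cells)
      z <- z / max(sd(z), 1e-12) * noise_sd
    } else {
      z <- 0
    }
    vals <- trend + z + (g$offset %||% 0)
    out[[nm]] <- land_raster(vals, xmin = 0, ymin = 0,
                             cell = config$cell_size)
  }
  out
}

# square moving-average smoother with edge renormalisation
smooth_matrix <- function(z, k) {
  if (k <= 1) return(z)
  n <- nrow(z)
  cs <- function(m) {
    # cumulative row sums padded with zeros for windowed sums
    cm <- apply(m, 2, cumsum)
    lo <- pmax(seq_len(n) - k, 0)
    hi <- pmin(seq_len(n) + k, n)
    top <- cm[hi, , drop = FALSE]
    bot <- rbind(matrix(0, sum(lo == 0), ncol(m)),
                 cm[lo[lo > 0], , drop = FALSE])
    (top - bot) / (hi - lo)
  }
  t(cs(t(cs(z))))
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header followed by rows north to south).
#'
#' @param r a [land_raster()].
#' @param path file path (conventionally `.asc`).
#' @return `path` (write) or a `land_raster` (read).
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", r$xmin), paste("yllcorner", r$ymin),
    paste("cellsize", r$cell), "NODATA_value -9999"
  )
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1, function(z) {
    z[is.na(z)] <- -9999
    paste(format(z, trim = TRUE, scientific = FALSE), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  v[v == val["nodata_value"]] <- NA
  land_raster(v[rev(seq_len(nrow(v))), , drop = FALSE],
              xmin = val["xllcorner"], ymin = val["yllcorner"],
              cell = val["cellsize"])
}

#' Attach edge covariates sampled from rasters
#'
#' For every graph edge and raster, collects the cells crossed by the
#' straight segment between the two nodes, buffered to `width_m` (the
#' native 30 m width is the cell path itself), and stores the chosen
#' statistic (median by default) as an edge covariate named after the
#' raster. Precomputed pairwise tables (e.g. stream distances) can be
#' attached separately with [attach_edge_table()].
#'
#' @param graph a [build_graph()] result.
#' @param rasters named list of [land_raster()] objects.
#' @param width_m sampling corridor width (m).
#' @param stat summary function applied to the sampled cell values.
#' @return the graph with covariate columns added to `edges`.
#' @export
extract_edge_covariates <- function(graph, rasters, width_m = 30,
                                    stat = stats::median) {
  edges <- graph$edges
  nodes <- graph$nodes
  xi <- nodes$x[match(edges$from, nodes$id)]
  yi <- nodes$y[match(edges$from, nodes$id)]
  xj <- nodes$x[match(edges$to, nodes$id)]
  yj <- nodes$y[match(edges$to, nodes$id)]
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    ext <- raster_extent(r)
    vals <- numeric(nrow(edges))
    for (e in seq_len(nrow(edges))) {
      pts <- segment_samples(xi[e], yi[e], xj[e], yj[e], r$cell, width_m)
      if (any(pts$x < ext["xmin"] | pts$x > ext["xmax"] |
              pts$y < ext["ymin"] | pts$y > ext["ymax"])) {
        stop(sprintf("edge %s-%s leaves the extent of raster '%s'",
                     edges$from[e], edges$to[e], nm), call. = FALSE)
      }
      v <- raster_value_at(r, pts$x, pts$y)
      if (all(is.na(v))) {
        warning(sprintf("edge %s-%s crosses only nodata in raster '%s'",
                        edges$from[e], edges$to[e], nm))
        vals[e] <- NA_real_
      } else {
        vals[e] <- stat(v[!is.na(v)])
      }
    }
    edges[[nm]] <- vals
  }
  graph$edges <- edges
  graph
}

# points along a segment at half-cell spacing, replicated at perpendicular
# offsets to cover a corridor of the requested width
segment_samples <- function(x1, y1, x2, y2, cell, width_m) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  n <- max(2L, ceiling(len / (cell / 2)) + 1L)
  tt <- seq(0, 1, length.out = n)
  px <- x1 + tt * (x2 - x1)
  py <- y1 + tt * (y2 - y1)
  offs <- 0
  if (width_m > cell) {
    half <- (width_m - cell) / 2
    offs <- unique(c(-rev(seq(0, half, by = cell / 2)),
                     seq(0, half, by = cell / 2)))
  }
  ux <- -(y2 - y1) / max(len, 1e-9)
  uy <- (x2 - x1) / max(len, 1e-9)
  list(x = as.vector(outer(px, offs * ux, "+")),
       y = as.vector(outer(py, offs * uy, "+")))
}

#' Sample rasters at node locations
#'
#' @param nodes tibble with `id`, `x`, `y`.
#' @param rasters named list of [land_raster()].
#' @return `nodes` with one column per raster.
#' @export
extract_node_covariates <- function(nodes, rasters) {
  for (nm in names(rasters)) {
    nodes[[nm]] <- raster_value_at(rasters[[nm]], nodes$x, nodes$y)
  }
  nodes
}
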