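#' Rectangular grid layer
#'
#' A minimal single-band raster: a numeric matrix with a planar extent in
#' projected metres.  Row 1 of the matrix is the southern (lowest-y) row of
#' cells; column 1 the western column.  All landscape covariates in this
#' package are carried as `grid_layer` objects.
#'
#' @param values numeric matrix (rows = south to north, cols = west to east)
#' @param xmin,ymin coordinates of the lower-left corner of the grid, metres
#' @param cell cell size in metres (square cells)
#' @return an object of class `grid_layer`
#' @export
grid_layer <- function(values, xmin = 0, ymin = 0, cell = 30) {
  stopifnot(is.matrix(values), is.numeric(values), cell > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cell = cell),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf(
    "<grid_layer> %d x %d cells, %g m cell, extent x [%g, %g] y [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$cell,
    x$xmin, x$xmin + ncol(x$values) * x$cell,
    x$ymin, x$ymin + nrow(x$values) * x$cell
  ))
  invisible(x)
}

#' Grid extent
#' @param layer a [grid_layer()]
#' @return named numeric vector (xmin, xmax, ymin, ymax) in metres
#' @export
grid_extent <- function(layer) {
  c(
    xmin = layer$xmin,
    xmax = layer$xmin + ncol(layer$values) * layer$cell,
    ymin = layer$ymin,
    ymax = layer$ymin + nrow(layer$values) * layer$cell
  )
}

#' Test whether points fall inside a grid's extent
#' @param layer a [grid_layer()]
#' @param x,y point coordinates, metres
#' @return logical vector
#' @export
grid_contains <- function(layer, x, y) {
  e <- grid_extent(layer)
  x >= e["xmin"] & x < e["xmax"] & y >= e["ymin"] & y < e["ymax"]
}

# Row/column of the cell containing each point (points must be in extent).
grid_cell_index <- function(layer, x, y) {
  col <- pmin(floor((x - layer$xmin) / layer$cell) + 1L, ncol(layer$values))
  row <- pmin(floor((y - layer$ymin) / layer$cell) + 1L, nrow(layer$values))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Nearest-cell sampling of a grid layer
#'
#' Returns the value of the cell containing each point.  Out-of-extent points
#' are an error naming the offending point, never a silent `NA`.
#'
#' @inheritParams grid_contains
#' @return numeric vector of sampled values
#' @export
grid_sample <- function(layer, x, y) {
  inside <- grid_contains(layer, x, y)
  if (!all(inside)) {
    i <- which(!inside)[1]
    stop(sprintf(
      "point %d (x = %.1f, y = %.1f) lies outside the layer extent",
      i, x[i], y[i]
    ), call. = FALSE)
  }
  idx <- grid_cell_index(layer, x, y)
  layer$values[idx]
}

#' Terrain ruggedness index
#'
#' Per cell, the mean absolute elevation difference between the cell and its
#' 8-neighbourhood; edge cells use their available neighbours.  Flat terrain
#' therefore scores exactly 0 and a cell 10 m above all eight neighbours
#' scores 10.
#'
#' @param elevation a [grid_layer()] of elevations in metres
#' @return a [grid_layer()] of ruggedness values (metres, >= 0)
#' @export
terrain_ruggedness <- function(elevation) {
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets$dr[k]; dc <- offsets$dc[k]
    r1 <- max(1, 1 + dr):min(nr, nr + dr)   # rows of the shifted neighbour
    r0 <- r1 - dr                           # rows of the centre
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    c0 <- c1 - dc
    d <- abs(z[r0, c0, drop = FALSE] - z[r1, c1, drop = FALSE])
    acc[r0, c0] <- acc[r0, c0] + d
    cnt[r0, c0] <- cnt[r0, c0] + 1L
  }
  grid_layer(acc / cnt, elevation$xmin, elevation$ymin, elevation$cell)
}

# Chamfer distance transform: distance (m) from each cell centre to the
# nearest TRUE cell, via two raster sweeps with in-row running-min passes.
# Exact along rows/columns/diagonal chains; a close upper bound elsewhere.
grid_distance_transform <- function(mask_layer) {
  m <- mask_layer$values
  cellsz <- mask_layer$cell
  nr <- nrow(m); nc <- ncol(m)
  d <- matrix(Inf, nr, nc)
  d[m != 0] <- 0
  diag_c <- cellsz * sqrt(2)
  jj <- seq_len(nc) * cellsz

  row_sweep <- function(v) {
    # running min: v_j <- min_k (v_k + |j-k| * cellsz); forward pass, then
    # the same pass on the reversed vector (spacing is symmetric)
    v <- jj + cummin(v - jj)
    rev(jj + cummin(rev(v) - jj))
  }
  for (i in seq_len(nr)) {          # south -> north
    if (i > 1) {
      prev <- d[i - 1, ]
      cand <- pmin(prev + cellsz,
                   c(Inf, prev[-nc] + diag_c),
                   c(prev[-1] + diag_c, Inf))
      d[i, ] <- pmin(d[i, ], cand)
    }
    d[i, ] <- row_sweep(d[i, ])
  }
  for (i in rev(seq_len(nr))) {     # north -> south
    if (i < nr) {
      prev <- d[i + 1, ]
      cand <- pmin(prev + cellsz,
                   c(Inf, prev[-nc] + diag_c),
                   c(prev[-1] + diag_c, Inf))
      d[i, ] <- pmin(d[i, ], cand)
    }
    d[i, ] <- row_sweep(d[i, ])
  }
  grid_layer(d, mask_layer$xmin, mask_layer$ymin, cellsz)
}

#' Write / read a grid layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values from the northern row down.
#'
#' @param layer a [grid_layer()]
#' @param path file path
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [grid_layer()].
#' @export
write_ascii_grid <- function(layer, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- layer$values
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", layer$xmin),
    sprintf("yllcorner %.6f", layer$ymin),
    sprintf("cellsize %.6f", layer$cell),
    "NODATA_value -9999"
  ), con)
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(formatC(v[i, ], format = "g", digits = 9), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  hv <- vapply(hdr, function(h) as.numeric(h[2]), numeric(1))
  names(hv) <- vapply(hdr, `[[`, character(1), 1)
  body <- lines[-(1:6)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m[m == hv["nodata_value"]] <- NA_real_
  # file stores north row first; flip to our south-first convention
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  grid_layer(m, unname(hv["xllcorner"]), unname(hv["yllcorner"]),
             unname(hv["cellsize"]))
}
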