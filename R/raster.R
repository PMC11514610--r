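#' Create a georeferenced raster grid
#'
#' A `raster_grid` is the package's spatial currency: a numeric matrix on a
#' regular lon/lat grid. Row 1 is the northmost row; the origin is the
#' upper-left corner of the upper-left cell; cells are square in degrees.
#' Missing cells are stored as `NA` internally and written out with the
#' declared nodata sentinel.
#'
#' @param values Numeric matrix (row 1 = north). `NA` marks nodata cells.
#' @param x_origin,y_origin Longitude/latitude of the upper-left corner of
#'   the upper-left cell, in decimal degrees.
#' @param cell_size Cell side, in degrees (cells are square).
#' @param nodata Sentinel written to file for `NA` cells.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, x_origin = 0, y_origin = 0,
                        cell_size = 1 / 24, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1, ncol(values) >= 1, cell_size > 0)
  storage.mode(values) <- "double"
  structure(
    list(values = values, x_origin = x_origin, y_origin = y_origin,
         cell_size = cell_size, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<raster_grid> %d x %d cells of %.5f deg, origin (%.4f, %.4f)\n",
    nrow(x$values), ncol(x$values), x$cell_size, x$x_origin, x$y_origin))
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_geometry <- function(g) {
  list(n_rows = nrow(g$values), n_cols = ncol(g$values),
       x_origin = g$x_origin, y_origin = g$y_origin, cell_size = g$cell_size)
}

#' Test whether two grids share one geometry
#'
#' @param a,b `raster_grid` objects.
#' @param tol Tolerance on origins and cell size, in degrees.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$x_origin - b$x_origin) < tol &&
    abs(a$y_origin - b$y_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Cell-centre coordinates of every cell
#'
#' @param grid A `raster_grid`.
#' @return A tibble with `row`, `col`, `lon`, `lat`, `value`.
#' @export
grid_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    lon = grid$x_origin + (rep(seq_len(nc), each = nr) - 0.5) * grid$cell_size,
    lat = grid$y_origin - (rep(seq_len(nr), times = nc) - 0.5) * grid$cell_size,
    value = as.vector(grid$values)
  )
}

## Row/col of the cell containing each (lon, lat); half-open intervals
## [edge, edge + cell_size), row index growing southward.
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$x_origin) / grid$cell_size) + 1L
  row <- floor((grid$y_origin - lat) / grid$cell_size) + 1L
  inside <- col >= 1L & col <= ncol(grid$values) &
    row >= 1L & row <= nrow(grid$values)
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Read an ESRI ASCII grid raster
#'
#' Reads a single-band ESRI ASCII grid (`.asc`). Cells equal to the declared
#' `NODATA_value` become `NA`.
#'
#' @param path Path to an `.asc` file.
#' @return A `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    stop("raster file does not exist: ", path, call. = FALSE)
  }
  if (!grepl("\\.asc$", path, ignore.case = TRUE)) {
    stop("unsupported raster format (expected .asc ESRI ASCII grid): ",
         path, call. = FALSE)
  }
  lines <- readLines(path, n = 6L)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_header <- n_header + 1L
    } else {
      break
    }
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(header))) {
    stop("missing georeference header in ", path, call. = FALSE)
  }
  has_corner <- all(c("xllcorner", "yllcorner") %in% names(header))
  has_centre <- all(c("xllcenter", "yllcenter") %in% names(header))
  if (!has_corner && !has_centre) {
    stop("missing georeference header (xllcorner/yllcorner) in ", path,
         call. = FALSE)
  }
  nc <- as.integer(header$ncols); nr <- as.integer(header$nrows)
  cs <- header$cellsize
  xll <- if (has_corner) header$xllcorner else header$xllcenter - cs / 2
  yll <- if (has_corner) header$yllcorner else header$yllcenter - cs / 2
  nodata <- if (!is.null(header$nodata_value)) header$nodata_value else -9999
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("raster body has ", length(vals), " values, expected ", nr * nc,
         " in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, x_origin = xll, y_origin = yll + nr * cs,
              cell_size = cs, nodata = nodata)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' The written file round-trips through [read_raster()]: values, nodata mask
#' and geometry are preserved.
#'
#' @param grid A `raster_grid`.
#' @param path Output path (`.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  header <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\ncellsize %.17g\nNODATA_value %.17g",
    nc, nr, grid$x_origin, grid$y_origin - nr * grid$cell_size,
    grid$cell_size, grid$nodata)
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Bundle named grids sharing one geometry into a layer stack
#'
#' @param ... Named `raster_grid` objects, or a single named list of them.
#' @return A `layer_stack`: a named list of grids with identical geometry.
#' @export
layer_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "raster_grid")) {
    layers <- layers[[1]]
  }
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("all layers must have unique names", call. = FALSE)
  }
  for (l in layers) {
    if (!inherits(l, "raster_grid")) {
      stop("every layer must be a raster_grid", call. = FALSE)
    }
    if (!same_geometry(l, layers[[1]])) {
      stop("all layers in a stack must share one geometry", call. = FALSE)
    }
  }
  structure(layers, class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  g <- x[[1]]
  cat(sprintf("<layer_stack> %d layers, %d x %d cells: %s\n",
              length(x), nrow(g$values), ncol(g$values),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
`[.layer_stack` <- function(x, i) {
  layer_stack(unclass(x)[i])
}

## Bilinear sample of a grid at arbitrary points, cell-centre anchored.
## Any NA among the (up to) four contributing centres -> NA.
bilinear_sample <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  ## fractional column/row in centre coordinates
  fc <- (lon - grid$x_origin) / cs + 0.5
  fr <- (grid$y_origin - lat) / cs + 0.5
  c0 <- pmin(pmax(floor(fc), 1), nc - 1); c0[nc == 1] <- 1
  r0 <- pmin(pmax(floor(fr), 1), nr - 1); r0[nr == 1] <- 1
  if (nc == 1) c0 <- rep(1, length(lon))
  if (nr == 1) r0 <- rep(1, length(lat))
  wx <- pmin(pmax(fc - c0, 0), 1)
  wy <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1, nc); r1 <- pmin(r0 + 1, nr)
  v <- grid$values
  v00 <- v[cbind(r0, c0)]; v01 <- v[cbind(r0, c1)]
  v10 <- v[cbind(r1, c0)]; v11 <- v[cbind(r1, c1)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

nearest_sample <- function(grid, lon, lat) {
  idx <- cell_index(grid, lon, lat)
  r <- pmin(pmax(idx$row, 1L), nrow(grid$values))
  c <- pmin(pmax(idx$col, 1L), ncol(grid$values))
  grid$values[cbind(r, c)]
}

#' Resample layers onto a template geometry
#'
#' Continuous layers are resampled bilinearly between cell centres;
#' layers named in `categorical` use nearest-neighbour. Nodata propagates:
#' any nodata contributor makes the output cell nodata.
#'
#' @param layers Named list of `raster_grid` objects (may differ in geometry).
#' @param template `raster_grid` providing the output geometry.
#' @param categorical Character vector of layer names to resample
#'   nearest-neighbour.
#' @return A `layer_stack` on the template geometry.
#' @export
align_stack <- function(layers, template, categorical = character()) {
  nms <- names(layers)
  if (is.null(nms) || any(nms == "")) {
    stop("layers must be named", call. = FALSE)
  }
  tmpl_ext <- c(template$x_origin,
                template$x_origin + ncol(template$values) * template$cell_size,
                template$y_origin - nrow(template$values) * template$cell_size,
                template$y_origin)
  ctr <- grid_centres(template)
  out <- lapply(nms, function(nm) {
    g <- layers[[nm]]
    ext <- c(g$x_origin, g$x_origin + ncol(g$values) * g$cell_size,
             g$y_origin - nrow(g$values) * g$cell_size, g$y_origin)
    if (ext[1] >= tmpl_ext[2] || ext[2] <= tmpl_ext[1] ||
        ext[3] >= tmpl_ext[4] || ext[4] <= tmpl_ext[3]) {
      stop("layer '", nm, "' does not overlap the template extent",
           call. = FALSE)
    }
    vals <- if (nm %in% categorical) {
      nearest_sample(g, ctr$lon, ctr$lat)
    } else {
      bilinear_sample(g, ctr$lon, ctr$lat)
    }
    outside <- ctr$lon < ext[1] | ctr$lon >= ext[2] |
      ctr$lat <= ext[3] | ctr$lat > ext[4]
    vals[outside] <- NA_real_
    m <- matrix(NA_real_, nrow(template$values), ncol(template$values))
    m[cbind(ctr$row, ctr$col)] <- vals
    raster_grid(m, template$x_origin, template$y_origin,
                template$cell_size, template$nodata)
  })
  names(out) <- nms
  layer_stack(out)
}

#' Extract layer values at occurrence coordinates
#'
#' Each record is assigned the cell containing its coordinate (half-open
#' cell intervals, row 1 north). Records outside the extent or hitting
#' nodata in any layer are flagged, never dropped.
#'
#' @param stack A `layer_stack`.
#' @param occ Occurrence tibble with `lon` and `lat` columns.
#' @return A tibble with `record`, one column per layer, and logical flags
#'   `out_of_extent` and `any_nodata`.
#' @export
extract_values <- function(stack, occ) {
  stopifnot(length(stack) >= 1)
  g <- stack[[1]]
  idx <- cell_index(g, occ$lon, occ$lat)
  out <- tibble::tibble(record = seq_len(nrow(occ)))
  for (nm in names(stack)) {
    v <- rep(NA_real_, nrow(occ))
    ok <- idx$inside
    v[ok] <- stack[[nm]]$values[cbind(idx$row[ok], idx$col[ok])]
    out[[nm]] <- v
  }
  out$out_of_extent <- !idx$inside
  vals <- as.matrix(out[names(stack)])
  out$any_nodata <- idx$inside & (rowSums(is.na(vals)) > 0)
  out
}
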