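#' Binarize a suitability map into a potential range
#'
#' A valid cell is presence iff its suitability is greater than or equal to
#' the threshold; nodata stays nodata.
#'
#' @param map Suitability `raster_grid` in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]` (typically from
#'   [mss_threshold()]).
#' @param species,scenario Identifiers recorded on the result.
#' @return A `binary_range`: a 0/1 `raster_grid` with the threshold and
#'   identifiers attached.
#' @export
binarize <- function(map, threshold, species = NA_character_,
                     scenario = NA_character_) {
  stopifnot(threshold >= 0, threshold <= 1)
  g <- raster_grid(ifelse(is.na(map$values), NA_real_,
                          as.numeric(map$values >= threshold)),
                   map$x_origin, map$y_origin, map$cell_size, map$nodata)
  structure(c(unclass(g), list(threshold = threshold, species = species,
                               scenario = scenario)),
            class = c("binary_range", "raster_grid"))
}

#' Classify suitability into the four standard classes
#'
#' High (> 0.6), medium (0.4-0.6), low (0.2-0.4) and extremely low (< 0.2)
#' habitat suitability; boundary values are assigned upward (0.4 is medium,
#' 0.6 is high). Nodata propagates.
#'
#' @param map Suitability `raster_grid`.
#' @return A tibble of cell centres with `lon`, `lat`, `suitability` and
#'   ordered factor `class`.
#' @export
classify_suitability <- function(map) {
  ctr <- grid_centres(map)
  cls <- cut(ctr$value, breaks = c(-Inf, 0.2, 0.4, 0.6, Inf),
             labels = c("extremely_low", "low", "medium", "high"),
             right = FALSE)
  ## cut(right = FALSE) puts boundaries upward: 0.4 -> medium, 0.6 -> high
  tibble::tibble(lon = ctr$lon, lat = ctr$lat, row = ctr$row, col = ctr$col,
                 suitability = ctr$value,
                 class = factor(cls, levels = c("extremely_low", "low",
                                                "medium", "high"),
                                ordered = TRUE))
}

#' Spherical cell areas of a lon/lat grid
#'
#' Area of the cell in row `i` is
#' `(pi/180) * R^2 * dlon * (sin(lat_top) - sin(lat_bottom))` with
#' `R = 6371` km: the spherical-band formula, constant across columns.
#'
#' @param grid A `raster_grid`.
#' @param radius_km Sphere radius in km.
#' @return A `raster_grid` of per-cell areas in km^2.
#' @export
cell_areas <- function(grid, radius_km = 6371) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  lat_top <- grid$y_origin - (seq_len(nr) - 1) * cs
  lat_bottom <- lat_top - cs
  band <- (pi / 180) * radius_km^2 * cs *
    (sin(lat_top * pi / 180) - sin(lat_bottom * pi / 180))
  raster_grid(matrix(band, nr, nc), grid$x_origin, grid$y_origin,
              cs, grid$nodata)
}

#' Area of a binary range in km^2
#'
#' @param range A `binary_range` (or 0/1 `raster_grid`).
#' @return Total spherical area of the presence cells, km^2.
#' @export
range_area <- function(range) {
  a <- cell_areas(range)$values
  sum(a[!is.na(range$values) & range$values > 0])
}

#' Range dynamics between a current and a future range
#'
#' Computes the range expansion ratio `RER = RF / RC`, the index of range
#' similarity `IRS = 2 * RS / (RC + RF)` (RS the shared area), and the
#' expanding range (future cells not currently occupied), all on spherical
#' areas in km^2.
#'
#' @param current,future `binary_range`s on one geometry.
#' @return A `range_dynamics` object with fields `rc_km2`, `rf_km2`,
#'   `rs_km2`, `rer`, `irs`, `expanding_km2` and the `expanding` map.
#'   `rer` is `NA` (flagged `rer_undefined`) when the current range is
#'   empty.
#' @export
compute_dynamics <- function(current, future) {
  stopifnot(same_geometry(current, future))
  a <- cell_areas(current)$values
  cur <- !is.na(current$values) & current$values > 0
  fut <- !is.na(future$values) & future$values > 0
  rc <- sum(a[cur]); rf <- sum(a[fut]); rs <- sum(a[cur & fut])
  expanding <- binarize(
    raster_grid(ifelse(is.na(current$values) | is.na(future$values),
                       NA_real_, as.numeric(fut & !cur)),
                current$x_origin, current$y_origin, current$cell_size,
                current$nodata),
    threshold = 1, species = future$species, scenario = future$scenario)
  structure(
    list(rc_km2 = rc, rf_km2 = rf, rs_km2 = rs,
         rer = if (rc > 0) rf / rc else NA_real_,
         rer_undefined = rc == 0,
         irs = if (rc + rf > 0) 2 * rs / (rc + rf) else NA_real_,
         expanding_km2 = rf - rs, expanding = expanding,
         species = future$species, scenario = future$scenario),
    class = "range_dynamics"
  )
}

#' Overlap of a specialist's range with its host's range
#'
#' `POR = S / RH`: the share of the specialist's range area overlapped by
#' the host's range.
#'
#' @param host,specialist `binary_range`s on one geometry.
#' @return A `range_overlap` object with `s_km2` (overlap), `rh_km2`
#'   (specialist range), `por`, and the overlap map. `por` is `NA`
#'   (flagged) when the specialist range is empty.
#' @export
compute_overlap <- function(host, specialist) {
  stopifnot(same_geometry(host, specialist))
  a <- cell_areas(host)$values
  h <- !is.na(host$values) & host$values > 0
  s <- !is.na(specialist$values) & specialist$values > 0
  s_km2 <- sum(a[h & s]); rh_km2 <- sum(a[s])
  overlap <- binarize(
    raster_grid(ifelse(is.na(host$values) | is.na(specialist$values),
                       NA_real_, as.numeric(h & s)),
                host$x_origin, host$y_origin, host$cell_size, host$nodata),
    threshold = 1, species = specialist$species,
    scenario = specialist$scenario)
  structure(
    list(s_km2 = s_km2, rh_km2 = rh_km2,
         por = if (rh_km2 > 0) s_km2 / rh_km2 else NA_real_,
         por_undefined = rh_km2 == 0, overlap = overlap,
         species = specialist$species, scenario = specialist$scenario),
    class = "range_overlap"
  )
}

#' Paired comparison of range statistics between scenario sets
#'
#' Standard paired-sample t-test on the differences (two-sided); an
#' unpaired Welch test when `paired = FALSE`. Zero-variance differences
#' are flagged degenerate instead of raising.
#'
#' @param values_a,values_b Numeric vectors of areas (paired by position
#'   when `paired = TRUE`).
#' @param paired Use a paired test.
#' @return A one-row tibble: `t`, `df`, `p`, `degenerate`.
#' @export
compare_scenarios <- function(values_a, values_b, paired = TRUE) {
  stopifnot(length(values_a) == length(values_b) || !paired)
  if (paired && length(values_a) < 2) {
    stop("paired comparison needs at least 2 pairs", call. = FALSE)
  }
  if (paired && stats::sd(values_a - values_b) == 0) {
    d <- values_a - values_b
    return(tibble::tibble(t = if (all(d == 0)) 0 else NA_real_,
                          df = length(d) - 1, p = NA_real_,
                          degenerate = TRUE))
  }
  res <- tryCatch(
    stats::t.test(values_a, values_b, paired = paired),
    error = function(e) NULL)
  if (is.null(res)) {
    return(tibble::tibble(t = NA_real_, df = length(values_a) - 1,
                          p = NA_real_, degenerate = TRUE))
  }
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, degenerate = FALSE)
}

#' @rdname compute_dynamics
#' @param x A `range_dynamics` or `range_overlap` object.
#' @param ... Unused.
#' @export
tidy.range_dynamics <- function(x, ...) {
  tibble::tibble(species = x$species, scenario = x$scenario,
                 rc_km2 = x$rc_km2, rf_km2 = x$rf_km2, rs_km2 = x$rs_km2,
                 rer = x$rer, irs = x$irs, expanding_km2 = x$expanding_km2)
}

#' @rdname compute_overlap
#' @param x A `range_overlap` object.
#' @param ... Unused.
#' @export
tidy.range_overlap <- function(x, ...) {
  tibble::tibble(species = x$species, scenario = x$scenario,
                 s_km2 = x$s_km2, rh_km2 = x$rh_km2, por = x$por)
}

#' @export
print.range_dynamics <- function(x, ...) {
  cat(sprintf(
    "<range_dynamics> RC %.1f km2, RF %.1f km2 | RER %.3f, IRS %.3f, expanding %.1f km2\n",
    x$rc_km2, x$rf_km2, x$rer, x$irs, x$expanding_km2))
  invisible(x)
}

#' @export
print.range_overlap <- function(x, ...) {
  cat(sprintf("<range_overlap> S %.1f km2 of RH %.1f km2 | POR %.3f\n",
              x$s_km2, x$rh_km2, x$por))
  invisible(x)
}

#' Jaccard similarity of two binary ranges
#'
#' Area of the intersection over area of the union (spherical km^2), used
#' to compare a recovered range with a known true range.
#'
#' @param a,b `binary_range`s on one geometry.
#' @return Jaccard index in `[0, 1]` (`NA` when both ranges are empty).
#' @export
range_jaccard <- function(a, b) {
  stopifnot(same_geometry(a, b))
  ar <- cell_areas(a)$values
  pa <- !is.na(a$values) & a$values > 0
  pb <- !is.na(b$values) & b$values > 0
  uni <- sum(ar[pa | pb])
  if (uni == 0) return(NA_real_)
  sum(ar[pa & pb]) / uni
}
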