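#' Read an occurrence table from CSV
#'
#' Expects a UTF-8 CSV with header columns `species`, `lon`, `lat`, and
#' optionally `uncertainty_m` (coordinate uncertainty, metres) and `source`.
#' Rows are kept in file order.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `species`, `lon`, `lat`, `uncertainty_m`,
#'   `source`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) {
    stop("occurrence file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("species", "lon", "lat"), names(df))
  if (length(missing)) {
    stop("occurrence CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- which(is.na(lon) | is.na(lat) | lon < -180 | lon > 180 |
                 lat < -90 | lat > 90)
  if (length(bad)) {
    stop("invalid coordinates at row(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  unc <- if ("uncertainty_m" %in% names(df)) {
    suppressWarnings(as.numeric(df$uncertainty_m))
  } else {
    rep(NA_real_, nrow(df))
  }
  if (any(!is.na(unc) & unc < 0)) {
    stop("negative coordinate uncertainty at row(s) ",
         paste(which(!is.na(unc) & unc < 0), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    species = as.character(df$species),
    lon = lon, lat = lat, uncertainty_m = unc,
    source = if ("source" %in% names(df)) as.character(df$source)
             else NA_character_
  )
}

#' Write an occurrence table to CSV
#'
#' @param occ Occurrence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop records with large coordinate uncertainty
#'
#' Removes records whose uncertainty is strictly greater than `max_m`
#' metres (default 5 km). Records with missing uncertainty are retained:
#' only a stated, excessive uncertainty disqualifies a record.
#'
#' @param occ Occurrence tibble.
#' @param max_m Maximum allowed uncertainty in metres.
#' @return The filtered tibble, input order preserved.
#' @export
filter_uncertainty <- function(occ, max_m = 5000) {
  keep <- is.na(occ$uncertainty_m) | occ$uncertainty_m <= max_m
  occ[keep, , drop = FALSE]
}

## Cylindrical equal-area projection anchored at (0, 0): x = R * lambda,
## y = R * sin(phi). Preserves area, so thinning cells are honest squares
## of cell_m side at every latitude.
cea_project <- function(lon, lat, radius_m = 6371000) {
  list(x = radius_m * lon * pi / 180, y = radius_m * sin(lat * pi / 180))
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Records are bucketed on a `cell_m` x `cell_m` grid (default 5 km) in a
#' cylindrical equal-area projection anchored at (0 deg, 0 deg), and exactly
#' one record is kept per occupied bucket: the one with the smallest stated
#' uncertainty, ties broken by earliest input order. Missing uncertainty
#' ranks after any stated uncertainty. Output preserves input order.
#'
#' @param occ Occurrence tibble.
#' @param cell_m Thinning cell side, metres.
#' @return The thinned tibble.
#' @export
thin_occurrences <- function(occ, cell_m = 5000) {
  if (nrow(occ) == 0) return(occ)
  p <- cea_project(occ$lon, occ$lat)
  bucket <- paste(floor(p$x / cell_m), floor(p$y / cell_m))
  rank_unc <- ifelse(is.na(occ$uncertainty_m), Inf, occ$uncertainty_m)
  ord <- order(rank_unc, seq_len(nrow(occ)))
  keep_idx <- ord[!duplicated(bucket[ord])]
  occ[sort(keep_idx), , drop = FALSE]
}
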