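#' Bundle monthly climate grids
#'
#' @param tmin,tmax List of 12 `raster_grid`s (degrees Celsius), January
#'   first.
#' @param prcp List of 12 `raster_grid`s (millimetres), January first.
#' @return A `monthly_climate` object.
#' @export
monthly_climate <- function(tmin, tmax, prcp) {
  stopifnot(length(tmin) == 12, length(tmax) == 12, length(prcp) == 12)
  all36 <- c(tmin, tmax, prcp)
  for (g in all36) {
    if (!inherits(g, "raster_grid")) {
      stop("all monthly inputs must be raster_grid objects", call. = FALSE)
    }
    if (!same_geometry(g, all36[[1]])) {
      stop("all 36 monthly grids must share one geometry", call. = FALSE)
    }
  }
  for (m in 1:12) {
    both <- !is.na(tmin[[m]]$values) & !is.na(tmax[[m]]$values)
    if (any(tmax[[m]]$values[both] < tmin[[m]]$values[both])) {
      stop("tmax < tmin in month ", m, call. = FALSE)
    }
  }
  structure(list(tmin = tmin, tmax = tmax, prcp = prcp),
            class = "monthly_climate")
}

## 12 x 12 indicator: column q selects the wrap-around quarter
## {q, q+1, q+2} (mod 12).
quarter_weights <- function() {
  w <- matrix(0, 12, 12)
  for (q in 1:12) w[(q - 1 + 0:2) %% 12 + 1, q] <- 1
  w
}

#' Quarterly statistics of a 12-month series
#'
#' Quarter `q` spans months `q`, `q+1`, `q+2` with December wrapping back to
#' January. Ties for the extreme quarter go to the earliest starting month.
#'
#' @param series Numeric vector of 12 monthly values.
#' @param reducer `"sum"` or `"mean"`.
#' @return A list with `values` (12 quarterly statistics, quarter 1 starting
#'   in January), `argmax` and `argmin` (1-based starting months).
#' @export
quarter_statistics <- function(series, reducer = c("sum", "mean")) {
  reducer <- match.arg(reducer)
  stopifnot(length(series) == 12, all(is.finite(series)))
  q <- as.vector(series %*% quarter_weights())
  if (reducer == "mean") q <- q / 3
  list(values = q, argmax = which.max(q), argmin = which.min(q))
}

## population standard deviation by row of an n x 12 matrix
pop_sd_rows <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

#' Compute the 19 bioclimatic variables from monthly climate
#'
#' Derives bio1-bio19 (the WorldClim set) cell-wise from 12 monthly minimum
#' temperatures, maximum temperatures and precipitation sums, with monthly
#' mean temperature taken as `(tmin + tmax) / 2`. Temperature variables are
#' in degrees Celsius (no x10 scaling); bio4 is the population standard
#' deviation of monthly means x 100; bio15 is 100 x population sd /
#' (1 + mean) of monthly precipitation. Quarters are 3-month wrap-around
#' windows; ties pick the earliest starting month. Any nodata among a cell's
#' 36 inputs makes all 19 outputs nodata there; bio3 is additionally nodata
#' where the annual temperature range (bio7) is zero.
#'
#' @param mc A [monthly_climate()] object.
#' @return A `layer_stack` with layers `bio1` ... `bio19`.
#' @export
compute_bioclim <- function(mc) {
  stopifnot(inherits(mc, "monthly_climate"))
  g <- mc$tmin[[1]]
  ncell <- length(g$values)
  as_cols <- function(grids) {
    matrix(vapply(grids, function(x) as.vector(x$values), numeric(ncell)),
           nrow = ncell)
  }
  tmin <- as_cols(mc$tmin)
  tmax <- as_cols(mc$tmax)
  prcp <- as_cols(mc$prcp)
  valid <- rowSums(is.na(tmin)) + rowSums(is.na(tmax)) +
    rowSums(is.na(prcp)) == 0
  tavg <- (tmin + tmax) / 2

  out <- matrix(NA_real_, ncell, 19)
  colnames(out) <- paste0("bio", 1:19)
  if (any(valid)) {
    tv <- tavg[valid, , drop = FALSE]
    tn <- tmin[valid, , drop = FALSE]
    tx <- tmax[valid, , drop = FALSE]
    pr <- prcp[valid, , drop = FALSE]
    w <- quarter_weights()

    qt <- tv %*% w / 3        # quarterly mean temperature
    qp <- pr %*% w            # quarterly precipitation sum
    wet_q <- max.col(qp, ties.method = "first")
    dry_q <- max.col(-qp, ties.method = "first")
    warm_q <- max.col(qt, ties.method = "first")
    cold_q <- max.col(-qt, ties.method = "first")
    pick <- function(m, j) m[cbind(seq_len(nrow(m)), j)]

    bio1 <- rowMeans(tv)
    bio2 <- rowMeans(tx - tn)
    bio4 <- pop_sd_rows(tv) * 100
    bio5 <- apply(tx, 1, max)
    bio6 <- apply(tn, 1, min)
    bio7 <- bio5 - bio6
    bio3 <- ifelse(bio7 > 0, bio2 / bio7 * 100, NA_real_)
    bio12 <- rowSums(pr)
    bio13 <- apply(pr, 1, max)
    bio14 <- apply(pr, 1, min)
    bio15 <- 100 * pop_sd_rows(pr) / (1 + rowMeans(pr))

    out[valid, ] <- cbind(
      bio1, bio2, bio3, bio4, bio5, bio6, bio7,
      pick(qt, wet_q), pick(qt, dry_q), pick(qt, warm_q), pick(qt, cold_q),
      bio12, bio13, bio14, bio15,
      pick(qp, wet_q), pick(qp, dry_q), pick(qp, warm_q), pick(qp, cold_q)
    )[, c(1:7, 8:11, 12:15, 16:19)]
  }

  layers <- lapply(seq_len(19), function(j) {
    raster_grid(matrix(out[, j], nrow(g$values), ncol(g$values)),
                g$x_origin, g$y_origin, g$cell_size, g$nodata)
  })
  names(layers) <- paste0("bio", 1:19)
  layer_stack(layers)
}
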