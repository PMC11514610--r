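## Virtual landscapes and virtual species with known truth: the in-silico
## stand-in for real occurrence and climate extracts, so every stage of the
## host -> specialist cascade can be validated against a known answer.

## Gaussian random field on a torus: white noise smoothed by a Gaussian
## kernel in the Fourier domain. `smoothness` is the kernel sd in cells.
gaussian_field <- function(n_rows, n_cols, smoothness) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  k <- exp(-outer(dr^2, dc^2, `+`) / (2 * smoothness^2))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
  sm
}

#' Generate a synthetic landscape of smooth environmental layers
#'
#' Each layer is an independent spatially autocorrelated random surface
#' (Gaussian-smoothed white noise), standardized to zero mean and unit
#' variance over its cells. Larger `smoothness` gives longer-range spatial
#' autocorrelation. Deterministic given `seed`.
#'
#' @param n_rows,n_cols Grid size (at least 8 each).
#' @param layer_names Character vector of layer names.
#' @param smoothness Autocorrelation length scale, in cells.
#' @param seed Integer seed.
#' @param x_origin,y_origin,cell_size Geometry of the output grids
#'   (defaults: a 2.5 arc-minute grid anchored at 0 deg E, 55 deg N).
#' @return A `layer_stack`.
#' @export
generate_landscape <- function(n_rows, n_cols, layer_names,
                               smoothness = 10, seed = 1,
                               x_origin = 0, y_origin = 55,
                               cell_size = 1 / 24) {
  stopifnot(n_rows >= 8, n_cols >= 8, smoothness > 0,
            length(layer_names) >= 1)
  layers <- withr::with_seed(seed, {
    lapply(layer_names, function(nm) {
      f <- gaussian_field(n_rows, n_cols, smoothness)
      f <- (f - mean(f)) / sqrt(mean((f - mean(f))^2))
      raster_grid(f, x_origin, y_origin, cell_size)
    })
  })
  names(layers) <- layer_names
  layer_stack(layers)
}

#' Define a virtual species
#'
#' A virtual species has a known true suitability: a logistic function of
#' named landscape layers, optionally plus a host-availability term whose
#' strength is `host_weight` (0 for the host plant itself).
#'
#' @param intercept Intercept of the linear predictor.
#' @param coefficients Named numeric vector: layer name -> coefficient.
#' @param host_weight Coefficient on host suitability (0 = no host term).
#' @param name Species identifier.
#' @return A `virtual_species` object.
#' @export
virtual_species <- function(intercept, coefficients, host_weight = 0,
                            name = "virtual") {
  coefficients <- unlist(coefficients)
  if (all(coefficients == 0) && host_weight == 0) {
    stop("a virtual species needs at least one nonzero coefficient or a ",
         "nonzero host_weight", call. = FALSE)
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 host_weight = host_weight, name = name),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' Cell-wise `plogis(intercept + sum(coef * layer) + host_weight * host)`.
#' Nodata in any contributing layer propagates.
#'
#' @param sp A [virtual_species()].
#' @param stack A `layer_stack` containing every coefficient's layer.
#' @param host_map Host suitability `raster_grid`; required iff
#'   `host_weight != 0`.
#' @return A suitability `raster_grid` with values in `[0, 1]`.
#' @export
true_suitability <- function(sp, stack, host_map = NULL) {
  missing_layers <- setdiff(names(sp$coefficients), names(stack))
  if (length(missing_layers)) {
    stop("layers missing from stack: ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  if (sp$host_weight != 0 && is.null(host_map)) {
    stop("host_map is required when host_weight != 0", call. = FALSE)
  }
  g <- stack[[1]]
  eta <- matrix(sp$intercept, nrow(g$values), ncol(g$values))
  for (nm in names(sp$coefficients)) {
    eta <- eta + sp$coefficients[[nm]] * stack[[nm]]$values
  }
  if (sp$host_weight != 0) {
    stopifnot(same_geometry(host_map, g))
    eta <- eta + sp$host_weight * host_map$values
  }
  raster_grid(stats::plogis(eta), g$x_origin, g$y_origin, g$cell_size,
              g$nodata)
}

#' Sample presence-only records from a true suitability surface
#'
#' Draws `n` distinct cells with probability proportional to suitability
#' (cells with zero or nodata suitability are never drawn); each record's
#' coordinate is the cell centre. Deterministic given `seed`.
#'
#' @param truth Suitability `raster_grid`.
#' @param n Number of presences.
#' @param seed Integer seed.
#' @param species Species identifier for the output records.
#' @return An occurrence tibble (`species`, `lon`, `lat`, `uncertainty_m`,
#'   `source`).
#' @export
sample_presences <- function(truth, n, seed = 1, species = "virtual") {
  ctr <- grid_centres(truth)
  cand <- which(!is.na(ctr$value) & ctr$value > 0)
  if (length(cand) < n) {
    stop("only ", length(cand), " cells with positive suitability; ",
         "cannot sample ", n, " presences", call. = FALSE)
  }
  pick <- withr::with_seed(seed,
    sample(cand, n, replace = FALSE, prob = ctr$value[cand]))
  tibble::tibble(
    species = species,
    lon = ctr$lon[pick], lat = ctr$lat[pick],
    uncertainty_m = NA_real_, source = "synthetic"
  )
}

#' Define an additive scenario shift
#'
#' @param name Scenario identifier.
#' @param offsets Named numeric vector: layer name -> additive scalar offset.
#' @return A `scenario_shift` object.
#' @export
scenario_shift <- function(name, offsets) {
  structure(list(name = name, offsets = unlist(offsets)),
            class = "scenario_shift")
}

#' Apply a scenario shift to a layer stack
#'
#' Named layers are offset additively; unnamed layers are copied unchanged;
#' geometry is preserved.
#'
#' @param stack A `layer_stack`.
#' @param shift A [scenario_shift()].
#' @return The shifted `layer_stack`.
#' @export
apply_scenario <- function(stack, shift) {
  absent <- setdiff(names(shift$offsets), names(stack))
  if (length(absent)) {
    stop("scenario '", shift$name, "' shifts layer(s) absent from the ",
         "stack: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- lapply(names(stack), function(nm) {
    g <- stack[[nm]]
    if (nm %in% names(shift$offsets)) {
      raster_grid(g$values + shift$offsets[[nm]], g$x_origin, g$y_origin,
                  g$cell_size, g$nodata)
    } else {
      g
    }
  })
  names(out) <- names(stack)
  layer_stack(out)
}
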