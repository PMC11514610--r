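# Small in-code fixtures shared across test files.

# toy grid with values 1..(nr*nc) filled by row, 1-degree cells at (0, nr)
toy_grid <- function(nr = 3, nc = 3, values = NULL, cell_size = 1,
                     y_origin = nr * cell_size) {
  if (is.null(values)) values <- matrix(seq_len(nr * nc), nr, nc,
                                        byrow = TRUE)
  raster_grid(values, x_origin = 0, y_origin = y_origin,
              cell_size = cell_size)
}

toy_occurrences <- function(lon, lat, uncertainty_m = NA_real_,
                            species = "sp") {
  tibble::tibble(species = species, lon = lon, lat = lat,
                 uncertainty_m = uncertainty_m, source = NA_character_)
}

# binary range on an equal-area toy grid near the equator (cells there are
# area-equal to well under 0.01%, so count ratios equal area ratios)
toy_range <- function(mask, species = "sp", scenario = "current") {
  g <- raster_grid(mask, x_origin = 0,
                   y_origin = nrow(as.matrix(mask)) * 0.01,
                   cell_size = 0.01)
  binarize(g, threshold = 1, species = species, scenario = scenario)
}

# labelled training table from a generating logistic model
sim_training_table <- function(n, beta, intercept = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * length(beta)), n)
    colnames(x) <- paste0("p", seq_along(beta))
    eta <- intercept + drop(x %*% beta)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    dplyr::bind_cols(tibble::tibble(label = y, weight = 1),
                     tibble::as_tibble(x))
  })
}

# small cascade settings for pipeline unit tests (full size is exercised
# in the acceptance suite)
small_cascade <- function(seed = 7) {
  cascade_defaults(n_rows = 100, n_cols = 100, n_presence = 300,
                   seed = seed)
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
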