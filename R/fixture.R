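#' Default parameters of the synthetic host-specialist cascade
#'
#' One virtual landscape (six standardized climate-like layers), a virtual
#' host plant driven by two of them, and a virtual specialist herbivore
#' whose suitability is dominated by host availability with a weak direct
#' climate term. Four future scenarios shift the layer the host responds
#' to positively, so true suitability rises and ranges expand with
#' scenario severity.
#'
#' @param n_rows,n_cols Landscape size in cells.
#' @param smoothness Spatial autocorrelation length scale, cells.
#' @param n_presence Presences sampled per species.
#' @param seed Base seed for the whole fixture.
#' @return A named list of generator settings.
#' @export
cascade_defaults <- function(n_rows = 200, n_cols = 200, smoothness = 10,
                             n_presence = 500, seed = 42) {
  list(
    n_rows = n_rows, n_cols = n_cols, smoothness = smoothness,
    n_presence = n_presence, seed = seed,
    ## four climate-like layers offered to every model plus two soil-like
    ## layers offered only to the host, as in real host-specialist designs
    ## where edaphic predictors constrain the plant but not the insects;
    ## the host-suitability layer is then genuinely irreplaceable in the
    ## specialist models
    layer_names = c(paste0("clim", 1:4), "soil1", "soil2"),
    specialist_layers = paste0("clim", 1:4),
    ## sharp niches occupying ~10-15% of the landscape, giving the high
    ## held-out discrimination (AUC > 0.85, TSS > 0.6) typical of
    ## well-performing presence/background ensembles
    host = list(intercept = -8,
                coefficients = c(clim1 = 6, clim2 = -4, soil1 = 3),
                host_weight = 0),
    specialist = list(intercept = -12, coefficients = c(clim3 = 2),
                      host_weight = 16),
    ## additive offsets on clim1 (positive host coefficient): true
    ## suitability rises with scenario severity
    scenarios = list(current = c(), F126 = c(clim1 = 0.25),
                     M126 = c(clim1 = 0.3), F585 = c(clim1 = 0.75),
                     M585 = c(clim1 = 0.8))
  )
}

#' Simulate the host-specialist cascade in memory
#'
#' Builds the virtual landscape, true host and specialist suitability under
#' every scenario, and presence samples, all with known truth.
#'
#' @param params Settings from [cascade_defaults()].
#' @return A list: `stacks` (per scenario), `host_truth` and
#'   `specialist_truth` (per scenario), `host_occ`, `specialist_occ`,
#'   `params`.
#' @export
simulate_cascade <- function(params = cascade_defaults()) {
  p <- params
  base <- generate_landscape(p$n_rows, p$n_cols, p$layer_names,
                             smoothness = p$smoothness, seed = p$seed)
  host_sp <- virtual_species(p$host$intercept, p$host$coefficients,
                             p$host$host_weight, name = "host")
  spec_sp <- virtual_species(p$specialist$intercept,
                             p$specialist$coefficients,
                             p$specialist$host_weight, name = "specialist")
  stacks <- lapply(names(p$scenarios), function(sc) {
    off <- p$scenarios[[sc]]
    if (length(off) == 0) base
    else apply_scenario(base, scenario_shift(sc, off))
  })
  names(stacks) <- names(p$scenarios)
  host_truth <- lapply(stacks, function(s) true_suitability(host_sp, s))
  specialist_truth <- mapply(function(s, h) {
    true_suitability(spec_sp, s, host_map = h)
  }, stacks, host_truth, SIMPLIFY = FALSE)
  list(
    stacks = stacks, host_truth = host_truth,
    specialist_truth = specialist_truth,
    host_occ = sample_presences(host_truth$current, p$n_presence,
                                seed = p$seed + 1, species = "host"),
    specialist_occ = sample_presences(specialist_truth$current,
                                      p$n_presence, seed = p$seed + 2,
                                      species = "specialist"),
    host_species = host_sp, specialist_species = spec_sp, params = p
  )
}

#' Write a complete fixture directory for the pipeline
#'
#' Emits per-scenario layer rasters, truth rasters, occurrence CSVs, a
#' pipeline config (`config.yml`) and a manifest recording every parameter
#' and seed.
#'
#' @param dir Output directory (created if absent).
#' @param params Settings from [cascade_defaults()].
#' @return `dir`, invisibly; the simulated objects as attribute `"sim"`.
#' @export
write_fixture <- function(dir, params = cascade_defaults()) {
  sim <- simulate_cascade(params)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sc in names(sim$stacks)) {
    d <- file.path(dir, "layers", sc)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(sim$stacks[[sc]])) {
      write_raster(sim$stacks[[sc]][[nm]], file.path(d, paste0(nm, ".asc")))
    }
  }
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (sc in names(sim$host_truth)) {
    write_raster(sim$host_truth[[sc]],
                 file.path(dir, "truth", paste0("host_", sc, ".asc")))
    write_raster(sim$specialist_truth[[sc]],
                 file.path(dir, "truth", paste0("specialist_", sc, ".asc")))
  }
  dir.create(file.path(dir, "occ"), showWarnings = FALSE)
  write_occurrences(sim$host_occ, file.path(dir, "occ", "host.csv"))
  write_occurrences(sim$specialist_occ,
                    file.path(dir, "occ", "specialist.csv"))
  config <- list(
    seed = params$seed,
    scenarios = stats::setNames(
      as.list(file.path("layers", names(sim$stacks))), names(sim$stacks)),
    species = list(
      list(name = "host", role = "host", occurrences = "occ/host.csv"),
      list(name = "specialist", role = "specialist",
           occurrences = "occ/specialist.csv",
           predictors = as.list(params$specialist_layers))
    ),
    thresholds = list(uncertainty_m = 5000, thin_m = 5000, cor = 0.7,
                      tss_gate = 0.6, auc_gate = 0.8),
    cv = list(repetitions = 5, test_fraction = 0.3),
    pa = list(floor = 1000)
  )
  yaml::write_yaml(config, file.path(dir, "config.yml"))
  manifest <- params
  manifest$host$coefficients <- as.list(manifest$host$coefficients)
  manifest$specialist$coefficients <-
    as.list(manifest$specialist$coefficients)
  manifest$scenarios <- lapply(manifest$scenarios, as.list)
  jsonlite::write_json(manifest, file.path(dir, "fixture_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(dir, sim = sim))
}
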