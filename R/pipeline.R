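## Orchestration of the two-stage analysis: host model -> host suitability
## per scenario -> specialist models with host suitability appended as a
## predictor -> binarization, dynamics and overlap reports.

#' Read and validate a pipeline run configuration
#'
#' The config is a YAML document with a scenario registry (name -> layer
#' directory), a species list (exactly one `host`, any number of
#' `specialist`s), cleaning/gating thresholds, cross-validation settings,
#' the pseudo-absence floor and a base seed. Relative paths resolve
#' against the config file's directory.
#'
#' @param path Path to `config.yml`.
#' @return A validated config list with absolute paths and a `base_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  config <- yaml::read_yaml(path)
  config$base_dir <- normalizePath(dirname(path))
  validate_config(config)
}

#' @rdname read_run_config
#' @param config A config list (as from [yaml::read_yaml()]).
#' @export
validate_config <- function(config) {
  defaults <- list(
    thresholds = list(uncertainty_m = 5000, thin_m = 5000, cor = 0.7,
                      tss_gate = 0.6, auc_gate = 0.8),
    cv = list(repetitions = 5, test_fraction = 0.3),
    pa = list(floor = 1000), seed = 1
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]])) {
      config[[k]] <- utils::modifyList(defaults[[k]], config[[k]])
    }
  }
  if (is.null(config$scenarios) || is.null(config$scenarios$current)) {
    stop("config must register scenarios including 'current'",
         call. = FALSE)
  }
  roles <- vapply(config$species, `[[`, character(1), "role")
  if (sum(roles == "host") != 1) {
    stop("config must declare exactly one host species (found ",
         sum(roles == "host"), ")", call. = FALSE)
  }
  config
}

resolve_path <- function(config, path) {
  if (is.null(config$base_dir) || grepl("^/", path)) path
  else file.path(config$base_dir, path)
}

#' Load a scenario's layer stack from its registered directory
#'
#' Reads every `.asc` raster in the directory; layer names are the file
#' names without extension, in alphabetical order.
#'
#' @param config Validated config.
#' @param scenario Scenario name.
#' @return A `layer_stack`.
#' @export
load_scenario_stack <- function(config, scenario) {
  dir <- resolve_path(config, config$scenarios[[scenario]])
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) {
    stop("no .asc layers found for scenario '", scenario, "' in ", dir,
         call. = FALSE)
  }
  layers <- lapply(files, read_raster)
  names(layers) <- sub("\\.asc$", "", basename(files))
  layer_stack(layers)
}

clean_occurrences <- function(occ, config) {
  occ |>
    filter_uncertainty(config$thresholds$uncertainty_m) |>
    thin_occurrences(config$thresholds$thin_m)
}

## a species config entry may carry its occurrence tibble directly (`occ`)
## instead of a CSV path (`occurrences`)
species_occurrences <- function(config, sp_cfg) {
  if (!is.null(sp_cfg[["occ"]])) return(sp_cfg[["occ"]])
  read_occurrences(resolve_path(config, sp_cfg$occurrences))
}

## Shared selection -> ensemble path for one species on the current stack:
## cleaning happened upstream. Preliminary committee for jackknife IVs,
## |r| pruning, formal committee on the retained predictors (whose
## jackknife IVs are the ones reported), gates, MSS.
fit_species_model <- function(stack_current, occ, config, seed,
                              algorithms = "ridge_logistic") {
  pa <- sample_pseudo_absences(stack_current[[1]], occ,
                               n_floor = config$pa$floor, seed = seed)
  table <- make_training_table(stack_current, occ, pa)
  splits <- make_cv_splits(table, config$cv$repetitions,
                           config$cv$test_fraction, seed = seed + 1)
  iv_prelim <- jackknife_importance(table, splits)
  cor_mat <- correlation_matrix(table)
  retained <- prune_collinear(iv_prelim, cor_mat, config$thresholds$cor)
  table_f <- table[c("label", "weight", retained)]
  iv <- if (length(retained) >= 2) {
    jackknife_importance(table_f, splits)
  } else {
    iv_prelim[iv_prelim$predictor %in% retained, ]
  }
  members <- fit_committee(table_f, splits, algorithms)
  ensemble <- gate_members(members, config$thresholds$tss_gate,
                           config$thresholds$auc_gate)
  scores <- ensemble_score(ensemble, table_f)
  mss <- mss_threshold(scores, table_f$label)
  list(occ = occ, pseudo_absences = pa, table = table_f, splits = splits,
       importance = iv, importance_preliminary = iv_prelim,
       retained = retained, ensemble = ensemble, mss = mss, seed = seed)
}

## candidate-predictor subset declared on a species config entry
species_stack <- function(stack, sp_cfg, extra = character()) {
  if (is.null(sp_cfg$predictors)) return(stack)
  keep <- union(unlist(sp_cfg$predictors), extra)
  missing_layers <- setdiff(keep, names(stack))
  if (length(missing_layers)) {
    stop("species '", sp_cfg$name, "' requests absent layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  stack[keep]
}

#' Run the host stage of the pipeline
#'
#' Cleans and thins the host occurrences, samples pseudo-absences, fits the
#' preliminary committee for jackknife importance, prunes collinear
#' predictors at the configured |r| threshold, fits and gates the formal
#' ensemble, then projects habitat suitability under every scenario and
#' binarizes it at the species' maximum sensitivity-specificity threshold.
#'
#' @param config Validated config from [read_run_config()].
#' @param stacks Optional pre-loaded named list of scenario stacks (loaded
#'   from the registry when `NULL`).
#' @return A list: `model` (selection and ensemble objects), `suitability`
#'   and `ranges` (per scenario), `mss`.
#' @export
run_host <- function(config, stacks = NULL) {
  config <- validate_config(config)
  if (is.null(stacks)) {
    stacks <- lapply(stats::setNames(nm = names(config$scenarios)),
                     function(sc) load_scenario_stack(config, sc))
  }
  host_cfg <- config$species[[which(vapply(config$species, `[[`,
                                           character(1), "role") == "host")]]
  occ <- clean_occurrences(species_occurrences(config, host_cfg), config)
  model <- fit_species_model(species_stack(stacks$current, host_cfg), occ,
                             config, seed = config$seed + 100)
  suitability <- lapply(stacks, function(s) {
    ensemble_predict(model$ensemble, s)
  })
  ranges <- lapply(names(suitability), function(sc) {
    binarize(suitability[[sc]], model$mss, species = host_cfg$name,
             scenario = sc)
  })
  names(ranges) <- names(suitability)
  list(name = host_cfg$name, model = model, suitability = suitability,
       ranges = ranges, mss = model$mss)
}

#' Run the specialist stage of the pipeline
#'
#' For each specialist, the scenario-matched host suitability map is
#' appended to the climate stack as a predictor layer named
#' `host_suitability`; the identical selection -> ensemble -> binarization
#' path then runs, followed by range dynamics (current vs each future
#' scenario) and range overlap with the host under the same scenario.
#'
#' @param config Validated config.
#' @param host Result of [run_host()] (provides per-scenario host
#'   suitability and ranges).
#' @param stacks Optional pre-loaded named list of scenario stacks.
#' @return A named list per specialist: `model`, `suitability`, `ranges`,
#'   `dynamics` and `overlap` tibbles.
#' @export
run_specialists <- function(config, host, stacks = NULL) {
  config <- validate_config(config)
  if (is.null(stacks)) {
    stacks <- lapply(stats::setNames(nm = names(config$scenarios)),
                     function(sc) load_scenario_stack(config, sc))
  }
  missing_sc <- setdiff(names(stacks), names(host$suitability))
  if (length(missing_sc)) {
    stop("host suitability missing for scenario(s): ",
         paste(missing_sc, collapse = ", "), call. = FALSE)
  }
  with_host <- lapply(stats::setNames(nm = names(stacks)), function(sc) {
    layer_stack(c(unclass(stacks[[sc]]),
                  list(host_suitability = host$suitability[[sc]])))
  })
  spec_cfgs <- config$species[vapply(config$species, `[[`, character(1),
                                     "role") == "specialist"]
  out <- lapply(seq_along(spec_cfgs), function(i) {
    sp <- spec_cfgs[[i]]
    occ <- clean_occurrences(species_occurrences(config, sp), config)
    model <- fit_species_model(
      species_stack(with_host$current, sp, extra = "host_suitability"),
      occ, config, seed = config$seed + 200 + i)
    suitability <- lapply(with_host, function(s) {
      ensemble_predict(model$ensemble, s)
    })
    ranges <- lapply(names(suitability), function(sc) {
      binarize(suitability[[sc]], model$mss, species = sp$name,
               scenario = sc)
    })
    names(ranges) <- names(suitability)
    futures <- setdiff(names(ranges), "current")
    dynamics <- dplyr::bind_rows(lapply(futures, function(sc) {
      tidy(compute_dynamics(ranges$current, ranges[[sc]]))
    }))
    overlap <- dplyr::bind_rows(lapply(names(ranges), function(sc) {
      tidy(compute_overlap(host$ranges[[sc]], ranges[[sc]]))
    }))
    list(name = sp$name, model = model, suitability = suitability,
         ranges = ranges, dynamics = dynamics, overlap = overlap)
  })
  names(out) <- vapply(spec_cfgs, `[[`, character(1), "name")
  out
}

gate_table <- function(species, model) {
  dplyr::mutate(tidy(model$ensemble), species = species, .before = 1)
}

#' Run the full two-stage pipeline from a config file
#'
#' Host stage, then specialists; writes suitability and range rasters,
#' importance/gate/dynamics/overlap CSV reports and a run manifest into
#' `out`. Refuses to write into a non-empty directory unless
#' `force = TRUE`.
#'
#' @param config_path Path to `config.yml` (or a validated config list).
#' @param out Output directory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, a list with the host and specialist results and the
#'   manifest.
#' @export
run_all <- function(config_path, out, force = FALSE) {
  config <- if (is.character(config_path)) read_run_config(config_path)
            else validate_config(config_path)
  if (dir.exists(out) && length(list.files(out)) > 0 && !force) {
    stop("output directory ", out, " is not empty; use force = TRUE to ",
         "overwrite", call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stacks <- lapply(stats::setNames(nm = names(config$scenarios)),
                   function(sc) load_scenario_stack(config, sc))
  message("[host] fitting host model")
  host <- run_host(config, stacks)
  message(sprintf("[host] MSS threshold %.3f", host$mss))
  specialists <- run_specialists(config, host, stacks)

  all_results <- c(list(host), unname(specialists))
  inventory <- character()
  emit_raster <- function(grid, rel) {
    path <- file.path(out, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write_raster(grid, path)
    inventory <<- c(inventory, rel)
  }
  for (res in all_results) {
    for (sc in names(res$suitability)) {
      emit_raster(res$suitability[[sc]],
                  file.path(res$name, paste0(sc, "_suitability.asc")))
      emit_raster(res$ranges[[sc]],
                  file.path(res$name, paste0(sc, "_range.asc")))
    }
  }
  emit_csv <- function(df, rel) {
    utils::write.csv(df, file.path(out, rel), row.names = FALSE)
    inventory <<- c(inventory, rel)
  }
  emit_csv(dplyr::bind_rows(lapply(all_results, function(r) {
    dplyr::mutate(tibble::as_tibble(r$model$importance),
                  species = r$name, .before = 1)
  })), "importance.csv")
  emit_csv(dplyr::bind_rows(lapply(all_results, function(r) {
    gate_table(r$name, r$model)
  })), "gates.csv")
  emit_csv(dplyr::bind_rows(lapply(specialists, `[[`, "dynamics")),
           "dynamics.csv")
  emit_csv(dplyr::bind_rows(lapply(specialists, `[[`, "overlap")),
           "overlap.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("hostsdm")),
    seed = config$seed,
    thresholds = config$thresholds, cv = config$cv, pa = config$pa,
    scenarios = names(config$scenarios),
    species = lapply(all_results, function(r) {
      list(name = r$name, seed = r$model$seed, mss = r$model$mss,
           retained = as.list(r$model$retained),
           n_presences = nrow(r$model$occ),
           n_pseudo_absences = nrow(r$model$pseudo_absences),
           n_members_included = sum(r$model$ensemble$weights > 0))
    }),
    inventory = sort(inventory)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("[done] outputs written to ", out)
  invisible(list(host = host, specialists = specialists,
                 manifest = manifest))
}
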