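## The modelling engine: pseudo-absences, repeated stratified splits, a
## pluggable learner committee with a native penalized-logistic member,
## TSS/AUC gating, TSS-weighted combination, jackknife importance and
## collinearity pruning.

#' Sample pseudo-absences for presence-only modelling
#'
#' Draws background points uniformly without replacement from the valid
#' cells of `region`, excluding every cell that contains a presence. The
#' count follows the floor rule: `n_floor` (default 1000) pseudo-absences
#' when there are fewer presences than the floor, otherwise as many as
#' there are presences.
#'
#' @param region `raster_grid` validity mask: cells with non-nodata values
#'   are candidate background cells.
#' @param presences Occurrence tibble of the species' presences.
#' @param n_presence Presence count governing the rule (defaults to
#'   `nrow(presences)`).
#' @param n_floor Minimum pseudo-absence count.
#' @param seed Integer seed.
#' @return An occurrence tibble of pseudo-absence points at cell centres.
#' @export
sample_pseudo_absences <- function(region, presences,
                                   n_presence = nrow(presences),
                                   n_floor = 1000, seed = 1) {
  n_pa <- if (n_presence < n_floor) n_floor else n_presence
  ctr <- grid_centres(region)
  idx <- cell_index(region, presences$lon, presences$lat)
  pres_cells <- unique((idx$col[idx$inside] - 1L) * nrow(region$values) +
                         idx$row[idx$inside])
  cand <- which(!is.na(ctr$value))
  cand <- setdiff(cand, pres_cells)
  if (length(cand) < n_pa) {
    stop("only ", length(cand), " candidate background cells; cannot ",
         "sample ", n_pa, " pseudo-absences", call. = FALSE)
  }
  pick <- withr::with_seed(seed, sample(cand, n_pa, replace = FALSE))
  tibble::tibble(
    species = if (nrow(presences)) presences$species[1] else "background",
    lon = ctr$lon[pick], lat = ctr$lat[pick],
    uncertainty_m = NA_real_, source = "pseudo-absence"
  )
}

#' Build a presence/background training table
#'
#' Extracts predictor values at presence and background coordinates and
#' drops rows that fall outside the extent or on nodata.
#'
#' @param stack Predictor `layer_stack`.
#' @param presences,absences Occurrence tibbles.
#' @return A tibble with `label` (1 = presence, 0 = background), `weight`,
#'   and one column per predictor.
#' @export
make_training_table <- function(stack, presences, absences) {
  build <- function(occ, label) {
    ex <- extract_values(stack, occ)
    ok <- !ex$out_of_extent & !ex$any_nodata
    dplyr::mutate(ex[ok, names(stack), drop = FALSE],
                  label = label, weight = 1, .before = 1)
  }
  tab <- dplyr::bind_rows(build(presences, 1), build(absences, 0))
  if (sum(tab$label == 1) < 1 || sum(tab$label == 0) < 1) {
    stop("training table needs at least one presence and one background ",
         "row after nodata filtering", call. = FALSE)
  }
  tab
}

predictor_names <- function(table) {
  setdiff(names(table), c("label", "weight"))
}

#' Repeated stratified train/test splits
#'
#' Produces `n_repetitions` independent random splits, each holding out
#' `test_fraction` of the rows of every label class (so the 70/30 ratio is
#' honoured per class to within one row).
#'
#' @param table Training tibble with a `label` column.
#' @param n_repetitions Number of repetitions.
#' @param test_fraction Held-out share per class.
#' @param seed Integer seed.
#' @return A list of splits, each `list(repetition, train, test)` of row
#'   indices.
#' @export
make_cv_splits <- function(table, n_repetitions = 5, test_fraction = 0.3,
                           seed = 1) {
  classes <- split(seq_len(nrow(table)), table$label)
  if (length(classes) < 2 || any(lengths(classes) < 2)) {
    stop("both classes need at least 2 rows to stratify", call. = FALSE)
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_repetitions), function(rep_i) {
      test <- unlist(lapply(classes, function(rows) {
        sample(rows, round(length(rows) * test_fraction))
      }), use.names = FALSE)
      list(repetition = rep_i,
           train = sort(setdiff(seq_len(nrow(table)), test)),
           test = sort(test))
    })
  })
}

## ---- learner interface -----------------------------------------------
## A learner is list(fit = function(x, y, w) model,
##                   predict = function(model, x) scores in [0,1]).
## The native member is ridge-penalized logistic regression fitted by
## iteratively reweighted least squares on standardized predictors.

ridge_logistic_learner <- function(lambda = 1e-6, tol = 1e-8,
                                   max_iter = 100) {
  list(
    fit = function(x, y, w = rep(1, length(y))) {
      x <- as.matrix(x)
      centre <- colMeans(x)
      scale <- apply(x, 2, stats::sd)
      scale[scale == 0] <- 1
      xs <- sweep(sweep(x, 2, centre), 2, scale, "/")
      xd <- cbind(1, xs)
      p <- ncol(xd)
      beta <- numeric(p)
      pen <- diag(c(0, rep(lambda, p - 1)))   # intercept unpenalized
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        eta <- drop(xd %*% beta)
        mu <- stats::plogis(eta)
        wt <- pmax(mu * (1 - mu), 1e-10) * w
        z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
        xtw <- t(xd * wt)
        beta_new <- tryCatch(
          solve(xtw %*% xd + pen, xtw %*% z),
          error = function(e) NULL)
        if (is.null(beta_new)) break
        delta <- max(abs(beta_new - beta))
        beta <- drop(beta_new)
        if (delta < tol) { converged <- TRUE; break }
      }
      list(beta = beta, centre = centre, scale = scale,
           converged = converged, names = colnames(x))
    },
    predict = function(model, x) {
      x <- as.matrix(x)[, model$names, drop = FALSE]
      xs <- sweep(sweep(x, 2, model$centre), 2, model$scale, "/")
      stats::plogis(drop(cbind(1, xs) %*% model$beta))
    }
  )
}

resolve_learner <- function(algorithm) {
  if (is.list(algorithm) && all(c("fit", "predict") %in% names(algorithm))) {
    return(algorithm)
  }
  switch(as.character(algorithm),
    ridge_logistic = ridge_logistic_learner(),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

#' Fit one committee member on a training table
#'
#' The built-in `"ridge_logistic"` member is penalized logistic regression
#' fitted by iteratively reweighted least squares (ridge penalty
#' `lambda = 1e-6` on standardized predictors, converged when the largest
#' coefficient change drops below `1e-8`, at most 100 iterations).
#' Non-convergence flags the member rather than raising an error, so it is
#' excluded downstream.
#'
#' @param train Training tibble (`label`, `weight`, predictors).
#' @param algorithm Algorithm id (`"ridge_logistic"`) or a learner:
#'   `list(fit = function(x, y, w), predict = function(model, x))`.
#' @param repetition Repetition index recorded on the member.
#' @return A `fitted_member` with unset held-out scores.
#' @export
fit_member <- function(train, algorithm = "ridge_logistic",
                       repetition = NA_integer_) {
  learner <- resolve_learner(algorithm)
  preds <- predictor_names(train)
  model <- learner$fit(as.matrix(train[preds]), train$label, train$weight)
  converged <- if (!is.null(model$converged)) model$converged else TRUE
  structure(
    list(algorithm = if (is.character(algorithm)) algorithm else "custom",
         model = model, learner = learner, predictors = preds,
         repetition = repetition, converged = converged,
         heldout_auc = NA_real_, heldout_tss = NA_real_,
         mss = NA_real_, included = NA),
    class = "fitted_member"
  )
}

#' Score rows with a fitted member
#'
#' @param member A `fitted_member`.
#' @param newdata Tibble or matrix holding the member's predictors.
#' @return Scores in `[0, 1]`.
#' @export
predict_member <- function(member, newdata) {
  member$learner$predict(member$model,
                         as.matrix(newdata[member$predictors]))
}

#' Fit and evaluate a committee across repeated splits
#'
#' For every (algorithm, split) pair, fits on the training rows and scores
#' the held-out rows; records held-out AUC, the held-out maximum
#' sensitivity-specificity threshold, and TSS at that threshold.
#'
#' @param table Training tibble.
#' @param splits Splits from [make_cv_splits()].
#' @param algorithms Named list (or character vector) of algorithms.
#' @return A list of evaluated `fitted_member`s.
#' @export
fit_committee <- function(table, splits, algorithms = "ridge_logistic") {
  if (is.character(algorithms)) {
    algorithms <- stats::setNames(as.list(algorithms), algorithms)
  }
  members <- list()
  for (alg_name in names(algorithms)) {
    for (sp in splits) {
      m <- fit_member(table[sp$train, , drop = FALSE],
                      algorithms[[alg_name]], repetition = sp$repetition)
      m$algorithm <- alg_name
      if (m$converged) {
        sc <- predict_member(m, table[sp$test, , drop = FALSE])
        lab <- table$label[sp$test]
        m$heldout_auc <- auc(sc, lab)
        m$mss <- mss_threshold(sc, lab)
        m$heldout_tss <- tss(sc, lab, m$mss)
      }
      members[[length(members) + 1]] <- m
    }
  }
  members
}

#' Gate committee members and build the ensemble
#'
#' A member enters the ensemble iff its held-out TSS is at least `tss_gate`
#' and its held-out AUC at least `auc_gate` (and it converged). Combination
#' weights are proportional to held-out TSS over the included members.
#'
#' @param members Evaluated `fitted_member`s.
#' @param tss_gate,auc_gate Inclusion thresholds.
#' @return An `ensemble_model`.
#' @export
gate_members <- function(members, tss_gate = 0.6, auc_gate = 0.8) {
  for (i in seq_along(members)) {
    m <- members[[i]]
    members[[i]]$included <- isTRUE(m$converged) &&
      !is.na(m$heldout_tss) && !is.na(m$heldout_auc) &&
      m$heldout_tss >= tss_gate && m$heldout_auc >= auc_gate
  }
  inc <- vapply(members, `[[`, logical(1), "included")
  if (!any(inc)) {
    stop("empty ensemble: no member passed the gates TSS >= ", tss_gate,
         " and AUC >= ", auc_gate, call. = FALSE)
  }
  tss_inc <- vapply(members[inc], `[[`, numeric(1), "heldout_tss")
  weights <- numeric(length(members))
  weights[inc] <- tss_inc / sum(tss_inc)
  structure(
    list(members = members, weights = weights,
         predictors = members[[1]]$predictors,
         tss_gate = tss_gate, auc_gate = auc_gate),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  inc <- sum(vapply(x$members, `[[`, logical(1), "included"))
  cat(sprintf(
    "<ensemble_model> %d/%d members included (TSS >= %.2f, AUC >= %.2f)\n",
    inc, length(x$members), x$tss_gate, x$auc_gate))
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Score rows with a gated ensemble
#'
#' TSS-weighted mean of the included members' scores.
#'
#' @param model An `ensemble_model`.
#' @param newdata Tibble or matrix of predictor values.
#' @return Scores in `[0, 1]`.
#' @export
ensemble_score <- function(model, newdata) {
  inc <- which(model$weights > 0)
  out <- numeric(nrow(newdata))
  for (i in inc) {
    out <- out + model$weights[i] * predict_member(model$members[[i]],
                                                   newdata)
  }
  out
}

#' Project an ensemble onto a layer stack
#'
#' Cell-wise TSS-weighted mean of the included members' scores; cells with
#' nodata in any predictor layer stay nodata.
#'
#' @param model An `ensemble_model`.
#' @param stack `layer_stack` containing every predictor.
#' @return A suitability `raster_grid` in `[0, 1]`.
#' @export
ensemble_predict <- function(model, stack) {
  missing_layers <- setdiff(model$predictors, names(stack))
  if (length(missing_layers)) {
    stop("predictor layer(s) missing from stack: ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  g <- stack[[1]]
  x <- vapply(model$predictors, function(nm) as.vector(stack[[nm]]$values),
              numeric(length(g$values)))
  ok <- rowSums(is.na(x)) == 0
  out <- rep(NA_real_, length(g$values))
  if (any(ok)) {
    out[ok] <- ensemble_score(model,
                              as.data.frame(x[ok, , drop = FALSE]))
  }
  raster_grid(matrix(out, nrow(g$values), ncol(g$values)),
              g$x_origin, g$y_origin, g$cell_size, g$nodata)
}

mean_heldout_auc <- function(table, splits, algorithm, predictors) {
  aucs <- vapply(splits, function(sp) {
    sub <- table[c("label", "weight", predictors)]
    m <- fit_member(sub[sp$train, , drop = FALSE], algorithm,
                    sp$repetition)
    if (!m$converged) return(NA_real_)
    auc(predict_member(m, sub[sp$test, , drop = FALSE]),
        table$label[sp$test])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Jackknife variable importance
#'
#' For each predictor, refits the model on every split with that predictor
#' removed; the raw importance value (IV) is the drop in mean held-out AUC
#' relative to the full model, floored at zero. Standardized IVs rescale
#' the raw values to `[0, 1]` by the max-min method. A `"permutation"`
#' variant (shuffle the predictor in the held-out rows instead of
#' refitting) is available behind `method`.
#'
#' @param table Training tibble.
#' @param splits Splits from [make_cv_splits()].
#' @param algorithm Algorithm id or learner (see [fit_member()]).
#' @param method `"jackknife"` (leave-one-variable-out refit, the default)
#'   or `"permutation"`.
#' @param seed Seed for the permutation variant.
#' @return An `importance_table` tibble: `predictor`, `iv_raw`, `iv_std`,
#'   sorted by decreasing raw IV.
#' @export
jackknife_importance <- function(table, splits,
                                 algorithm = "ridge_logistic",
                                 method = c("jackknife", "permutation"),
                                 seed = 1) {
  method <- match.arg(method)
  preds <- predictor_names(table)
  if (length(preds) < 2) {
    stop("importance needs at least 2 predictors", call. = FALSE)
  }
  full_auc <- mean_heldout_auc(table, splits, algorithm, preds)
  iv_raw <- if (method == "jackknife") {
    vapply(preds, function(p) {
      max(0, full_auc - mean_heldout_auc(table, splits, algorithm,
                                         setdiff(preds, p)))
    }, numeric(1))
  } else {
    withr::with_seed(seed, vapply(preds, function(p) {
      drops <- vapply(splits, function(sp) {
        m <- fit_member(table[sp$train, , drop = FALSE], algorithm,
                        sp$repetition)
        if (!m$converged) return(NA_real_)
        test <- table[sp$test, , drop = FALSE]
        a_full <- auc(predict_member(m, test), test$label)
        test[[p]] <- sample(test[[p]])
        a_full - auc(predict_member(m, test), test$label)
      }, numeric(1))
      max(0, mean(drops, na.rm = TRUE))
    }, numeric(1)))
  }
  rng <- max(iv_raw) - min(iv_raw)
  if (rng == 0) {
    warning("all importance values are equal; standardized IVs set to 0")
    iv_std <- rep(0, length(iv_raw))
  } else {
    iv_std <- (iv_raw - min(iv_raw)) / rng
  }
  out <- tibble::tibble(predictor = preds, iv_raw = unname(iv_raw),
                        iv_std = unname(iv_std))
  out <- out[order(-out$iv_raw), ]
  class(out) <- c("importance_table", class(out))
  out
}

#' Pearson correlation matrix of the predictors
#'
#' @param table Training tibble.
#' @return Symmetric correlation matrix over the predictor columns;
#'   zero-variance predictors yield `NA` entries (with a warning).
#' @export
correlation_matrix <- function(table) {
  preds <- predictor_names(table)
  x <- as.matrix(table[preds])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance predictor(s): ",
            paste(preds[sds == 0], collapse = ", "),
            "; their correlations are undefined (NA)")
  }
  suppressWarnings(stats::cor(x))
}

#' Iteratively prune collinear predictors by importance
#'
#' While any retained pair has `|r|` above `threshold`, the pair with the
#' largest `|r|` is found and its lower-IV member dropped (ties drop the
#' alphabetically later name). Output preserves the IV table's predictor
#' order.
#'
#' @param iv `importance_table` from [jackknife_importance()].
#' @param cor_mat Correlation matrix from [correlation_matrix()].
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return Character vector of retained predictor names.
#' @export
prune_collinear <- function(iv, cor_mat, threshold = 0.7) {
  stopifnot(setequal(iv$predictor, rownames(cor_mat)))
  retained <- iv$predictor
  iv_of <- stats::setNames(iv$iv_raw, iv$predictor)
  repeat {
    cm <- abs(cor_mat[retained, retained, drop = FALSE])
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (length(retained) < 2 || max(cm) <= threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- retained[ij[1]]; b <- retained[ij[2]]
    drop <- if (iv_of[a] < iv_of[b]) a
            else if (iv_of[b] < iv_of[a]) b
            else max(a, b)                     # tie: alphabetically later
    retained <- setdiff(retained, drop)
  }
  retained
}
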