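test_that("pseudo-absence counts follow the 1000 floor / n-matching rule", {
  region <- raster_grid(matrix(1, 220, 220), y_origin = 50,
                        cell_size = 1 / 24)
  occ <- toy_occurrences(lon = 0.1, lat = 49.9)
  pa_small <- sample_pseudo_absences(region, occ, n_presence = 118,
                                     seed = 1)
  expect_equal(nrow(pa_small), 1000)
  pa_large <- sample_pseudo_absences(region, occ, n_presence = 20790,
                                     seed = 1)
  expect_equal(nrow(pa_large), 20790)
  pa_edge <- sample_pseudo_absences(region, occ, n_presence = 1000,
                                    seed = 1)
  expect_equal(nrow(pa_edge), 1000)
})

test_that("pseudo-absences avoid presence cells and are seed-deterministic", {
  region <- raster_grid(matrix(1, 40, 40), y_origin = 40, cell_size = 0.05)
  occ <- withr::with_seed(2, toy_occurrences(
    lon = runif(30, 0, 2), lat = runif(30, 38, 40)))
  pa <- sample_pseudo_absences(region, occ, n_floor = 200, seed = 9)
  pres <- hostsdm:::cell_index(region, occ$lon, occ$lat)
  pac <- hostsdm:::cell_index(region, pa$lon, pa$lat)
  pres_id <- paste(pres$row, pres$col)
  expect_false(any(paste(pac$row, pac$col) %in% pres_id))
  expect_equal(anyDuplicated(paste(pac$row, pac$col)), 0)
  pa2 <- sample_pseudo_absences(region, occ, n_floor = 200, seed = 9)
  expect_identical(pa, pa2)

  tiny <- raster_grid(matrix(1, 3, 3), y_origin = 3, cell_size = 1)
  expect_error(
    sample_pseudo_absences(tiny, toy_occurrences(0.5, 0.5), n_floor = 100,
                           seed = 1),
    "candidate")
})

test_that("cv splits stratify 70/30 per class and partition the rows", {
  tab <- sim_training_table(100, beta = 1, seed = 4)
  tab$label <- rep(c(0, 1), 50)
  splits <- make_cv_splits(tab, n_repetitions = 5, seed = 11)
  expect_length(splits, 5)
  for (sp in splits) {
    expect_equal(length(sp$test), 30)
    expect_equal(length(sp$train), 70)
    expect_equal(sum(tab$label[sp$test]), 15)
    expect_setequal(c(sp$train, sp$test), 1:100)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_identical(splits, make_cv_splits(tab, 5, seed = 11))
  one_class <- tab[tab$label == 1, ]
  expect_error(make_cv_splits(one_class, 5, seed = 1), "stratify")
})

test_that("the ridge-logistic member separates separable data and recovers slopes", {
  sep <- withr::with_seed(123,
    tibble::tibble(label = rep(c(1, 0), each = 20), weight = 1,
                   x = c(rnorm(20, 3), rnorm(20, -3))))
  m <- fit_member(sep)
  expect_true(m$converged)
  expect_equal(auc(predict_member(m, sep), sep$label), 1.0)

  null_tab <- sim_training_table(2000, beta = 1.5, seed = 8)
  null_tab$label <- withr::with_seed(9, sample(null_tab$label))
  mn <- fit_member(null_tab)
  expect_lt(abs(auc(predict_member(mn, null_tab), null_tab$label) - 0.5),
            0.05)

  rec <- sim_training_table(5000, beta = 0.8, seed = 10)
  mr <- fit_member(rec)
  # coefficients are on standardized predictors; undo the scaling
  slope <- mr$model$beta[2] / mr$model$scale[1]
  expect_lt(abs(slope - 0.8) / 0.8, 0.1)
})

test_that("gating applies both thresholds and TSS-proportional weights", {
  fake_member <- function(tss, auc) {
    structure(list(algorithm = "fake", model = NULL, learner = NULL,
                   predictors = "x", repetition = 1L, converged = TRUE,
                   heldout_auc = auc, heldout_tss = tss, mss = 0.5,
                   included = NA),
              class = "fitted_member")
  }
  expect_error(gate_members(list(fake_member(0.55, 0.95))), "0.8")
  ens <- gate_members(list(fake_member(0.55, 0.95),   # TSS below gate
                           fake_member(0.8, 0.79),    # AUC below gate
                           fake_member(0.6, 0.9),
                           fake_member(0.9, 0.9)))
  expect_equal(ens$weights, c(0, 0, 0.4, 0.6))
  td <- tidy(ens)
  expect_equal(td$included, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(glance(ens)$n_included, 2)
})

test_that("ensemble predictions are convex combinations of member maps", {
  st <- generate_landscape(15, 15, "x", smoothness = 2, seed = 3)
  const_member <- function(v, tss) {
    structure(list(algorithm = "const",
                   model = v,
                   learner = list(predict = function(model, x) {
                     rep(model, nrow(x))
                   }),
                   predictors = "x", repetition = 1L, converged = TRUE,
                   heldout_auc = 0.9, heldout_tss = tss, mss = 0.5,
                   included = NA),
              class = "fitted_member")
  }
  ens <- gate_members(list(const_member(0.2, 0.7), const_member(0.8, 0.7)))
  out <- ensemble_predict(ens, st)
  expect_true(all(out$values == 0.5))

  single <- gate_members(list(const_member(0.31, 0.8)))
  expect_true(all(ensemble_predict(single, st)$values == 0.31))

  # excluded members do not contribute
  with_dud <- gate_members(list(const_member(0.2, 0.7),
                                const_member(0.8, 0.7),
                                const_member(0.99, 0.2)))
  expect_equal(ensemble_predict(with_dud, st)$values, out$values)

  expect_error(ensemble_predict(ens, generate_landscape(8, 8, "y",
                                                        seed = 1)),
               "missing")
})

test_that("ensemble output stays within [0, 1] and propagates nodata", {
  tab <- sim_training_table(400, beta = c(2, -1), seed = 6)
  splits <- make_cv_splits(tab, 3, seed = 7)
  ens <- gate_members(fit_committee(tab, splits), tss_gate = 0,
                      auc_gate = 0)
  st <- generate_landscape(20, 20, c("p1", "p2"), smoothness = 3, seed = 8)
  st$p1$values[4, 4] <- NA
  out <- ensemble_predict(ens, st)
  expect_true(is.na(out$values[4, 4]))
  v <- out$values[!is.na(out$values)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("jackknife importance recovers the informative predictor", {
  tab <- sim_training_table(2000, beta = c(2, 0), seed = 13)
  names(tab)[3:4] <- c("A", "B")
  splits <- make_cv_splits(tab, 5, seed = 14)
  iv <- jackknife_importance(tab, splits)
  expect_equal(iv$predictor[1], "A")
  expect_equal(iv$iv_std[iv$predictor == "A"], 1)
  expect_equal(iv$iv_std[iv$predictor == "B"], 0)
})

test_that("a duplicated predictor is compensated and both copies score ~0", {
  tab <- sim_training_table(2000, beta = 2, seed = 15)
  tab$p2 <- tab$p1
  tab$noise <- withr::with_seed(16, rnorm(2000))
  splits <- make_cv_splits(tab, 5, seed = 16)
  iv <- jackknife_importance(tab, splits)
  expect_lt(iv$iv_raw[iv$predictor == "p1"], 0.005)
  expect_lt(iv$iv_raw[iv$predictor == "p2"], 0.005)
})

test_that("an informative predictor outranks noise in repeated seeded runs", {
  hits <- sum(vapply(1:20, function(s) {
    tab <- sim_training_table(600, beta = c(1.5, 0, 0, 0, 0, 0), seed = s)
    splits <- make_cv_splits(tab, 3, seed = s + 500)
    jackknife_importance(tab, splits)$predictor[1] == "p1"
  }, logical(1)))
  expect_gte(hits, 19)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  tab <- sim_training_table(10000, beta = c(1, 1), seed = 18)
  tab$neg <- -tab$p1
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm), c(p1 = 1, p2 = 1, neg = 1))
  expect_equal(cm["p1", "neg"], -1)
  expect_lt(abs(cm["p1", "p2"]), 0.05)     # independent normals
  expect_equal(cm, t(cm))

  tab$flat <- 1
  expect_warning(cm2 <- correlation_matrix(tab), "zero-variance")
  expect_true(all(is.na(cm2["flat", setdiff(colnames(cm2), "flat")])))
})

test_that("collinearity pruning drops the lower-IV member iteratively", {
  iv <- tibble::tibble(predictor = c("A", "B", "C"),
                       iv_raw = c(0.3, 0.1, 0.2), iv_std = c(1, 0, 0.5))
  cm <- diag(3)
  dimnames(cm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  cm["A", "B"] <- cm["B", "A"] <- 0.9
  expect_equal(prune_collinear(iv, cm), c("A", "C"))

  cm_ok <- cm
  cm_ok["A", "B"] <- cm_ok["B", "A"] <- 0.6
  expect_setequal(prune_collinear(iv, cm_ok), c("A", "B", "C"))

  # chain: A-B .8, B-C .8, A-C .2 with IVs A .5 > C .3 > B .1
  iv2 <- tibble::tibble(predictor = c("A", "B", "C"),
                        iv_raw = c(0.5, 0.1, 0.3), iv_std = c(1, 0, 0.5))
  cm2 <- diag(3)
  dimnames(cm2) <- dimnames(cm)
  cm2["A", "B"] <- cm2["B", "A"] <- 0.8
  cm2["B", "C"] <- cm2["C", "B"] <- 0.8
  cm2["A", "C"] <- cm2["C", "A"] <- 0.2
  expect_equal(prune_collinear(iv2, cm2), c("A", "C"))
})
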