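test_that("binarization uses the >= convention and respects nodata", {
  m <- raster_grid(matrix(c(0.59, 0.60, 0.61, NA), 2, 2),
                   y_origin = 2, cell_size = 1)
  b <- binarize(m, 0.60)
  expect_equal(b$values[1, 1], 0)   # 0.59
  expect_equal(b$values[2, 1], 1)   # 0.60 exactly: presence
  expect_equal(b$values[1, 2], 1)
  expect_true(is.na(b$values[2, 2]))
  expect_equal(b$threshold, 0.6)

  all_in <- binarize(m, 0)
  expect_true(all(all_in$values[!is.na(m$values)] == 1))
})

test_that("raising the threshold never adds presence cells", {
  suit <- generate_landscape(25, 25, "z", smoothness = 3, seed = 6)$z
  suit <- raster_grid(plogis(suit$values), suit$x_origin, suit$y_origin,
                      suit$cell_size)
  prev <- NULL
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- binarize(suit, thr)
    if (!is.null(prev)) {
      expect_true(all(cur$values <= prev$values))
    }
    prev <- cur
  }
})

test_that("suitability classes follow the standard bins with upward boundaries", {
  m <- raster_grid(matrix(c(0.7, 0.5, 0.3, 0.1, 0.6, 0.4, 0.2, NA, 0), 3),
                   y_origin = 3, cell_size = 1)
  cls <- classify_suitability(m)
  lookup <- function(v) as.character(cls$class[match(v, cls$suitability)])
  expect_equal(lookup(0.7), "high")
  expect_equal(lookup(0.5), "medium")
  expect_equal(lookup(0.3), "low")
  expect_equal(lookup(0.1), "extremely_low")
  expect_equal(lookup(0.6), "high")
  expect_equal(lookup(0.4), "medium")
  expect_equal(lookup(0.2), "low")
  expect_true(is.na(cls$class[is.na(cls$suitability)]))
})

test_that("spherical cell areas match the band formula benchmarks", {
  # 2.5 arc-minute cell touching the equator
  g <- raster_grid(matrix(0, 1, 1), x_origin = 0, y_origin = 1 / 24,
                   cell_size = 1 / 24)
  expect_equal(cell_areas(g)$values[1, 1], 21.4, tolerance = 0.01)

  # thin band at 60 N is ~half the equatorial one (cos-latitude limit)
  g60 <- raster_grid(matrix(0, 1, 1), x_origin = 0,
                     y_origin = 60 + 1 / 24, cell_size = 1 / 24)
  ratio <- cell_areas(g60)$values[1, 1] / cell_areas(g)$values[1, 1]
  expect_equal(ratio, 0.5, tolerance = 0.01)

  # whole-sphere toy grid sums to 4 pi R^2
  sphere <- raster_grid(matrix(0, 18, 36), x_origin = -180, y_origin = 90,
                        cell_size = 10)
  expect_equal(sum(cell_areas(sphere)$values), 4 * pi * 6371^2,
               tolerance = 1e-3)
})

test_that("range areas are additive over disjoint ranges and zero when empty", {
  empty <- toy_range(matrix(0, 4, 4))
  expect_equal(range_area(empty), 0)

  full <- toy_range(matrix(1, 4, 4))
  expect_equal(range_area(full), sum(cell_areas(full)$values))

  a <- matrix(0, 4, 4); a[1, ] <- 1
  b <- matrix(0, 4, 4); b[3, ] <- 1
  expect_equal(range_area(toy_range(a)) + range_area(toy_range(b)),
               range_area(toy_range(a + b)))
})

test_that("range dynamics reproduce the RER and IRS identities", {
  cur <- toy_range(matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3))
  same <- compute_dynamics(cur, cur)
  expect_equal(same$rer, 1)
  expect_equal(same$irs, 1)
  expect_equal(same$expanding_km2, 0)

  other <- toy_range(matrix(c(0, 0, 0, 0, 0, 1, 1, 1, 1), 3))
  disj <- compute_dynamics(cur, other)
  expect_equal(disj$irs, 0)
  expect_equal(disj$rer, 1, tolerance = 1e-4)  # equal cell counts near equator

  # RC 4 cells, RF 6 cells, 3 shared
  rc <- matrix(0, 3, 3); rc[1, ] <- 1; rc[2, 1] <- 1
  rf <- matrix(0, 3, 3); rf[1, 1:3] <- 1; rf[3, ] <- 1
  dyn <- compute_dynamics(toy_range(rc), toy_range(rf))
  expect_equal(dyn$rer, 1.5, tolerance = 1e-4)
  expect_equal(dyn$irs, 0.6, tolerance = 1e-4)
  expect_equal(dyn$expanding_km2, dyn$rf_km2 - dyn$rs_km2)
  td <- tidy(dyn)
  expect_equal(td$rer, dyn$rer)

  none <- toy_range(matrix(0, 3, 3))
  und <- compute_dynamics(none, toy_range(rf))
  expect_true(und$rer_undefined)
  expect_true(is.na(und$rer))
})

test_that("the expanding range never intersects the current range", {
  withr::with_seed(66, {
    for (i in 1:20) {
      cur <- toy_range(matrix(rbinom(36, 1, 0.4), 6))
      fut <- toy_range(matrix(rbinom(36, 1, 0.5), 6))
      dyn <- compute_dynamics(cur, fut)
      expect_equal(sum(dyn$expanding$values * cur$values), 0)
      expect_equal(range_area(dyn$expanding) + dyn$rs_km2, dyn$rf_km2)
      expect_gte(dyn$irs, 0)
      expect_lte(dyn$irs, 1)
    }
  })
})

test_that("range overlap reproduces the POR ratio", {
  host <- toy_range(matrix(1, 3, 3))
  inside <- matrix(0, 3, 3); inside[2, 1:2] <- 1
  expect_equal(compute_overlap(host, toy_range(inside))$por, 1)

  off <- matrix(0, 3, 3); off[1, 1] <- 1
  host2 <- toy_range(matrix(c(0, 0, 0, 0, 1, 1, 0, 1, 1), 3))
  expect_equal(compute_overlap(host2, toy_range(off))$por, 0)

  spec4 <- matrix(0, 3, 3); spec4[1, 2:3] <- 1; spec4[2, 2:3] <- 1
  host3 <- matrix(0, 3, 3); host3[, 2] <- 1; host3[2, 3] <- 1
  ov <- compute_overlap(toy_range(host3), toy_range(spec4))
  expect_equal(ov$por, 0.75, tolerance = 1e-4)

  und <- compute_overlap(host, toy_range(matrix(0, 3, 3)))
  expect_true(und$por_undefined)
})

test_that("POR grows monotonically with the host range", {
  withr::with_seed(68, {
    spec <- toy_range(matrix(rbinom(36, 1, 0.5), 6))
    order_cells <- sample(36)
  })
  host_mask <- matrix(0, 6, 6)
  last <- 0
  for (k in seq(6, 36, by = 6)) {
    host_mask[order_cells[1:k]] <- 1
    por <- compute_overlap(toy_range(host_mask), spec)$por
    expect_gte(por + 1e-12, last)
    last <- por
  }
})

test_that("paired scenario comparisons match the closed-form t statistic", {
  res <- compare_scenarios(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, sqrt(3) * 2, tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_false(res$degenerate)

  same <- compare_scenarios(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$t, 0)

  const_diff <- compare_scenarios(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(const_diff$degenerate)
})

test_that("jaccard similarity behaves on nested and disjoint ranges", {
  a <- toy_range(matrix(c(1, 1, 0, 0), 2))
  expect_equal(range_jaccard(a, a), 1)
  b <- toy_range(matrix(c(0, 0, 1, 1), 2))
  expect_equal(range_jaccard(a, b), 0)
  expect_true(is.na(range_jaccard(toy_range(matrix(0, 2, 2)),
                                  toy_range(matrix(0, 2, 2)))))
})
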