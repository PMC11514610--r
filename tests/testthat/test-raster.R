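test_that("ESRI ASCII round-trip preserves values, nodata mask and geometry", {
  withr::with_tempdir({
    g <- withr::with_seed(11, raster_grid(matrix(rnorm(100), 10),
                                          x_origin = 3.5, y_origin = 47.25,
                                          cell_size = 1 / 24))
    g$values[c(3, 41, 87)] <- NA
    write_raster(g, "g.asc")
    g2 <- read_raster("g.asc")
    expect_equal(g2$values, g$values)
    expect_identical(is.na(g2$values), is.na(g$values))
    expect_true(same_geometry(g, g2))

    zero <- raster_grid(matrix(0, 5, 5))
    write_raster(zero, "zero.asc")
    expect_equal(sum(read_raster("zero.asc")$values), 0)

    one <- raster_grid(matrix(3.25, 1, 1), x_origin = -1, y_origin = 2)
    write_raster(one, "one.asc")
    expect_equal(read_raster("one.asc")$values, one$values)
  })
})

test_that("reading honours the declared nodata sentinel", {
  withr::with_tempdir({
    writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
                 "cellsize 1", "NODATA_value -9999",
                 "1 2 3", "4 -9999 6", "7 8 9"), "m.asc")
    g <- read_raster("m.asc")
    expect_true(is.na(g$values[2, 2]))
    expect_equal(sum(is.na(g$values)), 1)
    expect_equal(g$values[1, 1], 1)
  })
})

test_that("unreadable or malformed rasters give informative errors", {
  withr::with_tempdir({
    expect_error(read_raster("absent.asc"), "absent.asc")
    writeLines("x", "bad.tif")
    expect_error(read_raster("bad.tif"), "unsupported")
    writeLines(c("ncols 2", "nrows 2", "cellsize 1", "1 2", "3 4"),
               "nogeo.asc")
    expect_error(read_raster("nogeo.asc"), "georeference")
    expect_error(write_raster(toy_grid(), "no/such/dir/out.asc"),
                 "directory")
  })
})

test_that("align_stack is the identity on matching geometry and preserves constants", {
  tmpl <- toy_grid(6, 6)
  g <- withr::with_seed(5, toy_grid(6, 6, matrix(rnorm(36), 6)))
  out <- align_stack(list(a = g), tmpl)
  expect_equal(out$a$values, g$values)

  coarse <- raster_grid(matrix(4.5, 3, 3), x_origin = 0, y_origin = 6,
                        cell_size = 2)
  out2 <- align_stack(list(k = coarse), tmpl)
  expect_true(all(out2$k$values == 4.5))
})

test_that("bilinear resampling interpolates midway between columns to the mean", {
  # source columns hold 0 and 2; a template centre midway between the two
  # source centres must read exactly 1.0
  src <- raster_grid(matrix(c(0, 2, 0, 2), 2, 2, byrow = TRUE),
                     x_origin = 0, y_origin = 2, cell_size = 1)
  tmpl <- raster_grid(matrix(0, 1, 1), x_origin = 0.5, y_origin = 1.5,
                      cell_size = 1)
  out <- align_stack(list(v = src), tmpl)
  expect_equal(out$v$values[1, 1], 1.0)
})

test_that("align_stack propagates nodata and rejects non-overlapping layers", {
  tmpl <- toy_grid(4, 4)
  src <- toy_grid(4, 4)
  src$values[2, 2] <- NA
  out <- align_stack(list(a = src), tmpl)
  expect_true(is.na(out$a$values[2, 2]))

  far <- raster_grid(matrix(1, 3, 3), x_origin = 100, y_origin = 50)
  expect_error(align_stack(list(b = far), tmpl), "overlap")
})

test_that("layer stacks enforce unique names and shared geometry", {
  g <- toy_grid()
  expect_error(layer_stack(list(g, g)), "names")
  g2 <- toy_grid(4, 3)
  expect_error(layer_stack(a = g, b = g2), "geometry")
  st <- layer_stack(a = g, b = g)
  expect_named(st[c("b")], "b")
})

test_that("extract_values uses half-open cell membership and flags bad points", {
  g <- toy_grid(2, 2, matrix(c(1, 2, 3, 4), 2, byrow = TRUE))
  st <- layer_stack(v = g)
  occ <- toy_occurrences(lon = c(0.5, 1.0, 5.0), lat = c(1.5, 1.0, 1.0))
  ex <- extract_values(st, occ)
  expect_equal(ex$v[1], 1)        # centre of upper-left cell
  # (1.0, 1.0) sits on the shared edge: half-open intervals put it in
  # column 2 (lon in [1, 2)) and row 2 (lat in (0, 1] -> row index 2)
  expect_equal(ex$v[2], 4)
  expect_true(ex$out_of_extent[3])
  expect_false(any(ex$out_of_extent[1:2]))

  g$values[1, 1] <- NA
  ex2 <- extract_values(layer_stack(v = g), occ[1, ])
  expect_true(ex2$any_nodata[1])
})

test_that("constant layers extract their constant at any interior point", {
  st <- layer_stack(c7 = toy_grid(3, 3, matrix(7, 3, 3)))
  ex <- extract_values(st, toy_occurrences(lon = 1.5, lat = 1.5))
  expect_equal(ex$c7, 7)
})
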