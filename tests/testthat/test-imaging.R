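test_that("read_cell_table parses particle-analysis style CSVs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X,Y,Mean", "10,20,0.5", "30,40,0.25", "50,60,0.75"), tmp)
  ct <- read_cell_table(tmp, column_map = list(x = "X", y = "Y", mean = "Mean"),
                        kind = "tumor_dead")
  expect_equal(nrow(ct), 3)
  expect_equal(ct$x, c(10, 30, 50))
  expect_equal(ct$mean, c(0.5, 0.25, 0.75))
  expect_true(all(ct$kind == "tumor_dead"))

  # unknown class rejected with the class named
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X,Y,Class", "1,2,tumor_live", "3,4,stromal"), tmp2)
  expect_error(
    read_cell_table(tmp2, column_map = list(x = "X", y = "Y", kind = "Class"),
                    schema = schema_ex1()),
    "stromal")

  # missing mapped column and non-numeric coordinates are informative errors
  expect_error(read_cell_table(tmp, column_map = list(x = "Xc", y = "Y")),
               "Xc")
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X,Y", "1,2", "oops,4"), tmp3)
  expect_error(read_cell_table(tmp3, column_map = list(x = "X", y = "Y")),
               "row 2")
})

test_that("cell tables round-trip exactly through CSV", {
  set.seed(42)
  ct <- cell_table(x = runif(50, 0, 1000), y = runif(50, 0, 1000),
                   kind = sample(c("tumor_live", "tcell_active"), 50, TRUE),
                   pdl1 = runif(50, 0, 0.01))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(ct, tmp)
  back <- read_cell_table(tmp, column_map = list(x = "x", y = "y",
                                                 kind = "kind", pdl1 = "pdl1"))
  expect_identical(back$x, ct$x)
  expect_identical(back$y, ct$y)
  expect_identical(back$kind, ct$kind)
  expect_identical(back$pdl1, ct$pdl1)
})

test_that("rasterization bins cells at one cell diameter per grid site", {
  ct <- cell_table(x = c(10, 30.5), y = c(10, 10), kind = rep("tumor_live", 2))
  g <- rasterize_cells(ct, channel_schema(channel("tumor", kind = "tumor_live")),
                       cell_diameter = 20)
  expect_equal(dim(g), c(1, 2, 1))
  expect_equal(as.vector(g[1, , 1]), c(1, 1))

  # continuous channels are scaled to a maximum of one
  ct2 <- cell_table(x = c(10, 50), y = c(10, 10), kind = rep("tumor_live", 2),
                    pdl1 = c(0.002, 0.01))
  sch <- channel_schema(channel("pdl1", mode = "continuous",
                                kind = "tumor_live", property = "pdl1"))
  g2 <- rasterize_cells(ct2, sch, 20)
  expect_equal(sort(g2[g2 > 0]), c(0.2, 1.0))

  expect_error(rasterize_cells(ct[0, ], schema_ex1(), 20), "empty")
  expect_error(rasterize_cells(ct, schema_ex1(), 0), "positive")
})

test_that("rasterization agrees with the histogram-binning oracle", {
  set.seed(33)
  n <- 500
  ct <- cell_table(x = runif(n, -300, 300), y = runif(n, -300, 300),
                   kind = sample(c("tumor_live", "tcell_active",
                                   "tcell_suppressed"), n, TRUE),
                   pdl1 = runif(n, 0, 0.01))
  sch <- schema_ex1()
  got <- rasterize_cells(ct, sch, 20)
  want <- rasterize_oracle(ct, sch, 20)
  expect_equal(unclass(got), want, ignore_attr = TRUE)
})

test_that("cropping returns the minimal tumor bounding box", {
  g <- array(0, c(20, 15, 2))
  g[3:7, 4:9, 1] <- 1
  g[1:20, 1:15, 2] <- 0.5  # non-tumor channel everywhere
  gs <- structure(g, channels = c("tumor", "other"), cell_diameter = 20,
                  origin = c(x = 0, y = 0), class = "grid_stack")
  cr <- crop_to_tumor(gs, "tumor")
  expect_equal(dim(cr), c(5, 6, 2))

  # tumor filling the grid: identity
  g2 <- gs
  g2[, , 1] <- 1
  expect_equal(dim(crop_to_tumor(g2, "tumor")), c(20, 15, 2))

  # random sparse grids against a min/max index scan
  set.seed(9)
  for (i in 1:5) {
    g3 <- array(0, c(12, 11, 1))
    hits <- cbind(sample(3:10, 4, TRUE), sample(2:11, 4, TRUE), 1)
    g3[hits] <- 1
    gs3 <- structure(g3, channels = "tumor", cell_diameter = 20,
                     origin = c(x = 0, y = 0), class = "grid_stack")
    cr3 <- crop_to_tumor(gs3, "tumor")
    expect_equal(dim(cr3)[1:2],
                 c(diff(range(hits[, 1])) + 1, diff(range(hits[, 2])) + 1))
  }

  g4 <- gs
  g4[, , 1] <- 0
  expect_error(crop_to_tumor(g4, "tumor"), "empty")
})

test_that("downsampling is an exact area-weighted average", {
  # constant channels are preserved
  g <- structure(array(1, c(4, 4, 1)), channels = "tumor",
                 cell_diameter = 20, origin = c(x = 0, y = 0),
                 class = "grid_stack")
  img <- downsample_grid(g, c(2, 2))
  expect_equal(as.vector(img), rep(1, 4))

  # the hand-computable 2x2 -> 1x1 case: area mean 0.5 before rescaling
  Wr <- abmcal:::area_weights(2, 1)
  m <- matrix(c(1, 0, 1, 0), 2, 2)  # [[1,1],[0,0]]
  pre <- Wr %*% m %*% t(Wr)
  expect_equal(as.numeric(pre), 0.5)
  g2 <- structure(array(m, c(2, 2, 1)), channels = "tumor",
                  cell_diameter = 20, origin = c(x = 0, y = 0),
                  class = "grid_stack")
  img2 <- downsample_grid(g2, c(1, 1))
  expect_equal(as.numeric(img2), 1.0)  # rescaled so the max is one

  # area weights: rows sum to one for arbitrary sizes
  for (nin in c(3, 7, 16)) for (nout in c(2, 5)) {
    W <- abmcal:::area_weights(nin, nout)
    expect_equal(rowSums(W), rep(1, nout))
  }
  expect_error(downsample_grid(g, c(0, 2)), "positive")
})

test_that("simplified images obey the range law", {
  set.seed(12)
  for (i in 1:5) {
    n <- 150
    ct <- cell_table(x = runif(n, 0, 400), y = runif(n, 0, 400),
                     kind = sample(c("tumor_live", "tcell_active",
                                     "tcell_suppressed"), n, TRUE,
                                   prob = c(0.6, 0.3, 0.1)),
                     pdl1 = runif(n, 0, 0.01))
    img <- suppressMessages(process_cells(ct, process_spec_ex1(target = c(16, 16))))
    expect_true(all(img >= 0 & img <= 1))
    for (k in seq_len(dim(img)[3])) {
      ch <- img[, , k]
      if (any(ch > 0)) expect_equal(max(ch), 1)
    }
  }
})

test_that("processing yields the expected channel layouts", {
  ct <- simulate_abm(nominal_params_ex1(), quick_cfg_ex1(), seed = 6)
  img <- suppressMessages(process_cells(ct, process_spec_ex1(target = c(16, 16))))
  expect_equal(dim(img), c(16, 16, 4))
  expect_equal(attr(img, "channels"),
               c("tumor", "tcell_active", "tcell_suppressed", "pdl1"))

  p2 <- abm_params_ex2(0.005, 0.5, 2e-3, 80, 0.05)
  ct2 <- simulate_abm(p2, quick_cfg_ex2(), seed = 6)
  img2 <- suppressMessages(process_cells(ct2, process_spec_ex2_dead(target = c(16, 16))))
  expect_equal(dim(img2)[3], 1)
  expect_equal(attr(img2, "channels"), "tumor_dead")
})

test_that("processing is translation invariant and integer-scale invariant", {
  set.seed(77)
  n <- 200
  ct <- cell_table(x = runif(n, 0, 400), y = runif(n, 0, 400),
                   kind = sample(c("tumor_live", "tcell_active"), n, TRUE),
                   pdl1 = runif(n, 0, 0.01))
  spec <- process_spec_ex1(target = c(8, 8))
  base <- suppressMessages(process_cells(ct, spec))

  shifted <- ct
  shifted$x <- ct$x + 500
  shifted$y <- ct$y + 500
  expect_identical(unclass(suppressMessages(process_cells(shifted, spec))),
                   unclass(base))

  scaled <- ct
  scaled$x <- ct$x * 3
  scaled$y <- ct$y * 3
  spec3 <- process_spec_ex1(cell_diameter = 60, target = c(8, 8))
  expect_identical(unclass(suppressMessages(process_cells(scaled, spec3))),
                   unclass(base))
})

test_that("mirroring cells mirrors the processed image", {
  # bin-center aligned coordinates avoid crop-edge ties
  set.seed(5)
  d <- 20
  ij <- unique(cbind(sample(0:9, 60, TRUE), sample(0:9, 60, TRUE)))
  ct <- cell_table(x = (ij[, 1] + 0.5) * d, y = (ij[, 2] + 0.5) * d,
                   kind = "tumor_live", pdl1 = 0)
  spec <- process_spec(channel_schema(channel("tumor", kind = "tumor_live")),
                       cell_diameter = d, tumor_channels = "tumor",
                       target = c(8, 8))
  base <- suppressMessages(process_cells(ct, spec))
  mir <- ct
  mir$x <- -mir$x
  got <- suppressMessages(process_cells(mir, spec))
  expect_equal(unclass(got)[, , 1], unclass(base)[, 8:1, 1])
})

test_that("simplified images round-trip through the JSON container", {
  set.seed(3)
  ct <- cell_table(x = runif(80, 0, 300), y = runif(80, 0, 300),
                   kind = "tumor_live", pdl1 = runif(80))
  img <- suppressMessages(process_cells(ct, process_spec_ex1(target = c(8, 8))))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_simplified_image(img, tmp)
  back <- read_simplified_image(tmp)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)
  expect_equal(attr(back, "channels"), attr(img, "channels"))
})
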