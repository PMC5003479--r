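test_that("segmentation recovers well-separated nuclei", {
  layout <- test_grid(1, 1)
  scene <- render_field(scene_params(layout = layout, cell_density = 150,
                                     seed = 41))
  seg <- segment_nuclei(scene$field$nuclei, 1.33)
  cells <- add_physical_coords(seg$cells, 1.33, scene$field$field_origin)
  expect_identical(nrow(cells), nrow(scene$truth$cells))
  # count conservation: one record per label
  expect_identical(nrow(cells), max(seg$labels))
  # centroid error <= 2 px
  ev <- evaluate_segmentation(scene, cells)
  expect_identical(ev$recall, 1)
  expect_lt(ev$mean_centroid_error_um, 2 * 1.33)
})

test_that("segmentation of blank images yields no cells", {
  seg <- segment_nuclei(matrix(100, 80, 80), 1.33)
  expect_identical(nrow(seg$cells), 0L)
  withr::with_seed(2, img <- matrix(rnorm(80^2, 100, 10), 80, 80))
  expect_identical(nrow(segment_nuclei(img, 1.33)$cells), 0L)
})

test_that("watershed splits a 30%-overlapping nucleus pair", {
  # r = 7 um at 1.33 um/px; centres 1.7 r apart
  r_px <- 7 / 1.33
  img <- paint_discs_r(60, 60, c(25, 25 + 1.7 * r_px), c(30, 30),
                       c(r_px, r_px), c(3000, 3000), background = 100)
  seg <- segment_nuclei(img, 1.33)
  expect_identical(nrow(seg$cells), 2L)
})

test_that("measure_phenotype uses the dilated, disjoint region", {
  layout <- test_grid(1, 1)
  scene <- render_field(scene_params(layout = layout, cell_density = 200,
                                     seed = 42))
  seg <- segment_nuclei(scene$field$nuclei, 1.33)
  # uniform channel: every cell measures exactly v
  uni <- matrix(123.5, nrow(scene$field$nuclei), ncol(scene$field$nuclei))
  m <- measure_phenotype(seg$cells, seg$labels, uni, 1.33)
  expect_true(all(m$phenotype_intensity == 123.5))
  # dilation 0 equals the nucleus-mask mean
  m0 <- measure_phenotype(seg$cells, seg$labels, scene$field$phenotype,
                          1.33, dilation_radius_um = 0)
  lab <- seg$labels
  for (id in m0$cell_id[1:5]) {
    expect_equal(m0$phenotype_intensity[m0$cell_id == id],
                 mean(scene$field$phenotype[lab == id]))
  }
  expect_error(
    measure_phenotype(seg$cells, seg$labels, matrix(0, 2, 2), 1.33),
    class = "phenoarray_shape_mismatch")
})

test_that("expressing and silenced populations separate widely", {
  layout <- test_grid(2, 2, control_idx = 1L)
  scene <- test_scene(layout, fraction = 0.5, seed = 43,
                      cell_density = 500)
  seg <- segment_nuclei(scene$field$nuclei, 1.33)
  cells <- measure_phenotype(seg$cells, seg$labels, scene$field$phenotype,
                             1.33)
  cells <- add_physical_coords(cells, 1.33, scene$field$field_origin)
  truth <- scene$truth$cells
  m <- match_points(truth$x_um, truth$y_um, cells$x_um, cells$y_um, 5)
  on <- cells$phenotype_intensity[m$b[truth$expressing[m$a]]]
  off <- cells$phenotype_intensity[m$b[!truth$expressing[m$a]]]
  # generator draws are 18 sd apart; measured means keep > 5 sd separation
  expect_gt(mean(on) - mean(off), 5 * max(sd(on), sd(off)))
})

test_that("classification is correct and monotone in the threshold", {
  withr::with_seed(44, {
    n <- 2000
    expressing <- runif(n) < 0.8
    intensity <- rnorm(n, ifelse(expressing, 850, 600), 50)  # 5 sd apart
  })
  cells <- empty <- phenoarray:::empty_cell_records()
  cells <- data.frame(cell_id = seq_len(n), x_px = 0, y_px = 0,
                      area_px = 1L, area_um2 = 1,
                      phenotype_intensity = intensity,
                      expressing = NA, assigned_spot_id = NA_integer_)
  out <- classify_expressing(cells, "otsu")
  err <- mean(out$expressing != expressing)
  expect_lt(err, 0.02)
  # fixed-threshold extremes and monotonicity
  expect_true(all(classify_expressing(cells, min(intensity) - 1)$expressing))
  expect_false(any(classify_expressing(cells,
                                       max(intensity) + 1)$expressing))
  counts <- vapply(c(500, 600, 700, 800, 900),
                   function(t) sum(classify_expressing(cells, t)$expressing),
                   0L)
  expect_true(all(diff(counts) <= 0))
  # empty input passes through
  expect_identical(nrow(classify_expressing(empty, 10)), 0L)
  expect_error(classify_expressing(transform(cells,
                                             phenotype_intensity = NA),
                                   10),
               class = "phenoarray_bad_arg")
})

test_that("control-derived threshold sits at the stated percentile", {
  ctrl <- c(1:99, 1000)
  thr <- phenotype_threshold(strategy = "control",
                             control_intensities = ctrl,
                             percentile = 0.05)
  expect_equal(thr, as.numeric(quantile(ctrl, 0.05)))
  expect_error(phenotype_threshold(strategy = "control"),
               class = "phenoarray_bad_threshold")
  expect_error(phenotype_threshold(strategy = "fixed"),
               class = "phenoarray_bad_threshold")
})
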