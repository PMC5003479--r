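test_that("rendering is bit-identical for a fixed seed", {
  layout <- test_grid(2, 2)
  p <- scene_params(layout = layout, cell_density = 400, seed = 31)
  a <- render_field(p)
  b <- render_field(p)
  expect_identical(a$field$tracer, b$field$tracer)
  expect_identical(a$field$phenotype, b$field$phenotype)
  expect_identical(a$field$nuclei, b$field$nuclei)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- render_field(scene_params(layout = layout, cell_density = 400,
                                 seed = 32))
  expect_false(identical(a$field$nuclei, c$field$nuclei))
})

test_that("zero density leaves only background off the tracer", {
  layout <- test_grid(2, 2)
  scene <- render_field(scene_params(layout = layout, cell_density = 0,
                                     seed = 3))
  expect_identical(nrow(scene$truth$cells), 0L)
  # nuclei and phenotype are pure background: nothing near the signal level
  expect_lt(max(scene$field$nuclei), 300)
  expect_lt(max(scene$field$phenotype), 300)
  # tracer still shows exactly the 4 spots (reference labelling count)
  mask <- scene$field$tracer > otsu_threshold(scene$field$tracer)
  expect_identical(max(label_components(mask)), 4L)
})

test_that("tracer component count equals spots in the field", {
  for (k in c(1, 3)) {
    layout <- test_grid(1, k)
    scene <- render_field(scene_params(layout = layout, cell_density = 0,
                                       seed = k))
    mask <- scene$field$tracer > otsu_threshold(scene$field$tracer)
    expect_identical(max(label_components(mask)), as.integer(k))
  }
})

test_that("nuclei blob count matches ground-truth cells when sparse", {
  layout <- test_grid(1, 1)
  scene <- render_field(scene_params(layout = layout, cell_density = 120,
                                     seed = 8))
  n_truth <- nrow(scene$truth$cells)
  mask <- scene$field$nuclei > otsu_threshold(scene$field$nuclei)
  # at 120 cells/mm^2 with hard-core placement blobs are isolated
  expect_identical(max(label_components(mask)), n_truth)
})

test_that("well mode honours the silenced fraction", {
  p <- scene_params(off_spot_silenced_fraction = 1,
                    field_width_um = 500, field_height_um = 500,
                    seed = 5)
  all_off <- render_well(p)
  expect_true(all(!all_off$truth$cells$expressing))
  p$off_spot_silenced_fraction <- 0.8
  p$field_width_um <- p$field_height_um <- 1500
  scene <- render_well(p)
  n <- nrow(scene$truth$cells)
  k <- sum(!scene$truth$cells$expressing)
  ci <- stats::binom.test(k, n, 0.8)$conf.int
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
  expect_true(all(is.na(scene$truth$cells$spot_id)))
})

test_that("realized silenced fraction is unbiased across seeds", {
  # pooled binomial check over 50 independent small wells
  total_n <- 0L; total_sil <- 0L
  for (seed in 1:50) {
    scene <- render_well(scene_params(
      off_spot_silenced_fraction = 0.8, cell_density = 800,
      field_width_um = 400, field_height_um = 400, seed = seed))
    total_n <- total_n + nrow(scene$truth$cells)
    total_sil <- total_sil + sum(!scene$truth$cells$expressing)
  }
  expect_gt(total_n, 3000)
  expect_gt(stats::binom.test(total_sil, total_n, 0.8)$p.value, 0.01)
})

test_that("per-spot silenced fractions reach the right cells", {
  layout <- test_grid(2, 2, control_idx = 1L)
  scene <- test_scene(layout, fraction = 1, seed = 9)
  cells <- scene$truth$cells
  ctrl_id <- layout$spots$spot_id[layout$spots$role == "negative_control"]
  on_ctrl <- !is.na(cells$spot_id) & cells$spot_id == ctrl_id
  on_test <- !is.na(cells$spot_id) & cells$spot_id != ctrl_id
  expect_true(all(cells$expressing[on_ctrl]))
  expect_true(all(!cells$expressing[on_test]))
  # spot truth tallies agree with the per-cell table
  st <- scene$truth$spots
  for (i in seq_len(nrow(st))) {
    expect_identical(st$n_cells[i],
                     sum(!is.na(cells$spot_id) &
                           cells$spot_id == st$spot_id[i]))
  }
})

test_that("scene parameter validation rejects bad inputs", {
  expect_error(scene_params(um_per_pixel = 0),
               class = "phenoarray_bad_arg")
  expect_error(scene_params(off_spot_silenced_fraction = 1.2),
               class = "phenoarray_bad_arg")
  expect_error(scene_params(expressing_intensity_mean = 50,
                            silenced_intensity_mean = 100),
               class = "phenoarray_bad_arg")
  expect_error(render_field(scene_params(layout = NULL)),
               class = "phenoarray_bad_arg")
  # a field window that misses the layout entirely
  layout <- test_grid(2, 2)
  expect_error(render_field(scene_params(
    layout = layout, field_origin = c(1e6, 1e6),
    field_width_um = 500, field_height_um = 500)),
    class = "phenoarray_no_overlap")
})
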