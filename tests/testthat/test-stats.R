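make_cells <- function(x_um, y_um) {
  n <- length(x_um)
  data.frame(cell_id = seq_len(n), x_px = rep(0, n), y_px = rep(0, n),
             area_px = rep(1L, n), area_um2 = rep(1, n),
             phenotype_intensity = rep(0, n), expressing = rep(NA, n),
             assigned_spot_id = rep(NA_integer_, n),
             x_um = x_um, y_um = y_um)
}

test_that("cell-to-spot assignment follows nominal disc containment", {
  spots <- data.frame(spot_id = c(1L, 2L), center_x = c(0, 500),
                      center_y = c(0, 0))
  cells <- make_cells(c(0, 0.9 * 150, 1.1 * 150, 250, 250),
                      c(0, 0, 0, 0, 1e4))
  out <- assign_cells_to_spots(cells, spots, spot_diameter = 300)
  expect_identical(out$assigned_spot_id[1], 1L)   # at the centre
  expect_identical(out$assigned_spot_id[2], 1L)   # 0.9 r inside
  expect_true(is.na(out$assigned_spot_id[3]))     # 1.1 r outside
  # equidistant between 1 and 2 but outside both radii -> unassigned
  expect_true(is.na(out$assigned_spot_id[4]))
  expect_true(is.na(out$assigned_spot_id[5]))
  # overlap region goes to the nearer centre; exact tie -> lower id
  spots2 <- data.frame(spot_id = c(2L, 1L), center_x = c(200, 0),
                       center_y = c(0, 0))
  cells2 <- make_cells(c(90, 100), c(0, 0))
  out2 <- assign_cells_to_spots(cells2, spots2, spot_diameter = 300)
  expect_identical(out2$assigned_spot_id, c(1L, 1L))
})

test_that("assignment matches a brute-force all-pairs oracle", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      spots <- data.frame(spot_id = sample(100, 8),
                          center_x = runif(8, 0, 2000),
                          center_y = runif(8, 0, 2000))
      cells <- make_cells(runif(300, 0, 2000), runif(300, 0, 2000))
      factor <- runif(1, 0.5, 1.5)
      got <- assign_cells_to_spots(cells, spots, spot_diameter = 300,
                                   association_radius_factor = factor)
      # oracle: exhaustive scan with cutoff, nearest centre, low-id ties
      want <- rep(NA_integer_, nrow(cells))
      for (i in seq_len(nrow(cells))) {
        d <- sqrt((spots$center_x - cells$x_um[i])^2 +
                  (spots$center_y - cells$y_um[i])^2)
        ok <- which(d <= factor * 150)
        if (length(ok)) {
          best <- ok[d[ok] == min(d[ok])]
          want[i] <- min(spots$spot_id[best])
        }
      }
      expect_identical(got$assigned_spot_id, want)
    }
  })
})

test_that("percent_expressing counts and flags correctly", {
  cells <- make_cells(1:10, 1:10)
  cells$expressing <- c(rep(TRUE, 7), rep(FALSE, 3))
  out <- percent_expressing(cells, spot_id = 4L)
  expect_identical(out$percent_expressing, 70)
  expect_identical(out$n_cells, 10L)
  expect_true(out$low_count)                 # 10 < default 20
  cells$expressing <- TRUE
  expect_identical(percent_expressing(cells,
                                      min_cells = 5)$percent_expressing,
                   100)
  expect_false(percent_expressing(cells, min_cells = 5)$low_count)
  expect_error(percent_expressing(make_cells(numeric(), numeric())),
               class = "phenoarray_undefined_percent")
})

test_that("normalization fixes the control at exactly 100", {
  res <- data.frame(condition = rep(c("NTC", "kd"), each = 3),
                    percent_expressing = c(50, 50, 50, 15, 15, 15))
  out <- normalize_to_control(res, "NTC")
  expect_identical(
    out$mean_normalized_expression[out$condition == "NTC"], 100)
  expect_identical(out$knockdown_percent[out$condition == "NTC"], 0)
  # 15 vs control mean 75 -> 20% expression, 80% knockdown
  res2 <- data.frame(condition = c("NTC", "NTC", "kd"),
                     percent_expressing = c(70, 80, 15))
  out2 <- normalize_to_control(res2, "NTC")
  expect_identical(out2$mean_normalized_expression[out2$condition == "kd"],
                   20)
  expect_identical(out2$knockdown_percent[out2$condition == "kd"], 80)
  # test equal to control mean -> zero knockdown
  res3 <- data.frame(condition = c("NTC", "kd"),
                     percent_expressing = c(60, 60))
  expect_identical(
    normalize_to_control(res3, "NTC")$knockdown_percent, c(0, 0))
})

test_that("normalization is idempotent and validates inputs", {
  res <- data.frame(condition = rep(c("NTC", "kd"), each = 4),
                    percent_expressing = c(48, 52, 50, 50, 9, 11, 10, 10))
  once <- normalize_to_control(res, "NTC")
  renorm <- normalize_to_control(
    data.frame(condition = rep("NTC", 4),
               percent_expressing = once$replicates[[
                 which(once$condition == "NTC")]]), "NTC")
  expect_identical(renorm$mean_normalized_expression, 100)
  expect_error(normalize_to_control(res, "missing"),
               class = "phenoarray_bad_arg")
  zero <- data.frame(condition = "NTC", percent_expressing = 0)
  expect_error(normalize_to_control(zero, "NTC"),
               class = "phenoarray_normalization_undefined")
})

test_that("knockdown_test matches the closed-form Student's t", {
  # identical groups
  same <- knockdown_test(c(10, 12, 11), c(10, 12, 11))
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  # the reference case: 6 degrees of freedom, p < 1e-4
  a <- c(10, 12, 11, 9); b <- c(100, 98, 102, 100)
  got <- knockdown_test(a, b)
  # closed-form oracle computed independently
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_ref <- 2 * pt(-abs(t_ref), 6)
  expect_equal(got$t_statistic, t_ref)
  expect_equal(got$p_value, p_ref)
  expect_lt(got$p_value, 1e-4)
  expect_identical(got$df, 6L)
  # agreement with the reference implementation
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t_statistic, unname(tt$statistic))
  expect_equal(got$p_value, tt$p.value)
  # symmetry: swapping groups negates t, keeps p
  swapped <- knockdown_test(b, a)
  expect_equal(swapped$t_statistic, -got$t_statistic)
  expect_equal(swapped$p_value, got$p_value)
  expect_error(knockdown_test(1, c(1, 2)), class = "phenoarray_bad_arg")
  expect_warning(knockdown_test(c(0, 100), c(50, 51)), "4-fold")
})

test_that("quantify_array composes the stages coherently", {
  layout <- test_grid(2, 2, control_idx = c(1L, 4L))
  # all-zero silenced fraction: knockdown ~ 0 within sampling error
  scene <- test_scene(layout, fraction = 0, seed = 55)
  q <- suppressWarnings(suppressMessages(
    quantify_array(scene$field, layout)))
  tests <- q$conditions[q$conditions$condition != "NTC", ]
  expect_lt(abs(tests$knockdown_percent), 5)
  # structure: every cell contributes to at most one spot result
  expect_identical(sum(q$spot_results$n_cells),
                   sum(!is.na(q$cells$assigned_spot_id)))
  expect_true(all(q$spot_results$n_expressing <=
                    q$spot_results$n_cells))
  expect_setequal(q$spot_results$spot_id, layout$spots$spot_id)
  # determinism of the full chain
  q2 <- suppressWarnings(suppressMessages(
    quantify_array(scene$field, layout)))
  expect_identical(q$conditions$mean_normalized_expression,
                   q2$conditions$mean_normalized_expression)
  expect_error(pipeline_config(bogus = 1), class = "phenoarray_bad_arg")
})
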