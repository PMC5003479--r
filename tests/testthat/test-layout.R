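test_that("plan_grid reproduces the standard-slide capacity", {
  layout <- plan_grid(76000, 26000, 300, 200, 2000)
  expect_identical(layout$n_cols, 144L)
  expect_identical(layout$n_rows, 44L)
  expect_identical(nrow(layout$spots), 144L * 44L)   # 6336
  expect_gte(nrow(layout$spots), 4000)
  # invariants: unique row-major ids, containment in the printable region
  expect_identical(layout$spots$spot_id, seq_len(6336L))
  expect_true(all(diff(order(layout$spots$row, layout$spots$col)) == 1))
  r <- layout$spot_diameter / 2
  expect_true(all(layout$spots$center_x - r >= 0 &
                    layout$spots$center_x + r <= 76000 - 2 * 2000))
  expect_true(all(layout$spots$center_y - r >= 0 &
                    layout$spots$center_y + r <= 26000 - 2 * 2000))
})

test_that("plan_grid errors on degenerate geometry", {
  expect_error(plan_grid(500, 500, 300, 200, 200),
               class = "phenoarray_zero_capacity")
  expect_error(plan_grid(-1, 26000, 300, 200, 2000),
               class = "phenoarray_bad_arg")
  expect_error(plan_grid(76000, 26000, 300, -5, 2000),
               class = "phenoarray_bad_arg")
})

test_that("closed-form capacity matches brute-force placement", {
  cases <- rbind(
    c(76000, 26000, 300, 200, 2000),
    c(20000, 20000, 300, 200, 500),
    c(5000, 3000, 250, 0, 100),
    c(1000, 1000, 300, 200, 100))
  withr::with_seed(99, {
    random <- cbind(runif(12, 2000, 50000), runif(12, 2000, 50000),
                    runif(12, 50, 500), runif(12, 0, 400),
                    runif(12, 0, 800))
  })
  for (i in seq_len(nrow(cases))) {
    g <- plan_grid(cases[i, 1], cases[i, 2], cases[i, 3], cases[i, 4],
                   cases[i, 5])
    expect_identical(g$n_rows * g$n_cols,
                     brute_force_capacity(cases[i, 1], cases[i, 2],
                                          cases[i, 3], cases[i, 4],
                                          cases[i, 5]))
  }
  for (i in seq_len(nrow(random))) {
    bf <- brute_force_capacity(random[i, 1], random[i, 2], random[i, 3],
                               random[i, 4], random[i, 5])
    if (bf == 0L) {
      expect_error(do.call(plan_grid, as.list(random[i, ])),
                   class = "phenoarray_zero_capacity")
    } else {
      g <- do.call(plan_grid, as.list(random[i, ]))
      expect_identical(g$n_rows * g$n_cols, bf)
    }
  }
})

test_that("capacity is monotone in geometry parameters", {
  base <- c(sw = 30000, sh = 20000, d = 300, gap = 200, m = 1000)
  cap <- function(p) {
    g <- plan_grid(p["sw"], p["sh"], p["d"], p["gap"], p["m"])
    g$n_rows * g$n_cols
  }
  c0 <- cap(base)
  for (delta in c(50, 137, 400)) {
    up <- base; up["d"] <- up["d"] + delta
    expect_lte(cap(up), c0)
    up <- base; up["gap"] <- up["gap"] + delta
    expect_lte(cap(up), c0)
    up <- base; up["m"] <- up["m"] + delta
    expect_lte(cap(up), c0)
    up <- base; up["sw"] <- up["sw"] + delta
    expect_gte(cap(up), c0)
    up <- base; up["sh"] <- up["sh"] + delta
    expect_gte(cap(up), c0)
  }
})

test_that("allocate_controls hits exact seeded counts", {
  roles <- allocate_controls(3888, 0.16, seed = 5)
  expect_identical(sum(roles == "negative_control"), 622L)
  expect_identical(sum(allocate_controls(100, 0, 1) ==
                         "negative_control"), 0L)
  expect_identical(sum(allocate_controls(100, 1, 1) ==
                         "negative_control"), 100L)
  # reproducible scatter, and different seeds scatter differently
  expect_identical(allocate_controls(500, 0.16, 7),
                   allocate_controls(500, 0.16, 7))
  expect_false(identical(allocate_controls(500, 0.16, 7),
                         allocate_controls(500, 0.16, 8)))
  expect_error(allocate_controls(100, 1.5, 1),
               class = "phenoarray_bad_arg")
  # half-up rounding: 25 * 0.5 rounds to 13, not 12
  expect_identical(sum(allocate_controls(25, 0.5, 1) ==
                         "negative_control"), 13L)
})

test_that("partition_library fills a 5-array genome set exactly", {
  labels <- sprintf("gene_%05d", seq_len(16330))
  plan <- partition_library(labels, 5, 3888, 0.16)
  expect_identical(plan$controls_per_array, 622)
  per_array <- vapply(plan$assignments, function(a)
    c(ctrl = sum(a$role == "negative_control"),
      test = sum(a$role == "test"),
      blank = sum(a$role == "blank")), c(ctrl = 0, test = 0, blank = 0))
  expect_true(all(per_array["ctrl", ] == 622))
  expect_true(all(per_array["blank", ] == 0))     # fits exactly
  assigned <- unlist(lapply(plan$assignments, function(a)
    a$reagent_label[a$role == "test"]))
  expect_setequal(assigned, labels)
  expect_false(anyDuplicated(assigned) > 0)
  # control count conservation across the plan
  expect_identical(sum(per_array["ctrl", ]), 5 * 622)
})

test_that("partition_library handles blanks and capacity errors", {
  plan <- partition_library("only_one", 1, 4, 0)
  a <- plan$assignments[[1]]
  expect_identical(sum(a$role == "test"), 1L)
  expect_identical(sum(a$role == "blank"), 3L)
  expect_error(
    partition_library(sprintf("g%05d", seq_len(20000)), 5, 3888, 0.16),
    class = "phenoarray_capacity_exceeded")
  expect_error(partition_library(c("a", "a"), 1, 4, 0),
               class = "phenoarray_bad_arg")
})

test_that("set_spot_roles validates and labels spots", {
  layout <- subset_grid(plan_grid(), 1:2, 1:2)
  out <- set_spot_roles(layout, c("negative_control", "test", "test",
                                  "test"), labels = c("a", "b"))
  expect_identical(out$spots$role,
                   c("negative_control", "test", "test", "blank"))
  expect_identical(out$spots$reagent_label[1:3], c("NTC", "a", "b"))
  expect_error(set_spot_roles(layout, rep("weird", 4)),
               class = "phenoarray_bad_arg")
})
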