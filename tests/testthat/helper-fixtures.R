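# Shared fixtures: all synthetic, built in code at test time.

# a small printed grid (nr x nc spots at the default 300/500 um geometry)
# with controls on the main diagonal and one shared test reagent
test_grid <- function(nr = 2, nc = 2, control_idx = 1L,
                      test_label = "siRNA_X") {
  layout <- subset_grid(plan_grid(), seq_len(nr), seq_len(nc))
  roles <- rep("test", nr * nc)
  roles[control_idx] <- "negative_control"
  set_spot_roles(layout, roles,
                 labels = rep(test_label, sum(roles == "test")))
}

# scene over a grid with controls silenced at 0 and tests at `fraction`
test_scene <- function(layout, fraction = 0.8, seed = 1, ...) {
  ctrl <- layout$spots$spot_id[layout$spots$role == "negative_control"]
  test <- layout$spots$spot_id[layout$spots$role == "test"]
  fr <- stats::setNames(c(rep(0, length(ctrl)), rep(fraction, length(test))),
                        c(ctrl, test))
  render_field(scene_params(layout = layout,
                            per_spot_silenced_fraction = fr,
                            seed = seed, ...))
}

# paint hard-edged discs into a matrix (independent of the C++ renderer)
paint_discs_r <- function(nr, nc, cx, cy, radius, value, background = 0) {
  m <- matrix(background, nr, nc)
  for (i in seq_along(cx)) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if ((r - cy[i])^2 + (c - cx[i])^2 <= radius[i]^2)
        m[r, c] <- max(m[r, c], value[i])
    }
  }
  m
}

# brute-force grid capacity: iterate candidate centres at the stated pitch
# and test containment in the printable region
brute_force_capacity <- function(slide_width, slide_height, spot_diameter,
                                 edge_gap, margin) {
  pitch <- spot_diameter + edge_gap
  usable_w <- slide_width - 2 * margin
  usable_h <- slide_height - 2 * margin
  count_axis <- function(usable) {
    n <- 0L
    center <- spot_diameter / 2
    while (center + spot_diameter / 2 <= usable + 1e-9) {
      n <- n + 1L
      center <- center + pitch
    }
    n
  }
  count_axis(usable_w) * count_axis(usable_h)
}
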