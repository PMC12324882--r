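test_that("curvature recovers circles, lines and helices", {
  circ <- make_helix_centerline(2e-3, 0, n_points = 200L)$centerline
  expect_equal(average_curvature(circ), 500, tolerance = 0.005)

  line <- centerline(seq(0, 1e-2, length.out = 100),
                     seq(0, 1e-2, length.out = 100),
                     seq(0, 2e-2, length.out = 100))
  expect_lt(average_curvature(line), 1e-8)

  hx <- make_helix_centerline(1e-3, 1e-3, n_points = 500L)$centerline
  expect_equal(average_curvature(hx), 500, tolerance = 0.01)

  expect_error(average_curvature(circ[1:2, ]), "at least 3")
  expect_error(centerline(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)), "duplicate")
})

test_that("torsion recovers helices, vanishes on planar curves, ignores handedness", {
  circ <- make_helix_centerline(2e-3, 0, n_points = 200L)$centerline
  expect_lt(average_torsion(circ), 1e-6)

  hx <- make_helix_centerline(1e-3, 1e-3, n_points = 500L)$centerline
  expect_equal(average_torsion(hx), 500, tolerance = 0.01)

  neg <- make_helix_centerline(1e-3, -1e-3, n_points = 500L)$centerline
  expect_equal(average_torsion(hx), average_torsion(neg), tolerance = 1e-10)

  expect_warning(tors <- average_torsion(
    centerline(seq(0, 1e-2, length.out = 50), rep(0, 50),
               seq(0, 1e-2, length.out = 50))), "Frenet")
  expect_equal(tors, 0)
})

test_that("curvature and torsion are invariant under rigid motion", {
  hx <- make_helix_centerline(1e-3, 1e-3, n_points = 500L)$centerline
  k0 <- average_curvature(hx)
  t0 <- average_torsion(hx)
  for (seed in 1:5) {
    Q <- random_rotation(seed)
    moved <- apply_rigid(hx, Q, shift = c(0.01, -0.02, 0.005) * seed)
    expect_equal(average_curvature(moved), k0, tolerance = 1e-8)
    expect_equal(average_torsion(moved), t0, tolerance = 1e-8)
  }
})

test_that("curvature/torsion estimates converge with refinement", {
  errs <- sapply(c(60L, 120L, 240L), function(n) {
    hx <- make_helix_centerline(1e-3, 1e-3, n_points = n)$centerline
    c(abs(average_curvature(hx) - 500), abs(average_torsion(hx) - 500))
  })
  # curvature: observed order >= 1 on each halving of the spacing
  expect_gt(errs[1, 1] / errs[1, 2], 2)
  expect_gt(errs[1, 2] / errs[1, 3], 2)
  # torsion on the uniform helix is exact to discretisation noise already
  expect_lt(max(errs[2, ]) / 500, 1e-5)
})

test_that("mean diameter is the arc-length-weighted average", {
  n <- 101L
  unif <- centerline(rep(0, n), rep(0, n), seq(0, 0.02, length.out = n),
                     radius = rep(1e-3, n))
  expect_equal(mean_diameter(unif), 2e-3)
  taper <- centerline(rep(0, n), rep(0, n), seq(0, 0.02, length.out = n),
                      radius = seq(1e-3, 2e-3, length.out = n))
  expect_equal(mean_diameter(taper), 3e-3, tolerance = 1e-12)
  expect_equal(mean_diameter(taper, window = c(0, 0.01)),
               mean_diameter(taper[taper$arc_length <= 0.01, ]))
  expect_error(mean_diameter(taper, window = c(0.5, 0.6)), "fewer than 2")
  expect_error(mean_diameter(centerline(0:1, 0:1, 0:1)), "radius")
})

test_that("stenosis delineation finds the minimum and spans two reference diameters", {
  tube <- make_stenosed_tube(3e-3, 0.5, 20e-3, 40e-3)
  reg <- delineate_stenosis(tube, detection_threshold = 0.2)
  expect_equal(reg$s_min_diameter, 20e-3, tolerance = 1e-4)
  expect_equal(reg$degree, 0.5, tolerance = 0.02)
  expect_equal(reg$reference_diameter, 3e-3, tolerance = 0.02)
  expect_equal(reg$s_start, 14e-3, tolerance = 0.02)
  expect_equal(reg$s_end, 26e-3, tolerance = 0.02)

  flat <- make_stenosed_tube(3e-3, 0, 20e-3, 40e-3)
  expect_null(delineate_stenosis(flat, detection_threshold = 0.2))
  mild <- make_stenosed_tube(3e-3, 0.1, 20e-3, 40e-3)
  expect_null(delineate_stenosis(mild, detection_threshold = 0.2))
})

test_that("stenosis subdivision partitions the branch", {
  tube <- make_stenosed_tube(3e-3, 0.5, 20e-3, 40e-3)
  reg <- delineate_stenosis(tube)
  parts <- subdivide_segment(tube, reg)
  expect_equal(parts$region, c("pre_stenosis", "stenosed", "post_stenosis"))
  expect_equal(parts$s_start[1], 0)
  expect_equal(parts$s_end[3], 40e-3)
  expect_equal(parts$s_end[1], parts$s_start[2])
  expect_equal(parts$s_end[2], parts$s_start[3])
  # region hugging the branch start gives an empty pre range
  reg0 <- reg
  reg0$s_start <- 0
  p0 <- subdivide_segment(tube, reg0)
  expect_equal(p0$s_end[1] - p0$s_start[1], 0)
  bad <- reg
  bad$s_end <- 1
  expect_error(subdivide_segment(tube, bad), "outside")
})

test_that("small-branch trimming truncates at the first crossing and cascades", {
  n <- 101L
  z <- seq(0, 0.03, length.out = n)
  taper <- centerline(rep(0, n), rep(0, n), z,
                      radius = seq(2e-3, 0.5e-3, length.out = n),
                      label = "inlet")
  # diameter crosses 2 mm (r = 1e-3) two thirds of the way along, z = 0.02
  ok_branch <- straight_branch(1.5e-3, label = "child")
  small <- straight_branch(0.5e-3, label = "grandchild")
  tree <- vessel_tree(
    list(inlet = taper, child = ok_branch, grandchild = small),
    tibble::tibble(parent = c("inlet", "child"),
                   child_main = c("child", "grandchild"),
                   child_side = c(NA_character_, NA_character_)),
    inlet = "inlet")
  trimmed <- trim_small_branches(tree, 2e-3)
  expect_lt(max(trimmed$branches$inlet$arc_length), 0.0201)
  expect_gt(max(trimmed$branches$inlet$arc_length), 0.0192)
  expect_true(all(2 * trimmed$branches$inlet$radius >= 2e-3))
  expect_false("grandchild" %in% names(trimmed$branches))
  expect_true("child" %in% names(trimmed$branches))

  # all-above-threshold tree is untouched
  big <- vessel_tree(list(a = straight_branch(2e-3, label = "a")),
                     tibble::tibble(parent = character(),
                                    child_main = character(),
                                    child_side = character()), "a")
  expect_identical(trim_small_branches(big, 2e-3)$branches$a, big$branches$a)

  tiny <- vessel_tree(list(a = straight_branch(0.5e-3, label = "a")),
                      tibble::tibble(parent = character(),
                                     child_main = character(),
                                     child_side = character()), "a")
  expect_error(trim_small_branches(tiny, 2e-3), "inlet")
})

test_that("vessel tree validation catches broken topology", {
  a <- straight_branch(2e-3, label = "a")
  b <- straight_branch(1.5e-3, label = "b")
  expect_error(vessel_tree(list(a = a, b = b),
                           tibble::tibble(parent = "a", child_main = "c",
                                          child_side = "b"), "a"),
               "missing branch")
  expect_error(vessel_tree(list(a = a, b = b),
                           tibble::tibble(parent = character(),
                                          child_main = character(),
                                          child_side = character()), "a"),
               "unreachable")
})
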