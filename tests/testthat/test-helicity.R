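test_that("curl reconstruction is exact for rigid rotation and translation", {
  mesh <- make_cylinder_mesh(2e-3, 1e-2, 500L)
  ct <- mesh$cell_tbl
  omega <- c(3, -2, 5)
  rot <- tibble::tibble(
    cell = ct$cell, time = 0, x = ct$x, y = ct$y, z = ct$z,
    volume = ct$volume, segment = "tube",
    vx = omega[2] * ct$z - omega[3] * ct$y,
    vy = omega[3] * ct$x - omega[1] * ct$z,
    vz = omega[1] * ct$y - omega[2] * ct$x)
  f <- add_vorticity(rot, mesh$neighbors)
  expect_equal(f$wx, rep(2 * omega[1], nrow(f)), tolerance = 1e-9)
  expect_equal(f$wy, rep(2 * omega[2], nrow(f)), tolerance = 1e-9)
  expect_equal(f$wz, rep(2 * omega[3], nrow(f)), tolerance = 1e-9)

  trans <- dplyr::mutate(rot, vx = 0.1, vy = -0.2, vz = 0.3)
  ft <- add_vorticity(trans, mesh$neighbors)
  expect_lt(max(abs(c(ft$wx, ft$wy, ft$wz))), 1e-9)
})

test_that("swirl phantom vorticity and helicity density match the analytic curl", {
  ph <- oracle_swirl(mesh_density = 2000L)
  f <- add_vorticity(ph$field, ph$mesh$neighbors)
  # omega_z = 2 Omega everywhere (including near the axis)
  expect_equal(f$wz, rep(20, nrow(f)), tolerance = 0.02)
  hd <- helicity_density(f)
  expect_equal(hd$helicity, rep(4, nrow(hd)), tolerance = 0.02)
  # numeric curl agrees with the generator's analytic vorticity
  fa <- oracle_swirl(mesh_density = 2000L, analytic_vorticity = TRUE)$field
  expect_equal(f$wx, fa$wx, tolerance = 1e-6)
  expect_equal(f$wz, fa$wz, tolerance = 1e-6)
})

test_that("bulk descriptors recover the phantom ground truths", {
  ph <- oracle_swirl(mesh_density = 2000L)
  b <- bulk_descriptors(add_vorticity(ph$field, ph$mesh$neighbors))
  expect_equal(b$h1, 4, tolerance = 0.02)
  expect_equal(b$h2, 4, tolerance = 0.02)
  expect_equal(b$h3, 1, tolerance = 1e-6)
  expect_equal(b$h4, 1, tolerance = 1e-6)

  bal <- make_swirling_pipe(mean_flow = 1e-6, swirl_rate = 10,
                            handedness_layout = "counter_balanced",
                            mesh_density = 2000L)
  bb <- bulk_descriptors(add_vorticity(bal$field, bal$mesh$neighbors))
  expect_lt(abs(bb$h1), 0.01 * bb$h2)
  expect_lt(abs(bb$h3), 0.01)
  expect_lt(bb$h4, 0.01)

  imb <- make_swirling_pipe(mean_flow = 1e-6, swirl_rate = 10,
                            handedness_layout = "counter_imbalanced",
                            dominant_fraction = 0.75, mesh_density = 4000L)
  bi <- bulk_descriptors(add_vorticity(imb$field, imb$mesh$neighbors))
  expect_equal(bi$h3, 2 * imb$truth$phi_achieved - 1, tolerance = 0.05)
})

test_that("h2 dominates |h1| and ratios are undefined at zero intensity", {
  wave <- waveform_spec(0.8, "cosine_offset", cycle_mean = 1e-6)
  for (layout in c("single", "counter_imbalanced")) {
    ph <- make_swirling_pipe(mean_flow = 1e-6, swirl_rate = 10,
                             handedness_layout = layout,
                             waveform = wave, n_time_steps = 5L,
                             mesh_density = 500L,
                             analytic_vorticity = TRUE)
    b <- bulk_descriptors(ph$field)
    expect_gte(b$h2, abs(b$h1))
    expect_equal(b$h4, abs(b$h3))
  }
  still <- oracle_swirl(mesh_density = 500L, analytic_vorticity = TRUE)$field |>
    dplyr::mutate(vx = 0, vy = 0, vz = 0, wx = 0, wy = 0, wz = 1)
  b0 <- bulk_descriptors(still)
  expect_identical(b0$status, "zero_intensity")
  expect_true(is.na(b0$h3) && is.na(b0$h4))
})

test_that("sub-region descriptors volume-recombine to the whole-domain h1", {
  ph <- oracle_swirl(mesh_density = 1000L, analytic_vorticity = TRUE)
  f <- helicity_density(ph$field)
  zb <- quantile(f$z, c(1 / 3, 2 / 3))
  cells <- dplyr::distinct(f, cell, z)
  parts <- list(cells$cell[cells$z <= zb[1]],
                cells$cell[cells$z > zb[1] & cells$z <= zb[2]],
                cells$cell[cells$z > zb[2]])
  sub <- purrr::map_dfr(parts, function(p) bulk_descriptors(f, region = p))
  whole <- bulk_descriptors(f)
  expect_equal(sum(sub$h1 * sub$volume) / sum(sub$volume), whole$h1,
               tolerance = 1e-10)
  expect_equal(sum(sub$volume), whole$volume, tolerance = 1e-12)
})

test_that("pulsatile descriptors follow the quasi-steady closed form", {
  wave <- waveform_spec(0.8, "cosine_offset", cycle_mean = 1e-6,
                        shape_params = list(amplitude = 0.5))
  ph <- make_swirling_pipe(mean_flow = 1e-6, swirl_rate = 10,
                           waveform = wave, n_time_steps = 17L,
                           mesh_density = 1000L, analytic_vorticity = TRUE)
  b <- bulk_descriptors(ph$field)
  # mean of s(t)^2 = 1 + amplitude^2 / 2 for the offset cosine
  expect_equal(ph$truth$h1_ref,
               2 * ph$truth$u_max * 10 * (1 + 0.5^2 / 2), tolerance = 1e-6)
  expect_equal(b$h1, ph$truth$h1_ref, tolerance = 0.01)
})

test_that("LNH is the cosine between velocity and vorticity", {
  ph <- oracle_swirl(mesh_density = 1000L, analytic_vorticity = TRUE)
  ln <- lnh_field(ph$field)
  expect_true(all(ln$lnh >= -1 & ln$lnh <= 1))
  # near the axis v is parallel to w: LNH -> 1
  near_axis <- ln[sqrt(ln$x^2 + ln$y^2) < 2e-4, ]
  expect_true(all(near_axis$lnh > 0.99))
  # mirrored swirl flips the sign pointwise
  ph2 <- make_swirling_pipe(tube_radius = 2e-3, tube_length = 2e-2,
                            mean_flow = 0.2 * pi * (2e-3)^2 / 2,
                            swirl_rate = -10, mesh_density = 1000L,
                            analytic_vorticity = TRUE)
  ln2 <- lnh_field(ph2$field)
  expect_equal(ln2$lnh, -ln$lnh, tolerance = 1e-12)

  # planar shear: v orthogonal to w gives 0
  shear <- tibble::tibble(cell = 1:4, time = 0, x = 0, y = c(1, 2, 3, 4),
                          z = 0, volume = 1, segment = "s",
                          vx = c(1, 2, 3, 4), vy = 0, vz = 0,
                          wx = 0, wy = 0, wz = -1)
  expect_equal(lnh_field(shear)$lnh, rep(0, 4))
  # epsilon floor silences near-zero products
  still <- dplyr::mutate(shear, vx = 0)
  expect_equal(lnh_field(still)$lnh, rep(0, 4))

  avg <- lnh_cycle_average(ln)
  expect_equal(nrow(avg), dplyr::n_distinct(ln$cell))
  expect_true(all(abs(avg$lnh_mean) <= 1))
})

test_that("segment assignment maps cells to the nearest labelled centerline", {
  ph <- oracle_swirl(mesh_density = 500L)
  n <- 41L
  ref <- dplyr::bind_rows(
    centerline(rep(0, n), rep(0, n), seq(0, 0.01, length.out = n),
               label = "proximal"),
    centerline(rep(0, n), rep(0, n), seq(0.0101, 0.02, length.out = n),
               label = "distal"))
  f <- assign_segments(ph$field, ref)
  expect_setequal(unique(f$segment), c("proximal", "distal"))
  expect_true(all(f$segment[f$z < 0.005] == "proximal"))
  expect_true(all(f$segment[f$z > 0.015] == "distal"))
})
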