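test_that("swirl phantom ground truth matches hand-derived closed forms", {
  ph <- oracle_swirl(mesh_density = 500L)
  # H = 2 U Omega with U = 0.2, Omega = 10
  expect_equal(ph$truth$h1_ref, 4.0)
  expect_equal(ph$truth$h2_ref, 4.0)
  expect_equal(ph$truth$h3_ref, 1)
  expect_equal(ph$truth$h4_ref, 1)
  # independent evaluation of the Poiseuille wall shear 4 mu Q / (pi R^3)
  ph2 <- make_swirling_pipe(tube_radius = 1.5e-3, mean_flow = 1e-6,
                            swirl_rate = 0, mu = 0.00345,
                            mesh_density = 500L)
  expect_equal(ph2$truth$taess_ref,
               4 * 0.00345 * 1e-6 / (pi * (1.5e-3)^3), tolerance = 1e-12)
  expect_equal(ph2$truth$taess_ref, 1.302, tolerance = 2e-3)
})

test_that("counter-rotating layouts cancel or bias the signed helicity", {
  bal <- make_swirling_pipe(mean_flow = 1e-6, swirl_rate = 10,
                            handedness_layout = "counter_balanced",
                            mesh_density = 500L)
  expect_equal(bal$truth$h1_ref, 0)
  expect_equal(bal$truth$h3_ref, 0)
  expect_equal(bal$truth$h4_ref, 0)
  expect_equal(bal$truth$h2_ref, 2 * bal$truth$u_max * 10)
  imb <- make_swirling_pipe(mean_flow = 1e-6, swirl_rate = 10,
                            handedness_layout = "counter_imbalanced",
                            dominant_fraction = 0.75, mesh_density = 500L)
  expect_equal(imb$truth$h3_ref, 2 * imb$truth$phi_achieved - 1)
  expect_equal(imb$truth$phi_achieved, 0.75, tolerance = 0.05)
  expect_error(make_swirling_pipe(swirl_rate = 0,
                                  handedness_layout = "counter_balanced",
                                  mesh_density = 500L),
               "degenerate")
})

test_that("the velocity samples honour the analytic profile", {
  ph <- oracle_swirl(mesh_density = 500L)
  f <- ph$field
  r <- sqrt(f$x^2 + f$y^2)
  U <- ph$truth$u_max
  expect_equal(f$vz, U * (1 - r^2 / (2e-3)^2))
  utheta <- sqrt(f$vx^2 + f$vy^2)
  expect_equal(utheta, 10 * r)
  # generators are deterministic
  ph2 <- oracle_swirl(mesh_density = 500L)
  expect_identical(ph$field, ph2$field)
})

test_that("reversal wall phantom carries exact OSI ground truth", {
  expect_equal(make_reversal_wall_series(1, 0)$truth$osi_ref, 0)
  expect_equal(make_reversal_wall_series(1, 0.5)$truth$osi_ref, 0.5)
  rv <- make_reversal_wall_series(1, 0.25)
  expect_equal(rv$truth$osi_ref, 0.25)
  expect_equal(rv$truth$taess_ref, 1)
  # hand/quadrature oracle: 0.5 * (1 - |signed integral| / |abs integral|)
  w1 <- dplyr::filter(rv$wall, element == 1)
  expect_equal(0.5 * (1 - abs(trapz(w1$time, w1$taux)) /
                        trapz(w1$time, abs(w1$taux))),
               0.25, tolerance = 1e-12)
  expect_error(make_reversal_wall_series(-1, 0.2), "non-negative")
  expect_error(make_reversal_wall_series(1, 0.6), "reversed_fraction")
})

test_that("helix phantom encodes the standard curvature/torsion closed form", {
  hx <- make_helix_centerline(1e-3, 1e-3)
  expect_equal(hx$truth$curvature_ref, 500)   # a/(a^2+b^2) in 1/m
  expect_equal(hx$truth$torsion_ref, 500)
  circ <- make_helix_centerline(2e-3, 0, n_points = 200L)
  expect_equal(circ$truth$curvature_ref, 500)
  expect_equal(circ$truth$torsion_ref, 0)
  # unsigned torsion: handedness is ignored
  neg <- make_helix_centerline(1e-3, -1e-3)
  expect_equal(neg$truth$torsion_ref, 500)
  expect_error(make_helix_centerline(0, 0), "degenerate")
})

test_that("stenosed tube narrows to the prescribed diameter at the centre", {
  tube <- make_stenosed_tube(3e-3, 0.5, 20e-3, 40e-3)
  i_min <- which.min(tube$radius)
  expect_equal(2 * tube$radius[i_min], 1.5e-3, tolerance = 1e-9)
  expect_equal(tube$arc_length[i_min], 20e-3, tolerance = 40e-3 / 400)
  tube7 <- make_stenosed_tube(3e-3, 0.7, 20e-3, 40e-3)
  expect_equal(2 * min(tube7$radius), 0.9e-3, tolerance = 1e-9)
  flat <- make_stenosed_tube(3e-3, 0, 20e-3, 40e-3)
  expect_equal(diff(range(flat$radius)), 0)
  expect_error(make_stenosed_tube(3e-3, 0.5, 2e-3, 40e-3), "extent")
  expect_error(make_stenosed_tube(3e-3, 0.95, 20e-3, 40e-3), "degree")
})

test_that("group-sample generator plants rank correlations and is seeded", {
  t1 <- make_group_samples(20, effect = c(h2 = 1), planted_rho = 0.5,
                           seed = 7)
  t2 <- make_group_samples(20, effect = c(h2 = 1), planted_rho = 0.5,
                           seed = 7)
  expect_identical(t1, t2)
  t3 <- make_group_samples(20, planted_rho = 0.5, seed = 8)
  expect_false(identical(t1$value, t3$value))

  big <- make_group_samples(1000, planted_rho = 0.9, seed = 1)
  wide <- tidyr::pivot_wider(big, id_cols = c("case", "group"),
                             names_from = "descriptor",
                             values_from = "value")
  expect_equal(cor(wide$h2, wide$taess_avg, method = "spearman"), 0.9,
               tolerance = 0.05)
  null <- make_group_samples(1000, planted_rho = 0, seed = 2)
  wn <- tidyr::pivot_wider(null, id_cols = c("case", "group"),
                           names_from = "descriptor", values_from = "value")
  expect_lt(abs(cor(wn$h2, wn$taess_avg, method = "spearman")), 0.05)
  expect_error(make_group_samples(20, planted_rho = 1.2), "planted_rho")
  expect_error(make_group_samples(2), "at least 3")
})
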