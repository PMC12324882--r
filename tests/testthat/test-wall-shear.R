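test_that("TAESS averages the shear magnitude over the cycle", {
  # constant 2 Pa vector stays 2 Pa
  w <- tidyr::expand_grid(element = 1:3, time = seq(0, 1, by = 0.25)) |>
    dplyr::mutate(taux = 2, tauy = 0, tauz = 0, area = 1e-6,
                  segment = "wall")
  expect_equal(wall_descriptors(w)$taess, rep(2, 3))
  # sign flips leave the magnitude average unchanged
  wf <- dplyr::mutate(w, taux = ifelse(time > 0.5, -2, 2))
  expect_equal(wall_descriptors(wf)$taess, rep(2, 3))
  # steady Poiseuille phantom: 4 mu Q / (pi R^3)
  ph <- make_swirling_pipe(tube_radius = 1.5e-3, mean_flow = 1e-6,
                           swirl_rate = 0, mu = 0.00345, mesh_density = 500L)
  ref <- 4 * 0.00345 * 1e-6 / (pi * (1.5e-3)^3)
  expect_equal(wall_descriptors(ph$wall)$taess,
               rep(ref, nrow(ph$mesh$wall)), tolerance = 0.02)
  expect_equal(ref, 1.302, tolerance = 1e-3)
})

test_that("OSI hits the reversal-fraction closed forms exactly", {
  for (f in c(0, 0.25, 0.5)) {
    rv <- make_reversal_wall_series(1, f, n_steps = 16L)
    d <- wall_descriptors(rv$wall)
    expect_equal(d$osi, rep(f, nrow(d)), tolerance = 1e-10)
    expect_equal(d$taess, rep(1, nrow(d)), tolerance = 1e-12)
  }
  # all-zero history is flagged, OSI defined as 0
  z <- make_reversal_wall_series(0, 0.25)$wall
  dz <- wall_descriptors(z)
  expect_equal(dz$osi, rep(0, nrow(dz)))
  expect_true(all(dz$status == "zero_shear"))
})

test_that("RRT obeys its identity, including the pole", {
  expect_equal(rrt(tibble::tibble(taess = 2, osi = 0))$rrt, 0.5)
  expect_equal(rrt(tibble::tibble(taess = 1.302, osi = 0.25))$rrt,
               1 / (0.5 * 1.302), tolerance = 1e-12)
  expect_equal(rrt(tibble::tibble(taess = 1.302, osi = 0.25))$rrt, 1.536,
               tolerance = 1e-3)
  expect_equal(rrt(tibble::tibble(taess = 2, osi = 0.5))$rrt, Inf)
  expect_equal(rrt(tibble::tibble(taess = 0, osi = 0))$rrt, Inf)
  # element-wise identity on random descriptor tables
  set.seed(11)
  d <- tibble::tibble(taess = runif(50, 0.1, 6), osi = runif(50, 0, 0.49))
  expect_equal(rrt(d)$rrt, 1 / ((1 - 2 * d$osi) * d$taess),
               tolerance = 1e-12)
  expect_true(all(rrt(d)$rrt >= 1 / d$taess))
})

test_that("adverse-area fractions follow strict thresholds and partition", {
  th <- adverse_thresholds()
  base <- tibble::tibble(element = 1:2, area = c(1e-6, 1e-6),
                         segment = "w", osi = 0, rrt = 1)
  uni <- dplyr::mutate(base, taess = 0.3)
  fr <- adverse_area_fractions(uni, th)
  expect_equal(fr$low_taess_pct, 100)
  expect_equal(fr$high_taess_pct, 0)
  # half the area at 5 Pa, half at 2 Pa
  half <- dplyr::mutate(base, taess = c(5, 2))
  expect_equal(adverse_area_fractions(half, th)$high_taess_pct, 50)
  # element exactly at a threshold is not counted (strict comparison)
  edge <- dplyr::mutate(base, taess = c(0.5, 4.71))
  fe <- adverse_area_fractions(edge, th)
  expect_equal(fe$low_taess_pct, 0)
  expect_equal(fe$high_taess_pct, 0)
  expect_equal(fe$mid_taess_pct, 100)
  # infinite RRT counts as exceeding
  inf <- dplyr::mutate(base, taess = 1, rrt = c(Inf, 1))
  expect_equal(adverse_area_fractions(inf, th)$rrt_pct, 50)
  expect_error(adverse_area_fractions(uni[0, ], th), "empty")
})

test_that("TAESS band fractions always sum to 100", {
  th <- adverse_thresholds()
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:60, 1)
    d <- tibble::tibble(element = seq_len(n),
                        area = runif(n, 1e-8, 1e-5),
                        segment = sample(c("LAD", "LCx"), n, replace = TRUE),
                        taess = rlnorm(n, log(1.5), 1),
                        osi = runif(n, 0, 0.5))
    d <- rrt(d)
    fr <- adverse_area_fractions(d, th)
    expect_equal(fr$low_taess_pct + fr$mid_taess_pct + fr$high_taess_pct,
                 rep(100, nrow(fr)), tolerance = 1e-9)
    expect_true(all(fr$osi_pct >= 0 & fr$osi_pct <= 100))
  }
})

test_that("segment mean TAESS is the area-weighted average", {
  d <- tibble::tibble(element = 1:2, area = c(1, 3), segment = "w",
                      taess = c(2, 4))
  expect_equal(segment_mean_taess(d)$taess_avg, 3.5)
  expect_equal(segment_mean_taess(d[2:1, ])$taess_avg, 3.5)
  uni <- tibble::tibble(element = 1:5, area = 2, segment = "w", taess = 1.7)
  expect_equal(segment_mean_taess(uni)$taess_avg, 1.7)
})

test_that("descriptors are invariant under joint rigid rotation", {
  rv <- make_reversal_wall_series(1.5, 0.25, n_steps = 16L)
  d0 <- wall_descriptors(rv$wall)
  Q <- random_rotation(3)
  rot <- rv$wall
  tau <- cbind(rot$taux, rot$tauy, rot$tauz) %*% t(Q)
  rot$taux <- tau[, 1]; rot$tauy <- tau[, 2]; rot$tauz <- tau[, 3]
  d1 <- wall_descriptors(rot)
  expect_equal(d1$taess, d0$taess, tolerance = 1e-12)
  expect_equal(d1$osi, d0$osi, tolerance = 1e-12)
})

test_that("wall shear derived from velocity is exact for linear shear", {
  # Couette-like: u = (g y, 0, 0), wall at y = 0 with inward normal +y
  gshear <- 120
  d <- 5e-4
  field <- tibble::tibble(cell = 1L, time = 0, x = 0, y = d, z = 0,
                          volume = 1, segment = "w",
                          vx = gshear * d, vy = 0, vz = 0)
  wallm <- tibble::tibble(element = 1L, x = 0, y = 0, z = 0,
                          nx = 0, ny = 1, nz = 0, area = 1e-6, cell = 1L)
  ws <- wss_from_velocity(field, wallm, rheology = 0.003)
  expect_equal(ws$taux, 0.003 * gshear, tolerance = 1e-12)
  expect_equal(ws$tauy, 0)
  # Carreau-Yasuda viscosity is evaluated at the wall shear rate
  cy <- carreau_yasuda()
  ws2 <- wss_from_velocity(field, wallm, rheology = cy)
  expect_equal(ws2$taux, viscosity(gshear, cy) * gshear, tolerance = 1e-12)
})

test_that("velocity-derived Poiseuille wall shear approximates the closed form", {
  ph <- make_swirling_pipe(tube_radius = 1.5e-3, mean_flow = 1e-6,
                           swirl_rate = 0, mu = 0.00345,
                           mesh_density = 4000L)
  ws <- wss_from_velocity(ph$field, ph$mesh$wall, rheology = 0.00345)
  ref <- 4 * 0.00345 * 1e-6 / (pi * (1.5e-3)^3)
  d <- wall_descriptors(ws)
  expect_equal(mean(d$taess), ref, tolerance = 0.05)
  # shear points along the flow axis
  expect_true(all(ws$tauz > 0))
  expect_lt(max(abs(ws$taux)), 1e-12)
})

test_that("no-slip violations and missing adjacency are reported", {
  field <- tibble::tibble(cell = 1L, time = 0, x = 0, y = 1e-3, z = 0,
                          volume = 1, segment = "w", vx = 1, vy = 0, vz = 0)
  wallm <- tibble::tibble(element = 1L, x = 0, y = 0, z = 0, nx = 0, ny = 1,
                          nz = 0, area = 1e-6, cell = 1L,
                          wvx = 0.1, wvy = 0, wvz = 0)
  expect_warning(wss_from_velocity(field, wallm), "no-slip")
  orphan <- tibble::tibble(element = 1L, x = 0, y = 0, z = 0, nx = 0, ny = 1,
                           nz = 0, area = 1e-6, cell = 99L)
  expect_error(wss_from_velocity(field, orphan), "adjacent")
})
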