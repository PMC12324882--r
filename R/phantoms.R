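# Analytic flow phantoms with closed-form ground truth. They stand in for
# CFD exports so every descriptor stage can be validated without solver data.

#' Swirling pipe-flow phantom
#'
#' Axial Poiseuille flow `u_z(r) = U (1 - r^2/R^2)` with `U = 2Q/(pi R^2)`
#' superposed with solid-body swirl `u_theta(r) = Omega r`. The helicity
#' density of this field is uniform, `v . w = 2 U Omega`, which makes every
#' bulk helicity descriptor available in closed form. Solid-body swirl exerts
#' no wall shear, so the wall shear vector is purely axial with magnitude
#' `4 mu Q / (pi R^3)` (Newtonian `mu`). Pulsatile variants scale the whole
#' velocity field quasi-steadily by `Q(t)/Q_mean`.
#'
#' Handedness layouts: `"single"` applies `Omega` everywhere;
#' `"counter_balanced"` splits the tube into two mirror angular halves with
#' `+Omega` and `-Omega` (net helicity cancels exactly);
#' `"counter_imbalanced"` gives an angular volume fraction `dominant_fraction`
#' the positive handedness, so the signed balance is `h3 = 2 phi - 1`. The
#' fraction is snapped to the nearest angular sector boundary and the achieved
#' value is recorded in the ground truth.
#'
#' @param tube_radius Tube radius R (m).
#' @param tube_length Tube length (m).
#' @param mean_flow Cycle-mean volumetric flow Q (m^3/s).
#' @param swirl_rate Solid-body angular velocity Omega (rad/s).
#' @param handedness_layout `"single"`, `"counter_balanced"` or
#'   `"counter_imbalanced"`.
#' @param waveform Optional [waveform_spec()]; `NULL` gives a steady field
#'   with a single snapshot.
#' @param mesh_density Target cell count (>= 100).
#' @param mu Newtonian dynamic viscosity used for the wall-shear truth (Pa s).
#' @param dominant_fraction Volume fraction of the dominant handedness for the
#'   imbalanced layout.
#' @param n_time_steps Snapshots per cycle for pulsatile variants.
#' @param analytic_vorticity If `TRUE`, attach the exact vorticity columns
#'   (`wx`, `wy`, `wz`) to the field; by default vorticity is left for
#'   [add_vorticity()] to reconstruct numerically.
#' @param seed Unused for this deterministic generator; accepted for API
#'   uniformity.
#' @return A list of class `swirl_phantom`: `field` (long tibble: cell, time,
#'   x, y, z, volume, segment, vx, vy, vz), `wall` (long tibble: element,
#'   time, taux, tauy, tauz, area, segment), `mesh` (the [make_cylinder_mesh()]
#'   object), `truth` (one-row tibble of closed-form descriptor values) and
#'   `period`.
#' @examples
#' ph <- make_swirling_pipe(mean_flow = 0.2 * pi * 2e-3^2 / 2,
#'                          swirl_rate = 10, mesh_density = 500)
#' ph$truth$h1_ref   # 2 * U * Omega
#' @export
make_swirling_pipe <- function(tube_radius = 2e-3, tube_length = 2e-2,
                               mean_flow = 1e-6, swirl_rate = 10,
                               handedness_layout = c("single",
                                                     "counter_balanced",
                                                     "counter_imbalanced"),
                               waveform = NULL, mesh_density = 4000L,
                               mu = 0.00345, dominant_fraction = 0.75,
                               n_time_steps = 9L,
                               analytic_vorticity = FALSE, seed = NULL) {
  handedness_layout <- match.arg(handedness_layout)
  stopifnot_positive(tube_radius, "tube_radius")
  stopifnot_positive(tube_length, "tube_length")
  stopifnot_positive(mean_flow, "mean_flow")
  if (handedness_layout != "single" && swirl_rate == 0) {
    abort("counter-rotating layouts are degenerate with `swirl_rate = 0`.")
  }
  mesh <- make_cylinder_mesh(tube_radius, tube_length, mesh_density)
  R <- tube_radius
  U <- 2 * mean_flow / (pi * R^2)

  nt <- mesh$n_angular
  ct <- mesh$cell_tbl
  phi <- switch(handedness_layout,
    single = 1,
    counter_balanced = 0.5,
    counter_imbalanced = round(dominant_fraction * nt) / nt
  )
  sgn <- if (handedness_layout == "single") {
    rep(1, nrow(ct))
  } else {
    ifelse(ct$j < round(phi * nt), 1, -1)
  }
  omega_c <- swirl_rate * sgn

  if (is.null(waveform)) {
    times <- 0
    scales <- 1
    period <- 1
  } else {
    period <- waveform$period
    times <- seq(0, period, length.out = n_time_steps)
    scales <- waveform_eval(waveform, times) / waveform$cycle_mean
  }

  one_step <- function(t, s) {
    f <- tibble(
      cell = ct$cell, time = t,
      x = ct$x, y = ct$y, z = ct$z,
      volume = ct$volume, segment = "tube",
      vx = s * (-omega_c * ct$y),
      vy = s * (omega_c * ct$x),
      vz = s * U * (1 - ct$r^2 / R^2)
    )
    if (analytic_vorticity) {
      wth <- s * 2 * U * ct$r / R^2        # azimuthal vorticity -du_z/dr
      f$wx <- -wth * sin(ct$theta)
      f$wy <- wth * cos(ct$theta)
      f$wz <- s * 2 * omega_c
    }
    f
  }
  field <- purrr::map2_dfr(times, scales, one_step)

  tau_mag <- 4 * mu * mean_flow / (pi * R^3)
  wl <- mesh$wall
  wall <- purrr::map2_dfr(times, scales, function(t, s) {
    tibble(element = wl$element, time = t,
           taux = 0, tauy = 0, tauz = s * tau_mag,
           area = wl$area, segment = "tube")
  })

  # time averages of the quasi-steady scale factor, dense quadrature
  if (is.null(waveform)) {
    m_s2 <- 1; m_abs <- 1; osi_ref <- 0
  } else {
    td <- seq(0, period, length.out = 4001L)
    sd_ <- waveform_eval(waveform, td) / waveform$cycle_mean
    m_s2 <- trapz(td, sd_^2) / period
    m_abs <- trapz(td, abs(sd_)) / period
    osi_ref <- 0.5 * (1 - abs(trapz(td, sd_)) / trapz(td, abs(sd_)))
  }

  h1 <- 2 * U * swirl_rate * (2 * phi - 1) * m_s2
  h2 <- 2 * U * abs(swirl_rate) * m_s2
  taess_ref <- tau_mag * m_abs
  truth <- tibble(
    h1_ref = h1, h2_ref = h2,
    h3_ref = if (h2 > 0) h1 / h2 else NA_real_,
    h4_ref = if (h2 > 0) abs(h1) / h2 else NA_real_,
    taess_ref = taess_ref, osi_ref = osi_ref,
    rrt_ref = 1 / ((1 - 2 * osi_ref) * taess_ref),
    curvature_ref = NA_real_, torsion_ref = NA_real_,
    u_max = U, omega = swirl_rate, phi_achieved = phi, mu = mu
  )

  structure(list(field = field, wall = wall, mesh = mesh, truth = truth,
                 period = period, waveform = waveform,
                 layout = handedness_layout),
            class = "swirl_phantom")
}

#' @export
print.swirl_phantom <- function(x, ...) {
  cat(sprintf("<swirl_phantom> layout=%s, %d cells, %d snapshot(s)\n",
              x$layout, nrow(x$mesh$cell_tbl),
              length(unique(x$field$time))))
  print(x$truth[, c("h1_ref", "h2_ref", "h3_ref", "h4_ref", "taess_ref")])
  invisible(x)
}

#' Piecewise-constant reversing wall-shear phantom
#'
#' A wall shear vector of fixed magnitude points forward (+x) for
#' `(1 - f) T` and backward for `f T`. For this signal the oscillatory shear
#' index is exactly `f` and the time-averaged magnitude is `magnitude`. The
#' discontinuity time appears twice in the series (a duplicated node), so
#' trapezoidal time integration reproduces the closed forms exactly.
#'
#' @param magnitude Shear magnitude (Pa), non-negative.
#' @param reversed_fraction Fraction `f` of the period with reversed shear,
#'   in `[0, 0.5]`.
#' @param period Cycle period T (s).
#' @param n_steps Total number of time nodes (>= 4).
#' @param n_elements Number of identical wall elements to emit.
#' @param area Per-element area (m^2).
#' @return A list with `wall` (long tibble: element, time, taux, tauy, tauz,
#'   area, segment) and `truth` (tibble: taess_ref, osi_ref, rrt_ref).
#' @export
make_reversal_wall_series <- function(magnitude, reversed_fraction,
                                      period = 1, n_steps = 16L,
                                      n_elements = 4L, area = 1e-6) {
  if (magnitude < 0) abort("`magnitude` must be non-negative.")
  if (reversed_fraction < 0 || reversed_fraction > 0.5) {
    abort("`reversed_fraction` must lie in [0, 0.5].")
  }
  if (n_steps < 4) abort("`n_steps` must be at least 4.")
  stopifnot_positive(period, "period")
  f <- reversed_fraction
  a <- (1 - f) * period
  if (f == 0) {
    times <- seq(0, period, length.out = n_steps)
    vals <- rep(magnitude, n_steps)
  } else {
    n_fwd <- max(2L, ceiling((1 - f) * n_steps))
    n_bwd <- max(2L, n_steps - n_fwd)
    times <- c(seq(0, a, length.out = n_fwd), seq(a, period, length.out = n_bwd))
    vals <- c(rep(magnitude, n_fwd), rep(-magnitude, n_bwd))
  }
  wall <- tidyr::expand_grid(element = seq_len(n_elements),
                             idx = seq_along(times)) |>
    mutate(time = times[.data$idx], taux = vals[.data$idx],
           tauy = 0, tauz = 0, area = area, segment = "wall") |>
    select(-"idx")
  osi_ref <- f
  truth <- tibble(
    taess_ref = magnitude, osi_ref = osi_ref,
    rrt_ref = if (magnitude > 0 && osi_ref < 0.5) {
      1 / ((1 - 2 * osi_ref) * magnitude)
    } else {
      Inf
    }
  )
  list(wall = wall, truth = truth, period = period)
}

#' Helical centerline phantom
#'
#' Samples the helix `(a cos t, a sin t, b t)`; its curvature and torsion are
#' the closed forms `a / (a^2 + b^2)` and `|b| / (a^2 + b^2)` (torsion is
#' reported unsigned, so handedness does not matter).
#'
#' @param helix_radius Helix radius `a` (m); `b = 0` gives a planar circle.
#' @param pitch_param Pitch parameter `b` (m per radian).
#' @param n_points Number of samples (>= 10).
#' @param turns Number of full turns sampled.
#' @param lumen_radius Optional constant lumen radius to attach (m).
#' @return A list with `centerline` (tibble: x, y, z, arc_length, radius,
#'   label) and `truth` (tibble: curvature_ref, torsion_ref, 1/m).
#' @export
make_helix_centerline <- function(helix_radius, pitch_param, n_points = 500L,
                                  turns = 2, lumen_radius = NULL) {
  a <- helix_radius; b <- pitch_param
  if (n_points < 10) abort("`n_points` must be at least 10.")
  if (a == 0 && b == 0) abort("degenerate curve: helix_radius = pitch_param = 0.")
  th <- seq(0, 2 * pi * turns, length.out = n_points)
  cl <- centerline(a * cos(th), a * sin(th), b * th,
                   radius = if (is.null(lumen_radius)) NULL else
                     rep(lumen_radius, n_points),
                   label = "helix")
  truth <- tibble(curvature_ref = a / (a^2 + b^2),
                  torsion_ref = abs(b) / (a^2 + b^2))
  list(centerline = cl, truth = truth)
}

#' Straight tube centerline with a smooth stenosis
#'
#' The radius profile is the base radius narrowed by a cosine bell reaching
#' `(1 - degree)` of the base diameter at `stenosis_center`.
#'
#' @param base_diameter Healthy lumen diameter (m).
#' @param stenosis_degree Fractional diameter reduction, in (0, 0.9).
#' @param stenosis_center Arc-length position of the minimum (m).
#' @param segment_length Total tube length (m).
#' @param n_points Number of samples along the tube.
#' @param bell_halfwidth Half-extent of the cosine bell (m); defaults to two
#'   base diameters, matching the stenosis-region convention.
#' @return A centerline tibble (x, y, z, arc_length, radius, label).
#' @export
make_stenosed_tube <- function(base_diameter, stenosis_degree,
                               stenosis_center, segment_length,
                               n_points = 401L,
                               bell_halfwidth = 2 * base_diameter) {
  stopifnot_positive(base_diameter, "base_diameter")
  if (stenosis_degree < 0 || stenosis_degree >= 0.9) {
    abort("`stenosis_degree` must lie in [0, 0.9).")
  }
  if (stenosis_degree > 0 &&
      (stenosis_center - bell_halfwidth < 0 ||
       stenosis_center + bell_halfwidth > segment_length)) {
    abort("stenosis extent exceeds the segment.")
  }
  s <- seq(0, segment_length, length.out = n_points)
  r0 <- base_diameter / 2
  bell <- ifelse(abs(s - stenosis_center) <= bell_halfwidth,
                 0.5 * (1 + cos(pi * (s - stenosis_center) / bell_halfwidth)),
                 0)
  radius <- r0 * (1 - stenosis_degree * bell)
  centerline(rep(0, n_points), rep(0, n_points), s,
             radius = radius, label = "tube")
}

#' Synthetic per-segment descriptor table with planted effects
#'
#' Draws two labelled groups of cases. Each descriptor is Gaussian around a
#' physiologically plausible baseline; the `stenosed` group is shifted by
#' `effect` (in units of each descriptor's s.d.). One descriptor pair is drawn
#' from a Gaussian copula whose rank correlation targets `planted_rho` (the
#' bivariate-normal Pearson parameter is `2 sin(pi rho / 6)`, so the
#' population Spearman correlation equals `planted_rho`).
#'
#' @param n_per_group Cases per group (>= 3).
#' @param effect Named numeric vector of location shifts (s.d. units) applied
#'   to the `stenosed` group, e.g. `c(h2 = 2)`.
#' @param planted_rho Target Spearman correlation of `rho_pair`, in `[-1, 1]`.
#' @param seed Integer seed; the table is reproducible bit-for-bit.
#' @param rho_pair Character vector of the two correlated descriptors.
#' @param segment Segment label for the generated rows.
#' @param baselines,sds Named numeric vectors of descriptor means and s.d.s.
#' @return A tidy segment table: tibble (case, group, segment, descriptor,
#'   value).
#' @export
make_group_samples <- function(n_per_group, effect = c(), planted_rho = 0,
                               seed = 1L,
                               rho_pair = c("h2", "taess_avg"),
                               segment = "LAD",
                               baselines = c(h1 = 5, h2 = 15, h3 = 0.2,
                                             h4 = 0.45, taess_avg = 2.5,
                                             low_taess_pct = 12,
                                             high_taess_pct = 6,
                                             osi_pct = 1.5, rrt_pct = 4),
                               sds = NULL) {
  if (n_per_group < 3) abort("`n_per_group` must be at least 3.")
  if (!is.finite(planted_rho) || abs(planted_rho) > 1) {
    abort("`planted_rho` must lie in [-1, 1].")
  }
  desc <- names(baselines)
  if (!all(rho_pair %in% desc)) abort("`rho_pair` must name two descriptors.")
  if (is.null(sds)) sds <- setNames(pmax(abs(baselines) * 0.3, 0.1), desc)
  if (!is.null(effect) && length(effect) && !all(names(effect) %in% desc)) {
    abort("`effect` names must be descriptors.")
  }

  with_seed(seed, {
    n <- 2L * n_per_group
    r <- 2 * sin(pi * planted_rho / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    zs <- lapply(desc, function(d) {
      if (d == rho_pair[1]) z1
      else if (d == rho_pair[2]) z2
      else stats::rnorm(n)
    })
    names(zs) <- desc
    group <- rep(c("non_stenosed", "stenosed"), each = n_per_group)
    case <- sprintf("case_%03d", seq_len(n))
    purrr::map_dfr(desc, function(d) {
      shift <- if (d %in% names(effect)) effect[[d]] else 0
      tibble(case = case, group = group, segment = segment, descriptor = d,
             value = baselines[[d]] + sds[[d]] *
               (zs[[d]] + ifelse(group == "stenosed", shift, 0)))
    }) |>
      arrange(.data$case, .data$descriptor)
  })
}
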