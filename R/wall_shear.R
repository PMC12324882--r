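# Wall shear descriptors: TAESS, OSI, RRT and adverse-exposure area
# fractions at the standard thresholds.

#' Adverse haemodynamic thresholds
#'
#' The literature thresholds for adverse wall-shear exposure: time-averaged
#' endothelial shear stress below 0.5 Pa (low) or above 4.71 Pa (high),
#' oscillatory shear index above 0.1, relative residence time above
#' 4.17 Pa^-1. Comparisons are strict, matching the "less than"/"greater
#' than" definitions.
#'
#' @param low_taess,high_taess TAESS thresholds (Pa).
#' @param high_osi OSI threshold (dimensionless).
#' @param high_rrt RRT threshold (Pa^-1).
#' @return A list of class `adverse_thresholds`.
#' @export
adverse_thresholds <- function(low_taess = 0.5, high_taess = 4.71,
                               high_osi = 0.1, high_rrt = 4.17) {
  if (!(low_taess > 0 && high_taess > low_taess)) {
    abort("need 0 < low_taess < high_taess.")
  }
  stopifnot_positive(high_osi, "high_osi")
  stopifnot_positive(high_rrt, "high_rrt")
  structure(list(low_taess = low_taess, high_taess = high_taess,
                 high_osi = high_osi, high_rrt = high_rrt),
            class = "adverse_thresholds")
}

wall_series_check <- function(wall) {
  need <- c("element", "time", "taux", "tauy", "tauz", "area")
  if (!all(need %in% names(wall))) {
    abort(sprintf("wall series needs columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (any(!is.finite(wall$taux) | !is.finite(wall$tauy) |
            !is.finite(wall$tauz))) {
    abort("wall shear vectors must be finite.")
  }
  if (any(wall$area <= 0)) abort("element areas must be positive.")
  invisible(wall)
}

#' Per-element wall shear descriptors: TAESS, OSI and RRT
#'
#' TAESS is the trapezoidal time average of the wall shear vector magnitude
#' `(1/T) int |tau_w| dt`; OSI is
#' `0.5 (1 - |int tau_w dt| / int |tau_w| dt)` clamped to `[0, 0.5]` (defined
#' as 0 where the shear history is identically zero); RRT is
#' `1 / ((1 - 2 OSI) TAESS)`, infinite where `OSI = 0.5` or `TAESS = 0`.
#' A single-snapshot series is treated as steady (instantaneous magnitude,
#' OSI 0).
#'
#' @param wall Long wall-series tibble: `element`, `time`, `taux`, `tauy`,
#'   `tauz` (Pa), `area` (m^2), optional `segment`.
#' @return Tibble (element, area, segment, taess, osi, rrt, status).
#' @export
wall_descriptors <- function(wall) {
  wall_series_check(wall)
  if (is.null(wall[["segment"]])) wall$segment <- "wall"
  steady <- dplyr::n_distinct(wall$time) == 1L
  out <- wall |>
    group_by(.data$element, .data$area, .data$segment) |>
    arrange(.data$time, .by_group = TRUE) |>
    summarise(
      mag_int = trapz(.data$time, sqrt(.data$taux^2 + .data$tauy^2 +
                                         .data$tauz^2)),
      vx = trapz(.data$time, .data$taux),
      vy = trapz(.data$time, .data$tauy),
      vz = trapz(.data$time, .data$tauz),
      mag0 = sqrt(.data$taux[1]^2 + .data$tauy[1]^2 + .data$tauz[1]^2),
      .groups = "drop")
  if (steady) {
    out <- out |>
      mutate(taess = .data$mag0, osi = 0,
             status = ifelse(.data$taess == 0, "zero_shear", "steady"))
  } else {
    Tt <- max(wall$time) - min(wall$time)
    out <- out |>
      mutate(
        taess = .data$mag_int / Tt,
        osi = ifelse(.data$mag_int > 0,
                     pmin(0.5, pmax(0, 0.5 * (1 -
                       sqrt(.data$vx^2 + .data$vy^2 + .data$vz^2) /
                         .data$mag_int))),
                     0),
        status = ifelse(.data$mag_int == 0, "zero_shear", "ok"))
  }
  out |>
    mutate(rrt = 1 / ((1 - 2 * .data$osi) * .data$taess)) |>
    select("element", "area", "segment", "taess", "osi", "rrt", "status")
}

#' Time-averaged endothelial shear stress per element
#'
#' @inheritParams wall_descriptors
#' @return Tibble (element, area, segment, taess, status).
#' @export
taess <- function(wall) {
  select(wall_descriptors(wall), "element", "area", "segment", "taess",
         "status")
}

#' Oscillatory shear index per element
#'
#' @inheritParams wall_descriptors
#' @return Tibble (element, area, segment, osi, status).
#' @export
osi <- function(wall) {
  select(wall_descriptors(wall), "element", "area", "segment", "osi",
         "status")
}

#' Relative residence time from computed descriptors
#'
#' `RRT = 1 / ((1 - 2 OSI) TAESS)`; the pole at `OSI = 0.5` or `TAESS = 0`
#' yields `Inf`, which exceeds any finite threshold.
#'
#' @param descriptors Tibble with `taess` and `osi` columns.
#' @return The input with an `rrt` column added/replaced.
#' @export
rrt <- function(descriptors) {
  mutate(descriptors, rrt = 1 / ((1 - 2 * .data$osi) * .data$taess))
}

#' Adverse-exposure area fractions per segment
#'
#' Percentage of each segment's lumen area exposed beyond the adverse
#' thresholds (strict comparisons): `lowTAESS%` (taess < low), `highTAESS%`
#' (taess > high), `OSI%` (osi > threshold), `RRT%` (rrt > threshold;
#' infinite RRT counts as exceeding). `midTAESS%` (the inclusive in-between
#' band) is reported too, so the three TAESS fractions partition 100%.
#'
#' @param descriptors Per-element descriptor tibble from
#'   [wall_descriptors()] (needs element, area, segment, taess, osi, rrt).
#' @param thresholds An [adverse_thresholds()] set.
#' @return Tibble per segment: segment, area, low_taess_pct, mid_taess_pct,
#'   high_taess_pct, osi_pct, rrt_pct.
#' @export
adverse_area_fractions <- function(descriptors,
                                   thresholds = adverse_thresholds()) {
  if (!nrow(descriptors)) abort("empty descriptor table.")
  th <- thresholds
  out <- descriptors |>
    group_by(.data$segment) |>
    summarise(
      total_area = sum(.data$area),
      low_taess_pct = 100 * sum(.data$area[.data$taess < th$low_taess]) /
        .data$total_area,
      mid_taess_pct = 100 * sum(.data$area[.data$taess >= th$low_taess &
                                             .data$taess <= th$high_taess]) /
        .data$total_area,
      high_taess_pct = 100 * sum(.data$area[.data$taess > th$high_taess]) /
        .data$total_area,
      osi_pct = 100 * sum(.data$area[.data$osi > th$high_osi]) /
        .data$total_area,
      rrt_pct = 100 * sum(.data$area[.data$rrt > th$high_rrt]) /
        .data$total_area,
      .groups = "drop") |>
    rename(area = "total_area") |>
    # guard the percentages against round-off creeping past the bounds
    mutate(across(dplyr::ends_with("_pct"), ~ pmin(100, pmax(0, .x))))
  if (any(out$area <= 0)) abort("segment with non-positive total area.")
  out
}

#' Area-weighted mean TAESS per segment
#'
#' @param descriptors Per-element descriptor tibble with `taess` and `area`.
#' @return Tibble (segment, taess_avg).
#' @export
segment_mean_taess <- function(descriptors) {
  if (!nrow(descriptors)) abort("empty descriptor table.")
  descriptors |>
    group_by(.data$segment) |>
    summarise(taess_avg = sum(.data$taess * .data$area) / sum(.data$area),
              .groups = "drop")
}

#' Derive a wall shear series from near-wall velocities
#'
#' Fallback for exports that carry no solver-computed wall shear: for each
#' wall element, the velocity at the adjacent interior cell centroid is
#' projected onto the wall tangent plane and differenced one-sidedly against
#' the no-slip wall over the wall-normal distance. The apparent viscosity is
#' evaluated at the resulting shear rate (Carreau-Yasuda) or held constant
#' (Newtonian). Exact for linear shear profiles with constant viscosity.
#'
#' @param field Flow-field tibble (cell, time, x, y, z, vx, vy, vz).
#' @param wall_mesh Wall-element tibble with `element`, `x`, `y`, `z` (face
#'   centroid), `nx`, `ny`, `nz` (inward unit normal), `area`, `cell`
#'   (adjacent interior cell id), optional `segment` and optional wall
#'   velocity `wvx`, `wvy`, `wvz`.
#' @param rheology A [carreau_yasuda()] set, or a single Newtonian viscosity
#'   (Pa s).
#' @return A long wall-series tibble (element, time, taux, tauy, tauz, area,
#'   segment).
#' @export
wss_from_velocity <- function(field, wall_mesh, rheology = 0.00345) {
  need <- c("element", "x", "y", "z", "nx", "ny", "nz", "area", "cell")
  if (!all(need %in% names(wall_mesh))) {
    abort(sprintf("wall mesh needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (all(c("wvx", "wvy", "wvz") %in% names(wall_mesh)) &&
      any(abs(c(wall_mesh$wvx, wall_mesh$wvy, wall_mesh$wvz)) > 0)) {
    warn("wall velocities are nonzero: no-slip assumption violated.")
  }
  wm <- wall_mesh |>
    rename(xw = "x", yw = "y", zw = "z")
  if (is.null(wm[["segment"]])) wm$segment <- "wall"
  joined <- dplyr::inner_join(
    wm, select(field, "cell", "time", "x", "y", "z", "vx", "vy", "vz"),
    by = "cell", relationship = "many-to-many")
  if (dplyr::n_distinct(joined$element) < nrow(wm)) {
    abort("wall element without an adjacent interior cell in the field.")
  }
  joined <- joined |>
    mutate(
      dn = (.data$x - .data$xw) * .data$nx + (.data$y - .data$yw) * .data$ny +
        (.data$z - .data$zw) * .data$nz)
  if (any(joined$dn <= 0)) {
    abort("adjacent cell centroid is not on the inward side of the wall.")
  }
  joined |>
    mutate(
      un = .data$vx * .data$nx + .data$vy * .data$ny + .data$vz * .data$nz,
      utx = .data$vx - .data$un * .data$nx,
      uty = .data$vy - .data$un * .data$ny,
      utz = .data$vz - .data$un * .data$nz,
      shear_rate = sqrt(.data$utx^2 + .data$uty^2 + .data$utz^2) / .data$dn,
      mu = if (inherits(rheology, "carreau_yasuda")) {
        viscosity(.data$shear_rate, rheology)
      } else {
        rheology
      },
      taux = .data$mu * .data$utx / .data$dn,
      tauy = .data$mu * .data$uty / .data$dn,
      tauz = .data$mu * .data$utz / .data$dn
    ) |>
    select("element", "time", "taux", "tauy", "tauz", "area", "segment") |>
    arrange(.data$time, .data$element)
}
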