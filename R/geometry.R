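# Centerline differential geometry: average absolute curvature (tortuosity),
# unsigned torsion, diameters, stenosis delineation and segment bookkeeping.

#' Construct a centerline tibble
#'
#' A centerline is an ordered 3D polyline with cumulative arc length and an
#' optional per-point maximal-inscribed-sphere radius.
#'
#' @param x,y,z Point coordinates (m).
#' @param radius Optional per-point lumen radius (m), positive.
#' @param label Segment label (e.g. "LAD").
#' @return A tibble with columns x, y, z, arc_length, (radius), label.
#' @export
centerline <- function(x, y, z, radius = NULL, label = "segment") {
  n <- length(x)
  if (length(y) != n || length(z) != n) abort("x, y, z lengths differ.")
  if (n < 2) abort("a centerline needs at least 2 points.")
  seg <- sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2)
  if (any(seg == 0)) abort("duplicate consecutive points on the centerline.")
  out <- tibble(x = x, y = y, z = z, arc_length = c(0, cumsum(seg)))
  if (!is.null(radius)) {
    if (length(radius) != n || any(radius <= 0)) {
      abort("`radius` must be positive and match the number of points.")
    }
    out$radius <- radius
  }
  out$label <- label
  out
}

# Resample a centerline to uniform arc-length spacing via cubic spline
# interpolation of each coordinate against arc length. With smooth > 0 a
# smoothing spline (spar = smooth) replaces pure interpolation.
resample_centerline <- function(curve, spacing = NULL, smooth = 0) {
  s <- curve$arc_length
  L <- s[length(s)]
  if (is.null(spacing)) spacing <- stats::median(diff(s))
  ns <- max(length(s), ceiling(L / spacing) + 1L)
  su <- seq(0, L, length.out = ns)
  fit1 <- function(v) {
    if (smooth > 0 && length(s) >= 10) {
      stats::predict(stats::smooth.spline(s, v, spar = smooth), su)$y
    } else {
      stats::spline(s, v, xout = su, method = "natural")$y
    }
  }
  out <- tibble(x = fit1(curve$x), y = fit1(curve$y), z = fit1(curve$z),
                arc_length = su)
  if (!is.null(curve[["radius"]])) {
    out$radius <- pmax(stats::spline(s, curve$radius, xout = su,
                                     method = "natural")$y, .Machine$double.eps)
  }
  out$label <- curve$label[1]
  out
}

# Central finite-difference derivatives on a uniform grid (matrix columns =
# coordinates). Order: d1, d2 via 3-point central; d3 via 5-point central.
fd_derivatives <- function(P, h) {
  n <- nrow(P)
  idx <- 3:(n - 2L)
  d1 <- (P[idx + 1L, , drop = FALSE] - P[idx - 1L, , drop = FALSE]) / (2 * h)
  d2 <- (P[idx + 1L, , drop = FALSE] - 2 * P[idx, , drop = FALSE] +
           P[idx - 1L, , drop = FALSE]) / h^2
  d3 <- (P[idx + 2L, , drop = FALSE] - 2 * P[idx + 1L, , drop = FALSE] +
           2 * P[idx - 1L, , drop = FALSE] - P[idx - 2L, , drop = FALSE]) /
    (2 * h^3)
  list(idx = idx, d1 = d1, d2 = d2, d3 = d3)
}

geometry_prep <- function(curve, spacing, smooth, min_points) {
  if (nrow(curve) < min_points) {
    abort(sprintf("centerline needs at least %d points.", min_points))
  }
  rs <- resample_centerline(curve, spacing = spacing, smooth = smooth)
  P <- cbind(rs$x, rs$y, rs$z)
  h <- rs$arc_length[2] - rs$arc_length[1]
  c(fd_derivatives(P, h), list(h = h, s = rs$arc_length))
}

#' Average absolute curvature (tortuosity) of a centerline
#'
#' Evaluates the arc-length-normalised curvature integral
#' `(1/L) int |c' x c''| / |c'|^3 ds` on an arc-length-uniform resampling of
#' the curve, with derivatives from central finite differences. The estimate
#' is invariant under rigid motion and uniform reparameterisation.
#'
#' @param curve A [centerline()] tibble (>= 3 points).
#' @param spacing Resampling arc-length step (m); defaults to the native
#'   median spacing.
#' @param smooth Smoothing-spline `spar` in (0, 1]; 0 (default) interpolates.
#' @return Average curvature (1/m).
#' @export
average_curvature <- function(curve, spacing = NULL, smooth = 0) {
  g <- geometry_prep(curve, spacing, smooth, min_points = 3L)
  cx <- cross3(g$d1, g$d2)
  kappa <- rownorm(cx) / rownorm(g$d1)^3
  si <- g$s[g$idx]
  trapz(si, kappa) / (si[length(si)] - si[1])
}

#' Average unsigned torsion of a centerline
#'
#' Evaluates `(1/L) int |(c' x c'') . c'''| / |c' x c''|^2 ds` on the same
#' resampled support as [average_curvature()]. The numerator's absolute value
#' makes the result independent of handedness. Points where curvature
#' (numerically) vanishes are masked from the integral; if the whole curve is
#' straight the result is 0 with a warning about the undefined Frenet frame.
#'
#' @inheritParams average_curvature
#' @param curvature_tol Relative tolerance below which `|c' x c''|` is
#'   treated as zero and masked.
#' @return Average torsion (1/m), non-negative.
#' @export
average_torsion <- function(curve, spacing = NULL, smooth = 0,
                            curvature_tol = 1e-8) {
  g <- geometry_prep(curve, spacing, smooth, min_points = 4L)
  cx <- cross3(g$d1, g$d2)
  nrm2 <- rowSums(cx * cx)
  scale <- rownorm(g$d1)^3
  ok <- sqrt(nrm2) > curvature_tol * scale
  if (!any(ok)) {
    warn("curvature vanishes everywhere: Frenet frame undefined, torsion = 0.")
    return(0)
  }
  tau <- numeric(length(nrm2))
  tau[ok] <- abs(rowSums(cx[ok, , drop = FALSE] *
                           g$d3[ok, , drop = FALSE])) / nrm2[ok]
  si <- g$s[g$idx]
  trapz(si, tau) / (si[length(si)] - si[1])
}

#' Arc-length-weighted mean diameter
#'
#' @param curve A [centerline()] tibble with a `radius` column.
#' @param window Optional arc-length range `c(s_min, s_max)` (m); the whole
#'   curve by default.
#' @return Mean diameter (m).
#' @export
mean_diameter <- function(curve, window = NULL) {
  if (is.null(curve[["radius"]])) abort("centerline has no `radius` column.")
  s <- curve$arc_length
  d <- 2 * curve$radius
  if (!is.null(window)) {
    keep <- s >= window[1] & s <= window[2]
    if (sum(keep) < 2) abort("window selects fewer than 2 points.")
    s <- s[keep]; d <- d[keep]
  }
  trapz(s, d) / (s[length(s)] - s[1])
}

#' Locate and delineate a stenosis on a branch
#'
#' Finds the global minimum-diameter point, computes the stenosis degree
#' `1 - d_min / d_ref` against a reference diameter (the branch mean diameter
#' excluding a guard window of +/- `guard_factor * d_min` around the minimum)
#' and, if the degree reaches `detection_threshold`, returns the region
#' extending two reference diameters up- and downstream of the minimum,
#' clamped to the branch.
#'
#' @param curve A [centerline()] tibble with radii.
#' @param detection_threshold Minimum degree to report a stenosis.
#' @param guard_factor Half-width of the reference-exclusion window in units
#'   of the minimum diameter.
#' @param extent_diameters Region half-width in reference diameters.
#' @return A one-row tibble (branch, s_min_diameter, s_start, s_end, degree,
#'   reference_diameter, clamped) or `NULL` when no stenosis is detected.
#' @export
delineate_stenosis <- function(curve, detection_threshold = 0.2,
                               guard_factor = 3, extent_diameters = 2) {
  if (is.null(curve[["radius"]])) abort("centerline has no `radius` column.")
  s <- curve$arc_length
  d <- 2 * curve$radius
  i_min <- which.min(d)
  d_min <- d[i_min]
  s_min <- s[i_min]
  outside <- abs(s - s_min) > guard_factor * d_min
  d_ref <- if (sum(outside) >= 2) {
    mean_diameter(curve[outside, , drop = FALSE])
  } else {
    mean(d)
  }
  degree <- 1 - d_min / d_ref
  if (degree < detection_threshold) return(NULL)
  s0 <- s_min - extent_diameters * d_ref
  s1 <- s_min + extent_diameters * d_ref
  clamped <- s0 < s[1] || s1 > s[length(s)]
  if (clamped) {
    warn("stenosis region clamped to the branch extent.")
  }
  tibble(branch = curve$label[1],
         s_min_diameter = s_min,
         s_start = max(s0, s[1]), s_end = min(s1, s[length(s)]),
         degree = degree, reference_diameter = d_ref, clamped = clamped)
}

#' Subdivide a branch around a stenosis region
#'
#' Partitions the branch arc length into pre-stenosis, stenosed and
#' post-stenosis ranges. The three half-open ranges cover the branch exactly.
#'
#' @param curve A [centerline()] tibble.
#' @param region A stenosis region from [delineate_stenosis()].
#' @return A three-row tibble (region, s_start, s_end); empty pre/post ranges
#'   (zero length) are permitted when the region touches a branch end.
#' @export
subdivide_segment <- function(curve, region) {
  s0 <- curve$arc_length[1]
  s1 <- curve$arc_length[nrow(curve)]
  rs <- region$s_start
  re <- region$s_end
  if (rs < s0 || re > s1) {
    abort("stenosis region lies outside the branch.")
  }
  tibble(region = c("pre_stenosis", "stenosed", "post_stenosis"),
         s_start = c(s0, rs, re),
         s_end = c(rs, re, s1))
}

#' Summarise the geometry of one centerline
#'
#' One-stop tidy summary: average absolute curvature, average torsion, mean
#' diameter (when radii are present) and total length.
#'
#' @inheritParams average_curvature
#' @return A one-row tibble (label, length, curvature, torsion,
#'   mean_diameter).
#' @export
geometry_descriptors <- function(curve, spacing = NULL, smooth = 0) {
  tibble(
    label = curve$label[1],
    length = curve$arc_length[nrow(curve)] - curve$arc_length[1],
    curvature = average_curvature(curve, spacing, smooth),
    torsion = if (nrow(curve) >= 4) average_torsion(curve, spacing, smooth)
              else NA_real_,
    mean_diameter = if (!is.null(curve[["radius"]])) mean_diameter(curve)
                    else NA_real_
  )
}
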