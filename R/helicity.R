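# Helicity descriptors: vorticity reconstruction, helicity density, bulk
# descriptors h1-h4 and the local normalized helicity (LNH) field.

# Least-squares gradient reconstruction of per-cell vector data over
# neighbour stencils. The local model is quadratic (gradient + Hessian
# terms), so the recovered gradient is exact for any velocity field that is
# polynomial of degree <= 2 over the stencil -- in particular for affine
# fields and for parabolic (Poiseuille-type) profiles. Cells whose stencil
# cannot support the quadratic fit (< 9 well-conditioned neighbours) fall
# back to a regularised fit with a warning. Returns the 9 gradient
# components (d v_m / d x_j) as an n x 9 matrix.
ls_gradient <- function(X, V, pairs) {
  c_ <- pairs$cell
  nb <- pairs$nbr
  dx <- X[nb, , drop = FALSE] - X[c_, , drop = FALSE]
  du <- V[nb, , drop = FALSE] - V[c_, , drop = FALSE]
  # scale displacements to O(1) for conditioning
  h <- sqrt(stats::median(rowSums(dx * dx)))
  dx <- dx / h
  # quadratic basis: dx, dy, dz, dx^2/2, dy^2/2, dz^2/2, dxdy, dxdz, dydz
  B <- cbind(dx,
             dx[, 1]^2 / 2, dx[, 2]^2 / 2, dx[, 3]^2 / 2,
             dx[, 1] * dx[, 2], dx[, 1] * dx[, 3], dx[, 2] * dx[, 3])
  p <- ncol(B)
  # per-cell normal equations, accumulated with rowsum
  A_cols <- matrix(NA_real_, nrow(B), p * (p + 1) / 2)
  idx <- 1L
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  for (r in seq_len(nrow(ut))) {
    A_cols[, r] <- B[, ut[r, 1]] * B[, ut[r, 2]]
  }
  b_cols <- cbind(B * du[, 1], B * du[, 2], B * du[, 3])
  S <- rowsum(cbind(A_cols, b_cols), group = c_, reorder = TRUE)
  if (nrow(S) != nrow(X)) {
    abort("some cells have no neighbours; cannot reconstruct gradients.")
  }
  nA <- ncol(A_cols)
  g <- matrix(NA_real_, nrow(X), 9L)
  A <- matrix(0, p, p)
  up_lin <- (ut[, 2] - 1L) * p + ut[, 1]   # linear indices, upper triangle
  lo_lin <- (ut[, 1] - 1L) * p + ut[, 2]   # mirrored
  b_rng <- (nA + 1L):(nA + 3L * p)
  n_bad <- 0L
  for (cc in seq_len(nrow(S))) {
    vals <- S[cc, seq_len(nA)]
    A[up_lin] <- vals
    A[lo_lin] <- vals
    Bc <- matrix(S[cc, b_rng], p, 3L)
    beta <- tryCatch(solve(A, Bc), error = function(e) NULL)
    if (is.null(beta)) {
      n_bad <- n_bad + 1L
      beta <- solve(A + diag(1e-8 * mean(diag(A)), p), Bc)
    }
    g[cc, ] <- as.vector(beta[1:3, ]) / h
  }
  if (n_bad > 0L) {
    warn(sprintf(
      "%d cell(s) have a deficient (one-sided) stencil; gradients regularised.",
      n_bad))
  }
  g
}

#' Reconstruct the vorticity field from cell velocities
#'
#' Computes the curl of the velocity by least-squares linear gradient
#' reconstruction over each cell's neighbour stencil (exact for affine
#' velocity fields), per time snapshot.
#'
#' @param field A long flow-field tibble with columns `cell`, `time`, `x`,
#'   `y`, `z`, `vx`, `vy`, `vz` (as produced by [make_swirling_pipe()] or
#'   [read_flow_field()]).
#' @param neighbors Neighbour-pair tibble (`cell`, `nbr`), e.g.
#'   `mesh$neighbors` from [make_cylinder_mesh()].
#' @return The field with vorticity columns `wx`, `wy`, `wz` (1/s) added or
#'   replaced.
#' @export
add_vorticity <- function(field, neighbors) {
  stopifnot(all(c("cell", "time", "x", "y", "z", "vx", "vy", "vz") %in%
                  names(field)))
  out <- field |>
    group_by(.data$time) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$cell)
      X <- cbind(df$x, df$y, df$z)
      V <- cbind(df$vx, df$vy, df$vz)
      g <- ls_gradient(X, V, neighbors)
      # curl: (dvz/dy - dvy/dz, dvx/dz - dvz/dx, dvy/dx - dvx/dy)
      df$wx <- g[, 8] - g[, 6]
      df$wy <- g[, 3] - g[, 7]
      df$wz <- g[, 4] - g[, 2]
      df
    }) |>
    ungroup()
  out[, union(names(field), c("wx", "wy", "wz"))]
}

#' Pointwise helicity density
#'
#' The inner product `v . w` of velocity and vorticity per cell and time.
#'
#' @param field A flow-field tibble with velocity and vorticity columns (run
#'   [add_vorticity()] first if vorticity is absent).
#' @return The field with a `helicity` column (m/s^2) added.
#' @export
helicity_density <- function(field) {
  if (!all(c("wx", "wy", "wz") %in% names(field))) {
    abort("field has no vorticity; call add_vorticity() first.")
  }
  mutate(field, helicity = .data$vx * .data$wx + .data$vy * .data$wy +
           .data$vz * .data$wz)
}

#' Bulk helicity descriptors h1-h4
#'
#' Time-and-volume averages over one cardiac cycle:
#' `h1 = (1/(T V)) int_T int_V v . w dV dt` (signed average helicity),
#' `h2` the same with `|v . w|` (average helicity intensity), and the signed
#' and unsigned rotation-balance ratios `h3 = h1/h2`, `h4 = |h1|/h2`.
#' Volume integrals are volume-weighted cell sums; time integration is
#' trapezoidal over the snapshots (a single snapshot is treated as steady).
#'
#' @param field A flow-field tibble with `volume` and vorticity columns.
#' @param region Optional cell-id subset to restrict the volume of interest.
#' @param segment Optional segment label to restrict to (uses the `segment`
#'   column).
#' @return A one-row tibble (h1, h2, h3, h4, volume, n_cells, status). When
#'   `h2 = 0` the ratios are `NA` and the status flags the degeneracy.
#' @export
bulk_descriptors <- function(field, region = NULL, segment = NULL) {
  hd <- if ("helicity" %in% names(field)) field else helicity_density(field)
  if (!is.null(region)) hd <- filter(hd, .data$cell %in% region)
  if (!is.null(segment)) {
    seg <- segment
    hd <- filter(hd, .data$segment %in% seg)
  }
  if (!nrow(hd)) abort("empty region.")
  per_t <- hd |>
    group_by(.data$time) |>
    summarise(sh = sum(.data$volume * .data$helicity),
              sa = sum(.data$volume * abs(.data$helicity)),
              vol = sum(.data$volume), .groups = "drop") |>
    arrange(.data$time)
  vol <- per_t$vol[1]
  if (nrow(per_t) == 1L) {
    h1 <- per_t$sh / vol
    h2 <- per_t$sa / vol
    status <- "steady"
  } else {
    Tt <- max(per_t$time) - min(per_t$time)
    h1 <- trapz(per_t$time, per_t$sh) / (Tt * vol)
    h2 <- trapz(per_t$time, per_t$sa) / (Tt * vol)
    status <- "ok"
  }
  if (h2 <= 0) {
    tibble(h1 = h1, h2 = h2, h3 = NA_real_, h4 = NA_real_, volume = vol,
           n_cells = dplyr::n_distinct(hd$cell), status = "zero_intensity")
  } else {
    tibble(h1 = h1, h2 = h2, h3 = h1 / h2, h4 = abs(h1) / h2, volume = vol,
           n_cells = dplyr::n_distinct(hd$cell), status = status)
  }
}

#' Local normalized helicity (LNH)
#'
#' `LNH = v . w / (|v| |w|)`, the cosine of the angle between velocity and
#' vorticity, in `[-1, 1]`; its sign encodes rotation handedness. Where
#' `|v||w| < epsilon` the value is set to 0.
#'
#' @param field A flow-field tibble with velocity and vorticity columns.
#' @param epsilon Product-magnitude floor below which LNH is set to 0
#'   (SI units, default 1e-12).
#' @return Tibble (cell, time, x, y, z, lnh).
#' @export
lnh_field <- function(field, epsilon = 1e-12) {
  if (!all(c("wx", "wy", "wz") %in% names(field))) {
    abort("field has no vorticity; call add_vorticity() first.")
  }
  field |>
    mutate(
      vmag = sqrt(.data$vx^2 + .data$vy^2 + .data$vz^2),
      wmag = sqrt(.data$wx^2 + .data$wy^2 + .data$wz^2),
      prod = .data$vmag * .data$wmag,
      lnh = ifelse(.data$prod < epsilon, 0,
                   pmin(1, pmax(-1, (.data$vx * .data$wx + .data$vy * .data$wy +
                                       .data$vz * .data$wz) / .data$prod)))
    ) |>
    select("cell", "time", "x", "y", "z", "lnh")
}

#' Cycle-averaged LNH per cell
#'
#' Time average (trapezoidal over the snapshot times; equal to the arithmetic
#' mean for uniform sampling) of the instantaneous LNH.
#'
#' @param lnh A tibble from [lnh_field()].
#' @return Tibble (cell, x, y, z, lnh_mean).
#' @export
lnh_cycle_average <- function(lnh) {
  lnh |>
    group_by(.data$cell, .data$x, .data$y, .data$z) |>
    arrange(.data$time, .by_group = TRUE) |>
    summarise(lnh_mean = if (n() == 1L) .data$lnh else
      trapz(.data$time, .data$lnh) / (max(.data$time) - min(.data$time)),
      .groups = "drop")
}

#' Assign points to labelled segments by nearest centerline point
#'
#' Each row of `df` receives the label of its nearest reference point (a tube
#' map). Used to attribute volume cells and wall elements to anatomical
#' segments or to pre-/stenosed/post- regions.
#'
#' @param df Tibble with `x`, `y`, `z` columns (cells or wall elements).
#' @param reference Tibble with `x`, `y`, `z` and a label column (one or more
#'   concatenated centerlines).
#' @param label_col Name of the label column in `reference`.
#' @param chunk Rows of `df` processed per distance block.
#' @return `df` with its `segment` column set to the nearest label.
#' @export
assign_segments <- function(df, reference, label_col = "label",
                            chunk = 20000L) {
  R <- cbind(reference$x, reference$y, reference$z)
  labs <- reference[[label_col]]
  n <- nrow(df)
  seg <- character(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    P <- cbind(df$x[idx], df$y[idx], df$z[idx])
    # squared distances |p|^2 - 2 p.r + |r|^2; argmin over reference points
    d2 <- outer(rowSums(P^2), rep(1, nrow(R))) - 2 * P %*% t(R) +
      outer(rep(1, length(idx)), rowSums(R^2))
    seg[idx] <- labs[max.col(-d2, ties.method = "first")]
  }
  df$segment <- seg
  df
}
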