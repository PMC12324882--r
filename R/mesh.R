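# Structured cylindrical mesh presented through an unstructured interface
# (points + cell connectivity + neighbour pairs), so downstream integration
# code exercises the same paths a real CFD export would.

#' Build a cylindrical volume mesh
#'
#' Discretises a straight circular tube of radius `radius` and length `length`
#' into `n_radial x n_angular x n_axial` cells (inner ring = wedges, outer
#' rings = hexahedra). Cell volumes and the wall-element areas are the exact
#' cylindrical-sector values; centroids are the exact radial centroids of each
#' sector at mid-angle/mid-height. Face-adjacency neighbour pairs (including
#' across-axis pairs for the innermost ring) are precomputed for gradient
#' reconstruction.
#'
#' @param radius Tube radius (m).
#' @param length Tube length (m).
#' @param n_cells Target total cell count (>= 100); the three resolutions are
#'   derived from it.
#' @return A list of class `cyl_mesh` with elements `points` (n x 3 matrix),
#'   `cells` (list of 1-based point-index vectors), `cell_types` (VTK type
#'   ids), `cell_tbl` (tibble: cell, x, y, z, volume, r_in, r_out, i, j, k),
#'   `neighbors` (tibble: cell, nbr), `wall` (tibble of outer-surface
#'   elements: element, x, y, z, nx, ny, nz inward unit normal, area, cell id
#'   of the adjacent interior cell), `wall_polys` (list of point-index quads)
#'   and the resolutions.
#' @export
make_cylinder_mesh <- function(radius, length, n_cells = 4000L) {
  stopifnot_positive(radius, "radius")
  stopifnot_positive(length, "length")
  if (n_cells < 100) abort("`n_cells` must be at least 100.")

  nr <- max(3L, as.integer(round((n_cells / 8) ^ (1 / 3))))
  nt <- 2L * nr                       # even, needed for across-axis pairing
  nz <- max(3L, as.integer(round(n_cells / (nr * nt))))

  dr <- radius / nr
  dth <- 2 * pi / nt
  dz <- length / nz

  # points: axis line (nz+1) then rings i=1..nr, j=0..nt-1, k=0..nz
  zk <- seq(0, length, length.out = nz + 1L)
  axis_pts <- cbind(0, 0, zk)
  grid <- expand.grid(j = 0:(nt - 1L), i = 1:nr, k = 0:nz)
  rr <- grid$i * dr
  th <- grid$j * dth
  ring_pts <- cbind(rr * cos(th), rr * sin(th), zk[grid$k + 1L])
  points <- rbind(axis_pts, ring_pts)

  axis_id <- function(k) k + 1L                         # k in 0..nz
  ring_id <- function(i, j, k) {                        # j wraps mod nt
    (nz + 1L) + k * (nt * nr) + (i - 1L) * nt + (j %% nt) + 1L
  }

  cg <- expand.grid(j = 0:(nt - 1L), i = 1:nr, k = 0:(nz - 1L))
  ncell <- nrow(cg)
  cid <- function(i, j, k) k * (nt * nr) + (i - 1L) * nt + (j %% nt) + 1L

  cells <- vector("list", ncell)
  types <- integer(ncell)
  for (c in seq_len(ncell)) {
    i <- cg$i[c]; j <- cg$j[c]; k <- cg$k[c]
    if (i == 1L) {
      cells[[c]] <- c(axis_id(k), ring_id(1L, j, k), ring_id(1L, j + 1L, k),
                      axis_id(k + 1L), ring_id(1L, j, k + 1L),
                      ring_id(1L, j + 1L, k + 1L))
      types[c] <- 13L  # VTK wedge
    } else {
      cells[[c]] <- c(ring_id(i - 1L, j, k), ring_id(i, j, k),
                      ring_id(i, j + 1L, k), ring_id(i - 1L, j + 1L, k),
                      ring_id(i - 1L, j, k + 1L), ring_id(i, j, k + 1L),
                      ring_id(i, j + 1L, k + 1L), ring_id(i - 1L, j + 1L, k + 1L))
      types[c] <- 12L  # VTK hexahedron
    }
  }

  r_in <- (cg$i - 1L) * dr
  r_out <- cg$i * dr
  r_c <- (2 / 3) * (r_out^3 - r_in^3) / (r_out^2 - r_in^2)
  th_c <- (cg$j + 0.5) * dth
  z_c <- (cg$k + 0.5) * dz
  vol <- dth / 2 * (r_out^2 - r_in^2) * dz

  cell_tbl <- tibble(
    cell = seq_len(ncell),
    x = r_c * cos(th_c), y = r_c * sin(th_c), z = z_c,
    volume = vol, r = r_c, theta = th_c,
    r_in = r_in, r_out = r_out,
    i = cg$i, j = cg$j, k = cg$k
  )

  # lattice neighbour pairs: all 26 (di, dj, dk) offsets within bounds
  # (angular index wraps), plus across-axis partners for the innermost ring
  i <- cg$i; j <- cg$j; k <- cg$k
  nbrs_list <- list()
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0L && dj == 0L && dk == 0L) next
    ok <- (i + di >= 1L) & (i + di <= nr) & (k + dk >= 0L) & (k + dk <= nz - 1L)
    nbrs_list[[length(nbrs_list) + 1L]] <-
      cbind(cid(i, j, k)[ok], cid(i + di, j + dj, k + dk)[ok])
  }
  ax <- i == 1L
  nbrs_list[[length(nbrs_list) + 1L]] <-
    cbind(cid(i, j, k)[ax], cid(i, j + nt %/% 2L, k)[ax])
  # second-layer partners along one-sided directions so a quadratic fit
  # stays well-posed at the boundaries
  one_sided <- list(list(k == 0L & nz >= 3L, 0L, 2L),
                    list(k == nz - 1L & nz >= 3L, 0L, -2L),
                    list(i == nr & nr >= 3L, -2L, 0L),
                    list(i == 1L & nr >= 3L, 2L, 0L))
  for (os in one_sided) {
    ok <- os[[1]]
    nbrs_list[[length(nbrs_list) + 1L]] <-
      cbind(cid(i, j, k)[ok], cid(i + os[[2]], j, k + os[[3]])[ok])
  }
  nbrs <- do.call(rbind, nbrs_list)
  neighbors <- tibble(cell = nbrs[, 1L], nbr = nbrs[, 2L])

  # wall elements on r = radius
  wg <- expand.grid(j = 0:(nt - 1L), k = 0:(nz - 1L))
  wth <- (wg$j + 0.5) * dth
  wz <- (wg$k + 0.5) * dz
  wall <- tibble(
    element = seq_len(nrow(wg)),
    x = radius * cos(wth), y = radius * sin(wth), z = wz,
    nx = -cos(wth), ny = -sin(wth), nz = 0,
    area = radius * dth * dz,
    cell = cid(nr, wg$j, wg$k)
  )
  wall_polys <- lapply(seq_len(nrow(wg)), function(e) {
    j <- wg$j[e]; k <- wg$k[e]
    c(ring_id(nr, j, k), ring_id(nr, j + 1L, k),
      ring_id(nr, j + 1L, k + 1L), ring_id(nr, j, k + 1L))
  })

  structure(list(points = points, cells = cells, cell_types = types,
                 cell_tbl = cell_tbl, neighbors = neighbors,
                 wall = wall, wall_polys = wall_polys,
                 radius = radius, length = length,
                 n_radial = nr, n_angular = nt, n_axial = nz),
            class = "cyl_mesh")
}

#' @export
print.cyl_mesh <- function(x, ...) {
  cat(sprintf("<cyl_mesh> R=%g m, L=%g m, %d cells (%d x %d x %d), %d wall elements\n",
              x$radius, x$length, nrow(x$cell_tbl),
              x$n_radial, x$n_angular, x$n_axial, nrow(x$wall)))
  invisible(x)
}
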