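# Shared fixture builders. Everything is generated in code; no stored data.

# swirl phantom with the canonical oracle parameters U = 0.2 m/s, Omega = 10
# rad/s on a 2 mm tube (mean_flow chosen so the centreline velocity is U)
oracle_swirl <- function(mesh_density = 2000L, ...) {
  R <- 2e-3
  make_swirling_pipe(tube_radius = R, tube_length = 2e-2,
                     mean_flow = 0.2 * pi * R^2 / 2, swirl_rate = 10,
                     mesh_density = mesh_density, ...)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(curve, Q, shift) {
  P <- cbind(curve$x, curve$y, curve$z) %*% t(Q)
  centerline(P[, 1] + shift[1], P[, 2] + shift[2], P[, 3] + shift[3],
             radius = curve[["radius"]], label = curve$label[1])
}

# straight constant-radius branch along +z, offset in x for uniqueness
straight_branch <- function(radius, length = 2e-2, n = 41L, x0 = 0,
                            label = "branch") {
  centerline(rep(x0, n), rep(0, n), seq(0, length, length.out = n),
             radius = rep(radius, n), label = label)
}

# random bifurcating tree with n_outlets leaves; child diameters shrink by
# random factors so every split is non-trivial
make_random_tree <- function(n_outlets = 15L, seed = 1L,
                             inlet_diameter = 4.5e-3) {
  set.seed(seed)
  branches <- list(b1 = straight_branch(inlet_diameter / 2, x0 = 0,
                                        label = "b1"))
  bif <- tibble::tibble(parent = character(), child_main = character(),
                        child_side = character())
  leaves <- "b1"
  nid <- 1L
  while (length(leaves) < n_outlets) {
    leaf <- leaves[1]
    leaves <- leaves[-1]
    d <- 2 * branches[[leaf]]$radius[1]
    d_main <- d * runif(1, 0.75, 0.95)
    d_side <- d * runif(1, 0.45, 0.8)
    ids <- paste0("b", nid + 1:2)
    nid <- nid + 2L
    branches[[ids[1]]] <- straight_branch(d_main / 2, x0 = nid * 1e-2,
                                          label = ids[1])
    branches[[ids[2]]] <- straight_branch(d_side / 2, x0 = -nid * 1e-2,
                                          label = ids[2])
    bif <- dplyr::bind_rows(bif, tibble::tibble(
      parent = leaf, child_main = ids[1], child_side = ids[2]))
    leaves <- c(leaves, ids)
  }
  vessel_tree(branches, bif, "b1")
}
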