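# Shared fixture builders (kept tiny; heavier fixtures come from
# analytic_fixture()).

FL <- VOXEL_LABELS[["fluid"]]
WL <- VOXEL_LABELS[["wall"]]
SC <- VOXEL_LABELS[["scaffold"]]

# sealed box of fluid with wall padding
box_domain <- function(n = c(4L, 4L, 4L), spacing = 1e-3) {
  lab <- array(WL, n + 2L)
  lab[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- FL
  voxel_domain(lab, spacing)
}

# straight duct along z with full-section inlet/outlet end layers and
# optional seeded random internal obstacles; for flow/transport property
# tests
duct_domain <- function(nx = 5L, ny = 5L, nz = 8L, spacing = 1e-3,
                        n_obstacles = 0L, seed = 1L,
                        obstacle_label = WL) {
  lab <- array(WL, c(nx + 2L, ny + 2L, nz + 2L))
  lab[2:(nx + 1L), 2:(ny + 1L), 2:(nz + 1L)] <- FL
  lab[2:(nx + 1L), 2:(ny + 1L), 1L] <- VOXEL_LABELS[["inlet"]]
  lab[2:(nx + 1L), 2:(ny + 1L), nz + 2L] <- VOXEL_LABELS[["outlet"]]
  if (n_obstacles > 0L) {
    set.seed(seed)
    for (o in seq_len(n_obstacles)) {
      i <- sample(2:(nx + 1L), 1L)
      j <- sample(2:(ny + 1L), 1L)
      k <- sample(3:nz, 1L)
      lab[i, j, k] <- obstacle_label
    }
    # keep one open column so inlet and outlet stay connected
    lab[2L, 2L, 2:(nz + 1L)] <- FL
  }
  voxel_domain(lab, spacing)
}

# duct sealed at the bottom with an air interface on top
open_top_duct <- function(nx = 5L, ny = 5L, nz = 6L, spacing = 1e-3) {
  dom <- duct_domain(nx, ny, nz, spacing)
  lab <- dom$labels
  lab[2:(nx + 1L), 2:(ny + 1L), nz + 2L] <- VOXEL_LABELS[["interface"]]
  lab[2:(nx + 1L), 2:(ny + 1L), 1L] <- WL
  voxel_domain(lab, spacing)
}

expect_within <- function(value, target, rel_tol) {
  expect_lt(abs(value - target) / abs(target), rel_tol)
}
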