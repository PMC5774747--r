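# Shared fixtures. The reference phantom run is memoized so the controller
# executes once per test session and every suite asserts on the same plan.

.fixture_cache <- new.env(parent = emptyenv())

ref_phantom <- function() {
  if (is.null(.fixture_cache$phantom)) {
    .fixture_cache$phantom <- build_reference_phantom("pancreas2d", 0)
  }
  .fixture_cache$phantom
}

ref_autoplan <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_autoplan(ref_phantom(), autoplan_config())
  }
  .fixture_cache$run
}

# a small rectangular structure set: body fills the grid, a square target
# in the middle, one lateral OAR block
make_toy_set <- function(nx = 24, ny = 24, spacing = 4,
                         target_half = 8, oar_shift = 28) {
  grid <- voxel_grid(c(nx, ny, 1), rep(spacing, 3))
  P <- voxel_centers(grid)
  body <- rep(TRUE, n_voxels(grid))
  tg <- abs(P[, 1]) <= target_half & abs(P[, 2]) <= target_half
  oar <- abs(P[, 1] - oar_shift) <= 6 & abs(P[, 2]) <= 6
  structure_set(grid, list(
    structure_mask("body", "body", body, grid),
    structure_mask("ptv", "target", tg, grid),
    structure_mask("oar", "oar_serial", oar, grid)
  ))
}

# hand-built dose_influence for toy optimization problems
make_toy_influence <- function(M, grid = NULL) {
  M <- Matrix::Matrix(M, sparse = TRUE)
  if (is.null(grid)) grid <- voxel_grid(c(nrow(M), 1, 1), c(4, 4, 4))
  basis <- structure(
    list(gantry_angles = 0, beamlets_per_beam = ncol(M), n_z_rows = 1L,
         beamlet_width = 5, source_distance = 1000,
         isocenter = c(0, 0, 0),
         beamlets = data.frame(beam = 1L, angle = 0,
                               offset = seq_len(ncol(M)), zoffset = 0)),
    class = "beamlet_basis"
  )
  structure(
    list(matrix = M, grid = grid, basis = basis, mu = 0.005,
         sigma_p = 3, truncation = 0, calibration = 1),
    class = "dose_influence"
  )
}

# single-voxel structure mask helper for toy objectives
toy_mask <- function(idx, n, name = "s", role = "oar_serial") {
  grid <- voxel_grid(c(n, 1, 1), c(4, 4, 4))
  v <- rep(FALSE, n)
  v[idx] <- TRUE
  structure_mask(name, role, v, grid)
}
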