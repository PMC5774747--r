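#' Beamlet basis: equispaced coplanar beams around the target
#'
#' Builds `n_beams` coplanar beams equispaced over 360 degrees. Each beam is
#' a fan of parallel beamlets (rays) perpendicular to the beam axis, wide
#' enough to cover the target plus a 10 mm margin at the isocenter (the
#' target centroid). On volumetric grids the fan is extended along z to a
#' lateral-by-longitudinal grid of beamlets covering the target extent plus
#' the same margin. This dense static-beam set is the usual research
#' surrogate for arc delivery.
#'
#' @param n_beams number of beams, >= 2.
#' @param structures a `structure_set` (provides target and grid).
#' @param beamlet_width beamlet spacing/width at isocenter (mm).
#' @param source_distance nominal source-axis distance (mm); metadata only,
#'   beamlets are modelled as parallel rays.
#' @return An object of class `beamlet_basis` with a `beamlets` table
#'   (one row per beamlet: beam, gantry angle, lateral and z offsets).
#' @export
make_beams <- function(n_beams, structures, beamlet_width = 5,
                       source_distance = 1000) {
  n_beams <- as.integer(n_beams)
  if (n_beams < 2L) stop("n_beams must be >= 2")
  stopifnot(beamlet_width > 0)
  grid <- structures$grid
  tg <- target_union(structures)
  P <- voxel_centers(grid)
  iso <- colMeans(P[tg, , drop = FALSE])
  # fan half-width: max target radius about the isocenter + 10 mm margin
  tp <- P[tg, , drop = FALSE]
  r_xy <- sqrt(max((tp[, 1] - iso[1])^2 + (tp[, 2] - iso[2])^2))
  half <- r_xy + 10
  n_lat <- max(1L, as.integer(ceiling(2 * half / beamlet_width)))
  lat_offsets <- (seq_len(n_lat) - (n_lat + 1) / 2) * beamlet_width
  if (grid$shape[3] > 1L) {
    half_z <- max(abs(tp[, 3] - iso[3])) + 10
    n_z <- max(1L, as.integer(ceiling(2 * half_z / beamlet_width)))
    z_offsets <- (seq_len(n_z) - (n_z + 1) / 2) * beamlet_width
  } else {
    z_offsets <- 0
  }
  angles <- seq(0, 360, length.out = n_beams + 1L)[seq_len(n_beams)]
  beamlets <- expand.grid(
    zoffset = z_offsets, offset = lat_offsets, beam = seq_len(n_beams),
    KEEP.OUT.ATTRS = FALSE
  )
  beamlets$angle <- angles[beamlets$beam]
  beamlets <- beamlets[, c("beam", "angle", "offset", "zoffset")]
  structure(
    list(
      gantry_angles = angles,
      beamlets_per_beam = n_lat,
      n_z_rows = length(z_offsets),
      beamlet_width = beamlet_width,
      source_distance = source_distance,
      isocenter = iso,
      beamlets = beamlets
    ),
    class = "beamlet_basis"
  )
}

#' @export
print.beamlet_basis <- function(x, ...) {
  cat(sprintf(
    "beamlet_basis: %d beams x %d x %d beamlets (%.3g mm), iso (%.1f, %.1f, %.1f) mm\n",
    length(x$gantry_angles), x$beamlets_per_beam, x$n_z_rows,
    x$beamlet_width, x$isocenter[1], x$isocenter[2], x$isocenter[3]
  ))
  invisible(x)
}

#' Number of beamlets in a basis
#' @param basis a `beamlet_basis`.
#' @return integer.
#' @export
n_beamlets <- function(basis) nrow(basis$beamlets)

#' Compute the sparse dose-influence matrix
#'
#' Pencil-beam model in homogeneous water: the dose per unit fluence from
#' beamlet `b` in voxel `i` is
#' `C * exp(-mu * depth) * exp(-r^2 / (2 * sigma_p^2))`,
#' where `depth` is the water-equivalent path length (mm) from the body
#' entry point along the beamlet axis, `r` the lateral distance (mm) from
#' the axis, `mu` the effective linear attenuation (default 0.005 / mm,
#' roughly a 6 MV beam), and `sigma_p = 0.6 * beamlet_width` the pencil
#' kernel width. `C` is fixed so a unit-fluence beamlet deposits exactly
#' 1 Gy on axis at 100 mm depth. Entries below `truncation` times the
#' beamlet maximum are dropped for sparsity.
#'
#' @param basis a `beamlet_basis`.
#' @param structures a `structure_set` (body mask bounds the entry search).
#' @param mu effective attenuation coefficient (1/mm).
#' @param sigma_factor pencil kernel width as a fraction of beamlet width.
#' @param truncation relative sparsity cutoff (fraction of beamlet max).
#' @param march_step ray-march step (mm) used to locate the body entry.
#' @return An object of class `dose_influence`: sparse `n_voxels x
#'   n_beamlets` matrix plus grid/basis references.
#' @export
compute_dose_influence <- function(basis, structures, mu = 0.005,
                                   sigma_factor = 0.6, truncation = 1e-4,
                                   march_step = 1) {
  grid <- structures$grid
  body <- get_structure(structures, "body")$voxels
  if (!any(body)) stop("body mask is empty")
  P <- voxel_centers(grid)
  nv <- nrow(P)
  sigma_p <- sigma_factor * basis$beamlet_width
  calib <- exp(mu * 100)  # 1 Gy at 100 mm depth on axis
  iso <- basis$isocenter
  bl <- basis$beamlets
  body_arr <- body
  sh <- grid$shape

  ii <- vector("list", nrow(bl))
  xx <- vector("list", nrow(bl))
  missed <- integer(0)
  for (b in seq_len(nrow(bl))) {
    th <- bl$angle[b] * pi / 180
    u <- c(cos(th), sin(th), 0)
    v <- c(-sin(th), cos(th), 0)
    a <- iso + bl$offset[b] * v + c(0, 0, bl$zoffset[b])
    W1 <- P[, 1] - a[1]; W2 <- P[, 2] - a[2]; W3 <- P[, 3] - a[3]
    s <- W1 * u[1] + W2 * u[2]           # longitudinal coordinate (u_z = 0)
    r2 <- pmax(W1^2 + W2^2 + W3^2 - s^2, 0)
    # body entry along the axis: first marched sample inside the body
    sq <- seq(min(s) - march_step, max(s) + march_step, by = march_step)
    qx <- a[1] + sq * u[1]; qy <- a[2] + sq * u[2]
    jx <- as.integer(round((qx - grid$origin[1]) / grid$spacing[1]))
    jy <- as.integer(round((qy - grid$origin[2]) / grid$spacing[2]))
    jz <- as.integer(round((a[3] - grid$origin[3]) / grid$spacing[3]))
    ok <- jx >= 0L & jx < sh[1] & jy >= 0L & jy < sh[2] &
      jz >= 0L & jz < sh[3]
    lin <- jx[ok] + sh[1] * (jy[ok] + sh[2] * jz)
    inside <- body_arr[lin + 1L]
    if (!any(inside)) {
      missed <- c(missed, b)
      ii[[b]] <- integer(0); xx[[b]] <- numeric(0)
      next
    }
    t0 <- sq[ok][which(inside)[1]]
    depth <- s - t0
    dose <- calib * exp(-mu * depth) * exp(-r2 / (2 * sigma_p^2))
    dose[depth < 0] <- 0
    thr <- truncation * max(dose)
    keep <- which(dose >= thr & dose > 0)
    ii[[b]] <- keep
    xx[[b]] <- dose[keep]
  }
  if (length(missed)) {
    warning(sprintf(
      "%d beamlet(s) miss the body entirely (all-zero columns)",
      length(missed)
    ))
  }
  nnz <- lengths(ii)
  M <- Matrix::sparseMatrix(
    i = unlist(ii), j = rep.int(seq_len(nrow(bl)), nnz),
    x = unlist(xx), dims = c(nv, nrow(bl))
  )
  structure(
    list(matrix = M, grid = grid, basis = basis, mu = mu,
         sigma_p = sigma_p, truncation = truncation, calibration = calib),
    class = "dose_influence"
  )
}

#' @export
print.dose_influence <- function(x, ...) {
  cat(sprintf(
    "dose_influence: %d voxels x %d beamlets, %d nonzeros (%.2f%% dense)\n",
    nrow(x$matrix), ncol(x$matrix), Matrix::nnzero(x$matrix),
    100 * Matrix::nnzero(x$matrix) / prod(dim(x$matrix))
  ))
  invisible(x)
}

#' Dose distribution from a fluence map
#'
#' Applies the linear dose operator: `dose = D %*% fluence`. Fluence
#' weights must be non-negative.
#'
#' @param D a `dose_influence`.
#' @param x numeric fluence vector over beamlets (unitless, >= 0).
#' @return numeric dose vector over all grid voxels (Gy).
#' @export
dose_from_fluence <- function(D, x) {
  x <- as.numeric(x)
  if (length(x) != ncol(D$matrix)) {
    stop(sprintf(
      "fluence length %d does not match %d beamlets",
      length(x), ncol(D$matrix)
    ))
  }
  if (any(x < 0)) stop("fluence weights must be non-negative")
  as.numeric(D$matrix %*% x)
}
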