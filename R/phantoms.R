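#' Voxel grid geometry
#'
#' A regular voxel grid: integer shape `(nx, ny, nz)`, per-axis spacing in
#' millimetres, and the physical coordinate of the centre of voxel
#' `(0, 0, 0)`. Voxel indices are 0-based; physical coordinates refer to
#' voxel centres. By default the origin is chosen so that the grid is
#' centred on `(0, 0, 0)`.
#'
#' @param shape integer vector of length 3, all entries >= 1.
#' @param spacing numeric vector of length 3, voxel edge lengths in mm (> 0).
#' @param origin physical coordinate (mm) of the centre of voxel (0,0,0);
#'   default centres the grid on the physical origin.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = c(4, 4, 4), origin = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3, length(spacing) == 3)
  if (any(shape < 1L)) stop("all grid shape entries must be >= 1")
  if (any(spacing <= 0)) stop("all grid spacings must be > 0")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  structure(
    list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "voxel_grid: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a `voxel_grid`.
#' @return integer voxel count.
#' @export
n_voxels <- function(grid) prod(grid$shape)

#' Voxel volume in mm^3
#' @param grid a `voxel_grid`.
#' @return voxel volume (mm^3).
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Physical coordinates of all voxel centres
#'
#' Voxels are enumerated in column-major (R array) order: the first index
#' varies fastest. Row `k` of the result is the centre of the voxel with
#' linear index `k`.
#'
#' @param grid a `voxel_grid`.
#' @return numeric matrix `n_voxels x 3` (mm).
#' @export
voxel_centers <- function(grid) {
  s <- grid$shape
  ix <- rep.int(seq_len(s[1]) - 1L, s[2] * s[3])
  iy <- rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3])
  iz <- rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  cbind(
    grid$origin[1] + ix * grid$spacing[1],
    grid$origin[2] + iy * grid$spacing[2],
    grid$origin[3] + iz * grid$spacing[3]
  )
}

.structure_roles <- c("target", "oar_serial", "oar_parallel", "ring", "body")

#' Named structure mask
#'
#' A boolean voxel set over a grid with a name and a planning role. Roles
#' drive default behaviour downstream: serial organs at risk are judged by
#' near-maximum dose (D2%), parallel ones by mean dose, rings shape the
#' dose fall-off and the body bounds everything.
#'
#' @param name structure identifier (unique within a structure set).
#' @param role one of `"target"`, `"oar_serial"`, `"oar_parallel"`,
#'   `"ring"`, `"body"`.
#' @param voxels logical vector of length `n_voxels(grid)`.
#' @param grid the `voxel_grid` the mask lives on.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, role, voxels, grid) {
  role <- match.arg(role, .structure_roles)
  voxels <- as.logical(voxels)
  stopifnot(length(voxels) == n_voxels(grid))
  structure(
    list(name = name, role = role, voxels = voxels, grid = grid),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "structure_mask '%s' (%s): %d voxels, %.1f cm^3\n",
    x$name, x$role, sum(x$voxels), sum(x$voxels) * voxel_volume(x$grid) / 1000
  ))
  invisible(x)
}

#' Structure set: a grid plus named structure masks
#'
#' @param grid a `voxel_grid`.
#' @param structures list of `structure_mask` objects with unique names;
#'   exactly one body and at least one target are required.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, structures) {
  nm <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("structure names must be unique")
  roles <- vapply(structures, `[[`, character(1), "role")
  if (sum(roles == "body") != 1L) stop("structure set needs exactly one body")
  if (!any(roles == "target")) stop("structure set needs at least one target")
  names(structures) <- nm
  body <- structures[[which(roles == "body")]]$voxels
  for (st in structures[roles == "target"]) {
    if (any(st$voxels & !body)) {
      stop(sprintf("target '%s' must lie inside the body", st$name))
    }
  }
  structure(list(grid = grid, structures = structures), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  print(x$grid)
  for (st in x$structures) print(st)
  invisible(x)
}

#' Fetch a structure by name
#' @param structures a `structure_set`.
#' @param name structure name.
#' @return the `structure_mask`.
#' @export
get_structure <- function(structures, name) {
  st <- structures$structures[[name]]
  if (is.null(st)) {
    stop(sprintf(
      "no structure named '%s' (have: %s)", name,
      paste(names(structures$structures), collapse = ", ")
    ))
  }
  st
}

#' Structures with a given role
#' @param structures a `structure_set`.
#' @param role a role string (see [structure_mask()]); several allowed.
#' @return list of `structure_mask`.
#' @export
structures_by_role <- function(structures, role) {
  roles <- vapply(structures$structures, `[[`, character(1), "role")
  structures$structures[roles %in% role]
}

#' Union of all target voxels
#' @param structures a `structure_set`.
#' @return logical voxel vector.
#' @export
target_union <- function(structures) {
  tg <- structures_by_role(structures, "target")
  Reduce(`|`, lapply(tg, `[[`, "voxels"))
}

# geometric membership helpers (physical mm coordinates); for single-slice
# grids the z term is dropped so shapes become their 2D sections
.ellipsoid_mask <- function(P, center, semi, two_d = FALSE) {
  q <- ((P[, 1] - center[1]) / semi[1])^2 + ((P[, 2] - center[2]) / semi[2])^2
  if (!two_d) q <- q + ((P[, 3] - center[3]) / semi[3])^2
  q <= 1
}

.cylinder_mask <- function(P, center, radius, two_d = FALSE, half_length = Inf) {
  q <- (P[, 1] - center[1])^2 + (P[, 2] - center[2])^2 <= radius^2
  if (!two_d && is.finite(half_length)) {
    q <- q & abs(P[, 3] - center[3]) <= half_length
  }
  q
}

.phantom_presets <- c("pancreas2d", "pancreas3d")

#' Build a deterministic reference phantom
#'
#' Generates a voxel phantom emulating the geometric situation of pancreatic
#' SBRT planning: a roughly spherical target (`ptv`, diameter about 30 mm) at
#' the centre of a water-equivalent body, an abutting serial organ at risk
#' (`duodenum`, surface gap at most 5 mm), a distant serial organ (`cord`,
#' at least 60 mm posterior of the target surface) and two lateral parallel
#' organs (`kidney_l`, `kidney_r`). The seed perturbs non-critical placement
#' (the abutting organ's direction, small lateral-organ shifts) while the
#' abutment gap and the distant-organ clearance are held fixed, so every
#' seeded phantom presents the same planning problem.
#'
#' Presets:
#' \describe{
#'   \item{`pancreas2d`}{single axial slice, 96 x 96 x 1 voxels at 4 mm.}
#'   \item{`pancreas3d`}{volumetric, 64 x 64 x 32 voxels at 4 mm.}
#' }
#'
#' @param preset_name one of `"pancreas2d"`, `"pancreas3d"`.
#' @param seed integer; identical `(preset, seed)` gives bit-identical masks.
#' @return A `structure_set` with structures
#'   `body`, `ptv`, `duodenum`, `cord`, `kidney_l`, `kidney_r`.
#' @export
build_reference_phantom <- function(preset_name, seed = 0L) {
  if (!preset_name %in% .phantom_presets) {
    stop(sprintf(
      "unknown phantom preset '%s'; valid presets: %s",
      preset_name, paste(.phantom_presets, collapse = ", ")
    ))
  }
  # deterministic local RNG: never disturb the caller's stream
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  two_d <- preset_name == "pancreas2d"
  grid <- if (two_d) {
    voxel_grid(c(96, 96, 1), c(4, 4, 4))
  } else {
    voxel_grid(c(64, 64, 32), c(4, 4, 4))
  }
  P <- voxel_centers(grid)

  body_r <- if (two_d) 140 else 110
  ptv_r <- 15
  duo_r <- 10
  duo_gap <- 2        # abutting: surface-to-surface gap, <= 5 mm
  cord_r <- 6
  cord_post <- 85     # centre offset; surface clearance 85 - 15 - 6 = 64 mm

  # seeded, non-critical jitter
  duo_angle <- stats::runif(1, -15, 15) * pi / 180  # around +x
  kid_dx <- stats::runif(2, -4, 4)
  kid_dy <- stats::runif(2, -4, 4)

  body <- .cylinder_mask(P, c(0, 0, 0), body_r, two_d)
  ptv <- if (two_d) {
    .cylinder_mask(P, c(0, 0, 0), ptv_r, TRUE)
  } else {
    .ellipsoid_mask(P, c(0, 0, 0), rep(ptv_r, 3))
  }
  duo_c <- (ptv_r + duo_gap + duo_r) * c(cos(duo_angle), sin(duo_angle), 0)
  duo <- .cylinder_mask(P, duo_c, duo_r, two_d, half_length = 40)
  cord <- .cylinder_mask(P, c(0, -cord_post, 0), cord_r, two_d)
  kid_x <- if (two_d) 90 else 80
  kid_semi <- if (two_d) c(15, 25, Inf) else c(15, 25, 40)
  kid_l <- .ellipsoid_mask(P, c(-kid_x + kid_dx[1], -30 + kid_dy[1], 0),
                           kid_semi, two_d)
  kid_r <- .ellipsoid_mask(P, c(kid_x + kid_dx[2], -30 + kid_dy[2], 0),
                           kid_semi, two_d)

  structure_set(grid, list(
    structure_mask("body", "body", body, grid),
    structure_mask("ptv", "target", ptv & body, grid),
    structure_mask("duodenum", "oar_serial", duo & body, grid),
    structure_mask("cord", "oar_serial", cord & body, grid),
    structure_mask("kidney_l", "oar_parallel", kid_l & body, grid),
    structure_mask("kidney_r", "oar_parallel", kid_r & body, grid)
  ))
}

# target surface voxels: target voxels with at least one non-target
# 6-neighbour (out-of-grid neighbours count as non-target)
.target_surface <- function(voxels, grid) {
  s <- grid$shape
  a <- array(voxels, dim = s)
  inner <- array(TRUE, dim = s)
  shift_and <- function(ax, dir) {
    n <- s[ax]
    if (n == 1L) return()  # single-slice axis: all voxels are surface along it
    idx_to <- if (dir > 0) 2:n else 1:(n - 1)
    idx_from <- if (dir > 0) 1:(n - 1) else 2:n
    nb <- array(FALSE, dim = s)
    if (ax == 1L) nb[idx_to, , ] <- a[idx_from, , ]
    if (ax == 2L) nb[, idx_to, ] <- a[, idx_from, ]
    if (ax == 3L) nb[, , idx_to] <- a[, , idx_from]
    inner <<- inner & nb
  }
  for (ax in 1:3) {
    if (s[ax] > 1L) { shift_and(ax, 1L); shift_and(ax, -1L) }
  }
  as.logical(a & !inner)
}

#' Distance from every voxel centre to the target surface
#'
#' The target surface is the set of target voxels having at least one
#' non-target 6-neighbour; distance is the Euclidean distance between voxel
#' centres, in mm. Computed by blocked exact pairwise evaluation, which
#' handles anisotropic spacing.
#'
#' @param structures a `structure_set` (distance is to the union of all
#'   targets).
#' @return numeric vector over all grid voxels (mm); 0 on surface voxels,
#'   and interior target voxels carry their (positive) distance to the
#'   surface like any other voxel.
#' @export
target_surface_distance <- function(structures) {
  grid <- structures$grid
  tg <- target_union(structures)
  if (!any(tg)) stop("structure set has no target voxels")
  surf <- .target_surface(tg, grid)
  P <- voxel_centers(grid)
  S <- P[surf, , drop = FALSE]
  n <- nrow(P)
  out <- numeric(n)
  block <- 4096L
  s2 <- rowSums(S^2)
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    B <- P[i0:i1, , drop = FALSE]
    # squared distances via |b|^2 - 2 b.s + |s|^2
    d2 <- outer(rowSums(B^2), s2, `+`) - 2 * tcrossprod(B, S)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Generate concentric ring structures around the targets
#'
#' Rings (shells) are auxiliary structures used to force dose fall-off
#' around the target. Ring `k` collects body voxels whose centre lies at a
#' distance `d` from the target surface with `offsets[k] <= d <
#' offsets[k] + width`, excluding target voxels and previously created
#' rings. Rings may overlap organs at risk (common planning practice).
#'
#' @param structures a `structure_set`.
#' @param offsets strictly increasing ring start distances (mm);
#'   default `c(5, 35, 55)`.
#' @param width ring thickness (mm); default 10.
#' @return the `structure_set` augmented with structures `ring_1`, ...,
#'   role `"ring"`. Rings that would be empty are dropped with a warning.
#' @export
generate_rings <- function(structures, offsets = c(5, 35, 55), width = 10) {
  stopifnot(width > 0, length(offsets) >= 1)
  if (any(diff(offsets) <= 0)) stop("ring offsets must be strictly increasing")
  grid <- structures$grid
  dist <- target_surface_distance(structures)
  body <- get_structure(structures, "body")$voxels
  tg <- target_union(structures)
  taken <- tg
  sts <- structures$structures
  for (k in seq_along(offsets)) {
    ring <- body & !taken & dist >= offsets[k] & dist < offsets[k] + width
    if (!any(ring)) {
      warning(sprintf(
        "ring_%d (offset %g mm) is empty and was dropped", k, offsets[k]
      ))
      next
    }
    nm <- sprintf("ring_%d", k)
    sts[[nm]] <- structure_mask(nm, "ring", ring, grid)
    taken <- taken | ring
  }
  structure_set(grid, sts)
}
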