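#' Write a structure set to a directory (NIfTI + JSON manifest)
#'
#' One NIfTI volume per structure (0/1 masks, voxel spacing recorded in
#' the header) plus `manifest.json` mapping structure name to role and
#' file, alongside the grid specification.
#'
#' @param structures a `structure_set`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_structure_set <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- structures$grid
  entries <- lapply(structures$structures, function(st) {
    file <- sprintf("%s.nii.gz", st$name)
    arr <- array(as.integer(st$voxels), dim = grid$shape)
    img <- RNifti::asNifti(arr, pixdim = grid$spacing)
    RNifti::writeNifti(img, file.path(dir, file))
    list(name = st$name, role = st$role, file = file)
  })
  manifest <- list(
    grid = list(shape = grid$shape, spacing = grid$spacing,
                origin = grid$origin),
    structures = unname(entries)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structure set written by [write_structure_set()]
#'
#' @param dir directory containing `manifest.json` and the mask volumes.
#' @return a `structure_set`.
#' @export
read_structure_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  grid <- voxel_grid(manifest$grid$shape, manifest$grid$spacing,
                     manifest$grid$origin)
  sts <- lapply(seq_len(nrow(manifest$structures)), function(i) {
    e <- manifest$structures[i, ]
    arr <- RNifti::readNifti(file.path(dir, e$file))
    structure_mask(e$name, e$role, as.vector(arr) != 0, grid)
  })
  structure_set(grid, sts)
}

#' Write a dose distribution as a NIfTI volume
#'
#' @param dose dose vector over all grid voxels (Gy).
#' @param grid the `voxel_grid`.
#' @param file output path (`.nii` or `.nii.gz`).
#' @return `file`, invisibly.
#' @export
write_dose_nifti <- function(dose, grid, file) {
  arr <- array(dose, dim = grid$shape)
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = grid$spacing), file)
  invisible(file)
}

#' Persist a dose-influence matrix (MatrixMarket triplet + JSON sidecar)
#'
#' The sparse operator is written as MatrixMarket coordinate text and the
#' grid/basis/physics metadata as JSON next to it.
#'
#' @param D a `dose_influence`.
#' @param basename output path prefix; writes `<basename>.mtx` and
#'   `<basename>.json`.
#' @return the `.mtx` path, invisibly.
#' @export
write_dose_influence <- function(D, basename) {
  mtx <- paste0(basename, ".mtx")
  Matrix::writeMM(methods::as(D$matrix, "TsparseMatrix"), mtx)
  meta <- list(
    grid = list(shape = D$grid$shape, spacing = D$grid$spacing,
                origin = D$grid$origin),
    basis = list(
      gantry_angles = D$basis$gantry_angles,
      beamlets_per_beam = D$basis$beamlets_per_beam,
      n_z_rows = D$basis$n_z_rows,
      beamlet_width = D$basis$beamlet_width,
      source_distance = D$basis$source_distance,
      isocenter = D$basis$isocenter,
      beamlets = D$basis$beamlets
    ),
    mu = D$mu, sigma_p = D$sigma_p,
    truncation = D$truncation, calibration = D$calibration
  )
  jsonlite::write_json(meta, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mtx)
}

#' Read a dose-influence matrix written by [write_dose_influence()]
#'
#' @param basename the path prefix used at write time.
#' @return a `dose_influence`.
#' @export
read_dose_influence <- function(basename) {
  M <- methods::as(Matrix::readMM(paste0(basename, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::read_json(paste0(basename, ".json"),
                              simplifyVector = TRUE)
  grid <- voxel_grid(meta$grid$shape, meta$grid$spacing, meta$grid$origin)
  basis <- structure(
    list(
      gantry_angles = meta$basis$gantry_angles,
      beamlets_per_beam = meta$basis$beamlets_per_beam,
      n_z_rows = meta$basis$n_z_rows,
      beamlet_width = meta$basis$beamlet_width,
      source_distance = meta$basis$source_distance,
      isocenter = meta$basis$isocenter,
      beamlets = meta$basis$beamlets
    ),
    class = "beamlet_basis"
  )
  structure(
    list(matrix = M, grid = grid, basis = basis, mu = meta$mu,
         sigma_p = meta$sigma_p, truncation = meta$truncation,
         calibration = meta$calibration),
    class = "dose_influence"
  )
}

#' Read an autoplan configuration from YAML or JSON
#'
#' Fields mirror the arguments of [autoplan_config()]; omitted fields keep
#' their defaults. A nested `optimizer` block maps to
#' [optimizer_settings()].
#'
#' @param file path to a `.yaml`/`.yml` or `.json` configuration.
#' @return an `autoplan_config`.
#' @export
read_autoplan_config <- function(file) {
  raw <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  if (!is.null(raw$priority)) raw$priority <- unlist(raw$priority)
  if (!is.null(raw$optimizer)) {
    raw$optimizer <- do.call(optimizer_settings, raw$optimizer)
  }
  known <- names(formals(autoplan_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  do.call(autoplan_config, raw)
}

#' Write an autoplan configuration to YAML
#'
#' @param cfg an `autoplan_config`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_autoplan_config <- function(cfg, file) {
  lst <- unclass(cfg)
  lst$optimizer <- unclass(lst$optimizer)
  lst$priority <- as.list(lst$priority)
  yaml::write_yaml(lst, file)
  invisible(file)
}

#' Export cumulative DVH curves as a long CSV table
#'
#' Columns: structure, dose bin edge (Gy), cumulative volume (%).
#'
#' @param dose dose vector over all grid voxels (Gy).
#' @param structures a `structure_set`.
#' @param file output CSV path.
#' @param bin_width DVH bin width (Gy).
#' @return the table, invisibly.
#' @export
write_dvh_table <- function(dose, structures, file, bin_width = 0.05) {
  rows <- lapply(structures$structures, function(st) {
    dvh <- cumulative_dvh(dose, st, bin_width = bin_width)
    data.frame(structure = st$name, dose_gy = dvh$dose,
               volume_pct = dvh$volume, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Write a planning trace as JSON lines
#'
#' One JSON object per outer cycle, suitable for audit or plotting.
#'
#' @param result an `autoplan_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trace_jsonl <- function(result, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  tr <- result$trace
  for (i in seq_len(nrow(tr))) {
    row <- as.list(tr[i, ])
    hist <- result$objective_history
    row$oar_objective_doses <- hist[hist$cycle == tr$cycle[i],
                                    c("structure", "fractional_volume",
                                      "dose_gy")]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(file)
}
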