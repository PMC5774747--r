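#' Dose to the hottest fraction of a structure (sort-based)
#'
#' `dose_quantile(d, v)` is the dose received by the hottest `v`% of the
#' voxels: with doses sorted in decreasing order, the value at fractional
#' rank `v/100 * n`, linearly interpolated between neighbouring ranks.
#' This is the exact (unbinned) counterpart of reading `D_v` off the
#' cumulative DVH, and it is positively homogeneous, so rescaling the dose
#' rescales every index by the same factor.
#'
#' @param doses numeric vector of voxel doses (Gy), nonempty.
#' @param v fractional volume in percent, 0 < v <= 100.
#' @return dose in Gy.
#' @export
dose_quantile <- function(doses, v) {
  stopifnot(length(doses) >= 1, v > 0, v <= 100)
  ds <- sort(doses, decreasing = TRUE)
  n <- length(ds)
  h <- v / 100 * n
  if (h <= 1) return(ds[1])
  i <- floor(h)
  if (i >= n) return(ds[n])
  frac <- h - i
  ds[i] + (ds[i + 1] - ds[i]) * frac
}

#' Population standard deviation of structure dose, relative to prescription
#'
#' The single shared heterogeneity measure: used both by the planning
#' controller's termination test and by the reported plan metrics.
#'
#' @param dose dose vector over all grid voxels (Gy).
#' @param mask logical structure mask (or integer indices).
#' @param prescription prescription dose (Gy).
#' @return `sd(dose over mask, population convention) / prescription`
#'   (unitless fraction).
#' @export
dose_sd_rel <- function(dose, mask, prescription) {
  d <- dose[mask]
  sqrt(mean((d - mean(d))^2)) / prescription
}

#' Cumulative dose-volume histogram
#'
#' Exact voxel counting on a uniform dose-bin grid: the curve gives the
#' percentage of structure voxels receiving at least each bin-edge dose.
#' It starts at 100% at 0 Gy, is non-increasing, and reaches 0% above the
#' maximum dose.
#'
#' @param dose dose vector over all grid voxels (Gy).
#' @param mask a `structure_mask` (or logical vector).
#' @param bin_width dose bin width in Gy (default 0.05).
#' @param name structure name for labelling (taken from the mask when
#'   available).
#' @return An object of class `dvh_curve` with `dose` (bin edges, Gy) and
#'   `volume` (cumulative volume, %).
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.05, name = NULL) {
  stopifnot(bin_width > 0)
  if (inherits(mask, "structure_mask")) {
    if (is.null(name)) name <- mask$name
    mask <- mask$voxels
  }
  d <- dose[mask]
  if (!length(d)) {
    stop(sprintf("empty structure mask%s in cumulative_dvh",
                 if (is.null(name)) "" else sprintf(" '%s'", name)))
  }
  edges <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width, by = bin_width)
  # fraction of voxels with dose >= edge; findInterval on sorted doses
  ds <- sort(d)
  below <- findInterval(edges, ds, left.open = TRUE)  # strictly below edge
  vol <- 100 * (length(ds) - below) / length(ds)
  structure(
    list(structure = name, dose = edges, volume = vol,
         bin_width = bin_width),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "dvh_curve%s: %d bins of %g Gy, max dose < %.3g Gy\n",
    if (is.null(x$structure)) "" else sprintf(" '%s'", x$structure),
    length(x$dose), x$bin_width, max(x$dose)
  ))
  invisible(x)
}

#' Dose at volume from a cumulative DVH curve
#'
#' `D_v`: the dose received by the hottest `v`% of the structure, read off
#' the cumulative curve with linear interpolation between the bracketing
#' bins. Agrees with the sort-based [dose_quantile()] to within one bin
#' width.
#'
#' @param dvh a `dvh_curve`.
#' @param v fractional volume in percent, 0 < v <= 100.
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, v) {
  stopifnot(v > 0, v <= 100)
  vol <- dvh$volume
  dose <- dvh$dose
  j <- which(vol < v)[1]
  if (is.na(j)) return(dose[length(dose)])
  if (j == 1L) return(dose[1])
  # interpolate the crossing of the (non-increasing) curve with level v
  d0 <- dose[j - 1]; d1 <- dose[j]
  v0 <- vol[j - 1]; v1 <- vol[j]
  if (v0 == v1) return(d0)
  d0 + (v0 - v) / (v0 - v1) * (d1 - d0)
}

#' Volume at dose from a cumulative DVH curve
#'
#' @param dvh a `dvh_curve`.
#' @param d dose in Gy.
#' @return cumulative volume (%) receiving at least `d`, linearly
#'   interpolated.
#' @export
volume_at_dose <- function(dvh, d) {
  stats::approx(dvh$dose, dvh$volume, xout = d, rule = 2)$y
}

#' Clinical dose indices per structure
#'
#' Tallies, for each structure, the dose indices used to judge plan
#' quality: D95 and D5 (coverage and near-maximum for targets), D2% (the
#' near-maximum surrogate for serial organs), Dmean (parallel organs),
#' Dmax, and the dose standard deviation in Gy and as percent of the
#' prescription. An absolute-volume index `D_2cc` is also reported
#' (voxel count rounded half-up) since clinical protocols often state
#' near-maximum limits per 2 cm^3.
#'
#' @param dose dose vector over all grid voxels (Gy).
#' @param structures a `structure_set`.
#' @param prescription prescription dose (Gy), the denominator of the
#'   relative standard deviation.
#' @return data.frame, one row per structure, class `plan_metrics`.
#' @export
plan_metrics <- function(dose, structures, prescription) {
  vv <- voxel_volume(structures$grid)
  rows <- lapply(structures$structures, function(st) {
    d <- dose[st$voxels]
    n2cc <- max(1L, as.integer(floor(2000 / vv + 0.5)))
    d2cc <- if (n2cc >= length(d)) min(d) else sort(d, decreasing = TRUE)[n2cc]
    data.frame(
      structure = st$name, role = st$role,
      n_voxels = length(d),
      D95 = dose_quantile(d, 95), D5 = dose_quantile(d, 5),
      D2 = dose_quantile(d, 2), Dmean = mean(d), Dmax = max(d),
      D2cc = d2cc,
      sigma_gy = sqrt(mean((d - mean(d))^2)),
      sigma_pct = 100 * dose_sd_rel(dose, st$voxels, prescription),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "prescription") <- prescription
  class(out) <- c("plan_metrics", class(out))
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact-distribution related-samples signed-rank test (exact for up to 20
#' untied pairs, the regime of small planning cohorts).
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V, the positive-rank sum) and `p.value`
#'   (two-sided).
#' @export
paired_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = TRUE, correct = FALSE)
  )
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Compare two plans (or two cohorts of paired plans) by dose indices
#'
#' For a single pair of [plan_metrics()] tables the comparison reports,
#' per structure and index, the reference value, the comparison value,
#' their normalized ratio (comparison / reference, the usual reading: a
#' ratio below unity means the comparison plan delivers less dose) and
#' their difference in Gy. For cohorts (lists of paired metric tables) the
#' per-pair ratios are accompanied by an exact paired Wilcoxon signed-rank
#' p-value per structure and index.
#'
#' @param metrics_reference a `plan_metrics` table, or list of them.
#' @param metrics_comparison a `plan_metrics` table, or list of them,
#'   paired with the reference.
#' @param indices which index columns to compare.
#' @return data.frame with columns `structure`, `index`,
#'   `value_reference`, `value_comparison`, `ratio`, `difference` (and,
#'   for cohorts, `pair` plus an attached `tests` attribute with
#'   p-values).
#' @export
compare_plans <- function(metrics_reference, metrics_comparison,
                          indices = c("D95", "D5", "D2", "Dmean")) {
  if (is.data.frame(metrics_reference)) {
    return(.compare_one(metrics_reference, metrics_comparison, indices))
  }
  stopifnot(is.list(metrics_reference), is.list(metrics_comparison),
            length(metrics_reference) == length(metrics_comparison))
  per <- mapply(function(a, b, k) {
    cmp <- .compare_one(a, b, indices)
    cmp$pair <- k
    cmp
  }, metrics_reference, metrics_comparison,
  seq_along(metrics_reference), SIMPLIFY = FALSE)
  out <- do.call(rbind, per)
  tests <- do.call(rbind, lapply(split(out, out[c("structure", "index")]),
    function(g) {
      if (!nrow(g)) return(NULL)
      ht <- paired_signed_rank(g$value_reference, g$value_comparison)
      data.frame(structure = g$structure[1], index = g$index[1],
                 statistic = ht$statistic, p.value = ht$p.value,
                 stringsAsFactors = FALSE)
    }))
  rownames(tests) <- NULL
  attr(out, "tests") <- tests
  out
}

.compare_one <- function(a, b, indices) {
  if (!setequal(a$structure, b$structure)) {
    only_a <- setdiff(a$structure, b$structure)
    only_b <- setdiff(b$structure, a$structure)
    stop(sprintf(
      "plans tally different structures (only in reference: %s; only in comparison: %s)",
      paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")
    ))
  }
  missing_idx <- setdiff(indices, intersect(names(a), names(b)))
  if (length(missing_idx)) {
    stop(sprintf("unknown index column(s): %s",
                 paste(missing_idx, collapse = ", ")))
  }
  b <- b[match(a$structure, b$structure), ]
  rows <- lapply(indices, function(ix) {
    va <- a[[ix]]; vb <- b[[ix]]
    data.frame(
      structure = a$structure, index = ix,
      value_reference = va, value_comparison = vb,
      ratio = ifelse(va > 0, vb / va, NA_real_),
      difference = vb - va,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
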