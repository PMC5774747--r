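.objective_kinds <- c("max_dose", "min_dose", "uniform_dose", "mean_dose",
                      "dvh_point")

#' Dose-volume objective
#'
#' A weighted, volume-normalized quadratic penalty on a structure's dose.
#' For an objective dose `d_obj` and weight `w` the penalty is
#' `F = w * sum_i ((d_i - d_obj) / d_obj)^2 * dv_i` over the offending
#' voxels, where `dv_i` is the voxel volume divided by the structure
#' volume (so every structure contributes on a comparable scale):
#' \describe{
#'   \item{`max_dose`, `dvh_point`}{sum over voxels with `d_i > d_obj`
#'     (overdose); `dvh_point` additionally records the fractional volume
#'     it tracks, used by the planning controller.}
#'   \item{`min_dose`}{sum over voxels with `d_i < d_obj` (underdose).}
#'   \item{`uniform_dose`}{sum over all structure voxels (both sides).}
#'   \item{`mean_dose`}{`w * ((mean(d) - d_obj) / d_obj)^2` if the mean
#'     exceeds `d_obj`, else 0 (one-sided: rings and organs at risk only
#'     ever need a downward pull on the mean).}
#' }
#'
#' @param kind one of `"max_dose"`, `"min_dose"`, `"uniform_dose"`,
#'   `"mean_dose"`, `"dvh_point"`.
#' @param structure a `structure_mask` (nonempty).
#' @param dose_gy objective dose `d_obj` in Gy, > 0.
#' @param weight penalty weight `w`, >= 0.
#' @param fractional_volume percent in (0, 100]; required for
#'   `dvh_point`, bookkeeping for the DVH-reduction controller.
#' @return An object of class `objective`.
#' @export
objective <- function(kind, structure, dose_gy, weight = 1,
                      fractional_volume = NULL) {
  kind <- match.arg(kind, .objective_kinds)
  stopifnot(inherits(structure, "structure_mask"))
  idx <- which(structure$voxels)
  if (!length(idx)) stop(sprintf("structure '%s' is empty", structure$name))
  if (!is.numeric(dose_gy) || dose_gy <= 0) {
    stop("objective dose must be > 0 (the penalty divides by it)")
  }
  if (weight < 0) stop("objective weight must be >= 0")
  if (kind == "dvh_point") {
    if (is.null(fractional_volume)) {
      stop("dvh_point objectives need a fractional_volume")
    }
    stopifnot(fractional_volume > 0, fractional_volume <= 100)
  }
  structure(
    list(kind = kind, structure = structure$name, role = structure$role,
         voxels = idx, dose_gy = as.numeric(dose_gy),
         weight = as.numeric(weight),
         fractional_volume = fractional_volume),
    class = "objective"
  )
}

#' @export
print.objective <- function(x, ...) {
  fv <- if (!is.null(x$fractional_volume)) {
    sprintf(" @ %g%%", x$fractional_volume)
  } else ""
  cat(sprintf(
    "objective %s on '%s'%s: d = %.3g Gy, w = %g\n",
    x$kind, x$structure, fv, x$dose_gy, x$weight
  ))
  invisible(x)
}

#' Short label for an objective (used in traces and breakdowns)
#' @param obj an `objective`.
#' @return character scalar.
#' @export
objective_label <- function(obj) {
  if (!is.null(obj$fractional_volume)) {
    sprintf("%s:%s@%g", obj$structure, obj$kind, obj$fractional_volume)
  } else {
    sprintf("%s:%s", obj$structure, obj$kind)
  }
}

#' Evaluate an objective on a dose distribution
#'
#' @param obj an `objective`.
#' @param dose numeric dose vector over all grid voxels (Gy).
#' @return the objective value `F` (unitless, >= 0).
#' @export
evaluate_objective <- function(obj, dose) {
  d <- dose[obj$voxels]
  dj <- obj$dose_gy
  dv <- 1 / length(d)
  switch(obj$kind,
    max_dose = ,
    dvh_point = {
      over <- d[d > dj]
      obj$weight * sum(((over - dj) / dj)^2) * dv
    },
    min_dose = {
      under <- d[d < dj]
      obj$weight * sum(((dj - under) / dj)^2) * dv
    },
    uniform_dose = obj$weight * sum(((d - dj) / dj)^2) * dv,
    mean_dose = {
      m <- mean(d)
      if (m > dj) obj$weight * ((m - dj) / dj)^2 else 0
    }
  )
}

#' Exact gradient of an objective with respect to voxel dose
#'
#' Partial derivatives of `F` w.r.t. each voxel dose; zero outside the
#' structure (and outside the offending voxel set). The chain rule to
#' fluence space is the optimizer's job.
#'
#' @param obj an `objective`.
#' @param dose numeric dose vector over all grid voxels (Gy).
#' @param n length of the returned gradient (defaults to `length(dose)`).
#' @return numeric gradient vector of length `n`.
#' @export
objective_gradient <- function(obj, dose, n = length(dose)) {
  g <- numeric(n)
  idx <- obj$voxels
  d <- dose[idx]
  dj <- obj$dose_gy
  dv <- 1 / length(d)
  w <- obj$weight
  switch(obj$kind,
    max_dose = ,
    dvh_point = {
      over <- d > dj
      g[idx[over]] <- 2 * w * (d[over] - dj) / dj^2 * dv
    },
    min_dose = {
      under <- d < dj
      g[idx[under]] <- -2 * w * (dj - d[under]) / dj^2 * dv
    },
    uniform_dose = {
      g[idx] <- 2 * w * (d - dj) / dj^2 * dv
    },
    mean_dose = {
      m <- mean(d)
      if (m > dj) g[idx] <- 2 * w * (m - dj) / dj^2 * dv
    }
  )
  g
}

#' Composite objective: sum over a list of objectives
#'
#' @param objs nonempty list of `objective`s.
#' @param dose numeric dose vector (Gy).
#' @return list with `value` (the sum) and `breakdown` (named numeric
#'   vector of per-objective values, named by [objective_label()]).
#' @export
composite_objective <- function(objs, dose) {
  if (!length(objs)) stop("objective list is empty")
  vals <- vapply(objs, evaluate_objective, numeric(1), dose = dose)
  names(vals) <- vapply(objs, objective_label, character(1))
  list(value = sum(vals), breakdown = vals)
}

#' Composite gradient with respect to voxel dose
#'
#' @param objs list of `objective`s.
#' @param dose numeric dose vector (Gy).
#' @return numeric gradient vector, the sum of per-objective gradients.
#' @export
composite_gradient <- function(objs, dose) {
  g <- numeric(length(dose))
  for (obj in objs) {
    g <- g + objective_gradient(obj, dose, n = length(dose))
  }
  g
}

#' Solve for the objective dose achieving a prescribed objective value
#'
#' For an overdose-type objective (`dvh_point`, `max_dose`, `mean_dose`)
#' evaluated on a fixed dose distribution, `F(d_obj)` is continuous and
#' strictly decreasing in `d_obj` wherever it is positive, so the equation
#' `F(d_obj) = target_value` has a unique root when one exists. The root is
#' located by bisection on `(eps, max structure dose]` with `eps = 0.01 Gy`,
#' to an absolute F-tolerance of `1e-6 * target_value` within at most 200
#' bisections. If even `F(eps)` falls short of the target (the structure
#' dose is already near zero) the floor `eps` is returned with a flag; an
#' all-zero structure dose short-circuits to the same floor without root
#' finding.
#'
#' @param obj an overdose-type `objective`.
#' @param dose numeric dose vector (Gy), held fixed.
#' @param target_value desired objective value, > 0.
#' @param eps dose floor (Gy).
#' @return list with `dose_gy` (the root, or the floor), `floor` (logical),
#'   `zero_dose` (logical), `iterations`.
#' @export
solve_objective_dose <- function(obj, dose, target_value, eps = 0.01) {
  if (!obj$kind %in% c("dvh_point", "max_dose", "mean_dose")) {
    stop("solve_objective_dose applies to overdose-type objectives only")
  }
  stopifnot(target_value > 0)
  d <- dose[obj$voxels]
  if (all(d <= 0)) {
    return(list(dose_gy = eps, floor = TRUE, zero_dose = TRUE,
                iterations = 0L))
  }
  f_at <- function(dj) {
    o <- obj; o$dose_gy <- dj
    evaluate_objective(o, dose)
  }
  hi <- max(d)
  if (f_at(eps) < target_value) {
    return(list(dose_gy = eps, floor = TRUE, zero_dose = FALSE,
                iterations = 0L))
  }
  lo <- eps
  tol <- 1e-6 * target_value
  it <- 0L
  mid <- (lo + hi) / 2
  while (it < 200L) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    fm <- f_at(mid)
    if (abs(fm - target_value) <= tol) break
    if (fm > target_value) lo <- mid else hi <- mid
  }
  list(dose_gy = mid, floor = FALSE, zero_dose = FALSE, iterations = it)
}
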