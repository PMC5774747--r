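#' Configuration of the automated planning controller
#'
#' Bundles the prescription, beam/ring geometry, objective weights and the
#' controller parameters of the stepwise DVH-reduction loop. Defaults
#' encode the pancreatic SBRT setting: 35 Gy prescribed to 95% of the PTV
#' in five fractions; three 1 cm rings at 0.5, 3.5 and 5.5 cm from the
#' target; target/ring/OAR weights 100/80/1; five DVH points equispaced
#' from 1% to 70% of each OAR volume; OAR objective values scaled to 1.05
#' times the largest target objective value; termination when the PTV dose
#' standard deviation reaches 5% of the prescription.
#'
#' @param prescription prescription dose in Gy (total plan dose).
#' @param coverage PTV percent volume that must receive the prescription.
#' @param fractions number of fractions (metadata; all doses are plan
#'   totals).
#' @param n_beams equispaced static beams standing in for arc delivery.
#' @param beamlet_width beamlet width (mm).
#' @param ring_offsets,ring_width ring start distances and thickness (mm).
#' @param weight_target,weight_ring,weight_oar objective weights.
#' @param target_max_factor,target_uniform_factor target max / uniform
#'   objective doses as multiples of the prescription.
#' @param ring_max_fractions,ring_mean_fractions ring max / mean objective
#'   doses as fractions of the prescription, one per ring.
#' @param dvh_fractional_volumes OAR DVH sampling points (%).
#' @param oar_scaling_factor OAR objective values are driven to this
#'   multiple of the largest target objective value (> 1).
#' @param sigma_termination termination limit on the relative PTV dose
#'   standard deviation (fraction of prescription, in (0, 1)).
#' @param max_outer_cycles safety cap on DVH-reduction cycles.
#' @param priority named per-OAR priority multipliers; structures not
#'   named get 1. A multiplier above 1 raises the organ's objective-value
#'   target in the adjustment step, driving its objective doses lower and
#'   so sparing it harder (e.g. `c(duodenum = 2)` doubles the pressure on
#'   the abutting duodenum). Default: no multipliers.
#' @param optimizer an [optimizer_settings()] for the inner cycles.
#' @return An object of class `autoplan_config`.
#' @export
autoplan_config <- function(prescription = 35,
                            coverage = 95,
                            fractions = 5,
                            n_beams = 36,
                            beamlet_width = 5,
                            ring_offsets = c(5, 35, 55),
                            ring_width = 10,
                            weight_target = 100,
                            weight_ring = 80,
                            weight_oar = 1,
                            target_max_factor = 1.07,
                            target_uniform_factor = 1.02,
                            ring_max_fractions = c(0.95, 0.70, 0.45),
                            ring_mean_fractions = c(0.60, 0.35, 0.15),
                            dvh_fractional_volumes = seq(1, 70, length.out = 5),
                            oar_scaling_factor = 1.05,
                            sigma_termination = 0.05,
                            max_outer_cycles = 20,
                            priority = numeric(0),
                            optimizer = optimizer_settings()) {
  stopifnot(prescription > 0, coverage > 0, coverage <= 100,
            oar_scaling_factor > 1,
            sigma_termination > 0, sigma_termination < 1,
            max_outer_cycles >= 1)
  fv <- as.numeric(dvh_fractional_volumes)
  if (any(fv <= 0) || any(fv > 100) || any(diff(fv) <= 0)) {
    stop("dvh_fractional_volumes must be strictly increasing in (0, 100]")
  }
  if (length(ring_max_fractions) != length(ring_offsets) ||
      length(ring_mean_fractions) != length(ring_offsets)) {
    stop("ring dose fractions must have one entry per ring offset")
  }
  structure(
    list(prescription = prescription, coverage = coverage,
         fractions = as.integer(fractions),
         n_beams = as.integer(n_beams), beamlet_width = beamlet_width,
         ring_offsets = ring_offsets, ring_width = ring_width,
         weight_target = weight_target, weight_ring = weight_ring,
         weight_oar = weight_oar,
         target_max_factor = target_max_factor,
         target_uniform_factor = target_uniform_factor,
         ring_max_fractions = ring_max_fractions,
         ring_mean_fractions = ring_mean_fractions,
         dvh_fractional_volumes = fv,
         oar_scaling_factor = oar_scaling_factor,
         sigma_termination = sigma_termination,
         max_outer_cycles = as.integer(max_outer_cycles),
         priority = priority,
         optimizer = optimizer),
    class = "autoplan_config"
  )
}

#' Target and ring objectives (set once, never altered)
#'
#' Each target receives minimum, maximum and uniform dose objectives at
#' `prescription`, `target_max_factor * prescription` and
#' `target_uniform_factor * prescription`, all with the target weight.
#' Each ring `k` receives a maximum and a mean dose objective at the
#' configured fractions of the prescription, with the ring weight. These
#' objectives are fixed for the whole planning run; only OAR objectives
#' are adjusted later.
#'
#' @param structures a `structure_set` with rings already generated.
#' @param cfg an [autoplan_config()].
#' @return list of `objective`s.
#' @export
setup_target_and_ring_objectives <- function(structures, cfg) {
  rings <- structures_by_role(structures, "ring")
  if (!length(rings)) {
    stop("no ring structures present; run generate_rings() first")
  }
  rx <- cfg$prescription
  objs <- list()
  for (tg in structures_by_role(structures, "target")) {
    objs <- c(objs, list(
      objective("min_dose", tg, rx, cfg$weight_target),
      objective("max_dose", tg, cfg$target_max_factor * rx, cfg$weight_target),
      objective("uniform_dose", tg, cfg$target_uniform_factor * rx,
                cfg$weight_target)
    ))
  }
  for (rg in rings) {
    k <- as.integer(sub("^ring_", "", rg$name))
    objs <- c(objs, list(
      objective("max_dose", rg, cfg$ring_max_fractions[k] * rx,
                cfg$weight_ring),
      objective("mean_dose", rg, cfg$ring_mean_fractions[k] * rx,
                cfg$weight_ring)
    ))
  }
  objs
}

#' Normalize a plan so that the covered PTV fraction receives the prescription
#'
#' Scales fluence and dose linearly so that `D_coverage(PTV)` equals the
#' prescription exactly (the dose model is linear, so the rescaling is
#' exact). The scale factor is recorded on the result.
#'
#' @param result an `optimization_result`.
#' @param structures a `structure_set`.
#' @param cfg an [autoplan_config()].
#' @return the rescaled `optimization_result` (with `scale_factor`).
#' @export
normalize_to_prescription <- function(result, structures, cfg) {
  tg <- target_union(structures)
  dcov <- dose_quantile(result$dose[tg], cfg$coverage)
  if (dcov <= 0) stop("target coverage dose is zero; optimization failed")
  f <- cfg$prescription / dcov
  result$fluence <- result$fluence * f
  result$dose <- result$dose * f
  result$scale_factor <- f
  result
}

#' Initial target-plus-rings optimization (controller steps 1-2)
#'
#' Optimizes the fluence against the target and ring objectives only,
#' starting from the uniform reset fluence, then normalizes to the
#' prescription. The aim is solely to reach the prescription on the
#' target; the resulting PTV dose is typically very homogeneous (relative
#' standard deviation of the order of 1-2%).
#'
#' @param D a `dose_influence`.
#' @param objectives target and ring objectives (no OAR objectives
#'   allowed).
#' @param structures a `structure_set`.
#' @param cfg an [autoplan_config()].
#' @return a normalized `optimization_result`.
#' @export
initial_optimize <- function(D, objectives, structures, cfg) {
  roles <- vapply(objectives, `[[`, character(1), "role")
  if (any(roles %in% c("oar_serial", "oar_parallel"))) {
    stop("initial_optimize takes target and ring objectives only")
  }
  res <- optimize_fluence(D, objectives, reset_fluence(D$basis),
                          cfg$optimizer)
  normalize_to_prescription(res, structures, cfg)
}

#' Sample initial OAR objective doses from the cumulative DVH
#'
#' For each organ at risk and each configured fractional volume `v`, reads
#' the dose `D_v` off the current dose distribution. These doses seed the
#' OAR DVH objectives that the reduction loop subsequently drives down.
#'
#' @param dose dose vector over all grid voxels (Gy).
#' @param oars list of `structure_mask` (organs at risk).
#' @param cfg an [autoplan_config()].
#' @return data.frame with columns `structure`, `fractional_volume`,
#'   `dose_gy`. Empty masks are skipped with a warning.
#' @export
sample_initial_oar_doses <- function(dose, oars, cfg) {
  rows <- list()
  for (st in oars) {
    if (!any(st$voxels)) {
      warning(sprintf("OAR '%s' has an empty mask; skipped", st$name))
      next
    }
    d <- dose[st$voxels]
    rows[[st$name]] <- data.frame(
      structure = st$name,
      fractional_volume = cfg$dvh_fractional_volumes,
      dose_gy = vapply(cfg$dvh_fractional_volumes, function(v) {
        dose_quantile(d, v)
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the OAR DVH objectives from sampled seed doses
#'
#' One `dvh_point` objective per OAR and fractional volume, at the seeded
#' dose, with the (uniform) OAR weight.
#'
#' @param structures a `structure_set`.
#' @param seeds the table from [sample_initial_oar_doses()].
#' @param cfg an [autoplan_config()].
#' @return list of `objective`s.
#' @export
build_oar_objectives <- function(structures, seeds, cfg) {
  lapply(seq_len(nrow(seeds)), function(i) {
    objective(
      "dvh_point",
      get_structure(structures, seeds$structure[i]),
      dose_gy = max(seeds$dose_gy[i], 0.01),
      weight = cfg$weight_oar,
      fractional_volume = seeds$fractional_volume[i]
    )
  })
}

#' Rescale the OAR objective doses against the target objectives
#'
#' The adjustment step of the reduction loop: on the current dose
#' distribution, every OAR objective dose is re-solved so that its
#' objective value comes out `oar_scaling_factor` (about 1.05) times the
#' largest target objective value, times the organ's priority multiplier
#' (a higher-priority organ is driven to a lower objective dose, i.e.
#' spared harder). New objective doses are clamped so they never increase
#' across cycles, and organs whose dose is already near zero are held at
#' the 0.01 Gy floor.
#'
#' @param dose current plan dose (Gy).
#' @param oar_objs list of OAR `dvh_point` objectives.
#' @param target_objs list of target objectives (rings are not used as the
#'   reference).
#' @param cfg an [autoplan_config()].
#' @return list with `objectives` (updated list), `target_ref` (largest
#'   target objective value), `adjustments` (data.frame: structure,
#'   fractional volume, old/new dose, clamped/floored flags) and
#'   `no_pressure` (TRUE when the target objectives are all exactly zero,
#'   in which case the objectives are returned unchanged).
#' @export
scale_oar_objectives <- function(dose, oar_objs, target_objs, cfg) {
  tvals <- vapply(target_objs, evaluate_objective, numeric(1), dose = dose)
  target_ref <- max(tvals)
  if (target_ref == 0) {
    return(list(objectives = oar_objs, target_ref = 0,
                adjustments = NULL, no_pressure = TRUE))
  }
  adj <- vector("list", length(oar_objs))
  for (i in seq_along(oar_objs)) {
    obj <- oar_objs[[i]]
    prio <- 1
    if (obj$structure %in% names(cfg$priority)) {
      prio <- cfg$priority[[obj$structure]]
    }
    tv <- cfg$oar_scaling_factor * target_ref * prio
    sol <- solve_objective_dose(obj, dose, tv)
    clamped <- sol$dose_gy > obj$dose_gy
    new_dose <- if (sol$floor) sol$dose_gy else min(sol$dose_gy, obj$dose_gy)
    adj[[i]] <- data.frame(
      structure = obj$structure,
      fractional_volume = obj$fractional_volume,
      dose_old = obj$dose_gy, dose_new = new_dose,
      clamped = clamped, floored = sol$floor,
      stringsAsFactors = FALSE
    )
    obj$dose_gy <- new_dose
    oar_objs[[i]] <- obj
  }
  adjustments <- do.call(rbind, adj)
  rownames(adjustments) <- NULL
  list(objectives = oar_objs, target_ref = target_ref,
       adjustments = adjustments, no_pressure = FALSE)
}

#' Termination test on target dose heterogeneity
#'
#' The reduction loop stops once the PTV dose standard deviation (as a
#' fraction of the prescription) has grown to the configured limit.
#'
#' @param dose dose vector (Gy).
#' @param ptv logical PTV mask (or `structure_mask`).
#' @param cfg an [autoplan_config()].
#' @return list with `terminate` (logical: heterogeneity has reached the
#'   limit) and `sigma_rel` (the relative standard deviation).
#' @export
check_termination <- function(dose, ptv, cfg) {
  if (inherits(ptv, "structure_mask")) ptv <- ptv$voxels
  if (!any(ptv)) stop("PTV mask is empty")
  s <- dose_sd_rel(dose, ptv, cfg$prescription)
  list(terminate = s >= cfg$sigma_termination, sigma_rel = s)
}

#' Run the automated planning loop
#'
#' Executes the full controller: (1) generate rings and the fixed
#' target/ring objectives; (2) initial optimization with those objectives
#' only, normalized to the prescription; (3) sample each OAR's DVH at the
#' configured fractional volumes; (4) build the OAR DVH objectives and
#' scale their doses against the largest target objective value; then loop
#' (5) re-optimize from the reset fluence with all objectives, (6)
#' normalize and test the target-heterogeneity termination criterion, (7)
#' rescale the OAR objective doses downward; until the criterion fires or
#' the cycle cap is reached. The delivered plan is the last one whose
#' heterogeneity stayed below the limit (keep-best-feasible), so the final
#' plan always satisfies the criterion while OAR doses have been pushed as
#' far down as that allows.
#'
#' @param structures a `structure_set` (rings are generated internally if
#'   absent).
#' @param cfg an [autoplan_config()].
#' @param dose_influence optionally a precomputed `dose_influence` for
#'   this geometry (it is recomputed otherwise).
#' @param verbose print per-cycle progress.
#' @return An object of class `autoplan_result`: final `fluence`, `dose`,
#'   `metrics`, the normalized `initial` plan, `structures` (with rings),
#'   `trace` (per-cycle data.frame: sigma, composite objective, target
#'   reference, optimizer iterations), `objective_history` (per-cycle OAR
#'   objective doses; cycle 0 is the state after the first adjustment),
#'   `cycles` (loop cycles executed), `best_cycle` (cycle delivering the
#'   final plan; 0 is the initial plan), `termination_reason`
#'   (`"sigma limit"` or `"cycle cap"`), `sigma_rel`.
#' @export
run_autoplan <- function(structures, cfg = autoplan_config(),
                         dose_influence = NULL, verbose = FALSE) {
  has_rings <- length(structures_by_role(structures, "ring")) > 0
  if (!has_rings) {
    structures <- generate_rings(structures, cfg$ring_offsets, cfg$ring_width)
  }
  tr_objs <- setup_target_and_ring_objectives(structures, cfg)
  if (is.null(dose_influence)) {
    basis <- make_beams(cfg$n_beams, structures,
                        beamlet_width = cfg$beamlet_width)
    dose_influence <- compute_dose_influence(basis, structures)
  }
  D <- dose_influence
  ptv <- target_union(structures)

  init <- initial_optimize(D, tr_objs, structures, cfg)
  sigma0 <- dose_sd_rel(init$dose, ptv, cfg$prescription)
  if (verbose) {
    message(sprintf("initial plan: sigma = %.2f%% of prescription",
                    100 * sigma0))
  }

  oars <- structures_by_role(structures, c("oar_serial", "oar_parallel"))
  seeds <- sample_initial_oar_doses(init$dose, oars, cfg)
  oar_objs <- build_oar_objectives(structures, seeds, cfg)
  sc <- scale_oar_objectives(init$dose, oar_objs, tr_objs, cfg)
  oar_objs <- sc$objectives

  snap <- function(cycle) {
    data.frame(
      cycle = cycle,
      structure = vapply(oar_objs, `[[`, character(1), "structure"),
      fractional_volume = vapply(oar_objs, `[[`, numeric(1),
                                 "fractional_volume"),
      dose_gy = vapply(oar_objs, `[[`, numeric(1), "dose_gy"),
      stringsAsFactors = FALSE
    )
  }
  history <- list(snap(0L))
  trace <- list(data.frame(
    cycle = 0L, sigma_pct = 100 * sigma0, composite = init$objective,
    target_ref = sc$target_ref, iterations = init$iterations,
    optimizer_reason = init$reason, terminated = FALSE,
    stringsAsFactors = FALSE
  ))

  best <- init
  best_cycle <- 0L
  reason <- "cycle cap"
  cycles <- 0L
  all_objs <- function() c(tr_objs, oar_objs)

  for (cycle in seq_len(cfg$max_outer_cycles)) {
    cycles <- cycle
    res <- optimize_fluence(D, all_objs(), reset_fluence(D$basis),
                            cfg$optimizer)
    res <- normalize_to_prescription(res, structures, cfg)
    ct <- check_termination(res$dose, ptv, cfg)
    if (verbose) {
      message(sprintf("cycle %d: sigma = %.2f%%, F = %.4g (%s)", cycle,
                      100 * ct$sigma_rel, res$objective, res$reason))
    }
    trace[[length(trace) + 1L]] <- data.frame(
      cycle = cycle, sigma_pct = 100 * ct$sigma_rel,
      composite = res$objective, target_ref = sc$target_ref,
      iterations = res$iterations, optimizer_reason = res$reason,
      terminated = ct$terminate, stringsAsFactors = FALSE
    )
    if (ct$terminate) {
      reason <- "sigma limit"
      break
    }
    best <- res
    best_cycle <- cycle
    sc <- scale_oar_objectives(res$dose, oar_objs, tr_objs, cfg)
    oar_objs <- sc$objectives
    history[[length(history) + 1L]] <- snap(cycle)
  }

  final <- best
  structure(
    list(
      fluence = final$fluence, dose = final$dose,
      objective = final$objective, breakdown = final$breakdown,
      structures = structures, config = cfg,
      initial = init,
      metrics = plan_metrics(final$dose, structures, cfg$prescription),
      trace = do.call(rbind, trace),
      objective_history = do.call(rbind, history),
      cycles = cycles, best_cycle = best_cycle,
      termination_reason = reason,
      sigma_rel = dose_sd_rel(final$dose, ptv, cfg$prescription)
    ),
    class = "autoplan_result"
  )
}

#' @export
print.autoplan_result <- function(x, ...) {
  cat(sprintf(
    "autoplan_result: %d cycle(s), %s; final PTV sigma = %.2f%% of %g Gy\n",
    x$cycles, x$termination_reason, 100 * x$sigma_rel,
    x$config$prescription
  ))
  print(x$metrics[, c("structure", "role", "D95", "D2", "Dmean", "Dmax",
                      "sigma_pct")])
  invisible(x)
}
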