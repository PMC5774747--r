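#' Inner-loop optimizer settings
#'
#' The inner optimization cycle stops after `max_iterations` accepted
#' iterations (default 100) or when the composite objective changes by less
#' than `objective_change_tolerance` (default 1e-4, absolute) between
#' accepted iterates.
#'
#' @param max_iterations maximum accepted iterations, >= 1.
#' @param objective_change_tolerance absolute stopping tolerance on the
#'   composite objective, > 0.
#' @param armijo_c sufficient-decrease constant of the backtracking line
#'   search.
#' @param max_backtracks step halvings allowed per iteration.
#' @param initial_step starting step length; `NULL` picks one from the
#'   first gradient's scale.
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(max_iterations = 100,
                               objective_change_tolerance = 1e-4,
                               armijo_c = 1e-4,
                               max_backtracks = 60,
                               initial_step = NULL) {
  stopifnot(max_iterations >= 1, objective_change_tolerance > 0,
            armijo_c > 0, max_backtracks >= 1)
  structure(
    list(max_iterations = as.integer(max_iterations),
         objective_change_tolerance = objective_change_tolerance,
         armijo_c = armijo_c,
         max_backtracks = as.integer(max_backtracks),
         initial_step = initial_step),
    class = "optimizer_settings"
  )
}

#' Reset the fluence map to the uniform start
#'
#' Every outer planning cycle restarts the optimization from the same
#' uniform unit fluence (the "reset beams" convention), so cycles differ
#' only through their objectives.
#'
#' @param basis a `beamlet_basis`.
#' @return numeric fluence vector, all weights 1.
#' @export
reset_fluence <- function(basis) {
  rep(1, n_beamlets(basis))
}

#' Optimize a fluence map against a composite objective
#'
#' Projected gradient descent under the non-negativity bound: the fluence
#' gradient is `t(D) %*% g` with `g` the composite voxel-dose gradient;
#' steps are projected onto `x >= 0` and accepted under an Armijo
#' sufficient-decrease backtracking line search, so the accepted objective
#' sequence is non-increasing. The trial step each iteration is the
#' Barzilai-Borwein spectral step (a curvature estimate from the last two
#' gradients), which makes the monotone first-order method converge fast
#' enough to be useful within the 100-iteration inner budget. Stops at
#' `max_iterations`, when the objective change between accepted iterates
#' falls below the tolerance, or when no descent step can be found (a
#' bound-constrained stationary point).
#'
#' @param D a `dose_influence`.
#' @param objs nonempty list of `objective`s on `D`'s grid.
#' @param x0 starting fluence (defaults to [reset_fluence()]).
#' @param settings an [optimizer_settings()].
#' @return An object of class `optimization_result`: `fluence`, `dose`,
#'   `objective` (final composite value), `breakdown`, `trace` (accepted
#'   composite values, starting point first), `iterations`, `reason`
#'   (`"tolerance"` or `"max_iterations"`).
#' @export
optimize_fluence <- function(D, objs, x0 = NULL,
                             settings = optimizer_settings()) {
  if (!length(objs)) stop("objective list is empty")
  M <- D$matrix
  if (is.null(x0)) x0 <- reset_fluence(D$basis)
  x <- as.numeric(x0)
  if (length(x) != ncol(M)) stop("x0 length does not match beamlet count")
  if (any(x < 0)) stop("starting fluence must be non-negative")

  dose <- as.numeric(M %*% x)
  comp <- composite_objective(objs, dose)
  fval <- comp$value
  .check_finite <- function(br) {
    if (all(is.finite(br))) return(invisible())
    bad <- names(br)[!is.finite(br)]
    stop(sprintf("non-finite objective value for %s",
                 paste(bad, collapse = ", ")))
  }
  .check_finite(comp$breakdown)

  trace <- fval
  step <- settings$initial_step
  reason <- "max_iterations"
  iterations <- 0L
  tol <- settings$objective_change_tolerance

  for (k in seq_len(settings$max_iterations)) {
    gvox <- composite_gradient(objs, dose)
    g <- as.numeric(Matrix::crossprod(M, gvox))
    if (!all(is.finite(g))) {
      br <- vapply(objs, function(o) {
        sum(objective_gradient(o, dose))
      }, numeric(1))
      names(br) <- vapply(objs, objective_label, character(1))
      .check_finite(br)
      stop("non-finite fluence gradient")
    }
    if (k > 1L) {
      # Barzilai-Borwein spectral trial step from the last accepted move
      sx <- x - x_prev
      sy <- g - g_prev
      num <- sum(sx * sx); den <- sum(sx * sy)
      if (is.finite(den) && den > 0 && num > 0) step <- num / den
    }
    if (is.null(step)) {
      gm <- max(abs(g))
      step <- if (gm > 0) max(x, 1) / gm else 1
    }
    accepted <- FALSE
    s <- step
    for (bt in seq_len(settings$max_backtracks)) {
      xn <- pmax(x - s * g, 0)
      dn <- as.numeric(M %*% xn)
      cn <- composite_objective(objs, dn)
      .check_finite(cn$breakdown)
      # Armijo: decrease at least proportional to the projected step
      if (cn$value <= fval - settings$armijo_c * sum(g * (x - xn))) {
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    iterations <- k
    if (!accepted) {
      # no descent direction left: treat as converged
      reason <- "tolerance"
      trace <- c(trace, fval)
      break
    }
    dF <- fval - cn$value
    x_prev <- x; g_prev <- g
    x <- xn; dose <- dn; fval <- cn$value; comp <- cn
    trace <- c(trace, fval)
    step <- s * 2
    if (dF < tol) {
      reason <- "tolerance"
      break
    }
  }

  structure(
    list(fluence = x, dose = dose, objective = fval,
         breakdown = comp$breakdown, trace = trace,
         iterations = iterations, reason = reason),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "optimization_result: F = %.6g after %d iterations (%s)\n",
    x$objective, x$iterations, x$reason
  ))
  invisible(x)
}
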