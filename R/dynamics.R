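#' Declare the system-level output of an analysis
#'
#' The three kinds of output the sensitivity analyses differentiate: a
#' steady-state concentration, a steady-state flux, or the oscillation
#' period of a named variable.
#'
#' @param kind `"concentration"` (steady-state concentration of a
#'   species), `"flux"` (steady-state velocity of a reaction), or
#'   `"period"` (oscillation period of an observed species).
#' @param target species id (`concentration`, `period`) or reaction id
#'   (`flux`).
#' @param t_end total simulated time for period detection (model time
#'   units; must be long enough for several oscillations after the
#'   transient).
#' @param transient_frac fraction of the simulated window discarded as
#'   transient before maxima are collected (default 0.5).
#' @param n_points number of output points of the period time course.
#' @param min_maxima minimum number of post-transient maxima required for
#'   a defined period (default 3).
#' @return an object of class `output_spec`.
#' @export
output_spec <- function(kind = c("concentration", "flux", "period"),
                        target, t_end = 100, transient_frac = 0.5,
                        n_points = 4000, min_maxima = 3) {
  kind <- match.arg(kind)
  stopifnot(t_end > 0, transient_frac >= 0, transient_frac < 1)
  structure(list(kind = kind, target = target, t_end = t_end,
                 transient_frac = transient_frac, n_points = n_points,
                 min_maxima = min_maxima),
            class = "output_spec")
}

validate_spec <- function(model, spec) {
  stopifnot(inherits(spec, "output_spec"))
  if (spec$kind == "flux") {
    rids <- vapply(model$reactions, `[[`, "", "id")
    if (!spec$target %in% rids)
      stop("flux target '", spec$target, "' is not a reaction of the model")
  } else {
    if (!spec$target %in% model$species$id)
      stop("target '", spec$target, "' is not a species of the model")
  }
  invisible(spec)
}

#' Integrate the model in time
#'
#' Stiff-capable integration (LSODA) of the model ODEs. Integration
#' failures (blow-up, step-size collapse) are flagged in the returned
#' object rather than raised, so batch sampling runs are not aborted by a
#' single pathological parameter set.
#'
#' @param model a [kinetic_model()].
#' @param params named parameter vector (defaults to the reference set).
#' @param t_end end time (> 0).
#' @param n_points number of stored output points after `t = 0`.
#' @param y0 initial state; defaults to the model's reference state.
#' @param rtol,atol relative / absolute integration tolerances.
#' @return an object of class `trajectory`: list with `times`, `states`
#'   (time x species matrix), `status` (`"ok"` or `"failed"`), and
#'   `last_time` (last successfully integrated time).
#' @export
simulate <- function(model, params = reference_params(model), t_end,
                     n_points = 1000, y0 = reference_state(model),
                     rtol = 1e-8, atol = 1e-12) {
  stopifnot(t_end > 0)
  params <- parameter_set(model, params)
  rhs <- build_rhs(model)
  dfun <- function(t, y, p) list(rhs(y, p, t))
  times <- seq(0, t_end, length.out = n_points + 1)
  out <- try(suppressWarnings(
    deSolve::lsoda(y = y0, times = times, func = dfun, parms = params,
                   rtol = rtol, atol = atol)), silent = TRUE)
  if (inherits(out, "try-error")) {
    return(structure(list(times = numeric(0), states = NULL,
                          status = "failed", last_time = 0),
                     class = "trajectory"))
  }
  st <- as.matrix(out[, -1, drop = FALSE])
  finite <- apply(is.finite(st), 1, all)
  nok <- if (all(finite)) nrow(st) else max(0, which(!finite)[1] - 1)
  complete <- nok == length(times) &&
    abs(out[nrow(out), 1] - t_end) <= 1e-8 * max(1, t_end)
  structure(list(
    times = out[seq_len(nok), 1],
    states = st[seq_len(nok), , drop = FALSE],
    status = if (complete) "ok" else "failed",
    last_time = if (nok) out[nok, 1] else 0
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " points, status ", x$status,
      ", t in [0, ", format(x$last_time), "]\n", sep = "")
  invisible(x)
}

#' Write a trajectory to a TSV file
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
trajectory_tsv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

newton_polish <- function(rhs, x, params, free, tol, max_iter = 50) {
  # damped Newton on the free (non-boundary) coordinates
  n <- length(free)
  fx <- rhs(x, params)[free]
  for (it in seq_len(max_iter)) {
    nf <- sqrt(sum(fx^2))
    if (!is.finite(nf)) return(list(x = x, ok = FALSE, residual = nf))
    if (nf <= tol) break
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * (abs(x[free[j]]) + 1e-7)
      xp <- x; xp[free[j]] <- xp[free[j]] + h
      xm <- x; xm[free[j]] <- xm[free[j]] - h
      J[, j] <- (rhs(xp, params)[free] - rhs(xm, params)[free]) / (2 * h)
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      return(list(x = x, ok = FALSE, residual = nf))
    lambda <- 1
    improved <- FALSE
    for (ls in 1:25) {
      xt <- x
      xt[free] <- x[free] + lambda * step
      ft <- rhs(xt, params)[free]
      nt <- sqrt(sum(ft^2))
      if (is.finite(nt) && nt < nf) {
        x <- xt; fx <- ft; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) return(list(x = x, ok = FALSE, residual = nf))
  }
  nf <- sqrt(sum(rhs(x, params)[free]^2))
  list(x = x, ok = nf <= tol, residual = nf)
}

#' Find a steady state of the model
#'
#' Damped Newton iteration started from the reference state, with a
#' fallback to staged long-time integration followed by a Newton polish.
#' Stability is judged from the sign of the dominant eigenvalue of the
#' Jacobian (reported, but no sample is discarded for being unstable).
#'
#' @param model a [kinetic_model()].
#' @param params named parameter vector.
#' @param x0 starting state (defaults to the reference state; pass a
#'   previously found steady state to warm-start nearby solves).
#' @param tol residual tolerance on the RHS norm (default 1e-9).
#' @return an object of class `steady_state`: `concentrations` (full named
#'   state), `fluxes` (reaction velocities there), `stable`, `residual`,
#'   `status` (`"ok"` or `"undefined"`), `reason`.
#' @export
find_steady_state <- function(model, params = reference_params(model),
                              x0 = reference_state(model), tol = 1e-9) {
  params <- parameter_set(model, params)
  rhs <- build_rhs(model)
  free <- which(!model$species$boundary)
  if (length(free) == 0) stop("model has no non-boundary species")
  scale_tol <- tol * (1 + max(abs(x0)))

  res <- newton_polish(rhs, x0, params, free, scale_tol)
  if (!res$ok) {
    # fallback: relax toward the attractor by integration, then polish
    x <- x0
    prev <- Inf
    for (t_stage in c(10, 100, 1000, 1e4, 1e5)) {
      tr <- simulate(model, params, t_end = t_stage, n_points = 50, y0 = x,
                     rtol = 1e-8, atol = 1e-10)
      if (is.null(tr$states) || nrow(tr$states) == 0) break
      x <- tr$states[nrow(tr$states), ]
      nf <- sqrt(sum(rhs(x, params)[free]^2))
      if (!is.finite(nf)) break
      if (nf <= scale_tol) break
      if (nf > 0.9 * prev && t_stage >= 100) break # not relaxing: diverging
      prev <- nf
    }
    res <- newton_polish(rhs, x, params, free, scale_tol)
  }
  if (!res$ok) {
    return(structure(list(concentrations = NULL, fluxes = NULL,
                          stable = NA, residual = res$residual,
                          status = "undefined", reason = "no-steady-state"),
                     class = "steady_state"))
  }
  x <- res$x
  # stability from the Jacobian at the root
  n <- length(free)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * (abs(x[free[j]]) + 1e-7)
    xp <- x; xp[free[j]] <- xp[free[j]] + h
    xm <- x; xm[free[j]] <- xm[free[j]] - h
    J[, j] <- (rhs(xp, params)[free] - rhs(xm, params)[free]) / (2 * h)
  }
  ev <- tryCatch(eigen(J, only.values = TRUE)$values, error = function(e) NA)
  stable <- if (all(is.finite(Re(ev)))) max(Re(ev)) < 0 else NA
  structure(list(
    concentrations = x,
    fluxes = reaction_rates(model, x, params),
    stable = stable,
    residual = res$residual,
    status = "ok", reason = NA_character_
  ), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  if (x$status == "ok") {
    cat("<steady_state> residual ", format(x$residual),
        if (isTRUE(x$stable)) ", stable" else ", not stable", "\n", sep = "")
  } else {
    cat("<steady_state> undefined (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

# Locate maxima of the observed variable: sign changes (+ -> -) of its
# exact time derivative evaluated along the stored trajectory, refined by
# the root of a quadratic through the three bracketing derivative values.
# Decouples the period estimate from the output grid resolution.
refine_max <- function(t3, g3) {
  fit <- try(solve(cbind(1, t3, t3^2), g3), silent = TRUE)
  if (inherits(fit, "try-error") || abs(fit[3]) < 1e-300) {
    # fall back to the secant root of the bracketing pair
    return(t3[2] - g3[2] * (t3[3] - t3[2]) / (g3[3] - g3[2]))
  }
  a <- fit[3]; b <- fit[2]; c0 <- fit[1]
  disc <- b^2 - 4 * a * c0
  if (disc < 0) return(t3[2])
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  roots <- roots[roots >= t3[1] & roots <= t3[3]]
  if (length(roots) == 0) return(t3[2])
  roots[which.min(abs(roots - t3[2]))]
}

#' Measure the oscillation period of a model variable
#'
#' Integrates the model over `spec$t_end`, discards the transient, locates
#' the maxima of the observed variable (sign changes of its derivative,
#' refined by local quadratic interpolation) and returns the mean of the
#' successive maximum-to-maximum intervals. The period is undefined when
#' fewer than `spec$min_maxima` maxima occur after the transient, when the
#' intervals are irregular (coefficient of variation above `cv_tol`), or
#' when the oscillation is damped (systematic amplitude decay beyond
#' `amp_tol`).
#'
#' @param model a [kinetic_model()].
#' @param params named parameter vector.
#' @param spec an [output_spec()] with `kind = "period"`.
#' @param cv_tol maximum coefficient of variation of successive intervals.
#' @param amp_tol maximum relative drift of maxima heights across the
#'   retained window.
#' @return a list with `value` (the period, or `NA`), `status`
#'   (`"ok"`/`"undefined"`) and `reason`.
#' @export
detect_period <- function(model, params = reference_params(model), spec,
                          cv_tol = 0.05, amp_tol = 0.05) {
  stopifnot(spec$kind == "period")
  validate_spec(model, spec)
  params <- parameter_set(model, params)
  tr <- simulate(model, params, t_end = spec$t_end,
                 n_points = spec$n_points)
  if (tr$status != "ok") return(out_undefined("integration-failure"))
  rhs <- build_rhs(model)
  idx <- match(spec$target, model$species$id)
  g <- vapply(seq_along(tr$times), function(i)
    rhs(tr$states[i, ], params, tr$times[i])[idx], numeric(1))
  y <- tr$states[, idx]
  t_cut <- spec$transient_frac * spec$t_end
  t_max <- numeric(0)
  h_max <- numeric(0)
  for (i in seq_len(length(g) - 1)) {
    if (g[i] > 0 && g[i + 1] <= 0) {
      i0 <- max(1, i - 1)
      tm <- refine_max(tr$times[c(i0, i, i + 1)], g[c(i0, i, i + 1)])
      if (tm >= t_cut) {
        t_max <- c(t_max, tm)
        h_max <- c(h_max, max(y[i], y[i + 1]))
      }
    }
  }
  if (length(t_max) < spec$min_maxima)
    return(out_undefined("no-oscillation"))
  intervals <- diff(t_max)
  if (mean(intervals) <= 0) return(out_undefined("no-oscillation"))
  if (sd(intervals) / mean(intervals) > cv_tol)
    return(out_undefined("no-oscillation"))
  span <- max(abs(h_max))
  if (span > 0 && abs(h_max[length(h_max)] - h_max[1]) / span > amp_tol)
    return(out_undefined("no-oscillation"))
  out_value(mean(intervals))
}

#' Evaluate the declared output of a model
#'
#' Dispatch uniting the three output kinds: routes to the steady-state
#' solver or the period detector; undefined statuses propagate untouched.
#'
#' @param model a [kinetic_model()].
#' @param params named parameter vector.
#' @param spec an [output_spec()].
#' @param x0 optional starting state for steady-state solves (warm start).
#' @return a list with `value`, `status`, `reason`, and (for steady-state
#'   kinds) `state`, the steady state found, usable as the next warm
#'   start.
#' @export
evaluate_output <- function(model, params = reference_params(model), spec,
                            x0 = NULL) {
  validate_spec(model, spec)
  if (spec$kind == "period") {
    return(detect_period(model, params, spec))
  }
  ss <- find_steady_state(model, params,
                          x0 = x0 %||% reference_state(model))
  if (ss$status != "ok") return(out_undefined(ss$reason))
  val <- if (spec$kind == "concentration") ss$concentrations[[spec$target]]
         else ss$fluxes[[spec$target]]
  out <- out_value(val)
  out$state <- ss$concentrations
  out
}
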