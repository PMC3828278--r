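#' Particle swarm optimiser settings
#'
#' Swarm size and iteration limit follow the per-model settings of the
#' analyses this package supports (e.g. 50 particles x 2000 iterations for
#' a cheap steady-state model, 10 x 100 for an expensive oscillatory one).
#' The velocity-update coefficients default to the constriction-factor
#' values (inertia 0.7298, cognitive = social = 1.4962).
#'
#' @param swarm_size number of particles (>= 2).
#' @param max_iter iteration limit (>= 1).
#' @param inertia inertia weight.
#' @param c_cog,c_soc cognitive / social acceleration coefficients.
#' @param seed RNG seed for initialisation and velocity updates.
#' @return an object of class `swarm_settings`.
#' @export
swarm_settings <- function(swarm_size = 20, max_iter = 100,
                           inertia = 0.7298, c_cog = 1.4962,
                           c_soc = 1.4962, seed = 1) {
  stopifnot(swarm_size >= 2, max_iter >= 1)
  structure(list(swarm_size = swarm_size, max_iter = max_iter,
                 inertia = inertia, c_cog = c_cog, c_soc = c_soc,
                 seed = seed),
            class = "swarm_settings")
}

#' Global-best particle swarm minimisation over a parameter domain
#'
#' Standard global-best PSO: positions initialised uniformly in the
#' hypercube, velocities updated with inertia + cognitive + social terms,
#' positions clamped to the domain with the velocity zeroed on clamped
#' coordinates. An undefined objective value (`NA`) is treated as
#' worst-possible fitness, so the swarm retreats from non-viable regions;
#' the number of such encounters is reported. Deterministic given the
#' seed in `settings`.
#'
#' @param objective `function(params) -> scalar or NA`, where `params` is
#'   a named vector over the domain.
#' @param domain a [parameter_domain()].
#' @param settings a [swarm_settings()].
#' @return list with `value` (best objective), `par` (best parameter
#'   set), `trace` (best value by iteration), `evaluations`,
#'   `n_undefined`, and `status` (`"ok"`, or `"failed"` when every
#'   evaluation was undefined).
#' @export
pso_minimize <- function(objective, domain, settings = swarm_settings()) {
  lo <- domain$lower
  hi <- domain$upper
  p <- length(lo)
  free <- which(hi > lo)
  if (length(free) == 0) {
    # fully degenerate domain: single evaluation at the reference point
    par <- domain$reference
    val <- objective(par)
    bad <- is.na(val)
    return(list(value = if (bad) NA_real_ else val, par = par,
                trace = if (bad) numeric(0) else val,
                evaluations = 1L, n_undefined = as.integer(bad),
                status = if (bad) "failed" else "ok"))
  }
  set.seed(settings$seed)
  ns <- settings$swarm_size
  X <- matrix(runif(ns * p, rep(lo, each = ns), rep(hi, each = ns)), ns, p)
  colnames(X) <- names(lo)
  V <- matrix(0, ns, p)
  n_undef <- 0L
  evals <- 0L
  eval_at <- function(x) {
    v <- objective(setNames(x, names(lo)))
    evals <<- evals + 1L
    if (is.na(v) || !is.finite(v)) {
      n_undef <<- n_undef + 1L
      return(Inf)
    }
    v
  }
  fit <- apply(X, 1, eval_at)
  pbest_x <- X
  pbest_f <- fit
  g <- which.min(fit)
  gbest_x <- X[g, ]
  gbest_f <- fit[g]
  trace <- numeric(settings$max_iter)
  for (it in seq_len(settings$max_iter)) {
    r1 <- matrix(runif(ns * p), ns, p)
    r2 <- matrix(runif(ns * p), ns, p)
    V <- settings$inertia * V +
      settings$c_cog * r1 * (pbest_x - X) +
      settings$c_soc * r2 * sweep(X, 2, gbest_x, function(x, g) g - x, FALSE)
    X <- X + V
    # clamp to the domain, zeroing velocity on clamped coordinates
    for (j in seq_len(p)) {
      below <- X[, j] < lo[j]
      above <- X[, j] > hi[j]
      X[below, j] <- lo[j]
      X[above, j] <- hi[j]
      V[below | above, j] <- 0
    }
    fit <- apply(X, 1, eval_at)
    better <- fit < pbest_f
    pbest_x[better, ] <- X[better, , drop = FALSE]
    pbest_f[better] <- fit[better]
    g <- which.min(pbest_f)
    if (pbest_f[g] < gbest_f) {
      gbest_f <- pbest_f[g]
      gbest_x <- pbest_x[g, ]
    }
    trace[it] <- gbest_f
  }
  if (!is.finite(gbest_f)) {
    return(list(value = NA_real_, par = NULL, trace = trace,
                evaluations = evals, n_undefined = n_undef,
                status = "failed"))
  }
  list(value = gbest_f, par = setNames(gbest_x, names(lo)), trace = trace,
       evaluations = evals, n_undefined = n_undef, status = "ok")
}

#' Optimisation-based bounds on a sensitivity coefficient
#'
#' Runs two particle-swarm optimisations over the domain -- one minimising
#' the scaled sensitivity of the declared output to the given parameter,
#' one minimising its negation -- and reports the lower and upper bounds
#' together with the parameter sets attaining them.
#'
#' @param model a [kinetic_model()].
#' @param domain a [parameter_domain()].
#' @param spec an [output_spec()].
#' @param parameter id of the parameter whose coefficient is bounded; must
#'   be scalable (nonzero) at the reference point.
#' @param settings a [swarm_settings()]; the upper-bound search uses
#'   `seed + 1`.
#' @param rel_step relative finite-difference step for the objective.
#' @return an object of class `sensitivity_bounds`: `lower`, `upper`,
#'   `argmin`, `argmax`, per-side traces, evaluation and undefined counts,
#'   `status`.
#' @export
sensitivity_bounds <- function(model, domain, spec, parameter,
                               settings = swarm_settings(),
                               rel_step = 0.001) {
  validate_spec(model, spec)
  if (domain$reference[[parameter]] == 0)
    stop("parameter '", parameter, "' is not scalable at the reference")
  objective <- function(params) {
    params <- parameter_set(model, params)
    if (params[[parameter]] == 0) return(NA_real_)
    base <- evaluate_output(model, params, spec)
    res <- sens_one(model, params, spec, parameter, rel_step, "forward",
                    base)
    if (res$status != "ok") NA_real_ else res$value
  }
  s_up <- settings
  s_up$seed <- settings$seed + 1L
  lo <- pso_minimize(objective, domain, settings)
  up <- pso_minimize(function(p) {
    v <- objective(p)
    if (is.na(v)) NA_real_ else -v
  }, domain, s_up)
  status <- if (lo$status == "ok" && up$status == "ok") "ok" else "failed"
  structure(list(
    parameter = parameter, band = domain$band,
    lower = lo$value,
    upper = if (up$status == "ok") -up$value else NA_real_,
    argmin = lo$par, argmax = up$par,
    trace_lower = lo$trace, trace_upper = -up$trace,
    evaluations = lo$evaluations + up$evaluations,
    n_undefined = lo$n_undefined + up$n_undefined,
    objective = objective,
    status = status
  ), class = "sensitivity_bounds")
}

#' @export
print.sensitivity_bounds <- function(x, ...) {
  cat("<sensitivity_bounds> ", x$parameter, " (band +/-", x$band * 100,
      "%): [", format(x$lower), ", ", format(x$upper), "], ",
      x$evaluations, " evaluations\n", sep = "")
  invisible(x)
}

#' Compare optimisation bounds with a sampling run
#'
#' Neither evidence source dominates in general: the swarm can overshoot
#' every sampled extreme, or fail to reach values that brute-force
#' sampling stumbled on. This reports the comparison instead of assuming
#' a direction: positive shortfalls mean the sampling run escaped the
#' optimisation bounds on that side.
#'
#' @param bounds a [sensitivity_bounds()] result.
#' @param dist a [summarize_distribution()] result for the same
#'   parameter, domain and output.
#' @return list with `sampled_min`, `sampled_max`, `lower_shortfall`
#'   (`bounds$lower - sampled_min`), `upper_shortfall`
#'   (`sampled_max - bounds$upper`), and `dominated` (`TRUE` when the
#'   bounds enclose every sampled value).
#' @export
compare_bounds_sampling <- function(bounds, dist) {
  stopifnot(inherits(bounds, "sensitivity_bounds"),
            inherits(dist, "sensitivity_distribution"))
  if (isTRUE(dist$empty) || bounds$status != "ok")
    return(list(sampled_min = NA_real_, sampled_max = NA_real_,
                lower_shortfall = NA_real_, upper_shortfall = NA_real_,
                dominated = NA))
  ls <- bounds$lower - dist$min
  us <- dist$max - bounds$upper
  list(sampled_min = dist$min, sampled_max = dist$max,
       lower_shortfall = ls, upper_shortfall = us,
       dominated = ls <= 0 && us <= 0)
}

#' Write a table of sensitivity bounds to CSV
#'
#' @param bounds_list list of `sensitivity_bounds` objects.
#' @param path output file path.
#' @param local_values optional named vector of local coefficients to
#'   include alongside the bounds.
#' @return `path`, invisibly.
#' @export
write_bounds_csv <- function(bounds_list, path, local_values = NULL) {
  df <- do.call(rbind, lapply(bounds_list, function(b)
    data.frame(parameter = b$parameter, band = b$band, lower = b$lower,
               upper = b$upper,
               local = if (is.null(local_values)) NA_real_
                       else unname(local_values[b$parameter]))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
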