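#' Create a kinetic reaction-network model
#'
#' The central container of the package: an ODE model of a biochemical
#' network given either as a set of reactions with kinetic rate laws, as a
#' set of explicit rate rules (raw ODEs), or a mixture of both. All
#' analyses (steady states, periods, sensitivities, global sampling)
#' operate on this object.
#'
#' Species states are concentrations. The time derivative of a
#' non-boundary species is the stoichiometry-weighted sum of its reaction
#' rates divided by the volume of its compartment (rate laws are in
#' substance/time, the usual SBML convention); boundary species are held
#' constant. A rate rule overrides the reaction-derived derivative of its
#' target species.
#'
#' @param species data frame with columns `id`, `initial` (reference
#'   concentration), and optionally `compartment` (default `"cell"`) and
#'   `boundary` (logical, default `FALSE`). A named numeric vector is
#'   accepted as shorthand.
#' @param reactions list of [reaction()] objects (may be empty if
#'   `rate_rules` is given).
#' @param parameters data frame with columns `id`, `value` and optionally
#'   `role` (`"limiting-rate"` or `"other"`); or a named numeric vector.
#'   Values are the reference (published) parameter set.
#' @param compartments data frame with columns `id`, `volume`; defaults to
#'   a single unit-volume compartment `"cell"`.
#' @param rate_rules named character vector or list mapping a species id to
#'   an expression for its time derivative.
#' @param id model identifier string.
#' @return an object of class `kinetic_model`.
#' @examples
#' m <- make_irreversible_chain(2, k = c(2, 4), x0 = 1)$model
#' rhs <- build_rhs(m)
#' rhs(reference_state(m), reference_params(m))
#' @export
kinetic_model <- function(species, reactions = list(), parameters,
                          compartments = NULL, rate_rules = NULL,
                          id = "model") {
  if (is.numeric(species) && !is.null(names(species))) {
    species <- data.frame(id = names(species), initial = unname(species))
  }
  species <- as.data.frame(species)
  if (is.null(species$compartment)) species$compartment <- "cell"
  if (is.null(species$boundary)) species$boundary <- FALSE
  stopifnot(all(c("id", "initial") %in% names(species)))

  if (is.null(compartments)) {
    compartments <- data.frame(id = unique(species$compartment), volume = 1)
  }
  compartments <- as.data.frame(compartments)

  if (is.numeric(parameters) && !is.null(names(parameters))) {
    parameters <- data.frame(id = names(parameters), value = unname(parameters))
  }
  parameters <- as.data.frame(parameters)
  if (is.null(parameters$role)) parameters$role <- "other"

  if (!is.null(rate_rules)) {
    rate_rules <- as.list(rate_rules)
    rate_rules <- lapply(rate_rules, function(x) {
      if (is.character(x)) str2lang(x) else x
    })
  }

  m <- structure(list(
    id = id,
    species = species,
    compartments = compartments,
    reactions = reactions,
    parameters = parameters,
    rate_rules = rate_rules
  ), class = "kinetic_model")
  validate_kinetic_model(m)
  m
}

#' Define a reaction
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector: signed stoichiometric coefficients
#'   by species id (negative = consumed).
#' @param rate kinetic rate law, as a string or unevaluated expression over
#'   species, parameters and compartment volumes (substance/time).
#' @return an object of class `reaction`.
#' @export
reaction <- function(id, stoich, rate) {
  if (length(stoich) == 0 || is.null(names(stoich)))
    stop("reaction '", id, "': stoichiometry must be a named, nonempty vector")
  if (is.character(rate)) rate <- str2lang(rate)
  structure(list(id = id, stoich = stoich, rate = rate), class = "reaction")
}

validate_kinetic_model <- function(m) {
  sp <- m$species
  if (anyDuplicated(sp$id))
    stop("species ids must be unique")
  if (anyDuplicated(m$parameters$id))
    stop("parameter ids must be unique")
  if (!all(is.finite(m$parameters$value)))
    stop("reference parameter values must be finite: ",
         paste(m$parameters$id[!is.finite(m$parameters$value)], collapse = ", "))
  if (length(m$reactions) == 0 && length(m$rate_rules %||% list()) == 0)
    stop("model must have at least one reaction or rate rule")
  if (!all(sp$compartment %in% m$compartments$id))
    stop("species reference unknown compartment")
  known <- c(sp$id, m$parameters$id, m$compartments$id, "t", "time")
  check_expr <- function(e, where) {
    bad <- setdiff(all.vars(e), known)
    if (length(bad))
      stop("unresolved symbol(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  for (r in m$reactions) {
    unknown_sp <- setdiff(names(r$stoich), sp$id)
    if (length(unknown_sp))
      stop("reaction '", r$id, "' references unknown species: ",
           paste(unknown_sp, collapse = ", "))
    check_expr(r$rate, paste0("rate law of '", r$id, "'"))
  }
  for (tgt in names(m$rate_rules %||% list())) {
    if (!tgt %in% sp$id)
      stop("rate rule targets unknown species '", tgt, "'")
    check_expr(m$rate_rules[[tgt]], paste0("rate rule for '", tgt, "'"))
  }
  # rate laws must evaluate finitely at the reference state
  rhs <- build_rhs(m)
  d <- rhs(reference_state(m), reference_params(m), t = 0)
  if (!all(is.finite(d)))
    stop("RHS is not finite at the reference state")
  invisible(m)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", x$id, "\n",
      "  species:    ", nrow(x$species),
      " (", sum(x$species$boundary), " boundary)\n",
      "  reactions:  ", length(x$reactions), "\n",
      "  rate rules: ", length(x$rate_rules %||% list()), "\n",
      "  parameters: ", nrow(x$parameters), "\n", sep = "")
  invisible(x)
}

#' Reference parameter set of a model
#'
#' @param model a `kinetic_model`.
#' @return named numeric vector of reference parameter values (the
#'   operating point around which variation bands are defined).
#' @export
reference_params <- function(model) {
  setNames(model$parameters$value, model$parameters$id)
}

#' Reference state (initial concentrations) of a model
#'
#' @param model a `kinetic_model`.
#' @return named numeric vector of species concentrations.
#' @export
reference_state <- function(model) {
  setNames(model$species$initial, model$species$id)
}

#' Validate and complete a parameter set
#'
#' @param model a `kinetic_model`.
#' @param values named numeric vector or list of parameter values.
#' @return named numeric vector ordered as `model$parameters$id`.
#' @export
parameter_set <- function(model, values) {
  values <- unlist(values)
  ids <- model$parameters$id
  missing <- setdiff(ids, names(values))
  if (length(missing))
    stop("incomplete parameter set; missing: ", paste(missing, collapse = ", "))
  out <- values[ids]
  if (!all(is.finite(out)))
    stop("non-finite parameter value(s): ",
         paste(ids[!is.finite(out)], collapse = ", "))
  out
}

#' Replace the parameter values of a model
#'
#' Returns a view of the model evaluated at a different parameter set; the
#' original model is unmodified.
#'
#' @param model a `kinetic_model`.
#' @param params complete named parameter vector (see [parameter_set()]).
#' @return a `kinetic_model` with the given reference values.
#' @export
apply_parameters <- function(model, params) {
  params <- parameter_set(model, params)
  model$parameters$value <- unname(params)
  model
}

#' Compile the right-hand side of the model ODE system
#'
#' Resolution of every symbol in every rate law / rate rule happens here,
#' at build time; unknown symbols raise an error before any integration is
#' attempted.
#'
#' @param model a `kinetic_model`.
#' @return `function(state, params, t = 0)` returning the named derivative
#'   vector (d concentration / d time). Boundary species have derivative 0.
#' @export
build_rhs <- function(model) {
  sp <- model$species
  n_sp <- nrow(sp)
  sp_ids <- sp$id
  boundary <- sp$boundary
  vols <- setNames(model$compartments$volume, model$compartments$id)
  sp_vol <- unname(vols[sp$compartment])
  n_rx <- length(model$reactions)
  N <- matrix(0, n_sp, n_rx, dimnames = list(sp_ids, NULL))
  rates <- vector("list", n_rx)
  if (n_rx) {
    for (j in seq_len(n_rx)) {
      r <- model$reactions[[j]]
      N[names(r$stoich), j] <- r$stoich
      rates[[j]] <- r$rate
    }
  }
  rules <- model$rate_rules %||% list()
  rule_idx <- match(names(rules), sp_ids)

  known <- c(sp_ids, model$parameters$id, model$compartments$id, "t", "time")
  for (e in c(rates, unname(rules))) {
    bad <- setdiff(all.vars(e), known)
    if (length(bad))
      stop("cannot build RHS: unresolved symbol(s) ",
           paste(bad, collapse = ", "))
  }

  env <- new.env(parent = baseenv())
  for (k in seq_along(vols)) assign(names(vols)[k], vols[[k]], envir = env)

  function(state, params, t = 0) {
    e <- env
    pn <- names(params)
    for (k in seq_along(params)) assign(pn[k], params[[k]], envir = e)
    for (k in seq_len(n_sp)) assign(sp_ids[k], state[[k]], envir = e)
    assign("t", t, envir = e)
    assign("time", t, envir = e)
    if (n_rx) {
      v <- vapply(rates, eval, numeric(1), envir = e)
      d <- as.vector(N %*% v) / sp_vol
    } else {
      d <- numeric(n_sp)
    }
    d[boundary] <- 0
    if (length(rule_idx)) {
      for (k in seq_along(rule_idx)) {
        d[rule_idx[k]] <- eval(rules[[k]], envir = e)
      }
    }
    names(d) <- sp_ids
    d
  }
}

#' Evaluate all reaction rates at a given state
#'
#' @param model a `kinetic_model`.
#' @param state named concentration vector.
#' @param params named parameter vector.
#' @param t time (for explicitly time-dependent rate laws).
#' @return named numeric vector of reaction velocities.
#' @export
reaction_rates <- function(model, state, params, t = 0) {
  env <- new.env(parent = baseenv())
  vols <- setNames(model$compartments$volume, model$compartments$id)
  for (k in seq_along(vols)) assign(names(vols)[k], vols[[k]], envir = env)
  for (k in seq_along(params)) assign(names(params)[k], params[[k]], envir = env)
  for (k in seq_along(state)) assign(names(state)[k], state[[k]], envir = env)
  assign("t", t, envir = env)
  assign("time", t, envir = env)
  vapply(model$reactions, function(r) eval(r$rate, envir = env),
         numeric(1), USE.NAMES = FALSE) |>
    setNames(vapply(model$reactions, `[[`, "", "id"))
}

#' Define a fractional parameter variation domain
#'
#' The hypercube explored by the global analyses: each parameter varies
#' uniformly and independently in `[ref * (1 - band), ref * (1 + band)]`.
#' Bounds are ordered numerically, so bands around negative reference
#' values remain valid intervals. `band = 0` collapses the domain to the
#' reference point.
#'
#' @param model a `kinetic_model`, or a named numeric reference vector.
#' @param band fractional half-width (dimensionless, `>= 0`); e.g. `0.25`
#'   for a +/-25\% hypercube.
#' @param overrides optional named list of `c(lower, upper)` per-parameter
#'   bounds that replace the band-derived ones (use `c(v, v)` to pin a
#'   parameter).
#' @return an object of class `parameter_domain` with fields `reference`,
#'   `band`, `lower`, `upper`.
#' @export
parameter_domain <- function(model, band, overrides = NULL) {
  reference <- if (inherits(model, "kinetic_model")) reference_params(model)
               else model
  stopifnot(is.numeric(reference), !is.null(names(reference)),
            length(band) == 1, band >= 0)
  a <- reference * (1 - band)
  b <- reference * (1 + band)
  lower <- pmin(a, b)
  upper <- pmax(a, b)
  for (nm in names(overrides %||% list())) {
    if (!nm %in% names(reference))
      stop("override for unknown parameter '", nm, "'")
    ov <- overrides[[nm]]
    stopifnot(length(ov) == 2, ov[1] <= ov[2])
    lower[nm] <- ov[1]
    upper[nm] <- ov[2]
  }
  if (any(lower > upper)) stop("invalid domain: lower > upper")
  structure(list(reference = reference, band = band,
                 lower = lower, upper = upper),
            class = "parameter_domain")
}

#' @export
print.parameter_domain <- function(x, ...) {
  cat("<parameter_domain> band +/-", x$band * 100, "%, ",
      length(x$reference), " parameters\n", sep = "")
  invisible(x)
}

#' Export a model summary as JSON
#'
#' Species (with reference concentrations), compartments, parameters (with
#' reference values and role tags) and reaction ids, as a JSON string or
#' file.
#'
#' @param model a `kinetic_model`.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
model_summary_json <- function(model, path = NULL) {
  s <- list(
    id = model$id,
    species = model$species,
    compartments = model$compartments,
    parameters = model$parameters,
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, stoichiometry = as.list(r$stoich),
           rate = deparse1(r$rate))),
    rate_rules = lapply(model$rate_rules %||% list(), deparse1)
  )
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
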