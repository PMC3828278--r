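#' Scaled local sensitivity (response) coefficient
#'
#' The dimensionless sensitivity of the declared output `y` to one
#' parameter `p`: `(p / y) * (dy / dp)`, approximated by a relative finite
#' difference with step `rel_step * p`. The default is a forward
#' difference with a 0.1\% perturbation; a central difference (step
#' `rel_step` on each side) is available and is what the test oracles use.
#' Scaling uses the output value at the operating point.
#'
#' @param model a [kinetic_model()].
#' @param params named parameter vector (the evaluation point).
#' @param spec an [output_spec()].
#' @param parameter id of the perturbed parameter; its value must be
#'   nonzero (the scaling divides by it).
#' @param rel_step relative perturbation (default 0.001 = 0.1\%).
#' @param method `"forward"` or `"central"`.
#' @param base optional precomputed [evaluate_output()] result at
#'   `params`, to share the unperturbed solve across a spectrum.
#' @return an object of class `sensitivity_coefficient`: `parameter`,
#'   `value`, `status` (`"ok"`/`"undefined"`), `reason`.
#' @export
scaled_sensitivity <- function(model, params, spec, parameter,
                               rel_step = 0.001,
                               method = c("forward", "central"),
                               base = NULL) {
  method <- match.arg(method)
  params <- parameter_set(model, params)
  if (!parameter %in% names(params))
    stop("unknown parameter '", parameter, "'")
  p <- params[[parameter]]
  if (p == 0)
    stop("parameter '", parameter,
         "' has value 0 and cannot be relatively perturbed or scaled")
  if (is.null(base)) base <- evaluate_output(model, params, spec)
  res <- sens_one(model, params, spec, parameter, rel_step, method, base)
  structure(c(list(parameter = parameter, spec = spec), res),
            class = "sensitivity_coefficient")
}

# shared core: returns list(value, status, reason)
sens_one <- function(model, params, spec, parameter, rel_step, method, base) {
  if (!is_ok(base)) return(out_undefined(base$reason))
  y0 <- base$value
  if (y0 == 0) return(out_undefined("unscalable"))
  x0 <- base$state
  perturbed <- function(fac) {
    pp <- params
    pp[[parameter]] <- pp[[parameter]] * fac
    evaluate_output(model, pp, spec, x0 = x0)
  }
  if (method == "forward") {
    y1 <- perturbed(1 + rel_step)
    if (!is_ok(y1)) return(out_undefined(y1$reason))
    out_value((y1$value - y0) / (rel_step * y0))
  } else {
    yp <- perturbed(1 + rel_step)
    ym <- perturbed(1 - rel_step)
    if (!is_ok(yp)) return(out_undefined(yp$reason))
    if (!is_ok(ym)) return(out_undefined(ym$reason))
    out_value((yp$value - ym$value) / (2 * rel_step * y0))
  }
}

#' @export
print.sensitivity_coefficient <- function(x, ...) {
  if (x$status == "ok")
    cat("<sensitivity_coefficient> ", x$parameter, " -> ",
        x$spec$kind, "(", x$spec$target, "): ", format(x$value), "\n",
        sep = "")
  else
    cat("<sensitivity_coefficient> ", x$parameter, ": undefined (",
        x$reason, ")\n", sep = "")
  invisible(x)
}

#' Full spectrum of scaled sensitivities
#'
#' One scaled sensitivity coefficient per model parameter (the
#' distribution of control across the model). Parameters that cannot be
#' scaled (reference value 0) or whose perturbed output is undefined are
#' reported with status `"undefined"` rather than omitted. The
#' unperturbed output is solved once and shared.
#'
#' @inheritParams scaled_sensitivity
#' @return data frame of class `sensitivity_spectrum` with columns
#'   `parameter`, `value`, `status`, `reason`; the output value at the
#'   operating point is in `attr(, "base_value")`.
#' @export
sensitivity_spectrum <- function(model, params = reference_params(model),
                                 spec, rel_step = 0.001,
                                 method = c("forward", "central")) {
  method <- match.arg(method)
  params <- parameter_set(model, params)
  base <- evaluate_output(model, params, spec)
  ids <- model$parameters$id
  n <- length(ids)
  value <- rep(NA_real_, n)
  status <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (params[[ids[i]]] == 0) {
      res <- out_undefined("unscalable")
    } else {
      res <- sens_one(model, params, spec, ids[i], rel_step, method, base)
    }
    value[i] <- res$value
    status[i] <- res$status
    reason[i] <- res$reason
  }
  out <- data.frame(parameter = ids, value = value, status = status,
                    reason = reason)
  attr(out, "base_value") <- base$value
  attr(out, "spec") <- spec
  class(out) <- c("sensitivity_spectrum", "data.frame")
  out
}

# Wrap every rate law in a multiplicative factor f.<reaction id> with
# reference value 1. The scaled sensitivity with respect to that factor is
# the MCA control coefficient of the reaction, whatever the form of the
# rate law ("a parameter that affects the rate of reaction linearly").
inject_multipliers <- function(model) {
  rids <- vapply(model$reactions, `[[`, "", "id")
  fids <- paste0("f.", rids)
  rx <- model$reactions
  for (j in seq_along(rx)) {
    rx[[j]]$rate <- bquote(.(as.name(fids[j])) * (.(rx[[j]]$rate)))
  }
  pars <- rbind(model$parameters,
                data.frame(id = fids, value = 1, role = "limiting-rate"))
  kinetic_model(model$species, rx, pars, model$compartments,
                model$rate_rules, id = paste0(model$id, "+multipliers"))
}

#' Identify limiting-rate parameters
#'
#' A parameter is tagged as the limiting rate of a reaction when the rate
#' law is homogeneous of degree 1 in it (numerically tested by doubling
#' the parameter at the reference state) and it appears in that reaction
#' only -- the "V"-type handles through which MCA control coefficients can
#' be taken directly.
#'
#' @param model a [kinetic_model()].
#' @return named character vector: reaction id -> parameter id (`NA` when
#'   no such parameter exists; MCA then falls back to an injected
#'   multiplier).
#' @export
limiting_rate_parameters <- function(model) {
  params <- reference_params(model)
  state <- reference_state(model)
  state[state == 0] <- 1 # probe at a nonzero state so rates do not vanish
  rids <- vapply(model$reactions, `[[`, "", "id")
  uses <- lapply(model$reactions, function(r)
    intersect(all.vars(r$rate), names(params)))
  out <- setNames(rep(NA_character_, length(rids)), rids)
  v0 <- reaction_rates(model, state, params)
  for (j in seq_along(rids)) {
    for (pid in uses[[j]]) {
      if (sum(vapply(uses, function(u) pid %in% u, TRUE)) != 1) next
      if (params[[pid]] == 0) next
      p2 <- params
      p2[[pid]] <- 2 * p2[[pid]]
      v2 <- reaction_rates(model, state, p2)
      if (v0[j] != 0 && is.finite(v2[j]) &&
          abs(v2[j] - 2 * v0[j]) <= 1e-9 * abs(v0[j])) {
        out[j] <- pid
        break
      }
    }
  }
  out
}

#' MCA control-coefficient matrices
#'
#' Flux-control and concentration-control coefficients at a steady state,
#' computed as scaled sensitivities with respect to a limiting-rate
#' multiplier injected into each reaction (central difference, so that the
#' summation theorems -- flux-control rows summing to 1, concentration-
#' control rows to 0 -- hold to ~1e-6 rather than the O(step) bias of a
#' one-sided difference; the default step keeps the quadratic truncation
#' error below 1e-6 on coefficients of order 1).
#'
#' @param model a [kinetic_model()].
#' @param params named parameter vector.
#' @param rel_step relative perturbation of each multiplier.
#' @return an object of class `control_matrix`: `fcc` (reaction x
#'   reaction; row = controlled flux, column = perturbed reaction), `ccc`
#'   (non-boundary species x reaction), `steady_state`, `status`.
#' @export
control_coefficients <- function(model, params = reference_params(model),
                                 rel_step = 5e-4) {
  params <- parameter_set(model, params)
  aug <- inject_multipliers(apply_parameters(model, params))
  pa <- reference_params(aug)
  rids <- vapply(model$reactions, `[[`, "", "id")
  fids <- paste0("f.", rids)
  free_sp <- model$species$id[!model$species$boundary]

  base <- find_steady_state(aug, pa)
  if (base$status != "ok") {
    return(structure(list(fcc = NULL, ccc = NULL, steady_state = base,
                          status = "undefined", reason = base$reason),
                     class = "control_matrix"))
  }
  J0 <- base$fluxes
  S0 <- base$concentrations[free_sp]
  nR <- length(rids)
  fcc <- matrix(NA_real_, nR, nR, dimnames = list(rids, rids))
  ccc <- matrix(NA_real_, length(free_sp), nR,
                dimnames = list(free_sp, rids))
  for (j in seq_len(nR)) {
    solve_at <- function(fac) {
      pp <- pa
      pp[[fids[j]]] <- fac
      find_steady_state(aug, pp, x0 = base$concentrations)
    }
    up <- solve_at(1 + rel_step)
    dn <- solve_at(1 - rel_step)
    if (up$status != "ok" || dn$status != "ok") next
    dJ <- (up$fluxes - dn$fluxes) / (2 * rel_step)
    dS <- (up$concentrations[free_sp] - dn$concentrations[free_sp]) /
      (2 * rel_step)
    fcc[, j] <- ifelse(J0 != 0, dJ / J0, NA_real_)
    ccc[, j] <- ifelse(S0 != 0, dS / S0, NA_real_)
  }
  structure(list(fcc = fcc, ccc = ccc, steady_state = base,
                 status = "ok", reason = NA_character_),
            class = "control_matrix")
}

#' @export
print.control_matrix <- function(x, ...) {
  if (x$status != "ok") {
    cat("<control_matrix> undefined (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("<control_matrix>\nFlux control (rows sum to 1):\n")
  print(round(x$fcc, 6))
  cat("Concentration control (rows sum to 0):\n")
  print(round(x$ccc, 6))
  invisible(x)
}

#' Write a sensitivity spectrum or control matrix to CSV
#'
#' @param x a `sensitivity_spectrum` or `control_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(x, path) {
  if (inherits(x, "sensitivity_spectrum")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "control_matrix")) {
    if (x$status != "ok") stop("cannot export an undefined control matrix")
    fcc <- data.frame(block = "flux-control", target = rownames(x$fcc),
                      x$fcc, check.names = FALSE)
    ccc <- data.frame(block = "concentration-control",
                      target = rownames(x$ccc), x$ccc, check.names = FALSE)
    utils::write.csv(rbind(fcc, ccc), path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
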