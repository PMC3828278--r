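# Local maxima of a density curve with a simple prominence measure: the
# height above the higher of the valley minima separating the peak from
# higher ground on each side (the edge minimum when no higher point
# exists on a side).
density_peaks <- function(x, y) {
  n <- length(y)
  is_max <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > l && y[i] >= r
  }, TRUE))
  if (length(is_max) == 0) return(data.frame(x = numeric(0),
                                             height = numeric(0),
                                             prominence = numeric(0)))
  prom <- vapply(is_max, function(i) {
    side_min <- function(idx_seq) {
      m <- Inf
      for (k in idx_seq) {
        if (y[k] > y[i]) return(m)
        m <- min(m, y[k])
      }
      m
    }
    lmin <- if (i > 1) side_min((i - 1):1) else y[i]
    rmin <- if (i < n) side_min((i + 1):n) else y[i]
    lmin <- if (is.finite(lmin)) lmin else min(y[1:i])
    rmin <- if (is.finite(rmin)) rmin else min(y[i:n])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  out <- data.frame(x = x[is_max], height = y[is_max], prominence = prom)
  out[order(-out$height), , drop = FALSE]
}

#' Classify the pattern of control of a sensitivity distribution
#'
#' The qualitative signature of a sampled coefficient: its sign span
#' (positive-only / negative-only / mixed), whether the distribution has
#' appreciable density in a neighbourhood of zero, whether it is
#' multimodal (peaks of a Gaussian-smoothed density with prominence at
#' least `prominence_frac` of the maximum density), and whether it attains
#' high magnitude. Optimisation bounds, when supplied, can widen the sign
#' span and the magnitude beyond the sampled extremes, but carry no
#' density information and therefore never add modes.
#'
#' @param dist a [summarize_distribution()] result.
#' @param bounds optional [sensitivity_bounds()] for the same parameter
#'   and band.
#' @param threshold magnitude threshold for the high-magnitude flag
#'   (default 1).
#' @param prominence_frac minimum peak prominence, as a fraction of the
#'   maximum smoothed density (default 0.05).
#' @param zero_window half-width of the zero neighbourhood, as a fraction
#'   of the distribution's range (default 0.01).
#' @param zero_floor minimum density near zero, as a fraction of the peak
#'   density (default 0.01).
#' @return an object of class `pattern_flags`: `sign_span`,
#'   `attains_zero`, `multimodal`, `modes`, `high_magnitude`,
#'   `multiple_patterns` (mixed sign, or multimodal, or zero *and*
#'   high-magnitude control coexisting).
#' @export
classify_pattern <- function(dist, bounds = NULL, threshold = 1,
                             prominence_frac = 0.05, zero_window = 0.01,
                             zero_floor = 0.01) {
  stopifnot(inherits(dist, "sensitivity_distribution"))
  if (isTRUE(dist$empty)) stop("cannot classify an empty distribution")
  vmin <- dist$min
  vmax <- dist$max
  if (!is.null(bounds) && bounds$status == "ok") {
    vmin <- min(vmin, bounds$lower)
    vmax <- max(vmax, bounds$upper)
  }
  # coefficients below solver noise count as zero for the sign span
  sign_tol <- 1e-6 * max(1, abs(vmin), abs(vmax))
  sign_span <- if (vmin >= -sign_tol) "positive-only"
               else if (vmax <= sign_tol) "negative-only" else "mixed"

  values <- dist$values
  rng <- dist$max - dist$min
  # a spread at the level of solver noise (finite differences amplify the
  # steady-state tolerance by 1/rel_step) is structurally constant, not a
  # distribution with modes
  if (rng <= 1e-6 * max(abs(dist$min), abs(dist$max), 1)) rng <- 0
  if (rng == 0) {
    multimodal <- FALSE
    modes <- dist$min
    near0 <- abs(dist$min) <= max(1e-12, zero_window * max(1, abs(dist$min)))
    attains_zero <- near0
  } else {
    d <- stats::density(values, bw = "nrd0")
    pk <- density_peaks(d$x, d$y)
    pk <- pk[pk$prominence >= prominence_frac * max(d$y), , drop = FALSE]
    multimodal <- nrow(pk) >= 2
    modes <- pk$x
    w <- zero_window * rng
    if (0 < dist$min - w || 0 > dist$max + w) {
      attains_zero <- FALSE
    } else {
      dens0 <- mean(d$y[abs(d$x) <= w])
      attains_zero <- is.finite(dens0) && dens0 >= zero_floor * max(d$y)
    }
  }
  high_magnitude <- max(abs(vmin), abs(vmax)) >= threshold
  structure(list(
    sign_span = sign_span,
    attains_zero = attains_zero,
    multimodal = multimodal,
    modes = modes,
    high_magnitude = high_magnitude,
    multiple_patterns = sign_span == "mixed" || multimodal ||
      (attains_zero && high_magnitude)
  ), class = "pattern_flags")
}

#' @export
print.pattern_flags <- function(x, ...) {
  cat("<pattern_flags> ", x$sign_span,
      if (x$multimodal) paste0(", multimodal (modes ",
                               paste(signif(x$modes, 3), collapse = ", "),
                               ")") else ", unimodal",
      if (x$attains_zero) ", attains zero" else "",
      if (x$high_magnitude) ", high magnitude" else "",
      "\n", sep = "")
  invisible(x)
}

#' Robustness profile across variation bands
#'
#' The whole-model robustness measure: for each variation band, sample the
#' sensitivity spectrum, summarise each parameter's distribution, classify
#' its pattern of control, and report (i) the fraction of parameters whose
#' sampled coefficient attains magnitude `threshold` or more (and the same
#' from optimisation bounds, when enabled) and (ii) the smallest band at
#' which any parameter shows multiple coexisting patterns -- the level of
#' parameter uncertainty at which the distribution of control is no longer
#' a single pattern.
#'
#' Bands are sampled with the same master seed, so their hypercubes are
#' nested draw-by-draw and the exceedance fractions are monotone in the
#' band by construction.
#'
#' @param model a [kinetic_model()].
#' @param spec an [output_spec()].
#' @param bands strictly increasing vector of fractional half-widths.
#' @param n samples per band.
#' @param seed master seed.
#' @param threshold magnitude threshold (default 1).
#' @param pso optional [swarm_settings()]; when supplied, optimisation
#'   bounds are computed per parameter and band as a second evidence
#'   source.
#' @param rel_step finite-difference step.
#' @param parameters optional subset of parameters to profile.
#' @return an object of class `robustness_profile`: per-band exceedance
#'   fractions (`sampling` and, if enabled, `optimisation`), per
#'   parameter x band `pattern_flags`, the per-band distributions, and
#'   `robustness_level` (smallest band with multiple patterns, or `Inf`
#'   = "above the largest band probed").
#' @export
robustness_profile <- function(model, spec, bands, n, seed,
                               threshold = 1, pso = NULL,
                               rel_step = 0.001, parameters = NULL) {
  stopifnot(length(bands) >= 1)
  if (is.unsorted(bands, strictly = TRUE))
    stop("bands must be strictly increasing")
  ids <- parameters %||% model$parameters$id
  ref <- reference_params(model)
  local_spec <- sensitivity_spectrum(model, ref, spec, rel_step = rel_step)
  local_vals <- setNames(local_spec$value, local_spec$parameter)

  per_band <- vector("list", length(bands))
  exceed_sampling <- rep(NA_real_, length(bands))
  exceed_optim <- rep(NA_real_, length(bands))
  viable <- rep(TRUE, length(bands))
  base <- evaluate_output(model, ref, spec)
  for (b in seq_along(bands)) {
    if (!is_ok(base)) { # reference output itself undefined: band non-viable
      viable[b] <- FALSE
      next
    }
    domain <- parameter_domain(model, bands[b])
    gsa <- run_sampling_gsa(model, domain, spec, n, seed,
                            rel_step = rel_step, parameters = ids)
    dists <- list()
    flags <- list()
    bnds <- list()
    exc_s <- logical(length(ids))
    exc_o <- rep(NA, length(ids))
    for (i in seq_along(ids)) {
      pid <- ids[i]
      dist <- summarize_distribution(gsa, pid,
                                     local_value = unname(local_vals[pid]))
      bd <- NULL
      if (!is.null(pso) && ref[[pid]] != 0) {
        bd <- sensitivity_bounds(model, domain, spec, pid, settings = pso,
                                 rel_step = rel_step)
        exc_o[i] <- bd$status == "ok" &&
          max(abs(bd$lower), abs(bd$upper)) >= threshold
      }
      if (!isTRUE(dist$empty)) {
        flags[[pid]] <- classify_pattern(dist, bounds = bd,
                                         threshold = threshold)
        exc_s[i] <- max(abs(dist$min), abs(dist$max)) >= threshold
      } else {
        exc_s[i] <- FALSE
      }
      dists[[pid]] <- dist
      if (!is.null(bd)) bnds[[pid]] <- bd
    }
    if (all(vapply(dists, function(d) isTRUE(d$empty), TRUE)))
      viable[b] <- FALSE # no sample in this band had a defined output
    exceed_sampling[b] <- mean(exc_s)
    exceed_optim[b] <- if (is.null(pso)) NA_real_ else mean(exc_o, na.rm = TRUE)
    per_band[[b]] <- list(band = bands[b], distributions = dists,
                          flags = flags, bounds = bnds)
  }
  multi <- vapply(seq_along(bands), function(b) {
    if (!viable[b] || is.null(per_band[[b]])) return(FALSE)
    any(vapply(per_band[[b]]$flags, function(f) f$multiple_patterns, TRUE))
  }, TRUE)
  level <- if (any(multi)) bands[which(multi)[1]] else Inf
  structure(list(
    bands = bands,
    viable = viable,
    exceedance_sampling = exceed_sampling,
    exceedance_optimisation = exceed_optim,
    per_band = per_band,
    robustness_level = level,
    threshold = threshold,
    n = n, seed = seed,
    parameters = ids,
    local_values = local_vals
  ), class = "robustness_profile")
}

#' @export
print.robustness_profile <- function(x, ...) {
  cat("<robustness_profile> threshold |coef| >= ", x$threshold, "\n",
      sep = "")
  df <- data.frame(band = x$bands,
                   exceedance_sampling = x$exceedance_sampling,
                   exceedance_optimisation = x$exceedance_optimisation,
                   viable = x$viable)
  print(df, row.names = FALSE)
  cat("robustness level (first band with multiple patterns): ",
      if (is.finite(x$robustness_level)) x$robustness_level
      else "above the largest band probed", "\n", sep = "")
  invisible(x)
}

#' Export a robustness profile as JSON (and optionally CSV)
#'
#' @param profile a `robustness_profile`.
#' @param path output JSON path (optional).
#' @param csv_path optional CSV path for the per-band exceedance table.
#' @return the JSON string, invisibly when written.
#' @export
robustness_json <- function(profile, path = NULL, csv_path = NULL) {
  flags_by_band <- lapply(profile$per_band, function(pb) {
    if (is.null(pb)) return(NULL)
    lapply(pb$flags, function(f) f[c("sign_span", "attains_zero",
                                     "multimodal", "modes",
                                     "high_magnitude",
                                     "multiple_patterns")])
  })
  s <- list(
    bands = profile$bands,
    viable = profile$viable,
    threshold = profile$threshold,
    exceedance_sampling = profile$exceedance_sampling,
    exceedance_optimisation = profile$exceedance_optimisation,
    robustness_level = if (is.finite(profile$robustness_level))
      profile$robustness_level else "above-max-band",
    flags = flags_by_band,
    n = profile$n, seed = profile$seed
  )
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(
      band = profile$bands,
      exceedance_sampling = profile$exceedance_sampling,
      exceedance_optimisation = profile$exceedance_optimisation,
      viable = profile$viable), csv_path, row.names = FALSE)
  }
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
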