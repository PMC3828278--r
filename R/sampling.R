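# One RNG seed per sample index, derived from the master seed by an
# affine counter map modulo the Mersenne prime 2^31 - 1. Chunking then
# merely partitions sample indices, so results are independent of how a
# run is split into chunks (and chunks can run in parallel or be resumed).
derive_seed <- function(master, index) {
  as.integer((((master %% 2147483647) * 48271 + index * 16807) %%
                2147483647) + 1)
}

#' Sample parameter sets uniformly from a variation domain
#'
#' Each parameter is drawn independently and uniformly on
#' `[lower, upper]` of the [parameter_domain()]. The stream is
#' deterministic given the master seed, and sample `i` is reproducible in
#' isolation (per-index seed derivation), so chunked or resumed runs
#' produce identical values.
#'
#' @param domain a [parameter_domain()].
#' @param n number of parameter sets.
#' @param seed master seed (integer).
#' @param start index of the first sample (default 1); use `start = k + 1`
#'   to resume after `k` samples.
#' @return an `n x p` matrix with one parameter set per row.
#' @export
sample_domain <- function(domain, n, seed, start = 1) {
  stopifnot(inherits(domain, "parameter_domain"), n >= 1)
  p <- length(domain$reference)
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, names(domain$reference)))
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, start + i - 1))
    out[i, ] <- runif(p, domain$lower, domain$upper)
  }
  out
}

#' Monte-Carlo global sensitivity analysis
#'
#' Samples `n` parameter sets from the domain, computes the full scaled
#' sensitivity spectrum at each, and records one value per parameter per
#' sample. Samples where the output is undefined (no steady state, no
#' oscillation, unscalable parameter) are recorded with their reason code,
#' never silently dropped. Work proceeds in chunks whose results depend
#' only on the sample indices they cover.
#'
#' @param model a [kinetic_model()].
#' @param domain a [parameter_domain()] over the model's parameters.
#' @param spec an [output_spec()].
#' @param n number of samples.
#' @param seed master seed.
#' @param rel_step relative finite-difference step (default 0.001).
#' @param method `"forward"` (default) or `"central"`.
#' @param chunk_size samples per chunk.
#' @param parameters optional character vector restricting the recorded
#'   spectrum to these parameters (all are sampled regardless).
#' @return an object of class `gsa_samples`: `records` (long data frame
#'   with `sample`, `parameter`, `value`, `status`, `reason`), `samples`
#'   (the sampled matrix), plus the domain, spec, seed and undefined
#'   counts by reason.
#' @export
run_sampling_gsa <- function(model, domain, spec, n, seed,
                             rel_step = 0.001,
                             method = c("forward", "central"),
                             chunk_size = 500, parameters = NULL) {
  method <- match.arg(method)
  validate_spec(model, spec)
  stopifnot(n >= 1)
  ids <- parameters %||% model$parameters$id
  stopifnot(all(ids %in% model$parameters$id))
  p <- length(ids)
  value <- rep(NA_real_, n * p)
  status <- character(n * p)
  reason <- rep(NA_character_, n * p)
  samples <- matrix(NA_real_, n, length(domain$reference),
                    dimnames = list(NULL, names(domain$reference)))
  done <- 0
  while (done < n) {
    k <- min(chunk_size, n - done)
    chunk <- sample_domain(domain, k, seed, start = done + 1)
    samples[done + seq_len(k), ] <- chunk
    for (i in seq_len(k)) {
      params <- parameter_set(model, chunk[i, ])
      base <- evaluate_output(model, params, spec)
      off <- (done + i - 1) * p
      for (j in seq_len(p)) {
        res <- if (params[[ids[j]]] == 0) out_undefined("unscalable")
               else sens_one(model, params, spec, ids[j], rel_step,
                             method, base)
        value[off + j] <- res$value
        status[off + j] <- res$status
        reason[off + j] <- res$reason
      }
    }
    done <- done + k
  }
  records <- data.frame(
    sample = rep(seq_len(n), each = p),
    parameter = rep(ids, n),
    value = value, status = status, reason = reason)
  undef <- table(records$reason[records$status == "undefined"])
  structure(list(records = records, samples = samples, domain = domain,
                 spec = spec, n = n, seed = seed,
                 undefined_by_reason = undef),
            class = "gsa_samples")
}

#' @export
print.gsa_samples <- function(x, ...) {
  n_undef <- sum(x$records$status == "undefined")
  cat("<gsa_samples> ", x$n, " samples x ",
      length(unique(x$records$parameter)), " parameters (band +/-",
      x$domain$band * 100, "%), ", n_undef, " undefined records\n",
      sep = "")
  invisible(x)
}

#' Write sampling records to CSV
#'
#' One row per (sample, parameter) with the sampled parameter values
#' appended, suitable for streaming aggregation across chunked runs.
#'
#' @param gsa a `gsa_samples` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(gsa, path) {
  df <- cbind(gsa$records,
              gsa$samples[gsa$records$sample, , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Shapiro-Wilk normality test with a deterministic subsampling cap
#'
#' The test statistic is only calibrated for moderate sample sizes, so
#' inputs beyond `cap` values are thinned deterministically (evenly spaced
#' indices) before calling [stats::shapiro.test()].
#'
#' @param values numeric vector, `length >= 3` (after removing `NA`).
#' @param cap maximum number of values passed to the test (default 5000).
#' @return list with `W`, `p`, `n_used`, and `constant` (`TRUE` when the
#'   input is constant, in which case `W` and `p` are `NA`).
#' @export
shapiro_wilk <- function(values, cap = 5000) {
  values <- values[is.finite(values)]
  if (length(values) < 3)
    stop("Shapiro-Wilk requires at least 3 values")
  if (length(values) > cap) {
    idx <- unique(round(seq(1, length(values), length.out = cap)))
    values <- values[idx]
  }
  if (diff(range(values)) == 0)
    return(list(W = NA_real_, p = NA_real_, n_used = length(values),
                constant = TRUE))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = unname(sw$p.value),
       n_used = length(values), constant = FALSE)
}

fd_bins <- function(values, floor_bins = 50) {
  rng <- diff(range(values))
  iqr <- stats::IQR(values)
  if (rng == 0) return(floor_bins)
  if (iqr == 0) return(floor_bins)
  w <- 2 * iqr * length(values)^(-1 / 3)
  max(floor_bins, ceiling(rng / w))
}

#' Summarise sampled sensitivity values as a distribution
#'
#' Unit-area histogram plus the summary statistics used to describe each
#' sampled coefficient: peak location (centre of the modal bin),
#' normalised peak height (modal-bin frequency / total number of samples,
#' including undefined ones), extremes, and a Shapiro-Wilk normality test
#' on the defined values.
#'
#' @param gsa a `gsa_samples` object, or a numeric vector of sampled
#'   values (then `n_undefined` may be given directly).
#' @param parameter parameter id to summarise (required for a
#'   `gsa_samples` input).
#' @param n_bins number of histogram bins; default is Freedman-Diaconis
#'   with a floor of 50.
#' @param local_value optional local (reference-point) coefficient to
#'   attach for overlays.
#' @param n_undefined count of undefined samples when `gsa` is a plain
#'   vector.
#' @return an object of class `sensitivity_distribution`.
#' @export
summarize_distribution <- function(gsa, parameter = NULL, n_bins = NULL,
                                   local_value = NULL, n_undefined = 0) {
  if (inherits(gsa, "gsa_samples")) {
    stopifnot(!is.null(parameter))
    rec <- gsa$records[gsa$records$parameter == parameter, ]
    values <- rec$value[rec$status == "ok"]
    n_undefined <- sum(rec$status == "undefined")
    band <- gsa$domain$band
  } else {
    values <- gsa[is.finite(gsa)]
    parameter <- parameter %||% "values"
    band <- NA_real_
  }
  total <- length(values) + n_undefined
  if (length(values) == 0) {
    return(structure(list(parameter = parameter, band = band, empty = TRUE,
                          n_ok = 0, n_undefined = n_undefined),
                     class = "sensitivity_distribution"))
  }
  rng <- range(values)
  if (diff(rng) == 0) {
    # degenerate distribution (e.g. band = 0): a single unit-area spike
    w <- max(1e-6, abs(rng[1]) * 1e-6)
    breaks <- c(rng[1] - w / 2, rng[1] + w / 2)
    dens <- 1 / w
    mids <- rng[1]
    counts <- length(values)
  } else {
    nb <- n_bins %||% fd_bins(values)
    h <- graphics::hist(values, breaks = seq(rng[1], rng[2],
                                             length.out = nb + 1),
                        plot = FALSE)
    breaks <- h$breaks
    dens <- h$density
    mids <- h$mids
    counts <- h$counts
  }
  peak_i <- which.max(counts)
  sw <- if (length(values) >= 3) shapiro_wilk(values)
        else list(W = NA_real_, p = NA_real_, n_used = length(values),
                  constant = diff(rng) == 0)
  structure(list(
    parameter = parameter,
    band = band,
    empty = FALSE,
    breaks = breaks,
    density = dens,
    mids = mids,
    counts = counts,
    peak = mids[peak_i],
    peak_height = max(counts) / total,
    min = rng[1], max = rng[2],
    local_value = local_value,
    shapiro_W = sw$W, shapiro_p = sw$p,
    n_ok = length(values), n_undefined = n_undefined,
    values = values
  ), class = "sensitivity_distribution")
}

#' @export
print.sensitivity_distribution <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<sensitivity_distribution> ", x$parameter,
        ": empty (", x$n_undefined, " undefined)\n", sep = "")
    return(invisible(x))
  }
  cat("<sensitivity_distribution> ", x$parameter,
      ": n_ok ", x$n_ok, ", undefined ", x$n_undefined,
      "\n  range [", format(x$min), ", ", format(x$max),
      "], peak at ", format(x$peak),
      " (height ", format(x$peak_height), "), W = ", format(x$shapiro_W),
      "\n", sep = "")
  invisible(x)
}

#' Export a sensitivity distribution as JSON
#'
#' @param dist a `sensitivity_distribution`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
distribution_json <- function(dist, path = NULL) {
  keep <- setdiff(names(dist), "values")
  js <- jsonlite::toJSON(dist[keep], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
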