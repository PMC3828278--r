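#' Assemble and validate a run configuration
#'
#' A declarative description of one analysis run: which model, which
#' output, which variation bands, how many samples, which seed, optional
#' swarm settings and the magnitude threshold. Configurations serialise
#' to JSON and back unchanged, and every artifact written by the `cmd_*`
#' drivers embeds the configuration hash and seed, so a run can be
#' re-executed byte-for-byte from its outputs.
#'
#' @param model fixture name (`"chain"`, `"reversible_chain"`,
#'   `"oscillator"`, `"bimodal_toy"`) or path to an SBML file.
#' @param kind,target output kind and target id (see [output_spec()]).
#' @param bands increasing vector of fractional variation half-widths.
#' @param n samples per band.
#' @param seed master seed.
#' @param threshold magnitude threshold for robustness summaries.
#' @param pso optional list of [swarm_settings()] arguments; `NULL`
#'   disables optimisation-based evidence.
#' @param t_end simulated time for period outputs.
#' @param rel_step relative finite-difference step.
#' @param chunk_size sampling chunk size.
#' @param output_dir directory for artifacts.
#' @param figures write figures when ggplot2 is available (data outputs
#'   never depend on plotting).
#' @return an object of class `run_config`.
#' @export
run_config <- function(model, kind, target, bands = c(0.05, 0.1, 0.25, 0.5),
                       n = 1000, seed = 1, threshold = 1, pso = NULL,
                       t_end = 100, rel_step = 0.001, chunk_size = 500,
                       output_dir = ".", figures = FALSE) {
  stopifnot(is.character(model), length(model) == 1)
  if (is.unsorted(bands, strictly = TRUE))
    stop("bands must be strictly increasing")
  kind <- match.arg(kind, c("concentration", "flux", "period"))
  cfg <- structure(list(
    model = model, kind = kind, target = target, bands = bands,
    n = n, seed = seed, threshold = threshold, pso = pso,
    t_end = t_end, rel_step = rel_step, chunk_size = chunk_size,
    output_dir = output_dir, figures = figures
  ), class = "run_config")
  cfg
}

#' @rdname run_config
#' @param path JSON file path (for `config_to_json` / `config_from_json`).
#' @param cfg a `run_config`.
#' @export
config_to_json <- function(cfg, path = NULL) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname run_config
#' @export
config_from_json <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, s[!vapply(s, is.null, TRUE)])
}

#' @rdname run_config
#' @export
config_hash <- function(cfg) {
  # hash the scientific content only: where outputs land, whether figures
  # are drawn and how work is chunked cannot change any result
  core <- unclass(cfg)
  core <- core[setdiff(names(core),
                       c("output_dir", "figures", "chunk_size"))]
  txt <- as.character(jsonlite::toJSON(core, auto_unbox = TRUE,
                                       digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

resolve_model <- function(cfg) {
  if (file.exists(cfg$model)) return(load_sbml(cfg$model))
  fx <- try(fixture(cfg$model), silent = TRUE)
  if (inherits(fx, "try-error"))
    stop("model '", cfg$model,
         "' is neither an existing file nor a known fixture name")
  fx$model
}

config_spec <- function(cfg) {
  output_spec(cfg$kind, cfg$target, t_end = cfg$t_end)
}

stamp_lines <- function(cfg) {
  c(paste0("# kingsa v", as.character(utils::packageVersion("kingsa")),
           " schema=1"),
    paste0("# config_hash=", config_hash(cfg), " seed=", cfg$seed))
}

write_stamped_csv <- function(df, cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp_lines(cfg), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Local sensitivity spectrum driver
#'
#' Computes the scaled sensitivity spectrum at the reference parameter
#' set and writes `local_spectrum.csv` (columns `parameter`, `value`,
#' `status`, `reason`) into the configuration's output directory.
#'
#' @param cfg a [run_config()].
#' @return the spectrum data frame, invisibly.
#' @export
cmd_local <- function(cfg) {
  model <- resolve_model(cfg)
  spec <- config_spec(cfg)
  sp <- sensitivity_spectrum(model, reference_params(model), spec,
                             rel_step = cfg$rel_step)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_stamped_csv(as.data.frame(sp), cfg,
                    file.path(cfg$output_dir, "local_spectrum.csv"))
  invisible(sp)
}

#' Sampling-based GSA driver
#'
#' For each configured band: samples the domain, writes the records CSV
#' (`records_band<delta>.csv`), a JSON file of per-parameter distribution
#' summaries, and (optionally) histogram figures with the local value,
#' zero, and any supplied bounds overlaid.
#'
#' @param cfg a [run_config()].
#' @return named list of `gsa_samples`, one per band, invisibly.
#' @export
cmd_sample <- function(cfg) {
  model <- resolve_model(cfg)
  spec <- config_spec(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  local_sp <- sensitivity_spectrum(model, reference_params(model), spec,
                                   rel_step = cfg$rel_step)
  local_vals <- setNames(local_sp$value, local_sp$parameter)
  out <- list()
  for (band in cfg$bands) {
    domain <- parameter_domain(model, band)
    gsa <- run_sampling_gsa(model, domain, spec, cfg$n, cfg$seed,
                            rel_step = cfg$rel_step,
                            chunk_size = cfg$chunk_size)
    tag <- formatC(band, format = "g")
    write_stamped_csv(
      cbind(gsa$records, gsa$samples[gsa$records$sample, , drop = FALSE]),
      cfg, file.path(cfg$output_dir, paste0("records_band", tag, ".csv")))
    dists <- lapply(model$parameters$id, function(pid)
      summarize_distribution(gsa, pid,
                             local_value = unname(local_vals[pid])))
    names(dists) <- model$parameters$id
    djson <- lapply(dists, function(d)
      jsonlite::fromJSON(distribution_json(d), simplifyVector = TRUE))
    jsonlite::write_json(
      list(config_hash = config_hash(cfg), seed = cfg$seed, band = band,
           note = "undefined samples are excluded from histograms but counted in n_undefined",
           distributions = djson),
      file.path(cfg$output_dir, paste0("distributions_band", tag, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    if (isTRUE(cfg$figures)) {
      for (pid in model$parameters$id) {
        save_figure(plot_distribution(dists[[pid]]),
                    file.path(cfg$output_dir,
                              paste0("hist_", pid, "_band", tag, ".png")))
      }
    }
    out[[tag]] <- gsa
  }
  invisible(out)
}

#' Optimisation-based GSA driver
#'
#' For each configured band, runs the particle-swarm bound search for
#' every scalable parameter and writes `bounds_band<delta>.csv`
#' (parameter, band, lower, upper, local value).
#'
#' @param cfg a [run_config()] with a non-`NULL` `pso` element.
#' @return named list (by band) of lists of `sensitivity_bounds`,
#'   invisibly.
#' @export
cmd_optimise <- function(cfg) {
  model <- resolve_model(cfg)
  spec <- config_spec(cfg)
  settings <- do.call(swarm_settings, cfg$pso %||% list())
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  local_sp <- sensitivity_spectrum(model, reference_params(model), spec,
                                   rel_step = cfg$rel_step)
  local_vals <- setNames(local_sp$value, local_sp$parameter)
  ref <- reference_params(model)
  out <- list()
  for (band in cfg$bands) {
    domain <- parameter_domain(model, band)
    ids <- model$parameters$id[ref[model$parameters$id] != 0]
    bl <- lapply(ids, function(pid)
      sensitivity_bounds(model, domain, spec, pid, settings = settings,
                         rel_step = cfg$rel_step))
    names(bl) <- ids
    tag <- formatC(band, format = "g")
    df <- do.call(rbind, lapply(bl, function(b)
      data.frame(parameter = b$parameter, band = b$band,
                 lower = b$lower, upper = b$upper,
                 local = unname(local_vals[b$parameter]),
                 evaluations = b$evaluations,
                 n_undefined = b$n_undefined)))
    write_stamped_csv(df, cfg,
                      file.path(cfg$output_dir,
                                paste0("bounds_band", tag, ".csv")))
    out[[tag]] <- bl
  }
  invisible(out)
}

#' Robustness profile driver
#'
#' Runs [robustness_profile()] over the configured bands and writes
#' `robustness.json`, `robustness.csv` and (optionally) the grouped bar
#' chart of exceedance fractions by band and evidence source.
#'
#' @param cfg a [run_config()].
#' @return the `robustness_profile`, invisibly.
#' @export
cmd_robustness <- function(cfg) {
  model <- resolve_model(cfg)
  spec <- config_spec(cfg)
  pso <- if (is.null(cfg$pso)) NULL else do.call(swarm_settings, cfg$pso)
  prof <- robustness_profile(model, spec, cfg$bands, cfg$n, cfg$seed,
                             threshold = cfg$threshold, pso = pso,
                             rel_step = cfg$rel_step)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  robustness_json(prof, file.path(cfg$output_dir, "robustness.json"),
                  csv_path = file.path(cfg$output_dir, "robustness.csv"))
  if (isTRUE(cfg$figures)) {
    save_figure(plot_robustness(prof),
                file.path(cfg$output_dir, "robustness.png"))
  }
  invisible(prof)
}

#' Histogram figure for a sensitivity distribution
#'
#' Unit-area histogram with zero marked (dashed purple), the local
#' coefficient overlaid as a dashed blue line and optimisation bounds, if
#' given, as dashed green lines.
#'
#' @param dist a `sensitivity_distribution`.
#' @param bounds optional `sensitivity_bounds`.
#' @return a ggplot object, or `NULL` when ggplot2 is unavailable.
#' @export
plot_distribution <- function(dist, bounds = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(NULL)
  if (isTRUE(dist$empty)) stop("cannot plot an empty distribution")
  df <- data.frame(xmin = head(dist$breaks, -1),
                   xmax = tail(dist$breaks, -1),
                   density = dist$density)
  g <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax, ymin = 0,
      ymax = .data$density), fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "purple") +
    ggplot2::labs(x = "scaled sensitivity coefficient", y = "density",
                  title = dist$parameter,
                  subtitle = if (is.na(dist$band)) NULL
                             else paste0("band +/-", dist$band * 100, "%")) +
    ggplot2::theme_minimal()
  if (!is.null(dist$local_value) && is.finite(dist$local_value))
    g <- g + ggplot2::geom_vline(xintercept = dist$local_value,
                                 linetype = "dashed", colour = "blue")
  if (!is.null(bounds) && bounds$status == "ok")
    g <- g + ggplot2::geom_vline(xintercept = c(bounds$lower, bounds$upper),
                                 linetype = "dashed", colour = "darkgreen")
  g
}

#' Grouped bar chart of a robustness profile
#'
#' Fraction of parameters attaining the magnitude threshold, by variation
#' band and evidence source (sampling, and optimisation when available).
#'
#' @param profile a `robustness_profile`.
#' @return a ggplot object, or `NULL` when ggplot2 is unavailable.
#' @export
plot_robustness <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(NULL)
  df <- data.frame(band = factor(profile$bands),
                   source = "sampling",
                   fraction = profile$exceedance_sampling)
  if (!all(is.na(profile$exceedance_optimisation))) {
    df <- rbind(df, data.frame(band = factor(profile$bands),
                               source = "optimisation",
                               fraction = profile$exceedance_optimisation))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$fraction,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "parameter variation band (fractional half-width)",
                  y = paste0("fraction of parameters with |coef| >= ",
                             profile$threshold)) +
    ggplot2::theme_minimal()
}

save_figure <- function(g, path, width = 6, height = 4) {
  if (is.null(g)) return(invisible(NULL))
  tryCatch(suppressMessages(
    ggplot2::ggsave(path, g, width = width, height = height, dpi = 120)),
    error = function(e) invisible(NULL))
  invisible(path)
}
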