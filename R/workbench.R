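# Orchestration: validated run configs, stage execution, results-table
# assembly, and a machine-readable run log. All randomness flows from
# explicit config seeds; no stage touches the global RNG implicitly.

results_row <- function(variant, block, parameter, value,
                        uncertainty = NA_real_, display = NULL) {
  if (is.null(display)) display <- format(signif(value, 3))
  data.frame(variant = variant, block = block, parameter = parameter,
             value = value, uncertainty = uncertainty, display = display,
             stringsAsFactors = FALSE)
}

empty_results_table <- function() {
  data.frame(variant = character(), block = character(),
             parameter = character(), value = numeric(),
             uncertainty = numeric(), display = character(),
             stringsAsFactors = FALSE)
}

#' Build an assay scenario from a nested config list
#'
#' Accepts the `scenario` block of a run config (or YAML file): sub-lists
#' `buffer` and `calibration` plus `substrate0`, `enzyme_loading`,
#' `dilution_factor`, `temperature`.
#'
#' @param cfg Nested list.
#' @return An [assay_scenario()].
#' @export
scenario_from_config <- function(cfg) {
  if (is.null(cfg$buffer) || is.null(cfg$calibration) || is.null(cfg$substrate0))
    halocat_error("scenario config needs buffer, calibration and substrate0",
                  "halocat_validation")
  buf <- do.call(buffer_spec, cfg$buffer)
  cal <- do.call(indicator_calibration, cfg$calibration)
  assay_scenario(buffer = buf, calibration = cal,
                 substrate0 = cfg$substrate0,
                 enzyme_loading = cfg$enzyme_loading %||% 0.05,
                 dilution_factor = cfg$dilution_factor %||% 2,
                 temperature = cfg$temperature %||% 30)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      halocat_error(sprintf("config file not found: %s", config),
                    "halocat_validation")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    halocat_error("config must be a list or a YAML file path",
                  "halocat_validation")
  config$stages <- config$stages %||% character()
  known <- c("simulate", "quantify", "halide", "kinetics", "selectivity",
             "tm", "spm")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    halocat_error(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                  "halocat_validation")
  # every referenced input must exist before any computation starts
  for (st in config$stages) {
    blk <- config[[st]]
    for (key in intersect(names(blk),
                          c("plate", "standards", "data", "gc", "melt",
                            "reference", "ensemble")))
      if (is.character(blk[[key]]) && !file.exists(blk[[key]]))
        halocat_error(sprintf("stage '%s': input file not found: %s",
                              st, blk[[key]]), "halocat_validation")
    if (st != "simulate" && !is.null(config$seed_required) &&
        isTRUE(config$seed_required)) next
  }
  config
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stage chain (any of `simulate`, `quantify`,
#' `halide`, `kinetics`, `selectivity`, `tm`, `spm`), writes stage outputs
#' under `output_dir`, and assembles a results table shaped like the kinetic-
#' and selectivity-parameter tables this pipeline targets (one row per
#' (variant, block, parameter)). A JSON run log capturing the full config
#' (inputs, seeds, parameters, package version) is written alongside, so any
#' output is reproducible from the log alone. On stage failure, partial
#' outputs created by this run are removed.
#'
#' @param config Nested list or path to a YAML file. Recognized top-level
#'   fields: `stages` (character vector, executed in order), `output_dir`,
#'   `seed`, plus one block per stage (see the vignette for the schema).
#' @return Results-table data frame (invisibly also written to
#'   `output_dir/results.csv` when any stage produced rows).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  created <- character()
  note <- function(p) { created <<- c(created, p); p }
  rows <- empty_results_table()

  run_stage <- function(st) {
    blk <- config[[st]] %||% list()
    switch(st,
      simulate = {
        type <- blk$type %||% "resolution"
        seed <- blk$seed %||% config$seed %||% 1L
        if (type == "resolution") {
          obs <- simulate_resolution_outcome(blk$e_true, blk$target_conversion,
                                             blk$preferred %||% "S",
                                             label = blk$label %||% "sim")
          write_gc_table(obs, note(file.path(out_dir, blk$out %||% "gc_table.csv")))
        } else if (type == "melt") {
          mc <- simulate_melt_curve(blk$tm, blk$steepness %||% 1.5,
                                    plateaus = unlist(blk$plateaus %||% c(0, 1)),
                                    noise_sd = blk$noise_sd %||% 0, seed = seed)
          write_melt_csv(mc, note(file.path(out_dir, blk$out %||% "melt.csv")))
        } else if (type == "plate") {
          scen <- scenario_from_config(blk$scenario)
          truth <- do.call(true_kinetics, blk$kinetics)
          pc <- simulate_progress_curve(truth, scen$substrate0,
                                        blk$enzyme_site_conc %||% 1e-3,
                                        blk$times %||% c(30, 60, 180, 270, 360))
          zero <- progress_curve(c(0, pc$catalyzed$time_s),
                                 c(0, pc$catalyzed$product),
                                 substrate0 = scen$substrate0)
          ts <- simulate_plate_timeseries(zero, scen,
                                          noise_sd = blk$noise_sd %||% 0,
                                          seed = seed)
          write_plate_csv(ts, note(file.path(out_dir, blk$out %||% "plate.csv")))
        } else if (type == "ensemble") {
          spec <- ensemble_spec(do.call(rbind, blk$mean_coordinates),
                                do.call(rbind, blk$correlation_targets),
                                fluctuation_scale = blk$fluctuation_scale %||% 1,
                                n_frames = blk$n_frames %||% 1000, seed = seed)
          write_ensemble_table(simulate_ensemble(spec),
                               note(file.path(out_dir, blk$out %||% "ensemble.txt")))
        } else halocat_error(sprintf("unknown simulate type: %s", type),
                             "halocat_validation")
      },
      quantify = {
        scen <- scenario_from_config(blk$scenario)
        wells <- read_plate_csv(blk$plate)
        curves <- lapply(wells, quantify_timeseries, scenario = scen)
        write_progress_csv(curves, note(file.path(out_dir,
                                                  blk$out %||% "progress.csv")))
      },
      halide = {
        std <- utils::read.csv(blk$standards)
        curve <- fit_standard_curve(std$conc_mM, std$A460)
        reads <- utils::read.csv(blk$plate)
        names(reads)[names(reads) == "A460"] <- "a460"
        curves <- halide_progress(reads, curve, blk$substrate0 %||% 10)
        write_progress_csv(curves, note(file.path(out_dir,
                                                  blk$out %||% "progress.csv")))
        rows <<- rbind(rows, results_row("standards", "halide", "slope",
                                         curve$slope, display = NULL),
                       results_row("standards", "halide", "r_squared",
                                   curve$r_squared))
      },
      kinetics = {
        d <- utils::read.csv(blk$data)
        data <- kinetic_dataset(d$s, d$rate,
                                sd = if ("sd" %in% names(d)) d$sd else NULL)
        variant <- blk$variant %||% "sample"
        block <- blk$block %||% attr(data, "varied_species")
        if ((blk$model %||% "hill") == "mm") {
          fit <- fit_michaelis_menten(data)
          rows <<- rbind(rows,
            results_row(variant, block, "kcat", fit$kcat, fit$se_kcat),
            results_row(variant, block, "km", fit$km, fit$se_km),
            results_row(variant, block, "kcat_over_km", fit$efficiency,
                        fit$se_efficiency))
        } else {
          fit <- fit_hill(data)
          rows <<- rbind(rows,
            results_row(variant, block, "kobs_max", fit$kobs_max, fit$se_kobs_max),
            results_row(variant, block, "k50", fit$k50, fit$se_k50),
            results_row(variant, block, "n_h", fit$n_h, fit$se_n_h),
            results_row(variant, block, "kobs_max_over_k50", fit$efficiency,
                        fit$se_efficiency))
        }
      },
      selectivity = {
        gc <- read_gc_table(blk$gc)
        for (r in seq_len(nrow(gc))) {
          res <- e_from_c_eep(gc$conversion[r], gc$ee_p[r],
                              preferred = gc$preferred[r])
          rows <<- rbind(rows, results_row(gc$sample[r], "selectivity",
                                           "E", res$e_value,
                                           display = res$display))
        }
      },
      tm = {
        curves <- read_melt_csv(blk$melt)
        for (mc in curves) {
          mr <- melting_temperature(mc, blk$smoothing_window %||% 5)
          rows <<- rbind(rows, results_row(attr(mc, "label"), "stability",
                                           "tm", mr$tm))
        }
        if (!is.null(blk$reference)) {
          ref <- read_melt_csv(blk$reference)[[1]]
          for (mc in curves) {
            dt <- delta_tm(mc, ref, smoothing_window = blk$smoothing_window %||% 5)
            rows <<- rbind(rows, results_row(attr(mc, "label"), "stability",
                                             "delta_tm", dt$delta_tm))
          }
        }
      },
      spm = {
        ens <- read_ensemble(blk$ensemble)
        g <- build_spm_graph(mean_distance_matrix(ens), dccm(ens),
                             distance_cutoff = blk$cutoff %||% 6.0,
                             min_abs_corr = blk$min_abs_corr %||% 0.01)
        g <- shortest_path_map(g, usage_quantile = blk$usage_quantile %||% 0.8)
        write_edge_csv(g, note(file.path(out_dir, blk$out %||% "spm_edges.csv")))
        utils::write.csv(residue_usage(g),
                         note(file.path(out_dir, "spm_residues.csv")),
                         row.names = FALSE)
      })
  }

  for (st in config$stages) {
    tryCatch(run_stage(st), error = function(e) {
      unlink(created)
      halocat_error(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
                    "halocat_stage_failure")
    })
  }

  if (nrow(rows)) {
    utils::write.csv(rows, file.path(out_dir, "results.csv"), row.names = FALSE)
  }
  log <- list(package = "halocat",
              version = as.character(utils::packageVersion("halocat")),
              config = config)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rows
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `halocat` script (see `inst/exec/halocat.R`):
#' subcommands `quantify`, `halide`, `selectivity`, `tm`, `spm`, `simulate`
#' and `run`, each a direct wrapper over the exported functions.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
halocat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h")) {
    cat("usage: halocat {run|quantify|halide|selectivity|tm|spm|simulate} [--key value ...]\n")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat(sprintf("halocat %s\n", utils::packageVersion("halocat")))
    return(invisible(0L))
  }
  cmd <- args[1]
  kv <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    kv[[gsub("-", "_", key)]] <- if (i + 1 <= length(args)) args[i + 1] else ""
    i <- i + 2L
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  switch(cmd,
    run = { run_pipeline(kv$config); },
    quantify = {
      cfg <- yaml::read_yaml(kv$config)
      scen <- scenario_from_config(cfg$scenario %||% cfg)
      curves <- lapply(read_plate_csv(kv$plate), quantify_timeseries,
                       scenario = scen)
      write_progress_csv(curves, kv$out %||% "progress.csv")
    },
    halide = {
      std <- utils::read.csv(kv$standards)
      curve <- fit_standard_curve(std$conc_mM, std$A460)
      reads <- utils::read.csv(kv$plate)
      names(reads)[names(reads) == "A460"] <- "a460"
      write_progress_csv(halide_progress(reads, curve,
                                         num(kv$substrate0) %||% 10),
                         kv$out %||% "progress.csv")
    },
    selectivity = {
      gc <- read_gc_table(kv$gc)
      out <- do.call(rbind, lapply(seq_len(nrow(gc)), function(r) {
        res <- e_from_c_eep(gc$conversion[r], gc$ee_p[r],
                            preferred = gc$preferred[r])
        data.frame(sample = gc$sample[r], E = res$e_value,
                   display = res$display)
      }))
      if (!is.null(kv$out)) utils::write.csv(out, kv$out, row.names = FALSE)
      else print(out)
    },
    tm = {
      curves <- read_melt_csv(kv$melt)
      for (mc in curves) {
        mr <- melting_temperature(mc)
        cat(sprintf("%s\tTm = %.2f degC\n", attr(mc, "label"), mr$tm))
        if (!is.null(kv$reference)) {
          dt <- delta_tm(mc, read_melt_csv(kv$reference)[[1]])
          cat(sprintf("%s\tdelta Tm = %+.2f K\n", attr(mc, "label"), dt$delta_tm))
        }
      }
    },
    spm = {
      ens <- read_ensemble(kv$ensemble)
      g <- build_spm_graph(mean_distance_matrix(ens), dccm(ens),
                           distance_cutoff = num(kv$cutoff) %||% 6.0,
                           min_abs_corr = num(kv$min_abs_corr) %||% 0.01)
      g <- shortest_path_map(g, usage_quantile = num(kv$quantile) %||% 0.8)
      write_edge_csv(g, kv$out %||% "spm_edges.csv")
    },
    simulate = {
      type <- kv$type %||% "resolution"
      if (type == "resolution") {
        obs <- simulate_resolution_outcome(num(kv$e_true),
                                           num(kv$conversion))
        write_gc_table(obs, kv$out %||% "gc_table.csv")
      } else if (type == "melt") {
        mc <- simulate_melt_curve(num(kv$tm), num(kv$steepness) %||% 1.5,
                                  noise_sd = num(kv$noise_sd) %||% 0,
                                  seed = as.integer(num(kv$seed) %||% 1))
        write_melt_csv(mc, kv$out %||% "melt.csv")
      } else halocat_error(sprintf("unknown simulate type: %s", type),
                           "halocat_validation")
    },
    halocat_error(sprintf("unknown subcommand: %s", cmd), "halocat_validation"))
  invisible(0L)
}
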