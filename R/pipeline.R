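# End-to-end orchestration: respirometry -> kinetics -> mass balance ->
# treatment statistics, plus the command-line entry points.

#' Options controlling the analysis pipeline
#'
#' @param objective RMSE space for kinetic fits, `"log"` or `"linear"`.
#' @param min_points_per_phase Minimum observations per kinetic phase.
#' @param max_phases Maximum phases tried by the piecewise fit (1-3).
#' @param replicate_handling `"subtract_then_average"` (default) subtracts
#'   the control baseline from each replicate and averages the fitted rate
#'   constants; `"average_then_subtract"` pools replicate series first and
#'   fits once per fuel.
#' @param basis Mineralization basis for the mass balance, `"carbon"` or
#'   `"ch2"`.
#' @param volatilization Optional named vector of per-fuel volatilized
#'   percents overriding [volatilization_default()].
#' @param response Response variable for treatment comparisons: whole-window
#'   `"k"` (default), `"cumulative_co2"`, or `"mean_daily"` CO2.
#' @param include_t0 Anchor substrate trajectories at (day 0, C0).
#' @param mg_per_meq Trap titration constant, mg CO2 per meq.
#' @param alpha Significance level for treatment comparisons.
#' @return A named list of validated options.
#' @export
pipeline_options <- function(objective = c("log", "linear"),
                             min_points_per_phase = 3, max_phases = 3,
                             replicate_handling = c("subtract_then_average",
                                                    "average_then_subtract"),
                             basis = c("carbon", "ch2"),
                             volatilization = NULL,
                             response = c("k", "cumulative_co2",
                                          "mean_daily"),
                             include_t0 = TRUE, mg_per_meq = 22,
                             alpha = 0.05) {
  objective <- match.arg(objective)
  replicate_handling <- match.arg(replicate_handling)
  basis <- match.arg(basis)
  response <- match.arg(response)
  stopifnot(min_points_per_phase >= 2, max_phases >= 1, max_phases <= 3,
            mg_per_meq > 0, alpha > 0, alpha < 1)
  list(objective = objective,
       min_points_per_phase = min_points_per_phase,
       max_phases = as.integer(max_phases),
       replicate_handling = replicate_handling, basis = basis,
       volatilization = volatilization, response = response,
       include_t0 = isTRUE(include_t0), mg_per_meq = mg_per_meq,
       alpha = alpha)
}

.series_from_inputs <- function(metadata, titration, opts) {
  specs <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    microcosm_spec(m$microcosm_id, m$fuel, m$fuel_mass_mg, m$soil_mass_g,
                   m$n_added_mg, m$setup, m$replicate, m$temperature_c)
  })
  names(specs) <- metadata$microcosm_id
  pre_converted <- "co2_mg" %in% names(titration)
  series <- lapply(specs, function(sp) {
    rows <- titration[titration$microcosm_id == sp$id, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no titration/CO2 records for microcosm '", sp$id, "'")
    }
    if (pre_converted) {
      rows <- rows[order(rows$day), , drop = FALSE]
      respiration_series(rows$day, rows$co2_mg, microcosm = sp)
    } else {
      resp_from_titration(rows, microcosm = sp,
                          mg_per_meq = opts$mg_per_meq)
    }
  })
  list(specs = specs, series = series)
}

.subtract_controls <- function(specs, series) {
  is_control <- vapply(specs, function(s) s$fuel == "CONTROL", TRUE)
  out <- series
  for (setup in unique(vapply(specs, `[[`, "", "setup"))) {
    in_setup <- vapply(specs, function(s) s$setup == setup, TRUE)
    ctrl_ids <- names(specs)[in_setup & is_control]
    samp_ids <- names(specs)[in_setup & !is_control]
    if (length(ctrl_ids) == 0L) {
      if (length(samp_ids)) {
        warning("no control for setup ", setup,
                "; series left unsubtracted")
      }
      next
    }
    baseline <- if (length(ctrl_ids) == 1L) series[[ctrl_ids]] else {
      average_series(series[ctrl_ids])
    }
    for (id in samp_ids) {
      out[[id]] <- subtract_baseline(series[[id]], baseline, align = TRUE)
    }
  }
  out
}

.fit_microcosm <- function(net, spec, opts) {
  s <- build_substrate_series(net, c0 = spec$fuel_mass,
                              include_t0 = opts$include_t0,
                              require_baseline = FALSE)
  whole <- suppressWarnings(
    fit_single_phase(s, objective = opts$objective))
  fits <- list()
  for (np in seq_len(opts$max_phases)) {
    fit <- tryCatch(
      suppressWarnings(fit_piecewise(s, n_phases = np,
                                     min_points = opts$min_points_per_phase,
                                     objective = opts$objective)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  list(substrate = s, whole_window = whole, piecewise = fits)
}

.response_value <- function(kin, net, opts) {
  switch(opts$response,
         k = kin$whole_window$k,
         cumulative_co2 = net$cumulative_co2[length(net$cumulative_co2)],
         mean_daily = average_daily_rate(net))
}

#' Run the full analysis pipeline
#'
#' Respirometry (titration to net CO2 with baseline subtraction), kinetics
#' (whole-window and piecewise first-order fits for soil-bed microcosms),
#' endpoint carbon mass balance (when endpoint measurements are supplied),
#' and treatment comparisons (one-way ANOVA with Tukey HSD plus pairwise
#' paired t-tests on the chosen response). Inputs may be file paths or
#' data frames in the documented CSV dialects. The run is fully
#' deterministic; when `out_dir` is given, reports are written only after
#' the whole analysis has succeeded.
#'
#' @param metadata Metadata CSV path or data frame
#'   (see [read_metadata_csv()]).
#' @param titration Titration CSV path or data frame; a pre-converted CO2
#'   table (`microcosm_id, day, co2_mg`) is also accepted.
#' @param endpoint Optional endpoint CSV path or data frame.
#' @param out_dir Optional output directory for the report bundle
#'   (`respiration.csv`, `fits.csv`, `k_summary.csv`, `balance.csv`,
#'   `stats_pairwise.csv`, `summary.json`).
#' @param options A [pipeline_options()] list.
#' @return Invisibly, an `analysis_report`: list with `respiration`,
#'   `fits`, `k_summary`, `balance`, `balance_summary`, `anova`,
#'   `pairwise_t`, `kinetics` (per-microcosm fit objects), `options`.
#' @export
analyze <- function(metadata, titration, endpoint = NULL, out_dir = NULL,
                    options = pipeline_options()) {
  metadata <- .as_table(metadata, read_metadata_csv)
  pre <- is.data.frame(titration) && "co2_mg" %in% names(titration)
  titration <- .as_table(titration, function(p) {
    # accept either dialect on disk
    head <- names(utils::read.csv(p, nrows = 1))
    if ("co2_mg" %in% head) read_co2_csv(p) else read_titration_csv(p)
  })
  if (!is.null(endpoint)) endpoint <- .as_table(endpoint, read_endpoint_csv)
  opts <- options

  built <- .series_from_inputs(metadata, titration, opts)
  specs <- built$specs
  net <- .subtract_controls(specs, built$series)

  respiration <- do.call(rbind, lapply(net, as.data.frame))
  rownames(respiration) <- NULL

  soil_ids <- names(specs)[vapply(specs, function(s) {
    s$setup == "SOIL_BED" && s$fuel != "CONTROL"
  }, TRUE)]

  kinetics <- lapply(soil_ids, function(id) {
    .fit_microcosm(net[[id]], specs[[id]], opts)
  })
  names(kinetics) <- soil_ids

  if (opts$replicate_handling == "average_then_subtract" &&
      length(soil_ids)) {
    # pool replicate series per fuel, refit once per fuel
    fuels <- vapply(specs[soil_ids], `[[`, "", "fuel")
    pooled <- lapply(split(soil_ids, fuels), function(ids) {
      avg <- average_series(net[ids])
      avg$microcosm <- specs[[ids[1]]]
      .fit_microcosm(avg, specs[[ids[1]]], opts)
    })
    k_vals <- vapply(pooled, function(x) x$whole_window$k, 0)
    k_summary <- summarize_k(k_vals, names(pooled))
  } else if (length(soil_ids)) {
    k_vals <- vapply(kinetics, function(x) x$whole_window$k, 0)
    k_summary <- summarize_k(
      k_vals, vapply(specs[soil_ids], `[[`, "", "fuel"))
  } else {
    k_summary <- NULL
  }

  fits <- if (length(kinetics)) {
    do.call(rbind, lapply(soil_ids, function(id) {
      kin <- kinetics[[id]]
      rows <- lapply(kin$piecewise, as.data.frame)
      rows[[length(rows) + 1L]] <- data.frame(
        microcosm_id = id, n_phases = 1L, phase = 1L,
        t_start = kin$whole_window$t_start,
        t_end = kin$whole_window$t_end, k = kin$whole_window$k,
        c_start = kin$whole_window$c_start,
        n_points = kin$whole_window$n, rmse = kin$whole_window$rmse)
      do.call(rbind, rows)
    }))
  } else NULL

  balance <- NULL
  balance_summary <- NULL
  if (!is.null(endpoint) && length(soil_ids)) {
    rows <- lapply(soil_ids, function(id) {
      ep <- endpoint[endpoint$microcosm_id == id, , drop = FALSE]
      if (nrow(ep) == 0L) return(NULL)
      sp <- specs[[id]]
      volat <- if (!is.null(opts$volatilization) &&
                   sp$fuel %in% names(opts$volatilization)) {
        opts$volatilization[[sp$fuel]]
      } else NULL
      bal <- assemble_balance(
        net[[id]],
        dro_result(ep$dro_measured_mg[1], ep$surrogate_recovery[1]),
        nitrogen_budget(ep$n_final_mg[1], sp$n_added),
        sp, volat_assumed_pct = volat, basis = opts$basis)
      as.data.frame(bal)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) {
      balance <- do.call(rbind, rows)
      rownames(balance) <- NULL
      comp <- c("pct_mineralized", "pct_residual_dro", "pct_biomass",
                "pct_volatilized", "pct_unaccounted")
      balance_summary <- do.call(rbind, lapply(
        split(balance, balance$fuel), function(d) {
          out <- data.frame(fuel = d$fuel[1], n = nrow(d))
          for (cc in comp) {
            out[[paste0("mean_", cc)]] <- mean(d[[cc]])
            out[[paste0("se_", cc)]] <-
              if (nrow(d) >= 2) standard_error(d[[cc]]) else NA_real_
          }
          out
        }))
      rownames(balance_summary) <- NULL
    }
  }

  anova_res <- NULL
  pairwise_t <- NULL
  if (length(soil_ids) >= 4L) {
    fuels <- vapply(specs[soil_ids], `[[`, "", "fuel")
    resp_vals <- vapply(soil_ids, function(id) {
      .response_value(kinetics[[id]], net[[id]], opts)
    }, 0)
    groups <- split(unname(resp_vals), fuels)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) >= 2L) {
      anova_res <- anova_tukey(groups, alpha = opts$alpha)
      combs <- utils::combn(names(groups), 2, simplify = FALSE)
      rows <- lapply(combs, function(pr) {
        a <- groups[[pr[1]]]
        b <- groups[[pr[2]]]
        if (length(a) != length(b)) return(NULL)
        tt <- paired_t_test(a, b, alpha = opts$alpha)
        data.frame(group_a = pr[1], group_b = pr[2],
                   statistic = tt$statistic, p_value = tt$p_value,
                   degenerate = tt$degenerate,
                   significant = isTRUE(tt$significant),
                   stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows)) pairwise_t <- do.call(rbind, rows)
    }
  }

  report <- structure(
    list(respiration = respiration, fits = fits, k_summary = k_summary,
         balance = balance, balance_summary = balance_summary,
         anova = anova_res, pairwise_t = pairwise_t, kinetics = kinetics,
         net_series = net, options = opts),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  if (!is.null(x$k_summary)) {
    cat("  Whole-window first-order rate constants (per day):\n")
    print(x$k_summary, row.names = FALSE)
  }
  if (!is.null(x$balance_summary)) {
    cat("  Carbon balance (per-fuel means, % of initial C):\n")
    cols <- c("fuel", "n", grep("^mean_", names(x$balance_summary),
                                value = TRUE))
    print(x$balance_summary[, cols], row.names = FALSE, digits = 3)
  }
  if (!is.null(x$anova)) {
    cat(sprintf("  ANOVA on %s: F = %.3f, p = %.3g\n",
                "treatment groups", x$anova$statistic, x$anova$p_value))
  }
  invisible(x)
}

#' Write an analysis report bundle to disk
#'
#' @param report An `analysis_report` from [analyze()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$respiration, "respiration.csv")
  wr(report$fits, "fits.csv")
  wr(report$k_summary, "k_summary.csv")
  wr(report$balance, "balance.csv")
  wr(report$pairwise_t, "stats_pairwise.csv")
  summary <- list(
    k_summary = report$k_summary,
    balance_summary = report$balance_summary,
    anova = if (!is.null(report$anova)) list(
      statistic = report$anova$statistic,
      p_value = report$anova$p_value,
      degenerate = report$anova$degenerate,
      pairwise = report$anova$pairwise) else NULL,
    options = report$options[c("objective", "min_points_per_phase",
                               "max_phases", "replicate_handling",
                               "basis", "response", "alpha")]
  )
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(c(paths, p))
}

# --- command line ----------------------------------------------------------

.read_json_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop("config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.cli_simulate <- function(args) {
  parser <- optparse::OptionParser(
    usage = "mineralize simulate --out DIR [--config CFG.json] [--seed N]")
  parser <- optparse::add_option(parser, "--out", type = "character")
  parser <- optparse::add_option(parser, "--config", type = "character",
                                 default = NULL)
  parser <- optparse::add_option(parser, "--seed", type = "integer",
                                 default = NULL)
  opt <- optparse::parse_args(parser, args)
  if (is.null(opt$out)) stop("simulate: --out is required")
  over <- .read_json_config(opt$config)
  over <- over[names(over) %in% names(formals(generator_config))]
  if (!is.null(opt$seed)) over$seed <- opt$seed
  cfg <- do.call(generator_config, over)
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, opt$out)
  message("wrote cohort (", nrow(cohort$metadata), " microcosms) to ",
          opt$out)
  invisible(cohort)
}

.cli_analyze <- function(args, fits_only = FALSE, print_summary = FALSE) {
  parser <- optparse::OptionParser(
    usage = paste("mineralize analyze --metadata CSV --titration CSV",
                  "[--endpoint CSV] --out DIR [--config CFG.json]"))
  for (o in c("--metadata", "--titration", "--endpoint", "--out",
              "--config")) {
    parser <- optparse::add_option(parser, o, type = "character",
                                   default = NULL)
  }
  opt <- optparse::parse_args(parser, args)
  if (is.null(opt$metadata) || is.null(opt$titration) || is.null(opt$out)) {
    stop("analyze: --metadata, --titration and --out are required")
  }
  over <- .read_json_config(opt$config)
  over <- over[names(over) %in% names(formals(pipeline_options))]
  opts <- do.call(pipeline_options, over)
  report <- analyze(opt$metadata, opt$titration,
                    endpoint = if (fits_only) NULL else opt$endpoint,
                    out_dir = NULL, options = opts)
  if (fits_only) {
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$fits, file.path(opt$out, "fits.csv"),
                     row.names = FALSE)
  } else {
    write_report(report, opt$out)
  }
  if (print_summary) print(report)
  message("wrote report to ", opt$out)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `analyze` (full
#' pipeline to a report bundle), `fit` (kinetic fits only), `report`
#' (analyze and print the summary). Invoked by the `exec/mineralize`
#' script; callable directly with an argument vector for testing.
#'
#' @param args Character vector of command-line arguments; defaults to
#'   the process arguments.
#' @return Invisibly, the subcommand's result object.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: mineralize <simulate|analyze|fit|report> [options]")
  }
  cmd <- args[1]
  rest <- args[-1]
  switch(cmd,
         simulate = .cli_simulate(rest),
         analyze = .cli_analyze(rest),
         fit = .cli_analyze(rest, fits_only = TRUE),
         report = .cli_analyze(rest, print_summary = TRUE),
         stop("unknown subcommand '", cmd,
              "'; expected simulate, analyze, fit or report"))
}
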