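# Text-first result serialization and the command-line entry point.

#' Write analysis results as delimited / structured text
#'
#' Gridded objects (bifurcation branches, region maps, heat maps, IBI
#' curves) are written as tab-separated tables with headers; scalar records
#' (square-root-law fits, experiment reports) as `key = value` structured
#' text. Numeric precision is 9 significant digits. Missing heat-map cells
#' are serialized as the sentinel `NA`, never as 0.
#'
#' @param x a data frame, `sac_bifdiag`, `sqrt_law_fit`, `ibi_stats`, or
#'   `sac_experiment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.9g", v) else as.character(v)
  }
  if (inherits(x, "sqrt_law_fit")) {
    writeLines(c(
      sprintf("K = %.9g", x$K),
      sprintf("K_ci_low = %.9g", x$K_ci[1]),
      sprintf("K_ci_high = %.9g", x$K_ci[2]),
      sprintf("I_c = %.9g", x$I_c),
      sprintf("I_c_ci_low = %.9g", x$I_c_ci[1]),
      sprintf("I_c_ci_high = %.9g", x$I_c_ci[2]),
      sprintf("residual_norm = %.9g", x$residual_norm),
      sprintf("form = %s", x$form),
      sprintf("n_points = %d", x$n_points)), path)
  } else if (inherits(x, "ibi_stats")) {
    writeLines(c(
      sprintf("mean_ibi_ms = %.9g", x$mean_ibi),
      sprintf("n_bursts = %d", x$n_bursts),
      sprintf("n_trajectories = %d", x$n_trajectories),
      sprintf("n_zero_burst = %d", x$n_zero_burst),
      sprintf("total_time_ms = %.9g", x$total_time),
      paste("ibis_ms =", paste(sprintf("%.9g", x$ibis), collapse = " "))),
      path)
  } else if (inherits(x, "sac_experiment")) {
    keys <- setdiff(names(x), "trajectory")
    writeLines(vapply(keys, function(k) paste(k, "=", fmt(x[[k]])), ""), path)
  } else if (inherits(x, "sac_bifdiag")) {
    utils::write.table(format(x$branches, digits = 9, trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(x$events))
      utils::write.table(format(x$events, digits = 9, trim = TRUE),
                         paste0(path, ".events"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  } else if (is.data.frame(x)) {
    utils::write.table(format(x, digits = 9, trim = TRUE), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  } else stop("don't know how to serialize an object of class ",
              paste(class(x), collapse = "/"))
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: sacburst <command> [options]",
    "",
    "commands:",
    "  simulate      --T <ms> [--iext <pA>] [--sigma <pA.ms^1/2>] [--dt <ms>]",
    "  fixed-points  --itot <pA>",
    "  continuation  --from <pA> --to <pA> --step <pA>",
    "  map2d         --x {I_tot|g_C|V_3} --xfrom --xto --xstep",
    "                --gkfrom --gkto --gkstep",
    "  ibi-sweep     --iext <from:to:step> [--sigma] [--gk] [--gc] [--T <ms>]",
    "  heatmap       --gcfrom --gcto --gkfrom --gkto [--res <nS>] [--T <ms>]",
    "  experiment    --type {pulse|scenario} [--variant ...] [--name ...]",
    "",
    "global options: --config <file> --seed <int> --out <file>",
    sep = "\n")
}

cli_opts <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1L], "--"))
      stop("option --", key, " needs a value")
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

opt_num <- function(opts, key, default = NULL) {
  if (!is.null(opts[[key]])) as.numeric(opts[[key]])
  else if (!is.null(default)) default
  else stop("missing required option --", key)
}

#' Command-line dispatcher
#'
#' Entry point behind the `inst/cli/sacburst` Rscript. Subcommands:
#' `simulate`, `fixed-points`, `continuation`, `map2d`, `ibi-sweep`,
#' `heatmap`, `experiment`. Global options `--config` (parameter file for
#' [read_params_config()]), `--seed`, `--out`. Results go to `--out` when
#' given, otherwise to stdout. Returns a nonzero status on any error.
#'
#' @param argv character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_dispatch <- function(argv) {
  status <- tryCatch({
    if (!length(argv)) { message(cli_usage()); return(invisible(2L)) }
    cmd <- argv[1]
    opts <- cli_opts(argv[-1])
    params <- if (!is.null(opts$config)) read_params_config(opts$config)
              else sac_params()
    seed <- as.integer(opt_num(opts, "seed", 1))
    emit <- function(x) {
      if (!is.null(opts$out)) {
        write_results(x, opts$out)
        message("wrote ", opts$out)
      } else if (is.data.frame(x)) {
        utils::write.table(format(x, digits = 9, trim = TRUE), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      } else print(x)
    }
    switch(cmd,
      "simulate" = {
        p <- params
        if (!is.null(opts$sigma)) p$sigma <- as.numeric(opts$sigma)
        if (!is.null(opts$iext)) p$I_ext_baseline <- as.numeric(opts$iext)
        tr <- simulate_sac(p, T = opt_num(opts, "T"),
                           dt = opt_num(opts, "dt", 0.05), seed = seed)
        if (!is.null(opts$out)) {
          write_trajectory(tr, opts$out); message("wrote ", opts$out)
        } else print(tr)
      },
      "fixed-points" = {
        emit(find_fixed_points(opt_num(opts, "itot"), params))
      },
      "continuation" = {
        bd <- continue_in_current(params,
                                  I_range = c(opt_num(opts, "from"),
                                              opt_num(opts, "to")),
                                  step = opt_num(opts, "step"))
        emit(bd)
      },
      "map2d" = {
        x <- if (is.null(opts$x)) "I_tot" else opts$x
        rm2 <- region_map_2d(x,
          x_grid = seq(opt_num(opts, "xfrom"), opt_num(opts, "xto"),
                       by = opt_num(opts, "xstep")),
          gK_grid = seq(opt_num(opts, "gkfrom"), opt_num(opts, "gkto"),
                        by = opt_num(opts, "gkstep")),
          params = params)
        emit(as.data.frame(rm2))
      },
      "ibi-sweep" = {
        spec <- as.numeric(strsplit(opts$iext %||% stop("need --iext"),
                                    ":")[[1]])
        if (length(spec) != 3) stop("--iext must be from:to:step")
        p <- params
        if (!is.null(opts$sigma)) p$sigma <- as.numeric(opts$sigma)
        if (!is.null(opts$gk)) p$g_K <- as.numeric(opts$gk)
        if (!is.null(opts$gc)) p$g_C <- as.numeric(opts$gc)
        emit(ibi_vs_iext(seq(spec[1], spec[2], by = spec[3]), p,
                         T = opt_num(opts, "T", 5e5), base_seed = seed))
      },
      "heatmap" = {
        emit(ibi_heatmap(c(opt_num(opts, "gcfrom"), opt_num(opts, "gcto")),
                         c(opt_num(opts, "gkfrom"), opt_num(opts, "gkto")),
                         resolution = opt_num(opts, "res", 0.25),
                         params = params, T = opt_num(opts, "T", 5e5),
                         base_seed = seed))
      },
      "experiment" = {
        type <- opts$type %||% stop("need --type pulse|scenario")
        if (type == "pulse")
          emit(run_pulse_experiment(opts$variant %||% "control", params,
                                    seed = seed))
        else if (type == "scenario")
          emit(run_developmental_scenario(opts$name %||%
                                            stop("need --name"), seed = seed))
        else stop("unknown experiment type: ", type)
      },
      {
        message("unknown command: ", cmd, "\n\n", cli_usage())
        return(invisible(2L))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
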