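# Operational shell: config files, result serialization, command line.

CONFIG_KEYS <- c("scenario", "grid", "mode", "r", "threshold",
                 "max_generations", "previous_resistance", "cry_p0",
                 "output_dir")

parse_grid_spec <- function(spec) {
  if (is.numeric(spec)) return(refuge_grid(spec[1], spec[2], spec[3]))
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop(sprintf("malformed grid spec '%s' (expected 'from:to:by')", spec),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals)) {
    stop(sprintf("malformed grid spec '%s' (non-numeric component)", spec),
         call. = FALSE)
  }
  refuge_grid(vals[1], vals[2], vals[3])
}

#' Parse a run-configuration file
#'
#' Reads a YAML configuration describing a scenario run. Recognized keys:
#' `scenario` (1-6, required), `grid` (`"from:to:by"`, default
#' `"0:1:0.01"`), `mode` (`"exact"` or `"le"`, default `"exact"`), `r`
#' (recombination fraction, default 0.5), `threshold` (default 0.5),
#' `max_generations` (default 20), `previous_resistance` (logical: run the
#' previous-Cry3Bb1-resistance pyramid sweep instead of the scenario's
#' standard arms; default `FALSE`), `cry_p0` (levels for that sweep) and
#' `output_dir` (default `"."`). Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("malformed config file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.list(raw)) stop("malformed config file: not a key/value mapping",
                          call. = FALSE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(raw$scenario)) stop("config must name a `scenario` (1..6)",
                                  call. = FALSE)
  if (!raw$scenario %in% 1:6) {
    stop(sprintf("unknown scenario '%s' (must be 1..6)", raw$scenario),
         call. = FALSE)
  }
  cfg <- list(
    scenario = as.integer(raw$scenario),
    grid = parse_grid_spec(raw$grid %||% "0:1:0.01"),
    mode = match.arg(raw$mode %||% "exact", c("exact", "le")),
    r = raw$r %||% 0.5,
    threshold = raw$threshold %||% 0.5,
    max_generations = raw$max_generations %||% 20L,
    previous_resistance = isTRUE(raw$previous_resistance),
    cry_p0 = raw$cry_p0 %||% table1_registry("p0.prior.levels"),
    output_dir = raw$output_dir %||% "."
  )
  # validate numeric settings through the same checks the engine applies
  sim_config(threshold = cfg$threshold, max_generations = cfg$max_generations,
             r = cfg$r, mode = cfg$mode)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a parsed run configuration
#'
#' @param cfg A [parse_run_config()] result.
#' @return The long `sweep_result` data frame, invisibly after writing it
#'   (and its metadata sidecar) under `cfg$output_dir`.
#' @export
run_config_execute <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  res <- if (cfg$previous_resistance) {
    previous_resistance_sweep(cfg$scenario, cry_p0 = cfg$cry_p0,
                              grid = cfg$grid, mode = cfg$mode, r = cfg$r,
                              threshold = cfg$threshold,
                              max_generations = cfg$max_generations)
  } else {
    run_scenario(cfg$scenario, grid = cfg$grid, mode = cfg$mode, r = cfg$r,
                 threshold = cfg$threshold,
                 max_generations = cfg$max_generations)
  }
  stem <- if (cfg$previous_resistance) {
    sprintf("scenario-%d-previous-resistance", cfg$scenario)
  } else sprintf("scenario-%d", cfg$scenario)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$output_dir, paste0(stem, ".csv"))
  write_results(res, path, meta = unclass(cfg)[setdiff(names(cfg), "grid")])
  invisible(res)
}

#' Write sweep results as long-format CSV
#'
#' Writes one row per (scenario, arm, refuge proportion) with integer
#' generations and a logical censoring flag. Refuge proportions are
#' serialized as exact two-decimal strings so the grid round-trips without
#' floating drift; a YAML metadata sidecar (`<path>.meta.yaml`) records the
#' settings needed to reproduce the run bit-exactly.
#'
#' @param results A `sweep_result` data frame (see [refuge_sweep()]).
#' @param path Output CSV path.
#' @param meta Optional named list of run metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, meta = NULL) {
  stopifnot(is.data.frame(results))
  out <- as.data.frame(results)
  out$refuge_prop <- sprintf("%.2f", out$refuge_prop)
  out$censored <- tolower(as.character(out$censored))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  sidecar <- c(list(package = "btrefuge",
                    version = as.character(utils::packageVersion("btrefuge"))),
               meta)
  yaml::write_yaml(sidecar, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read sweep results written by [write_results()]
#'
#' @param path CSV path.
#' @return A `sweep_result` data frame with numeric `refuge_prop`, integer
#'   `generations` and logical `censored`.
#' @export
read_results <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$refuge_prop <- as.numeric(out$refuge_prop)
  out$generations <- as.integer(out$generations)
  out$censored <- out$censored == "true"
  class(out) <- c("sweep_result", "data.frame")
  out
}

cli_usage <- function() {
  paste(
    "usage: btrefuge <command> [options]",
    "",
    "commands:",
    "  run        --scenario N [--out DIR] [--mode exact|le] [--grid F:T:B]",
    "             [--previous-resistance]   run a study scenario, write CSV",
    "  run        --config FILE             run from a YAML config file",
    "  sweep      --w-ss X --h X [--cost X] [--cost-dominance X] --p0 X",
    "             [--w-ss2 ... --p02 ...] [--out FILE] [--mode M] [--grid F:T:B]",
    "                                       ad-hoc refuge sweep",
    "  min-refuge same options as sweep, plus [--target N]",
    "                                       smallest refuge delaying resistance",
    "  validate                             neutrality + segregation checks",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    }
    key <- gsub("-", "_", substring(a, 3))
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE  # bare switch
      i <- i + 1L
    }
  }
  flags
}

flags_to_loci <- function(fl) {
  num <- function(x, d = 0) if (is.null(x)) d else as.numeric(x)
  if (is.null(fl$w_ss) || is.null(fl$h) || is.null(fl$p0)) {
    stop("sweep requires --w-ss, --h and --p0", call. = FALSE)
  }
  l1 <- locus_params(w_ss = num(fl$w_ss), h = num(fl$h), cost = num(fl$cost),
                     cost_dominance = num(fl$cost_dominance),
                     p0 = num(fl$p0), label = "locus1")
  if (is.null(fl$w_ss2)) return(list(l1))
  l2 <- locus_params(w_ss = num(fl$w_ss2), h = num(fl$h2),
                     cost = num(fl$cost2),
                     cost_dominance = num(fl$cost_dominance2),
                     p0 = num(fl$p02), label = "locus2")
  list(l1, l2)
}

cli_run <- function(fl) {
  cfg <- if (!is.null(fl$config)) {
    parse_run_config(fl$config)
  } else {
    if (is.null(fl$scenario)) stop("run requires --scenario or --config",
                                   call. = FALSE)
    if (!fl$scenario %in% 1:6) {
      stop(sprintf("unknown scenario '%s' (must be 1..6)", fl$scenario),
           call. = FALSE)
    }
    structure(list(scenario = as.integer(fl$scenario),
                   grid = parse_grid_spec(fl$grid %||% "0:1:0.01"),
                   mode = match.arg(fl$mode %||% "exact", c("exact", "le")),
                   r = as.numeric(fl$r %||% 0.5),
                   threshold = as.numeric(fl$threshold %||% 0.5),
                   max_generations = as.integer(fl$max_generations %||% 20L),
                   previous_resistance = isTRUE(fl$previous_resistance),
                   cry_p0 = table1_registry("p0.prior.levels"),
                   output_dir = fl$out %||% "."),
              class = "run_config")
  }
  res <- run_config_execute(cfg)
  cat(sprintf("wrote %d rows for scenario %d to %s\n",
              nrow(res), cfg$scenario, cfg$output_dir))
  0L
}

cli_sweep <- function(fl, min_refuge = FALSE) {
  loci <- flags_to_loci(fl)
  cfg <- sim_config(mode = match.arg(fl$mode %||% "exact", c("exact", "le")),
                    r = as.numeric(fl$r %||% 0.5),
                    threshold = as.numeric(fl$threshold %||% 0.5),
                    max_generations = as.integer(fl$max_generations %||% 20L),
                    pyramid = length(loci) == 2L)
  grid <- parse_grid_spec(fl$grid %||% "0:1:0.01")
  if (min_refuge) {
    target <- as.integer(fl$target %||% 20L)
    phi <- min_refuge_for_delay(loci, cfg, target_generations = target,
                                grid = grid)
    cat(if (is.na(phi)) "none\n" else sprintf("%.2f\n", phi))
    return(0L)
  }
  res <- refuge_sweep(loci, cfg, grid = grid, scenario = NA, arm = "adhoc")
  if (!is.null(fl$out)) {
    write_results(res, fl$out)
    cat(sprintf("wrote %d rows to %s\n", nrow(res), fl$out))
  } else {
    utils::write.csv(res, row.names = FALSE)
  }
  0L
}

cli_validate <- function() {
  # neutrality: allele frequencies constant without selection or costs
  neut <- neutral_scenario()$arms$neutral$loci
  cfg <- sim_config(refuge_prop = 0.3, pyramid = TRUE)
  fit <- landscape_fitness(
    pyramid_fitness(locus_fitness(neut[[1]]), locus_fitness(neut[[2]])), 0.3)
  st <- initial_state(neut[[1]]$p0, neut[[2]]$p0)
  for (g in 1:20) st <- step_generation(st, fit)
  drift <- max(abs(allele_frequency(st, 1) - neut[[1]]$p0),
               abs(allele_frequency(st, 2) - neut[[2]]$p0))
  # segregation: closed form vs brute-force enumeration on random tables
  draws <- sample_scenarios(20, seed = 1L)
  seg <- 0
  for (d in draws) {
    f <- landscape_fitness(
      pyramid_fitness(locus_fitness(d$locus1), locus_fitness(d$locus2)),
      d$refuge[1])
    gt <- apply_selection(
      genotype_frequencies(initial_state(d$locus1$p0, d$locus2$p0)), f)
    for (r in c(0, 0.25, 0.5)) {
      seg <- max(seg, max(abs(produce_gametes(gt, r)$gametes -
                              mating_table_oracle(gt, r)$gametes)))
    }
  }
  ok <- drift <= 1e-12 && seg <= 1e-12
  cat(sprintf("neutral allele-frequency drift: %.3g (tolerance 1e-12)\n", drift))
  cat(sprintf("segregation closed-form vs enumeration: %.3g (tolerance 1e-12)\n",
              seg))
  cat(if (ok) "validation passed\n" else "validation FAILED\n")
  if (ok) 0L else 1L
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; see `inst/cli/btrefuge` for
#' the executable wrapper. Subcommands: `run` (study scenario to CSV),
#' `sweep` (ad-hoc parameters to CSV), `min-refuge` (smallest refuge
#' delaying resistance to a target generation count), `validate` (neutrality
#' and segregation self-checks).
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly: 0 on success, 1 on a run error,
#'   2 on a usage error.
#' @export
cli_main <- function(argv = character()) {
  if (length(argv) == 0 || argv[[1]] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(argv) == 0) 2L else 0L))
  }
  cmd <- argv[[1]]
  rest <- argv[-1]
  code <- tryCatch({
    fl <- parse_flags(rest)
    switch(cmd,
           run = cli_run(fl),
           sweep = cli_sweep(fl),
           `min-refuge` = cli_sweep(fl, min_refuge = TRUE),
           validate = cli_validate(),
           {
             message(sprintf("unknown command '%s'", cmd))
             message(cli_usage())
             2L
           })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
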