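#' Simulation settings
#'
#' @param refuge_prop Proportion of the landscape planted to non-Bt refuge,
#'   in `[0, 1]`.
#' @param threshold Resistance-allele frequency defining resistance; the
#'   comparison is inclusive (a frequency equal to the threshold counts).
#'   Must lie in `(0, 1)`. Default 0.5.
#' @param max_generations Generation cap; runs not reaching the criterion by
#'   then are censored. Default 20.
#' @param r Recombination fraction between the loci, in `[0, 0.5]`. Default
#'   0.5 (unlinked).
#' @param mode `"exact"` phased-gamete recursion (default) or `"le"`
#'   linkage-equilibrium approximation; see [step_generation()].
#' @param pyramid Logical: must both loci cross the threshold (pyramid
#'   cultivar), or only locus 1 (single-toxin cultivar)?
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(refuge_prop = 0, threshold = 0.5, max_generations = 20L,
                       r = 0.5, mode = c("exact", "le"), pyramid = FALSE) {
  refuge_prop <- check_prop(refuge_prop, "refuge_prop")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(max_generations) || length(max_generations) != 1L ||
      max_generations < 1) {
    stop("`max_generations` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 0.5) {
    stop("`r` must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(refuge_prop = refuge_prop, threshold = threshold,
                 max_generations = as.integer(max_generations), r = r,
                 mode = match.arg(mode), pyramid = isTRUE(pyramid)),
            class = "sim_config")
}

resolve_loci <- function(params) {
  if (inherits(params, "locus_params")) params <- list(params)
  if (!is.list(params) || !length(params) %in% c(1L, 2L) ||
      !all(vapply(params, inherits, logical(1), "locus_params"))) {
    stop("`params` must be one or two locus_params objects", call. = FALSE)
  }
  if (length(params) == 1L) params <- c(params, list(neutral_locus()))
  params
}

#' Generations until the resistance criterion is met
#'
#' Runs the deterministic recursion at a fixed refuge proportion until the
#' post-selection resistance-allele frequency reaches the threshold (at
#' locus 1 for a single-toxin cultivar; at both loci in the same generation
#' for a pyramid), or until the generation cap. The landscape fitness table
#' is built once and held constant. Generations are counted as 1-based
#' selection-reproduction cycles, and the criterion is evaluated on the
#' post-selection adult allele frequency (identical, under random mating, to
#' the next egg cohort's frequency).
#'
#' @param params One `locus_params` (single-toxin run) or a list of two
#'   (pyramid run; a single-locus run is internally a pyramid with a neutral
#'   second locus).
#' @param cfg A [sim_config()]. If `cfg$pyramid` is missing its default, it
#'   is taken as `TRUE` exactly when two non-degenerate loci are supplied.
#' @return An object of class `time_to_resistance`: list with integer
#'   `generations`, logical `censored`, and `trajectory`, a data frame of
#'   per-generation post-selection allele frequencies (`generation`,
#'   `freq1`, `freq2`).
#' @examples
#' cry <- locus_params(w_ss = 0.104, h = 0.375, cost = 0.041, p0 = 0.001,
#'                     label = "Cry3Bb1")
#' time_to_resistance(cry, sim_config(refuge_prop = 0))  # 6 generations
#' @export
time_to_resistance <- function(params, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  loci <- resolve_loci(params)
  fit <- landscape_fitness(
    pyramid_fitness(locus_fitness(loci[[1]]), locus_fitness(loci[[2]])),
    cfg$refuge_prop)
  state <- initial_state(loci[[1]]$p0, loci[[2]]$p0)
  traj <- matrix(NA_real_, cfg$max_generations, 2L)
  hit <- NA_integer_
  for (g in seq_len(cfg$max_generations)) {
    state <- step_generation(state, fit, r = cfg$r, mode = cfg$mode)
    f1 <- allele_frequency(state, 1)
    f2 <- allele_frequency(state, 2)
    traj[g, ] <- c(f1, f2)
    resistant <- if (cfg$pyramid) f1 >= cfg$threshold && f2 >= cfg$threshold
                 else f1 >= cfg$threshold
    if (resistant) {
      hit <- g
      break
    }
  }
  censored <- is.na(hit)
  gens <- if (censored) cfg$max_generations else hit
  traj <- traj[seq_len(gens), , drop = FALSE]
  structure(list(generations = as.integer(gens), censored = censored,
                 trajectory = data.frame(generation = seq_len(gens),
                                         freq1 = traj[, 1], freq2 = traj[, 2]),
                 config = cfg),
            class = "time_to_resistance")
}

#' @export
print.time_to_resistance <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Resistance not reached within %d generations (censored)\n",
                x$generations))
  } else {
    cat(sprintf("Resistance reached at generation %d\n", x$generations))
  }
  invisible(x)
}

#' Refuge-proportion grid
#'
#' Grid points are generated by integer index (`i / denominator`) so that
#' they are exact two-decimal values, never accumulated by repeated
#' addition.
#'
#' @param from,to Range endpoints in `[0, 1]`.
#' @param by Step size; must be a multiple of 1/10000 within tolerance.
#' @return Numeric vector of grid points, inclusive of both endpoints.
#' @export
refuge_grid <- function(from = 0, to = 1, by = 0.01) {
  from <- check_prop(from, "from")
  to <- check_prop(to, "to")
  if (!is.numeric(by) || by <= 0 || to < from) {
    stop("need `by` > 0 and `to` >= `from`", call. = FALSE)
  }
  den <- 10000L
  i0 <- round(from * den)
  i1 <- round(to * den)
  st <- round(by * den)
  if (st == 0) stop("`by` is too small", call. = FALSE)
  seq.int(i0, i1, by = st) / den
}

#' Time to resistance across a grid of refuge proportions
#'
#' @inheritParams time_to_resistance
#' @param grid Vector of refuge proportions, strictly increasing within
#'   `[0, 1]`; default the 0 to 1 grid in 0.01 increments.
#' @param scenario,arm Optional identifier strings carried into the result.
#' @return A `sweep_result`: data frame with columns `refuge_prop`,
#'   `generations`, `censored` (plus `scenario` and `arm` if supplied), one
#'   row per grid point.
#' @export
refuge_sweep <- function(params, cfg = sim_config(), grid = refuge_grid(),
                         scenario = NULL, arm = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(diff(grid) <= 0) || any(grid < 0) || any(grid > 1)) {
    stop("`grid` must be strictly increasing within [0, 1]", call. = FALSE)
  }
  rows <- lapply(grid, function(phi) {
    cfg$refuge_prop <- phi
    res <- time_to_resistance(params, cfg)
    data.frame(refuge_prop = phi, generations = res$generations,
               censored = res$censored)
  })
  out <- do.call(rbind, rows)
  if (!is.null(arm)) out <- cbind(arm = arm, out)
  if (!is.null(scenario)) out <- cbind(scenario = scenario, out)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Minimum refuge achieving a target delay
#'
#' Finds the smallest grid refuge proportion at which resistance is delayed
#' by at least `target_generations`: the run is censored at the cap, or the
#' criterion is first met at generation `target_generations` or later.
#'
#' @inheritParams refuge_sweep
#' @param target_generations Target delay in generations; default 20, the
#'   generation cap.
#' @return The smallest qualifying refuge proportion, or `NA` if no grid
#'   point qualifies.
#' @export
min_refuge_for_delay <- function(params, cfg = sim_config(),
                                 target_generations = 20L,
                                 grid = refuge_grid()) {
  stopifnot(inherits(cfg, "sim_config"))
  for (phi in grid) {
    cfg$refuge_prop <- phi
    res <- time_to_resistance(params, cfg)
    if (res$censored || res$generations >= target_generations) return(phi)
  }
  NA_real_
}
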