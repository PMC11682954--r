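# Published parameter values for western corn rootworm on Cry3Bb1 and
# Gpp34/Tpp35Ab1 maize: literature means for field survival of susceptibles,
# inheritance (dominance) of resistance, fitness costs on non-Bt maize, and
# initial resistance-allele frequencies, plus the low/high variants used in
# the sensitivity scenarios.
TABLE1 <- list(
  cry3bb1.baseline = list(w_ss = 0.104, h = 0.375, cost = 0.041,
                          cost_dominance = 0),
  gpp34tpp35.baseline = list(w_ss = 0.118, h = 0.36, cost = 0.0555,
                             cost_dominance = 0),
  inheritance.low = 0.14,
  inheritance.high = 0.73,
  cost.none = list(cost = 0, cost_dominance = 0),
  cost.high = list(cost = 0.15, cost_dominance = 0.4),
  p0.common = 0.001,
  p0.realistic.cry3bb1 = 0.2,
  p0.realistic.gpp34tpp35 = 0.075,
  p0.prior.scenario1 = 0.1,
  p0.prior.scenario2 = 0.35,
  p0.prior.levels = c(0.2, 0.35, 0.5, 0.8)
)

#' Registry of published model parameters
#'
#' Named registry of the parameter values used by the rootworm scenarios:
#' baseline per-toxin sets (`cry3bb1.baseline`, `gpp34tpp35.baseline`), the
#' low/high inheritance bounds (0.14, 0.73; applied to both toxins in the
#' sensitivity scenarios), the no-cost and high nonrecessive-cost variants
#' (15% with a 0.4 heterozygote multiplier, i.e. 6% in heterozygotes), and
#' the initial resistance-allele frequencies (common assumption 0.001;
#' realistic 0.2 for Cry3Bb1 and 0.075 for Gpp34/Tpp35Ab1; the
#' previous-resistance levels 0.2, 0.35, 0.5, 0.8).
#'
#' @param name Optional entry name; omitted returns the whole registry.
#' @return The registry list, or the named entry.
#' @examples
#' table1_registry("cry3bb1.baseline")$w_ss
#' @export
table1_registry <- function(name = NULL) {
  if (is.null(name)) return(TABLE1)
  if (!name %in% names(TABLE1)) {
    stop(sprintf("unknown parameter set '%s'; available: %s", name,
                 paste(names(TABLE1), collapse = ", ")), call. = FALSE)
  }
  TABLE1[[name]]
}

# Build locus_params for one toxin with optional scenario overrides.
toxin_params <- function(toxin = c("cry3bb1", "gpp34tpp35"), p0,
                         h = NULL, cost = NULL, cost_dominance = NULL) {
  toxin <- match.arg(toxin)
  base <- TABLE1[[paste0(toxin, ".baseline")]]
  locus_params(
    w_ss = base$w_ss,
    h = if (is.null(h)) base$h else h,
    cost = if (is.null(cost)) base$cost else cost,
    cost_dominance = if (is.null(cost_dominance)) base$cost_dominance
                     else cost_dominance,
    p0 = p0,
    label = if (toxin == "cry3bb1") "Cry3Bb1" else "Gpp34/Tpp35Ab1")
}

scenario_overrides <- function(id) {
  switch(id,
    `1` = list(),
    `2` = list(),
    `3` = list(h = TABLE1$inheritance.low),
    `4` = list(h = TABLE1$inheritance.high),
    `5` = list(cost = TABLE1$cost.none$cost,
               cost_dominance = TABLE1$cost.none$cost_dominance),
    `6` = list(cost = TABLE1$cost.high$cost,
               cost_dominance = TABLE1$cost.high$cost_dominance))
}

scenario_descriptions <- c(
  "common initial frequencies (0.001), baseline inheritance and costs",
  "realistic initial frequencies (0.2 Cry3Bb1, 0.075 Gpp34/Tpp35Ab1)",
  "low inheritance of resistance (h = 0.14 at both loci)",
  "high inheritance of resistance (h = 0.73 at both loci)",
  "no fitness costs at either locus",
  "high nonrecessive fitness costs (15%; 6% in heterozygotes)")

#' Definition of one study scenario
#'
#' Six scenarios vary initial resistance-allele frequency, inheritance of
#' resistance, and fitness costs. Scenario 1 uses the common assumed initial
#' frequency 0.001 at both loci (its prior-resistance pyramid arm raises
#' Cry3Bb1 to 0.1). Scenario 2 uses the realistic frequencies, 0.2 for
#' Cry3Bb1 and 0.075 for Gpp34/Tpp35Ab1 (prior-resistance arm: Cry3Bb1 at
#' 0.35, halfway between 0.2 and the 0.5 resistance cutoff). Scenarios 3 and
#' 4 set inheritance at both loci to the low (0.14) and high (0.73) bounds;
#' scenarios 5 and 6 set fitness costs to zero and to the high nonrecessive
#' value (15%, 6% in heterozygotes). Scenarios 3-6 keep scenario 2's initial
#' frequencies. Every scenario has four arms: each single-toxin cultivar and
#' two pyramid arms (without and with previous Cry3Bb1 resistance).
#'
#' @param id Scenario number, 1 to 6.
#' @return An object of class `scenario_spec`: list with `id`, `description`
#'   and a named list `arms`; each arm has a `type` (`"single"` or
#'   `"pyramid"`) and one or two [locus_params()].
#' @export
scenario_spec <- function(id) {
  if (!(length(id) == 1L && id %in% 1:6)) {
    stop(sprintf("unknown scenario '%s' (must be 1..6)", paste(id, collapse = ",")),
         call. = FALSE)
  }
  id <- as.integer(id)
  ov <- scenario_overrides(as.character(id))
  cry <- function(p0) do.call(toxin_params, c(list("cry3bb1", p0 = p0), ov))
  gpp <- function(p0) do.call(toxin_params, c(list("gpp34tpp35", p0 = p0), ov))
  if (id == 1L) {
    p_common <- TABLE1$p0.common
    arms <- list(
      single.cry3bb1 = list(type = "single", loci = list(cry(p_common))),
      single.gpp34tpp35 = list(type = "single", loci = list(gpp(p_common))),
      pyr1 = list(type = "pyramid", loci = list(cry(p_common), gpp(p_common))),
      pyr2 = list(type = "pyramid",
                  loci = list(cry(TABLE1$p0.prior.scenario1), gpp(p_common))))
  } else {
    p_cry <- TABLE1$p0.realistic.cry3bb1
    p_gpp <- TABLE1$p0.realistic.gpp34tpp35
    arms <- list(
      single.cry3bb1 = list(type = "single", loci = list(cry(p_cry))),
      single.gpp34tpp35 = list(type = "single", loci = list(gpp(p_gpp))),
      pyr3 = list(type = "pyramid", loci = list(cry(p_cry), gpp(p_gpp))),
      pyr4 = list(type = "pyramid",
                  loci = list(cry(TABLE1$p0.prior.scenario2), gpp(p_gpp))))
  }
  structure(list(id = id, description = scenario_descriptions[id], arms = arms),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %d: %s\n", x$id, x$description))
  for (nm in names(x$arms)) {
    a <- x$arms[[nm]]
    p0s <- vapply(a$loci, function(l) l$p0, numeric(1))
    cat(sprintf("  %-18s %-7s p0 = %s\n", nm, a$type,
                paste(format(p0s), collapse = ", ")))
  }
  invisible(x)
}

arm_sweep <- function(arm, arm_name, scenario_id, grid, mode, r,
                      threshold, max_generations) {
  cfg <- sim_config(threshold = threshold, max_generations = max_generations,
                    r = r, mode = mode, pyramid = arm$type == "pyramid")
  refuge_sweep(arm$loci, cfg, grid = grid,
               scenario = scenario_id, arm = arm_name)
}

#' Run all arms of a scenario over the refuge grid
#'
#' @param spec A [scenario_spec()] or a scenario number 1-6.
#' @param grid Refuge-proportion grid; default 0 to 1 in 0.01 steps.
#' @param mode Recursion mode passed to the engine; `"le"` reproduces the
#'   published curves (see the methods vignette), `"exact"` keeps full
#'   gamete-frequency dynamics.
#' @param r Recombination fraction.
#' @param threshold,max_generations Resistance criterion settings.
#' @return A long `sweep_result` data frame with columns `scenario`, `arm`,
#'   `refuge_prop`, `generations`, `censored`.
#' @export
run_scenario <- function(spec, grid = refuge_grid(), mode = c("exact", "le"),
                         r = 0.5, threshold = 0.5, max_generations = 20L) {
  if (!inherits(spec, "scenario_spec")) spec <- scenario_spec(spec)
  mode <- match.arg(mode)
  out <- do.call(rbind, lapply(names(spec$arms), function(nm) {
    arm_sweep(spec$arms[[nm]], nm, spec$id, grid, mode, r,
              threshold, max_generations)
  }))
  rownames(out) <- NULL
  out
}

#' Pyramid sweeps under previous resistance to Cry3Bb1
#'
#' Re-runs a scenario's pyramid arm with elevated initial Cry3Bb1
#' resistance-allele frequencies (default 0.2, 0.35, 0.5, 0.8 — 0.2 being
#' the realistic frequency, i.e. no previous exposure beyond background),
#' holding the Gpp34/Tpp35Ab1 initial frequency at 0.075, and includes the
#' single-toxin Gpp34/Tpp35Ab1 sweep as a reference arm.
#'
#' @param scenario A [scenario_spec()] or scenario number (2-6 use this
#'   sweep in the study; scenario 1's settings are permitted too).
#' @param cry_p0 Initial Cry3Bb1 resistance-allele frequencies to sweep.
#' @inheritParams run_scenario
#' @return A long `sweep_result` data frame; pyramid arms are labelled
#'   `pyr.cry<p0>` plus the `single.gpp34tpp35` reference.
#' @export
previous_resistance_sweep <- function(scenario = 2,
                                      cry_p0 = TABLE1$p0.prior.levels,
                                      grid = refuge_grid(),
                                      mode = c("exact", "le"), r = 0.5,
                                      threshold = 0.5, max_generations = 20L) {
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  mode <- match.arg(mode)
  ov <- scenario_overrides(as.character(scenario$id))
  gpp <- do.call(toxin_params,
                 c(list("gpp34tpp35", p0 = TABLE1$p0.realistic.gpp34tpp35), ov))
  arms <- lapply(cry_p0, function(p0) {
    list(type = "pyramid",
         loci = list(do.call(toxin_params, c(list("cry3bb1", p0 = p0), ov)),
                     gpp))
  })
  names(arms) <- sprintf("pyr.cry%s", format(cry_p0))
  arms$single.gpp34tpp35 <- list(type = "single", loci = list(gpp))
  out <- do.call(rbind, lapply(names(arms), function(nm) {
    arm_sweep(arms[[nm]], nm, scenario$id, grid, mode, r,
              threshold, max_generations)
  }))
  rownames(out) <- NULL
  out
}
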