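# Seeded generator of random parameter sets for property-based testing. The
# model itself is deterministic; randomness exists only here.

draw_ranges <- list(w_ss = c(0.01, 0.5), h = c(0, 1), cost = c(0, 0.2),
                    cost_dominance = c(0, 1), p0 = c(1e-4, 0.5))

runif_in <- function(range) stats::runif(1, range[1], range[2])

random_locus <- function(label) {
  locus_params(w_ss = runif_in(draw_ranges$w_ss),
               h = runif_in(draw_ranges$h),
               cost = runif_in(draw_ranges$cost),
               cost_dominance = if (stats::runif(1) < 0.5) 0
                                else runif_in(draw_ranges$cost_dominance),
               p0 = runif_in(draw_ranges$p0),
               label = label)
}

# Deterministic edge cases included in every batch: dominance extremes, zero
# cost, and initial frequencies at the range bounds.
edge_draws <- function() {
  mk <- function(h1, cost1, p1, p2) {
    list(locus1 = locus_params(w_ss = 0.1, h = h1, cost = cost1,
                               cost_dominance = 0, p0 = p1, label = "edge1"),
         locus2 = locus_params(w_ss = 0.2, h = 0.5, cost = 0.05,
                               cost_dominance = 0.4, p0 = p2, label = "edge2"),
         refuge = c(0, 0.25, 0.5, 1))
  }
  list(mk(0, 0.05, 1e-4, 0.01),   # recessive resistance, p0 at lower bound
       mk(1, 0.05, 0.01, 1e-4),   # dominant resistance
       mk(0.5, 0, 0.5, 0.5),      # no cost, p0 at upper bound
       mk(0.5, 0.2, 0.25, 0.25))  # cost at upper bound
}

#' Random parameter sets for property-based tests
#'
#' Draws `n` two-locus parameter sets from documented ranges bracketing the
#' empirical literature values (`w_ss` in \[0.01, 0.5\], `h` in \[0, 1\],
#' `cost` in \[0, 0.2\], `cost_dominance` 0 or in \[0, 1\], `p0` in
#' \[1e-4, 0.5\]), each with a small refuge-grid subset. The first four
#' draws of every batch are fixed edge cases (recessive and dominant
#' inheritance, zero cost, initial frequency at both bounds), so edge
#' coverage is guaranteed rather than probabilistic. Identical seeds yield
#' identical batches; the caller's RNG state is left untouched.
#'
#' @param n Number of draws (at least 1; at least 4 are returned because the
#'   edge cases are always included).
#' @param seed Integer seed.
#' @return A list of draws; each is a list with `locus1`, `locus2`
#'   ([locus_params()]) and `refuge`, a vector of refuge proportions.
#' @export
sample_scenarios <- function(n, seed = 20240101L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fixed <- edge_draws()
  extra <- if (n > length(fixed)) {
    lapply(seq_len(n - length(fixed)), function(i) {
      list(locus1 = random_locus(sprintf("draw%d.1", i)),
           locus2 = random_locus(sprintf("draw%d.2", i)),
           refuge = sort(sample(refuge_grid(), 4)))
    })
  } else list()
  c(fixed, extra)
}

#' Neutral validation scenario
#'
#' A scenario in which selection and fitness costs are absent at both loci
#' (all survivals 1), used to verify the engine conserves allele frequencies:
#' under neutrality, frequencies must not change across generations at any
#' refuge proportion or recombination fraction.
#'
#' @param p1,p2 Initial resistance-allele frequencies.
#' @return A `scenario_spec`-like list with a single pyramid arm whose loci
#'   are under no selection.
#' @export
neutral_scenario <- function(p1 = 0.3, p2 = 0.1) {
  l1 <- locus_params(w_ss = 1, h = 0, cost = 0, cost_dominance = 0, p0 = p1,
                     label = "neutral1")
  l2 <- locus_params(w_ss = 1, h = 0, cost = 0, cost_dominance = 0, p0 = p2,
                     label = "neutral2")
  structure(list(id = NA_integer_,
                 description = "neutral validation (no selection, no costs)",
                 arms = list(neutral = list(type = "pyramid",
                                            loci = list(l1, l2)))),
            class = "scenario_spec")
}
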