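test_that("baseline single-toxin run at zero refuge takes six generations", {
  res <- time_to_resistance(cry_baseline(), sim_config(refuge_prop = 0))
  expect_equal(res$generations, 6L)
  expect_false(res$censored)
  # allele-frequency trajectory, frozen from the independent scalar recursion
  expect_equal(res$trajectory$freq1,
               c(0.004209, 0.017428, 0.067701, 0.214952, 0.465435, 0.700851),
               tolerance = 1e-4)
})

test_that("runs that cannot reach the threshold are censored", {
  neutral <- locus_params(w_ss = 1, h = 0, cost = 0, p0 = 0.01)
  res <- time_to_resistance(neutral, sim_config(refuge_prop = 0.2))
  expect_true(res$censored)
  expect_equal(res$generations, 20L)
  # pure refuge with a recessive cost: selection only acts against resistance
  costly <- locus_params(w_ss = 0.1, h = 0.375, cost = 0.1,
                         cost_dominance = 0.5, p0 = 0.2)
  res <- time_to_resistance(costly, sim_config(refuge_prop = 1))
  expect_true(res$censored)
  expect_lt(tail(res$trajectory$freq1, 1), 0.2)  # frequency declined
})

test_that("config validation rejects out-of-range settings", {
  expect_error(sim_config(threshold = 1.5), "threshold")
  expect_error(sim_config(max_generations = 0), "max_generations")
  expect_error(sim_config(r = 0.7), "r")
  expect_error(sim_config(refuge_prop = -0.2), "refuge_prop")
})

test_that("refuge sweep covers the grid and is monotone for the baseline", {
  sweep <- refuge_sweep(cry_baseline(), sim_config())
  expect_equal(nrow(sweep), 101L)
  expect_equal(sweep$refuge_prop, seq(0, 1, by = 0.01))
  expect_equal(sweep$generations[1], 6L)
  expect_true(all(diff(sweep$generations) >= 0))
  one <- refuge_sweep(cry_baseline(), sim_config(), grid = 0)
  expect_equal(nrow(one), 1L)
  expect_error(refuge_sweep(cry_baseline(), sim_config(), grid = c(0.2, 0.1)),
               "grid")
})

test_that("minimum refuge for a target delay honours censoring and neutrality", {
  neutral <- locus_params(w_ss = 1, h = 0, cost = 0, p0 = 0.01)
  expect_equal(min_refuge_for_delay(neutral, sim_config()), 0)
  phi <- min_refuge_for_delay(cry_baseline(), sim_config())
  sweep <- refuge_sweep(cry_baseline(), sim_config(),
                        grid = refuge_grid(phi - 0.01, phi))
  expect_lt(sweep$generations[1], 20L)
  expect_gte(sweep$generations[2], 20L)
})

test_that("time to resistance is monotone in refuge, p0, h and cost", {
  for (d in sample_scenarios(60, seed = 19L)) {
    cfg <- sim_config(pyramid = TRUE)
    base_params <- list(d$locus1, d$locus2)
    phis <- d$refuge
    times <- vapply(phis, function(phi) {
      cfg$refuge_prop <- phi
      ttr_value(time_to_resistance(base_params, cfg))
    }, numeric(1))
    expect_true(all(diff(times) >= 0))
    cfg$refuge_prop <- phis[2]
    t0 <- ttr_value(time_to_resistance(base_params, cfg))
    vary <- function(field, by) {
      ttr_value(time_to_resistance(list(vary_locus(d$locus1, field, by),
                                        d$locus2), cfg))
    }
    expect_lte(vary("p0", 0.2), t0)    # more initial resistance: not later
    expect_lte(vary("h", 0.3), t0)     # more dominant resistance: not later
    # costs are raised at both loci: raising a single locus's cost can
    # accelerate a pyramid by shifting selective weight toward the Bt
    # habitat at the other locus (see the methods vignette)
    both <- list(vary_locus(d$locus1, "cost", 0.3),
                 vary_locus(d$locus2, "cost", 0.3))
    expect_gte(ttr_value(time_to_resistance(both, cfg)), t0)
    # in the single-toxin reduction every perturbation is monotone
    scfg <- sim_config(refuge_prop = phis[2])
    s0 <- ttr_value(time_to_resistance(d$locus1, scfg))
    expect_gte(ttr_value(time_to_resistance(vary_locus(d$locus1, "cost", 0.3),
                                            scfg)), s0)
    expect_lte(ttr_value(time_to_resistance(vary_locus(d$locus1, "h", 0.3),
                                            scfg)), s0)
  }
})

test_that("identical inputs give bit-identical results", {
  cfg <- sim_config(refuge_prop = 0.25, pyramid = TRUE)
  params <- list(cry_baseline(0.2), gpp_baseline(0.075))
  a <- time_to_resistance(params, cfg)
  b <- time_to_resistance(params, cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$generations, b$generations)
})

test_that("extinction in a degenerate landscape surfaces as an error", {
  dead <- locus_params(w_ss = 0, h = 0, p0 = 0)
  expect_error(time_to_resistance(dead, sim_config(refuge_prop = 0)),
               class = "btrefuge_extinction")
})
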