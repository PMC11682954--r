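test_that("initial state sits at linkage equilibrium", {
  st <- initial_state(0.001, 0.001)
  expect_equal(st$gametes[["R1R2"]], 1e-6)
  expect_equal(sum(st$gametes), 1, tolerance = 1e-12)
  expect_equal(st$generation, 0L)
  st2 <- initial_state(0.2, 0.075)
  expect_equal(st2$gametes[["R1S2"]], 0.2 * 0.925)
  expect_equal(allele_frequency(st2, 1), 0.2, tolerance = 1e-15)
  expect_equal(allele_frequency(st2, 2), 0.075, tolerance = 1e-15)
  expect_equal(initial_state(0, 0)$gametes[["S1S2"]], 1)
  expect_error(initial_state(-0.1, 0), "p1")
  expect_error(allele_frequency(st, 3), "locus")
})

test_that("random union of gametes gives Hardy-Weinberg genotype classes", {
  fixed <- genotype_classes(genotype_frequencies(initial_state(0, 0)))
  expect_equal(fixed["SS", "SS"], 1)
  half <- genotype_classes(genotype_frequencies(initial_state(0.5, 0)))
  expect_equal(sum(half["RS", ]), 0.5)  # 2pq at p = 0.5
  gt <- genotype_classes(genotype_frequencies(initial_state(0.2, 0.075)))
  expect_equal(gt["RR", "SS"], (0.2 * 0.925)^2)
  expect_equal(sum(gt), 1, tolerance = 1e-12)
})

test_that("selection matches the single-locus closed form and flags extinction", {
  # neutral table leaves frequencies unchanged
  st <- initial_state(0.3, 0.2)
  neutral <- fit_for(neutral_locus(), neutral_locus(), 0)
  post <- apply_selection(genotype_frequencies(st), neutral)
  expect_equal(unclass(post), unclass(genotype_frequencies(st)),
               tolerance = 1e-15, ignore_attr = TRUE)
  # single-locus baseline at refuge 0: post-selection p from scalar recursion
  cry <- cry_baseline()
  post <- apply_selection(genotype_frequencies(initial_state(0.001, 0)),
                          fit_for(cry, phi = 0))
  p_post <- sum(unclass(post)[c(1, 2), ]) / 2 + sum(unclass(post)[, c(1, 2)]) / 2
  expect_equal(p_post, scalar_step(0.001, scalar_landscape(cry, 0)),
               tolerance = 1e-12)
  expect_equal(p_post, 0.004209, tolerance = 1e-4)
  # all-susceptible population with lethal Bt everywhere: mean fitness zero
  dead <- locus_params(w_ss = 0, h = 0, p0 = 0)
  expect_error(
    apply_selection(genotype_frequencies(initial_state(0, 0)),
                    fit_for(dead, phi = 0)),
    class = "btrefuge_extinction")
})

test_that("segregation closed form equals brute-force mating enumeration", {
  draws <- sample_scenarios(100, seed = 7L)
  worst <- 0
  for (d in draws) {
    fit <- fit_for(d$locus1, d$locus2, d$refuge[2])
    gt <- apply_selection(
      genotype_frequencies(initial_state(d$locus1$p0, d$locus2$p0)), fit)
    for (r in c(0, 0.17, 0.5)) {
      delta <- abs(produce_gametes(gt, r)$gametes -
                   mating_table_oracle(gt, r)$gametes)
      worst <- max(worst, max(delta))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("segregation handles monomorphic and cis-only parents exactly", {
  # population fixed for genotype R1R1 / S2S2 transmits only R1S2 gametes
  gt <- genotype_frequencies(initial_state(1, 0))
  out <- produce_gametes(apply_selection(gt, fit_for(neutral_locus())), 0.5)
  expect_equal(out$gametes[["R1S2"]], 1)
  # r = 0 with only cis double heterozygotes emits no recombinants
  m <- matrix(0, 4, 4, dimnames = list(HAPLOTYPES, HAPLOTYPES))
  m[1, 4] <- m[4, 1] <- 0.5
  gt <- structure(m, class = c("genotype_table", "matrix"),
                  stage = "post", generation = 0L)
  out <- produce_gametes(gt, 0)
  expect_equal(unname(out$gametes), c(0.5, 0, 0, 0.5))
  expect_equal(mating_table_oracle(gt, 0)$gametes, out$gametes,
               tolerance = 1e-15)
  # same table at r = 0.5: half the gametes are recombinant
  out5 <- produce_gametes(gt, 0.5)
  expect_equal(unname(out5$gametes), c(0.25, 0.25, 0.25, 0.25))
  expect_error(produce_gametes(gt, 0.7), "r")
})

test_that("random mating conserves allele frequencies exactly", {
  for (d in sample_scenarios(25, seed = 3L)) {
    fit <- fit_for(d$locus1, d$locus2, d$refuge[1])
    gt <- apply_selection(
      genotype_frequencies(initial_state(d$locus1$p0, d$locus2$p0)), fit)
    m <- unclass(gt)
    adult_p1 <- sum((rowSums(m) + colSums(m)) / 2 * c(1, 1, 0, 0))
    adult_p2 <- sum((rowSums(m) + colSums(m)) / 2 * c(1, 0, 1, 0))
    nxt <- produce_gametes(gt, 0.31)
    expect_equal(allele_frequency(nxt, 1), adult_p1, tolerance = 1e-14)
    expect_equal(allele_frequency(nxt, 2), adult_p2, tolerance = 1e-14)
  }
})

test_that("neutral linkage disequilibrium decays as (1 - r)^t", {
  neutral <- fit_for(neutral_locus(), neutral_locus(), 0.5)
  for (r in c(0.1, 0.5)) {
    # start with maximal LD: only cis haplotypes present
    st <- population_state(c(0.5, 0, 0, 0.5), 0L)
    d0 <- linkage_disequilibrium(st)
    for (t in 1:20) {
      st <- step_generation(st, neutral, r = r)
      expect_equal(linkage_disequilibrium(st), (1 - r)^t * d0,
                   tolerance = 1e-10)
    }
  }
})

test_that("allele frequencies are invariant under neutrality", {
  neut <- neutral_scenario(p1 = 0.27, p2 = 0.08)$arms$neutral$loci
  for (phi in c(0, 0.5, 1)) {
    fit <- fit_for(neut[[1]], neut[[2]], phi)
    st <- initial_state(0.27, 0.08)
    for (g in 1:20) st <- step_generation(st, fit, r = 0.5)
    expect_equal(allele_frequency(st, 1), 0.27, tolerance = 1e-12)
    expect_equal(allele_frequency(st, 2), 0.08, tolerance = 1e-12)
    expect_equal(sum(st$gametes), 1, tolerance = 1e-12)
    expect_equal(st$generation, 20L)
  }
})

test_that("two-locus engine reduces to the scalar recursion and stays at LE on pure Bt", {
  # degenerate locus 2: the gamete engine must track the scalar recursion
  cry <- cry_baseline()
  for (phi in c(0, 0.3)) {
    fit <- fit_for(cry, phi = phi)
    st <- initial_state(0.001, 0)
    p <- 0.001
    W <- scalar_landscape(cry, phi)
    for (g in 1:10) {
      st <- step_generation(st, fit, r = 0.5)
      p <- scalar_step(p, W)
      expect_equal(allele_frequency(st, 1), p, tolerance = 1e-12)
    }
  }
  # multiplicative two-locus fitness (pure Bt, no costs) preserves LE
  fit <- fit_for(locus_params(0.104, 0.375), locus_params(0.118, 0.36), 0)
  st <- initial_state(0.05, 0.02)
  for (g in 1:10) {
    st <- step_generation(st, fit, r = 0.5)
    expect_lt(abs(linkage_disequilibrium(st)), 1e-12)
  }
})

test_that("relabelling the loci mirrors the trajectory", {
  a <- locus_params(0.104, 0.375, cost = 0.041, p0 = 0.01)
  b <- locus_params(0.118, 0.36, cost = 0.0555, p0 = 0.075)
  f_ab <- fit_for(a, b, 0.2)
  f_ba <- fit_for(b, a, 0.2)
  st_ab <- initial_state(a$p0, b$p0)
  st_ba <- initial_state(b$p0, a$p0)
  for (g in 1:15) {
    st_ab <- step_generation(st_ab, f_ab)
    st_ba <- step_generation(st_ba, f_ba)
    expect_equal(allele_frequency(st_ab, 1), allele_frequency(st_ba, 2),
                 tolerance = 1e-14)
    expect_equal(allele_frequency(st_ab, 2), allele_frequency(st_ba, 1),
                 tolerance = 1e-14)
  }
})
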