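# Baseline western corn rootworm parameter sets used across tests.
cry_baseline <- function(p0 = 0.001) {
  locus_params(w_ss = 0.104, h = 0.375, cost = 0.041, cost_dominance = 0,
               p0 = p0, label = "Cry3Bb1")
}
gpp_baseline <- function(p0 = 0.001) {
  locus_params(w_ss = 0.118, h = 0.36, cost = 0.0555, cost_dominance = 0,
               p0 = p0, label = "Gpp34/Tpp35Ab1")
}

# Independent single-locus oracle: the scalar selection recursion
# p' = p (p W_RR + q W_RS) / wbar for landscape survivals W = c(SS, RS, RR).
# Written directly from the textbook formula; shares no code with the engine.
scalar_step <- function(p, W) {
  q <- 1 - p
  wbar <- p^2 * W[3] + 2 * p * q * W[2] + q^2 * W[1]
  p * (p * W[3] + q * W[2]) / wbar
}

scalar_landscape <- function(params, phi) {
  bt <- c(params$w_ss, params$w_ss + params$h * (1 - params$w_ss), 1)
  ref <- c(1, 1 - params$cost_dominance * params$cost, 1 - params$cost)
  phi * ref + (1 - phi) * bt
}

# Effective time to resistance for ordering comparisons: a censored run is
# later than any run that met the criterion within the cap.
ttr_value <- function(res) res$generations + as.integer(res$censored)

# Rebuild a locus_params with one field nudged upward (clamped at 1).
vary_locus <- function(l, field, by) {
  v <- list(w_ss = l$w_ss, h = l$h, cost = l$cost,
            cost_dominance = l$cost_dominance, p0 = l$p0)
  v[[field]] <- min(v[[field]] + by, 1)
  do.call(locus_params, v)
}

fit_for <- function(l1, l2 = neutral_locus(), phi = 0) {
  landscape_fitness(pyramid_fitness(locus_fitness(l1), locus_fitness(l2)), phi)
}
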