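# Haplotype bookkeeping. Order is fixed throughout the package:
#   1 = R1R2, 2 = R1S2, 3 = S1R2, 4 = S1S2
# where R1/S1 are the alleles at the locus for toxin 1 and R2/S2 at toxin 2.
HAPLOTYPES <- c("R1R2", "R1S2", "S1R2", "S1S2")
HAP_R1 <- c(1L, 1L, 0L, 0L)  # copies of R contributed at locus 1
HAP_R2 <- c(1L, 0L, 1L, 0L)

# genotype class index (1 = SS, 2 = RS, 3 = RR) for each ordered gamete pair
CLASS1 <- outer(HAP_R1, HAP_R1, `+`) + 1L
CLASS2 <- outer(HAP_R2, HAP_R2, `+`) + 1L

#' Population state: gamete frequencies and generation counter
#'
#' The model's state is the frequency vector of the four haplotypes
#' (`R1R2`, `R1S2`, `S1R2`, `S1S2`) in the current egg cohort, plus a counter
#' of completed selection-reproduction cycles. Frequencies must be
#' non-negative and sum to 1 (within 1e-9).
#'
#' @param gametes Numeric vector of length 4 (order `R1R2`, `R1S2`, `S1R2`,
#'   `S1S2`).
#' @param generation Non-negative integer.
#' @return An object of class `population_state`.
#' @export
population_state <- function(gametes, generation = 0L) {
  if (length(gametes) != 4L || !is.numeric(gametes)) {
    stop("`gametes` must be a numeric vector of length 4", call. = FALSE)
  }
  if (any(gametes < -1e-12)) {
    stop("gamete frequencies must be non-negative", call. = FALSE)
  }
  gametes <- pmax(gametes, 0)
  if (abs(sum(gametes) - 1) > 1e-9) {
    stop("gamete frequencies must sum to 1", call. = FALSE)
  }
  structure(list(gametes = stats::setNames(as.numeric(gametes), HAPLOTYPES),
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state, generation %d\n", x$generation))
  print(round(x$gametes, 6))
  cat(sprintf("  allele frequencies: locus 1 = %.6g, locus 2 = %.6g\n",
              allele_frequency(x, 1), allele_frequency(x, 2)))
  invisible(x)
}

#' Initial population at linkage equilibrium
#'
#' Initializes the gamete pool from independent per-locus resistance-allele
#' frequencies, i.e. at linkage equilibrium: the frequency of haplotype
#' `R1R2` is `p1 * p2`, and so on.
#'
#' @param p1,p2 Initial resistance-allele frequencies at loci 1 and 2,
#'   in `[0, 1]`.
#' @return A [population_state()] with `generation = 0`.
#' @examples
#' initial_state(0.2, 0.075)$gametes  # R1S2 gamete = 0.2 * 0.925
#' @export
initial_state <- function(p1, p2 = 0) {
  p1 <- check_prop(p1, "p1")
  p2 <- check_prop(p2, "p2")
  population_state(c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2,
                     (1 - p1) * (1 - p2)), 0L)
}

#' Resistance-allele frequency at one locus
#'
#' @param state A [population_state()].
#' @param locus 1 or 2.
#' @return The frequency of the resistance allele at that locus: the sum of
#'   the two gamete frequencies carrying it.
#' @export
allele_frequency <- function(state, locus) {
  stopifnot(inherits(state, "population_state"))
  if (!(length(locus) == 1L && locus %in% c(1, 2))) {
    stop("`locus` must be 1 or 2", call. = FALSE)
  }
  carriers <- if (locus == 1) HAP_R1 else HAP_R2
  sum(state$gametes[carriers == 1L])
}

#' Phased genotype frequencies under random mating
#'
#' Eggs are formed by random union of gametes, so the frequency of the
#' ordered gamete pair (i, j) is `x[i] * x[j]`. Cis (`R1R2 / S1S2`) and trans
#' (`R1S2 / S1R2`) double heterozygotes are kept distinct in the phased table
#' but belong to the same unphased fitness class.
#'
#' @param state A [population_state()].
#' @return A `genotype_table`: a 4 x 4 matrix of ordered phased genotype
#'   frequencies (rows and columns indexed by haplotype), with attributes
#'   `stage = "pre"` and `generation`.
#' @export
genotype_frequencies <- function(state) {
  stopifnot(inherits(state, "population_state"))
  gt <- outer(state$gametes, state$gametes)
  dimnames(gt) <- list(HAPLOTYPES, HAPLOTYPES)
  structure(gt, class = c("genotype_table", "matrix"),
            stage = "pre", generation = state$generation)
}

#' Reduce a phased genotype table to unphased 3 x 3 classes
#'
#' @param gt A `genotype_table`.
#' @return A 3 x 3 matrix (locus-1 class x locus-2 class, `SS`/`RS`/`RR`)
#'   summing the phased frequencies in each class.
#' @export
genotype_classes <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  out <- matrix(0, 3, 3, dimnames = list(GENO_CLASSES, GENO_CLASSES))
  for (i in 1:4) for (j in 1:4) {
    out[CLASS1[i, j], CLASS2[i, j]] <- out[CLASS1[i, j], CLASS2[i, j]] + gt[i, j]
  }
  out
}

#' Larval viability selection
#'
#' Multiplies each phased genotype frequency by the landscape survival of its
#' unphased class and renormalizes by the mean fitness, which is recorded as
#' an attribute. Selection acts once per generation, at the larval stage.
#'
#' @param gt A pre-selection `genotype_table`.
#' @param fit A [landscape_fitness()].
#' @return A post-selection `genotype_table` with attributes
#'   `stage = "post"` and `mean_fitness`.
#' @section Extinction: if mean fitness is zero (no genotype present can
#'   survive anywhere on the landscape) an error of class
#'   `btrefuge_extinction` is thrown rather than dividing by zero.
#' @export
apply_selection <- function(gt, fit) {
  stopifnot(inherits(gt, "genotype_table"), inherits(fit, "landscape_fitness"))
  w <- matrix(fit$table[cbind(as.vector(CLASS1), as.vector(CLASS2))], 4, 4)
  post <- unclass(gt) * w
  wbar <- sum(post)
  if (wbar <= 0) {
    stop(structure(class = c("btrefuge_extinction", "error", "condition"),
                   list(message = "population extinct: mean fitness is zero",
                        call = sys.call())))
  }
  post <- post / wbar
  structure(post, class = c("genotype_table", "matrix"),
            stage = "post", generation = attr(gt, "generation"),
            mean_fitness = wbar)
}

#' Gamete production with Mendelian segregation and recombination
#'
#' Maps the post-selection adult genotype pool to the gamete pool of the next
#' egg cohort. Single and double homozygotes segregate without ambiguity;
#' double heterozygotes emit their two parental haplotypes with probability
#' `(1 - r) / 2` each and the two recombinants with `r / 2` each. The
#' implementation uses the closed-form haplotype-margin identity: the output
#' gamete frequency equals the adult haplotype frequency, corrected by
#' `r / 2` times the excess of trans over cis double heterozygotes (with
#' opposite sign for the single-heterozygous haplotypes). Random mating
#' conserves allele frequencies exactly, so the returned state's allele
#' frequencies equal those of the adult pool.
#'
#' @param gt A post-selection `genotype_table`.
#' @param r Recombination fraction between the two loci, in `[0, 0.5]`;
#'   `0.5` means unlinked.
#' @return A [population_state()] with the generation counter incremented.
#' @seealso [mating_table_oracle()] for the brute-force enumeration this
#'   closed form is checked against.
#' @export
produce_gametes <- function(gt, r = 0.5) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    stop("`r` must be a single number in [0, 0.5]", call. = FALSE)
  }
  m <- unclass(gt)
  hap <- (rowSums(m) + colSums(m)) / 2          # adult haplotype frequencies
  cis <- m[1, 4] + m[4, 1]                      # R1R2 / S1S2
  trans <- m[2, 3] + m[3, 2]                    # R1S2 / S1R2
  adj <- (r / 2) * (trans - cis)
  gam <- hap + c(adj, -adj, -adj, adj)
  gam <- pmax(gam, 0)
  gam <- gam / sum(gam)
  population_state(gam, attr(gt, "generation") + 1L)
}

#' Brute-force mating-table reference for gamete production
#'
#' Independent re-derivation of [produce_gametes()] by explicit enumeration:
#' every ordered pair of phased parental genotypes is formed with probability
#' equal to the product of their frequencies, each parent's meiotic output is
#' enumerated haplotype by haplotype (parental haplotypes at `(1 - r) / 2`,
#' recombinants built allele-by-allele at `r / 2`), offspring phased
#' genotypes are accumulated over all matings, and the egg gamete pool is
#' read off as the margin of the offspring table. Used as a test oracle; the
#' production path uses a closed form instead.
#'
#' @inheritParams produce_gametes
#' @return A [population_state()]; equal to `produce_gametes(gt, r)` up to
#'   floating-point error.
#' @export
mating_table_oracle <- function(gt, r = 0.5) {
  stopifnot(inherits(gt, "genotype_table"))
  m <- unclass(gt)
  alle <- cbind(HAP_R1, HAP_R2)
  # meiotic output of the phased genotype (i, j): named numeric over haplotypes
  meiosis <- function(i, j) {
    out <- numeric(4)
    out[i] <- out[i] + (1 - r) / 2
    out[j] <- out[j] + (1 - r) / 2
    rec1 <- which(HAP_R1 == alle[i, 1] & HAP_R2 == alle[j, 2])
    rec2 <- which(HAP_R1 == alle[j, 1] & HAP_R2 == alle[i, 2])
    out[rec1] <- out[rec1] + r / 2
    out[rec2] <- out[rec2] + r / 2
    out
  }
  offspring <- matrix(0, 4, 4)
  for (i1 in 1:4) for (j1 in 1:4) {
    f1 <- m[i1, j1]
    if (f1 == 0) next
    g1 <- meiosis(i1, j1)
    for (i2 in 1:4) for (j2 in 1:4) {
      f2 <- m[i2, j2]
      if (f2 == 0) next
      g2 <- meiosis(i2, j2)
      offspring <- offspring + (f1 * f2) * outer(g1, g2)
    }
  }
  population_state(rowSums(offspring), attr(gt, "generation") + 1L)
}

#' Advance the population one generation
#'
#' One full cycle of the recursion: random union of gametes into eggs, larval
#' viability selection on the blended landscape, and gamete production by the
#' surviving adults. In `"le"` mode, linkage equilibrium is re-imposed on the
#' resulting gamete pool (allele frequencies are retained, associations
#' between loci are dropped), mimicking recursions that track only allele
#' frequencies; `"exact"` keeps the full phased-gamete dynamics.
#'
#' @param state A [population_state()].
#' @param fit A [landscape_fitness()].
#' @param r Recombination fraction, in `[0, 0.5]`.
#' @param mode `"exact"` (default) or `"le"`.
#' @return The next [population_state()].
#' @export
step_generation <- function(state, fit, r = 0.5, mode = c("exact", "le")) {
  mode <- match.arg(mode)
  out <- produce_gametes(apply_selection(genotype_frequencies(state), fit), r)
  if (mode == "le") {
    p1 <- allele_frequency(out, 1)
    p2 <- allele_frequency(out, 2)
    out <- population_state(c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2,
                              (1 - p1) * (1 - p2)), out$generation)
  }
  out
}

#' Linkage disequilibrium of a gamete pool
#'
#' `D = f(R1R2) - p1 * p2`, the standard coefficient of gametic
#' disequilibrium.
#'
#' @param state A [population_state()].
#' @return A single number.
#' @export
linkage_disequilibrium <- function(state) {
  stopifnot(inherits(state, "population_state"))
  state$gametes[[1]] - allele_frequency(state, 1) * allele_frequency(state, 2)
}
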