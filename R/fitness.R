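GENO_CLASSES <- c("SS", "RS", "RR")

check_prop <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                 field, deparse(x)), call. = FALSE)
  }
  as.numeric(x)
}

#' Per-toxin genetic parameters
#'
#' Bundles the five quantities that define selection at one resistance locus:
#' survival of homozygous-susceptible larvae on Bt maize producing the toxin
#' (`w_ss`, relative to survival on non-Bt maize), inheritance (dominance) of
#' resistance (`h`), the proportional fitness cost suffered by
#' homozygous-resistant larvae on non-Bt (refuge) maize (`cost`), the fraction
#' of that cost expressed in heterozygotes (`cost_dominance`; 0 makes costs
#' recessive), and the initial resistance-allele frequency (`p0`). Survival of
#' homozygous-resistant larvae on Bt maize is fixed at 1.
#'
#' @param w_ss Survival proportion of SS larvae on Bt maize, in `[0, 1]`.
#' @param h Inheritance (dominance) of resistance, in `[0, 1]`; 0 = recessive,
#'   1 = dominant.
#' @param cost Proportional reduction in survival of RR larvae on non-Bt
#'   maize, in `[0, 1]`.
#' @param cost_dominance Multiplier applied to `cost` for RS larvae on non-Bt
#'   maize, in `[0, 1]`.
#' @param p0 Initial frequency of the resistance allele, in `[0, 1]`.
#' @param label Toxin name, used in printing and result tables.
#' @return An object of class `locus_params`.
#' @examples
#' locus_params(w_ss = 0.104, h = 0.375, cost = 0.041, p0 = 0.001,
#'              label = "Cry3Bb1")
#' @export
locus_params <- function(w_ss, h, cost = 0, cost_dominance = 0, p0 = 0,
                         label = "") {
  out <- list(
    w_ss = check_prop(w_ss, "w_ss"),
    h = check_prop(h, "h"),
    cost = check_prop(cost, "cost"),
    cost_dominance = check_prop(cost_dominance, "cost_dominance"),
    p0 = check_prop(p0, "p0"),
    label = as.character(label)
  )
  structure(out, class = "locus_params")
}

#' @export
print.locus_params <- function(x, ...) {
  cat(sprintf("Locus parameters%s\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  cat(sprintf("  W_SS on Bt: %.4g   h: %.4g   cost: %.4g (dominance %.4g)   p0: %.4g\n",
              x$w_ss, x$h, x$cost, x$cost_dominance, x$p0))
  invisible(x)
}

#' A locus whose toxin is absent
#'
#' Convenience constructor for a degenerate locus with survival 1 in both
#' habitats and `p0 = 0`. Single-toxin cultivars are modelled as a pyramid
#' whose second locus is neutral, so one engine serves both cases.
#'
#' @param label Optional label.
#' @return A `locus_params` object under no selection and no cost.
#' @export
neutral_locus <- function(label = "neutral") {
  locus_params(w_ss = 1, h = 0, cost = 0, cost_dominance = 0, p0 = 0,
               label = label)
}

#' Genotype survival table for one locus
#'
#' Builds per-genotype survival in each habitat from `locus_params`. On Bt
#' maize, heterozygote survival is interpolated by the dominance relation
#' `h = (W_RS - W_SS) / (W_RR - W_SS)` with `W_RR = 1`, so
#' `W_RS = W_SS + h (1 - W_SS)`. On refuge (non-Bt) maize all genotypes
#' survive fully except for fitness costs of resistance:
#' `refuge[RR] = 1 - cost`, `refuge[RS] = 1 - cost_dominance * cost`.
#' Costs never affect survival on Bt maize. Derived values are kept at full
#' floating precision; no rounding is applied.
#'
#' @param params A [locus_params()] object.
#' @return An object of class `locus_fitness`: a list with numeric vectors
#'   `bt` and `refuge`, each named `SS`, `RS`, `RR`, plus the input `params`.
#' @examples
#' # baseline Cry3Bb1: W_RS = 0.104 + 0.375 * (1 - 0.104) = 0.440
#' locus_fitness(locus_params(w_ss = 0.104, h = 0.375))$bt[["RS"]]
#' @export
locus_fitness <- function(params) {
  stopifnot(inherits(params, "locus_params"))
  bt <- c(SS = params$w_ss,
          RS = params$w_ss + params$h * (1 - params$w_ss),
          RR = 1)
  refuge <- c(SS = 1,
              RS = 1 - params$cost_dominance * params$cost,
              RR = 1 - params$cost)
  structure(list(bt = bt, refuge = refuge, params = params),
            class = "locus_fitness")
}

#' @export
print.locus_fitness <- function(x, ...) {
  cat("Genotype survival by habitat\n")
  m <- rbind(bt = x$bt, refuge = x$refuge)
  print(round(m, 6))
  invisible(x)
}

#' Two-locus survival table for a Bt pyramid
#'
#' Combines two single-locus survival tables into a 3 x 3 genotype-class
#' table per habitat, assuming mortality imposed by the two toxins acts
#' multiplicatively: each entry is the product of the corresponding per-locus
#' survivals. The same multiplicative rule is applied on refuge plants, so
#' fitness costs combine as the product of the per-locus cost factors. The
#' exact product is retained at full precision.
#'
#' @param lf1,lf2 [locus_fitness()] objects (locus 1 on rows, locus 2 on
#'   columns of the resulting tables).
#' @return An object of class `pyramid_fitness`: list with 3 x 3 matrices
#'   `bt` and `refuge` (dimnames `SS`/`RS`/`RR`) and the per-locus inputs.
#' @examples
#' cry <- locus_fitness(locus_params(w_ss = 0.104, h = 0.375))
#' gpp <- locus_fitness(locus_params(w_ss = 0.118, h = 0.36))
#' pyramid_fitness(cry, gpp)$bt["SS", "SS"]  # 0.104 * 0.118 = 0.012272
#' @export
pyramid_fitness <- function(lf1, lf2) {
  stopifnot(inherits(lf1, "locus_fitness"), inherits(lf2, "locus_fitness"))
  bt <- outer(lf1$bt[GENO_CLASSES], lf2$bt[GENO_CLASSES])
  refuge <- outer(lf1$refuge[GENO_CLASSES], lf2$refuge[GENO_CLASSES])
  dimnames(bt) <- dimnames(refuge) <- list(GENO_CLASSES, GENO_CLASSES)
  structure(list(bt = bt, refuge = refuge, locus1 = lf1, locus2 = lf2),
            class = "pyramid_fitness")
}

#' @export
print.pyramid_fitness <- function(x, ...) {
  cat("Two-locus survival, Bt habitat (locus 1 rows x locus 2 columns):\n")
  print(round(x$bt, 6))
  cat("Refuge habitat:\n")
  print(round(x$refuge, 6))
  invisible(x)
}

as_pyramid_fitness <- function(fit) {
  if (inherits(fit, "pyramid_fitness")) return(fit)
  if (inherits(fit, "locus_fitness")) {
    return(pyramid_fitness(fit, locus_fitness(neutral_locus())))
  }
  stop("`fit` must be a locus_fitness or pyramid_fitness object", call. = FALSE)
}

#' Landscape-level expected survival
#'
#' Blends the Bt-field and refuge survival tables into the expected survival
#' of each genotype class over a landscape in which a proportion
#' `refuge_prop` of plants are non-Bt. Because larvae complete development on
#' a single plant and space is implicit, the landscape fitness of class `g`
#' is the plant-frequency average
#' `refuge_prop * refuge(g) + (1 - refuge_prop) * bt(g)`.
#'
#' @param fit A [pyramid_fitness()] object (a [locus_fitness()] is promoted
#'   via a neutral second locus).
#' @param refuge_prop Proportion of plants that are non-Bt, in `[0, 1]`.
#' @return An object of class `landscape_fitness`: list with the blended
#'   3 x 3 `table` and `refuge_prop`.
#' @export
landscape_fitness <- function(fit, refuge_prop) {
  refuge_prop <- check_prop(refuge_prop, "refuge_prop")
  fit <- as_pyramid_fitness(fit)
  tab <- refuge_prop * fit$refuge + (1 - refuge_prop) * fit$bt
  structure(list(table = tab, refuge_prop = refuge_prop),
            class = "landscape_fitness")
}

#' @export
print.landscape_fitness <- function(x, ...) {
  cat(sprintf("Landscape survival at refuge proportion %.2f:\n", x$refuge_prop))
  print(round(x$table, 6))
  invisible(x)
}
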