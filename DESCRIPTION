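Package: btrefuge
Title: Deterministic Two-Locus Model of Bt Resistance Evolution Under the
    Refuge Strategy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of resistance by western corn rootworm
    (Diabrotica virgifera virgifera) to transgenic maize producing one or two
    Bacillus thuringiensis (Bt) toxins, under the refuge strategy. The model is
    a deterministic two-locus, two-allele diploid selection recursion: larvae
    undergo viability selection on a landscape blended from Bt and non-Bt
    (refuge) plants, survivors mate at random, and gamete frequencies are
    advanced one generation per step, with Mendelian segregation and optional
    recombination between the two resistance loci. Genotype fitnesses are built
    from field survival of susceptibles on Bt maize, dominance (inheritance) of
    resistance, and fitness costs expressed on refuge plants. The package
    encodes the published parameter sets for Cry3Bb1 and Gpp34/Tpp35Ab1
    resistance, sweeps refuge proportion to compute time-to-resistance curves,
    locates the minimum refuge delaying resistance past a generation cap, and
    ships a seeded synthetic-parameter generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
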