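Package: funnelcross
Title: Haplotype Inference and QTL Power Analysis for Multiparent Funnel Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and characterizing large multiparent
    "funnel cross" mapping populations in budding yeast. Includes a
    synthetic funnel-cross generator (eight founders, three rounds of
    pooled mating, Poisson crossovers, low-coverage allele-count
    sampling), founder-of-origin haplotype inference from sparse allele
    counts via an eight-state hidden Markov model with cross-structure
    transition probabilities (monosomic and disomic chromosomes),
    chromosome copy-number calling from relative depth, scaffolding
    marker selection, maximum-likelihood fitting of the physical-to-
    genetic distance conversion, detection of shared intermediate-cross
    ancestry by haplotype discordance, LOD-score QTL scans with
    empirical family-wise thresholds and power/resolution simulation,
    and single-marker and pairwise selection scans with overdispersion
    calibration and Holm multiple-testing control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
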