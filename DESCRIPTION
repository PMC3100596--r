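Package: xylink
Title: Sex-Specific Linkage, Y-Haplotype Inference, and X-Y Recombination
    Scenario Discrimination from Sibship Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying homomorphic sex chromosomes with microsatellite
    sibships and gametolog sequences. Implements sex-specific two-point
    recombination-fraction estimation by maximum likelihood over unknown
    parental phase (with null-allele aware transmission models), LOD scores,
    Morton's M heterogeneity test with chi-squared and permutation references,
    exhaustive marker ordering with Haldane map construction, allele-frequency
    sex-difference G tests, Y-haplotype reconstruction from sibships and
    population samples, two permutation tests of X-Y similarity (conspecific
    allele-size differences and cross-amplification concordance, the latter
    with an exact combinatorial reference), and a structured-coalescent
    simulator of X/Y gene genealogies with Jukes-Cantor sequence evolution,
    neighbor-joining estimation, bootstrap support, and species-versus-
    gametolog clustering classification. A pedigree simulator with full ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
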