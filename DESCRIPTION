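Package: genassocmeta
Title: Meta-Analysis of Genetic Association Studies from Genotype Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooling case-control genetic association studies from
    per-study genotype (or allele) counts. Builds 2x2 contrasts under the five
    standard genetic models (allele, dominant, recessive, heterozygous,
    homozygous), estimates per-study log odds ratios with Woolf variances,
    pools them with fixed-effect and DerSimonian-Laird random-effects models,
    quantifies heterogeneity (Cochran Q, I-squared, tau-squared), and provides
    subgroup analysis, univariate random-effects meta-regression, cumulative
    and leave-one-out meta-analysis, Hardy-Weinberg equilibrium checks, funnel
    plot coordinates, and Egger and Begg small-study bias tests. Includes a
    synthetic study-collection generator with known truth for calibration and
    power studies, and a worked cohort of published restenosis studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
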