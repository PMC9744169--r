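Package: grasshybrid
Title: Marker-Assisted Hybrid Identification and Trait Evaluation for
    Cross-Pollinated Grass Breeding
Version: 0.1.0
Authors@R:
    person("Forage Breeding", "Toolkit Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for marker-assisted hybrid identification and quantitative
    trait evaluation in cross-pollinated grass breeding programs that rely on
    dominant (presence/absence) SSR band matrices. Detects parental
    characteristic bands, classifies putative F1 and BC1 offspring as true
    hybrids or maternal (self) types and computes population purity; computes
    dominant-marker diversity statistics (observed and effective allele
    numbers, Nei gene diversity, Shannon index, percentage of polymorphic
    bands) and genetic similarity matrices (simple matching, Dice, Jaccard);
    evaluates quantitative traits (normality with skewness and kurtosis,
    coefficients of variation, Pearson correlation with significance tiers,
    mid-parent heterosis and heterobeltiosis, self-fertility rates); and ranks
    plants for backcross-parent selection with a contribution-weighted PCA
    synthesis score. A synthetic-data generator simulates diploid parents,
    Mendelian F1/BC1 offspring with maternal-self contamination, and
    correlated trait tables so the whole pipeline is testable without gel or
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
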