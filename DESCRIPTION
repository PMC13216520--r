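Package: hallmarktiming
Title: Timing of Genome Instability from Hallmark VAF Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers whether tumors acquired genome instability early or late
    in their evolution from the variant allele frequencies (VAF) of somatic
    mutations in genes of the ten canonical cancer hallmarks. Provides
    per-patient hallmark VAF profiling and ranking, PCA plus elbow-selected
    k-means clustering into early (EGI) and late (LGI) genome-instability
    groups, SBS96 trinucleotide-context classification with reference-catalog
    signature refitting and dominant-signature calls, and the downstream
    cluster-association statistics: contingency tests with false-discovery
    control, bootstrap Anderson-Darling comparisons with Cohen's d effect
    sizes, per-feature logistic odds ratios, Mann-Whitney VAF comparisons,
    and substitution-frequency versus VAF correlation controls. A synthetic
    cohort generator with known group structure supplies ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
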