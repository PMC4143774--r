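Package: linkassoc
Title: Combined Linkage and Family-Based Association Evidence for Gene Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines multipoint linkage evidence (LOD scores) with gene-based
    family association p-values into a single combined p-value per gene.
    LOD scores are converted to one-sided p-values under the boundary null
    (a 0.5:0.5 mixture of a 1-df chi-square and a point mass at zero), genes
    are mapped from physical to genetic coordinates by linear interpolation
    of a genetic map, each gene is assigned the mean LOD of its mapped region,
    and linkage and association p-values are combined by the unweighted
    Liptak (Stouffer) method, optionally with a permutation-estimated
    correlation correction. Includes a long-term mean blood-pressure trait
    builder, synthetic-data generators, type-I-error and top-K detection-power
    experiments, TSV/BED readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
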