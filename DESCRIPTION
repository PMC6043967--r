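Package: admixbreed
Title: Genomic Characterization of Recently Admixed Breeds with Pedigree-Recorded Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize the genome of a recently founded hybrid breed
    descending from two divergent parental populations (a wild and a domestic
    one), in the style of SNP-array studies of wolf x dog breeds. Provides a
    forward-in-time, pedigree-recorded simulator of the breed history with
    scheduled wild introgressions and exact ancestry-tract ground truth; PLINK
    text PED/MAP input and output; the standard filtering cascade (call rate,
    sex chromosomes, sliding-window LD pruning, complete-case sites); core
    population-genetic statistics (observed heterozygosity, method-of-moments
    inbreeding F, Weir-Cockerham F_ST, PCA, genotypic LD r-squared, PLINK-style
    IBD pi-hat); pedigree kinship, inbreeding and relatedness coefficients with
    expected founder-ancestry fractions; runs of homozygosity and F_ROH with
    shared-ROH regions; PCA-based local-ancestry deconvolution of phased
    haplotypes in fixed SNP blocks with optional HMM smoothing; admixture and
    demography dating (LD-based effective-size trajectories, weighted-LD decay
    dating, ancestry-switch dating); and ancestry-informative-marker outlier
    panels with interval expansion and consolidation. Results are returned as
    tibbles with broom-style tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
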