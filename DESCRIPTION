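Package: pharmacotype
Title: Pharmacogenomic Drug-Response Subtyping of Tumor Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for deriving tumor molecular subtypes from
    cell-line pharmacogenomics and projecting them across patient cohorts.
    Cell lines are trichotomized per drug into sensitive, partial-response and
    resistant groups (mean +/- 0.5 SD of a sensitivity metric); genes
    differentially expressed between sensitive and resistant lines
    consistently in two drug-response databases define drug response-featured
    genes. Patient cohorts are clustered on those genes by consensus
    non-negative matrix factorization (Brunet Kullback-Leibler updates,
    cophenetic rank selection, silhouette pruning), co-expression modules are
    detected from topological overlap, and per-subtype signature genes (module
    genes intersected with up-regulated genes) feed nearest-template
    prediction with permutation FDR and a submap-style cross-cohort
    correspondence test. Downstream characterization includes single-sample
    gene-set enrichment (ssGSEA), signature z-scores, tumor mutation burden,
    mutational-signature exposures by non-negative least squares over 96
    trinucleotide contexts, fraction of genome altered/gained/lost, arm and
    focal copy-number burden, ridge-regression drug-response prediction
    trained on cell lines, and per-subtype benchmarking of coefficient-based
    prognostic gene signatures by Harrell's C-index. A synthetic-data module
    generates cell-line panels, patient cohorts, mutation (MAF) and
    copy-number segment (SEG) tables with known ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
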