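Package: poolconcord
Title: Concordance of Individual and Pooled Sequencing Allele Frequency
    Estimates
Version: 0.1.0
Authors@R:
    person("INIA", "Genomics Tools", email = "tools@example.org",
           role = c("aut", "cre"))
Description: Evaluates how well pooled sequencing (pool-seq) of forage
    grass accessions reproduces allele frequencies obtained from
    genotyping individual plants (ind-seq).  Provides a synthetic-data
    generator for nested pool designs with tissue replicates and depth
    classes, readers and writers for DArT-style SNP score and count
    reports, per-accession allele-frequency estimation with missing-data
    and minor-allele-frequency filters, shared-SNP Representativity and
    Lin's concordance correlation coefficient over a factorial design
    grid, within-accession diversity statistics (observed and expected
    heterozygosity, inbreeding coefficient, rarefaction allelic richness,
    effective alleles, delta-H_E), between-accession structure (Nei and
    Rogers distances, Weir-Cockerham F_ST, AMOVA with permutation test,
    classical MDS, Mantel test), and the factorial comparison statistics
    (one- and two-way ANOVA, Tukey HSD, Levene/Brown-Forsythe).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
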