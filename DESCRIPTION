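Package: crosskin
Title: Kinship Analysis and Pedigree Reconstruction for Two-Breed Crossbred Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing pedigrees in two-breed crossbreeding
    programs genotyped by reduced-representation sequencing. From a
    multi-sample genotype VCF and lists of founder sires and dams, the
    package applies hard site filters, selects diagnostic SNP panels,
    classifies offspring into F1 and F2 subclasses from heterozygosity and
    parental-allele ratios, estimates pairwise relatedness
    (method-of-moments IBD, centered-IBS kinship, p-distance
    neighbor-joining trees), and assigns parentage by three independent
    engines (likelihood ratios with simulated critical values, Mendelian
    transmission probabilities, and exclusion counting) with a consensus
    step. A simulation module generates crossbred herds with
    depth-dependent genotyping error so every stage can be validated
    against known pedigree truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    ape,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
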