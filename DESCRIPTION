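Package: trioscan
Title: Trio-Based Variant Prioritization for Recessive and De Novo Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variant prioritization from trio (and half-sib trio) whole-genome
    sequencing for rare monogenic and digenic disorders in livestock and other
    diploid species. Implements Mendelian genotype-pattern filtering under
    competing inheritance scenarios (autosomal recessive with obligate-carrier
    parents; paternal germline de novo), control-cohort exclusion and
    functional-impact filtering as an auditable cascade; detection of runs of
    homozygosity with cross-case allelic matching to map shared
    identity-by-descent regions; a binned read-depth screen for aneuploidies
    and large structural variants; population segregation analysis (genotype
    counting, allele-frequency estimation with Wilson intervals, carrier
    prevalence by group, digenic co-segregation verdicts); and a seeded
    synthetic pedigree-cohort generator that emits VCF, pedigree, cohort
    catalogs, depth profiles and a truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
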