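write_test_vcf <- function(lines, samples = c("case1", "dam1", "sire")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>", "##contig=<ID=2>",
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

trio_roles <- c(case1 = "CASE", dam1 = "DAM", sire = "SIRE")

test_that("GT recoding matches the hand-enumerated dosage table", {
  # biallelic view on alt 1 of a 2-alt site: alleles other than {0,1} are
  # foreign and make the call missing
  expected_k1 <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                   "0/2" = NA, "2/0" = NA, "1/2" = NA, "2/1" = NA,
                   "2/2" = NA, "./." = NA, "./1" = NA, "1/." = NA,
                   "0|1" = 1L, "1|1" = 2L, "." = NA)
  expect_equal(recode_gt(names(expected_k1), 1L), unname(expected_k1))
  expected_k2 <- c("0/0" = 0L, "0/2" = 1L, "2/0" = 1L, "2/2" = 2L,
                   "0/1" = NA, "1/2" = NA, "1/1" = NA, "./." = NA)
  expect_equal(recode_gt(names(expected_k2), 2L), unname(expected_k2))
})

test_that("read_vcf parses genotypes, missing calls and sample roles", {
  path <- write_test_vcf("1\t100\t.\tA\tT\t.\t.\t.\tGT\t1/1\t0/1\t0/1")
  vs <- read_vcf(path, trio_roles)
  expect_equal(n_variants(vs), 1L)
  expect_equal(vs$geno[1, ], c(case1 = 2L, dam1 = 1L, sire = 1L))

  path2 <- write_test_vcf("1\t100\t.\tA\tT\t.\t.\t.\tGT\t./.\t0/0\t0/1")
  vs2 <- read_vcf(path2, trio_roles)
  expect_true(is.na(vs2$geno[1, "case1"]))

  expect_error(read_vcf(path, c(trio_roles, ghost = "DAM")),
               "absent from VCF header")
})

test_that("multi-allelic sites split into per-alt records with recoding", {
  path <- write_test_vcf(c(
    "1\t100\t.\tA\tT,G\t.\t.\t.\tGT\t1/2\t0/1\t0/2",
    "2\t50\t.\tC\tA\t.\t.\t.\tGT\t0/0\t0/1\t1/1"))
  vs <- read_vcf(path, trio_roles)
  expect_equal(n_variants(vs), 3L)
  expect_equal(variant_keys(vs), c("1:100:A:T", "1:100:A:G", "2:50:C:A"))
  # case1 1/2 carries a foreign allele in both biallelic views
  expect_true(all(is.na(vs$geno[1:2, "case1"])))
  expect_equal(vs$geno[1, "dam1"], c(dam1 = 1L))
  expect_true(is.na(vs$geno[1, "sire"]))   # 0/2 foreign on the A>T view
  expect_equal(vs$geno[2, "sire"], c(sire = 1L))
})

test_that("splitting conserves alt dosage across the per-alt views", {
  # a genotype whose alleles fit a single biallelic view keeps its full alt
  # dosage on that view; mixed-alt genotypes become missing in every view
  set.seed(42)
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2", "./.")
  for (rep in 1:20) {
    g3 <- sample(gts, 3, replace = TRUE)
    path <- write_test_vcf(sprintf("1\t100\t.\tA\tT,G\t.\t.\t.\tGT\t%s",
                                   paste(g3, collapse = "\t")))
    vs <- read_vcf(path, trio_roles)
    for (s in colnames(vs$geno)) {
      gt_in <- g3[match(s, names(trio_roles))]
      alleles <- strsplit(gt_in, "[/|]")[[1]]
      alt_used <- unique(alleles[!alleles %in% c("0", ".")])
      split_dosage <- vs$geno[, s]
      if (gt_in == "./.") {
        expect_true(all(is.na(split_dosage)))
      } else if (length(alt_used) <= 1) {
        expect_equal(sum(split_dosage, na.rm = TRUE),
                     sum(!alleles %in% c("0", ".")))
      } else {
        # alleles from two different alts: foreign in both views
        expect_true(all(is.na(split_dosage)))
      }
    }
  }
})

test_that("ANN parsing keeps the most severe impact and flags bad tokens", {
  expect_equal(parse_snpeff_ann("T|missense_variant|MODERATE|TGDS|x", "T"),
               list(gene = "TGDS", impact = "MODERATE"))
  two <- "T|intron|MODIFIER|GENEA|x,T|stop_gained|HIGH|GENEA|x"
  expect_equal(parse_snpeff_ann(two, "T")$impact, "HIGH")
  expect_warning(res <- parse_snpeff_ann("G|intron|MODIFIER|GENEA|x", "T"),
                 "no ANN entry matching")
  expect_true(is.na(res$impact))
  expect_error(parse_snpeff_ann("T|x|SEVERE|GENEA|x", "T"), "SEVERE")
})

test_that("sidecar annotation is case-insensitive and validated", {
  vs <- random_trio_vs(4, seed = 7)
  vs$variants$impact <- NA_character_
  for (tok in c("high", "MODERATE", "Low", "modifier")) {
    sidecar <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "T",
                          gene = "G1", impact = tok)
    out <- annotate_variants(vs, sidecar)
    expect_equal(unique(out$variants$impact), toupper(tok))
  }
  sidecar_bad <- data.frame(chrom = "1", pos = 1, ref = "A", alt = "T",
                            gene = "G1", impact = "bogus")
  expect_error(annotate_variants(vs, sidecar_bad), "BOGUS")
})

test_that("variant table write/read round trip is lossless", {
  for (seed in 1:5) {
    vs <- random_trio_vs(40, seed = seed, p_missing = 0.2)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_variant_table(vs, path)
    back <- read_variant_table(path)
    expect_equal(back$variants, vs$variants)
    expect_equal(back$geno, vs$geno)
    expect_equal(as.data.frame(back$samples), as.data.frame(vs$samples))
  }
  # empty set: header-only body
  empty <- subset_variants(random_trio_vs(3), integer(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(empty, path)
  expect_equal(n_variants(read_variant_table(path)), 0L)
})

test_that("duplicate variant keys are rejected and sorting is total", {
  vs <- random_trio_vs(5)
  dup <- vs$variants[c(1, 1, 2), ]
  expect_error(variant_set(dup, vs$geno[c(1, 1, 2), ], vs$samples),
               "duplicate variant key")
  shuffled <- subset_variants(vs, c(3, 1, 5, 2, 4))
  expect_equal(variant_keys(sort_variants(shuffled)), variant_keys(vs))
})
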