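test_that("scenario specs encode the two inheritance hypotheses", {
  rec <- scenario_spec("RECESSIVE_HOMOZYGOUS")
  expect_equal(rec$pattern, list(CASE = 2L, DAM = 1L, SIRE = 1L))
  expect_equal(rec$control_policy, "EXCLUDE_IF_HOM_ALT")
  dn <- scenario_spec("PATERNAL_GERMLINE_DENOVO")
  expect_equal(dn$pattern, list(CASE = 1L, SIRE = 1L, DAM = 0L))
  expect_equal(dn$control_policy, "EXCLUDE_IF_ANY_ALT")
})

test_that("pattern filter agrees with a per-record brute-force predicate", {
  vs <- random_trio_vs(1000, seed = 11, p_missing = 0.15)
  for (sc in c("RECESSIVE_HOMOZYGOUS", "PATERNAL_GERMLINE_DENOVO")) {
    got <- variant_keys(genotype_pattern_filter(vs, sc))
    want <- variant_keys(vs)[vapply(seq_len(n_variants(vs)), function(i)
      brute_force_pattern(as.list(vs$geno[i, ]), vs$samples, sc), logical(1))]
    expect_equal(got, want)
  }
})

test_that("obligate-carrier trio configuration survives, violations do not", {
  samples <- sample_set(c("case1", "case2", "dam1", "dam2", "sire"),
                        c("CASE", "CASE", "DAM", "DAM", "SIRE"))
  variants <- data.frame(chrom = "12", pos = c(69092831L, 1000L),
                         ref = "A", alt = "T")
  geno <- rbind(c(2L, 2L, 1L, 1L, 1L),   # cases hom, parents het
                c(2L, 1L, 1L, 1L, 1L))   # one case het: violated
  vs <- variant_set(variants, geno, samples)
  out <- genotype_pattern_filter(vs, "RECESSIVE_HOMOZYGOUS")
  expect_equal(variant_keys(out), "12:69092831:A:T")
  # missing genotype in a pattern sample is strict
  geno[1, 3] <- NA
  vs2 <- variant_set(variants, geno, samples)
  expect_equal(n_variants(genotype_pattern_filter(vs2, "RECESSIVE_HOMOZYGOUS")), 0L)
})

test_that("cohort exclusion policies follow the carrier-tolerance semantics", {
  vs <- random_trio_vs(3, seed = 2)
  cat_counts <- cohort_catalog(data.frame(
    chrom = "1", pos = 1:2, ref = "A", alt = "T",
    n_hom_ref = c(940L, 941L), n_het = c(2L, 1L), n_hom_alt = c(0L, 0L)))
  hom_pol <- cohort_exclusion_filter(vs, cat_counts, "EXCLUDE_IF_HOM_ALT")
  expect_equal(n_variants(hom_pol), 3L)  # carriers tolerated; pos 3 uncataloged
  any_pol <- cohort_exclusion_filter(vs, cat_counts, "EXCLUDE_IF_ANY_ALT")
  expect_equal(variant_keys(any_pol), "1:3:A:T")  # only the private record
  cat_hom <- cohort_catalog(data.frame(
    chrom = "1", pos = 1L, ref = "A", alt = "T",
    n_hom_ref = 940L, n_het = 1L, n_hom_alt = 1L))
  expect_equal(n_variants(cohort_exclusion_filter(vs, cat_hom,
                                                  "EXCLUDE_IF_HOM_ALT")), 2L)
})

test_that("impact filter keeps exactly the allowed classes", {
  samples <- sample_set("c1", "CASE")
  variants <- data.frame(chrom = "1", pos = 1:5, ref = "A", alt = "T",
                         impact = c("HIGH", "MODERATE", "LOW", "MODIFIER", NA))
  vs <- variant_set(variants, matrix(0L, 5, 1), samples)
  out <- impact_filter(vs)
  expect_equal(out$variants$impact, c("HIGH", "MODERATE"))
  expect_equal(attr(out, "n_unannotated"), 1L)
  expect_equal(impact_filter(vs, "HIGH")$variants$impact, "HIGH")
  expect_error(impact_filter(vs, "SEVERE"), "SEVERE")
})

test_that("cascade counts shrink monotonically and report every step", {
  sim <- simulate_cohort(small_config(seed = 5))
  rep <- run_cascade(sim$vs, sim$local_catalog, sim$global_catalog,
                     "RECESSIVE_HOMOZYGOUS")
  expect_equal(rep$steps$step,
               c("genotype_pattern", "impact", "local_cohort", "global_cohort"))
  expect_true(all(rep$steps$variants_out <= rep$steps$variants_in))
  expect_equal(rep$steps$variants_in[-1], rep$steps$variants_out[-4])
  expect_true(all(variant_keys(rep$candidates) %in% variant_keys(sim$vs)))
  expect_equal(unique(rep$candidates$variants$manual_review), "not_reviewed")
})

test_that("filters commute: permuting impact/local/global leaves the final set", {
  sim <- simulate_cohort(small_config(seed = 6))
  vs <- sim$vs
  sc <- scenario_spec("RECESSIVE_HOMOZYGOUS")
  patterned <- genotype_pattern_filter(vs, sc)
  f_imp <- function(v) impact_filter(v)
  f_loc <- function(v) cohort_exclusion_filter(v, sim$local_catalog,
                                               sc$control_policy)
  f_glo <- function(v) cohort_exclusion_filter(v, sim$global_catalog,
                                               sc$control_policy)
  orders <- list(c(1, 2, 3), c(3, 2, 1), c(2, 1, 3))
  finals <- lapply(orders, function(o) {
    v <- patterned
    for (f in list(f_imp, f_loc, f_glo)[o]) v <- f(v)
    sort(variant_keys(v))
  })
  expect_equal(finals[[2]], finals[[1]])
  expect_equal(finals[[3]], finals[[1]])
})

test_that("no fully observed record satisfies both scenarios", {
  vs <- random_trio_vs(2000, seed = 13, p_missing = 0)
  rec <- variant_keys(genotype_pattern_filter(vs, "RECESSIVE_HOMOZYGOUS"))
  dn <- variant_keys(genotype_pattern_filter(vs, "PATERNAL_GERMLINE_DENOVO"))
  expect_length(intersect(rec, dn), 0L)
})

test_that("cascade on an empty record set reports zero counts", {
  vs <- subset_variants(random_trio_vs(3), integer(0))
  rep <- run_cascade(vs, NULL, NULL, "RECESSIVE_HOMOZYGOUS")
  expect_true(all(rep$steps$variants_in == 0L))
  expect_true(all(rep$steps$variants_out == 0L))
  expect_equal(n_variants(rep$candidates), 0L)
})

test_that("candidate region flags match brute-force interval membership", {
  set.seed(17)
  cand <- data.frame(chrom = sample(c("1", "2", "3"), 100, replace = TRUE),
                     pos = sample.int(1e6, 100))
  regions <- data.frame(chrom = sample(c("1", "2"), 30, replace = TRUE),
                        start = sample.int(9e5, 30))
  regions$end <- regions$start + sample.int(2e5, 30)
  regions$region_id <- sprintf("R%02d", seq_len(30))
  out <- candidate_region_check(cand, regions)
  for (i in seq_len(nrow(cand))) {
    inside <- regions$region_id[regions$chrom == cand$chrom[i] &
                                  regions$start <= cand$pos[i] &
                                  cand$pos[i] <= regions$end]
    if (length(inside)) {
      expect_true(out$ibd_region[i] %in% inside)
    } else {
      expect_true(is.na(out$ibd_region[i]))
    }
  }
  # candidate on a chromosome with no regions
  none <- candidate_region_check(data.frame(chrom = "9", pos = 5L), regions)
  expect_true(is.na(none$ibd_region))
})
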