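test_that("basic run detection: all-het is empty, one clean run is exact", {
  params <- roh_params()
  pos <- seq(1, by = 10000, length.out = 200)  # 2.0 Mb span
  expect_equal(nrow(detect_roh(pos, rep(1L, 200), params)), 0L)
  seg <- detect_roh(pos, rep(2L, 200), params)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 1)
  expect_equal(seg$end, pos[200])
  expect_equal(seg$length_bp, pos[200])
  expect_equal(seg$n_snps, 200L)
  expect_equal(seg$n_het, 0L)
  expect_error(detect_roh(c(5, 3), c(0L, 0L)), "strictly increasing")
})

test_that("scanner equals the exhaustive maximal-run enumerator", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(50:200, 1)
    pos <- cumsum(sample.int(40000, n, replace = TRUE))
    geno <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                   prob = c(0.45, 0.25, 0.2, 0.1))
    params <- roh_params(
      min_length_kb = sample(c(20, 50, 100), 1),
      min_snps = sample(c(3L, 5L, 10L), 1),
      max_het_in_run = sample(0:2, 1),
      max_missing_in_run = sample(0:3, 1),
      max_gap_kb = sample(c(15, 25, 50), 1))
    got <- detect_roh(pos, geno, params)
    want <- brute_force_roh(pos, geno, params)
    expect_equal(got[, c("start", "end", "n_snps")],
                 want, ignore_attr = TRUE)
  }
})

test_that("detected runs satisfy their own invariants", {
  set.seed(7)
  params <- roh_params(min_length_kb = 50, min_snps = 5, max_het_in_run = 1,
                       max_missing_in_run = 2, max_gap_kb = 50)
  for (rep in 1:10) {
    n <- 300
    pos <- cumsum(sample.int(20000, n, replace = TRUE))
    geno <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                   prob = c(0.5, 0.15, 0.25, 0.1))
    seg <- detect_roh(pos, geno, params)
    if (!nrow(seg)) next
    expect_true(all(seg$length_bp >= params$min_length_kb * 1000))
    expect_true(all(seg$n_snps >= params$min_snps))
    expect_true(all(seg$n_het <= params$max_het_in_run))
    expect_true(all(seg$n_missing <= params$max_missing_in_run))
    # endpoints are homozygous calls
    for (r in seq_len(nrow(seg))) {
      g_start <- geno[match(seg$start[r], pos)]
      g_end <- geno[match(seg$end[r], pos)]
      expect_true(g_start %in% c(0L, 2L) && g_end %in% c(0L, 2L))
    }
  }
})

test_that("runs are maximal: flanking heterozygous markers change nothing", {
  params <- roh_params(min_length_kb = 100, min_snps = 10, max_gap_kb = 50)
  pos <- seq(1, by = 20000, length.out = 50)
  geno <- rep(0L, 50)
  base <- detect_roh(pos, geno, params)
  pos_ext <- c(pos[1] - 40000, pos[1] - 20000, pos, max(pos) + 20000)
  geno_ext <- c(1L, 1L, geno, 1L)
  ext <- detect_roh(pos_ext, geno_ext, params)
  # the core run is unchanged (modulo the one tolerated flanking het
  # extending the admissible window but trimming back to hom endpoints)
  expect_true(any(ext$start == base$start & ext$end == base$end))
})

test_that("allelic matching certifies identical runs and rejects mismatches", {
  params <- roh_params()
  pos <- seq(1, by = 15000, length.out = 100)
  seg <- data.frame(chrom = "1", start = 1, end = max(pos))
  g_a <- rep(2L, 100)
  m <- match_segments(seg, seg, pos, g_a, g_a, params)
  expect_equal(m$match_fraction, 1.0)
  expect_equal(m$n_joint, 100L)
  g_b <- g_a; g_b[1:4] <- 0L
  m2 <- match_segments(seg, seg, pos, g_a, g_b, params)
  expect_equal(m2$match_fraction, 0.96)
  g_c <- g_a; g_c[1:10] <- 0L  # 0.90 < 0.95
  expect_null(match_segments(seg, seg, pos, g_a, g_c, params))
  # disjoint segments
  seg1 <- data.frame(chrom = "1", start = 1, end = 1000)
  seg2 <- data.frame(chrom = "1", start = 5000, end = 9000)
  expect_null(match_segments(seg1, seg2, pos, g_a, g_a, params))
  # too few jointly non-missing markers certify nothing
  g_d <- g_a; g_d[1:90] <- NA
  expect_null(match_segments(seg, seg, pos, g_a, g_d, params))
})

test_that("shared regions recover the planted IBD haplotype with carrier parents", {
  sim <- simulate_cohort(small_config(seed = 21))
  regions <- shared_regions(sim$vs)
  inj <- sim$truth$injections
  rec <- inj[inj$type == "RECESSIVE_IBD", ]
  for (i in seq_len(nrow(rec))) {
    hit <- regions[regions$chrom == rec$chrom[i] &
                     regions$start <= rec$pos[i] &
                     rec$pos[i] <= regions$end, , drop = FALSE]
    expect_equal(nrow(hit), 1L)
    expect_true(all(hit$match_fraction >= 0.95))
    expect_equal(unname(unlist(hit[, grep("^parent_", names(hit))])),
                 rep("HETEROZYGOUS_COMPATIBLE", 3))
  }
})

test_that("shared regions are symmetric in the two cases", {
  sim <- simulate_cohort(small_config(seed = 22))
  vs <- sim$vs
  r1 <- shared_regions(vs)
  # swap the two case columns (labels swapped, data identical)
  swapped <- vs
  ord <- match(c("case2", "case1", "dam1", "dam2", "sire",
                 setdiff(vs$samples$sample_id,
                         c("case1", "case2", "dam1", "dam2", "sire"))),
               vs$samples$sample_id)
  swapped$geno <- vs$geno[, ord, drop = FALSE]
  colnames(swapped$geno) <- vs$samples$sample_id
  r2 <- shared_regions(swapped)
  expect_equal(r1[, c("chrom", "start", "end", "match_fraction")],
               r2[, c("chrom", "start", "end", "match_fraction")])
})

test_that("region summaries aggregate exactly", {
  expect_equal(summarize_regions(NULL),
               list(n_regions = 0L, max_length_bp = 0, n_chroms = 0L))
  regions <- data.frame(chrom = c("1", "1", "5"),
                        start = c(100L, 5000L, 1L),
                        end = c(3099999L + 100L, 6000L, 200L))
  s <- summarize_regions(regions)
  expect_equal(s$n_regions, 3L)
  expect_equal(s$max_length_bp, 3.1e6)
  expect_equal(s$n_chroms, 2L)
  set.seed(3)
  rr <- data.frame(chrom = as.character(sample(1:8, 40, TRUE)),
                   start = sample.int(1e6, 40))
  rr$end <- rr$start + sample.int(3e6, 40)
  s2 <- summarize_regions(rr)
  expect_equal(s2$n_regions, nrow(rr))
  expect_equal(s2$max_length_bp, max(rr$end - rr$start + 1))
  expect_equal(s2$n_chroms, length(unique(rr$chrom)))
})

test_that("segment export writes PLINK-style TSV and 0-based BED", {
  seg <- data.frame(sample_id = "case1", chrom = "1", start = 101L,
                    end = 1100L, n_snps = 10L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_segments(seg, tsv)
  back <- read.delim(tsv)
  expect_equal(back$length_kb, 1.0)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_segments(seg, bed, format = "bed")
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, 100L)  # 0-based half-open start
  expect_equal(b$V3, 1100L)
})
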