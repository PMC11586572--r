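# Independent oracles used to cross-check the package implementation.
# These deliberately use naive enumeration / closed forms, not the package's
# own algorithms.

# Exhaustive maximal-run enumerator for ROH detection: consider every window
# [i, j] with homozygous endpoints; admissible iff het/missing counts and all
# internal gaps are within limits; keep windows not strictly contained in
# another admissible window; then apply the length/marker-count filters.
brute_force_roh <- function(pos, geno, params) {
  n <- length(pos)
  is_het <- !is.na(geno) & geno == 1L
  is_mis <- is.na(geno)
  is_hom <- !is_het & !is_mis
  hom_idx <- which(is_hom)
  max_gap <- params$max_gap_kb * 1000
  cum_het <- cumsum(is_het)
  cum_mis <- cumsum(is_mis)
  cum_brk <- cumsum(c(FALSE, diff(pos) > max_gap))
  # for every admissible start, enumerate all admissible windows and keep
  # the widest; a window is maximal iff no earlier start reaches as far
  wins <- list()
  for (i in hom_idx) {
    js <- hom_idx[hom_idx >= i]
    base_het <- if (i > 1) cum_het[i - 1] else 0
    base_mis <- if (i > 1) cum_mis[i - 1] else 0
    ok <- (cum_het[js] - base_het) <= params$max_het_in_run &
      (cum_mis[js] - base_mis) <= params$max_missing_in_run &
      (cum_brk[js] - cum_brk[i]) == 0
    if (any(ok)) wins[[length(wins) + 1L]] <- c(i, max(js[ok]))
  }
  if (!length(wins)) return(data.frame(start = integer(), end = integer(),
                                       n_snps = integer()))
  w <- do.call(rbind, wins)
  maximal <- vapply(seq_len(nrow(w)), function(r) {
    !any(w[, 1] <= w[r, 1] & w[, 2] >= w[r, 2] &
           (w[, 1] != w[r, 1] | w[, 2] != w[r, 2]))
  }, logical(1))
  w <- w[maximal, , drop = FALSE]
  out <- data.frame(start = pos[w[, 1]], end = pos[w[, 2]],
                    n_snps = w[, 2] - w[, 1] + 1L)
  keep <- (out$end - out$start + 1) >= params$min_length_kb * 1000 &
    out$n_snps >= params$min_snps
  out <- out[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Per-record predicate for the trio genotype pattern.
brute_force_pattern <- function(geno_row, samples, scenario_name) {
  pattern <- switch(scenario_name,
                    RECESSIVE_HOMOZYGOUS = c(CASE = 2L, DAM = 1L, SIRE = 1L),
                    PATERNAL_GERMLINE_DENOVO = c(CASE = 1L, DAM = 0L, SIRE = 1L))
  for (r in names(pattern)) {
    for (id in samples$sample_id[samples$role == r]) {
      g <- geno_row[[id]]
      if (is.na(g) || g != pattern[[r]]) return(FALSE)
    }
  }
  TRUE
}

# Closed-form Wilson score interval.
wilson_oracle <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

# Mendelian-consistency check of offspring dosages given parental dosages:
# a child dosage is consistent iff it can be formed from one paternal and
# one maternal allele.
mendel_consistent <- function(child, sire, dam) {
  alleles <- function(g) switch(as.character(g), "0" = 0L, "1" = c(0L, 1L),
                                "2" = 1L)
  if (is.na(child) || is.na(sire) || is.na(dam)) return(TRUE)
  any(outer(alleles(sire), alleles(dam), `+`) == child)
}

random_trio_vs <- function(n = 100, seed = 1, p_missing = 0.1) {
  set.seed(seed)
  samples <- sample_set(c("case1", "case2", "dam1", "dam2", "sire"),
                        c("CASE", "CASE", "DAM", "DAM", "SIRE"))
  geno <- matrix(sample(c(0:2, NA), n * 5, replace = TRUE,
                        prob = c(rep((1 - p_missing) / 3, 3), p_missing)),
                 nrow = n)
  variants <- data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "T",
                         gene = sprintf("G%04d", seq_len(n)),
                         impact = sample(c("HIGH", "MODERATE", "LOW",
                                           "MODIFIER", NA), n, replace = TRUE))
  variant_set(variants, geno, samples)
}
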