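# Runs of homozygosity and shared identity-by-descent mapping.
#
# The detector is a consecutive-runs scanner (in the spirit of the
# "consecutive" method of ROH detection, as opposed to sliding-window
# heuristics): it reports every maximal marker window with homozygous
# endpoints whose heterozygous-call count, missing-call count and
# inter-marker gaps stay within the configured limits, then discards windows
# shorter than the minimum physical length or marker count. Deterministic,
# parameter-light, and directly checkable against exhaustive enumeration.

#' Parameters for ROH detection and cross-case matching
#'
#' @param min_length_kb Minimum physical run length in kb (default 1000, i.e.
#'   homozygous segments of at least 1 Mb).
#' @param min_snps Minimum number of markers spanned by a run (default 50).
#' @param max_het_in_run Maximum heterozygous calls tolerated inside a run
#'   (default 1).
#' @param max_missing_in_run Maximum missing calls tolerated (default 5).
#' @param max_gap_kb Maximum gap between adjacent markers inside a run, in kb
#'   (default 1000).
#' @param match_threshold Minimum fraction of identical genotypes required to
#'   certify allelic matching between two cases' overlapping runs
#'   (default 0.95).
#' @param min_match_snps Minimum jointly non-missing markers in an overlap
#'   before matching can be certified (default 20); matching a handful of
#'   markers at 0.95 would be meaningless.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_kb = 1000, min_snps = 50L,
                       max_het_in_run = 1L, max_missing_in_run = 5L,
                       max_gap_kb = 1000, match_threshold = 0.95,
                       min_match_snps = 20L) {
  stopifnot(min_length_kb > 0, min_snps >= 1,
            max_het_in_run >= 0, max_missing_in_run >= 0, max_gap_kb > 0,
            match_threshold > 0, match_threshold <= 1, min_match_snps >= 1)
  structure(list(min_length_kb = min_length_kb, min_snps = as.integer(min_snps),
                 max_het_in_run = as.integer(max_het_in_run),
                 max_missing_in_run = as.integer(max_missing_in_run),
                 max_gap_kb = max_gap_kb, match_threshold = match_threshold,
                 min_match_snps = as.integer(min_match_snps)),
            class = "roh_params")
}

empty_roh <- function() {
  data.frame(sample_id = character(), chrom = character(), start = integer(),
             end = integer(), n_snps = integer(), n_het = integer(),
             n_missing = integer(), length_bp = integer(),
             stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity along one chromosome
#'
#' @param pos Strictly increasing integer marker positions (1-based bp).
#' @param geno Alt dosages in \{0,1,2,NA\} aligned with `pos`.
#' @param params A [roh_params()].
#' @param chrom Chromosome label for the output.
#' @param sample_id Sample label for the output.
#' @return Data frame of run segments: `sample_id`, `chrom`, `start`, `end`
#'   (1-based inclusive bp), `n_snps`, `n_het`, `n_missing`, `length_bp`.
#' @export
detect_roh <- function(pos, geno, params = roh_params(), chrom = "1",
                       sample_id = "sample") {
  n <- length(pos)
  stopifnot(length(geno) == n)
  if (n && any(diff(pos) <= 0)) stop("marker positions must be strictly increasing")
  if (!n) return(empty_roh())
  is_het <- !is.na(geno) & geno == 1L
  is_mis <- is.na(geno)
  is_hom <- !is_het & !is_mis
  max_gap <- params$max_gap_kb * 1000
  # gap_break[j] TRUE when the step from marker j-1 to j exceeds max_gap
  gap_break <- c(FALSE, diff(pos) > max_gap)

  # last homozygous index at or before j (0 = none)
  last_hom <- cummax(ifelse(is_hom, seq_len(n), 0L))

  # Two-pointer scan over candidate windows [i..j]: i runs over homozygous
  # markers; j is extended greedily while the window stays admissible
  # (het/missing counts within limits, no gap break). Since shrinking the
  # window from the left never violates a constraint, j and the trimmed end
  # are nondecreasing in i, and a window is maximal iff its trimmed end
  # strictly exceeds the previous recorded end.
  starts <- integer(0); ends <- integer(0)
  j <- 0L; het <- 0L; mis <- 0L
  i_prev <- 1L
  prev_end <- 0L
  for (i in which(is_hom)) {
    if (j >= i) {
      if (i_prev < i) { # markers [i_prev, i-1] leave the window
        rem <- i_prev:(i - 1L)
        het <- het - sum(is_het[rem])
        mis <- mis - sum(is_mis[rem])
      }
    } else { # window collapsed; restart at i
      j <- i; het <- 0L; mis <- 0L
    }
    while (j < n && !gap_break[j + 1L] &&
           het + is_het[j + 1L] <= params$max_het_in_run &&
           mis + is_mis[j + 1L] <= params$max_missing_in_run) {
      j <- j + 1L
      het <- het + is_het[j]; mis <- mis + is_mis[j]
    }
    e <- last_hom[j]
    if (e >= i && e > prev_end) {
      starts <- c(starts, i); ends <- c(ends, e)
      prev_end <- e
    }
    i_prev <- i
  }
  if (!length(starts)) return(empty_roh())
  seg <- data.frame(sample_id = sample_id, chrom = chrom,
                    start = pos[starts], end = pos[ends],
                    n_snps = ends - starts + 1L,
                    n_het = vapply(seq_along(starts), function(q)
                      sum(is_het[starts[q]:ends[q]]), integer(1)),
                    n_missing = vapply(seq_along(starts), function(q)
                      sum(is_mis[starts[q]:ends[q]]), integer(1)),
                    stringsAsFactors = FALSE)
  seg$length_bp <- seg$end - seg$start + 1L
  keep <- seg$length_bp >= params$min_length_kb * 1000 &
    seg$n_snps >= params$min_snps
  seg <- seg[keep, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Detect ROH for selected samples of a variant_set
#'
#' @param vs A [variant_set()].
#' @param sample_ids Samples to scan (default: all `CASE` samples).
#' @param params A [roh_params()].
#' @param exclude_chroms Chromosomes excluded from scanning (default the sex
#'   chromosomes `X`/`Y` in common spellings).
#' @return Data frame of run segments across samples and chromosomes.
#' @export
detect_roh_samples <- function(vs, sample_ids = NULL, params = roh_params(),
                               exclude_chroms = c("X", "Y", "chrX", "chrY")) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.null(sample_ids)) sample_ids <- samples_with_role(vs$samples, "CASE")
  out <- list()
  for (chrom in setdiff(unique(vs$variants$chrom), exclude_chroms)) {
    i <- which(vs$variants$chrom == chrom)
    i <- i[order(vs$variants$pos[i])]
    p <- vs$variants$pos[i]
    for (s in sample_ids) {
      out[[length(out) + 1L]] <- detect_roh(p, vs$geno[i, s], params,
                                            chrom = chrom, sample_id = s)
    }
  }
  if (!length(out)) return(empty_roh())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allelic matching between two overlapping run segments
#'
#' @param seg_a,seg_b Single-row segment data frames (as returned by
#'   [detect_roh()]) for two different samples on the same chromosome.
#' @param pos Marker positions of that chromosome.
#' @param geno_a,geno_b The two samples' dosages aligned with `pos`.
#' @param params A [roh_params()].
#' @return `NULL` when the segments do not overlap, fewer than
#'   `min_match_snps` markers are jointly non-missing in the overlap, or the
#'   identical-genotype fraction falls below `match_threshold`; otherwise a
#'   list with `start`, `end` (the overlap interval), `match_fraction` and
#'   `n_joint` (jointly non-missing markers).
#' @export
match_segments <- function(seg_a, seg_b, pos, geno_a, geno_b,
                           params = roh_params()) {
  if (seg_a$chrom != seg_b$chrom) stop("segments on different chromosomes")
  s <- max(seg_a$start, seg_b$start)
  e <- min(seg_a$end, seg_b$end)
  if (s > e) return(NULL)
  in_ov <- pos >= s & pos <= e
  ga <- geno_a[in_ov]; gb <- geno_b[in_ov]
  joint <- !is.na(ga) & !is.na(gb)
  n_joint <- sum(joint)
  if (n_joint < params$min_match_snps) return(NULL)
  frac <- mean(ga[joint] == gb[joint])
  if (frac < params$match_threshold) return(NULL)
  list(start = s, end = e, match_fraction = frac, n_joint = n_joint)
}

empty_regions <- function() {
  data.frame(region_id = character(), chrom = character(), start = integer(),
             end = integer(), match_fraction = numeric(), n_joint = integer(),
             stringsAsFactors = FALSE)
}

#' Shared IBD regions between the affected cases
#'
#' Detects ROH in each case, certifies allelic matching between every
#' positionally overlapping pair of case runs, and reports the intersection
#' intervals as candidate identity-by-descent regions. Each parent (DAM/SIRE
#' sample) is annotated `HETEROZYGOUS_COMPATIBLE` when the region contains at
#' least one marker at which both cases are hom-alt and that parent is
#' heterozygous -- i.e. the region can harbor a recessive allele for which
#' the parent is an obligate carrier -- and `NOT_COMPATIBLE` otherwise.
#'
#' @param vs A [variant_set()] with two (or more) `CASE` samples and the
#'   parental samples.
#' @param params A [roh_params()].
#' @param merge Merge overlapping certified regions with identical
#'   parent-state annotation (default `TRUE`); the unmerged pairwise regions
#'   are kept in attribute `raw`.
#' @param exclude_chroms Chromosomes excluded from scanning.
#' @return Data frame of regions: `region_id`, `chrom`, `start`, `end`,
#'   `match_fraction`, `n_joint`, plus one `parent_<id>` state column per
#'   parental sample.
#' @export
shared_regions <- function(vs, params = roh_params(), merge = TRUE,
                           exclude_chroms = c("X", "Y", "chrX", "chrY")) {
  stopifnot(inherits(vs, "variant_set"))
  cases <- samples_with_role(vs$samples, "CASE")
  if (length(cases) < 2) stop("shared_regions needs at least two CASE samples")
  parents <- samples_with_role(vs$samples, c("DAM", "SIRE"))
  segs <- detect_roh_samples(vs, cases, params, exclude_chroms)
  if (!nrow(segs)) return(add_parent_cols(empty_regions(), parents))

  regions <- list()
  for (chrom in unique(segs$chrom)) {
    i <- which(vs$variants$chrom == chrom)
    i <- i[order(vs$variants$pos[i])]
    p <- vs$variants$pos[i]
    sc <- segs[segs$chrom == chrom, , drop = FALSE]
    pairs <- utils::combn(cases, 2, simplify = FALSE)
    for (pr in pairs) {
      sa <- sc[sc$sample_id == pr[1], , drop = FALSE]
      sb <- sc[sc$sample_id == pr[2], , drop = FALSE]
      if (!nrow(sa) || !nrow(sb)) next
      ga <- vs$geno[i, pr[1]]; gb <- vs$geno[i, pr[2]]
      for (a in seq_len(nrow(sa))) for (b in seq_len(nrow(sb))) {
        m <- match_segments(sa[a, ], sb[b, ], p, ga, gb, params)
        if (is.null(m)) next
        in_reg <- p >= m$start & p <= m$end
        both_hom_alt <- in_reg & !is.na(ga) & !is.na(gb) & ga == 2L & gb == 2L
        states <- vapply(parents, function(pid) {
          gp <- vs$geno[i, pid]
          if (any(both_hom_alt & !is.na(gp) & gp == 1L))
            "HETEROZYGOUS_COMPATIBLE" else "NOT_COMPATIBLE"
        }, character(1))
        row <- data.frame(chrom = chrom, start = m$start, end = m$end,
                          match_fraction = m$match_fraction,
                          n_joint = m$n_joint, stringsAsFactors = FALSE)
        for (pid in parents) row[[paste0("parent_", pid)]] <- states[[pid]]
        regions[[length(regions) + 1L]] <- row
      }
    }
  }
  if (!length(regions)) return(add_parent_cols(empty_regions(), parents))
  raw <- do.call(rbind, regions)
  raw <- raw[order(raw$chrom, raw$start), , drop = FALSE]
  rownames(raw) <- NULL
  out <- if (merge) merge_regions(raw, parents) else raw
  out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out <- out[, c("region_id", setdiff(names(out), "region_id"))]
  rownames(out) <- NULL
  attr(out, "raw") <- raw
  out
}

add_parent_cols <- function(df, parents) {
  for (pid in parents) df[[paste0("parent_", pid)]] <- character(0)
  df
}

# Merge overlapping regions whose parent-state annotation is identical;
# match_fraction of a merged region is the minimum over its members.
merge_regions <- function(raw, parents) {
  pcols <- paste0("parent_", parents)
  key <- do.call(paste, c(list(raw$chrom), raw[pcols], list(sep = "\r")))
  out <- list()
  for (k in unique(key)) {
    sub <- raw[key == k, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur <- sub[1, , drop = FALSE]
    for (r in seq_len(nrow(sub))[-1]) {
      if (sub$start[r] <= cur$end + 1L) {
        cur$end <- max(cur$end, sub$end[r])
        cur$match_fraction <- min(cur$match_fraction, sub$match_fraction[r])
        cur$n_joint <- cur$n_joint + sub$n_joint[r]
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- sub[r, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Summary of shared IBD regions
#'
#' @param regions Region data frame from [shared_regions()].
#' @return List with `n_regions`, `max_length_bp` and `n_chroms`.
#' @export
summarize_regions <- function(regions) {
  if (is.null(regions) || !nrow(regions)) {
    return(list(n_regions = 0L, max_length_bp = 0, n_chroms = 0L))
  }
  list(n_regions = nrow(regions),
       max_length_bp = max(regions$end - regions$start + 1),
       n_chroms = length(unique(regions$chrom)))
}

#' Write segments/regions in PLINK-.hom-style TSV or BED
#'
#' BED output converts 1-based inclusive intervals to 0-based half-open.
#'
#' @param x Segment or region data frame (needs `chrom`, `start`, `end`).
#' @param path Output path.
#' @param format `"tsv"` (as-is, plus `length_kb`) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x$length_kb <- (x$end - x$start + 1) / 1000
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    name <- if (!is.null(x$region_id)) x$region_id
            else if (!is.null(x$sample_id)) x$sample_id else "."
    bed <- data.frame(x$chrom, x$start - 1L, x$end, name)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
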