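# Read-depth screen for aneuploidies and large structural variants from
# pre-binned coverage. Depth is consumed as windowed TSV (chrom, start, end,
# mean_depth), as produced by standard coverage tools in windowed mode.

#' Read a binned depth profile
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `mean_depth`
#'   (1-based inclusive bins of constant width).
#' @param sample_id Sample label attached to the profile.
#' @return A data frame of class `depth_profile`.
#' @export
read_depth_profile <- function(path, sample_id = basename(path)) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "mean_depth")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("depth profile lacks column(s): ",
                         paste(miss, collapse = ", "))
  depth_profile(x, sample_id)
}

#' Construct a depth profile
#'
#' @param bins Data frame with columns `chrom`, `start`, `end`, `mean_depth`.
#' @param sample_id Sample label.
#' @return A data frame of class `depth_profile` with attribute `sample_id`.
#' @export
depth_profile <- function(bins, sample_id = "sample") {
  stopifnot(all(c("chrom", "start", "end", "mean_depth") %in% names(bins)))
  if (any(bins$mean_depth < 0, na.rm = TRUE)) stop("depths must be >= 0")
  bins$chrom <- as.character(bins$chrom)
  attr(bins, "sample_id") <- sample_id
  class(bins) <- c("depth_profile", "data.frame")
  bins
}

#' Normalize a depth profile by its autosomal median
#'
#' Every bin's depth is divided by the sample's median depth over autosomal
#' bins, so a diploid baseline sits at ratio 1.0 regardless of sequencing
#' depth; sex chromosomes are excluded from the baseline.
#'
#' @param profile A [depth_profile()].
#' @param exclude_chroms Chromosomes excluded from the normalization baseline
#'   (default sex chromosomes).
#' @return The profile with an added `ratio` column and attribute
#'   `autosomal_median` (the raw-depth divisor).
#' @export
normalize_depth <- function(profile,
                            exclude_chroms = c("X", "Y", "chrX", "chrY")) {
  stopifnot(inherits(profile, "depth_profile"))
  auto <- !(profile$chrom %in% exclude_chroms)
  if (!any(auto)) stop("no autosomal bins to normalize against")
  med <- stats::median(profile$mean_depth[auto], na.rm = TRUE)
  if (!is.finite(med) || med <= 0) {
    stop("autosomal median depth is zero; cannot normalize")
  }
  profile$ratio <- profile$mean_depth / med
  attr(profile, "autosomal_median") <- med
  profile
}

depth_flag <- function(ratio, loss_threshold, gain_threshold) {
  ifelse(is.na(ratio), "NO_DATA",
         ifelse(ratio < loss_threshold, "LOSS",
                ifelse(ratio > gain_threshold, "GAIN", "NORMAL")))
}

#' Flag chromosomes and query regions by normalized depth
#'
#' Chromosome-level medians screen for aneuploidies (e.g. a trisomy sits near
#' ratio 1.5, a monosomy near 0.5); region-level means screen for larger
#' deletions/duplications inside candidate intervals. Default thresholds
#' 0.75/1.25 lie midway between the diploid expectation (1.0) and the
#' single-copy (0.5) / three-copy (1.5) expectations.
#'
#' @param profile A normalized [depth_profile()] (see [normalize_depth()]).
#' @param regions Optional data frame of query intervals (`chrom`, `start`,
#'   `end`, optionally `region_id`), e.g. shared IBD regions.
#' @param loss_threshold,gain_threshold Flag `LOSS` below / `GAIN` above
#'   these normalized ratios; `NORMAL` within.
#' @return A list of class `depth_summary` with data frames `chromosomes`
#'   (`chrom`, `median_ratio`, `n_bins`, `flag`) and `regions` (`region_id`,
#'   `chrom`, `start`, `end`, `mean_ratio`, `n_bins`, `flag`; flag `NO_DATA`
#'   when no bin overlaps the region).
#' @export
flag_regions <- function(profile, regions = NULL, loss_threshold = 0.75,
                         gain_threshold = 1.25) {
  stopifnot(inherits(profile, "depth_profile"))
  if (is.null(profile$ratio)) stop("profile is not normalized; run normalize_depth() first")
  stopifnot(loss_threshold < gain_threshold)
  chroms <- unique(profile$chrom)
  chrom_med <- vapply(chroms, function(ch)
    stats::median(profile$ratio[profile$chrom == ch], na.rm = TRUE), numeric(1))
  chrom_df <- data.frame(
    chrom = chroms, median_ratio = unname(chrom_med),
    n_bins = as.integer(table(profile$chrom)[chroms]),
    flag = depth_flag(unname(chrom_med), loss_threshold, gain_threshold),
    stringsAsFactors = FALSE)

  reg_df <- data.frame(region_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       mean_ratio = numeric(), n_bins = integer(),
                       flag = character(), stringsAsFactors = FALSE)
  if (!is.null(regions) && nrow(regions)) {
    if (is.null(regions$region_id)) {
      regions$region_id <- sprintf("%s:%d-%d", regions$chrom,
                                   regions$start, regions$end)
    }
    rows <- lapply(seq_len(nrow(regions)), function(r) {
      hit <- profile$chrom == regions$chrom[r] &
        profile$end >= regions$start[r] & profile$start <= regions$end[r]
      n <- sum(hit)
      mr <- if (n) mean(profile$ratio[hit], na.rm = TRUE) else NA_real_
      data.frame(region_id = regions$region_id[r], chrom = regions$chrom[r],
                 start = regions$start[r], end = regions$end[r],
                 mean_ratio = mr, n_bins = n,
                 flag = if (n) depth_flag(mr, loss_threshold, gain_threshold)
                        else "NO_DATA",
                 stringsAsFactors = FALSE)
    })
    reg_df <- do.call(rbind, rows)
  }
  structure(list(sample_id = attr(profile, "sample_id"),
                 chromosomes = chrom_df, regions = reg_df,
                 loss_threshold = loss_threshold,
                 gain_threshold = gain_threshold),
            class = "depth_summary")
}

#' @method print depth_summary
#' @export
print.depth_summary <- function(x, ...) {
  cat("depth_summary [", x$sample_id, "]\n", sep = "")
  print.data.frame(x$chromosomes, row.names = FALSE)
  if (nrow(x$regions)) {
    cat("regions:\n")
    print.data.frame(x$regions, row.names = FALSE)
  }
  invisible(x)
}
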