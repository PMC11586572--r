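#' @keywords internal
"_PACKAGE"

ROLES <- c("CASE", "DAM", "SIRE", "LOCAL_CONTROL")
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Sample set with pedigree roles
#'
#' A `sample_set` is an ordered table of sample identifiers with the role each
#' sample plays in the trio design: `CASE` (affected), `DAM` / `SIRE`
#' (parents, obligate carriers under the recessive scenario) or
#' `LOCAL_CONTROL` (sequenced control cohort member).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param role Character vector (same length) of roles, each one of
#'   `"CASE"`, `"DAM"`, `"SIRE"`, `"LOCAL_CONTROL"`.
#' @return A data frame of class `sample_set` with columns `sample_id`, `role`.
#' @examples
#' sample_set(c("case1", "case2", "dam1", "dam2", "sire"),
#'            c("CASE", "CASE", "DAM", "DAM", "SIRE"))
#' @export
sample_set <- function(sample_id, role) {
  sample_id <- as.character(sample_id)
  role <- toupper(as.character(role))
  if (length(sample_id) != length(role)) {
    stop("sample_id and role must have the same length")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(role), ROLES)
  if (length(bad)) {
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ROLES, collapse = "/"), ")")
  }
  if (!any(role == "CASE")) stop("a sample_set needs at least one CASE sample")
  out <- data.frame(sample_id = sample_id, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_set", "data.frame")
  out
}

#' @method print sample_set
#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set:", nrow(x), "samples (",
      paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
            collapse = ", "), ")\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

samples_with_role <- function(samples, role) {
  samples$sample_id[samples$role %in% role]
}

#' Construct a set of biallelic variants with per-sample genotypes
#'
#' The central container of the package: one row per biallelic variant
#' (`chrom`, 1-based `pos`, `ref`, single `alt`, optional `gene` and snpEff
#' `impact` class), plus an integer matrix of alternate-allele dosages
#' (0/1/2, `NA` = missing call) with one column per sample. Phase is
#' discarded; all inheritance logic works on dosages.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `gene`, `impact`.
#' @param geno Integer matrix (`nrow(variants)` x `nrow(samples)`) of alt
#'   dosages in \{0,1,2,NA\}; column names must equal `samples$sample_id`.
#' @param samples A [sample_set()].
#' @return An object of class `variant_set`: a list with elements `variants`,
#'   `geno`, `samples`.
#' @export
variant_set <- function(variants, geno, samples) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lacks column(s): ", paste(miss, collapse = ", "))
  if (!inherits(samples, "sample_set")) {
    samples <- sample_set(samples$sample_id, samples$role)
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  if (is.null(variants$gene)) variants$gene <- NA_character_
  if (is.null(variants$impact)) variants$impact <- NA_character_
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(grepl(",", variants$alt, fixed = TRUE))) {
    stop("variant_set records must carry exactly one alt allele")
  }
  bad_imp <- setdiff(stats::na.omit(unique(variants$impact)), IMPACT_LEVELS)
  if (length(bad_imp)) stop("unknown impact class(es): ", paste(bad_imp, collapse = ", "))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants)) stop("geno rows must match variants rows")
  if (is.null(colnames(geno)) || !identical(colnames(geno), samples$sample_id)) {
    if (ncol(geno) != nrow(samples)) stop("geno columns must match samples")
    colnames(geno) <- samples$sample_id
  }
  if (any(!is.na(geno))) {
    rng <- range(geno, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > 2L) {
      stop("genotype dosages must lie in {0, 1, 2} or be NA")
    }
  }
  key <- variant_keys_df(variants)
  if (anyDuplicated(key)) {
    stop("duplicate variant key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(geno) <- NULL
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno, samples = samples),
            class = "variant_set")
}

variant_keys_df <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Variant identity keys
#'
#' @param x A `variant_set` or a variant data frame.
#' @return Character vector `chrom:pos:ref:alt`, unique within a dataset.
#' @export
variant_keys <- function(x) {
  if (inherits(x, "variant_set")) x <- x$variants
  variant_keys_df(x)
}

#' @method print variant_set
#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x", nrow(x$samples),
      "samples on", length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of variants in a variant_set
#' @param x A `variant_set`.
#' @return Integer count of variant records.
#' @export
n_variants <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  nrow(x$variants)
}

#' Subset a variant_set by variant index
#'
#' @param vs A `variant_set`.
#' @param i Logical or integer index over variant rows.
#' @return A `variant_set` with the selected records (samples unchanged).
#' @export
subset_variants <- function(vs, i) {
  stopifnot(inherits(vs, "variant_set"))
  variant_set(vs$variants[i, , drop = FALSE],
              vs$geno[i, , drop = FALSE],
              vs$samples)
}

#' Order a variant_set by chromosome and position
#'
#' @param vs A `variant_set`.
#' @param chrom_order Optional character vector giving chromosome order
#'   (e.g. the VCF header contig order); unlisted chromosomes follow, sorted.
#' @return The reordered `variant_set`.
#' @export
sort_variants <- function(vs, chrom_order = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  chr <- vs$variants$chrom
  if (is.null(chrom_order)) chrom_order <- unique(chr[order(chr)])
  lev <- c(chrom_order, setdiff(sort(unique(chr)), chrom_order))
  o <- order(match(chr, lev), vs$variants$pos)
  subset_variants(vs, o)
}
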