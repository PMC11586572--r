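# VCF and annotation input/output. VCF parsing is delegated to vcfR; this
# layer only recodes GT strings to alt dosages and splits multi-allelic
# sites into one biallelic record per alt allele.

#' Recode a vector of GT strings against one alt allele index
#'
#' Alleles other than \{0, alt_index\} (including half-missing calls such as
#' `./1`) make the call missing for that biallelic view.
#'
#' @param gt Character vector of VCF GT strings (`"0/1"`, `"1|1"`, `"./."`, ...).
#' @param alt_index Integer allele index (1 = first alt) defining the
#'   biallelic view.
#' @return Integer vector of alt dosages in \{0,1,2\} with `NA` for missing.
#' @export
recode_gt <- function(gt, alt_index = 1L) {
  gt <- as.character(gt)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != "."
  if (!any(ok)) return(out)
  parts <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(parts, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai)) return(NA_integer_)
    if (!all(ai %in% c(0L, alt_index))) return(NA_integer_)
    sum(ai == alt_index)
  }, integer(1))
  out
}

#' Read a multi-sample VCF into a variant_set
#'
#' Reads a VCF 4.x file (plain or gzip), keeps the role-mapped samples, splits
#' multi-allelic sites into one biallelic record per alt allele (recoding
#' genotypes via [recode_gt()]), parses snpEff `ANN` annotations when present,
#' and returns records sorted by header contig order and position.
#'
#' @param path Path to the VCF file.
#' @param sample_roles Named character vector mapping sample id to role
#'   (`CASE`/`DAM`/`SIRE`/`LOCAL_CONTROL`). Samples absent from the map are
#'   dropped.
#' @param pass_only If `TRUE`, keep only records whose FILTER is `PASS` or
#'   `.`. Off by default.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path, sample_roles, pass_only = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  hdr_samples <- colnames(v@gt)[-1]
  absent <- setdiff(names(sample_roles), hdr_samples)
  if (length(absent)) {
    stop("role-mapped sample(s) absent from VCF header: ",
         paste(absent, collapse = ", "))
  }
  fmt <- v@gt[, "FORMAT"]
  if (nrow(v@fix) && !all(grepl("(^|:)GT(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)GT(:|$)", fmt))[1]
    stop("no GT field at ", v@fix[bad, "CHROM"], ":", v@fix[bad, "POS"])
  }
  samples <- sample_set(names(sample_roles), unname(sample_roles))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = nrow(v@fix),
                                             dimnames = list(NULL, hdr_samples))
  gt_raw <- gt_raw[, samples$sample_id, drop = FALSE]

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(fix))
  if (pass_only && "FILTER" %in% names(fix)) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  }
  ann_all <- extract_info_field(fix$INFO, "ANN")

  rows <- list()
  genos <- list()
  n_out <- 0L
  for (i in which(keep)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (!length(alts) || identical(alts, ".")) next
    for (k in seq_along(alts)) {
      n_out <- n_out + 1L
      ga <- parse_ann_for_alt(ann_all[i], alts[k],
                              site = paste0(fix$CHROM[i], ":", fix$POS[i]))
      rows[[n_out]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        gene = ga$gene, impact = ga$impact, stringsAsFactors = FALSE)
      genos[[n_out]] <- recode_gt(gt_raw[i, ], alt_index = k)
    }
  }
  if (!n_out) {
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gene = character(), impact = character(),
                           stringsAsFactors = FALSE)
    geno <- matrix(integer(), 0, nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
    return(variant_set(variants, geno, samples))
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- samples$sample_id
  vs <- variant_set(variants, geno, samples)
  contigs <- vcf_header_contigs(v)
  sort_variants(vs, chrom_order = contigs)
}

vcf_header_contigs <- function(v) {
  meta <- v@meta
  ids <- regmatches(meta, regexpr("##contig=<ID=[^,>]+", meta))
  if (!length(ids)) return(NULL)
  sub("##contig=<ID=", "", ids, fixed = TRUE)
}

extract_info_field <- function(info, key) {
  out <- rep(NA_character_, length(info))
  if (!length(info)) return(out)
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  ok <- !is.na(info)
  m <- regexpr(pat, info[ok], perl = TRUE)
  hit <- m > 0
  vals <- rep(NA_character_, sum(ok))
  vals[hit] <- sub(pat, "\\1", regmatches(info[ok], m), perl = TRUE)
  out[ok] <- vals
  out
}

# Severity ranking: HIGH > MODERATE > LOW > MODIFIER.
impact_rank <- function(impact) match(impact, IMPACT_LEVELS)

parse_ann_for_alt <- function(ann, alt, site = "") {
  if (is.na(ann) || !nzchar(ann)) {
    return(list(gene = NA_character_, impact = NA_character_))
  }
  entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  match_alt <- vapply(fields, function(f) length(f) >= 1 && f[[1]] == alt,
                      logical(1))
  if (!any(match_alt)) {
    warning("no ANN entry matching alt ", alt,
            if (nzchar(site)) paste0(" at ", site), "; impact left unset")
    return(list(gene = NA_character_, impact = NA_character_))
  }
  fields <- fields[match_alt]
  imp <- vapply(fields, function(f) {
    if (length(f) >= 3) toupper(f[[3]]) else NA_character_
  }, character(1))
  gene <- vapply(fields, function(f) {
    if (length(f) >= 4 && nzchar(f[[4]])) f[[4]] else NA_character_
  }, character(1))
  bad <- setdiff(stats::na.omit(unique(imp)), IMPACT_LEVELS)
  if (length(bad)) {
    stop("unknown impact token(s) in ANN",
         if (nzchar(site)) paste0(" at ", site), ": ",
         paste(bad, collapse = ", "))
  }
  best <- which.min(impact_rank(imp))
  if (!length(best) || is.na(imp[best])) {
    return(list(gene = NA_character_, impact = NA_character_))
  }
  list(gene = gene[best], impact = imp[best])
}

#' Parse a snpEff ANN string for one alt allele
#'
#' When multiple ANN entries match the alt, the entry with the most severe
#' impact (HIGH > MODERATE > LOW > MODIFIER) is kept, with its gene symbol.
#'
#' @param ann The value of the `ANN` INFO field (comma-separated,
#'   pipe-delimited entries).
#' @param alt The alt allele of the biallelic record.
#' @return A list with elements `gene` and `impact` (either may be `NA`).
#' @export
parse_snpeff_ann <- function(ann, alt) parse_ann_for_alt(ann, alt)

#' Attach gene/impact annotation from a sidecar table
#'
#' The sidecar must have columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `impact`; impact tokens are matched case-insensitively. Records without a
#' sidecar row keep their current annotation.
#'
#' @param vs A [variant_set()].
#' @param sidecar Data frame or path to a TSV with the columns above.
#' @return The `variant_set` with `gene` and `impact` filled in.
#' @export
annotate_variants <- function(vs, sidecar) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.character(sidecar)) {
    sidecar <- utils::read.delim(sidecar, stringsAsFactors = FALSE,
                                 colClasses = "character")
  }
  need <- c("chrom", "pos", "ref", "alt", "gene", "impact")
  miss <- setdiff(need, names(sidecar))
  if (length(miss)) stop("sidecar lacks column(s): ", paste(miss, collapse = ", "))
  imp <- toupper(as.character(sidecar$impact))
  bad <- setdiff(stats::na.omit(unique(imp[nzchar(imp)])), IMPACT_LEVELS)
  if (length(bad)) stop("unknown impact token(s): ", paste(bad, collapse = ", "))
  skey <- paste(sidecar$chrom, as.integer(sidecar$pos), sidecar$ref,
                sidecar$alt, sep = ":")
  idx <- match(variant_keys(vs), skey)
  hit <- !is.na(idx)
  vs$variants$gene[hit] <- as.character(sidecar$gene)[idx[hit]]
  vs$variants$impact[hit] <- imp[idx[hit]]
  vs
}

#' Write a variant_set as a tab-separated table
#'
#' Columns are `chrom`, `pos`, `ref`, `alt`, `gene`, `impact` followed by one
#' genotype column per sample (alt dosage 0/1/2, `NA` for missing). Sample
#' roles are preserved in `#sample` header comments so that
#' [read_variant_table()] is a lossless inverse.
#'
#' @param vs A [variant_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample\t%s\t%s", vs$samples$sample_id, vs$samples$role),
             con)
  tab <- cbind(vs$variants[, c("chrom", "pos", "ref", "alt", "gene", "impact")],
               as.data.frame(vs$geno))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a variant table written by [write_variant_table()]
#'
#' @param path Path to the table.
#' @return A [variant_set()].
#' @export
read_variant_table <- function(path) {
  lines <- readLines(path)
  smp <- grep("^#sample\t", lines, value = TRUE)
  if (!length(smp)) stop("missing #sample role header in ", path)
  parts <- strsplit(smp, "\t", fixed = TRUE)
  samples <- sample_set(vapply(parts, `[[`, "", 2L),
                        vapply(parts, `[[`, "", 3L))
  body <- lines[!startsWith(lines, "#sample")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          gene = "character",
                                          impact = "character"))
  variants <- tab[, c("chrom", "pos", "ref", "alt", "gene", "impact")]
  geno <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  variant_set(variants, geno, samples)
}
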