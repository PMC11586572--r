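# Genotype-pattern filtering cascade under competing inheritance scenarios,
# with control-cohort exclusion and functional-impact filtering.

#' Inheritance scenario specifications
#'
#' Two scenarios are supported:
#' \describe{
#'   \item{RECESSIVE_HOMOZYGOUS}{autosomal recessive: cases homozygous for
#'     the alt allele, all dams and the sire heterozygous obligate carriers;
#'     controls may be het or hom-ref (`EXCLUDE_IF_HOM_ALT`).}
#'   \item{PATERNAL_GERMLINE_DENOVO}{paternal germline (gonadal) mosaicism:
#'     cases and sire heterozygous, dams hom-ref; the variant must be absent
#'     from controls entirely (`EXCLUDE_IF_ANY_ALT`).}
#' }
#'
#' @param name `"RECESSIVE_HOMOZYGOUS"` or `"PATERNAL_GERMLINE_DENOVO"`.
#' @return A list of class `scenario_spec` with elements `name`, `pattern`
#'   (role -> allowed dosage set) and `control_policy`.
#' @export
scenario_spec <- function(name = c("RECESSIVE_HOMOZYGOUS",
                                   "PATERNAL_GERMLINE_DENOVO")) {
  name <- match.arg(name)
  spec <- switch(name,
    RECESSIVE_HOMOZYGOUS = list(
      pattern = list(CASE = 2L, DAM = 1L, SIRE = 1L),
      control_policy = "EXCLUDE_IF_HOM_ALT"),
    PATERNAL_GERMLINE_DENOVO = list(
      pattern = list(CASE = 1L, SIRE = 1L, DAM = 0L),
      control_policy = "EXCLUDE_IF_ANY_ALT"))
  structure(c(list(name = name), spec), class = "scenario_spec")
}

as_scenario <- function(scenario) {
  if (inherits(scenario, "scenario_spec")) scenario else scenario_spec(scenario)
}

#' Filter variants on a trio genotype pattern
#'
#' A record survives iff every sample whose role appears in the scenario
#' pattern has a non-missing genotype that lies in the allowed dosage set for
#' its role. Missing genotypes in pattern samples fail the record (strict):
#' the trio genotypes are treated as confirmed calls, not as an occurrence
#' catalog.
#'
#' @param vs A [variant_set()] whose `samples` carry the scenario roles.
#' @param scenario A [scenario_spec()] or its name.
#' @return The surviving `variant_set` (possibly empty).
#' @export
genotype_pattern_filter <- function(vs, scenario) {
  stopifnot(inherits(vs, "variant_set"))
  scenario <- as_scenario(scenario)
  keep <- rep(TRUE, n_variants(vs))
  for (role in names(scenario$pattern)) {
    ids <- samples_with_role(vs$samples, role)
    if (!length(ids)) {
      stop("scenario ", scenario$name, " requires role ", role,
           " but the sample set has none")
    }
    allowed <- scenario$pattern[[role]]
    g <- vs$geno[, ids, drop = FALSE]
    ok <- !is.na(g) & matrix(g %in% allowed, nrow(g), ncol(g))
    keep <- keep & (rowSums(ok) == length(ids))
  }
  subset_variants(vs, keep)
}

#' Build a genotype-count catalog from control samples
#'
#' @param vs A [variant_set()].
#' @param sample_ids Samples to count; defaults to all `LOCAL_CONTROL`
#'   samples.
#' @return A data frame of class `cohort_catalog` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `n_hom_ref`, `n_het`, `n_hom_alt`, `n_missing`.
#' @export
count_cohort <- function(vs, sample_ids = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.null(sample_ids)) {
    sample_ids <- samples_with_role(vs$samples, "LOCAL_CONTROL")
  }
  g <- vs$geno[, sample_ids, drop = FALSE]
  out <- cbind(
    vs$variants[, c("chrom", "pos", "ref", "alt")],
    n_hom_ref = rowSums(g == 0L, na.rm = TRUE),
    n_het = rowSums(g == 1L, na.rm = TRUE),
    n_hom_alt = rowSums(g == 2L, na.rm = TRUE),
    n_missing = rowSums(is.na(g)))
  cohort_catalog(out)
}

#' Validate/construct a cohort genotype-count catalog
#'
#' @param x Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `n_hom_ref`, `n_het`, `n_hom_alt` and optionally `n_missing`.
#' @return `x` with class `cohort_catalog`.
#' @export
cohort_catalog <- function(x) {
  need <- c("chrom", "pos", "ref", "alt", "n_hom_ref", "n_het", "n_hom_alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$n_missing)) x$n_missing <- 0L
  cnt <- as.matrix(x[, c("n_hom_ref", "n_het", "n_hom_alt", "n_missing")])
  if (any(cnt < 0, na.rm = TRUE)) stop("catalog counts must be >= 0")
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  rownames(x) <- NULL
  class(x) <- c("cohort_catalog", "data.frame")
  x
}

#' Read / write cohort catalogs as TSV
#' @param path File path.
#' @return `read_cohort_catalog` returns a [cohort_catalog()];
#'   `write_cohort_catalog` returns `path` invisibly.
#' @export
read_cohort_catalog <- function(path) {
  cohort_catalog(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_catalog
#' @param catalog A [cohort_catalog()].
#' @export
write_cohort_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Exclude variants observed in a control cohort
#'
#' Under `EXCLUDE_IF_HOM_ALT` a record is removed when the cohort contains
#' any hom-alt individual (carriers tolerated); under `EXCLUDE_IF_ANY_ALT`
#' when it contains any alt allele at all. Records absent from the catalog
#' survive (absence of evidence = private). Missing control calls never veto.
#'
#' @param vs A [variant_set()].
#' @param catalog A [cohort_catalog()].
#' @param policy `"EXCLUDE_IF_HOM_ALT"` or `"EXCLUDE_IF_ANY_ALT"`.
#' @return The surviving `variant_set`.
#' @export
cohort_exclusion_filter <- function(vs, catalog,
                                    policy = c("EXCLUDE_IF_HOM_ALT",
                                               "EXCLUDE_IF_ANY_ALT")) {
  stopifnot(inherits(vs, "variant_set"))
  policy <- match.arg(policy)
  idx <- match(variant_keys(vs), variant_keys_df(catalog))
  hom_alt <- ifelse(is.na(idx), 0L, catalog$n_hom_alt[idx])
  het <- ifelse(is.na(idx), 0L, catalog$n_het[idx])
  drop <- if (policy == "EXCLUDE_IF_HOM_ALT") hom_alt > 0L else het + hom_alt > 0L
  subset_variants(vs, !drop)
}

#' Keep protein-changing impact classes
#'
#' @param vs A [variant_set()] with impacts parsed.
#' @param allowed Impact classes to keep (default MODERATE and HIGH, the
#'   usual "protein-changing" set). Records with unset impact are removed.
#' @return The surviving `variant_set`; the number of removed unannotated
#'   records is attached as attribute `n_unannotated`.
#' @export
impact_filter <- function(vs, allowed = c("MODERATE", "HIGH")) {
  stopifnot(inherits(vs, "variant_set"))
  allowed <- toupper(allowed)
  bad <- setdiff(allowed, IMPACT_LEVELS)
  if (length(bad)) stop("unknown impact class(es): ", paste(bad, collapse = ", "))
  imp <- vs$variants$impact
  keep <- !is.na(imp) & imp %in% allowed
  out <- subset_variants(vs, keep)
  attr(out, "n_unannotated") <- sum(is.na(imp))
  out
}

#' Run the full variant-filtering cascade for one scenario
#'
#' Applies, in order: (1) trio genotype-pattern filter; (2) impact filter;
#' (3) local-cohort exclusion; (4) global-cohort exclusion, using the
#' scenario's control policy for both cohorts. Per-step in/out counts are
#' recorded so the cascade can be audited step by step.
#'
#' @param vs A [variant_set()].
#' @param local_catalog,global_catalog [cohort_catalog()] objects (either may
#'   be `NULL` to skip that step).
#' @param scenario A [scenario_spec()] or its name.
#' @param impact_allowed Impact classes kept by the impact step.
#' @return A list of class `filter_report` with elements `scenario`, `steps`
#'   (data frame: `step`, `scenario`, `variants_in`, `variants_out`) and
#'   `candidates` (surviving `variant_set`, with a `manual_review` column
#'   initialised to `"not_reviewed"`).
#' @export
run_cascade <- function(vs, local_catalog = NULL, global_catalog = NULL,
                        scenario = "RECESSIVE_HOMOZYGOUS",
                        impact_allowed = c("MODERATE", "HIGH")) {
  stopifnot(inherits(vs, "variant_set"))
  scenario <- as_scenario(scenario)
  steps <- list()
  cur <- vs

  advance <- function(step_name, nxt) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step_name, scenario = scenario$name,
      variants_in = n_variants(cur), variants_out = n_variants(nxt),
      stringsAsFactors = FALSE)
    cur <<- nxt
  }
  advance("genotype_pattern", genotype_pattern_filter(cur, scenario))
  advance("impact", impact_filter(cur, impact_allowed))
  if (!is.null(local_catalog)) {
    advance("local_cohort",
            cohort_exclusion_filter(cur, local_catalog, scenario$control_policy))
  }
  if (!is.null(global_catalog)) {
    advance("global_cohort",
            cohort_exclusion_filter(cur, global_catalog, scenario$control_policy))
  }
  candidates <- cur
  candidates$variants$manual_review <- rep("not_reviewed",
                                           n_variants(candidates))
  structure(list(scenario = scenario$name,
                 steps = do.call(rbind, steps),
                 candidates = candidates),
            class = "filter_report")
}

#' @method print filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report [", x$scenario, "]\n", sep = "")
  print.data.frame(x$steps, row.names = FALSE)
  cat("final candidates:", n_variants(x$candidates), "\n")
  invisible(x)
}

#' Flag candidates contained in shared IBD regions
#'
#' @param candidates A `variant_set` or variant data frame (needs `chrom`,
#'   `pos`).
#' @param regions Data frame of shared IBD regions with columns `chrom`,
#'   `start`, `end` and `region_id` (see [shared_regions()]).
#' @return The candidate variant data frame with an `ibd_region` column
#'   (region id, or `NA` when no region contains the candidate).
#' @export
candidate_region_check <- function(candidates, regions) {
  df <- if (inherits(candidates, "variant_set")) candidates$variants else candidates
  df$ibd_region <- NA_character_
  if (!nrow(df) || is.null(regions) || !nrow(regions)) return(df)
  if (is.null(regions$region_id)) {
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom,
                                 regions$start, regions$end)
  }
  for (i in seq_len(nrow(df))) {
    hit <- which(regions$chrom == df$chrom[i] &
                   regions$start <= df$pos[i] & df$pos[i] <= regions$end)
    if (length(hit)) df$ibd_region[i] <- regions$region_id[hit[1]]
  }
  df
}

#' Write a filter report as TSV and JSON
#'
#' @param report A `filter_report`.
#' @param prefix Output path prefix; writes `<prefix>_steps.tsv`,
#'   `<prefix>_candidates.tsv` and `<prefix>.json`.
#' @return The written paths, invisibly.
#' @export
write_filter_report <- function(report, prefix) {
  stopifnot(inherits(report, "filter_report"))
  p1 <- paste0(prefix, "_steps.tsv")
  p2 <- paste0(prefix, "_candidates.tsv")
  p3 <- paste0(prefix, ".json")
  utils::write.table(report$steps, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_variant_table(report$candidates, p2)
  jsonlite::write_json(
    list(scenario = report$scenario, steps = report$steps,
         candidates = report$candidates$variants),
    p3, dataframe = "rows", auto_unbox = TRUE, na = "null")
  invisible(c(p1, p2, p3))
}
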