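# Orchestration: load inputs, run both filtering scenarios, ROH/IBD mapping,
# depth screen and segregation analysis, and emit TSV + JSON reports.

#' Read a run configuration file
#'
#' JSON (always) or YAML (when the `yaml` package is installed), holding the
#' fields documented in [run_full_analysis()].
#'
#' @param path Path to the configuration file.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("id", "role")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("pedigree lacks column(s): ", paste(miss, collapse = ", "))
  ped
}

#' Run the full trio variant-prioritization analysis
#'
#' Loads a multi-sample VCF and pedigree, runs the filtering cascade for each
#' configured inheritance scenario, maps shared IBD regions across the cases,
#' flags candidates by containing region, screens binned read depth, and (if
#' a screening table is configured) runs the segregation analysis. All
#' outputs are written as TSV plus a machine-readable JSON bundle; the run is
#' deterministic for identical inputs.
#'
#' @param config A configuration list or path to a JSON/YAML file with
#'   fields: `vcf`, `pedigree` (paths); optional `local_catalog`,
#'   `global_catalog`, `depth` (named list/vector of per-sample depth TSVs),
#'   `screening` (genotype TSV with `affected` and `year` columns plus
#'   `locus_*` genotype columns); `scenarios` (default both); `roh` (list of
#'   [roh_params()] overrides); `depth_thresholds` (`loss`, `gain`);
#'   `impact_allowed`; `pass_only`; `out_dir`.
#' @return A list of class `trioscan_run` with elements `reports` (one
#'   [run_cascade()] report per scenario), `candidates` (region-annotated
#'   candidate tables), `regions`, `region_summary`, `depth_summaries`,
#'   `segregation`, and `out_dir`; written files under `out_dir`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$vcf) || is.null(config$pedigree)) {
    stop("config must provide 'vcf' and 'pedigree' paths")
  }
  scenarios <- config$scenarios %||%
    c("RECESSIVE_HOMOZYGOUS", "PATERNAL_GERMLINE_DENOVO")
  if (!length(scenarios)) stop("no scenario configured")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ped <- read_pedigree(config$pedigree)
  roles <- stats::setNames(ped$role, ped$id)
  message("reading VCF: ", config$vcf)
  vs <- read_vcf(config$vcf, roles, pass_only = isTRUE(config$pass_only))
  message(n_variants(vs), " biallelic records, ", nrow(vs$samples), " samples")

  local_catalog <- if (!is.null(config$local_catalog)) {
    read_cohort_catalog(config$local_catalog)
  } else if (any(vs$samples$role == "LOCAL_CONTROL")) {
    count_cohort(vs)
  } else NULL
  global_catalog <- if (!is.null(config$global_catalog)) {
    read_cohort_catalog(config$global_catalog)
  } else NULL

  rp <- do.call(roh_params, config$roh %||% list())
  regions <- shared_regions(vs, rp)
  region_summary <- summarize_regions(regions)
  message(sprintf("shared IBD regions: %d (max %.1f kb on %d chromosome(s))",
                  region_summary$n_regions,
                  region_summary$max_length_bp / 1000,
                  region_summary$n_chroms))
  write_segments(regions, file.path(out_dir, "shared_regions.tsv"))

  impact_allowed <- config$impact_allowed %||% c("MODERATE", "HIGH")
  reports <- list()
  candidates <- list()
  for (sc in scenarios) {
    rep <- run_cascade(vs, local_catalog, global_catalog, sc,
                       impact_allowed = impact_allowed)
    message("cascade [", sc, "]: ",
            paste(sprintf("%s %d->%d", rep$steps$step, rep$steps$variants_in,
                          rep$steps$variants_out), collapse = "; "))
    cand <- candidate_region_check(rep$candidates, regions)
    write_filter_report(rep, file.path(out_dir, paste0("cascade_", tolower(sc))))
    utils::write.table(cand,
                       file.path(out_dir, paste0("candidates_", tolower(sc), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    reports[[sc]] <- rep
    candidates[[sc]] <- cand
  }

  thr <- config$depth_thresholds %||% list(loss = 0.75, gain = 1.25)
  depth_summaries <- list()
  if (!is.null(config$depth)) {
    for (id in names(config$depth)) {
      prof <- normalize_depth(read_depth_profile(config$depth[[id]], id))
      depth_summaries[[id]] <- flag_regions(prof, regions,
                                            loss_threshold = thr$loss,
                                            gain_threshold = thr$gain)
    }
    depth_tab <- do.call(rbind, lapply(depth_summaries, function(s)
      cbind(sample_id = s$sample_id, s$chromosomes)))
    utils::write.table(depth_tab, file.path(out_dir, "depth_chromosomes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  segregation <- NULL
  if (!is.null(config$screening)) {
    scr <- utils::read.delim(config$screening, stringsAsFactors = FALSE)
    segregation <- segregation_report(scr)
    utils::write.table(segregation$frequencies,
                       file.path(out_dir, "segregation_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  bundle <- list(
    region_summary = region_summary,
    steps = do.call(rbind, lapply(reports, `[[`, "steps")),
    candidates = candidates,
    segregation = if (!is.null(segregation)) segregation$frequencies)
  jsonlite::write_json(bundle, file.path(out_dir, "run_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, na = "null",
                       digits = NA)
  structure(list(reports = reports, candidates = candidates,
                 regions = regions, region_summary = region_summary,
                 depth_summaries = depth_summaries,
                 segregation = segregation, out_dir = out_dir),
            class = "trioscan_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segregation report over a screening genotype table
#'
#' @param screening Data frame with `affected`, optional `year`/`cohort`
#'   columns and one or more `locus_*` genotype columns (alt dosage).
#' @return List with `frequencies` (per-locus allele-frequency table),
#'   `prevalence` (per-locus, per-year carrier prevalence, when `year`
#'   present) and `digenic` (a [digenic_cosegregation()] verdict over the
#'   first two loci, when at least two are present).
#' @export
segregation_report <- function(screening) {
  loci <- grep("^locus_", names(screening), value = TRUE)
  if (!length(loci)) stop("screening table has no locus_* genotype columns")
  freq <- do.call(rbind, lapply(loci, function(lc) {
    cnt <- count_genotypes(screening[[lc]])
    af <- allele_frequency(cnt)
    data.frame(locus = sub("^locus_", "", lc),
               n = cnt$n, n_ref_ref = cnt$n_ref_ref,
               n_ref_var = cnt$n_ref_var, n_var_var = cnt$n_var_var,
               q_hat = af$q_hat, ci_lower = af$ci95[["lower"]],
               ci_upper = af$ci95[["upper"]],
               percent_rounded = af$percent_rounded,
               stringsAsFactors = FALSE)
  }))
  prevalence <- NULL
  if (!is.null(screening$year)) {
    prevalence <- do.call(rbind, lapply(loci, function(lc)
      cbind(locus = sub("^locus_", "", lc),
            carrier_prevalence_by_group(screening[[lc]], screening$year))))
  }
  digenic <- NULL
  if (length(loci) >= 2) {
    aff <- if (!is.null(screening$affected)) screening$affected else FALSE
    digenic <- digenic_cosegregation(screening[[loci[1]]],
                                     screening[[loci[2]]], aff)
  }
  list(frequencies = freq, prevalence = prevalence, digenic = digenic)
}
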