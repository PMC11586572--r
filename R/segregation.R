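# Population segregation analysis: genotype counting, allele-frequency
# estimation, carrier prevalence by group, and digenic co-segregation.

#' Count genotype classes per cohort at one locus
#'
#' @param genotype Alt dosages in \{0,1,2,NA\} (NA = missing / not genotyped).
#' @param cohort Cohort label per individual (single label recycled, or a
#'   vector the same length as `genotype`).
#' @return Data frame of class `genotype_count_table`: one row per cohort
#'   with `n_ref_ref`, `n_ref_var`, `n_var_var`, `n_missing` and `n`
#'   (genotyped individuals, missing excluded).
#' @examples
#' count_genotypes(c(0, 1, 2), "cohort_a")
#' @export
count_genotypes <- function(genotype, cohort = "all") {
  genotype <- as.integer(genotype)
  if (length(cohort) == 1L) {
    levels <- cohort  # an empty cohort still gets its zero-count row
    cohort <- rep(cohort, length(genotype))
  } else {
    stopifnot(length(cohort) == length(genotype))
    levels <- unique(cohort)
  }
  if (any(!is.na(genotype) & !(genotype %in% 0:2))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  rows <- lapply(levels, function(co) {
    g <- genotype[cohort == co]
    data.frame(cohort = co,
               n_ref_ref = sum(g == 0L, na.rm = TRUE),
               n_ref_var = sum(g == 1L, na.rm = TRUE),
               n_var_var = sum(g == 2L, na.rm = TRUE),
               n_missing = sum(is.na(g)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n <- out$n_ref_ref + out$n_ref_var + out$n_var_var
  class(out) <- c("genotype_count_table", "data.frame")
  out
}

#' Allele-frequency estimate with Wilson 95% interval
#'
#' The variant-allele frequency is `(n_ref_var + 2 n_var_var) / (2N)` over
#' the `2N` genotyped alleles; the confidence interval is the Wilson score
#' interval on the allele trials (preferred over the Wald interval for the
#' small counts typical of carrier screens). The original report style is an
#' integer-rounded percentage, returned as `percent_rounded`.
#'
#' @param n_ref_ref,n_ref_var,n_var_var Genotype-class counts. Alternatively
#'   pass a single-row [count_genotypes()] table as `n_ref_ref`.
#' @return A list of class `allele_frequency`: `q_hat`, `n_alleles`, `ci95`
#'   (lower/upper), `percent_rounded`.
#' @examples
#' allele_frequency(296, 32, 1)  # q ~ 0.0517 -> 5%
#' @export
allele_frequency <- function(n_ref_ref, n_ref_var = NULL, n_var_var = NULL) {
  if (is.data.frame(n_ref_ref)) {
    tab <- n_ref_ref
    stopifnot(nrow(tab) == 1L)
    n_ref_var <- tab$n_ref_var; n_var_var <- tab$n_var_var
    n_ref_ref <- tab$n_ref_ref
  }
  stopifnot(n_ref_ref >= 0, n_ref_var >= 0, n_var_var >= 0)
  n <- n_ref_ref + n_ref_var + n_var_var
  if (n < 1) stop("no genotyped individuals; cannot estimate allele frequency")
  n_alleles <- 2L * as.integer(n)
  n_alt <- n_ref_var + 2L * n_var_var
  q_hat <- n_alt / n_alleles
  ci <- wilson_interval(n_alt, n_alleles)
  structure(list(q_hat = q_hat, n_alleles = n_alleles,
                 ci95 = c(lower = ci[1], upper = ci[2]),
                 percent_rounded = as.integer(round(100 * q_hat))),
            class = "allele_frequency")
}

# Wilson score interval = prop.test without continuity correction (the
# chi-square approximation warning concerns the test, not the interval).
wilson_interval <- function(x, n, conf_level = 0.95) {
  ci <- suppressWarnings(stats::prop.test(x, n, correct = FALSE,
                                          conf.level = conf_level)$conf.int)
  if (x == 0L) ci[1] <- 0
  if (x == n) ci[2] <- 1
  as.numeric(ci)
}

#' @method print allele_frequency
#' @export
print.allele_frequency <- function(x, ...) {
  cat(sprintf("q = %.4f (%d alleles), 95%% CI [%.4f, %.4f], ~%d%%\n",
              x$q_hat, x$n_alleles, x$ci95[1], x$ci95[2], x$percent_rounded))
  invisible(x)
}

#' Digenic co-segregation of two loci
#'
#' Tabulates the 3x3 joint genotype classes of two loci over dually genotyped
#' individuals and issues consistency verdicts:
#' \itemize{
#'   \item `digenic_consistent`: every affected individual is var/var at both
#'     loci AND no unaffected individual is var/var at both.
#'   \item `monogenic_a_inconsistent` / `monogenic_b_inconsistent`: some
#'     unaffected individual is var/var at locus A (resp. B), arguing against
#'     that locus acting alone as a fully penetrant recessive.
#'   \item `uninformative`: all dually genotyped individuals are ref/ref.
#' }
#'
#' @param geno_a,geno_b Alt dosages at the two loci (same individuals).
#' @param affected Logical vector of affection status.
#' @return A list of class `digenic_table`: `table` (3x3 counts over dually
#'   genotyped individuals), `n` (dually genotyped), verdict flags as above,
#'   and `verdicts` (character vector of the labels that apply).
#' @export
digenic_cosegregation <- function(geno_a, geno_b, affected) {
  stopifnot(length(geno_a) == length(geno_b),
            length(geno_a) == length(affected))
  geno_a <- as.integer(geno_a); geno_b <- as.integer(geno_b)
  ok <- !is.na(geno_a) & !is.na(geno_b)
  ga <- geno_a[ok]; gb <- geno_b[ok]; aff <- as.logical(affected)[ok]
  lab <- c("ref/ref", "ref/var", "var/var")
  tab <- table(factor(lab[ga + 1L], levels = lab),
               factor(lab[gb + 1L], levels = lab), dnn = c("locus_a", "locus_b"))
  aff_both <- aff & ga == 2L & gb == 2L
  digenic_consistent <- all(aff_both[aff]) && !any(!aff & ga == 2L & gb == 2L)
  mono_a <- any(!aff & ga == 2L)
  mono_b <- any(!aff & gb == 2L)
  uninformative <- all(ga == 0L & gb == 0L)
  verdicts <- c(
    if (digenic_consistent) "digenic-consistent" else "digenic-inconsistent",
    if (mono_a) "monogenic-A-inconsistent",
    if (mono_b) "monogenic-B-inconsistent",
    if (uninformative) "uninformative")
  structure(list(table = tab, n = sum(ok),
                 digenic_consistent = digenic_consistent,
                 monogenic_a_inconsistent = mono_a,
                 monogenic_b_inconsistent = mono_b,
                 uninformative = uninformative,
                 verdicts = verdicts),
            class = "digenic_table")
}

#' @method print digenic_table
#' @export
print.digenic_table <- function(x, ...) {
  print(x$table)
  cat("verdicts:", paste(x$verdicts, collapse = ", "), "\n")
  invisible(x)
}

#' Carrier prevalence by group
#'
#' Carriers are individuals with at least one variant allele (het or
#' hom-var); typical groups are birth years of a screening program.
#'
#' @param genotype Alt dosages in \{0,1,2,NA\}.
#' @param group Group label per individual.
#' @return Data frame: `group`, `n` (genotyped), `n_carriers`, `fraction`
#'   (`NA` and `flag = "no_data"` when a group has no genotyped individuals).
#' @export
carrier_prevalence_by_group <- function(genotype, group) {
  stopifnot(length(genotype) == length(group))
  genotype <- as.integer(genotype)
  rows <- lapply(unique(group), function(gr) {
    g <- genotype[group == gr]
    n <- sum(!is.na(g))
    carriers <- sum(g >= 1L, na.rm = TRUE)
    data.frame(group = gr, n = n, n_carriers = carriers,
               fraction = if (n) carriers / n else NA_real_,
               flag = if (n) "ok" else "no_data",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
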