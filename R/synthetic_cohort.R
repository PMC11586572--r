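# Seeded generator of a synthetic pedigree cohort with the statistical
# structure the analysis assumes: two affected paternal half-sibs bred from
# one sire and two dams, an ancestral haplotype transmitted through both
# parental lines (forcing homozygosity-by-descent around planted recessive
# variants), a paternal germline variant, Hardy-Weinberg control cohorts,
# a screened-bull genotyping table and binned depth profiles.

#' Configuration for the synthetic pedigree cohort
#'
#' Defaults emulate the study design the package targets: a half-sib trio
#' (two affected calves, two dams, one common sire), a sequenced local
#' control cohort of 942 and a global catalog cohort of 5279, ~10,000
#' biallelic background markers (5 chromosomes x 20 Mb x 100 markers/Mb)
#' with a Beta-distributed allele-frequency spectrum skewed toward rare
#' alleles, a 2 Mb ancestral haplotype around each planted recessive
#' variant, and one digenic pair of recessive variants on different
#' chromosomes plus one paternal germline variant.
#'
#' @param seed Integer seed; fully determines every emitted byte.
#' @param n_chroms,chrom_length_bp Autosome count and length.
#' @param markers_per_mb Background marker density.
#' @param af_beta Shape parameters of the Beta allele-frequency spectrum.
#' @param n_local_controls,n_global_controls Control cohort sizes.
#' @param injections List of planted variants; entries are lists with
#'   `type` (`"RECESSIVE_IBD"`, `"PATERNAL_DENOVO"` or `"DIGENIC_PAIR"`),
#'   `chrom`, `pos` (vectors of length 2 for a digenic pair), `gene`,
#'   `impact`, `carrier_freq_in_controls` (het carrier frequency among local
#'   controls) and `screen_freq` (variant-allele frequency in the screened
#'   male population, recessive types only).
#' @param ancestral_haplotype_kb Length of the planted identical haplotype
#'   around each recessive variant.
#' @param recomb_rate_per_mb Expected crossovers per Mb per meiosis
#'   (default 0.01, i.e. one crossover per 100 Mb).
#' @param missing_rate Per-call missingness applied to local controls.
#' @param impact_probs Named probabilities of background impact classes.
#' @param n_screened,screen_years Size and birth-year labels of the screened
#'   male cohort.
#' @param depth List: `mean` coverage, lognormal `cv`, `bin_kb`, and
#'   `events` (list of `list(type = "trisomy"|"deletion", sample, chrom,
#'   start, end)`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 5L, chrom_length_bp = 2e7,
                       markers_per_mb = 100,
                       af_beta = c(0.3, 3),
                       n_local_controls = 942L, n_global_controls = 5279L,
                       injections = default_injections(),
                       ancestral_haplotype_kb = 2000,
                       recomb_rate_per_mb = 0.01,
                       missing_rate = 0,
                       impact_probs = c(HIGH = 0.005, MODERATE = 0.035,
                                        LOW = 0.16, MODIFIER = 0.80),
                       n_screened = 332L, screen_years = 2017:2020,
                       depth = list(mean = 18.2, cv = 0.1, bin_kb = 10,
                                    events = list())) {
  stopifnot(n_chroms >= 1, chrom_length_bp > 0, markers_per_mb > 0,
            length(af_beta) == 2, all(af_beta > 0),
            n_local_controls >= 1, n_global_controls >= 1,
            ancestral_haplotype_kb > 0, recomb_rate_per_mb >= 0,
            missing_rate >= 0, missing_rate < 1,
            abs(sum(impact_probs) - 1) < 1e-8,
            identical(sort(names(impact_probs)), sort(IMPACT_LEVELS)))
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = chrom_length_bp,
              markers_per_mb = markers_per_mb, af_beta = af_beta,
              n_local_controls = as.integer(n_local_controls),
              n_global_controls = as.integer(n_global_controls),
              injections = injections,
              ancestral_haplotype_kb = ancestral_haplotype_kb,
              recomb_rate_per_mb = recomb_rate_per_mb,
              missing_rate = missing_rate, impact_probs = impact_probs,
              n_screened = as.integer(n_screened),
              screen_years = screen_years, depth = depth)
  cfg$injections <- expand_injections(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_injections <- function() {
  list(
    list(type = "DIGENIC_PAIR", chrom = c("1", "2"), pos = c(1e7, 1e7),
         gene = c("GENE_R1", "GENE_R2"), impact = c("MODERATE", "HIGH"),
         carrier_freq_in_controls = c(0.01, 0.01),
         screen_freq = c(0.05, 0.02)),
    list(type = "PATERNAL_DENOVO", chrom = "3", pos = 1e7,
         gene = "GENE_D1", impact = "MODERATE",
         carrier_freq_in_controls = 0))
}

# Expand DIGENIC_PAIR entries into two linked RECESSIVE_IBD injections and
# validate uniqueness of injection sites.
expand_injections <- function(cfg) {
  out <- list()
  for (inj in cfg$injections) {
    if (identical(inj$type, "DIGENIC_PAIR")) {
      stopifnot(length(inj$chrom) == 2, length(inj$pos) == 2)
      for (k in 1:2) {
        out[[length(out) + 1L]] <- list(
          type = "RECESSIVE_IBD", chrom = as.character(inj$chrom[k]),
          pos = inj$pos[k], gene = inj$gene[k], impact = inj$impact[k],
          carrier_freq_in_controls = inj$carrier_freq_in_controls[k],
          screen_freq = inj$screen_freq[k], digenic = TRUE,
          digenic_member = k)
      }
    } else {
      stopifnot(inj$type %in% c("RECESSIVE_IBD", "PATERNAL_DENOVO"))
      inj$chrom <- as.character(inj$chrom)
      inj$digenic <- isTRUE(inj$digenic)
      out[[length(out) + 1L]] <- inj
    }
  }
  for (inj in out) {
    if (!(inj$chrom %in% as.character(seq_len(cfg$n_chroms))) ||
        inj$pos < 1 || inj$pos > cfg$chrom_length_bp) {
      stop("injection position outside simulated genome: ",
           inj$chrom, ":", inj$pos)
    }
  }
  keys <- vapply(out, function(i) paste0(i$chrom, ":", i$pos), character(1))
  if (anyDuplicated(keys)) stop("duplicate injection site(s): ",
                                paste(keys[duplicated(keys)], collapse = ", "))
  out
}

trio_samples <- function() {
  sample_set(c("case1", "case2", "dam1", "dam2", "sire"),
             c("CASE", "CASE", "DAM", "DAM", "SIRE"))
}

trio_pedigree <- function() {
  data.frame(
    id = c("sire", "dam1", "dam2", "case1", "case2"),
    sire = c(NA, NA, NA, "sire", "sire"),
    dam = c(NA, NA, NA, "dam1", "dam2"),
    sex = c("M", "F", "F", "M", "F"),
    status = c("unaffected", "unaffected", "unaffected",
               "affected", "affected"),
    role = c("SIRE", "DAM", "DAM", "CASE", "CASE"),
    stringsAsFactors = FALSE)
}

# One meiotic gamete over a marker interval: Poisson crossovers at
# rate_per_mb, alternating between the two parental haplotypes; `req_idx`
# marker indices must carry allele 1 in the transmitted gamete (flip the
# phase wholesale if needed, preserving the crossover pattern).
meiosis_gamete <- function(h1, h2, pos, span_bp, rate_per_mb,
                           req_idx = integer(0)) {
  for (attempt in 1:50) {
    ncx <- stats::rpois(1, rate_per_mb * span_bp / 1e6)
    bp <- if (ncx > 0) {
      sort(stats::runif(ncx, min(pos), min(pos) + span_bp))
    } else numeric(0)
    phase <- (findInterval(pos, bp) + sample(0:1, 1)) %% 2
    g <- ifelse(phase == 0, h1, h2)
    if (!length(req_idx) || all(g[req_idx] == 1L)) return(as.integer(g))
    g2 <- ifelse(phase == 1, h1, h2)
    if (all(g2[req_idx] == 1L)) return(as.integer(g2))
  }
  as.integer(h1)
}

# A transmitted gamete: background markers segregate independently per site
# (each marker draws one of the parent's two alleles at random -- marginally
# exact Mendelian transmission, independent across sites and offspring),
# while markers inside each planted ancestral window are transmitted as a
# haplotype block with Poisson crossovers, conditioned to carry the planted
# allele at the injected site. Linkage is thus simulated exactly where it
# carries signal (the IBD windows); elsewhere sites are unlinked.
transmit_gamete <- function(h1, h2, pos, rate_per_mb, windows = list()) {
  pick <- stats::rbinom(length(pos), 1L, 0.5)
  g <- ifelse(pick == 1L, h1, h2)
  for (w in windows) {
    idx <- w$idx
    g[idx] <- meiosis_gamete(h1[idx], h2[idx], pos[idx],
                             span_bp = max(pos[idx]) - min(pos[idx]) + 1,
                             rate_per_mb, req_idx = w$req)
  }
  as.integer(g)
}

#' Simulate the synthetic pedigree cohort
#'
#' Draws founder haplotypes from the configured allele-frequency spectrum,
#' copies a common-ancestor haplotype into one haplotype of the sire and of
#' each dam within a window around every planted recessive variant (so both
#' cases become homozygous-by-descent there and all three parents are
#' carriers), transmits gametes with Poisson recombination, and emits
#' Hardy-Weinberg control cohorts, a screened-male genotype table and binned
#' depth profiles. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `trio_sim` with elements `vs` (a [variant_set()]
#'   holding the trio and the per-sample local controls), `pedigree`,
#'   `local_catalog`, `global_catalog` ([cohort_catalog()]s), `depth` (list
#'   of [depth_profile()]s for the trio), `screening` (screened-male
#'   genotype table), and `truth` (planted injections with their expected
#'   cascade membership and IBD windows, planted depth events, and the
#'   background allele-frequency vector).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- as.character(seq_len(config$n_chroms))
  clen <- config$chrom_length_bp
  half_win <- config$ancestral_haplotype_kb * 1000 / 2
  inj <- config$injections
  inj_by_chrom <- split(inj, vapply(inj, `[[`, "", "chrom"))

  bases <- c("A", "C", "G", "T")
  samples <- trio_samples()
  local_ids <- sprintf("ctrl%03d", seq_len(config$n_local_controls))
  all_samples <- sample_set(c(samples$sample_id, local_ids),
                            c(samples$role, rep("LOCAL_CONTROL",
                                                length(local_ids))))

  marker_list <- list()
  geno_list <- list()
  global_list <- list()
  for (chrom in chroms) {
    n_mk <- round(clen / 1e6 * config$markers_per_mb)
    pos <- sort(sample.int(clen, n_mk))
    cinj <- inj_by_chrom[[chrom]]
    inj_pos <- if (is.null(cinj)) integer(0)
               else vapply(cinj, function(i) as.integer(i$pos), integer(1))
    pos <- sort(unique(c(setdiff(pos, inj_pos), inj_pos)))
    n_mk <- length(pos)
    q <- stats::rbeta(n_mk, config$af_beta[1], config$af_beta[2])
    ref <- sample(bases, n_mk, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    impact <- sample(names(config$impact_probs), n_mk, replace = TRUE,
                     prob = config$impact_probs)
    gene <- sprintf("G%s_%05d", chrom, seq_len(n_mk))
    inj_idx <- match(inj_pos, pos)
    inj_type <- rep(NA_character_, n_mk)
    if (length(inj_idx)) {
      for (k in seq_along(inj_idx)) {
        i <- inj_idx[k]
        inj_type[i] <- cinj[[k]]$type
        impact[i] <- cinj[[k]]$impact
        gene[i] <- cinj[[k]]$gene
        # injected allele frequencies are governed by the cohort knobs, not
        # by the background spectrum
        q[i] <- 0
      }
    }

    # founder haplotypes: sire (2), dam1 (2), dam2 (2)
    H <- matrix(stats::rbinom(6L * n_mk, 1L, rep(q, 6L)), nrow = n_mk, ncol = 6L)
    colnames(H) <- c("s1", "s2", "d1a", "d1b", "d2a", "d2b")
    in_ibd_window <- rep(FALSE, n_mk)
    denovo_idx <- integer(0)  # sites forced into both paternal gametes
    rec_windows <- list()     # haplotype-block transmission intervals
    windows <- list()
    if (length(inj_idx)) {
      for (k in seq_along(inj_idx)) {
        i <- inj_idx[k]
        if (cinj[[k]]$type == "RECESSIVE_IBD") {
          w <- which(pos >= pos[i] - half_win & pos <= pos[i] + half_win)
          anc <- stats::rbinom(length(w), 1L, q[w])
          anc[w == i] <- 1L
          # one haplotype of each parent carries the ancestral segment
          H[w, "s1"] <- anc; H[w, "d1a"] <- anc; H[w, "d2a"] <- anc
          H[i, c("s2", "d1b", "d2b")] <- 0L
          in_ibd_window[w] <- TRUE
          rec_windows[[length(rec_windows) + 1L]] <-
            list(idx = w, req = match(i, w))
          windows[[length(windows) + 1L]] <-
            data.frame(chrom = chrom, pos = pos[i],
                       window_start = max(1, pos[i] - half_win),
                       window_end = min(clen, pos[i] + half_win))
        } else { # PATERNAL_DENOVO: germline het in the sire only
          H[i, ] <- 0L
          H[i, "s1"] <- 1L
          denovo_idx <- c(denovo_idx, i)
        }
      }
    }

    rate <- config$recomb_rate_per_mb
    pat1 <- transmit_gamete(H[, "s1"], H[, "s2"], pos, rate, rec_windows)
    pat2 <- transmit_gamete(H[, "s1"], H[, "s2"], pos, rate, rec_windows)
    mat1 <- transmit_gamete(H[, "d1a"], H[, "d1b"], pos, rate, rec_windows)
    mat2 <- transmit_gamete(H[, "d2a"], H[, "d2b"], pos, rate, rec_windows)
    # the germline variant rides in every sperm-derived gamete by design
    pat1[denovo_idx] <- H[denovo_idx, "s1"]
    pat2[denovo_idx] <- H[denovo_idx, "s1"]

    trio_geno <- cbind(case1 = pat1 + mat1, case2 = pat2 + mat2,
                       dam1 = H[, "d1a"] + H[, "d1b"],
                       dam2 = H[, "d2a"] + H[, "d2b"],
                       sire = H[, "s1"] + H[, "s2"])

    ctrl <- matrix(stats::rbinom(n_mk * config$n_local_controls, 2L,
                                 rep(q, config$n_local_controls)),
                   nrow = n_mk)
    n_vv <- stats::rbinom(n_mk, config$n_global_controls, q^2)
    p_het_rem <- ifelse(q < 1, 2 * q * (1 - q) / (1 - q^2), 1)
    n_rv <- stats::rbinom(n_mk, config$n_global_controls - n_vv, p_het_rem)
    if (length(inj_idx)) {
      for (k in seq_along(inj_idx)) {
        i <- inj_idx[k]
        cf <- cinj[[k]]$carrier_freq_in_controls
        ctrl[i, ] <- stats::rbinom(config$n_local_controls, 1L, cf)
        n_vv[i] <- 0L
        n_rv[i] <- 0L
      }
    }
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(length(ctrl)) < config$missing_rate,
                     nrow = n_mk)
      ctrl[drop] <- NA_integer_
    }

    marker_list[[chrom]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      impact = impact, q = q, injection = inj_type,
      in_ibd_window = in_ibd_window, stringsAsFactors = FALSE)
    geno_list[[chrom]] <- cbind(trio_geno, ctrl)
    global_list[[chrom]] <- data.frame(
      n_hom_ref = config$n_global_controls - n_rv - n_vv,
      n_het = n_rv, n_hom_alt = n_vv)
    if (length(windows)) {
      attr(marker_list[[chrom]], "windows") <- do.call(rbind, windows)
    }
  }

  markers <- do.call(rbind, marker_list)
  rownames(markers) <- NULL
  geno <- do.call(rbind, geno_list)
  colnames(geno) <- all_samples$sample_id
  vs <- variant_set(markers[, c("chrom", "pos", "ref", "alt", "gene", "impact")],
                    geno, all_samples)
  global_catalog <- cohort_catalog(cbind(
    markers[, c("chrom", "pos", "ref", "alt")],
    do.call(rbind, global_list),
    n_missing = 0L))
  local_catalog <- count_cohort(vs)

  ibd_windows <- do.call(rbind, c(list(
    data.frame(chrom = character(), pos = numeric(), window_start = numeric(),
               window_end = numeric())),
    lapply(marker_list, attr, "windows")))
  rownames(ibd_windows) <- NULL

  screening <- simulate_screening(config)
  depth <- simulate_trio_depth(config)

  inj_keys <- vapply(inj, function(i) {
    r <- which(markers$chrom == i$chrom & markers$pos == i$pos)
    variant_keys_df(markers[r, , drop = FALSE])
  }, character(1))
  truth <- list(
    injections = data.frame(
      key = inj_keys,
      type = vapply(inj, `[[`, "", "type"),
      chrom = vapply(inj, `[[`, "", "chrom"),
      pos = vapply(inj, function(i) as.numeric(i$pos), numeric(1)),
      gene = vapply(inj, `[[`, "", "gene"),
      expected_scenario = ifelse(
        vapply(inj, `[[`, "", "type") == "RECESSIVE_IBD",
        "RECESSIVE_HOMOZYGOUS", "PATERNAL_GERMLINE_DENOVO"),
      stringsAsFactors = FALSE),
    ibd_windows = ibd_windows,
    depth_events = config$depth$events,
    markers = markers,
    seed = config$seed)

  structure(list(vs = vs, pedigree = trio_pedigree(),
                 local_catalog = local_catalog,
                 global_catalog = global_catalog,
                 depth = depth, screening = screening, truth = truth,
                 config = config),
            class = "trio_sim")
}

# Screened-male genotype table at the planted recessive loci; the first
# screened individual of a digenic pair is hom-alt at the first member and
# hom-ref at the second (the discordant top-sire configuration).
simulate_screening <- function(config) {
  rec <- Filter(function(i) i$type == "RECESSIVE_IBD", config$injections)
  n <- config$n_screened
  out <- data.frame(
    sample = sprintf("bull%03d", seq_len(n)),
    year = rep(config$screen_years, length.out = n),
    affected = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(rec)) {
    qs <- rec[[k]]$screen_freq
    if (is.null(qs)) qs <- 0
    g <- stats::rbinom(n, 2L, qs)
    if (isTRUE(rec[[k]]$digenic)) {
      g[1] <- if (rec[[k]]$digenic_member == 1L) 2L else 0L
    }
    out[[paste0("locus_", rec[[k]]$gene)]] <- g
  }
  out
}

#' Simulate one binned depth profile
#'
#' Bin depths are `mean * copy_ratio * lognormal(cv)` with unit-mean
#' lognormal noise; planted events multiply the copy ratio (trisomy: 1.5
#' over a whole chromosome; deletion: 0.5 over an interval). Uses the
#' current RNG state (seed at the caller).
#'
#' @param chroms Chromosome names.
#' @param chrom_length_bp Chromosome length.
#' @param bin_kb Bin width in kb.
#' @param mean_depth Diploid mean coverage.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param events List of `list(type, chrom, start, end)` events for this
#'   sample.
#' @param sample_id Sample label.
#' @return A [depth_profile()].
#' @export
sim_depth_profile <- function(chroms, chrom_length_bp, bin_kb = 10,
                              mean_depth = 18.2, cv = 0.1, events = list(),
                              sample_id = "sample") {
  bw <- bin_kb * 1000
  rows <- lapply(chroms, function(ch) {
    starts <- seq(1, chrom_length_bp, by = bw)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bw - 1, chrom_length_bp),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  ratio <- rep(1, nrow(bins))
  for (ev in events) {
    if (ev$type == "trisomy") {
      ratio[bins$chrom == ev$chrom] <- 1.5
    } else if (ev$type == "deletion") {
      hit <- bins$chrom == ev$chrom & bins$end >= ev$start &
        bins$start <= ev$end
      ratio[hit] <- 0.5
    } else stop("unknown depth event type: ", ev$type)
  }
  s <- sqrt(log(1 + cv^2))
  noise <- stats::rlnorm(nrow(bins), meanlog = -s^2 / 2, sdlog = s)
  bins$mean_depth <- mean_depth * ratio * noise
  depth_profile(bins, sample_id)
}

simulate_trio_depth <- function(config) {
  chroms <- as.character(seq_len(config$n_chroms))
  ids <- trio_samples()$sample_id
  out <- lapply(ids, function(id) {
    evs <- Filter(function(e) is.null(e$sample) || e$sample == id,
                  config$depth$events)
    sim_depth_profile(chroms, config$chrom_length_bp, config$depth$bin_kb,
                      config$depth$mean, config$depth$cv, evs, id)
  })
  names(out) <- ids
  out
}

#' Write the simulated cohort to disk
#'
#' Emits `cohort.vcf` (trio plus local controls, snpEff-style ANN
#' annotation), `pedigree.tsv`, `local_catalog.tsv`, `global_catalog.tsv`,
#' `depth_<sample>.tsv` per trio sample, `screening.tsv` and `truth.json`.
#'
#' @param sim A `trio_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"))
  write_vcf(sim$vs, paths["vcf"],
            contig_lengths = stats::setNames(
              rep(sim$config$chrom_length_bp, sim$config$n_chroms),
              as.character(seq_len(sim$config$n_chroms))))
  paths["pedigree"] <- file.path(dir, "pedigree.tsv")
  utils::write.table(sim$pedigree, paths["pedigree"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  paths["local_catalog"] <- file.path(dir, "local_catalog.tsv")
  write_cohort_catalog(sim$local_catalog, paths["local_catalog"])
  paths["global_catalog"] <- file.path(dir, "global_catalog.tsv")
  write_cohort_catalog(sim$global_catalog, paths["global_catalog"])
  for (id in names(sim$depth)) {
    p <- file.path(dir, paste0("depth_", id, ".tsv"))
    utils::write.table(as.data.frame(sim$depth[[id]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[paste0("depth_", id)] <- p
  }
  paths["screening"] <- file.path(dir, "screening.tsv")
  utils::write.table(sim$screening, paths["screening"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(injections = sim$truth$injections,
         ibd_windows = sim$truth$ibd_windows,
         depth_events = sim$truth$depth_events,
         seed = sim$truth$seed),
    paths["truth"], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a variant_set as a VCF 4.2 file
#'
#' Genotypes are written unphased (`0/0`, `0/1`, `1/1`, `./.`); gene/impact
#' annotation is carried in a snpEff-style `ANN` INFO field so that
#' [read_vcf()] round-trips it.
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, contig_lengths = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  chroms <- unique(v$chrom)
  hdr <- c("##fileformat=VCFv4.2", "##source=trioscan")
  for (ch in chroms) {
    len <- if (!is.null(contig_lengths) && ch %in% names(contig_lengths)) {
      sprintf(",length=%d", as.integer(contig_lengths[[ch]]))
    } else ""
    hdr <- c(hdr, sprintf("##contig=<ID=%s%s>", ch, len))
  }
  hdr <- c(hdr,
           paste0("##INFO=<ID=ANN,Number=.,Type=String,",
                  "Description=\"Functional annotations: ",
                  "'Allele | Annotation | Annotation_Impact | Gene_Name'\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples$sample_id), collapse = "\t"))
  gt_lookup <- c("0/0", "0/1", "1/1")
  g <- vs$geno
  gt <- matrix("./.", nrow(g), ncol(g))
  known <- !is.na(g)
  gt[known] <- gt_lookup[g[known] + 1L]
  info <- ifelse(is.na(v$impact), ".",
                 sprintf("ANN=%s|custom|%s|%s", v$alt, v$impact,
                         ifelse(is.na(v$gene), "", v$gene)))
  left <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s\tGT",
                  v$chrom, v$pos, v$ref, v$alt, info)
  body <- if (nrow(g)) {
    paste(left, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Deterministic genotyping fixture mirroring a published carrier screen
#'
#' Builds, without randomness, a genotype table for two recessive candidate
#' loci (a missense variant in *TGDS* and a splice-site variant in *LAMA4*)
#' with the cohort genotype-class counts of the original carrier screen:
#' affected calves var/var at both loci; three obligate-carrier parents het
#' at both; 332 screened bulls with counts (296, 32, 1) at the TGDS locus
#' (3 failed calls) and (321, 11, 0) at the LAMA4 locus, including one bull
#' hom-var at TGDS but hom-ref at LAMA4; plus an external control catalog
#' with counts (5279, 0, 0) and (5278, 1, 0).
#'
#' @return A list with `genotypes` (per-individual table: `sample`,
#'   `cohort`, `affected`, `year`, `TGDS`, `LAMA4`), `external_counts`
#'   (per-locus genotype-class counts of the external control cohort) and
#'   `trio_vs` (a [variant_set()] of the two loci over the trio, for
#'   end-to-end pattern-filter tests).
#' @export
emit_table2_fixture <- function() {
  n_bulls <- 332L
  tgds <- c(rep(0L, 296), rep(1L, 32), 2L, rep(NA_integer_, 3))
  lama4 <- c(rep(1L, 11), rep(0L, n_bulls - 11L))
  # the hom-var TGDS bull (index 329) is hom-ref at LAMA4 by construction
  stopifnot(lama4[329] == 0L)
  bulls <- data.frame(
    sample = sprintf("bull%03d", seq_len(n_bulls)),
    cohort = "screened_bull", affected = FALSE,
    year = rep(2017:2020, length.out = n_bulls),
    TGDS = tgds, LAMA4 = lama4, stringsAsFactors = FALSE)
  trio <- data.frame(
    sample = c("case1", "case2", "sire", "dam1", "dam2"),
    cohort = c("affected", "affected", "obligate_carrier",
               "obligate_carrier", "obligate_carrier"),
    affected = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    year = NA_integer_,
    TGDS = c(2L, 2L, 1L, 1L, 1L), LAMA4 = c(2L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  genotypes <- rbind(trio, bulls)

  external_counts <- data.frame(
    locus = c("TGDS", "LAMA4"),
    n_ref_ref = c(5279L, 5278L), n_ref_var = c(0L, 1L),
    n_var_var = c(0L, 0L), stringsAsFactors = FALSE)

  variants <- data.frame(
    chrom = c("12", "9"), pos = c(69092831L, 38176716L),
    ref = c("A", "GAGAAAGTGAGAGAGGGAAACAGAGGGGAGAGAGAA"),
    alt = c("T", "G"), gene = c("TGDS", "LAMA4"),
    impact = c("MODERATE", "HIGH"), stringsAsFactors = FALSE)
  geno <- rbind(c(case1 = 2L, case2 = 2L, dam1 = 1L, dam2 = 1L, sire = 1L),
                c(case1 = 2L, case2 = 2L, dam1 = 1L, dam2 = 1L, sire = 1L))
  trio_vs <- variant_set(variants, geno, trio_samples())

  list(genotypes = genotypes, external_counts = external_counts,
       trio_vs = trio_vs)
}
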