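# Synthetic targeted-panel cohort generator.
#
# Emulates the statistical structure the downstream analyses assume:
# anatomic-site membership with site-dependent per-gene mutation
# probabilities, MSI-H prevalence differing by site, pileup depth /
# allele-fraction structure with sequencing-error alt reads, MSS vs MSI-H
# microsatellite read-length histograms, and group differences in
# mutational burden. Every draw is reproducible from one base seed;
# per-patient sub-seeds are counter-based so enlarging a cohort never
# reshuffles earlier patients.

#' Simulation configuration
#'
#' Defaults mirror a 298-patient small-bowel-cancer cohort: ~90% duodenal
#' primaries and ~10% jejunum/ileum, the published top-ten per-gene
#' mutation frequencies (TP53 53%, KRAS 51%, APC 31%, ...), a low MSI-H
#' prevalence in duodenum versus jejunum/ileum, 500x mean panel depth with
#' 1% per-base error, somatic allele fractions in [0.10, 0.60], and mean
#' eligible-mutation counts that separate MSI-H from MSS burden.
#'
#' @param n_patients Cohort size (default 298).
#' @param site_probs Named probabilities over
#'   `c("duodenum","jejunum","ileum")`, summing to 1.
#' @param gene_mut_probs Matrix of per-gene mutation probabilities, genes
#'   in rows, sites in columns (default [default_gene_site_probs()]).
#' @param msi_h_prob_by_site Named MSI-H prevalence per site.
#' @param mean_depth Mean sequencing depth (reads) for pileups and locus
#'   histograms.
#' @param error_rate Per-base sequencing error rate, in (0, 0.5).
#' @param true_af_range Interval of true somatic allele fractions.
#' @param msi_unstable_locus_fraction Interval for the fraction of panel
#'   loci shifted in an MSI-H sample.
#' @param tmb_rate_by_msi Named mean counts of eligible background
#'   mutations per sample for `"MSI-H"` and `"MSS"`.
#' @param region_size_mb Coding footprint (Mb) of the synthetic panel used
#'   when normalising TMB.
#' @param seed Base seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 298L,
                       site_probs = c(duodenum = 268 / 298,
                                      jejunum = 15 / 298,
                                      ileum = 15 / 298),
                       gene_mut_probs = default_gene_site_probs(),
                       msi_h_prob_by_site = c(duodenum = 0.05,
                                              jejunum = 0.30,
                                              ileum = 0.30),
                       mean_depth = 500,
                       error_rate = 0.01,
                       true_af_range = c(0.10, 0.60),
                       msi_unstable_locus_fraction = c(0.60, 0.90),
                       tmb_rate_by_msi = c("MSI-H" = 50, "MSS" = 8),
                       region_size_mb = 2.2,
                       seed = 1L) {
  cfg <- list(n_patients = n_patients, site_probs = site_probs,
              gene_mut_probs = gene_mut_probs,
              msi_h_prob_by_site = msi_h_prob_by_site,
              mean_depth = mean_depth, error_rate = error_rate,
              true_af_range = true_af_range,
              msi_unstable_locus_fraction = msi_unstable_locus_fraction,
              tmb_rate_by_msi = tmb_rate_by_msi,
              region_size_mb = region_size_mb, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_count(cfg$n_patients, "n_patients", positive = TRUE)
  if (!setequal(names(cfg$site_probs), c("duodenum", "jejunum", "ileum"))) {
    pp_stop("'site_probs' must name duodenum, jejunum, ileum")
  }
  for (p in cfg$site_probs) assert_prob(p, "site_probs")
  if (abs(sum(cfg$site_probs) - 1) > 1e-9) {
    pp_stop("'site_probs' must sum to 1 (got ", sum(cfg$site_probs), ")")
  }
  if (!is.matrix(cfg$gene_mut_probs) ||
      is.null(rownames(cfg$gene_mut_probs)) ||
      !all(colnames(cfg$gene_mut_probs) %in% names(cfg$site_probs))) {
    pp_stop("'gene_mut_probs' must be a gene x site matrix with named dims")
  }
  if (any(cfg$gene_mut_probs < 0) || any(cfg$gene_mut_probs > 1)) {
    pp_stop("'gene_mut_probs' entries must lie in [0, 1]")
  }
  for (s in names(cfg$msi_h_prob_by_site)) {
    assert_prob(cfg$msi_h_prob_by_site[[s]], "msi_h_prob_by_site")
  }
  assert_scalar_number(cfg$mean_depth, "mean_depth")
  if (cfg$mean_depth <= 0) pp_stop("'mean_depth' must be > 0")
  assert_scalar_number(cfg$error_rate, "error_rate")
  if (cfg$error_rate <= 0 || cfg$error_rate >= 0.5) {
    pp_stop("'error_rate' must lie in (0, 0.5)")
  }
  rng <- cfg$true_af_range
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] <= 0 || rng[2] > 1) {
    pp_stop("'true_af_range' must be an interval within (0, 1]")
  }
  rng <- cfg$msi_unstable_locus_fraction
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] <= 0 || rng[2] > 1) {
    pp_stop("'msi_unstable_locus_fraction' must be an interval within (0, 1]")
  }
  if (!all(c("MSI-H", "MSS") %in% names(cfg$tmb_rate_by_msi))) {
    pp_stop("'tmb_rate_by_msi' must name MSI-H and MSS")
  }
  assert_scalar_number(cfg$region_size_mb, "region_size_mb")
  if (cfg$region_size_mb <= 0) pp_stop("'region_size_mb' must be > 0")
  assert_count(cfg$seed, "seed")
  invisible(cfg)
}

#' Default per-gene, per-site mutation probabilities
#'
#' Overall frequencies follow the published top-ten list (TP53 0.53, KRAS
#' 0.51, APC 0.31, SMAD4 0.19, VEGFA/CDKN2A/RAC1 0.15, LRP1B/MGMT 0.14,
#' CD74 0.13) plus a handful of site-discriminating genes. Site structure:
#' APC, LRP1B, PIK3CA, POLE, MSH6 and MTOR are enriched in jejunum/ileum;
#' SMAD4, CDKN2A, VEGFA, CTNNB1 and ERBB2 in duodenum. Per-site values are
#' chosen so the site-weighted marginal equals the overall frequency.
#'
#' @param site_probs Site weights used to preserve the marginal.
#' @return Matrix, genes x sites.
#' @export
default_gene_site_probs <- function(site_probs = c(duodenum = 268 / 298,
                                                   jejunum = 15 / 298,
                                                   ileum = 15 / 298)) {
  overall <- c(TP53 = 0.53, KRAS = 0.51, APC = 0.31, SMAD4 = 0.19,
               VEGFA = 0.15, CDKN2A = 0.15, RAC1 = 0.15, LRP1B = 0.14,
               MGMT = 0.14, CD74 = 0.13, PIK3CA = 0.12, ERBB2 = 0.10,
               FBXW7 = 0.08, KMT2D = 0.08, MSH6 = 0.08, CTNNB1 = 0.07,
               MTOR = 0.06, POLE = 0.05)
  ji_higher <- c("APC", "LRP1B", "PIK3CA", "POLE", "MSH6", "MTOR")
  duo_higher <- c("SMAD4", "CDKN2A", "VEGFA", "CTNNB1", "ERBB2")
  w_ji <- sum(site_probs[c("jejunum", "ileum")])
  w_duo <- site_probs[["duodenum"]]
  m <- matrix(rep(overall, 3), ncol = 3,
              dimnames = list(names(overall),
                              c("duodenum", "jejunum", "ileum")))
  for (g in ji_higher) {
    pj <- min(0.95, 2.5 * overall[[g]])
    m[g, c("jejunum", "ileum")] <- pj
    m[g, "duodenum"] <- max(0, (overall[[g]] - w_ji * pj) / w_duo)
  }
  for (g in duo_higher) {
    pj <- 0.4 * overall[[g]]
    m[g, c("jejunum", "ileum")] <- pj
    m[g, "duodenum"] <- min(1, (overall[[g]] - w_ji * pj) / w_duo)
  }
  m
}

#' Default MSS baseline panel
#'
#' A deterministic 100-locus panel of (cut-point repeat length `cut_point`,
#' baseline beyond-cut-point read fraction `p_i`) pairs spanning cut-points
#' of 10-25 repeat units and baseline rates of roughly 0.5-3%. The baseline
#' is an input to the MSI model (it would come from an MSS reference cohort
#' in practice); this synthetic panel is labelled as such.
#'
#' @param n_loci Panel size (default 100).
#' @return Data frame `locus_id`, `cut_point`, `p_i`.
#' @export
default_baseline_panel <- function(n_loci = 100L) {
  n_loci <- assert_count(n_loci, "n_loci", positive = TRUE)
  i <- seq_len(n_loci)
  data.frame(locus_id = sprintf("MS%03d", i),
             cut_point = as.integer(10 + (i * 7) %% 16),
             p_i = 0.005 + 0.025 * ((i * 37) %% 100) / 99,
             stringsAsFactors = FALSE)
}

# Read-length distribution over cut_point + (-4..3). Under MSS the mass
# beyond the cut-point equals p_i exactly; a shifted (unstable) locus
# carries shift_tail_prob beyond the cut-point instead.
locus_length_probs <- function(cut_point, p_beyond) {
  body <- c(0.05, 0.15, 0.30, 0.30, 0.20) * (1 - p_beyond)
  tail <- c(0.70, 0.20, 0.10) * p_beyond
  list(lengths = (cut_point - 4L):(cut_point + 3L),
       probs = c(body, tail))
}

#' Simulate microsatellite read-length histograms for one sample
#'
#' MSS samples draw each locus's read lengths multinomially from the
#' baseline distribution (expected beyond-cut-point fraction exactly
#' `p_i`). MSI-H samples first pick `round(unstable_fraction * n_loci)`
#' loci and shift them so that `shift_tail_prob` of the read mass falls
#' beyond the cut-point.
#'
#' @param msi_status `"MSI-H"` or `"MSS"`.
#' @param n_loci Number of panel loci to emit (the first `n_loci` rows of
#'   `baseline`); defaults to the whole baseline.
#' @param depth Mean reads per locus (Poisson); must be >= 1.
#' @param baseline Baseline panel (`locus_id`, `cut_point`, `p_i`).
#' @param seed Seed for this sample.
#' @param unstable_fraction Fraction of loci shifted when MSI-H.
#' @param shift_tail_prob Beyond-cut-point read probability at a shifted
#'   locus (default 0.30).
#' @param sample_id Sample identifier written into the output.
#' @return List with `profiles` (long data frame `sample_id`, `locus_id`,
#'   `repeat_length`, `read_count`) and `shifted_loci` (character).
#' @export
simulate_locus_profiles <- function(msi_status = c("MSS", "MSI-H"),
                                    n_loci = NULL, depth = 500,
                                    baseline = default_baseline_panel(),
                                    seed = 1L,
                                    unstable_fraction = 0.75,
                                    shift_tail_prob = 0.30,
                                    sample_id = "S1") {
  msi_status <- match.arg(msi_status)
  depth <- assert_count(depth, "depth", positive = TRUE)
  n_loci <- if (is.null(n_loci)) nrow(baseline) else
    assert_count(n_loci, "n_loci", positive = TRUE)
  if (n_loci > nrow(baseline)) {
    pp_stop("baseline has only ", nrow(baseline), " loci (",
            setdiff(sprintf("MS%03d", seq_len(n_loci)),
                    baseline$locus_id)[1] %||% "", " missing)")
  }
  assert_prob(unstable_fraction, "unstable_fraction")
  assert_prob(shift_tail_prob, "shift_tail_prob")
  panel <- baseline[seq_len(n_loci), , drop = FALSE]
  set.seed(as.integer(seed))
  shifted <- character(0)
  if (msi_status == "MSI-H") {
    n_shift <- round(unstable_fraction * n_loci)
    shifted <- sort(sample(panel$locus_id, n_shift))
  }
  out <- vector("list", n_loci)
  for (j in seq_len(n_loci)) {
    is_shifted <- panel$locus_id[j] %in% shifted
    d <- locus_length_probs(panel$cut_point[j],
                            if (is_shifted) shift_tail_prob else panel$p_i[j])
    n_reads <- stats::rpois(1, depth)
    counts <- if (n_reads > 0) {
      as.integer(stats::rmultinom(1, n_reads, d$probs))
    } else integer(length(d$lengths))
    out[[j]] <- data.frame(sample_id = sample_id,
                           locus_id = panel$locus_id[j],
                           repeat_length = d$lengths,
                           read_count = counts,
                           stringsAsFactors = FALSE)
  }
  list(profiles = do.call(rbind, out), shifted_loci = shifted)
}

#' Simulate pileup records
#'
#' Emits one pileup record per true variant (alt reads binomial at the true
#' allele fraction) plus `n_null_sites` variant-free sites whose alt reads
#' arise purely from sequencing error. Strand counts split the alt reads
#' binomially half/half.
#'
#' @param true_variants Data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `true_af` (may have zero rows).
#' @param mean_depth Mean Poisson depth per site.
#' @param error_rate Per-base error rate in (0, 0.5).
#' @param seed Seed.
#' @param n_null_sites Number of error-only sites appended.
#' @return Pileup data frame (`chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_reads`, `alt_fwd`, `alt_rev`, `mean_bq`).
#' @export
simulate_pileups <- function(true_variants, mean_depth = 500,
                             error_rate = 0.01, seed = 1L,
                             n_null_sites = 0L) {
  assert_scalar_number(error_rate, "error_rate")
  if (error_rate <= 0 || error_rate >= 0.5) {
    pp_stop("'error_rate' must lie in (0, 0.5), got ", error_rate)
  }
  n_null_sites <- assert_count(n_null_sites, "n_null_sites")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  n_var <- if (is.null(true_variants)) 0L else nrow(true_variants)
  n <- n_var + n_null_sites
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_reads = integer(),
                      alt_fwd = integer(), alt_rev = integer(),
                      mean_bq = numeric(), stringsAsFactors = FALSE))
  }
  chrom <- c(if (n_var) as.character(true_variants$chrom),
             rep("chrN", n_null_sites))
  pos <- c(if (n_var) as.integer(true_variants$pos),
           seq_len(n_null_sites) * 101L)
  ref <- c(if (n_var) as.character(true_variants$ref),
           sample(bases, n_null_sites, replace = TRUE))
  p_alt <- c(if (n_var) true_variants$true_af, rep(error_rate, n_null_sites))
  alt <- character(n)
  if (n_var) alt[seq_len(n_var)] <- as.character(true_variants$alt)
  if (n_null_sites) {
    idx <- n_var + seq_len(n_null_sites)
    alt[idx] <- vapply(ref[idx],
                       function(r) sample(setdiff(bases, r), 1), character(1))
  }
  depth <- stats::rpois(n, mean_depth)
  alt_reads <- stats::rbinom(n, depth, p_alt)
  alt_fwd <- stats::rbinom(n, alt_reads, 0.5)
  mean_bq <- round(pmax(2, stats::rnorm(n, 32, 2)), 1)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             depth = depth, alt_reads = alt_reads, alt_fwd = alt_fwd,
             alt_rev = alt_reads - alt_fwd, mean_bq = mean_bq,
             stringsAsFactors = FALSE)
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = alt)
}

# One annotated variant-table block. Classes for SNVs split missense /
# stopgain / silent-etc according to `class_probs`.
draw_variant_rows <- function(patient_id, genes, n_rows, class_probs,
                              af_lo, af_hi, mean_depth, driver_prob,
                              popfreq = 0) {
  if (n_rows == 0) return(NULL)
  classes <- sample(names(class_probs), n_rows, replace = TRUE,
                    prob = class_probs)
  is_indel <- classes %in% c("frameshift_indel", "nonframeshift_indel")
  al <- random_snv_alleles(n_rows)
  true_af <- stats::runif(n_rows, af_lo, af_hi)
  depth <- stats::rpois(n_rows, mean_depth)
  alt_reads <- stats::rbinom(n_rows, depth, true_af)
  data.frame(
    patient_id = patient_id,
    gene = genes,
    chrom = paste0("chr", 1 + (abs(vapply(genes, function(g)
      sum(utf8ToInt(g)), numeric(1))) %% 22)),
    pos = as.integer(1e5 + sample.int(1e7, n_rows, replace = TRUE)),
    ref = ifelse(is_indel, paste0(al$ref, "A"), al$ref),
    alt = ifelse(is_indel, al$ref, al$alt),
    variant_type = ifelse(is_indel, "DEL", "SNV"),
    functional_class = classes,
    af = ifelse(depth > 0, alt_reads / depth, 0),
    depth = depth,
    alt_reads = alt_reads,
    popfreq = popfreq,
    is_driver = stats::runif(n_rows) < driver_prob,
    true_af = true_af,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates patient metadata, an annotated MAF-like variant table, pileup
#' records, microsatellite locus histograms and the ground truth needed to
#' score recovery. Deterministic for a fixed config + seed; patient `i`
#' draws from a counter-based sub-seed so earlier patients are unchanged
#' when `n_patients` grows.
#'
#' @param config A [sim_config()].
#' @param include Character subset of `c("pileups", "profiles")`; trimming
#'   it skips the corresponding (costly) outputs for analyses that only
#'   need metadata and the variant table.
#' @return List of class `"synthetic_cohort"` with elements `patients`,
#'   `maf`, `pileups`, `profiles`, `baseline`, `truth` (per-patient MSI
#'   status, mutated gene set, true variant list with true AFs) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            include = c("pileups", "profiles")) {
  validate_sim_config(config)
  if (length(include) > 0) {
    include <- match.arg(include, c("pileups", "profiles"),
                         several.ok = TRUE)
  }
  baseline <- default_baseline_panel()
  sites <- names(config$site_probs)
  genes <- rownames(config$gene_mut_probs)
  af_lo <- config$true_af_range[1]
  af_hi <- config$true_af_range[2]

  patients <- vector("list", config$n_patients)
  mafs <- vector("list", config$n_patients)
  pileups <- vector("list", config$n_patients)
  profiles <- vector("list", config$n_patients)
  truth_genes <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    seed_i <- sub_seed(config$seed, i)
    set.seed(seed_i)
    pid <- sprintf("P%04d", i)
    site <- sample(sites, 1, prob = config$site_probs)
    sex <- if (stats::runif(1) < 0.6) "male" else "female"
    age <- sample(40:80, 1)
    msi_true <- if (stats::runif(1) < config$msi_h_prob_by_site[[site]])
      "MSI-H" else "MSS"
    mut_genes <- genes[stats::runif(length(genes)) <
                         config$gene_mut_probs[, site]]
    pdl1 <- if (stats::runif(1) < 0.55) 0 else
      round(100 * stats::rbeta(1, 1.2, 3), 1)

    # landscape variants: one per truly mutated gene, reportable classes
    land <- draw_variant_rows(
      pid, mut_genes, length(mut_genes),
      c(missense = 0.70, stopgain = 0.15,
        frameshift_indel = 0.10, nonframeshift_indel = 0.05),
      af_lo, af_hi, config$mean_depth, driver_prob = 0.4)
    # background passenger burden (eligible classes, never drivers)
    n_bg <- stats::rpois(1, config$tmb_rate_by_msi[[msi_true]])
    bg <- draw_variant_rows(
      pid, sprintf("PANEL%03d", sample.int(600, n_bg, replace = TRUE)), n_bg,
      c(missense = 0.45, silent = 0.30, stopgain = 0.08, stoploss = 0.02,
        frameshift_indel = 0.08, nonframeshift_indel = 0.07),
      0.05, 0.40, config$mean_depth, driver_prob = 0)
    # non-coding / other-class rows (never TMB-eligible)
    n_other <- stats::rpois(1, 2)
    oth <- draw_variant_rows(
      pid, sprintf("PANEL%03d", sample.int(600, n_other, replace = TRUE)),
      n_other, c(other = 1), 0.05, 0.40, config$mean_depth, driver_prob = 0)
    # population-frequent (germline-like) rows removed by the popfreq filter
    n_snp <- stats::rpois(1, 1.5)
    snp <- draw_variant_rows(
      pid, sprintf("PANEL%03d", sample.int(600, n_snp, replace = TRUE)),
      n_snp, c(missense = 0.6, silent = 0.4), 0.35, 0.65,
      config$mean_depth, driver_prob = 0,
      popfreq = round(stats::runif(n_snp, 0.02, 0.40), 4))
    maf_i <- do.call(rbind, Filter(Negate(is.null), list(land, bg, oth, snp)))

    if ("pileups" %in% include) {
      snv_rows <- maf_i[maf_i$variant_type == "SNV" & maf_i$popfreq == 0, ,
                        drop = FALSE]
      tv <- data.frame(chrom = snv_rows$chrom, pos = snv_rows$pos,
                       ref = snv_rows$ref, alt = snv_rows$alt,
                       true_af = snv_rows$true_af, stringsAsFactors = FALSE)
      pu <- simulate_pileups(tv, config$mean_depth, config$error_rate,
                             seed = sub_seed(seed_i, 7L), n_null_sites = 40L)
      pu$patient_id <- pid
      pileups[[i]] <- pu
    }
    if ("profiles" %in% include) {
      set.seed(sub_seed(seed_i, 11L))
      u <- stats::runif(1, config$msi_unstable_locus_fraction[1],
                        config$msi_unstable_locus_fraction[2])
      pr <- simulate_locus_profiles(msi_true, depth = config$mean_depth,
                                    baseline = baseline,
                                    seed = sub_seed(seed_i, 13L),
                                    unstable_fraction = u,
                                    sample_id = pid)
      profiles[[i]] <- pr$profiles
    }

    patients[[i]] <- data.frame(patient_id = pid, sex = sex, age = age,
                                site = site, msi_true = msi_true,
                                pdl1_tps = pdl1, stringsAsFactors = FALSE)
    mafs[[i]] <- maf_i
    truth_genes[[i]] <- mut_genes
  }

  maf <- do.call(rbind, Filter(Negate(is.null), mafs))
  truth_variants <- maf[, c("patient_id", "gene", "chrom", "pos", "ref",
                            "alt", "functional_class", "true_af"),
                        drop = FALSE]
  maf$true_af <- NULL
  structure(list(
    patients = do.call(rbind, patients),
    maf = maf,
    pileups = if ("pileups" %in% include)
      do.call(rbind, Filter(Negate(is.null), pileups)) else NULL,
    profiles = if ("profiles" %in% include)
      do.call(rbind, Filter(Negate(is.null), profiles)) else NULL,
    baseline = baseline,
    truth = list(
      msi_status = stats::setNames(
        vapply(patients, function(p) p$msi_true, character(1)),
        vapply(patients, function(p) p$patient_id, character(1))),
      mutated_genes = stats::setNames(
        truth_genes,
        vapply(patients, function(p) p$patient_id, character(1))),
      variants = truth_variants),
    config = config
  ), class = "synthetic_cohort")
}
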