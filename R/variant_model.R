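# Somatic SNV detection: exact binomial test on pileup alt counts against a
# sequencing-error null, followed by the filter cascade (allele fraction,
# supporting reads, strand bias, base quality) and the reporting-level
# landscape filter (functional-class keep list + population frequency).

#' Sample-level tumor-content QC
#'
#' A specimen is eligible for profiling only if its estimated tumor cell
#' content reaches the minimum fraction (default 20%); the boundary is
#' inclusive.
#'
#' @param tumor_content Estimated tumor cell fraction in `[0, 1]`.
#' @param tumor_content_min Minimum eligible fraction (default `0.20`).
#' @return `"pass"` or `"fail"`.
#' @examples
#' qc_sample(0.20) # "pass"
#' qc_sample(0.19) # "fail"
#' @export
qc_sample <- function(tumor_content, tumor_content_min = 0.20) {
  assert_prob(tumor_content, "tumor_content")
  assert_prob(tumor_content_min, "tumor_content_min")
  if (tumor_content >= tumor_content_min) "pass" else "fail"
}

#' Binomial alt-read p-value at a pileup site
#'
#' The detection model: under the null hypothesis that all alternate reads
#' arise from sequencing error at rate `error_rate`, the alt count is
#' `Binomial(depth, error_rate)`; the p-value is the exact upper tail
#' `P(X >= alt_reads)`.
#'
#' @param alt_reads Alternate-supporting read count, `0 <= alt_reads <= depth`.
#' @param depth Total read depth at the site.
#' @param error_rate Per-base sequencing error rate, in `(0, 1)`.
#' @return Upper-tail p-value; monotone non-increasing in `alt_reads` at
#'   fixed depth.
#' @examples
#' binomial_alt_pvalue(0, 100, 0.01)   # 1: zero alt reads are never evidence
#' binomial_alt_pvalue(10, 100, 0.01)  # deep in the tail
#' @export
binomial_alt_pvalue <- function(alt_reads, depth, error_rate) {
  assert_scalar_number(error_rate, "error_rate")
  if (error_rate <= 0 || error_rate >= 1) {
    pp_stop("'error_rate' must lie strictly in (0, 1), got ", error_rate)
  }
  binom_upper_tail(alt_reads, depth, error_rate)
}

#' Strand-bias exact test
#'
#' Two-sided Fisher exact test on the 2x2 table of alt/ref read counts by
#' strand. A perfectly symmetric table gives p = 1; the all-zero table
#' returns p = 1 by convention.
#'
#' @param alt_fwd,alt_rev Alt-supporting reads on forward/reverse strand.
#' @param ref_fwd,ref_rev Reference reads on forward/reverse strand.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
strand_bias_pvalue <- function(alt_fwd, alt_rev, ref_fwd, ref_rev) {
  counts <- c(alt_fwd = alt_fwd, alt_rev = alt_rev,
              ref_fwd = ref_fwd, ref_rev = ref_rev)
  for (nm in names(counts)) assert_count(counts[[nm]], nm)
  tab <- matrix(as.integer(counts), nrow = 2L, byrow = TRUE)
  if (sum(tab) == 0L) return(1)
  stats::fisher.test(tab)$p.value
}

#' Caller parameters
#'
#' Bundles the thresholds of the SNV filter cascade. The allele-fraction
#' floor (`min_af = 0.05`, inclusive keep) and the population-frequency
#' ceiling (`max_popfreq = 0.015`, strict removal) are the validated
#' reporting thresholds; the remaining knobs carry conventional defaults
#' and are fully configurable.
#'
#' @param error_rate Null per-base error rate for the binomial test.
#' @param alpha_call P-value threshold for calling (inclusive).
#' @param min_af Minimum allele fraction (inclusive keep).
#' @param min_alt_reads Minimum alt-supporting reads (inclusive keep).
#' @param max_strand_bias_p Strand-bias Fisher p below which a site fails,
#'   applied only when one strand carries zero alt reads.
#' @param min_base_quality Minimum mean base quality (Phred, inclusive keep).
#' @param max_popfreq Population frequency above which a variant is removed.
#' @param tumor_content_min Minimum tumor content for sample QC.
#' @return A list of class `"caller_params"`.
#' @export
caller_params <- function(error_rate = 0.01,
                          alpha_call = 1e-6,
                          min_af = 0.05,
                          min_alt_reads = 5L,
                          max_strand_bias_p = 0.01,
                          min_base_quality = 25,
                          max_popfreq = 0.015,
                          tumor_content_min = 0.20) {
  assert_prob(error_rate, "error_rate")
  assert_prob(alpha_call, "alpha_call")
  assert_prob(min_af, "min_af")
  assert_count(min_alt_reads, "min_alt_reads")
  assert_prob(max_strand_bias_p, "max_strand_bias_p")
  assert_scalar_number(min_base_quality, "min_base_quality")
  assert_prob(max_popfreq, "max_popfreq")
  assert_prob(tumor_content_min, "tumor_content_min")
  structure(list(error_rate = error_rate, alpha_call = alpha_call,
                 min_af = min_af, min_alt_reads = as.integer(min_alt_reads),
                 max_strand_bias_p = max_strand_bias_p,
                 min_base_quality = min_base_quality,
                 max_popfreq = max_popfreq,
                 tumor_content_min = tumor_content_min),
            class = "caller_params")
}

pileup_columns <- c("chrom", "pos", "ref", "alt", "depth", "alt_reads",
                    "alt_fwd", "alt_rev", "mean_bq")

validate_pileups <- function(pileups) {
  missing <- setdiff(pileup_columns, names(pileups))
  if (length(missing) > 0) {
    pp_stop("pileup table is missing column(s): ",
            paste(missing, collapse = ", "))
  }
  bad <- which(pileups$alt_reads > pileups$depth)
  if (length(bad) > 0) {
    pp_stop("alt_reads exceeds depth at row(s) ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(pileups$alt_fwd + pileups$alt_rev != pileups$alt_reads)
  if (length(bad) > 0) {
    pp_stop("alt_fwd + alt_rev != alt_reads at row(s) ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(pileups)
}

#' Call somatic SNVs from pileup counts
#'
#' A site is called when all of the following hold: binomial p-value
#' `<= alpha_call`, allele fraction `>= min_af`, alt reads
#' `>= min_alt_reads`, mean base quality `>= min_base_quality`, and the
#' strand rule passes. The strand rule fails a site only when one strand
#' carries zero alt reads *and* the Fisher exact test on the alt/ref-by-
#' strand table is below `max_strand_bias_p`; reference reads are split
#' evenly between strands since the pileup format records only the alt
#' strand split.
#'
#' @param pileups Data frame of pileup records (see [read_pileup_tsv()]
#'   for the column set).
#' @param params A [caller_params()] object.
#' @return A data frame of variant calls sorted by `(chrom, pos)` with
#'   columns `gene` (NA until annotation), `chrom`, `pos`, `ref`, `alt`,
#'   `variant_type`, `functional_class` (NA until annotation), `af`,
#'   `depth`, `alt_reads`, `popfreq` (NA), `is_driver`, `p_value`.
#' @export
call_snvs <- function(pileups, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  if (is.null(pileups) || nrow(pileups) == 0) return(empty_calls())
  validate_pileups(pileups)

  n <- nrow(pileups)
  af <- ifelse(pileups$depth > 0, pileups$alt_reads / pileups$depth, 0)

  # cheap threshold filters first; the exact binomial tail and the strand
  # test are evaluated only for surviving candidates
  candidate <- af >= params$min_af &
    pileups$alt_reads >= params$min_alt_reads &
    pileups$mean_bq >= params$min_base_quality

  p_value <- rep(NA_real_, n)
  for (i in which(candidate)) {
    p_value[i] <- binomial_alt_pvalue(pileups$alt_reads[i],
                                      pileups$depth[i], params$error_rate)
  }
  candidate <- candidate & !is.na(p_value) & p_value <= params$alpha_call

  strand_ok <- rep(TRUE, n)
  for (i in which(candidate)) {
    one_sided <- pileups$alt_fwd[i] == 0L || pileups$alt_rev[i] == 0L
    if (!one_sided || pileups$alt_reads[i] == 0L) next
    ref_n <- pileups$depth[i] - pileups$alt_reads[i]
    p_sb <- strand_bias_pvalue(pileups$alt_fwd[i], pileups$alt_rev[i],
                               ref_n %/% 2L, ref_n - ref_n %/% 2L)
    strand_ok[i] <- p_sb >= params$max_strand_bias_p
  }

  keep <- candidate & strand_ok

  if (!any(keep)) return(empty_calls())
  called <- pileups[keep, , drop = FALSE]
  out <- data.frame(
    gene = NA_character_,
    chrom = as.character(called$chrom),
    pos = as.integer(called$pos),
    ref = as.character(called$ref),
    alt = as.character(called$alt),
    variant_type = "SNV",
    functional_class = NA_character_,
    af = af[keep],
    depth = as.integer(called$depth),
    alt_reads = as.integer(called$alt_reads),
    popfreq = NA_real_,
    is_driver = FALSE,
    p_value = p_value[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}

empty_calls <- function() {
  data.frame(gene = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), variant_type = character(),
             functional_class = character(), af = numeric(), depth = integer(),
             alt_reads = integer(), popfreq = numeric(), is_driver = logical(),
             p_value = numeric(), stringsAsFactors = FALSE)
}

#' Functional classes retained by the landscape filter
#' @export
landscape_keep_classes <- c("missense", "stopgain", "frameshift_indel",
                            "nonframeshift_indel")

#' Functional classes eligible for TMB
#' @export
tmb_eligible_classes <- c("missense", "silent", "stopgain", "stoploss",
                          "nonframeshift_indel", "frameshift_indel")

#' Remove population-frequent (putatively germline) variants
#'
#' Drops calls whose annotated population frequency exceeds `max_popfreq`
#' (strict inequality: exactly 0.015 is kept). Missing `popfreq` is treated
#' as 0 — a novel variant cannot be excluded as common without evidence.
#'
#' @param calls Data frame of variant calls with a `popfreq` column.
#' @param max_popfreq Removal threshold (default 0.015).
#' @return The filtered calls, input order preserved.
#' @export
filter_popfreq <- function(calls, max_popfreq = 0.015) {
  if (nrow(calls) == 0) return(calls)
  pf <- calls$popfreq
  pf[is.na(pf)] <- 0
  calls[pf <= max_popfreq, , drop = FALSE]
}

#' Landscape (reporting) filter
#'
#' The keep list applied before reporting gene alterations: only missense,
#' stopgain, frameshift-indel and non-frameshift-indel calls are retained,
#' and population-frequent calls (`popfreq > max_popfreq`) are removed.
#' Idempotent; input order preserved.
#'
#' @inheritParams filter_popfreq
#' @param keep_classes Functional classes to retain.
#' @return The filtered calls.
#' @export
apply_landscape_filter <- function(calls, max_popfreq = 0.015,
                                   keep_classes = landscape_keep_classes) {
  if (nrow(calls) == 0) return(calls)
  calls <- filter_popfreq(calls, max_popfreq)
  calls[!is.na(calls$functional_class) &
          calls$functional_class %in% keep_classes, , drop = FALSE]
}
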