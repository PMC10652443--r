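# Fixtures built in code.

# Cohort reconstructed from the published summary counts: 298 patients,
# 184 male, 268 duodenal primaries (jejunum/ileum split 15/15), ages
# dichotomised 149/149 at 60, KRAS mutated in 152, TP53 in 158.
table1_cohort <- function() {
  n <- 298
  cohort <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    sex = rep(c("male", "female"), c(184, 114)),
    age = rep(c(65L, 55L), c(149, 149)),
    site = rep(c("duodenum", "jejunum", "ileum"), c(268, 15, 15)),
    stringsAsFactors = FALSE
  )
  cohort$mutated_genes <- lapply(seq_len(n), function(i) {
    c(if (i <= 152) "KRAS", if (i <= 158) "TP53")
  })
  cohort
}

# Ten pileup sites whose pass/fail status under the default caller
# parameters is decided by hand, one filter at a time (depth 1000,
# error rate 0.01, alpha 1e-6 -> >= 23 alt reads needed; af >= 0.05 ->
# >= 50 alt reads; min_alt 5; mean bq >= 25; strand fail only if one
# strand empty AND Fisher p < 0.01).
toy_pileups <- function() {
  data.frame(
    chrom = paste0("chr", c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)),
    pos = c(100L, 200L, 100L, 200L, 100L, 200L, 100L, 200L, 100L, 200L),
    ref = rep("A", 10), alt = rep("T", 10),
    depth = rep(1000L, 10),
    #            pass  af.03  pass   low-p  low-bq strand pass  few-alt zero  af.049
    alt_reads = c(300L, 30L,  100L,  15L,   200L,  100L,  500L, 4L,    0L,   49L),
    alt_fwd   = c(150L, 15L,  50L,   8L,    100L,  100L,  250L, 2L,    0L,   25L),
    alt_rev   = c(150L, 15L,  50L,   7L,    100L,  0L,    250L, 2L,    0L,   24L),
    mean_bq   = c(32,   32,   32,    32,    20,    32,    32,   32,    32,   32),
    stringsAsFactors = FALSE
  )
}

# Hand-decided: sites 1, 3, 7 pass every filter.
toy_pileups_expected_pos <- function() {
  data.frame(chrom = c("chr1", "chr2", "chr4"), pos = c(100L, 100L, 100L),
             stringsAsFactors = FALSE)
}

# Ten annotated variant rows for the landscape filter, survival decided by
# hand: keep-class with popfreq <= 0.015 survives.
toy_maf_calls <- function() {
  data.frame(
    patient_id = "P1",
    gene = sprintf("G%02d", 1:10),
    chrom = "chr1", pos = 1:10 * 100L, ref = "A", alt = "T",
    variant_type = "SNV",
    functional_class = c("missense", "missense", "silent", "stopgain",
                         "other", "frameshift_indel", "nonframeshift_indel",
                         "missense", "stoploss", "stopgain"),
    af = 0.3, depth = 100L, alt_reads = 30L,
    popfreq = c(0, 0.02, 0, 0.015, 0, 0, 0.5, NA, 0, 0.0151),
    is_driver = FALSE,
    stringsAsFactors = FALSE
  )
  # survivors: rows 1 (missense, 0), 4 (stopgain, 0.015 kept: strict >),
  # 6 (frameshift, 0), 8 (missense, NA -> 0); removed: 2 (popfreq), 3
  # (silent), 5 (other), 7 (popfreq 0.5), 9 (stoploss), 10 (0.0151 > 0.015)
}

toy_maf_surviving_genes <- function() c("G01", "G04", "G06", "G08")

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (probability-ordering rule with the standard
# relative tolerance).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  as <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, as) + lchoose(n - c1, r1 - as) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- p[match(a, as)]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Chi-square statistic on a 2x2 table by the textbook formula sum (O-E)^2/E.
chisq_closed_form <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}
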