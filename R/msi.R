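# Microsatellite instability from per-locus read-length histograms.
#
# For each locus i a stable (MSS) baseline provides a cut-point repeat
# length C_i and the fraction p_i of MSS reads observed at lengths beyond
# the cut-point. In a tumor sample, with N_i total reads at the locus and
# n_i "unstable" reads beyond C_i, the locus is tested against
# X ~ Binomial(N_i, p_i): it is unstable when the exact upper tail
# P(X >= n_i) falls at or below alpha (default 1e-3). The MSI score is the
# fraction of unstable loci among the 30 best-covered loci of the 100-locus
# panel; a score >= 0.4 classifies the sample MSI-H, otherwise MSS.

#' Binomial tail probability for a microsatellite locus
#'
#' `P(X >= n_i)` for `X ~ Binomial(N_i, p_i)` by exact pmf summation, where
#' `n_i` is the unstable-read count, `N_i` the total reads at the locus and
#' `p_i` the MSS-baseline fraction of reads beyond the cut-point.
#'
#' @param n_i Unstable read count, `0 <= n_i <= N_i`.
#' @param N_i Total reads at the locus.
#' @param p_i Baseline unstable-read probability in `[0, 1]`.
#' @return The exact upper-tail probability; monotone non-increasing in
#'   `n_i`.
#' @export
locus_tail_probability <- function(n_i, N_i, p_i) {
  binom_upper_tail(n_i, N_i, p_i)
}

count_unstable_reads <- function(repeat_length, read_count, cut_point,
                                 side = c("greater", "geq")) {
  side <- match.arg(side)
  beyond <- if (side == "greater") repeat_length > cut_point
            else repeat_length >= cut_point
  sum(read_count[beyond])
}

#' Classify a single microsatellite locus
#'
#' @param histogram Data frame with columns `repeat_length`, `read_count`
#'   for one locus in one sample.
#' @param baseline One-row data frame (or list) with `cut_point` and `p_i`
#'   for the locus.
#' @param alpha Tail-probability threshold; unstable iff
#'   `P(X >= n_i) <= alpha` (boundary inclusive). Default `0.001`.
#' @param side Whether unstable reads lie strictly beyond the cut-point
#'   (`"greater"`, default) or at-or-beyond it (`"geq"`).
#' @return `"stable"` or `"unstable"`.
#' @export
classify_locus <- function(histogram, baseline, alpha = 0.001,
                           side = c("greater", "geq")) {
  side <- match.arg(side)
  assert_prob(alpha, "alpha")
  if (any(histogram$read_count < 0)) pp_stop("negative read_count")
  N_i <- sum(histogram$read_count)
  n_i <- count_unstable_reads(histogram$repeat_length, histogram$read_count,
                              baseline$cut_point, side)
  p <- locus_tail_probability(n_i, N_i, baseline$p_i)
  if (p <= alpha) "unstable" else "stable"
}

#' Select the best-covered loci
#'
#' Returns the `k` loci with largest total read count; ties at the
#' selection boundary are broken by ascending locus id. Loci with zero
#' reads are excluded before selection; if fewer than `k` loci have reads,
#' all of them are returned with a warning.
#'
#' @param profiles Long-format data frame with columns `locus_id`,
#'   `repeat_length`, `read_count` for one sample.
#' @param k Number of loci to keep (default 30).
#' @return The subset of `profiles` for the selected loci.
#' @export
select_loci <- function(profiles, k = 30L) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    pp_stop("no locus profiles supplied")
  }
  k <- assert_count(k, "k", positive = TRUE)
  totals <- tapply(profiles$read_count, profiles$locus_id, sum)
  totals <- totals[totals > 0]
  if (length(totals) == 0) pp_stop("no locus has read coverage")
  ord <- order(-totals, names(totals))
  if (length(totals) < k) {
    warning("only ", length(totals), " loci with coverage; requested ", k)
    chosen <- names(totals)[ord]
  } else {
    chosen <- names(totals)[ord][seq_len(k)]
  }
  profiles[profiles$locus_id %in% chosen, , drop = FALSE]
}

#' MSI score and sample classification from per-locus flags
#'
#' The MSI score is the fraction of evaluated loci flagged unstable; a
#' score at or above `score_threshold` (default 0.4, inclusive) classifies
#' the sample MSI-H, otherwise MSS.
#'
#' @param flags Character vector of `"stable"` / `"unstable"`.
#' @param score_threshold MSI-H boundary on the score (default 0.4).
#' @param alpha The per-locus alpha used (recorded in the result).
#' @return An object of class `"msi_result"`.
#' @export
msi_score_and_class <- function(flags, score_threshold = 0.4, alpha = 0.001) {
  if (length(flags) == 0) pp_stop("no locus flags supplied")
  if (!all(flags %in% c("stable", "unstable"))) {
    pp_stop("flags must be 'stable' or 'unstable'")
  }
  assert_prob(score_threshold, "score_threshold")
  n <- length(flags)
  unstable <- sum(flags == "unstable")
  score <- unstable / n
  structure(list(
    per_locus = NULL,
    loci_evaluated = n,
    unstable_loci = unstable,
    msi_score = score,
    msi_class = if (score >= score_threshold) "MSI-H" else "MSS",
    alpha = alpha,
    score_threshold = score_threshold
  ), class = "msi_result")
}

#' End-to-end MSI call for one sample
#'
#' Composition of [select_loci()] (top `k` by coverage),
#' [classify_locus()] per selected locus, and [msi_score_and_class()].
#'
#' @param profiles Long-format histograms for one sample: `locus_id`,
#'   `repeat_length`, `read_count`.
#' @param baseline Baseline panel data frame: `locus_id`, `cut_point`,
#'   `p_i`.
#' @param alpha Per-locus tail threshold (default 0.001, inclusive).
#' @param k Loci evaluated per sample (default 30).
#' @param score_threshold MSI-H score boundary (default 0.4, inclusive).
#' @param side Unstable-read convention, see [classify_locus()].
#' @return An `"msi_result"` with a `per_locus` table recording, for every
#'   evaluated locus, `N_i`, `n_i`, the baseline `p_i`, the tail p-value
#'   and the flag.
#' @export
call_msi <- function(profiles, baseline, alpha = 0.001, k = 30L,
                     score_threshold = 0.4, side = c("greater", "geq")) {
  side <- match.arg(side)
  selected <- select_loci(profiles, k)
  loci <- sort(unique(selected$locus_id))
  missing <- setdiff(loci, baseline$locus_id)
  if (length(missing) > 0) {
    pp_stop("no baseline for locus/loci: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(loci, function(id) {
    h <- selected[selected$locus_id == id, , drop = FALSE]
    b <- baseline[match(id, baseline$locus_id), , drop = FALSE]
    N_i <- sum(h$read_count)
    n_i <- count_unstable_reads(h$repeat_length, h$read_count,
                                b$cut_point, side)
    p <- locus_tail_probability(n_i, N_i, b$p_i)
    data.frame(locus_id = id, N_i = N_i, n_i = n_i, p_i = b$p_i,
               p_value = p,
               flag = if (p <= alpha) "unstable" else "stable",
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  res <- msi_score_and_class(per_locus$flag, score_threshold, alpha)
  res$per_locus <- per_locus
  res
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("MSI call: %s (score %.3f; %d/%d loci unstable; alpha=%g, threshold=%g)\n",
              x$msi_class, x$msi_score, x$unstable_loci, x$loci_evaluated,
              x$alpha, x$score_threshold))
  invisible(x)
}
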