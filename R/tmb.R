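# Tumor mutational burden: count of eligible somatic coding mutations
# (missense, silent, stopgain, stoploss, in-frame and frameshift indels)
# with annotated driver mutations excluded, normalised per megabase of the
# examined coding region. TMB must be computed on calls BEFORE the
# landscape (reporting) filter, which would remove silent and stoploss
# variants that TMB counts.

#' Compute tumor mutational burden
#'
#' @param calls Data frame of somatic variant calls with at least
#'   `functional_class` and `is_driver` columns; these must be
#'   pre-landscape-filter calls (silent variants still present). Germline
#'   removal (population-frequency filter) is expected upstream, see
#'   [filter_popfreq()].
#' @param region_size_mb Megabases of examined coding region. Required: the
#'   panel footprint is assay-specific, so no default is supplied.
#' @param eligible_classes Functional classes counted (default
#'   [tmb_eligible_classes]).
#' @return An object of class `"tmb_result"` with `eligible_count`,
#'   `region_size_mb`, `tmb_per_mb` and `excluded_drivers`.
#' @export
compute_tmb <- function(calls, region_size_mb,
                        eligible_classes = tmb_eligible_classes) {
  assert_scalar_number(region_size_mb, "region_size_mb")
  if (region_size_mb <= 0) {
    pp_stop("'region_size_mb' must be > 0, got ", region_size_mb)
  }
  if (nrow(calls) == 0) {
    eligible <- 0L
    drivers <- 0L
  } else {
    in_class <- !is.na(calls$functional_class) &
      calls$functional_class %in% eligible_classes
    drv <- !is.na(calls$is_driver) & calls$is_driver
    eligible <- sum(in_class & !drv)
    drivers <- sum(in_class & drv)
  }
  structure(list(eligible_count = as.integer(eligible),
                 region_size_mb = region_size_mb,
                 tmb_per_mb = eligible / region_size_mb,
                 excluded_drivers = as.integer(drivers)),
            class = "tmb_result")
}

#' TMB-high flag
#'
#' `TRUE` when TMB reaches the pan-tumor immunotherapy cutoff of 10
#' mutations per megabase (inclusive).
#'
#' @param tmb_per_mb Non-negative TMB value (mut/Mb).
#' @param cutoff TMB-H boundary (default 10, inclusive).
#' @return Logical.
#' @export
tmb_high_flag <- function(tmb_per_mb, cutoff = 10) {
  assert_scalar_number(tmb_per_mb, "tmb_per_mb")
  if (tmb_per_mb < 0) pp_stop("'tmb_per_mb' must be >= 0, got ", tmb_per_mb)
  assert_scalar_number(cutoff, "cutoff")
  tmb_per_mb >= cutoff
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB: %.2f mut/Mb (%d eligible mutations / %.3f Mb; %d drivers excluded)\n",
              x$tmb_per_mb, x$eligible_count, x$region_size_mb,
              x$excluded_drivers))
  invisible(x)
}
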