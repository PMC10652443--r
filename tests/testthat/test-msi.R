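# Microsatellite-instability locus model, locus selection and MSI scoring.

test_that("locus tail probability: degenerate cases and brute-force oracle", {
  expect_equal(locus_tail_probability(0, 50, 0.05), 1.0)
  expect_equal(locus_tail_probability(0, 1, 0.5), 1.0)
  expect_equal(locus_tail_probability(7, 30, 1.0), 1.0)
  expect_equal(locus_tail_probability(1, 30, 0), 0)
  oracle <- sum(stats::dbinom(10:30, 30, 0.05))
  expect_equal(locus_tail_probability(10, 30, 0.05), oracle,
               tolerance = 1e-12)
  expect_error(locus_tail_probability(31, 30, 0.05),
               class = "pp_validation_error")
})

test_that("locus classification boundary at tail probability 0.001 is inclusive", {
  # scan n at N = 50, p = 0.05 for the exact decision boundary
  tails <- vapply(0:50, locus_tail_probability, numeric(1),
                  N_i = 50, p_i = 0.05)
  n_boundary <- min(which(tails <= 0.001)) - 1L  # first unstable n
  expect_gt(n_boundary, 0)
  hist_at <- function(n) data.frame(repeat_length = c(10, 15),
                                    read_count = c(50 - n, n))
  base <- list(cut_point = 12L, p_i = 0.05)
  expect_equal(classify_locus(hist_at(n_boundary), base), "unstable")
  expect_equal(classify_locus(hist_at(n_boundary - 1L), base), "stable")
  # trivial ends
  expect_equal(classify_locus(hist_at(0), base), "stable")
  expect_equal(classify_locus(hist_at(1), list(cut_point = 12L, p_i = 0)),
               "unstable")
})

test_that("locus selection takes the k best-covered loci with deterministic ties", {
  profiles <- data.frame(
    locus_id = rep(sprintf("L%03d", 1:40), each = 2),
    repeat_length = rep(c(10, 14), 40),
    read_count = rep(c(100, 1), 40) + rep(40:1, each = 2)
  )
  sel <- select_loci(profiles, k = 30)
  expect_equal(sort(unique(sel$locus_id)), sprintf("L%03d", 1:30))
  # tie at the selection boundary: lexicographically smaller id wins
  tied <- data.frame(locus_id = rep(c("B", "A", "C"), each = 1),
                     repeat_length = 10, read_count = c(5, 5, 9))
  sel2 <- select_loci(tied, k = 2)
  expect_setequal(unique(sel2$locus_id), c("C", "A"))
  sel3 <- select_loci(tied[c(3, 1, 2), ], k = 2)  # order invariant
  expect_setequal(unique(sel3$locus_id), c("C", "A"))
  # degenerate: fewer loci than requested -> all returned with a warning
  expect_warning(sel4 <- select_loci(tied, k = 30), "only 3 loci")
  expect_setequal(unique(sel4$locus_id), c("A", "B", "C"))
  # zero-coverage loci are excluded before selection
  zc <- rbind(tied, data.frame(locus_id = "Z", repeat_length = 10,
                               read_count = 0))
  expect_false("Z" %in% suppressWarnings(select_loci(zc, k = 10))$locus_id)
  expect_error(select_loci(tied[0, ]), class = "pp_validation_error")
})

test_that("MSI score boundary: 12/30 unstable is MSI-H, score stays in [0,1]", {
  r <- msi_score_and_class(rep(c("unstable", "stable"), c(12, 18)))
  expect_equal(r$msi_score, 0.4)
  expect_equal(r$msi_class, "MSI-H")
  r2 <- msi_score_and_class(rep(c("unstable", "stable"), c(13, 17)))
  expect_equal(r2$msi_score, 13 / 30)
  expect_equal(r2$msi_class, "MSI-H")
  r3 <- msi_score_and_class(rep("stable", 30))
  expect_equal(r3$msi_score, 0)
  expect_equal(r3$msi_class, "MSS")
  r4 <- msi_score_and_class(rep(c("unstable", "stable"), c(11, 19)))
  expect_equal(r4$msi_class, "MSS")
  expect_error(msi_score_and_class(character()), class = "pp_validation_error")
})

test_that("shifting reads beyond the cut-point never flips unstable to stable", {
  base <- list(cut_point = 12L, p_i = 0.03)
  flags <- vapply(0:60, function(n) {
    h <- data.frame(repeat_length = c(10, 14), read_count = c(60 - n, n))
    classify_locus(h, base)
  }, character(1))
  expect_true(all(diff(flags == "unstable") >= 0))
})

test_that("end-to-end MSI call recovers simulated status and reports evaluated loci", {
  baseline <- default_baseline_panel()
  mss <- simulate_locus_profiles("MSS", depth = 500, baseline = baseline,
                                 seed = 11, sample_id = "S_MSS")
  r <- call_msi(mss$profiles, baseline)
  expect_equal(r$msi_class, "MSS")
  expect_equal(r$loci_evaluated, 30L)
  expect_equal(nrow(r$per_locus), 30L)
  # fully shifted sample: every evaluated locus unstable, score 1
  msih <- simulate_locus_profiles("MSI-H", depth = 500, baseline = baseline,
                                  seed = 12, unstable_fraction = 1,
                                  sample_id = "S_H")
  r2 <- call_msi(msih$profiles, baseline)
  expect_equal(r2$msi_class, "MSI-H")
  expect_equal(r2$msi_score, 1)
  # missing baseline rows are reported by locus
  small <- default_baseline_panel(10)
  prof10 <- simulate_locus_profiles("MSS", depth = 200, baseline = small,
                                    seed = 13)$profiles
  expect_error(call_msi(prof10, small[-1, ], k = 10), "MS001",
               class = "pp_validation_error")
})
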