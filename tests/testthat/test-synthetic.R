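# Synthetic cohort generator: validation, determinism, recovery of the
# configured statistical structure.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_patients = 0), "n_patients",
               class = "pp_validation_error")
  expect_error(sim_config(site_probs = c(duodenum = 0.5, jejunum = 0.3,
                                         ileum = 0.3)),
               "site_probs", class = "pp_validation_error")
  expect_error(sim_config(error_rate = 0.6), "error_rate",
               class = "pp_validation_error")
  expect_error(sim_config(true_af_range = c(0, 0.5)), "true_af_range",
               class = "pp_validation_error")
  expect_error(sim_config(tmb_rate_by_msi = c(MSS = 5)), "tmb_rate_by_msi",
               class = "pp_validation_error")
})

test_that("identical config and seed give identical outputs; prefixes are stable", {
  a <- simulate_cohort(sim_config(n_patients = 6, seed = 3))
  b <- simulate_cohort(sim_config(n_patients = 6, seed = 3))
  expect_identical(a$patients, b$patients)
  expect_identical(a$maf, b$maf)
  expect_identical(a$pileups, b$pileups)
  expect_identical(a$profiles, b$profiles)
  # counter-based sub-seeds: growing the cohort leaves earlier patients
  bigger <- simulate_cohort(sim_config(n_patients = 9, seed = 3),
                            include = character(0))
  expect_equal(a$patients, bigger$patients[1:6, ], ignore_attr = TRUE)
  # a different seed changes the draw
  c_ <- simulate_cohort(sim_config(n_patients = 6, seed = 4))
  expect_false(identical(a$maf, c_$maf))
})

test_that("per-gene mutation frequencies recover the configured probabilities", {
  co <- simulate_cohort(sim_config(n_patients = 2000, seed = 21),
                        include = character(0))
  probs <- default_gene_site_probs()
  site_w <- c(duodenum = 268 / 298, jejunum = 15 / 298, ileum = 15 / 298)
  for (g in c("TP53", "KRAS", "APC", "SMAD4", "CD74")) {
    marginal <- sum(probs[g, names(site_w)] * site_w)
    hits <- sum(vapply(co$truth$mutated_genes, function(s) g %in% s,
                       logical(1)))
    ci <- stats::qbinom(c(0.005, 0.995), 2000, marginal)
    expect_gte(hits, ci[1])
    expect_lte(hits, ci[2])
  }
})

test_that("MSS locus histograms put the baseline mass beyond the cut-point", {
  baseline <- default_baseline_panel(20)
  sim <- simulate_locus_profiles("MSS", depth = 60000, baseline = baseline,
                                 seed = 8)
  pr <- sim$profiles
  for (j in seq_len(nrow(baseline))) {
    h <- pr[pr$locus_id == baseline$locus_id[j], ]
    n_beyond <- sum(h$read_count[h$repeat_length > baseline$cut_point[j]])
    frac <- n_beyond / sum(h$read_count)
    # law of large numbers at depth 60000: 5 sigma band around p_i
    p <- baseline$p_i[j]
    expect_lt(abs(frac - p), 5 * sqrt(p * (1 - p) / 60000) + 1e-9)
  }
  expect_length(sim$shifted_loci, 0)
})

test_that("MSI-H profile generation shifts the requested loci", {
  baseline <- default_baseline_panel(30)
  all_shift <- simulate_locus_profiles("MSI-H", depth = 300,
                                       baseline = baseline, seed = 9,
                                       unstable_fraction = 1)
  expect_length(all_shift$shifted_loci, 30)
  some <- simulate_locus_profiles("MSI-H", depth = 300, baseline = baseline,
                                  seed = 9, unstable_fraction = 0.5)
  expect_length(some$shifted_loci, 15)
  expect_error(simulate_locus_profiles("MSS", depth = 0,
                                       baseline = baseline),
               class = "pp_validation_error")
  expect_error(simulate_locus_profiles("MSS", n_loci = 40,
                                       baseline = baseline),
               class = "pp_validation_error")
})

test_that("pileup simulation tracks true allele fractions and the error null", {
  tv <- data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "T",
                   true_af = 0.5)
  pu <- simulate_pileups(tv, mean_depth = 10000, error_rate = 0.01,
                         seed = 2)
  expect_equal(nrow(pu), 1L)
  af <- pu$alt_reads / pu$depth
  expect_gt(af, 0.45)
  expect_lt(af, 0.55)
  expect_equal(pu$alt_fwd + pu$alt_rev, pu$alt_reads)
  # error-only sites carry near-zero alt reads at tiny error rates
  nul <- simulate_pileups(tv[0, ], mean_depth = 200, error_rate = 1e-6,
                          seed = 3, n_null_sites = 200)
  expect_equal(sum(nul$alt_reads), 0L)
  expect_identical(simulate_pileups(tv, seed = 5),
                   simulate_pileups(tv, seed = 5))
  expect_error(simulate_pileups(tv, error_rate = 0.7),
               class = "pp_validation_error")
})
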