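# Cohort-level frequency tables and group comparisons.

test_that("frequency table reproduces known per-gene counts and is order invariant", {
  cohort <- table1_cohort()
  ft <- frequency_table(cohort, c("KRAS", "TP53", "BRAF"))
  expect_equal(ft$count, c(152L, 158L, 0L))
  expect_equal(ft$total, rep(298L, 3))
  expect_equal(ft$percentage, c(51.01, 53.02, 0.00))
  shuffled <- cohort[sample(nrow(cohort)), ]
  expect_equal(frequency_table(shuffled, c("KRAS", "TP53", "BRAF")), ft)
  expect_error(frequency_table(cohort[0, ], "KRAS"),
               class = "pp_validation_error")
})

test_that("categorical breakdown matches known demographics and sums to 100", {
  cohort <- table1_cohort()
  sex <- categorical_breakdown(cohort, "sex")
  expect_equal(sex$percentage[sex$level == "male"], 61.74)
  expect_equal(sex$percentage[sex$level == "female"], 38.26)
  site <- categorical_breakdown(cohort, "site", merge_jejunum_ileum = TRUE)
  expect_equal(site$percentage[site$level == "duodenum"], 89.93)
  expect_equal(site$percentage[site$level == "jejunum/ileum"], 10.07)
  age <- categorical_breakdown(cohort, "age_ge60")
  expect_equal(sort(age$percentage), c(50, 50))
  expect_equal(sum(sex$percentage), 100)
  one <- categorical_breakdown(cohort[1, ], "sex")
  expect_equal(one$percentage, 100)
  expect_error(categorical_breakdown(cohort, "height"),
               class = "pp_validation_error")
})

test_that("proportion comparison: switching rule, closed-form chi-square, Fisher enumeration", {
  # identical balanced proportions
  r <- compare_proportions(5, 10, 5, 10)
  expect_equal(r$p_value, 1.0)
  # chi-square branch against the textbook formula
  r2 <- compare_proportions(50, 100, 30, 100)
  expect_equal(r2$test_used, "chi-square")
  stat <- chisq_closed_form(50, 50, 30, 70)
  expect_equal(r2$statistic, stat, tolerance = 1e-12)
  expect_equal(r2$p_value, stats::pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # small expected cells force Fisher; p matches hypergeometric enumeration
  r3 <- compare_proportions(1, 5, 4, 5)
  expect_equal(r3$test_used, "fisher")
  expect_equal(r3$p_value, fisher_enum_p(1, 4, 4, 1), tolerance = 1e-10)
  expect_error(compare_proportions(1, 0, 2, 5), class = "pp_validation_error")
  expect_error(compare_proportions(6, 5, 2, 5), class = "pp_validation_error")
})

test_that("proportion comparison is symmetric in the two groups", {
  set.seed(7)
  for (i in 1:25) {
    ta <- sample(1:30, 1); tb <- sample(1:30, 1)
    a <- sample(0:ta, 1); b <- sample(0:tb, 1)
    expect_equal(compare_proportions(a, ta, b, tb)$p_value,
                 compare_proportions(b, tb, a, ta)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("mean comparison: Welch default, pooled behind flag, ANOVA for 3+, SEM formula", {
  x <- c(1, 2, 3)
  r <- compare_means(list(a = x, b = x))
  expect_equal(r$p_value, 1.0)
  expect_equal(r$statistic, 0)
  expect_equal(r$test_used, "welch-t")
  expect_equal(r$summary$mean, c(2, 2))
  expect_equal(r$summary$sem, rep(1 / sqrt(3), 2), tolerance = 1e-10)
  expect_equal(round(r$summary$sem[1], 4), 0.5774)
  rp <- compare_means(list(a = c(1, 2, 4), b = c(2, 3, 3)), var_equal = TRUE)
  expect_equal(rp$test_used, "student-t")
  expect_equal(rp$p_value,
               stats::t.test(c(1, 2, 4), c(2, 3, 3), var.equal = TRUE)$p.value)
  r3 <- compare_means(list(a = c(1, 2), b = c(5, 6), c = c(9, 10)))
  expect_equal(r3$test_used, "anova")
  expect_lt(r3$p_value, 0.01)
  expect_error(compare_means(list(a = 1, b = c(1, 2))),
               class = "pp_validation_error")
  expect_error(compare_means(list(a = c(1, 2))), class = "pp_validation_error")
})

test_that("BH adjustment: hand-worked step-up, order preserved, never below input", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(1.0), 1.0)
  expect_equal(adjust_pvalues(numeric(0)), numeric(0))
  set.seed(5)
  p <- stats::runif(50)
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p))
  # monotone: larger p never gets a smaller adjusted value
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_equal(adjust_pvalues(p[order(p)]), sort(adj))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "pp_validation_error")
})

test_that("two-cohort gene frequency comparison assembles counts, tests and BH", {
  a <- data.frame(gene = c("KRAS", "TP53"), count = c(152L, 158L),
                  total = 298L)
  b <- data.frame(gene = c("KRAS", "TP53"), count = c(40L, 90L),
                  total = 200L)
  cmp <- gene_frequency_comparison(a, b, "cohort", "reference")
  expect_equal(nrow(cmp), 2L)
  expect_true(all(cmp$p_adjusted >= cmp$p_value))
  kras <- cmp[cmp$gene == "KRAS", ]
  expect_equal(kras$p_value,
               compare_proportions(152, 298, 40, 200)$p_value)
  expect_lt(kras$p_value, 0.05)
})

test_that("biomarker site comparison detects configured MSI-H and TMB site effects", {
  set.seed(99)
  n <- 500
  site <- sample(c("duodenum", "jejunum", "ileum"), n, TRUE,
                 prob = c(0.6, 0.2, 0.2))
  msi_p <- ifelse(site == "duodenum", 0.05, 0.30)
  cohort <- data.frame(
    patient_id = sprintf("P%03d", 1:n), sex = "male", age = 60L,
    site = site,
    msi_class = ifelse(stats::runif(n) < msi_p, "MSI-H", "MSS"),
    stringsAsFactors = FALSE
  )
  cohort$tmb_per_mb <- ifelse(cohort$msi_class == "MSI-H",
                              stats::rnorm(n, 22, 4), stats::rnorm(n, 4, 1.5))
  cohort$pdl1_tps <- round(100 * stats::rbeta(n, 1.2, 3), 1)
  rep_ <- biomarker_site_comparison(cohort)
  expect_lt(rep_$msi$overall$p_value, 0.05)
  d_vs_j <- rep_$msi$pairwise[rep_$msi$pairwise$site_a == "duodenum" &
                                rep_$msi$pairwise$site_b == "jejunum", ]
  expect_lt(d_vs_j$p_value, 0.05)
  jej <- rep_$msi$per_site[rep_$msi$per_site$site == "jejunum", ]
  duo <- rep_$msi$per_site[rep_$msi$per_site$site == "duodenum", ]
  expect_gt(jej$proportion, duo$proportion)
  expect_equal(rep_$tmb$test_used, "anova")
  expect_true(!is.null(rep_$pdl1))
  expect_equal(sum(rep_$sites$n), n)
})

test_that("biomarker site comparison needs two sites and warns on empty ones", {
  cohort <- data.frame(patient_id = c("A", "B"), sex = "male", age = 60L,
                       site = "duodenum", msi_class = "MSS",
                       tmb_per_mb = c(3, 4), pdl1_tps = c(0, 10),
                       stringsAsFactors = FALSE)
  expect_error(suppressWarnings(biomarker_site_comparison(cohort)),
               class = "pp_validation_error")
  cohort2 <- rbind(cohort,
                   data.frame(patient_id = c("C", "D"), sex = "male",
                              age = 60L, site = "jejunum",
                              msi_class = c("MSI-H", "MSS"),
                              tmb_per_mb = c(20, 5), pdl1_tps = c(55, 2),
                              stringsAsFactors = FALSE))
  expect_warning(r <- biomarker_site_comparison(cohort2), "ileum")
  expect_equal(nrow(r$sites), 2L)
})
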