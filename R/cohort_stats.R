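# Cohort-level statistics: per-gene mutation frequency tables, demographic
# breakdowns, proportion and mean comparisons between groups and anatomic
# sites, multiple-testing adjustment, and the immunotherapy-biomarker
# comparison (MSI-H proportion, TMB level, PD-L1 TPS category) across
# duodenum / jejunum / ileum.
#
# A cohort is a data frame with one row per patient: patient_id, sex
# ("male"/"female"), age (years), site ("duodenum"/"jejunum"/"ileum"),
# msi_class ("MSI-H"/"MSS"), tmb_per_mb, pdl1_tps (percent, may be NA) and
# a list-column mutated_genes holding each patient's post-landscape-filter
# mutated gene symbols.

cohort_sites <- c("duodenum", "jejunum", "ileum")

validate_cohort <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0) pp_stop("cohort is empty")
  if ("site" %in% names(cohort) &&
      !all(cohort$site %in% cohort_sites)) {
    pp_stop("cohort 'site' values must be one of: ",
            paste(cohort_sites, collapse = ", "))
  }
  if ("pdl1_tps" %in% names(cohort)) {
    tps <- cohort$pdl1_tps[!is.na(cohort$pdl1_tps)]
    if (length(tps) > 0 && (min(tps) < 0 || max(tps) > 100)) {
      pp_stop("pdl1_tps must lie in [0, 100]")
    }
  }
  invisible(cohort)
}

#' Attach per-patient mutated gene sets from a variant table
#'
#' Builds the `mutated_genes` list-column from a MAF-like long table of
#' (post-landscape-filter) calls, joined on `patient_id`. Patients absent
#' from the variant table get an empty set.
#'
#' @param patients Patient metadata data frame with `patient_id`.
#' @param maf Variant table with `patient_id` and `gene` columns.
#' @return `patients` with a `mutated_genes` list-column.
#' @export
add_mutated_genes <- function(patients, maf) {
  validate_cohort(patients)
  sets <- split(as.character(maf$gene), as.character(maf$patient_id))
  patients$mutated_genes <- lapply(as.character(patients$patient_id),
                                   function(id) unique(sets[[id]] %||% character()))
  patients
}

#' Per-gene mutation frequency table
#'
#' @param cohort Cohort data frame with a `mutated_genes` list-column.
#' @param genes Gene symbols to tabulate; genes mutated in no patient
#'   report zero.
#' @return Data frame `gene`, `count`, `total`, `percentage`
#'   (two decimals).
#' @export
frequency_table <- function(cohort, genes) {
  validate_cohort(cohort)
  if (!"mutated_genes" %in% names(cohort)) {
    pp_stop("cohort lacks 'mutated_genes'; see add_mutated_genes()")
  }
  total <- nrow(cohort)
  count <- vapply(genes, function(g) {
    sum(vapply(cohort$mutated_genes, function(s) g %in% s, logical(1)))
  }, integer(1))
  data.frame(gene = genes, count = count, total = total,
             percentage = round(100 * count / total, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Demographic breakdown of a cohort
#'
#' @param cohort Cohort data frame.
#' @param field One of `"sex"`, `"site"`, `"age_ge60"` (age dichotomised at
#'   60, inclusive).
#' @param merge_jejunum_ileum For `field = "site"`, pool jejunum and ileum
#'   into one `"jejunum/ileum"` level (the pooling used for cohort-level
#'   demographics).
#' @return Data frame `level`, `count`, `percentage` (two decimals;
#'   percentages sum to 100 up to rounding).
#' @export
categorical_breakdown <- function(cohort,
                                  field = c("sex", "site", "age_ge60"),
                                  merge_jejunum_ileum = FALSE) {
  validate_cohort(cohort)
  field <- tryCatch(match.arg(field),
                    error = function(e) pp_stop("unknown field"))
  values <- switch(field,
    sex = as.character(cohort$sex),
    site = {
      s <- as.character(cohort$site)
      if (merge_jejunum_ileum) s[s %in% c("jejunum", "ileum")] <- "jejunum/ileum"
      s
    },
    age_ge60 = ifelse(cohort$age >= 60, ">=60", "<60")
  )
  tab <- table(values)
  data.frame(level = names(tab), count = as.integer(tab),
             percentage = round(100 * as.integer(tab) / nrow(cohort), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two mutation proportions
#'
#' Chi-square test without continuity correction on the 2x2 table, unless
#' any expected cell count is below 5, in which case the two-sided Fisher
#' exact test is used (the conventional switching rule; the choice is
#' recorded in `test_used`).
#'
#' @param a_mut,a_total Mutated count and group size for group A.
#' @param b_mut,b_total Mutated count and group size for group B.
#' @param test `"auto"` (default switching rule), or force `"chisq"` /
#'   `"fisher"`.
#' @return List with `test_used`, `statistic` (chi-square statistic, NA for
#'   Fisher), `p_value`, `freq_a`, `freq_b`.
#' @export
compare_proportions <- function(a_mut, a_total, b_mut, b_total,
                                test = c("auto", "chisq", "fisher")) {
  test <- match.arg(test)
  for (nm in c("a_mut", "a_total", "b_mut", "b_total")) {
    assert_count(get(nm), nm)
  }
  if (a_total == 0 || b_total == 0) pp_stop("group totals must be > 0")
  if (a_mut > a_total || b_mut > b_total) {
    pp_stop("mutated count exceeds group total")
  }
  tab <- matrix(c(a_mut, a_total - a_mut, b_mut, b_total - b_mut),
                nrow = 2L, byrow = TRUE,
                dimnames = list(group = c("a", "b"),
                                status = c("mut", "wt")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- switch(test,
    auto = any(expected < 5),
    fisher = TRUE,
    chisq = FALSE)
  if (use_fisher) {
    res <- stats::fisher.test(tab)
    list(test_used = "fisher", statistic = NA_real_, p_value = res$p.value,
         freq_a = a_mut / a_total, freq_b = b_mut / b_total)
  } else {
    res <- stats::chisq.test(tab, correct = FALSE)
    list(test_used = "chi-square", statistic = unname(res$statistic),
         p_value = res$p.value,
         freq_a = a_mut / a_total, freq_b = b_mut / b_total)
  }
}

#' Compare group means
#'
#' Two groups: unpaired t-test, Welch by default (`var_equal = TRUE` for
#' the pooled-variance Student t). More than two groups: one-way ANOVA.
#' Group summaries are mean +/- SEM with SEM = sd/sqrt(n) (n-1 denominator
#' in sd).
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @param var_equal Use pooled variance for the two-group t-test.
#' @return List with `test_used`, `statistic`, `p_value`, and `summary`
#'   (data frame `group`, `n`, `mean`, `sem`).
#' @export
compare_means <- function(groups, var_equal = FALSE) {
  if (!is.list(groups) || length(groups) < 2) {
    pp_stop("need at least two groups")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) pp_stop("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  summ <- data.frame(
    group = names(groups),
    n = sizes,
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (length(groups) == 2) {
    res <- stats::t.test(groups[[1]], groups[[2]], var.equal = var_equal)
    list(test_used = if (var_equal) "student-t" else "welch-t",
         statistic = unname(res$statistic), p_value = res$p.value,
         summary = summ)
  } else {
    dat <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), sizes))
    )
    fit <- stats::aov(value ~ group, data = dat)
    tab <- summary(fit)[[1]]
    list(test_used = "anova", statistic = tab[["F value"]][1],
         p_value = tab[["Pr(>F)"]][1], summary = summ)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input and
#' adjusted values never fall below their inputs.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    pp_stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene frequency comparison between two cohorts
#'
#' Builds the comparison table behind between-cohort mutation-frequency
#' analyses: per-gene counts in each cohort, the proportion test (with the
#' chi-square/Fisher switching rule), and BH-adjusted p-values. The second
#' cohort may be supplied as published per-gene counts rather than patient
#' records.
#'
#' @param freq_a,freq_b Data frames from [frequency_table()] (or any table
#'   with `gene`, `count`, `total`) for the two groups.
#' @param label_a,label_b Group labels recorded in the output.
#' @return Data frame, one row per shared gene: counts, totals,
#'   frequencies, `p_value`, `p_adjusted`, `test_used`.
#' @export
gene_frequency_comparison <- function(freq_a, freq_b,
                                      label_a = "A", label_b = "B") {
  genes <- intersect(freq_a$gene, freq_b$gene)
  if (length(genes) == 0) pp_stop("no shared genes to compare")
  rows <- lapply(genes, function(g) {
    a <- freq_a[match(g, freq_a$gene), ]
    b <- freq_b[match(g, freq_b$gene), ]
    cmp <- compare_proportions(a$count, a$total, b$count, b$total)
    data.frame(gene = g, group_a = label_a, group_b = label_b,
               a_mut = a$count, a_total = a$total,
               b_mut = b$count, b_total = b$total,
               freq_a = cmp$freq_a, freq_b = cmp$freq_b,
               p_value = cmp$p_value, test_used = cmp$test_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_value)
  out
}

#' PD-L1 TPS categories
#'
#' Conventional 22C3 bins: negative (< 1), low (1-49), high (>= 50);
#' configurable via `breaks`.
#'
#' @param tps Numeric TPS values in `[0, 100]`; NA allowed.
#' @param breaks Two ascending cutoffs, default `c(1, 50)`.
#' @return Factor with levels `"<1"`, `"1-49"`, `">=50"` (labels follow
#'   `breaks`).
#' @export
pdl1_category <- function(tps, breaks = c(1, 50)) {
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  labels <- c(paste0("<", breaks[1]),
              paste0(breaks[1], "-", breaks[2] - 1),
              paste0(">=", breaks[2]))
  cut(tps, breaks = c(-Inf, breaks, Inf), labels = labels, right = FALSE)
}

rxc_test <- function(tab) {
  # chi-square unless any expected cell < 5, then exact
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(test_used = "fisher", statistic = NA_real_,
         p_value = stats::fisher.test(tab)$p.value)
  } else {
    res <- stats::chisq.test(tab, correct = FALSE)
    list(test_used = "chi-square", statistic = unname(res$statistic),
         p_value = res$p.value)
  }
}

#' Immunotherapy-biomarker comparison across anatomic sites
#'
#' Compares, across the sites represented in the cohort: the MSI-H
#' proportion (overall r x 2 test plus pairwise proportion tests), the TMB
#' level (Welch t for two sites, one-way ANOVA for three; mean +/- SEM per
#' site), and the PD-L1 TPS category distribution (chi-square or Fisher).
#' Sites with no patients are dropped with a warning; at least two sites
#' must remain.
#'
#' @param cohort Cohort data frame (see module header for columns).
#' @param merge_jejunum_ileum Pool jejunum and ileum into one group.
#' @param pdl1_breaks Passed to [pdl1_category()].
#' @return List of class `"biomarker_report"` with elements `sites`
#'   (per-site n), `msi` (per-site MSI-H counts/proportions, overall test,
#'   pairwise tests), `tmb` ([compare_means()] result), `pdl1` (category
#'   table and test).
#' @export
biomarker_site_comparison <- function(cohort, merge_jejunum_ileum = FALSE,
                                      pdl1_breaks = c(1, 50)) {
  validate_cohort(cohort)
  site <- as.character(cohort$site)
  if (merge_jejunum_ileum) site[site %in% c("jejunum", "ileum")] <- "jejunum/ileum"
  levels_present <- unique(site)
  expected_levels <- if (merge_jejunum_ileum) {
    c("duodenum", "jejunum/ileum")
  } else cohort_sites
  absent <- setdiff(expected_levels, levels_present)
  if (length(absent) > 0) {
    warning("site(s) with no patients dropped: ",
            paste(absent, collapse = ", "))
  }
  if (length(levels_present) < 2) {
    pp_stop("need patients from at least two sites")
  }
  site <- factor(site, levels = intersect(expected_levels, levels_present))

  sizes <- as.data.frame(table(site = site), stringsAsFactors = FALSE)
  names(sizes) <- c("site", "n")

  # MSI-H proportion
  msi_h <- cohort$msi_class == "MSI-H"
  msi_tab <- table(site, factor(msi_h, levels = c(TRUE, FALSE),
                                labels = c("MSI-H", "MSS")))
  per_site <- data.frame(site = rownames(msi_tab),
                         n = as.integer(rowSums(msi_tab)),
                         msi_h = as.integer(msi_tab[, "MSI-H"]),
                         proportion = as.numeric(msi_tab[, "MSI-H"] /
                                                   rowSums(msi_tab)),
                         row.names = NULL, stringsAsFactors = FALSE)
  overall <- rxc_test(unclass(msi_tab))
  pairs <- utils::combn(levels(site), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- per_site[match(pr[1], per_site$site), ]
    b <- per_site[match(pr[2], per_site$site), ]
    cmp <- compare_proportions(a$msi_h, a$n, b$msi_h, b$n)
    data.frame(site_a = pr[1], site_b = pr[2], p_value = cmp$p_value,
               test_used = cmp$test_used, stringsAsFactors = FALSE)
  }))

  # TMB level
  tmb_groups <- split(cohort$tmb_per_mb, site)
  tmb <- compare_means(tmb_groups)

  # PD-L1 category distribution (patients with a TPS value)
  has_tps <- !is.na(cohort$pdl1_tps)
  pdl1 <- NULL
  if (any(has_tps)) {
    cat_tab <- table(site[has_tps],
                     pdl1_category(cohort$pdl1_tps[has_tps], pdl1_breaks))
    pdl1 <- c(list(table = cat_tab), rxc_test(unclass(cat_tab)))
  }

  structure(list(sites = sizes,
                 msi = list(per_site = per_site, overall = overall,
                            pairwise = pairwise),
                 tmb = tmb, pdl1 = pdl1),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("Biomarker comparison across sites\n")
  cat("  group sizes: ",
      paste(sprintf("%s=%d", x$sites$site, x$sites$n), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  MSI-H proportion: overall %s p = %.4g\n",
              x$msi$overall$test_used, x$msi$overall$p_value))
  for (i in seq_len(nrow(x$msi$per_site))) {
    r <- x$msi$per_site[i, ]
    cat(sprintf("    %-14s %d/%d (%.1f%%)\n", r$site, r$msi_h, r$n,
                100 * r$proportion))
  }
  cat(sprintf("  TMB: %s p = %.4g\n", x$tmb$test_used, x$tmb$p_value))
  for (i in seq_len(nrow(x$tmb$summary))) {
    r <- x$tmb$summary[i, ]
    cat(sprintf("    %-14s %.2f +/- %.2f mut/Mb (n=%d)\n",
                r$group, r$mean, r$sem, r$n))
  }
  if (!is.null(x$pdl1)) {
    cat(sprintf("  PD-L1 TPS categories: %s p = %.4g\n",
                x$pdl1$test_used, x$pdl1$p_value))
  }
  invisible(x)
}
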