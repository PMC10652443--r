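# Readers and writers for the exchanged plain-text formats. All tables are
# UTF-8 TSV with a header row and '.' decimal separator. Readers validate
# structure and reject rather than coerce: a missing column or an
# unparseable numeric is an error (with the offending line number), not a
# silent NA.

read_tsv_checked <- function(path, required, numeric_cols = character(),
                             integer_cols = character(),
                             logical_cols = character()) {
  if (!file.exists(path)) pp_stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    pp_stop("file ", path, " is missing required column(s): ",
            paste(missing, collapse = ", "))
  }
  convert <- function(col, fn, what) {
    x <- raw[[col]]
    suppressWarnings(v <- fn(x))
    bad <- which(is.na(v) & !(x %in% c("NA", "")))
    if (length(bad) > 0) {
      pp_stop("column '", col, "' of ", path, ": cannot parse ", what,
              " value '", x[bad[1]], "' at line ", bad[1] + 1L,
              " (1 header line)")
    }
    v
  }
  for (col in intersect(numeric_cols, names(raw))) {
    raw[[col]] <- convert(col, as.numeric, "numeric")
  }
  for (col in intersect(integer_cols, names(raw))) {
    raw[[col]] <- convert(col, function(x) {
      v <- as.numeric(x)
      ifelse(!is.na(v) & v == floor(v), as.integer(v), NA_integer_)
    }, "integer")
  }
  for (col in intersect(logical_cols, names(raw))) {
    raw[[col]] <- convert(col, function(x) {
      as.logical(toupper(x))
    }, "logical")
  }
  raw
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

maf_columns <- c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                 "variant_type", "functional_class", "af", "depth",
                 "alt_reads", "popfreq", "is_driver")

functional_class_vocab <- c("missense", "silent", "stopgain", "stoploss",
                            "frameshift_indel", "nonframeshift_indel",
                            "other")

#' Read a MAF-like variant table
#'
#' Columns: `patient_id, gene, chrom, pos, ref, alt, variant_type,
#' functional_class, af, depth, alt_reads, popfreq, is_driver`. Functional
#' classes outside the vocabulary are mapped to `"other"` with a warning;
#' row order is preserved.
#'
#' @param path TSV path.
#' @return Data frame of typed variant records.
#' @export
read_maf_like <- function(path) {
  df <- read_tsv_checked(path, maf_columns,
                         numeric_cols = c("af", "popfreq"),
                         integer_cols = c("pos", "depth", "alt_reads"),
                         logical_cols = "is_driver")
  unknown <- !(df$functional_class %in% functional_class_vocab)
  if (any(unknown)) {
    warning("functional_class value(s) outside vocabulary mapped to 'other': ",
            paste(unique(df$functional_class[unknown]), collapse = ", "))
    df$functional_class[unknown] <- "other"
  }
  df
}

#' Write a MAF-like variant table
#' @param calls Variant data frame.
#' @param path Output TSV path.
#' @export
write_maf_like <- function(calls, path) {
  write_tsv(calls[, intersect(c(maf_columns, "p_value"), names(calls)),
                  drop = FALSE], path)
}

#' Read a pileup table
#'
#' Columns: `chrom, pos, ref, alt, depth, alt_reads, alt_fwd, alt_rev,
#' mean_bq` (plus optional `patient_id`).
#' @param path TSV path.
#' @return Data frame of pileup records (validated).
#' @export
read_pileup_tsv <- function(path) {
  df <- read_tsv_checked(path, pileup_columns,
                         numeric_cols = "mean_bq",
                         integer_cols = c("pos", "depth", "alt_reads",
                                          "alt_fwd", "alt_rev"))
  validate_pileups(df)
  df
}

#' Write a pileup table
#' @param pileups Pileup data frame.
#' @param path Output TSV path.
#' @export
write_pileup_tsv <- function(pileups, path) write_tsv(pileups, path)

#' Read microsatellite locus histograms
#'
#' Columns: `sample_id, locus_id, repeat_length, read_count`. Duplicate
#' (sample, locus, length) rows are summed with a warning; negative counts
#' are an error.
#' @param path TSV path.
#' @return Long data frame of histograms.
#' @export
read_locus_histograms <- function(path) {
  df <- read_tsv_checked(path,
                         c("sample_id", "locus_id", "repeat_length",
                           "read_count"),
                         integer_cols = c("repeat_length", "read_count"))
  if (any(df$read_count < 0)) {
    pp_stop("negative read_count at line ",
            which(df$read_count < 0)[1] + 1L, " of ", path)
  }
  key <- paste(df$sample_id, df$locus_id, df$repeat_length, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (sample, locus, repeat_length) rows summed")
    agg <- stats::aggregate(read_count ~ sample_id + locus_id + repeat_length,
                            data = df, FUN = sum)
    df <- agg[order(agg$sample_id, agg$locus_id, agg$repeat_length), ,
              drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write microsatellite locus histograms
#' @param profiles Long histogram data frame.
#' @param path Output TSV path.
#' @export
write_locus_histograms <- function(profiles, path) write_tsv(profiles, path)

#' Read an MSS baseline panel
#'
#' Columns: `locus_id, cut_point, p_i` with `cut_point >= 1` and
#' `p_i` in `[0, 1]`.
#' @param path TSV path.
#' @return Baseline data frame.
#' @export
read_baseline_panel <- function(path) {
  df <- read_tsv_checked(path, c("locus_id", "cut_point", "p_i"),
                         numeric_cols = "p_i", integer_cols = "cut_point")
  if (any(df$cut_point < 1)) pp_stop("cut_point must be >= 1")
  if (any(df$p_i < 0 | df$p_i > 1)) pp_stop("p_i must lie in [0, 1]")
  df
}

#' Write an MSS baseline panel
#' @param baseline Baseline data frame.
#' @param path Output TSV path.
#' @export
write_baseline_panel <- function(baseline, path) write_tsv(baseline, path)

#' Read a patient metadata table
#'
#' Columns: `patient_id, sex, age, site, pdl1_tps` (optional extra columns
#' such as `msi_class`, `tmb_per_mb` pass through typed).
#' @param path TSV path.
#' @return Data frame of patient records.
#' @export
read_patient_table <- function(path) {
  df <- read_tsv_checked(path,
                         c("patient_id", "sex", "age", "site", "pdl1_tps"),
                         numeric_cols = c("pdl1_tps", "tmb_per_mb"),
                         integer_cols = "age")
  if (!all(df$sex %in% c("male", "female"))) {
    pp_stop("sex must be 'male' or 'female'")
  }
  if (!all(df$site %in% cohort_sites)) {
    pp_stop("site must be one of: ", paste(cohort_sites, collapse = ", "))
  }
  df
}

#' Write a patient metadata table
#' @param patients Patient data frame (list-columns dropped).
#' @param path Output TSV path.
#' @export
write_patient_table <- function(patients, path) {
  keep <- !vapply(patients, is.list, logical(1))
  write_tsv(patients[, keep, drop = FALSE], path)
}

#' Write a minimal VCF v4.2
#'
#' One record per call with `DP`, `AF` and `AD` (alt depth) in INFO.
#' Records are sorted by `(chrom, pos)`; an empty call set writes a valid
#' header-only file.
#'
#' @param calls Variant calls with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `af`, `depth`, `alt_reads`).
#' @param path Output path.
#' @export
write_vcf_minimal <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelprofiler",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt read depth\">",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  lines <- header
  if (!is.null(calls) && nrow(calls) > 0) {
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    contigs <- unique(as.character(calls$chrom))
    lines <- c(header[1:5],
               paste0("##contig=<ID=", contigs, ">"),
               header[7],
               sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AF=%.6g;AD=%d",
                       calls$chrom, as.integer(calls$pos), calls$ref,
                       calls$alt,
                       as.integer(calls$depth %||% 0),
                       as.numeric(calls$af %||% 0),
                       as.integer(calls$alt_reads %||% 0)))
  }
  writeLines(lines, path)
  invisible(path)
}

pipeline_config_keys <- list(
  caller = c("error_rate", "alpha_call", "min_af", "min_alt_reads",
             "max_strand_bias_p", "min_base_quality", "max_popfreq",
             "tumor_content_min"),
  msi = c("alpha", "top_k", "score_threshold", "side"),
  tmb = c("region_size_mb", "cutoff"),
  stats = c("merge_jejunum_ileum", "alpha", "adjust"),
  run = c("seed", "log_level", "outdir")
)

#' Read and validate a pipeline configuration (YAML)
#'
#' Sections `caller`, `msi`, `tmb`, `stats`, `run`; unknown sections or
#' keys are rejected. Numeric parameters are range-checked by the
#' constructors they feed ([caller_params()] etc.).
#'
#' @param path YAML path.
#' @return Named list of configuration sections.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) pp_stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(pipeline_config_keys))
  if (length(unknown) > 0) {
    pp_stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_config_keys[[sec]])
    if (length(bad) > 0) {
      pp_stop("unknown key(s) in section '", sec, "': ",
              paste(bad, collapse = ", "))
    }
  }
  if (!is.null(cfg$caller)) do.call(caller_params, cfg$caller)
  cfg
}
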