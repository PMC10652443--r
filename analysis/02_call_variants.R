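#!/usr/bin/env Rscript
# Stage 2: run the binomial SNV caller on every patient's pileups and
# check detection against the simulated truth. Calls are written as TSV
# and as a minimal VCF.

suppressPackageStartupMessages(library(panelprofiler))

outdir <- "results/synthetic"
pileups <- read_pileup_tsv(file.path(outdir, "pileups.tsv"))
truth <- readRDS(file.path(outdir, "truth.rds"))
params <- caller_params()

by_patient <- split(pileups, pileups$patient_id)
calls <- do.call(rbind, lapply(names(by_patient), function(pid) {
  cc <- call_snvs(by_patient[[pid]], params)
  if (nrow(cc) > 0) cc$patient_id <- pid
  cc
}))
write_maf_like(calls, file.path(outdir, "snv_calls.tsv"))
write_vcf_minimal(calls, file.path(outdir, "snv_calls.vcf"))

# detection vs truth (SNVs with AF in the somatic range were simulated)
tv <- truth$variants
tv <- tv[paste(tv$chrom, tv$pos) %in% paste(pileups$chrom, pileups$pos), ]
hit <- paste(calls$patient_id, calls$chrom, calls$pos) %in%
  paste(tv$patient_id, tv$chrom, tv$pos)
sens <- sum(hit) / nrow(tv)
cat(sprintf("Called %d SNVs across %d patients.\n", nrow(calls),
            length(by_patient)))
cat(sprintf("Sensitivity vs simulated truth: %.3f (%d/%d true sites).\n",
            sens, sum(hit), nrow(tv)))
cat(sprintf("False calls (sites not in truth): %d.\n", sum(!hit)))
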