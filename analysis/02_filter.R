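#!/usr/bin/env Rscript
# Stage 2: SNP quality-filter chain with audit trail.
#
# Individuals are kept above 0.35 call rate; loci must pass, in order:
# repeatability > 0.95, read balance within [0.15, 0.85], coverage not
# above 3.5x the median, call rate >= 0.8, one SNP per contig (greatest
# repeatability), and minor-allele frequency >= 0.02.

library(markerstruct)

dat <- file.path("results", "data")
out <- file.path("results", "filtered")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

snp <- read_structure_file(file.path(dat, "snp.str"), marker = "snp")
report <- read.csv(file.path(dat, "dart_report.csv"))

res <- filter_chain(snp, report)
write_structure_file(res$genotypes, file.path(out, "snp_filtered.str"))
audit <- res$report
audit$removed_ids <- vapply(audit$removed_ids, paste, character(1),
                            collapse = ";")
write.csv(audit, file.path(out, "filter_report.csv"), row.names = FALSE)

cat("filter audit:\n")
print(audit[, c("step", "n_loci_before", "n_loci_after")])
cat(sprintf("individuals: %d -> %d; loci: %d -> %d\n",
            n_ind(snp), n_ind(res$genotypes),
            n_loci(snp), n_loci(res$genotypes)))
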