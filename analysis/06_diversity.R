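#!/usr/bin/env Rscript
# Stage 6: genetic diversity and its spatial structure.
#
# Per marker: standardized multilocus heterozygosity (sMLH) per
# individual, medians per locality, the cross-marker Pearson correlation
# of individual sMLH, and ordinary least squares of sMLH on latitude and
# longitude (the refugial-expansion gradient).

library(markerstruct)

out <- file.path("results", "diversity")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

snp <- read_structure_file(file.path("results", "filtered",
                                     "snp_filtered.str"), marker = "snp")
ms <- read_structure_file(file.path("results", "data", "microsat.str"),
                          marker = "microsat")
locs <- read.csv(file.path("results", "data", "localities.csv"))

div <- list(snp = diversity_table(snp, locs),
            microsat = diversity_table(ms, locs))

for (marker in names(div)) {
  d <- div[[marker]]
  write.csv(data.frame(ind = names(d$smlh), smlh = d$smlh),
            file.path(out, paste0("smlh_", marker, ".csv")),
            row.names = FALSE)
  write.csv(data.frame(locality = names(d$medians), median = d$medians),
            file.path(out, paste0("medians_", marker, ".csv")),
            row.names = FALSE)
  g <- d$gradient
  cat(sprintf(
    "[%s] beta_lat = %.3f (p = %.2g); beta_lon = %.3f (p = %.2g); n = %d\n",
    marker, g$beta_latitude, g$p_latitude, g$beta_longitude,
    g$p_longitude, g$n))
}

shared <- intersect(names(div$snp$smlh), names(div$microsat$smlh))
corr <- marker_correlation(div$snp$smlh[shared], div$microsat$smlh[shared])
cat(sprintf("cross-marker sMLH correlation: r = %.3f (p = %.2g, n = %d)\n",
            corr$r, corr$p, corr$n))
jsonlite::write_json(
  list(correlation = corr,
       gradient_snp = div$snp$gradient[c("beta_latitude", "p_latitude",
                                         "beta_longitude", "p_longitude")],
       gradient_microsat = div$microsat$gradient[c("beta_latitude",
                                                   "p_latitude",
                                                   "beta_longitude",
                                                   "p_longitude")]),
  file.path(out, "diversity_summary.json"), auto_unbox = TRUE, digits = NA)
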