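#!/usr/bin/env Rscript
# Stage 5: congruence of ancestry matrices within and between markers.
#
# Replicate runs at each K are aligned (CLUMPP-style SSC maximization),
# grouped into modes, and compared across markers; individual admixture is
# summarized with the coefficient of admixture (CA). The headline contrast
# is the distribution of intra-marker versus inter-marker SSC values and
# the mean CA per marker.

library(markerstruct)

out <- file.path("results", "qcompare")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_q <- function(marker, K) {
  d <- file.path("results", "runs", marker)
  qf <- list.files(d, pattern = sprintf("^K%d_rep\\d+_Q\\.txt$", K),
                   full.names = TRUE)
  setNames(lapply(qf, read_qmatrix),
           paste0(marker, "_", sub("_Q\\.txt$", "", basename(qf))))
}

rows <- list()
for (K in 2:4) {
  qs <- c(read_q("snp", K), read_q("ms", K))
  labs <- ifelse(grepl("^snp", names(qs)), "snp", "microsat")
  pm <- pairwise_ssc_matrix(qs, labels = labs)
  idx <- which(upper.tri(pm$ssc), arr.ind = TRUE)
  rows[[length(rows) + 1]] <- data.frame(
    K = K, run_a = rownames(pm$ssc)[idx[, 1]],
    run_b = colnames(pm$ssc)[idx[, 2]],
    marker_a = labs[idx[, 1]], marker_b = labs[idx[, 2]],
    ssc = pm$ssc[idx])

  for (marker in c("snp", "ms")) {
    ql <- read_q(marker, K)
    modes <- find_modes(ql, threshold = 0.9)
    cons <- modes$consensus_Q[[modes$major_mode]]
    write_qmatrix(cons, file.path(out, sprintf("consensus_%s_K%d.txt",
                                               marker, K)))
    ca <- coefficient_of_admixture(cons)
    cat(sprintf("[K=%d %s] %d mode(s); major mode %d/%d runs; mean CA %.3f\n",
                K, marker, length(modes$groups),
                length(modes$groups[[modes$major_mode]]), length(ql),
                ca$mean))
  }
}
long <- do.call(rbind, rows)
write.csv(long, file.path(out, "ssc_pairs.csv"), row.names = FALSE)

intra <- function(df, m) df$ssc[df$marker_a == m & df$marker_b == m]
inter <- function(df) df$ssc[df$marker_a != df$marker_b]
for (K in 2:4) {
  d <- long[long$K == K, ]
  cat(sprintf(
    "K=%d: intra-SNP SSC %.2f-%.2f; intra-microsat %.2f-%.2f; inter %.2f-%.2f\n",
    K, min(intra(d, "snp")), max(intra(d, "snp")),
    min(intra(d, "microsat")), max(intra(d, "microsat")),
    min(inter(d)), max(inter(d))))
}
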