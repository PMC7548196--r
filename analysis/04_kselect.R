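#!/usr/bin/env Rscript
# Stage 4: K selection and convergence diagnostics.
#
# Per marker and per K: Gelman-Rubin across replicate log-likelihood
# traces, mean lnP(X|K) and Pr[X|K], Evanno's delta-K, and the parsimony
# index. A model-free neighbour-joining tree on allele-sharing distances
# gives an assumption-light cross-check of the clustering.

library(markerstruct)

out <- file.path("results", "kselect")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_runs <- function(dir) {
  qf <- list.files(dir, pattern = "_Q\\.txt$", full.names = TRUE)
  runs <- lapply(qf, function(f) {
    nm <- sub("_Q\\.txt$", "", basename(f))
    K <- as.integer(sub("K(\\d+)_rep\\d+", "\\1", nm))
    tr <- read.csv(file.path(dir, paste0(nm, "_trace.csv")))
    list(K = K, Q = read_qmatrix(f), loglik_trace = tr$loglik,
         alpha_trace = tr$alpha)
  })
  names(runs) <- sub("_Q\\.txt$", "", basename(qf))
  class(runs) <- "run_set"
  runs
}

for (marker in c("snp", "ms")) {
  runs <- read_runs(file.path("results", "runs", marker))
  tab <- kselection_table(runs)
  write.csv(tab, file.path(out, paste0("kselect_", marker, ".csv")),
            row.names = FALSE)
  best_dk <- tab$K[which.max(tab$delta_k)]
  best_pi <- tab$K[which.max(tab$parsimony_index)]
  cat(sprintf("[%s] delta-K peak at K=%d; parsimony index maximal at K=%d\n",
              marker, best_dk, best_pi))
  print(tab[, c("K", "mean_lnP", "sd_lnP", "delta_k", "parsimony_index",
                "gelman_rubin")], digits = 4)
}

snp <- read_structure_file(file.path("results", "filtered",
                                     "snp_filtered.str"), marker = "snp")
tree <- neighbor_joining(allele_sharing_distance(snp))
ape::write.tree(tree, file.path(out, "nj_snp.nwk"))
cat("NJ tree written to", file.path(out, "nj_snp.nwk"), "\n")
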