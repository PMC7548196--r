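#!/usr/bin/env Rscript
# Stage 3: Bayesian admixture clustering for both marker panels.
#
# lambda is first estimated at K = 1 (three replicate runs, averaged) for
# the SNPs; microsatellites use lambda = 1. Each marker then gets
# replicate runs across K = 1..5 under the correlated-frequency model.
# Run lengths are desk-scale (see the methods vignette): 1,600 burn-in /
# 400 recorded sweeps for SNPs, 2,000 / 600 for the 15 microsatellites.

library(markerstruct)

out <- file.path("results", "runs")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

snp <- read_structure_file(file.path("results", "filtered",
                                     "snp_filtered.str"), marker = "snp")
ms <- read_structure_file(file.path("results", "data", "microsat.str"),
                          marker = "microsat")

lam <- estimate_lambda(snp, mcmc_options(burnin = 400, iterations = 400,
                                         seed = 101))
cat(sprintf("lambda (K=1, 3 replicates): %.3f (per replicate: %s)\n",
            lam$lambda, paste(round(lam$per_replicate, 3), collapse = ", ")))

K_range <- 1:4
n_rep <- 3

# slower alpha proposal keeps exploration alive within short burn-ins
# (see the methods vignette on run lengths at desk scale)
runs_snp <- replicate_runs(snp, K_range, n_rep,
                           mcmc_options(burnin = 1600, iterations = 400,
                                        lambda = lam$lambda,
                                        alpha_proposal_sd = 0.01, seed = 300))
runs_ms <- replicate_runs(ms, K_range, n_rep,
                          mcmc_options(burnin = 2000, iterations = 600,
                                       lambda = 1,
                                       alpha_proposal_sd = 0.01, seed = 400))

for (marker in c("snp", "ms")) {
  runs <- if (marker == "snp") runs_snp else runs_ms
  d <- file.path(out, marker)
  dir.create(d, showWarnings = FALSE)
  for (nm in names(runs)) {
    write_qmatrix(runs[[nm]]$Q, file.path(d, paste0(nm, "_Q.txt")))
    write.csv(data.frame(step = seq_along(runs[[nm]]$loglik_trace),
                         loglik = runs[[nm]]$loglik_trace,
                         alpha = runs[[nm]]$alpha_trace),
              file.path(d, paste0(nm, "_trace.csv")), row.names = FALSE)
  }
}
writeLines(sprintf("%.6f", lam$lambda), file.path(out, "lambda_snp.txt"))
cat(sprintf("wrote %d SNP runs and %d microsatellite runs under %s\n",
            length(runs_snp), length(runs_ms), out))
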