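#!/usr/bin/env Rscript
# Stage 1: generate the paired SNP / microsatellite study dataset.
#
# Two marker panels are drawn for the same 90 individuals from a K = 3
# admixture model with correlated allele frequencies (F = 0.05 per
# population, alpha = 0.1), 15 localities ordered south-to-north with a
# founder-event heterozygosity cline of -0.08 sMLH units per degree
# latitude, and 7.6% missing calls. DArT-style locus metadata carries
# planted quality violations so stage 2's audit can be checked.

library(markerstruct)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(K_true = 3, n_individuals = 90, n_snp_loci = 800,
                  n_microsat_loci = 15, alpha_sim = 0.1,
                  F_k = rep(0.05, 3), microsat_allele_count = 10,
                  missing_rate = 0.076, n_localities = 15,
                  gradient_slope = -0.08, seed = 20200721)
sim <- simulate_dataset(cfg)

# plant known violations of every SNP quality rule
ids <- sim$snp$locus_ids
snp <- plant_genotype_violations(sim$snp,
                                 low_callrate_loci = ids[41:50],
                                 callrate = 0.5,
                                 low_maf_loci = ids[61:70],
                                 seed = cfg$seed + 1)
plan <- dart_plan(low_repavg = ids[1:10], unbalanced = ids[11:20],
                  high_coverage = ids[21:30],
                  contig_groups = list(ids[31:32], ids[33:34]),
                  contig_repavg = list(c(0.99, 0.97), c(0.98, 0.96)))
report <- make_dart_report(snp, plan)

write_structure_file(snp, file.path(out, "snp.str"))
write_structure_file(sim$microsat, file.path(out, "microsat.str"))
write.csv(report, file.path(out, "dart_report.csv"), row.names = FALSE)
write.csv(sim$localities, file.path(out, "localities.csv"), row.names = FALSE)
tq <- data.frame(ind = sim$snp$ind_ids, locality = sim$truth$locality_ids,
                 sim$truth$coordinates, true_Q = I(sim$truth$true_Q))
write.csv(cbind(tq[1:4], as.data.frame(sim$truth$true_Q)),
          file.path(out, "truth_Q.csv"), row.names = FALSE)

cat(sprintf("wrote %d SNP loci, %d microsat loci for %d individuals (%.1f%% missing)\n",
            n_loci(snp), n_loci(sim$microsat), n_ind(snp),
            100 * missing_fraction(snp)))
cat(sprintf("planted violations: repavg %s; balance %s; coverage %s; callrate %s; maf %s\n",
            "1-10", "11-20", "21-30", "41-50", "61-70"))
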