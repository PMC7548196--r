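test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(K_true = 0), "K_true")
  expect_error(sim_config(F_k = c(0.5, 1.2), K_true = 2), "F_k")
  expect_error(sim_config(F_k = 0), "F_k")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_individuals = -5), "positive")
  expect_error(sim_config(n_localities = 200, n_individuals = 50),
               "n_localities")
})

test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  cfg <- sim_config(K_true = 2, n_individuals = 20, n_snp_loci = 50,
                    n_microsat_loci = 5, seed = 42)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$snp$alleles, s2$snp$alleles)
  expect_identical(s1$microsat$alleles, s2$microsat$alleles)
  expect_identical(s1$truth$true_Q, s2$truth$true_Q)
  cfg$seed <- 43L
  s3 <- simulate_dataset(cfg)
  expect_false(identical(s1$snp$alleles, s3$snp$alleles))
})

test_that("true ancestries are simplex rows and marker allele counts respect bounds", {
  cfg <- sim_config(K_true = 3, n_individuals = 40, n_snp_loci = 100,
                    n_microsat_loci = 10, microsat_allele_count = 6,
                    alpha_sim = 0.5, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_lt(max(abs(rowSums(sim$truth$true_Q) - 1)), 1e-9)
  expect_true(all(sim$truth$true_Q >= 0))
  expect_true(all(alleles_per_locus(sim$snp) <= 2))
  expect_true(all(alleles_per_locus(sim$microsat) <= 6))
})

test_that("a single ancestral population yields Hardy-Weinberg genotype frequencies", {
  cfg <- sim_config(K_true = 1, n_individuals = 500, n_snp_loci = 200,
                    F_k = 1e-4, alpha_sim = 1, n_localities = 5, seed = 8)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$true_Q == 1))
  # chi-square goodness of fit of genotype counts to HWE at the observed
  # allele frequency, per locus
  pvals <- vapply(seq_len(n_loci(sim$snp)), function(l) {
    a1 <- sim$snp$alleles[, l, 1]; a2 <- sim$snp$alleles[, l, 2]
    n11 <- sum(a1 == 1 & a2 == 1); n22 <- sum(a1 == 2 & a2 == 2)
    n12 <- sum(a1 != a2)
    n <- n11 + n12 + n22
    p <- (2 * n11 + n12) / (2 * n)
    exp_cnt <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(exp_cnt < 1)) return(NA_real_)
    suppressWarnings(stats::chisq.test(c(n11, n12, n22), p = exp_cnt / n)$p.value)
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("tiny admixture concentration produces nearly pure individuals", {
  # exact oracle: P(max q > 0.99) = 3 P(Beta(0.01, 0.02) > 0.99) = 0.9125
  # for a symmetric Dirichlet(0.01) on three clusters
  oracle_frac <- 3 * pbeta(0.99, 0.01, 0.02, lower.tail = FALSE)
  expect_equal(oracle_frac, 0.9125, tolerance = 1e-4)

  cfg <- sim_config(K_true = 3, n_individuals = 1000, n_snp_loci = 5,
                    alpha_sim = 0.01, F_k = rep(0.2, 3), n_localities = 10,
                    seed = 5)
  sim <- simulate_dataset(cfg)
  frac <- mean(apply(sim$truth$true_Q, 1, max) > 0.99)
  expect_lt(abs(frac - oracle_frac), 0.04)
  # and virtually everyone is strongly assigned to a single cluster
  expect_gte(mean(apply(sim$truth$true_Q, 1, max) > 0.9), 0.93)
})

test_that("F-model drift produces the expected FST between pure groups", {
  cfg <- sim_config(K_true = 2, n_individuals = 200, n_snp_loci = 500,
                    F_k = c(0.2, 0.2), alpha_sim = 0.01, n_localities = 4,
                    seed = 1)
  sim <- simulate_dataset(cfg)
  grp <- apply(sim$truth$true_Q, 1, which.max)
  # brute-force Hudson-style FST estimator written here as the oracle
  fst_l <- vapply(seq_len(n_loci(sim$snp)), function(l) {
    p <- vapply(1:2, function(g) {
      a <- c(sim$snp$alleles[grp == g, l, 1], sim$snp$alleles[grp == g, l, 2])
      mean(a == 1)
    }, numeric(1))
    num <- (p[1] - p[2])^2
    den <- p[1] * (1 - p[2]) + p[2] * (1 - p[1])
    c(num, den)
  }, numeric(2))
  fst <- mean(fst_l[1, ]) / mean(fst_l[2, ])
  expect_lt(abs(fst - 0.2), 0.05)
})

test_that("vanishing drift leaves population frequencies at the ancestral values", {
  cfg <- sim_config(K_true = 2, n_individuals = 4, n_snp_loci = 1000,
                    F_k = c(1e-4, 1e-4), n_localities = 2, seed = 2)
  sim <- simulate_dataset(cfg)
  dev <- max(vapply(seq_len(1000), function(l) {
    max(abs(t(sim$truth$population_freqs$snp[[l]]) -
            sim$truth$ancestral_freqs$snp[[l]]))
  }, numeric(1)))
  expect_lt(dev, 0.02)
})

test_that("missing-data injection hits the requested rate", {
  g <- random_snp_geno(100, 100, seed = 4)
  expect_identical(inject_missing(g, 0)$alleles, g$alleles)

  gm <- inject_missing(g, 0.5, seed = 9)
  expect_gte(missing_fraction(gm), 0.45)
  expect_lte(missing_fraction(gm), 0.55)

  # both copies of a call are always blanked together
  expect_identical(is.na(gm$alleles[, , 1]), is.na(gm$alleles[, , 2]))

  g2 <- random_snp_geno(100, 100, seed = 5)
  gm2 <- inject_missing(g2, 0.076, seed = 10)
  n_missing <- sum(is.na(gm2$alleles[, , 1]))
  expect_gte(n_missing, 690)
  expect_lte(n_missing, 830)
})

test_that("dart report defaults are clean and planted violations are recorded", {
  g <- random_snp_geno(20, 30, seed = 6)
  rep0 <- make_dart_report(g, dart_plan())
  expect_true(all(rep0$rep_avg == 0.99))
  expect_true(all(rep0$allele_read_proportion == 0.5))
  expect_true(all(rep0$mean_coverage == stats::median(rep0$mean_coverage)))
  expect_equal(anyDuplicated(rep0$contig_id), 0L)

  planted <- g$locus_ids[1:10]
  rep1 <- make_dart_report(g, dart_plan(low_repavg = planted))
  expect_setequal(rep1$locus_id[rep1$rep_avg < 0.95], planted)

  rep2 <- make_dart_report(
    g, dart_plan(contig_groups = list(g$locus_ids[4:5]),
                 contig_repavg = list(c(0.99, 0.97))))
  expect_equal(rep2$contig_id[4], rep2$contig_id[5])
  expect_equal(rep2$rep_avg[4:5], c(0.99, 0.97))

  gm <- genotype_matrix(array(1L, c(3, 2, 2)), marker = "microsat")
  expect_error(make_dart_report(gm), "SNP")
})

test_that("the latitudinal founder cline lowers heterozygosity northwards", {
  cfg <- sim_config(K_true = 1, n_individuals = 90, n_snp_loci = 400,
                    F_k = 0.5, alpha_sim = 1, n_localities = 9,
                    gradient_slope = -0.08, seed = 12)
  sim <- simulate_dataset(cfg)
  het <- vapply(seq_len(n_ind(sim$snp)), function(i)
    mean(sim$snp$alleles[i, , 1] != sim$snp$alleles[i, , 2]), numeric(1))
  lat <- sim$truth$coordinates$latitude
  south <- het[lat <= stats::median(lat)]
  north <- het[lat > stats::median(lat)]
  expect_gt(mean(south), mean(north))
})
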