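test_that("the log-likelihood matches hand computations", {
  # one heterozygous diploid at one biallelic locus, K = 1, p = (0.5, 0.5)
  g <- geno_from_mats(matrix(1L), matrix(2L))
  Q <- matrix(1, 1, 1)
  P <- list(matrix(c(0.5, 0.5), 1, 2))
  expect_equal(log_likelihood(g, Q, P), log(0.5) + log(0.5))
  expect_equal(log_likelihood(g, Q, P), -1.3863, tolerance = 1e-4)

  # all genotypes missing: empty sum
  gm <- geno_from_mats(matrix(NA_integer_, 2, 2), matrix(NA_integer_, 2, 2))
  Qm <- matrix(1, 2, 1)
  Pm <- list(matrix(c(0.5, 0.5), 1, 2), matrix(c(0.5, 0.5), 1, 2))
  expect_equal(log_likelihood(gm, Qm, Pm), 0)

  # pure individuals in clusters fixed for their own allele: probability 1
  g2 <- geno_from_mats(rbind(1L, 2L), rbind(1L, 2L))
  Q2 <- rbind(c(1, 0), c(0, 1))
  P2 <- list(rbind(c(1, 0), c(0, 1)))
  expect_equal(log_likelihood(g2, Q2, P2), 0)

  # inconsistent support: observed allele with zero mixture probability
  P3 <- list(rbind(c(1, 0), c(1, 0)))
  expect_error(log_likelihood(g2, Q2, P3), "zero mixture")
})

test_that("K = 1 returns a single column of ones and a finite trace", {
  g <- random_snp_geno(12, 30, seed = 31)
  run <- run_admixture_mcmc(g, 1, mcmc_options(burnin = 20, iterations = 40,
                                               seed = 2))
  expect_equal(unname(run$Q), matrix(1, 12, 1))
  expect_true(all(is.finite(run$loglik_trace)))
  expect_length(run$loglik_trace, 40)
})

test_that("chains are reproducible under a fixed seed", {
  g <- random_snp_geno(15, 40, seed = 32)
  o <- mcmc_options(burnin = 50, iterations = 100, seed = 7)
  r1 <- run_admixture_mcmc(g, 2, o)
  r2 <- run_admixture_mcmc(g, 2, o)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$loglik_trace, r2$loglik_trace)
  o$seed <- 8L
  r3 <- run_admixture_mcmc(g, 2, o)
  expect_false(identical(r1$loglik_trace, r3$loglik_trace))
})

test_that("recorded state respects simplex and prior-support invariants", {
  g <- random_snp_geno(10, 25, seed = 33)
  run <- run_admixture_mcmc(g, 3, mcmc_options(burnin = 30, iterations = 60,
                                               store_q_draws = TRUE, seed = 3))
  expect_lt(max(abs(rowSums(run$Q) - 1)), 1e-9)
  for (pm in run$P) expect_lt(max(abs(rowSums(pm) - 1)), 1e-9)
  expect_true(all(run$alpha_trace > 0 & run$alpha_trace <= 10))
  qd <- run$q_draws
  expect_equal(dim(qd), c(3, 10, 60))
  expect_lt(max(abs(apply(qd, c(2, 3), sum) - 1)), 1e-9)
})

test_that("independent runs agree up to label switching", {
  # posterior means carry Monte Carlo error, so agreement is near-exact
  # only once the recorded window is long enough
  cfg <- sim_config(K_true = 2, n_individuals = 60, n_snp_loci = 300,
                    F_k = c(0.05, 0.05), alpha_sim = 0.05, n_localities = 6,
                    seed = 34)
  sim <- simulate_dataset(cfg)
  r1 <- run_admixture_mcmc(sim$snp, 2, mcmc_options(burnin = 2000,
                                                    iterations = 2000,
                                                    seed = 1))
  r2 <- run_admixture_mcmc(sim$snp, 2, mcmc_options(burnin = 2000,
                                                    iterations = 2000,
                                                    seed = 99))
  al <- align_qmatrices(r1$Q, r2$Q)
  expect_gt(al$ssc, 0.95)
})

test_that("replicate_runs produces independent, well-labelled runs", {
  g <- random_snp_geno(10, 20, seed = 35)
  runs <- replicate_runs(g, 1, n_replicates = 3,
                         mcmc_options(burnin = 10, iterations = 20, seed = 5))
  expect_length(runs, 3)
  expect_named(runs, c("K1_rep1", "K1_rep2", "K1_rep3"))
  expect_true(all(vapply(runs, function(r) ncol(r$Q) == 1, logical(1))))

  runs2 <- replicate_runs(g, 1:2, n_replicates = 2,
                          mcmc_options(burnin = 10, iterations = 30, seed = 6))
  expect_length(runs2, 4)
  traces <- lapply(runs_at_k(runs2, 2), function(r) r$loglik_trace)
  expect_false(identical(traces[[1]], traces[[2]]))
})

test_that("model fit improves at the true K in replicate comparisons", {
  cfg <- sim_config(K_true = 2, n_individuals = 40, n_snp_loci = 150,
                    F_k = c(0.05, 0.05), alpha_sim = 0.05, seed = 36)
  sim <- simulate_dataset(cfg)
  runs <- replicate_runs(sim$snp, 1:2, n_replicates = 3,
                         mcmc_options(burnin = 400, iterations = 200, seed = 9))
  ln1 <- vapply(runs_at_k(runs, 1), function(r) mean(r$loglik_trace), numeric(1))
  ln2 <- vapply(runs_at_k(runs, 2), function(r) mean(r$loglik_trace), numeric(1))
  expect_gt(mean(ln2 > max(ln1)), 0.9)
})

test_that("posterior credible intervals cover the simulated ancestries", {
  # conditions are chosen so the likelihood, not the ancestry prior,
  # dominates the posterior: interval calibration is only meaningful when
  # the data are informative about q
  cfg <- sim_config(K_true = 2, n_individuals = 40, n_snp_loci = 300,
                    F_k = c(0.2, 0.2), alpha_sim = 0.5, n_localities = 4,
                    seed = 37)
  sim <- simulate_dataset(cfg)
  run <- run_admixture_mcmc(sim$snp, 2,
           mcmc_options(burnin = 2000, iterations = 1500,
                        store_q_draws = TRUE, seed = 4))
  # align the posterior to the simulated truth, then check 90% intervals
  perm <- align_qmatrices(sim$truth$true_Q, run$Q)$permutation
  qd <- run$q_draws[perm, , , drop = FALSE]
  lo <- apply(qd, c(1, 2), stats::quantile, probs = 0.05)
  hi <- apply(qd, c(1, 2), stats::quantile, probs = 0.95)
  truth <- t(sim$truth$true_Q)
  covered <- mean(truth >= lo & truth <= hi)
  expect_gte(covered, 0.8)
})

test_that("lambda estimation recovers the frequency-prior concentration", {
  # uniform ancestral frequencies (lambda_sim = 1) versus rare-allele skew
  # (lambda_sim = 0.3); drift is negligible so observed frequencies sit at
  # the ancestral draw
  est <- numeric(2)
  for (i in 1:2) {
    lam <- c(1, 0.3)[i]
    cfg <- sim_config(K_true = 1, n_individuals = 150, n_snp_loci = 600,
                      F_k = 1e-4, alpha_sim = 1, lambda_sim = lam,
                      n_localities = 5, seed = 71)
    sim <- simulate_dataset(cfg)
    est[i] <- estimate_lambda(sim$snp,
                              mcmc_options(burnin = 250, iterations = 350,
                                           seed = 72))$lambda
  }
  expect_gt(est[1], 0.8)
  expect_lt(est[1], 1.2)
  expect_lt(est[2], 0.7)
  expect_lt(est[2], est[1])  # monotone in the generating concentration
})

test_that("invalid sampler inputs are rejected", {
  g <- random_snp_geno(5, 10, seed = 38)
  expect_error(run_admixture_mcmc(g, 6), "exceeds")
  expect_error(run_admixture_mcmc(g, 0), "K")
  expect_error(mcmc_options(lambda = -1), "lambda")
  expect_error(mcmc_options(iterations = 0), "iterations")
  expect_error(estimate_lambda(g, n_replicates = 0), "replicate")
})
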