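test_that("Gelman-Rubin matches its closed form on constructed chains", {
  set.seed(1)
  v <- rnorm(100)
  # identical chains: B = 0, statistic = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(v, v, v)), sqrt(99 / 100))

  # two long chains from the same distribution converge below 1.05
  set.seed(2)
  c1 <- rnorm(10000); c2 <- rnorm(10000)
  expect_lt(gelman_rubin(list(c1, c2)), 1.05)

  # far-separated chains: B dominates W
  set.seed(3)
  expect_gt(gelman_rubin(list(rnorm(1000, 0), rnorm(1000, 100))), 5)

  expect_error(gelman_rubin(list(rep(1, 10), rep(2, 10))), "degenerate")
  expect_error(gelman_rubin(list(rnorm(10))), "two chains")
  expect_equal(gelman_rubin(list(rep(1, 10), rep(1, 10))), 1)
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(4)
  chains <- list(rnorm(500, 0, 1), rnorm(500, 0.3, 1.2), rnorm(500, -0.2, 0.9))
  ours <- gelman_rubin(chains)
  ref <- unname(coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                                  autoburnin = FALSE)$psrf[1, 1])
  # coda adds a small-sample d.f. correction; agreement is close, not exact
  expect_equal(ours, ref, tolerance = 0.05)
})

test_that("the Pr[X|K] estimator is mean minus half the variance", {
  expect_equal(pr_x_given_k(rep(-50, 10)), -50)
  set.seed(5)
  tr <- rnorm(5000, mean = -100, sd = 2)
  expect_equal(pr_x_given_k(tr), mean(tr) - stats::var(tr) / 2)
  expect_lte(pr_x_given_k(tr), mean(tr))
  expect_error(pr_x_given_k(numeric(0)), "empty")
})

test_that("Evanno delta-K reproduces worked examples and scale behaviour", {
  ks <- as.character(1:4)
  lin <- stats::setNames(c(-100, -90, -80, -70), ks)
  sd1 <- stats::setNames(rep(1, 4), ks)
  expect_equal(unname(evanno_delta_k(lin, sd1)), c(0, 0))

  L <- stats::setNames(c(-100, -80, -75, -74), ks)
  dk <- evanno_delta_k(L, sd1)
  expect_equal(dk, c(`2` = 15, `3` = 4))
  # doubling every sd halves every delta-K
  expect_equal(evanno_delta_k(L, sd1 * 2), dk / 2)

  expect_warning(d0 <- evanno_delta_k(L, stats::setNames(c(1, 0, 1, 1), ks)),
                 "Inf")
  expect_true(is.infinite(d0[["2"]]))
  expect_error(evanno_delta_k(L[c(1, 2, 4)], sd1[c(1, 2, 4)]), "contiguous")
})

test_that("the parsimony index is the product of consistency and parsimony", {
  pure <- rbind(matrix(rep(c(1, 0), each = 5), ncol = 2),
                matrix(rep(c(0, 1), each = 5), ncol = 2))
  res <- parsimony_index(list(pure, pure, pure))
  expect_equal(res$pi, 1)

  unif <- matrix(0.5, 10, 2)
  expect_equal(parsimony_index(list(unif, unif))$pi, 0)

  # runs with known SSC and consensus admixture: all-pure vs partly mixed
  Q1 <- matrix(rep(c(1, 0), each = 10), ncol = 2)
  a <- 0.8
  Q2 <- matrix(rep(c(a, 1 - a), each = 10), ncol = 2)  # SSC(Q1,Q2) = a
  res2 <- parsimony_index(list(Q1, Q2))
  expect_equal(res2$consistency, a)
  cons_row <- c((1 + a) / 2, (1 - a) / 2)
  expect_equal(res2$parsimony, 1 - entropy_ca(cons_row))
  expect_equal(res2$pi, res2$consistency * res2$parsimony)

  single <- parsimony_index(list(Q1))
  expect_true(single$single_run)
  expect_equal(single$consistency, 1)
})

test_that("allele-sharing distances come from the shared-allele proportion", {
  a1 <- rbind(c(1L, 1L), c(1L, 1L))
  a2 <- rbind(c(2L, 1L), c(2L, 1L))
  g_same <- geno_from_mats(a1, a2)
  d <- allele_sharing_distance(g_same)
  expect_equal(d[1, 2], 0)

  g_disjoint <- geno_from_mats(rbind(1L, 3L), rbind(2L, 4L))
  expect_equal(allele_sharing_distance(g_disjoint)[1, 2], 1)

  # (A/B) vs (A/C): one shared allele of two
  g_half <- geno_from_mats(rbind(1L, 1L), rbind(2L, 3L))
  expect_equal(allele_sharing_distance(g_half)[1, 2], 0.5)

  # a pair with no co-typed loci is an error
  g_nt <- geno_from_mats(rbind(1L, NA), rbind(1L, NA))
  expect_error(allele_sharing_distance(g_nt), "co-typed")
})

test_that("neighbor joining inverts an additive four-taxon distance matrix", {
  # tree: (a:1, b:2):5 , (c:3, d:4) with internal branch 5
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 1 + 2
  dm["a", "c"] <- dm["c", "a"] <- 1 + 5 + 3
  dm["a", "d"] <- dm["d", "a"] <- 1 + 5 + 4
  dm["b", "c"] <- dm["c", "b"] <- 2 + 5 + 3
  dm["b", "d"] <- dm["d", "b"] <- 2 + 5 + 4
  dm["c", "d"] <- dm["d", "c"] <- 3 + 4
  tr <- neighbor_joining(dm)
  back <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(back, dm, tolerance = 1e-9)

  # taxon order invariance (up to relabeling)
  perm <- c(3, 1, 4, 2)
  tr2 <- neighbor_joining(dm[perm, perm])
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)

  expect_error(neighbor_joining(dm[1:2, 1:2]), "three")
  expect_true(all(neighbor_joining(dm)$edge.length >= 0))
})

test_that("NJ groups simulated pure populations into clades", {
  cfg <- sim_config(K_true = 2, n_individuals = 20, n_snp_loci = 400,
                    F_k = c(0.05, 0.05), alpha_sim = 0.01, n_localities = 2,
                    seed = 21)
  sim <- simulate_dataset(cfg)
  grp <- apply(sim$truth$true_Q, 1, which.max)
  tr <- neighbor_joining(allele_sharing_distance(sim$snp))
  tips1 <- sim$snp$ind_ids[grp == 1]
  tips2 <- sim$snp$ind_ids[grp == 2]
  skip_if(length(tips1) < 2 || length(tips2) < 2)
  rooted <- ape::root(tr, outgroup = tips2[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, tips1))
})
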