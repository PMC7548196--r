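test_that("SSC matches hand-computed values and is maximal at identity", {
  Q <- random_q(10, 3, seed = 1)
  expect_equal(ssc(Q, Q), 1)

  Q1 <- rbind(c(1, 0), c(1, 0))
  Q2 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  # Frobenius norm 1, denominator sqrt(2 * 2) = 2
  expect_equal(ssc(Q1, Q2), 0.5)

  Qa <- rbind(c(1, 0), c(0, 1))
  Qb <- rbind(c(0, 1), c(1, 0))
  expect_equal(ssc(Qa, Qb, permutation = c(2, 1)), 1)
  expect_error(ssc(Q, random_q(9, 3)), "individuals")
})

test_that("alignment recovers column shuffles; assignment search matches exhaustive", {
  Q <- random_q(30, 3, seed = 2)
  perm <- c(3, 1, 2)
  al <- align_qmatrices(Q, Q[, perm])
  expect_equal(al$ssc, 1)
  expect_equal(al$aligned_Q, Q, ignore_attr = TRUE)

  # brute force over all 6 permutations as the oracle
  for (i in 1:20) {
    Qx <- random_q(15, 3, seed = 100 + i)
    Qy <- random_q(15, 3, seed = 200 + i)
    best <- max(apply(markerstruct:::permutations(3), 1,
                      function(p) ssc(Qx, Qy, p)))
    expect_equal(align_qmatrices(Qx, Qy)$ssc, best)
    hung <- markerstruct:::assignment_permutation(Qx, Qy)
    expect_equal(ssc(Qx, Qy, hung), best, tolerance = 1e-12)
  }
})

test_that("matrices with different K are matched through zero padding", {
  # two pure groups at K=2; at K=3 the second group splits
  Q2 <- rbind(matrix(rep(c(1, 0), each = 10), ncol = 2),
              matrix(rep(c(0, 1), each = 10), ncol = 2))
  Q3 <- rbind(cbind(1, matrix(0, 10, 2)),
              cbind(0, matrix(rep(c(0.5, 0.5), each = 10), ncol = 2)))
  al <- align_qmatrices(Q2, Q3)
  expect_equal(ncol(al$aligned_Q), 3)
  # the shared pure cluster must map onto itself
  expect_gt(stats::cor(al$aligned_Q[, 1], Q2[, 1]), 0.99)
})

test_that("pairwise SSC matrices are symmetric with unit diagonal", {
  qs <- lapply(1:4, function(i) random_q(12, 3, seed = i))
  m <- pairwise_ssc_matrix(qs)$ssc
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)

  qs_id <- rep(list(random_q(12, 3, seed = 9)), 3)
  expect_true(all(pairwise_ssc_matrix(qs_id)$ssc == 1))

  # identical within marker, orthogonal across markers
  A <- cbind(rep(1, 10), 0)
  B <- cbind(rep(0, 10), 1)[, c(2, 1)]  # same as A after relabeling
  C <- matrix(0.5, 10, 2)
  m2 <- pairwise_ssc_matrix(list(A, A, C, C))$ssc
  expect_true(all(m2[1:2, 1:2] == 1))
  expect_true(all(m2[3:4, 3:4] == 1))
  expect_true(all(m2[1:2, 3:4] < 1))
})

test_that("mode detection groups runs by similarity", {
  base <- rbind(matrix(rep(c(1, 0), each = 10), ncol = 2),
                matrix(rep(c(0, 1), each = 10), ncol = 2))
  other <- matrix(0.5, 20, 2)  # aligned SSC(base, other) = 0.5
  runs <- c(rep(list(base), 7), rep(list(other), 3))
  ms <- find_modes(runs, threshold = 0.9)
  expect_equal(length(ms$groups), 2L)
  expect_equal(sort(lengths(ms$groups), decreasing = TRUE), c(7L, 3L))
  expect_equal(length(ms$groups[[ms$major_mode]]), 7L)
  expect_equal(ms$consensus_Q[[ms$major_mode]], base, ignore_attr = TRUE)

  ms0 <- find_modes(runs, threshold = 0)
  expect_equal(length(ms0$groups), 1L)

  ms1 <- find_modes(rep(list(base), 10))
  expect_equal(lengths(ms1$groups), 10L)
})

test_that("locality averaging preserves the simplex", {
  Q <- rbind(c(1, 0), c(0, 1), c(0.6, 0.4), c(0.6, 0.4), c(0, 1))
  avg <- average_by_locality(Q, c("a", "a", "b", "b", "b"))
  expect_equal(avg["a", ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(avg["b", ], c(0.4, 0.6), ignore_attr = TRUE)
  expect_equal(rowSums(avg), c(a = 1, b = 1))

  single <- average_by_locality(Q[3, , drop = FALSE], "x")
  expect_equal(single["x", ], Q[3, ], ignore_attr = TRUE)
  expect_error(average_by_locality(Q, c("a", "a", NA, "b", "b")), "locality")
})

test_that("coefficient of admixture hits its endpoints and known values", {
  for (K in 2:8) {
    pure <- matrix(0, 1, K); pure[1] <- 1
    unif <- matrix(1 / K, 1, K)
    expect_equal(coefficient_of_admixture(pure)$ca, 0, ignore_attr = TRUE)
    expect_equal(coefficient_of_admixture(unif)$ca, 1, ignore_attr = TRUE)
  }
  ca <- coefficient_of_admixture(rbind(c(0.75, 0.25)))$ca
  expect_equal(unname(ca), entropy_ca(c(0.75, 0.25)))
  expect_equal(unname(ca), 0.8113, tolerance = 1e-4)
  expect_error(coefficient_of_admixture(matrix(1, 3, 1)), "K = 1")

  # invariant to column permutation; increases when mixing toward uniform
  Q <- random_q(20, 4, seed = 5)
  expect_equal(coefficient_of_admixture(Q)$ca,
               coefficient_of_admixture(Q[, c(3, 1, 4, 2)])$ca)
  row <- c(0.9, 0.06, 0.03, 0.01)
  mixes <- seq(0, 1, by = 0.1)
  vals <- vapply(mixes, function(w) {
    q <- (1 - w) * row + w * rep(0.25, 4)
    entropy_ca(q)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  pkg_vals <- coefficient_of_admixture(
    t(vapply(mixes, function(w) (1 - w) * row + w * rep(0.25, 4),
             numeric(4))))$ca
  expect_true(all(diff(pkg_vals) > 0))

  # the max-based alternative shares the endpoints
  expect_equal(coefficient_of_admixture(rbind(c(1, 0, 0)), "max")$ca, 0,
               ignore_attr = TRUE)
  expect_equal(coefficient_of_admixture(rbind(rep(1 / 3, 3)), "max")$ca, 1,
               ignore_attr = TRUE)
})
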