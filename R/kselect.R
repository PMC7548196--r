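# K-selection diagnostics and metrics: Gelman-Rubin convergence across
# replicate runs, the Pr[X|K] model-evidence estimator, Evanno's delta-K,
# a parsimony index combining run consistency and minimal admixture, and a
# model-free neighbour-joining check on allele-sharing distances.

#' Gelman-Rubin potential scale reduction factor
#'
#' For m chains of length n: `W` = mean within-chain variance, `B/n` =
#' variance of the chain means, `Vhat = (n-1)/n W + B/n + B/(m n)`, and the
#' statistic is `sqrt(Vhat / W)`. Values below 1.05 are taken as good
#' convergence.
#'
#' @param traces list of >= 2 equal-length numeric vectors (length >= 4).
#' @return the scale reduction factor (a single number).
#' @export
gelman_rubin <- function(traces) {
  m <- length(traces)
  if (m < 2) stop("need at least two chains")
  n <- unique(lengths(traces))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 4) stop("chains must have length >= 4")
  W <- mean(vapply(traces, stats::var, numeric(1)))
  mns <- vapply(traces, mean, numeric(1))
  B_over_n <- stats::var(mns)          # = B/n
  if (W == 0) {
    if (B_over_n > 0) stop("degenerate chains: zero within-chain variance ",
                           "with distinct chain means")
    return(1)
  }
  Vhat <- (n - 1) / n * W + B_over_n + B_over_n / m
  sqrt(Vhat / W)
}

#' Model-evidence estimator Pr[X|K] on the log scale
#'
#' The harmonic-style estimator used for K-selection on log-likelihood
#' traces: `mean(trace) - var(trace)/2`.
#'
#' @param loglik_trace numeric vector of recorded log-likelihoods
#'   (length >= 2; a length-1 trace returns its value).
#' @return the estimate (log scale).
#' @export
pr_x_given_k <- function(loglik_trace) {
  if (!length(loglik_trace)) stop("empty trace")
  if (length(loglik_trace) == 1L) return(loglik_trace)
  mean(loglik_trace) - stats::var(loglik_trace) / 2
}

#' Evanno's delta-K
#'
#' Rate of change of the log-probability of the data between successive K:
#' `deltaK(k) = |L(k+1) - 2 L(k) + L(k-1)| / sd(k)`, undefined at the
#' smallest and largest K of the range.
#'
#' @param mean_lnP named numeric vector: mean lnP(X|K) per K (names are the
#'   K values, which must form a contiguous range of length >= 3).
#' @param sd_lnP named numeric vector: replicate standard deviation of lnP
#'   per K.
#' @return named numeric vector of delta-K over the interior K values
#'   (infinite, with a warning, where sd = 0).
#' @export
evanno_delta_k <- function(mean_lnP, sd_lnP) {
  ks <- as.integer(names(mean_lnP))
  if (is.null(names(mean_lnP)) || anyNA(ks)) {
    ks <- seq_along(mean_lnP)
    names(mean_lnP) <- ks
  }
  o <- order(ks)
  ks <- ks[o]; L <- as.numeric(mean_lnP[o]); s <- as.numeric(sd_lnP[o])
  if (length(ks) < 3) stop("need a contiguous K range of length >= 3")
  if (any(diff(ks) != 1)) stop("K range must be contiguous")
  mid <- seq(2, length(ks) - 1)
  num <- abs(L[mid + 1] - 2 * L[mid] + L[mid - 1])
  if (any(s[mid] == 0))
    warning("zero replicate sd at some K; delta-K reported as Inf")
  dk <- ifelse(s[mid] == 0, ifelse(num == 0, 0, Inf), num / s[mid])
  stats::setNames(dk, ks[mid])
}

#' Parsimony index for one K
#'
#' Favours K values whose replicate runs are consistent and whose consensus
#' ancestries are minimally admixed: the product of (i) run consistency,
#' the mean pairwise aligned SSC among the K's replicate Q-matrices, and
#' (ii) parsimony, `1 -` the mean coefficient of admixture of the consensus
#' Q. Identical pure runs give 1; uniformly admixed runs give 0. The
#' optimal K maximizes the index.
#'
#' @param qlist list of replicate Q-matrices at one K (same individuals).
#' @return list: `pi` (the index), `consistency`, `parsimony`,
#'   `consensus_Q`, and `single_run` flag when consistency is undefined
#'   (fewer than 2 runs; consistency taken as 1 with a flag).
#' @export
parsimony_index <- function(qlist) {
  if (!length(qlist)) stop("need at least one run")
  K <- ncol(as_qmatrix(qlist[[1]]))
  single <- length(qlist) < 2
  if (single) {
    consistency <- 1
    consensus <- as_qmatrix(qlist[[1]])
  } else {
    sm <- pairwise_ssc_matrix(qlist)$ssc
    consistency <- mean(sm[upper.tri(sm)])
    ref <- as_qmatrix(qlist[[1]])
    acc <- ref
    for (i in seq_along(qlist)[-1])
      acc <- acc + align_qmatrices(ref, qlist[[i]])$aligned_Q
    consensus <- acc / length(qlist)
  }
  parsimony <- if (K < 2) 1 else
    1 - coefficient_of_admixture(consensus)$mean
  list(pi = consistency * parsimony, consistency = consistency,
       parsimony = parsimony, consensus_Q = consensus,
       single_run = single)
}

#' K-selection summary table from a set of replicate runs
#'
#' Per K: the mean and replicate standard deviation of the per-run mean
#' log-likelihood (the input to Evanno's delta-K; at short recorded run
#' lengths the raw mean is a far more stable run summary than the
#' variance-corrected evidence estimate, whose var/2 term is itself
#' noisy), the mean Pr[X|K] estimate, Evanno's delta-K, the parsimony
#' index, and the Gelman-Rubin statistic across the replicate
#' log-likelihood traces.
#'
#' @param runs a `run_set` from [replicate_runs()].
#' @return data frame of class `kselection_table`, one row per K.
#' @export
kselection_table <- function(runs) {
  ks <- sort(unique(vapply(runs, function(r) r$K, integer(1))))
  rows <- lapply(ks, function(K) {
    rk <- runs_at_k(runs, K)
    mlnp <- vapply(rk, function(r) mean(r$loglik_trace), numeric(1))
    prx <- vapply(rk, function(r) pr_x_given_k(r$loglik_trace), numeric(1))
    gr <- if (length(rk) >= 2)
      gelman_rubin(lapply(rk, function(r) r$loglik_trace)) else NA_real_
    pi_val <- if (K >= 2)
      parsimony_index(lapply(rk, function(r) r$Q))$pi else NA_real_
    data.frame(K = K, n_runs = length(rk), mean_lnP = mean(mlnp),
               sd_lnP = if (length(rk) >= 2) stats::sd(mlnp) else NA_real_,
               pr_x_given_k = mean(prx), parsimony_index = pi_val,
               gelman_rubin = gr)
  })
  tab <- do.call(rbind, rows)
  tab$delta_k <- NA_real_
  if (nrow(tab) >= 3 && all(diff(tab$K) == 1) && !anyNA(tab$sd_lnP)) {
    dk <- evanno_delta_k(stats::setNames(tab$mean_lnP, tab$K),
                         stats::setNames(tab$sd_lnP, tab$K))
    tab$delta_k[match(as.integer(names(dk)), tab$K)] <- dk
  }
  class(tab) <- c("kselection_table", class(tab))
  tab
}

#' Allele-sharing distance matrix
#'
#' `d(i, j) = 1 -` the mean, over loci typed in both individuals, of the
#' proportion of shared alleles at the locus (0, 0.5 or 1 for diploids:
#' comparing genotype {a, b} with {c, d}, the shared proportion is half the
#' size of the maximal one-to-one matching between the two allele pairs).
#'
#' @param genotypes a [genotype_matrix()] with >= 2 individuals.
#' @return symmetric N x N distance matrix with zero diagonal, dimnames =
#'   individual ids. A pair with no co-typed loci is an error.
#' @export
allele_sharing_distance <- function(genotypes) {
  n <- n_ind(genotypes)
  if (n < 2) stop("need at least two individuals")
  a1 <- genotypes$alleles[, , 1, drop = TRUE]
  a2 <- genotypes$alleles[, , 2, drop = TRUE]
  if (is.null(dim(a1))) { a1 <- matrix(a1, nrow = n); a2 <- matrix(a2, nrow = n) }
  d <- matrix(0, n, n, dimnames = list(genotypes$ind_ids, genotypes$ind_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(a1[i, ]) & !is.na(a1[j, ]) & !is.na(a2[i, ]) & !is.na(a2[j, ])
    if (!any(ok)) stop(sprintf("no co-typed loci for pair (%s, %s)",
                               genotypes$ind_ids[i], genotypes$ind_ids[j]))
    x1 <- a1[i, ok]; x2 <- a2[i, ok]; y1 <- a1[j, ok]; y2 <- a2[j, ok]
    # maximal matching between allele pairs {x1,x2} and {y1,y2}
    m_direct <- (x1 == y1) + (x2 == y2)
    m_cross <- (x1 == y2) + (x2 == y1)
    shared <- pmax(m_direct, m_cross) / 2
    d[i, j] <- d[j, i] <- 1 - mean(shared)
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the length transferred to the adjacent branch.
#'
#' @param distances symmetric non-negative matrix with zero diagonal, N >= 3.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distances) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 3) stop("need at least three taxa")
  if (any(abs(distances - t(distances)) > 1e-9) || any(diag(distances) != 0) ||
      any(distances < 0))
    stop("distances must be symmetric, non-negative, zero-diagonal")
  tr <- ape::nj(stats::as.dist(distances))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    # transfer to branches adjacent through the child node
    child <- tr$edge[e, 2]
    adj <- which(tr$edge[, 1] == child)
    if (length(adj)) tr$edge.length[adj] <- tr$edge.length[adj] + len
  }
  tr
}
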