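# Q-matrix alignment and comparison across replicate runs, K values and
# marker types: CLUMPP-style label-switching resolution by maximizing the
# symmetric similarity coefficient (SSC), mode detection, per-locality
# averaging, and the coefficient of admixture (CA).

as_qmatrix <- function(Q) {
  Q <- as.matrix(Q)
  if (any(Q < -1e-9)) stop("Q entries must be non-negative")
  rs <- rowSums(Q)
  if (any(abs(rs - 1) > 1e-6)) stop("Q rows must sum to 1")
  Q
}

#' Symmetric similarity coefficient between two Q-matrices
#'
#' `SSC = 1 - ||Q1 - Q2 Pi||_F / sqrt(2N)` where `Pi` permutes the columns
#' of `Q2` and N is the number of individuals. Equals 1 iff the matrices
#' are identical under the permutation; can be negative for very dissimilar
#' matrices.
#'
#' @param Q1,Q2 N x K ancestry matrices (rows sum to 1).
#' @param permutation integer vector: column `j` of the aligned `Q2` is
#'   column `permutation[j]` of the input `Q2`. Default identity.
#' @return the SSC, a real number <= 1.
#' @export
ssc <- function(Q1, Q2, permutation = seq_len(ncol(Q2))) {
  Q1 <- as_qmatrix(Q1); Q2 <- as_qmatrix(Q2)
  if (nrow(Q1) != nrow(Q2)) stop("Q-matrices must share individuals")
  if (ncol(Q1) != ncol(Q2)) stop("Q-matrices must share K (pad first)")
  Q2p <- Q2[, permutation, drop = FALSE]
  1 - norm(Q1 - Q2p, type = "F") / sqrt(2 * nrow(Q1))
}

# all permutations of 1..n (n <= 8 in practice)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Optimal column matching as a linear assignment problem. Maximizing the
# SSC is equivalent to minimizing the sum of squared distances between
# paired columns, so the Hungarian algorithm gives the exact optimum in
# O(K^3) -- identical to exhaustive permutation search at every K.
assignment_permutation <- function(Q1, Q2) {
  K <- ncol(Q1)
  cost <- matrix(0, K, K)  # squared distance between Q1 col a and Q2 col b
  for (a in seq_len(K)) for (b in seq_len(K))
    cost[a, b] <- sum((Q1[, a] - Q2[, b])^2)
  solve_assignment(cost)
}

# Hungarian algorithm (shortest augmenting paths with potentials);
# returns perm with perm[i] = column assigned to row i, minimizing
# sum_i cost[i, perm[i]]. Columns are indexed 1..n at positions 2..n+1;
# position 1 is the virtual start column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row matched to column (j-1); 0 = none
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n) + 1) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1]] <- j
  perm
}

#' Align two Q-matrices by column permutation
#'
#' Finds the column permutation of `Q2` maximizing the SSC against `Q1`:
#' exhaustive search over permutations for K <= `exhaustive_max`, Hungarian
#' assignment (exact, O(K^3)) above. When the matrices have different K, the smaller
#' is padded with zero columns before the search, so clusters can be
#' matched across successive values of K.
#'
#' @param Q1,Q2 ancestry matrices over the same individuals; K may differ.
#' @param exhaustive_max largest K searched exhaustively.
#' @return list of class `q_alignment`: `permutation` (applied to the
#'   padded `Q2`), `ssc`, `aligned_Q` (the permuted, padded `Q2`), `K`.
#' @export
align_qmatrices <- function(Q1, Q2, exhaustive_max = 8L) {
  Q1 <- as_qmatrix(Q1); Q2 <- as_qmatrix(Q2)
  if (nrow(Q1) != nrow(Q2)) stop("different individual sets")
  K <- max(ncol(Q1), ncol(Q2))
  pad <- function(Q) if (ncol(Q) < K)
    cbind(Q, matrix(0, nrow(Q), K - ncol(Q))) else Q
  Q1 <- pad(Q1); Q2 <- pad(Q2)
  if (K <= exhaustive_max) {
    perms <- permutations(K)
    sscs <- apply(perms, 1, function(p) ssc(Q1, Q2, p))
    best <- which.max(sscs)
    perm <- as.integer(perms[best, ])
  } else {
    perm <- assignment_permutation(Q1, Q2)
  }
  structure(list(permutation = perm, ssc = ssc(Q1, Q2, perm),
                 aligned_Q = Q2[, perm, drop = FALSE], K = K),
            class = "q_alignment")
}

#' Pairwise aligned-SSC matrix over a collection of runs
#'
#' Entry (a, b) is the SSC after optimal column alignment of run b onto run
#' a; the diagonal is 1. Labels are retained so intra- versus inter-marker
#' subsets can be extracted.
#'
#' @param qlist list of Q-matrices over the same individuals (names kept).
#' @param labels optional grouping labels (e.g. marker type) per run.
#' @return list: `ssc` (symmetric matrix), `labels`.
#' @export
pairwise_ssc_matrix <- function(qlist, labels = NULL) {
  n <- length(qlist)
  m <- diag(1, n)
  for (a in seq_len(n)) for (b in seq_len(n)) if (b > a) {
    s <- align_qmatrices(qlist[[a]], qlist[[b]])$ssc
    m[a, b] <- m[b, a] <- s
  }
  nm <- names(qlist)
  if (is.null(nm)) nm <- sprintf("run%02d", seq_len(n))
  dimnames(m) <- list(nm, nm)
  list(ssc = m, labels = labels)
}

#' Group replicate runs into modes
#'
#' Single-linkage grouping: runs joined whenever their pairwise aligned SSC
#' is at least `threshold` (transitively). Each group's consensus is the
#' mean of member Q-matrices after alignment to the group's first member;
#' the major mode is the largest group, ties broken by higher mean
#' intra-group SSC.
#'
#' @param qlist list of Q-matrices over the same individuals.
#' @param threshold SSC threshold for joining runs into one mode.
#' @return list of class `mode_set`: `groups` (list of integer index
#'   vectors), `major_mode` (index into groups), `consensus_Q` (list of
#'   consensus matrices), `ssc` (the pairwise matrix used).
#' @export
find_modes <- function(qlist, threshold = 0.9) {
  if (!length(qlist)) stop("need at least one run")
  n <- length(qlist)
  sm <- pairwise_ssc_matrix(qlist)$ssc
  # union-find over edges with SSC >= threshold (single linkage)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n)) for (b in seq_len(n)) if (b > a && sm[a, b] >= threshold) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  names(groups) <- NULL
  consensus <- lapply(groups, function(g) {
    ref <- as_qmatrix(qlist[[g[1]]])
    acc <- ref
    for (i in g[-1]) acc <- acc + align_qmatrices(ref, qlist[[i]])$aligned_Q
    acc / length(g)
  })
  sizes <- lengths(groups)
  intra <- vapply(groups, function(g)
    if (length(g) < 2) 1 else mean(sm[g, g][upper.tri(sm[g, g])]), numeric(1))
  major <- order(-sizes, -intra)[1]
  structure(list(groups = groups, major_mode = major,
                 consensus_Q = consensus, ssc = sm, threshold = threshold),
            class = "mode_set")
}

#' Average individual ancestries per locality
#'
#' @param Q N x K ancestry matrix.
#' @param locality_ids locality label per individual (length N, no NA).
#' @return Q-matrix over localities (rows in order of first appearance;
#'   row names = locality ids), rows still summing to 1.
#' @export
average_by_locality <- function(Q, locality_ids) {
  Q <- as_qmatrix(Q)
  if (length(locality_ids) != nrow(Q))
    stop("every individual needs a locality")
  if (anyNA(locality_ids)) stop("every individual needs a locality")
  locs <- unique(locality_ids)
  out <- t(vapply(locs, function(lc)
    colMeans(Q[locality_ids == lc, , drop = FALSE]), numeric(ncol(Q))))
  rownames(out) <- locs
  out
}

#' Coefficient of admixture
#'
#' Per-individual admixture index: 0 when all ancestry belongs to a single
#' cluster, 1 for equal proportions across clusters. Implemented as the
#' normalized Shannon entropy of the ancestry row,
#' `CA_i = -sum_k q_ik ln q_ik / ln K` (terms with q = 0 contribute 0); a
#' max-based alternative `1 - K/(K-1) (max_k q_ik - 1/K)` with the same
#' endpoints is available via `method = "max"`.
#'
#' @param Q N x K ancestry matrix with K >= 2.
#' @param method `"entropy"` (default) or `"max"`.
#' @return list of class `admixture_profile`: `ca` (per individual),
#'   `mean`, `quantiles` (5%, 25%, 50%, 75%, 95%), `K`.
#' @export
coefficient_of_admixture <- function(Q, method = c("entropy", "max")) {
  method <- match.arg(method)
  Q <- as_qmatrix(Q)
  K <- ncol(Q)
  if (K < 2) stop("CA is undefined for K = 1")
  ca <- if (method == "entropy") {
    apply(Q, 1, function(q) {
      q <- q[q > 0]
      -sum(q * log(q)) / log(K)
    })
  } else {
    1 - K / (K - 1) * (apply(Q, 1, max) - 1 / K)
  }
  ca <- pmin(pmax(ca, 0), 1)
  structure(list(ca = ca, mean = mean(ca),
                 quantiles = stats::quantile(ca, c(.05, .25, .5, .75, .95)),
                 K = K, method = method),
            class = "admixture_profile")
}
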