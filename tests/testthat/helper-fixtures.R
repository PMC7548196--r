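# Small fixtures built in code.

# genotype matrix from two N x L integer matrices of allele copies
geno_from_mats <- function(a1, a2, marker = "snp", localities = NULL,
                           ind_ids = NULL, locus_ids = NULL) {
  arr <- array(NA_integer_, c(nrow(a1), ncol(a1), 2))
  arr[, , 1] <- as.integer(a1)
  arr[, , 2] <- as.integer(a2)
  genotype_matrix(arr, ind_ids = ind_ids, locus_ids = locus_ids,
                  localities = localities, marker = marker)
}

# random biallelic genotypes, complete data
random_snp_geno <- function(n, l, seed = 1) {
  set.seed(seed)
  p <- runif(l, 0.1, 0.9)
  a1 <- sapply(p, function(pp) rbinom(n, 1, pp) + 1L)
  a2 <- sapply(p, function(pp) rbinom(n, 1, pp) + 1L)
  geno_from_mats(a1, a2)
}

# random Q-matrix with rows summing to 1
random_q <- function(n, k, conc = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rgamma(n * k, conc), n, k)
  x / rowSums(x)
}

# normalized Shannon entropy, written independently of the package
entropy_ca <- function(q) {
  k <- length(q)
  q <- q[q > 0]
  -sum(q * log(q)) / log(k)
}
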