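#' Diploid genotype matrix
#'
#' Container for diploid allele calls of N individuals at L loci, for either
#' biallelic SNPs or multiallelic microsatellites. Alleles are stored as an
#' integer array of dimension `N x L x 2`; missing allele copies are `NA`
#' (written as -9 on disk, the STRUCTURE convention). Allele labels are
#' arbitrary integers (e.g. 1/2 for SNPs, repeat counts for microsatellites).
#'
#' @param alleles integer array `N x L x 2` (NA = missing call).
#' @param ind_ids character vector of individual identifiers (length N).
#' @param locus_ids character vector of locus identifiers (length L).
#' @param localities optional character vector of locality labels (length N).
#' @param marker `"snp"` or `"microsat"`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, ind_ids = NULL, locus_ids = NULL,
                            localities = NULL, marker = c("snp", "microsat")) {
  marker <- match.arg(marker)
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("`alleles` must be an N x L x 2 array")
  storage.mode(alleles) <- "integer"
  n <- dim(alleles)[1]
  l <- dim(alleles)[2]
  if (is.null(ind_ids)) ind_ids <- sprintf("ind_%03d", seq_len(n))
  if (is.null(locus_ids)) locus_ids <- sprintf("loc_%05d", seq_len(l))
  if (length(ind_ids) != n) stop("ind_ids length mismatch")
  if (length(locus_ids) != l) stop("locus_ids length mismatch")
  if (!is.null(localities) && length(localities) != n)
    stop("localities length mismatch")
  structure(
    list(alleles = alleles, ind_ids = as.character(ind_ids),
         locus_ids = as.character(locus_ids),
         localities = if (is.null(localities)) NULL else as.character(localities),
         marker = marker),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d %s loci (%.1f%% missing)\n",
              n_ind(x), n_loci(x), x$marker, 100 * missing_fraction(x)))
  invisible(x)
}

#' Number of individuals
#' @param g a `genotype_matrix`
#' @export
n_ind <- function(g) dim(g$alleles)[1]

#' Number of loci
#' @param g a `genotype_matrix`
#' @export
n_loci <- function(g) dim(g$alleles)[2]

#' Fraction of missing genotype calls
#'
#' A genotype call (both allele copies of one individual at one locus) is
#' missing when either copy is `NA`; the simulator always blanks both copies
#' together.
#' @param g a `genotype_matrix`
#' @export
missing_fraction <- function(g) {
  miss <- is.na(g$alleles[, , 1]) | is.na(g$alleles[, , 2])
  mean(miss)
}

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`
#' @param ind indices (integer/logical) of individuals to keep; NULL = all.
#' @param loci indices of loci to keep; NULL = all.
#' @export
subset_genotypes <- function(g, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_len(n_ind(g))
  if (is.null(loci)) loci <- seq_len(n_loci(g))
  genotype_matrix(g$alleles[ind, loci, , drop = FALSE],
                  ind_ids = g$ind_ids[ind],
                  locus_ids = g$locus_ids[loci],
                  localities = if (is.null(g$localities)) NULL else g$localities[ind],
                  marker = g$marker)
}

#' Per-individual call rate
#'
#' Proportion of loci with a non-missing genotype call, per individual.
#' @param g a `genotype_matrix`
#' @export
individual_call_rate <- function(g) {
  miss <- is.na(g$alleles[, , 1]) | is.na(g$alleles[, , 2])
  stats::setNames(1 - rowMeans(miss), g$ind_ids)
}

#' Per-locus call rate
#'
#' Proportion of individuals with a non-missing call, per locus.
#' @param g a `genotype_matrix`
#' @export
locus_call_rate <- function(g) {
  miss <- is.na(g$alleles[, , 1]) | is.na(g$alleles[, , 2])
  stats::setNames(1 - colMeans(miss), g$locus_ids)
}

#' Minor allele frequency per locus
#'
#' Computed from non-missing allele copies. Loci with a single observed
#' allele get MAF 0; loci with no observed copies get NA.
#' @param g a `genotype_matrix`
#' @export
minor_allele_freq <- function(g) {
  vapply(seq_len(n_loci(g)), function(l) {
    a <- c(g$alleles[, l, 1], g$alleles[, l, 2])
    a <- a[!is.na(a)]
    if (!length(a)) return(NA_real_)
    tab <- tabulate(match(a, unique(a)))
    if (length(tab) < 2L) 0 else min(tab) / sum(tab)
  }, numeric(1)) |> stats::setNames(g$locus_ids)
}

#' Observed alleles per locus
#' @param g a `genotype_matrix`
#' @return integer vector: number of distinct non-missing alleles per locus.
#' @export
alleles_per_locus <- function(g) {
  vapply(seq_len(n_loci(g)), function(l) {
    a <- c(g$alleles[, l, 1], g$alleles[, l, 2])
    length(unique(a[!is.na(a)]))
  }, integer(1)) |> stats::setNames(g$locus_ids)
}

# Map arbitrary integer allele labels to dense 0-based indices per locus.
# Returns list(codes = N x 2L integer matrix (-1 = missing, loci-major pairs),
# n_alleles = per-locus count, labels = per-locus label vectors).
dense_allele_codes <- function(g) {
  n <- n_ind(g); l <- n_loci(g)
  codes <- matrix(-1L, n, 2L * l)
  n_alleles <- integer(l)
  labels <- vector("list", l)
  for (j in seq_len(l)) {
    a1 <- g$alleles[, j, 1]; a2 <- g$alleles[, j, 2]
    labs <- sort(unique(c(a1, a2)[!is.na(c(a1, a2))]))
    if (!length(labs)) labs <- integer(0)
    labels[[j]] <- labs
    n_alleles[j] <- max(1L, length(labs))
    codes[, 2L * j - 1L] <- ifelse(is.na(a1), -1L, match(a1, labs) - 1L)
    codes[, 2L * j] <- ifelse(is.na(a2), -1L, match(a2, labs) - 1L)
  }
  list(codes = codes, n_alleles = n_alleles, labels = labels)
}
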