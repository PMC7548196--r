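# Individual genetic diversity: standardized multilocus heterozygosity
# (sMLH), per-locality medians, cross-marker correlation and linear
# latitude/longitude gradient models.

#' Standardized multilocus heterozygosity
#'
#' `sMLH_i` = (proportion of individual i's typed loci that are
#' heterozygous) / (mean dataset heterozygosity `h_l` of the loci typed in
#' i), where `h_l` is the fraction of typed individuals heterozygous at
#' locus l. With complete data the individual values average exactly 1.
#' Loci monomorphic in the dataset (h_l = 0) are excluded: they carry no
#' heterozygosity information and would deflate the denominator.
#'
#' @param genotypes a [genotype_matrix()] with >= 2 individuals.
#' @return named numeric vector of per-individual sMLH.
#' @export
smlh <- function(genotypes) {
  if (n_ind(genotypes) < 2) stop("need at least two individuals")
  a1 <- genotypes$alleles[, , 1, drop = FALSE][, , 1]
  a2 <- genotypes$alleles[, , 2, drop = FALSE][, , 1]
  typed <- !is.na(a1) & !is.na(a2)
  het <- typed & (a1 != a2)
  h_l <- colSums(het) / pmax(colSums(typed), 1L)
  poly <- h_l > 0
  if (!any(poly)) stop("all loci are monomorphic; sMLH undefined")
  typed <- typed[, poly, drop = FALSE]
  het <- het[, poly, drop = FALSE]
  h_l <- h_l[poly]
  n_typed <- rowSums(typed)
  if (any(n_typed == 0))
    stop("individual(s) typed at zero polymorphic loci: ",
         paste(genotypes$ind_ids[n_typed == 0], collapse = ", "))
  prop_het <- rowSums(het) / n_typed
  mean_h <- (typed %*% h_l)[, 1] / n_typed
  stats::setNames(prop_het / mean_h, genotypes$ind_ids)
}

#' Median sMLH per locality
#'
#' @param values named or plain numeric vector of per-individual sMLH.
#' @param locality_ids locality label per individual.
#' @return named numeric vector of medians (even counts: midpoint of the
#'   two central values), ordered by first appearance.
#' @export
locality_medians <- function(values, locality_ids) {
  if (length(values) != length(locality_ids))
    stop("every individual must be assigned to a locality")
  locs <- unique(locality_ids)
  stats::setNames(
    vapply(locs, function(lc) stats::median(values[locality_ids == lc]),
           numeric(1)),
    locs)
}

#' Cross-marker correlation of individual heterozygosity
#'
#' Pearson correlation between paired per-individual sMLH values from two
#' marker panels, with the two-sided p-value from the t-distribution with
#' n - 2 degrees of freedom.
#'
#' @param smlh_a,smlh_b paired numeric vectors (same individuals, n >= 3).
#' @return list: `r`, `p`, `n`.
#' @export
marker_correlation <- function(smlh_a, smlh_b) {
  if (length(smlh_a) != length(smlh_b)) stop("vectors must be paired")
  n <- length(smlh_a)
  if (n < 3) stop("need at least three individuals")
  if (stats::sd(smlh_a) == 0 || stats::sd(smlh_b) == 0)
    stop("zero variance in an sMLH vector")
  ct <- stats::cor.test(smlh_a, smlh_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Linear spatial gradient of heterozygosity
#'
#' Ordinary least squares `sMLH ~ latitude + longitude` (no interaction),
#' with two-sided t-test p-values per coefficient.
#'
#' @param values per-individual sMLH.
#' @param latitudes,longitudes decimal-degree coordinates per individual.
#' @return list of class `gradient_fit`: `beta_latitude`, `beta_longitude`,
#'   `p_latitude`, `p_longitude`, `intercept`, `n`, and the underlying `lm`
#'   fit.
#' @export
spatial_gradient <- function(values, latitudes, longitudes) {
  n <- length(values)
  if (n < 4) stop("need at least four observations")
  if (length(latitudes) != n || length(longitudes) != n)
    stop("coordinate vectors must match values")
  df <- data.frame(smlh = values, lat = latitudes, lon = longitudes)
  if (stats::sd(df$lat) == 0 || stats::sd(df$lon) == 0 ||
      abs(stats::cor(df$lat, df$lon)) > 1 - 1e-12)
    stop("collinear or constant coordinates: design is singular")
  fit <- stats::lm(smlh ~ lat + lon, data = df)
  cf <- summary(fit)$coefficients
  structure(list(beta_latitude = cf["lat", "Estimate"],
                 beta_longitude = cf["lon", "Estimate"],
                 p_latitude = cf["lat", "Pr(>|t|)"],
                 p_longitude = cf["lon", "Pr(>|t|)"],
                 intercept = cf["(Intercept)", "Estimate"],
                 n = n, fit = fit),
            class = "gradient_fit")
}

#' Full diversity summary for one marker panel
#'
#' @param genotypes a [genotype_matrix()] carrying locality labels.
#' @param localities data frame with columns `id`, `latitude`, `longitude`.
#' @return list: `smlh` (per individual), `medians` (per locality),
#'   `gradient` (a `gradient_fit`).
#' @export
diversity_table <- function(genotypes, localities) {
  if (is.null(genotypes$localities))
    stop("genotypes carry no locality labels")
  s <- smlh(genotypes)
  med <- locality_medians(s, genotypes$localities)
  i <- match(genotypes$localities, localities$id)
  if (anyNA(i)) stop("locality table is missing some sampled localities")
  grad <- spatial_gradient(s, localities$latitude[i], localities$longitude[i])
  list(smlh = s, medians = med, gradient = grad)
}
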