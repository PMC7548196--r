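# SNP quality-filter chain for DArT-style genotype reports, with a
# per-step audit trail. Threshold semantics (ties included or excluded)
# follow the chain's published wording: individual call rate retained
# strictly > threshold; RepAvg retained strictly > 0.95; allele read
# proportion retained on the closed interval [0.15, 0.85]; coverage removed
# strictly > 3.5 x median; locus call rate removed strictly < 0.8; MAF
# removed strictly < 0.02.

#' Default locus-filter thresholds
#'
#' @param repavg minimum repeatability; loci retained when `rep_avg > repavg`.
#' @param balance_min,balance_max closed retention interval for the allele
#'   read proportion.
#' @param coverage_mult loci removed when mean coverage exceeds
#'   `coverage_mult` times the median coverage across loci.
#' @param locus_callrate loci removed when call rate is `< locus_callrate`.
#' @param maf loci removed when minor-allele frequency is `< maf`.
#' @return list of thresholds.
#' @export
filter_params <- function(repavg = 0.95, balance_min = 0.15,
                          balance_max = 0.85, coverage_mult = 3.5,
                          locus_callrate = 0.8, maf = 0.02) {
  list(repavg = repavg, balance_min = balance_min, balance_max = balance_max,
       coverage_mult = coverage_mult, locus_callrate = locus_callrate,
       maf = maf)
}

#' Filter individuals by call rate
#'
#' Retains individuals whose proportion of non-missing loci is strictly
#' greater than `threshold`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param threshold call-rate threshold in (0, 1].
#' @return list: `genotypes` (filtered), `removed` (ids of dropped
#'   individuals).
#' @export
filter_individual_callrate <- function(genotypes, threshold = 0.35) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (n_ind(genotypes) == 0L || n_loci(genotypes) == 0L)
    stop("empty genotype matrix")
  cr <- individual_call_rate(genotypes)
  keep <- cr > threshold
  list(genotypes = subset_genotypes(genotypes, ind = which(keep)),
       removed = genotypes$ind_ids[!keep])
}

#' Apply the SNP locus-filter chain
#'
#' Applies, in order: (1) repeatability `rep_avg > repavg`; (2) allele read
#' proportion within `[balance_min, balance_max]`; (3) removal of loci whose
#' mean coverage exceeds `coverage_mult` times the median coverage of the
#' loci present at that step; (4) removal of loci with call rate below
#' `locus_callrate`, recomputed from the (post-individual-filter) genotype
#' matrix; (5) retention of one SNP per contig — the one with greatest
#' repeatability, ties broken by higher call rate then lexicographic locus
#' id; (6) removal of loci with minor-allele frequency below `maf`, computed
#' from non-missing allele copies.
#'
#' @param genotypes a SNP [genotype_matrix()] (after any individual filter).
#' @param report DArT-style locus report, one row per genotyped locus
#'   (see [make_dart_report()]).
#' @param params thresholds from [filter_params()].
#' @return list: `genotypes` (filtered), `report` (a `filter_report` data
#'   frame: step, loci before/after, individuals, removed ids as a
#'   list-column).
#' @export
apply_locus_filters <- function(genotypes, report, params = filter_params()) {
  if (!all(genotypes$locus_ids %in% report$locus_id))
    stop("every genotyped locus needs a report record")
  rep <- report[match(genotypes$locus_ids, report$locus_id), ]
  steps <- list()
  g <- genotypes
  n_i <- n_ind(g)

  drop_step <- function(name, removed_ids) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name,
      n_individuals_before = n_i, n_individuals_after = n_i,
      n_loci_before = n_loci(g),
      n_loci_after = n_loci(g) - length(removed_ids),
      stringsAsFactors = FALSE)
    steps[[length(steps)]]$removed_ids <<- I(list(removed_ids))
    if (length(removed_ids)) {
      keep <- !(g$locus_ids %in% removed_ids)
      g <<- subset_genotypes(g, loci = which(keep))
      rep <<- rep[keep, , drop = FALSE]
    }
  }

  # 1. repeatability
  drop_step("repavg", rep$locus_id[!(rep$rep_avg > params$repavg)])
  # 2. allele read-proportion balance (retain closed interval)
  bad <- rep$allele_read_proportion < params$balance_min |
    rep$allele_read_proportion > params$balance_max
  drop_step("balance", rep$locus_id[bad])
  # 3. coverage vs median of remaining loci
  med <- stats::median(rep$mean_coverage)
  drop_step("coverage",
            rep$locus_id[rep$mean_coverage > params$coverage_mult * med])
  # 4. locus call rate, recomputed from the genotype matrix
  cr <- locus_call_rate(g)
  drop_step("locus_callrate", g$locus_ids[cr < params$locus_callrate])
  # 5. one SNP per contig: keep greatest rep_avg; ties -> call rate -> id
  cr <- locus_call_rate(g)
  ord <- order(rep$contig_id, -rep$rep_avg, -cr, rep$locus_id)
  keep_first <- !duplicated(rep$contig_id[ord])
  drop <- rep$locus_id[ord][!keep_first]
  drop_step("one_snp_per_contig", drop)
  # 6. minor-allele frequency
  maf <- minor_allele_freq(g)
  drop_step("maf", g$locus_ids[!is.na(maf) & maf < params$maf])

  fr <- do.call(rbind, steps)
  class(fr) <- c("filter_report", class(fr))
  if (n_loci(g) == 0L)
    warning("all loci removed by the filter chain; check thresholds")
  list(genotypes = g, report = fr)
}

#' Run the full SNP filter chain
#'
#' Convenience wrapper: individual call-rate filter followed by the locus
#' chain of [apply_locus_filters()], returning a single audit trail whose
#' first row records the individual filter.
#'
#' @param genotypes a SNP [genotype_matrix()].
#' @param report DArT-style locus report.
#' @param ind_callrate individual call-rate threshold.
#' @param params locus thresholds from [filter_params()].
#' @return list: `genotypes`, `report` (audit trail incl. the individual
#'   step), `removed_individuals`.
#' @export
filter_chain <- function(genotypes, report, ind_callrate = 0.35,
                         params = filter_params()) {
  st1 <- filter_individual_callrate(genotypes, ind_callrate)
  res <- apply_locus_filters(st1$genotypes, report, params)
  ind_row <- data.frame(step = "individual_callrate",
                        n_individuals_before = n_ind(genotypes),
                        n_individuals_after = n_ind(st1$genotypes),
                        n_loci_before = n_loci(genotypes),
                        n_loci_after = n_loci(genotypes),
                        stringsAsFactors = FALSE)
  ind_row$removed_ids <- I(list(st1$removed))
  full <- rbind(ind_row, res$report)
  class(full) <- c("filter_report", class(full))
  list(genotypes = res$genotypes, report = full,
       removed_individuals = st1$removed)
}

#' Removed ids for one filter step
#'
#' @param report a `filter_report` from [apply_locus_filters()] or
#'   [filter_chain()].
#' @param step step name.
#' @return character vector of removed locus (or individual) ids.
#' @export
removed_at_step <- function(report, step) {
  i <- match(step, report$step)
  if (is.na(i)) stop("unknown filter step: ", step)
  report$removed_ids[[i]]
}
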