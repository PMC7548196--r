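# Paired-marker genotype simulator: K ancestral populations under the
# correlated-allele-frequencies (F) model, Dirichlet(alpha) individual
# admixture, SNP + microsatellite panels drawn from the same individuals,
# and a south-to-north heterozygosity cline built from serial founder events.

#' Simulation configuration
#'
#' Parameters of the paired-marker generative model. `K_true` ancestral
#' populations have per-locus allele frequencies drawn around a shared
#' ancestral frequency (symmetric Dirichlet with concentration `lambda_sim`)
#' with population-specific drift `F_k` (the F-model). Individuals receive
#' admixture proportions from a symmetric Dirichlet(`alpha_sim`) and both
#' marker panels are generated from the same ancestries. Localities are
#' ordered along a latitudinal expansion axis; serial founder bottlenecks
#' make expected heterozygosity decline northwards at `gradient_slope`
#' (sMLH units per degree latitude; 0 disables the cline).
#'
#' @param K_true number of ancestral populations (>= 1).
#' @param n_individuals number of diploid individuals.
#' @param n_snp_loci number of biallelic SNP loci.
#' @param n_microsat_loci number of multiallelic microsatellite loci.
#' @param alpha_sim Dirichlet admixture concentration (> 0); small values
#'   give nearly pure individuals.
#' @param F_k vector of drift parameters in (0,1), one per population
#'   (recycled if scalar).
#' @param microsat_allele_count maximum alleles per microsatellite locus (>= 2).
#' @param missing_rate fraction of genotype calls set to missing, in `[0,1)`.
#' @param n_localities number of sampling localities (<= n_individuals;
#'   default 15, capped at the number of individuals).
#' @param gradient_slope expected sMLH change per degree latitude (<= 0 for
#'   the northward-decline scenario; 0 = no cline).
#' @param lambda_sim Dirichlet concentration of ancestral allele frequencies.
#' @param lat_range latitudinal span of the localities, degrees.
#' @param lat_origin latitude of the southernmost locality, decimal degrees.
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(K_true = 2L, n_individuals = 90L, n_snp_loci = 2000L,
                       n_microsat_loci = 15L, alpha_sim = 0.1,
                       F_k = rep(0.1, K_true), microsat_allele_count = 10L,
                       missing_rate = 0,
                       n_localities = min(15L, n_individuals),
                       gradient_slope = 0, lambda_sim = 1,
                       lat_range = 5, lat_origin = 36, seed = 1L) {
  cfg <- list(K_true = as.integer(K_true),
              n_individuals = as.integer(n_individuals),
              n_snp_loci = as.integer(n_snp_loci),
              n_microsat_loci = as.integer(n_microsat_loci),
              alpha_sim = alpha_sim,
              F_k = rep_len(as.numeric(F_k), max(1L, as.integer(K_true))),
              microsat_allele_count = as.integer(microsat_allele_count),
              missing_rate = missing_rate,
              n_localities = as.integer(n_localities),
              gradient_slope = gradient_slope,
              lambda_sim = lambda_sim,
              lat_range = lat_range, lat_origin = lat_origin,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$K_true < 1L) stop("K_true must be >= 1")
  if (cfg$n_individuals < 1L || cfg$n_snp_loci < 0L || cfg$n_microsat_loci < 0L)
    stop("sizes must be positive")
  if (any(cfg$F_k <= 0) || any(cfg$F_k >= 1))
    stop("all F_k must lie in the open interval (0, 1)")
  if (cfg$alpha_sim <= 0) stop("alpha_sim must be > 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$microsat_allele_count < 2L) stop("microsat_allele_count must be >= 2")
  if (cfg$n_localities < 1L || cfg$n_localities > cfg$n_individuals)
    stop("n_localities must be in [1, n_individuals]")
  if (cfg$lambda_sim <= 0) stop("lambda_sim must be > 0")
  invisible(cfg)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  # tiny concentrations underflow all gammas to zero; in that limit the
  # draw is a one-hot vector with category probabilities alpha / sum(alpha)
  zero <- rowSums(x) == 0
  if (any(zero)) {
    cat_idx <- sample.int(k, sum(zero), replace = TRUE,
                          prob = alpha / sum(alpha))
    x[zero, ] <- 0
    x[cbind(which(zero), cat_idx)] <- 1
  }
  x / rowSums(x)
}

# F-model drift of one frequency simplex: p' ~ Dirichlet(p * (1-f)/f).
drift_simplex <- function(p, f) {
  if (f <= 0) return(p)
  a <- pmax(p * (1 - f) / f, 1e-12)
  as.numeric(rdirichlet(1, a))
}

#' Simulate a paired SNP / microsatellite dataset with known truth
#'
#' Draws ancestral allele frequencies per locus from a symmetric
#' Dirichlet(`lambda_sim`), population frequencies from the F-model
#' `Dirichlet(pi * (1-F_k)/F_k)`, individual ancestries from
#' Dirichlet(`alpha_sim`), and each of the 2L allele copies of an individual
#' by first choosing a population with probability `q_ik`, then an allele
#' from that population's (locality-drifted) frequencies. Both marker panels
#' share the same true ancestries. When `gradient_slope` is non-zero, each
#' locality's allele frequencies are re-drawn from its southern neighbour's
#' with a founder bottleneck sized so that expected heterozygosity declines
#' linearly with latitude at the requested rate (on the sMLH scale).
#'
#' @param config a [sim_config()].
#' @return list with elements `snp`, `microsat` (both [genotype_matrix()]),
#'   `dart_report` (a data frame, see [make_dart_report()]), `truth` (class
#'   `sim_truth`: `true_Q`, `ancestral_freqs`, `population_freqs`,
#'   `locality_freqs`, `coordinates`, `locality_ids`), and `localities`
#'   (data frame: id, latitude, longitude).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  K <- cfg$K_true
  n <- cfg$n_individuals
  m <- cfg$n_localities

  # localities south -> north along the expansion axis
  lat <- cfg$lat_origin +
    if (m > 1) (seq_len(m) - 1) / (m - 1) * cfg$lat_range else 0
  lon <- stats::runif(m, -9, 3)
  loc_ids <- sprintf("loc%02d", seq_len(m))
  ind_loc <- sort(rep_len(seq_len(m), n))

  true_Q <- rdirichlet(n, rep(cfg$alpha_sim, K))

  pi_snp <- lapply(seq_len(cfg$n_snp_loci), function(l)
    as.numeric(rdirichlet(1, rep(cfg$lambda_sim, 2))))
  pi_ms <- lapply(seq_len(cfg$n_microsat_loci), function(l)
    as.numeric(rdirichlet(1, rep(cfg$lambda_sim, cfg$microsat_allele_count))))

  draw_pop_freqs <- function(pi_list) {
    lapply(pi_list, function(pl) {
      t(vapply(seq_len(K), function(k) {
        a <- pmax(pl * (1 - cfg$F_k[k]) / cfg$F_k[k], 1e-12)
        as.numeric(rdirichlet(1, a))
      }, numeric(length(pl))))
    })
  }
  p_snp <- draw_pop_freqs(pi_snp)   # each: K x J matrix
  p_ms <- draw_pop_freqs(pi_ms)

  # Serial founder cline: per-locality bottleneck factors f_j chosen so that
  # expected heterozygosity follows a linear latitudinal target whose slope,
  # after sMLH standardization (division by the dataset mean), equals
  # gradient_slope. Exact for K_true = 1; approximate under admixture.
  f_chain <- rep(0, m)
  if (cfg$gradient_slope != 0 && m > 1) {
    h0 <- expected_het(true_Q, p_snp)
    mean_off <- mean(lat[ind_loc]) - lat[1]
    denom <- 1 - cfg$gradient_slope * mean_off
    s_raw <- cfg$gradient_slope * h0 / denom
    target <- pmax(h0 + s_raw * (lat - lat[1]), 0.05 * h0)
    f_chain[-1] <- pmin(pmax(1 - target[-1] / target[-m], 0), 0.9)
  }

  drift_all <- function(p_list) {
    # returns list over localities of list over loci of K x J matrices
    out <- vector("list", m)
    out[[1]] <- p_list
    for (j in seq_len(m)[-1]) {
      f <- f_chain[j]
      out[[j]] <- if (f <= 0) out[[j - 1]] else
        lapply(out[[j - 1]], function(pm)
          t(apply(pm, 1, drift_simplex, f = f)))
    }
    out
  }
  ploc_snp <- drift_all(p_snp)
  ploc_ms <- drift_all(p_ms)

  draw_panel <- function(ploc, allele_labels) {
    L <- length(ploc[[1]])
    if (L == 0) return(array(NA_integer_, c(n, 0, 2)))
    arr <- array(NA_integer_, c(n, L, 2))
    cq <- t(apply(true_Q, 1, cumsum))  # per-individual ancestry CDF
    for (l in seq_len(L)) {
      labs <- allele_labels[[l]]
      # stacked locality x population frequency CDFs for this locus
      PP <- do.call(rbind, lapply(seq_len(m), function(j) ploc[[j]][[l]]))
      cu <- t(apply(PP, 1, cumsum))
      for (cp in 1:2) {
        # population of origin of each allele copy: iid Cat(q_i)
        z <- pmin(rowSums(stats::runif(n) > cq) + 1L, K)
        r <- (ind_loc - 1L) * K + z
        a <- pmin(rowSums(stats::runif(n) > cu[r, , drop = FALSE]) + 1L,
                  length(labs))
        arr[, l, cp] <- labs[a]
      }
    }
    arr
  }

  snp_arr <- draw_panel(ploc_snp, rep(list(1:2), cfg$n_snp_loci))
  ms_labels <- rep(list(100L + 2L * seq_len(cfg$microsat_allele_count)),
                   cfg$n_microsat_loci)
  ms_arr <- draw_panel(ploc_ms, ms_labels)

  ind_ids <- sprintf("ind_%03d", seq_len(n))
  snp <- genotype_matrix(snp_arr, ind_ids = ind_ids,
                         locus_ids = sprintf("snp_%05d", seq_len(cfg$n_snp_loci)),
                         localities = loc_ids[ind_loc], marker = "snp")
  ms <- genotype_matrix(ms_arr, ind_ids = ind_ids,
                        locus_ids = sprintf("ms_%03d", seq_len(cfg$n_microsat_loci)),
                        localities = loc_ids[ind_loc], marker = "microsat")

  if (cfg$missing_rate > 0) {
    snp <- inject_missing(snp, cfg$missing_rate,
                          seed = cfg$seed + 104729L)
    ms <- inject_missing(ms, cfg$missing_rate, seed = cfg$seed + 104730L)
  }

  truth <- structure(
    list(true_Q = true_Q,
         ancestral_freqs = list(snp = pi_snp, microsat = pi_ms),
         population_freqs = list(snp = p_snp, microsat = p_ms),
         locality_freqs = list(snp = ploc_snp, microsat = ploc_ms),
         founder_f = f_chain,
         coordinates = data.frame(latitude = lat[ind_loc],
                                  longitude = lon[ind_loc]),
         locality_ids = loc_ids[ind_loc]),
    class = "sim_truth")

  list(snp = snp, microsat = ms,
       dart_report = make_dart_report(snp, dart_plan()),
       truth = truth,
       localities = data.frame(id = loc_ids, latitude = lat, longitude = lon))
}

# Expected probability that a random individual is heterozygous at a random
# locus, given ancestries Q and per-locus K x J population frequencies.
expected_het <- function(Q, p_list) {
  if (!length(p_list)) return(0)
  hets <- vapply(p_list, function(pm) {
    mix <- Q %*% pm            # N x J mixture frequency per individual
    mean(1 - rowSums(mix^2))
  }, numeric(1))
  mean(hets)
}

#' Inject missing genotype calls
#'
#' Sets each genotype call (both allele copies of one individual at one
#' locus) to missing independently with probability `rate`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param rate missing probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A `genotype_matrix` with missing calls added.
#' @export
inject_missing <- function(genotypes, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(genotypes)
  with_seed(seed, {
    n <- n_ind(genotypes); l <- n_loci(genotypes)
    hit <- matrix(stats::runif(n * l) < rate, n, l)
    arr <- genotypes$alleles
    arr[, , 1][hit] <- NA_integer_
    arr[, , 2][hit] <- NA_integer_
    genotype_matrix(arr, genotypes$ind_ids, genotypes$locus_ids,
                    genotypes$localities, genotypes$marker)
  })
}

#' Plan of deliberate quality violations for a DArT-style locus report
#'
#' Used with [make_dart_report()] to plant loci that violate each SNP
#' quality rule with known identities, so filter selections can be checked
#' against a ground truth. Unplanted loci get clean defaults: repeatability
#' 0.99, read proportion 0.5, coverage `base_coverage`, one contig per locus.
#'
#' @param low_repavg locus ids planted with repeatability `repavg_value`.
#' @param repavg_value repeatability for planted low-RepAvg loci.
#' @param unbalanced locus ids planted with read proportion `balance_value`.
#' @param balance_value allele read proportion for unbalanced loci.
#' @param high_coverage locus ids planted with `coverage_mult` x base coverage.
#' @param coverage_mult coverage multiplier for high-coverage loci.
#' @param contig_groups list of locus-id vectors; each group shares one contig.
#' @param contig_repavg list of numeric vectors parallel to `contig_groups`
#'   giving each member's repeatability (NULL = keep defaults).
#' @param base_coverage clean-locus mean coverage.
#' @return list of class `dart_plan`.
#' @export
dart_plan <- function(low_repavg = character(), repavg_value = 0.90,
                      unbalanced = character(), balance_value = 0.10,
                      high_coverage = character(), coverage_mult = 5,
                      contig_groups = list(), contig_repavg = NULL,
                      base_coverage = 20) {
  structure(list(low_repavg = low_repavg, repavg_value = repavg_value,
                 unbalanced = unbalanced, balance_value = balance_value,
                 high_coverage = high_coverage, coverage_mult = coverage_mult,
                 contig_groups = contig_groups, contig_repavg = contig_repavg,
                 base_coverage = base_coverage),
            class = "dart_plan")
}

#' Fabricate a DArT-style per-locus quality report
#'
#' Emits one record per SNP locus with the quality fields used by the filter
#' chain: repeatability (RepAvg), locus call rate (computed from the
#' genotypes), mean coverage, allele read proportion, and contig id. A
#' [dart_plan()] can plant loci violating each rule with known identities.
#'
#' @param genotypes a SNP [genotype_matrix()].
#' @param plan a [dart_plan()].
#' @return data frame with columns `locus_id`, `contig_id`, `rep_avg`,
#'   `locus_call_rate`, `mean_coverage`, `allele_read_proportion`.
#' @export
make_dart_report <- function(genotypes, plan = dart_plan()) {
  if (genotypes$marker != "snp") stop("DArT reports are defined for SNP data")
  ids <- genotypes$locus_ids
  rep <- data.frame(
    locus_id = ids,
    contig_id = paste0("contig_", ids),
    rep_avg = rep(0.99, length(ids)),
    locus_call_rate = as.numeric(locus_call_rate(genotypes)),
    mean_coverage = rep(plan$base_coverage, length(ids)),
    allele_read_proportion = rep(0.5, length(ids)),
    stringsAsFactors = FALSE)
  idx <- function(x) match(x, ids)
  if (length(plan$low_repavg))
    rep$rep_avg[idx(plan$low_repavg)] <- plan$repavg_value
  if (length(plan$unbalanced))
    rep$allele_read_proportion[idx(plan$unbalanced)] <- plan$balance_value
  if (length(plan$high_coverage))
    rep$mean_coverage[idx(plan$high_coverage)] <-
      plan$coverage_mult * plan$base_coverage
  if (length(plan$contig_groups)) {
    for (gi in seq_along(plan$contig_groups)) {
      grp <- plan$contig_groups[[gi]]
      rep$contig_id[idx(grp)] <- sprintf("contig_shared_%02d", gi)
      if (!is.null(plan$contig_repavg))
        rep$rep_avg[idx(grp)] <- plan$contig_repavg[[gi]]
    }
  }
  rep
}

#' Plant genotype-level filter violations
#'
#' Modifies a genotype matrix so chosen loci violate the locus call-rate or
#' minor-allele-frequency rule, for filter-audit tests. Call-rate loci have
#' calls blanked at random until their call rate equals `callrate`; MAF loci
#' are rewritten as major-allele homozygotes except `minor_copies` allele
#' copies.
#'
#' @param genotypes a [genotype_matrix()].
#' @param low_callrate_loci locus ids to degrade.
#' @param callrate target call rate for degraded loci.
#' @param low_maf_loci locus ids to make nearly monomorphic.
#' @param minor_copies number of minor-allele copies left at low-MAF loci.
#' @param seed integer RNG seed.
#' @return The modified `genotype_matrix`.
#' @export
plant_genotype_violations <- function(genotypes, low_callrate_loci = character(),
                                      callrate = 0.5,
                                      low_maf_loci = character(),
                                      minor_copies = 1L, seed = 1L) {
  with_seed(seed, {
    arr <- genotypes$alleles
    n <- n_ind(genotypes)
    for (id in low_callrate_loci) {
      l <- match(id, genotypes$locus_ids)
      n_blank <- n - floor(callrate * n)
      rows <- sample(n, n_blank)
      arr[rows, l, ] <- NA_integer_
    }
    for (id in low_maf_loci) {
      l <- match(id, genotypes$locus_ids)
      a <- c(arr[, l, 1], arr[, l, 2])
      a <- a[!is.na(a)]
      major <- as.integer(names(sort(table(a), decreasing = TRUE))[1])
      minor <- setdiff(unique(a), major)
      minor <- if (length(minor)) minor[1] else major + 1L
      arr[, l, 1] <- major
      arr[, l, 2] <- major
      rows <- sample(n, min(minor_copies, n))
      arr[rows, l, 1] <- minor
    }
    genotype_matrix(arr, genotypes$ind_ids, genotypes$locus_ids,
                    genotypes$localities, genotypes$marker)
  })
}
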