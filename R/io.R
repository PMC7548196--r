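# Readers/writers for the on-disk formats (STRUCTURE genotype text in both
# dialects, Q-matrix text, CSV tables, JSON manifests) and the top-level
# pipeline runner.

#' Write genotypes as a STRUCTURE-format text file
#'
#' Two dialects: `"two_row"` (two rows per individual, one column per
#' locus) and `"one_row"` (one row per individual, two adjacent columns per
#' locus). Missing allele copies are written as -9. The first line is a
#' whitespace-separated header of locus ids; each data row starts with the
#' individual id and, when present, the locality label.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @param dialect `"two_row"` or `"one_row"`.
#' @export
write_structure_file <- function(genotypes, path,
                                 dialect = c("two_row", "one_row")) {
  dialect <- match.arg(dialect)
  a <- genotypes$alleles
  a[is.na(a)] <- -9L
  n <- n_ind(genotypes); l <- n_loci(genotypes)
  has_loc <- !is.null(genotypes$localities)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(genotypes$locus_ids, collapse = " "), con)
  for (i in seq_len(n)) {
    lead <- c(genotypes$ind_ids[i],
              if (has_loc) genotypes$localities[i])
    if (dialect == "two_row") {
      writeLines(paste(c(lead, a[i, , 1]), collapse = " "), con)
      writeLines(paste(c(lead, a[i, , 2]), collapse = " "), con)
    } else {
      inter <- as.integer(rbind(a[i, , 1], a[i, , 2]))
      writeLines(paste(c(lead, inter), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a STRUCTURE-format genotype file
#'
#' Counterpart of [write_structure_file()]; `-9` is parsed as missing.
#'
#' @param path input file.
#' @param dialect `"two_row"` or `"one_row"`.
#' @param has_locality whether a locality column follows the individual id;
#'   NULL (default) detects it from the row width.
#' @param marker marker type recorded on the result.
#' @return a [genotype_matrix()].
#' @export
read_structure_file <- function(path, dialect = c("two_row", "one_row"),
                                has_locality = NULL,
                                marker = c("snp", "microsat")) {
  dialect <- match.arg(dialect)
  marker <- match.arg(marker)
  lines <- readLines(path)
  if (length(lines) < 2) stop("file has no genotype rows")
  locus_ids <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(locus_ids)
  body <- strsplit(trimws(lines[-1]), "\\s+")
  geno_n <- if (dialect == "two_row") L else 2L * L
  if (is.null(has_locality)) {
    # detect from the row width: id [locality] genotypes
    has_locality <- lengths(body)[1] == geno_n + 2L
  }
  lead_n <- 1L + as.integer(has_locality)
  exp_len <- lead_n + geno_n
  if (any(lengths(body) != exp_len))
    stop("ragged rows: expected ", exp_len, " fields per row")
  to_int <- function(x) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v) && any(is.na(v) != (x == "NA"))) stop("non-integer tokens")
    v
  }
  if (dialect == "two_row") {
    if (length(body) %% 2 != 0)
      stop("odd row count in two-row dialect")
    n <- length(body) %/% 2
    arr <- array(NA_integer_, c(n, L, 2))
    ids <- character(n); locs <- character(n)
    for (i in seq_len(n)) {
      r1 <- body[[2 * i - 1]]; r2 <- body[[2 * i]]
      if (r1[1] != r2[1]) stop("row pair has mismatched individual ids")
      ids[i] <- r1[1]
      if (has_locality) locs[i] <- r1[2]
      arr[i, , 1] <- to_int(r1[-seq_len(lead_n)])
      arr[i, , 2] <- to_int(r2[-seq_len(lead_n)])
    }
  } else {
    n <- length(body)
    arr <- array(NA_integer_, c(n, L, 2))
    ids <- character(n); locs <- character(n)
    for (i in seq_len(n)) {
      r <- body[[i]]
      ids[i] <- r[1]
      if (has_locality) locs[i] <- r[2]
      v <- to_int(r[-seq_len(lead_n)])
      arr[i, , 1] <- v[seq(1, 2 * L, by = 2)]
      arr[i, , 2] <- v[seq(2, 2 * L, by = 2)]
    }
  }
  arr[arr == -9L] <- NA_integer_
  genotype_matrix(arr, ind_ids = ids,
                  locus_ids = locus_ids,
                  localities = if (has_locality) locs else NULL,
                  marker = marker)
}

#' Write a Q-matrix as plain text
#'
#' One row per individual: id followed by K ancestry columns (CLUMPP
#' individual-file style), whitespace separated.
#'
#' @param Q N x K matrix (rownames used as ids when present).
#' @param path output file.
#' @export
write_qmatrix <- function(Q, path) {
  ids <- rownames(Q)
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(nrow(Q)))
  lines <- vapply(seq_len(nrow(Q)), function(i)
    paste(c(ids[i], sprintf("%.6f", Q[i, ])), collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Q-matrix written by [write_qmatrix()]
#'
#' @param path input file.
#' @param has_ids whether the first column is an id column.
#' @return numeric matrix with rows renormalized to sum to 1.
#' @export
read_qmatrix <- function(path, has_ids = TRUE) {
  body <- strsplit(trimws(readLines(path)), "\\s+")
  ids <- if (has_ids) vapply(body, `[`, character(1), 1) else NULL
  vals <- lapply(body, function(r)
    as.numeric(r[(1 + as.integer(has_ids)):length(r)]))
  Q <- do.call(rbind, vals)
  rownames(Q) <- ids
  Q / rowSums(Q)
}

#' Pipeline configuration
#'
#' Collects everything one end-to-end comparison needs. Genotypes and
#' tables may be given as in-memory objects or file paths (STRUCTURE text /
#' CSV).
#'
#' @param snp SNP genotypes ([genotype_matrix()] or STRUCTURE file path).
#' @param microsat microsatellite genotypes (object or path).
#' @param locus_report DArT-style locus report (data frame or CSV path).
#' @param localities locality table with `id`, `latitude`, `longitude`
#'   (data frame or CSV path).
#' @param ind_callrate individual call-rate threshold for the SNP filter.
#' @param filter locus thresholds from [filter_params()].
#' @param mcmc_snp,mcmc_microsat [mcmc_options()] per marker.
#' @param K_range K values for replicate clustering (within 1..20).
#' @param n_replicates replicate runs per K.
#' @param mode_threshold SSC threshold for mode grouping.
#' @param out_dir output directory (NULL = no files written).
#' @param seed master seed; per-run seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(snp, microsat, locus_report, localities,
                            ind_callrate = 0.35, filter = filter_params(),
                            mcmc_snp = mcmc_options(burnin = 300L,
                                                    iterations = 400L),
                            mcmc_microsat = mcmc_options(burnin = 500L,
                                                         iterations = 800L),
                            K_range = 1:4, n_replicates = 3L,
                            mode_threshold = 0.9, out_dir = NULL,
                            seed = 1L) {
  if (any(K_range < 1) || any(K_range > 20))
    stop("K_range must lie within [1, 20]")
  structure(list(snp = snp, microsat = microsat,
                 locus_report = locus_report, localities = localities,
                 ind_callrate = ind_callrate, filter = filter,
                 mcmc_snp = mcmc_snp, mcmc_microsat = mcmc_microsat,
                 K_range = as.integer(K_range),
                 n_replicates = as.integer(n_replicates),
                 mode_threshold = mode_threshold, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; path
#' fields (`snp`, `microsat`, `locus_report`, `localities`) are resolved
#' relative to the YAML file. Nested `filter`, `mcmc_snp` and
#' `mcmc_microsat` blocks are passed to [filter_params()] /
#' [mcmc_options()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  for (f in c("snp", "microsat", "locus_report", "localities")) {
    if (is.null(y[[f]])) stop("config is missing required path: ", f)
    p <- rel(y[[f]])
    if (!file.exists(p)) stop("configured path does not exist: ", p)
    y[[f]] <- p
  }
  args <- list(snp = y$snp, microsat = y$microsat,
               locus_report = y$locus_report, localities = y$localities)
  if (!is.null(y$filter)) args$filter <- do.call(filter_params, y$filter)
  if (!is.null(y$mcmc_snp)) args$mcmc_snp <- do.call(mcmc_options, y$mcmc_snp)
  if (!is.null(y$mcmc_microsat))
    args$mcmc_microsat <- do.call(mcmc_options, y$mcmc_microsat)
  for (f in c("ind_callrate", "K_range", "n_replicates", "mode_threshold",
              "out_dir", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(args$K_range) && length(args$K_range) == 2 &&
      !is.null(y$K_range_is_span) && isTRUE(y$K_range_is_span))
    args$K_range <- seq(args$K_range[1], args$K_range[2])
  do.call(pipeline_config, args)
}

resolve_genotypes <- function(x, marker) {
  if (inherits(x, "genotype_matrix")) return(x)
  read_structure_file(x, marker = marker)
}

resolve_table <- function(x) {
  if (is.data.frame(x)) return(x)
  utils::read.csv(x, stringsAsFactors = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full marker-comparison pipeline
#'
#' Executes, in order: the SNP filter chain; lambda estimation at K = 1 for
#' the SNPs; replicate admixture clustering over the K range for both
#' markers (microsatellites with lambda fixed to 1); the K-selection table
#' (Gelman-Rubin, Pr[X|K], Evanno delta-K, parsimony index); mode detection
#' per K; cross-marker SSC at each K; the coefficient of admixture; and the
#' diversity stage (sMLH, locality medians, cross-marker correlation,
#' latitude/longitude gradients). Artifacts are written under `out_dir`
#' when set, along with a JSON manifest of versions, seeds and parameters;
#' rerunning an identical configuration reproduces them.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `filtered`,
#'   `lambda`, `runs` (per marker), `kselect` (per marker), `modes`,
#'   `cross_ssc`, `admixture` (CA summaries), `diversity`, `manifest`.
#' @export
run_pipeline <- function(config) {
  snp <- stage("load_snp", resolve_genotypes(config$snp, "snp"))
  ms <- stage("load_microsat", resolve_genotypes(config$microsat, "microsat"))
  report <- stage("load_locus_report", resolve_table(config$locus_report))

  filt <- stage("filter", filter_chain(snp, report,
                                       ind_callrate = config$ind_callrate,
                                       params = config$filter))
  snp_f <- filt$genotypes

  lam_opts <- config$mcmc_snp
  lam_opts$seed <- config$seed
  lam <- stage("lambda", estimate_lambda(snp_f, lam_opts, n_replicates = 3L))

  snp_opts <- config$mcmc_snp
  snp_opts$lambda <- lam$lambda
  snp_opts$estimate_lambda <- FALSE
  snp_opts$seed <- config$seed + 1000L
  ms_opts <- config$mcmc_microsat
  ms_opts$lambda <- 1
  ms_opts$estimate_lambda <- FALSE
  ms_opts$seed <- config$seed + 2000L

  runs_snp <- stage("cluster_snp",
    replicate_runs(snp_f, config$K_range, config$n_replicates, snp_opts))
  runs_ms <- stage("cluster_microsat",
    replicate_runs(ms, config$K_range, config$n_replicates, ms_opts))

  ks_snp <- stage("kselect_snp", kselection_table(runs_snp))
  ks_ms <- stage("kselect_microsat", kselection_table(runs_ms))

  ks_multi <- config$K_range[config$K_range >= 2]
  modes <- stage("modes", lapply(stats::setNames(ks_multi, paste0("K", ks_multi)),
    function(K) list(
      snp = find_modes(lapply(runs_at_k(runs_snp, K), function(r) r$Q),
                       config$mode_threshold),
      microsat = find_modes(lapply(runs_at_k(runs_ms, K), function(r) r$Q),
                            config$mode_threshold))))

  cross <- stage("cross_ssc", lapply(stats::setNames(ks_multi, paste0("K", ks_multi)),
    function(K) {
      qs <- c(lapply(runs_at_k(runs_snp, K), function(r) r$Q),
              lapply(runs_at_k(runs_ms, K), function(r) r$Q))
      labs <- rep(c("snp", "microsat"),
                  c(length(runs_at_k(runs_snp, K)),
                    length(runs_at_k(runs_ms, K))))
      pm <- pairwise_ssc_matrix(qs, labels = labs)
      m <- pm$ssc
      intra_snp <- m[labs == "snp", labs == "snp"]
      intra_ms <- m[labs == "microsat", labs == "microsat"]
      inter <- m[labs == "snp", labs == "microsat"]
      list(ssc = m, labels = labs,
           intra_snp = intra_snp[upper.tri(intra_snp)],
           intra_microsat = intra_ms[upper.tri(intra_ms)],
           inter = as.numeric(inter))
    }))

  ca <- stage("admixture_coefficient",
    lapply(stats::setNames(ks_multi, paste0("K", ks_multi)), function(K) list(
      snp = coefficient_of_admixture(
        find_major_consensus(modes[[paste0("K", K)]]$snp)),
      microsat = coefficient_of_admixture(
        find_major_consensus(modes[[paste0("K", K)]]$microsat)))))

  manifest <- list(package = "markerstruct",
                   version = as.character(utils::packageVersion("markerstruct")),
                   seed = config$seed, K_range = config$K_range,
                   n_replicates = config$n_replicates,
                   lambda_snp = lam$lambda,
                   ind_callrate = config$ind_callrate,
                   filter = config$filter,
                   mode_threshold = config$mode_threshold)

  res <- structure(list(filtered = filt, lambda = lam,
                        runs = list(snp = runs_snp, microsat = runs_ms),
                        kselect = list(snp = ks_snp, microsat = ks_ms),
                        modes = modes, cross_ssc = cross, admixture = ca,
                        diversity = NULL, manifest = manifest),
                   class = "pipeline_result")
  # clustering artifacts land on disk before the diversity stage, so a
  # failure there (e.g. a bad locality table) leaves them usable
  if (!is.null(config$out_dir)) write_clustering_artifacts(res, config)

  locs <- stage("load_localities", resolve_table(config$localities))
  res$diversity <- stage("diversity", {
    d_snp <- diversity_table(snp_f, locs)
    d_ms <- diversity_table(ms, locs)
    shared <- intersect(names(d_snp$smlh), names(d_ms$smlh))
    corr <- marker_correlation(d_snp$smlh[shared], d_ms$smlh[shared])
    list(snp = d_snp, microsat = d_ms, correlation = corr)
  })
  if (!is.null(config$out_dir)) write_diversity_artifacts(res, config)
  res
}

find_major_consensus <- function(mode_set) {
  mode_set$consensus_Q[[mode_set$major_mode]]
}

write_clustering_artifacts <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  # filtered genotypes + audit trail
  write_structure_file(res$filtered$genotypes,
                       file.path(od, "snp_filtered.str"))
  fr <- res$filtered$report
  fr$removed_ids <- vapply(fr$removed_ids, paste, character(1), collapse = ";")
  utils::write.csv(fr, file.path(od, "filter_report.csv"), row.names = FALSE)
  # K-selection tables
  utils::write.csv(res$kselect$snp, file.path(od, "kselect_snp.csv"),
                   row.names = FALSE)
  utils::write.csv(res$kselect$microsat,
                   file.path(od, "kselect_microsat.csv"), row.names = FALSE)
  # per-run Q matrices and traces
  for (marker in c("snp", "microsat")) {
    qd <- file.path(od, paste0("runs_", marker))
    dir.create(qd, showWarnings = FALSE)
    for (nm in names(res$runs[[marker]])) {
      run <- res$runs[[marker]][[nm]]
      write_qmatrix(run$Q, file.path(qd, paste0(nm, "_Q.txt")))
      utils::write.csv(
        data.frame(step = seq_along(run$loglik_trace),
                   loglik = run$loglik_trace, alpha = run$alpha_trace),
        file.path(qd, paste0(nm, "_trace.csv")), row.names = FALSE)
    }
  }
  # cross-marker SSC long format
  long <- do.call(rbind, lapply(names(res$cross_ssc), function(kn) {
    x <- res$cross_ssc[[kn]]
    idx <- which(upper.tri(x$ssc), arr.ind = TRUE)
    data.frame(K = as.integer(sub("K", "", kn)),
               run_a = rownames(x$ssc)[idx[, 1]],
               run_b = colnames(x$ssc)[idx[, 2]],
               marker_a = x$labels[idx[, 1]], marker_b = x$labels[idx[, 2]],
               ssc = x$ssc[idx])
  }))
  utils::write.csv(long, file.path(od, "ssc_pairs.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(od)
}

write_diversity_artifacts <- function(res, config) {
  od <- config$out_dir
  for (marker in c("snp", "microsat")) {
    d <- res$diversity[[marker]]
    utils::write.csv(data.frame(ind = names(d$smlh), smlh = d$smlh),
                     file.path(od, paste0("smlh_", marker, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(locality = names(d$medians),
                                median_smlh = d$medians),
                     file.path(od, paste0("smlh_medians_", marker, ".csv")),
                     row.names = FALSE)
    gf <- d$gradient
    jsonlite::write_json(
      list(beta_latitude = gf$beta_latitude,
           beta_longitude = gf$beta_longitude,
           p_latitude = gf$p_latitude, p_longitude = gf$p_longitude,
           intercept = gf$intercept, n = gf$n),
      file.path(od, paste0("gradient_", marker, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$diversity$correlation,
                       file.path(od, "smlh_correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(od)
}
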