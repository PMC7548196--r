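# Bayesian admixture-model clustering: R surface over the compiled Gibbs
# sampler. The model is the standard one for unlinked diploid genotypes:
# each allele copy of individual i originates from cluster k with
# probability q_ik and is then drawn from that cluster's allele
# frequencies. Cluster frequencies follow, by default, the correlated
# allele-frequencies (F) model: p_kl ~ Dirichlet(pi_l (1-F_k)/F_k) around a
# shared ancestral frequency pi_l ~ Dirichlet(lambda).

#' MCMC options for the admixture sampler
#'
#' @param burnin burn-in sweeps (discarded).
#' @param iterations post-burn-in sweeps.
#' @param record_interval record the chain every this many sweeps.
#' @param lambda allele-frequency prior concentration: a positive number,
#'   or `"estimate"` to give it a Metropolis update (uniform prior on
#'   (0, 10]).
#' @param model `"correlated"` (F-model, default) or `"uncorrelated"`.
#' @param alpha_init initial admixture concentration alpha.
#' @param alpha_proposal_sd Metropolis proposal sd for alpha; 0 keeps alpha
#'   fixed at `alpha_init` (the no-inference setting of the reference
#'   implementation).
#' @param alpha_prior_max upper bound of alpha's uniform prior.
#' @param f_proposal_sd logit-scale random-walk sd for the drift F_k.
#' @param pi_proposal_conc concentration of the Dirichlet random-walk
#'   proposal for the ancestral frequencies.
#' @param store_q_draws keep recorded per-step Q draws (for posterior
#'   intervals); memory scales with N x K x recorded steps.
#' @param seed integer RNG seed.
#' @return list of class `mcmc_options`.
#' @export
mcmc_options <- function(burnin = 500L, iterations = 1000L,
                         record_interval = 1L, lambda = 1,
                         model = c("correlated", "uncorrelated"),
                         alpha_init = 1.0, alpha_proposal_sd = 0.05,
                         alpha_prior_max = 10, f_proposal_sd = 0.1,
                         pi_proposal_conc = 100, store_q_draws = FALSE,
                         seed = 1L) {
  model <- match.arg(model)
  est <- identical(lambda, "estimate")
  lam <- if (est) 1.0 else as.numeric(lambda)
  if (!est && lam <= 0) stop("lambda must be positive or \"estimate\"")
  if (burnin < 0L) stop("burnin must be >= 0")
  if (iterations < record_interval || record_interval < 1L)
    stop("need iterations >= record_interval >= 1")
  structure(list(burnin = as.integer(burnin),
                 iterations = as.integer(iterations),
                 record_interval = as.integer(record_interval),
                 lambda = lam, estimate_lambda = est, model = model,
                 alpha_init = alpha_init,
                 alpha_proposal_sd = alpha_proposal_sd,
                 alpha_prior_max = alpha_prior_max,
                 f_proposal_sd = f_proposal_sd,
                 pi_proposal_conc = pi_proposal_conc,
                 store_q_draws = store_q_draws,
                 seed = as.integer(seed)),
            class = "mcmc_options")
}

#' Admixture-model log-likelihood
#'
#' `ln Pr(X | Q, P)`: the sum over non-missing allele copies (i, l, a) of
#' `ln sum_k q_ik p_k,l,allele(i,l,a)`. Missing copies contribute nothing.
#'
#' @param genotypes a [genotype_matrix()].
#' @param Q N x K matrix of ancestry proportions.
#' @param P list (one per locus) of K x J_l allele-frequency matrices, on
#'   the same per-locus allele ordering as `dense_allele_codes`
#'   (sorted allele labels).
#' @return the log-likelihood (0 when every call is missing).
#' @export
log_likelihood <- function(genotypes, Q, P) {
  dc <- dense_allele_codes(genotypes)
  if (nrow(Q) != n_ind(genotypes)) stop("Q rows must match individuals")
  if (length(P) != n_loci(genotypes)) stop("P must have one matrix per locus")
  .loglik_cpp(dc$codes, dc$n_alleles, Q, lapply(P, as.matrix))
}

#' Run the admixture Gibbs sampler
#'
#' One MCMC replicate at a fixed K. Updates: latent origin of every allele
#' copy (categorical), ancestry rows `q_i` (Dirichlet), cluster allele
#' frequencies `p_kl` (Dirichlet), and Metropolis steps for the F-model
#' hyperparameters (drift `F_k` on the logit scale, ancestral frequencies
#' `pi_l`), for alpha, and for lambda when it is estimated. Posterior means
#' of Q and P are accumulated over every recorded post-burn-in step.
#'
#' @param genotypes a [genotype_matrix()].
#' @param K number of clusters (1 <= K <= N).
#' @param opts an [mcmc_options()].
#' @return list of class `structure_run`: `K`, `Q` (posterior-mean, rows
#'   named by individual), `P`, `alpha_trace`, `loglik_trace`,
#'   `lambda_trace`, `lambda`, `F`, acceptance rates, the options used,
#'   and `q_draws` (K x N x steps array) when requested.
#' @export
run_admixture_mcmc <- function(genotypes, K, opts = mcmc_options()) {
  if (n_ind(genotypes) < 1L || n_loci(genotypes) < 1L)
    stop("empty genotype matrix")
  if (K < 1L) stop("K must be >= 1")
  dc <- dense_allele_codes(genotypes)
  res <- with_seed(opts$seed,
    .admixture_gibbs(dc$codes, dc$n_alleles, as.integer(K),
                     opts$burnin, opts$iterations, opts$record_interval,
                     opts$model == "correlated", opts$lambda,
                     opts$estimate_lambda, opts$alpha_init,
                     opts$alpha_proposal_sd, opts$alpha_prior_max,
                     opts$f_proposal_sd, opts$pi_proposal_conc,
                     opts$store_q_draws))
  rownames(res$Q) <- genotypes$ind_ids
  run <- c(res, list(K = as.integer(K), seed = opts$seed, opts = opts,
                     ind_ids = genotypes$ind_ids,
                     localities = genotypes$localities))
  class(run) <- "structure_run"
  run
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("structure_run: K=%d, %d individuals, %d recorded steps, mean lnL %.1f\n",
              x$K, nrow(x$Q), length(x$loglik_trace), mean(x$loglik_trace)))
  invisible(x)
}

#' Estimate the allele-frequency prior concentration lambda at K = 1
#'
#' Runs the single-cluster sampler with lambda treated as a parameter
#' (Metropolis update, uniform prior on (0, 10]) and returns the mean of
#' the posterior-mean lambda across replicate runs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param opts an [mcmc_options()]; its lambda setting is overridden.
#' @param n_replicates number of replicate runs averaged (>= 1).
#' @return list: `lambda` (the averaged estimate), `per_replicate`.
#' @export
estimate_lambda <- function(genotypes, opts = mcmc_options(),
                            n_replicates = 3L) {
  if (n_replicates < 1L) stop("need at least one replicate")
  opts$estimate_lambda <- TRUE
  opts$model <- "uncorrelated"  # at K = 1 lambda is the frequency prior
  per <- vapply(seq_len(n_replicates), function(r) {
    o <- opts
    o$seed <- opts$seed + r - 1L
    run_admixture_mcmc(genotypes, K = 1L, o)$lambda_mean
  }, numeric(1))
  list(lambda = mean(per), per_replicate = per)
}

#' Replicate admixture runs across a range of K
#'
#' Independent replicate runs for each K, with per-run seeds derived
#' deterministically from the base seed (`seed + run index`), so the set is
#' reproducible yet the replicates are independent.
#'
#' @param genotypes a [genotype_matrix()].
#' @param K_range integer vector of K values (e.g. `1:8`).
#' @param n_replicates replicate runs per K.
#' @param opts an [mcmc_options()] shared by all runs.
#' @return list of class `run_set`; elements named `"K<k>_rep<r>"`, each a
#'   `structure_run`.
#' @export
replicate_runs <- function(genotypes, K_range, n_replicates = 10L,
                           opts = mcmc_options()) {
  if (!length(K_range)) stop("K_range must be non-empty")
  runs <- list()
  idx <- 0L
  for (K in sort(unique(as.integer(K_range)))) {
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      o <- opts
      o$seed <- opts$seed + idx
      runs[[sprintf("K%d_rep%d", K, r)]] <-
        run_admixture_mcmc(genotypes, K, o)
    }
  }
  class(runs) <- "run_set"
  runs
}

#' Extract runs at one K from a run set
#' @param runs a `run_set` from [replicate_runs()].
#' @param K the K value.
#' @export
runs_at_k <- function(runs, K) {
  runs[vapply(runs, function(r) r$K == K, logical(1))]
}
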