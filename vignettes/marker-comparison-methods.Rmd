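---
title: "Methods: comparing genetic structure and diversity across marker types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing genetic structure and diversity across marker types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`markerstruct` implements an end-to-end comparison of population genetic
structure and diversity between a dense biallelic SNP panel and a small
multiallelic microsatellite panel genotyped on the same individuals (or the
same localities). This vignette documents the models, the tunable
parameters, the numerical choices, and the places where the design was
genuinely open.

## The admixture model

The clustering engine is the standard Bayesian admixture model for unlinked
diploid genotypes. Individual $i$ carries ancestry proportions
$q_i = (q_{i1},\dots,q_{iK})$ on the $K$-simplex; each of its $2L$ allele
copies originates from cluster $k$ with probability $q_{ik}$ and is then
drawn from that cluster's allele frequencies $p_{kl}$ at locus $l$. The
likelihood of the observed copies is

$$\ln \Pr(X \mid Q, P) \;=\; \sum_{(i,l,a)\ \mathrm{observed}}
\ln \sum_{k=1}^{K} q_{ik}\, p_{k,l,\mathrm{allele}(i,l,a)} .$$

Missing allele copies (code −9 on disk) are skipped everywhere — no
imputation.

Cluster frequencies follow, by default, the **correlated allele frequencies
(F) model**: a shared ancestral frequency vector $\pi_l \sim
\mathrm{Dirichlet}(\lambda)$ per locus, and
$p_{kl} \sim \mathrm{Dirichlet}\big(\pi_l (1-F_k)/F_k\big)$, with one drift
parameter $F_k \in (0,1)$ per cluster. Small $F_k$ means frequencies close
to the ancestral values; $F_k$ plays the role of a cluster-specific
$F_{ST}$. An uncorrelated variant
($p_{kl} \sim \mathrm{Dirichlet}(\lambda)$) is available through
`mcmc_options(model = "uncorrelated")`, mainly for testing.

### Gibbs sampler

`run_admixture_mcmc()` alternates:

1. latent origin $z_{ila} \sim \mathrm{Cat}\big(\propto q_{ik}
   p_{kl,\mathrm{allele}}\big)$ for every observed allele copy;
2. $q_i \sim \mathrm{Dirichlet}(\alpha + n_{i\cdot})$, with $n_{ik}$ the
   copy counts assigned to cluster $k$;
3. $p_{kl} \sim \mathrm{Dirichlet}(\mathrm{prior} + c_{kl\cdot})$, prior
   $\pi_l(1-F_k)/F_k$ (correlated) or $\lambda$ (uncorrelated);
4. Metropolis updates for $F_k$ (Gaussian random walk on the logit scale,
   step 0.1, uniform(0,1) prior) and for $\pi_l$ (Dirichlet random-walk
   proposal with concentration 100, prior $\mathrm{Dirichlet}(\lambda)$);
5. a Metropolis update for the single shared $\alpha$ (proposal sd 0.05,
   uniform prior on $(0, 10]$), starting at $\alpha = 1$;
6. optionally a Metropolis update for $\lambda$ (uniform prior on
   $(0, 10]$).

A single $\alpha$ is shared across clusters. Posterior means of $Q$ and $P$
are accumulated over every recorded post-burn-in sweep
(`record_interval = 1` by default); the log-likelihood and $\alpha$ are
recorded on the same schedule. All randomness goes through R's RNG, so a
run is reproducible to full precision from its seed.

### Lambda

$\lambda$ is the Dirichlet concentration of the allele-frequency prior;
values below 1 favour skew toward rare alleles, which suits SNP panels.
`estimate_lambda()` follows the standard protocol: run the $K=1$ sampler
with $\lambda$ as a free parameter, three replicate runs, and average the
posterior means. At $K=1$ the uncorrelated and correlated models coincide
in the role $\lambda$ plays, so the uncorrelated form is used there.
Microsatellite runs keep $\lambda = 1$.

### Run lengths at desk scale

The reference protocol uses 30,000/10,000 (burn-in/recorded) sweeps for
SNP panels and 500,000/1,000,000 for microsatellites. Those lengths exist
to be safe on real data; the analyses and tests in this package run on
simulated data an order of magnitude smaller, and were sized by
convergence diagnostics instead: the slowest-moving quantity is $\alpha$,
whose random walk (sd 0.05 from $\alpha_0 = 1$) needs roughly a thousand
sweeps to equilibrate near a small true $\alpha$. The package therefore
uses 1,600/400 sweeps for SNP-panel runs and 2,000/600 for
microsatellite runs in its analysis scripts (`analysis/03_cluster.R`),
and the replicate spread of mean log-likelihood at fixed $K$ is monitored
through the Gelman–Rubin statistic.

One interaction deserves a note. While $\alpha$ is still large the
ancestry rows stay diffuse, which lets the latent assignments migrate
between clusters; once $\alpha$ has descended near a small true value,
a run that has not yet populated all $K$ clusters is effectively trapped
in a lower-$K$ mode (the familiar label-mode stickiness of admixture
Gibbs samplers). In short runs the descent speed of $\alpha$ therefore
controls the exploration window: replicate K-selection experiments in
this package use a slower $\alpha$ proposal (sd 0.01), which keeps
exploration alive through the burn-in and makes replicate log-likelihoods
agree closely at every $K$; with the descent-limited window of the
default sd, a minority of short replicates lock into merged-cluster
modes. The long-run default remains sd 0.05. Problem sizes in the scripts
(90 individuals, 800 SNPs, 15 microsatellites, $K \le 4$, 3 replicates)
keep a full pipeline run in the minutes range on one core.

## K selection

Four quantities are tabulated per $K$ by `kselection_table()`:

- **Gelman–Rubin** across the replicate log-likelihood traces, computed as
  $\sqrt{\hat V / W}$ with $\hat V = \frac{n-1}{n} W + \frac{B}{n} +
  \frac{B}{mn}$; values below 1.05 are read as good convergence. The
  monitored statistic is the log-likelihood — the one per-sweep scalar
  every run logs; a multivariate version (e.g. jointly with $\alpha$) was
  considered and rejected as it changes nothing at desk scale.
- **Pr[X|K]** estimated from the trace as
  $\overline{\ln L} - \tfrac12 \mathrm{Var}(\ln L)$.
- **Evanno's $\Delta K$**: $|L(K{+}1) - 2L(K) + L(K{-}1)| / s(K)$ where
  $L$ is the replicate mean of mean $\ln L$ and $s$ its replicate standard
  deviation; undefined at the ends of the $K$ range; infinite (with a
  warning) when $s = 0$.
- **Parsimony index**: the product of run-consistency (mean pairwise
  aligned SSC among the $K$'s replicates) and parsimony (one minus the
  mean coefficient of admixture of the aligned consensus). This
  operationalizes "consistent runs with minimal average admixture" as a
  product of two unit-interval terms — 1 for identical, fully pure
  solutions; 0 for uniformly admixed ones — and is deliberately isolated
  in one function (`parsimony_index()`) so a different published form can
  be substituted without touching callers.

A model-free cross-check is provided by neighbour joining
(`neighbor_joining()`, via `ape::nj`) on allele-sharing distances
($d = 1 -$ mean proportion of shared alleles over co-typed loci, values
0/0.5/1 per diploid locus). Negative NJ branches are clamped to zero with
the deficit moved to the adjacent branch.

## Q-matrix comparison

Replicate runs of the same data differ by column order (label switching).
`align_qmatrices()` resolves this by maximizing the **symmetric similarity
coefficient**

$$\mathrm{SSC}(Q_1, Q_2; \Pi) = 1 - \frac{\lVert Q_1 - Q_2 \Pi
\rVert_F}{\sqrt{2N}},$$

which is 1 iff the matrices are identical under the permutation and can go
negative for very dissimilar pairs. Maximizing the SSC over permutations
is a linear assignment problem (the Frobenius norm decomposes over column
pairs), so the search is exhaustive up to $K = 8$ ($8! = 40{,}320$
permutations) and solved by the Hungarian algorithm — exact in $O(K^3)$ —
above; the tests verify that the two routes agree on random pairs for
$K \le 6$. A best-remaining-pair greedy heuristic was considered and
rejected: it provably misses the optimum on some inputs. When two
matrices have different $K$, the smaller is padded with zero columns
first, which is how clusters are matched across successive $K$ values — a
simpler scheme than divisive matching, chosen because downstream use only
needs the shared clusters to map onto each other.

`find_modes()` groups replicate runs by single-linkage on aligned SSC at
threshold 0.9 (a conventional default; the threshold is exposed). Each
mode's consensus is the mean of member matrices aligned to the group's
first member; the major mode is the largest group, ties broken by higher
mean intra-group SSC.

The **coefficient of admixture** is implemented as normalized Shannon
entropy, $\mathrm{CA}_i = -\sum_k q_{ik} \ln q_{ik} / \ln K$: 0 when all
ancestry sits in one cluster, 1 at equal proportions — the two conditions
that define the index. Entropy is the canonical functional with those
endpoints, but it is not the only one, so a max-based alternative
($1 - \frac{K}{K-1}(\max_k q_{ik} - 1/K)$) is available via
`coefficient_of_admixture(..., method = "max")`.

When the two markers were genotyped on different individuals from the same
localities, `average_by_locality()` averages ancestries per locality
before comparison; cross-marker SSC values are computed over all run
pairs, not only mode consensuses.

## Diversity

`smlh()` computes standardized multilocus heterozygosity: the proportion
of an individual's typed loci that are heterozygous, divided by the mean
dataset heterozygosity $h_l$ of exactly those loci. With complete data the
individual values average 1 — an algebraic identity the tests enforce to
$10^{-9}$. Loci monomorphic in the dataset are excluded (they would
deflate the denominator while carrying no information). Per-locality
summaries use the standard midpoint median. The cross-marker association
is a Pearson correlation on individual values with the usual $t$-based
p-value; the spatial gradient is OLS of sMLH on latitude and longitude
(no interaction), individual-level rather than locality-median — the
correlation is defined on individuals, and using the same unit in the
regression keeps the two analyses comparable (medians remain available
via `locality_medians()`).

## The synthetic-data generator

`simulate_dataset()` draws from exactly the model the sampler assumes —
$\pi_l \sim \mathrm{Dirichlet}(\lambda_{\mathrm{sim}})$ (default 1),
$p_{kl}$ from the F-model, $q_i \sim \mathrm{Dirichlet}(\alpha_{\mathrm{sim}})$
— and generates both marker panels from the *same* $q_i$: SNPs biallelic,
microsatellites with up to `microsat_allele_count` alleles labelled as
repeat counts. Missing calls are injected independently per genotype call
(both copies together), default rate 7.6%.

The spatial diversity cline is a **serial founder-event chain**:
localities are ordered along latitude, and each locality's allele
frequencies are redrawn from its southern neighbour's with a bottleneck
$p^{(j)} \sim \mathrm{Dirichlet}\big(p^{(j-1)} (1-f_j)/f_j\big)$. Because
this drift step loses heterozygosity in expectation by the factor
$(1-f_j)$, the chain $f_2, \dots, f_m$ can be solved so that expected
heterozygosity follows a linear latitudinal target whose slope, after
sMLH standardization, equals `gradient_slope` (default −0.08 per degree —
the magnitude reported for Iberian amphibian SNP panels). The calibration
is exact for a single ancestral population and approximate under
admixture; the recovery tests accept ±0.03 on the slope. This generative
cline is a stand-in: south-to-north diversity loss is an empirical
pattern, not a published generative model, and the founder chain is the
simplest mechanism that reproduces it.

What the generator does *not* emulate: linkage and recombination,
realistic microsatellite mutation (alleles drift by resampling, not
stepwise mutation), ascertainment bias in SNP discovery, and
locality-level deviations from Hardy–Weinberg beyond the founder chain.
Passing tests therefore show the estimators are correct *under the model
they assume*, and that the marker contrast (few multiallelic loci versus
many biallelic loci) behaves as reported; they do not certify behaviour
on real DArT data with those extra complications.

DArT-style locus metadata (`make_dart_report()`) is fabricated with clean
defaults (repeatability 0.99, read proportion 0.5, constant coverage, one
contig per locus) plus a plan of deliberate violations with known
identities, so the filter audit can be checked exactly. Loci violating
the call-rate and minor-allele-frequency rules are planted in the
genotypes themselves (`plant_genotype_violations()`).

## Filtering

`apply_locus_filters()` applies the chain in its published order:
repeatability, read balance, coverage, locus call rate (recomputed on the
post-individual-filter matrix), one SNP per contig, minor-allele
frequency. Tie handling at thresholds follows the rule wording:
repeatability and individual call rate are strict ("greater than"), locus
call rate removal is strict ("lower than 0.8", so exactly 0.8 is kept),
coverage removal is strict (`> 3.5 ×` midpoint-interpolated median), the
balance interval [0.15, 0.85] is closed, and MAF removal is strict
(`< 0.02`). "Removing" an allele rarer than 2% on biallelic data would
leave a monomorphic locus, so the rule is implemented as removal of the
locus. Within-contig ties on repeatability break by higher call rate,
then lexicographic locus id, so output is deterministic. MAF is computed
after the within-contig deduplication, matching the order the rules are
stated in.

## Numerical choices and degenerate inputs

- Dirichlet draws use gamma variates floored at $10^{-300}$; ancestry and
  frequency floors avoid $\log 0$ without affecting results at reported
  precision.
- The F-model prior concentration $\pi_l(1-F_k)/F_k$ is floored at
  $10^{-6}$ per component.
- `gelman_rubin()` signals zero within-chain variance with distinct chain
  means as a degenerate input rather than returning a value; equal
  constant chains return 1.
- `evanno_delta_k()` reports infinity with a warning when a replicate sd
  is zero, and refuses non-contiguous K ranges.
- An individual typed at zero polymorphic loci, a pair with no co-typed
  loci, or a singular coordinate design each raise an explicit error.
- `ssc()` requires equal K; `align_qmatrices()` handles unequal K by
  padding, and validates simplex rows to $10^{-6}$.

## Known limitations

- Evanno's $\Delta K$ carries a documented bias toward low $K$ (it is one
  of the reasons a parsimony-style index exists at all): on a
  three-population F-model dataset with drift 0.05 and nearly pure
  individuals, desk-scale replicate experiments in this package find the
  $\Delta K$ peak at $K = 3$ in roughly seven of ten simulations, with
  the remainder peaking at $K = 2$ — the successive-gain curvature at
  $K = 2$ is a dataset-level quantity that no amount of extra MCMC
  removes, and the replicate standard deviation at $K = 2$ is small
  precisely when the runs converge well. Treat $\Delta K$ as one vote
  among the tabulated criteria, not an oracle.
- The parsimony index is a documented operationalization (product form),
  not a transcription of a specific published formula.
- The Gibbs sampler can stick in label-permutation modes at large $K$ on
  weakly structured data within desk-scale run lengths — exactly the
  behaviour the replicate-consistency metrics are designed to expose.
- Cross-$K$ alignment by zero padding does not model cluster splitting;
  a split cluster maps onto whichever child matches best.
- The founder-event cline confounds drift with spatial structure by
  construction; gradient recovery tests hold at the calibrated slope but
  per-locality drift realizations are stochastic, so single-seed slopes
  scatter around the target.
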