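---
title: "Methods: admixture-based geolocation and trait prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture-based geolocation and trait prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whogem)
```

## The model in one page

A sample's genome is summarized by a vector of admixture proportions
$\theta = (\theta_1, \dots, \theta_K)$ on the probability simplex: the
fractions contributed by $K$ putative ancestral populations.  `whogem`
builds two predictions on top of $\theta$:

* **Geolocation.**  Under isolation by distance the Euclidean distance
  between admixture vectors, $\Delta$, increases approximately linearly
  with geographic distance at short range.  A calibration
  $\mathrm{Geo} = a + b\,\Delta$ is fitted over sample pairs closer than a
  distance cutoff; a query is then placed near its genetically closest
  reference units, at most $a + b\,\Delta_{\min}$ away from their centroid.
* **Trait prediction.**  A quantitative trait is regressed on a subset of
  the components, $y = \beta_0 + \sum_{k \in S}\beta_k \theta_k +
  \varepsilon$.  Admixture integrates drift, migration and selection, so
  for traits shaped by population history this small model can rival
  genome-wide marker regressions.

Both predictions presuppose that admixture is geographically structured.
The package therefore ships a simulator whose outputs provably have that
structure, so every claim is testable without external data.

## Admixture estimation

Dosages $g_{ij} \in \{0,1,2\}$ are modelled as
$g_{ij} \sim \mathrm{Binomial}(2, \sum_k q_{ik} f_{kj})$.  Both estimation
modes maximize this likelihood with multiplicative EM updates:

* **Supervised** (`estimate_q_supervised`): ancestral frequencies
  $\hat f_{kj}$ are per-class observed frequencies with a $\pm 0.5$
  pseudo-count, held fixed; each sample's $q$ is optimized over the
  simplex.
* **Unsupervised** (`estimate_admixture_unsupervised`): $Q$ and $F$ are
  updated jointly from the same responsibilities, initialized from
  k-means on the top-10 PCA scores with seeded perturbation.

Design notes:

* We use plain EM, not quasi-Newton block relaxation.  The contract is
  likelihood monotonicity (asserted on every run — a decrease raises an
  error) and parameter recovery on synthetic data, not bit-level
  concordance with any external program.  Externally produced `.Q` files
  are accepted by every downstream function.
* Frequencies are clipped to $[10^{-6}, 1 - 10^{-6}]$; EM stops when the
  log-likelihood improves by less than $10^{-7}$ or after 2000 iterations
  (both configurable; tests cap iterations, since parameter error
  stabilizes long before the likelihood tolerance bites).
* Component labels are arbitrary.  Output columns are ordered by total
  weight; cross-run comparisons should align components with
  `match_components()` (exhaustive correlation matching, $K \le 8$).
* Missing genotypes simply drop out of the likelihood.

The K-selection cross-validation (`admixture_cv_error`) masks a fraction
of the non-missing entries per fold, refits on the remainder, and scores
root-mean-square error of the predicted dosage $2\sum_k \hat q_{ik}\hat
f_{kj}$ on the masked entries.  Masked-entry RMSE is our defined
criterion; reference implementations do not document theirs at this
granularity.

## Choosing K

Three independent signals are combined (`choose_k`):

1. the masked-entry CV error curve — candidate region: within one
   standard error of the minimum;
2. a k-means/BIC scan on PCA scores (`bic_scan`), with
   $\mathrm{BIC}(K) = N\ln(\mathrm{WSS}/N) + K\ln N$ — candidate region:
   within $\ln N$ of the minimum (one parameter's worth of penalty);
3. leave-one-out geolocation accuracy for the candidate Ks, resolved by
   the parsimony rule of `select_k`: the smallest K whose median error is
   within 5% of the best and whose country accuracy is within 5% of the
   best.

The BIC formula is fixed by design and documented rather than matched to
any external tool; its argmin behaviour is only meaningful on score
matrices with enough retained dimensions that a spurious split cannot
absorb much within-cluster variance (the usual DAPC regime of tens of
PCs).  On low-dimensional embeddings the $K\ln N$ penalty is too weak and
the curve keeps decreasing — a property, not a bug, of this classical
criterion.

## The placement algorithm

Given a calibration and a reference panel (accession-level rows, or
population-level mean vectors with geographic centroids — the same code
path), `predict_location`:

1. computes $\Delta_m$ to every panel unit and $\Delta_{\min}$;
2. pools all units with $\Delta_m \le \Delta_{\min}(1 + \texttt{tie\_tol})$
   into a tie set; the placement origin $g_0$ is the tie set's centroid
   (ties are genuinely common for selfing species, where distinct
   accessions can share an admixture vector);
3. if $\Delta_{\min}$ is numerically zero, returns $g_0$;
4. otherwise converts $\Delta_{\min}$ to a radius $r = a + b\Delta_{\min}$,
   takes the $M$ nearest units (default 10, capped at panel size), weights
   them $w_m = \Delta_{\min}/\Delta_m \in (0, 1]$, and forms the
   displacement $D = \sum_{m \notin \text{tie set}} w_m (g_m - g_0)$;
5. returns $g_0 + \min(1, r/\lVert D\rVert)\,D$.

Design choices made where the procedure was genuinely open:

* **Clip, not project.**  "Scaled to fit on a circle of radius r" admits
  two readings; we clip (`min(1, r/||D||)`) so that short, internally
  consistent displacements are preserved, and expose
  `scale_rule = "project"` for the always-rescale reading.
* **Metric discipline.**  Distances and displacements are computed in one
  metric, tagged on the calibration object: `euclidean-degrees` (naive
  degrees, adequate at regional scale) or `great-circle-km` (haversine,
  displacements in the local tangent plane).  Mixing is impossible by
  construction.
* **Country correctness** in validation is the country label of the panel
  unit nearest to the predicted point — a deliberate proxy that avoids
  polygon shapefiles and is exact on the simulator's Voronoi countries.
* The packaged *M. truncatula* constants (`mtruncatula_calibration()`,
  $\mathrm{Geo} = 0.204 + 4.973\,\mathrm{Gen}$, 950-km cutoff, Mantel
  r = 0.294 full / 0.78 restricted) are stored verbatim.  The source does
  not state the regression's distance units; the magnitudes are consistent
  with Euclidean degrees ($a + b\sqrt2 \approx 7.2^\circ \approx 800$ km,
  inside the 950-km linear range), so the object is tagged
  `euclidean-degrees` with a 111.32 km/degree reporting factor and the
  unit assignment is flagged as inferred.

Leave-one-out validation at population level replaces the focal sample's
population mean by the adjusted mean over the remaining $n_i - 1$ members
(and recomputes the centroid likewise) before placing it; singleton
populations are skipped with a warning.  Accession-level validation
simply drops the focal sample.

## Trait models

`ls_means` fits the fixed-effects block model
$y_{ijk} = \mu + \mathrm{block}_i + \mathrm{accession}_j + \varepsilon$
and averages predictions over blocks with equal weight — the standard
adjustment for augmented designs.  Ordinal disease scores (e.g. 0–4
symptom scales) are treated as numeric, matching the field's practice;
no ordinal-regression alternative is offered.

`fit_admixture_lm` searches all $2^K - 2$ proper non-empty component
subsets (exhaustive is cheap at the K of admixture analyses; a
BIC-stepwise option exists), picks the best BIC — ties broken by fewer
terms, then lexicographic order — and prunes backward until every term
has $p \le \alpha$ (default 5%).  The full K-term model is never fitted:
the simplex constraint makes it exactly collinear.

## Genomic-selection baselines

Five standard methods sit behind one fit/predict contract
(`fit_genomic_model` / `predict_genomic`), all consuming the same
mean-imputed, column-centered design matrix:

| method | estimator | tuning |
|---|---|---|
| rrblup | ridge BLUP via eigen-REML of $WW'$ | REML (score-equation polish) |
| gblup  | kinship BLUP, VanRaden $WW'/c$ | REML (same objective) |
| bayesb | Gibbs, per-marker inclusion (π = 0.95), scaled-t prior | fixed priors, seeded chain |
| rkhs   | Gaussian kernel, median-squared-distance bandwidth | ridge penalty by GCV |
| lasso  | glmnet coordinate descent | 5-fold CV, 1-SE rule, seeded |

rrblup and gblup are one model in two parameterizations; the REML routine
normalizes the kernel scale so both walk the identical objective and
their predictions agree to machine precision (asserted in tests at
$10^{-6}$).  BayesB hyperparameters (prior exclusion probability, chain
length, the variance scale heuristic) are ours and configurable; numeric
concordance with other implementations is not claimed.

## Evaluation protocol

`stratified_folds` deals each population round-robin into k folds from a
random start, so fold sizes are proportional to population sizes (within
one).  `repeated_cv` records one Pearson correlation per fold; degenerate
folds are skipped and logged.  Admixture proportions are estimated once
on all samples — as in the original protocol — so a mild optimistic
leakage into test folds is inherent to the admixture predictor's
benchmark and is documented rather than hidden.  `compare_methods` runs
the tie-corrected Kruskal–Wallis omnibus test and Holm-adjusted pairwise
Mann–Whitney tests, assembling a compact letter display from the maximal
non-significant cliques.

## Environmental association

`component_env_correlations` Bonferroni-corrects over every tested
(component, variable) pair; the family is per call, and its size is
reported.  `rda_partition` implements redundancy analysis as multivariate
least squares on centered matrices; partial fractions residualize both
response and predictors on the conditioning block.  Raw (unadjusted)
fractions are reported by default so the identity
$a + b + c + \mathrm{residual} = 1$ holds exactly; ecosystem tools often
report adjusted $R^2$, which breaks the identity — the difference is a
documented trade-off.  Admixture rows are used as-is; compositional
log-ratio transforms are out of scope.

## The simulator: what a green test does and does not establish

`simulate_dataset` draws, from one integer seed:

* **Map** — K centroids uniform in the map box, rejected until separated
  by 5% of the diagonal; samples scatter around their centroid with
  standard deviation `pop_sd` (default `decay_rho`, so the geographic and
  genetic scales match).
* **Admixture** — $q \propto e^{-d/\rho}$ towards each centroid, then
  Dirichlet noise with concentration `dirichlet_conc`·q (default 100:
  visible but moderate individual variation).  As $\rho \to 0$ samples
  become purebred.
* **Genotypes** — Balding–Nichols: common frequency
  $p_j \sim U(0.05, 0.95)$, per-population
  $f_{kj} \sim \mathrm{Beta}\left(\tfrac{p(1-F)}{F}, \tfrac{(1-p)(1-F)}{F}\right)$,
  dosage binomial.  One differentiation parameter `fst_f` is shared by
  all populations, and loci are independent (the pipeline consumes
  LD-pruned SNPs; no linkage is simulated).
* **Traits** — exactly linear in q plus Gaussian noise.
* **Climate** — affine in (lat, lon) plus a smooth interaction and noise,
  with one pure-noise null-control column.

Default sizes in tests (K = 4, 50 samples/population, 2000 loci,
fst\_f = 0.2, decay ρ = 1°) give strongly differentiated, geographically
coherent populations — the regime the method is designed for, and the
regime in which its published validations operate.  A green test
establishes correctness of the algorithms under that stated world; it
does not establish robustness to weak structure, linked loci, clinal
(non-centroid) variation, or non-linear trait architectures, none of
which the generator emulates.

## Numerical choices

* All randomness flows through explicit seed arguments into a
  save/restore wrapper; no function perturbs the caller's RNG state.
  Derived child seeds stay below $2^{31}$.
* VIF pruning (`ld_prune`) computes VIFs as the diagonal of the inverse
  correlation matrix within each window, removes the worst variant until
  all fall below the threshold, and sweeps windows repeatedly until a
  full pass removes nothing — guaranteeing the post-condition (every
  window of the survivors has max VIF below threshold) rather than
  replicating any particular tool's recursion.  Exact duplicates have
  infinite VIF; the lowest-index copy survives.
* Mantel p values use the $(1 + \text{exceedances})/(n_{\mathrm{perm}}+1)$
  convention, one-sided for positive association.  On very small matrices
  a sampled permutation can be the identity, so the minimal attainable p
  is only reached for matrices large enough that automorphisms are rare.
* LS means are computed by explicit prediction over the block × accession
  grid, which is numerically identical to contrast-based LS means for
  connected designs; disconnected designs raise an error naming the
  components.
* Ties: UPGMA merge ties follow `hclust`'s deterministic lowest-index
  rule; BIC subset ties prefer smaller models; placement ties use a
  relative tolerance of $10^{-9}$ plus the same value as the absolute
  zero-distance threshold.

## Known limitations

* The unsupervised EM can need many iterations near the simplex boundary;
  for K scans use the iteration cap (the default tests do).
* Geolocation quality degrades gracefully but silently when the panel's
  populations overlap in admixture space; inspect the calibration's
  restricted Mantel r before trusting placements.
* The great-circle tangent-plane displacement is a small-displacement
  approximation; placements spanning tens of degrees of latitude should
  use `euclidean-degrees` only for screening.
* BayesB chains at the default length dominate the benchmark runtime;
  shorten them (`hyper = list(n_iter = ..., burn_in = ...)`) for
  exploratory comparisons.
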