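---
title: "Inferring and annotating protist co-occurrence networks from monthly time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and annotating protist co-occurrence networks from monthly time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtNet)
```

## The problem

Marine protist communities sampled monthly at ocean time-series stations
show strong seasonal cyclicity and slow interannual drift, yet measured
environmental variables typically explain only a small fraction of the
compositional variability. A large part of the remainder is thought to
come from biotic interactions — parasitism (notably by Syndiniales),
predation, photosymbioses and other associations. ProtNet implements a
complete chain for interrogating this hypothesis from an ASV (amplicon
sequence variant) count table with collection dates and depth labels:

1. **Temporal structure**: Bray-Curtis similarity as a function of the
   month lag between samples, Mantel tests of time-distance association,
   ANOSIM between depths, and regression of community similarity on
   environmental PC1 distance.
2. **Constrained ordination**: redundancy analysis (RDA) of
   CLR-transformed abundances on standardized environmental variables,
   with adjusted-R² forward selection under a Bonferroni-adjusted
   permutation stopping rule.
3. **Network inference**: prevalence filtering, centered log-ratio (CLR)
   normalization, seasonal GAM detrending, the nonparanormal transform,
   and graphical-lasso estimation of a sparse precision matrix with StARS
   stability selection; separate networks per depth merged to find
   associations present at both.
4. **Annotation**: taxonomy-aware matching of predicted edges against a
   curated interaction database with typed records (parasitism,
   predation, symbiosis, unresolved), and Spearman-correlation ranking of
   unmatched edges as candidate novel interactions.

Because curated interaction databases and real station data are external
resources, the package ships a first-class synthetic-data module that
generates communities with *known planted dependencies* and a toy
database covering them, so every stage — including recall accounting —
is testable end to end.

## The model behind the network stage

Let $x_{tj}$ be the CLR-transformed abundance of feature $j$ (ASV or
environmental variable) in sample $t$. After removing seasonal and
long-term signal and Gaussianizing the margins, the joint distribution is
modeled as multivariate normal with precision matrix $\Theta$. The
graphical lasso maximizes

$$\log\det\Theta \;-\; \mathrm{tr}(S\Theta)\;-\;\lambda \sum_{i\neq j}|\Theta_{ij}|,$$

with $S$ the empirical correlation matrix and the diagonal unpenalized.
Zero off-diagonal entries encode conditional independence, so a non-zero
$\Theta_{ij}$ — an edge — means features $i$ and $j$ co-vary *given all
other features*, which suppresses indirect associations that plague
correlation networks. Edge strength is reported as the partial
correlation $\rho_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$.

The solver is a compiled block coordinate-descent implementation
(Friedman-style lasso subproblems per row/column, warm-started along the
path). Its off-diagonal zeros are exact — edge support needs no
thresholding — and unit tests verify the Karush-Kuhn-Tucker conditions
and agreement with an independent proximal-gradient solver to $10^{-6}$
in the objective. At $\lambda = 0$ the unpenalized maximum-likelihood
estimate $S^{-1}$ is returned by Cholesky inversion.

### Choosing the penalty: StARS

The path is 30 log-spaced penalties from $\lambda_{\max} = \max_{i\ne
j}|S_{ij}|$ (empty graph) down to $0.1\,\lambda_{\max}$. StARS draws 50
subsamples without replacement (size $b = \lfloor 10\sqrt n\rfloor$ for
$n > 144$, else $0.8n$), solves the path on each, and computes for every
feature pair the selection frequency $\hat\theta$. The graph instability
at each penalty is the average of $2\hat\theta(1-\hat\theta)$; after
monotonizing it (non-decreasing toward small $\lambda$), the selected
penalty is the **smallest** $\lambda$ whose monotonized instability is
still at most $\beta = 0.05$ — the densest graph whose edge set is
reproducible across subsamples. If even the sparsest end of the path is
unstable, the empty $\lambda_{\max}$ graph is returned with a warning.
Subsampling is driven by one seed, so results are bit-reproducible.

### Pre-network conditioning and why the order is fixed

- **Prevalence filter (default 0.20)**: ASVs present (non-zero) in at
  least 20% of a depth's samples enter the network. The bound is
  inclusive, and each depth is filtered independently.
- **CLR**: read counts are compositional; CLR maps each sample to
  log-ratios against its geometric mean, whose rows sum to zero. Zero
  handling is explicit because the literature rarely states it: the
  default adds a pseudocount of 1 to count tables (half the smallest
  non-zero value for relative-abundance tables); multiplicative
  replacement is available.
- **GAM detrending**: each series is residualized against a cyclic cubic
  spline of annual phase (period 365.25 days, basis size 6) plus a
  thin-plate smooth of elapsed time (basis size 5), fitted by REML with
  shrinkage (`select = TRUE`) so featureless series pass through almost
  unchanged. Without this step, two ASVs that merely share a seasonal
  peak would be joined by an edge. A failed fit falls back to harmonic
  (sine/cosine + linear trend) regression with a warning.
- **Nonparanormal transform**: average-tie ranks through the Winsorized
  empirical CDF (truncation $\delta = 1/(4 n^{1/4}\sqrt{\pi\ln n})$),
  then the standard normal quantile, rescaled to unit variance. Only
  ranks enter, so the transform is exactly invariant under monotone
  marginal distortions.

Stage tags (`clr` → `detrended` → `npn`) are carried on the matrices and
checked, so the stages cannot be silently reordered; `force = TRUE`
overrides deliberately (e.g. re-detrending residuals to confirm nothing
is left).

## Temporal analyses

Month lags are day differences divided by the 30.4-day average month and
binned to the nearest integer (half-lags round up; zero-lag pairs are
excluded). The Mantel statistic is the Spearman correlation of the
vectorized upper triangles; ANOSIM is
$R = (\bar r_B - \bar r_W)/(M/2)$ on average-tie ranks. Both use the
add-one permutation estimator $p = (1 + \#\{r^* \ge r\})/(1 + n_{perm})$
— valid (never anti-conservative) at any permutation count — and both
offer exhaustive enumeration for small $n$, which the test suite checks
against brute-force oracles.

For RDA, forward selection adds the candidate maximizing partial
adjusted R², tests each addition by residual permutation of the reduced
model, Bonferroni-corrects by the number of candidates still in play,
and applies the double-stopping rule: selection ends when the adjusted p
is no longer below 0.05 *or* when the candidate model's adjusted R²
would exceed that of the global model with all candidates (the candidate
crossing the bound is rejected). A subtlety worth knowing: with a few
strong drivers and purely uninformative co-candidates, the global
model's adjusted R² sits marginally *below* the true submodel's
(expected shortfall $\approx (1-R^2)\,16/n^2$ for 8 spurious terms), so
the scope guard can block the last true driver. The guard is meaningful
when the candidate panel carries diffuse real structure — as
environmental panels do — and the package's recovery simulations are
built that way (two strong drivers, effect sizes 2 and 1.5, over a faint
0.08 background).

## The synthetic-data generator

`generateCommunity()` emulates the sampling design of a long monthly
time series: by default 177 calendar months with 31% dropped (≈122
retained samples, mirroring a 14-year-and-9-month series with missed
cruises), samples on the 1st of each month so the day arithmetic is
non-trivial. Per ASV, latent log-abundance is

$$\ell_{tj} = b_j + A\,\mathbb{1}[j \in \mathcal S]\sin(2\pi d_t/365.25 + \phi_j) + w_{tj} + \varepsilon_{tj},$$

with baseline $b_j\sim N(0,1)$, half the ASVs seasonal at amplitude 1, a
random-walk drift $w$ (step SD 0.02/month), and residuals
$\varepsilon_t$ drawn from $N(0, \Theta^{-1})$ where the constructed
precision $\Theta$ has non-zero off-diagonals exactly at the planted
edges (default 20 edges at partial correlation 0.6, diagonal inflated
until positive definite). Counts are multinomial draws of 50,000 reads
over the softmax of the latent values — inducing exactly the
compositional coupling CLR is meant to address. Lineages are synthesized
so every database-matching rule is exercisable: Syndiniales Group
I/II/III parasites, Clade F acantharians, polycystines, MAST-3
subclades, genus-resolved hosts, and a few unresolved placeholder stubs.
One master seed drives deterministic child seeds per sub-generator, so
artifact sets are bit-reproducible and individual draws (e.g. which
planted edges the toy database covers) can be replayed in isolation.

What the generator does **not** emulate: sequencing error and chimeras,
read-level data, overdispersion beyond multinomial sampling (the real
data's noise law is uncharacterized; the multinomial is a stand-in and
the library size is a knob), 18S copy-number variation beyond an
optional per-ASV multiplicative factor, and environmental forcing of
ASV abundances (drivers run the other way: designated env variables are
linear functions of ASV latents plus noise). Passing tests therefore
demonstrate that the chain recovers conditional-dependence structure
under realistic sampling, seasonality, drift and compositional noise —
not that any particular field data set satisfies the model.

## Database matching rules

Genus- and species-level identifications are often unavailable exactly
for the lineages most involved in known interactions, so matching is
taxonomy-aware, in precedence order:

1. **Syndiniales**: group (I/II/III...) + host genus — sub-genus
   Syndiniales taxonomy is unresolved, so genus keys are never derived
   for them.
2. **Radiolarian photosymbioses**: host class (Acantharea Clade F, or
   polycystines) + symbiont genus.
3. **MAST**: clade token (e.g. MAST-3E; a database record at MAST-3
   matches by prefix) + symbiont genus.
4. **Genus-genus** for everything else (case-insensitive, whitespace
   normalized, species/strain suffixes stripped; self-matches allowed —
   life-cycle stages of one species can appear as distinct ASVs).

Both edge orientations are tested; one database record may support many
ASV-level edges (multi-copy marker genes make this common), and an edge
matching several records reports the set of their types. The types
`symbiosis` and `unresolved` are folded into `other_symbioses` for
reporting. Edges with no usable key on one side are flagged
`rank-unresolvable` rather than silently called novel matches. Novel
edges are ranked by the Spearman correlation of their CLR series, with
|SCC| ≥ 0.64 flagged "strong" (inclusive bound).

## Numerical choices and degenerate inputs

- glasso convergence: mean absolute change of the working covariance
  below `tol` (default 1e-9 relative to the mean |off-diagonal| of S);
  exceeding `max_iter` is an error carrying the last gap. StARS
  subsample solves use a relaxed 1e-7 since only edge support matters.
- Ties in ranks: average rank everywhere (nonparanormal, Spearman,
  ANOSIM).
- Lag binning: round-half-up, so bins are symmetric around integer lags.
- PCA sign: PC1's largest-magnitude loading is made positive (distances
  are sign-invariant; this only stabilizes reported scores).
- Constant features: hard errors in `nonparanormal()` and
  `buildLambdaPath()` naming the feature; constant CLR series are
  excluded from SCC ranking with a flag.
- All-zero samples: CLR refuses them (geometric mean undefined);
  Bray-Curtis refuses a pair of all-zero samples.
- Imputation: iterative chained regression (random-forest regressor by
  default, linear or mean alternatives), mean-initialized, swept until
  stable; same model family as the random-forest imputation commonly
  used for time-series environmental panels, but deterministic under a
  seed.
- Relative-abundance inputs (rows summing to 1) are accepted; the CLR
  pseudocount then defaults to half the smallest non-zero value.

## Problem sizes used in the tests

The test suite exercises the full chain at desk scale, chosen once: edge
recovery uses 30 ASVs × 150 retained months with 20 planted edges over
10 seeds (mean F1 is required to be ≥ 0.5 and ≥ 3× a density-matched
random baseline); StARS contracts are checked at 30 features, 50
subsamples, 30 penalties; Mantel calibration uses 500 null replicates of
12 samples at 199 permutations; cyclicity uses the generator's default
(122-sample) configuration. `scripts/acceptance.R` reruns the whole
study — two depths, environment, toy database — at the same scale from a
single seed.

## Known limitations

- The Gaussian copula model sees only monotone pairwise structure;
  threshold or hump-shaped interactions are invisible by design.
- StARS instability is estimated over feature pairs jointly; with very
  few features the instability curve is coarse.
- GAM detrending assumes a single annual cycle plus a smooth trend;
  sub-annual periodicities (e.g. episodic blooms) remain in the
  residuals and can create edges.
- The double-stopping RDA guard inherits the knife-edge behavior
  discussed above when candidate panels are purely uninformative.
- Interaction direction is not modeled: the graphical model is
  undirected, so "parasite-of" vs "host-of" comes only from the
  database record, never from the network.
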