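---
title: "Multi-domain soil microbiome networks along an elevational gradient: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain soil microbiome networks along an elevational gradient: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`elevnet` analyses multi-domain soil amplicon surveys sampled along an
elevational gradient: OTU count tables for bacteria, archaea and
eukaryota, a taxonomy table assigning each OTU a domain and phylum, and
per-site metadata (geography, mean annual temperature and precipitation,
pH, electrical conductivity, total carbon, total nitrogen and their
ratio). Five stages are chained: α-diversity with diversity-environment
regressions, ordination (PCA, RDA) with variance partitioning,
co-occurrence network construction, domain-importance statistics, and a
synthetic-data generator that provides ground truth for all of them.
This vignette explains the models, the defaults, and what the package's
validation does and does not demonstrate.

# α-diversity

Counts are rarefied per domain to a fixed depth (defaults 30,671 /
17,561 / 42,299 reads for bacteria / archaea / eukaryota) by a single
seeded draw without replacement; a sample whose domain total falls short
of the depth is excluded with a warning rather than silently retained.
Estimators follow the mothur conventions:

* **Chao1**, bias-corrected: $S_{obs} + F_1(F_1-1) / (2(F_2+1))$, which
  stays defined when no doubletons are observed; the classic
  $F_1^2/(2F_2)$ form is available by flag.
* **ACE** with the standard rare-abundance cutoff of 10 reads; when the
  rare class consists entirely of singletons the coverage estimate is
  zero and the function falls back to Chao1 with a warning.
* **Shannon** in natural log; **Simpson** as the unbiased Gini-Simpson
  complement $1 - \sum n_i(n_i-1)/(N(N-1))$, with the dominance form
  exposed as a variant (field usage is split between the two, so both
  are available and the choice is explicit).
* **Good's coverage** $1 - F_1/N$.

Diversity-environment relationships are plain OLS fits of an index
against one covariate at a time (slope, intercept, $R^2$, two-sided $t$
test on the slope with $n-2$ df), producing the familiar
one-row-per-variable regression table. Regressions use the rarefied
index values, consistent with the workflow order rarefy → estimate →
regress.

# Ordination and variance partitioning

Communities are Hellinger-transformed by default (square root of
per-sample relative abundances), the standard pre-transformation that
makes count data behave in Euclidean ordination; `relative` and `none`
are provided for sensitivity analysis. PCA is the eigendecomposition of
the covariance of the transformed, column-centred matrix; axis $k$
explains $\lambda_k / \sum \lambda$, so fractions sum to 1 over all
axes. Axis signs are fixed by forcing the largest-magnitude species
loading positive.

RDA regresses the transformed community on the standardized explanatory
matrix and takes the PCA of the fitted values. Axis variances are
reported as fractions of the *total* community variance (so the
constrained fractions sum to the redundancy $R^2$, not to 1). Exactly
collinear predictors (condition number above $10^8$) are rejected with
the offending columns named rather than silently dropped.

Variance partitioning uses Ezekiel-adjusted $R^2$ from full and reduced
redundancy models. A group's unique fraction is
$R^2_{adj}(\text{all}) - R^2_{adj}(\text{all} \setminus \text{group})$,
the shared fraction is what the full model explains beyond the sum of
unique fractions, and the residual is $1 - R^2_{adj}(\text{all})$; the
three components sum to 1 by construction. Individual variables are
partialled out against all others the same way. Adjusted fractions can
be slightly negative; they are reported as-is in data output because
clamping would destroy the additivity that makes the partition checkable.

# Co-occurrence networks

OTUs at or below 0.05% pooled relative abundance *of their own domain's
pooled total* are discarded (strict inequality retains anything above
the threshold). Associations between the remaining OTUs are estimated
either by Spearman rank correlation (average ranks on ties; p by the
$t$ approximation, or by permutation with exhaustive enumeration
whenever $n! \le$ the requested permutation count) or by SparCC.

The SparCC implementation follows the original algorithm: per outer
iteration, fractions are drawn from a Dirichlet posterior
(counts + pseudocount 1), the log-ratio variance matrix
$T_{ij} = \mathrm{var}\,\log(x_i/x_j)$ is formed, basis variances solve
the linear system implied by the sparsity assumption, and the most
strongly correlated pairs (|r| above 0.1, up to 10 pairs) are
iteratively excluded from that system. The reported correlation is the
per-entry median over 20 Dirichlet iterations; p-values come from a
permutation bootstrap that shuffles each OTU's counts independently
(100 datasets by default, so the smallest attainable p is just under
0.01). SparCC requires at least 10 OTUs — the basis-variance
approximation degrades on small compositions, for which the function
directs the user to Spearman.

Edges require $|r| > 0.6$ **and** $p < 0.01$, both strict; the network
keeps every OTU that entered the correlation analysis, isolates
included, since link-frequency denominators are defined over analysed
OTUs. The threshold "r above ±0.6" is read as $|r| > 0.6$ — the only
reading under which negative links can exist. No multiple-testing
correction is applied by default (matching the common raw-p practice
this pipeline emulates); Benjamini-Hochberg-adjusted workflows can be
built from the returned p matrix. Topology is reported per scope:
per-domain metrics on the induced single-domain subgraphs (intradomain
edges only) and a total row for the whole graph, with density
$2E/(N(N-1))$, mean unnormalized betweenness and the global clustering
coefficient.

# Domain importance

**Correlation frequency** between domains A and B is
$100 \times \text{real links} / \text{possible links}$ with
$n_A n_B$ possible interdomain pairs (or $n(n-1)/2$ within a domain).
The ablation table removes one domain at a time *by node subsetting of
the single full network* — no correlation re-estimation — which is the
only convention under which all absence/presence scenarios derive from
one network; a re-estimation analysis can be assembled from
`filter_rare_otus()` + `build_network()` per scenario if wanted.

**Natural connectivity** is
$\bar\lambda = \ln\!\big(\tfrac1N \sum_i e^{\lambda_i}\big)$ over the
adjacency eigenvalues, computed by symmetric eigendecomposition with an
overflow-safe log-sum-exp (stable for graphs of thousands of nodes,
where $e^{\lambda_1}$ overflows doubles). Robustness curves remove a
fraction of nodes — uniformly at random, averaged over seeded
repetitions, or deterministically by descending degree — and recompute
natural connectivity on the induced remaining subgraph with the
*remaining* node count in the denominator and isolates kept. The
domain-ablation experiment compares the full network with each
two-domain subnetwork on a shared fraction grid and reports
per-fraction Wilcoxon rank-sum comparisons across repetitions. The
default grid is five fractions (0 to 0.8 in steps of 0.2) with 100
repetitions, enough to order the scenarios decisively while keeping a
full run to a few minutes of eigendecompositions.

# The synthetic generator

The generator emulates, at the OTU-table level, a 14-site alpine-meadow
survey spanning 1,936–3,896 m with narrowly alkaline soils
(pH 8.24–8.95): per-site climate follows configurable lapse/slope lines
(plus small micro-climate deviations so that climate covariates are not
exact linear functions of elevation, which would make joint RDA
ill-posed), and TC is derived from TN and a site-level TC/TN ratio so
the stored ratio is exact.

Each domain has a regional OTU pool with log-normal baseline abundances.
Realized per-site richness follows
`intercept + slope × elevation(km) + noise`, with defaults that encode
the emulated survey's scales and trends: bacteria 700 + 560/km
(richness in the low thousands, rising), archaea 420 + 0/km with large
scatter (flat), eukaryota −20 + 60/km (small, rising). The realized OTU
set per site is the planted members plus the highest-latent-abundance
remaining OTUs, and counts are one multinomial draw at the domain's
depth, so per-sample per-domain totals close exactly.

Association structure is planted on the latent log scale, matching the
"basis correlation" notion SparCC estimates, through three components:

* **Planted blocks**: members share one latent factor with loading
  $\pm\sqrt{\rho/(1-\rho)}$ against unit idiosyncratic noise, so every
  within-block pair has latent correlation exactly $\rho$ with sign
  equal to the product of member signs. The default structure plants a
  large, tight archaeal clique (40 members, $\rho = 0.9$), smaller
  bacterial and eukaryotic blocks ($\rho = 0.85$, a minority of
  negative members), and cross-domain blocks bridging archaea to both
  other domains — making archaea the structural hub, positive edges
  dominant and intradomain edges more numerous than interdomain ones.
  Planted members are placed near the 90th percentile of their domain's
  abundance distribution so their associations survive count noise; a
  fixed large offset instead would let a few OTUs dominate small
  compositions and generate closure artifacts.
* **A shared elevation response**: per-OTU loadings
  $\sim N(0.15, 0.25)$ on standardized elevation give the communities a
  weak, mostly concordant gradient signal. It is deliberately weak:
  in the kind of survey emulated here, measured environment explains
  only a few percent of community variance.
* **Domain-private guild factors**: per-OTU loadings
  $\sim N(0.55\text{–}0.6, 0.3\text{–}0.45)$ on one of $k$ iid factors
  per domain (bacteria $k=10$, archaea $k=1$, eukaryota $k=4$) model
  coherent within-domain co-variation not shared across domains. This
  is what gives real multi-domain networks their intradomain excess;
  splitting the bacterial background across many guilds spreads its
  spectral mass so no accidental bacterial core rivals the archaeal hub.

With 14 samples and a raw $p < 0.01$ edge rule, roughly 1% of all
analysed pairs pass by chance; recovered networks are therefore a mix
of planted and threshold-noise edges — exactly the regime real
14-site surveys operate in. The qualitative patterns the defaults
encode (bacterial and eukaryotic diversity rising with elevation while
archaeal diversity stays flat; positive-link dominance; intradomain
excess; the archaea-ablated network being least robust) were designed
into the generative structure and verified to be stable across seeds
before the test values were frozen.

The ground truth records true richness per site and domain, the planted
edge list with signs (the positive-edge fraction equals the complement
of `fraction_negative` exactly, because the fraction is computed from
the realized edge list rather than prescribed), and the generative
parameters.

## What passing tests do and do not show

The generator validates estimator correctness, threshold contracts,
parameter recovery (a planted basis correlation of 0.8 among 50 OTUs is
recovered by SparCC within ±0.15 at 100 samples, with planted-edge
precision ≥ 0.8) and the qualitative gradient patterns under known
conditions. It does **not** model sequence-level artifacts (chimeras,
clustering errors), spatial autocorrelation between sites, phylogenetic
signal in abundances, or domain-specific compositional biases of
primer choice — conclusions about real data still require the usual
caution on those fronts.

# Numerical choices and degenerate inputs

* Every stochastic operation takes a seed and restores the caller's RNG
  state; the pipeline fans a single global seed out per stage by stable
  hashing, so stages never share streams.
* Constant OTU rows have undefined rank correlations; their pairs are
  set to r = 0, p = 1 with a message.
* Negative SparCC basis variances (possible under the approximation)
  are clamped to a tiny positive value before the correlation is
  formed; correlations are clipped to [−1, 1].
* An all-zero count vector is an error for every diversity estimator;
  rarefaction beyond the available reads is an error at the vector
  level and a logged exclusion at the table level.
* Scopes with fewer than two nodes report density 0; transitivity of a
  triangle-free scope is NA.
* Exhaustive permutation p-values use the full permutation distribution
  (no +1 correction); sampled ones use $(k+1)/(B+1)$.
* Floats are written with 6 significant digits, except the metadata
  TC/TN column (9 digits, recomputed from the rounded TC and TN) so the
  reader's 1e-6 consistency check is meaningful after a round trip.

# Problem sizes used in validation

The shipped validation exercises the generator at its default scale
(≈ 4,500 realized OTUs × 14 samples; ≈ 900 network nodes after rare-OTU
filtering), the parameter-recovery fixture at 50 OTUs × 100 samples,
and robustness at 100 random-removal repetitions over a 5-point
fraction grid — sizes chosen so the full suite completes in a few
minutes while keeping every statistical check well-powered.

# Known limitations

* The archaea-hub default is one plausible configuration of domain
  importance, not an empirical claim; users studying other regimes
  should supply their own `planted_structure()`.
* SparCC p-values are bootstrap-based and lower-bounded by
  1/(n_bootstrap+1); at the default 100 bootstraps an edge can only
  pass p < 0.01 if no null replicate matches it.
* VPA reports a self-consistent adjusted-R² partition (unique + shared
  + residual = 1). Published VPA figures do not always follow a
  coherent convention; this package's output is additive by design and
  will not reproduce reports that are not.
* The per-domain columns of the topology table describe induced
  single-domain subgraphs; interdomain edges are visible only in the
  total row. Published per-domain topology tables are not always
  explicit about this convention.
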