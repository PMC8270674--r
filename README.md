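# elevnet

Analysis of multi-domain (bacteria, archaea, eukaryota) soil amplicon
surveys along elevational gradients: how within-sample diversity tracks
elevation and soil chemistry, how community composition is structured by
climatic and edaphic drivers, how the three domains wire together into a
co-occurrence network, and which domain matters most for holding that
network together.

It is written for microbial ecologists working with OTU count tables
(OTUs × samples), a taxonomy table assigning each OTU a domain and
lineage, and per-site metadata (latitude, longitude, elevation, MAT,
MAP, pH, EC, TC, TN, TC/TN).

## What it computes

**α-diversity.** Seeded rarefaction to per-domain depths, then Chao1
(bias-corrected: S_obs + F₁(F₁−1)/(2(F₂+1))), ACE (rare cutoff 10),
Shannon (nats), unbiased Gini–Simpson 1 − Σnᵢ(nᵢ−1)/(N(N−1)) and Good's
coverage 1 − F₁/N, plus OLS regressions of an index against each
environmental variable (slope, R², two-sided t test).

**Ordination.** PCA of Hellinger-transformed communities; RDA (PCA of
the fitted values from regressing the community on standardized
environmental variables, axes reported as fractions of total variance);
variance partitioning by adjusted R², where unique + shared + residual
fractions sum to 1 by construction.

**Co-occurrence networks.** Rare-OTU filtering (discard at ≤ 0.05% of
the OTU's own domain total), Spearman (t-approximation or permutation
p) or SparCC correlation — the compositional "basis correlation"
estimator with Dirichlet resampling, iterative pair exclusion and
permutation-bootstrap p-values — then thresholding at |r| > 0.6 and
p < 0.01 into a signed, domain-labelled undirected graph (isolates
kept), with per-domain and whole-graph topology (density, degree,
betweenness, transitivity, positive/negative link shares).

**Domain importance.** Correlation frequency (100 × real links /
possible links) within and between domains under domain ablation, and
network robustness as natural connectivity λ̄ = ln(Σᵢ e^{λᵢ} / N) over
adjacency eigenvalues, recomputed while removing growing fractions of
nodes — for the full network and for each two-domain subnetwork.

**Synthetic data.** A generator producing multi-domain OTU tables with
known ground truth: log-normal abundances, elevational richness trends
per domain, planted correlation blocks on the latent log scale, a
shared gradient response and domain-private guild factors. Every
analysis stage is validated against it.

## Worked example

```r
library(elevnet)

md  <- generate_metadata(gradient_config())     # 14 sites, 1,936-3,896 m
sim <- generate_otu_tables(md, default_domain_configs(),
                           default_planted_structure(), seed = 1)
sim$table
#> otu_table: 4641 OTUs x 14 samples (bacteria 3256, archaea 985, eukaryota 400)

div <- diversity_table(sim$table,
                       c(bacteria = 30671, archaea = 17561, eukaryota = 42299),
                       seed = 1)
reg <- regression_table(div, md)
subset(reg, variable == "elevation")
#>       domain  variable    slope intercept r_squared   p_value  n
#>     bacteria elevation  0.41111    917.09    0.8561 2.140e-06 14
#>      archaea elevation -0.12329    770.86    0.2806 5.139e-02 14
#>    eukaryota elevation  0.03636     56.84    0.4117 1.338e-02 14
```

Bacterial and eukaryotic Chao1 richness rise significantly with
elevation (p = 2.1e-06 and 0.013) while the archaeal trend is not
significant (p = 0.051) — the per-domain diversity pattern the default
study conditions encode.

```r
filt <- filter_rare_otus(sim$table)             # > 0.05% of own domain
net  <- build_network(spearman_matrix(filt), filt$domain,
                      pooled_rel_abundance(filt))
net
#> coocc_network (spearman, |r| > 0.6, p < 0.01): 953 nodes, 6816 edges

network_topology(net)[, c("scope", "n_nodes", "n_edges", "density",
                          "transitivity", "pct_positive")]
#>       scope n_nodes n_edges density transitivity pct_positive
#>    bacteria     391    1592  0.0209        0.317         66.5
#>     archaea     318    1409  0.0280        0.620         76.5
#>   eukaryota     244     492  0.0166        0.337         77.2
#>       total     953    6816  0.0150        0.331         64.3

rob <- ablation_robustness(net, n_reps = 30, seed = 1)
sapply(rob$curves, function(cu) round(cu$summary$mean, 2))
#> fractions 0, 0.2, ..., 0.8 per row:
#> all-three        26.69 19.79 13.04 7.07 2.27
#> bacteria-absent  26.53 19.60 13.22 7.05 2.12
#> archaea-absent    9.20  6.81  4.52 2.74 1.19
#> eukaryota-absent 24.47 18.91 13.19 7.30 2.03
```

Positive links dominate in every scope, intradomain links outnumber
interdomain ones, and deleting the archaea — the planted hub domain —
collapses natural connectivity far more than deleting either other
domain at every removal fraction.

The whole chain (simulate → diversity → ordination → network →
importance, all results as TSV plus a log and a reproducibility
manifest) runs as one call:

```r
run_pipeline(default_run_config(seed = 1), "results/run1")
```

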