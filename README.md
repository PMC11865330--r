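# acidonet

Network-ecology tools for identifying slow-growing keystone taxa in soil
microbial communities along pH gradients — built around the question of
how an acid-favoured complete ammonia oxidizer (comammox *Nitrospira*)
can anchor cooperation in weakly acidic soils.

The package is aimed at microbial ecologists working with taxon-by-sample
abundance tables (16S ASVs or MAG coverages), guild-level *amoA* qPCR
tables, genome feature annotations and DNA-SIP density fractions. It
implements, as composable R functions:

- **Co-occurrence networks** — prevalence filtering, Pearson correlation
  of log-transformed abundances, and a random-matrix-theory (RMT)
  threshold: the smallest cutoff *t* at which the thresholded matrix's
  nearest-neighbour eigenvalue spacings follow the Poisson law
  *P(s) = e^(−s)* rather than the Wigner–Dyson law of noise-dominated
  spectra.
- **Node roles** — within-module degree *Zi* and among-module
  connectivity *Pi = 1 − Σ_t (k_it/k_i)²*; nodes with *Zi ≥ 2.5* or
  *Pi ≥ 0.62* are key nodes (module hubs / connectors / network hubs).
- **Cohesion** — null-model-corrected pairwise correlations ("taxa
  shuffle": each partner's abundances permuted across samples), averaged
  into per-taxon positive/negative connectedness, then summed per sample
  weighted by relative abundance. Positive cohesion proxies potential
  cooperation, negative cohesion potential competition.
- **Extinction cascades** — the abundance-weighted mean interaction
  strength of node *i* over surviving neighbours *j*,
  *wMIS_i = Σ_j b_j s_ij / Σ_j b_j*, iterated synchronously: any node
  with *wMIS ≤ 0* or no surviving neighbour is removed until a fixed
  point; targeted (keystone) removal is compared with random removal.
- **Community screening** — rarefaction, three-criterion core-genus
  screening, marker-correlated taxon screening, dominant-oxidizer
  classification, and the community mean rrn copy number
  (MCN_s = Σ_i p_is·rrn_i / Σ_i p_is), a growth-strategy index.
- **Cobalamin supply/demand** — genomes classified as
  cobalamin-dependent (mutA/metH/rsmB) vs cobalamin-synthesizing
  (complete pathway steps A∧B∧C), with per-sample supplier shares.
- **Environmental statistics** — correlations with Fisher-z intervals,
  variance partitioning (unique/shared adjusted-R² fractions), the
  Emerson free-ammonia equilibrium NH₃ = TAN/(1 + 10^(pKa−pH)), and
  potential nitrification rates from NOx time series.
- **DNA-SIP** — density-fraction normalisation, weighted-mean-density
  label-shift detection, and heavy-window guild composition.
- **A synthetic-data generator** — pH-gradient communities with a
  planted keystone, cooperation block, acid-favoured guild, rrn
  copy-number structure, cobalamin suppliers and SIP peaks, so the whole
  pipeline is testable with known ground truth and no sequencing data.

## Worked example

Simulate a 36-sample pH 4.4–9.7 survey with the default planted design
and run the core analyses:

```r
library(acidonet)

spec <- community_spec(seed = 42)
sim  <- simulate_study(spec)
rel  <- to_relative(sim$table$counts)
k    <- sim$truth$keystone_id

# keystone abundance declines with pH
correlate(rel[k, ], sim$meta$ph)
#> r = -0.615, p = 6.5e-05, 95% CI [-0.785, -0.359]

# co-occurrence network at |r| >= 0.6 on prevalence-filtered taxa
net <- build_network(correlation_matrix(prevalence_filter(rel, 0.5)), 0.6)
net
#> signed_network: 31 nodes, 79 edges (92% positive), |r| >= 0.60;
#> 69 isolated dropped

mod   <- detect_modules(net)
roles <- compute_zipi(net, mod$membership)
table(roles$role)
#>  connector peripheral
#>          9         22

# positive cohesion tracks the keystone's abundance
coh <- cohesion_analysis(rel, seed = 42)
cor(coh$cohesion$pos, rel[k, ])
#> [1] 0.774

# removing the keystone cascades through its dependents
casc <- simulate_removal_cascade(net, rowMeans(rel), k)
casc$surviving_frac      #> 0.71  (8 secondary extinctions)

# slow growers dominate at low pH: community mean rrn copy number
rrn <- assign_rrn(sim$table$taxonomy, sim$truth$rrn_lookup)
cor(compute_mcn(rel, rrn), sim$meta$ph)
#> [1] 0.479

# the labelled comammox guild shifts to heavier buoyant density
detect_label_shift(sip_profile(sim$sip, "13C", "comammox"),
                   sip_profile(sim$sip, "12C", "comammox"))
#> shift = 0.0092 g/mL, is_labeled = TRUE
```

The keystone–pH correlation is negative (the planted target is −0.6),
MCN rises with pH (acid-favoured taxa carry few rrn operons, so acidic
communities are dominated by slow growers), positive cohesion follows
the keystone-anchored cooperation block, targeted keystone removal
extinguishes its dependents, and the ¹³C-labelled guild's density shift
clears the 0.005 g/mL detection cutoff.

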