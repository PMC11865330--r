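---
title: "Methods: keystone detection in pH-structured microbial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keystone detection in pH-structured microbial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidonet)
```

# Scope

`acidonet` packages the statistical machinery used to argue that an
acid-favoured, slow-growing nitrifier can be a keystone of soil
bacterial communities: co-occurrence networks with spectral threshold
selection, node-role classification, null-corrected cohesion, wMIS
extinction cascades, growth-strategy (rrn) indices, cobalamin
supply/demand screening, and DNA-SIP fraction analysis. Every stage can
be exercised on synthetic communities with planted ground truth, which
is how the test suite validates the estimators.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices made where the methods literature is
silent, and what the synthetic validation does and does not establish
about real data.

# Co-occurrence networks

Abundance tables are prevalence-filtered (taxa present in at least half
the samples, `min_frac = 0.5`) because correlation estimates degrade
badly for zero-dominated taxa. Pearson correlations are computed on
log-transformed abundances; zeros are first replaced by half the
smallest nonzero value in the table. This pseudo-abundance is
scale-stable: multiplying a taxon by a constant leaves its log-scale
correlations unchanged, so counts and relative abundances give the same
network.

## RMT threshold selection

`select_rmt_threshold()` scans cutoffs `t` (default 0.30–0.99 in steps
of 0.01). For each `t` the matrix is hard-thresholded (`|r| < t` set to
0) and its eigenvalue spectrum examined. Random-matrix theory predicts
that noise-dominated symmetric matrices show Wigner–Dyson
nearest-neighbour spacing statistics (level repulsion,
`P(s) = (pi/2) s exp(-pi s^2/4)`), while matrices whose remaining
structure is modular — effectively independent blocks — show Poisson
spacings (`P(s) = exp(-s)`). The selected threshold is the smallest `t`
whose spacing distribution is consistent with Poisson.

Numerical choices, all of which the methods literature leaves open:

- **Degenerate eigenvalues** (within `1e-8`) are collapsed before
  unfolding; heavily thresholded matrices otherwise contribute long runs
  of identical eigenvalues that are not genuine spacings.
- **Unfolding** uses a smoothing spline fit to the cumulative eigenvalue
  staircase with `df = min(10, n/4)`; spacings are differences of the
  fitted cumulative counts, normalised to unit mean.
- **Goodness of fit** is a chi-square test on 12 spacing bins over
  `[0, 3]` plus an open tail bin; Poisson consistency means `p > 0.05`.
  At least 30 spacings are required for a cutoff to be testable.
- Matrices smaller than 30 x 30 have too short a spectrum for spacing
  statistics; the function warns and returns a configurable fallback
  (default 0.70).
- Thresholding uses `|r|`; whether the original pipeline thresholds
  signed or absolute correlations before the eigen-spectrum step is not
  recoverable, and `|r|` matches how edges are subsequently kept.

The test suite validates the selector in both regimes: a pure-noise
correlation matrix at a near-zero cutoff is closer to Wigner–Dyson than
Poisson, and on (jittered) block-diagonal matrices the selected
threshold leaves no between-block edges. On *sampled* block data,
finite-sample noise correlations have unbounded tails, so the honest
guarantee — and what is tested — is that the threshold clears the bulk
(95th percentile) of the between-block correlations, not their maximum.

## Modules, Zi–Pi and roles

Modules are found by greedy modularity maximisation on the
`|r|`-weighted graph (deterministic, via igraph). Node roles follow the
Guimerà–Amaral formulation with **unweighted** degrees: `Zi` is the
z-score of the within-module degree relative to the node's module
(defined as 0 when the module's spread is zero), and
`Pi = 1 - sum_t (k_it/k_i)^2`. The role rule is applied verbatim:
`Zi >= 2.5` marks a module hub, `Pi >= 0.62` a connector, both a network
hub; any of these is a "key node". A weighted variant is available
behind `weighted = TRUE`.

# Cohesion

For each ordered taxon pair the observed Pearson correlation is
corrected by the mean correlation against `n_iter = 200` "taxa shuffle"
permutations of the partner (each taxon's abundances permuted across
samples); the two directions are averaged into a symmetric matrix.
A taxon's positive (negative) connectedness is the mean of its strictly
positive (negative) corrected correlations, and per-sample cohesion is
the abundance-weighted sum: `C_pos(s) = sum_j a_js conn_pos(j)`, with
total cohesion `C_pos + |C_neg|`.

Two properties drove the numerical design:

- The mean of a Pearson correlation over all permutations of one vector
  is exactly `-1/(n-1)`, not zero. The corrected value of an unrelated
  pair is therefore centred at zero *in the taxa-shuffled reference
  frame*, which is the frame the null-calibration tests use.
- Linear-scale correlations of heavy-tailed count data are skewed under
  permutation (shared extreme samples produce large positive
  coincidences with no negative counterpart), which leaves a small
  positive offset in net cohesion even on shuffled data. Correlations
  are therefore computed on **log-transformed abundances** by default —
  the same scale the network uses — which removes the skew;
  `log_transform = FALSE` restores plain linear-scale Pearson.

`n_iter` defaults to 200 and the per-pair Monte-Carlo standard error is
returned as an attribute so users can raise it. Cohesion is computed
from the full table passed in, not only network nodes; whether to
prevalence-filter first is left to the caller (both variants are one
line).

# wMIS extinction cascades

The abundance-weighted mean interaction strength of node `i` is
`wMIS_i = sum_j b_j s_ij / sum_j b_j` over *surviving* neighbours `j`,
with `s_ij` the signed edge correlation and `b_j` the neighbour's
relative abundance (fixed at its across-sample mean; which abundance
vector weighted the original cascades is unstated, and the mean is the
least arbitrary choice). After removing the target set, extinction is
iterated **synchronously to a fixed point**: every survivor with
`wMIS <= 0`, or with no surviving neighbour ("extinct or isolated"), is
removed in the same sweep. Whether extinction should be evaluated once
or iterated is an open choice; iterated synchronous updates are the
standard cascade semantics, are order-independent (tested by node
permutation), terminate in at most `n` sweeps, and a `single_pass` flag
provides the one-sweep variant. Cascades are validated against an
independent brute-force fixed-point implementation on hundreds of random
signed graphs with up to 6 nodes.

For keystone-vs-random comparisons the network is built at the fixed
conventional cutoff `|r| >= 0.60` rather than the per-dataset RMT
threshold. The RMT selector is validated separately on planted block
matrices; pinning the cascade analysis to one cutoff keeps the
robustness comparison from conflating keystone structure with
seed-to-seed variability in spectral threshold selection. At n = 36
samples the critical correlation for two-sided p = 0.001 is about 0.52,
so 0.60 comfortably excludes noise edges.

# Screening and growth strategy

- **Rarefaction** subsamples each sample without replacement to a common
  depth (via `vegan::rrarefy`) under a fixed seed; retained columns sum
  exactly to the depth and short samples are dropped with a warning.
- **Core genera** must pass three predicates: occurrence in strictly
  more than 80% of samples; mean relative abundance above 0.1% (the
  default "overall abundant" rule — a top-quantile alternative is
  provided because the two published phrasings differ, and the flag
  table records which predicates each genus passed); and an abundance
  rank within the top 80% of genera in strictly more than half the
  samples. The literal reading of "relative abundance above 80% in more
  than 50% of samples" is impossible (abundances sum to 1), so the rank
  reading is used. Zero-abundance ties take the worst rank.
- **Marker screening** selects, within a user-supplied lineage subset,
  taxa whose relative abundance correlates with a per-sample marker
  (e.g. guild qPCR copies) at `r >= 0.5` and `p <= 0.05`, returning the
  summed abundance of the selected group for downstream correlation with
  pH. Lineage membership is an input: taxonomy and phylogenetics are out
  of scope.
- **Dominance** labels each sample by the guild with most copies; ties
  break alphabetically and are flagged, all-zero samples are
  unclassifiable.
- **rrn / MCN**: copy numbers are assigned at the best available rank
  (species, then genus, then family); unmatched taxa are flagged and
  excluded. `MCN_s = sum_i p_is rrn_i / sum_i p_is` over matched taxa;
  the renormalisation by matched mass is the default so unmatched taxa
  do not bias the mean downward (the raw weighted sum is available with
  `renormalize = FALSE`). MCN is invariant to rescaling, always lies
  within the range of the matched copy numbers, and under the planted
  design rises with pH because acid-favoured taxa carry 1–2 operons and
  the flat background 4–6.

# Cobalamin supply and demand

A genome is cobalamin-dependent (CD) if it encodes any of mutA, metH or
rsmB, and cobalamin-synthesizing (CS) if all three pathway steps are
complete; partial step sets are reported. Step-level completeness is a
boolean input — mapping annotation output to steps is deliberately left
to the user's annotation pipeline. Per-sample summaries give CD and CS
abundance and the share of CS abundance attributable to each genome
label (e.g. the comammox share of total supply), with zero-CS samples
flagged rather than silently dropped. The same operation applies
unchanged to contig-level feature tables.

# Environmental statistics

- `correlate()` wraps the exact Pearson t-test with a Fisher-z interval.
- `variance_partition()` fits every non-empty predictor subset (up to
  three predictors), records adjusted R² (raw R² behind a flag), and
  decomposes the full model by inclusion–exclusion into unique fractions
  per predictor, shared fractions per subset and a residual. Fractions
  reconstruct the full adjusted R² exactly and may be slightly negative,
  as is conventional. The "individual" outputs reported by variance
  partitioning figures are the unique (conditional) fractions.
  Agreement with `vegan::varpart` is part of the test suite.
- `free_ammonia()` uses the Emerson temperature-dependent dissociation
  constant `pKa(T) = 0.09018 + 2729.92 / T_K`, so
  `NH3 = TAN / (1 + 10^(pKa - pH))`; mass balance `NH3 + NH4 = TAN`
  holds by construction. Inputs are molar; unit conversion from soil
  extraction protocols is the caller's responsibility.
- `nitrification_rate()` is the OLS slope of summed nitrite + nitrate
  against time, with fit R².

# DNA-SIP

Profiles are ordered density fractions (16 by default, 1.69–1.76 g/mL).
Normalisation gives per-fraction shares and the total (used to check
that labelled and control incubations carry comparable copies). The
labelling statistic is the weighted mean buoyant density
`WMD = sum_f share_f density_f`; a profile counts as labelled when
`WMD(labelled) - WMD(control) >= 0.005 g/mL`. The 0.005 default is half
the planted shift used throughout validation and roughly one fraction
spacing. Mismatched density grids are linearly interpolated (fractions
are nearly evenly spaced in density); extrapolation is refused. "Heavy"
fractions are defined by a density window (default 1.72–1.75 g/mL,
configurable) since heavy-fraction identification is otherwise a visual
call; guild composition is the per-guild copy sum over the window,
normalised across guilds.

# The synthetic-data generator

`community_spec()` fixes the study conditions: 36 samples spanning pH
4.4–9.7 evenly (groups A: pH < 6.5, B: 6.5–7.5, C: > 7.5), 100 taxa,
multinomial counts at 20 000 reads per sample, and 16-fraction SIP
profiles — the scale of the emulated survey design. Latent
log-abundances are built from standardised loadings on a centred pH
axis, a shared acid-guild factor, a keystone-anchored cooperation
factor, and idiosyncratic noise (`noise_sd = 0.5` log units), so
pairwise latent correlations equal loading cross-products by
construction:

- The **keystone** loads on pH with (inflated) loading such that the
  realised Pearson correlation between its relative abundance and pH
  lands near the target `keystone_ph_slope = -0.6`; multinomial
  resampling and compositional closure attenuate latent correlations by
  roughly 20% at the default depth, and the 1.2x compensation is
  calibrated to that. It also loads (0.55) on the acid-guild cooperation
  factor: the keystone takes part in the cooperative co-variation that
  positive cohesion measures.
- The **cooperation block** (10 taxa) anchors on the keystone's latent
  abundance at `coop_r = 0.75`, with residuals centred within the block
  (cooperators competing for the shared benefit), so block members are
  strongly tied to the keystone but only weakly to each other — which is
  what makes them *dependents*: when the keystone node is removed they
  lose their main anchor and cascade out.
- The **acid guild** (20 taxa) loads negatively on pH (0.5) and on its
  shared factor (0.65). There is deliberately **no alkaline guild** by
  default (`alk_block_size = 0`): the planted cooperative structure is
  one-sided, which is exactly the asymmetry the cohesion and cascade
  estimators are meant to recover, and high-pH samples are instead
  dominated by the unstructured background taxa. An alkaline guild can
  be switched on for more symmetric scenarios.
- **rrn copy numbers** are assigned per genus: 1 for the keystone genus
  (as for *Nitrospira*), 1–2 for acid-favoured genera, 4–6 for the flat
  background — the planted slow-grower/fast-grower gradient.
- **Genome features** plant 85% CD prevalence and 3% full-pathway CS
  prevalence, with the keystone genome always a complete synthesizer and
  one guaranteed second supplier so supplier shares are defined; the
  keystone genome's abundance profile is tied to the keystone taxon.
- **SIP profiles** are Gaussian peaks (sd 0.010 g/mL) over 16 fractions;
  labelled treatments of active guilds (comammox, AOA) shift the peak
  centre by `planted_shift = 0.01 g/mL`; counts get Poisson noise.

Every artifact draws from its own labelled sub-seed of the master seed,
so adding an output never perturbs the others, and identical spec +
seed gives byte-identical outputs. In the `noise_sd = 0` limit all
stochastic latent components vanish and planted gradients are exactly
monotone in pH.

**What passing tests do and do not show.** The generator produces
Gaussian-copula latents with multinomial sampling. It emulates
compositionality, sequencing-depth noise, planted keystone/cooperation
structure and guild-level environmental filtering. It does not emulate
phylogenetic correlation structure, zero inflation beyond multinomial
sampling, PCR/chimera artefacts, spatial autocorrelation among samples,
or real taxonomies. Parameter-recovery results therefore demonstrate
that the estimators recover the structures they target at realistic
signal-to-noise, not that real soils contain those structures.

# Validation design

The test suite follows three patterns: exact oracle equivalence
(cascades, Zi–Pi, topology, core screening, connectedness, variance
partitioning and weighted mean density are checked against independent
brute-force implementations to 1e-9); null calibration (net cohesion of
taxa-shuffled structureless communities centred at zero; type-I error of
the correlation test at nominal level); and parameter recovery over 50
simulation seeds (keystone–pH sign, MCN–pH sign, cohesion–keystone
coupling above 0.5, targeted-vs-random cascade contrast, supplier-share
decline, SIP label detection). Problem sizes (100 taxa, 36–40 samples,
200 null iterations, 50 seeds) were chosen so the full suite represents
the emulated study scale while remaining quick to run.

# Known limitations

- The RMT selector needs a reasonably rich spectrum; matrices under
  30 x 30 fall back to a fixed threshold, and heavily degenerate spectra
  return a "no transition" flag rather than a cutoff.
- Cohesion's null correction removes average association, not
  compositional closure; on raw (unshuffled) independent compositions a
  small residual offset of order 1/n_samples remains.
- Cascade results depend on the abundance vector used for weighting;
  group-specific weighting (e.g. per-pH-group means) must be supplied
  explicitly by the caller.
- The cobalamin classifier trusts its input booleans; annotation
  completeness thresholds upstream will dominate the CD/CS rates.
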