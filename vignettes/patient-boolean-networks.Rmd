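---
title: "Patient-specific Boolean networks: models, personalization and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific Boolean networks: models, personalization and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatientBoolNet)
```

## The model

A Boolean network assigns each node (gene/protein) a binary activity and a
logic rule over its regulators, written in the community "targets, factors"
dialect with operators `!`, `&`, `|`, parentheses and constants `0`/`1`
(precedence `!` > `&` > `|`; node names are case-sensitive identifiers over
`[A-Za-z0-9_]`, which accommodates fusion nodes such as `AR_ERG`). The
signed influence graph is derived from the rules: a regulator appearing
under an even number of negations contributes a positive edge, odd a
negative one, and a regulator occurring with both parities contributes both
edges. Published models (for instance the 133-node / 499-edge prostate
cancer network this package is designed to drive) are loaded from their
rule file with `readRules()`; they are not bundled here, and all packaged
analyses run on the frozen `toyARNetwork()` fixture and generated networks.

Dynamics are continuous-time asynchronous stochastic logical dynamics, the
standard semantics for personalized logical models: a non-forced node whose
current value disagrees with its rule flips after an exponential waiting
time, at its *up* rate (0→1, rule satisfied) or *down* rate (1→0, rule
unsatisfied), and exactly one node flips per jump. Forced nodes never flip.
A state with no eligible flip is absorbing, and the simulation simply idles
there until the horizon. The per-node *activity* is the probability of
being ON as a function of time, estimated two ways:

- `estimateActivity()`: a Gillespie ensemble (default 5000 trajectories),
  activity = ON-fraction per grid time with binomial standard errors;
- `exactMasterEquation()`: the transient solution of the full
  `2^m`-state master equation over the `m` non-forced nodes, propagated by
  uniformization. Capped at `m ≤ 12` by default (the cost is
  `O(2^m · m)` per matrix-vector product); beyond the cap the error message
  points to the Monte Carlo engine.

## Personalization

Subject-specificity enters through three channels, mirroring how
multi-omics patient data are formatted (mutation incidence tables, a
gene × sample ploidy matrix, a gene × sample expression matrix):

- **Forcings.** Inactivating mutations and deep deletions (ploidy −2) pin a
  node at 0; activating mutations and high amplifications (+2) pin it at 1.
  Mutations of unknown functional effect and single-copy changes (|ploidy|
  = 1) deliberately contribute nothing — a conservative default, exposed in
  the API, since no printed rule prescribes their handling. Where mutation
  and copy-number evidence disagree, the default `mutation_first` policy
  lets the annotated functional effect win (with a warning); a `strict`
  policy turns the conflict into an error. Copy-ratio segments arrive
  either pre-discretized or as FACETS log-ratios, discretized by
  `discretizeLrr()` (half-open intervals, upper bounds inclusive except the
  open top class).
- **Rates.** Cohort-normalized expression `x ∈ [0,1]` (per-gene min–max by
  default; rank-percentile available; constant genes map to 0.5) is clamped
  to `[0.01, 0.99]` and mapped linearly: up rate `s·x`, down rate
  `s·(1−x)`, initial ON-probability `x`, with rate scale `s = 1` in
  reciprocal arbitrary time units. This is the simplest transfer satisfying
  "higher expression ⇒ higher propensity to be ON"; it is closed-form
  testable (an input-free two-state node has stationary ON-probability
  exactly `x`) and is isolated behind `deriveRatesAndInitial()` so that
  alternative transfers can be swapped without touching the rest of the
  pipeline. Nodes without expression data get the neutral
  `up = down = s/2`, initial 0.5.
- **Gene→node mapping.** Exact name match after an optional alias table;
  fusion nodes (AR_ERG) have no single transcript and are never forced from
  omics unless explicitly aliased. Genes absent from the network are logged
  and skipped.

The clamping bound 0.01 keeps all rates strictly positive (the jump process
stays irreducible over its reachable set and no waiting time degenerates),
while preserving the ordering of expression values.

## Knockout scoring and the group comparison

`simulatePair()` runs a model before and after applying perturbation
forcings (AR knockout = `c(AR = 0)`) and scores each node by
ΔAUC(%) = (AUC_ap − AUC_bp)/AUC_bp × 100, the relative change in the
trapezoidal area under the activity curve over the simulation window. Three
numerical decisions:

- AUC is computed on the ensemble-averaged activity curve; by linearity of
  the trapezoid rule this matches the average of per-trajectory AUCs in
  expectation.
- The two runs share the random seed by default (common random numbers,
  which cancels much of the Monte Carlo noise in the difference);
  `pairedSeeds = FALSE` gives independent streams.
- Baselines below `10⁻³ · tMax` make the ratio numerically meaningless, so
  ΔAUC is reported as undefined (`NA`) instead of exploding — a guard the
  method definition itself does not discuss.

`compareGroups()` tests each node's per-sample ΔAUC between exactly two
groups. The admission filter "change in AUC ≥ 3%" is read as: *test a node
when at least one group's median |ΔAUC| reaches the threshold*. A per-node
cohort summary is the only reading that yields a well-defined pre-test
filter; the threshold is an argument, so per-sample or mean variants are a
one-line change. Benjamini–Hochberg adjustment runs across exactly the
tested node set (treating the 3% rule as a pre-filter, not a post-hoc
selection), and significance is called at adjusted p < 0.05. The
Mann-Whitney U test is exact (enumeration) when there are no ties and
`n_A·n_B ≤ 400`, and the tie-corrected normal approximation otherwise; a
fully degenerate comparison (every observation tied, e.g. the knocked-out
node itself at −100% in both groups) reports p = 1.

## Methylation–expression integration

The integration stage consumes a probe × sample β matrix and a DMR table
(upstream array preprocessing, normalization, batch correction and DMR
calling are external pipelines, not reimplemented). `betaValue()` and
`mValue()` implement β = M/(M+U+a) and M = log2((M+a)/(U+a)) with the
conventional intensity offset a = 100. Each DMR is summarized by its
*representative probe*, the member probe with the largest β range across
samples; exact range ties resolve to the lowest genomic coordinate so the
choice is deterministic. Spearman correlation between the representative
probe's β and matched normalized expression is computed overall and within
each (tissue, group) stratum — the tumor/non-tumor × group cross-product is
the default granularity — with exact p-values for n < 10 without ties and
the t-approximation otherwise. Strata under 3 paired samples are skipped
with a log message. Coordinates are 1-based inclusive throughout
(array-annotation convention). Raw p-values are reported, with BH
adjustment across records available in `correlateAllDmrs()` since no
printed rule fixes the multiplicity handling for this stage.

## The synthetic cohort generator

`simulateCohort()` emulates the *structure* of a two-group multi-omics
study — a mutation table with functional-effect annotations, a gene ×
sample copy-ratio matrix, a gene × sample expression matrix, and sample
metadata, in the exact TSV schemas the personalization stage consumes — not
the empirical marginals of any real dataset. Defaults, chosen once as
study conditions:

- groups "AA"/"EA" with 10 samples each, matching the scale of a small
  surgical cohort profiled with all three data types;
- per-gene mutation probability 0.02 per sample (primary prostate tumors
  are mutationally quiet; per-gene driver frequencies are a few percent),
  with a fixed per-gene functional-effect label;
- copy-ratio lRR ~ Normal(0, 0.3), so that ploidy categories ±2 occur
  essentially only under planted shifts;
- expression log-normal around per-gene log-means drawn from Normal(3, 1)
  with log-scale noise SD 0.5.

Planted effects are orthogonal, composable per-channel group-A
modifications (`mutation_rate`, `cnv`, `expression_shift`,
`methylation_coupling`). The default recovery experiment plants an
expression shift of +2 log units on AR; the magnitude was calibrated so
that a single planted effect is reliably detectable at 10 samples per group
under the default simulation settings, which is the generator's stated
design goal. Ligand/stimulus nodes (Androgen, GF) and the fusion node
AR_ERG are excluded from the gene universe — they have no measurable
transcript of their own — and a few non-network genes (GSTP1, TP53, PTEN)
are included to exercise the ignored-gene path.

The frozen `toyARNetwork()` fixture is hand-written, not random, so that
exact master-equation expectations for knockout directions are fixed test
oracles: AR drives AR_ERG and ZBTB17 and represses the TGFB→SMAD and IDH1
branches, so fixing AR = 0 must lower the former and raise the latter. Its
input nodes are self-negating two-state nodes (stationary ON-probability
equal to the expression-derived rate fraction), i.e. fluctuating ligand
availability; this keeps transition rates relevant at steady state rather
than only during the initial transient.

`simulateMethylationCoupling()` generates DMRs of 3–10 probes over
2 groups × 2 tissues. For a coupled gene the representative probe's β is a
monotone-decreasing noisy function of expression built on a Gaussian
copula with latent Pearson correlation r = 2·sin(π·ρ/6), which hits the
target Spearman ρ in expectation *exactly* rather than by trial-and-error
noise tuning; magnitude 1 is the noise-free strictly decreasing link
(recovered ρ = −1) and magnitude 0 is independence. Non-representative
member probes get a deliberately narrow β spread so the widest-range rule
provably selects the coupled probe.

What the generator does **not** capture — and hence what passing tests do
not show about real data: linkage between channels (real deep deletions
silence expression; here the channels are independent unless both are
planted), realistic gene-gene correlation structure, batch effects, tumor
purity, and the empirical distributions of any GEO/TCGA dataset.

## Numerical choices

- Uniformization truncates each step's Poisson series at a 10⁻¹² tail;
  probability mass over the grid is conserved to better than 10⁻⁹
  (asserted in the tests via the solver's `massErr` attribute).
- Per-trajectory random streams are counter-based (splitmix64 seeded by
  `(seed, trajectory index)`), so trajectory *i* is bit-reproducible in
  isolation and the full pipeline is bit-identical under an identical
  configuration.
- Steady state is declared when the activity range over the final 20% of
  the grid is ≤ 0.01 (tied to the Monte Carlo error at the default
  ensemble size); failing the check is a recorded warning, not an error.
- Defaults `tMax = 50`, `nGrid = 101`, 5000 trajectories: the packaged
  fixtures equilibrate well within the horizon (relaxation times are order
  1/s = 1).
- Validation problem sizes: Monte Carlo vs exact agreement uses 5000
  trajectories against all packaged networks with ≤ 10 non-forced nodes at
  a 5-binomial-SE band (plus a 3/n discreteness floor where the exact
  probability sits at 0 or 1); the planted-effect power experiment uses 50
  replicate cohorts of 10 + 10 samples; the null calibration uses 200
  replicate cohorts; the methylation recovery uses 50 replicates at 30
  samples per stratum.

## Known limitations

- The published prostate network and the original patient-level results
  require data and model files not distributable here; the package
  validates the *method* on synthetic cohorts with known ground truth, and
  group-difference magnitudes on real cohorts are not comparable to the
  toy fixture's.
- The linear expression-to-rate transfer is one defensible choice among
  several (logistic or rank-based transfers are drop-in replacements
  behind the same interface).
- The exact solver is limited to small non-forced state spaces; large
  published networks run through the Monte Carlo engine only.
- No synchronous-update mode, attractor enumeration, drug-dose modeling
  (knockout is binary forcing), or rate fitting to time-series data.
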