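---
title: "Methods and design notes for sarcoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for sarcoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcoscreen)
```

sarcoscreen reimplements, as a tested and reusable pipeline, the
computational core of a multi-omic drug-discovery workflow of the kind used
to nominate therapies for osteosarcoma: a high-throughput viability screen
with hit calling, dose-response fitting, Bliss and Chou-Talalay synergy
scoring of a pairwise combination screen, consensus hub-gene detection on a
protein-protein interaction (PPI) network, a tumor-specific-gene (TSG)
filter cascade down to candidate cell-surface immunotherapy targets, and a
percent-spliced-in (PSI) alternative-splicing screen. Because the original
raw data are not required, every input can be produced by seeded
synthetic-data generators whose statistical structure matches what the
analysis assumes; the generators are first-class, tested code.

## Screen normalization, hit calling and dose-response fitting

Relative viability of a drug well is its luminescence signal divided by the
aggregated DMSO control signal of the same plate set; inhibition is
`1 - viability`. The aggregation rule is the arithmetic mean of control
wells (a linear-unbiased choice; the median is exposed as an option for
robustness against single contaminated control wells). Viabilities above 1
are retained rather than clipped so apparent stimulation stays visible for
QC. Normalization is scale-invariant: multiplying all signals on a plate by
a constant leaves viabilities unchanged.

A drug is a primary-screen hit when its inhibition **strictly** exceeds the
threshold (default 0.60) in at least one cell line. Threshold comparisons
follow the symbols of the conventions they encode: ">60%" is strict, as is
the "less than 50%" bound used for combination-dose selection below.

Dose-response curves use the decreasing four-parameter logistic (4PL)

$$v(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (d/\mathrm{IC}_{50})^{h}},$$

fitted by least squares in a log-dose parameterization. Numerical choices:
five heuristic starts (asymptotes from the viability extremes, midpoints
from log-dose quartiles, Hill slopes 0.5/1/2), bounded L-BFGS-B with
top/bottom restricted to [-0.1, 1.5] and the Hill slope to [0.05, 20]. The
reported IC50 is the fitted midpoint parameter. Degenerate inputs are
contracts, not crashes: fewer than four distinct doses is an error;
all-identical viabilities return a non-converged fit with an undefined
IC50. On noiseless data drawn from the model class the fit recovers all
four parameters (residual SSE below 1e-8), and with 3% multiplicative
noise the IC50 is recovered within 15% in at least 90% of fits — both
verified by the test suite.

Combination doses are chosen from a fixed candidate grid (default: half-log
steps spanning three decades either side of the fitted IC50) as the largest
dose whose **predicted** inhibition is strictly below 0.5. Using a grid
rather than an analytic inverse keeps the rule well-defined when the
constraint never binds (a curve whose bottom asymptote already exceeds 0.5
viability simply returns the top grid dose) and mirrors how screening doses
are picked from discrete stock dilutions in practice.

## Bliss Independence and Chou-Talalay scoring

Fractional responses are interpreted as fractional **inhibition**
(`1 - viability`): Bliss independence treats the two drugs as independent
probabilistic events, and that reading only makes sense on the effect
scale. The expected combined response of independent drugs is
`Pt = Pa + Pb - Pa*Pb`, and the Bliss index is `BI = Po / Pt` for observed
`Po`. `Pt = 0` (two inert agents) leaves the index undefined and is an
error rather than an NaN. Classification uses a floating-point tolerance
of 1e-9 around `BI = 1` for the additive label, since an exact trichotomy
assumes exact arithmetic; "obvious" synergy requires `BI > 1.3` strictly.
Replicated pair measurements are averaged before scoring, with
per-replicate indices kept for dispersion.

The Chou-Talalay combination index is `CI = DA/da + DB/db`, where `da`,
`db` are single-agent IC50 doses and `DA`, `DB` are the combination doses
reaching the IC50 effect. How those combination doses are located is not
standardized; here they are obtained by log-linear interpolation of a
fixed-ratio combination series to the 50%-effect level
(`interpolate_ic50_doses()`), preserving the dose ratio of the bracketing
points.

The synergy summary reports the number and percentage (one decimal) of
pairs above the obvious-synergy threshold; `percent_of()` is the single
rounding rule used by all such reports. Whether indices should be computed
per cell line and then aggregated, or on pooled data, is genuinely open;
sarcoscreen scores per cell line (each `synergy_matrix()` call is one
line's screen) and leaves aggregation to the caller.

## Consensus hub genes from ten centralities

Hub genes are nodes ranked in the top fraction (default 10% of network
nodes, rounded up) by **all ten** centrality measures: Degree, Closeness,
Betweenness, Stress, EcCentricity, Radiality, MNC, MCC, BottleNeck and
EPC. The measures follow the CytoHubba conventions, with three choices
made explicit because the source conventions under-specify them — each a
known divergence risk against other implementations:

- **Closeness** is harmonic (`sum of 1/d(v, w)` over reachable `w`), which
  stays meaningful on disconnected graphs.
- **BottleNeck** needs a deterministic shortest-path tree per root; here
  every non-root vertex attaches to its smallest-labelled predecessor
  (a neighbor one step closer to the root). A vertex scores one point per
  root whose tree places more than a quarter of the graph in that vertex's
  subtree.
- **EPC** is simplified to seeded Bernoulli edge retention: each of `R`
  realizations (default 1000) keeps every edge independently with
  probability 0.5, and a node's score is its mean component size. With
  keep probability 1 this equals the component size exactly, which the
  tests assert.

Other definitions: `EcCentricity(v)` is the reciprocal of the maximum
distance to any reachable vertex (0 for isolated vertices);
`Radiality(v)` sums `diameter + 1 - d(v, w)` over reachable `w`, scaled by
`1/(n-1)`, with the diameter taken within `v`'s component; `MNC(v)` is the
size of the largest connected component of the open neighborhood;
`MCC(v)` sums `(|C|-1)!` over maximal cliques containing `v` (Bron-Kerbosch
enumeration; PPI graphs at TSG scale are small enough for exact
enumeration). Ranking ties are broken by ascending node label, and top-k
uses `ceiling(fraction * n)` so small graphs never produce empty sets.
Every deterministic measure is checked against an independent brute-force
oracle (explicit path/clique/tree enumeration) on hundreds of random small
graphs.

Whether "top 10%" should mean 10% of network nodes or of a pre-ranked
candidate list is unstated in the conventions this follows; 10% of network
nodes is used.

## The differential-expression filter cascade

The cascade consumes only `(log2fc, adj_p, mean_cpm_tumor)` per gene, so
any DE engine can feed it through the readers. The built-in engine is
deliberately simple and fully specified rather than a wrapper around a
heavier model: counts are CPM-normalized (`cpm_normalize()`), the fold
change is `log2((mean CPM tumor + 1)/(mean CPM normal + 1))` with a
pseudocount of 1 CPM to avoid infinite fold changes at zero counts, and
p-values come from a two-sided Wilcoxon rank-sum test on `log2(CPM + 1)`
(signed-rank on per-pair differences in paired mode), BH-adjusted across
all tested genes. The rank-test p-values are computed by a vectorized
engine — exact via the Wilcoxon/signed-rank distributions when tie-free,
normal approximation with tie correction and continuity correction
otherwise — that matches `stats::wilcox.test` to machine precision in the
tests; vectorization keeps the 50-seed power and type-I simulations fast.

Boundary conventions are fixed by the symbols being encoded and asserted
in the tests: fold-change bounds are **inclusive** ("FC >= 2" means
`|log2fc| >= 1`), significance bounds are **strict** ("p < 0.05"), the ACT
surface-target CPM bound is inclusive ("CPM >= 90"), and the single-cell
percent-expressed bound is strict ("> 25%"). Pan-cancer exclusion removes
a TSG only on positive evidence of up-regulation in another cancer type;
genes absent from the reference table are retained and flagged
unevaluated. The cascade is monotone by construction: specific genes are a
subset of TSGs, surface-target candidates a subset of surface-annotated
TSGs, and every functional-class set a subset of TSGs.

## The splicing screens

Alternative-splicing events are classified from two-transcript comparisons
of exon chains: ES when one transcript skips one or more internal exons
present in the other between shared flanking splice sites, A3SS/A5SS when
one boundary of a shared intron shifts (assigned relative to strand, so a
strand flip swaps the two labels, which is asserted as a property), IR
when a single exon exactly spans the other transcript's
exon-intron-exon triplet, and MEE for two private, non-overlapping
internal exons between shared flanks. Differences are matched greedily
from the 5' end; composite differences beyond the five types are labelled
"complex" and excluded from five-type counts. Coordinates are handled
1-based inclusive end-to-end (the GTF and GRanges convention), and the
classifier is symmetric in its arguments and translation-equivariant.

PSI uses junction counts with per-form junction normalization:

$$\mathrm{PSI} = \frac{I/n_I}{I/n_I + E/n_E},$$

where `I`, `E` are inclusion/exclusion junction reads and `n_I`, `n_E` the
number of junctions supporting each form (an ES inclusion form has two
junctions, its exclusion form one). Dedicated splicing engines each use
their own PSI variant; this junction-normalized form is standard, fully
testable, and documented here as a potential divergence from any specific
engine. A coverage floor (`min_total = 10` reads) returns `NA` rather than
an unstable estimate — variance control that matters for the SD-based
heterogeneity screen. PSI is scale-invariant in the counts and consistent
as coverage grows, both asserted as properties.

Differential splicing averages per-pair PSI differences over complete
tumor/normal pairs (at least 3), tests them with a two-sided paired t-test
on the raw PSI scale (the thresholds are stated on that scale, so no logit
transform), adjusts by BH across events, and calls significance at
`|dPSI| > 0.10` (strict) and adjusted `p < 0.01` (strict). The
heterogeneity screen passes events whose tumor PSI sample SD (n-1
denominator) strictly exceeds 0.15; the intersection with the differential
set gives the "tumor-specific and patient-heterogeneous" report.

## What the generators emulate — and what they do not

All generators are pure functions of their parameters and a seed.

- `sim_screen_plates()` / `sim_dose_response()`: latent 4PL responses times
  multiplicative lognormal noise (mean exactly 1 at any CV) — plate
  readers exhibit multiplicative error. One shared DMSO control-well set
  per plate set, matching how control plates are laid out at the level the
  pipeline needs. Default IC50s are log-uniform on 0.5-2000 uM so a 10 uM
  single-dose screen flags a realistic minority of a drug library. Not
  emulated: spatial plate effects (edge effects), which the pipeline also
  does not correct for.
- `sim_combination_screen()`: observed combined inhibition is the Bliss
  expectation plus a planted `bliss_excess`, clamped to [0, 1], times
  noise. With zero excess and zero noise every pair satisfies `BI = 1`
  exactly — the oracle identity the tests lean on.
- `sim_ppi_network()`: Erdős–Rényi background (mean degree 4, typical PPI
  sparsity at this scale) plus planted hubs forming a clique, each wired to
  5x the background mean degree of random nodes. Hub labels sort before
  background labels so the documented ascending-label tie-break can never
  evict a planted hub on a tied score. Real PPI networks are heavier-tailed
  than this background; the generator's job is a controlled recovery
  benchmark, not topological realism.
- `sim_expression_counts()`: negative-binomial counts (Poisson at zero
  dispersion) over lognormal baseline means, library-size factors within
  2x, and exactly `round(de_fraction * n_genes)` planted genes shifted by
  `2^(±lfc)`. No gene-gene correlation, batch structure, or
  outlier samples — so a green power test establishes sensitivity under
  the stated noise model, not robustness to confounding.
- `sim_splicing_dataset()`: Poisson junction coverage split binomially
  between forms with a junction-count-adjusted probability (so the PSI
  estimator is consistent by construction), tumor PSI drawn from a normal
  truncated to [0, 1] (simple, and exactly what an SD-threshold screen
  assumes), and a two-transcript gene model per event realizing its AS
  type. Normal-tissue PSI is held at its latent value; between-normal
  variability beyond counting noise is not modelled.
- `sim_scrna_counts()`: Bernoulli detection times Poisson counts per cell
  type — enough to control percent-expressed exactly; no dropout curves,
  no depth variation.

## Known limitations

- The built-in DE engine is rank-based and unshrunken; with very few
  samples per group a negative-binomial model has more power. The cascade
  accepts any engine's output for that reason.
- BottleNeck and EPC scores depend on the documented tree rule and
  retention scheme; other implementations may rank borderline nodes
  differently.
- The AS classifier handles pairwise transcript comparisons; genes with
  many isoforms are analyzed pair by pair, and overlapping composite
  differences fall into the "complex" bucket rather than being decomposed
  exhaustively.
- The Chou-Talalay interpolation assumes the fixed-ratio series brackets
  the 50% effect; it errors (by design) when the combination never reaches
  it.
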