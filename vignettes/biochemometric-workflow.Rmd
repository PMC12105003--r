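---
title: "Joint MS- and NMR-based biochemometrics of microfractionated extracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint MS- and NMR-based biochemometrics of microfractionated extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biochemnet)
```

## The problem

Natural-product discovery routinely faces complex extracts in which the
constituent responsible for a measured bioactivity is unknown.
Biochemometrics shortcuts bioassay-guided isolation: the extract is
separated into a long series of consecutive *microfractions* (here ~34),
each microfraction is bioassayed (e.g. DPPH radical scavenging, where
capacity is `(blank - sample) / blank` on the measured absorbances) and
profiled both by LC-MS² and by ¹H NMR, and the chemical signals whose
intensities *co-vary with activity* across neighbouring fractions point to
the active constituents before anything is isolated.

Correlations are computed over a **package**: a run of at least three
consecutive microfractions with clearly increasing or decreasing activity.
Within a package the constituents' concentrations change smoothly (each
compound elutes as a unimodal profile spanning several fractions), so a
compound driving the activity produces feature intensities that are nearly
affine in the activity — Pearson's r close to +1 — while compounds absent
from the package contribute nothing.

Two independent branches provide the evidence:

* **MS branch.** Every MS feature (an ion with m/z, retention time,
  per-fraction intensity, and an MS² spectrum) is correlated with activity
  over the package. Features are simultaneously organised into a molecular
  network: nodes are features, edges connect features whose fragment
  spectra are similar under the *modified cosine* (peaks match directly or
  shifted by the precursor mass difference), and connected components —
  *spectral families*, conventionally reported when larger than 3 nodes —
  group structural congeners. Node colors encode r: red/orange positive,
  yellow none, green/blue negative, and gray for features not present in
  the package.
* **NMR branch (HetCA).** Binned ¹H NMR spectra of the package fractions
  are correlated bin-by-bin with activity, yielding a color-coded
  *pseudospectrum*: positively correlated proton signals point up in red,
  negatively correlated ones down in blue. Contiguous correlated bins are
  merged into regions and quantified by their share of the integral in the
  most active fraction, which estimates how much of that fraction's proton
  signal belongs to the correlated constituent.

The two branches are finally *combined by presentation, not by a fused
score*: features are grouped by co-elution (same retention time within
tolerance — adducts and in-source fragments of one compound), groups are
ranked by their best MS r, and each group is shown next to the matching
NMR-region coefficient. Inventing a numeric MS+NMR fusion statistic would
claim more than correlation evidence supports; a ranked table showing both
coefficients side by side is what an analyst actually interprets. A
co-eluting inactive "passenger" is indistinguishable from the active by
correlation alone; the co-elution grouping at least makes the ambiguity
explicit.

## The correlation model

For a package of $n \ge 3$ fractions with activity $y$ and a feature or
bin intensity $x$,

$$ r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
            {\sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}} $$

computed by one shared kernel (`cor_bioactivity()`) for both branches, so
identical intensity vectors give bit-identical coefficients on either
side. Zero-variance vectors are flagged *degenerate* with $r = 0$ (never
`NaN`) and colored yellow. With $n = 3\ldots5$ fractions there is no
meaningful null-hypothesis machinery — we deliberately report correlation
magnitude only, no p-values and no multiple-testing correction, and
document that small-package correlations are an effect-screening tool,
not inference.

The pseudospectrum display is $r \times$ mean package intensity per bin.
This keeps the familiar spectrum-like shape (tall signals stay tall),
while the sign carries the correlation direction; the covariance and the
raw $r$ are both emitted alongside for users who prefer either convention
as the display axis (`display = "cov"` or `"r"`).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| bin width | 0.01 | ppm | resolves multiplets at typical 1H linewidths |
| analysis range | 0–10 | ppm | full proton window |
| solvent exclusion | 2.45–2.55, 3.2–3.4 | ppm | residual DMSO-d6 and water |
| row normalization | off | — | fractions measured at equal nominal concentration (e.g. 3 mg/mL aliquots); a total-integral switch exists for unequal loadings |
| baseline `lambda`, `p` | 1e5, 0.001 | — | asymmetric least squares; smooth enough to ignore peaks, asymmetric enough to hug the base |
| fragment tolerance | 0.02 | Da | high-resolution instrument convention |
| `min_score`, `min_matched` | 0.7, 6 | — | spectral-networking convention for edge acceptance |
| `top_k` | 10 | — | mutual-rank cap keeping families interpretable |
| color breaks | 0.3, 0.7 | r | the five-color code names colors, not numbers; 0.3/0.7 split "none / moderate / strong" |
| region threshold | 0.7 | r | same "strong" boundary as the red class |
| `presence_min` | 0 | intensity | package membership is presence-based (strictly positive) |
| `rt_tol` | 0.05 | min | co-elution window; features 0.2 min apart are distinct compounds |

All parameters are echoed into the run log (`run_log.json`) so no silent
defaults exist; a run is reproducible from its inputs and log alone.

## The synthetic-data generator

The generator emulates the statistical structure of a microfractionation
study with known ground truth, so every claim the tests make is checkable:

* **Elution**: each constituent's concentration over the 34 fractions is a
  discretized Gaussian (center, width ~1 fraction), truncated below 2% of
  its own maximum — the order of peak-detection cutoffs applied by MS
  preprocessing — giving each compound a support of ~5–6 consecutive
  fractions and making "absent from the package" an exact zero.
* **MS features**: one feature per (constituent, ion) with shared
  retention time; intensity factorizes as concentration × ion abundance ×
  multiplicative lognormal noise (CV 10% by default) — positive and
  heteroscedastic, as MS intensities are. Congener families share their
  ten dominant MS² fragments (plus three low-abundance unique peaks each),
  so fragment networking reassembles the families.
* **NMR**: per-fraction spectra are concentration-weighted sums of
  Gaussian multiplets with a global 0.07 ppm center separation (signals
  resolvable at the 0.01 ppm bin width, so bins are attributable to
  constituents) and compact ±4 sd lineshape support. Spectra are generated
  noise-free: at acquisition concentrations of a few mg/mL the ¹H SNR is
  high and assay noise dominates the workflow's uncertainty.
* **Bioactivity**: noiseless activity is $S(\sum_c \text{potency}_c \cdot
  \text{conc}_{c,f})$ with the bounded saturating transform $S(z) = 100
  \tanh(z)$, plus Gaussian noise with sd = 5% of the activity range. We
  chose $\tanh$ over a Michaelis-type hyperbola deliberately: at realistic
  peak responses a Michaelis curve flattens the between-fraction contrast
  inside a 3-fraction package so strongly that assay noise swamps the
  correlation signal, which contradicts the observable fact that
  small-package biochemometrics works. Potency defaults put the best
  fraction near ~57% scavenging, within the range reported for moderately
  active extracts.
* **Determinism**: every stochastic operation draws from its own stream
  derived from `(seed, operation name)`, so outputs are bit-identical per
  seed and adding an operation never perturbs the others. Fixture files
  hash-stably round-trip.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: chromatographic tailing and co-elution of
unrelated compounds, ionization suppression, isotope patterns, NMR peak
overlap and coupling structure, baseline drift (unless explicitly added),
and matrix effects on the assay. Real packages also rarely isolate a
single active; the report format (groups, families, both coefficients) is
designed for the ambiguous cases the simulation keeps clean.

## Numerical choices

* **Binning** augments the spectral grid with the bin edges and integrates
  trapezoidally, so row totals equal the spectrum's integral over the
  analysis range to machine precision (the 1e-6 contract is met with
  orders of magnitude to spare). Bin edges are deterministic; ties at
  edges belong to the higher-ppm bin by the edge-augmentation convention.
* **Baseline correction** is asymmetric least squares (sparse Whittaker
  smoother, iteratively reweighted, ≤ 20 iterations, early exit on weight
  convergence). It replaces the manual baseline work of an analyst;
  near-idempotence (second pass changes peak integrals < 0.5%) is tested.
* **Modified cosine** square-root-transforms intensities (dominant-peak
  robustness), L2-normalizes, and uses a greedy highest-product-first
  one-to-one assignment with deterministic tie-breaks (lower m/z in the
  first, then second spectrum). At fragment-spectrum sparsity the greedy
  matching equals the exhaustive optimum; the test suite verifies this
  against full enumeration on hundreds of random pairs.
* **Mutual top-k rule**: an edge survives only if it ranks within `top_k`
  for both endpoints — monotone in `top_k` (raising it never removes an
  edge), tested.
* **Degenerate inputs**: empty MGF files give empty lists; empty peak
  lists score 0; packages smaller than 3, non-consecutive packages, and
  missing fraction ids are errors naming the offender; a region threshold
  passed by no bin returns an empty table, not an error.
* **Ranking ties**: regions tie-break by higher ppm; candidate groups by
  larger summed intensity — determinism over aesthetics.

## Problem sizes used in tests and scripts

The bundled analyses run at the study's native scale: 34 fractions,
12 constituents (36 MS features), 4096-point spectra, 0.01 ppm bins. The
recovery study (`analysis/05_recovery_study.R`, and the acceptance
checks) repeats the full in-memory pipeline over 200 independent seeds;
the acceptance script uses 50 seeds per invocation. These sizes keep a
complete run in seconds while leaving the per-experiment computation
identical to a real-data run.

## Known limitations

* Correlation is not causation: a passenger co-eluting with the active is
  ranked equally; the report flags group membership rather than resolving
  it.
* Packages of 3–5 fractions cannot support significance testing; the
  coefficients are screening evidence.
* The NMR-region-to-feature link requires an external mapping (ground
  truth in simulations, analyst assignment in practice); the package does
  not auto-assign proton regions to compounds.
* The MGF and JCAMP-DX readers cover the dialects the workflow writes and
  the common MZmine/vendor exports, not the full format specifications.
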