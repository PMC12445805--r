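---
title: "Methods: quantification, compositional statistics and phylogenetic signal in sterolome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, compositional statistics and phylogenetic signal in sterolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolome)
options(sterolome.verbose = FALSE)
```

`sterolome` analyses pollen sterol profiles from LC-MS feature tables
through to phylogenetic and nutritional conclusions. This vignette is the
package's account of the underlying models, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Quantification model

The instrument reports one row per chromatographic signal: *m/z*,
retention time and area. The analysis assumes sterol dehydration ions
\[M−H₂O+H\]⁺ under APCI, so a sterol of formula CcH(2c+2−2(4+d))O appears
as the cation CcH(2c+1−2(4+d))⁺, where *d* counts double-bond equivalents
beyond the four-ring core (cholesterol is ST(27:1), cycloartenol-type
sterols ST(30:2) because the cyclopropane ring closure contributes one
DBE). Theoretical masses are sums of monoisotopic atomic masses
(C 12.000000, H 1.0078250319, D 2.0141018, O 15.9949146) minus one
electron mass per charge.

Every sample carries a fixed molar spike of d₇-cholesterol
(20 µl × 0.1 mg ml⁻¹ / 393.71 g mol⁻¹ = 5.08 nmol). Dividing each
analyte's area by the IS area cancels injection and ionization
variability under the assumption of equal response factors — the standard
one-point internal-standard model. Absolute content follows as

$$\mathrm{mg\,kg^{-1}} = \frac{MW \times signal \times 5.08\times10^{-9}\,\mathrm{mol} \times 10^{6}}{weight_{mg}/1000}.$$

*MW* here is the average (chemical) molar mass, since the quantity being
reported is gravimetric; monoisotopic masses are used only for *m/z*
matching. Level-2 sterols use the molar mass implied by their (C, D)
code; level-3 features (mass fits no sterol composition) stay in the
compositional analysis but are excluded from mg/kg totals with a warning.

Key tunables (all in `run_config()`): extraction windows (3–11 min,
360–442 *m/z*, area ≥ 5×10⁵ counts — the acquisition settings of the
assay), `ppm_tolerance` (3 ppm, the instrument's mass accuracy),
`rt_tolerance` (0.1 min, the extraction RT window, reused for
cross-sample feature alignment because both reflect the same
chromatographic reproducibility), `qc_threshold` (Pearson *r* ≥ 0.75
between nominal QC load and IS-normalized signal), and `blank_factor`
(3× the median blank signal — the assay states the intent of blank
subtraction but no rule, so a conventional 3× median rule is used).

Annotation resolves ties deterministically: a feature matching several
references within tolerance takes the nearest retention time (warning
logged); level-2 features sharing (C, D) are lettered A, B, C… in
ascending retention time, an arbitrary but reproducible convention.

## Compositional statistics

Analysis operates on proportions (0–1 internally; percentages only at
presentation). Two distinct distance paths exist on purpose: the outlier
screen uses Bray–Curtis on **raw** proportions (a sample whose minimum
dissimilarity to every other sample exceeds 0.5 has no compositional
neighbour and is removed), while ordination and the permutation tests use
Bray–Curtis on **arcsine-square-root** transformed proportions, the
variance-stabilizing transform for proportion data. Taxon means are
arithmetic means of per-sample proportions renormalized to 1, guarding
against per-sample rounding drift.

Simpson diversity is computed on taxon-mean profiles by default (a flag
allows sample-level input); means are the unit of all cross-taxon
summaries, so diversity is reported on the same unit.

## Permutation statistics

NMDS, PERMANOVA, the dispersion test, indicator-value analysis,
Kruskal–Wallis with Dunn post hoc, and Benjamini–Hochberg correction are
implemented from their definitions; the test suite cross-checks each
against an independent reference implementation (vegan, stats) on small
fixtures, keeping implementation and oracle separate.

* **NMDS** minimizes Kruskal stress-1 by alternating weighted
  pool-adjacent-violators isotonic regression of configuration distances
  on the dissimilarities with Guttman-transform majorization steps. Ties
  receive the primary treatment (no order constraint within a tie block,
  approximated by breaking ties on the fixed principal-coordinate
  distances). The first start is the principal-coordinate configuration,
  the rest random; restarts stop once two starts agree on the minimum to
  1e-6 or the stress is below 1e-6. Iteration stops when stress changes
  by < 1e-8 (500-iteration cap). `nmds_screen()` escalates k from 2 until
  stress ≤ 0.2, the conventional acceptability cut-off.
* **PERMANOVA** partitions the sum of squared dissimilarities (total:
  Σd²/n; within-group: the analogue within groups) into a pseudo-F;
  p-values permute group labels with the (1 + b)/(1 + m) estimator so p
  is never zero and equals 1/(m+1) when the observed statistic is
  unmatched. Pairwise tests are BH-adjusted. Permutations default to 999.
* **Dispersion** embeds the distance matrix by principal coordinates,
  keeps negative-eigenvalue axes as imaginary components (distance² =
  real part − imaginary part, floored at zero), measures each sample's
  distance to its group centroid and permutes those distances; the
  classical F-table p is reported alongside.
* **IndVal** tests each sterol's maximum-group statistic √(A·B) by
  group-label permutation; groups are tested singly, never in
  combination.
* **Kruskal–Wallis/Dunn** use tie-corrected rank formulas throughout.

## Phylogenetic signal

Blomberg's *K* compares the observed ratio MSE₀/MSE (variance about the
phylogenetic mean over the GLS mean-squared error under the tree's
variance–covariance matrix C) with its Brownian expectation
(tr(C) − n/(1ᵀC⁻¹1))/(n−1); K = 1 under Brownian motion on the given
tree, and K is exactly 1 on a star tree for any trait. Inference shuffles
trait values across tips (999 permutations by default, statistic = K).

Pagel's λ scales the off-diagonal of C while fixing the diagonal and
maximizes the profile likelihood (Brownian rate and root state profiled
out) over λ ∈ \[0, λ_max\], where λ_max is the largest value keeping C(λ)
positive semidefinite — computed from the tree by bisection rather than
fixed at 1, with the reported value capped at 1 for display. The
optimizer is bounded scalar search to 1e-6 with explicit endpoint checks;
near the PSD boundary the Cholesky factorization is stabilized with a
relative jitter of 1e-8, and log-likelihood is −∞ outside the cone. The
λ test is a likelihood-ratio test against λ = 0 with a plain χ²₁
reference by default; because λ = 0 sits on the parameter boundary the
50:50 mixture correction is available as an option (`mixture_null`), a
documented choice rather than a claim about any particular software's
internals.

Traits enter the screen as untransformed proportions (plus total mg/kg,
always included, and carbon-/B-ring-class sums); a sterol is screened
only if its maximum taxon proportion exceeds 1%, since signals estimated
on near-absent traits are dominated by detection noise. Taxa identified
only to genus level are excluded from the screen by default when species
in the same genus are present, mirroring standard practice for tip
matching. Tree preparation applies rename rules (synonym, subspecies →
species, hybrid → parent, congener substitute) in order, refusing a
congener substitution whenever the genus already has a correctly matched
species.

## Honeybee sufficiency

Pollen profiles are subset to the six sterols reported from honeybee
prepupae and scored against strict (>) thresholds stored as fractions
(0.30, 0.19, 0.10, 0.05, 0.005, 0.005) **without renormalizing** — a
pollen's cholesterol either exceeds 0.5% of its whole sterolome or it
does not, regardless of what else is present. Scoring is therefore
monotone: raising any of the six proportions never lowers the count of
requirements met. The bundled reference bee mean profile is synthetic —
constructed so each component exceeds its own threshold — because the
underlying per-sample bee measurements are not distributed with this
package; users with measured bee data should supply it via
`bee_requirements(bee_mean = ...)`.

## What the synthetic generator emulates — and what it does not

`sim_tree()` draws constant-rate birth–death trees conditioned on the tip
count. `sim_traits()` draws traits from the λ-transformed Brownian
covariance, so the generator's λ_true is exactly the quantity the
estimators target. Latent traits become compositions by softmax — the
standard way to obtain valid simplex data from an unconstrained
evolutionary model — and per-taxon totals are lognormal
(`total_mean` 5000 mg/kg, `total_cv` 1), spanning roughly the two orders
of magnitude observed between low- and high-producing pollens.
`sim_sample_tables()` writes areas as
IS_area × total × proportion × (weight/1000)/(MW × is_moles × 10⁶) times
multiplicative lognormal noise with mean 1 (`noise_cv` 0.1 by default; MS
areas are positive and heteroscedastic, and no per-sample noise magnitude
is published for this assay, so the value is a package choice), so
quantification inverts to the truth exactly at zero noise and unbiasedly
otherwise. QC samples repeat a pooled profile at loads 1.0/0.5/0.25;
blanks carry only sparse sub-threshold background and no IS.

The generator does **not** emulate chromatographic peak shapes, isotope
patterns, co-elution interference, response-factor differences between
sterols, or missingness structure. Tests passing on synthetic data
therefore demonstrate the correctness of the computational chain and the
calibration of the estimators under the stated model — not robustness to
instrument artefacts.

## Problem sizes and determinism

Calibration checks use 100-tip trees with 30–100 traits (the standard
error of a mean K is ≈ 0.035 at 100 traits); bias checks at intermediate
λ average over several independent trees because a single tree's
information content shifts the single-tree mean. Permutation counts in
tests are reduced (49–199) where only reproducibility or oracle equality
is at stake; the package default stays 999. Every stochastic stage draws
from an explicit seed and logs it, making the full pipeline, including
JSON output, byte-reproducible.

## Known limitations

One-point internal-standard quantification assumes equal molar response
across sterols, which APCI only approximates. Level-2 annotation cannot
separate isomers beyond retention time. The dispersion test uses group
centroids (not spatial medians). The λ LRT's χ²₁ reference is
conservative at the boundary. NMDS restarts make the global optimum
probable, not guaranteed.
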