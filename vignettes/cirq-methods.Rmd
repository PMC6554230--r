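---
title: "Quantitation and refinement methods in cirq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitation and refinement methods in cirq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirq)
```

`cirq` quantifies iTRAQ 4-plex reporter ions from MS/MS spectra and
refines the resulting peptide-level ratios into protein-level ratios.
This vignette is the package's account of the methods: the signal model,
the parameters that matter, the refinement rules and the reasoning behind
the choices that were genuinely open, what the synthetic-data generator
does and does not emulate, and the numerical conventions.

## Reporter-ion signal model

An MS/MS spectrum of an iTRAQ-labeled peptide carries four reporter ions
near m/z 114.1112, 115.1083, 116.1116 and 117.1150 (the standard 4-plex
reporter masses; configurable in `reporter_panel()`). The package
implements the two competing ways of turning the low-m/z region into four
channel signals.

**Sum of peak intensities (RSPI).** The signal of channel $c$ is the sum
of the intensities of all peaks within the tolerance window
$[m_c - \tau,\, m_c + \tau]$. Peak height is proportional to the detector
ion count, so summed heights read the reporter count directly, regardless
of the peak's width. This applies unchanged to centroid data (usually one
stick per channel) and to profile data (the samples of a trace sum to a
quantity proportional to the count for a fixed sampling step).

**Trapezoidal peak area (RPA).** The signal of channel $c$ is the
trapezoidal integral of the profile intensity trace over the same window,
with linear interpolation of the trace at the exact window edges when
samples exist just outside. Units are counts·Da. Area confounds height
with width: two peaks of equal height but different widths have equal
RSPI signals and different RPA signals. The test suite asserts both
directions of this contrast on constructed Gaussian peaks. RPA on a
centroid spectrum is accepted with a warning but every zero-width stick
contributes zero area; a window with fewer than two profile samples also
yields zero and is counted on the returned object. These degenerate
results are deliberate: silently switching strategies would defeat the
comparison the two functions exist for.

Both strategies use the same default tolerance $\tau = 0.05$ Da so that a
comparison between them isolates the integration strategy rather than the
window. The window is inclusive at both edges, and the panel constructor
rejects windows that overlap (channel spacing must exceed $2\tau$), which
is what makes "assign each peak to the nearest window" unambiguous.

## Isotope-impurity correction

Each label's reporter envelope leaks certified fractions of signal into
the channels −2, −1, +1 and +2 Da away. Writing $M_{ij}$ for the fraction
of label $j$ observed in channel $i$ (columns may sum to less than 1;
leakage past the panel edge is lost), the observed signals are
$o = M t$. `correct_isotopes()` solves this 4×4 linear system for the
true signals $t$ — an exact inversion of the declared mixing model rather
than the one-pass subtraction heuristic some tools use, because the
system is tiny and the inversion is exact for any well-conditioned $M$.
Two numerical guards apply:

- $M$ with condition number above $10^8$ is refused as a configuration
  error;
- negative components of the solution (possible under noise) are clamped
  to zero and counted; a clamped channel yields a null ratio downstream,
  which is exactly the discard path the refinement filter defines for
  unquantifiable channels.

The package ships `example_correction_table()`, a certificate-style table
with values in the typical range (a few percent at ±1 Da, tenths of a
percent at ±2 Da). It is a synthetic example, not any specific reagent
lot; real analyses should load their lot's table with
`read_correction_table()`.

## Ratios and the null convention

Ratios are formed per spectrum against the replicate's reference channel:
$r_c = t_c / t_{\mathrm{ref}}$. If the reference signal is zero, all
ratios are null; if a channel signal is zero, that ratio is null. In the
tab-delimited jpf dialect a null is written as `0.0` or an empty/`NA`
cell — both forms are preserved on read (provenance) and both trigger the
same discard rule at filter time.

## The refinement workflow

**Exclusion cascade** (`circ_filter()`). A PSM is discarded at the first
failing criterion, in this fixed order:

1. *low score* — identification confidence. The score must be strictly
   above the threshold; equality discards. Defaults: 30 on the Mascot
   scale, 95 on the Paragon confidence scale.
2. *null ratio* — quantification confidence: every condition ratio must
   have been calculated (no nulls, no 0.0).
3. *Fragment annotation* — partial-sequence database entries.
4. *REVERSED annotation* — decoy entries. Decoys are filtered under both
   integration strategies; quantifying a decoy is meaningless regardless
   of how its reporter region was integrated.
5. *shared peptide* — within a replicate, the same sequence mapping to
   more than one distinct accession (including multi-accession rows).
   Matching is by exact sequence string including modification
   annotations; cross-replicate razor-peptide assignment is out of scope.

The order is fixed so that the per-reason counts in the filter report are
well defined; a record failing several criteria is counted once, under
the first. Shared-ness is assessed among the records that survive
criteria 1–4, which gives the filter a clean algebraic property: it is
idempotent (re-filtering the retained set discards nothing), and the
report partitions its input exactly. Both properties, plus monotonicity
in the threshold, are enforced by property-style tests.

**Catalog** (`build_catalog()`). Tag rotation means channel 115 is one
condition in one replicate and another condition in the next, so ratios
are re-keyed from channels to conditions through each replicate's mapping
before anything is merged. Every (sequence, accession) pair then receives
a frequency index: the number of replicates in which it was retained with
full quantitation. "Retained" — not merely identified — is the operative
word: a peptide identified in five replicates but quantifiable in three
has frequency index 3, because the index exists to gate which ratios are
trustworthy enough to pool.

**Rollup** (`rollup_proteins()`). For each (accession, condition), the
ratios of all peptides at or above the frequency threshold are pooled
across replicates; the report carries the overall median (even counts
average the central pair), per-replicate medians, an intensity-weighted
mean and the sample SD (n−1; absent below two pooled ratios). The weights
are the summed corrected reporter signals of each PSM — a peptide
measured on strong signals is more reliable than one at the noise floor —
with uniform weights both available as an option and used automatically
when signals are absent (e.g. tables imported from the peptide-summary
dialect, which carries no intensities). No normalization, outlier
trimming or log transformation is applied anywhere in the rollup: the
median is the only robustness device, by design.

The default frequency threshold equals the replicate count (5): only
ubiquitous peptides quantify. The threshold is exposed (`min_frequency`)
precisely because the reliability/coverage trade-off is the interesting
dial: lowering it admits more peptides at the cost of pooling
less-replicated ratios.

## Method agreement

`bland_altman()` works on raw paired differences $d_i = y_i - x_i$ (test
minus reference): bias $= \bar d$, and 95% limits of agreement
$\bar d \pm 1.96\, s_d$ with the classic normal multiplier, not a
t-quantile — the convention of the original method, and the arithmetic
that reproduces published limits from published bias/SD pairs.
Differences are taken on the ratio scale with no log transform,
consistent with the workflow's no-transformation rule. `pearson_test()`
computes the product-moment correlation and the zero-slope t test
($t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided); internally it delegates to
`stats::cor.test`, and the test suite checks it against the explicit
formula to $10^{-12}$. Pairs with a missing member on either side are
excluded before both statistics and reported as a count
(`excluded_pairs`), since mismatches where one method could not quantify
are informative about the methods, not about their agreement.
`normalize_reference()` implements the usual densitometry practice of
dividing reference measurements by a housekeeping protein per
(condition, replicate); it is the caller's decision, not an automatic
step.

## The synthetic-data generator

`simulate_dataset()` exists so that every stage is testable against known
truth without any external data. Per peptide and replicate it draws a
lognormal base intensity, applies the condition fold changes through the
replicate's (rotated) channel mapping, multiplies per-channel lognormal
noise, mixes channels through the panel's correction matrix, adds the
background floor, and drops channels at the missing-channel probability —
then writes both a spectrum containing the four reporter regions (sticks
or Gaussian profiles, plus a few distractor peaks) and the PSM row that
spectrum-level extraction + correction would produce from it. The two
representations are kept exactly consistent, which is what lets the test
suite assert that the spectrum-level and table-level pipeline entry
points agree.

Default conditions, chosen once as a realistic small experiment: 30
proteins × 3–8 peptides, five replicates with the rotating design,
peptide noise `sdlog = 0.12` (≈ ±13% per channel measurement, so ≈ ±17%
on a ratio — peptide-level scatter on top of which biological variation
between replicates of roughly ±25% emerges in the pooled ratios),
background floor 50 counts against a median base intensity of ~5000
(≈ 1–2% compression at ratio 2), 2% missing channels, and 5% each of
decoy, fragment and shared peptides. Identification scores are drawn from
two shifted normals (targets ~N(60, 15²), decoys ~N(18, 8²), truncated at
0) so the score filter separates but imperfectly — a handful of decoys
survive the score criterion and must be caught by the annotation
criterion, and a tail of genuine peptides is lost, as in real data.

Three modeled features deserve comment:

- **Ratio compression.** The additive floor $f$ turns a true ratio $a$
  into $(a s + f)/(s + f)$, strictly between 1 and $a$ for $a > 1$ —
  the same mechanism by which co-isolated background compresses real
  isobaric ratios. Compression is monotone in $f$, and the acceptance
  suite checks both the direction and the monotonicity on a floor grid.
- **Missing channels** produce an *empty* reporter window: zero signal,
  null ratio, discard by criterion 2. (A channel at the bare floor would
  instead produce an absurd finite ratio that nothing filters — precisely
  the pathology the null-ratio rule exists to prevent.)
- **Spike-in scenario.** `simulate_spikein()` fixes the truth at
  1.00 / 1.25 / 0.75 / 1.00 across conditions N1 / UP / DOWN / N2 — a
  25% increase and a 25% decrease against two unchanged channels — the
  classic standard-mixture benchmark for isobaric quantitation. Under a
  moderate floor the recovered medians stay ordered DOWN < N2 < UP while
  shrinking toward 1, which is the qualitative signature such benchmarks
  show on real instruments.

What the generator does **not** emulate: chromatographic co-elution and
co-isolation interference (background is a flat floor, not structured),
retention time, fragment-ion series (spectra contain only the reporter
region plus distractors), charge-state effects, and protein inference
ambiguity beyond the shared-peptide flag. Passing tests therefore
demonstrate the correctness of the algorithms under the stated noise
model — not instrument-level performance on real data.

Determinism is part of the generator's contract: all randomness flows
from the config seed through a scoped RNG (the global RNG stream is left
untouched), and equal seeds give byte-identical written datasets.

## Numerical conventions and degenerate inputs

- Window-boundary ties are inclusive (`|Δm| ≤ τ`).
- Median of an even count is the mean of the two central values
  (`stats::median`).
- Sample SD uses n−1 and is reported absent (`NA`) below two values.
- Text round-trips: protein reports are written at 9 significant digits
  (round-trip error < 10⁻⁶ relative); MGF peaks at 10.
- Empty inputs: an empty MGF yields an empty list; a header-only PSM
  table yields a zero-row table; an empty protein list writes a
  header-only report.
- Unreadable cells fail loudly with the row/line: silent coercion to NA
  is never used for malformed numbers, only for the declared null
  sentinels.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
configurations — 5–30 proteins, five replicates, hundreds of PSMs,
spectra of a few hundred peaks — chosen so the whole suite completes in
well under a minute while still exercising every code path (rotation,
all five discard reasons, missing channels, both peak shapes, both
dialects). All quantitative claims scale-independently: the exactness
checks (isotope round-trip 10⁻⁹, noiseless recovery 10⁻⁹, formula
oracles 10⁻¹²) do not become easier at small n, and the stochastic
checks (compression ordering and monotonicity) are seeded.

## Known limitations

- Only the 4-plex geometry ships as a default panel; the structures
  permit other panels but 8-plex/TMT masses and correction tables are
  not bundled.
- Protein grouping is by accession string; no parsimony inference.
- No FDR estimation: the score threshold is taken as given.
- RPA requires profile data; there is no peak-shape reconstruction from
  centroids.
- The comparison statistics assume roughly interval-scale ratios; no
  robust/regression-based agreement alternatives are provided.
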