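---
title: "Active-site comparative analysis and sequence-function relations"
author: "sitefunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-site comparative analysis and sequence-function relations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitefunc)
```

## Scope and model

`sitefunc` analyses an enzyme family through the lens of a single
reference structure. The user supplies (i) a family multiple sequence
alignment containing the template sequence, (ii) a *site scheme* — the
1-based template positions of the catalytic pocket's first-shell
residues, grouped into named functional clusters and annotated with the
residue expected in the template — and (iii) an enzyme × substrate
activity table in s⁻¹. From these the package derives per-sequence
residue states at every pocket position, per-clade diversity profiles,
cluster-level property aggregates for candidate selection, and
property–activity correlations that nominate mutagenesis hot spots.

The statistical model behind the correlation analysis is deliberately
minimal: activities are assumed multiplicative, so all statistics operate
on log₁₀ rates, and the effect of a pocket position is summarized by the
linear association between a numeric residue property and log activity
across the family. With family sizes of 5–50 enzymes, anything richer
than a univariate correlation per (position, substrate) plus a combined
(summed) property regression would overfit; the package therefore
computes exactly those two views and is explicit about their
limitations (confounded positions, phylogenetic non-independence; see
*Limitations*).

## Position mapping

`buildPositionMap()` records one (template position, alignment column)
pair per non-gap template character. Both coordinates are 1-based —
template positions because crystal-structure numbering is 1-based, and
columns because that is the natural indexing in R; all user-facing
reports use the same convention, so there is no hidden offset.
`renumberPosition()` converts template numbering to any homolog's
numbering through the shared column, returning `NA` when the homolog has
a gap in that column (a gap is never silently converted into a
neighbouring residue number).

`extractSiteStates()` verifies, by default, that the template row of the
alignment carries exactly the residues the scheme declares (e.g. Gly at
392). This sanity anchor catches the two failure modes that silently
corrupt every downstream number: off-by-one numbering and anchoring on
the wrong sequence. It can be disabled (`checkTemplate = FALSE`) when a
close homolog serves as the template.

A homolog's gap at a scheme position is stored as the distinct state
`"-"`. Gaps and the ambiguity state `X` are excluded from diversity
counts, make a sequence ineligible for property aggregation and
candidate criteria, and drop the enzyme from correlations at that
position. They are never imputed and never scored zero — a zero volume
would be a fictitious, maximally small residue.

## Property scales

Three published tables ship as defaults, one per axis the analysis needs:

| scale | table | units | default role |
|---|---|---|---|
| `volume` | Zamyatnin (1972) total residue volume | Å³ | size of T-, H-, A-cluster residues |
| `hydropathy` | Kyte & Doolittle (1982) | — | hydrophobicity checks |
| `polarity` | Grantham (1974) | — | W-cluster polarity |

The choice of table is a genuine design freedom (size-correlation
results are robust to swapping volume tables, which are mutually
correlated at r > 0.98); the citation is recorded in the scale object
and any axis can be replaced via `propertyScale()` or a YAML file. The
shipped hydropathy and polarity values are cross-checked cell-by-cell
against the AAindex database in the test suite; the volume table against
an independent transcription of the published table.

## Diversity, aggregation and selection

`diversityProfiles()` computes residue frequencies per (position, clade);
frequencies are over non-gap states and always sum to 1.
`aggregateProperty()` defaults to the **sum** aggregator because the
combined volume of a residue triple is what constrains a substrate
channel; `mean` and `max` are available. `selectCandidates()` evaluates
user criteria ("T-cluster volume sum ≤ t") and returns a deterministic
ranking: by the first criterion's aggregate (ascending for `<=`,
descending for `>=`), ties broken by sequence ID.

## Phylogenetic context

Distances are protein p-distances (mismatch fraction), with pairwise
deletion of gapped column pairs by default and complete deletion as an
option — at the within-family identities this package targets (50–80%),
p-distances are monotone in evolutionary distance and sufficient for
clade reading. Trees come from neighbor joining; on additive matrices
the reconstruction is exact (the test suite verifies path lengths to
1e-9). Negative NJ branch estimates, which can occur on non-additive
input, are clamped to zero with the deficit moved to the sibling edge,
preserving path lengths through the parent node. Clades are assigned by
nearest characterized reference (path length, ties to the
lexicographically first clade name). This nearest-reference rule is a
simplification: it does not enforce monophyly, and a reference sitting
on a long branch can attract leaves from a neighbouring subclade.
Maximum-likelihood inference and bootstrap support are out of scope.

## Correlation analysis

`positionActivityCorrelation()` computes the Pearson product-moment
correlation between property values and log₁₀ activity. Pearson is the
package's choice because the combined-volume displays the analysis is
built around are linear in log space; a Spearman option is available for
robustness against single-enzyme leverage. Each result carries an
explicit status:

* `ok` — r is defined, computed over `nUsed ≥ 3` enzymes. Two points
  always give |r| = 1, so a 2-point correlation is noise by
  construction and is reported as `insufficient` instead.
* `conserved` — the property is constant across the used enzymes
  (≥ 2 of them). No correlation exists; heatmaps render these cells
  neutrally but exports keep the status string, never a numeric 0.
* `insufficient` — fewer than 3 usable pairs, or (rare) the activity
  side is constant so the coefficient is 0/0. The activity-constant case
  is classed as insufficiency rather than conservation because it says
  nothing about the residue.

Below-detection handling defaults to **exclude**: flooring places all
inactive enzymes at one artificial log-activity value and fabricates
leverage points exactly where the data are least informative. The
`floor` policy (log₁₀ of the detection floor, cells flagged) exists for
sensitivity analyses.

`hotspotRanking()` ranks positions by max |r| over substrates passing
`minAbsR` (default 0.5) and `minN` (default 3), ties by mean |r|, then
position number. Conserved positions can never rank.

## Kinetics and screening

`fitKinetics()` fits, by Levenberg–Marquardt nonlinear least squares,
one of: Michaelis–Menten v = k~cat~·S/(K~M~+S); substrate inhibition
v = k~cat~·S/(K~M~+S+S²/K~i~); Hill v = k~cat~·Sⁿ/(K~M~ⁿ+Sⁿ). These
three cover the rate behaviour reported for flavin-dependent phenol
oxidases, and additional laws can be registered at run time. Interfaces
are fixed to µM and s⁻¹. Determinism: starts come from a fixed
data-derived grid (K~M~ from the min/median/max concentration, k~cat~
from max(v)·{1, 1.5}), tried in a fixed order, best converged RSS wins;
parameters are bounded positive; standard errors come from the local
curvature. Noiseless synthetic data are recovered to solver tolerance
(≤ 1e-6 relative) for all three models, and a 200-replicate simulation
at 5% multiplicative noise and 8 concentrations bounds the median
|relative K~M~ bias| at 0.10 — a bound fixed once from that simulation,
not tuned.

`normalizeScreen()` maps raw plate activities to
(raw − mean blank)/(mean wildtype − mean blank): blank ↦ 0,
wildtype ↦ 1, affine-invariant in the raw signal, requiring ≥ 2 wells of
each control. `callHits()` thresholds the score (≥ threshold > 1),
descending order. The assay chemistry (absorbance calibration) is out of
scope; the input is already a rate-like signal.

## The synthetic-family generator

`generateFamily()`/`generateActivities()` exist so that the whole
pipeline — mapping, extraction, correlation, ranking — can be validated
end to end with known ground truth. The generator emulates the
*statistical* structure the analysis assumes, not evolutionary realism:

* a random ancestor; clade founders diverge at 2× the within-clade
  substitution rate (capped at 1), members at 1×, independently and
  uniformly per position — no rate heterogeneity, no codon model, no
  selection;
* planted positions are overwritten with states drawn uniformly from a
  chosen residue set, decoupled from the phylogeny;
* log₁₀ activity = baseline + Σ slope·property(state) + Gaussian noise;
  rates under the detection floor become not-detected;
* optional uniform indels (never in the template) exercise gap handling.

Defaults mirror the intended use case: 8 family members over three
clades, substitution rate 0.15 (within-clade identities around 70–85%,
matching a family selected at 50–80% identity), noise sd 0.2 log units
(mid single-digit percent rate CV compounded with between-substrate
variability), detection floor 1e-3 s⁻¹. All randomness flows through the
spec's single seed; identical seeds give bit-identical families, and the
caller's RNG state is untouched.

Because planted couplings are noise-free linear signals at decoupled
positions, passing the recovery tests shows the machinery is correct —
it does **not** show that real families, where positions covary along
the phylogeny and activities are measured with structured error, will
yield correlations this clean.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 100
random fixtures per brute-force-oracle comparison (agreement to 1e-12);
20 additive matrices of 4–8 taxa for NJ exactness (1e-9); 200 seeded
families of 8–50 sequences, alignment length 40, one planted hot spot at
signal-to-noise 4, for recovery (≥ 95% top-1 and universal sign
agreement required); 200 replicates for the kinetic noise simulation;
1000 random gapped alignments for mapping round trips. These sizes give
stable pass/fail behaviour across seeds while keeping a full run in tens
of seconds.

## Limitations

* Correlations treat family members as independent observations;
  phylogenetic autocorrelation inflates |r| when a property tracks the
  tree. Use the clade labels to inspect this; phylogenetic regression is
  not implemented.
* One position at a time: compensating substitutions across positions
  are only visible through the combined-property view the user requests.
* The nearest-reference clade rule does not enforce monophyly.
* Property scales are global residue summaries; they ignore
  conformation and context (a buried Phe and an exposed Phe score the
  same volume).
* NJ on p-distances is a pragmatic tree for clade reading, not a
  publication-grade phylogeny.
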