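---
title: "Fragment-ion index search: models, parameters and design choices"
author: "fionidx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-ion index search: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fionidx)
```

## The problem

Tandem mass spectrometry identifies peptides by fragmenting ionized
precursors and recording the m/z and intensity of the fragments. Database
search matches each experimental MS/MS spectrum against theoretical spectra
predicted from an in-silico digest of a protein database. The naive
formulation scores every spectrum against every candidate peptide; a
fragment-ion index instead sorts *all* theoretical fragment m/z values of
the database into one array, so that each experimental peak retrieves its
matching fragments (and hence votes for candidate peptides) with a pair of
binary searches. `fionidx` implements this engine at desk scale, in pure R,
with every stage testable against brute-force oracles and seeded synthetic
data.

## Pipeline

1. **Database construction.** Proteins are digested with the trypsin rule
   (cleave C-terminal to K/R, suppressed before proline), modification
   variants are enumerated, each form's neutral monoisotopic mass is
   computed, forms are stably sorted by mass (the rank is the peptide id),
   and all b/y fragment m/z values are generated and stably sorted.
2. **Spectrum preprocessing.** MS2 files are parsed; each spectrum is
   normalized and reduced to its K most intense peaks; out-of-range
   precursors are flagged. A dataset-level cache skips this stage on
   reruns.
3. **Database search.** For each query, a precursor-mass window selects
   candidate ids; each peak's fragment-window hits increment per-candidate
   b/y counts and intensity sums (the scorecard); candidates sharing enough
   ions are scored and histogrammed.
4. **Postprocessing.** Expectation values are extrapolated from the null
   histogram by a linear fit to the log survival, and results are written
   as TSV.

## Scoring model

With $n_b$ and $n_y$ the counts of shared b- and y-ions between a
theoretical and an experimental spectrum and $i_{b,j}$, $i_{y,k}$ the
matched experimental intensities, the similarity is the hyperscore

$$ h = \log(n_b!) + \log(n_y!) +
   \log\left(\sum_j i_{b,j}\right) + \log\left(\sum_k i_{y,k}\right). $$

A log term whose intensity sum is zero contributes 0, so a spectrum
matching only one series still gets a finite score. The factorial logs are
taken from a table memoized by the recurrence
$\log(n!) = \log(n) + \log((n-1)!)$ for $n = 0..120$, which avoids both
repeated computation and the 64-bit overflow that exact $n!$ hits at
$n \ge 21$; counts beyond the table raise a capacity error rather than
silently extending it. The logarithm base is a property of the table and
defaults to base 10 (the X!Tandem convention); the scoring formula itself
does not fix a base, so it is configurable rather than guessed
(`buildLogFactorialTable(120, exp(1))` switches every term to natural
logs).

For each query the scored candidates' hyperscores form a **null
distribution**: an integer histogram over unit-width bins
$\lfloor h \rfloor$. Normalized intensity sums below 1 can make $h$
slightly negative; such scores are clamped into bin 0 so the histogram
stays indexed by non-negative integers. The expectation value of the top
hit extrapolates the survival function $S(s) = \sum_{b \ge s} N[b]$:
$\log_{10} S$ is fitted by least squares over the tail bins and
$e = 10^{c + a\,h_{top}}$ with slope $a$ and intercept $c$. On a survival
that is exactly log-linear the fit recovers the generating slope and
intercept to machine precision, which is how the implementation is tested.

### Tail window and gating

The reference for the linear tail fit does not pin down the exact window,
so this package defines it as: all bins strictly above the histogram mode
(ties broken to the smallest bin) that still have nonzero survival, with at
least `minTailPoints = 4` usable bins required and a strictly negative
fitted slope; otherwise the e-value is undefined and carries a reason code
(`insufficient_hits`, `degenerate_tail`, `nonnegative_slope`). E-values are
only computed when at least `minHits = 4` candidates were scored. The null
distribution is built from candidates *after* the shared-ion candidacy
filter; that choice (rather than all window candidates) is flagged in the
code and configurable by adjusting `minShared`.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `deltaM` | 1 (closed) / 100–500 (open) | Da | precursor neutral-mass tolerance, both boundaries inclusive |
| `deltaF` | 0.01 | Da | fragment m/z tolerance |
| `minShared` | 4 | ions | minimum shared b+y ions for candidacy |
| `minHits` | 4 | candidates | minimum scored candidates for an e-value |
| `k` | 100 | peaks | top-K peaks retained per spectrum |
| `maxCharge` | 3 | — | fragment charges generated 1..3, independent of precursor charge |
| missed cleavages | 2 | — | tryptic digest depth |
| peptide length | 6–46 | residues | filter on the unmodified sequence |
| peptide mass | 500–5000 | Da | filter on each modified form |
| precursor charge | +1..+4 | — | spectra outside are flagged excluded |
| `maxVarMods` | 5 | sites | cap on variable modifications per peptide |

Masses are monoisotopic throughout (water 18.01056, proton 1.00728, residue
masses to five decimals); I and L share 113.08406 Da but are never
collapsed. The tolerance windows are symmetric and inclusive on both
boundaries — candidates sitting exactly on a boundary are a classic source
of cross-implementation score discrepancies, so the convention is explicit
and the window queries are property-tested against linear scans, including
`delta = 0` boundary cases.

## Design choices where the design was open

- **Stable sorts everywhere.** Peptides tie-broken by canonical input
  order; fragments with equal m/z keep generation order, so entries from
  one peptide stay adjacent. Any stable sort satisfies the contract (R's
  radix sort is used); the adjacency invariant is asserted in tests.
- **Tie-breaking.** Equal top hyperscores resolve to the smaller peptide
  id. Because ids are mass ranks with a deterministic tie rule, repeated
  runs are bit-identical; this is tested by engineering exact ties from
  duplicated peptides.
- **Match counting.** Each (experimental peak, fragment entry) pair counts
  once, even when one peak matches several entries of the same peptide; no
  per-peak cap is imposed. The brute-force oracle applies the identical
  rule, which is what makes bit-for-bit equivalence testing meaningful.
- **Floating-point m/z.** Fragment m/z values are stored as doubles and
  queried with tolerance-window binary search; no integer binning. Window
  membership is decided by the predicate `|x - q| <= delta` itself, so the
  binary-search path cannot disagree with a linear scan at boundaries.
- **Digestion order of filters.** The length filter applies to the
  unmodified sequence, the mass filter to each modified form; both bounds
  are stated without an order by the settings they mimic, so the choice is
  documented and configurable via `digestParams()`.
- **Proline rule.** On by default, with a flag, since digestion tools
  differ.
- **Normalization.** The preprocessing contract says "normalized" without
  a formula; the default scales the base peak to 100 (idempotent, so
  re-preprocessing is a no-op), with `sqrt` and `identity` options. The
  rule is recorded in the cache sidecar so changed settings force
  re-processing.
- **`minShared` counts b and y jointly**, not per series; a per-series
  variant would only need a different aggregation in the scorecard.

## The synthetic-data generator

`generateFasta()` builds proteins as concatenations of tryptic segments
(5–40 non-K/R residues capped by K or R), so every protein is guaranteed at
least one peptide in the 6–46 length window. `generateSpectra()` emits each
peptide form's complete singly-charged b/y ladder with rank-decaying
intensities (100/rank, so top-K selection and the intensity sums in the
hyperscore are exercised non-trivially), plus uniform noise peaks rejected
within `2 * deltaF` of any signal peak — ground-truth matched-ion counts
are therefore exact. An optional precursor mass shift emulates an
unanticipated modification for open-search tests. Everything is
deterministic under the spec's seed.

What the generator does **not** emulate: realistic fragmentation intensity
patterns, missing ladder ions, isotope envelopes, chimeric spectra,
calibration error, or decoy-like sequence composition. Passing recovery
tests on these fixtures demonstrates the correctness of the indexing,
matching, scoring and statistics machinery — not identification
sensitivity on real instrument data.

## Problem sizes and verification

The test suite verifies the indexed search against a naive all-pairs
scorer (bit-identical PSM id, hyperscore, ion counts and null histogram)
over randomized databases of up to ~60 peptide forms and precursor
tolerances of 1, 100 and 500 Da; window queries against linear scans over
thousands of random draws; digestion against exhaustive cleavage-site
enumeration; modification-form counts against the closed form
$\sum_j \binom{m}{j}$; the tail fit against exactly log-linear survivals;
and end-to-end recovery (>= 99% required) on noise-bearing fixtures of
~100 spectra. These sizes keep the whole suite under two minutes on one
core while still exercising every code path; the same properties hold at
larger sizes by construction (the index is exact, not approximate).

## Known limitations

- Top-1 PSM per spectrum only; no decoys, FDR, protein inference or
  rescoring.
- b/y series only by default (the data model carries a series field, but
  a/c/x/z generation, neutral losses and isotope peaks are not
  implemented).
- Semi-tryptic and non-specific digestion, N-terminal methionine clipping
  and terminus-specific modifications are out of scope.
- mzML/mzXML must be converted to MS2 upstream.
- The e-value model is the linear tail fit only; extreme-value (Gumbel)
  fitting is a possible extension hook, not implemented.
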