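---
title: "Methods: ex situ gap analysis and climate-change prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ex situ gap analysis and climate-change prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwrgap)
```

`cwrgap` audits how well a crop's gene pool — the crop itself plus its
wild relatives, tiered by crossability into primary, secondary and
tertiary pools — is represented in genebank collections, and combines
that audit with ensemble niche modelling to rank taxa for collecting.
This vignette is the package's own account of the methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical choices that make results reproducible.

## The registry and passport statistics

The unit of ex situ conservation is the accession. Passport data follow
the Multi-Crop Passport Descriptors (MCPD), so the parser consumes
comma- or tab-delimited tables with MCPD headers and tolerates the
inconsistencies of aggregated catalogues: unknown columns are ignored,
unparseable `ORIGCTY` entries degrade to "unknown origin" with a warning
(the record still counts toward totals), and duplicated
`(INSTCODE, ACCENUMB)` pairs are an error rather than a silent double
count.

Names are the main source of friction between an inventory and passport
data. The registry therefore indexes every canonical name *and* every
known synonym, and falls back to authority-stripped matching
("*Brassica cretica*" matches "*Brassica cretica* Lam.") because passport
rows frequently omit authorities; fallback matches are flagged. Subtaxon
text is ignored when tallying — infraspecific information is too
inconsistently populated to be load-bearing — except where the registry
itself lists a trinomial, which is then matched first. Ambiguous
authority-stripped forms are never resolved.

Two statistics drive everything downstream:

* `total_accessions` — all records resolving to the taxon;
* `native_collected` — records whose origin country lies in the taxon's
  native range *and* whose status marks them as collected material.

MCPD has no single field that operationalises "collected material". The
default is `COLLSRC` in 10–19 (wild/collecting sources) or, when
`COLLSRC` is absent, `SAMPSTAT` in 100–199 (wild biological status). Both
code sets are arguments of `is_collected()`; this is a documented,
configurable convention, not a claim about how any particular catalogue
is populated. Records with unknown origin never count as
native-collected — the conservative choice, since the statistic is meant
to measure demonstrated coverage of the native range.

Percentages (tertiary-pool under-representation fractions, per-taxon
native-collected shares) are rounded half away from zero to integers,
and range changes to one decimal, matching how such tables are printed;
base R's round-half-even would disagree on exact halves.

## Grid, cleaning and spatial thinning

The analysis lattice is a 2.5-arc-minute grid (roughly 4 × 4 km cells in
mid-latitudes) anchored at its north-west corner; cells are half-open
and indices zero-based, with `row = floor((lat_max − lat)/res)` and
points on the extreme east/south boundary clamped into the last cell.
The default study region is the bounding box 32°W–62°E, 20–72°N — Europe
and the countries bordering the Mediterranean — and is configurable, as
the exact polygon of any given study rarely is published.

Occurrence cleaning rejects records with missing or non-numeric
coordinates, coordinates outside the valid lon/lat domain, and records
outside the region, each with a logged reason. Multiple records per cell
collapse to one. Thinning then enforces "separated by at least one empty
grid cell": retained cells have pairwise Chebyshev distance ≥ 2. The
Chebyshev (8-neighbourhood) reading is the default because a diagonal
neighbour has no intervening empty cell; a rook (4-neighbour) mode is
provided since the alternative reading is defensible. The algorithm is a
greedy row-major scan keeping a cell iff it conflicts with no kept cell:
deterministic (no RNG, no tie ambiguity), idempotent, and maximal — no
rejected cell can be re-added. Greedy thinning does not maximise the
*number* of retained cells globally; determinism and auditability were
preferred over optimality. Taxa with fewer than `min_cells = 10` thinned
cells are excluded from modelling ("insufficient records"); ten is a
pragmatic floor below which model skill estimates are meaningless, and
it is configurable.

## The ensemble niche model

Presence-only modelling contrasts presences with pseudo-absences:
uniform draws, without replacement, from valid non-presence cells; three
sets, each the size of the presence set, by default. The ensemble has two
member families, deliberately the smallest roster that still exercises
consensus, weighting and thresholding:

* **Climate envelope** (surface range envelope): per-layer bounds at the
  *q*-th and (100 − *q*)-th percentiles of presence values (default
  *q* = 2.5, trimming outlying presences; *q* = 0 gives the exact
  support). Suitability of a cell is the fraction of layers within
  bounds.
* **Logistic regression**: a binomial GLM (`stats::glm`) of presence
  against layers standardised over the training cells, one member per
  pseudo-absence set. Each standardised layer also enters squared by
  default, the usual regression-SDM response shape that permits unimodal
  suitability; constant layers are dropped with a warning, and under
  complete separation the coefficient vector is rescaled to a magnitude
  cap and flagged rather than left divergent.

Members are scored on a common pool (presences plus the first
pseudo-absence set) with repeated random evaluation subsets (default
30 % of items, 5 repetitions): TSS maximised over candidate thresholds —
midpoints of sorted unique scores plus 0 and 1, ties resolved toward the
lower threshold — and AUC by the rank statistic. The reported threshold
is the mean of per-repetition maximisers. Members with TSS below the
admission cutoff (default 0.7) are dropped; admitted members are weighted
by TSS, normalised to sum one. Consensus suitability is the weighted mean;
the binary map applies each member's own threshold and takes the weighted
majority (≥ 0.5). Masked cells are never predicted. None of the ensemble
constants (pseudo-absence counts, split ratio, repetitions, cutoff, *q*)
is prescribed by the underlying methodology in citable form; all are
exposed as configuration and echoed into the run manifest together with
every seed.

The model deliberately ignores dispersal ability and geographic
barriers: projected "full-migration" ranges assume any newly suitable
cell is reachable, and "no-migration" ranges assume none is, bracketing
reality. Range metrics are pure set functions of cell sets: with current
range \(C\) and future range \(F\),
\(\Delta_{mig} = 100(|F|-|C|)/|C|\) and
\(\Delta_{nomig} = 100(|F\cap C|-|C|)/|C|\), so
\(\Delta_{nomig}\in[-100,0]\) and \(\Delta_{nomig}\le\Delta_{mig}\)
always. The no-migration range is *defined* as the intersection of
current and future suitable sets. The projection horizon is nominally
2070; it is a label on outputs, not a model input.

## Raster format

Environmental stacks are read and written as ESRI ASCII grids — a
plain-text header plus value rows — with layer names taken from file
stems and the mask from the format's no-data value. Cells missing in any
layer are masked in all layers, so every modelled cell has a complete
predictor vector. Which seven bioclimatic and two soil variables a user
supplies is configuration: layer identity is data, not a package
constant.

## Collecting priorities

The priority classifier is a rule cascade evaluated in a fixed order,
with every assignment reporting the rule that fired:

1. **excluded** — cultivated or partly cultivated taxa (collection
   statistics cannot distinguish natural occurrences from escapes),
   taxa outside the study area, and explicitly listed exclusions;
2. **high** — Red List EN or NT (the threat override: it beats every
   other field);
3. **high** — at most 2 native-collected accessions;
4. **high** — projected RCP 8.5 no-migration loss ≥ 60 % with fewer than
   50 native-collected accessions;
5. **low** — at least 100 native-collected accessions;
6. **medium** — otherwise.

The pessimistic scenario without migration is the deliberate basis for
rule 4: recent warming rates make the optimistic scenario the less
likely guide for collecting decisions, and the no-migration bound is the
risk-averse one. The numeric thresholds (2, 60 %, 50, 100) are the
package's defaults, chosen so that the cascade reproduces the published
priority list for the rapeseed gene pool exactly — the original rule
document is not available in citable form — and the regression test
pins all 38 published assignments. Every threshold is a `rule_config()`
argument. Two wild taxa (*Sinapis alba* L., *Raphanus raphanistrum* L.)
are absent from the published list without a stated reason; the default
configuration records this as an explicit exclusion list rather than
guessing a rationale. Unmodelled taxa can still reach high priority
through rules 2 and 3; for them rule 4 simply cannot fire.

## Synthetic data: what passing tests do and do not show

The generator builds gradient-plus-noise landscapes (west–east and
north–south linear gradients, optional Gaussian noise, optional masked
cells), a known niche in one of two truth modes, a future stack shifted
by prescribed per-layer deltas, and passport files expanded from
per-taxon/per-country/per-status count specifications. Every generator
is a pure function of its specification and seed.

* **Envelope truth** (hard bounds) gives exact oracles: the truly
  suitable cell set is computable by direct evaluation under any shift,
  so `expected_range_change()` returns analytic range changes, and
  noiseless sampling guarantees a *q* = 0 envelope fit recovers the
  bounds of the sampled support exactly.
* **Gaussian truth** exercises realistic misspecification: no member of
  the reduced ensemble matches the generating model.

The recovery test fits on a 200 × 200 landscape with 1000 presences
drawn noiselessly from a rectangular niche of several thousand cells —
dense enough that the extreme-valued rows and columns of the niche are
sampled with overwhelming probability, which is what makes the
exact-bounds assertion meaningful. The end-to-end check runs simulate →
clean → grid → thin → fit → project → range change against the analytic
oracle within ±5 percentage points.

What this does *not* show: real occurrence data are spatially biased,
real climate surfaces are not additive shifts of the present, real
niches are not boxes, and taxonomic noise in real passport data exceeds
anything the generator emits. Passing tests demonstrate that the
machinery is correct and self-consistent, not that any particular
real-world projection is right. Accordingly, the published range-change
table ships as a verbatim fixture — its inputs (GBIF downloads,
WorldClim and soil layers, the full multi-algorithm ensemble) are out of
package scope — and is checked only for structure and for the
set-theoretic invariants every valid table must satisfy.

## Numerical and degenerate-input choices

* Rounding is half-away-from-zero throughout reported tables.
* Candidate thresholds always include 0 and 1, so constant score vectors
  evaluate cleanly (TSS 0, AUC 0.5) instead of erroring.
* Single-class evaluation splits are redrawn up to a bounded retry count,
  then error.
* `fit_envelope()` requires ≥ 2 presences; empty presence sets are
  errors, as are empty current ranges in the change metrics (the
  denominator vanishes).
* An all-constant predictor matrix degrades to an intercept-only
  logistic member predicting the prevalence.
* Registry loading fails loudly on duplicate canonical names, synonym
  collisions and empty sources; unresolvable country names warn and are
  reported, not dropped silently.
* Problem sizes in the test suite (grids up to 200 × 200, hundreds to a
  thousand presences, tens of brute-force randomised cases per property)
  were chosen as the smallest scales at which the properties under test
  are non-trivial.

## Known limitations

Country-level native ranges are a coarse gap currency — a large country
with one collection site counts as covered. The reduced two-family
ensemble brackets, but does not reproduce, multi-algorithm consensus
modelling. Thinning is greedy rather than optimal. GeoTIFF input is not
supported; grids must be supplied as ESRI ASCII. Subtaxon-level
accounting is intentionally out of scope.
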