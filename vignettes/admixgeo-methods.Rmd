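---
title: "admixgeo: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{admixgeo: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixgeo)
```

# The data model

The unit of analysis is an admixture proportion vector: K non-negative
fractions summing to 1 that describe an individual's genome as a mixture of
K putative ancestral components (K = 9 throughout the standard analyses;
the component labels are treated as opaque ordered names). Vectors are
validated on load — non-negative entries, row sums within 1 ± 10⁻⁴ — and
then renormalized to sum exactly to 1. The tolerance absorbs the rounding
of admixture software that prints six decimals without masking corrupt
rows; renormalization is idempotent, so repeated load/write cycles are
stable.

A *reference panel* groups individuals into named populations; each
population carries the renormalized arithmetic mean of its members'
vectors and one geographic centroid (WGS84 decimal degrees; degree-minute
strings such as `40°9'N` are converted by minutes/60 on input). Region
boundaries are GeoJSON polygons; haplogroup tables are per-individual
mtDNA/Y haplogroup strings with cohort labels.

# Genetic admixture distance

The genetic distance d between an individual **x** and a population P is
the *minimal* Euclidean distance between **x** and the vectors of P's
members; distances are reported in percentage points (fraction × 100).
When an individual is scored against its own population, it is excluded
from the target set, so within-population diversity is never contaminated
by self-matches. Cohort comparisons return both the median ± SD (the
primary convention) and the mean of the per-individual minima, since
either summary appears in published practice. Distance distributions are
compared with the two-sample Kolmogorov–Smirnov test in its asymptotic
form (`stats::ks.test`, effective sample size n₁n₂/(n₁+n₂)); an exact
small-sample p-value is deliberately not computed, as the analyses only
use coarse significance thresholds. The similarity graph connects pairs
with pairwise d strictly below 0.75% (strict `<`, matching the convention
of the figure it reproduces).

# Origin prediction

Given a panel of N populations, a query's distances dᵢ to the population
*mean* signatures are ranked (ties broken by panel order, so results are
deterministic), and the M = 10 genetically nearest populations are
retained. If d₁ = 0 the best population's centroid is returned exactly.
Otherwise population i receives weight wᵢ = (d₁/dᵢ)², normalized to sum
to 1, and the prediction is the spherical weighted centroid: the weighted
mean of the unit-sphere 3-vectors of the M centroids, renormalized and
converted back to latitude/longitude.

The genetic-to-geographic conversion of the original GPS tool is not
published in reusable form; the inverse-square relative weighting was
adopted here because it is exact at panel vertices, continuous in the
query, scale-free in d (multiplying all distances by a constant changes
nothing), and it confines predictions to the spherical convex hull of the
best-matching populations. The exponent is a parameter (`exponent`,
default 2); larger values snap predictions toward the single best
population. Whether the original tool weighted population means or nearest
members is equally unrecoverable; means are used here, and the strategy is
isolated in `predictOrigin()` should an alternative be needed.

Evaluation uses leave-one-out at the *population* level: the test
individual's entire population — members and centroid — is removed before
prediction. This is deliberately harsher than per-individual leave-one-out
and is the scheme the curation loop optimizes. Accuracy is the fraction of
individuals whose prediction falls within T km (T = 250, 500) of their
home region, where the distance to a region is 0 inside and otherwise the
minimum great-circle distance to its boundary.

## Geometry

All point distances are haversine great-circle distances on a sphere of
radius 6371.0 km; at the 250-km decision scales used, the ellipsoidal
correction (≲ 0.3%) is irrelevant. Point-to-boundary distances are
computed *exactly* per boundary arc (cross-track distance where the
perpendicular foot lies on the arc, else the nearer endpoint) rather than
by the cruder approach of densifying edges and scoring nearest vertices;
the exact form reproduces analytic cases (a point 1° east of a meridian
edge at the equator is 111.1949 km away) and agrees with a 0.01°
dense-sampling oracle to well under 1 km. Point-in-polygon tests run on
the (lon, lat) plane with GeoJSON ring semantics (first ring boundary,
later rings holes); boundary points count as inside. Antimeridian-crossing
polygons and panels are not supported.

# Panel curation

Two mechanisms keep a reference panel honest:

**Subpopulation splitting.** Populations with at least 4 members are
examined by k-means (k = 2, Euclidean, 5 restarts seeded `seed+0 …
seed+4`, best within-cluster sum of squares kept). The acceptance
statistic is BSS/TSS, the between-cluster share of the total sum of
squares — bounded in [0, 1] and scale-free, which makes 0.9 a meaningful
threshold. A split is accepted when the ratio is ≥ 0.9: clusters with more
than 3 members become subpopulations (`pop-1`, `pop-2`) with centroids at
their members' mean origins where coordinates exist; clusters of ≤ 3
members are treated as outliers and removed. If no cluster exceeds 3
members, the population is left unchanged. The printed description of this
procedure in the source literature states the acceptance inequality in the
opposite direction ("< 0.9"), which would accept precisely the *unseparated*
clusterings; the package defaults to the internally consistent direction
and offers `acceptBelowThreshold = TRUE` to reproduce the printed text
verbatim. Note that for very low-dimensional admixture vectors (K = 2, an
effectively one-dimensional simplex) 2-means on pure noise can pass the
ratio rule; at the working dimension K = 9 this is rare.

**Retention loop.** Each round compiles a panel (with splitting), runs
population-level leave-one-out, and marks an individual correct when its
prediction is inside its home region or < 200 km outside. Incorrect
individuals are dropped — removal is the round's action, and the loop
*stops* once the correct rate exceeds 80% (the final round's filtering is
still applied; a round that removes nobody while below target also stops,
since the procedure is then at a fixed point). A `maxIter = 20` guard
bounds the loop on adversarial input. Populations named on a keep-list are
exempt from removal: geographically extreme populations systematically
fail the retention criterion — with all their neighbours on one side, the
weighted centroid is necessarily pulled inward — and the historical
analyses likewise re-added their extreme populations by fiat. Populations
that lose all members are dropped with a warning.

# Spatial interpolation and native cohorts

The admixture field is a Delaunay triangulation of the population
centroids on the plate-carrée plane (x = lon, y = lat) with barycentric
linear interpolation of each component independently — the same
construction as 2-D scattered linear interpolation in numerical libraries.
Because each vertex vector sums to 1 and the interpolation is linear,
interpolated vectors sum to 1 up to float error; this is asserted at
10⁻¹⁰ and then renormalized. Evaluation at a vertex returns that vertex's
vector exactly; points outside the convex hull raise an error — no
extrapolation. The triangulation is a from-scratch Bowyer–Watson
implementation (panel sizes are tens of points, so the O(n²) insertion is
immaterial); no installed triangulation library was available, and the
implementation is oracle-tested against direct 3×3 barycentric solves.

"Native" cohorts are simulated by rejection-sampling coordinates uniformly
from a region's bounding box, accepting points inside both the region and
the hull (hard cap 10⁶ draws), and assigning each point the interpolated
signature — deterministic given the coordinate, as in the analyses this
emulates; an optional Dirichlet jitter exists but defaults off. The
standard cohort sizes are 100 or 200. Closest-group assignment supports
both a genetic metric (nearest member in admixture space) and a
geographic one (nearest member origin in km), because published usage is
ambiguous between the two; the caller chooses.

# The synthetic world

Restricted genotype data cannot ship with the package, so every
quantitative claim is exercised on a generative model with known ground
truth: K ancestral sources at map coordinates, component j at point p
proportional to exp(−dist(p, source_j)/λ_j), giving smooth continental
clines; population sites draw members from Dirichlet(α · expectation).

Defaults, chosen once as a realistic desk-scale analogue of a curated
West-Eurasian panel and not revisited:

| parameter | default | rationale |
|---|---|---|
| K | 9 | standard component count of the emulated analyses |
| λ | 1500 km | smooth clines spanning the map, several site spacings |
| α | 200 | per-component SD ≈ 2–3 points, visible within-population noise |
| sites | 25 on a jittered 5×5 grid | panel of ~25 populations |
| extent | lat 36–50, lon 16–38 | ~390–450 km neighbour spacing, the density of a curated continental panel |
| sources | 3×3 grid over extent +4° | each component peaks in a different map sector |
| samples/site | 16 | typical per-population sample size |
| home regions | 500-km squares | country-sized stand-ins for political boundaries |

A single master seed drives every stream (per-site draws, migrants,
haplogroup tables) through a deterministic seed derivation, so whole
experiments are byte-reproducible.

What the generator does *not* emulate: linkage and drift (vectors are
conditionally independent Dirichlet draws), admixture events (each site
sits exactly on the cline), uneven sampling density, and real political
geometry (squares, not borders). Passing recovery tests on this world
therefore demonstrates the correctness and internal consistency of the
pipeline — not the field accuracy of any historical inference drawn from
real panels.

On this world, population-level leave-one-out places ≥ 80% (in practice
~100%) of individuals within 500 km of their home region, migrants
simulated at panel sites are recovered with a median error under 300 km,
and curation with 10% planted mislabelled individuals (relabelled to a
site ≥ 800 km away, excluding the keep-list extremes) removes essentially
all plants while sparing ≳ 95% of clean individuals — the four grid-corner
sites play the role of the exempt geographic extremes. These are exactly
the quantities `scripts/acceptance.R` recomputes.

# Haplogroup statistics

Low-resolution grouping uses explicit prefix lists rather than a fixed
truncation depth, because published low-resolution labels mix depths (K1a
vs H1 vs HV). A haplogroup matches a prefix when it starts with it and the
match respects the nomenclature's alternating letter/digit levels: a
digit-final prefix must not be followed by another digit (H1 covers H1a1
but not its sibling H10), while a letter-final prefix may be (K1a covers
K1a9). Nested prefixes never double-count (set union). Printed notation
variants (e.g. a lineage cited under two names) are handled by passing
aliases as additional prefixes. Per-locus denominators count only
individuals with a call at that locus — females lack Y calls — so mtDNA
and Y percentages are comparable to per-locus published tables.

# Numerical and degenerate-input policy

- Ties in nearest-M selection and nearest-member assignment break by input
  order (stable), making every result deterministic.
- d₁ = 0 short-circuits to the best population's centroid (no 0/0 weights).
- All-identical member vectors define a split ratio of 0 (no split).
- Empty groups, empty panels, unknown regions/cohorts, out-of-hull and
  out-of-extent queries raise immediate errors naming the offender.
- Proportions are stored as fractions; percent appears only in reported
  summaries and file formats (`d_best` written with 2 decimals;
  coordinates at full precision, round-tripping to 10⁻⁶ degrees).

# Known limitations

- The weighting function is a principled reconstruction, not the original
  tool's unpublished regression; absolute predictions on real panels may
  differ from historical results even where rankings agree.
- Plate-carrée interpolation distorts at high latitudes and cannot cross
  the antimeridian.
- Population-level leave-one-out systematically penalizes hull-boundary
  populations (hence the keep-list); accuracy summaries should be read
  per-population before being read overall.
- The one-sample Kolmogorov–Smirnov variant and multi-origin decomposition
  of mixed individuals are out of scope.
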