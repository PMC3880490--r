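---
title: "Fragment-based shape signatures: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based shape signatures: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsig)
```

## The descriptor

A shape signature is a probability histogram harvested from a billiard-style
ray-trace bouncing inside a molecule's solvent-excluded surface.  Because the
specular billiard preserves the Liouville measure on the boundary (surface
area x cosine-weighted direction), the segment lengths of a long, well-mixed
trace sample the molecule's interior chord-length distribution — a compact,
alignment-free summary of 3D shape.  A "1D" signature is the histogram of
segment lengths; "2D" signatures are joint histograms of, per reflection, the
sum of its two incident segment lengths against the molecular electrostatic
potential (MEP) interpolated at the reflection point.  Two collapsed variants
keep only the sign of the potential (*reduced*) or its flipped sign
(*reduced inverted*, for complementarity matching against receptors).

The fragment-based extension partitions the molecule into ring-system-based
fragments and maintains a separate histogram per fragment (intra-fragment
segments) and per fragment pair (inter-fragment segments).  Two molecules are
compared by enumerating injective fragment mappings consistent with bond
connectivity and scoring each mapping with a segment-count-weighted average
of per-fragment L1 histogram distances,

$$S(q,t/M) \;=\; \frac{1}{C^q + C^t}\sum_{m \in M}
  \bigl(c^q_{x(m)} + c^t_{\mu(m)}\bigr)\,
  S\!\bigl(f^q_{x(m)}, f^t_{\mu(m)}\bigr),$$

where $S(\cdot,\cdot)=\sum_\mu|h^q_\mu - h^t_\mu|$ is the discretized L1
metric on normalized histograms (0 for identical, 2 for disjoint support),
$c$ are intra-fragment segment counts, and $C^q, C^t$ their sums over the
mapping.  Hits rank by ascending raw score; the similarity transform
$T(s) = 1 - \log_2 s$ is reported alongside for readability ($T(2)=0$,
$T(1)=1$).  Mappings need not cover all fragments: substructure matches are
deliberate first-class results, and the *unused fraction* — the percentage of
a molecule's intra-fragment segments lying in unmapped fragments — is
recorded so screening can discard matches that ignore too much of either
molecule (25% by default, mirroring typical screening practice).

## Fragmentation

Heavy atoms and bonds form the molecular graph.  Ring closures are the edges
left out of a depth-first maximal spanning subtree; their number always
equals the cyclomatic number $E - V + C$, though which bonds close rings
depends on the traversal, so the traversal here is deterministic
(lowest-index bond seed, neighbors in index order).  The atoms lying on
simple paths between a closure's end points form a ring system; fused and
spiro systems sharing atoms merge.  Remaining non-ring components become
their own fragment when they border two or more ring systems, or when they
border one ring system and carry more than five heavy atoms; smaller
single-attachment substituents are absorbed into their ring system.
Hydrogens follow the heavy atom they are bonded to.  An acyclic molecule is
a single fragment, which makes single-fragment comparison reduce exactly to
the original unfragmented method.  Users can override all of this with a
plain-text `atom_index fragment_id` file (`load_fragment_assignment()`),
e.g. for polymers.

## Surface generation

The surface is the inward face of a 1.4 Å probe rolling over Bondi-radius
atom spheres.  `triangulate_surface()` extracts it as the zero level set of
a probe-erosion distance field on a regular grid: a point is inside the
surface when its distance to the solvent region (the complement of the
probe-inflated atom spheres) is at least the probe radius.  The distance is
the maximum of two lower bounds — the analytic penetration depth into the
inflated-sphere union, exact on all convex contact surface, and a voxel
Euclidean distance transform with a conservative half-diagonal correction
that captures probe erosion in concave grooves.  Polygonization uses
marching *tetrahedra* on the Freudenthal 6-tet cube decomposition, which is
free of the ambiguous configurations of classic marching cubes and therefore
watertight by construction; tests assert every edge is shared by exactly two
triangles and the Euler characteristic is 2 per genus-0 component.  Closed
shells with negative enclosed volume are interior cavities unreachable by
solvent and are dropped.

This grid construction was chosen over an analytic patch-by-patch Connolly
construction (spheres, tori, spherical triangles with trimming) as a matter
of robustness: the ray-trace statistics depend on the surface's geometry,
not on how it was tessellated, and the analytic route's self-intersection
surgery is a large subsystem whose failure modes are exactly the molecules
one cares about.  The cost is a smoothing of deep concave features on the
order of half a grid spacing (default 0.6 Å grid, median triangle edge
about 0.4 Å); the single-atom sphere area converges to $4\pi r^2$ at first
order in the spacing and is within 2% at a 0.4 Å grid.

Element classes follow the probe-contact count: the probe center is placed
one probe radius along the element's outward normal, and atoms whose
inflated spheres pass within a tolerance (matched to the grid spacing) of
that point are the touched set — one atom is contact surface, two saddle,
three or more reentrant, with 1/2/3 atoms assigned respectively and the
principal atom being the assigned atom closest to the element center
(lowest index on ties).  The MEP at surface vertices is the plain Coulomb
sum $\sum_i q_i / (\varepsilon\,|v - r_i|)$ in e/Å with dielectric 1 by
default; partial charges come from the input file when present, otherwise
from an in-package Gasteiger-type electronegativity-equalization (PEOE)
calculation, and a zero-charge mode supports pure-shape work.

## Ray-tracing

Rays start at the center of a random contact element (contact surface
cannot trap the launch) heading along the inward normal, and propagate by
specular reflection.  A uniform acceleration grid registers each element in
the cube(s) containing its corners — one to three cubes — and the ray walks
cubes with a 3D DDA.  Because registration is corner-based, the walk
inspects the full 27-cube neighbourhood of every cube it crosses and the
cube spacing is clamped to at least the longest mesh edge; any triangle
point is then within one cube of a corner, so the grid search provably
returns the same intersection as a brute-force scan over all elements (an
equivalence the test suite checks step for step over a 1000-reflection
trace).  Exact distance ties go to the lower element index; intersections
closer than $10^{-6}$ Å are rejected as self-hits and the launching element
is excluded for one step.  When propagation fails (a ray slipping through
the numerical seam between elements), the trace truncates at the last good
reflection, keeps its segments, and restarts from a fresh random contact
element; repeated failures from fresh starts abort with a mesh-quality
error.

### The perturbation and why it is Metropolized

A purely specular billiard can lock into periodic orbits (opposite parallel
faces; a sphere preserves its incidence angle forever), so each reflection
is perturbed randomly within a small cone around the ideal direction
(default 3°, exposed as `cone_angle`).  A perturbation drawn *uniformly*
over the cone, however, is a symmetric random walk in direction space whose
stationary distribution is uniform — not the cosine-weighted boundary
measure the billiard itself preserves.  On an analytic sphere this is not a
small effect: with a 3° uniform cone the mean segment settles near $0.98R$
instead of the chord-theorem value $4R/3 \approx 1.33R$, and on icosphere
meshes the mean sits 3–5% low whenever the cone angle is comparable to the
facet angular scale.  `trace()` therefore uses the uniform-cone draw as a
Metropolis proposal against the cosine-weighted measure: the candidate is
accepted with probability $\min(1, \cos\theta'/\cos\theta)$ and otherwise
the ideal specular direction is kept.  The composition of a
measure-preserving deterministic map with a Metropolis kernel targeting the
same measure preserves it exactly, so segment lengths sample the true
chord-length distribution: sphere and cube fixtures reproduce $4V/S$
(sphere $4R/3$, cube $2L/3$) within ~1% at $10^5$ segments, independent of
mesh resolution.  The exported `reflect()` primitive keeps the plain
uniform-cap behaviour (bounded deviation, uniform azimuth), which is also
what the perturbation's trapping-prevention role requires.

The default of $10^5$ segments per molecule was fixed once against the
stability requirement that two independently seeded signatures of the same
molecule differ by less than 0.05 in raw score on every per-fragment
histogram; measured self-scores on the toy set run 0.01–0.04.  Histogram
bin width defaults to 0.5 Å on the shape axis (0.025 e/Å bins clamped at
±0.5 with overflow bins on the full MEP axis); signatures are only
comparable when their bin parameters match, and every comparison entry
point enforces that.  A reflection with potential exactly zero falls in the
positive bin of the reduced axes by convention.  2D histograms attribute a
reflection to the fragment of its element's principal atom; when its two
incident segments tie it to another fragment the count moves to that pair's
inter-fragment histogram (the first differing neighbour decides if both
differ).  Inter-fragment histograms — typically around 20% of segments on
the multi-fragment toys, matching long-standing observations — are stored
and serialized but not scored; summing raw counts over all intra and inter
histograms reconstructs the unfragmented global histogram exactly, which
the tests assert bin for bin.

## Mapping enumeration

`enumerate_mappings()` starts from all single links and recursively extends
each in every way that keeps the mapping injective both ways and
connectivity-consistent (bonded query fragments must map to bonded target
fragments; nothing constrains non-adjacent ones), deduplicating by the
canonical link set.  Expansion is greedy: a mapping is kept only when no
single link can be added, so bare single links survive only when nothing
extends them.  The suite checks the result against a brute-force
enumeration of *all* injective consistent maps filtered to maximal ones,
for every path pair up to 4x4 and for star and triangle topologies.  For
linear (path) topologies the count of contiguous-interval mappings has the
closed form $mn + 2\sum_{k=2}^{\min(m,n)}(m-k+1)(n-k+1)$ — 85 at
$m=n=5$ — which `linear_mapping_count()` implements and the tests
cross-check by direct enumeration up to $m,n = 6$.  Among equal-score
mappings the ranking prefers more links, then the lexicographic link list,
so results are deterministic.

## The screening prefilter

Screening first shortlists candidates with a cheap bound computed from
*reduced records*: per-fragment shape-only histograms plus segment counts,
connectivity dropped.  For each query fragment the best (minimum) L1
distance to any target fragment is found, targets reusable.  Combining
these optima into the same count-weighted form as the full score over *all*
query fragments — the obvious construction — is **not** a lower bound on the
best mapped score: a maximal mapping may simply omit a query fragment that
matches everything badly, and in simulation such substructure mappings beat
that bound on 40% of random signature pairs.  The prefilter therefore uses
a conservative combination: the minimum over query-fragment *pairs* of the
weighted average of their two optima, with each weight pushed to the end of
its feasible range $[c^q_x + \min_\mu c^t_\mu,\; c^q_x + \max_\mu c^t_\mu]$
that minimizes the average.  Every maximal mapping carries at least two
links whenever both fragment graphs are connected with at least two
vertices (a single link always extends through any free neighbour), a
weighted average only decreases when restricted to its two smallest terms
with free weights, and each true link's distance is at least its fragment's
optimum — so the bound never exceeds any maximal mapping's score.  In the
degenerate cases where a one-link mapping can be maximal (single-fragment
query or target; a dominating query fragment against an isolated target
fragment) the single best optimum is also admitted.  The suite verifies
admissibility against the full mapped search on 200 random synthetic
signature pairs; the bound is tight (slack is exactly zero in the median
random pair) because the minimizing pair usually is the mapped pair.

## What the fixtures do and do not show

All tests run on generated fixtures: analytic meshes (icosphere, cube) with
known chord statistics, idealized toy hydrocarbons built from standard bond
lengths and angles, and random synthetic signatures.  The toys cover the
fragmentation cases — single rings, fused (naphthalene, a linear fused
tetracycle), linked (biphenyl), saturated (decalin), long and short
substituents, bridges bordering two ring systems — but they are planar-ish
single conformers of pure hydrocarbons: no conformational ensembles,
heteroatom chemistry, formal charges, or experimental geometry.  Passing
tests demonstrate the machinery (geometry, counting, scoring, bounds), not
retrieval performance on real screening libraries.

The 30-molecule self-retrieval library deserves one honest caveat: mapped
scoring rewards substructure matches by design, so a library containing
quasi-exact fragment-level homolog pairs makes self-retrieval ill-posed.
Concretely, a quaterphenyl query scores terphenyl at 0.032 — three
essentially identical ring fragments, 16% of the target unused — while its
own stochastic self-match scores 0.034.  That is the method working as
intended (it is how scaffold hopping surfaces close analogs), and it is why
the shipped library spans distinct sizes and topologies instead of nested
homolog series.

## Problem sizes and defaults

| parameter | default | notes |
|---|---|---|
| probe radius | 1.4 Å | water-sized probe |
| radii set | Bondi | editable text resource, selectable by name |
| surface grid spacing | 0.6 Å | median mesh edge ≈ 0.4 Å; sphere-area error ~2% |
| ray-trace segments | 100,000 | self-score < 0.05 between independent seeds |
| cone angle | 3° | Metropolized; any small value gives unbiased chords |
| acceleration grid | 1.0 Å | clamped to the longest mesh edge; speed-only knob |
| shape bin width | 0.5 Å | must match between query and database |
| MEP bins (full) | 0.025 e/Å, clamp ±0.5 | reduced axes: 2 sign bins |
| prefilter K / max hits / max unused | 20,000 / 5,000 / 25% | screening defaults |

Unit tests run traces of $10^4$–$10^5$ segments on meshes of a few
thousand triangles; the library-scale checks build sixty full signatures at
the default $10^5$ segments.  One toy signature takes a few seconds on one
core end to end.

## Known limitations

* The grid surface smooths concave features below roughly half a grid
  spacing and classifies elements by a tolerance-based probe-contact test;
  saddle/reentrant boundaries are fuzzy at the mesh scale (the class
  *fractions* are stable, which is what classification feeds: launch-point
  selection and atom assignment).
* Gasteiger-type charges cover common organic elements only and ignore
  formal charges; import charges from the source file for anything exotic.
* Exterior (receptor-pocket) tracing is not implemented; the interior
  tracer and the sign-inverted descriptor variant keep the interface ready
  for it.
* Scoring ignores inter-fragment histograms, as retained-but-unscored
  descriptor components.
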