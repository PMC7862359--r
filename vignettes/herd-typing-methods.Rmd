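---
title: "Herd typing from register data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herd typing from register data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `herdtyper`: how a one-year cattle-register extract becomes nine
herd-level variables, how self-organising maps support rule extraction,
how the 17-type decision tree is defined, and what the synthetic register
generator does and does not emulate.

## The register model

A register is two tables. The **animal table** carries one residency row
per animal: identity, sex, own/dam/sire breed codes, birth date, an
ever-calved-by-September flag, and the entry/exit dates of its current
herd spell (an open exit means the animal is still present). The
**movement table** carries one row per transfer in the study year: animal,
date, source herd, and a destination that is either another herd or a
terminal code (`SLAUGHTER`, `EXPORT`). Marts are not modelled as holdings;
a movement is herd-to-herd or herd-to-terminal.

Three snapshot dates (1 January, 1 May, 1 September — chosen around the
seasonality of calving) define herd membership through a *half-open*
interval: an animal is a member on date $d$ iff
$\text{entry} \le d$ and ($\text{exit}$ open or $\text{exit} > d$). An
animal moving on a snapshot day is therefore counted exactly once, in the
destination herd.

**Breed typing.** An animal is *dairy* if both dam and sire belong to the
six-breed dairy list, *beef* if both belong to the 25-breed beef list,
*cross* for one of each, and *other* whenever a parent is missing or
unlisted. *Other* animals count in herd-size denominators but in no
breed-proportion numerator; the register is silent on their pedigree and
guessing would bias the proportions.

**Birth herd.** Two transport variables need each animal's birth herd,
which a one-year window cannot always attest. The package uses the
earliest evidence available: the residency herd when
$\text{entry} = \text{birth}$, otherwise the source herd of the animal's
earliest movement in the year, otherwise unknown (and the animal counts in
no birth-herd numerator). On the synthetic register this proxy is exact,
because the generator always emits the within-year movement chain that
establishes it.

## The nine variables

| Variable | Quotient | Snapshot |
|---|---|---|
| `pFemaleAnimals` | females / herd size | May |
| `pDairyBreed` | dairy-bred / herd size | May |
| `pCrossBreed` | cross-bred / herd size | May |
| `pCalvedAnimals` | ever-calved / herd size | September |
| `pMalesBetween1and2Years` | male yearlings / all yearlings | May |
| `pAnimalsLess30Days` | animals in-and-out within < 30 days / yearly out-moves | — |
| `pOutMovesToSL` | yearly moves to slaughter / **maximum** snapshot size | — |
| `pOutMovesToBirthHerd` | out-moves returning an animal to its birth herd / yearly out-moves | — |
| `pInMovesToBirthHerd` | in-moves returning an animal to this, its birth, herd / yearly in-moves | — |

Conventions that the definitions leave open were fixed once:

* **Age band.** "Between 1 and 2 years" is $[365, 730)$ completed days at
  the May snapshot; no leap-year special-casing.
* **Short stays.** An animal counts for `pAnimalsLess30Days` if it entered
  by an inward movement during the year and left by any outward movement
  *strictly* less than 30 days later ("less than 30 days"); the
  denominator is all out-moves of the year.
* **Zero denominators** yield a 0 proportion plus a flag row (attribute
  `"flags"` on the feature table) rather than a missing value, so map
  training and tree classification always receive complete vectors.
* **`pOutMovesToSL` above 1** is possible by construction (the
  denominator is a stock, the numerator a flow); such herds are flagged
  but not truncated.

The seed ("initial") classification is: breeding iff
`pCalvedAnimals` $\ge 0.25$; breeding herds are dairy at
`pDairyBreed` $\ge 0.70$, beef below $0.30$, mixed otherwise; non-breeding
herds stay `unknown`. Whether the dairy share should be computed over
breeding animals only is not decidable from the definitions; the package
uses the May herd as in `pDairyBreed`.

## Self-organising and bi-directional Kohonen maps

The map is a rectangular $X \times Y$ grid of weight vectors
$w_{xy} \in \mathbb{R}^N$ trained on z-score-normalised records
(population variance convention, so the training matrix has unit variance
exactly; constant variables are rejected by name). Per epoch every record
is visited in a seeded random permutation; for record $z$ the best
matching unit (BMU) minimises the Euclidean distance $|w_{xy} - z|$ (ties
break towards the smallest node index, nodes ordered x-fastest), and all
nodes update as

$$w_{xy} \leftarrow w_{xy} + \alpha\,\beta_{xy}\,(z - w_{xy}),
  \qquad \beta_{xy} = \exp\!\left(-\tfrac{d^2}{2\sigma^2}\right),$$

with $d$ the grid-coordinate distance to the BMU ($\beta = 1$ there; no
toroidal wrap). After each epoch $\alpha$ and $\sigma$ shrink
geometrically. Defaults: $\alpha_0 = 0.5$, decay $0.95$/epoch;
$\sigma_0 =$ half the larger grid dimension, decay $0.95$/epoch; 50
epochs; weights initialised uniformly in $[-1, 1]$ per normalised
variable. Nothing in the method requires these exact values — only
monotone reduction — and all are configurable through
`training_schedule()`. Since $0 < \alpha\beta \le 1$, an update can only
move nodes towards the record, which the tests exploit as a contraction
invariant.

**Supervised (BDK) training** couples the feature grid with a
class-membership grid (one simplex vector per node, initialised uniform).
At epoch $t$ of $T$ the BMU minimises
$\tfrac{t}{T}\, d^2_{\text{features}} + (1 - \tfrac{t}{T})\, d^2_{\text{class}}$,
so label structure organises the map early and features take over late —
one concrete reading of the bi-directional scheme, and the only property
downstream code relies on. Both grids receive the same Gaussian update
(classes towards the record's one-hot label, which keeps each node's class
vector a convex combination, hence a simplex). Prediction uses the
feature part alone; the per-node majority label defines the map's class
regions.

**Rule extraction instrumentation.** `component_plane()` de-normalises
one variable's weights into an $X \times Y$ matrix (rendered red-high /
blue-low by `plot_component_planes()`); `region_histogram()` histograms a
raw variable over the records whose BMU falls in a node subset.
`rule_extraction_walkthrough()` packages the canonical two-stage episode:
a 2-variable supervised map (`pDairyBreed`, `pCalvedAnimals`) in which
the unclassified non-breeding herds occupy the low-calving region, then a
3-variable map adding `pOutMovesToSL` whose histogram over that region
splits into fatteners (most out-moves to slaughter) and store/rearing
herds (almost none). The suggested split is the midpoint of the sparsest
bins between the histogram's two main peaks — a deliberately simple
antimode heuristic, adequate for well-separated modes and not meant as a
general bimodality test.

## The classification tree

Thirteen decisions (ten binary, three ternary — the leaf count 17 forces
ternary splits to be counted as single decisions), nine distinct
variables, at most six decisions per herd. Every comparison uses $\ge$ on
the boundary, matching the breeding criterion's convention.

| Node | Variable | Threshold(s) | Outcome |
|---|---|---|---|
| D1 | `pCalvedAnimals` | **0.25** | breeding vs non-breeding |
| D2 | `pDairyBreed` | **0.30 / 0.70** | beef subtree / `M` / dairy subtree |
| D3 | `pMalesBetween1and2Years` | 0.40 | high → `DRm` |
| D4 | `pCalvedAnimals` | 0.60 | high → non-rearing (D5), low → `D` |
| D5 | `pInMovesToBirthHerd` | 0.40 | high → `DnR-C`, low → `DnR-nC` |
| D6 | `pCrossBreed` | 0.15 | low → `BP` |
| D7 | `pOutMovesToSL` | 0.30 | high → `BSB` |
| D8 | `pMalesBetween1and2Years` | 0.20 / 0.75 | `BSW` / `BSY` / `BSY-nR` |
| D9 | `pAnimalsLess30Days` | 0.50 | high → `T` |
| D10 | `pOutMovesToSL` | **0.50** | high → `F` |
| D11 | `pOutMovesToBirthHerd` | 0.40 | high → `Rdf` |
| D12 | `pDairyBreed` | 0.50 | high → `Sdm` |
| D13 | `pFemaleAnimals` | 0.30 / 0.70 | `Sbm` / `Sbmx` / `Sbf` |

Bold thresholds are externally fixed classification constants (together
with the 30-day window inside `pAnimalsLess30Days`);
`build_default_tree()` refuses to override them. The remaining values are
package configuration defaults, chosen midway between the archetype
nominals on either side of each split and serialisable to an editable
YAML file (`write_tree()`/`read_tree()`) so domain experts can adjust
them. Two genuinely open design points were resolved as follows: the
pedigree split D6 tests `pCrossBreed` alone (the beef branch has already
bounded `pDairyBreed` below 0.30), and ternary splits count as one
decision each.

**Sensitivity bands.** For the herds reaching a node,
`threshold_sensitivity()` returns the smallest interval around the
threshold whose ends would each reassign $\lceil 0.10\,n \rceil$ herds
($n$ = herds at the node). The band ends are the $(m+1)$-th empirical
value beyond the threshold on each side; with fewer herds than that on a
side the bound is open and flagged, and a zero fraction degenerates to
the threshold itself.

## The synthetic register generator

Real register extracts are confidential, so the generator is a
first-class module: 17 `archetype_spec()`s encode, per herd type, a
herd-size range, breed composition, calving level, age structure with
per-age-class male fractions (the yearling male fraction *is* the nominal
`pMalesBetween1and2Years`), and movement intensities with a destination
mix (slaughter, sales, short trading stays, contract-rearing cycles,
purchases). The derived `female_fraction` is stored so nominal and
generative values coincide. `expected_features()` maps a spec to the
feature vector it implies — including the bookkeeping corrections for
contract animals — and every default archetype's nominal vector falls
strictly inside its own leaf of the default tree, with margins of roughly
2.5–3 standard deviations at typical herd sizes, so label recovery is
high but not degenerate (the neighbouring yearling-share boundaries
between `BSW`/`BSY`/`BSY-nR` produce the occasional, realistic swap).

The nominal values themselves are calibration constants of the generator,
chosen once from the qualitative type signatures (e.g. fatteners send
most out-moves to slaughter; weanling-selling sucklers keep almost no
male yearlings; traders turn most animals around within 30 days) — they
are not measured properties of any real population.

Movement bookkeeping keeps every animal on one residency row: core
animals are born in the herd; slaughter/sale exits happen after the
September snapshot so snapshot composition stays interpretable;
contract-reared animals arrive from and return to a counterpart birth
herd within the year; returning heifers get a paired early out-move and
late return in-move (their row records the post-return spell); purchases
arrive late in the year. Counterpart herds are emitted as ids only and
labelled `counterpart` in the truth table so recovery statistics are
computed over primary herds alone.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real herd-size distributions (sizes are uniform
on type-specific ranges), within-year births, mart-mediated trade,
multi-year life histories, seasonal calving waves, missing or erroneous
records, and the real prevalence mix of herd types (all types are equally
frequent by design). Results on the synthetic register validate the
*machinery*, not national statistics.

## Numerical choices and degenerate inputs

* BMU ties break deterministically towards the smallest node index;
  training is therefore reproducible bit-for-bit under a fixed seed, and
  independent of record identities.
* All randomness flows through explicit seeds; per-herd generator
  sub-seeds are drawn once from the run seed, and the package restores
  the caller's RNG state afterwards.
* Empty map regions give zero-count histograms; unknown herds give empty
  member sets; a register that fails validation is rejected at
  construction with the offending record ids.
* Normalisation inversion is exact (used by the component planes), and
  `apply ∘ invert` round-trips to machine precision.

## Problem sizes

The test suite and the acceptance script run the pipeline at 20 herds per
type (340 primary herds, ~30,000 animals), supervised maps at
$8\times8$–$10\times10$ nodes for 25–30 epochs, and threshold recovery on
controlled 200-animal registers — sizes at which every statistic of
interest is stable across seeds while the whole suite completes in about
a minute. The implementation itself is vectorised over nodes and has no
intrinsic scale limit beyond memory ($O(KMN)$ per training epoch for $K$
records, $M$ nodes, $N$ variables).

## Known limitations

* The tree's non-printed thresholds are calibrated to the synthetic
  archetypes; applying the classifier to a real register would require
  re-reading them from that register's component planes and histograms
  (the intended workflow, which `run_pipeline()`'s artifacts support).
* The birth-herd proxy under-counts birth-herd returns for animals whose
  defining movements fall outside the one-year window.
* The BDK mixing curve (linear class-to-feature shift) is one concrete
  choice; only the "labels early, features late" contract is relied on.
* Sex-specific fattening sub-types are deliberately not modelled; the
  fattening leaf absorbs them.
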