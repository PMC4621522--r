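---
title: "Methods: LC-MS cyclotide screening with cycloscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LC-MS cyclotide screening with cycloscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloscreen)
```

## The problem

Cyclotides are ~30-residue plant peptides with a head-to-tail cyclic
backbone and three disulfide bonds arranged in a cyclic cystine knot
(CCK). In the Violaceae they occur as species-specific cocktails of up to
25 peptides, detectable by LC-MS as late-eluting ions with neutral masses
between 2.8 and 3.8 kDa. `cycloscreen` turns per-sample LC-MS feature
lists into a deduplicated, cross-species cyclotide registry, annotates
glycoform and other derivative mass ladders, supports MS/MS sequence
confirmation by in-silico digestion, clusters species by their cyclotide
fingerprints, and extrapolates family-wide diversity. Because large
herbarium screens are not redistributable, the package includes a
first-class synthetic-panel generator with full ground truth, so every
stage can be validated end to end.

## Mass chemistry

A head-to-tail cyclic peptide has no free termini, so its neutral mass is
the sum of residue (dehydrated) masses with **no water term**:

$$M_\text{cyclic} = \sum_i m_{r_i} - 2\,n_{SS}\, m_H + \sum_k c_k\,\Delta_k$$

Each disulfide bond removes two hydrogen atoms ($m_H$ = 1.00783 Da); for
the canonical three-disulfide knot the correction is −6.047 Da. Linear
digestion products regain one water (18.01056 Da). Conversions between
neutral mass and m/z use the electrospray convention $[M + zH]^{z+}$ with
the *proton* mass 1.00728 Da — the hydrogen-atom and proton masses are
deliberately distinct constants.

Registered modification deltas (monoisotopic, per event): hexose
glycosylation +162.05282, reduction plus carbamidomethylation +58.02929
per cysteine (1.00783 reduction + 57.02146 alkylation), acetylation
+42.01057, oxidation +15.99491, deamidation +0.98402. Nominal values are
obtained by half-up rounding, giving the familiar integer shifts: 348 Da
for six alkylated cysteines, 162 Da per hexose, 84 Da for two acetyls.

MS sequencing cannot distinguish leucine from isoleucine; both symbols are
accepted and share one residue mass. Cyclic identity is defined up to
rotation: `canonical_rotation()` (lexicographically smallest rotation) is
used for equality only, display keeps the input rotation. One bundled
reference value is knowingly discrepant: mema A recomputes to 3307.48
versus a published 3307.4 while every other reliable row agrees within
0.05 Da; the published number is kept verbatim and not asserted.

## Detection: deconvolution, calling, derivative ladders

`deconvolute()` merges features within one sample whose implied neutral
masses agree within `mass_tol` (default 0.5 Da — unit-resolution ion-trap
data) and which co-elute within `rt_tol` (default 0.2 min). Observations
supported by two or more charge states (typically 2+/3+ in m/z 800–1900)
are unambiguous; single-charge observations are flagged. Unknown-charge
features are tried at each charge in 1–4 and ranked by a prior favoring
2+/3+; only the top-ranked interpretation counts as the feature's
assignment, so no feature supports two observations. Features are assumed
already centroided and monoisotopic — there is no isotope-envelope
deconvolution, a documented limitation.

`call_cyclotides()` is a pure window filter: accepted iff neutral mass in
[2800, 3800] Da and retention time in the configured window. The classic
cyclotide elution region is 25–40 min, but full screens show detections
from 15 to 60 min, so `run_screen()` defaults to [15, 60]; both are
configuration, not inference.

`annotate_derivatives()` links a heavier call to a lighter co-eluting base
(within 1.0 min — glycoforms elute closely or co-elute with their parent)
when the mass difference matches n × 162.0528 Da (n = 1..3), +15.995
(oxidation) or, only when `mass_tol` < 0.5 Da, +0.984 (deamidation, not
resolvable on unit-resolution data). Candidates are processed in
ascending mass and may only link to bases that are not themselves
derivatives, so a hexose ladder anchors all its rungs on one underived
base and links are acyclic by construction. `verify_alkylation()` checks
the 6 × 58.03 = 348 Da reduction/alkylation shift that confirms the six
cysteines.

## The registry criterion

Two accepted calls are the *same* cyclotide iff their masses agree within
`mass_tol` (default 1.0 Da across runs — inter-run calibration drift
exceeds within-run error) **and** their retention times agree within ±1
min; a peak differing in either is a new cyclotide. Records are connected
components under this relation (single-linkage). Single linkage follows
directly from the pairwise criterion; its chaining risk is real and is
why shrinking either tolerance can only increase the record count (a
tested invariant). Derivative satellites are excluded from the registry
so glycoforms do not inflate the distinct-cyclotide count; they are
reported separately.

## MS/MS support

`digest()` linearizes a cyclic peptide in silico: k cleavage sites give k
linear fragments, each gaining one water, so fragment masses sum to the
open-chain mass plus k waters — an exact conservation law tested over
random peptides. GluC is modeled as Glu-specific only (the
bicarbonate-buffer specificity used to cut cyclotides at the conserved
Glu); trypsin cleaves after Lys/Arg except before Pro. Digestion is
computed on the reduced, carbamidomethylated form by default because that
is the state in which cyclotides are digested; `alkylated = FALSE`
restores native cysteine masses. `fragment_ladder()` emits full b/y
series (charges 1–2 by default; a/x/c/z omitted) with the complementarity
invariant $b_i + y_{n-i} = M_\text{linear}$, and `match_fragments()`
reports bond coverage and unsupported spans — the practical signature of
poorly fragmenting regions such as a glycosylated loop 5.

`parse_loops()` numbers the six inter-cysteine segments so that loop 1
contains the conserved Glu; zero or multiple Glu-containing loops raise
an ambiguous-anchor error with an explicit `anchor` escape hatch (needed
for real sequences such as rigra A, which carries a second Glu).
Subfamily classification uses the loop-5 rule: Möbius iff loop 5 has a
Pro immediately preceded by an aromatic residue (W/F/Y), bracelet iff
loop 5 has no Pro, otherwise atypical (e.g. hyde A's GSTVPL).

## Chemotaxonomy

Species profiles are presence/absence vectors over records. Jaccard
distance is the default — joint absence of a cyclotide says nothing about
relatedness — with simple matching available for comparison; a species
with an empty profile takes distance 1 to all (logged). UPGMA is
average-linkage agglomeration (via `stats::hclust`) returning an
ultrametric tree; neighbor joining is Saitou–Nei (via `ape::nj`) with
negative branch lengths clamped to zero and the deficit recorded. Labels
are sorted lexicographically before clustering so distance ties break
deterministically. On planted clades with disjoint pools the bipartition
is recovered at zero noise; on realistic sparse sharing the resolution is
poor — that behavior is documented, not asserted, because it reflects the
data, not the algorithm.

## Diversity

`unique_per_species()` counts records confined to a single species and
the global shared fraction. `extrapolate_total()` is deliberately the
naive product — mean species-unique cyclotides per species × total family
species × an under-detection correction (up to ~5, floor-rounded) — with
no richness estimator substituted, because fidelity to the screen's own
arithmetic is the goal. `loop_library_size()` multiplies six per-loop
variant counts in exact integer arithmetic (guarded at 2^53); the
per-loop counts come from `count_loop_variants()` over a user-supplied
sequence collection.

## The synthetic panel generator

The generator emulates the statistical structure of a 143-species
herbarium screen with 744 distinct cyclotides. Design choices, each made
once:

* **Loop grammar.** Sequences are `C loop2 C loop3 C loop4 C loop5 C
  loop6 C loop1` with the conserved Glu in loop 1, no Cys inside loops
  and no Glu outside loop 1, so `parse_loops()` is unambiguous by
  construction (a `messy` flag relaxes this for robustness testing).
  Loop-length distributions (loop 4 one residue; loops 2/3/5/6 variable)
  and a small/polar-weighted alphabet were calibrated once so that
  in-window masses average ≈3090 Da (median ≈3065), close to the
  3070/3048 of real screens. One third of sequences get a Möbius loop 5.
* **Mass window.** Rejection sampling into [2800, 3800] Da.
* **Distinguishability.** The planted pool is pairwise distinct under the
  registry's own criterion (±1 Da AND ±1 min) plus a 3σ noise guard. The
  real screen's "744 different cyclotides" is *defined* by that
  criterion, so a faithful generator must plant a pool that is countable
  under it; otherwise planted and recoverable counts differ by
  construction rather than by pipeline error.
* **Retention model.** rt = 32 + 0.55 × (Kyte–Doolittle sum), clamped to
  15–60 min; about 70% of detections fall in the classic 25–40 min
  region. Only rank plausibility is claimed — no real RT calibration
  exists for this chemistry.
* **Sharing structure.** One third of the pool is planted in ≥2 species;
  the first three shared cyclotides are "varv A-like" widespread peptides
  occupying 70/50/50% of the Viola genus block (28% of species). The
  remaining shared cyclotides get 2 + Poisson(0.1) species each, drawn
  with gamma-distributed species weights; every species receives at least
  one species-unique cyclotide and loads are capped at 25. Per-species
  counts therefore *emerge* (mean ≈7.5, range 1–25) rather than being
  drawn directly: the published marginals (mean 7.3 detections/species,
  1/3 sharing with each shared cyclotide in ≥2 species, and widespread
  cyclotides covering most of one genus) are mutually incompatible by a
  few percent, and the generator resolves the tension in favor of exact
  distinct count, sharing fraction and prevalences.
* **Glycosylation.** 15% of distinct cyclotides (≈115/744) are
  glycosylated and emit a co-eluting +162.0528 Da satellite at ~0.3×
  intensity in every species where they occur.
* **Noise.** Per-feature Gaussian mass noise (σ 0.15 Da), per-detection
  RT shift (σ 0.15 min), log-normal intensities, optional uniform noise
  features, and an instrument scan-range filter at m/z 800–1900.
* **Determinism.** Each stage (pool, assignment, emission) seeds its own
  named substream derived from the master seed, so panels are
  byte-identical under a fixed seed and stages can be re-run
  independently.

What the generator does **not** emulate: raw spectra, isotope envelopes,
chromatographic peak shape, retention drift between runs, ion
suppression, or degradation chemistry. Passing recovery tests therefore
demonstrates the pipeline's correctness under the stated error model, not
instrument-level robustness.

## Numerical choices and degenerate inputs

Tolerances are part of each function signature and echoed in outputs.
Mass equality is never tested exactly; all comparisons are
tolerance-banded. Empty feature tables deconvolve to empty tibbles (not
errors); empty occurrence matrices and non-positive extrapolation inputs
raise typed errors; an unreachable simulator mass window aborts after
bounded retries. Unknown residue symbols report the offending character
and position. Ties in derivative linking resolve to the smallest mass
residual against an underived base; ties in UPGMA resolve by label order.

## Problem sizes

The test suite validates the desk-scale oracles on exact hand-derived
values, property invariants on hundreds of randomized cases, and
parameter recovery end to end at full scale (143 species, 744 planted
cyclotides, seed 1), which runs in well under a minute; module-level
simulation tests use 25-species/120-cyclotide panels. At the full scale
the pipeline recovers 740 records (planted 744), a shared fraction of
0.332 (planted 1/3), 100% glycoform recall, and widespread-cyclotide
prevalences within two percentage points of their planted values — all
recomputed by the suite itself.

## Limitations

Single-linkage chaining can merge genuinely distinct peptides in dense
mass/RT regions; cross-run retention alignment is out of scope; the
extrapolation carries no confidence interval (none is defined for the
naive product); Leu/Ile and other isobaric substitutions are invisible to
the mass-level registry; and chemotaxonomic resolution is limited by how
little sharing there is between species — a property of the biology the
package reports rather than repairs.
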