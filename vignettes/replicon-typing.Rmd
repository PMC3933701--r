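---
title: "Designing and auditing a replicon-typing PCR system"
author: "reptype authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and auditing a replicon-typing PCR system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reptype)
```

## The problem

Plasmids of the IncP-9 (and related IncP-1, IncP-7) incompatibility
groups are frequent vehicles of catabolic genes in polluted habitats.
Detecting them directly in total-community DNA requires a PCR system
whose primers amplify *every* known subgroup of the target replicon while
amplifying *no* plasmid of another group. `reptype` implements that
design problem and its audit trail: conservation-guided degenerate primer
design, in-silico PCR validation, and phylogenetic classification of the
amplicons a survey recovers.

This vignette records the model choices, defaults and their rationale,
what the synthetic data emulate, and the package's known limits.

## Degenerate matching: the subset rule

A degenerate primer is a mixture: position `i` with code `W` contains
both an `A`-oligo and a `T`-oligo. We say primer base $p$ matches
template base $t$ iff $E(t) \subseteq E(p)$, where $E(\cdot)$ is the
IUPAC expansion set. For concrete templates this is ordinary degenerate
matching. For ambiguous template bases (public records do contain `N`s)
the rule is deliberately conservative: an `N` in a template never
satisfies the match unless the primer base is `N` itself, because some
concretization of the template would escape the primer mixture. Public
databases do not state how ambiguous reference bases should be treated
during in-silico validation; the subset rule is this package's choice and
is applied uniformly (and flagged here rather than buried in code).

Within an *alignment*, by contrast, two degenerate residues score as a
match when their expansions merely intersect — alignment asks whether two
observed sequences could be the same, not whether one mixture covers the
other, and the relation should be symmetric.

## Primer-binding model

A binding site must satisfy two constraints, evaluated per target:

* **3′ anchor** — a perfect-match run of at least `anchor_len` (default
  12 nt) at the primer's 3′ terminus, where the polymerase initiates;
* **mismatch budget** — at most `max_mismatch` (default 4) failed
  positions, all of which consequently lie 5′ of the anchor. Zero
  mismatches also passes: a budget stated as an observed 1–4 range would
  be perverse to enforce as a lower bound.

Sites are scanned on both strands; a reverse primer's plus-strand image
is its reverse complement with the anchor at the window's *left* edge.
An amplicon is any forward/reverse site pair in productive orientation;
its length spans both primer footprints, so with two 21-mers and a
568–595 bp spacer the products run 610–637 bp. "Amplified" in the
specificity screen means *any* product by default — on a gel any band
would be seen — and size filtering is opt-in. Coordinates are 1-based
inclusive throughout, the R convention.

## Design constraints and defaults

`primer_constraints()` centralises the tunables: 21-nt windows, maximum
degeneracy 8, anchor 12 nt, mismatch budget 4, product window 610–637 bp,
indel-free windows (`max_gap_fraction = 0`; a primer cannot span an
indel), and `f_min = 0`, meaning the window consensus must cover every
base observed in any target — the "no sequence type left behind" reading
of degenerate design. Raising `f_min` lets singleton noise be
down-weighted at the cost of guaranteed coverage.

Melting temperatures use the Wallace rule, $T_m = 2(A{+}T) + 4(G{+}C)$,
averaged over the primer's expansions (computable per position without
enumeration). The accepted window is 55–65 °C: the published IncP-9 pair
itself evaluates to 60 and 61 °C under this rule, consistent with the
common heuristic of annealing ~5–10 °C below the Wallace estimate (the
system anneals at 53 °C). A 50–60 °C window may look natural but would
reject the very primers the constraint set is modelled on, so the default
brackets them; nearest-neighbour thermodynamics, dimer and hairpin
screening are out of scope.

Ranking of feasible pairs is a package convention, not a claim about how
any published pair was chosen: lowest pair degeneracy, then fewest total
mismatches across targets, then smallest $|T_{m,F} - T_{m,R}|$, then
leftmost forward window. The constraint system typically has several
equally-ranked solutions — windows shifted by a base or two against a
conserved block satisfy every predicate just as well — so "recovering" a
known-good pair means finding its footprints among the designs, not that
the single top row must match it byte for byte. Every tie-break in the package (alignment
traceback diagonal > up > left; best-binding-site by mismatches, anchor,
position; NJ joins by lowest index pair) is fixed so identical inputs
give identical outputs.

## Alignment

Multiple alignment is progressive: Needleman–Wunsch with match 1,
mismatch −1, linear gap −2 supplies pairwise distances, a neighbor-joining
guide tree fixes the merge order, and profile–profile alignment (expected
pair score between column base-frequency vectors; gap costs scaled by the
opposing column's residue fraction) merges leaf-to-root. Replicon
backbones within a group are close homologs, which is why linear gap
costs suffice and affine gaps or profile HMMs would add little here.
Column-exact agreement with any external aligner is explicitly not a
goal; downstream steps depend only on conserved blocks aligning cleanly,
which the test suite checks against planted ground truth.

## Distances, trees, classification

Distances are proportions of differing sites over pairwise-deleted
columns (literal character inequality — an ambiguity code is a
difference unless identical), corrected by Jukes–Cantor,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$. The substitution model behind
published replicon trees is typically unstated; JC is the minimal
defensible choice and raw p-distance is selectable. Saturation
($p \ge 0.75$) is an *error*, never a silent clamp — silent infinities
corrupt neighbor joining. The one deliberate exception is
classification: there a saturated query–reference pair is treated as
infinitely distant (it can never be the nearest reference, and a query
saturated against everything is an error), which keeps the
nearest-reference rule total without hiding saturation inside a tree.

Neighbor joining is the Saitou–Nei agglomeration with the
Studier–Keppler criterion
$Q_{ij} = (n-2)d_{ij} - R_i - R_j$; negative branch lengths are clamped
to zero without redistribution (documented, affects lengths only).
Bootstrap supports resample alignment columns with replacement,
per-replicate column index streams from a single seed; rows are put in
canonical (id-sorted) order first so supports cannot depend on input
order through floating-point tie-breaking. 1,000 replicates is the
conventional default; tests use fewer.

Classification replaces a remote-database similarity search with local
nearest-reference assignment: queries are co-aligned with labelled
references and take the label of the nearest reference by JC distance,
with `unaffiliated` beyond `tau = 0.10` substitutions/site. That
threshold marks "novel subgroup" territory: within-subgroup replicon
divergence sits well below 10 % while between-subgroup divergence sits
well above it, so the default separates the two regimes with margin on
both sides. Support is the percentage of column-resample replicates that
reproduce the assigned label. Equidistant references resolve to the
lowest index, and the support value makes the ambiguity visible (~50 %).

## What the synthetic panels emulate — and what they do not

`simulate_panel()` grows a nine-subgroup family from a random root:
subgroup ancestors at `between_divergence` (default 0.15
substitutions/site), members at `within_divergence` (default 0.02),
substitutions only. The root carries the primer-pair architecture —
forward footprint, maximal 595 bp spacer, reverse footprint — at a
uniformly drawn position, keeping at least 30 nt of homologous flank on
each side (a site flush against a sequence end makes the terminal
alignment columns ambiguous and can split the planted block across a
spurious gap column); per member the spacer is shortened to a
568–595 bp draw by a centred deletion, so members stay homologous, the
planted blocks occupy gap-free alignment columns, and products span
610–637 bp by construction (568 = 610 − 2·21, 595 = 637 − 2·21).

The primer-binding blocks are *conserved regions by construction*: at
degenerate primer positions the planted base varies only inside the
code's expansion set (at the mutation rate), and with
`anchor_protect = TRUE` (default) mutation never damages a site. This is
the biological premise of the design method — primers are sought where
sequences are conserved. It is also a mathematical necessity for the
recovery tests: under a planted-then-mutated model the chance that a
given site column is hit somewhere in a 27-member panel is
$1 - 0.98^{27} \approx 0.42$, so most site columns would be polymorphic,
the covering consensus would exceed any sane degeneracy cap, and no
designer honouring the constraints could recover the pair.
`anchor_protect = FALSE` provides the stress mode: an unconstrained
post-planting substitution pass over the whole sequence, anchors
included. Decoy non-targets are site-free uniform random sequences.

Accordingly, a passing recovery suite demonstrates correctness of the
machinery — coordinates, matching rules, constraint logic, recovery under
the stated noise model — not performance on real replicon panels, which
add indels in flanks, compositional bias, incomplete subgroup sampling
and ambiguous bases. `simulate_queries()` emulates a clone library by
cutting planted amplicons and diverging them (default 2 %), labelled with
their generating subgroup.

The no-noise limit deserves one note: with both divergences zero *and* a
single-valued `insert_length_range`, all targets are identical; with the
default range they still differ in spacer length, because per-member
spacer draws are part of the architecture, not of the noise model.

## Problem sizes and determinism

Defaults are 27 targets (9 × 3, comparable to the 28-reference design
panels of the IncP-9 system) of ~900 bp, 6 decoys, 18 queries; design,
screening and classification of one panel run in a few seconds, and the
test suite and the acceptance script use exactly these sizes with a
handful of seeds. Every stochastic step takes an explicit integer seed
(generator, bootstrap, CLI `--seed`), RNG state is restored on exit, and
repeated runs are byte-identical, manifests aside.

## Known limitations

* Linear templates only: circular plasmid topology is not modelled, so a
  site pair spanning the origin of a circular map is missed.
* No amplification kinetics: all site pairs are reported, with no
  polymerase-competition or efficiency model.
* No thermodynamic screening (dimers, hairpins, nearest-neighbour Tm).
* Substitution-only evolution in the generator by default; it does not
  stress the aligner with indel-rich histories.
* Classification is nearest-reference, not clade placement; a query
  equidistant between subgroups is resolved by order and flagged only
  through its support value.
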