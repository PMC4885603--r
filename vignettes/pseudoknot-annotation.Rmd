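---
title: "Annotating pseudoknotted RNA secondary structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating pseudoknotted RNA secondary structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotann)
```

## The problem

The classical vocabulary of RNA secondary structure — hairpins, bulges,
internal loops, multibranch junctions — is defined on pseudoknot-free
structures, where base pairs nest perfectly and every helix closes a
well-defined loop.  Real structures cross that line constantly: a
pseudoknot is nothing more than two helices whose pairs interleave, and
the moment one appears the classical loop definition stops applying.
`knotann` implements a generalized decomposition that treats both regimes
uniformly and specializes exactly to the classical one when no pairs
cross.  This vignette explains the model, the choices made where the
definitions leave room, and what the validation does and does not show.

All coordinates in the package are 1-based and intervals are inclusive on
both ends.  The secondary structure is required to be a matching; contacts
that violate that (non-canonical pairs, multiplet partners) travel
separately as *tertiary pairs* and never influence the topology.

## Stems, crossing, and elementary closed regions

A *stem* is a maximal run of at least two stacked pairs.  Maximality is
not optional: contiguous stacks must be one stem, or faces, wings and
everything built on them fragment arbitrarily.  Only complementary pairs
(Watson–Crick and GU wobble, which may mix within one stem) form
*standard* stems, the default; `stem_type = "arbitrary"` accepts any
pairs when no sequence is available.  A single unstacked pair is not a
stem.  Such isolated pairs are excluded from all downstream computation
by default, because the closed-region machinery is built from stems; the
`keep_isolated` flag turns them into nonstandard one-pair stems for
exploratory work, clearly labelled `"arbitrary"`.

An *elementary closed region* (ECR) is an interval that no stem pair
connects to the outside, that cannot be split into a closed prefix and
suffix, and whose boundary consists of stem faces — either its end pair
is itself a face (a *classical* ECR) or two faces meet its two ends (a
*pseudoknotted* ECR).  Because every ECR boundary position is a face
endpoint, the implementation only scans the (few) face-endpoint pairs as
candidates and verifies closure and elementarity on a partner vector.
The brute-force oracle `oracle_ecrs()` ignores that observation and tests
every interval literally against the conditions; the two agree on every
generated structure we test, which is the strongest evidence that the
candidate restriction is sound.

Evaluating closure over stem pairs only (rather than all pairs) is a
consequence of excluding isolated pairs and is deliberate: the boundary
condition is stem-based, and admitting lone pairs would create regions
whose boundary no face can justify.

## Loops

The loop of a stem H with internal pair (r, s) is the set of positions
internal to H that are not strictly inside any stem lying (with both
wings) inside H.  The equivalent operational form cuts H's *H-ECRs* out
of \[r+1, s−1\]: an H-ECR repeats the ECR conditions relative to H's
interior, with the crucial twist that pairs leaving the interior
altogether are invisible to it.  That twist is what makes the definition
pseudoknot-proof — a crossing stem's wing inside H hides nothing, so it
simply stays in the loop, and a loop containing such a wing is
*pseudoknotted*.

The implementation computes loop membership via H-ECRs and then
re-derives it from the position-wise predicate, stopping on any
disagreement; the test suite additionally checks the predicate route
independently (`oracle_loop()`) across the random-structure budget.  Two
representation choices are worth recording:

* *Zero-length sides* are kept explicitly with `end = start − 1`,
  anchored between their delimiters.  Bulges are defined by a zero-length
  side, so the representation must be able to say where nothing is.
* *Only outermost H-ECRs* are returned.  The defining conditions allow an
  H-ECR to sit inside another (a hairpin deep inside an excluded region
  satisfies them relative to H), but the loop is determined by the
  outermost excluded fragments, and faces of inner regions belong to
  inner loops.  This is an interpretation; the position-wise cross-check
  guards it.
* A wing of a crossing stem can never lie partially in a loop (the H-ECR
  boundary would have to be one of the wing's own paired positions,
  which already have partners).  The code asserts this instead of
  assuming it, so a pathological input would fail loudly rather than
  silently misclassify.

The classification axes are total: size (hairpin = no faces, internal =
one face, bulge = internal with a zero-length side, multiple junction =
two or more faces) and pseudoknot involvement (pseudoknotted = contains
wings; isolated = no wings; classical = no wings and no pseudoknot
faces).  Every classical loop is in particular isolated; the label
reports the most specific class.  On pseudoknot-free structures the
whole decomposition coincides with the classical nearest-neighbour-model
one, which the suite verifies against an independent oracle built from
the stem nesting tree — not from H-ECRs.

## Signatures

Each stem of a pseudoknotted ECR contributes an arc.  An arc's end
coordinate is the leftmost position of the corresponding wing; since
wings are contiguous and position-disjoint, any consistent choice of
representative yields the same end order, and the code asserts
distinctness rather than assuming it.  Letters are assigned in
alphabetical order of left ends; the word lists ends in coordinate
order.

The *upper* level removes every stem lying inside a nested sub-ECR of
the pseudoknot — regardless of whether that child is classical or
pseudoknotted, since either way it is a self-contained region whose
internal topology is described by its own signature.  The *reduced*
level collapses *parallel families* (bands): maximal sets of arcs that
are pairwise nested and cross exactly the same set of other families.
Two subtleties:

* Identical crossing sets do not imply nesting — the two outer hairpins
  of a kissing-hairpin motif cross exactly the same partner but are
  disjoint and must not merge.  Families are therefore nested chains
  within each crossing-set class.
* One collapse pass suffices, because crossing sets are family-level
  invariants.  The code still re-runs the collapse and stops if the
  result changes, and the iterative pairwise reducer in
  `oracle_signature()` provides an independent route to the same word.

Words with more than 26 arcs switch to indexed tokens (`a1`/`A1`, …)
joined by dots; practical structures never get close.

## The generator and what the tests show

`generate_structure()` plants stems one at a time: lengths default to
100 nt with six stems of 2–6 pairs, a hairpin gap of at least three
unpaired positions, and a 30% chance per stem of being forced to cross
an existing one (placed by sampling its wings on opposite sides of an
existing face).  A one-position spacer rule — no planted pair may
diagonally extend an existing one — guarantees that maximal-stem
detection recovers exactly the planting log, which the suite asserts.
Sequences are emitted complementarily (10% wobble) so standard-stem
detection sees every planted pair.  Placement can corner itself; the
generator restarts the whole layout up to 25 times before declaring a
configuration infeasible, and the same seed always yields the same
structure.

The validation budgets are chosen to finish comfortably on one CPU: 200
pseudoknot-free structures of 40–150 nt against the classical NNM oracle
and 300 mixed structures of 40–120 nt against the ECR, loop and
signature oracles, plus the deterministic worked fixtures.  What passing
shows: the implementation agrees with the literal definitions across a
broad sample of matchings, including dense pseudoknots.  What it does
not show: anything about base-pair *extraction* — real annotation
pipelines start from 3D coordinates and inherit all the ambiguity of
hydrogen-bond assignment, which is explicitly out of scope here (inputs
are base-pair lists).  The generator also does not attempt
thermodynamic realism: stem lengths and placements are uniform, not
Boltzmann-weighted, so motif *frequencies* in generated collections are
not biological.

## Tertiary interaction taxonomy

Tertiary pairs are annotations laid over the finished secondary
annotation.  Each endpoint maps to an element with helix priority: a
wing position counts as helix even inside another stem's loop, because
the Helix/Loop axis is about paired context and a position cannot be
both (the `loop_priority` flag inverts this for sensitivity analysis).
In pseudoknots a position can belong to several loops; the innermost
owner (smallest internal-pair span) is chosen, which keeps same-loop
contacts local.  *Local* is defined constructively: same element, or a
stem paired with an adjacent loop — its own loop, a loop carrying its
face as one of its faces, or a loop containing one of its wings.  The
pseudoknot/classical context of an interaction follows the kind of the
innermost ECR enclosing either endpoint; assigning by one endpoint
rather than both is a recorded choice, made so that a contact reaching
into a pseudoknot is counted with the pseudoknot.

`tabulate_interactions()` reports the full
type x locality x context grid with two fraction blocks, each summing to
100% within its group: the share of each cell among its context's
interactions, and the pseudoknot/classical split of each cell.

## Numerical and degenerate-input notes

Everything is exact integer arithmetic; there are no tolerances.
Degenerate inputs are handled explicitly: empty structures parse to
length 0 and annotate to empty tables; structures without stems have no
ECRs and no loops; an empty interaction collection yields the all-zero
grid rather than an error.  Multiplets (a position in two canonical
pairs, which DSSR-style inputs can contain) are a hard error by default
because the topology requires a matching; `resolve_multiplets = "first"`
keeps the first pair and demotes the rest to tertiary annotations.
Dot-bracket output assigns bracket families by greedy colouring of the
crossing graph in left-end order — deterministic and minimal for the
greedy order, though not guaranteed globally minimal.

## Limitations

* Input is a base-pair list; computing pairs from 3D coordinates, and
  therefore Leontis–Westhof classes, is out of scope (classes are
  carried through from input verbatim).
* Coaxial stacking (helices spanning several stems) is not modelled.
* Loop thermodynamics are not computed; the decomposition is purely
  topological.
* Search predicates cover annotation only — no ions, ligands or entry
  metadata.
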