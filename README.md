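# knotann

Pseudoknot-aware annotation of RNA secondary structures.

Most loop classifications (hairpin, bulge, internal loop, multibranch
junction) are defined only for pseudoknot-free secondary structures, yet a
large fraction of experimentally solved RNAs contain pseudoknots.
`knotann` implements a decomposition that works identically in both
regimes, for anyone who needs to annotate, count or search structural
motifs in base-pair lists: developers of structure-prediction tools
building stratified benchmark sets, and structural biologists asking
questions like "which of my structures contain a kissing-hairpin
pseudoknot?".

## The model

A secondary structure is a matching of chain positions.  From it the
package computes:

* **Stems** — maximal runs of stacked complementary pairs
  (i, j), (i+1, j−1), …, (i+k, j−k) with k > 0.  The outermost pair is
  the *face*, the innermost the *internal pair*, the two chain fragments
  \[i, i+k\] and \[j−k, j\] the *wings*.  A pair (m, n) *crosses* a stem
  with face (i, j) when m < i < n < j or i < m < j < n — the defining
  relation of pseudoknots.
* **Elementary closed regions (ECRs)** — intervals \[i, j\] that no pair
  connects to the outside, that cannot be split into smaller closed
  regions, and whose ends are stem-face endpoints.  An ECR is *classical*
  when (i, j) is itself a stem face, otherwise it is a *pseudoknot*.
  ECRs nest into a forest.
* **Loops** — one per stem: the positions internal to the stem's internal
  pair that are not strictly inside any stem nested within it.
  Equivalently, the interior with the stem's own *H-ECRs* (ECRs
  relativized to its interior — pairs leaving the interior altogether are
  ignored) cut out, keeping their boundary *faces*.  A loop decomposes
  into *sides* between consecutive faces and is classified twice: by size
  (hairpin / internal / bulge / multiple junction, from face count and
  zero-length sides) and by pseudoknot involvement (classical / isolated
  / pseudoknotted, from pseudoknot faces and contained wings of crossing
  stems).  On pseudoknot-free input this reduces exactly to the classical
  nearest-neighbour-model decomposition.
* **Pseudoknot signatures** — each stem of a pseudoknotted ECR is an arc;
  writing a lower-case letter at each arc's left end and the matching
  capital at its right end, in coordinate order, gives a word (e.g.
  `abAB`).  Three levels form a reduction chain: *full* (all member
  stems), *upper* (stems inside nested sub-ECRs removed), *reduced*
  (parallel families of arcs — bands — collapsed).  Reduced words name
  topological classes: `abAB` is an H-knot, `abAcBC` kissing hairpins,
  `abcABC` a triple knot.
* **Tertiary interaction taxonomy** — non-canonical contacts carried in
  the input are labelled Helix–Helix / Helix–Loop / Loop–Loop by the
  secondary elements of their endpoints, local vs long-range by element
  adjacency, and pseudoknot vs classical by the innermost enclosing ECR.

## Worked example

```r
library(knotann)

s  <- fixture_figure3()          # a 31-nt, six-stem pseudoknot
st <- find_stems(s)
ec <- find_ecrs(s, st)
as.data.frame(ec[, 1:6])
#>   id start end          kind parent depth
#> 1  1     1  31 pseudoknotted     NA     1
#> 2  2     6  16     classical      1     2
#> 3  3     9  13     classical      2     3

top <- ec$id[is.na(ec$parent)]
full_signature(top, ec, st)$word     # "abcdDCefBAFE"
upper_signature(top, ec, st)$word    # "abcdBADC"
reduced_signature(top, ec, st)$word  # "abAB"  -> an H-knot
```

The chain reads: the region 1–31 is one pseudoknot built from six stems;
dropping the two stems of the nested classical region 6–16 leaves four
arcs, and collapsing the two parallel pairs of arcs shows the topology is
a plain H-knot.  Loops work the same way on the five-stem example:

```r
loop_of(fixture_figure1(), 1, find_stems(fixture_figure1()))
#> Loop of stem 1: multiple_junction, pseudoknotted
#>   sides: [11,17] [32,33] [44,46]
#>   faces: (18,31):pseudoknot_face (34,43):stem_face
#>   wings: [13,15]
```

Batch annotation, statistics and DNF search are available both in R
(`annotate_structure()`, `collection_stats()`, `search_structures()`) and
from the shell via the thin wrapper in `inst/scripts/knotann`:

```sh
Rscript inst/scripts/knotann annotate --out-dir out structures/*.ct
Rscript inst/scripts/knotann search --query "signature=abAB AND min_stems=2" structures/*.ct
```

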