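---
title: "Sorting plastid-protein gene trees and scoring bipartite targeting signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting plastid-protein gene trees and scoring bipartite targeting signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastosort)
```

## The problem

Kareniacean dinoflagellates (Karenia, Karlodinium, Takayama) carry a
fucoxanthin plastid acquired from a haptophyte endosymbiont that replaced
the ancestral peridinin plastid. Their nucleus-encoded plastid proteome is
therefore a mosaic: *plastid-late* proteins acquired from the haptophyte
donor, *plastid-early* proteins inherited vertically from the
dinoflagellate host, and occasional lateral acquisitions from green algal,
ochrophyte ("brown") or prokaryotic sources. Two computational questions
dominate this kind of study, and this package implements both:

1. **Tree sorting** — given thousands of single-gene phylogenies, assign
   each seed protein an evolutionary-origin category with a bootstrap
   score, and tally topologies and haptophyte-family affiliations.
2. **Targeting prediction** — given signal-peptide predictions, classify
   bipartite (signal peptide + transit peptide) plastid-targeting
   presequences with a cleavage-site scoring matrix adapted to kareniacean
   sequence features (arginine-rich transit-peptide starts rather than the
   diatom phenylalanine motif), plus motif and composition statistics of
   the presequence regions.

Around these cores sit the gating filters of the tree-building pipeline
(homology-hit retention, decontamination, alignment acceptance) and
deterministic synthetic-data generators that let every stage be validated
without any external downloads.

## Tree sorting

### Data model

Trees arrive as Newick or Nexus (`parseTreeFile()`); supports may be
internal node labels or `[&support=x]` branch annotations, and values on a
0–1 scale are rescaled to 0–100. Internal edges without a label are
imputed as support 0 and flagged — they can never exceed a positive
threshold, which is the conservative choice. Polytomies are preserved.
`enumerateBipartitions()` exposes the unrooted bipartition structure; the
two root-adjacent edges of a rooted binary input describe one bipartition
and are collapsed, keeping the larger label (with a warning when two
explicit labels disagree) while retaining each side's own clade label.

A `TaxonScheme` maps leaf labels to datasets by ordered regular-expression
rules (first match wins; the packaged default uses the
`<dataset>_<serial>` convention, so paralog suffixes of any shape are
tolerated) and datasets to nested groups. Group membership is transitively
closed: a Karenia leaf is also kareniacean, dinoflagellate and alveolate.

### The sorting rule

For a category to qualify on a tree, the seed protein must be sister to or
nested within a subtree consisting exclusively of members of the
category's group, with at least two member taxa (`minMembers`, the "of at
least 2 taxa" rule). Concretely, every subtree (printed clade) of the
input tree that contains the seed is checked: after setting aside the seed
itself and seed-lineage leaves, all remaining leaves must belong to the
member group, at least `minMembers` of them, and — where the category
declares a witness subgroup — at least one witness. The support of a
qualifying subtree is the bootstrap label of the edge dividing it from the
rest of the tree, and the category's score is the maximum over its
qualifying subtrees. Among categories the highest score wins; at an exact
tie, a nested pair (one member group ancestral to the other and one
qualifying side containing the other) resolves to the wider category, any
other tie is unresolved.

Three design choices deserve justification:

* **Seed-lineage neutrality.** Kareniacean leaves are ignored in purity
  checks by default (`seed_lineage_neutral`). Without this, a qualifying
  haptophyte clade that also recovers Kareniaceae as monophyletic inside
  it would be impossible, yet counting exactly those trees is part of the
  analysis. The strict alternative is one scheme flag away.
* **The alveolate witness.** The alveolate (non-plastid host signal)
  category requires one non-dinoflagellate alveolate (ciliate) on the
  qualifying side. Every pure dinoflagellate clade is trivially a pure
  alveolate clade; without the witness, the wider-category tie rule would
  absorb the entire plastid-early class into "alveolate".
* **Tie ordering.** The higher score always wins first; the
  wider-category rule applies only at exact score ties, and the
  unresolved verdict only when tied categories are not nested. This
  ordering keeps plastid-early and alveolate as distinct classes.

Scoring is clade-directional: a support label belongs to the subtree it
subtends in the written tree. The complement of a clade (the "rest of the
tree" seen from an internal edge) is not itself a scoreable subtree, which
is how a tree-traversal sorter behaves and what the reference decisions
require. The practical consequence is that input trees should be rooted
away from the seed's neighbourhood — true of automatically built trees,
which are unrooted (trifurcating) with the seed deep inside — and that
classification is invariant to leaf order and to exchanging root subtrees,
but not to adversarial re-rooting at the seed itself. The
75-bootstrap interpretation threshold annotates every call
(`passedThreshold`) without suppressing lower-scoring calls.

`tallyInternalTopology()` applies the strictest reading of topology
support: `XY|Z` is supported by an edge whose side contains every leaf of
genera X and Y present in the tree, no leaf of Z and no non-kareniacean
leaf; ties between topologies are ambiguous. Kareniacean monophyly is a
side-set equality over all bipartitions. `familyAffiliation()` reruns the
classifier with one category per haptophyte subgroup
(Chrysochromulinaceae, Isochrysidales, Prymnesiales, Phaeocystales,
Coccolithales, Pavlovales), requiring family-pure clades.

## Gating filters

`filterHits()` retains hits at e-value ≤ 1e-10 (the threshold is
inclusive, matching the "1E-10 or lower" decontamination convention; one
convention is used everywhere), drops the query's self-hit, and keeps the
single best hit per in-house dataset but the best five per fucoxanthin
dinoflagellate library, accommodating recent paralog expansions. Best
means lowest e-value, ties broken by higher bitscore then subject id, so
results are order-independent. `categorizeHomologSet()` labels queries
with no hits `lineage-specific` and queries whose homologs are all
dinoflagellate `dinoflagellate-specific`; only the rest proceed to trees.
`decontaminate()` drops sequences whose overall best hit is eubacterial,
archaeal or metazoan at e ≤ 1e-10.

`filterAlignment()` consumes a trimmed alignment (trimming itself is an
external step), removes rows with strictly more than 75% gaps — the
denominator is total alignment columns — and accepts what remains only at
≥ 100 columns and ≥ 10 rows. Residues are never altered.

## Targeting prediction

`parseSignalp5()` reads SignalP 5.0 short-format tables (the cleavage
position is the last signal-peptide residue, taken from the `CS pos: a-b`
field); `writeLegacySignalp()`/`readLegacySignalp()` provide the
SignalP 3.0–4.1-style tabular dialect for downstream tools, round-tripping
id, decision and cleavage position. Because translated UTRs and spliced
leaders can hide a true start codon, each protein is also analysed after
trimming to its first methionine (`firstMetTrim()`), and
`poolVariantCalls()` pools the two predictions, preferring a positive call
and mapping trimmed coordinates back by the trim offset; when both
variants are positive the original-coordinates call is kept (the
untrimmed sequence is the observed one).

The scoring matrix (`PSSM`) covers a contiguous window of positions
relative to the cleavage site; coordinate 0 is the first transit-peptide
residue. The default build geometry is −5…+21 (27 columns), spanning the
signal-peptide C-terminus with its LACLAC/GHG-type motifs and the
arginine-rich transit-peptide start; geometry is matrix metadata, so a
published matrix of any width loads unchanged (`readPssm()`).
`buildPssm()` computes pseudocount-smoothed log2-odds,

```
score(p, a) = log2( (count(p, a) + pc * bg[a]) / (N + pc) / bg[a] ),
```

which is 0 wherever training matches the background, and `log2(1/bg)` for
a pure column at zero pseudocount.

`asafindClassify()` keeps the original ASAFind decision structure: the
window is scored at the predicted site and at offsets −2…+2; a protein is
`plastid_high` when the at-site score reaches the high threshold *and* is
the maximum over the scan, `plastid_low` when it only reaches the low
threshold, `not_plastid` otherwise, `no_sp` without a signal peptide.
Window positions outside the sequence contribute 0 — the background
expectation — so C-terminally truncated models remain classifiable.
Because the published thresholds are deferred to external code, the
defaults here scale with the matrix: with `S*` the sum of per-position
maxima, `tHigh = 0.4 S*` and `tLow = 0.2 S*`; both are plain arguments.

The alternative route parses PrediSI- and ChloroP-style tables; a protein
is alternative-positive only when **both** tools are positive.
`mergeRoutes()` produces the final proteome id list: primary positives
unprefixed, alternative-only positives prefixed `SPTP-` so the weaker
evidence class stays visible downstream.

`extractRegions()` slices the signal-peptide region and the ~25-residue
putative partial transit peptide; `motifOccurrence()` reports, per
three-letter motif, the percentage of regions containing it at least once
(multiple hits in one region count once); `compositionAndLogo()` returns
gap-aware composition and a position × residue frequency matrix ready for
logo rendering. Alignment of regions is out of scope; the logo function
consumes aligned input.

## Synthetic data and what it shows

The generators in this package are first-class, tested code:

* `simulateOriginTree()` plants a seed sister to a pure category clade of
  chosen size with a chosen support, and places background leaves drawn
  from groups sharing no category-relevant ancestry with the planted
  group (alternating between two such groups). Every seed-containing
  subtree other than the planted one then contains an impure leaf by
  construction, so recovery of the planted category and support is exact,
  not statistical. Member datasets that belong to a second, non-ancestral
  category's group are excluded from clades — such a dataset would
  legitimately tie two categories and yield `unresolved`.
* `simulateAlignment()` plants exact per-row gap counts
  (`round(frac * columns)`).
* `simulatePresequences()` samples signal peptides of random length
  (starting with methionine) and draws the cleavage-site window from a
  matrix's implied positional distributions, emitting a matching
  SignalP 5.0 document with the true sites.

All generators are byte-deterministic under their seed and emit the exact
external formats the consuming functions read. What passing tests on
these fixtures shows is that the machinery is correct at its contracts —
thresholds applied exactly, categories recovered when the signal is
unambiguous, scores additive. What they do not show is performance on
real data: real gene trees have conflicting signal, rogue taxa and
contamination; real presequences do not follow a product-of-positions
model; and e-values here are placeholders, not alignment statistics.
Desk-scale validation sizes (1,000 random trees for oracle agreement, 500
planted trees per category, 200-sequence presequence screens) were chosen
to exercise every code path while keeping the whole suite under a minute
per property.

## Numerical choices and degenerate inputs

* Supports are validated into [0, 100]; out-of-range values are errors,
  never clamped. Proportion-scale detection triggers when all labelled
  supports are ≤ 1.
* Tie-breaking among equal-support qualifying edges within one category
  is deterministic: smaller side, then lexicographic.
* Proportion constraints with an empty denominator (a side holding only
  the seed and neutral leaves) fail rather than divide by zero.
* Empty alignments are rejected with a report; an empty hit set is
  `lineage-specific`; a star tree has no internal bipartitions and every
  topology call on it is ambiguous.
* Motif percentages use at-least-one-per-region semantics, so doubling a
  dataset changes nothing.

## Limitations

* The sorter assumes one seed per tree; multi-copy seeds must be sorted
  per copy.
* Clade-directional scoring means adversarial rootings (at or next to the
  seed) hide otherwise qualifying subtrees; inputs should be unrooted or
  rooted away from the seed, as automatically built trees are.
* SignalP, PrediSI and ChloroP are consumed as tables, never re-run or
  re-implemented; prediction quality is inherited from those tools.
* Default high/low thresholds of the presequence classifier are
  matrix-scaled conventions, not calibrated operating points; users with
  benchmark sets should set explicit thresholds.
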