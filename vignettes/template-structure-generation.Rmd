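---
title: "Generating RNA secondary structures from homologous templates"
author: "RNAtemplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating RNA secondary structures from homologous templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNAtemplate)
```

## The problem and the model

De-novo secondary-structure prediction degrades badly for long RNAs and for
structures with long single-stranded segments, while the number of
experimentally determined structures keeps growing. When a solved homolog is
available, a much easier and biologically meaningful task replaces free
folding: *transfer* the conserved parts of the homolog's structure onto the
sequence of interest, and re-predict only what the transfer could not
support. RNAtemplate implements that procedure end to end, together with a
bootstrap that decides whether the transferred structure should be believed
at all.

The pipeline, exposed as `generateStructure()`, runs in six stages:

1. **Alignment.** A global pairwise alignment of query and template
   (Needleman–Wunsch with affine gaps; defaults match 1.9, mismatch 0, gap
   opening 7, gap extension 0.5 — the ClustalW2 nucleotide settings; a gap
   of length $L$ costs $7 + 0.5L$). The alignment defines two position maps
   $A_q$ (query to template) and $A_t$ (template to query). A precomputed
   alignment can be supplied instead (`alignmentFromGapped()`,
   `readAlignedFasta()`).
2. **Template mapping.** Each query position $p$ falls into one of four
   cases: (1) $A_q(p)$ is a gap; (2) $A_q(p)$ is unpaired in the template;
   (3) $A_q(p)$ pairs with $r$ but $A_t(r)$ is a gap or the query residues
   at $p$ and $A_t(r)$ cannot form a canonical pair (Watson–Crick or G·U
   wobble); (4) the pair transfers. Cases 2/4 are *consistent*, cases 1/3
   *inconsistent*; only case-4 positions are paired in the resulting
   *intermediate structure* (`buildIntermediate()`).
3. **Decomposition.** The intermediate structure is cut into elementary
   elements (`decomposeStructure()`): *hairpins* — grown outward from each
   loop-closing pair through every enclosing pair that closes only that
   loop, absorbing interior bulges and adjacent single-strand runs — and
   *stems* — chains of the remaining pairs between multiloop junctions,
   which take no single-strand flanks.
4. **Classification.** An element is *inconsistent* when its fraction of
   inconsistent positions is strictly over a threshold: 20% for hairpins,
   10% for stems (`classifyElements()`). The thresholds are the published
   operating point of the method; both are exposed as parameters.
5. **Refinement.** Inconsistent elements are re-predicted de novo
   (`refineElement()`): hairpins by folding their contiguous span, stems by
   duplex prediction of their two strands. Because inconsistent elements
   are small, their de-novo prediction is far more dependable than free
   folding of the whole molecule.
6. **Assembly.** Consistent elements keep their transferred pairing
   verbatim, refined elements contribute their new pairs, everything else
   stays single-stranded (`assembleStructure()`); the result carries
   per-position provenance.

## Reliability: the dinucleotide-shuffle bootstrap

The pipeline produces *some* structure for any input, related or not, so
reliability must be assessed separately. `bootstrapStructure()` draws $N$
(default 100) dinucleotide-preserving shuffles of the query
(Altschul–Erickson Eulerian-path sampling, `dinucleotideShuffle()`), runs
the identical pipeline on each, and records the tree edit distance of every
generated structure to the template structure ($d$) and its free energy
($e$). The observed values are standardized against these null samples.

A note on the sign convention: we report
$z = (\bar{x}_{\mathrm{null}} - x_{\mathrm{obs}}) / s_{\mathrm{null}}$
for both metrics, so that *better than the null* (smaller distance, lower
energy) is positive and the decision rule is uniformly $z_d \ge 2$.
The standard deviation is the sample (n−1) estimator. A zero-variance null
(e.g. a homopolymer query, which only shuffles to itself) yields an NA
z-score, a degenerate-null flag, and an unreliable verdict.

The distance-based score $z_d$ is the decision metric; $z_e$ is computed
and reported but is known to be much weaker, because free energy is
position-independent — two very different structures with similar helix
content have similar energies. `repeatedBootstrap()` exposes the
run-to-run variance of the scores.

## Tree edit distance

`treeEditDistance()` implements the ordered-tree edit distance
(Zhang–Shasha, unit costs for relabel/insert/delete) on the full structure
tree: a virtual root, one internal `P` node per base pair, one `U` leaf per
unpaired position. Distances are raw integers and scale with structure
size; zero means identity. This representation choice matters when
comparing absolute values across tools: RNAdistance's full mode charges
pair insertions/deletions 2 rather than 1, so its distances differ by small
constants from the unit-cost values reported here. The implementation is
verified exhaustively against a brute-force forest-edit recursion for all
structure pairs up to length 10.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hairpinThreshold` | 0.20 | max tolerated inconsistent fraction, hairpins |
| `stemThreshold` | 0.10 | max tolerated inconsistent fraction, stems |
| `gapOpening`, `gapExtension` | 7, 0.5 | affine gap cost (score units) |
| `match`, `mismatch` | 1.9, 0 | substitution scores |
| `N` | 100 | bootstrap shuffles per run |
| `minLoop` | 3 | minimum hairpin loop of the built-in engine (nt) |

"Over the threshold" is strict: an element at exactly 20% (hairpin) or 10%
(stem) inconsistency is kept. The denominator is the number of positions
the element *owns* — paired members plus attached unpaired positions —
which is the only per-element position count the decomposition defines.

## Folding engines

The refinement stage is engine-agnostic (`FoldingEngine` contract).
`viennaEngine()` adapts the RNAfold / RNAduplex / RNAeval command-line
programs and is the production choice. `nussinovEngine()` is a built-in,
fully deterministic engine — maximum canonical pairing with a minimum
hairpin loop of 3, duplexes as maximum antiparallel non-crossing matchings,
energy −1 kcal/mol per pair — which makes every stage of the pipeline
testable and bit-reproducible with no external software. The engine choice
changes refined elements only; transferred pairing is engine-independent.

## What the synthetic data emulate — and what they do not

The package ships a generator used by its own test suite
(`randomNestedStructure()`, `makeTemplateSequence()`, `mutateHomolog()`,
`homologFixture()`):

* Structures are drawn from a stochastic grammar over *helices*: stacked
  runs of at least two base pairs (2 + geometric extension, mean ≈ 4 bp),
  hairpin loops of at least 3 nt, and interval splits that create
  multiloops. Isolated lonely pairs — which real RNAs avoid and folding
  tools explicitly suppress — are never produced. With the default
  branching probabilities roughly half of the positions are paired,
  typical of structured RNAs.
* Template sequences realize every pair with a canonical type drawn
  uniformly from A·U/U·A/G·C/C·G/G·U/U·G.
* Homologs diverge by per-position substitutions (default 15%), of which
  80% at paired sites are compensatory (the pair is rewritten with a fresh
  canonical type), plus 2% indels with geometric length (p = 0.5);
  deletions never remove both members of one pair, so gap cases are
  exercised without silently conserving pairing.

These defaults describe a mid-range homolog: clearly diverged, mostly
structure-preserving. What the generator does **not** emulate:
phylogenetic correlation (no trees or rate matrices), sequence-dependent
mutation biases, non-canonical and tertiary interactions, pseudoknots, or
the length and composition heterogeneity of real families. Passing tests
on these fixtures therefore demonstrate the correctness of the machinery
and the statistical behaviour of the bootstrap under controlled
divergence, not the biological accuracy attainable on any particular real
family.

## Numerical and design choices

* **Coordinates** are 1-based internally and externally, matching
  ViennaRNA-style pair tables and R convention.
* **Canonical pairs** include the G·U wobble, matching the pair set of the
  folding engines the pipeline feeds; `N` never pairs.
* **Alignment tie-breaks** are deterministic (diagonal over gap-in-template
  over gap-in-query), so identical inputs give identical alignments.
* **Pseudoknot removal** (`removePseudoknots()`) keeps a
  maximum-cardinality crossing-free subset of the input pairs (dynamic
  programming over the pair set); ties prefer pairs with the smaller
  opening position. Pseudoknotted input is accepted everywhere structures
  are read (bracket tiers `[] {} <>`), but the pipeline itself operates on
  nested structures.
* **Unpaired-run sharing**: a run between two hairpins is split at its
  midpoint, the left half (including the middle position of an odd run)
  going to the upstream hairpin, so no position is shared. Runs adjacent
  to a hairpin on one side only are attached whole; runs touching only
  stems (dangling ends, multiloop cores) stay unassigned and are never
  re-predicted.
* **Stem refinement** folds the two strand intervals as a duplex; refined
  stems may leave formerly paired positions unpaired, and such positions
  are recorded with de-novo provenance either way.
* **Degenerate inputs**: empty structures, all-unpaired templates, and
  homopolymer queries are legal; the bootstrap flags the resulting
  zero-variance nulls instead of dividing by zero.
* **Seeding**: every stochastic entry point takes a `seed` argument,
  derives all internal draws from it, and restores the caller's RNG state,
  so seeded runs are bit-reproducible.

## Problem sizes used by the shipped checks

The package's own verification (test suite and `scripts/acceptance.R`)
runs entirely on synthetic data at desk scale: 200 identity transfers with
50-shuffle bootstraps (lengths 20–120), 500 random homolog triples for the
mapping oracle, 1,000 structures for decomposition invariants, exhaustive
tree-edit verification over all 131 structures of length ≤ 10 (8,646
pairs), 1,000 shuffle-exactness draws, and 20-seed bootstrap
discrimination at the default divergence (15% substitutions, 80%
compensatory). These sizes were chosen as the smallest that exercise every
code path with stable statistics.

One behaviour of the method is worth stating plainly: even for an
identity transfer (query = template), the bootstrap does not certify every
structure. Small or sparsely paired structures have null distance
distributions whose mean is within two standard deviations of zero, so
their $z_d$ can fall below 2 with the generated structure being exactly
the template. This is a property of the z-score at small structure sizes,
not of the transfer machinery; on the shipped study conditions about 92%
of identity transfers score $z_d \ge 2$ (median $z_d \approx 4.7$).

## Known limitations

* Pseudoknots are removed, never predicted.
* The percent-correct metric requires both structures on the same
  sequence; cross-coordinate comparison through an alignment is out of
  scope.
* Absolute tree-edit distances are representation-dependent (see above);
  compare like with like.
* The built-in engine is a maximum-pairing model, not a thermodynamic
  one; use `viennaEngine()` when energies matter.

## A worked example

```{r example}
fx <- homologFixture(length = 70, seed = 42)
gen <- generateStructure(fx$query, fx$template, fx$structure)
gen
table(provenance(gen))
treeEditDistance(finalStructure(gen), fx$structure)
```

```{r bootstrap}
bootstrapStructure(fx$query, fx$template, fx$structure, N = 50, seed = 1)
```
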