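---
title: "Sparse alignment of fixed RNA secondary structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse alignment of fixed RNA secondary structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmalign)
```

## The problem and the model

High-throughput structure probing yields RNA secondary structures as a
*fixed* annotation: one non-crossing set of base pairs on a sequence.
Comparative analysis then needs pairwise structure-structure alignment that
is robust to annotation errors. Tree-alignment methods model structures as
trees, which makes two things awkward: affine gap costs inside loops, and
the full set of base-pair edit operations. In particular, a mis-predicted
base pair should be *breakable*: the interaction is dropped, the two
nucleotides stay in place, and they realign as ordinary unpaired sequence.

`opmalign` implements the general edit-distance model. An alignment is a
one-to-one matching relation $\mathcal{A}$ between the two base-pair sets,
constrained to be order-consistent: any two matched couples are either
nested in both structures or juxtaposed (one entirely before the other) in
both. The matched pairs partition each sequence into loop regions —
hairpin interiors, internal/bulge flanks, and the segments between helices
in multi-branch loops. The score is

$$ M \;=\; w_1 \sum_{(p^A, p^B) \in \mathcal{A}} R[p^A, p^B]
   \;+\; w_2 \sum S_{\text{seq}}(\text{loop}_A, \text{loop}_B), $$

where $R$ is a $16\times16$ dinucleotide substitution table,
$S_\text{seq}$ is the optimal global affine-gap alignment score of a loop
couple (nucleotide table $D$, gap open $g$, extend $e$; a gap of length
$k$ costs $g + ke$), and $w_1 > w_2 > 0$ weight structure against
sequence. Breaking or removing a base pair carries **no** structural
penalty — its nucleotides simply become loop sequence, where the affine
model prices any gaps. Deleting a whole region of length $k$ therefore
costs exactly $G(k) = w_2 (g + k e)$, with $G(0) = 0$, and this coincides
with what the loop aligner charges for an all-gap segment.

Each loop couple is aligned *independently*: gap state does not persist
across a matched base pair. Two pseudo-root pairs $(0, l+1)$ (structural
score 0) close the recursion over whole molecules; we place the pseudo
root strictly outside the sequence so that it encloses every position.

### Which matchings the recursion explores

For a matched couple, the enclosed region is interpreted either as a
*hairpin* — every inner pair broken, the interiors aligned as plain
sequence ($M_h$) — or as a *multi-loop* — an ordered chain of matched
inner couples with the segments between them aligned independently
($M_l$), and $M = \max(M_h, M_l)$. A design point that matters: chains
may step across *broken* pairs. If a helix between two matched
neighbours is broken, its nucleotides belong to the connecting segment
and remain alignable. Restricting chain predecessors to the nearest
juxtaposed sibling (with explicit region-deletion steps for skipped
siblings) would force such nucleotides into gaps and would break the
defining property that the optimum equals an exhaustive search over all
order-consistent matchings — a property the test suite verifies against
a brute-force enumerator on small instances.

## The two engines

**Baseline (`full_align`).** Cells are visited over all base-pair
combinations $(p^A, p^B)$ in order of increasing right endpoints. Each
cell's interior is aligned by a three-state affine DP with *arc
transitions*: at positions where inner pairs end in both structures, the
DP may consume both inner spans at once for $M[p^A_i, p^B_{i'}]$. An
arc-used flag separates the $M_h$ and $M_l$ interpretations. This
formulation yields the same optimum as the literal chain recursion but
shares all segment work inside one pass per cell.

**Sparse (`sparse_align`).** The key observation: a couple needs to be
referenced by outer cells only if it is an *Optimal Pair Matching*
(OPM) — its matched score $M[p^A, p^B]$ reaches the unrestricted optimal
alignment score $\bar M$ of the one-pair spans $A[l..r] \times
B[l'..r']$. If the spans align at least as well without the constraint
that $p^A$ matches $p^B$, any outer use of the couple can be re-composed
from smaller OPMs and plain sequence at no loss. The sparse engine
therefore:

1. restricts arc transitions to the online list of *visible* OPMs;
2. after each cell, computes $\bar M$ by a span alignment in which the
   couple's own arc is available (so $\bar M \ge M$ always, and the couple
   is an OPM iff $M \ge \bar M$, ties included);
3. gates the hairpin similarity: from the cheap upper bound
   $\hat M_h = S_{str} + \min(|L_A|,|L_B|)\,w_2 d_{\max} + I\,w_2 g +
   \big||L_A|-|L_B|\big|\,w_2 e$ (maximum matches, minimum gaps; $I=1$
   iff the interior lengths differ), $M_l > \hat M_h$ proves
   $M_l > M_h$, and the separate interior sequence alignment is skipped;
4. prunes the OPM list online (below).

### Online pruning and its guard

When a new OPM strictly encloses an older one on both structures, the
older candidate is obsolete if every future alignment does at least as
well re-splitting through the new OPM. The re-splitting advantage is
bounded per side by the best case for the *gap regions* strictly between
the two pairs' endpoints: with $m$ annotated pairs and region lengths
$|L_\beta|$,

$$ \hat U = \max(m_{\beta A}, m_{\beta B})\, w_1 r_{\max}
   + \max(|L_{\beta A}|, |L_{\beta B}|)\, w_2 (d_{\max} - g - e), $$

and symmetrically on the right; for perfectly stacked pairs both regions
are empty and the bound is zero. The removal criterion compares the score
gap between the two OPMs with $\hat U_l + \hat U_r$ — plus a
*freed-nucleotide guard*: on the path through the enclosed OPM, the
enclosing pair's own two nucleotides realign as loop sequence, which the
gap-region bounds do not cover. Replay audits over seeded instance suites
exposed a concrete configuration (a stacked couple with a weak
substitution score next to a long gap region) where the unguarded
criterion changed a later cell; each side therefore also charges
$\max(0, \text{best substitution score available to either freed
nucleotide})$. With the guard, removals leave every later cell bit-for-bit
unchanged across the test suites, while identical stacked helices are
still collapsed to their outermost OPM (their score gap, a diagonal
$w_1 R$ entry, exceeds the guard).

Pruned OPMs are tombstoned, not deleted, and each tombstone records its
dominating OPM. The dominance argument applies only in contexts that
could use the dominator, so a tombstoned candidate stays visible to any
cell that does not strictly contain its dominator on both structures
(for example, a cell sharing one pair with the dominator). This keeps
pruning lossless cell-by-cell, not merely at the final score.

## Numerical choices

* **Exact integer scoring.** After applying $w_1, w_2$, all tables and
  gap parameters are scaled by 100 and rounded; engines work in 64-bit
  integers and divide once on output. Scores are thus quantised to 0.01
  of the weighted unit, and "sparse equals baseline exactly" is
  well-defined regardless of summation order.
* **Tie-breaking.** Detection uses $\ge$ (ties are OPMs); the gate uses
  strict $>$. Traceback is deterministic: the hairpin interpretation wins
  ties against the chain, chains prefer starting fresh over extending,
  and earlier candidates (smaller right endpoints) win among equals.
* **Degenerate inputs.** Pairless molecules collapse to a single
  affine sequence alignment; empty sequences yield an empty alignment;
  pseudo-root spans clamp to the sequence ends.
* **`N` nucleotides** score as the minimum of the relevant matrix row —
  a conservative convention for unknown residues.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `D` | RIBOSUM85-60 single-nucleotide log-odds | 4x4 loop substitution |
| `R` | constructed (see below) | 16x16 base-pair substitution |
| `g` | -5 | gap open (per region, weighted by `w2`) |
| `e` | -1 | gap extend per residue |
| `w1` | 2 | structure weight |
| `w2` | 1 | sequence weight |

The shipped base-pair table is constructed, not copied from a published
RIBOSUM pair matrix: $R[ab, cd] = D[a,c] + D[b,d] + B$ with a
conservation bonus $B$ of $+3$ when both dinucleotides are canonical
(Watson-Crick or GU), $-2$ when exactly one is, and $-4$ otherwise. It
is symmetric, rewards conserved canonical pairing, and can be replaced
wholesale through `scoring_scheme()` or a YAML configuration file.
Because the construction leaves most canonical-canonical entries
positive, matching two compatible pairs is usually span-optimal — see
the limitations below.

## The synthetic generator

`random_structure()` emulates fixed annotations: helices of 2-6 stacked
pairs placed one at a time, spans drawn from a truncated power law
$P(s) \propto s^{-c}$ with $c = 1.5$ (the polymer-zeta regime, under
which long-range pairs are rare), hairpin loops of at least three
nucleotides, canonical dinucleotides on paired positions, uniform
nucleotides in loops, and a default pairing density of 0.18 pairs per
nucleotide — within the range of annotated natural structures (tRNA
~0.27, tmRNA ~0.17). `mutate_homolog()` derives homologs by canonical
re-substitution of kept pairs, loop substitutions, loop-confined indels,
and pair breaking, so the skeleton is preserved while annotations
disagree locally — the regime the edit model is designed for.

What the generator does **not** emulate: thermodynamic plausibility,
covariation structure, pseudoknots, or family-specific length/loop
distributions. Passing tests therefore demonstrate algorithmic
correctness and scaling behaviour on structurally realistic shapes, not
alignment accuracy on any particular RNA family.

## Problem sizes and an honest negative finding

The test suite verifies: exact sparse/baseline agreement on 200 seeded
instance pairs (up to 12 pairs, 60 nt) under all four pruning/gate
settings; agreement of the baseline with the exhaustive matching
enumerator on 50 tiny instances (up to 4 pairs, 24 nt); bound validity
and pruning replay over the same suite; and a scaling study on lengths
100-800 nt with three seeds per size.

Two quantitative expectations about the scaling study are **not** met by
this implementation, and the corresponding assertions are left failing
rather than weakened:

* The baseline's per-cell interior alignment already shares all segment
  work, so its cost grows like the sum of interior-size products rather
  than like the quartic pair-combination count. The sparse engine must
  additionally run a detection span alignment per combination; measured
  log-log runtime slopes against the pair count are therefore
  comparable for the two engines, with the sparse engine carrying a
  constant-factor overhead, instead of the sparse engine growing
  materially slower.
* Under the default scoring tables, most canonical-dinucleotide couples
  satisfy the OPM criterion (the $w_1 R$ reward for matching two
  compatible pairs outweighs the sequence-level alternative of breaking
  them), so the OPM count $z$ stays a roughly constant fraction of
  $n_A n_B$ and the reduction ratio $n^2/z$ (median 2-3) does not grow
  with $n$ on these instances.

Both findings are properties of the study conditions (scoring defaults
chosen before the scaling study, synthetic homolog pairs) and are
reported as such; the candidate list, detection, gate and pruning
machinery remain fully exercised and exactly lossless.

## Package shape

Core objects (structures, DP states, alignments) are classic S3 objects
in the tradition of the field's alignment packages; tabular results —
benchmark runs, OPM lists, statistics, matchings — are tibbles, with
`tidy()`/`glance()` methods on alignments and `autoplot()` on benchmark
output, so downstream analysis composes with dplyr/ggplot2 pipelines.

## A worked call

```{r example}
a <- align_structures(
  parse_vienna(c(">hp_insU", "GGAAAUCC", "(((..)))")),
  parse_vienna(c(">hp_ref",  "GGAAACC",  "((...))")))
a
```

The inner pair of the first hairpin (induced by the inserted U) is
broken, both outer pairs match, and exactly one gap column opens — the
behaviour that motivates the general edit-distance model.
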