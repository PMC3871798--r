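# opmalign

Pairwise alignment of **fixed RNA secondary structures** — a sequence plus
one non-crossing set of base pairs, as produced by experimental structure
probing or by annotation databases — under the general edit-distance model:
base pairs can be matched, mismatched, **broken** (the interaction is
dropped, the nucleotides realign as loop sequence, at no structural
penalty) or removed, and unpaired loop regions are compared by global
affine-gap sequence alignment.

The optimal alignment maximises

```
M = w1 * Σ R[p_A, p_B]           over matched base-pair couples
  + w2 * Σ S_seq(L_A, L_B)       over the loop regions the matching induces
```

with `R` a 16x16 dinucleotide substitution table, `S_seq` the Gotoh
affine-gap score (open `g`, extend `e`; a gap of length `k` costs
`g + k*e`), and `w1 > w2 > 0`. Two engines compute the identical optimum:

* `full_align()` — the baseline over all base-pair combinations, used as
  the exactness oracle;
* `sparse_align()` — restricts the recursion to **Optimal Pair Matchings**
  (couples whose matched score reaches the unrestricted score of their
  spans; only those can ever be needed), with a hairpin upper-bound gate
  and online candidate pruning.

`align_structures()` adds full traceback (matching relation, gapped rows,
structure annotation, exact score decomposition), with Stockholm output and
`tidy()`/`glance()` accessors. A seeded generator (`random_structure()`,
`mutate_homolog()`) produces polymer-zeta-style test structures, and
`bench_scaling()` reproduces the engine scaling study.

## Worked example

```r
library(opmalign)
a <- align_structures(
  read_vienna(system.file("extdata", "synthetic_a.vienna", package = "opmalign"))[[1]],
  read_vienna(system.file("extdata", "synthetic_b.vienna", package = "opmalign"))[[1]])
a
#> rna_alignment (sparse engine): score 215.52 = structure 173.18 + sequence 42.34
#>   14 matched base-pair couple(s); 0/0 pairs broken in synthetic_trna_like_a/synthetic_trna_like_b
#>   ........((((.((........)).....))))((((((.....((...))......)))))).....-.......
#>   UAAGCUCUUCCUGUAACAUCUUUUAUGCCAAGGAGCUUGAAGCUCAAUCUUUUCAUAUUCAGGCCCCAC-ACCACGA
#>   UAUGCUAUUCCUGUAACAUCGUUUAUGCCAAGGAGCUUGAAGCUCAAUCUUUUUAU-UUCAGGCCUCACUACCACGU
#>   ........((((.((........)).....))))((((((.....((...))....-.)))))).............
```

The total score 215.52 decomposes exactly into the structure term (the
`w1`-weighted substitution scores of the 14 matched base-pair couples) and
the sequence term (the `w2`-weighted affine-gap similarity of the loop
regions between them); one loop indel on each molecule shows up as the two
gap columns. The motivating case — a mis-predicted base pair induced by a
single inserted nucleotide — is bundled as `insertion_fixture()`: the
optimal alignment breaks the extra pair and opens exactly one gap column
instead of forcing a mismatch or a double gap.

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","opmalign.R",package="opmalign"))')" \
    align --engine sparse --report report.json a.vienna b.vienna
```

with subcommands `align`, `gen` (seeded synthetic structures), `bench`
(scaling CSV with an embedded engine-equivalence check) and `check`
(format validation). See `vignettes/sparse-structure-alignment.Rmd` for
the model, the OPM detection/pruning machinery and its guard terms, all
default parameters, and known limitations.

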