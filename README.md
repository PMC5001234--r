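# emsfinder

Exact solver for the **(l,d) edit-distance motif search (EMS)** problem:
given `n` sequences, find *all* strings of length `l` (l-mers) that occur
in every sequence with at most `d` errors of type substitution, insertion
or deletion (Levenshtein distance). EMS is the indel-aware generalisation
of planted (Hamming) motif search, aimed at signals — promoter elements,
binding sites, splice signals — whose instances diverge by more than point
mutation. The search is exact: the output is provably the complete motif
set, not a sample or a local optimum.

## Method in brief

For a sequence `S` of length `m`, the motif set is

```
M_{l,d}(S) = ⋃_{k=l−d}^{l+d} ⋃_{j=1}^{m−k+1} N_{l,d}(S_{j,k}),
```

the union over all k-mers of their distance-`≤ d` l-mer neighborhoods, and
the answer is `⋂_i M_{l,d}(S^(i))`. `emsfinder` makes this tractable by

* generating only neighbors at distance **exactly** `d` per k-mer
  (neighbors at smaller distance are covered by longer k-mers),
* writing substituted/inserted positions as a **wildcard** `*`, so one
  compact candidate stands for `|Σ|^#wildcards` l-mers,
* pruning duplicate candidates with nine **skip rules** on the
  edit-operation trace (provably duplication-free when all characters of
  the string are distinct), and
* storing per-string candidate sets either in a **motif trie** with
  mutually-exclusive subset-labelled edges, or in flat arrays sorted by a
  **compact radix sort** that expands wildcards while it sorts; the radix
  engine also supports a deterministic multi-worker mode.

Both engines, and every worker count, produce identical output and are
validated against a brute-force oracle. See the vignette
(`vignettes/ems-methods.Rmd`) for the full model and the design choices.

## Worked example

```r
library(emsfinder)

# a standard benchmark instance: 20 random DNA strings of length 600, a
# random 8-mer planted with exactly 1 mismatch in each string
inst <- generate_instance(l = 8, d = 1, n = 20, m = 600, seed = 7)
inst
#> <ems_instance> (8,1), n = 20, m = 600, alphabet ACGT, planted motif TGAACATG

ems_solve(inst, engine = "trie")
#> [1] "TGAACATG"
```

The exact solver recovers precisely the planted motif — on unplanted
`(8,1)` instances of this size the expected number of chance motifs is
numerically zero, so the single reported motif is the signal. The
duplication statistics of the candidate generator are available per
string:

```r
repetition_stats(inst$sequences[1], 8, 1)
#> <ems_repstats> 13,047 generated / 11,389 distinct = mean multiplicity 1.146
```

From a shell, the same workflow is:

```sh
ems generate --l 8 --d 1 --n 20 --m 600 --seed 7 --output inst.fasta
ems search --input inst.fasta --l 8 --d 1 --engine radix --workers 4 --output motifs.txt
ems stats repetition --l 11 --d 3 --m 600 --seed 1
```

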