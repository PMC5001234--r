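---
title: "Exact edit-distance motif search: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact edit-distance motif search: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsfinder)
```

## The problem

Regulatory elements, splice signals and protein binding sites diverge not
only by point mutation but also by insertion and deletion. The
edit-distance motif search (EMS) problem models this directly: given `n`
sequences `S(1), ..., S(n)` of length `m` over an alphabet `Σ` and two
integers `l > d ≥ 0`, find **every** string `M` of length `l` (an *l-mer*)
such that each input sequence contains a substring within Levenshtein
distance `d` of `M`. Because an edit operation changes string length by at
most one, only substrings of length `k` with `l − d ≤ k ≤ l + d` can
matter, so the motif set of one string `S` is

```
M_{l,d}(S) = ∪_{k=l−d..l+d} ∪_{j=1..m−k+1} N_{l,d}(S[j..j+k−1])
```

where `N_{l,d}(L)` is the set of l-mers within edit distance `d` of the
k-mer `L`, and the common motifs are the intersection of the `M_{l,d}(S(i))`
over all input sequences. `emsfinder` computes this set *exactly* — no
sampling, no heuristics — which is what distinguishes it from Gibbs-sampling
or genetic-algorithm motif finders.

The package requires `l > d`. For `l ≤ d` every l-mer is trivially within
distance `d` of short substrings and the answer degenerates to all of
`Σ^l`; ruling it out keeps every code path meaningful.

## Exact-distance generation of compact candidates

Writing `F_{l,t}(L)` for the l-mers at distance *exactly* `t` from `L`,
one has `N_{l,d}(L) = ∪_{t=0..d} F_{l,t}(L)`. The solver only ever
generates `F_{l,d}`, the friends at distance exactly `d`: a neighbor at
distance `t < d` of `L = S[j..j+k−1]` is also a neighbor (at distance
`≤ d`) of the one-longer substring `S[j..j+k]`, so over the union of all
k-mers nothing is lost. This *exactness* restriction is the first large
saving: the union over `t` never needs to be materialized.

The second saving is the *compact* representation. Substituted and
inserted positions never need a concrete symbol — any symbol of `Σ` works
equally and all choices are members of the motif set (a substitution to
the original character yields a distance-`d−1` neighbor, which is legal in
the motif set by the exactness argument above). They are therefore written
as a single wildcard `*`, so one compact motif with `w` wildcards stands
for `|Σ|^w` l-mers. Generation proceeds in three phases per k-mer:
`δ` deletions, then `β` substitutions, then `α` insertions, with

```
δ + β + α = d,   k − δ + α = l
⇒  max(0, q) ≤ δ ≤ (d + q)/2,   α = δ − q,   β = d − 2δ + q,   q = k − l.
```

`phase_plan()` exposes these triples. Within each phase, operation
positions are enumerated canonically: deletions at strictly increasing
positions, substitutions likewise, insertion points left to right with
repetition allowed (one *or more* wildcards may be inserted before a
position, and a run of `c` insertions at one point is generated as a
single canonical choice, not `c!` orderings). Deleted characters are kept
in the working string as the sentinel `-` until emission, so that rule
predicates over *original* string positions stay computable; the sentinel
is stripped when the length-`l` compact motif is emitted. An insertion
just before position `p` records `p` in the trace; an insertion at the
right end of the k-mer records `p = j + k`.

### Skip rules

Even with exact-distance compact generation, the same compact motif is
produced by several `(j, k, trace)` combinations — e.g. deleting the first
base of a k-mer gives the same result as taking the k-mer one to the right
and deleting at its far end. Nine local rules on the trace (see
`?should_skip`) prune such duplicates at generation time. Two properties
pin the implementation down, and both are enforced by tests:

* **Completeness** — the union of expansions with the rules on equals the
  union with the rules off equals the brute-force motif set.
* **Duplication-freeness on distinct characters** — on a string whose
  characters are all distinct, no compact motif is ever generated twice.

Every rule condition is a membership condition on the trace set, hence
monotone: once a partial trace matches, every completion matches. The
generator therefore re-evaluates the predicate after each appended
operation and prunes the recursion, which is provably equivalent to
filtering completed candidates (a property test checks the equivalence
explicitly against the rules-off enumeration).

On random DNA the duplication that remains is modest: on planted `(11,3)`
instances with `m = 600`, `scripts/acceptance.R` measures a mean
generation multiplicity of about **1.55** per distinct compact motif with
the rules on, versus about **2.7** for the full canonical three-phase
enumeration with the rules off. The rules-off multiset was additionally
verified against the closed-form trace count
`Σ_k (m−k+1) Σ_δ C(k,δ)·C(k−δ,β)·C(k+α,α)`, which it matches exactly, so
the 2.7 baseline is the complete canonical enumeration and not an
artifact of missing traces.

## The two set engines

Per input string the compact candidates must be stored, deduplicated and
intersected with the accumulated common set. Two engines implement this
contract; they are interchangeable and tested to produce identical output.

### Motif trie

A trie of depth `l` whose edges carry mutually exclusive non-empty subsets
of `Σ` (bitmasks). A compact motif inserts in one pass: a concrete
character descends into the unique child whose label contains it —
splitting that child copy-on-write when the label is not already a
singleton — and a wildcard descends into every child, with uncovered
symbols collected under one fresh child. Intersection pairs children by
label intersection and prunes branches with no surviving leaf eagerly, so
emptiness is visible at the root in O(1). A depth-first traversal visiting
each edge once per symbol in alphabet order enumerates the stored l-mers
sorted and duplicate-free. `trie_intersect()` is pure (it builds a new
trie); `trie_insert()` mutates in place, which is what the solver loop
wants.

### Radix arrays

The array engine stores compact motifs in flat vectors and uses a
counting sort per base position that *expands while it sorts*
(`compact_radix_sort()`): in the phase for a position, a wildcard there
increments every symbol's bucket and the motif is emitted as `|Σ|` copies
with that wildcard finalized. Phases run from the last position to the
first with a stable counting sort, so the final pass leaves the fully
expanded multiset in lexicographic order — the classical LSD argument.
The processing direction is a deliberate choice pinned by the
sorted-output contract (an MSD direction would finalize wildcards in the
same way but would need recursive bucketing to sort). Duplicate removal
and set intersection/union are then linear merge scans over strictly
increasing arrays; the scans validate their sortedness contract and abort
on violation rather than silently producing garbage.

All ordering — trie enumeration, radix phases, merge scans, and
`sort_lmers()` on the R side — is induced by the alphabet's symbol order,
never by byte values or the locale, so custom alphabets sort correctly.

### Parallel contract

With `workers > 1` the radix engine partitions the `(2d+1)(m−l+1)`
per-k-mer generation workloads of each string: the workload list is
shuffled with the solver seed (workload costs vary because of the skip
rules, so a random even split balances load), divided evenly, and each
worker generates, radix-sorts, dedupes, and — from the second string on —
filters its candidates against the accumulated common set. Workers share
nothing mutable; their sorted arrays are combined by a binary-tree union
over `log2(workers)` rounds, padding with empty arrays when the worker
count is not a power of two. The result is set-identical to the
sequential computation by construction, and a test asserts bit-identical
output for `workers ∈ {1, 2, 4}` and across partition seeds. Workers map
to forked processes (`parallel::mclapply`) where the platform supports
it, and to a sequential loop otherwise; the contract is the deterministic
partition and isolation-until-merge, not the execution vehicle.

## Solver orchestration

`ems_solve()` processes strings in input order, initializes the
accumulator from the first string's motif set and intersects it with each
subsequent set, exiting early when the accumulator empties. No
string-ordering heuristic (e.g. rarest-first) is applied — input order is
the documented behavior. A candidate-count guard (`max_candidates`,
default `5e7` compact candidates per string) aborts with a clear error
instead of exhausting memory when a user requests an `(l, d)` combination
beyond the machine; `verbose = TRUE` reports per-string candidate and
accumulator sizes. Characters outside the alphabet are rejected with an
error — the i.i.d. background model the method is built for has no
ambiguity codes, so there is no silent handling of `N`.

## Synthetic instances and statistics

`generate_instance()` implements the standard planted benchmark model:
`n = 20` i.i.d. uniform strings of length `m = 600` by default, and, per
string, an independent Hamming-distance-*exactly*-`d` neighbor of one
random l-mer written over a uniformly chosen window. Overwriting (rather
than inserting) preserves `m`, matching the benchmark tradition this
model comes from; `hamming_neighbor(at_most = TRUE)` provides the
distance-`≤ d` variant for sensitivity checks. A planted occurrence at
Hamming distance `d` is automatically within edit distance `d`, so the
planted motif is always in the exact solver's output — a property the
acceptance tests assert on twenty `(8,1)` benchmark-scale instances.

What the generator does *not* emulate: real promoter sequences are not
i.i.d. (composition bias, repeats, low-complexity stretches), real motif
instances are not uniformly mutated, and real data contain ambiguity
codes. Passing tests therefore demonstrate algorithmic correctness of the
exact search, not biological sensitivity on genomic sequence.

`repetition_stats()` measures the duplication behavior of the generator
(multiset size, distinct count, multiplicity histogram) per string.
`estimate_spurious()` estimates the expected number of *spurious* motifs —
motifs reported on unplanted random input purely by chance — by Monte
Carlo: solve `r` unplanted instances and average the output counts. A
closed-form expectation is deliberately not attempted; the Monte-Carlo
route uses the same exact solver that is validated against the
brute-force oracle, so it inherits its correctness. Two regimes are worth
knowing about at the default `n = 20`, `m = 600`: for short motifs the
count saturates near `|Σ|^l` (at `(5,1)` essentially every 5-mer is a
motif of every string), while for `(8,1)` the measured probability that a
random 8-mer is a motif of a single string is ≈ 0.32, so the expected
common count `4^8 · 0.32^20` is numerically zero — unplanted `(8,1)`
instances essentially never yield a motif, which the simulation reports
honestly.

## Oracles and test design

Correctness is defined by a brute-force oracle that shares no code with
the engines: `oracle_motifs_one_string()` checks every l-mer of `Σ^l`
against every admissible substring with a quadratic distance DP
(`utils::adist`), and a second independent route grows neighborhoods one
edit at a time (`grow_one_edit()`, iterated) and filters by length. The
two oracle variants are tested against each other, the unit-cost DP is
tested against a literal recursive definition of edit distance, and both
engines plus the parallel path are tested against the oracle on a seeded
sweep of 100 random instances with `n ∈ [2,5]`, `m ∈ [10,30]`,
`l ∈ [3,6]`, `d ∈ [0,2]`. Benchmark-scale checks use `(8,1)` and `(11,3)`
instances at `n = 20`, `m = 600`, with multiplicity statistics averaged
over a subset of strings (they are i.i.d., so a few strings estimate the
instance mean well); the single-string `(16,3)` compact-versus-expanded
comparison runs at reduced `m = 25`, where the compact representation is
already an order of magnitude smaller than its expansion. These sizes are
the package's own test design; the underlying operations have no
size-specific code paths.

## Numerical and representation choices

* Positions are 1-based and closed throughout (R convention; also the
  convention of the trace tuples), including `j`, trace positions and
  plant positions.
* Compact motifs, l-mers and arrays are plain character data; the C++
  core works on `std::string`. No bit-packed motif encoding is used — at
  the problem sizes this package targets, character arrays keep every
  interface inspectable at no relevant cost.
* Tries cap the alphabet at 31 symbols (labels are one-word bitmasks);
  DNA and the 20-letter protein alphabet both fit.
* The radix expansion guards against blow-ups past 2e8 items; the solver
  guards per-string compact counts via `max_candidates`.
* All randomness (instance generation, workload shuffling, sub-seed
  derivation for replicates) flows from explicit integer seeds through
  R's RNG; internal seeding never touches the caller's RNG state.

## Limitations

* Exactness costs exponential work in `d`; the candidate guard exists
  precisely because `(l, d)` combinations like `(20, 4)` are out of reach
  of an interpreted front end over a single-machine core.
* Weighted edit costs and approximate/heuristic search are out of scope.
* The duplication left by the skip rules on repeated characters
  (multiplicity ~1.5 on random DNA at `(11,3)`) is inherent to the local
  rule set; a globally duplication-free generator would need non-local
  coordination between k-mers.
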