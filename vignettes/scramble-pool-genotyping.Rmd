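---
title: "Simulating and genotyping Cre/loxPsym rearrangement pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and genotyping Cre/loxPsym rearrangement pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrambleseq)
```

## The system being modelled

A loxPsym-segmented module is a synthetic gene cluster in which `n` gene
cassettes alternate with `n + 1` copies of the 34 bp palindromic
loxPsym site, flanked by fixed sequence carrying the PCR primer anchors:

```
left_flank · lox · seg1 · lox · seg2 · ... · segN · lox · right_flank
```

Because the loxPsym spacer is its own reverse complement, Cre
recombination between any two sites can resolve as a **deletion** of the
intervening block, an **inversion** of it, or a tandem **duplication**.
`scrambleseq` represents the state of the array as a *signed sequence of
segment ids* (`+k` = segment `k` in reference orientation, `-k` =
inverted), the natural state space for these events. All three event
types preserve the alternating segment/lox layout, so lox sites are kept
implicit — every adjacency and both ends carry exactly one — which makes
the representation provably equivalent to tracking sites explicitly
while keeping the algebra a plain signed vector.

Conventions used throughout: `+` means "reference strand as read from
the left flank", and rendering a `-` element emits the reverse
complement of the whole segment. Internally all interval arithmetic is
0-based half-open; GFF3 I/O converts to 1-based inclusive at the
boundary. Genotype keys (e.g. `"+1,-2"`) are exact: no
reverse-complement collapsing is applied, because the flanks fix the
reading orientation of every amplicon.

## The size of the deletion/inversion design space

Deletions and inversions generate, from an intact `n`-segment module,
exactly the signed arrangements of subsets of the segments:

$$N(n) \;=\; \sum_{k=0}^{n} \binom{n}{k}\,k!\,2^k,$$

choose the `k` surviving segments, order them, orient each. `N(7)` is
1,063,623 — about one million genotypes for a seven-gene module, the
scale that makes pool-level (rather than colony-level) genotyping
necessary. Rather than assuming the formula, the package *validates* it:
`enumerate_reachable_bfs()` computes the breadth-first closure of
`apply_event()` over all applicable events and `verify_closed_form()`
checks agreement (3, 13, 79, 633, 6331 states for `n = 1..5`; the test
suite pins `n ≤ 4` and freezes the once-computed `n = 5` value to keep
runtimes low). The count includes the fully deleted genotype; a
±1 change of convention is invisible at the "about one million"
resolution, and `include_empty = FALSE` is available. Duplications are
excluded by construction — with them the space is unbounded.

```{r diversity}
verify_closed_form(3)
count_del_inv_space(7)
```

## The pool simulator and its defaults

`simulate_induction()` draws, per cell: Cre activity
(`p_cre_active = 0.6`); for active cells a Poisson(`lambda_events = 1.5`)
number of events, each with type weights (deletion 0.35, inversion 0.45,
duplication 0.20) and a uniformly chosen lox-site pair, applied
sequentially; and a reporter state (`p_reporter_flip = 0.9` for active
cells, leak `p_leak = 0.01` otherwise). Reporter and module events are
conditionally independent given Cre activity, so gated pools legitimately
contain cells with an unrearranged module. Poisson is the minimal
memoryless choice for an event count accumulated over a fixed induction
window; the type weights are set so that all three event classes appear
in modest pools. All of these are exposed in `pool_config()` — none of
them is measurable from the kind of data the package emulates, so they
are honest model knobs, not estimates.

`facs_gate()` keeps the GFP-positive mass per genotype.
`grow_select()` applies deterministic exponential growth,
`abundance × 2^(generations·μ/μmax)`, with `genotype_fitness()` encoding
the biology of a dosage-limited module in selective medium: in
`minus_his` every essential cassette must be present, and the dosage
gene's copy number maps to relative rate through a non-decreasing,
saturating `mu_of_copy` (default for `HIS5`: one copy → 0.4, two or more
→ 1.0). This encodes "one weakly expressed copy grows slowly, a second
copy restores near-wild-type growth" without claiming measured rates.
Zero-fitness genotypes drop out by default; `dead_carryover` can retain
a fraction, modelling template amplified from dead or non-growing cells.

`run_iterative_rounds()` restarts each round from the `top_k` most
abundant genotypes (clonal restart — the reporter is cured and
re-introduced between rounds in the emulated protocol) and reports the
dominant genotype's frequency and the mean dosage-gene copy number per
round.

Two qualitative behaviours follow from these mechanics and are pinned in
the acceptance tests. First, one induce→gate→select cycle drives the
dosage-gene duplication frequency among reads above 0.8: any genotype
retaining a single weak copy is outgrown by factor `2^(0.6·generations)`.
Second, under the saturating dosage response the dominant genotype's
frequency jumps between rounds 1 and 2 (the founder becomes saturated)
and is *stationary* thereafter: founder and surviving variants grow at
the same rate, so in the infinite-pool limit the frequency is exactly
constant from round 2 on. At the simulated pool size (2×10⁴ cells per
round in the test) the round-to-round difference is a zero-mean sampling
fluctuation, so the plateau check allows two binomial standard errors
(0.02) below the previous round rather than demanding literal
monotonicity from a finite sample.

Pool sizes are scaled down relative to a real sorted library (>10⁶
cells): defaults of 10⁴–2×10⁴ simulated cells preserve every frequency
the analyses compare at the package's test tolerances.

## Read synthesis

`pcr_sample()` draws molecules multinomially with weights
`abundance · exp(−β · length/1000)`. The default is `β = 0` — no length
bias — reflecting that pool-level amplicon data of this kind does not
show systematic enrichment of shorter amplicons; positive `β` is
available to study the caveat that PCR bias could distort sub-population
frequencies. No bias correction is applied at calling time; the
distortion, when enabled, is deliberately visible in the output.

`synthesize_reads()` renders each molecule, picks a strand uniformly,
and applies independent per-base substitutions (0.03), insertions
(0.02) and deletions (0.04) — a generic R9-era nanopore profile — plus
whole-read truncation with probability 0.02 at a uniform breakpoint.
Qualities are a constant placeholder (Q12): the genotyper never uses
them. Read ids carry a `truth=` tag purely so tests can score calls;
analysis code never reads it.

What the generator does *not* emulate: chimeric reads, homopolymer-
dependent error rates, strand-specific error profiles, inter-molecular
(trans) recombination, and heterotypic lox variants beyond the
probabilistic reporter model. Passing tests therefore demonstrate
correctness of the algebra, the statistics and the caller's tolerance to
uniform indel noise — not robustness to every real-world nanopore
artefact.

## The pool genotyper

Calling one read proceeds in four steps.

1. **Anchor detection.** Both primer anchors (and their reverse
   complements) are located by Myers' bit-parallel semiglobal
   edit-distance search (free start/end in the read). A read is full
   length iff both anchors are found within `max_edit_frac = 0.2` of
   their length, in one orientation and in the correct order; the read
   is then re-oriented so the left anchor leads. Reads failing this, or
   shorter than `|left_flank| + |right_flank| + 2·34` bp (the default
   minimum; note it sits just above the empty-genotype amplicon, which
   carries a single lox site — pools expected to contain fully deleted
   modules should pass an explicit `min_length`), are removed with
   per-rule QC counts. Nothing is dropped silently.

2. **Lox chunking.** loxPsym occurrences are located the same way
   (threshold `0.2 × 34 ≈ 7` edits) and accepted greedily by increasing
   distance subject to a minimum separation (0.4 × the shortest
   segment), since two genuine sites can never be closer than one
   segment. Fixed boundaries are added at the flank/array junctions,
   derived from the anchor positions and the anchors' known offsets
   inside the flanks, so terminal segments survive even when a terminal
   lox site is missed.

3. **Segment assignment.** Each inter-lox chunk is assigned by exact
   k-mer voting (k = 13, both strands of every segment) and verified by
   a banded global alignment; hits require identity ≥ 0.70 and segment
   coverage ≥ 0.80 — tolerant of ~10% read error, rejecting of spurious
   matches. A chunk that fails is retried after splitting at its best
   interior lox candidate (recursion depth ≤ 3): this repairs the ~1% of
   sites whose 34 bp were noised past the primary threshold, which would
   otherwise merge two segments into one unassignable chunk. Chunks that
   still fail are counted and flag the read (`unassigned_chunk`), as do
   unannotated interior stretches longer than `gap_max = 500` bp
   (`gap`); flagged reads are kept by default (`drop_flagged = FALSE`)
   because a partial annotation is still informative — both behaviours
   are exposed.

4. **Aggregation.** Ordered signed hits become the genotype key;
   `aggregate_calls()` tabulates keys (count-descending, ties broken by
   key for determinism) and `summary_stats()` derives the TU-count
   histogram, per-gene duplication/deletion frequencies and the
   copy-number spectrum, all read-frequency weighted.

The alignment engine (Myers search, banded Levenshtein, k-mer counting)
is a small Rcpp unit, the same design choice the edlib-backed tools in
this space make; both C++ kernels are verified in the test suite against
an independent dynamic-programming oracle written in R. Scores and
thresholds are all deterministic. Overlap resolution (greedy by score,
then longer hit, then leftmost, ≤ 20% overlap of the shorter hit) is
retained for API completeness although lox-delimited chunks are disjoint
by construction.

Numerical edge cases: the empty genotype renders and calls as the empty
key `""` (never indexed by name internally — R treats `""` specially as
a vector name); an error-free chunk short-circuits to identity 1 without
alignment; alignment bands are centred on the length-scaled diagonal and
widened by the chunk/segment length difference plus 150 bp, far beyond
the indel drift of a 2.7 kb cassette at 9% error.

## Event explanation and gene impact

`diff_genotype()` is descriptive, not a parsimony history: deletions and
duplications are read off copy numbers, and inversion blocks are maximal
runs of minus-oriented elements whose ids descend consecutively in
reference order (an isolated minus element is its own block).
Reconstructing minimal rearrangement scenarios (signed-reversal
distance) is explicitly out of scope — the analyses the package supports
report events, not histories. `annotate_gene_impact()` classifies each
annotated gene (deleted / duplicated / inverted, reported jointly when
they co-occur) and adds `utr_disrupted` when a deletion or
inversion-block boundary — a reference lox interval — overlaps the
gene's annotated 3' UTR; without UTR features a 200 bp downstream window
is used and flagged as inferred.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; a single run seed fans out to
stage-keyed substreams (`stage_seed()`), so adding a stage never
perturbs another stage's draws, and all outputs are byte-identical given
a seed. The shipped test suite runs on a scaled-down module (250–300 bp
segments) for unit tests and on the full-size ~20 kb module for the
end-to-end checks: 500 error-free reads / 20 genotypes for exact
round-trip recovery, a 2,000-read noisy pool at the default error model
for frequency recovery (±0.03) and key accuracy (≥ 99%), and 10⁴–2×10⁴
cell pools for the selection and plateau properties.

## Known limitations

* Duplication geometry is modelled as strictly tandem (block, block) —
  the minimal Cre-consistent outcome; dispersed duplications are not
  generated and would be called as whatever signed sequence they
  produce.
* The marker cassette sits outside the lox array by default and is
  excluded from TU counts; `marker_inside_lox_array` exists but marker
  rearrangement is not part of the default study conditions.
* The caller assumes segments are mutually distinguishable at the k-mer
  level; near-identical cassettes (e.g. two copies of the same promoter
  fused to different genes) would need longer k or alignment-only
  assignment.
* Genotype frequencies estimated from reads are not corrected for PCR
  length bias; with `β > 0` the distortion is intentional and visible.
* Whole-chromosome analyses (translocations, centromere repositioning)
  are out of scope; the event model is segment-level within one module.
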