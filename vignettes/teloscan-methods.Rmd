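---
title: "Detecting and classifying telomeric repeat arrays in long reads"
author: "teloscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying telomeric repeat arrays in long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant telomeres are tandem arrays of the Arabidopsis-type heptamer
TTTAGGG. Long nanopore reads are long enough to carry a whole telomeric
tract together with its subtelomeric or interstitial context, which makes
them a direct instrument for questions that assemblies answer poorly:
whether a telomeric array sits at a read end (terminal) or in its middle
(interstitial telomeric repeat, ITR); whether it is homogeneous or
block-organized, with runs of a derivative monomer such as TTTAAAA
interleaved between canonical blocks; whether interstitial arrays of
derivative monomers of the (C)CCTGGG family (DTRs) colocalize with ITRs;
and whether short canonical cores flanked by opposite-orientation
derivative arrays — candidate derivation events caught in the act — exist.

`teloscan` implements that read-level analysis as a tested pipeline:
exact-seed motif scanning, array assembly and monomer decomposition,
positional/compositional classification, junction and colocalization
detection, consensus-monomer inference by wraparound alignment (including
elongated, higher-order-repeat-like units), a strand-exchange recombinant
model for derivative monomers, and a seeded read simulator with planted
truth so that every stage is testable without external data.

All coordinates inside the package are 0-based half-open; conversion to
1-based closed happens only in the GFF3 writer.

## Seed scanning

Scanning follows the strictest published practice: the query for each
monomer class is three exact tandem copies of the motif —
`(TTTAGGG)3`, `(TTTAAAA)3`, `(CCTGGG)3` — matched with zero mismatches on
both strands (`find_exact_seeds()`, via `Biostrings::matchPattern`).
Overlapping occurrences are all reported. Zero-mismatch seeds keep the
query semantics sharp; tolerance for the 1–2-nt degenerate monomers that
real arrays contain lives entirely in the array-extension and
decomposition stages, not in the seed.

## Array assembly

`assemble_arrays()` merges seed matches of the same strand into candidate
arrays when they lie within `max_intra_array_gap` (default 14 bp, two
monomer lengths — enough to bridge a single indel-broken monomer) *and*
their monomer groups are compatible. Group compatibility is deliberately
non-transitive:

* canonical (G) and TTTAAAA (A) monomers merge — block-organized combined
  arrays are a single biological unit;
* A and CCTGGG-family (C) monomers merge — an array of the two basic
  derivatives *without* canonical blocks would be a remarkable object, and
  the pipeline must be able to see it as one array to count it
  (`check_forbidden_combination()`; the count is reported, never enforced
  as a filter, and is zero in all real libraries examined);
* G and C never merge — an ITR–DTR junction is three arrays (derivative
  flank, canonical core, derivative flank), and collapsing them would
  erase the very signal `detect_junctions()` looks for.

Boundaries are then extended outward monomer by monomer: the next window
(monomer length ± 1) must lie within `max_monomer_edit_distance`
(default 2) of a catalog monomer whose group is compatible with the
current edge monomer. Because a seed can match out of phase — `(CCTGGG)3`
matches one base into a `CCCTGGG` monomer — a polish step runs before and
after extension, moving an edge outward by 1–2 bases when that completes
an *exact* catalog monomer overlapping the array. Extended arrays that
touch are re-merged; residual overlaps between incompatible arrays keep
the longer array.

Arrays are reported in the orientation of the query motif (reverse-strand
hits are reverse-complemented before decomposition, original strand
retained), so downstream code reasons in one monomer alphabet.

## Monomer decomposition

`decompose_array()` tiles the array sequence left to right. At each
offset every catalog monomer is scored over windows of its length ± 1 bp,
and candidates are ranked by own edit distance *plus* the best achievable
distance of the following window (a one-step lookahead). The lookahead
matters: an edited monomer such as `TTTAGGA` shares its first six bases
with the degenerate catalog monomer `TTTAGG`, and a purely local choice
would take the shorter exact window and push the whole tiling out of
frame, double-counting variants. Remaining ties break canonical-first,
then exact-length window, longer window, longer monomer, lexicographic —
all documented so the tiling is deterministic. Concatenating the observed
windows always reconstructs the input exactly.

Calls are classed `canonical`, `variant` (degenerate canonical, 1–2 nt
off), `derivative_TTTAAAA`, `derivative_CCTGGG_family`, or `unassigned`
(further than 2 edits from everything). The greedy tiler is linear-time
on 20-kb reads; the test suite checks it against an exhaustive dynamic
programming tiling oracle on short strings — it attains the optimum for
substitution-type variants and stays a valid bounded tiling in the
general indel case.

## Classification

`classify_position()` calls an array TERMINAL when it starts or ends
within `edge_tol` of a read end, boundary inclusive. The default 100 bp
absorbs adapter remnants and ragged read ends; the underlying observation
("at the edge of the read") has no published distance, so the parameter
is exposed and the tests rely on planted truth rather than on the
default's absolute value.

`detect_blocks()` takes maximal runs of one monomer class (canonical
variants count as canonical and never start a block; unassigned calls
join the enclosing run) and absorbs runs shorter than `min_block_copies`
(default 3 — a block should be at least seed-sized) into the longer
flanking run, tie to the left. Copy counts always sum to the number of
monomer calls. `classify_composition()` then maps block-class sets to
`PURE_TEL`, `COMBINED_TEL_TTTAAAA`, `DTR`, or `MIXED_OTHER`.

`detect_junctions()` reports short canonical cores (at most
`core_max_copies` = 10 monomers — "a few") flanked within
`max_flank_gap` = 50 bp by DTR arrays of opposite orientations; for each
core the flank pair with the smallest total gap is kept.
`detect_colocations()` pairs interstitial telomeric arrays with
interstitial DTR arrays within `max_coloc_gap` = 1000 bp, greedily by
increasing gap, each array in at most one event; arrays already assigned
to a junction are not recycled as colocations.

## Consensus monomers and elongated units

`estimate_periods()` histograms the distances between successive
occurrences of identical words (default word 8): in a self dot plot these
are the spacings of the off-main diagonals, which equal the repeat unit
lengths. Candidates need `min_support` = 3 supporting word pairs, and the
span of supporting positions localizes each candidate within a longer
sequence. `self_dotplot()` provides the corresponding visual evidence.

`wraparound_consensus()` aligns the sequence against a cyclic template by
wraparound dynamic programming — free starting phase, best ending phase,
with an improvement sweep so deletions can cross the copy boundary —
then replaces the template by the per-column majority and iterates to
stability (at most 5 rounds; columns where deletions outnumber bases are
dropped). Alignment weights default to match +2, mismatch −3, indel −5;
they are configurable because published tandem-repeat consensus tools do
not agree on a single set, and unit lengths inferred for noisy arrays can
shift by a few base pairs between weightings. Consensus sequences are
reported in their lexicographically smallest rotation — a tandem tract
has no distinguished phase, and a canonical rotation makes outputs
comparable. The engine is a deliberate reimplementation of the
wraparound-consensus idea, not a wrapper around any external program, and
makes no claim of byte-identical output to one.

`detect_elongated_monomers()` runs the period/consensus machinery on the
sequence context around an interstitial hit (default 2 kb each side —
elongated units often flank the seed-detectable core), keeps periods of
at least twice the base motif and consensus monomers with at least two
copies that contain the base motif within 2 edits, and reports the number
of distinct consensus sequences. Arrays whose monomers are degenerate
support many motif-multiple periods, so several consensus rows per array
are expected — consistent with published reports of tens of distinct
consensus monomers per array.

## The recombinant model for derivative monomers

The derivative monomers observed next to canonical arrays resemble
recombinants of the G-rich strand (TTTAGGG) and the C-rich strand
(CCCTAAA): TTTAAAA = TTTA (G-strand) + AAA (C-strand); CCTGGG = CCT
(C-strand) + GGG (G-strand). `recombinant_decomposition()` enumerates
every way to write a monomer as a substring of one *cyclic* strand
followed by a substring of the other — cyclic because a telomeric tract
has no distinguished phase; both segment orders because the proposed
exchange has no fixed polarity; segments between 1 base and two monomer
lengths to bound the enumeration (the two extreme bounds are modelling
choices, not observations). The test suite checks the enumeration against
an independent brute-force oracle over every length-6 and length-7
monomer; about 7% of random hexamers are recombinant-valid, which
calibrates how discriminating the decomposition is.

Two generative events let the simulator reproduce the observed classes:
`strand_exchange_event()` (replace one monomer by a uniformly sampled
recombinant product — double-strand-break-plus-exchange-like) and
`amplify_block()` (insert tandem copies of a monomer —
t-loop/rolling-circle-like block elongation). Exchange followed by
amplification converts a pure canonical array into the block-organized
combined class. Two alternative formation mechanisms have been proposed
for these monomers; both are represented only as generator events, and
the package takes no position on which operates in vivo.

## The synthetic-data generator

`simulate_library()` stands in for the sequenced libraries. Each read
gets a seed-free i.i.d.-uniform backbone and one sampled architecture:
pure terminal array (50–400 monomers, flush with a read end), combined
terminal array (2–6 alternating blocks of 3 + Geometric(mean 5) copies),
ITR (30–150 monomers with a planted variant fraction, default 3%,
observed range 2–5%), DTR (30–150 monomers, CCTGGG:CCTAGG:CCCTGGG at
0.7:0.2:0.1), ITR–DTR colocation (gap 50–800 bp), ITR–DTR junction
(flanks 15–40 monomers, gaps 15–50 bp, core 3–8 monomers), HOR tract
(unit = TTTAGGG + 14–35 bp spacer, 8–15 copies, 15–30 bp from a canonical
ITR), or none. Read lengths are lognormal (median 12 kb, clipped
5–25 kb). Variant monomers are planted as an exact count
(`round(f × n)`), not Bernoulli-sampled, so a planted fraction is a sharp
truth for the estimator; they are 1–2-nt edits kept 6–8 bp long and away
from array edges. Array and block size distributions are placeholders —
the real distributions are unpublished — and no acceptance property
depends on them.

Two generator details exist purely to make truth boundaries well-defined:
boundary flanks are screened so no monomer-sized window at a planted
boundary is within 2 edits of a catalog monomer, and no window crossing a
boundary equals a catalog monomer exactly (otherwise the flank base that
happens to complete a longer monomer makes the "true" boundary genuinely
ambiguous at 1 bp). The derivative-only (TTTAAAA + CCTGGG) architecture
is planted only under the `adversarial` flag, mirroring its absence from
real libraries.

The error model is i.i.d. per base — deletion, then substitution, then
insertion-after, at defaults (2.2%, 1.7%, 1.7%) in the middle of the
cited nanopore ranges (deletions 1.6–2.7%, mismatches 1.2–2.2%,
insertions 1.1–2.4%). Truth coordinates are mapped through the edits, not
re-discovered. What the generator does *not* emulate: homopolymer-biased
errors, signal-level artefacts, quality strings, chimeric reads, or real
genomic repeat context. Passing tests therefore demonstrate correctness
of the algorithms under the stated error model, not performance on any
particular real library.

`measure_error_rates()` aligns read to truth with a banded unit-cost
global aligner (band centred on the interpolated diagonal, auto-widened
whenever the optimal path touches the band edge) and reports edits per
truth base. Single-channel rates are recovered exactly — for
deletion-only data the minimal alignment must contain exactly the planted
deletions. With all channels on, colliding edits (a deletion next to an
insertion) can be explained more cheaply as a substitution, so
alignment-measured indel rates are slight lower bounds (about 7% relative
at default rates; cost ties are broken toward gap moves to keep the
effect small). This is a property of alignment-based error estimation in
general, not of this implementation.

## Numerical choices and degenerate inputs

* Greedy tie-breaks and the canonical consensus rotation make every
  analysis path deterministic; `run_pipeline()` contains no randomness
  and reruns byte-identically.
* Length ties in `select_longest()` break by read identifier.
* Empty libraries, empty seed sets, arrays shorter than 3 monomers, and
  periods longer than the sequence all return empty results or informative
  errors rather than propagating nonsense.
* The wraparound aligner drops consensus columns only when deletions
  outnumber aligned bases, and refuses an all-deletion consensus.
* N bases never match any motif position (edit distance treats them as
  mismatches), so basecaller ambiguity cannot seed or extend an array.

## Problem sizes used by the test suite

The suite validates the zero-error round trip on a 1,000-read library
(scan→classify reproduces every planted interval, class, block structure
and event exactly), class recall/precision on a 400-read library at
default error rates (≥ 0.95 per composition class for arrays of ≥ 30
monomers), deletion-rate calibration on 1,000 × 10-kb reads at the 2.7%
upper bound (within 3 binomial standard errors), variant-fraction
recovery on 12,000 planted monomers at 5% (within 1 percentage point),
and consensus recovery for planted units of 7/28/195 bp under 3%
substitutions (within 2 edits). Junction events are deliberately fragile
under sequencing error — their cores carry only 3–8 monomers, so a single
edit can erase the exact seed — and are therefore validated on zero-error
libraries, with the error-rate behaviour reported descriptively in the
analysis scripts.

## Known limitations

* Greedy decomposition is not globally optimal for adjacent
  indel-containing variants; the variant-fraction estimate carries a
  small (+0.1 to +0.5 pp) upward bias from residual frame splits.
* Elongated-monomer reports on degenerate arrays include motif-multiple
  periods; callers interested only in genuinely composite units should
  inspect the period spectrum, as the analysis scripts do.
* The simulator's architecture frequencies are enrichment settings for
  pipeline validation, not estimates of genomic frequencies.
* Reads whose arrays are entirely shorter than three exact monomer copies
  are invisible to the scanner by design (zero-mismatch seed semantics).
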