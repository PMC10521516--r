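# teloscan

Telomeric repeat arrays in long reads: detection, classification,
consensus monomers, and a derivative-monomer model — with a seeded
simulator that makes the whole pipeline testable end to end.

## The problem

Most plant telomeres are tandem arrays of the Arabidopsis-type heptamer
(TTTAGGG)ₙ (G-strand; the C-strand reads (CCCTAAA)ₙ). Long nanopore reads
span whole telomeric tracts plus context, so read-level analysis can ask
questions assemblies obscure:

* Is an array **terminal** (at a read end) or **interstitial** (an ITR,
  in the read middle)?
* Is it homogeneous, or **block-organized** — runs of the derivative
  monomer TTTAAAA interleaved with canonical TTTAGGG blocks?
* Do interstitial derivative arrays of the (C)CCTGGG family (**DTRs**)
  colocalize with ITRs, and do short canonical cores flanked by
  opposite-orientation DTR arrays (**ITR–DTR junctions**) exist —
  candidate snapshots of derivative-monomer formation?
* Do arrays develop **elongated consensus monomers** (units up to
  ~195 bp containing the base motif), the first step toward higher-order
  repeat structure?

`teloscan` is aimed at people studying telomere variability and
satellitome evolution from long-read libraries. Scanning uses exact
`(motif)₃` seed queries with zero mismatches on both strands; arrays then
tolerate the 1–2-nt degenerate monomers (2–5% of calls) that real tracts
contain. Consensus monomers come from wraparound dynamic programming
against a cyclic template. Derivative monomers are modelled as
recombinants of the G-rich and C-rich strands: TTTAAAA = TTTA + AAA,
CCTGGG = CCT + GGG, each part a substring of one cyclic strand.

## Worked example

The 70-bp junction-mimicking probe (TTTAGGG)₅(TTTAAAA)₅ is a minimal
block-organized array:

```r
library(teloscan)
probe <- paste0(strrep("TTTAGGG", 5), strrep("TTTAAAA", 5))
read  <- data.frame(read_id = "probe", sequence = probe, length = 70L)
cl <- classify_arrays(scan_read(read), 70L)
cl[, c("start", "end", "n_monomers", "composition")]
#>   start end n_monomers          composition
#> 1     0  70         10 COMBINED_TEL_TTTAAAA
cl$blocks[[1]]
#>       class copy_count start end
#> 1 canonical          5     0  35
#> 2   TTTAAAA          5    35  70
```

One array spanning all 70 bp, two blocks of five copies each, classified
as a combined TTTAGGG+TTTAAAA array. On a simulated library the pipeline
produces the per-library frequency table (read-level and array-level
counts by composition class, zeros reported explicitly):

```r
lib <- simulate_library(sim_config(n_reads = 50), seed = 1)
run_pipeline(lib$reads, "demo_out", library_id = "demo")
#> Library: demo - 50 reads scanned, 35 with arrays
#>        PURE_TEL COMBINED_TEL_TTTAAAA DTR MIXED_OTHER
#> reads        23                   10   6           0
#> arrays       24                   10   8           0
```

`demo_out/` then holds `arrays.tsv`/`arrays.bed`/`arrays.gff3` (0-based
half-open internally; GFF3 converted at the writer), `junctions.tsv`,
`colocations.tsv`, `consensus.fasta` and a `summary.json` with the exact
parameter snapshot.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on simulated data
and write their tables under `results/`:

1. `01_simulate_library.R` — 300-read library with planted architectures
   and truth table.
2. `02_scan_classify.R` — scan, classify, count; compare with truth.
3. `03_consensus_monomers.R` — periods, wraparound consensus, elongated
   (HOR-like) units, dot plot.
4. `04_derivative_models.R` — recombinant decompositions; strand exchange
   plus amplification reproduces the combined class.
5. `05_error_calibration.R` — measured vs configured error rates across
   the cited nanopore range.

`scripts/fetch_zenodo.R` documents how to download the published
*Chenopodium* nanopore libraries and run the same pipeline on them
(multi-GB; entirely optional).

The methods vignette (`vignettes/teloscan-methods.Rmd`) explains the
model, every tunable parameter with its default and rationale, what the
simulator does and does not emulate, and known limitations.

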