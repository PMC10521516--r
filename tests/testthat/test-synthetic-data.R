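test_that("identical seeds give byte-identical libraries", {
  cfg <- sim_config(n_reads = 25)
  f1 <- tempfile(fileext = ".fasta"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fasta"); t2 <- tempfile(fileext = ".tsv")
  simulate_library(cfg, seed = 42, fasta = f1, truth_tsv = t1)
  simulate_library(cfg, seed = 42, fasta = f2, truth_tsv = t2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(t1), readLines(t2))
  # a different seed changes the output
  f3 <- tempfile(fileext = ".fasta")
  simulate_library(cfg, seed = 43, fasta = f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("planted class counts follow the configured frequencies", {
  cfg <- sim_config(n_reads = 200,
                    class_freqs = c(pure_terminal = 0.5, none = 0.5),
                    error_model = error_model(0, 0, 0))
  lib <- simulate_library(cfg, seed = 13)
  k <- sum(lib$reads$architecture == "pure_terminal")
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.5)   # exact binomial 99% CI
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("coordinate maps track truth positions through edits", {
  set.seed(3)
  s <- rand_dna(500)
  id <- apply_error_model(s, error_model(0, 0, 0))
  expect_equal(id$sequence, s)
  expect_equal(id$map, 0:500)

  noisy <- apply_error_model(s, error_model(0.05, 0.05, 0.05))
  expect_equal(length(noisy$map), 501)
  expect_true(all(diff(noisy$map) >= 0))
  expect_equal(noisy$map[501], nchar(noisy$sequence))
})

test_that("the banded aligner reproduces adist costs and exact edit counts", {
  set.seed(29)
  for (i in 1:10) {
    a <- rand_dna(400)
    b <- apply_error_model(a, error_model(0.04, 0.03, 0.03))$sequence
    r <- teloscan:::.banded_align_cpp(a, b, 60)
    expect_equal(r$cost, utils::adist(a, b)[1, 1])
    expect_equal(r$deletions - r$insertions, nchar(a) - nchar(b))
  }
  expect_equal(unname(measure_error_rates("ACGTACGT", "ACGTACGT")),
               c(0, 0, 0))
  # deletion-only edits are recovered exactly (cost equals planted count)
  set.seed(30)
  a <- rand_dna(2000)
  out <- apply_error_model(a, error_model(0.03, 0, 0))
  planted <- 2000 - nchar(out$sequence)
  rates <- measure_error_rates(out$sequence, a)
  expect_equal(unname(rates["deletion"]) * 2000, planted)
})

test_that("measured error rates match configured rates within binomial noise", {
  base_cfg <- function(em) {
    sim_config(n_reads = 60, read_len_median = 2000, read_len_sdlog = 0,
               read_len_range = c(2000, 2000),
               class_freqs = c(pure_terminal = 0, none = 1),
               error_model = em)
  }
  # each channel in isolation is recovered without bias (upper bounds of
  # the nanopore ranges)
  single <- list(deletion = error_model(0.027, 0, 0),
                 mismatch = error_model(0, 0.022, 0),
                 insertion = error_model(0, 0, 0.024))
  for (ch in names(single)) {
    lib <- simulate_library(base_cfg(single[[ch]]), seed = 77)
    counts <- t(mapply(measure_error_rates, lib$reads$sequence,
                       lib$reads$truth_sequence))
    n_bases <- sum(nchar(lib$reads$truth_sequence))
    p <- single[[ch]][[ch]]
    se <- sqrt(p * (1 - p) / n_bases)
    expect_lt(abs(mean(counts[, ch]) - p), 3.5 * se)
    others <- setdiff(colnames(counts), ch)
    if (ch == "mismatch") {
      # substitution pairs can tie with a deletion-insertion explanation;
      # the leakage is bounded, not zero
      expect_lt(max(colMeans(counts)[others]), 1e-3)
    } else {
      # length accounting forces indel-only channels to stay pure
      expect_equal(unname(colSums(counts)[others]), c(0, 0))
    }
  }
  # with all channels on, colliding edits (a deletion next to an insertion
  # aligns as one substitution) make alignment-measured rates slight lower
  # bounds; allow that collision bias on top of binomial noise
  em <- error_model(0.027, 0.017, 0.02)
  lib <- simulate_library(base_cfg(em), seed = 78)
  counts <- t(mapply(measure_error_rates, lib$reads$sequence,
                     lib$reads$truth_sequence))
  for (ch in c("deletion", "mismatch", "insertion")) {
    p <- em[[ch]]
    expect_lt(abs(mean(counts[, ch]) - p) / p, 0.12)
  }
})

test_that("zero-error libraries round-trip through scan and classify exactly", {
  cfg <- sim_config(n_reads = 40, error_model = error_model(0, 0, 0))
  lib <- simulate_library(cfg, seed = 99)
  res <- scan_library(lib$reads)
  expect_equal(nrow(res$arrays), nrow(lib$truth))
  for (i in seq_len(nrow(lib$truth))) {
    tr <- lib$truth[i, ]
    hit <- res$arrays[res$arrays$read_id == tr$read_id &
                        res$arrays$start == tr$start &
                        res$arrays$end == tr$end, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$composition, tr$composition)
    expect_equal(hit$strand, tr$strand)
    expect_equal(hit$n_monomers, tr$n_monomers)
    # planted block structure is recovered verbatim
    got_blocks <- paste(hit$blocks[[1]]$class, hit$blocks[[1]]$copy_count,
                        sep = ":", collapse = ";")
    expect_equal(got_blocks, tr$blocks)
  }
  # planted events are recovered
  expect_equal(nrow(res$junctions),
               sum(lib$truth$role == "junction_core"))
  expect_equal(nrow(res$colocations),
               sum(lib$truth$role == "coloc_itr"))
  # no derivative-only arrays under non-adversarial settings
  expect_equal(check_forbidden_combination(res$arrays), 0L)
})
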