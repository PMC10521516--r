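test_that("period estimation finds exact and noisy tandem periods", {
  pd <- estimate_periods(strrep("TTTAGGG", 20))
  expect_equal(pd$period[1], 7L)

  # planted 195-bp unit x8 with 2% substitutions
  set.seed(14)
  unit <- paste0("TTTAGGG", rand_dna(188))
  arr <- strsplit(strrep(unit, 8), "")[[1]]
  hit <- sample(length(arr), round(0.02 * length(arr)))
  arr[hit] <- vapply(arr[hit],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     "")
  pd <- estimate_periods(paste(arr, collapse = ""), max_period = 250)
  expect_lte(abs(pd$period[1] - 195L), 2L)

  # non-repetitive sequence: nothing above the support threshold
  set.seed(16)
  pd0 <- estimate_periods(rand_dna(1000))
  expect_equal(nrow(pd0), 0)

  # period is invariant under reverse complementation
  comb <- paste0(strrep("TTTAGGG", 15), strrep("TTTAAAA", 12))
  expect_equal(estimate_periods(comb)$period[1],
               estimate_periods(rc(comb))$period[1])
})

test_that("wraparound consensus is exact on clean tandems of many unit sizes", {
  set.seed(41)
  for (m_len in c(6, 7, 8, 28, 195)) {
    for (k in c(3, 10, 50)) {
      if (m_len == 195 && k == 50) k <- 10   # keep the case set lean
      unit <- rand_dna(m_len)
      rep <- wraparound_consensus(strrep(unit, k), m_len)
      expect_equal(rep$consensus, teloscan:::canonical_rotation(unit))
      expect_equal(rep$copy_number, k)
      expect_equal(rep$percent_identity, 1)
      expect_equal(rep$indel_rate, 0)
    }
  }
  expect_error(wraparound_consensus("ACGT", 10), "period exceeds")
})

test_that("a single substitution costs exactly one identity unit", {
  s <- strrep("TTTAGGG", 10)
  substr(s, 20, 20) <- "C"
  rep <- wraparound_consensus(s, 7)
  expect_equal(rep$consensus, "AGGGTTT")     # canonical rotation of TTTAGGG
  expect_equal(rep$percent_identity, 69 / 70)
  expect_equal(rep$indel_rate, 0)
})

test_that("planted 195-bp units are recovered within edit distance 2", {
  set.seed(52)
  for (trial in 1:3) {
    unit <- paste0("TTTAGGG", rand_dna(188))
    arr <- strsplit(strrep(unit, 6), "")[[1]]
    hit <- sample(length(arr), round(0.03 * length(arr)))
    arr[hit] <- vapply(arr[hit],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1), "")
    seq <- paste(arr, collapse = "")
    pd <- estimate_periods(seq, max_period = 250)
    rep <- wraparound_consensus(seq, pd$period[1])
    dists <- utils::adist(rep$consensus,
                          vapply(1:195, function(i) {
                            paste0(substr(unit, i, 195), substr(unit, 1, i - 1))
                          }, ""))
    expect_lte(min(dists), 2)
  }
})

test_that("elongated monomers are reported only when a longer unit exists", {
  set.seed(63)
  # planted HOR: TTTAGGG + 21-bp spacer, 12 copies
  unit <- paste0("TTTAGGG", teloscan:::.gen_spacer(21, clean_left = TRUE,
                                                   clean_right = TRUE))
  lead <- teloscan:::.gen_spacer(300, clean_left = TRUE, clean_right = TRUE)
  read <- make_read(paste0(lead, strrep("TTTAGGG", 25), strrep(unit, 12),
                           lead))
  hit <- data.frame(read_id = "r1", start = 300L, end = 300L + 175L,
                    stringsAsFactors = FALSE)
  rep <- detect_elongated_monomers(read, hit, context = 600L)
  expect_gte(nrow(rep), 1)
  expect_true(28 %in% rep$period)
  best <- rep[rep$period == 28, ][1, ]
  expect_true(teloscan:::contains_motif_cyclic(best$consensus, "TTTAGGG", 2))

  # a pure array has only the 7-bp period: no elongated monomer
  pure <- make_read(paste0(lead, strrep("TTTAGGG", 40), lead))
  hitp <- data.frame(read_id = "r1", start = 300L, end = 300L + 280L)
  expect_equal(nrow(detect_elongated_monomers(pure, hitp, context = 400L)), 0)

  # two distinct units (28 and 42 bp) -> two distinct consensus monomers
  unit2 <- paste0("TTTAGGG", teloscan:::.gen_spacer(35, clean_left = TRUE,
                                                    clean_right = TRUE))
  read2 <- make_read(paste0(lead, strrep("TTTAGGG", 25), strrep(unit, 12),
                            strrep(unit2, 10), lead))
  rep2 <- detect_elongated_monomers(read2, hit, context = 1500L)
  expect_equal(rep2$distinct_consensus_count[1], 2L)
})

test_that("dot plots show tandem diagonals whose spacing is the period", {
  dp <- self_dotplot(strrep("TTTAGGG", 10), word = 7)
  offs <- dp$forward$j - dp$forward$i
  expect_true(all(offs %% 7 == 0))
  expect_true(all(c(7, 14, 21) %in% offs))
  # main diagonal present
  expect_true(any(offs == 0))

  # palindromic insert populates the reverse-complement set
  set.seed(71)
  pal <- "ACCGGTACGTACCGGT"
  core <- rand_dna(40)
  dp2 <- self_dotplot(paste0(core, pal, rc(pal), core), word = 6)
  expect_gt(nrow(dp2$reverse), 0)

  # diagonal spacing mode equals the top estimated period
  comb <- strrep("TTTAGGG", 30)
  dp3 <- self_dotplot(comb, word = 7)
  off3 <- dp3$forward$j - dp3$forward$i
  off3 <- off3[off3 > 0]
  mode_off <- as.integer(names(which.max(table(off3))))
  expect_equal(mode_off, estimate_periods(comb)$period[1])

  tsv <- tempfile(fileext = ".tsv")
  write_dotplot_tsv(dp, tsv)
  expect_true(file.exists(tsv))
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(dp$forward) + nrow(dp$reverse))
})
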