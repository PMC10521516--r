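test_that("position classification is edge-inclusive, exhaustive and monotone", {
  expect_equal(classify_position(0, 2000, 19572), "TERMINAL")
  expect_equal(classify_position(10000, 10400, 24378), "INTERSTITIAL")
  # array ending exactly edge_tol from the read end is still terminal
  expect_equal(classify_position(5000, 10000 - 100, 10000), "TERMINAL")
  expect_equal(classify_position(5000, 10000 - 101, 10000), "INTERSTITIAL")
  expect_error(classify_position(-1, 50, 100), "outside")
  expect_error(classify_position(10, 200, 100), "outside")

  # growing edge_tol never flips TERMINAL -> INTERSTITIAL
  set.seed(4)
  for (i in 1:50) {
    L <- sample(1000:20000, 1)
    s <- sample(0:(L - 10), 1); e <- s + sample(1:(L - s), 1)
    cls <- vapply(c(0, 50, 100, 500, 2000),
                  function(tol) classify_position(s, e, L, tol), "")
    expect_true(all(diff(cls == "TERMINAL") >= 0))
  }
})

test_that("block detection finds runs, absorbs short ones, and conserves calls", {
  probe_calls <- decompose_array(paste0(strrep("TTTAGGG", 5),
                                        strrep("TTTAAAA", 5)))
  b <- detect_blocks(probe_calls)
  expect_equal(b$class, c("canonical", "TTTAAAA"))
  expect_equal(b$copy_count, c(5L, 5L))
  expect_equal(b$start, c(0L, 35L))
  expect_equal(b$end, c(35L, 70L))

  one <- detect_blocks(decompose_array(strrep("TTTAGGG", 50)))
  expect_equal(one$class, "canonical")
  expect_equal(one$copy_count, 50L)

  # planted pattern G10 A5 G8 A7
  pat <- paste0(strrep("TTTAGGG", 10), strrep("TTTAAAA", 5),
                strrep("TTTAGGG", 8), strrep("TTTAAAA", 7))
  b4 <- detect_blocks(decompose_array(pat))
  expect_equal(b4$copy_count, c(10L, 5L, 8L, 7L))
  expect_equal(b4$class, rep(c("canonical", "TTTAAAA"), 2))

  # runs below min_block_copies are absorbed by the longer flank (tie: left)
  short <- paste0(strrep("TTTAGGG", 10), strrep("TTTAAAA", 2),
                  strrep("TTTAGGG", 4))
  bs <- detect_blocks(decompose_array(short))
  expect_equal(bs$class, "canonical")
  expect_equal(bs$copy_count, 16L)

  set.seed(8)
  for (i in 1:20) {
    ks <- sample(1:12, sample(2:5, 1), replace = TRUE)
    cls <- rep(c("TTTAGGG", "TTTAAAA"), length.out = length(ks))
    calls <- decompose_array(paste(rep(cls, ks), collapse = ""))
    b <- detect_blocks(calls)
    expect_equal(sum(b$copy_count), nrow(calls))
    expect_true(all(b$class[-1] != b$class[-nrow(b)]))
  }
})

test_that("composition classes follow the definition table exactly", {
  blk <- function(cls) data.frame(class = cls, copy_count = 5,
                                  start = 0, end = 35)
  expect_equal(classify_composition(blk("canonical")), "PURE_TEL")
  expect_equal(classify_composition(blk(c("canonical", "TTTAAAA"))),
               "COMBINED_TEL_TTTAAAA")
  expect_equal(classify_composition(blk(c("CCTGGG", "CCTGGG"))), "DTR")
  # enumeration over all class multisets up to length 3
  classes <- c("canonical", "TTTAAAA", "CCTGGG")
  combos <- expand.grid(a = classes, b = classes, c = classes,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    present <- unique(unlist(combos[i, ]))
    want <-
      if (setequal(present, "canonical")) "PURE_TEL"
      else if (setequal(present, c("canonical", "TTTAAAA")))
        "COMBINED_TEL_TTTAAAA"
      else if (setequal(present, "CCTGGG")) "DTR"
      else "MIXED_OTHER"
    expect_equal(classify_composition(blk(unlist(combos[i, ]))), want)
  }
})

test_that("junction detection matches the brute-force triple scan", {
  # adjacent DTR(+) / short canonical core / DTR(-) with zero gaps
  jread <- make_read(paste0(strrep("CCTGGG", 20), strrep("TTTAGGG", 4),
                            rc(strrep("CCTGGG", 18))))
  cl <- classify_arrays(scan_read(jread), jread$length, edge_tol = 0)
  expect_equal(nrow(cl), 3)
  j <- detect_junctions(cl)
  expect_equal(nrow(j), 1)
  expect_equal(j$core_copies, 4L)
  expect_equal(j$left_strand, "+")
  expect_equal(j$right_strand, "-")

  # one flank only -> no junction
  half <- make_read(paste0(strrep("CCTGGG", 20), strrep("TTTAGGG", 4)))
  clh <- classify_arrays(scan_read(half), half$length, edge_tol = 0)
  expect_equal(nrow(detect_junctions(clh)), 0)

  # simulated junction reads: implementation == oracle
  cfg <- sim_config(n_reads = 8, error_model = error_model(0, 0, 0))
  set.seed(19)
  for (k in 1:8) {
    sim <- simulate_read(cfg, sprintf("jr%d", k), arch = "junction")
    cl <- classify_arrays(scan_read(sim$read), sim$read$length)
    got <- detect_junctions(cl)
    want <- junction_oracle(cl)
    expect_equal(nrow(got), length(want))
    expect_equal(nrow(got), 1)
    expect_equal(got$core_start, unname(want[[1]]["core"]))
  }

  # two junctions on one read, non-overlapping
  set.seed(23)
  s1 <- simulate_read(cfg, "a", arch = "junction")
  gap <- teloscan:::.gen_spacer(3000, clean_left = TRUE, clean_right = TRUE)
  double <- make_read(paste0(s1$read$truth_sequence, gap,
                             s1$read$truth_sequence))
  cl2 <- classify_arrays(scan_read(double), double$length)
  expect_equal(nrow(detect_junctions(cl2)), 2)
})

test_that("colocation pairing is nearest-first and respects the gap cap", {
  cfg <- sim_config(n_reads = 4, error_model = error_model(0, 0, 0))
  set.seed(31)
  sim <- simulate_read(cfg, "c1", arch = "colocated")
  cl <- classify_arrays(scan_read(sim$read), sim$read$length)
  co <- detect_colocations(cl)
  expect_equal(nrow(co), 1)
  tr <- sim$truth
  planted_gap <- max(tr$start[2] - tr$end[1], tr$start[1] - tr$end[2])
  expect_equal(co$gap, planted_gap)

  # far apart -> nothing
  expect_equal(nrow(detect_colocations(cl, max_coloc_gap = 10L)), 0)

  # ITR flanked by two DTRs: nearest DTR wins; equals the oracle
  mk <- function(s, e, comp, pos = "INTERSTITIAL") {
    data.frame(read_id = "x", start = s, end = e, strand = "+",
               n_monomers = 30L, composition = comp, position = pos,
               stringsAsFactors = FALSE)
  }
  trio <- rbind(mk(1000, 1500, "DTR"), mk(1900, 2400, "PURE_TEL"),
                mk(2500, 3000, "DTR"))
  got <- detect_colocations(trio)
  expect_equal(nrow(got), 1)
  expect_equal(got$dtr_start, 2500)     # gap 100 beats gap 400
  orc <- colocation_oracle(trio)
  expect_equal(got$gap, unname(orc[[1]]["gap"]))
})

test_that("derivative-only combined arrays are counted, never filtered", {
  # adversarial array: TTTAAAA block plus CCTGGG block, no canonical
  adv <- make_read(paste0(strrep("TTTAAAA", 5), strrep("CCTGGG", 5)))
  cl <- classify_arrays(scan_read(adv), adv$length)
  expect_equal(nrow(cl), 1)            # assembles as ONE array
  expect_equal(cl$composition, "MIXED_OTHER")
  expect_equal(check_forbidden_combination(cl), 1L)

  # mixed library: planted count recovered exactly
  cfg <- sim_config(n_reads = 12, error_model = error_model(0, 0, 0),
                    adversarial = TRUE,
                    class_freqs = c(pure_terminal = 0.4, itr = 0.3,
                                    forbidden = 0.3))
  lib <- simulate_library(cfg, seed = 61)
  res <- scan_library(lib$reads)
  planted <- sum(lib$truth$role == "forbidden")
  expect_gt(planted, 0)
  expect_equal(check_forbidden_combination(res$arrays), planted)
})
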