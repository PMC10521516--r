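probe <- paste0(strrep("TTTAGGG", 5), strrep("TTTAAAA", 5))  # 70 bp

test_that("compile_seed builds tandem queries", {
  expect_equal(compile_seed("TTTAGGG", 3), "TTTAGGGTTTAGGGTTTAGGG")
  expect_equal(nchar(compile_seed("TTTAGGG", 3)), 21)
  expect_equal(compile_seed("A", 1), "A")
  expect_equal(compile_seed("CCTGGG", 3),
               paste(rep("CCTGGG", 3), collapse = ""))
})

test_that("exact seeds are found at every overlapping position on both strands", {
  s <- find_exact_seeds(make_read(probe))
  can <- s[s$motif == "TTTAGGG", ]
  expect_equal(can$start, c(0L, 7L, 14L))
  expect_equal(can$strand, rep("+", 3))
  aaa <- s[s$motif == "TTTAAAA", ]
  expect_equal(aaa$start, c(35L, 42L, 49L))

  set.seed(9)
  expect_equal(nrow(find_exact_seeds(make_read(rand_dna(1000)))), 0)

  # C-strand tract: canonical seeds on strand "-" with + coordinates
  cstrand <- make_read(strrep("CCCTAAA", 4))
  sm <- find_exact_seeds(cstrand)
  expect_true(all(sm$strand == "-"))
  expect_true(all(sm$motif == "TTTAGGG"))
  expect_equal(sm$start, c(0L, 7L))
  # mirrored coordinates match a scan of the reverse complement
  sp <- find_exact_seeds(make_read(rc(cstrand$sequence)))
  expect_equal(sort(28L - sm$end), sort(sp$start))
})

test_that("greedy decomposition reconstructs its input on reference cases", {
  d <- decompose_array(strrep("TTTAGGG", 3))
  expect_equal(d$class, rep("canonical", 3))

  d <- decompose_array(probe)
  expect_equal(d$class, c(rep("canonical", 5), rep("derivative_TTTAAAA", 5)))

  # middle monomer with one deletion -> degenerate variant call
  d <- decompose_array("TTTAGGGTTTAGGTTTAGGG")
  expect_equal(d$class, c("canonical", "variant", "canonical"))
  expect_equal(d$observed[2], "TTTAGG")

  # substitution-only variants keep the greedy tiler in frame, where it
  # attains the DP tiling optimum; with indel variants greedy stays a
  # valid (reconstructing) tiling bounded below by the optimum
  set.seed(33)
  subst <- function(m) {
    i <- sample(7, 1)
    substr(m, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(m, i, i)), 1)
    m
  }
  for (rep_i in 1:10) {
    mono <- rep("TTTAGGG", 6)
    for (j in sample(6, sample(0:2, 1))) mono[j] <- subst(mono[j])
    s <- paste(mono, collapse = "")
    d <- decompose_array(s)
    expect_equal(paste(d$observed, collapse = ""), s)
    expect_equal(sum(d$dist), dp_tiling_cost(s))
  }
  for (rep_i in 1:10) {
    mono <- rep("TTTAGGG", 6)
    for (j in sample(6, sample(0:2, 1))) {
      mono[j] <- teloscan:::.mutate_canonical()
    }
    s <- paste(mono, collapse = "")
    d <- decompose_array(s)
    expect_equal(paste(d$observed, collapse = ""), s)
    expect_gte(sum(d$dist), dp_tiling_cost(s))
  }
})

test_that("arrays assemble with exact boundaries and variant accounting", {
  tract <- strrep("TTTAGGG", 50)
  set.seed(21)
  read <- make_read(paste0("GATCAC", tract, "CATGAT"))
  h <- scan_read(read)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(6L, 6L + 350L))
  expect_equal(h$n_canonical, 50L)

  # two substituted monomers -> 48 canonical + 2 variant (4%)
  mono <- rep("TTTAGGG", 50)
  mono[c(20, 35)] <- c("TTTAGCG", "TATAGGG")
  read2 <- make_read(paste0("GATCAC", paste(mono, collapse = ""), "CATGAT"))
  h2 <- scan_read(read2)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$n_canonical, 48L)
  expect_equal(h2$n_variant, 2L)
  expect_equal(h2$variant_fraction, 0.04)
  expect_false(h2$degenerate_rich)

  # distant tracts stay separate
  set.seed(3)
  spacer <- teloscan:::.gen_spacer(5000, clean_left = TRUE,
                                   clean_right = TRUE)
  read3 <- make_read(paste0(tract, spacer, strrep("TTTAGGG", 30)))
  h3 <- scan_read(read3)
  expect_equal(nrow(h3), 2)
  expect_error(assemble_arrays(make_read("ACGT", "other"),
                               find_exact_seeds(make_read(probe))),
               "different read")
})

test_that("scanning is strand-symmetric and arrays reconstruct their sequence", {
  set.seed(12)
  cfg <- sim_config(n_reads = 12, error_model = error_model(0, 0, 0))
  lib <- simulate_library(cfg, seed = 55)
  for (i in seq_len(nrow(lib$reads))) {
    read <- lib$reads[i, ]
    h <- scan_read(read)
    if (nrow(h) == 0) next
    # reconstruction: concatenated calls equal the (oriented) subsequence
    for (k in seq_len(nrow(h))) {
      sub <- substr(read$sequence, h$start[k] + 1, h$end[k])
      if (h$strand[k] == "-") sub <- rc(sub)
      expect_equal(paste(h$monomer_calls[[k]]$observed, collapse = ""), sub)
    }
    # strand symmetry: mirrored coordinates, flipped strands
    mirror <- scan_read(make_read(rc(read$sequence), read$read_id))
    expect_equal(nrow(mirror), nrow(h))
    expect_equal(sort(read$length - mirror$end), sort(h$start))
    expect_equal(sort(read$length - mirror$start), sort(h$end))
    expect_equal(sum(mirror$strand == "+"), sum(h$strand == "-"))
    expect_equal(sum(mirror$strand == "-"), sum(h$strand == "+"))
  }
})

test_that("planted variant fractions are recovered within two points", {
  set.seed(77)
  for (f in c(0, 0.02, 0.05)) {
    mono <- teloscan:::.calls_canonical(150, f)
    read <- make_read(paste0(
      teloscan:::.gen_spacer(30, clean_right = TRUE,
                             right_ctx = paste(mono, collapse = "")),
      paste(mono, collapse = ""),
      teloscan:::.gen_spacer(30, clean_left = TRUE,
                             left_ctx = paste(mono, collapse = ""))))
    h <- scan_read(read)
    expect_equal(nrow(h), 1)
    expect_lt(abs(h$variant_fraction - f), 0.02 + 1e-9)
  }
})
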