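#' Oxford-Nanopore-like per-base error model
#'
#' Independent per-base deletion, mismatch and insertion probabilities.
#' Defaults sit at the midpoints of the rates reported for R9.4/Guppy
#' nanopore data: deletions 1.6--2.7%, mismatches 1.2--2.2%, insertions
#' 1.1--2.4%. The model is i.i.d. per base (no homopolymer bias).
#'
#' @param deletion,mismatch,insertion per-base rates, each in `[0, 0.1]`.
#' @return list of class `tel_error_model`.
#' @export
error_model <- function(deletion = 0.022, mismatch = 0.017,
                        insertion = 0.017) {
  for (r in c(deletion, mismatch, insertion)) {
    stopifnot(r >= 0, r <= 0.1)
  }
  structure(list(deletion = deletion, mismatch = mismatch,
                 insertion = insertion), class = "tel_error_model")
}

#' Simulation configuration
#'
#' Defines the read-length distribution, the planted repeat-architecture
#' frequencies, block/array size distributions and the error model for a
#' simulated library. The default architecture mix is enriched in
#' array-bearing reads so that every pipeline stage sees material (real
#' libraries carry arrays on well under 1% of reads; see the methods
#' vignette).
#'
#' @param n_reads number of reads.
#' @param read_len_median,read_len_sdlog,read_len_range lognormal read
#'   length parameters (median bp, sdlog) and clip range.
#' @param class_freqs named numeric vector over architectures
#'   `pure_terminal`, `combined_terminal`, `itr`, `dtr`, `colocated`,
#'   `junction`, `hor`, `none` (plus `forbidden` when `adversarial`);
#'   must sum to 1.
#' @param variant_fraction fraction of 1--2-nt variant monomers planted in
#'   interstitial telomeric arrays (observed range 2--5%).
#' @param error_model see [error_model()].
#' @param adversarial also plant derivative-only (TTTAAAA + CCTGGG) arrays,
#'   which are never observed in real libraries.
#' @return list of class `tel_sim_config`.
#' @export
sim_config <- function(n_reads = 100L,
                       read_len_median = 12000, read_len_sdlog = 0.35,
                       read_len_range = c(5000, 25000),
                       class_freqs = c(pure_terminal = 0.20,
                                       combined_terminal = 0.15,
                                       itr = 0.15, dtr = 0.10,
                                       colocated = 0.04, junction = 0.03,
                                       hor = 0.03, none = 0.30),
                       variant_fraction = 0.03,
                       error_model = teloscan::error_model(),
                       adversarial = FALSE) {
  if (adversarial && !"forbidden" %in% names(class_freqs)) {
    class_freqs <- c(class_freqs * 0.9, forbidden = 0.1)
  }
  stopifnot(abs(sum(class_freqs) - 1) < 1e-8, n_reads >= 0)
  structure(list(n_reads = as.integer(n_reads),
                 read_len_median = read_len_median,
                 read_len_sdlog = read_len_sdlog,
                 read_len_range = read_len_range,
                 class_freqs = class_freqs,
                 variant_fraction = variant_fraction,
                 error_model = error_model,
                 adversarial = adversarial),
            class = "tel_sim_config")
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# every catalog monomer and its reverse complement
.catalog_monomer_space <- function(catalog = tel_catalog()) {
  m <- catalog$decomp$monomer
  unique(c(m, revcomp(m)))
}

# TRUE when no 5..9 bp window anchored at the given side of `x` is within
# edit distance 2 of a catalog monomer (either orientation); such windows
# are exactly what boundary extension inspects
.flank_clean <- function(x, side, monomers) {
  n <- nchar(x)
  for (L in 5:9) {
    if (L > n) next
    w <- if (side == "left") substr(x, 1, L) else substr(x, n - L + 1, n)
    if (any(edit_dist(w, monomers) <= 2)) return(FALSE)
  }
  TRUE
}

# TRUE when no window crossing the left_seq|right_seq boundary equals a
# catalog monomer exactly: such a window would let boundary extension
# annex flank bases that happen to complete a longer monomer
.joint_clean <- function(left_seq, right_seq, monomers) {
  a <- substr(left_seq, max(1, nchar(left_seq) - 7L), nchar(left_seq))
  b <- substr(right_seq, 1, 8L)
  joint <- paste0(a, b)
  na <- nchar(a)
  for (L in 6:8) {
    if (L > nchar(joint)) next
    for (s in seq_len(nchar(joint) - L + 1L)) {
      if (s <= na && s + L - 1L > na &&
          substr(joint, s, s + L - 1L) %in% monomers) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# random DNA whose requested flank(s) stop boundary extension; whole piece
# free of seed queries. `left_ctx`/`right_ctx` are the sequences of the
# planted arrays adjacent to the respective flank (used for the
# boundary-crossing window screen).
.gen_spacer <- function(n, clean_left = FALSE, clean_right = FALSE,
                        catalog = tel_catalog(), left_ctx = "",
                        right_ctx = "", max_tries = 200L) {
  monomers <- .catalog_monomer_space(catalog)
  seeds <- unlist(lapply(catalog$seed_motifs, function(m) {
    s <- strrep(m, 3L); c(s, revcomp(s))
  }), use.names = FALSE)
  for (t in seq_len(max_tries)) {
    x <- random_dna(n)
    if (n == 0) return(x)
    if (any(vapply(seeds, function(s) grepl(s, x, fixed = TRUE),
                   logical(1)))) next
    if (clean_left && !.flank_clean(x, "left", monomers)) next
    if (clean_right && !.flank_clean(x, "right", monomers)) next
    if (clean_left && nzchar(left_ctx) &&
        !.joint_clean(left_ctx, x, monomers)) next
    if (clean_right && nzchar(right_ctx) &&
        !.joint_clean(x, right_ctx, monomers)) next
    return(x)
  }
  stop("could not generate clean spacer of length ", n)
}

# a 1-2 nt edit of the canonical monomer that standalone decomposition
# would label "variant" (length kept within 6..8 so tiling stays stable)
.mutate_canonical <- function(catalog = tel_catalog()) {
  canon <- catalog$canonical
  dc <- catalog$decomp
  repeat {
    x <- strsplit(canon, "")[[1]]
    for (k in seq_len(sample(1:2, 1))) {
      op <- sample(c("sub", "ins", "del"), 1)
      i <- sample(length(x), 1)
      if (op == "sub") {
        x[i] <- sample(setdiff(BASES, x[i]), 1)
      } else if (op == "ins") {
        x <- append(x, sample(BASES, 1), after = i)
      } else if (length(x) > 2) {
        x <- x[-i]
      }
    }
    e <- paste(x, collapse = "")
    if (nchar(e) < 6 || nchar(e) > 8 || e == canon) next
    d <- edit_dist(e, dc$monomer)
    best <- which.min(d)               # catalog order puts canonical first
    if (dc$class[best] %in% c("canonical", "variant") && d[best] > 0 ||
        dc$class[best] == "variant") {
      if (dc$family[best] == "tel" && dc$monomer[best] != "TTTAAAA") return(e)
    }
  }
}

# monomer vectors for each planted architecture element -------------------

.calls_canonical <- function(n, variant_fraction = 0,
                             catalog = tel_catalog()) {
  m <- rep(catalog$canonical, n)
  nv <- round(variant_fraction * n)
  if (nv > 0) {
    lo <- min(4L, n); hi <- max(n - 3L, lo)
    idx <- sample(lo:hi, nv)
    for (i in idx) m[i] <- .mutate_canonical(catalog)
  }
  attr(m, "n_variant") <- if (nv > 0) nv else 0L
  m
}

.calls_combined <- function(catalog = tel_catalog()) {
  n_blocks <- sample(2:6, 1)
  cls <- rep(c("canonical", "TTTAAAA"), length.out = n_blocks)
  copies <- 3L + stats::rgeom(n_blocks, 1 / 6)
  m <- unlist(mapply(function(cl, k) {
    rep(if (cl == "canonical") catalog$canonical else
      catalog$derivative_terminal, k)
  }, cls, copies, SIMPLIFY = FALSE), use.names = FALSE)
  attr(m, "blocks") <- paste(cls, copies, sep = ":", collapse = ";")
  m
}

.calls_dtr <- function(n, catalog = tel_catalog()) {
  m <- sample(c("CCTGGG", "CCTAGG", "CCCTGGG"), n, replace = TRUE,
              prob = c(0.7, 0.2, 0.1))
  runs <- rle(m)
  if (!any(runs$values == "CCTGGG" & runs$lengths >= 3) && n >= 3) {
    i <- sample(n - 2L, 1)
    m[i:(i + 2L)] <- "CCTGGG"
  }
  m
}

# assemble one architecture into segments ---------------------------------
# each segment: list(kind = "array"|"gap", seq, and for arrays the truth
# metadata (strand, composition, blocks, n_monomers, n_variant, unit, role))

.array_segment <- function(monomers, strand, composition, role,
                           blocks = NULL, n_variant = 0L, unit = NA) {
  gseq <- paste(monomers, collapse = "")
  if (is.null(blocks)) {
    cls <- ifelse(monomers == "TTTAAAA", "TTTAAAA",
                  ifelse(monomers %in% c("CCTGGG", "CCTAGG", "CCCTGGG",
                                         "CCCAGG"), "CCTGGG", "canonical"))
    r <- rle(cls)
    blocks <- paste(r$values, r$lengths, sep = ":", collapse = ";")
  }
  list(kind = "array",
       seq = if (strand == "-") revcomp(gseq) else gseq,
       strand = strand, composition = composition, blocks = blocks,
       n_monomers = length(monomers), n_variant = as.integer(n_variant),
       unit = unit, role = role)
}

# gaps are generated at read-assembly time, when both neighbours are known
.gap_segment <- function(n, catalog) {
  list(kind = "gap", seq = NA_character_, len = n)
}

.architecture_segments <- function(arch, config, catalog = tel_catalog()) {
  vf <- config$variant_fraction
  strand <- sample(c("+", "-"), 1)
  switch(arch,
    none = list(),
    pure_terminal = {
      m <- .calls_canonical(sample(50:400, 1))
      list(.array_segment(m, strand, "PURE_TEL", "terminal_tel"))
    },
    combined_terminal = {
      m <- .calls_combined(catalog)
      list(.array_segment(m, strand, "COMBINED_TEL_TTTAAAA",
                          "terminal_combined",
                          blocks = attr(m, "blocks")))
    },
    itr = {
      m <- .calls_canonical(sample(30:150, 1), vf, catalog)
      list(.array_segment(m, strand, "PURE_TEL", "itr",
                          n_variant = attr(m, "n_variant")))
    },
    dtr = {
      m <- .calls_dtr(sample(30:150, 1), catalog)
      list(.array_segment(m, strand, "DTR", "dtr"))
    },
    colocated = {
      m1 <- .calls_canonical(sample(30:150, 1), vf, catalog)
      m2 <- .calls_dtr(sample(30:150, 1), catalog)
      segs <- list(
        .array_segment(m1, strand, "PURE_TEL", "coloc_itr",
                       n_variant = attr(m1, "n_variant")),
        .gap_segment(sample(50:800, 1), catalog),
        .array_segment(m2, sample(c("+", "-"), 1), "DTR", "coloc_dtr"))
      if (stats::runif(1) < 0.5) segs <- rev(segs)
      segs
    },
    junction = {
      s1 <- sample(c("+", "-"), 1)
      s2 <- setdiff(c("+", "-"), s1)
      list(
        .array_segment(.calls_dtr(sample(15:40, 1), catalog), s1, "DTR",
                       "junction_flank"),
        .gap_segment(sample(15:50, 1), catalog),
        .array_segment(.calls_canonical(sample(3:8, 1)), "+", "PURE_TEL",
                       "junction_core"),
        .gap_segment(sample(15:50, 1), catalog),
        .array_segment(.calls_dtr(sample(15:40, 1), catalog), s2, "DTR",
                       "junction_flank"))
    },
    hor = {
      m <- .calls_canonical(sample(20:40, 1), vf, catalog)
      unit <- paste0(catalog$canonical,
                     .gen_spacer(sample(14:35, 1), clean_left = TRUE,
                                 clean_right = TRUE, catalog))
      copies <- sample(8:15, 1)
      segs <- list(
        .array_segment(m, strand, "PURE_TEL", "hor_itr",
                       n_variant = attr(m, "n_variant"), unit = unit),
        .gap_segment(sample(15:30, 1), catalog),
        list(kind = "hor_tract", seq = strrep(unit, copies), unit = unit))
      segs
    },
    forbidden = {
      m <- c(rep(catalog$derivative_terminal, sample(5:15, 1)),
             .calls_dtr(sample(5:15, 1), catalog))
      list(.array_segment(m, "+", "MIXED_OTHER", "forbidden"))
    },
    stop("unknown architecture: ", arch)
  )
}

#' Plant a telomeric array with a controlled variant fraction
#'
#' Builds the monomer sequence of an interstitial-style telomeric array:
#' canonical TTTAGGG monomers with exactly `round(variant_fraction * n)`
#' of them replaced by 1--2-nt edited variants (the count is planted
#' exactly, not Bernoulli-sampled, so the planted fraction is the truth a
#' decomposition estimate can be compared against). Variants are kept away
#' from the first and last three monomers so array boundaries stay
#' unambiguous. Uses R's RNG (seed with [set.seed()]).
#'
#' @param n_monomers number of monomers.
#' @param variant_fraction fraction of variant monomers (observed range in
#'   interstitial arrays: 2--5%).
#' @return list `monomers` (character vector), `sequence` (their
#'   concatenation), `n_variant` (planted variant count).
#' @export
plant_telomeric_array <- function(n_monomers, variant_fraction = 0.05) {
  stopifnot(n_monomers >= 1, variant_fraction >= 0, variant_fraction <= 1)
  m <- .calls_canonical(n_monomers, variant_fraction)
  list(monomers = as.character(m),
       sequence = paste(m, collapse = ""),
       n_variant = attr(m, "n_variant"))
}

#' Apply the per-base error model to a sequence
#'
#' Each truth base is deleted with probability `deletion`, otherwise
#' substituted with probability `mismatch`; an extra base is inserted after
#' each truth base with probability `insertion`. Returns the mutated
#' sequence plus the coordinate map from truth positions to read positions,
#' so planted truth intervals can be tracked through the edits rather than
#' re-discovered.
#'
#' @param seq truth sequence.
#' @param em [error_model()].
#' @return list `sequence`, `map` (integer vector of length
#'   `nchar(seq) + 1`; `map[p + 1]` is the 0-based read coordinate of truth
#'   position `p`).
#' @export
apply_error_model <- function(seq, em) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  del <- stats::runif(n) < em$deletion
  sub <- !del & stats::runif(n) < em$mismatch
  ins <- stats::runif(n) < em$insertion
  if (any(sub)) {
    chars[sub] <- vapply(chars[sub],
                         function(b) sample(setdiff(BASES, b), 1), "",
                         USE.NAMES = FALSE)
  }
  pieces <- ifelse(del, "", chars)
  if (any(ins)) {
    pieces[ins] <- paste0(pieces[ins], sample(BASES, sum(ins),
                                              replace = TRUE))
  }
  list(sequence = paste(pieces, collapse = ""),
       map = c(0L, cumsum(as.integer(!del) + as.integer(ins))))
}

#' Simulate one read with planted truth
#'
#' Samples an architecture, builds a seed-free random backbone, plants the
#' architecture (terminal arrays flush with a read end, interstitial
#' elements at least 2 kb from both ends, boundary flanks screened so truth
#' boundaries are unambiguous), applies the error model and maps truth
#' coordinates through the edits.
#'
#' @param config [sim_config()].
#' @param read_id identifier for the read.
#' @param arch architecture name; sampled from `config$class_freqs` when
#'   `NULL`.
#' @return list `read` (one-row data.frame) and `truth` (data.frame, one
#'   row per planted array; zero rows for architecture `"none"`).
#' @export
simulate_read <- function(config = sim_config(), read_id = "read_1",
                          arch = NULL) {
  catalog <- tel_catalog()
  if (is.null(arch)) {
    arch <- sample(names(config$class_freqs), 1,
                   prob = config$class_freqs)
  }
  for (attempt in 1:100) {
    L <- round(stats::rlnorm(1, log(config$read_len_median),
                             config$read_len_sdlog))
    L <- min(max(L, config$read_len_range[1]), config$read_len_range[2])
    segs <- .architecture_segments(arch, config, catalog)
    if (length(segs)) {
      # fill gap segments now that both neighbours are known
      for (k in seq_along(segs)) {
        if (segs[[k]]$kind != "gap") next
        segs[[k]]$seq <- .gen_spacer(
          segs[[k]]$len, clean_left = TRUE, clean_right = TRUE, catalog,
          left_ctx = segs[[k - 1]]$seq, right_ctx = segs[[k + 1]]$seq)
      }
    }
    seg_len <- sum(vapply(segs, function(s) nchar(s$seq), numeric(1)))
    terminal <- arch %in% c("pure_terminal", "combined_terminal")
    need <- if (!length(segs)) 1 else if (terminal) seg_len + 1000 else
      seg_len + 4200
    if (need <= L) break
    if (attempt == 100) stop("architecture does not fit in any read")
  }
  pieces <- character(0)
  truth <- list()
  offset <- 0L
  add_piece <- function(s) {
    pieces[length(pieces) + 1L] <<- s
    offset <<- offset + nchar(s)
  }
  add_segments <- function(segs) {
    for (s in segs) {
      if (s$kind == "array") {
        truth[[length(truth) + 1L]] <<- data.frame(
          read_id = read_id, architecture = arch,
          start = offset, end = offset + nchar(s$seq),
          strand = s$strand, composition = s$composition,
          blocks = s$blocks, n_monomers = s$n_monomers,
          n_variant = s$n_variant, unit = s$unit, role = s$role,
          stringsAsFactors = FALSE)
      }
      add_piece(s$seq)
    }
  }
  if (length(segs) == 0) {
    add_piece(.gen_spacer(L, catalog = catalog))
  } else if (terminal) {
    side <- sample(c("start", "end"), 1)
    if (side == "start") {
      add_segments(segs)
      add_piece(.gen_spacer(L - seg_len, clean_left = TRUE,
                            catalog = catalog,
                            left_ctx = segs[[length(segs)]]$seq))
    } else {
      add_piece(.gen_spacer(L - seg_len, clean_right = TRUE,
                            catalog = catalog, right_ctx = segs[[1]]$seq))
      add_segments(segs)
    }
  } else {
    lead <- sample(2000:(L - 2000 - seg_len), 1)
    add_piece(.gen_spacer(lead, clean_right = TRUE, catalog = catalog,
                          right_ctx = segs[[1]]$seq))
    add_segments(segs)
    add_piece(.gen_spacer(L - lead - seg_len, clean_left = TRUE,
                          catalog = catalog,
                          left_ctx = segs[[length(segs)]]$seq))
  }
  truth_seq <- paste(pieces, collapse = "")
  err <- apply_error_model(truth_seq, config$error_model)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read_id = character(), architecture = character(),
               start = integer(), end = integer(), strand = character(),
               composition = character(), blocks = character(),
               n_monomers = integer(), n_variant = integer(),
               unit = character(), role = character(),
               stringsAsFactors = FALSE)
  if (nrow(truth)) {
    truth$start <- err$map[truth$start + 1L]
    truth$end <- err$map[truth$end + 1L]
  }
  read <- data.frame(read_id = read_id, sequence = err$sequence,
                     length = nchar(err$sequence),
                     architecture = arch, truth_sequence = truth_seq,
                     stringsAsFactors = FALSE)
  list(read = read, truth = truth)
}

#' Simulate a library with truth annotations
#'
#' Generates `config$n_reads` reads under a fixed seed (identical seed and
#' config give byte-identical outputs) and optionally writes the FASTA and
#' the truth table TSV.
#'
#' @param config [sim_config()].
#' @param seed RNG seed.
#' @param fasta,truth_tsv optional output paths.
#' @return list `reads` (data.frame `read_id`, `sequence`, `length`,
#'   `architecture`, `truth_sequence`) and `truth` (array-level truth
#'   table).
#' @export
simulate_library <- function(config = sim_config(), seed = 1L,
                             fasta = NULL, truth_tsv = NULL) {
  stopifnot(config$n_reads >= 0)
  set.seed(seed)
  reads <- list(); truths <- list()
  for (i in seq_len(config$n_reads)) {
    sim <- simulate_read(config, read_id = sprintf("read_%05d", i))
    reads[[i]] <- sim$read
    truths[[i]] <- sim$truth
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(read_id = character(), sequence = character(),
               length = integer(), architecture = character(),
               truth_sequence = character(), stringsAsFactors = FALSE)
  truth <- do.call(rbind, truths[vapply(truths, nrow, 1L) > 0])
  if (is.null(truth)) {
    truth <- data.frame(read_id = character(), architecture = character(),
                        start = integer(), end = integer(),
                        strand = character(), composition = character(),
                        blocks = character(), n_monomers = integer(),
                        n_variant = integer(), unit = character(),
                        role = character(), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  if (!is.null(fasta)) write_fasta(reads, fasta)
  if (!is.null(truth_tsv)) {
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Measure empirical error rates by global alignment
#'
#' Globally aligns a simulated read against its truth sequence with a
#' banded unit-cost aligner (the band auto-widens until the optimal path no
#' longer touches its boundary) and reports per-truth-base deletion,
#' mismatch and insertion fractions.
#'
#' @param read_seq observed (mutated) sequence.
#' @param truth_seq truth sequence.
#' @return named numeric vector `deletion`, `mismatch`, `insertion`.
#' @export
measure_error_rates <- function(read_seq, truth_seq) {
  n <- nchar(truth_seq); m <- nchar(read_seq)
  # the band centre line already absorbs uniform indel drift; deviations
  # are bridge-like, so a narrow initial band almost always suffices and
  # the edge check below widens it when it does not
  band <- max(48L, abs(n - m) %/% 8L + 48L)
  repeat {
    res <- .banded_align_cpp(truth_seq, read_seq, band)
    if (!res$edge || band >= max(n, m)) break
    band <- band * 2L
  }
  c(deletion = res$deletions / n,
    mismatch = res$mismatches / n,
    insertion = res$insertions / n)
}
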