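#' Estimate candidate tandem periods of a sequence
#'
#' Builds the histogram of distances between successive occurrences of
#' identical words (k-mers): in a self-to-self dot plot these distances are
#' the spacings of the off-main diagonals, which equal the repeat unit
#' lengths. Candidates are ranked by support (number of successive
#' identical-word pairs at that distance), with the smallest period first
#' among ties. The span of supporting positions is reported so a candidate
#' period can be localized within a longer sequence.
#'
#' @param seq DNA string (`nchar(seq) >= 2 * word`).
#' @param word word (k-mer) size.
#' @param max_period largest period (bp) considered.
#' @param min_support minimum number of supporting word pairs.
#' @return data.frame `period`, `support`, `start`, `end` (0-based span of
#'   the supporting region), ranked by support descending then period
#'   ascending. Zero rows when nothing reaches `min_support`.
#' @export
estimate_periods <- function(seq, word = 8L, max_period = 200L,
                             min_support = 3L) {
  n <- nchar(seq)
  stopifnot(n >= 2 * word)
  starts <- seq_len(n - word + 1L)
  words <- substring(seq, starts, starts + word - 1L)
  pos <- split(starts - 1L, words)            # 0-based positions per word
  pos <- pos[lengths(pos) >= 2]
  if (!length(pos)) {
    return(data.frame(period = integer(), support = integer(),
                      start = integer(), end = integer()))
  }
  d_all <- integer(); p_all <- integer()
  for (p in pos) {
    d <- diff(p)
    ok <- d <= max_period
    d_all <- c(d_all, d[ok])
    p_all <- c(p_all, p[-length(p)][ok])
  }
  if (!length(d_all)) {
    return(data.frame(period = integer(), support = integer(),
                      start = integer(), end = integer()))
  }
  agg <- tapply(seq_along(d_all), d_all, function(i) {
    c(support = length(i), start = min(p_all[i]),
      end = max(p_all[i] + d_all[i]) + word)
  })
  out <- data.frame(period = as.integer(names(agg)),
                    t(vapply(agg, identity, numeric(3))))
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(-out$support, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus monomer by wraparound alignment
#'
#' Aligns the sequence against a cyclic template of the candidate period by
#' wraparound dynamic programming (free starting phase, best ending phase),
#' takes the per-column majority base as the new template, and iterates
#' until the consensus is stable. Columns where deletions outnumber aligned
#' bases are dropped, so the final period may differ slightly from the
#' candidate. The consensus is reported in its lexicographically smallest
#' rotation, since a tandem tract has no distinguished phase.
#'
#' @param seq array sequence.
#' @param period candidate period from [estimate_periods()].
#' @param weights named numeric vector `c(match=, mismatch=, indel=)`
#'   (alignment scores; defaults +2/-3/-5).
#' @param max_iter maximum template refinement iterations.
#' @return A one-row data.frame (`consensus`, `period`, `copy_number`,
#'   `percent_identity`, `indel_rate`, `score`).
#' @export
wraparound_consensus <- function(seq, period,
                                 weights = c(match = 2, mismatch = -3,
                                             indel = -5),
                                 max_iter = 5L) {
  n <- nchar(seq)
  if (period > n) stop("period exceeds sequence length")
  stopifnot(period >= 1)
  tmpl <- substr(seq, 1, period)
  aln <- NULL
  for (it in seq_len(max_iter)) {
    aln <- .wraparound_align_cpp(seq, tmpl, as.integer(weights[["match"]]),
                                 as.integer(weights[["mismatch"]]),
                                 as.integer(weights[["indel"]]))
    cn <- aln$counts
    bases <- c("A", "C", "G", "T")
    keep <- colSums(cn[1:4, , drop = FALSE]) >= cn[5, ]
    if (!any(keep)) stop("degenerate alignment: all-deletion consensus")
    new_tmpl <- paste(bases[apply(cn[1:4, keep, drop = FALSE], 2,
                                  which.max)], collapse = "")
    if (new_tmpl == tmpl) break
    tmpl <- new_tmpl
  }
  p_final <- nchar(tmpl)
  data.frame(
    consensus = canonical_rotation(tmpl),
    period = p_final,
    copy_number = n / p_final,
    percent_identity = aln$matches / aln$aln_len,
    indel_rate = (aln$insertions + aln$deletions) / aln$aln_len,
    score = aln$score,
    stringsAsFactors = FALSE
  )
}

# does `consensus` (treated cyclically) contain a copy of `motif` within
# edit distance `max_edit`?
contains_motif_cyclic <- function(consensus, motif, max_edit = 2L) {
  m <- nchar(motif)
  dbl <- paste0(consensus, substr(consensus, 1, min(nchar(consensus), m + max_edit)))
  n <- nchar(dbl)
  for (L in max(1, m - max_edit):(m + max_edit)) {
    if (L > n) next
    st <- seq_len(n - L + 1L)
    wins <- unique(substring(dbl, st, st + L - 1L))
    if (any(edit_dist(motif, wins) <= max_edit)) return(TRUE)
  }
  FALSE
}

#' Detect elongated (higher-order-repeat-like) consensus monomers
#'
#' Interstitial telomeric and derivative arrays can develop longer repeat
#' units built from the base motif plus additional sequence -- a first step
#' towards higher-order repeat structure, with units reaching ~195 bp.
#' This routine estimates periods over the sequence context of a hit, runs
#' [wraparound_consensus()] at every supported period of at least twice the
#' base motif length (localized to its supporting span), and keeps consensus
#' monomers that contain at least one copy of the base motif within edit
#' distance 2.
#'
#' @param read one-row data.frame (`read_id`, `sequence`).
#' @param hit one array-hit row (interstitial); its sequence context
#'   (`context` bp each side, clipped to the read) is analysed, since
#'   elongated units often flank the seed-detectable core.
#' @param base_motif the base motif (default canonical TTTAGGG).
#' @param context bp of flanking context included on each side.
#' @param word,max_period,min_support see [estimate_periods()].
#' @param weights see [wraparound_consensus()].
#' @param min_copies minimum copy number for a consensus to be reported (a
#'   repeat unit needs at least two copies to be a tandem repeat).
#' @return data.frame of consensus reports (possibly 0 rows) with an added
#'   `distinct_consensus_count` column (number of distinct consensus
#'   sequences over all reported periods).
#' @export
detect_elongated_monomers <- function(read, hit, base_motif = "TTTAGGG",
                                      context = 2000L, word = 8L,
                                      max_period = 200L, min_support = 3L,
                                      weights = c(match = 2, mismatch = -3,
                                                  indel = -5),
                                      min_copies = 2) {
  s0 <- max(0L, hit$start - context)
  e0 <- min(nchar(read$sequence), hit$end + context)
  seq <- substr(read$sequence, s0 + 1, e0)
  empty <- data.frame(consensus = character(), period = integer(),
                      copy_number = numeric(), percent_identity = numeric(),
                      indel_rate = numeric(), score = numeric(),
                      distinct_consensus_count = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < 2 * word) return(empty)
  pd <- estimate_periods(seq, word = word, max_period = max_period,
                         min_support = min_support)
  pd <- pd[pd$period >= 2L * nchar(base_motif), , drop = FALSE]
  if (nrow(pd) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(pd))) {
    loc <- substr(seq, pd$start[i] + 1, pd$end[i])
    if (nchar(loc) < pd$period[i]) next
    rep <- tryCatch(
      wraparound_consensus(loc, pd$period[i], weights = weights),
      error = function(e) NULL)
    if (is.null(rep)) next
    if (rep$copy_number < min_copies) next
    if (!contains_motif_cyclic(rep$consensus, base_motif, 2L)) next
    out[[length(out) + 1L]] <- rep
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$distinct_consensus_count <- length(unique(res$consensus))
  rownames(res) <- NULL
  res
}

#' Self-to-self dot plot of a sequence
#'
#' All coordinate pairs `(i, j)` (0-based, `i <= j`) whose `word`-bp windows
#' are identical (forward set) or reverse complements of each other
#' (reverse set). Tandem repeats appear as parallel diagonals whose spacing
#' equals the repeat unit length; the main diagonal is part of the forward
#' set.
#'
#' @param seq DNA string.
#' @param word word size (`>= 4`).
#' @param allow_rc also compute the reverse-complement match set.
#' @param max_pairs cap on reported pairs per set (kept deterministically
#'   in coordinate order) to bound memory on repeat-dense sequences.
#' @return An object of class `tel_dotplot`: list with `word`, `n`,
#'   `forward` and `reverse` data.frames of `(i, j)` pairs.
#' @export
self_dotplot <- function(seq, word = 7L, allow_rc = TRUE,
                         max_pairs = 2e6) {
  stopifnot(word >= 4)
  n <- nchar(seq)
  starts <- seq_len(max(0L, n - word + 1L))
  words <- substring(seq, starts, starts + word - 1L)
  pos <- split(starts - 1L, words)
  pair_up <- function(idx_by_word) {
    res_i <- integer(); res_j <- integer()
    for (p in idx_by_word) {
      if (length(p) < 2) next
      cmb <- utils::combn(p, 2)
      res_i <- c(res_i, cmb[1, ]); res_j <- c(res_j, cmb[2, ])
      if (length(res_i) > max_pairs) break
    }
    data.frame(i = res_i, j = res_j)[order(res_i, res_j), , drop = FALSE]
  }
  fwd <- pair_up(pos)
  fwd <- rbind(data.frame(i = starts - 1L, j = starts - 1L), fwd)
  fwd <- fwd[!duplicated(fwd) & seq_len(nrow(fwd)) <= max_pairs, ,
             drop = FALSE]
  rev_df <- data.frame(i = integer(), j = integer())
  if (allow_rc) {
    rc_words <- revcomp(words)
    res_i <- integer(); res_j <- integer()
    for (k in seq_along(words)) {
      hit <- pos[[rc_words[k]]]
      if (is.null(hit)) next
      hit <- hit[hit >= k - 1L]
      res_i <- c(res_i, rep(k - 1L, length(hit))); res_j <- c(res_j, hit)
      if (length(res_i) > max_pairs) break
    }
    rev_df <- data.frame(i = res_i, j = res_j)
  }
  structure(list(word = as.integer(word), n = n, forward = fwd,
                 reverse = rev_df),
            class = "tel_dotplot")
}

#' Plot a dot plot
#'
#' Forward matches in green, reverse-complement matches in red, as in the
#' usual self-comparison rendering of tandem-repeat-bearing reads.
#'
#' @param x a `tel_dotplot` object.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.tel_dotplot <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, x$n), ylim = c(0, x$n), xlab = "position",
                 ylab = "position", asp = 1, ...)
  if (nrow(x$forward)) {
    graphics::points(x$forward$i, x$forward$j, pch = ".", col = "darkgreen")
    graphics::points(x$forward$j, x$forward$i, pch = ".", col = "darkgreen")
  }
  if (nrow(x$reverse)) {
    graphics::points(x$reverse$i, x$reverse$j, pch = ".", col = "red")
    graphics::points(x$reverse$j, x$reverse$i, pch = ".", col = "red")
  }
  invisible(x)
}

#' Write dot-plot matches to TSV
#'
#' @param x a `tel_dotplot` object.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_dotplot_tsv <- function(x, path) {
  f <- x$forward; f$set <- "forward"
  r <- x$reverse
  if (nrow(r)) r$set <- "reverse"
  utils::write.table(rbind(f, if (nrow(r)) r), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
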