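# phases (0-based) at which `x` occurs as a substring of the cyclic monomer
cyclic_phases <- function(x, monomer) {
  L <- nchar(x)
  if (L < 1 || L > 2 * nchar(monomer)) return(integer(0))
  m <- nchar(monomer)
  big <- strrep(monomer, ceiling(L / m) + 1L)
  which(vapply(0:(m - 1L), function(p) {
    substr(big, p + 1L, p + L) == x
  }, logical(1))) - 1L
}

#' Decompose a monomer as a G-strand/C-strand recombinant
#'
#' Derivative telomeric monomers (terminal TTTAAAA, interstitial
#' (C)CCTGGG family) resemble recombinants of the G-rich telomeric strand
#' (TTTAGGG) and its reverse-complement C-rich strand (CCCTAAA): a strand
#' exchange joins a piece of one cyclic strand to a piece of the other.
#' This enumerates every way to write `monomer` as
#' (substring of one cyclic strand) + (substring of the other), with both
#' segments non-empty and at most two monomer lengths long. Both segment
#' orders are enumerated, since the exchange scheme has no fixed polarity,
#' and segments are substrings of the *cyclic* monomer because telomeric
#' tracts have no distinguished phase.
#'
#' @param monomer DNA string of length `>= 2`.
#' @param g_monomer G-strand monomer (default TTTAGGG).
#' @param c_monomer C-strand monomer (default CCCTAAA).
#' @return data.frame with one row per decomposition: `monomer`, `order`
#'   (`"GC"` or `"CG"`), `split` (length of the first segment), `seg1`,
#'   `seg2`, `phase1`, `phase2` (0-based phases on the cyclic strands),
#'   `valid` (always TRUE for returned rows). Zero rows when the monomer is
#'   not decomposable. Deterministically ordered by split position, order,
#'   then phases.
#' @export
#' @examples
#' recombinant_decomposition("TTTAAAA")   # TTTA (G-strand) + AAA (C-strand)
#' recombinant_decomposition("CCTGGG")    # CCT (C-strand) + GGG (G-strand)
recombinant_decomposition <- function(monomer, g_monomer = "TTTAGGG",
                                      c_monomer = "CCCTAAA") {
  if (!grepl("^[ACGT]+$", monomer)) {
    stop("monomer contains non-DNA characters: ", monomer)
  }
  L <- nchar(monomer)
  stopifnot(L >= 2)
  max_seg <- 2L * nchar(g_monomer)
  out <- list()
  for (k in seq_len(L - 1L)) {
    if (k > max_seg || (L - k) > max_seg) next
    pre <- substr(monomer, 1, k)
    suf <- substr(monomer, k + 1, L)
    for (ord in c("GC", "CG")) {
      m1 <- if (ord == "GC") g_monomer else c_monomer
      m2 <- if (ord == "GC") c_monomer else g_monomer
      ph1 <- cyclic_phases(pre, m1)
      if (!length(ph1)) next
      ph2 <- cyclic_phases(suf, m2)
      if (!length(ph2)) next
      grid <- expand.grid(phase1 = ph1, phase2 = ph2)
      out[[length(out) + 1L]] <- data.frame(
        monomer = monomer, order = ord, split = k, seg1 = pre, seg2 = suf,
        phase1 = grid$phase1, phase2 = grid$phase2, valid = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(monomer = character(), order = character(),
                      split = integer(), seg1 = character(),
                      seg2 = character(), phase1 = integer(),
                      phase2 = integer(), valid = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$split, res$order, res$phase1, res$phase2), , drop = FALSE]
}

#' Enumerate recombinant monomer products
#'
#' All distinct strings of total length within `len_range` formed as
#' (cyclic substring of the G-strand monomer) + (cyclic substring of the
#' C-strand monomer), in either order. Every product is
#' [recombinant_decomposition()]-valid by construction.
#'
#' @param g_monomer G-strand monomer.
#' @param len_range integer vector `c(min, max)` of product lengths.
#' @return Sorted character vector of distinct products.
#' @export
enumerate_recombinant_products <- function(g_monomer = "TTTAGGG",
                                           len_range = c(6L, 8L)) {
  c_monomer <- revcomp(g_monomer)
  m <- nchar(g_monomer)
  cyc_sub <- function(mono, L) {
    big <- strrep(mono, ceiling(L / m) + 1L)
    unique(substring(big, 1:m, 1:m + L - 1L))
  }
  out <- character(0)
  for (tot in len_range[1]:len_range[2]) {
    for (k in 1:(tot - 1)) {
      a <- cyc_sub(g_monomer, k); b <- cyc_sub(c_monomer, tot - k)
      out <- c(out, as.vector(outer(a, b, paste0)),
               as.vector(outer(b, a, paste0)))
    }
  }
  sort(unique(out))
}

#' Apply a strand-exchange event to an array
#'
#' Replaces the monomer at `position` with a recombinant monomer sampled
#' uniformly from the valid G/C-strand recombinant products of the array's
#' monomer, modelling a double-strand break with strand exchange. All other
#' monomers are unchanged. Uses R's RNG (seed with [set.seed()]).
#'
#' @param monomers character vector of monomer sequences.
#' @param position 1-based index of the monomer to replace.
#' @param g_monomer G-strand monomer of the array's class.
#' @param len_range allowed product lengths.
#' @return The modified monomer vector.
#' @export
strand_exchange_event <- function(monomers, position,
                                  g_monomer = "TTTAGGG",
                                  len_range = c(6L, 8L)) {
  if (length(monomers) == 0) stop("empty array")
  if (position < 1 || position > length(monomers)) {
    stop("position out of range")
  }
  products <- enumerate_recombinant_products(g_monomer, len_range)
  monomers[position] <- sample(products, 1L)
  monomers
}

#' Amplify a monomer block
#'
#' Inserts `added_copies` tandem copies of the monomer at `position`
#' adjacent to it, modelling local block amplification (t-loop /
#' rolling-circle-like elongation of derivative blocks). The array grows by
#' exactly `added_copies` monomers.
#'
#' @param monomers character vector of monomer sequences.
#' @param position 1-based index of the monomer to amplify.
#' @param added_copies number of copies to insert (`>= 1`).
#' @return The modified monomer vector.
#' @export
amplify_block <- function(monomers, position, added_copies) {
  if (length(monomers) == 0) stop("empty array")
  if (position < 1 || position > length(monomers)) {
    stop("position out of range")
  }
  stopifnot(added_copies >= 1)
  append(monomers, rep(monomers[position], added_copies), after = position)
}
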