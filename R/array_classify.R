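#' Positional class of an array: terminal vs interstitial
#'
#' An array is TERMINAL when it starts within `edge_tol` of a read end (the
#' boundary is inclusive on both sides), mirroring arrays "at the edge" of a
#' read versus ITR arrays in the read middle. The default tolerance absorbs
#' adapter remnants and ragged read ends.
#'
#' @param start,end 0-based half-open interval on the read.
#' @param read_length read length in bp.
#' @param edge_tol distance from a read end (bp) still counted as terminal.
#' @return `"TERMINAL"` or `"INTERSTITIAL"`.
#' @export
classify_position <- function(start, end, read_length, edge_tol = 100L) {
  if (any(start < 0) || any(end > read_length) || any(start >= end)) {
    stop("array interval outside read bounds")
  }
  ifelse(start <= edge_tol | (read_length - end) <= edge_tol,
         "TERMINAL", "INTERSTITIAL")
}

# monomer-call class -> block class; canonical variants never start a block
block_class_of <- function(class) {
  out <- rep(NA_character_, length(class))
  out[class %in% c("canonical", "variant")] <- "canonical"
  out[class == "derivative_TTTAAAA"] <- "TTTAAAA"
  out[class == "derivative_CCTGGG_family"] <- "CCTGGG"
  out
}

#' Detect monomer blocks within an array
#'
#' A block is a maximal run of consecutive monomers of one class (canonical
#' variants count as canonical; unassigned calls join the enclosing run).
#' Runs shorter than `min_block_copies` are absorbed into the longer
#' flanking run (tie broken to the left), so the returned list alternates
#' classes and its copy counts sum to the number of monomer calls.
#'
#' @param monomer_calls decomposition from [decompose_array()].
#' @param min_block_copies minimum copies for a run to stand as a block.
#' @return data.frame `class`, `copy_count`, `start`, `end` (bp offsets
#'   within the array).
#' @export
detect_blocks <- function(monomer_calls, min_block_copies = 3L) {
  stopifnot(nrow(monomer_calls) > 0)
  cls <- block_class_of(monomer_calls$class)
  # unassigned calls inherit the previous class (or the next at the start)
  if (all(is.na(cls))) cls[] <- "canonical"
  for (i in seq_along(cls)) {
    if (is.na(cls[i])) cls[i] <- if (i > 1) cls[i - 1] else cls[!is.na(cls)][1]
  }
  r <- rle(cls)
  repeat {
    if (length(r$lengths) <= 1) break
    small <- which(r$lengths < min_block_copies)
    if (!length(small)) break
    i <- small[1]
    left <- if (i > 1) r$lengths[i - 1] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
    tgt <- if (left >= right) i - 1L else i + 1L
    r$values[i] <- r$values[tgt]
    # merge equal neighbours
    r <- rle(inverse.rle(r))
  }
  ends_call <- cumsum(r$lengths)
  starts_call <- c(0L, utils::head(ends_call, -1)) + 1L
  call_end_bp <- monomer_calls$offset + nchar(monomer_calls$observed)
  data.frame(
    class = r$values,
    copy_count = r$lengths,
    start = monomer_calls$offset[starts_call],
    end = call_end_bp[ends_call],
    stringsAsFactors = FALSE
  )
}

#' Compositional class of an array from its blocks
#'
#' `PURE_TEL`: all blocks canonical. `COMBINED_TEL_TTTAAAA`: canonical and
#' TTTAAAA blocks both present (the block-organized double-monomer pattern).
#' `DTR`: all blocks from the CCTGGG family. Anything else `MIXED_OTHER`.
#'
#' @param blocks data.frame from [detect_blocks()].
#' @return One of `"PURE_TEL"`, `"COMBINED_TEL_TTTAAAA"`, `"DTR"`,
#'   `"MIXED_OTHER"`.
#' @export
classify_composition <- function(blocks) {
  cls <- unique(blocks$class)
  if (setequal(cls, "canonical")) return("PURE_TEL")
  if (setequal(cls, c("canonical", "TTTAAAA"))) return("COMBINED_TEL_TTTAAAA")
  if (setequal(cls, "CCTGGG")) return("DTR")
  "MIXED_OTHER"
}

#' Classify all arrays of a read
#'
#' Adds `position`, `composition` and a `blocks` list-column to the array
#' hits of one read.
#'
#' @param hits array hits from [assemble_arrays()] (one read).
#' @param read_length read length (bp).
#' @param edge_tol terminal tolerance, see [classify_position()].
#' @param min_block_copies see [detect_blocks()].
#' @return The input with columns `position`, `composition`, `blocks`.
#' @export
classify_arrays <- function(hits, read_length, edge_tol = 100L,
                            min_block_copies = 3L) {
  if (nrow(hits) == 0) {
    hits$position <- character(0)
    hits$composition <- character(0)
    hits$blocks <- list()
    return(hits)
  }
  hits$position <- classify_position(hits$start, hits$end, read_length,
                                     edge_tol)
  blocks <- lapply(hits$monomer_calls, detect_blocks,
                   min_block_copies = min_block_copies)
  hits$composition <- vapply(blocks, classify_composition, character(1))
  hits$blocks <- blocks
  hits
}

#' Detect ITR-DTR junctions on a read
#'
#' A junction is a short canonical core (at most `core_max_copies` TTTAGGG
#' monomers) flanked on both sides by CCTGGG-family (DTR) arrays of opposite
#' orientations, with flank gaps at most `max_flank_gap` bp -- the pattern
#' interpreted as a derivation event captured in the act. For each core the
#' opposite-orientation flank pair with the smallest total gap is reported;
#' each core yields at most one event.
#'
#' @param classified classified arrays of one read, sorted by `start`.
#' @param max_flank_gap maximum gap (bp) between core and either flank.
#' @param core_max_copies maximum monomer count of the canonical core.
#' @return data.frame `read_id`, `core_start`, `core_end`, `core_copies`,
#'   `left_start`, `left_end`, `left_strand`, `right_start`, `right_end`,
#'   `right_strand`.
#' @export
detect_junctions <- function(classified, max_flank_gap = 50L,
                             core_max_copies = 10L) {
  empty <- data.frame(read_id = character(), core_start = integer(),
                      core_end = integer(), core_copies = integer(),
                      left_start = integer(), left_end = integer(),
                      left_strand = character(), right_start = integer(),
                      right_end = integer(), right_strand = character(),
                      stringsAsFactors = FALSE)
  if (nrow(classified) < 3) return(empty)
  a <- classified[order(classified$start), , drop = FALSE]
  is_core <- a$composition == "PURE_TEL" & a$n_monomers <= core_max_copies
  is_dtr <- a$composition == "DTR"
  out <- list()
  for (j in which(is_core)) {
    lefts <- which(is_dtr & a$end <= a$start[j] &
                     (a$start[j] - a$end) <= max_flank_gap)
    rights <- which(is_dtr & a$start >= a$end[j] &
                      (a$start - a$end[j]) <= max_flank_gap)
    if (!length(lefts) || !length(rights)) next
    best <- NULL
    for (l in lefts) for (r in rights) {
      if (a$strand[l] == a$strand[r]) next
      gap <- (a$start[j] - a$end[l]) + (a$start[r] - a$end[j])
      if (is.null(best) || gap < best$gap) best <- list(l = l, r = r, gap = gap)
    }
    if (is.null(best)) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = a$read_id[j],
      core_start = a$start[j], core_end = a$end[j],
      core_copies = a$n_monomers[j],
      left_start = a$start[best$l], left_end = a$end[best$l],
      left_strand = a$strand[best$l],
      right_start = a$start[best$r], right_end = a$end[best$r],
      right_strand = a$strand[best$r],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect ITR-DTR colocalizations on a read
#'
#' Pairs of interstitial arrays -- a telomeric (PURE_TEL or combined) array
#' and a DTR array -- separated by at most `max_coloc_gap` bp. Pairing is
#' greedy by increasing gap and each array joins at most one event.
#'
#' @param classified classified arrays of one read.
#' @param max_coloc_gap maximum gap (bp) between the two arrays.
#' @return data.frame `read_id`, `itr_start`, `itr_end`, `dtr_start`,
#'   `dtr_end`, `gap`.
#' @export
detect_colocations <- function(classified, max_coloc_gap = 1000L) {
  empty <- data.frame(read_id = character(), itr_start = integer(),
                      itr_end = integer(), dtr_start = integer(),
                      dtr_end = integer(), gap = integer(),
                      stringsAsFactors = FALSE)
  a <- classified
  itr <- which(a$position == "INTERSTITIAL" &
                 a$composition %in% c("PURE_TEL", "COMBINED_TEL_TTTAAAA"))
  dtr <- which(a$position == "INTERSTITIAL" & a$composition == "DTR")
  if (!length(itr) || !length(dtr)) return(empty)
  pairs <- expand.grid(i = itr, d = dtr)
  pairs$gap <- pmax(a$start[pairs$d] - a$end[pairs$i],
                    a$start[pairs$i] - a$end[pairs$d])
  pairs <- pairs[pairs$gap >= 0 & pairs$gap <= max_coloc_gap, , drop = FALSE]
  pairs <- pairs[order(pairs$gap, pairs$i, pairs$d), , drop = FALSE]
  used <- integer(0)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; d <- pairs$d[k]
    if (i %in% used || d %in% used) next
    used <- c(used, i, d)
    out[[length(out) + 1L]] <- data.frame(
      read_id = a$read_id[i], itr_start = a$start[i], itr_end = a$end[i],
      dtr_start = a$start[d], dtr_end = a$end[d], gap = pairs$gap[k],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Count derivative-only combined arrays
#'
#' Counts arrays whose blocks contain both TTTAAAA and CCTGGG-family classes
#' but no canonical block. In real libraries such arrays were never
#' observed, which argues that the two basic derivatives do not form
#' simultaneously; the count is reported as a statistic, never enforced as a
#' filter.
#'
#' @param classified classified arrays (any number of reads).
#' @return Integer count.
#' @export
check_forbidden_combination <- function(classified) {
  if (nrow(classified) == 0) return(0L)
  sum(vapply(classified$blocks, function(b) {
    cls <- unique(b$class)
    all(c("TTTAAAA", "CCTGGG") %in% cls) && !("canonical" %in% cls)
  }, logical(1)))
}
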