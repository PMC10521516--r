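#' Scan and classify every read of a library
#'
#' Runs seed scanning, array assembly and classification over all reads and
#' collects junction and colocalization events. Deterministic: the analysis
#' path contains no randomness.
#'
#' @param reads data.frame from [read_sequences()] (or
#'   [simulate_library()]`$reads`).
#' @param catalog motif catalog.
#' @param params scanning parameters.
#' @param edge_tol,min_block_copies see [classify_arrays()].
#' @param max_flank_gap,core_max_copies see [detect_junctions()].
#' @param max_coloc_gap see [detect_colocations()].
#' @return list `arrays` (classified array hits over all reads),
#'   `junctions`, `colocations`.
#' @export
scan_library <- function(reads, catalog = tel_catalog(),
                         params = scan_params(), edge_tol = 100L,
                         min_block_copies = 3L, max_flank_gap = 50L,
                         core_max_copies = 10L, max_coloc_gap = 1000L) {
  arrays <- list(); junctions <- list(); colocs <- list()
  for (i in seq_len(nrow(reads))) {
    read <- reads[i, , drop = FALSE]
    hits <- scan_read(read, catalog, params)
    if (nrow(hits) == 0) next
    cls <- classify_arrays(hits, read$length, edge_tol, min_block_copies)
    arrays[[length(arrays) + 1L]] <- cls
    j <- detect_junctions(cls, max_flank_gap, core_max_copies)
    if (nrow(j)) junctions[[length(junctions) + 1L]] <- j
    # arrays taking part in a junction are that event, not a colocation
    in_junction <- rep(FALSE, nrow(cls))
    for (k in seq_len(nrow(j))) {
      in_junction <- in_junction |
        (cls$start %in% c(j$core_start[k], j$left_start[k],
                          j$right_start[k]))
    }
    co <- detect_colocations(cls[!in_junction, , drop = FALSE],
                             max_coloc_gap)
    if (nrow(co)) colocs[[length(colocs) + 1L]] <- co
  }
  empty_arr <- classify_arrays(
    assemble_arrays(list(read_id = "x", sequence = "ACGT"),
                    data.frame(read_id = character(), start = integer(),
                               end = integer(), strand = character(),
                               motif = character(), group = character())),
    4L)
  list(
    arrays = if (length(arrays)) do.call(rbind, arrays) else empty_arr,
    junctions = if (length(junctions)) do.call(rbind, junctions) else
      detect_junctions(empty_arr),
    colocations = if (length(colocs)) do.call(rbind, colocs) else
      detect_colocations(empty_arr)
  )
}

#' Per-library frequency summary
#'
#' The per-library tabulation of telomeric-array carriers: how many reads
#' carry pure TTTAGGG arrays, combined TTTAGGG+TTTAAAA arrays, and
#' CCTGGG-family (DTR) arrays. Counts are of *reads* (a read with two pure
#' arrays counts once); a parallel array-level table is reported because
#' per-read and per-array tallies answer different questions. Zero counts
#' are reported explicitly -- the absence of combined arrays in a library
#' is a finding, not a missing value.
#'
#' @param arrays classified arrays (from [scan_library()]`$arrays`).
#' @param n_reads number of reads scanned.
#' @param library_id label for the library.
#' @param params parameter snapshot to record (any list).
#' @return list of class `tel_library_summary`: `library_id`,
#'   `n_reads_scanned`, `read_counts` and `array_counts` (named integer
#'   vectors over `PURE_TEL`, `COMBINED_TEL_TTTAAAA`, `DTR`, `MIXED_OTHER`),
#'   `n_reads_with_arrays`, `params`.
#' @export
summarize_library <- function(arrays, n_reads, library_id = "library",
                              params = list()) {
  classes <- c("PURE_TEL", "COMBINED_TEL_TTTAAAA", "DTR", "MIXED_OTHER")
  read_counts <- array_counts <- stats::setNames(integer(length(classes)),
                                                 classes)
  for (cl in classes) {
    sel <- arrays$composition == cl
    array_counts[cl] <- sum(sel)
    read_counts[cl] <- length(unique(arrays$read_id[sel]))
  }
  structure(list(
    library_id = library_id,
    n_reads_scanned = as.integer(n_reads),
    read_counts = read_counts,
    array_counts = array_counts,
    n_reads_with_arrays = length(unique(arrays$read_id)),
    params = params
  ), class = "tel_library_summary")
}

#' @export
print.tel_library_summary <- function(x, ...) {
  cat("Library:", x$library_id, "-", x$n_reads_scanned, "reads scanned,",
      x$n_reads_with_arrays, "with arrays\n")
  tab <- rbind(reads = x$read_counts, arrays = x$array_counts)
  print(tab)
  invisible(x)
}

#' Run the full pipeline on a library
#'
#' read (or accept) a library, keep the `top_n` longest reads, scan and
#' classify, then write annotations (TSV/BED/GFF3), event tables, consensus
#' monomers for interstitial arrays, and a JSON summary with the exact
#' parameter snapshot. Rerunning with the same inputs gives byte-identical
#' outputs.
#'
#' @param input path to FASTA/FASTQ (plain or gzip) or a reads data.frame.
#' @param out_dir output directory (created if needed).
#' @param top_n keep only the n longest reads (`NULL` keeps all; library
#'   scans in the source study used the 50,000 longest).
#' @param library_id label; defaults to the input file name.
#' @param consensus also compute consensus monomers for interstitial
#'   arrays.
#' @inheritParams scan_library
#' @return The [summarize_library()] object, invisibly; side effects on
#'   disk: `arrays.tsv`, `arrays.bed`, `arrays.gff3`, `junctions.tsv`,
#'   `colocations.tsv`, `consensus.fasta` (optional), `summary.json`.
#' @export
run_pipeline <- function(input, out_dir, top_n = NULL,
                         library_id = NULL, consensus = TRUE,
                         catalog = tel_catalog(), params = scan_params(),
                         edge_tol = 100L, min_block_copies = 3L,
                         max_flank_gap = 50L, core_max_copies = 10L,
                         max_coloc_gap = 1000L) {
  if (is.character(input)) {
    if (is.null(library_id)) library_id <- basename(input)
    reads <- read_sequences(input)
  } else {
    if (is.null(library_id)) library_id <- "library"
    reads <- input
  }
  if (!is.null(top_n)) reads <- select_longest(reads, top_n)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- scan_library(reads, catalog, params, edge_tol, min_block_copies,
                      max_flank_gap, core_max_copies, max_coloc_gap)
  arr <- res$arrays
  write_annotations(arr, file.path(out_dir, "arrays.tsv"), "TSV")
  write_annotations(arr, file.path(out_dir, "arrays.bed"), "BED")
  write_annotations(arr, file.path(out_dir, "arrays.gff3"), "GFF3")
  utils::write.table(res$junctions, file.path(out_dir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$colocations, file.path(out_dir, "colocations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (consensus) {
    cons <- list()
    inter <- arr[arr$position == "INTERSTITIAL", , drop = FALSE]
    for (i in seq_len(nrow(inter))) {
      read <- reads[reads$read_id == inter$read_id[i], , drop = FALSE]
      seq <- substr(read$sequence[1], inter$start[i] + 1, inter$end[i])
      if (inter$strand[i] == "-") seq <- revcomp(seq)
      pd <- tryCatch(estimate_periods(seq), error = function(e) NULL)
      if (is.null(pd) || nrow(pd) == 0) next
      rep <- tryCatch(wraparound_consensus(seq, pd$period[1]),
                      error = function(e) NULL)
      if (is.null(rep)) next
      nm <- sprintf("%s_%d_%d period=%d copies=%.1f identity=%.3f",
                    inter$read_id[i], inter$start[i], inter$end[i],
                    rep$period, rep$copy_number, rep$percent_identity)
      cons[[nm]] <- rep$consensus
    }
    if (length(cons)) {
      set <- Biostrings::DNAStringSet(unlist(cons))
      Biostrings::writeXStringSet(set, file.path(out_dir, "consensus.fasta"))
    }
  }
  param_snapshot <- list(
    scan = unclass(params), edge_tol = edge_tol,
    min_block_copies = min_block_copies, max_flank_gap = max_flank_gap,
    core_max_copies = core_max_copies, max_coloc_gap = max_coloc_gap,
    top_n = top_n
  )
  summary <- summarize_library(arr, nrow(reads), library_id, param_snapshot)
  json <- jsonlite::toJSON(list(
    library_id = summary$library_id,
    n_reads_scanned = summary$n_reads_scanned,
    n_reads_with_arrays = summary$n_reads_with_arrays,
    read_counts = as.list(summary$read_counts),
    array_counts = as.list(summary$array_counts),
    n_junctions = nrow(res$junctions),
    n_colocations = nrow(res$colocations),
    params = param_snapshot
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  writeLines(json, file.path(out_dir, "summary.json"))
  invisible(summary)
}
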