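#' Read a long-read library from FASTA or FASTQ
#'
#' Parses FASTA or FASTQ (optionally gzip-compressed), returning one row per
#' record in file order. Sequences are upper-cased and U is mapped to T;
#' quality strings are ignored (the scanning procedure does not use them).
#'
#' @param path path to a FASTA/FASTQ file, plain or `.gz`.
#' @param format `"auto"` (default, inferred from the first non-blank
#'   character), `"fasta"` or `"fastq"`.
#' @return A data.frame with columns `read_id`, `sequence`, `length`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- ""
    while (length(ln <- readLines(con, n = 1)) == 1 && !nzchar(trimws(ln))) {}
    if (length(ln) == 1) first <- substr(trimws(ln), 1, 1)
    format <- if (first == "@") "fastq" else "fasta"
  }
  if (file.size(path) == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(set))
  bad <- which(!grepl("^[ACGTN]*$", seqs))
  if (length(bad)) {
    stop("record ", bad[1], " ('", ids[bad[1]],
         "') contains non-DNA characters")
  }
  data.frame(read_id = ids, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Select the n longest reads
#'
#' Mirrors the study design of scanning the 50,000 longest reads of a
#' library. Ties in length are broken by `read_id` (ascending) so pipelines
#' are reproducible.
#'
#' @param reads data.frame as from [read_sequences()].
#' @param n number of reads to keep (`min(n, nrow(reads))` returned).
#' @return The selected rows, sorted by length descending.
#' @export
select_longest <- function(reads, n) {
  stopifnot(is.data.frame(reads), n >= 0)
  if (n == 0 || nrow(reads) == 0) return(reads[integer(0), , drop = FALSE])
  ord <- order(-reads$length, reads$read_id)
  out <- reads[ord[seq_len(min(n, nrow(reads)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write array annotations to BED, GFF3 or TSV
#'
#' Internal coordinates are 0-based half-open throughout the package; BED is
#' written as-is, GFF3 converts to 1-based closed at this boundary only, and
#' TSV mirrors the in-memory record.
#'
#' @param hits data.frame with at least `read_id`, `start`, `end`, `strand`;
#'   a `composition` or `name` column is used as the feature name if present.
#' @param path output file path.
#' @param format one of `"BED"`, `"GFF3"`, `"TSV"`.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(hits, path, format = c("BED", "GFF3", "TSV")) {
  if (!format[1] %in% c("BED", "GFF3", "TSV")) {
    stop("unknown annotation format: ", format[1])
  }
  format <- match.arg(format)
  nm <- if (!is.null(hits$name)) hits$name
        else if (!is.null(hits$composition)) hits$composition
        else rep(".", nrow(hits))
  if (format == "TSV") {
    cols <- intersect(c("read_id", "start", "end", "strand", "position",
                        "composition", "n_monomers", "variant_fraction",
                        "degenerate_rich"), names(hits))
    utils::write.table(hits[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (nrow(hits) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = hits$read_id,
      ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
      strand = ifelse(hits$strand %in% c("+", "-"), hits$strand, "*")
    )
    gr$name <- nm
  }
  if (format == "BED") {
    if (length(gr)) gr$score <- 0L
    rtracklayer::export.bed(gr, path)
  } else {
    if (length(gr)) {
      gr$type <- "tandem_repeat"
      gr$source <- "teloscan"
    }
    rtracklayer::export.gff3(gr, path)
  }
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' Returns 0-based half-open intervals regardless of the on-disk convention.
#'
#' @param path annotation file.
#' @param format one of `"BED"`, `"GFF3"`, `"TSV"`.
#' @return data.frame with `read_id`, `start`, `end`, `strand` (and `name`
#'   for BED/GFF3).
#' @export
read_annotations <- function(path, format = c("BED", "GFF3", "TSV")) {
  format <- match.arg(format)
  if (format == "TSV") {
    return(utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = tolower(format))
  data.frame(
    read_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = if (!is.null(gr$name)) as.character(gr$name) else
      rep(NA_character_, length(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write a library to FASTA (optionally gzipped)
#'
#' @param reads data.frame with `read_id` and `sequence`.
#' @param path output path; a `.gz` suffix triggers compression.
#' @param width line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(reads, path, width = 80L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(c(paste0(">", reads$read_id[i]),
                 substring(s, starts, pmin(starts + width - 1L, n))),
               con, sep = "\n")
  }
  invisible(path)
}
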