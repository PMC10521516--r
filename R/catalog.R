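#' Telomeric motif catalog
#'
#' The monomers recognised by the scanner: the canonical Arabidopsis-type
#' telomere heptamer TTTAGGG (G-strand; its reverse complement CCCTAAA is the
#' C-strand), the terminal derivative TTTAAAA, the interstitial derivative
#' (C)CCTGGG family, and the common degenerate canonical variants TTTAGG and
#' TTAGGG seen at low (2--5%) frequency inside otherwise homogeneous arrays.
#'
#' Seed scanning uses only the three query motifs (`seed_motifs`); the full
#' catalog is used for array extension and monomer decomposition.
#'
#' @return A list with components `canonical`, `canonical_rc`,
#'   `derivative_terminal`, `derivative_interstitial`, `cctggg_family`,
#'   `degenerate_canonical`, `seed_motifs`, and `decomp` (the decomposition
#'   table: monomer, class, family, canonical flag).
#' @export
#' @examples
#' tel_catalog()$canonical
tel_catalog <- function() {
  cctggg <- c("CCTGGG", "CCCTGGG", "CCTAGG", "CCCAGG")
  decomp <- data.frame(
    monomer = c("TTTAGGG", "TTTAGG", "TTAGGG", "TTTAAAA", cctggg),
    class = c("canonical", "variant", "variant", "derivative_TTTAAAA",
              rep("derivative_CCTGGG_family", length(cctggg))),
    family = c("tel", "tel", "tel", "tel", rep("dtr", length(cctggg))),
    canonical = c(TRUE, rep(FALSE, 3 + length(cctggg))),
    stringsAsFactors = FALSE
  )
  decomp$monomer_rc <- revcomp(decomp$monomer)
  list(
    canonical = "TTTAGGG",
    canonical_rc = "CCCTAAA",
    derivative_terminal = "TTTAAAA",
    derivative_interstitial = "CCTGGG",
    cctggg_family = cctggg,
    degenerate_canonical = c("TTTAGG", "TTAGGG"),
    seed_motifs = c(TTTAGGG = "TTTAGGG", TTTAAAA = "TTTAAAA",
                    CCTGGG = "CCTGGG"),
    seed_family = c(TTTAGGG = "tel", TTTAAAA = "tel", CCTGGG = "dtr"),
    decomp = decomp
  )
}

#' Scanning parameters
#'
#' @param min_seed_copies exact tandem copies required in a seed query
#'   (queries are `(motif)_3` by default, matched with zero mismatches).
#' @param max_monomer_edit_distance maximum edit distance between an observed
#'   monomer-sized window and a catalog monomer during array extension and
#'   decomposition. Arrays tolerate 1--2-nt deviant monomers.
#' @param max_variant_fraction fraction of variant monomer calls above which
#'   an array is flagged degenerate-rich.
#' @param max_intra_array_gap maximum gap (bp) bridged when merging seed
#'   matches of the same strand and motif family into one array; the default
#'   of two monomer lengths bridges a single indel-broken monomer.
#' @return A list of class `tel_scan_params`.
#' @export
scan_params <- function(min_seed_copies = 3L,
                        max_monomer_edit_distance = 2L,
                        max_variant_fraction = 0.05,
                        max_intra_array_gap = 14L) {
  stopifnot(min_seed_copies >= 1L,
            max_variant_fraction >= 0, max_variant_fraction <= 1,
            max_monomer_edit_distance >= 0L, max_intra_array_gap >= 0L)
  structure(list(min_seed_copies = as.integer(min_seed_copies),
                 max_monomer_edit_distance = as.integer(max_monomer_edit_distance),
                 max_variant_fraction = max_variant_fraction,
                 max_intra_array_gap = as.integer(max_intra_array_gap)),
            class = "tel_scan_params")
}

# reverse complement of plain character vectors (N-safe)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# edit distance of one string against a vector of strings (Rcpp kernel)
edit_dist <- function(x, ys) .edit_dist_cpp(x, ys)

# lexicographically smallest rotation of a string
canonical_rotation <- function(x) {
  n <- nchar(x)
  if (n <= 1) return(x)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(x, i, n), substr(x, 1, i - 1))
  }, character(1))
  sort(rots)[1]
}
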