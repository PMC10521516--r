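#' Build an exact seed query from a motif
#'
#' Seed queries are tandem repeats of the motif, e.g. `(TTTAGGG)_3`, matched
#' with zero mismatches.
#'
#' @param motif DNA string.
#' @param copies number of tandem copies (`>= 1`).
#' @return The motif repeated `copies` times.
#' @export
#' @examples
#' compile_seed("TTTAGGG", 3)
compile_seed <- function(motif, copies) {
  stopifnot(copies >= 1, nchar(motif) >= 1)
  strrep(motif, copies)
}

#' Find exact seed matches on both strands
#'
#' Scans a read for exact occurrences of each seed query (`(motif)_k` for
#' each catalog query motif) on the forward strand and, via the seed's
#' reverse complement, on the reverse strand. Overlapping occurrences are
#' all reported. Coordinates are 0-based half-open on the forward strand of
#' the read; reverse-strand hits carry `strand == "-"`.
#'
#' @param read one-row data.frame (`read_id`, `sequence`) or a list with
#'   those fields.
#' @param catalog motif catalog, see [tel_catalog()].
#' @param params scanning parameters, see [scan_params()].
#' @return data.frame `read_id`, `start`, `end`, `strand`, `motif`,
#'   `group`, sorted by `(start, strand)`.
#' @export
find_exact_seeds <- function(read, catalog = tel_catalog(),
                             params = scan_params()) {
  stopifnot(nchar(read$sequence) > 0)
  subj <- Biostrings::DNAString(read$sequence)
  groups <- c(TTTAGGG = "G", TTTAAAA = "A", CCTGGG = "C")
  out <- list()
  for (mn in names(catalog$seed_motifs)) {
    motif <- catalog$seed_motifs[[mn]]
    seed <- compile_seed(motif, params$min_seed_copies)
    for (str in c("+", "-")) {
      pat <- if (str == "+") seed else revcomp(seed)
      mt <- Biostrings::matchPattern(pat, subj)
      if (length(mt) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        read_id = read$read_id,
        start = Biostrings::start(mt) - 1L,
        end = Biostrings::end(mt),
        strand = str, motif = motif, group = groups[[mn]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      motif = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Monomer-group adjacency: canonical (G) mixes with TTTAAAA (A) in combined
# arrays, and A can sit next to CCTGGG-family (C) monomers, but G and C are
# never part of one array (an ITR-DTR junction is three arrays, not one).
groups_compatible <- function(a, b) {
  a == b || (a %in% c("G", "A") && b %in% c("G", "A")) ||
    (a %in% c("A", "C") && b %in% c("A", "C"))
}

# distance from a read-space window to the nearest catalog monomer, in the
# orientation of the array (reverse-strand arrays compare against the
# pre-computed reverse-complemented monomer set, so no per-window revcomp)
nearest_monomer <- function(window, strand, catalog) {
  set <- if (strand == "-") catalog$decomp$monomer_rc else
    catalog$decomp$monomer
  d <- edit_dist(window, set)
  i <- which.min(d)
  grp <- c(tel = "G", dtr = "C")[[catalog$decomp$family[i]]]
  if (catalog$decomp$monomer[i] == "TTTAAAA") grp <- "A"
  list(dist = d[i], group = grp, monomer = catalog$decomp$monomer[i])
}

# extend one boundary of an interval monomer-by-monomer while the nearest
# catalog monomer of the next window is within tolerance and its group is
# compatible with the group at the current array edge
extend_boundary <- function(seq, pos, dir, strand, edge_group, catalog,
                            params) {
  n <- nchar(seq)
  lens <- sort(unique(unlist(lapply(nchar(catalog$decomp$monomer),
                                    function(l) (l - 1L):(l + 1L)))))
  lens <- lens[lens >= 1]
  repeat {
    best <- NULL
    for (L in lens) {
      if (dir > 0) { s <- pos; e <- pos + L } else { s <- pos - L; e <- pos }
      if (s < 0 || e > n) next
      nm <- nearest_monomer(substr(seq, s + 1, e), strand, catalog)
      nm$exact_len <- L == nchar(nm$monomer)
      # ties: prefer the exact-monomer-length window, then the longer one
      if (is.null(best) || nm$dist < best$dist ||
          (nm$dist == best$dist &&
             ((nm$exact_len && !best$exact_len) ||
                (nm$exact_len == best$exact_len && L > best$L)))) {
        best <- c(nm, list(L = L))
      }
    }
    if (is.null(best) || best$dist > params$max_monomer_edit_distance ||
        !groups_compatible(edge_group, best$group)) {
      return(list(pos = pos, edge_group = edge_group))
    }
    pos <- pos + dir * best$L
    edge_group <- best$group
  }
}

# seed matches can sit out of phase with the array's monomer tiling (a
# (CCTGGG)_3 query matches one base into a CCCTGGG monomer), leaving an
# edge short by 1-2 bases. Polish: move an edge outward by e bases when the
# window ending (or starting) there completes an exact catalog monomer that
# overlaps the current array.
polish_boundary <- function(seq, pos, dir, strand, edge_group, catalog,
                            params) {
  n <- nchar(seq)
  mono_lens <- unique(nchar(catalog$decomp$monomer))
  repeat {
    moved <- FALSE
    for (e in seq_len(params$max_monomer_edit_distance)) {
      for (L in mono_lens) {
        if (dir > 0) { s <- pos + e - L; t <- pos + e }
        else { s <- pos - e; t <- pos - e + L }
        if (s < 0 || t > n) next
        if (L <= e) next                  # window must overlap the array
        nm <- nearest_monomer(substr(seq, s + 1, t), strand, catalog)
        if (nm$dist == 0 && groups_compatible(edge_group, nm$group)) {
          pos <- pos + dir * e
          edge_group <- nm$group
          moved <- TRUE
          break
        }
      }
      if (moved) break
    }
    if (!moved) return(list(pos = pos, edge_group = edge_group))
  }
}

#' Assemble seed matches into repeat arrays
#'
#' Seed matches of the same strand are merged into candidate arrays when
#' they lie within `max_intra_array_gap` of each other and their motif
#' groups are compatible (see Details). Array boundaries are then extended
#' outward monomer-by-monomer while each next monomer-sized window lies
#' within `max_monomer_edit_distance` of a compatible catalog monomer, and
#' extended arrays that touch are merged again. Array sequences are reported
#' on the strand of the query motif: reverse-strand hits are
#' reverse-complemented before decomposition, with the original strand
#' retained. Arrays shorter than `min_seed_copies` monomers are discarded;
#' remaining overlaps between incompatible arrays are resolved in favour of
#' the longer one.
#'
#' @details Canonical TTTAGGG and derivative TTTAAAA monomers co-occur in
#' block-organized combined arrays and so merge; TTTAAAA and CCTGGG-family
#' monomers merge (such an array would be a derivative-only combination,
#' counted by [check_forbidden_combination()]); canonical and CCTGGG-family
#' monomers never merge, which keeps the two derivative flanks and the
#' canonical core of an ITR-DTR junction as separate arrays.
#'
#' @param read one-row data.frame (`read_id`, `sequence`).
#' @param seeds seed matches from [find_exact_seeds()] for the same read.
#' @param catalog motif catalog.
#' @param params scanning parameters.
#' @return data.frame of array hits (`read_id`, `start`, `end`, `strand`,
#'   `n_monomers`, class counts, `variant_fraction`, `degenerate_rich`) with
#'   a `monomer_calls` list-column of per-monomer decompositions (see
#'   [decompose_array()]).
#' @export
assemble_arrays <- function(read, seeds, catalog = tel_catalog(),
                            params = scan_params()) {
  if (nrow(seeds) > 0 && any(seeds$read_id != read$read_id)) {
    stop("seeds come from a different read than ", read$read_id)
  }
  empty <- data.frame(read_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_monomers = integer(),
                      n_canonical = integer(), n_variant = integer(),
                      n_tttaaaa = integer(), n_cctggg = integer(),
                      n_unassigned = integer(), variant_fraction = numeric(),
                      degenerate_rich = logical(), stringsAsFactors = FALSE)
  empty$monomer_calls <- list()
  if (nrow(seeds) == 0) return(empty)
  seq <- read$sequence

  # 1. group-aware merging of sorted seeds, per strand
  iv <- list()
  for (str in unique(seeds$strand)) {
    g <- seeds[seeds$strand == str, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    cs <- g$start[1]; ce <- g$end[1]
    lg <- g$group[1]; fg <- g$group[1]
    push <- function(s, e, left, right) {
      iv[[length(iv) + 1L]] <<- data.frame(
        start = s, end = e, strand = str, left_group = left,
        right_group = right, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] - ce <= params$max_intra_array_gap &&
          groups_compatible(lg, g$group[i])) {
        ce <- max(ce, g$end[i]); lg <- g$group[i]
      } else {
        push(cs, ce, fg, lg)
        cs <- g$start[i]; ce <- g$end[i]; lg <- g$group[i]; fg <- g$group[i]
      }
    }
    push(cs, ce, fg, lg)
  }
  iv <- do.call(rbind, iv)

  # 2. edge polish alternating with boundary extension. Polish runs first:
  # a seed can match out of phase (one base into a CCCTGGG monomer), and
  # extension from a mid-monomer position would probe windows that
  # straddle the true boundary
  grow <- function(pos, dir, strand, grp) {
    repeat {
      a <- polish_boundary(seq, pos, dir, strand, grp, catalog, params)
      b <- extend_boundary(seq, a$pos, dir, strand, a$edge_group, catalog,
                           params)
      b <- polish_boundary(seq, b$pos, dir, strand, b$edge_group, catalog,
                           params)
      if (b$pos == pos) return(b)
      pos <- b$pos; grp <- b$edge_group
    }
  }
  for (i in seq_len(nrow(iv))) {
    l <- grow(iv$start[i], -1L, iv$strand[i], iv$left_group[i])
    r <- grow(iv$end[i], +1L, iv$strand[i], iv$right_group[i])
    iv$start[i] <- l$pos; iv$left_group[i] <- l$edge_group
    iv$end[i] <- r$pos; iv$right_group[i] <- r$edge_group
  }

  # 3. re-merge extended arrays that now touch (same strand, compatible
  # facing edges)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- nrow(merged)
    if (iv$strand[i] == merged$strand[k] &&
        iv$start[i] - merged$end[k] <= params$max_intra_array_gap &&
        groups_compatible(merged$right_group[k], iv$left_group[i])) {
      merged$end[k] <- max(merged$end[k], iv$end[i])
      merged$right_group[k] <- iv$right_group[i]
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  iv <- merged

  # 4. residual overlaps (opposite strands or incompatible groups): keep
  # the longer array
  keep <- rep(TRUE, nrow(iv))
  if (nrow(iv) > 1) {
    for (i in seq_len(nrow(iv) - 1)) {
      for (j in (i + 1):nrow(iv)) {
        if (!keep[i] || !keep[j]) next
        if (iv$start[j] < iv$end[i] && iv$start[i] < iv$end[j]) {
          li <- iv$end[i] - iv$start[i]; lj <- iv$end[j] - iv$start[j]
          if (lj > li) keep[i] <- FALSE else keep[j] <- FALSE
        }
      }
    }
  }
  iv <- iv[keep, , drop = FALSE]

  # 5. decomposition and per-array statistics
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    sub <- substr(seq, iv$start[i] + 1, iv$end[i])
    if (iv$strand[i] == "-") sub <- revcomp(sub)
    calls <- decompose_array(sub, catalog, params)
    if (nrow(calls) < params$min_seed_copies) next
    n <- nrow(calls)
    nv <- sum(calls$class == "variant")
    vf <- nv / n
    row <- data.frame(
      read_id = read$read_id, start = iv$start[i], end = iv$end[i],
      strand = iv$strand[i],
      n_monomers = n,
      n_canonical = sum(calls$class == "canonical"),
      n_variant = nv,
      n_tttaaaa = sum(calls$class == "derivative_TTTAAAA"),
      n_cctggg = sum(calls$class == "derivative_CCTGGG_family"),
      n_unassigned = sum(calls$class == "unassigned"),
      variant_fraction = vf,
      degenerate_rich = vf > params$max_variant_fraction,
      stringsAsFactors = FALSE)
    row$monomer_calls <- list(calls)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose an array sequence into monomer calls
#'
#' Greedy left-to-right tiling: at each offset, the catalog monomer with
#' minimal edit distance over windows of the monomer length plus or minus
#' one is chosen (ties broken by canonical first, then exact-length window,
#' longer window, longer monomer, lexicographic). Concatenating the observed
#' windows reconstructs the input exactly. Calls further than
#' `max_monomer_edit_distance` from every catalog monomer are labelled
#' `unassigned`; degenerate canonical monomers and near-canonical windows
#' are labelled `variant`.
#'
#' @param seq array sequence (query-motif orientation).
#' @param catalog motif catalog.
#' @param params scanning parameters.
#' @return data.frame `offset` (0-based, within the array), `observed`,
#'   `monomer` (nearest catalog monomer), `dist`, `class`.
#' @export
#' @examples
#' decompose_array(strrep("TTTAGGG", 3))
decompose_array <- function(seq, catalog = tel_catalog(),
                            params = scan_params()) {
  stopifnot(nchar(seq) > 0)
  dc <- catalog$decomp
  g <- .decompose_greedy_cpp(seq, dc$monomer, dc$canonical)
  monomer <- dc$monomer[g$monomer]
  cls <- dc$class[g$monomer]
  cls[cls == "canonical" & g$dist > 0] <- "variant"
  cls[g$dist > params$max_monomer_edit_distance] <- "unassigned"
  data.frame(
    offset = g$offset,
    observed = substring(seq, g$offset + 1, g$offset + g$len),
    monomer = monomer, dist = g$dist, class = cls,
    stringsAsFactors = FALSE
  )
}

#' Scan one read for telomeric arrays
#'
#' Convenience wrapper: [find_exact_seeds()] then [assemble_arrays()].
#'
#' @inheritParams find_exact_seeds
#' @return See [assemble_arrays()].
#' @export
scan_read <- function(read, catalog = tel_catalog(), params = scan_params()) {
  assemble_arrays(read, find_exact_seeds(read, catalog, params),
                  catalog, params)
}
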