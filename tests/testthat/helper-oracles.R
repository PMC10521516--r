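# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (full sorts, exhaustive enumeration, global
# DP) so the implementation can be checked against them on small inputs.

make_read <- function(sequence, read_id = "r1") {
  data.frame(read_id = read_id, sequence = sequence,
             length = nchar(sequence), stringsAsFactors = FALSE)
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# optimal tiling cost: DP over prefixes, any catalog monomer, window
# lengths |m| - 1 .. |m| + 1 (same move set as the greedy tiler)
dp_tiling_cost <- function(seq, catalog = tel_catalog()) {
  n <- nchar(seq)
  monomers <- catalog$decomp$monomer
  cost <- rep(Inf, n + 1)
  cost[1] <- 0
  for (i in seq_len(n)) {
    if (!is.finite(cost[i])) next
    for (m in monomers) {
      for (L in (nchar(m) - 1L):(nchar(m) + 1L)) {
        Lc <- min(L, n - i + 1L)
        if (Lc < 1) next
        w <- substr(seq, i, i + Lc - 1L)
        d <- utils::adist(w, m)[1, 1]
        cost[i + Lc] <- min(cost[i + Lc], cost[i] + d)
      }
    }
  }
  cost[n + 1]
}

# exhaustive recombinant validity: precomputed cyclic-substring sets
recombinant_oracle <- local({
  cyc_subs <- function(mono, max_len = 14L) {
    m <- nchar(mono)
    big <- strrep(mono, ceiling(max_len / m) + 1L)
    unlist(lapply(1:max_len, function(L) {
      unique(substring(big, 1:m, 1:m + L - 1L))
    }))
  }
  gset <- NULL; cset <- NULL
  function(monomer, g = "TTTAGGG", c = "CCCTAAA") {
    if (is.null(gset)) {
      gset <<- cyc_subs(g); cset <<- cyc_subs(c)
    }
    L <- nchar(monomer)
    for (k in seq_len(L - 1)) {
      pre <- substr(monomer, 1, k)
      suf <- substr(monomer, k + 1, L)
      if ((pre %in% gset && suf %in% cset) ||
          (pre %in% cset && suf %in% gset)) {
        return(TRUE)
      }
    }
    FALSE
  }
})

# brute-force junction scan: every ordered array triple, core in the
# middle, opposite-orientation DTR flanks within the gap limit; per core
# keep the flank pair with the smallest total gap
junction_oracle <- function(classified, max_flank_gap = 50L,
                            core_max_copies = 10L) {
  a <- classified[order(classified$start), , drop = FALSE]
  n <- nrow(a)
  found <- list()
  for (j in seq_len(n)) {
    if (a$composition[j] != "PURE_TEL" || a$n_monomers[j] > core_max_copies)
      next
    best <- NULL
    for (l in seq_len(n)) for (r in seq_len(n)) {
      if (l == j || r == j || l == r) next
      if (a$composition[l] != "DTR" || a$composition[r] != "DTR") next
      if (a$end[l] > a$start[j] || a$start[r] < a$end[j]) next
      gl <- a$start[j] - a$end[l]; gr <- a$start[r] - a$end[j]
      if (gl > max_flank_gap || gr > max_flank_gap) next
      if (a$strand[l] == a$strand[r]) next
      if (is.null(best) || gl + gr < best$gap) {
        best <- list(l = l, r = r, gap = gl + gr)
      }
    }
    if (!is.null(best)) {
      found[[length(found) + 1L]] <- c(core = a$start[j],
                                       left = a$start[best$l],
                                       right = a$start[best$r])
    }
  }
  found
}

# slow nearest-pair colocation matching by exhaustive gap ordering
colocation_oracle <- function(classified, max_coloc_gap = 1000L) {
  a <- classified
  itr <- which(a$position == "INTERSTITIAL" &
                 a$composition %in% c("PURE_TEL", "COMBINED_TEL_TTTAAAA"))
  dtr <- which(a$position == "INTERSTITIAL" & a$composition == "DTR")
  cand <- list()
  for (i in itr) for (d in dtr) {
    gap <- max(a$start[d] - a$end[i], a$start[i] - a$end[d])
    if (gap >= 0 && gap <= max_coloc_gap) {
      cand[[length(cand) + 1L]] <- c(i = i, d = d, gap = gap)
    }
  }
  if (!length(cand)) return(list())
  cand <- cand[order(vapply(cand, `[[`, 0, "gap"),
                     vapply(cand, `[[`, 0, "i"),
                     vapply(cand, `[[`, 0, "d"))]
  used <- integer(0); out <- list()
  for (p in cand) {
    if (p[["i"]] %in% used || p[["d"]] %in% used) next
    used <- c(used, p[["i"]], p[["d"]])
    out[[length(out) + 1L]] <- p
  }
  out
}

# match detected arrays against a truth table by >= 50% reciprocal-ish
# overlap on the same read
match_truth <- function(truth, detected) {
  hits <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    de <- detected[detected$read_id == truth$read_id[i], , drop = FALSE]
    if (!nrow(de)) next
    ov <- pmin(de$end, truth$end[i]) - pmax(de$start, truth$start[i])
    len <- truth$end[i] - truth$start[i]
    k <- which(ov >= 0.5 * len)
    if (length(k)) hits[i] <- which(detected$read_id == truth$read_id[i])[k[1]]
  }
  hits
}
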