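# Maximal direct and palindromic repeat pairs under a Hamming-distance
# model (REPuter-style search semantics: length >= 30 bp at >= 90% identity,
# i.e. at most 3 mismatches, in the defaults).
#
# Semantics.  For every budget b in 0..max_mismatch, a *candidate window* on
# a diagonal (direct: offset between the two copies; palindromic:
# antidiagonal against the reverse complement) is a segment pair that cannot
# be extended at either end without exceeding b mismatches or leaving the
# sequence.  This reproduces the nested same-locus listings of suffix-tree
# repeat finders (a 36-bp entry alongside a 30-bp entry at one position).
# The *reported* set is locus-canonical: per diagonal, candidates are ranked
# by (fewest mismatches, then longest, then leftmost) and greedily selected,
# suppressing any candidate overlapping an already selected window.  An
# exact repeat copy is therefore reported once, with mismatches = 0, even
# when the mismatch budget would allow longer degenerate extensions.
#
# Ambiguity codes never match anything, including themselves.

#' Repeat search parameters
#'
#' @param min_len minimum reported length in bp (default 30, >= 8).
#' @param max_mismatch Hamming budget (default 3; 30 bp at 3 mismatches is
#'   90% identity).
#' @param kinds which orientations to search: `"direct"`, `"palindromic"`.
#' @param exclude_trivial_self drop the identity self-match of the sequence
#'   against itself (default TRUE).
#' @export
search_params <- function(min_len = 30L, max_mismatch = 3L,
                          kinds = c("direct", "palindromic"),
                          exclude_trivial_self = TRUE) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  stopifnot(min_len >= 8L, max_mismatch >= 0L)
  structure(list(min_len = as.integer(min_len),
                 max_mismatch = as.integer(max_mismatch),
                 kinds = kinds,
                 exclude_trivial_self = isTRUE(exclude_trivial_self)),
            class = "search_params")
}

empty_pairs <- function() {
  data.frame(pos1 = integer(0), pos2 = integer(0), length = integer(0),
             orientation = character(0), mismatches = integer(0),
             seq1 = character(0), seq2 = character(0),
             stringsAsFactors = FALSE)
}

#' Find maximal repeat pairs
#'
#' Seed-and-extend search for direct and palindromic (reverse-complement)
#' repeat pairs at `>= min_len` bp within `max_mismatch` Hamming distance.
#' Seeds are exact k-mers with `k = floor(min_len / (max_mismatch + 1))`
#' (pigeonhole guarantee).  See the file header for the maximality and
#' locus-canonicalization contract.  Output is sorted by (pos1, pos2,
#' length) and deterministic; overlapping copies (tandem arrays) are
#' permitted.  The genome is treated as linear.
#'
#' @param rec a [plastome_record()] or DNA string.
#' @param params a [search_params()].
#' @return data frame of class `repeat_pairs`: `pos1 <= pos2` (1-based
#'   starts), `length`, `orientation`, `mismatches`, and the two genomic
#'   substrings `seq1`, `seq2` (`seq2` as written on the genome; for
#'   palindromic pairs `seq1` matches the reverse complement of `seq2`).
#' @export
find_maximal_repeats <- function(rec, params = search_params()) {
  if (inherits(rec, "plastome_record")) rec <- rec$sequence
  stopifnot(is.character(rec), length(rec) == 1L)
  if (nchar(rec) == 0L) stop("empty sequence", call. = FALSE)
  if (nchar(rec) < params$min_len) {
    out <- empty_pairs()
    class(out) <- c("repeat_pairs", class(out))
    return(out)
  }
  S <- dna_codes(rec)
  n <- length(S)
  res <- list()
  if ("direct" %in% params$kinds)
    res$direct <- find_repeats_oriented(S, S, params, n, palindromic = FALSE)
  if ("palindromic" %in% params$kinds) {
    Rv <- rev(comp_codes(S))
    res$pal <- find_repeats_oriented(S, Rv, params, n, palindromic = TRUE)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) out <- empty_pairs()[0, 1:5]
  out <- out[order(out$pos1, out$pos2, out$length, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$seq1 <- if (nrow(out) > 0L)
    substring(rec, out$pos1, out$pos1 + out$length - 1L) else character(0)
  out$seq2 <- if (nrow(out) > 0L)
    substring(rec, out$pos2, out$pos2 + out$length - 1L) else character(0)
  attr(out, "params") <- params
  class(out) <- c("repeat_pairs", class(out))
  out
}

# One orientation.  xa is the genome; xb is the genome (direct) or its
# reverse complement (palindromic).  Windows live on diagonals d = j - i.
find_repeats_oriented <- function(xa, xb, params, n, palindromic) {
  min_len <- params$min_len
  mm <- params$max_mismatch
  k <- max(2L, min(21L, min_len %/% (mm + 1L)))
  if (k > min_len) k <- min_len
  hits <- seed_hits(kmer_codes(xa, k), kmer_codes(xb, k))
  if (!palindromic) {
    hits <- if (params$exclude_trivial_self) hits[hits$j > hits$i, ]
            else hits[hits$j >= hits$i, ]
  }
  if (nrow(hits) == 0L) return(NULL)
  hits$d <- hits$j - hits$i
  data.table::setDT(hits)
  wins <- hits[, {
    dd <- .BY$d
    runs <- merge_seed_runs(i, k)
    w <- enumerate_windows(xa, xb, dd, runs, min_len, mm)
    if (is.null(w)) list(start = integer(0), end = integer(0),
                         mmc = integer(0))
    else {
      sel <- select_canonical(w)
      list(start = sel$start, end = sel$end, mmc = sel$mmc)
    }
  }, by = "d"]
  if (nrow(wins) == 0L) return(NULL)
  len <- wins$end - wins$start + 1L
  if (!palindromic) {
    out <- data.frame(pos1 = wins$start, pos2 = wins$start + wins$d,
                      length = len,
                      orientation = "direct", mismatches = wins$mmc,
                      stringsAsFactors = FALSE)
    if (params$exclude_trivial_self) {
      out <- out[!(out$pos2 == out$pos1), , drop = FALSE]
    }
  } else {
    # map the B-side footprint back to genome coordinates
    p2 <- n - (wins$end + wins$d) + 1L
    pos1 <- pmin(wins$start, p2)
    pos2 <- pmax(wins$start, p2)
    out <- data.frame(pos1 = pos1, pos2 = pos2, length = len,
                      orientation = "palindromic", mismatches = wins$mmc,
                      stringsAsFactors = FALSE)
    out <- out[!duplicated(out), , drop = FALSE]
  }
  out
}

# Enumerate candidate windows around each exact run on one diagonal:
# for every budget b in 0..mm, the b-maximal windows containing the run.
# Returns data.frame(start, end, mmc) of unique candidates >= min_len.
enumerate_windows <- function(xa, xb, d, runs, min_len, mm) {
  na <- length(xa); nb <- length(xb)
  lo <- max(1L, 1L - d); hi <- min(na, nb - d)
  match_at <- function(p) {
    v <- xa[p]
    v > 0L && v == xb[p + d]
  }
  res_s <- integer(0); res_e <- integer(0); res_m <- integer(0)
  for (ri in seq_len(nrow(runs))) {
    rs <- runs[ri, 1L]; re <- runs[ri, 2L]
    # blockers leftwards / rightwards: mm+1 mismatch positions or boundary
    Lpos <- integer(mm + 1L); Lreal <- logical(mm + 1L)
    p <- rs; cnt <- 0L
    while (cnt < mm + 1L) {
      p <- p - 1L
      if (p < lo) { Lpos[(cnt + 1L):(mm + 1L)] <- lo - 1L; break }
      if (!match_at(p)) { cnt <- cnt + 1L; Lpos[cnt] <- p; Lreal[cnt] <- TRUE }
    }
    Rpos <- integer(mm + 1L); Rreal <- logical(mm + 1L)
    p <- re; cnt <- 0L
    while (cnt < mm + 1L) {
      p <- p + 1L
      if (p > hi) { Rpos[(cnt + 1L):(mm + 1L)] <- hi + 1L; break }
      if (!match_at(p)) { cnt <- cnt + 1L; Rpos[cnt] <- p; Rreal[cnt] <- TRUE }
    }
    for (b in 0:mm) {
      for (t in 0:b) {
        s <- Lpos[t + 1L] + 1L
        e <- Rpos[b - t + 1L] - 1L
        if (e - s + 1L < min_len) next
        mmc <- sum(Lreal[seq_len(t)]) + sum(Rreal[seq_len(b - t)])
        res_s <- c(res_s, s); res_e <- c(res_e, e); res_m <- c(res_m, mmc)
      }
    }
  }
  if (length(res_s) == 0L) return(NULL)
  w <- data.frame(start = res_s, end = res_e, mmc = res_m)
  w[!duplicated(w[, c("start", "end")]), , drop = FALSE]
}

# Locus-canonical greedy selection on one diagonal: rank candidates by
# (mismatches, -length, start), select unless overlapping a selected window.
select_canonical <- function(w) {
  len <- w$end - w$start + 1L
  ord <- order(w$mmc, -len, w$start)
  w <- w[ord, , drop = FALSE]
  sel_s <- integer(0); sel_e <- integer(0); keep <- integer(0)
  for (q in seq_len(nrow(w))) {
    s <- w$start[q]; e <- w$end[q]
    if (length(sel_s) == 0L || all(e < sel_s | s > sel_e)) {
      sel_s <- c(sel_s, s); sel_e <- c(sel_e, e); keep <- c(keep, q)
    }
  }
  out <- w[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Ungapped identity of two equal-length sequences
#'
#' `1 - Hamming(a, b) / length`.  Ambiguity codes never match, including
#' against themselves.  A 30-bp pair with 3 mismatches is 0.90.
#'
#' @param a,b DNA strings of equal length.
#' @export
pair_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length", call. = FALSE)
  if (nchar(a) == 0L) stop("empty sequences", call. = FALSE)
  ca <- dna_codes(a); cb <- dna_codes(b)
  1 - sum(!(ca > 0L & ca == cb)) / length(ca)
}
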