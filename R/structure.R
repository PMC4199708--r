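# Quadripartite structure: inverted-repeat detection, segment lengths,
# GC content, and the bp-extent of border genes duplicated within the IR.

#' Detect the quadripartite partition of a plastome
#'
#' Finds the longest pair of non-overlapping segments where one is the exact
#' reverse complement of the other (each at least `min_ir_len` bp): the
#' inverted repeat.  The longer of the two single-copy segments between the
#' IR copies is the LSC, the shorter the SSC.  For circular records the
#' search considers origin-spanning placements; the returned intervals are on
#' the canonical rotation that starts at the LSC start, with the rotation
#' offset relative to the input recorded in the result.  Exact matching is
#' the default; `max_mismatch > 0` enables mismatch-tolerant end extension.
#'
#' @param rec a [plastome_record()].
#' @param min_ir_len minimum IR length in bp (default 10000, well under the
#'   ~25 kb IRs of legume plastomes but above spurious matches).
#' @param max_mismatch mismatches tolerated when extending the IR ends
#'   (default 0: exact).
#' @return a `quadripartite_partition`: segment intervals `lsc`, `ira`,
#'   `ssc`, `irb` (1-based closed, on the canonical rotation), lengths
#'   `lsc_len`, `ssc_len`, `ir_len`, and `rotation` (bases to rotate the
#'   input left to reach the canonical frame; 0 for linear records).
#' @export
detect_inverted_repeat <- function(rec, min_ir_len = 10000L,
                                   max_mismatch = 0L) {
  stopifnot(inherits(rec, "plastome_record"))
  n <- seq_length(rec)
  if (n <= 2L * min_ir_len)
    stop("sequence length must exceed 2 * min_ir_len", call. = FALSE)

  S <- dna_codes(rec$sequence)
  D <- if (rec$circular) c(S, S) else S
  m <- length(D)
  Rv <- rev(comp_codes(D))

  if (max_mismatch == 0L) {
    cand <- exact_matches(D, Rv, min_ir_len)
  } else {
    # pigeonhole: an IR pair with <= max_mismatch mismatches contains an
    # exact run of at least min_ir_len / (max_mismatch + 1) bases
    seed_min <- max(32L, min_ir_len %/% (max_mismatch + 1L))
    cand <- exact_matches(D, Rv, seed_min)
    if (nrow(cand) > 0L) {
      cand <- extend_through_mismatches(D, Rv, cand, max_mismatch)
      cand <- cand[cand$len >= min_ir_len, , drop = FALSE]
    }
  }

  if (nrow(cand) > 0L) {
    # footprints on D: copy1 [i, i+len-1]; copy2 maps back from Rv
    f1s <- cand$i
    f1e <- cand$i + cand$len - 1L
    f2s <- m - (cand$j + cand$len - 1L) + 1L
    f2e <- m - cand$j + 1L
    # canonical: first copy = smaller start
    swap <- f2s < f1s
    tmp <- f1s[swap]; f1s[swap] <- f2s[swap]; f2s[swap] <- tmp
    tmp <- f1e[swap]; f1e[swap] <- f2e[swap]; f2e[swap] <- tmp
    keep <- !duplicated(data.frame(f1s, f2s, cand$len))
    f1s <- f1s[keep]; f1e <- f1e[keep]; f2s <- f2s[keep]; f2e <- f2e[keep]
    len <- (f1e - f1s + 1L)
    if (rec$circular) {
      keep2 <- f1s <= n & len <= n
      f1s <- f1s[keep2]; f1e <- f1e[keep2]
      f2s <- f2s[keep2]; f2e <- f2e[keep2]; len <- len[keep2]
    }
    # non-overlap of the two copies (on the circle for circular records)
    if (rec$circular) {
      a1 <- (f1s - 1L) %% n; a2 <- (f2s - 1L) %% n
      no_ov <- vapply(seq_along(f1s), function(q) {
        !circular_intervals_overlap(a1[q], len[q], a2[q], len[q], n)
      }, TRUE)
    } else {
      no_ov <- f2s > f1e
    }
    f1s <- f1s[no_ov]; f1e <- f1e[no_ov]
    f2s <- f2s[no_ov]; f2e <- f2e[no_ov]; len <- len[no_ov]
  } else len <- integer(0)

  if (length(len) == 0L)
    stop("no IR found: no reverse-complement segment pair of at least ",
         min_ir_len, " bp (inverted-repeat-loss genome?)", call. = FALSE)

  best <- order(-len, f1s)[1L]
  ir_len <- len[best]

  if (rec$circular) {
    s1 <- (f1s[best] - 1L) %% n   # 0-based circle starts
    s2 <- (f2s[best] - 1L) %% n
    e1 <- (s1 + ir_len - 1L) %% n
    e2 <- (s2 + ir_len - 1L) %% n
    gap_after_1 <- (s2 - e1 - 1L) %% n   # single-copy segment copy1 -> copy2
    gap_after_2 <- (s1 - e2 - 1L) %% n
    if (gap_after_1 >= gap_after_2) {
      # LSC follows copy2; copy1 is IRa in canonical orientation? No:
      # canonical order is LSC, IRa, SSC, IRb; LSC is the longer gap.
      lsc_len <- gap_after_1; ssc_len <- gap_after_2
      lsc_start0 <- (e1 + 1L) %% n      # after copy1
      ira_start0 <- s2                   # copy2 follows LSC
    } else {
      lsc_len <- gap_after_2; ssc_len <- gap_after_1
      lsc_start0 <- (e2 + 1L) %% n
      ira_start0 <- s1
    }
    rotation <- lsc_start0
  } else {
    s1 <- f1s[best]; e1 <- f1e[best]; s2 <- f2s[best]; e2 <- f2e[best]
    flank <- (s1 - 1L) + (n - e2)       # linearized-circle outer segment
    mid <- s2 - e1 - 1L
    lsc_len <- max(flank, mid); ssc_len <- min(flank, mid)
    rotation <- 0L
  }

  if (lsc_len + ssc_len + 2L * ir_len != n)
    stop("internal error: partition does not cover the sequence")

  part <- structure(list(
    ir_len = as.integer(ir_len), lsc_len = as.integer(lsc_len),
    ssc_len = as.integer(ssc_len),
    lsc = c(1L, as.integer(lsc_len)),
    ira = c(lsc_len + 1L, lsc_len + ir_len),
    ssc = c(lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len),
    irb = c(lsc_len + ir_len + ssc_len + 1L, n),
    rotation = as.integer(rotation), n = n, circular = rec$circular),
    class = "quadripartite_partition")

  if (!rec$circular) {
    # report intervals in the input frame when they are expressible
    if (n - e2 == 0L) {          # ends exactly at IRb (generator layout)
      part$lsc <- c(1L, s1 - 1L); part$ira <- c(s1, e1)
      part$ssc <- c(e1 + 1L, s2 - 1L); part$irb <- c(s2, e2)
      if (mid > flank) {         # mid segment is the LSC, flank the SSC
        names(part)[match(c("lsc", "ssc"), names(part))] <- c("ssc", "lsc")
      }
    }
  }
  part
}

circular_intervals_overlap <- function(s1, len1, s2, len2, n) {
  # 0-based starts on a circle of size n
  if (len1 + len2 >= n) return(TRUE)
  # distance from s1 to s2 along the circle
  fwd <- (s2 - s1) %% n
  bwd <- (s1 - s2) %% n
  fwd < len1 || bwd < len2
}

# Mismatch-tolerant IR end extension: X-drop extension (+1 match,
# -3 mismatch, drop-off 12) from each exact candidate, capped at `budget`
# total mismatches.  The score decays quickly in unrelated flanking
# sequence, so extension self-terminates at the IR junctions while crossing
# isolated substitutions inside a diverged IR.
extend_through_mismatches <- function(D, Rv, cand, budget,
                                      xdrop = 12L, penalty = 3L) {
  m <- length(D)
  grow <- function(pos, dir, d, lo, hi, mism_left) {
    score <- 0L; best <- 0L; best_pos <- pos; best_mism <- 0L; used <- 0L
    p <- pos
    repeat {
      p <- p + dir
      if (p < lo || p > hi) break
      if (D[p] > 0L && D[p] == Rv[p + d]) score <- score + 1L
      else {
        used <- used + 1L
        if (used > mism_left) break
        score <- score - penalty
      }
      if (score > best) { best <- score; best_pos <- p; best_mism <- used }
      if (score < best - xdrop) break
    }
    list(pos = best_pos, mism = best_mism)
  }
  for (q in seq_len(nrow(cand))) {
    i <- cand$i[q]; len <- cand$len[q]
    d <- cand$j[q] - i
    lo <- max(1L, 1L - d); hi <- min(m, m - d)
    r <- grow(i + len - 1L, +1L, d, lo, hi, budget)
    l <- grow(i, -1L, d, lo, hi, budget - r$mism)
    cand$i[q] <- l$pos; cand$j[q] <- l$pos + d
    cand$len[q] <- r$pos - l$pos + 1L
  }
  cand[!duplicated(cand), , drop = FALSE]
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("<quadripartite_partition> LSC %d bp | IR %d bp x2 | SSC %d bp (total %d)\n",
              x$lsc_len, x$ir_len, x$ssc_len, x$n))
  cat(sprintf("  lsc [%d,%d] ira [%d,%d] ssc [%d,%d] irb [%d,%d] rotation %d\n",
              x$lsc[1], x$lsc[2], x$ira[1], x$ira[2], x$ssc[1], x$ssc[2],
              x$irb[1], x$irb[2], x$rotation))
  invisible(x)
}

#' Canonical rotation of a circular record
#'
#' Rotates the record so position 1 is the LSC start found by
#' [detect_inverted_repeat()].  If a feature table is supplied and contains a
#' feature named `trnH`, the rotation starts at that feature instead
#' (the conventional plastome linearization).
#'
#' @param rec a [plastome_record()].
#' @param part its `quadripartite_partition`.
#' @param features optional feature table (input coordinates).
#' @export
canonical_rotation <- function(rec, part, features = NULL) {
  off <- part$rotation
  if (!is.null(features) && nrow(features) > 0L &&
      any(features$name == "trnH"))
    off <- features$start[match("trnH", features$name)] - 1L
  rotate_record(rec, off)
}

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguity codes and N are excluded from both
#' numerator and denominator.
#'
#' @param rec a [plastome_record()] or DNA string.
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(rec) {
  if (inherits(rec, "plastome_record")) rec <- rec$sequence
  codes <- dna_codes(rec)
  denom <- sum(codes > 0L)
  if (denom == 0L)
    stop("GC content undefined: no unambiguous bases", call. = FALSE)
  sum(codes == 2L | codes == 3L) / denom
}

#' AT content over unambiguous bases
#' @inheritParams gc_content
#' @export
at_content <- function(rec) {
  if (inherits(rec, "plastome_record")) rec <- rec$sequence
  codes <- dna_codes(rec)
  denom <- sum(codes > 0L)
  if (denom == 0L)
    stop("AT content undefined: no unambiguous bases", call. = FALSE)
  sum(codes == 1L | codes == 4L) / denom
}

#' Extent of a feature inside the inverted repeats
#'
#' Number of bases of `feature` lying inside IRa or IRb of `part`.  The
#' feature must be given in the partition's coordinate frame; an interval
#' with `start > end` is interpreted as wrapping the origin of a circular
#' record.
#'
#' @param feature integer vector `c(start, end)` (1-based closed) or a
#'   one-row feature table.
#' @param part a `quadripartite_partition`.
#' @return overlap in bp (0 when disjoint).
#' @export
ir_overlap_extent <- function(feature, part) {
  stopifnot(inherits(part, "quadripartite_partition"))
  if (is.data.frame(feature)) feature <- c(feature$start[1L], feature$end[1L])
  s <- feature[1L]; e <- feature[2L]
  pieces <- if (s <= e) list(c(s, e)) else list(c(s, part$n), c(1L, e))
  tot <- 0L
  for (p in pieces) {
    tot <- tot +
      interval_overlap(p[1L], p[2L], part$ira[1L], part$ira[2L]) +
      interval_overlap(p[1L], p[2L], part$irb[1L], part$irb[2L])
  }
  as.integer(tot)
}

#' Summary table of plastome architecture
#'
#' One row per genome: total length, LSC/SSC/IR lengths, the IR-duplicated
#' extent of each requested border gene, and GC content rounded to three
#' decimals (a Table-1-style summary).
#'
#' @param recs list of [plastome_record()] objects.
#' @param features_list list of feature tables, parallel to `recs` (or NULL).
#' @param border_genes character vector of gene names to measure.
#' @param min_ir_len passed to [detect_inverted_repeat()].
#' @return data frame.
#' @export
structure_table <- function(recs, features_list = NULL,
                            border_genes = character(0),
                            min_ir_len = 10000L) {
  if (inherits(recs, "plastome_record")) recs <- list(recs)
  rows <- lapply(seq_along(recs), function(k) {
    rec <- recs[[k]]
    part <- detect_inverted_repeat(rec, min_ir_len = min_ir_len)
    row <- data.frame(id = rec$id, total = seq_length(rec),
                      lsc = part$lsc_len, ssc = part$ssc_len,
                      ir = part$ir_len, stringsAsFactors = FALSE)
    feats <- if (!is.null(features_list)) features_list[[k]] else NULL
    for (g in border_genes) {
      ext <- NA_integer_
      if (!is.null(feats) && g %in% feats$name) {
        fr <- feats[feats$name == g, , drop = FALSE][1L, ]
        ext <- ir_overlap_extent(c(fr$start, fr$end), part)
      }
      row[[paste0(g, "_ir_bp")]] <- ext
    }
    row$gc <- round(gc_content(rec), 3L)
    row
  })
  do.call(rbind, rows)
}
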