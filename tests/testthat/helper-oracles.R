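# Independent brute-force oracles.  These re-implement the contracts by
# exhaustive sweeps (no seeding, no shared code with the package engine)
# and are intentionally slow.

orc_codes <- function(s) {
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  match(v, c("A", "C", "G", "T"), nomatch = 0L)
}

orc_comp <- function(codes) ifelse(codes == 0L, 0L, 5L - codes)

# All maximal windows on one diagonal for every budget 0..max_mm, then
# locus-canonical greedy selection (fewest mismatches, longest, leftmost).
# `match` is a logical vector for positions lo..hi of the A side.
orc_diagonal_windows <- function(match, lo, hi, min_len, max_mm) {
  mism <- which(!match) + lo - 1L
  res <- NULL
  for (b in 0:max_mm) {
    if (length(mism) <= b) {
      if (hi - lo + 1L >= min_len)
        res <- rbind(res, c(lo, hi, length(mism)))
    } else {
      B <- c(lo - 1L, mism, hi + 1L)
      for (t in seq_len(length(B) - b - 1L)) {
        s <- B[t] + 1L
        e <- B[t + b + 1L] - 1L
        if (e - s + 1L >= min_len) res <- rbind(res, c(s, e, b))
      }
    }
  }
  if (is.null(res)) return(NULL)
  res <- unique(res)
  # greedy selection
  ord <- order(res[, 3L], -(res[, 2L] - res[, 1L]), res[, 1L])
  res <- res[ord, , drop = FALSE]
  sel <- NULL
  for (q in seq_len(nrow(res))) {
    s <- res[q, 1L]; e <- res[q, 2L]
    if (is.null(sel) || all(e < sel[, 1L] | s > sel[, 2L]))
      sel <- rbind(sel, res[q, , drop = FALSE])
  }
  sel
}

# Exhaustive maximal-repeat oracle: every diagonal, both orientations.
# Returns a data.frame(pos1, pos2, length, orientation, mismatches) sorted
# like find_maximal_repeats output.
oracle_repeats <- function(s, min_len, max_mm,
                           kinds = c("direct", "palindromic")) {
  x <- orc_codes(s)
  n <- length(x)
  rows <- list()
  if ("direct" %in% kinds) {
    for (d in seq_len(n - 1L)) {
      hi <- n - d
      if (hi < min_len) next
      m <- x[1:hi] > 0L & x[1:hi] == x[(1L + d):n]
      w <- orc_diagonal_windows(m, 1L, hi, min_len, max_mm)
      if (!is.null(w))
        rows[[length(rows) + 1L]] <- data.frame(
          pos1 = w[, 1L], pos2 = w[, 1L] + d,
          length = w[, 2L] - w[, 1L] + 1L,
          orientation = "direct", mismatches = w[, 3L])
    }
  }
  if ("palindromic" %in% kinds) {
    y <- rev(orc_comp(x))   # reverse complement codes
    for (d in (1L - n):(n - 1L)) {
      lo <- max(1L, 1L - d); hi <- min(n, n - d)
      if (hi - lo + 1L < min_len) next
      idx <- lo:hi
      m <- x[idx] > 0L & x[idx] == y[idx + d]
      w <- orc_diagonal_windows(m, lo, hi, min_len, max_mm)
      if (is.null(w)) next
      p2 <- n - (w[, 2L] + d) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        pos1 = pmin(w[, 1L], p2), pos2 = pmax(w[, 1L], p2),
        length = w[, 2L] - w[, 1L] + 1L,
        orientation = "palindromic", mismatches = w[, 3L])
    }
  }
  out <- if (length(rows) > 0L) unique(do.call(rbind, rows))
         else data.frame(pos1 = integer(0), pos2 = integer(0),
                         length = integer(0), orientation = character(0),
                         mismatches = integer(0))
  out <- out[order(out$pos1, out$pos2, out$length, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Quadratic IR oracle for linear sequences: the longest pair of
# non-overlapping segments, one the exact reverse complement of the other,
# found by sweeping every antidiagonal for maximal match runs.
oracle_longest_palindrome_pair <- function(s, min_len) {
  x <- orc_codes(s)
  n <- length(x)
  y <- rev(orc_comp(x))
  best <- NULL
  for (d in (1L - n):(n - 1L)) {
    lo <- max(1L, 1L - d); hi <- min(n, n - d)
    if (hi - lo + 1L < min_len) next
    idx <- lo:hi
    m <- x[idx] > 0L & x[idx] == y[idx + d]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values & r$lengths >= min_len)) {
      a1 <- idx[starts[q]]; a2 <- idx[ends[q]]
      len <- a2 - a1 + 1L
      b2 <- n - (a2 + d) + 1L           # start of the mapped second copy
      p1 <- min(a1, b2); p2 <- max(a1, b2)
      if (p2 <= p1 + len - 1L) next     # overlapping copies: not an IR pair
      cand <- c(p1, p2, len)
      if (is.null(best) || len > best[3L] ||
          (len == best[3L] && p1 < best[1L])) best <- cand
    }
  }
  best  # c(pos1, pos2, len) or NULL
}

# Per-column SNP recount for two aligned rows.
oracle_pair_snps <- function(a, b) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  list(snps = sum(ok & va != vb), compared = sum(ok))
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

mutate_string <- function(s, k) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  at <- sample(length(v), k)
  for (i in at) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}
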