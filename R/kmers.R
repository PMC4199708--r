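# Shared k-mer seeding machinery for exact/approximate match discovery.
# Sequences are integer code vectors (A=1..T=4, 0 = ambiguity, never matches).

# Base-5 numeric k-mer codes; windows containing an ambiguity code are NA.
# k is capped at 21 so codes stay exact in double precision (5^21 < 2^53).
kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (k > 21L) stop("k-mer length capped at 21", call. = FALSE)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  km <- numeric(m)
  for (t in 0:(k - 1L)) km <- km * 5 + codes[(1L + t):(m + t)]
  amb <- cumsum(c(0L, codes == 0L))
  bad <- (amb[(k + 1L):(n + 1L)] - amb[1:m]) > 0L
  km[bad] <- NA_real_
  km
}

# All seed hit pairs (i in A, j in B) sharing a k-mer.  data.table join.
seed_hits <- function(kma, kmb) {
  A <- data.table::data.table(key_ = kma, i = seq_along(kma))
  A <- A[!is.na(A$key_)]
  B <- data.table::data.table(key_ = kmb, j = seq_along(kmb))
  B <- B[!is.na(B$key_)]
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(data.table::data.table(i = integer(0), j = integer(0)))
  m <- merge(A, B, by = "key_", allow.cartesian = TRUE)
  m[, c("i", "j")]
}

# Merge seed hits on one diagonal into maximal exact runs.
# `iv` = sorted start positions (A side) of k-mer hits on the diagonal.
# Returns matrix start,end of exact intervals (A side).
merge_seed_runs <- function(iv, k) {
  iv <- sort(iv)
  brk <- c(TRUE, diff(iv) > k)         # new run starts here
  starts <- iv[brk]
  last <- iv[c(brk[-1L], TRUE)]        # last seed start of each run
  cbind(start = starts, end = last + k - 1L)
}

# Maximal exact matches of length >= min_len between code vectors xa and xb.
# Returns data.frame(i, j, len): xa[i..i+len-1] == xb[j..j+len-1], maximal.
exact_matches <- function(xa, xb, min_len, k = min(21L, min_len)) {
  hits <- seed_hits(kmer_codes(xa, k), kmer_codes(xb, k))
  if (nrow(hits) == 0L)
    return(data.frame(i = integer(0), j = integer(0), len = integer(0)))
  hits[, d := j - i]
  na <- length(xa); nb <- length(xb)
  out <- hits[, {
    dd <- .BY$d
    runs <- merge_seed_runs(i, k)
    # extend each run outwards while bases match exactly
    s <- runs[, 1L]; e <- runs[, 2L]
    for (ri in seq_along(s)) {
      while (s[ri] > 1L && s[ri] + dd > 1L &&
             xa[s[ri] - 1L] > 0L &&
             xa[s[ri] - 1L] == xb[s[ri] - 1L + dd]) s[ri] <- s[ri] - 1L
      while (e[ri] < na && e[ri] + dd < nb &&
             xa[e[ri] + 1L] > 0L &&
             xa[e[ri] + 1L] == xb[e[ri] + 1L + dd]) e[ri] <- e[ri] + 1L
    }
    keep <- !duplicated(s)
    list(start = s[keep], end = e[keep])
  }, by = "d"]
  out <- out[out$end - out$start + 1L >= min_len]
  if (nrow(out) == 0L)
    return(data.frame(i = integer(0), j = integer(0), len = integer(0)))
  data.frame(i = out$start, j = out$start + out$d,
             len = out$end - out$start + 1L)
}
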