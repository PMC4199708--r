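# Low-level DNA string helpers shared across the package.  Sequences are
# plain uppercase character scalars; positions are 1-based closed intervals.

.datatable.aware <- TRUE

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse complement of a DNA string
#'
#' IUPAC-aware reverse complement on a plain character scalar.
#'
#' @param x single DNA string (IUPAC alphabet).
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Integer encoding: A=1 C=2 G=3 T=4, anything else (N/IUPAC ambiguity) 0.
# Ambiguity codes never match anything, including themselves.
dna_codes <- function(x) {
  v <- utf8ToInt(toupper(x))
  out <- integer(length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  out
}

# Complement on the integer encoding (0 stays 0).
comp_codes <- function(codes) {
  lut <- c(4L, 3L, 2L, 1L)
  out <- integer(length(codes))
  keep <- codes > 0L
  out[keep] <- lut[codes[keep]]
  out
}

codes_to_dna <- function(codes) {
  stopifnot(all(codes >= 0L, codes <= 4L))
  chars <- c("N", "A", "C", "G", "T")[codes + 1L]
  paste(chars, collapse = "")
}

substr_at <- function(x, start, len) substr(x, start, start + len - 1L)

# Run code with a deterministic RNG stream, restoring the caller's stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, force(code))
}

# Overlap in bp of two 1-based closed intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

validate_dna <- function(x, what = "sequence") {
  chars <- unique(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad) > 0L)
    stop(sprintf("%s contains non-IUPAC characters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
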