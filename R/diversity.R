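# Alignment-based polymorphism and rate estimation: pairwise SNP counts,
# nucleotide diversity (pi), sliding-window identity, and substitution
# rates calibrated by divergence dates.
#
# Gap/ambiguity treatment is pairwise deletion: a column counts for a pair
# only when both rows carry an unambiguous base (A/C/G/T); indel
# polymorphisms are thereby excluded, and for two sequences pi = S / L
# exactly.

#' Build an alignment matrix
#'
#' @param x named character vector of equal-length aligned sequences, a
#'   `Biostrings::DNAStringSet`, or a path to an aligned FASTA file.
#' @return object of class `alignment_matrix` with fields `ids`, `seqs`.
#' @export
alignment_matrix <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (inherits(x, "DNAStringSet")) {
    ids <- sub("\\s.*$", "", names(x))
    x <- stats::setNames(as.character(x), ids)
  }
  stopifnot(is.character(x), length(x) >= 2L)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("seq", seq_along(x))
  widths <- nchar(x)
  if (length(unique(widths)) != 1L)
    stop("malformed alignment: rows have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  structure(list(ids = names(x), seqs = toupper(unname(x)),
                 width = widths[1L]),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("<alignment_matrix> %d sequences x %d columns\n",
              length(x$ids), x$width))
  invisible(x)
}

aln_row <- function(aln, i) {
  if (is.character(i)) {
    idx <- match(i, aln$ids)
    if (is.na(idx)) stop("no such sequence: ", i, call. = FALSE)
    idx
  } else {
    stopifnot(i >= 1L, i <= length(aln$ids))
    as.integer(i)
  }
}

#' Pairwise SNP count and per-pair diversity
#'
#' A column is compared when both rows carry an unambiguous base (not a gap,
#' not N/IUPAC); SNPs are compared columns where the bases differ;
#' `pi = snps / compared_sites`.
#'
#' @param aln an [alignment_matrix()].
#' @param i,j row indices or ids (i != j).
#' @return list: `snps`, `compared_sites`, `pi`.
#' @export
count_pairwise_snps <- function(aln, i, j) {
  stopifnot(inherits(aln, "alignment_matrix"))
  ii <- aln_row(aln, i); jj <- aln_row(aln, j)
  if (ii == jj) stop("i and j must differ", call. = FALSE)
  a <- dna_codes(aln$seqs[ii]); b <- dna_codes(aln$seqs[jj])
  comp <- a > 0L & b > 0L
  snps <- sum(comp & a != b)
  compared <- sum(comp)
  list(snps = snps, compared_sites = compared,
       pi = if (compared > 0L) snps / compared else NA_real_)
}

#' Nucleotide diversity of an alignment
#'
#' Average over all unordered row pairs of the per-pair proportion of
#' differing sites (pairwise deletion of gapped/ambiguous columns).  For two
#' rows this equals [count_pairwise_snps()]'s `pi` exactly.
#'
#' @param aln an [alignment_matrix()].
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "alignment_matrix"))
  m <- length(aln$ids)
  cmb <- utils::combn(m, 2L)
  mean(vapply(seq_len(ncol(cmb)), function(k)
    count_pairwise_snps(aln, cmb[1L, k], cmb[2L, k])$pi, 0))
}

#' Calibrated substitution rate
#'
#' `rate = snps / (aligned_sites * divergence_time)`.  The default follows
#' the divide-by-T convention (divergence date measures the tip-to-tip
#' path); `per_lineage = TRUE` divides by 2T instead.
#'
#' @param snps pairwise SNP count.
#' @param aligned_sites alignment length used for the count.
#' @param divergence_time divergence date in years (> 0).
#' @param per_lineage divide by 2T rather than T.
#' @return list of class `rate_estimate`: `rate` (subs/site/year), inputs
#'   echoed.
#' @export
substitution_rate <- function(snps, aligned_sites, divergence_time,
                              per_lineage = FALSE) {
  if (!(aligned_sites > 0)) stop("aligned_sites must be > 0", call. = FALSE)
  if (!(divergence_time > 0)) stop("divergence_time must be > 0",
                                   call. = FALSE)
  if (snps < 0) stop("snps must be >= 0", call. = FALSE)
  denom <- aligned_sites * divergence_time * if (per_lineage) 2 else 1
  structure(list(rate = snps / denom, snps = snps,
                 aligned_sites = aligned_sites,
                 divergence_time = divergence_time,
                 per_lineage = per_lineage),
            class = "rate_estimate")
}

#' Divergence-time calibration table
#'
#' @param taxon1,taxon2 character vectors naming unordered taxon pairs.
#' @param time_years divergence dates in years (> 0).
#' @export
calibration_table <- function(taxon1, taxon2, time_years) {
  stopifnot(length(taxon1) == length(taxon2),
            length(taxon1) == length(time_years), all(time_years > 0))
  structure(data.frame(taxon1 = as.character(taxon1),
                       taxon2 = as.character(taxon2),
                       time_years = as.numeric(time_years),
                       stringsAsFactors = FALSE),
            class = c("calibration_table", "data.frame"))
}

calibration_lookup <- function(calib, a, b) {
  hit <- (calib$taxon1 == a & calib$taxon2 == b) |
         (calib$taxon1 == b & calib$taxon2 == a)
  if (!any(hit))
    stop(sprintf("no calibration for taxon pair %s / %s", a, b),
         call. = FALSE)
  calib$time_years[which(hit)[1L]]
}

#' Pairwise SNP / substitution-rate matrix
#'
#' Square table with SNP counts above the diagonal and calibrated rates
#' below (Table-3 layout).  Cells whose rate falls below
#' `flag_factor * median` of the off-diagonal rates in their row are
#' flagged: rates that look anomalously slow given the calibration suggest
#' the calibration date overestimates the plastome divergence (chloroplast
#' capture).
#'
#' @param aln an [alignment_matrix()].
#' @param calib a [calibration_table()] covering every taxon pair.
#' @param flag_factor fold-threshold for slow-rate flagging (default 0.5).
#' @param per_lineage passed to [substitution_rate()].
#' @return list of class `rate_matrix`: `snps`, `rates` (symmetric
#'   matrices), `layout` (character matrix, SNPs above / rates below),
#'   `flags` (logical matrix).
#' @export
rate_matrix <- function(aln, calib, flag_factor = 0.5,
                        per_lineage = FALSE) {
  stopifnot(inherits(aln, "alignment_matrix"))
  ids <- sort(aln$ids)
  m <- length(ids)
  snps <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  rates <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      st <- count_pairwise_snps(aln, ids[a], ids[b])
      tt <- calibration_lookup(calib, ids[a], ids[b])
      r <- substitution_rate(st$snps, st$compared_sites, tt,
                             per_lineage = per_lineage)$rate
      snps[a, b] <- snps[b, a] <- st$snps
      rates[a, b] <- rates[b, a] <- r
    }
  }
  flags <- matrix(FALSE, m, m, dimnames = list(ids, ids))
  for (a in seq_len(m)) {
    rr <- rates[a, -a]
    med <- stats::median(rr, na.rm = TRUE)
    flags[a, -a] <- !is.na(rr) & rr < flag_factor * med
  }
  layout <- matrix("", m, m, dimnames = list(ids, ids))
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a < b) layout[a, b] <- format(snps[a, b])
      if (a > b) layout[a, b] <- sprintf("%.2e%s", rates[a, b],
                                         if (flags[a, b]) "*" else "")
    }
  }
  structure(list(snps = snps, rates = rates, flags = flags, layout = layout),
            class = "rate_matrix")
}

#' Sliding-window identity against a reference row
#'
#' For each non-reference row, the fraction of matching unambiguous columns
#' per window against the reference (windows of `window` columns advanced by
#' `step`; a window longer than the alignment collapses to one full-length
#' window).  Columns where either row is gapped/ambiguous are excluded from
#' the window's denominator; a window with no comparable column is NA.
#'
#' @param aln an [alignment_matrix()].
#' @param ref_row reference row id or index.
#' @param window,step window size and step in alignment columns.
#' @return data frame: `id`, `start`, `end`, `identity`.
#' @export
windowed_identity <- function(aln, ref_row = 1L, window = 100L, step = 25L) {
  stopifnot(inherits(aln, "alignment_matrix"))
  stopifnot(window >= 1L, step >= 1L)
  ri <- aln_row(aln, ref_row)
  w <- aln$width
  if (window > w) { window <- w }
  starts <- seq.int(1L, w - window + 1L, by = step)
  ref <- dna_codes(aln$seqs[ri])
  out <- lapply(setdiff(seq_along(aln$ids), ri), function(oi) {
    oth <- dna_codes(aln$seqs[oi])
    comp <- ref > 0L & oth > 0L
    eq <- comp & ref == oth
    ccum <- cumsum(comp); ecum <- cumsum(eq)
    e <- starts + window - 1L
    ncomp <- ccum[e] - c(0L, ccum)[starts]
    neq <- ecum[e] - c(0L, ecum)[starts]
    data.frame(id = aln$ids[oi], start = starts, end = e,
               identity = ifelse(ncomp > 0L, neq / ncomp, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Drop the second inverted repeat from an alignment
#'
#' Comparative plastome statistics are conventionally computed excluding the
#' second IR copy (it is a duplication, not independent sequence).  Removes
#' the IRb column range of the given partition; the alignment columns must
#' correspond to the partition's coordinate frame (true for the no-indel
#' alignments produced by [evolve_sequences()]).
#'
#' @param aln an [alignment_matrix()].
#' @param part a `quadripartite_partition`.
#' @export
drop_second_ir <- function(aln, part) {
  stopifnot(inherits(aln, "alignment_matrix"),
            inherits(part, "quadripartite_partition"))
  if (part$irb[2L] > aln$width)
    stop("partition extends beyond alignment width", call. = FALSE)
  keep <- setdiff(seq_len(aln$width), part$irb[1L]:part$irb[2L])
  seqs <- vapply(aln$seqs, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1L]][keep], collapse = ""), "")
  alignment_matrix(stats::setNames(seqs, aln$ids))
}
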