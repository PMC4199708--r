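# Consolidation of raw repeat pairs into tandem/dispersed classes, IR-aware
# filtering, and unique repeat families with unique locations.  Raw maximal
# pair listings inflate repeat counts: a repeat at k locations appears as
# C(k,2) pairs, and near-identical sequences recur across loci.  These
# operations deflate the raw listing to the biologically meaningful counts.

#' Classify repeat pairs as tandem or dispersed
#'
#' A pair is tandem when the gap between the end of the first copy and the
#' start of the second is under `threshold` bp (copies "within 1000 bp of
#' each other"); overlapping copies (gap <= 0) are tandem.
#'
#' @param pairs a `repeat_pairs` data frame (or anything with `pos1`,
#'   `pos2`, `length`).
#' @param threshold gap threshold in bp (default 1000).
#' @return character vector, `"tandem"` or `"dispersed"` per pair.
#' @export
classify_tandem <- function(pairs, threshold = 1000L) {
  if (nrow(pairs) == 0L) return(character(0))
  gap <- pairs$pos2 - (pairs$pos1 + pairs$length)   # bases between copies
  ifelse(gap < threshold, "tandem", "dispersed")
}

contained_in <- function(s, e, iv) s >= iv[1L] & e <= iv[2L]

#' Drop pairs confined to the inverted repeats
#'
#' Dispersed repeats occurring only inside IRa/IRb are expected (the IR is
#' itself a duplication) and are not considered further; pairs with at least
#' one copy intersecting a single-copy region are retained.
#'
#' @param pairs a `repeat_pairs` data frame.
#' @param part a `quadripartite_partition` for the same sequence.
#' @return the retained subset of `pairs`.
#' @export
filter_ir_duplicates <- function(pairs, part) {
  stopifnot(inherits(part, "quadripartite_partition"))
  if (nrow(pairs) == 0L) return(pairs)
  e1 <- pairs$pos1 + pairs$length - 1L
  e2 <- pairs$pos2 + pairs$length - 1L
  in_ir1 <- contained_in(pairs$pos1, e1, part$ira) |
            contained_in(pairs$pos1, e1, part$irb)
  in_ir2 <- contained_in(pairs$pos2, e2, part$ira) |
            contained_in(pairs$pos2, e2, part$irb)
  pairs[!(in_ir1 & in_ir2), , drop = FALSE]
}

#' Expand repeat pairs to per-copy instances
#'
#' Each pair contributes its two genomic copies.  Used as input to
#' [cluster_families()].
#'
#' @param pairs a `repeat_pairs` data frame.
#' @return data frame with `position`, `length`, `sequence`, `orientation`.
#' @export
repeat_instances <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(position = integer(0), length = integer(0),
                      sequence = character(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    position = c(pairs$pos1, pairs$pos2),
    length = rep(pairs$length, 2L),
    sequence = c(pairs$seq1, pairs$seq2),
    orientation = rep(pairs$orientation, 2L),
    stringsAsFactors = FALSE)
}

# Best ungapped match count of `short` against `long` over every offset,
# dangling ends allowed (overhanging positions score nothing).
best_offset_matches <- function(short, long) {
  ls <- length(short); ll <- length(long)
  best <- 0L; best_off <- 0L
  for (off in (-(ls - 1L)):(ll - 1L)) {
    i1 <- max(1L, 1L - off); i2 <- min(ls, ll - off)
    if (i2 < i1) next
    idx <- i1:i2
    m <- sum(short[idx] > 0L & short[idx] == long[idx + off])
    if (m > best) { best <- m; best_off <- off }
  }
  list(matches = best, offset = best_off)
}

# Best ungapped identity over the shorter sequence's length, all offsets,
# forward and reverse-complement.  Overhanging bases count as mismatches,
# so 0.90 identity requires at least 90% of the shorter sequence aligned
# and matching.
best_identity <- function(a, b) {
  ca <- dna_codes(a); cb <- dna_codes(b)
  if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  best <- max(best_offset_matches(ca, cb)$matches,
              best_offset_matches(rev(comp_codes(ca)), cb)$matches)
  best / length(ca)
}

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  lut <- c(A = "A", C = "C", G = "G", T = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  out <- lut[key]
  if (is.na(out)) "N" else unname(out)
}

# Majority consensus with IUPAC on ties, members aligned to the longest
# member at their best forward/revcomp offset (dangling ends ignored).
family_consensus <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  longest <- seqs[[which.max(nchar(seqs))]]
  cl <- dna_codes(longest)
  ll <- length(cl)
  cols <- vector("list", ll)
  for (sq in seqs) {
    ca <- dna_codes(sq)
    fwd <- best_offset_matches(ca, cl)
    rc <- best_offset_matches(rev(comp_codes(ca)), cl)
    if (rc$matches > fwd$matches) { ca <- rev(comp_codes(ca)); al <- rc }
    else al <- fwd
    for (t in seq_along(ca)) {
      p <- al$offset + t
      if (p >= 1L && p <= ll && ca[t] > 0L)
        cols[[p]] <- c(cols[[p]], c("A", "C", "G", "T")[ca[t]])
    }
  }
  chars <- vapply(cols, function(cs) {
    if (length(cs) == 0L) return("N")
    tab <- table(cs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) winners else iupac_code(winners)
  }, "")
  paste(chars, collapse = "")
}

#' Cluster repeat instances into families
#'
#' Two-stage consolidation: (i) instances at the same locus differing only
#' in extent (one interval containing the other, or overlapping by at least
#' 80% of the shorter) are merged, keeping the longest; (ii) merged
#' instances are single-linkage clustered at `>= identity_threshold`
#' ungapped identity over the shorter member, with reverse-complement
#' matches clustering together.  Deterministic: input order is canonicalized
#' before clustering.
#'
#' @param instances instance table from [repeat_instances()].
#' @param identity_threshold clustering identity (default 0.90, matching the
#'   search identity).
#' @return list of `repeat_family` objects: `family_id`, `representative`
#'   (majority consensus, IUPAC on ties), `members` (data frame),
#'   `n_locations`, `classification` (`"tandem"` if every consecutive pair
#'   of locations is under 1000 bp apart, else `"dispersed"`), and
#'   `coding_flags` (NA until [annotate_locations()]).
#' @export
cluster_families <- function(instances, identity_threshold = 0.90) {
  if (nrow(instances) == 0L) return(list())
  inst <- instances[order(instances$position, -instances$length), ,
                    drop = FALSE]
  rownames(inst) <- NULL
  m <- nrow(inst)
  s <- inst$position; e <- inst$position + inst$length - 1L

  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  # stage (i): same-locus merge
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      if (s[b] > e[a]) break
      ov <- interval_overlap(s[a], e[a], s[b], e[b])
      shorter <- min(inst$length[a], inst$length[b])
      contain <- (s[a] <= s[b] && e[b] <= e[a]) || (s[b] <= s[a] && e[a] <= e[b])
      if (contain || ov >= 0.8 * shorter) union_(a, b)
    }
  }
  grp <- vapply(seq_len(m), find, 0L)
  merged <- lapply(split(seq_len(m), grp), function(idx) {
    pick <- idx[which.max(inst$length[idx])]
    inst[pick, , drop = FALSE]
  })
  merged <- do.call(rbind, merged)
  merged <- merged[order(merged$position), , drop = FALSE]
  rownames(merged) <- NULL

  # stage (ii): single-linkage sequence clustering
  mm <- nrow(merged)
  parent <- seq_len(mm)
  if (mm > 1L) {
    for (a in seq_len(mm - 1L)) {
      for (b in (a + 1L):mm) {
        if (best_identity(merged$sequence[a], merged$sequence[b]) >=
            identity_threshold) union_(a, b)
      }
    }
  }
  grp <- vapply(seq_len(mm), find, 0L)
  comps <- split(seq_len(mm), grp)
  comps <- comps[order(vapply(comps, function(ix) min(merged$position[ix]), 0L))]

  lapply(seq_along(comps), function(fi) {
    ix <- comps[[fi]]
    members <- merged[ix, , drop = FALSE]
    members <- members[order(members$position), , drop = FALSE]
    rownames(members) <- NULL
    pos <- members$position
    gaps <- if (length(pos) > 1L)
      pos[-1L] - (pos[-length(pos)] + members$length[-length(pos)])
    else integer(0)
    structure(list(
      family_id = sprintf("family_%02d", fi),
      representative = family_consensus(members$sequence),
      members = members,
      n_locations = nrow(members),
      classification = if (length(gaps) > 0L && all(gaps < 1000L)) "tandem"
                       else "dispersed",
      ir_status = NA_character_,
      coding_flags = rep(NA, nrow(members))),
      class = "repeat_family")
  })
}

#' @export
print.repeat_family <- function(x, ...) {
  cat(sprintf("<repeat_family> %s: %d locations (%s), representative %s\n",
              x$family_id, x$n_locations, x$classification,
              x$representative))
  invisible(x)
}

#' Annotate family members against the IR partition
#'
#' Sets each family's `ir_status`: `"ir_only"` (all members inside IRa/IRb),
#' `"spans_ir_and_sc"`, or `"single_copy_regions"`.
#'
#' @param families list from [cluster_families()].
#' @param part a `quadripartite_partition`.
#' @export
annotate_ir_status <- function(families, part) {
  lapply(families, function(f) {
    s <- f$members$position; e <- s + f$members$length - 1L
    in_ir <- contained_in(s, e, part$ira) | contained_in(s, e, part$irb)
    f$ir_status <- if (all(in_ir)) "ir_only"
                   else if (any(in_ir)) "spans_ir_and_sc"
                   else "single_copy_regions"
    f
  })
}

#' Flag family members that fall in coding sequence
#'
#' A member is coding when its interval intersects any feature of type
#' `gene` or `CDS` (a single shared base counts).
#'
#' @param families list from [cluster_families()].
#' @param features feature table (name, start, end, strand, type).
#' @export
annotate_locations <- function(families, features) {
  coding <- features[features$type %in% c("gene", "CDS"), , drop = FALSE]
  lapply(families, function(f) {
    s <- f$members$position; e <- s + f$members$length - 1L
    f$coding_flags <- vapply(seq_along(s), function(q) {
      nrow(coding) > 0L &&
        any(interval_overlap(s[q], e[q], coding$start, coding$end) > 0L)
    }, TRUE)
    f
  })
}

#' Families as a flat table
#' @param families list from [cluster_families()].
#' @export
family_table <- function(families) {
  if (length(families) == 0L)
    return(data.frame(family_id = character(0), representative = character(0),
                      n_locations = integer(0), classification = character(0),
                      ir_status = character(0), locations = character(0),
                      coding = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(families, function(f) data.frame(
    family_id = f$family_id, representative = f$representative,
    n_locations = f$n_locations, classification = f$classification,
    ir_status = f$ir_status,
    locations = paste(f$members$position, collapse = ","),
    coding = paste(ifelse(is.na(f$coding_flags), "NA",
                          ifelse(f$coding_flags, "yes", "no")),
                   collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Drop the structural IRa/IRb pair from a repeat listing
#'
#' A whole-genome search necessarily reports the inverted repeat itself as
#' one full-length palindromic pair.  That pair is the genome architecture,
#' not a small repeat, and is excluded from repeat tallies.
#'
#' @param pairs a `repeat_pairs` data frame.
#' @param part a `quadripartite_partition` in the same coordinate frame.
#' @export
drop_structural_ir_pair <- function(pairs, part) {
  if (is.null(part) || nrow(pairs) == 0L) return(pairs)
  structural <- pairs$orientation == "palindromic" &
    pairs$pos1 == part$ira[1L] & pairs$pos2 == part$irb[1L] &
    pairs$length == part$ir_len
  pairs[!structural, , drop = FALSE]
}

#' Repeat summary for one genome
#'
#' Tallies the raw pair count, tandem pairs, and - after removing IR-only
#' pairs and clustering - the number of unique dispersed repeat sequences
#' and unique locations (a Table-2-style deflation summary).  When a
#' partition is supplied, the structural IRa/IRb pair itself is excluded
#' from all tallies (see [drop_structural_ir_pair()]).
#'
#' @param pairs a `repeat_pairs` data frame.
#' @param part optional `quadripartite_partition` (enables the IR filter).
#' @param identity_threshold clustering identity for [cluster_families()].
#' @param tandem_threshold gap threshold for [classify_tandem()].
#' @return one-row data frame: `raw_pair_count`, `tandem_count`,
#'   `dispersed_unique_locations`, `dispersed_unique_sequences`.
#' @export
summarize_repeats <- function(pairs, part = NULL,
                              identity_threshold = 0.90,
                              tandem_threshold = 1000L) {
  pairs <- drop_structural_ir_pair(pairs, part)
  raw <- nrow(pairs)
  cls <- classify_tandem(pairs, tandem_threshold)
  tandem_count <- sum(cls == "tandem")
  dispersed <- pairs[cls == "dispersed", , drop = FALSE]
  if (!is.null(part)) dispersed <- filter_ir_duplicates(dispersed, part)
  fams <- cluster_families(repeat_instances(dispersed), identity_threshold)
  data.frame(
    raw_pair_count = raw,
    tandem_count = tandem_count,
    dispersed_unique_locations = sum(vapply(fams, `[[`, 0L, "n_locations")),
    dispersed_unique_sequences = length(fams))
}
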