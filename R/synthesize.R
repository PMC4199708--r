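# Synthetic plastome generator.  Emits a quadripartite LSC|IRa|SSC|IRb
# genome with i.i.d. background tuned to a GC target, planted repeat
# families (direct/palindromic, tandem/dispersed, controlled mismatches),
# genes straddling the IR borders, and a machine-readable truth record.
#
# Layout of the emitted genome, 1-based closed coordinates:
#   LSC [1 .. l], IRa [l+1 .. l+r], SSC [l+r+1 .. l+r+s], IRb [l+r+s+1 .. n]
# with IRb the exact reverse complement of IRa and n = l + s + 2r.

#' Specification of a planted repeat family
#'
#' @param family_id label for the family.
#' @param repeat_len length in bp of each copy (typical plastome dispersed
#'   repeats are 30-60 bp).
#' @param n_copies number of copies (>= 2).
#' @param orientation `"direct"` (all copies same strand) or `"palindromic"`
#'   (copies beyond the first inserted as reverse complements).
#' @param mismatches_per_copy Hamming edits applied to each copy after the
#'   first.  Edit positions are drawn without replacement across copies when
#'   possible, so the pairwise distance between copies i and j is exactly
#'   `m_i + m_j`.
#' @param placement `"dispersed"` (nearest-end gaps >= 1000 bp) or
#'   `"tandem"` (gaps < 1000 bp).
#' @param region `"LSC"`, `"SSC"`, `"IR"` (copies go into IRa and are
#'   mirrored into IRb by construction) or `"any"`.
#' @export
plant_spec <- function(family_id, repeat_len = 37L, n_copies = 2L,
                       orientation = c("direct", "palindromic"),
                       mismatches_per_copy = 0L,
                       placement = c("dispersed", "tandem"),
                       region = c("any", "LSC", "SSC", "IR")) {
  orientation <- match.arg(orientation)
  placement <- match.arg(placement)
  region <- match.arg(region)
  stopifnot(repeat_len >= 1L, n_copies >= 2L, mismatches_per_copy >= 0L,
            mismatches_per_copy < repeat_len)
  structure(list(family_id = as.character(family_id),
                 repeat_len = as.integer(repeat_len),
                 n_copies = as.integer(n_copies),
                 orientation = orientation,
                 mismatches_per_copy = as.integer(mismatches_per_copy),
                 placement = placement, region = region),
            class = "plant_spec")
}

#' Specification of a gene straddling an IR border
#'
#' Models genes such as ycf1 and rps19 that are only partially duplicated
#' in the inverted repeat: `duplicated_extent` bases of the gene lie inside
#' the IR, the rest in the adjacent single-copy region.
#'
#' @param name gene name.
#' @param duplicated_extent bp of the gene inside the IR (0 < extent < total).
#' @param total_len total gene length in bp.
#' @export
border_gene_spec <- function(name, duplicated_extent, total_len) {
  stopifnot(duplicated_extent > 0L, duplicated_extent < total_len)
  structure(list(name = as.character(name),
                 duplicated_extent = as.integer(duplicated_extent),
                 total_len = as.integer(total_len)),
            class = "border_gene_spec")
}

#' Generator configuration
#'
#' @param lsc_len,ssc_len,ir_len segment lengths in bp (all > 0).
#' @param gc_target target GC fraction of the background, in `[0, 1]`.
#'   Default 0.353, typical of legume plastomes.
#' @param planted_repeats list of [plant_spec()] objects.
#' @param border_genes list of [border_gene_spec()] objects; genes are placed
#'   alternately at the LSC/IRa and SSC/IRb junctions.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @export
generator_config <- function(lsc_len, ssc_len, ir_len, gc_target = 0.353,
                             planted_repeats = list(),
                             border_genes = list(), seed = NULL) {
  stopifnot(lsc_len > 0L, ssc_len > 0L, ir_len > 0L,
            gc_target >= 0, gc_target <= 1)
  if (length(planted_repeats) > 0L) {
    stopifnot(all(vapply(planted_repeats, inherits, TRUE, "plant_spec")))
    longest <- max(vapply(planted_repeats, `[[`, 0L, "repeat_len"))
    if (ir_len < 2L * longest)
      stop("ir_len must be at least twice the longest planted repeat",
           call. = FALSE)
  }
  if (length(border_genes) > 0L)
    stopifnot(all(vapply(border_genes, inherits, TRUE, "border_gene_spec")))
  structure(list(lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len),
                 gc_target = gc_target,
                 planted_repeats = planted_repeats,
                 border_genes = border_genes,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "generator_config")
}

# i.i.d. background codes with P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2.
random_codes <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p)
}

# Sample non-overlapping start positions for copies of one family inside
# [1, region_len], respecting gap constraints and previously occupied
# intervals (two-column matrix start,end in region coordinates).
place_copies <- function(region_len, len, n_copies, placement, occupied,
                         tries = 400L) {
  gap_ok <- function(starts) {
    if (length(starts) < 2L) return(TRUE)
    s <- sort(starts)
    gaps <- s[-1L] - (s[-length(s)] + len)     # bases between neighbours
    if (placement == "tandem") all(gaps >= 0L) && all(gaps < 1000L)
    else all(gaps >= 1000L)
  }
  clash <- function(starts) {
    if (nrow(occupied) == 0L) return(FALSE)
    any(vapply(starts, function(s)
      any(interval_overlap(s, s + len - 1L, occupied[, 1L], occupied[, 2L]) > 0L),
      TRUE))
  }
  # copies keep 1 bp clear of the region ends so junction bases stay free
  for (t in seq_len(tries)) {
    if (placement == "tandem") {
      gaps <- sample(0L:999L, n_copies - 1L, replace = TRUE)
      block <- n_copies * len + sum(gaps)
      if (block > region_len - 2L) next
      s0 <- sample.int(region_len - block - 1L, 1L) + 1L
      starts <- s0 + cumsum(c(0L, gaps + len))
    } else {
      # constructive spacing: base gaps of 1000 bp plus randomly allocated
      # slack before, between, and after the copies
      need <- n_copies * len + (n_copies - 1L) * 1000L
      slack <- region_len - 2L - need
      if (slack < 0L) next
      extra <- if (slack > 0L)
        as.integer(stats::rmultinom(1L, slack,
                                    rep(1, n_copies + 1L)))
      else rep(0L, n_copies + 1L)
      starts <- 2L + extra[1L] +
        cumsum(c(0L, rep(len + 1000L, n_copies - 1L) +
                      extra[2:n_copies]))
    }
    if (gap_ok(starts) && !clash(starts)) return(sort(starts))
  }
  NULL
}

mutate_copy <- function(codes, positions) {
  for (p in positions) {
    codes[p] <- sample(setdiff(1:4, codes[p]), 1L)
  }
  codes
}

# Exact-duplicate self-scan of the single-copy+IRa core: positions of 30-mers
# that occur twice directly or match the core's reverse complement.  Planted
# copies are expected to trigger it; anything else means an accidental repeat.
accidental_repeat_positions <- function(core, expected, k = 30L) {
  nc <- nchar(core)
  if (nc < k) return(integer(0))
  km <- substring(core, 1:(nc - k + 1L), k:nc)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  rc <- revcomp(core)
  kmrc <- substring(rc, 1:(nc - k + 1L), k:nc)
  pal <- km %in% kmrc
  pos <- which(dup | pal)
  if (length(pos) == 0L) return(integer(0))
  if (nrow(expected) == 0L) return(pos)
  ok <- vapply(pos, function(p)
    any(interval_overlap(p, p + k - 1L,
                         pmax(1L, expected[, 1L] - k), expected[, 2L] + k) > 0L),
    TRUE)
  pos[!ok]
}

#' Generate a synthetic quadripartite plastome
#'
#' Builds an LSC|IRa|SSC|IRb genome from a [generator_config()]: i.i.d.
#' background at the GC target, planted repeat families, border genes, and
#' IRb as the exact reverse complement of IRa.  A post-generation self-scan
#' rejects (and regenerates under a perturbed seed) backgrounds carrying
#' accidental exact repeats of 30 bp or more; near-exact accidental repeats
#' are vanishingly rare at plastome scale and are not scanned for.
#'
#' @param config a [generator_config()].
#' @return list with elements `record` ([plastome_record]), `features`
#'   (border genes, data frame), and `truth` (a `plastome_truth` list: the
#'   true partition, every planted instance with realized position, strand,
#'   mismatch count and sequence - IR-mirrored copies included and flagged -
#'   plus a config echo).
#' @export
generate_plastome <- function(config, id = "synthetic_plastome") {
  stopifnot(inherits(config, "generator_config"))
  with_seed_or_not(config$seed, generate_plastome_impl(config, id))
}

generate_plastome_impl <- function(config, id, max_attempts = 20L) {
  l <- config$lsc_len; s <- config$ssc_len; r <- config$ir_len
  gc <- config$gc_target
  n <- l + s + 2L * r

  for (attempt in seq_len(max_attempts)) {
    regions <- list(LSC = random_codes(l, gc),
                    IR  = random_codes(r, gc),
                    SSC = random_codes(s, gc))
    region_offset <- c(LSC = 0L, IR = l, SSC = l + r)  # genome offset of IRa/LSC/SSC
    occupied <- list(LSC = matrix(integer(0), 0, 2),
                     IR = matrix(integer(0), 0, 2),
                     SSC = matrix(integer(0), 0, 2))
    instances <- list()
    failed <- FALSE

    for (ps in config$planted_repeats) {
      reg <- ps$region
      if (reg == "any") {
        lens <- c(LSC = l, SSC = s)
        min_need <- if (ps$placement == "dispersed")
          ps$n_copies * ps$repeat_len + (ps$n_copies - 1L) * 1000L + 2L
        else ps$n_copies * ps$repeat_len + 2L
        lens <- lens[lens >= min_need]
        if (length(lens) == 0L)
          stop(sprintf("cannot place repeat family '%s': no region large enough",
                       ps$family_id), call. = FALSE)
        reg <- sample(names(lens), 1L, prob = lens / sum(lens))
      }
      region_len <- length(regions[[reg]])
      starts <- place_copies(region_len, ps$repeat_len, ps$n_copies,
                             ps$placement, occupied[[reg]])
      if (is.null(starts)) {
        failed <- TRUE
        stop(sprintf("cannot place repeat family '%s' (%d copies of %d bp, %s) in %s",
                     ps$family_id, ps$n_copies, ps$repeat_len, ps$placement, reg),
             call. = FALSE)
      }
      ref <- random_codes(ps$repeat_len, gc)
      # distinct edit positions across copies where possible
      m <- ps$mismatches_per_copy
      pool <- sample.int(ps$repeat_len)
      for (ci in seq_along(starts)) {
        copy <- ref
        mm <- 0L
        if (ci > 1L && m > 0L) {
          if (length(pool) >= m) {
            at <- pool[seq_len(m)]; pool <- pool[-seq_len(m)]
          } else {
            at <- sample.int(ps$repeat_len, m)
          }
          copy <- mutate_copy(copy, at)
          mm <- m
        }
        strand <- "+"
        if (ps$orientation == "palindromic" && ci > 1L) {
          copy <- rev(comp_codes(copy))
          strand <- "-"
        }
        st <- starts[ci]
        regions[[reg]][st:(st + ps$repeat_len - 1L)] <- copy
        occupied[[reg]] <- rbind(occupied[[reg]],
                                 c(st, st + ps$repeat_len - 1L))
        gstart <- st + region_offset[[reg]]
        instances[[length(instances) + 1L]] <- data.frame(
          family_id = ps$family_id, copy = ci,
          start = gstart, end = gstart + ps$repeat_len - 1L,
          orientation = ps$orientation, strand = strand,
          mismatches = mm, mirrored = FALSE,
          sequence = codes_to_dna(copy), stringsAsFactors = FALSE)
      }
    }
    if (failed) next

    # break reverse-complementary extension of the IR pair at its junctions:
    # the maximal exact IR must be exactly the planted one.  SSC junction:
    # first SSC base pairs with last SSC base under extension; LSC wrap
    # junction (circular): first LSC base pairs with last LSC base.
    if (s > 1L && regions$SSC[1L] == comp_codes(regions$SSC[s]))
      regions$SSC[s] <- sample(setdiff(1:4, comp_codes(regions$SSC[1L])), 1L)
    if (l > 1L && regions$LSC[1L] == comp_codes(regions$LSC[l]))
      regions$LSC[l] <- sample(setdiff(1:4, comp_codes(regions$LSC[1L])), 1L)

    core <- codes_to_dna(c(regions$LSC, regions$IR, regions$SSC))
    exp_iv <- if (length(instances) > 0L) {
      inst <- do.call(rbind, instances)
      as.matrix(inst[, c("start", "end")])
    } else matrix(integer(0), 0, 2)
    bad <- accidental_repeat_positions(core, exp_iv)
    if (length(bad) > 0L) next  # accidental >=30 bp repeat: regenerate

    # assemble genome: LSC | IRa | SSC | IRb
    ira <- regions$IR
    genome_codes <- c(regions$LSC, ira, regions$SSC, rev(comp_codes(ira)))
    genome <- codes_to_dna(genome_codes)

    # mirror instances planted in IRa into IRb
    inst <- if (length(instances) > 0L) do.call(rbind, instances)
            else data.frame()
    if (nrow(inst) > 0L) {
      ira_start <- l + 1L; ira_end <- l + r
      irb_start <- l + r + s + 1L
      in_ira <- inst$start >= ira_start & inst$end <= ira_end
      if (any(in_ira)) {
        mir <- inst[in_ira, , drop = FALSE]
        new_start <- irb_start + (ira_end - mir$end)
        mir$end <- new_start + (mir$end - mir$start)
        mir$start <- new_start
        mir$strand <- ifelse(mir$strand == "+", "-", "+")
        mir$mirrored <- TRUE
        mir$sequence <- vapply(mir$sequence, revcomp, "")
        inst <- rbind(inst, mir)
      }
      inst <- inst[order(inst$family_id, inst$copy, inst$start), ]
      rownames(inst) <- NULL
    }

    # border genes, alternating LSC/IRa and SSC/IRb junctions
    features <- empty_features()
    bg_rows <- list()
    for (gi in seq_along(config$border_genes)) {
      bg <- config$border_genes[[gi]]
      junction <- if (gi %% 2L == 1L) "lsc_ira" else "ssc_irb"
      sc_part <- bg$total_len - bg$duplicated_extent
      if (junction == "lsc_ira") {
        gs <- l - sc_part + 1L; ge <- l + bg$duplicated_extent
      } else {
        ssc_end <- l + r + s
        gs <- ssc_end - sc_part + 1L; ge <- ssc_end + bg$duplicated_extent
      }
      if (gs < 1L || ge > n)
        stop(sprintf("border gene '%s' does not fit its junction", bg$name),
             call. = FALSE)
      features <- rbind(features, data.frame(
        name = bg$name, start = gs, end = ge, strand = "+", type = "gene",
        stringsAsFactors = FALSE))
      bg_rows[[gi]] <- data.frame(
        name = bg$name, start = gs, end = ge,
        duplicated_extent = bg$duplicated_extent,
        total_len = bg$total_len, junction = junction,
        stringsAsFactors = FALSE)
    }

    partition <- data.frame(
      segment = c("lsc", "ira", "ssc", "irb"),
      start = c(1L, l + 1L, l + r + 1L, l + r + s + 1L),
      end = c(l, l + r, l + r + s, n),
      stringsAsFactors = FALSE)

    truth <- structure(list(
      config = list(seed = config$seed, lsc_len = l, ssc_len = s,
                    ir_len = r, gc_target = gc, genome_len = n,
                    attempt = attempt),
      partition = partition,
      instances = inst,
      border_genes = if (length(bg_rows) > 0L) do.call(rbind, bg_rows)
                     else data.frame()),
      class = "plastome_truth")

    return(list(record = plastome_record(id, genome, circular = TRUE),
                features = features, truth = truth))
  }
  stop("could not generate an accidental-repeat-free background in ",
       max_attempts, " attempts", call. = FALSE)
}
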