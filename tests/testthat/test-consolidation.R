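# Repeat consolidation: tandem/dispersed classification, IR filtering,
# family clustering and the deflation summary.

contained <- function(s, e, part) {
  (s >= part$ira[1] & e <= part$ira[2]) | (s >= part$irb[1] & e <= part$irb[2])
}

mk_pairs <- function(pos1, pos2, length, orientation = "direct",
                     mismatches = 0L, seq1 = NA_character_,
                     seq2 = NA_character_) {
  data.frame(pos1 = pos1, pos2 = pos2, length = length,
             orientation = orientation, mismatches = mismatches,
             seq1 = seq1, seq2 = seq2, stringsAsFactors = FALSE)
}

test_that("the 1000-bp rule separates tandem from dispersed", {
  # gap measured end of first copy to start of second
  p <- mk_pairs(pos1 = c(1L, 1L, 1L, 10L),
                pos2 = c(1030L, 1031L, 1032L, 20L),
                length = 30L)
  # gaps: 999, 1000, 1001, overlapping
  expect_equal(classify_tandem(p),
               c("tandem", "dispersed", "dispersed", "tandem"))
  expect_equal(classify_tandem(p[0, ]), character(0))
})

test_that("pairs confined to the inverted repeats are dropped", {
  cfg <- generator_config(10000, 2000, 3000, seed = 31,
                          planted_repeats = list(
                            plant_spec("ir_fam", 30, 2, region = "IR"),
                            plant_spec("lsc_fam", 30, 2, region = "LSC")))
  sim <- generate_plastome(cfg)
  part <- detect_inverted_repeat(sim$record, min_ir_len = 1000)
  pairs <- find_maximal_repeats(sim$record, search_params(30, 3))
  kept <- filter_ir_duplicates(pairs, part)
  # IR-internal pairs (including each planted copy against its IRb mirror)
  # vanish; the LSC family's pair survives
  e1 <- kept$pos1 + kept$length - 1L
  e2 <- kept$pos2 + kept$length - 1L
  both_ir <- (contained(kept$pos1, e1, part) & contained(kept$pos2, e2, part))
  expect_false(any(both_ir))
  lsc_inst <- sim$truth$instances[sim$truth$instances$family_id == "lsc_fam", ]
  hit <- kept$pos1 <= lsc_inst$start[1] & e1 >= lsc_inst$end[1]
  expect_true(any(hit))
})

test_that("same-locus listings differing only in length merge to one member", {
  inst <- data.frame(position = c(100L, 100L, 5000L),
                     length = c(36L, 30L, 36L),
                     sequence = c("ATCGATCGATCGATCGATCGATCGATCGATCGATCG",
                                  "ATCGATCGATCGATCGATCGATCGATCGAT",
                                  "ATCGATCGATCGATCGATCGATCGATCGATCGATCG"),
                     orientation = "direct", stringsAsFactors = FALSE)
  fams <- cluster_families(inst)
  expect_equal(length(fams), 1L)
  expect_equal(fams[[1]]$n_locations, 2L)
  expect_equal(fams[[1]]$members$length, c(36L, 36L))
})

test_that("families below the identity threshold stay separate", {
  withr::with_seed(32, {
    a <- random_dna(40); b <- random_dna(40)
    # ensure dissimilar
    while (pair_identity(a, b) > 0.6) b <- random_dna(40)
    inst <- data.frame(position = c(100L, 3000L, 8000L, 12000L),
                       length = 40L, sequence = c(a, a, b, b),
                       orientation = "direct", stringsAsFactors = FALSE)
    fams <- cluster_families(inst, identity_threshold = 0.90)
    expect_equal(length(fams), 2L)
    expect_equal(vapply(fams, `[[`, 0L, "n_locations"), c(2L, 2L))
  })
})

test_that("reverse-complement copies cluster into one family", {
  withr::with_seed(33, {
    a <- random_dna(36)
    inst <- data.frame(position = c(100L, 4000L, 9000L),
                       length = 36L,
                       sequence = c(a, revcomp(a), a),
                       orientation = c("direct", "palindromic", "direct"),
                       stringsAsFactors = FALSE)
    fams <- cluster_families(inst)
    expect_equal(length(fams), 1L)
    expect_equal(fams[[1]]$n_locations, 3L)
  })
})

test_that("consensus representative uses IUPAC codes on ties", {
  inst <- data.frame(position = c(100L, 4000L),
                     length = 8L,
                     sequence = c("AAAAAAAA", "AAAACAAA"),
                     orientation = "direct", stringsAsFactors = FALSE)
  fams <- cluster_families(inst, identity_threshold = 0.85)
  expect_equal(length(fams), 1L)
  expect_equal(fams[[1]]$representative, "AAAAMAAA")  # A/C tie -> M
})

test_that("coding flags follow intersection semantics", {
  feats <- data.frame(name = c("geneA", "spacer"),
                      start = c(1000L, 5000L), end = c(2000L, 6000L),
                      strand = "+", type = c("CDS", "misc"),
                      stringsAsFactors = FALSE)
  inst <- data.frame(position = c(1200L, 3000L, 970L),
                     length = c(40L, 40L, 31L),
                     sequence = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"),
                     orientation = "direct", stringsAsFactors = FALSE)
  fams <- cluster_families(inst, identity_threshold = 0.5)
  fams <- annotate_locations(fams, feats)
  flags <- unlist(lapply(fams, `[[`, "coding_flags"))
  members <- do.call(rbind, lapply(fams, `[[`, "members"))
  # inside CDS -> TRUE; intergenic -> FALSE; 1-bp straddle (970..1000) -> TRUE
  expect_equal(flags[order(members$position)], c(TRUE, TRUE, FALSE))
})

test_that("a k-location family deflates to one sequence and k locations", {
  withr::with_seed(34, {
    for (k in c(2, 3, 4)) {
      cfg <- generator_config(4000 + 1100 * k, 1500, 1200, seed = 40 + k,
                              planted_repeats = list(
                                plant_spec("fam", 37, k, region = "LSC")))
      sim <- generate_plastome(cfg)
      part <- detect_inverted_repeat(sim$record, min_ir_len = 500)
      pairs <- find_maximal_repeats(sim$record, search_params(30, 3))
      summ <- summarize_repeats(pairs, part)
      expect_equal(summ$raw_pair_count, choose(k, 2))
      expect_equal(summ$tandem_count, 0L)
      expect_equal(summ$dispersed_unique_sequences, 1L)
      expect_equal(summ$dispersed_unique_locations, k)
    }
  })
})

test_that("a clean genome gives an all-zero summary", {
  cfg <- generator_config(6000, 1500, 1500, seed = 55)
  sim <- generate_plastome(cfg)
  part <- detect_inverted_repeat(sim$record, min_ir_len = 500)
  pairs <- find_maximal_repeats(sim$record, search_params(30, 3))
  summ <- summarize_repeats(pairs, part)
  expect_equal(unlist(summ), c(raw_pair_count = 0L, tandem_count = 0L,
                               dispersed_unique_locations = 0L,
                               dispersed_unique_sequences = 0L))
})

test_that("mixed scenario matches the truth-derived expectation", {
  withr::with_seed(35, {
    cfg <- generator_config(16000, 4000, 2500, seed = 66,
                            planted_repeats = list(
                              plant_spec("disp_a", 37, 3, region = "LSC"),
                              plant_spec("disp_b", 42, 2, region = "SSC"),
                              plant_spec("tand", 33, 2, placement = "tandem",
                                         region = "LSC"),
                              plant_spec("ir_only", 31, 2, region = "IR")))
    sim <- generate_plastome(cfg)
    part <- detect_inverted_repeat(sim$record, min_ir_len = 1000)
    pairs <- find_maximal_repeats(sim$record, search_params(30, 3))
    summ <- summarize_repeats(pairs, part)
    # truth-derived raw count: C(3,2) disp_a + 1 disp_b + 1 tandem, plus the
    # IR family (2 planted copies + 2 IRb mirrors = 4 instances).  Of its
    # C(4,2) = 6 pairs, the two copy-vs-own-mirror pairs lie on the same
    # antidiagonal as the structural IRa/IRb match and are suppressed by it,
    # leaving 4; the structural pair itself is excluded from tallies.
    expect_equal(summ$raw_pair_count, choose(3, 2) + 1L + 1L + 4L)
    expect_equal(summ$tandem_count, 1L)
    # dispersed survivors: disp_a (3 locations) + disp_b (2); the tandem
    # array and the IR-confined family are excluded
    expect_equal(summ$dispersed_unique_sequences, 2L)
    expect_equal(summ$dispersed_unique_locations, 5L)
  })
})

test_that("consolidation is idempotent and order invariant", {
  withr::with_seed(36, {
    a <- random_dna(37)
    inst <- data.frame(position = c(100L, 2000L, 5000L, 9000L),
                       length = 37L,
                       sequence = c(a, mutate_string(a, 1),
                                    mutate_string(a, 2), a),
                       orientation = "direct", stringsAsFactors = FALSE)
    f1 <- cluster_families(inst)
    # permute input order
    f2 <- cluster_families(inst[c(3, 1, 4, 2), ])
    expect_equal(family_table(f1), family_table(f2))
    # re-consolidating the merged members changes nothing
    members <- do.call(rbind, lapply(f1, `[[`, "members"))
    f3 <- cluster_families(members)
    expect_equal(family_table(f3)$n_locations, family_table(f1)$n_locations)
    expect_equal(family_table(f3)$representative,
                 family_table(f1)$representative)
  })
})

test_that("every retained pair contributes both copies to one family", {
  withr::with_seed(37, {
    cfg <- generator_config(12000, 3000, 2000, seed = 77,
                            planted_repeats = list(
                              plant_spec("f1", 35, 3, region = "LSC"),
                              plant_spec("f2", 40, 2, region = "SSC")))
    sim <- generate_plastome(cfg)
    part <- detect_inverted_repeat(sim$record, min_ir_len = 800)
    pairs <- find_maximal_repeats(sim$record, search_params(30, 3))
    kept <- filter_ir_duplicates(pairs[classify_tandem(pairs) == "dispersed", ],
                                 part)
    fams <- cluster_families(repeat_instances(kept))
    members <- do.call(rbind, lapply(fams, `[[`, "members"))
    for (q in seq_len(nrow(kept))) {
      for (p in c(kept$pos1[q], kept$pos2[q])) {
        covering <- members$position <= p + 2L &
          members$position + members$length >= p
        expect_true(any(covering))
      }
    }
  })
})
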