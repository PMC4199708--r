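# Synthetic plastome generator: structural contracts, planted-repeat truth,
# determinism, and the sequence-evolution model.

test_that("generated genome has the configured architecture", {
  cfg <- generator_config(10000, 2000, 3000, seed = 101)
  sim <- generate_plastome(cfg)
  expect_equal(seq_length(sim$record), 18000L)
  s <- sim$record$sequence
  ira <- substr(s, 10001, 13000)
  irb <- substr(s, 15001, 18000)
  expect_identical(irb, revcomp(ira))
  expect_equal(sim$truth$partition$start, c(1L, 10001L, 13001L, 15001L))
  expect_equal(sim$truth$partition$end, c(10000L, 13000L, 15000L, 18000L))
})

test_that("same seed gives byte-identical output, different seed differs", {
  cfg <- generator_config(5000, 1000, 1500, seed = 7,
                          planted_repeats = list(plant_spec("fam_a")))
  a <- generate_plastome(cfg)
  b <- generate_plastome(cfg)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$truth$instances, b$truth$instances)
  cfg2 <- generator_config(5000, 1000, 1500, seed = 8,
                           planted_repeats = list(plant_spec("fam_a")))
  expect_false(identical(generate_plastome(cfg2)$record$sequence,
                         a$record$sequence))
})

test_that("every planted instance is recoverable by exact scan of the genome", {
  plants <- list(
    plant_spec("dispersed_lsc", repeat_len = 40, n_copies = 3,
               mismatches_per_copy = 1, region = "LSC"),
    plant_spec("tandem_ssc", repeat_len = 32, n_copies = 2,
               placement = "tandem", region = "SSC"),
    plant_spec("pal_pair", repeat_len = 35, n_copies = 2,
               orientation = "palindromic", region = "LSC"),
    plant_spec("ir_only", repeat_len = 30, n_copies = 2, region = "IR"))
  cfg <- generator_config(12000, 4000, 3000, seed = 202,
                          planted_repeats = plants)
  sim <- generate_plastome(cfg)
  s <- sim$record$sequence
  inst <- sim$truth$instances
  expect_gt(nrow(inst), 0L)
  for (q in seq_len(nrow(inst))) {
    expect_identical(substr(s, inst$start[q], inst$end[q]),
                     inst$sequence[q])
  }
  # mirrored copies present for the IR family, strands flipped
  ir_inst <- inst[inst$family_id == "ir_only", ]
  expect_equal(sum(ir_inst$mirrored), 2L)
  # recorded mismatch counts hold against each family reference (copy 1)
  for (fam in unique(inst$family_id)) {
    fi <- inst[inst$family_id == fam & !inst$mirrored, ]
    ref <- fi$sequence[fi$copy == 1]
    for (q in seq_len(nrow(fi))) {
      seqq <- fi$sequence[q]
      if (fi$strand[q] == "-") seqq <- revcomp(seqq)
      d <- round((1 - pair_identity(ref, seqq)) * nchar(ref))
      expect_equal(d, fi$mismatches[q])
    }
  }
})

test_that("planted dispersed family is recovered by the repeat finder", {
  cfg <- generator_config(14000, 3000, 3000, seed = 303,
                          planted_repeats = list(
                            plant_spec("f35", repeat_len = 35, n_copies = 4,
                                       mismatches_per_copy = 1,
                                       region = "LSC")))
  sim <- generate_plastome(cfg)
  inst <- sim$truth$instances
  pairs <- find_maximal_repeats(sim$record, search_params(30, 3))
  # every copy pair (pairwise Hamming <= 2) appears as a reported pair whose
  # footprints overlap the planted copies by at least min_len bases (the
  # locus-canonical pair may be the exact sub-window of a mismatched copy)
  covered <- 0L
  for (a in 1:3) for (b in (a + 1):4) {
    ia <- inst[inst$copy == a, ]; ib <- inst[inst$copy == b, ]
    e1 <- pairs$pos1 + pairs$length - 1L
    e2 <- pairs$pos2 + pairs$length - 1L
    ov1 <- pmin(e1, ia$end) - pmax(pairs$pos1, ia$start) + 1L
    ov2 <- pmin(e2, ib$end) - pmax(pairs$pos2, ib$start) + 1L
    if (any(ov1 >= 30L & ov2 >= 30L)) covered <- covered + 1L
  }
  expect_equal(covered, choose(4, 2))
})

test_that("impossible placements fail naming the family", {
  cfg <- generator_config(2000, 200, 600, seed = 5,
                          planted_repeats = list(
                            plant_spec("too_big", repeat_len = 60,
                                       n_copies = 30, region = "SSC")))
  expect_error(generate_plastome(cfg), "too_big")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(0, 100, 100), ">")
  expect_error(generator_config(1000, 100, 100, gc_target = 1.2))
  expect_error(generator_config(1000, 500, 50,
                                planted_repeats = list(plant_spec("f", 40))),
               "twice")
})

test_that("truth records round-trip through their text serialization", {
  cfg <- generator_config(6000, 1500, 2000, seed = 11,
                          planted_repeats = list(
                            plant_spec("f", 33, 2, region = "LSC")),
                          border_genes = list(
                            border_gene_spec("ycf1", 463, 1200)))
  sim <- generate_plastome(cfg)
  path <- tempfile(fileext = ".truth.txt")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$partition, sim$truth$partition)
  expect_equal(back$instances$start, sim$truth$instances$start)
  expect_equal(back$instances$sequence, sim$truth$instances$sequence)
  expect_equal(back$config$lsc_len, 6000)
  expect_equal(back$border_genes$duplicated_extent, 463)
})

test_that("rate 0 evolution leaves tips identical to the ancestor", {
  anc <- plastome_record("anc", paste(rep("ACGT", 250), collapse = ""))
  tr <- two_taxon_tree(1e6)
  out <- evolve_sequences(anc, tr, rate = 0, seed = 1)
  expect_identical(unname(out$sequences[1]), anc$sequence)
  expect_identical(unname(out$sequences[2]), anc$sequence)
  expect_equal(sum(out$truth$branches$substitutions), 0L)
})

test_that("evolution is seed-deterministic and rejects negative rates", {
  anc <- plastome_record("anc", paste(rep("ACGT", 500), collapse = ""))
  tr <- two_taxon_tree(2e6)
  a <- evolve_sequences(anc, tr, 1e-8, seed = 3)
  b <- evolve_sequences(anc, tr, 1e-8, seed = 3)
  expect_identical(a$sequences, b$sequences)
  expect_error(evolve_sequences(anc, tr, -1e-9), "rate")
})

test_that("realized pairwise differences match the expected 2*T*r*L", {
  # two tips, total path 2T: E[diffs] ~= 2 T r L, binomial sampling error
  withr::with_seed(42, {
    L <- 20000L
    r <- 2.5e-10; Tyr <- 1e7          # 2Tr = 0.005
    anc <- plastome_record("anc", random_dna(L))
    tr <- two_taxon_tree(2 * Tyr)     # tip-to-tip path 2T
    reps <- 50
    diffs <- vapply(seq_len(reps), function(i)
      evolve_sequences(anc, tr, r)$truth$pairs$substitutions[1], 0L)
    expected <- 2 * Tyr * r * L
    se <- sd(diffs) / sqrt(reps)
    expect_lt(abs(mean(diffs) - expected), 3 * se + 1e-9)
    # truth branch counts sum consistently with tip differences (no
    # coincident-hit sites in most replicates at this divergence)
  })
})

test_that("evolution truth round-trips through serialization", {
  anc <- plastome_record("anc", paste(rep("ACGT", 300), collapse = ""))
  tr <- ape::read.tree(text = "((a:1e6,b:1e6):5e5,c:1.5e6);")
  out <- evolve_sequences(anc, tr, 5e-8, seed = 17)
  path <- tempfile()
  write_truth(out$truth, path)
  back <- read_truth(path)
  expect_equal(back$rate, 5e-8)
  expect_equal(back$branches$substitutions, out$truth$branches$substitutions)
  expect_equal(back$pairs$substitutions, out$truth$pairs$substitutions)
})
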