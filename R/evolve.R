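# Evolve an ancestral sequence along a dated tree (branch lengths in years)
# at a per-site per-year substitution rate.  Equal-rates (Jukes-Cantor-style)
# model, no indels: tips stay aligned by construction.

#' Evolve sequences along a dated tree
#'
#' Each branch of `t` years substitutes `Binomial(L, rate * t)` sites, drawn
#' uniformly without replacement; a substituted site receives one of the
#' three other bases uniformly.  This keeps the realized per-branch
#' substitution count unbiased at the small divergences modelled
#' (`rate * t` well below 0.1); multiple hits within a branch are not
#' modelled, so expected pairwise differences are `rate * path_years * L`
#' up to rare coincident hits on both lineages.
#'
#' @param ancestor a [plastome_record()] (or single DNA string) used as the
#'   root sequence.
#' @param tree an `ape::phylo` tree with branch lengths in years (need not
#'   be ultrametric; lengths must be >= 0).
#' @param rate substitutions per site per year (>= 0).
#' @param seed optional integer seed; same seed, same tips.
#' @return list with `sequences` (named character vector, one per tip, all
#'   equal length) and `truth` (an `evolution_truth` list: per-branch realized
#'   substitution counts, per-pair realized Hamming differences, rate and
#'   seed echo).
#' @export
evolve_sequences <- function(ancestor, tree, rate, seed = NULL) {
  if (inherits(ancestor, "plastome_record")) ancestor <- ancestor$sequence
  stopifnot(is.character(ancestor), length(ancestor) == 1L,
            nchar(ancestor) > 0L)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object",
                                     call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths (years)", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("branch lengths must be >= 0", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("rate must be a single number >= 0", call. = FALSE)
  with_seed_or_not(seed, evolve_impl(ancestor, tree, rate, seed))
}

evolve_impl <- function(ancestor, tree, rate, seed) {
  codes <- dna_codes(ancestor)
  L <- length(codes)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- codes

  # parents before children
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  ord <- rev(ape::postorder(tree))
  edge_tab <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                         years = tree$edge.length, substitutions = 0L)
  for (e in ord) {
    par <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
    t_yr <- tree$edge.length[e]
    p <- rate * t_yr
    if (p > 1) stop("rate * branch length exceeds 1 substitution per site; ",
                    "model is only valid at small divergences", call. = FALSE)
    sq <- node_seq[[par]]
    nsub <- stats::rbinom(1L, L, p)
    if (nsub > 0L) {
      at <- sample.int(L, nsub)
      for (i in at) sq[i] <- sample(setdiff(1:4, sq[i]), 1L)
    }
    node_seq[[chd]] <- sq
    edge_tab$substitutions[e] <- nsub
  }

  tips <- vapply(seq_len(ntip), function(i) codes_to_dna(node_seq[[i]]), "")
  names(tips) <- tree$tip.label

  labels <- tree$tip.label
  pair_tab <- if (ntip >= 2L) {
    cmb <- utils::combn(ntip, 2L)
    data.frame(
      tip1 = labels[cmb[1L, ]], tip2 = labels[cmb[2L, ]],
      substitutions = vapply(seq_len(ncol(cmb)), function(k) {
        a <- node_seq[[cmb[1L, k]]]; b <- node_seq[[cmb[2L, k]]]
        sum(a != b)
      }, 0L),
      stringsAsFactors = FALSE)
  } else data.frame()

  edge_tab$child_label <- ifelse(edge_tab$child <= ntip,
                                 labels[edge_tab$child],
                                 paste0("node", edge_tab$child))
  truth <- structure(list(rate = rate, seed = seed, sites = L,
                          branches = edge_tab, pairs = pair_tab),
                     class = "evolution_truth")
  list(sequences = tips, truth = truth)
}

#' Two-taxon dated tree helper
#'
#' Convenience constructor for a two-tip tree whose tip-to-tip path length is
#' `divergence_years` (two branches of half that each), matching the
#' calibration convention in which pairwise SNPs are divided by the
#' divergence date.
#'
#' @param divergence_years total tip-to-tip path length in years.
#' @param labels the two tip labels.
#' @export
two_taxon_tree <- function(divergence_years, labels = c("t1", "t2")) {
  stopifnot(divergence_years >= 0, length(labels) == 2L)
  half <- divergence_years / 2
  txt <- sprintf("(%s:%.10g,%s:%.10g);", labels[1L], half, labels[2L], half)
  ape::read.tree(text = txt)
}
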