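# Pipeline stages tying the modules into the end-to-end comparative
# analysis: simulate -> structure -> repeats -> diversity.  Each stage reads
# standard formats (FASTA, GFF3, aligned FASTA, TSV), writes TSV artifacts
# with a provenance header, and is deterministic given its inputs.

pkg_version <- function() {
  as.character(utils::packageVersion("plastomer"))
}

write_tsv_artifact <- function(df, path, params = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  pstr <- if (length(params) > 0L)
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(v) paste(format(v), collapse = ","),
                         "")),
          collapse = "; ")
  else "none"
  cat(sprintf("# plastomer %s; parameters: %s\n", pkg_version(), pstr),
      file = con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_artifact <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Simulate stage: write a synthetic plastome with its truth
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @param prefix file name prefix.
#' @return paths of the FASTA, GFF3 and truth files (invisibly).
#' @export
run_simulate <- function(config, out_dir, prefix = "synthetic") {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_plastome(config, id = prefix)
  fasta <- file.path(out_dir, paste0(prefix, ".fasta"))
  gff <- file.path(out_dir, paste0(prefix, ".gff3"))
  truth <- file.path(out_dir, paste0(prefix, ".truth.txt"))
  write_plastomes(sim$record, fasta)
  write_features(sim$features, gff, seqid = prefix)
  write_truth(sim$truth, truth)
  message(sprintf("simulate: wrote %d bp genome, %d planted instances",
                  seq_length(sim$record),
                  nrow(sim$truth$instances)))
  invisible(list(fasta = fasta, gff = gff, truth = truth, sim = sim))
}

#' Structure stage: Table-1-style architecture summary
#'
#' @param fasta path to a FASTA of one or more plastomes.
#' @param gff optional GFF3 of gene features (shared coordinate frame).
#' @param border_genes gene names whose IR-duplicated extent to report.
#' @param out output TSV path.
#' @param min_ir_len passed to [detect_inverted_repeat()].
#' @return the summary data frame (invisibly).
#' @export
run_structure <- function(fasta, gff = NULL, border_genes = character(0),
                          out = NULL, min_ir_len = 10000L) {
  recs <- read_plastomes(fasta)
  feats <- if (!is.null(gff)) read_features(gff) else NULL
  features_list <- if (!is.null(feats)) rep(list(feats), length(recs))
                   else NULL
  if (length(border_genes) == 0L && !is.null(feats))
    border_genes <- unique(feats$name[feats$type == "gene"])
  tab <- structure_table(recs, features_list, border_genes,
                         min_ir_len = min_ir_len)
  if (!is.null(out))
    write_tsv_artifact(tab, out,
                       params = list(min_ir_len = min_ir_len,
                                     input = basename(fasta)))
  invisible(tab)
}

#' Repeats stage: raw pairs, families, and the deflation summary
#'
#' @param fasta path to a FASTA of one or more plastomes.
#' @param params a [search_params()].
#' @param out_dir output directory (raw pairs, family table and summary TSVs
#'   per genome, plus a BED track of family locations).
#' @param min_ir_len IR detection threshold; detection failure (an IR-less
#'   genome) disables the IR filter for that genome.
#' @param identity_threshold family clustering identity.
#' @return named list per genome: `pairs`, `families`, `summary` (invisibly).
#' @export
run_repeats <- function(fasta, params = search_params(), out_dir = NULL,
                        min_ir_len = 10000L, identity_threshold = 0.90) {
  recs <- read_plastomes(fasta)
  out <- lapply(recs, function(rec) {
    pairs <- find_maximal_repeats(rec, params)
    part <- tryCatch(detect_inverted_repeat(rec, min_ir_len = min_ir_len),
                     error = function(e) NULL)
    pairs <- drop_structural_ir_pair(pairs, part)
    cls <- classify_tandem(pairs)
    dispersed <- pairs[cls == "dispersed", , drop = FALSE]
    if (!is.null(part)) dispersed <- filter_ir_duplicates(dispersed, part)
    fams <- cluster_families(repeat_instances(dispersed), identity_threshold)
    if (!is.null(part)) fams <- annotate_ir_status(fams, part)
    summ <- cbind(id = rec$id,
                  summarize_repeats(pairs, part, identity_threshold))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      prm <- list(min_len = params$min_len,
                  max_mismatch = params$max_mismatch,
                  kinds = params$kinds,
                  identity_threshold = identity_threshold)
      raw_out <- pairs
      raw_out$pos_end1 <- raw_out$pos1 + raw_out$length - 1L
      raw_out$pos_end2 <- raw_out$pos2 + raw_out$length - 1L
      write_tsv_artifact(
        raw_out[, c("pos1", "pos2", "length", "orientation", "mismatches")],
        file.path(out_dir, paste0(rec$id, ".pairs.tsv")), prm)
      write_tsv_artifact(family_table(fams),
                         file.path(out_dir, paste0(rec$id, ".families.tsv")),
                         prm)
      write_tsv_artifact(summ,
                         file.path(out_dir, paste0(rec$id, ".summary.tsv")),
                         prm)
      write_family_bed(fams, rec$id,
                       file.path(out_dir, paste0(rec$id, ".families.bed")))
    }
    list(pairs = pairs, families = fams, summary = summ)
  })
  names(out) <- vapply(recs, `[[`, "", "id")
  invisible(out)
}

# BED (0-based half-open) track of family member locations.
write_family_bed <- function(families, seqid, path) {
  rows <- list()
  for (f in families) {
    s <- f$members$position; e <- s + f$members$length - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = seqid, start = s - 1L, end = e,
      name = f$family_id, stringsAsFactors = FALSE)
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows)
        else data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Diversity stage: SNP/rate matrix and windowed identity
#'
#' @param aln_fasta aligned FASTA path (or an [alignment_matrix()]).
#' @param calib a [calibration_table()] or path to a TSV with columns
#'   taxon1, taxon2, time_years.
#' @param out_dir optional output directory.
#' @param ref_row reference row for [windowed_identity()].
#' @param window,step windowed-identity parameters.
#' @param flag_factor slow-rate flag threshold for [rate_matrix()].
#' @return list: `rates` (a `rate_matrix`), `pi`, `windows` (invisibly).
#' @export
run_diversity <- function(aln_fasta, calib, out_dir = NULL, ref_row = 1L,
                          window = 100L, step = 25L, flag_factor = 0.5) {
  aln <- if (inherits(aln_fasta, "alignment_matrix")) aln_fasta
         else alignment_matrix(aln_fasta)
  if (is.character(calib)) {
    df <- read_tsv_artifact(calib)
    calib <- calibration_table(df$taxon1, df$taxon2, df$time_years)
  }
  rm_ <- rate_matrix(aln, calib, flag_factor = flag_factor)
  pi_ <- nucleotide_diversity(aln)
  wins <- windowed_identity(aln, ref_row, window, step)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prm <- list(window = window, step = step, flag_factor = flag_factor)
    lay <- data.frame(taxon = rownames(rm_$layout), rm_$layout,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_artifact(lay, file.path(out_dir, "rate_matrix.tsv"), prm)
    write_tsv_artifact(wins, file.path(out_dir, "windowed_identity.tsv"),
                       prm)
  }
  invisible(list(rates = rm_, pi = pi_, windows = wins))
}
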