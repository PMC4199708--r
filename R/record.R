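# PlastomeRecord: one genome sequence with an identifier and a circularity
# flag, plus FASTA / GFF3 input-output.  Feature tables are plain data frames
# with columns name, start, end, strand, type (1-based closed coordinates).

#' Create a plastome record
#'
#' @param id record identifier.
#' @param sequence DNA string over the IUPAC alphabet.
#' @param circular is the molecule circular? Plastomes are; linearized
#'   fragments are not.
#' @return an object of class `plastome_record`.
#' @export
plastome_record <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty", call. = FALSE)
  validate_dna(sequence)
  structure(list(id = id, sequence = sequence,
                 circular = isTRUE(circular)),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %d bp (%s)\n", x$id,
              nchar(x$sequence), if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Sequence length of a plastome record
#' @param rec a `plastome_record`.
#' @export
seq_length <- function(rec) nchar(rec$sequence)

#' Rotate a circular record
#'
#' Moves the origin so that position `offset + 1` of the input becomes
#' position 1.  Only meaningful for circular records.
#'
#' @param rec a `plastome_record`.
#' @param offset number of leading bases moved to the end (0 = no change).
#' @export
rotate_record <- function(rec, offset) {
  n <- seq_length(rec)
  offset <- as.integer(offset %% n)
  if (offset == 0L) return(rec)
  if (!rec$circular)
    stop("cannot rotate a linear record", call. = FALSE)
  s <- rec$sequence
  rec$sequence <- paste0(substr(s, offset + 1L, n), substr(s, 1L, offset))
  rec
}

#' Read plastome records from a FASTA file
#'
#' @param path FASTA file (one or more records).
#' @param circular circularity flag applied to all records.
#' @return a list of `plastome_record` objects.
#' @export
read_plastomes <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    plastome_record(ids[i], as.character(set[[i]]), circular = circular))
}

#' Write plastome records to FASTA
#'
#' @param recs a `plastome_record` or list of them.
#' @param path output path.
#' @export
write_plastomes <- function(recs, path) {
  if (inherits(recs, "plastome_record")) recs <- list(recs)
  seqs <- Biostrings::DNAStringSet(vapply(recs, `[[`, "", "sequence"))
  names(seqs) <- vapply(recs, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

empty_features <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             strand = character(), type = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, n = NULL) {
  need <- c("name", "start", "end", "strand", "type")
  if (!all(need %in% names(features)))
    stop("feature table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(features) > 0L) {
    stopifnot(all(features$start >= 1L), all(features$end >= features$start))
    if (!is.null(n) && any(features$end > n))
      stop("feature extends beyond sequence end", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read gene features from GFF3
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return data frame with columns name, start, end, strand, type.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_features())
  md <- S4Vectors::mcols(gr)
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else NA_character_
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  name <- ifelse(is.na(nm) | !nzchar(nm), id, nm)
  data.frame(name = name,
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             type = as.character(md$type),
             stringsAsFactors = FALSE)
}

#' Write gene features to GFF3
#'
#' @param features feature data frame (name, start, end, strand, type).
#' @param path output path.
#' @param seqid sequence identifier for column 1.
#' @export
write_features <- function(features, path, seqid = "genome") {
  validate_features(features)
  strand <- ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$Name <- features$name
  S4Vectors::mcols(gr)$ID <- make.unique(features$name)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
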