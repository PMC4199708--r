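# Structured-text serialization of ground-truth records.
#
# Format ("plastomer truth v1"): named [section] blocks.  [config] and
# [evolution] hold key<TAB>value lines; every other section is a TSV table
# with a header row.  Strings are plain, logicals TRUE/FALSE, numbers
# full-precision.  Round-trips losslessly.

write_kv <- function(con, x) {
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v)) v <- "NULL"
    cat(sprintf("%s\t%s\n", k, format(v, digits = 17, scientific = FALSE,
                                      trim = TRUE)),
        file = con)
  }
}

write_table_section <- function(con, df) {
  if (is.null(df) || nrow(df) == 0L) return(invisible())
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write a truth record to a structured-text file
#'
#' @param truth a `plastome_truth` (from [generate_plastome()]) or
#'   `evolution_truth` (from [evolve_sequences()]).
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("# plastomer truth v1\n", file = con)
  if (inherits(truth, "plastome_truth")) {
    cat("[config]\n", file = con)
    write_kv(con, truth$config)
    cat("[partition]\n", file = con)
    write_table_section(con, truth$partition)
    cat("[instances]\n", file = con)
    write_table_section(con, truth$instances)
    cat("[border_genes]\n", file = con)
    write_table_section(con, truth$border_genes)
  } else if (inherits(truth, "evolution_truth")) {
    cat("[evolution]\n", file = con)
    write_kv(con, truth[c("rate", "seed", "sites")])
    cat("[branches]\n", file = con)
    write_table_section(con, truth$branches)
    cat("[pairs]\n", file = con)
    write_table_section(con, truth$pairs)
  } else stop("unknown truth object", call. = FALSE)
  invisible(path)
}

parse_kv <- function(lines) {
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    v <- parts[2L]
    num <- suppressWarnings(as.numeric(v))
    out[[parts[1L]]] <- if (identical(v, "NULL")) NULL
                        else if (!is.na(num)) num else v
  }
  out
}

parse_table <- function(lines) {
  if (length(lines) == 0L) return(data.frame())
  utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Read a truth record written by [write_truth()]
#'
#' @param path truth file path.
#' @return a `plastome_truth` or `evolution_truth` object.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  heads <- grep("^\\[", lines)
  names <- sub("^\\[(.*)\\]$", "\\1", lines[heads])
  bounds <- c(heads, length(lines) + 1L)
  sections <- stats::setNames(lapply(seq_along(heads), function(i)
    lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)][
      seq_len(max(0L, bounds[i + 1L] - bounds[i] - 1L))]), names)
  if ("config" %in% names) {
    structure(list(config = parse_kv(sections$config),
                   partition = parse_table(sections$partition),
                   instances = parse_table(sections$instances),
                   border_genes = parse_table(sections$border_genes)),
              class = "plastome_truth")
  } else {
    ev <- parse_kv(sections$evolution)
    structure(list(rate = ev$rate, seed = ev$seed, sites = ev$sites,
                   branches = parse_table(sections$branches),
                   pairs = parse_table(sections$pairs)),
              class = "evolution_truth")
  }
}
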