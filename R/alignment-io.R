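#' Read a multiple alignment from FASTA or NEXUS
#'
#' FASTA is parsed with Biostrings; NEXUS (a simple DATA/CHARACTERS block)
#' with ape.  Taxon order is preserved, lowercase is normalized to uppercase
#' and `?` to `N`.
#'
#' @param path file path
#' @param format `"fasta"` or `"nexus"`; default guesses from the file
#'   extension (`.nex`/`.nexus` vs anything else).
#' @return a [multiple_alignment()]
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(set), names(set))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      bad <- names(seqs)[which(lens != lens[1])[1]]
      stop(sprintf(
        "alignment is ragged: taxon '%s' has %d columns, expected %d",
        bad, nchar(seqs[[bad]]), lens[1]), call. = FALSE)
    }
    multiple_alignment(seqs)
  } else {
    rows <- ape::read.nexus.data(path)
    mat <- do.call(rbind, rows)
    rownames(mat) <- names(rows)
    multiple_alignment(mat)
  }
}

#' Write a multiple alignment to FASTA or NEXUS
#'
#' @param aln a [multiple_alignment()]
#' @param path output file path
#' @param format `"fasta"` or `"nexus"`; default guesses from the extension.
#' @return `path`, invisibly
#' @export
write_alignment <- function(aln, path, format = c("auto", "fasta", "nexus")) {
  stopifnot(inherits(aln, "multiple_alignment"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::BStringSet(alignment_strings(aln))
    Biostrings::writeXStringSet(set, path, width = 80L)
  } else {
    rows <- lapply(seq_along(aln$taxa), function(i) aln$mat[i, ])
    names(rows) <- aln$taxa
    ape::write.nexus.data(rows, path, format = "dna", interleaved = FALSE)
  }
  invisible(path)
}

#' Serialize a column map as TSV
#'
#' One row per surviving output column, mapping it back to its source column.
#'
#' @param column_map integer vector of source column indices (1-based)
#' @param path output TSV path
#' @param header optional comment lines written before the table
#' @return `path`, invisibly
#' @export
write_column_map <- function(column_map, path, header = character(0)) {
  df <- data.frame(out_column = seq_along(column_map),
                   source_column = as.integer(column_map))
  write_tsv_with_header(df, path, header)
}

#' Serialize a gap-strip report as TSV
#' @param report the `report` element returned by [strip_gap_columns()]
#' @param path output TSV path
#' @param header optional comment lines
#' @return `path`, invisibly
#' @export
write_strip_report <- function(report, path, header = character(0)) {
  df <- data.frame(n_before = report$n_before,
                   n_after = report$n_after,
                   fraction_removed = report$fraction_removed)
  write_tsv_with_header(df, path, header)
}

## shared TSV writer: deterministic, full precision, comment header
write_tsv_with_header <- function(df, path, header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

output_header <- function(seed = NULL, inputs = character(0)) {
  h <- sprintf("plastgap %s",
               as.character(utils::packageVersion("plastgap")))
  if (!is.null(seed)) h <- c(h, sprintf("seed=%d", as.integer(seed)))
  if (length(inputs) > 0) {
    dig <- vapply(inputs, function(p) {
      if (file.exists(p)) tools::md5sum(p)[[1]] else "absent"
    }, character(1))
    h <- c(h, sprintf("input %s md5=%s", basename(inputs), dig))
  }
  h
}
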