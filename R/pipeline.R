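#' Preprocess an alignment into an analysis matrix
#'
#' Applies the matrix-construction rules: optional excision of column
#' intervals (duplicated inverted-repeat copy, inversion-bearing regions)
#' followed by removal of every column containing a gap.  Writes the
#' processed alignment, the column provenance map and the strip report.
#'
#' @param alignment path to the input alignment (FASTA or NEXUS)
#' @param out output directory
#' @param excise optional 2-column matrix or list of `c(start, end)` column
#'   intervals (1-based, closed) to remove before gap stripping
#' @param format alignment format passed to [read_alignment()]
#' @return invisibly, a list with the processed alignment, column map and
#'   strip report; files `processed.fasta`, `column_map.tsv`,
#'   `strip_report.tsv` appear under `out`.
#' @export
cmd_preprocess <- function(alignment, out, excise = NULL, format = "auto") {
  aln <- read_alignment(alignment, format)
  hdr <- output_header(inputs = alignment)
  exc <- excise_columns(aln, excise)
  stripped <- strip_gap_columns(exc$alignment)
  ## compose provenance through both steps
  column_map <- exc$column_map[stripped$column_map]
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_alignment(stripped$alignment, file.path(out, "processed.fasta"))
  write_column_map(column_map, file.path(out, "column_map.tsv"), hdr)
  write_strip_report(stripped$report, file.path(out, "strip_report.tsv"),
                     hdr)
  invisible(list(alignment = stripped$alignment, column_map = column_map,
                 report = stripped$report))
}

#' Score indels in a gapped alignment
#'
#' Builds the indel catalogue (acceptance criteria, slipped-strand
#' mispairing, region classes), the binary presence/absence character
#' matrix and a summary block.
#'
#' @param alignment path to the gapped alignment (pre-strip)
#' @param out output directory
#' @param annotation optional GFF3 path on alignment-column coordinates
#' @param criteria an [indel_criteria()]
#' @param format alignment format
#' @return invisibly, list with `events`, `matrix`, `summary`; files
#'   `catalog.tsv`, `characters.tsv`, `characters.nex`, `summary.tsv`.
#' @export
cmd_indels <- function(alignment, out, annotation = NULL,
                       criteria = indel_criteria(), format = "auto") {
  aln <- read_alignment(alignment, format)
  ann <- if (!is.null(annotation)) {
    read_region_annotation(annotation, n_columns(aln))
  }
  hdr <- output_header(inputs = c(alignment, annotation))
  events <- indel_catalog(aln, criteria, ann)
  mat <- build_character_matrix(events, aln)
  summ <- summarize_catalog(events)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_indel_catalog(events, file.path(out, "catalog.tsv"), hdr)
  write_character_matrix(mat, file.path(out, "characters.tsv"),
                         header = hdr)
  write_character_matrix(mat, file.path(out, "characters.nex"), "nexus")
  summ_df <- data.frame(
    quantity = c("total", "accepted",
                 paste0("rejected_", names(summ$rejected)),
                 paste0("ssm_", names(summ$ssm)),
                 paste0("region_", names(summ$region))),
    count = c(summ$total, summ$accepted, unname(summ$rejected),
              as.integer(summ$ssm), as.integer(summ$region)))
  write_tsv_with_header(summ_df, file.path(out, "summary.tsv"), hdr)
  invisible(list(events = events, matrix = mat, summary = summ))
}

#' Map indel characters onto a reference tree
#'
#' Classifies every binary character as a putative synapomorphy or
#' homoplasy against the tree rooted on the outgroup, and tabulates
#' synapomorphies per named clade.
#'
#' @param characters path to a character matrix TSV from [cmd_indels()]
#' @param tree path to the reference tree (Newick)
#' @param out output directory
#' @param outgroup character vector of outgroup taxa (may be empty if the
#'   tree is already rooted)
#' @param clades optional TSV with columns `clade` and `taxa`
#'   (comma-joined) naming leaf sets for the tabulation
#' @return invisibly, list with `classifications` and `tabulation`; files
#'   `classification.tsv`, `clade_tabulation.tsv`.
#' @export
cmd_map <- function(characters, tree, out, outgroup = character(0),
                    clades = NULL) {
  mat <- read_character_matrix(characters)
  tr <- read_tree(tree)
  hdr <- output_header(inputs = c(characters, tree))
  clade_defs <- list()
  if (!is.null(clades)) {
    cd <- utils::read.delim(clades, comment.char = "#",
                            stringsAsFactors = FALSE)
    clade_defs <- setNames(strsplit(cd$taxa, ",", fixed = TRUE), cd$clade)
  }
  cls <- classify_characters(tr, mat, outgroup)
  tab <- tabulate_clades(cls, clade_defs)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tsv_with_header(cls, file.path(out, "classification.tsv"), hdr)
  write_tsv_with_header(tab, file.path(out, "clade_tabulation.tsv"), hdr)
  invisible(list(classifications = cls, tabulation = tab))
}

#' Run the randomized outgroup jackknife from files
#'
#' @param alignment path to the pre-aligned matrix holding ingroup and all
#'   outgroup candidates
#' @param pools path to a pool config: TSV with columns `pool` and `taxon`
#'   (one row per candidate)
#' @param out output directory
#' @param config a [jackknife_config()]
#' @param format alignment format
#' @return invisibly, the `outgroup_jackknife` result; files
#'   `iteration_<i>.nwk`, `congruence.tsv`, `support.tsv`, `jackknife.log`.
#' @export
cmd_jackknife <- function(alignment, pools, out,
                          config = jackknife_config(), format = "auto") {
  aln <- read_alignment(alignment, format)
  pool_df <- utils::read.delim(pools, comment.char = "#",
                               stringsAsFactors = FALSE)
  pool_list <- split(pool_df$taxon, pool_df$pool)
  ingroup <- setdiff(aln$taxa, unlist(pool_list))
  hdr <- output_header(seed = config$seed, inputs = c(alignment, pools))
  res <- outgroup_jackknife(aln, ingroup, pool_list, config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (it in res$iterations) {
    write_tree(it$tree, file.path(out, sprintf("iteration_%02d.nwk",
                                               it$iteration)))
  }
  rf <- res$congruence$rf
  cong <- data.frame(iteration_a = row(rf)[upper.tri(rf)],
                     iteration_b = col(rf)[upper.tri(rf)],
                     rf = rf[upper.tri(rf)])
  write_tsv_with_header(cong, file.path(out, "congruence.tsv"),
                        c(hdr, sprintf("all_identical=%s",
                                       res$congruence$all_identical)))
  write_tsv_with_header(res$support, file.path(out, "support.tsv"), hdr)
  sel <- vapply(res$selections, paste, character(1), collapse = ",")
  writeLines(c(paste0("# ", hdr),
               sprintf("backend=%s", config$backend),
               sprintf("iteration %02d: %s", seq_along(sel), sel)),
             file.path(out, "jackknife.log"))
  invisible(res)
}

#' Simulate a dataset and write it to a directory
#'
#' @param out output directory
#' @param config a [simulation_config()]
#' @return invisibly, the `synthetic_dataset`
#' @export
cmd_simulate <- function(out, config = simulation_config()) {
  ds <- simulate_dataset(config)
  write_dataset(ds, out)
  invisible(ds)
}
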