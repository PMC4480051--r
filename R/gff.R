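#' Read a region annotation from GFF3
#'
#' Features are expected on alignment-column coordinates (GFF3 is 1-based,
#' closed, matching the package convention).  Feature types are mapped
#' `CDS -> coding` and `intron -> intron`; every maximal span between these
#' features is classed `igs` (intergenic spacer).  Other feature types are
#' ignored.
#'
#' @param path GFF3 file
#' @param n_columns total alignment columns, used to close the final
#'   intergenic span
#' @return a [region_annotation()]
#' @export
read_region_annotation <- function(path, n_columns) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("CDS", "intron")
  gr <- gr[keep]
  type <- type[keep]
  cls <- ifelse(type == "CDS", "coding", "intron")
  nm <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("%s_%03d", cls, seq_along(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  o <- order(st, en)
  st <- st[o]; en <- en[o]; cls <- cls[o]; nm <- nm[o]
  ## intergenic spacers: complement of annotated features over the columns
  feat <- IRanges::reduce(IRanges::IRanges(st, en))
  gaps <- IRanges::gaps(feat, start = 1L, end = as.integer(n_columns))
  if (length(gaps) > 0) {
    st <- c(st, IRanges::start(gaps))
    en <- c(en, IRanges::end(gaps))
    cls <- c(cls, rep("igs", length(gaps)))
    nm <- c(nm, sprintf("igs_%03d", seq_along(gaps)))
  }
  o <- order(st, en)
  region_annotation(st[o], en[o], cls[o], nm[o])
}

#' Write a region annotation as GFF3
#'
#' Only `coding` (as `CDS`) and `intron` features are written; intergenic
#' spacers are implicit as the spans between them and are rederived on read.
#'
#' @param annotation a [region_annotation()]
#' @param path output GFF3 path
#' @return `path`, invisibly
#' @export
write_region_annotation <- function(annotation, path) {
  keep <- annotation$class %in% c("coding", "intron")
  ann <- annotation[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = "alignment",
    ranges = IRanges::IRanges(ann$start, ann$end),
    type = ifelse(ann$class == "coding", "CDS", "intron"),
    phase = ifelse(ann$class == "coding", 0L, NA_integer_),
    ID = ann$name)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
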