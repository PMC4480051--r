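#' @section Coordinates:
#' All column coordinates in plastgap are 1-based and closed, following the
#' R/Bioconductor convention (an interval `c(3, 5)` covers columns 3, 4 and 5
#' and has width 3).  GFF3 annotations use the same convention natively.
#'
#' @keywords internal
"_PACKAGE"

## Character sets --------------------------------------------------------

ALN_BASES <- c("A", "C", "G", "T")
ALN_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
ALN_GAP <- "-"
ALN_ALPHABET <- c(ALN_BASES, ALN_AMBIG, ALN_GAP)

#' Construct a multiple alignment
#'
#' A `multiple_alignment` is a taxa-by-columns character matrix over
#' `A,C,G,T`, IUPAC ambiguity codes, `N` and the gap symbol `-`.  Input is
#' normalized: lowercase is raised to uppercase and `?` becomes `N`.  The
#' match character `.` is rejected (dot dialects are not supported).
#' IUPAC ambiguity codes and `N` are retained but treated as missing data by
#' downstream comparisons; only `-` counts as a gap.
#'
#' @param seqs named character vector of aligned sequences (one string per
#'   taxon, all the same length), or a character matrix with one row per
#'   taxon and one single-character column per alignment column.
#' @return An object of class `multiple_alignment`: a list with elements
#'   `taxa` (character), `mat` (character matrix, rows named by taxa) and
#'   `n_columns` (integer).
#' @examples
#' aln <- multiple_alignment(c(t1 = "ACGT", t2 = "AC-T"))
#' n_columns(aln)
#' @export
multiple_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
    taxa <- rownames(mat)
  } else {
    taxa <- names(seqs)
    if (is.null(taxa)) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      bad <- taxa[which(lens != lens[1])[1]]
      stop(sprintf("alignment is ragged: taxon '%s' has %d columns, expected %d",
                   bad, lens[taxa == bad][1], lens[1]),
           call. = FALSE)
    }
    mat <- if (lens[1] == 0) {
      matrix(character(0), nrow = length(seqs), ncol = 0)
    } else {
      do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    }
    rownames(mat) <- taxa
  }
  if (is.null(taxa)) stop("alignment matrix must have row names (taxa)")
  if (anyDuplicated(taxa)) {
    stop(sprintf("duplicate taxon label: '%s'", taxa[duplicated(taxa)][1]),
         call. = FALSE)
  }
  mat <- toupper(mat)
  mat[mat == "?"] <- "N"
  if (any(mat == ".")) {
    stop("'.' (match character) is not supported in alignments", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("invalid alignment character(s): %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  structure(list(taxa = taxa, mat = mat, n_columns = ncol(mat)),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d taxa x %d columns\n",
              length(x$taxa), x$n_columns))
  invisible(x)
}

#' Number of alignment columns
#' @param aln a [multiple_alignment()]
#' @return integer column count
#' @export
n_columns <- function(aln) aln$n_columns

#' Alignment rows as strings
#' @param aln a [multiple_alignment()]
#' @return named character vector, one string per taxon
#' @export
alignment_strings <- function(aln) {
  out <- apply(aln$mat, 1L, paste, collapse = "")
  if (aln$n_columns == 0) out <- setNames(rep("", length(aln$taxa)), aln$taxa)
  out
}

check_intervals <- function(intervals, n_col) {
  if (length(intervals) == 0) return(matrix(integer(0), ncol = 2))
  if (is.numeric(intervals) && length(intervals) == 2 && !is.matrix(intervals)) {
    intervals <- matrix(intervals, ncol = 2)
  }
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  if (!is.matrix(intervals) || ncol(intervals) != 2) {
    stop("intervals must be a 2-column matrix or list of c(start, end) pairs")
  }
  storage.mode(intervals) <- "integer"
  if (any(intervals[, 1] > intervals[, 2])) {
    stop("interval start exceeds end", call. = FALSE)
  }
  if (any(intervals[, 1] < 1L) || any(intervals[, 2] > n_col)) {
    stop(sprintf("interval out of range [1, %d]", n_col), call. = FALSE)
  }
  intervals
}

#' Excise column intervals from an alignment
#'
#' Removes the union of the given column intervals (1-based, closed), as used
#' to drop the duplicated inverted-repeat copy (IRa) and alignment regions
#' containing inversions before analysis.  Overlapping intervals are unioned.
#'
#' @param aln a [multiple_alignment()]
#' @param intervals 2-column matrix or list of `c(start, end)` pairs; may be
#'   empty for the identity transformation.
#' @return list with `alignment` (the excised [multiple_alignment()]) and
#'   `column_map` (integer vector of surviving source column indices, strictly
#'   increasing).
#' @export
excise_columns <- function(aln, intervals = NULL) {
  stopifnot(inherits(aln, "multiple_alignment"))
  iv <- check_intervals(intervals, aln$n_columns)
  drop <- rep(FALSE, aln$n_columns)
  if (nrow(iv) > 0) {
    for (k in seq_len(nrow(iv))) drop[iv[k, 1]:iv[k, 2]] <- TRUE
  }
  kept <- which(!drop)
  out <- multiple_alignment(aln$mat[, kept, drop = FALSE])
  list(alignment = out, column_map = kept)
}

#' Remove all columns containing a gap
#'
#' Drops every alignment column in which at least one taxon has `-`, the
#' standard guard against alignment ambiguity before model-based inference.
#' Ambiguity codes and `N` never trigger removal; only the gap symbol does.
#'
#' @param aln a [multiple_alignment()]
#' @return list with `alignment` (gap-free [multiple_alignment()]),
#'   `column_map` (surviving source columns) and `report` (list with
#'   `n_before`, `n_after`, `fraction_removed`).
#' @examples
#' aln <- multiple_alignment(c(a = "AC-GT", b = "ACTG-"))
#' strip_gap_columns(aln)$report$fraction_removed
#' @export
strip_gap_columns <- function(aln) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (aln$n_columns == 0) {
    kept <- integer(0)
  } else {
    kept <- which(colSums(aln$mat == ALN_GAP) == 0L)
  }
  out <- multiple_alignment(aln$mat[, kept, drop = FALSE])
  n_before <- aln$n_columns
  n_after <- length(kept)
  list(alignment = out,
       column_map = kept,
       report = list(n_before = n_before,
                     n_after = n_after,
                     fraction_removed = if (n_before == 0) 0
                                        else (n_before - n_after) / n_before))
}

#' Pairwise percent difference or identity between aligned sequences
#'
#' Compares two rows of an alignment column by column, restricted to columns
#' where both characters are unambiguous bases (`A`, `C`, `G`, `T`).  Gaps,
#' `N` and IUPAC ambiguity codes are excluded from the comparison.
#'
#' @param a,b aligned sequences of equal length (strings or character
#'   vectors).
#' @param mode `"difference"` (percent mismatching columns) or `"identity"`
#'   (100 minus the difference).
#' @return list with `percent` (numeric, on the 0-100 scale), `mode`,
#'   `n_compared` (columns entering the comparison) and `n_mismatch`.
#' @examples
#' pairwise_percent_difference("ACGT", "ACGA")$percent  # 25
#' @export
pairwise_percent_difference <- function(a, b,
                                        mode = c("difference", "identity")) {
  mode <- match.arg(mode)
  av <- if (length(a) == 1L) strsplit(a, "", fixed = TRUE)[[1]] else a
  bv <- if (length(b) == 1L) strsplit(b, "", fixed = TRUE)[[1]] else b
  av <- toupper(av); bv <- toupper(bv)
  if (length(av) != length(bv)) {
    stop("sequences must be the same (aligned) length", call. = FALSE)
  }
  use <- av %in% ALN_BASES & bv %in% ALN_BASES
  n <- sum(use)
  if (n == 0) {
    stop("no comparable columns (both sequences unambiguous nowhere)",
         call. = FALSE)
  }
  mism <- sum(av[use] != bv[use])
  diff_pct <- 100 * mism / n
  list(percent = if (mode == "difference") diff_pct else 100 - diff_pct,
       mode = mode, n_compared = n, n_mismatch = mism)
}
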