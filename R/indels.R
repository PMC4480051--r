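#' Indel acceptance criteria
#'
#' Configuration for indel scoring.  The defaults encode the four classical
#' criteria used for scoring plastome indels as single evolutionary events:
#' (i) at least 2 bp long, excluding mononucleotide repeats regardless of
#' length; (ii) slipped-strand mispairing assessed from a perfect or
#' near-perfect adjacent repeat; (iii) unambiguous, not overlapping any other
#' indel; (iv) shared by two or more rows (no autapomorphies).
#'
#' @param min_length minimum indel length in bp (default 2)
#' @param min_shared minimum number of rows sharing the gap (default 2)
#' @param exclude_mononucleotide reject homopolymer indels adjacent to the
#'   same base (default TRUE)
#' @param ssm_identity_threshold flank identity at or above which an
#'   imperfect adjacent repeat still counts as slipped-strand mispairing
#'   ("near-perfect"; default 0.80)
#' @param require_non_overlap reject events whose footprint partially
#'   overlaps another event (default TRUE)
#' @return an `indel_criteria` list
#' @export
indel_criteria <- function(min_length = 2L,
                           min_shared = 2L,
                           exclude_mononucleotide = TRUE,
                           ssm_identity_threshold = 0.80,
                           require_non_overlap = TRUE) {
  stopifnot(min_length >= 1, min_shared >= 1,
            ssm_identity_threshold > 0, ssm_identity_threshold <= 1)
  structure(list(min_length = as.integer(min_length),
                 min_shared = as.integer(min_shared),
                 exclude_mononucleotide = isTRUE(exclude_mononucleotide),
                 ssm_identity_threshold = ssm_identity_threshold,
                 require_non_overlap = isTRUE(require_non_overlap)),
            class = "indel_criteria")
}

#' Extract maximal gap runs per alignment row
#'
#' Every maximal run of `-` in every row, with runs touching the row start or
#' end flagged `terminal` (leading/trailing gaps are missing data, not
#' indels).  Output is ordered by taxon (alignment order) then start column.
#'
#' @param aln a [multiple_alignment()]
#' @return data.frame with columns `taxon`, `start`, `end`, `terminal`
#' @export
extract_gap_runs <- function(aln) {
  stopifnot(inherits(aln, "multiple_alignment"))
  nc <- aln$n_columns
  out <- vector("list", length(aln$taxa))
  for (i in seq_along(aln$taxa)) {
    gap <- aln$mat[i, ] == ALN_GAP
    if (!any(gap)) {
      out[[i]] <- NULL
      next
    }
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    s <- starts[keep]; e <- ends[keep]
    out[[i]] <- data.frame(taxon = aln$taxa[i], start = s, end = e,
                           terminal = (s == 1L) | (e == nc),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(taxon = character(0), start = integer(0),
                      end = integer(0), terminal = logical(0))
  }
  rownames(res) <- NULL
  res
}

new_indel_events <- function(start = integer(0), end = integer(0),
                             taxa = list()) {
  structure(data.frame(event = seq_along(start),
                       start = as.integer(start), end = as.integer(end),
                       length = as.integer(end - start + 1L),
                       n_taxa = vapply(taxa, length, integer(1)),
                       status = rep("candidate", length(start)),
                       reject_reason = rep(NA_character_, length(start)),
                       ssm = rep("unassessed", length(start)),
                       region = rep("unassigned", length(start)),
                       stringsAsFactors = FALSE),
            taxa = taxa, class = c("indel_events", "data.frame"))
}

#' Taxa sharing each indel event
#' @param events an `indel_events` table
#' @return list of character vectors, one per event row
#' @export
event_taxa <- function(events) attr(events, "taxa")

#' Cluster gap runs into candidate indel events
#'
#' Runs with an identical column footprint are merged into one event shared
#' by their taxa (a shared gap is interpreted as a single evolutionary
#' event).  Terminal runs are excluded entirely.  Events whose intervals
#' partially overlap (intersecting but not identical, including nested) are
#' both marked `rejected`/`ambiguous_overlap`, implementing the
#' "unambiguous, non-overlapping" criterion.
#'
#' @param runs data.frame from [extract_gap_runs()]
#' @return an `indel_events` data.frame (columns `event`, `start`, `end`,
#'   `length`, `n_taxa`, `status`, `reject_reason`, `ssm`, `region`) carrying
#'   the per-event taxon sets as attribute `"taxa"` (see [event_taxa()]).
#' @export
cluster_events <- function(runs) {
  runs <- runs[!runs$terminal, , drop = FALSE]
  if (nrow(runs) == 0) return(new_indel_events())
  key <- paste(runs$start, runs$end, sep = ":")
  grp <- split(seq_len(nrow(runs)), key)
  ## deterministic order: by start, then end
  starts <- vapply(grp, function(ix) as.integer(runs$start[ix[1]]),
                   integer(1))
  ends <- vapply(grp, function(ix) as.integer(runs$end[ix[1]]), integer(1))
  o <- order(starts, ends)
  grp <- grp[o]
  starts <- unname(starts[o]); ends <- unname(ends[o])
  taxa <- unname(lapply(grp, function(ix) unique(runs$taxon[ix])))
  ev <- new_indel_events(starts, ends, taxa)
  ## pairwise partial-overlap flagging (intervals sorted by start)
  n <- nrow(ev)
  overlap <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- i + 1
      while (j <= n && ev$start[j] <= ev$end[i]) {
        ## identical footprints were already merged, so this is partial
        overlap[i] <- TRUE; overlap[j] <- TRUE
        j <- j + 1
      }
    }
  }
  ev$status[overlap] <- "rejected"
  ev$reject_reason[overlap] <- "ambiguous_overlap"
  ev
}

## representative row for reading the ungapped segment of an event:
## first taxon in alignment order with no gap inside the interval
event_representative <- function(ev_row, aln) {
  cols <- ev_row$start:ev_row$end
  for (i in seq_along(aln$taxa)) {
    if (!any(aln$mat[i, cols] == ALN_GAP)) return(i)
  }
  NA_integer_
}

is_mononucleotide_event <- function(ev_row, aln) {
  i <- event_representative(ev_row, aln)
  if (is.na(i)) return(FALSE)
  seg <- aln$mat[i, ev_row$start:ev_row$end]
  if (length(unique(seg)) != 1L || !(seg[1] %in% ALN_BASES)) return(FALSE)
  b <- seg[1]
  left <- if (ev_row$start > 1L) aln$mat[i, ev_row$start - 1L] else NA
  right <- if (ev_row$end < aln$n_columns) aln$mat[i, ev_row$end + 1L] else NA
  isTRUE(left == b) || isTRUE(right == b)
}

#' Apply the indel acceptance criteria
#'
#' Each candidate event is accepted or rejected with the first failing
#' criterion, evaluated in the fixed order `too_short`, `mononucleotide`,
#' `ambiguous_overlap`, `autapomorphic` (the order makes reports
#' deterministic).  The mononucleotide rule fires when the ungapped segment
#' at the event interval is a single repeated base and at least one
#' immediately adjacent base equals that base.
#'
#' @param events `indel_events` from [cluster_events()]
#' @param aln the [multiple_alignment()] the events derive from
#' @param criteria an [indel_criteria()]
#' @return the events table with `status`/`reject_reason` filled in
#' @export
apply_criteria <- function(events, aln, criteria = indel_criteria()) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (nrow(events) == 0) return(events)
  if (any(events$end > aln$n_columns) || any(events$start < 1L)) {
    stop("event interval outside alignment", call. = FALSE)
  }
  taxa <- event_taxa(events)
  for (k in seq_len(nrow(events))) {
    reason <- NA_character_
    if (events$length[k] < criteria$min_length) {
      reason <- "too_short"
    } else if (criteria$exclude_mononucleotide &&
               is_mononucleotide_event(events[k, ], aln)) {
      reason <- "mononucleotide"
    } else if (criteria$require_non_overlap &&
               identical(events$reject_reason[k], "ambiguous_overlap")) {
      reason <- "ambiguous_overlap"
    } else if (length(taxa[[k]]) < criteria$min_shared) {
      reason <- "autapomorphic"
    }
    if (is.na(reason)) {
      events$status[k] <- "accepted"
      events$reject_reason[k] <- NA_character_
    } else {
      events$status[k] <- "rejected"
      events$reject_reason[k] <- reason
    }
  }
  events
}

## majority-vote ungapped segment for an event; ties per column broken by
## the earliest ungapped taxon carrying a tied character
event_segment <- function(ev_row, aln) {
  cols <- ev_row$start:ev_row$end
  sub <- aln$mat[, cols, drop = FALSE]
  ungapped <- which(rowSums(sub == ALN_GAP) == 0L)
  if (length(ungapped) == 0) return(NULL)
  seg <- character(length(cols))
  for (j in seq_along(cols)) {
    chars <- sub[ungapped, j]
    tab <- table(chars)
    winners <- names(tab)[tab == max(tab)]
    seg[j] <- chars[chars %in% winners][1]
  }
  list(segment = seg, representative = ungapped[1])
}

#' Detect slipped-strand mispairing for an indel event
#'
#' Reads the ungapped segment at the event interval (per-column majority vote
#' across ungapped rows, ties broken by first taxon order) and compares it
#' with the equal-length windows immediately upstream and downstream of the
#' event in the first ungapped row.  An identical window means `perfect`
#' (one repeat copy gained or lost at a tandem repeat); best identity at or
#' above `ssm_identity_threshold` means `near_perfect`; otherwise `none`.
#' Windows truncated by the alignment edge are skipped; if both are skipped
#' the result is `none`.
#'
#' @param ev_row single-row subset of an `indel_events` table
#' @param aln the source [multiple_alignment()]
#' @param criteria an [indel_criteria()]
#' @return `"perfect"`, `"near_perfect"` or `"none"`
#' @export
detect_ssm <- function(ev_row, aln, criteria = indel_criteria()) {
  es <- event_segment(ev_row, aln)
  if (is.null(es)) return("unassessed")
  len <- ev_row$length
  row <- aln$mat[es$representative, ]
  idents <- c()
  if (ev_row$start - len >= 1L) {
    up <- row[(ev_row$start - len):(ev_row$start - 1L)]
    idents <- c(idents, mean(up == es$segment))
  }
  if (ev_row$end + len <= aln$n_columns) {
    down <- row[(ev_row$end + 1L):(ev_row$end + len)]
    idents <- c(idents, mean(down == es$segment))
  }
  if (length(idents) == 0) return("none")
  best <- max(idents)
  if (best == 1) "perfect"
  else if (best >= criteria$ssm_identity_threshold) "near_perfect"
  else "none"
}

#' Region annotation table
#'
#' @param start,end integer feature intervals on alignment columns (1-based,
#'   closed)
#' @param class feature classes, from `coding`, `intron`, `igs`
#' @param name feature names
#' @return a `region_annotation` data.frame
#' @export
region_annotation <- function(start = integer(0), end = integer(0),
                              class = character(0), name = character(0)) {
  stopifnot(all(class %in% c("coding", "intron", "igs")),
            length(start) == length(end), length(start) == length(class))
  if (length(name) == 0) name <- sprintf("feature_%03d", seq_along(start))
  structure(data.frame(start = as.integer(start), end = as.integer(end),
                       class = class, name = name, stringsAsFactors = FALSE),
            class = c("region_annotation", "data.frame"))
}

#' Classify the genomic region of an indel event
#'
#' Assigns the class of the annotation feature with maximal column overlap;
#' ties are broken by the precedence coding > intron > igs.  Events
#' overlapping no feature are `unassigned`.
#'
#' @param ev_row single-row subset of an `indel_events` table
#' @param annotation a [region_annotation()]
#' @return `"coding"`, `"intron"`, `"igs"` or `"unassigned"`
#' @export
classify_region <- function(ev_row, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0) return("unassigned")
  ov <- pmin(annotation$end, ev_row$end) -
        pmax(annotation$start, ev_row$start) + 1L
  ov[ov < 0L] <- 0L
  if (all(ov == 0L)) return("unassigned")
  best <- which(ov == max(ov))
  prec <- c(coding = 1L, intron = 2L, igs = 3L)
  cls <- annotation$class[best]
  cls[order(prec[cls])][1]
}

#' Binary presence/absence character matrix from accepted indel events
#'
#' One binary character per accepted event: state 1 means the gap is present
#' (segment absent), 0 means the segment is present.  Rows that carry only
#' `N`/ambiguity across the whole event interval are coded missing (`NA`).
#'
#' @param events `indel_events` table (only accepted rows are used)
#' @param aln the source [multiple_alignment()]
#' @return integer matrix (taxa x characters, values 0/1/NA) with character
#'   ids `indel<k>` as column names; class `binary_character_matrix`.
#' @export
build_character_matrix <- function(events, aln) {
  stopifnot(inherits(aln, "multiple_alignment"))
  acc <- which(events$status == "accepted")
  m <- matrix(NA_integer_, nrow = length(aln$taxa), ncol = length(acc),
              dimnames = list(aln$taxa,
                              sprintf("indel%d", events$event[acc])))
  taxa <- event_taxa(events)
  for (j in seq_along(acc)) {
    k <- acc[j]
    cols <- events$start[k]:events$end[k]
    state <- integer(length(aln$taxa))
    for (i in seq_along(aln$taxa)) {
      chars <- aln$mat[i, cols]
      if (aln$taxa[i] %in% taxa[[k]]) {
        state[i] <- 1L
      } else if (all(chars %in% ALN_AMBIG)) {
        state[i] <- NA_integer_
      } else {
        state[i] <- 0L
      }
    }
    m[, j] <- state
  }
  structure(m, class = c("binary_character_matrix", class(m)))
}

#' Build a full indel catalogue from a gapped alignment
#'
#' Convenience pipeline: gap-run extraction, event clustering, acceptance
#' criteria, slipped-strand-mispairing assessment (accepted events only) and
#' region classification.
#'
#' @param aln a gapped [multiple_alignment()]
#' @param criteria an [indel_criteria()]
#' @param annotation optional [region_annotation()]
#' @return an `indel_events` table with all columns filled
#' @export
indel_catalog <- function(aln, criteria = indel_criteria(),
                          annotation = NULL) {
  runs <- extract_gap_runs(aln)
  ev <- cluster_events(runs)
  ev <- apply_criteria(ev, aln, criteria)
  for (k in seq_len(nrow(ev))) {
    if (ev$status[k] == "accepted") {
      ev$ssm[k] <- detect_ssm(ev[k, ], aln, criteria)
    }
    if (!is.null(annotation)) {
      ev$region[k] <- classify_region(ev[k, ], annotation)
    }
  }
  ev
}

#' Summarize an indel catalogue
#'
#' Totals, per-rejection-reason counts, SSM class counts and region counts,
#' mirroring the standard results summary for scored plastome indels.
#'
#' @param events an `indel_events` table
#' @return named list of counts
#' @export
summarize_catalog <- function(events) {
  reasons <- c("too_short", "mononucleotide", "ambiguous_overlap",
               "autapomorphic")
  acc <- events$status == "accepted"
  list(
    total = nrow(events),
    accepted = sum(acc),
    rejected = setNames(
      vapply(reasons, function(r)
        sum(!acc & events$reject_reason == r, na.rm = TRUE), integer(1)),
      reasons),
    ssm = table(factor(events$ssm[acc],
                       levels = c("perfect", "near_perfect", "none",
                                  "unassessed"))),
    region = table(factor(events$region[acc],
                          levels = c("coding", "intron", "igs",
                                     "unassigned")))
  )
}

#' Write an indel catalogue as TSV
#' @param events an `indel_events` table
#' @param path output path
#' @param header optional comment lines
#' @return `path`, invisibly
#' @export
write_indel_catalog <- function(events, path, header = character(0)) {
  df <- as.data.frame(events)
  df$taxa <- vapply(event_taxa(events), paste, character(1), collapse = ",")
  write_tsv_with_header(df, path, header)
}

#' Read an indel catalogue written by [write_indel_catalog()]
#' @param path TSV path
#' @return an `indel_events` table
#' @export
read_indel_catalog <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  taxa <- strsplit(ifelse(is.na(df$taxa), "", df$taxa), ",", fixed = TRUE)
  ev <- new_indel_events(df$start, df$end, taxa)
  ev$event <- df$event
  ev$status <- df$status
  ev$reject_reason <- as.character(df$reject_reason)
  ev$ssm <- df$ssm
  ev$region <- df$region
  ev
}

#' Write a binary character matrix as TSV or NEXUS
#'
#' The NEXUS form uses a standard-datatype DATA block so the characters can
#' feed external parsimony programs; missing states are written as `?`.
#'
#' @param mat a `binary_character_matrix`
#' @param path output path
#' @param format `"tsv"` or `"nexus"`
#' @param header optional comment lines (TSV only)
#' @return `path`, invisibly
#' @export
write_character_matrix <- function(mat, path, format = c("tsv", "nexus"),
                                   header = character(0)) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon = rownames(mat), unclass(mat),
                     check.names = FALSE)
    write_tsv_with_header(df, path, header)
  } else {
    rows <- apply(mat, 1L, function(x)
      paste(ifelse(is.na(x), "?", x), collapse = ""))
    con <- file(path, "wt"); on.exit(close(con))
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                         nrow(mat), ncol(mat)),
                 "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"01\";",
                 "  MATRIX"), con)
    writeLines(sprintf("    %s  %s", rownames(mat), rows), con)
    writeLines(c("  ;", "END;"), con)
  }
  invisible(path)
}

#' Read a binary character matrix from the TSV written by
#' [write_character_matrix()]
#' @param path TSV path
#' @return a `binary_character_matrix`
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$taxon
  structure(m, class = c("binary_character_matrix", class(m)))
}
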