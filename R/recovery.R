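#' Expected indel catalogue entries for a synthetic dataset
#'
#' Translates ground-truth events into the footprint the catalogue should
#' report: deletions gap the member taxa, insertions gap everyone else.
#' Each truth row is annotated with the expected gapped taxon set, the
#' expected slipped-strand-mispairing label and whether the event should be
#' accepted under the given criteria (mononucleotide events and events whose
#' gapped set is below `min_shared` must be rejected).
#'
#' @param dataset a `synthetic_dataset`
#' @param criteria an [indel_criteria()]
#' @return the truth data.frame with extra columns `gapped_taxa`,
#'   `expected_ssm`, `expected_accepted`
#' @export
expected_catalog <- function(dataset, criteria = indel_criteria()) {
  truth <- dataset$truth
  all_taxa <- dataset$alignment$taxa
  gapped <- character(nrow(truth))
  exp_ssm <- character(nrow(truth))
  exp_acc <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    members <- strsplit(truth$members[i], ",", fixed = TRUE)[[1]]
    g <- if (grepl("deletion", truth$type[i])) members
         else setdiff(all_taxa, members)
    gapped[i] <- paste(sort(g), collapse = ",")
    exp_ssm[i] <- if (startsWith(truth$type[i], "ssm")) "perfect" else "none"
    exp_acc[i] <- truth$type[i] != "mononucleotide" &&
      length(g) >= criteria$min_shared &&
      truth$length[i] >= criteria$min_length
  }
  truth$gapped_taxa <- gapped
  truth$expected_ssm <- exp_ssm
  truth$expected_accepted <- exp_acc
  truth
}

#' Evaluate indel-catalogue recovery against simulated ground truth
#'
#' Compares the accepted events of a catalogue with the expected accepted
#' events of a synthetic dataset on three attributes: the column interval,
#' the gapped taxon set, and the slipped-strand-mispairing label.  A truth
#' event is recovered when an accepted event matches its interval and taxon
#' set exactly.
#'
#' @param events an `indel_events` table from [indel_catalog()]
#' @param dataset the `synthetic_dataset` the alignment came from
#' @param criteria the [indel_criteria()] used for the catalogue
#' @return list with `precision`, `recall`, `ssm_accuracy` (fraction of
#'   recovered events with the expected SSM label), `n_expected`,
#'   `n_accepted`, `n_recovered`
#' @export
evaluate_recovery <- function(events, dataset,
                              criteria = indel_criteria()) {
  exp_tab <- expected_catalog(dataset, criteria)
  exp_tab <- exp_tab[exp_tab$expected_accepted, , drop = FALSE]
  acc <- events[events$status == "accepted", , drop = FALSE]
  acc_taxa <- event_taxa(events)[events$status == "accepted"]
  acc_key <- sprintf("%d:%d:%s", acc$start, acc$end,
                     vapply(acc_taxa, function(x)
                       paste(sort(x), collapse = ","), character(1)))
  exp_key <- sprintf("%d:%d:%s", exp_tab$start, exp_tab$end,
                     exp_tab$gapped_taxa)
  hit <- exp_key %in% acc_key
  n_rec <- sum(hit)
  ssm_ok <- 0L
  if (n_rec > 0) {
    m <- match(exp_key[hit], acc_key)
    ssm_ok <- sum(acc$ssm[m] == exp_tab$expected_ssm[hit])
  }
  list(precision = if (nrow(acc) == 0) NA_real_ else
         sum(acc_key %in% exp_key) / nrow(acc),
       recall = if (nrow(exp_tab) == 0) NA_real_ else n_rec / nrow(exp_tab),
       ssm_accuracy = if (n_rec == 0) NA_real_ else ssm_ok / n_rec,
       n_expected = nrow(exp_tab),
       n_accepted = nrow(acc),
       n_recovered = n_rec)
}

#' Per-branch injection counts expected in the clade tabulation
#'
#' For classification against the true tree rooted on one of its two basal
#' clades, only events on branches strictly inside the ingroup and shared by
#' two or more taxa yield clade synapomorphies.  Returns those expected
#' counts keyed by the sorted member leaf set.
#'
#' @param dataset a `synthetic_dataset`
#' @param outgroup taxa excluded from the ingroup
#' @param criteria an [indel_criteria()]
#' @return named integer vector: comma-joined sorted member sets -> counts
#' @export
expected_clade_counts <- function(dataset, outgroup,
                                  criteria = indel_criteria()) {
  exp_tab <- expected_catalog(dataset, criteria)
  exp_tab <- exp_tab[exp_tab$expected_accepted, , drop = FALSE]
  ingroup <- setdiff(dataset$alignment$taxa, outgroup)
  counts <- integer(0)
  for (i in seq_len(nrow(exp_tab))) {
    members <- strsplit(exp_tab$members[i], ",", fixed = TRUE)[[1]]
    if (length(members) < 2) next                      # autapomorphic
    if (!all(members %in% ingroup)) next               # outgroup side
    if (length(members) >= length(ingroup)) next       # ingroup-invariant
    key <- paste(sort(members), collapse = ",")
    counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) + 1L
  }
  counts
}
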