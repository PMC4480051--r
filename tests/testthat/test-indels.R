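test_that("gap runs are extracted maximally with terminal flags", {
  aln <- multiple_alignment(c(u = "AC--GT", v = "--ACGT", w = "ACGT--",
                              x = "A-C-GT", y = "ACGTAC"))
  runs <- extract_gap_runs(aln)
  u <- runs[runs$taxon == "u", ]
  expect_equal(c(u$start, u$end, u$terminal), c(3, 4, 0))
  v <- runs[runs$taxon == "v", ]
  expect_equal(c(v$start, v$end, v$terminal), c(1, 2, 1))
  w <- runs[runs$taxon == "w", ]
  expect_true(w$terminal)
  expect_equal(nrow(runs[runs$taxon == "x", ]), 2)
  expect_equal(nrow(runs[runs$taxon == "y", ]), 0)
})

test_that("gap runs equal a per-character scan on random matrices", {
  set.seed(77)
  for (rep in 1:25) {
    aln <- random_gapped_alignment(sample(3:6, 1), sample(15:40, 1),
                                   gap_prob = 0.25)
    runs <- extract_gap_runs(aln)
    for (i in seq_along(aln$taxa)) {
      expected <- scan_gap_runs(aln$mat[i, ])
      got <- runs[runs$taxon == aln$taxa[i], ]
      expect_equal(nrow(got), length(expected))
      for (k in seq_along(expected)) {
        expect_equal(c(got$start[k], got$end[k]), expected[[k]])
      }
    }
  }
})

test_that("identical footprints merge; partial and nested overlaps reject", {
  runs <- data.frame(
    taxon = c("X", "Y", "Z"),
    start = c(4, 4, 4), end = c(8, 8, 8),
    terminal = FALSE, stringsAsFactors = FALSE)
  ev <- cluster_events(runs)
  expect_equal(nrow(ev), 1)
  expect_setequal(event_taxa(ev)[[1]], c("X", "Y", "Z"))
  expect_equal(ev$status, "candidate")

  part <- data.frame(taxon = c("X", "Y"), start = c(4, 6), end = c(8, 10),
                     terminal = FALSE, stringsAsFactors = FALSE)
  evp <- cluster_events(part)
  expect_equal(evp$status, c("rejected", "rejected"))
  expect_equal(evp$reject_reason, rep("ambiguous_overlap", 2))

  nest <- data.frame(taxon = c("X", "Y"), start = c(4, 5), end = c(8, 7),
                     terminal = FALSE, stringsAsFactors = FALSE)
  expect_equal(cluster_events(nest)$reject_reason,
               rep("ambiguous_overlap", 2))

  term <- data.frame(taxon = "X", start = 1, end = 3, terminal = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_events(term)), 0)
})

test_that("overlap flags agree with an all-pairs interval predicate", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    start <- sample(1:30, n, replace = TRUE)
    len <- sample(1:6, n, replace = TRUE)
    runs <- data.frame(taxon = paste0("t", seq_len(n)), start = start,
                       end = start + len, terminal = FALSE,
                       stringsAsFactors = FALSE)
    ev <- cluster_events(runs)
    for (i in seq_len(nrow(ev))) {
      partners <- setdiff(seq_len(nrow(ev)), i)
      overlaps <- any(ev$start[partners] <= ev$end[i] &
                      ev$end[partners] >= ev$start[i])
      expect_equal(identical(ev$reject_reason[i], "ambiguous_overlap"),
                   overlaps)
    }
  }
})

test_that("each rejection criterion fires with the documented precedence", {
  ## columns:       123456789012345678
  aln <- multiple_alignment(c(
    r1 = "ATTCG-AAAAGGCAGTTA",   # length-1 gap shared by 3 rows
    r2 = "ATTCG-AAAAGGCAGTTA",
    r3 = "ATTCG-AAAAGGCAGTTA",
    r4 = "ATTCGTAAAAGGCAGTTA",
    r5 = "ATTCGTAAAAGGCAGTTA"))
  ev <- apply_criteria(cluster_events(extract_gap_runs(aln)), aln)
  expect_equal(ev$status, "rejected")
  expect_equal(ev$reject_reason, "too_short")

  ## homopolymer gap flanked by the same base -> mononucleotide,
  ## regardless of its length
  aln2 <- multiple_alignment(c(
    r1 = "ATTCG----AGGCAGTTA",
    r2 = "ATTCG----AGGCAGTTA",
    r3 = "ATTCGAAAAAGGCAGTTA",
    r4 = "ATTCGAAAAAGGCAGTTA"))
  ev2 <- apply_criteria(cluster_events(extract_gap_runs(aln2)), aln2)
  expect_equal(ev2$reject_reason, "mononucleotide")

  ## non-homopolymer, length 5, single row -> autapomorphic
  aln3 <- multiple_alignment(c(
    r1 = "ATTCG-----GGCAGTTA",
    r2 = "ATTCGTACTGGGCAGTTA",
    r3 = "ATTCGTACTGGGCAGTTA"))
  ev3 <- apply_criteria(cluster_events(extract_gap_runs(aln3)), aln3)
  expect_equal(ev3$reject_reason, "autapomorphic")

  ## partial overlap -> ambiguous_overlap on both parties
  aln4 <- multiple_alignment(c(
    r1 = "ATTCG---TGGGCAGTTA",
    r2 = "ATTCGT---GGGCAGTTA",
    r3 = "ATTCGTACTGGGCAGTTA",
    r4 = "ATTCGTACTGGGCAGTTA"))
  ev4 <- apply_criteria(cluster_events(extract_gap_runs(aln4)), aln4)
  expect_equal(ev4$reject_reason, rep("ambiguous_overlap", 2))

  ## terminal runs never become events
  aln5 <- multiple_alignment(c(
    r1 = "---CGTACTGGGCAGTTA",
    r2 = "---CGTACTGGGCAGTTA",
    r3 = "ATTCGTACTGGGCAGTTA"))
  expect_equal(nrow(indel_catalog(aln5)), 0)

  ## precedence: too_short fires before autapomorphic on a 1-bp autapomorphy
  aln6 <- multiple_alignment(c(
    r1 = "ATTCG-ACTGGGCAGTTA",
    r2 = "ATTCGTACTGGGCAGTTA",
    r3 = "ATTCGTACTGGGCAGTTA"))
  ev6 <- apply_criteria(cluster_events(extract_gap_runs(aln6)), aln6)
  expect_equal(ev6$reject_reason, "too_short")

  ## a clean shared event is accepted
  aln7 <- multiple_alignment(c(
    r1 = "ATTCG-----GGCAGTTA",
    r2 = "ATTCG-----GGCAGTTA",
    r3 = "ATTCGTACTGGGCAGTTA",
    r4 = "ATTCGTACTGGGCAGTTA"))
  ev7 <- apply_criteria(cluster_events(extract_gap_runs(aln7)), aln7)
  expect_equal(ev7$status, "accepted")
  expect_true(is.na(ev7$reject_reason))
})

test_that("slipped-strand mispairing detection honors flanks and threshold", {
  ## segment ATG with upstream flank ATG -> perfect tandem repeat
  aln <- multiple_alignment(c(
    a = "CCATG---TTCCGGAA",
    b = "CCATG---TTCCGGAA",
    c = "CCATGATGTTCCGGAA",
    d = "CCATGATGTTCCGGAA"))
  ev <- indel_catalog(aln)
  expect_equal(ev$status, "accepted")
  expect_equal(ev$ssm, "perfect")

  ## best flank identity exactly 4/5 = 0.8 -> near_perfect at the default
  aln2 <- multiple_alignment(c(
    a = "CCATGCA-----TTCCGGAA",
    b = "CCATGCA-----TTCCGGAA",
    c = "CCATGCATGCTATTCCGGAA",
    d = "CCATGCATGCTATTCCGGAA"))
  ## ungapped segment TGCTA vs upstream ATGCA (2/5) and downstream TTCCG;
  ## construct instead explicitly:
  seg <- c("A", "T", "G", "C", "A")
  near <- c("A", "T", "G", "C", "T")  # 4/5 identity
  row_has <- paste(c("GG", near, seg, "GGCCTTAA"), collapse = "")
  row_gap <- paste(c("GG", near, rep("-", 5), "GGCCTTAA"), collapse = "")
  aln3 <- multiple_alignment(c(a = row_gap, b = row_gap,
                               c = row_has, d = row_has))
  ev3 <- indel_catalog(aln3)
  expect_equal(ev3$ssm, "near_perfect")

  ## identity below the threshold on both flanks -> none
  far <- c("T", "A", "C", "G", "G")
  row_has <- paste(c("GG", far, seg, "GGCCTTAA"), collapse = "")
  row_gap <- paste(c("GG", far, rep("-", 5), "GGCCTTAA"), collapse = "")
  aln4 <- multiple_alignment(c(a = row_gap, b = row_gap,
                               c = row_has, d = row_has))
  expect_equal(indel_catalog(aln4)$ssm, "none")

  ## a stricter threshold reclassifies the 0.8 case
  crit <- indel_criteria(ssm_identity_threshold = 0.9)
  expect_equal(indel_catalog(aln3, crit)$ssm, "none")
})

test_that("region classification uses maximal overlap then precedence", {
  ann <- region_annotation(start = c(1, 11, 21), end = c(10, 20, 30),
                           class = c("coding", "intron", "igs"))
  ev <- data.frame(start = 22, end = 25, length = 4)
  expect_equal(classify_region(ev, ann), "igs")
  ## 3 columns coding, 1 igs -> coding (majority)
  ann2 <- region_annotation(start = c(1, 9), end = c(8, 20),
                            class = c("coding", "igs"))
  expect_equal(classify_region(data.frame(start = 6, end = 9), ann2),
               "coding")
  ## precedence audit over every tying class pair
  classes <- c("coding", "intron", "igs")
  prec <- c(coding = 1, intron = 2, igs = 3)
  for (c1 in classes) for (c2 in setdiff(classes, c1)) {
    ann3 <- region_annotation(start = c(1, 5), end = c(4, 8),
                              class = c(c1, c2))
    got <- classify_region(data.frame(start = 3, end = 6), ann3)
    expect_equal(got, if (prec[c1] < prec[c2]) c1 else c2)
  }
  ## no overlap -> unassigned
  expect_equal(classify_region(data.frame(start = 50, end = 60), ann),
               "unassigned")
})

test_that("character matrix encodes gap presence with missing for N rows", {
  aln <- multiple_alignment(c(
    X = "ATTCG-----GGCAGTTA",
    Y = "ATTCG-----GGCAGTTA",
    Z = "ATTCGTACTGGGCAGTTA",
    W = "ATTCGNNNNNGGCAGTTA"))
  ev <- indel_catalog(aln)
  m <- build_character_matrix(ev, aln)
  expect_equal(dim(m), c(4, 1))
  expect_equal(unname(m[, 1]), c(1L, 1L, 0L, NA_integer_))

  empty <- build_character_matrix(
    cluster_events(extract_gap_runs(
      multiple_alignment(c(a = "ACGT", b = "ACGT")))),
    multiple_alignment(c(a = "ACGT", b = "ACGT")))
  expect_equal(ncol(empty), 0)
})

test_that("catalogue invariants hold on random gapped alignments", {
  set.seed(1234)
  for (rep in 1:15) {
    aln <- random_gapped_alignment(sample(4:8, 1), sample(30:80, 1),
                                   gap_prob = 0.12)
    runs <- extract_gap_runs(aln)
    ev <- indel_catalog(aln)
    ## every non-terminal run is covered by exactly one event footprint
    nonterm <- runs[!runs$terminal, ]
    for (k in seq_len(nrow(nonterm))) {
      hits <- sum(ev$start == nonterm$start[k] & ev$end == nonterm$end[k])
      expect_equal(hits, 1)
    }
    ## accepted events are pairwise disjoint in columns
    acc <- ev[ev$status == "accepted", ]
    if (nrow(acc) > 1) {
      for (i in 1:(nrow(acc) - 1)) {
        expect_true(all(acc$start[(i + 1):nrow(acc)] > acc$end[i] |
                        acc$end[(i + 1):nrow(acc)] < acc$start[i]))
      }
    }
    ## accepted = total - sum(rejected by reason)
    s <- summarize_catalog(ev)
    expect_equal(s$accepted, s$total - sum(s$rejected))
  }
})

test_that("catalogue and character matrix survive a TSV round trip", {
  aln <- multiple_alignment(c(
    X = "ATTCG-----GGCAGTTA",
    Y = "ATTCG-----GGCAGTTA",
    Z = "ATTCGTACTGGGCAGTTA",
    W = "ATTCGTACTGGGCAGTTA"))
  ev <- indel_catalog(aln)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_indel_catalog(ev, path)
  back <- read_indel_catalog(path)
  expect_equal(back$start, ev$start)
  expect_equal(back$status, ev$status)
  expect_equal(event_taxa(back), lapply(event_taxa(ev), sort))

  m <- build_character_matrix(ev, aln)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_character_matrix(m, mpath)
  m2 <- read_character_matrix(mpath)
  expect_equal(unclass(m2), unclass(m))

  npath <- withr::local_tempfile(fileext = ".nex")
  write_character_matrix(m, npath, "nexus")
  expect_true(any(grepl("DATATYPE=STANDARD", readLines(npath))))
})
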