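test_that("Newick trees parse with supports and round-trip", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),(C,D));", path)
  tr <- read_tree(path)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))

  writeLines("((A,B)95,(C,D)87);", path)
  trs <- read_tree(path)
  expect_true(all(c("95", "87") %in% trs$node.label))

  writeLines("((A,B),(C,D;", path)
  expect_error(read_tree(path), "malformed")

  set.seed(4)
  big <- ape::rtree(20)
  write_tree(big, path)
  back <- read_tree(path)
  expect_equal(rf_distance(big, back), 0)
})

test_that("outgroup rooting places the root on the separating branch", {
  tr <- ape::read.tree(text = "(A,B,(C,D));")
  rooted <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  expect_setequal(ape::extract.clade(
    rooted, ape::getMRCA(rooted, c("A", "B", "C")))$tip.label,
    c("A", "B", "C"))

  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")),
               "proper subset")
  expect_error(root_with_outgroup(tr, character(0)), "nonempty")
  ## non-separable outgroup
  tr2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_error(root_with_outgroup(tr2, c("A", "B")), "monophyletic")

  ## rooting then unrooting preserves the unrooted topology
  set.seed(10)
  for (rep in 1:10) {
    t <- ape::rtree(8, rooted = FALSE)
    og <- sample(t$tip.label, 1)
    expect_equal(rf_distance(ape::unroot(root_with_outgroup(t, og)), t), 0)
  }
})

test_that("fitch_steps matches spec examples and brute-force enumeration", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_steps(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(fitch_steps(tr, c(A = 1, C = 1, B = 0, D = 0)), 2)
  expect_equal(fitch_steps(tr, c(A = 1, B = 1, C = 1, D = 1)), 0)
  expect_error(fitch_steps(tr, c(A = NA, B = NA, C = NA, D = NA)),
               "missing")

  set.seed(55)
  for (rep in 1:30) {
    t <- ape::rtree(sample(4:9, 1))
    ch <- random_binary_character(t$tip.label)
    expect_equal(fitch_steps(t, ch), brute_fitch(t, ch))
  }
})

test_that("fitch_steps handles missing leaves as free states", {
  set.seed(56)
  for (rep in 1:20) {
    t <- ape::rtree(6)
    ch <- random_binary_character(t$tip.label, missing_prob = 0.3)
    expect_equal(fitch_steps(t, ch), brute_fitch(t, ch))
  }
})

test_that("fitch_steps is invariant under rerooting and leaf permutation", {
  set.seed(57)
  for (rep in 1:15) {
    t <- ape::rtree(8)
    ch <- random_binary_character(t$tip.label)
    s0 <- fitch_steps(t, ch)
    og <- sample(t$tip.label, 1)
    expect_equal(fitch_steps(ape::root(t, og, resolve.root = TRUE), ch), s0)
    expect_equal(fitch_steps(t, ch[sample(names(ch))]), s0)
    expect_equal(fitch_steps(ape::unroot(t), ch), s0)
  }
})

test_that("fitch_steps agrees with phangorn parsimony", {
  skip_if_not_installed("phangorn")
  set.seed(58)
  for (rep in 1:20) {
    t <- ape::rtree(10)
    ch <- random_binary_character(t$tip.label)
    dat <- phangorn::phyDat(matrix(as.character(ch), ncol = 1,
                                   dimnames = list(names(ch), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(fitch_steps(t, ch), phangorn::parsimony(t, dat))
  }
})

test_that("characters classify as synapomorphic, homoplastic or excluded", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),O);")
  rooted <- root_with_outgroup(tr, "O")
  ingroup <- ape::drop.tip(rooted, "O")

  syn <- classify_character(ingroup, c(A = 1, B = 1, C = 0, D = 0), 0)
  expect_equal(syn$status, "synapomorphic")
  expect_setequal(syn$supported_clade, c("A", "B"))
  expect_equal(syn$fitch_steps, 1)

  hom <- classify_character(ingroup, c(A = 1, C = 1, B = 0, D = 0), 0)
  expect_equal(hom$status, "homoplastic")
  expect_equal(hom$fitch_steps, 2)

  inv <- classify_character(ingroup, c(A = 1, B = 1, C = 1, D = 1), 0)
  expect_equal(inv$status, "invariant_excluded")

  aut <- classify_character(ingroup, c(A = 1, B = 0, C = 0, D = 0), 0)
  expect_equal(aut$status, "autapomorphic")

  ## outgroup state flips the polarity: derived = state 0 clade
  syn0 <- classify_character(ingroup, c(A = 1, B = 1, C = 0, D = 0), 1)
  expect_setequal(syn0$supported_clade, c("C", "D"))

  ## two conspecific rows forming a cherry are a valid supported clade
  tr2 <- ape::read.tree(text = "(((sp1a,sp1b),(X,Y)),O);")
  ing2 <- ape::drop.tip(root_with_outgroup(tr2, "O"), "O")
  cherry <- classify_character(ing2, c(sp1a = 1, sp1b = 1, X = 0, Y = 0), 0)
  expect_equal(cherry$status, "synapomorphic")
  expect_setequal(cherry$supported_clade, c("sp1a", "sp1b"))
})

test_that("synapomorphy status equals the monophyly test on random data", {
  set.seed(60)
  for (rep in 1:40) {
    t <- ape::rtree(sample(5:10, 1))
    ch <- random_binary_character(t$tip.label)
    cl <- classify_character(t, ch)
    derived <- cl$derived_state
    d_leaves <- names(ch)[ch == derived]
    if (cl$status %in% c("synapomorphic", "homoplastic")) {
      mono <- ape::is.monophyletic(t, d_leaves)
      expect_equal(cl$status == "synapomorphic", mono)
      ## with the root pinned to the ancestral state, one step on the tree
      ## is exactly equivalent to monophyly of the derived set
      if (length(d_leaves) >= 2) {
        rooted_steps <- brute_fitch_rooted(t, ch, 1 - derived)
        expect_equal(rooted_steps == 1, mono)
      }
    }
  }
})

test_that("classification sums and tabulation reconcile", {
  set.seed(61)
  t <- ape::rtree(8)
  mat <- do.call(cbind, lapply(1:12, function(i)
    random_binary_character(t$tip.label)))
  colnames(mat) <- sprintf("indel%d", 1:12)
  class(mat) <- c("binary_character_matrix", class(mat))
  cls <- classify_characters(t, mat)
  expect_equal(nrow(cls), 12)
  expect_equal(sum(table(cls$status)), 12)

  tab <- tabulate_clades(cls, list())
  syn_rows <- tab[tab$clade != "Homoplasious indels", ]
  expect_equal(sum(syn_rows$indels), sum(cls$status == "synapomorphic"))
  expect_equal(tab$indels[tab$clade == "Homoplasious indels"],
               sum(cls$status == "homoplastic"))
})

test_that("clade tabulation counts named and literal leaf sets", {
  cls <- data.frame(
    character_id = paste0("i", 1:5),
    fitch_steps = c(1, 1, 1, 2, 1),
    status = c("synapomorphic", "synapomorphic", "synapomorphic",
               "homoplastic", "synapomorphic"),
    derived_state = 1,
    supported_clade = c("X,Y", "X,Y", "X,Y", NA, "P,Q,R"),
    stringsAsFactors = FALSE)
  tab <- tabulate_clades(cls, list(pair = c("Y", "X")))
  expect_equal(tab$indels[tab$clade == "pair"], 3)
  expect_equal(tab$indels[tab$clade == "P,Q,R"], 1)
  expect_equal(tab$indels[tab$clade == "Homoplasious indels"], 1)

  empty <- tabulate_clades(cls[0, ], list(pair = c("X", "Y")))
  expect_equal(empty$indels, c(0, 0))
})

test_that("RF distance matches brute-force bipartitions and phangorn", {
  t1 <- ape::read.tree(text = "((A,B),C,D);")
  t2 <- ape::read.tree(text = "((A,C),B,D);")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)

  set.seed(70)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    a <- ape::rtree(n, rooted = FALSE)
    b <- ape::rtree(n, rooted = FALSE)
    b$tip.label <- sample(a$tip.label)
    expect_setequal(tree_bipartitions(a), brute_bipartitions(a))
    ba <- brute_bipartitions(a); bb <- brute_bipartitions(b)
    expect_equal(rf_distance(a, b),
                 length(setdiff(ba, bb)) + length(setdiff(bb, ba)))
    if (requireNamespace("phangorn", quietly = TRUE)) {
      expect_equal(rf_distance(a, b), phangorn::RF.dist(a, b))
    }
  }
})
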