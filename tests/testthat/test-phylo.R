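test_that("pdistance_matrix computes gap-excluded p-distances", {
  a <- "ACDEFGHIKL"
  b <- "ACDEFGHIKW"            # 1 of 10 comparable columns differs
  d <- pdistance_matrix(c(x = a, y = b, z = a))
  expect_equal(d["x", "y"], 0.1)
  expect_equal(d["x", "z"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_error(pdistance_matrix(c(x = a, y = b)), "at least 3")
})

test_that("nj_tree recovers the spec'd additive four-taxon topology", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(d)
  # four-point condition oracle: of the three pairings, (AB|CD) is the
  # split with the smallest sum, so the tree must contain it
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # and reproduce the path distances exactly (additivity)
  expect_equal(ape::cophenetic.phylo(tr)[ids, ids], d, tolerance = 1e-9)

  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d2 <- d; d2[1, 2] <- 3
  expect_error(nj_tree(d2), "non-symmetric")
})

test_that("nj_tree handles n = 3 and is invariant to leaf order", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")],
               d, tolerance = 1e-9)

  set.seed(10)
  ra <- random_additive(7L)
  perm <- sample(rownames(ra$d))
  t1 <- nj_tree(ra$d)
  t2 <- nj_tree(ra$d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("root_by_outgroup places and validates the root", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,OUT:1):1);")
  r <- root_by_outgroup(tr, "OUT")
  expect_true(attr(r, "outgroup_clean"))
  # OUT is sister to everything else within its split
  expect_true(ape::is.monophyletic(r, c("A", "B", "C")))

  expect_error(root_by_outgroup(tr, c("A", "B", "C", "OUT")), "all leaves")
  expect_error(root_by_outgroup(tr, "nope"), "unknown")
})

test_that("call_clades follows the minimal-clade rule", {
  labels <- data.frame(
    id = c("REF_CDDP", "REF_OUT", "REF_COMP"),
    dioxane_label = c("CDDP", "OUT", "COMP"),
    group = c("V", "V", "II"), subtype = "x",
    dioxane_positive = c(FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  tr <- ape::read.tree(text = "((Q1:1,REF_CDDP:1):1,(REF_OUT:1,Q2:1):1);")
  cc <- call_clades(tr, labels)
  expect_identical(cc$call[cc$query_id == "Q1"], "CDDP-like")
  expect_identical(cc$call[cc$query_id == "Q2"], "outgroup-like")
  expect_identical(cc$group, c("V", "V"))

  # minimal clade containing both a CDDP and an OUT reference: ambiguous
  tr2 <- ape::read.tree(
    text = "(((REF_CDDP:1,REF_OUT:1):1,Q1:1):1,REF_COMP:2);")
  cc2 <- call_clades(tr2, labels)
  expect_identical(cc2$call[cc2$query_id == "Q1"], "ambiguous")

  tr3 <- ape::read.tree(text = "((Q1:1,Q2:1):1,Q3:2);")
  expect_error(call_clades(tr3, labels), "no panel leaves")
})

test_that("call_clades is invariant to query leaf insertion order", {
  panel <- synthetic_panel()
  set.seed(19)
  qs <- setNames(
    vapply(c("CDDP1", "CDDP3", "OUT5"), function(r)
      mutate_to_identity(panel$proteins[[r]], 94)$seq, character(1)),
    c("qa", "qb", "qc"))
  mk <- function(order) {
    seqs <- c(qs[order], panel$proteins)
    tr <- nj_tree(pdistance_matrix(seqs))
    tr <- root_by_outgroup(tr, panel_outgroup_ids(panel),
                           ignore_ids = names(qs))
    cc <- call_clades(tr, panel$labels)
    cc[order(cc$query_id), c("query_id", "call", "group")]
  }
  expect_identical(mk(c(1, 2, 3)), mk(c(3, 1, 2)))
})

test_that("confirm_group scores hydrophobicity-class agreement of flanks", {
  # reference: motif DEGRH at anchor 11, hydrophobic flanks (V/L), 5 aside
  ref <- paste0("NNNNN", "VLVLV", "DEGRH", "LVLVL", "NNNNN")
  expect_equal(confirm_group(ref, ref, ref_anchor1 = 11L), 1.0)
  # flip every flank residue to polar: 0.0
  qry <- paste0("NNNNN", "STSTS", "DEGRH", "TSTST", "NNNNN")
  expect_equal(confirm_group(qry, ref, ref_anchor1 = 11L), 0.0)
  # single flip among the 10 flank positions: 0.9
  qry1 <- paste0("NNNNN", "SLVLV", "DEGRH", "LVLVL", "NNNNN")
  expect_equal(confirm_group(qry1, ref, ref_anchor1 = 11L), 0.9)
  # gapped motif region: undefined, flagged
  qry2 <- paste0("NNNNN", "VLVLV", "LVLVL", "NNNNN")
  sc <- confirm_group(qry2, ref, ref_anchor1 = 11L)
  expect_true(is.na(sc))
  expect_true(attr(sc, "flagged"))
})

test_that("select_representative applies the abundance/motif override", {
  out <- select_representative(
    c("A", "B"), abundances = c(A = 5, B = 3),
    motif1_states = c(A = "gap", B = "present"))
  expect_identical(out$representative_id, "B")
  expect_identical(out$skipped$id, "A")
  expect_match(out$skipped$reason, "motif1 gap")
  expect_false(out$flagged)

  one <- select_representative("Z", c(Z = 1), c(Z = "present"))
  expect_identical(one$representative_id, "Z")

  allgap <- select_representative(
    c("A", "B"), c(A = 5, B = 3), c(A = "gap", B = "gap"))
  expect_identical(allgap$representative_id, "A")
  expect_true(allgap$flagged)

  # invariant: no skipped member is both more abundant and motif1-present
  set.seed(6)
  for (i in 1:20) {
    n <- sample(2:6, 1L)
    ids <- paste0("m", seq_len(n))
    ab <- setNames(round(runif(n, 0, 10), 3), ids)
    st <- setNames(sample(c("present", "gap", "absent"), n, TRUE), ids)
    r <- select_representative(ids, ab, st)
    if (!r$flagged) {
      expect_true(all(st[r$skipped$id] != "present"))
      expect_identical(st[[r$representative_id]], "present")
    }
  }
})
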