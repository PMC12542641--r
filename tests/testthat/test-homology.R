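test_that("align_local matches direct matrix lookups on trivial cases", {
  mat <- .oracle_blosum()
  aln <- align_local("ACDE", "ACDE")
  expect_equal(aln$score,
               mat["A", "A"] + mat["C", "C"] + mat["D", "D"] + mat["E", "E"])
  st <- hit_stats(aln)
  expect_equal(st$pident, 100)
  expect_equal(st$qcov, 100)

  # all-vs-nothing pair: empty, zero-score local alignment
  aln0 <- align_local("AAAA", "CCCC")
  expect_equal(aln0$score, 0)
  expect_identical(nchar(aln0$q_aln), 0L)

  expect_error(align_local("", "ACDE"), "empty")
  expect_error(align_local("ACDE", "ACDE", gap_open = 1, gap_extend = 2),
               "gap_open")
})

test_that("self-alignment of random proteins gives pident 100, qcov 100", {
  set.seed(5)
  for (i in 1:10) {
    x <- random_protein(sample(60:200, 1L))
    st <- hit_stats(align_local(x, x))
    expect_equal(st$pident, 100)
    expect_equal(st$qcov, 100)
  }
})

test_that("align_local score is symmetric and matches the DP oracle", {
  set.seed(11)
  for (i in 1:50) {
    a <- random_protein(sample(8:30, 1L))
    b <- random_protein(sample(8:30, 1L))
    s_ab <- align_local(a, b)$score
    expect_equal(s_ab, align_local(b, a)$score)
    expect_equal(s_ab, sw_oracle(a, b))
  }
  # including X, which scores 0 against everything
  sx <- align_local("ACXDE", "ACWDE")
  expect_equal(sx$score, sw_oracle("ACXDE", "ACWDE"))
})

test_that("hit_stats applies the identity and coverage formulas", {
  # fabricated alignment: 100 columns, 92 identical, query span 65 of 100
  q <- paste(c(rep("A", 92), rep("C", 8)), collapse = "")
  fake <- structure(list(score = 1, q_aln = q,
                         r_aln = paste(c(rep("A", 92), rep("W", 8)),
                                       collapse = ""),
                         q_start = 1L, q_end = 65L, r_start = 1L,
                         r_end = 100L, query_len = 100L, ref_len = 100L),
                    class = "tm_alignment")
  st <- hit_stats(fake, query_len = 100L)
  expect_equal(st$pident, 92)
  expect_equal(st$qcov, 65)

  # 10 gap columns count in alen, never as identities: 90/100 -> 90%
  qg <- paste(c(rep("A", 90), rep("-", 10)), collapse = "")
  rg <- paste(rep("A", 100), collapse = "")
  fake$q_aln <- qg; fake$r_aln <- rg
  # independent recount by a column walk
  cols <- strsplit(qg, "")[[1L]] == strsplit(rg, "")[[1L]] &
    strsplit(qg, "")[[1L]] != "-"
  expect_equal(hit_stats(fake, 100L)$pident, 100 * sum(cols) / 100)
  expect_equal(hit_stats(fake, 100L)$pident, 90)

  expect_error(hit_stats(fake, query_len = 10L), "smaller than")
})

test_that("screen_panel finds planted homologs and rejects decoys", {
  panel <- synthetic_panel()
  set.seed(21)
  planted <- mutate_to_identity(panel$proteins[["CDDP3"]], 95)$seq
  hits <- screen_panel(c(q1 = planted), panel)
  expect_identical(hits$reference_id[hits$best], "CDDP3")

  # empty query set
  expect_identical(nrow(screen_panel(setNames(character(0), character(0)),
                                     panel)), 0L)

  # 100 composition-shuffled decoys: none retained
  decoys <- vapply(1:100, function(i) {
    src <- sample(panel$proteins, 1L)
    paste(sample(strsplit(src, "")[[1L]]), collapse = "")
  }, character(1))
  names(decoys) <- paste0("d", 1:100)
  expect_identical(nrow(screen_panel(decoys, panel)), 0L)
})

test_that("screen_panel ingests tabular hits with the e-value gate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("q1", "r1", "95.0", "130", "5", "0", "1", "130", "1", "130",
          "1e-60", "250", sep = "\t"),
    paste("q1", "r2", "99.0", "130", "1", "0", "1", "130", "1", "130",
          "1e-20", "300", sep = "\t")), f)
  tab <- read_tabular_hits(f)
  hits <- screen_panel(c(q1 = random_protein(200L)),
                       c(r1 = random_protein(200L)),
                       hits = tab, evalue_max = 1e-50)
  expect_identical(nrow(hits), 1L)          # 1e-20 fails the gate
  expect_identical(hits$reference_id, "r1")
  expect_equal(hits$qcov, 100 * 130 / 200)
})
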