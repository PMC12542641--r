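test_that("read_fasta parses records, truncates ids, keeps descriptions", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a first protein", "ACDE", ">b", "MKLV", "WYX"), f)
  x <- read_fasta(f, "protein")
  expect_identical(names(x), c("a", "b"))
  expect_equal(unname(x), c("ACDE", "MKLVWYX"), ignore_attr = TRUE)
  expect_identical(attr(x, "description"), c("a first protein", "b"))
})

test_that("read_fasta errors and degenerate cases follow the contract", {
  dup <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "ACDE", ">a", "MKLV"), dup)
  expect_error(read_fasta(dup, "protein"), "duplicate id.*a")

  empty <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), empty)
  expect_warning(x <- read_fasta(empty, "protein"), "empty")
  expect_length(x, 0L)

  bad <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "ACDE", ">b", "ACGJ"), bad)
  expect_error(read_fasta(bad, "protein"), "illegal character 'J'.*line 4")
  expect_error(read_fasta(bad, "dna"), "illegal character")
})

test_that("fasta read/write round-trips 100+ random records", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 12L
    seqs <- vapply(seq_len(n), function(i)
      random_protein(sample(50:120, 1L)), character(1))
    names(seqs) <- paste0("rec", rep, "_", seq_len(n))
    f <- tempfile(fileext = ".faa")
    write_fasta(seqs, f)
    back <- read_fasta(f, "protein")
    expect_equal(unname(back), unname(seqs), ignore_attr = TRUE)
    expect_identical(names(back), names(seqs))
    unlink(f)
  }
  # dna too
  dna <- setNames(vapply(1:10, function(i) random_dna(200L), character(1)),
                  paste0("c", 1:10))
  f <- withr::local_tempfile(fileext = ".fna")
  write_fasta(dna, f)
  expect_equal(unname(read_fasta(f, "dna")), unname(dna),
               ignore_attr = TRUE)
})

test_that("read_tabular_hits parses the 12-column dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "r1", "92.0", "130", "10", "1", "1", "130", "1",
                   "130", "1e-60", "250", sep = "\t"), f)
  h <- read_tabular_hits(f)
  expect_equal(h$pident, 92.0)
  expect_equal(h$alen, 130L)
  expect_equal(h$evalue, 1e-60)
  expect_true(is.na(h$qcov))

  writeLines(character(0), f)
  expect_identical(nrow(read_tabular_hits(f)), 0L)

  writeLines(paste(letters[1:11], collapse = "\t"), f)
  expect_error(read_tabular_hits(f), "line 1.*12.*columns.*11")
})

test_that("newick read/write round-trips and validates", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  write_newick(tr, f)
  once <- readLines(f)
  write_newick(read_newick(f), f)
  expect_identical(readLines(f), once)

  writeLines("A;", f)
  leaf <- read_newick(f)
  expect_identical(leaf$tip.label, "A")

  writeLines("((A,B", f)
  expect_error(read_newick(f), "unbalanced parentheses")
})

test_that("newick round-trip preserves topology and branch lengths", {
  set.seed(7)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:12, 1L))
    tr$edge.length <- round(tr$edge.length, 6L)
    f <- tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
    unlink(f)
  }
})

test_that("feature/counts/votes tables validate their contracts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(contig_id = "c1", gene_id = "g1", start = 10L,
                   end = 5L, strand = "+", product_id = "g1")
  write_features(df, f)
  expect_error(read_features(f), "start <= end")
  df$end <- 50L; df$strand <- "*"
  write_features(df, f)
  expect_error(read_features(f), "strand")
  df$strand <- "-"
  write_features(df, f)
  expect_identical(read_features(f)$end, 50L)

  cf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcontig_id\tcount", "S1\tc1\t-3"), cf)
  expect_error(read_counts(cf), "negative")
  writeLines(c("sample_id\ttotal_mapped", "S1\t0"), cf)
  expect_error(read_totals(cf), "positive")

  vf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tannotator\tannotation\tevalue",
               "g1\tblastp\ttransposase\t1e-10",
               "g1\trast\ttransposase\t"), vf)
  v <- read_votes(vf)
  expect_identical(nrow(v), 2L)
  expect_true(is.na(v$evalue[2L]))
})
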