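test_that("annotation labels are normalized for exact-match voting", {
  expect_identical(normalize_annotation("  IS5-family Transposase "),
                   "is5 family transposase")
  expect_true(is.na(normalize_annotation("hypothetical protein")))
  expect_true(is.na(normalize_annotation("Unknown")))
  expect_true(is.na(normalize_annotation("")))
  expect_true(is.na(normalize_annotation(NA_character_)))
})

test_that("consensus_annotation applies the three-branch rule", {
  v <- function(ann, src, ev = NA_real_) {
    data.frame(gene_id = "g1", annotator = src, annotation = ann,
               evalue = ev, stringsAsFactors = FALSE)
  }
  # two sources agree -> consensus
  votes <- rbind(v("Transposase", "dram"), v("transposase", "rast"),
                 v("hypothetical protein", "pfam"))
  cc <- consensus_annotation(votes)
  expect_identical(cc$label, "transposase")
  expect_identical(cc$status, "consensus")

  # all distinct, homology vote below the gate -> putative
  votes2 <- rbind(v("integrase", "blastp", 1e-10), v("recombinase", "rast"),
                  v("helicase", "dram"))
  cc2 <- consensus_annotation(votes2)
  expect_identical(cc2$label, "putative integrase")
  expect_identical(cc2$status, "putative")

  # no votes at all -> hypothetical
  cc3 <- consensus_annotation(votes2[0, ])
  expect_identical(cc3$status, "hypothetical")

  # homology vote above the gate cannot rescue
  votes4 <- rbind(v("integrase", "blastp", 1e-3), v("recombinase", "rast"))
  expect_identical(consensus_annotation(votes4)$status, "hypothetical")

  # the homology source votes with its lowest-e-value annotated hit and
  # can complete a consensus
  votes5 <- rbind(v("hypothetical protein", "blastp", 1e-80),
                  v("integrase", "blastp", 1e-40),
                  v("zeta toxin", "blastp", 1e-30),
                  v("integrase", "kegg"))
  cc5 <- consensus_annotation(votes5)
  expect_identical(cc5$label, "integrase")
  expect_identical(cc5$status, "consensus")
})

test_that("consensus_annotation is order-invariant in its votes", {
  set.seed(9)
  votes <- data.frame(
    gene_id = "g", annotator = c("dram", "rast", "kegg", "pfam", "blastp"),
    annotation = c("kinase", "transporter", "kinase", NA, "permease"),
    evalue = c(NA, NA, NA, NA, 1e-12), stringsAsFactors = FALSE)
  ref <- consensus_annotation(votes)
  for (i in 1:5) {
    perm <- votes[sample(nrow(votes)), ]
    expect_identical(consensus_annotation(perm), ref)
  }
})

test_that("check_operon_order is strand-aware and reports partial contigs", {
  feats <- function(roles, strand = "+", starts = NULL) {
    n <- length(roles)
    if (is.null(starts)) starts <- seq(1L, by = 1000L, length.out = n)
    data.frame(contig_id = "c1", gene_id = paste0("g", seq_len(n)),
               start = starts, end = starts + 500L, strand = strand,
               product_id = paste0("g", seq_len(n)),
               stringsAsFactors = FALSE)
  }
  lab <- function(roles) setNames(roles, paste0("g", seq_along(roles)))

  ok <- check_operon_order(feats(c("alpha", "reductase", "beta", "coupling")),
                           lab(c("alpha", "reductase", "beta", "coupling")))
  expect_true(ok$conforms)

  bad <- check_operon_order(feats(c("alpha", "beta", "reductase", "coupling")),
                            lab(c("alpha", "beta", "reductase", "coupling")))
  expect_false(bad$conforms)

  part <- check_operon_order(feats(c("alpha", "reductase")),
                             lab(c("alpha", "reductase")))
  expect_true(is.na(part$conforms))
  expect_setequal(part$missing, c("beta", "coupling"))

  dup <- check_operon_order(feats(c("alpha", "alpha")),
                            lab(c("alpha", "alpha")))
  expect_false(dup$conforms)
  expect_identical(dup$duplicated, "alpha")

  # reverse-strand operon: genes laid right-to-left conform when read
  # along the strand
  rev <- check_operon_order(
    feats(c("coupling", "beta", "reductase", "alpha"), strand = "-"),
    lab(c("coupling", "beta", "reductase", "alpha")))
  expect_true(rev$conforms)
})

test_that("reverse-complementing a contig preserves the operon verdict", {
  panel <- synthetic_panel()
  cfg <- simulation_config(seed = 21, n_samples = 1L,
                           n_contigs_per_sample = 0L,
                           planted_operons = list(plant_spec("CDDP1", 95)))
  sim <- simulate_metagenome(cfg, panel)
  f <- sim$features
  lab <- setNames(sim$truth$role, sim$truth$gene_id)
  v1 <- check_operon_order(f, lab)$conforms
  # re-coordinate features onto the reverse complement
  L <- nchar(sim$contigs[[f$contig_id[1L]]])
  f2 <- f
  f2$start <- L - f$end + 1L
  f2$end <- L - f$start + 1L
  f2$strand <- ifelse(f$strand == "+", "-", "+")
  v2 <- check_operon_order(f2, lab)$conforms
  expect_identical(v1, v2)
  expect_true(v1)
})

test_that("find_itr detects terminal reverse-complement structures", {
  set.seed(33)
  gene <- random_dna(400L)
  mid <- random_dna(1000L)
  contig <- paste0(gene, mid, oracle_revcomp(gene))
  feats <- data.frame(
    contig_id = "c1", gene_id = c("g1", "g2"),
    start = c(1L, 1401L), end = c(400L, 1800L),
    strand = c("+", "-"), product_id = c("g1", "g2"),
    stringsAsFactors = FALSE)
  hit <- find_itr(contig, feats, min_len = 100L)
  expect_true("terminal_gene_pair" %in% hit$type)
  expect_true("terminal_repeat" %in% hit$type)
  expect_equal(hit$length_bp[hit$type == "terminal_repeat"], 400L)

  none <- find_itr(paste0(random_dna(500L), random_dna(500L)),
                   feats, min_len = 100L)
  expect_false("terminal_repeat" %in% none$type)
})

test_that("find_terminal_overlaps reports exact end matches only", {
  set.seed(44)
  block <- random_dna(127L)
  a <- paste0(random_dna(800L), block)
  b <- paste0(block, random_dna(700L))
  ov <- find_terminal_overlaps(c(a = a, b = b), min_len = 100L)
  expect_identical(nrow(ov), 1L)
  expect_equal(ov$length_bp, 127L)
  expect_identical(ov$a_end, "3'")
  expect_identical(ov$b_end, "5'")
  expect_equal(ov$identity, 1.0)

  short <- random_dna(50L)
  a2 <- paste0(random_dna(500L), short)
  b2 <- paste0(short, random_dna(500L))
  expect_identical(
    nrow(find_terminal_overlaps(c(a = a2, b = b2), min_len = 100L)), 0L)

  expect_error(find_terminal_overlaps(c(a = a), min_len = 100L),
               "at least 2")
})

test_that("find_terminal_overlaps agrees with the quadratic oracle", {
  set.seed(55)
  for (i in 1:8) {
    min_len <- 30L
    block <- random_dna(sample(30:150, 1L))
    combo <- sample(4L, 1L)
    x <- random_dna(sample(300:900, 1L))
    y <- random_dna(sample(300:900, 1L))
    if (combo == 1L) { a <- paste0(x, block); b <- paste0(block, y) }
    if (combo == 2L) { a <- paste0(block, x); b <- paste0(y, block) }
    if (combo == 3L) { a <- paste0(x, block)
                       b <- paste0(y, oracle_revcomp(block)) }
    if (combo == 4L) { a <- paste0(block, x)
                       b <- paste0(oracle_revcomp(block), y) }
    got <- find_terminal_overlaps(c(a = a, b = b), min_len = min_len)
    want <- brute_overlaps(a, b, min_len)
    expect_identical(nrow(got), length(want))
    key <- paste(got$a_end, got$b_end, sep = "/")
    expect_setequal(key, names(want))
    expect_identical(as.integer(got$length_bp[match(names(want), key)]),
                     as.integer(want))
  }
})
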