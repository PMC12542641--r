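# Independent oracles used by the test suite. These deliberately share no
# code with the package: the aligner oracle is a plain iterative affine-gap
# DP, the overlap oracle scans all offsets, and the clustering oracle
# replays the greedy scan from its definition.

.oracle_blosum <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

# Smith-Waterman with affine gaps (gap of length k costs open + k * extend),
# returning the optimal local score (0 if nothing positive).
sw_oracle <- function(q, r, gap_open = 11, gap_extend = 1,
                      mat = .oracle_blosum()) {
  qs <- strsplit(q, "", fixed = TRUE)[[1L]]
  rs <- strsplit(r, "", fixed = TRUE)[[1L]]
  n <- length(qs); m <- length(rs)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in a gap in r (consumes q)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in a gap in q (consumes r)
  M[1L, ] <- M[, 1L] <- 0
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[qs[i], rs[j]]
      M[i + 1L, j + 1L] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                               X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                               Y[i + 1L, j] - gap_extend)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

random_protein <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1L]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# quadratic all-offsets scanner: longest exact terminal overlap >= min_len
# for each of the four end combinations of an (a, b) contig pair
brute_overlaps <- function(a, b, min_len) {
  lsp <- function(x, y) {     # longest k: suffix_k(x) == prefix_k(y)
    nx <- nchar(x)
    best <- 0L
    for (k in seq_len(min(nx, nchar(y)))) {
      if (substr(x, nx - k + 1L, nx) == substr(y, 1L, k)) best <- k
    }
    best
  }
  rb <- oracle_revcomp(b)
  res <- c(`3'/5'` = lsp(a, b), `5'/3'` = lsp(b, a),
           `3'/3'` = lsp(a, rb), `5'/5'` = lsp(rb, a))
  res[res >= min_len]
}

# replay the greedy clustering definition: length-descending (id ascending)
# scan, join the first cluster whose representative matches at >= c (and
# coverage >= aS when set), identity/coverage recomputed with the package's
# pairwise definition
replay_greedy <- function(seqs, c, aS = NULL, space = "protein") {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  assign <- character(length(seqs))
  names(assign) <- names(seqs)
  reps <- character(0)
  for (i in seq_along(seqs)) {
    placed <- NA_character_
    for (rid in reps) {
      st <- tierminer::seq_identity(seqs[[rid]], seqs[[i]], space = space)
      if (st$identity >= c && (is.null(aS) || st$coverage_short >= aS)) {
        placed <- rid
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, names(seqs)[i])
      placed <- names(seqs)[i]
    }
    assign[names(seqs)[i]] <- placed
  }
  assign
}

# a random additive distance matrix from a random tree with positive
# branch lengths, plus the generating topology
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# family of sequences radiating from a centre at given divergence fractions
radiating_family <- function(centre_len = 200L,
                             divergences = c(0, 0.02, 0.02, 0.04, 0.04,
                                             0.08, 0.08)) {
  centre <- random_protein(centre_len)
  seqs <- vapply(divergences, function(f) {
    if (f == 0) return(centre)
    tierminer::mutate_to_identity(centre, 100 * (1 - f),
                                  protected = integer(0))$seq
  }, character(1))
  names(seqs) <- sprintf("fam%02d", seq_along(seqs))
  seqs
}

# ---- shared recovery-run configuration (acceptance criterion 5) ----

# ~30 planted operons over 4 samples spanning SDIMO groups I-VI and both
# tier windows at boundary-safe identities (>= 92 or <= 85), plus two
# motif-ablated plants, two ITR plants and one 127-bp overlap pair
recovery_plants <- function() {
  t1 <- list(
    c("CDDP1", 97), c("CDDP3", 95), c("CDDP4", 93), c("CDDP5", 92),
    c("CDDP6", 97), c("COMP11", 95), c("OUT5", 93), c("OUT1", 92),
    c("COMP9", 97), c("CDDP8", 95), c("OUT4", 93), c("COMPOUT5", 92))
  t2 <- list(
    c("CDDP1", 85), c("CDDP3", 80), c("CDDP4", 70), c("CDDP6", 55),
    c("COMP11", 85), c("OUT5", 70), c("CDDP5", 80), c("OUT8", 85),
    c("CDDP8", 70), c("OUT2", 55), c("COMP9", 85), c("CDDP7", 80))
  none <- list(c("CDDP1", 40), c("OUT1", 40))
  plants <- c(
    lapply(t1, function(x) plant_spec(x[1L], as.numeric(x[2L]))),
    lapply(t2, function(x) plant_spec(x[1L], as.numeric(x[2L]))),
    lapply(none, function(x) plant_spec(x[1L], as.numeric(x[2L]))),
    list(plant_spec("CDDP1", 95, ablate_first_motif = TRUE,
                    ablate_second_motif = TRUE),
         plant_spec("CDDP2", 95, ablate_first_motif = TRUE,
                    ablate_second_motif = TRUE)))
  plants[[1L]]$add_terminal_itr <- TRUE
  plants[[5L]]$add_terminal_itr <- TRUE
  plants[[2L]]$paired_overlap_len <- 127L
  plants
}

# run the full pipeline on one simulated metagenome and score it against
# the planted truth
recovery_run <- function(seed) {
  panel <- synthetic_panel()
  cfg <- simulation_config(seed = seed, n_samples = 4L,
                           n_contigs_per_sample = 2L,
                           planted_operons = recovery_plants())
  sim <- simulate_metagenome(cfg, panel)
  res <- sdimo_pipeline(sim$proteins, sim$contigs, sim$features, sim$counts,
                        sim$totals, panel = panel,
                        contig_origin = sim$contig_origin,
                        do_ladder = FALSE)
  truth <- sim$truth[sim$truth$role == "alpha", ]
  got_tier <- ifelse(truth$gene_id %in% res$gate$tier1$query_id, "1",
              ifelse(truth$gene_id %in% res$gate$tier2$query_id, "2",
                     "none"))
  group_of <- c(setNames(res$clade_calls$group, res$clade_calls$query_id),
                if (!is.null(res$tier2_calls))
                  setNames(res$tier2_calls$group, res$tier2_calls$query_id))
  call_of <- setNames(res$clade_calls$call, res$clade_calls$query_id)
  classified <- truth$gene_id[got_tier != "none" &
                                truth$gene_id %in% names(group_of)]
  t1_ids <- truth$gene_id[got_tier == "1"]
  ablated <- truth$gene_id[!truth$motif1_intact & !truth$motif2_intact]
  itr_contigs <- unique(sim$features$contig_id[
    sim$features$gene_id %in%
      sim$truth$gene_id[sim$truth$role == "transposase"]])
  counts_ok <- all(tapply(sim$counts$count, sim$counts$sample_id, sum) <=
                     setNames(sim$totals$total_mapped, sim$totals$sample_id))
  list(
    truth = truth, res = res, sim = sim,
    tier_ok = got_tier == truth$expected_tier,
    n_classified = length(classified),
    group_ok = group_of[classified] ==
      truth$group[match(classified, truth$gene_id)],
    n_tier1 = length(t1_ids),
    label_ok = call_of[t1_ids] ==
      truth$dioxane_label[match(t1_ids, truth$gene_id)],
    ablated_in_tier1 = sum(ablated %in% res$gate$tier1$query_id),
    itr_detected = !is.null(res$itr) &&
      all(itr_contigs %in% res$itr$contig_id[
        res$itr$type == "terminal_gene_pair"]),
    overlap_lengths = if (!is.null(res$overlaps)) {
      ot <- sim$overlap_truth
      res$overlaps$length_bp[
        res$overlaps$contig_a %in% ot$contig_a &
          res$overlaps$contig_b %in% ot$contig_b]
    } else integer(0),
    counts_ok = counts_ok)
}
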