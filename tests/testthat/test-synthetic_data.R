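test_that("mutate_to_identity controls realized identity exactly", {
  set.seed(3)
  p <- random_protein(200L)

  m <- mutate_to_identity(p, 100, protected = integer(0), seed = 1)
  expect_identical(m$seq, p)
  expect_equal(m$realized_identity, 100)

  m <- mutate_to_identity(p, 90, protected = integer(0), seed = 7)
  expect_length(m$positions, 20L)
  expect_equal(m$realized_identity, 90)
  # oracle: direct positional (hamming) identity recount
  ham <- mean(strsplit(p, "")[[1L]] == strsplit(m$seq, "")[[1L]])
  expect_equal(100 * ham, 90)

  m <- mutate_to_identity(p, 50, protected = integer(0), seed = 11)
  ham <- 100 * mean(strsplit(p, "")[[1L]] == strsplit(m$seq, "")[[1L]])
  expect_gte(ham, 48); expect_lte(ham, 52)
  expect_equal(m$realized_identity, ham)
})

test_that("mutate_to_identity validates inputs and reachability", {
  p <- random_protein(60L)
  expect_error(mutate_to_identity(random_protein(40L), 90), "too short")
  expect_error(mutate_to_identity(p, 0), "target_identity")
  expect_error(mutate_to_identity(p, 101), "target_identity")
  # protect almost everything: a 50% target becomes unreachable
  expect_error(
    mutate_to_identity(p, 50, protected = seq_len(55L), seed = 1),
    "unreachable")
})

test_that("ablation is forced into the motif and flips the expected tier", {
  panel <- synthetic_panel()
  cfg <- simulation_config(
    seed = 5, n_samples = 1L, n_contigs_per_sample = 0L,
    planted_operons = list(
      plant_spec("CDDP1", 95, ablate_first_motif = TRUE,
                 ablate_second_motif = TRUE),
      plant_spec("CDDP1", 95)))
  sim <- simulate_metagenome(cfg, panel)
  tr <- sim$truth[sim$truth$role == "alpha", ]
  expect_setequal(tr$expected_tier, c("none", "1"))
  abl <- tr[tr$expected_tier == "none", ]
  expect_false(abl$motif1_intact); expect_false(abl$motif2_intact)
  # the ablated protein has no intact motif near the anchors
  seq <- sim$proteins[[abl$gene_id]]
  expect_false(grepl("DE.RH", seq))
})

test_that("simulate_metagenome is byte-identical under a fixed seed", {
  panel <- synthetic_panel()
  cfg <- simulation_config(
    seed = 1, n_samples = 2L, n_contigs_per_sample = 1L,
    planted_operons = list(plant_spec("CDDP1", 95),
                           plant_spec("OUT5", 70)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_metagenome(cfg, panel, outdir = d1)
  simulate_metagenome(cfg, panel, outdir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("planted operons have the four subunits in order with truth", {
  panel <- synthetic_panel()
  cfg <- simulation_config(seed = 2, n_samples = 2L,
                           n_contigs_per_sample = 0L,
                           planted_operons = list(plant_spec("CDDP1", 95)))
  sim <- simulate_metagenome(cfg, panel)
  tr <- sim$truth
  expect_identical(tr$role, c("alpha", "reductase", "beta", "coupling"))
  f <- sim$features[match(tr$gene_id, sim$features$gene_id), ]
  expect_true(all(diff(f$start) > 0))        # emitted left to right
  expect_identical(tr$expected_tier[1L], "1")
  expect_true(all(tr$contig_id == tr$contig_id[1L]))
  # plant realized exactly once, in sample 1 (round-robin)
  expect_identical(unique(tr$sample), 1L)
})

test_that("count tables respect the totals invariant across seeds", {
  panel <- synthetic_panel()
  for (seed in c(3, 17, 23)) {
    cfg <- simulation_config(seed = seed, n_samples = 3L,
                             n_contigs_per_sample = 2L,
                             planted_operons = list(plant_spec("CDDP3", 92)))
    sim <- simulate_metagenome(cfg, panel)
    sums <- tapply(sim$counts$count, sim$counts$sample_id, sum)
    tot <- setNames(sim$totals$total_mapped, sim$totals$sample_id)
    expect_true(all(sums <= tot[names(sums)]))
    expect_true(all(sim$counts$contig_id %in% names(sim$contigs)))
  }
})

test_that("paired overlap contigs share an exactly L-bp terminal block", {
  panel <- synthetic_panel()
  cfg <- simulation_config(
    seed = 9, n_samples = 1L, n_contigs_per_sample = 0L,
    planted_operons = list(plant_spec("CDDP1", 95,
                                      paired_overlap_len = 127L)))
  sim <- simulate_metagenome(cfg, panel)
  ot <- sim$overlap_truth
  a <- sim$contigs[[ot$contig_a]]; b <- sim$contigs[[ot$contig_b]]
  expect_identical(substr(a, nchar(a) - 126L, nchar(a)),
                   substr(b, 1L, 127L))
  # and not one base longer
  expect_false(substr(a, nchar(a) - 127L, nchar(a)) ==
                 substr(b, 1L, 128L))
})
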