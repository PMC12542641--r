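# End-to-end orchestration: screen -> tier -> dereplicate -> classify ->
# abundance -> ladder -> neighborhood, with one config, one log and
# machine-readable outputs. Deterministic given its inputs (no RNG is used
# after simulation).

# infer each contig's assembly sample from the id prefix (S<k>_...) used by
# the simulator, unless an explicit mapping is given
.infer_origin <- function(contig_ids, sample_ids) {
  pre <- sub("_.*$", "", contig_ids)
  if (!all(pre %in% sample_ids)) {
    stop("cannot infer contig origin samples from contig ids; ",
         "pass contig_origin explicitly")
  }
  setNames(pre, contig_ids)
}

#' Run the full SDIMO discovery pipeline on in-memory inputs
#'
#' Screens every predicted protein against the reference panel, validates
#' DE*RH motifs positionally through the best-hit alignment, gates
#' candidates into contig-exclusive Tiers 1 and 2, dereplicates Tier-1 (and
#' optionally Tier-2) contigs, builds a neighbor-joining tree of the
#' non-redundant Tier-1 proteins with the panel, roots it with the group V
#' outgroup entries, calls dioxane-degrader vs outgroup clades and SDIMO
#' groups, aggregates origin-sample RPKM per clade and sample, selects
#' clade representatives (motif-1-intact, most abundant), and analyses gene
#' neighborhoods (operon order when subunit roles are supplied, inverted
#' terminal repeats, terminal contig overlaps).
#'
#' @param proteins named character vector of predicted proteins.
#' @param contigs named character vector of contigs.
#' @param features gene feature table (see [read_features()]).
#' @param counts,totals count tables (see [read_counts()]).
#' @param panel a `tm_panel`.
#' @param contig_origin named vector contig_id -> assembly sample; inferred
#'   from contig id prefixes when NULL.
#' @param thresholds a [tier_thresholds()].
#' @param derep_c,derep_aS dereplication clustering parameters.
#' @param hits optional precomputed tabular hits (see
#'   [read_tabular_hits()]); computed in-repo when NULL.
#' @param score_floor screen retention floor (see [screen_panel()]).
#' @param classify_tier2 also dereplicate and group-classify Tier-2
#'   candidates on their own tree.
#' @param do_ladder run the identity-ladder analysis (protein and
#'   nucleotide space) on the non-redundant Tier-1 set.
#' @param subunit_labels optional named vector gene_id -> subunit role for
#'   the operon-order check.
#' @param min_overlap_len minimum terminal-overlap / ITR length.
#' @param outgroup_group SDIMO group whose OUT/COMPOUT panel entries root
#'   the tree.
#' @param outdir optional output directory (tiers.tsv, clusters.tsv,
#'   cladecalls.tsv, clade_matrix.tsv, table1.tsv, neighborhood outputs,
#'   tree.nwk, log.txt).
#' @return list with `hits`, `candidates`, `gate` (tier lists), `derep`,
#'   `tree`, `clade_calls`, `abundance`, `clade_matrix`,
#'   `representatives`, `ladder`, `tier2_calls`, `itr`, `overlaps`,
#'   `operons`, `log`.
#' @export
sdimo_pipeline <- function(proteins, contigs, features, counts, totals,
                           panel = synthetic_panel(), contig_origin = NULL,
                           thresholds = tier_thresholds(),
                           derep_c = 0.999, derep_aS = 0.999,
                           hits = NULL, score_floor = 1.0,
                           classify_tier2 = TRUE, do_ladder = TRUE,
                           subunit_labels = NULL, min_overlap_len = 100L,
                           outgroup_group = "V", outdir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  if (is.null(contig_origin)) {
    contig_origin <- .infer_origin(names(contigs), totals$sample_id)
  }
  gene2contig <- setNames(features$contig_id, features$product_id)

  hits <- screen_panel(proteins, panel, evalue_max = thresholds$evalue_max,
                       hits = hits, score_floor = score_floor)
  note("screen: ", nrow(hits), " retained hits for ",
       length(unique(hits$query_id)), " queries")

  best <- hits[hits$best, , drop = FALSE]
  cand <- vector("list", nrow(best))
  if (nrow(best)) {
    for (i in seq_len(nrow(best))) {
      q <- best$query_id[i]; r <- best$reference_id[i]
      aln <- align_local(proteins[[q]], panel$proteins[[r]])
      lb <- panel$labels[panel$labels$id == r, ]
      mot <- detect_motifs(proteins[[q]], aln,
                           anchors = c(lb$motif1_anchor, lb$motif2_anchor))
      ctg <- unname(gene2contig[q])
      cand[[i]] <- data.frame(
        query_id = q, contig_id = ctg,
        sample_id = unname(contig_origin[ctg]),
        reference_id = r, pident = best$pident[i], alen = best$alen[i],
        qcov = best$qcov[i], score = best$score[i],
        motif1 = mot$motif1$state, motif2 = mot$motif2$state,
        stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(query_id = character(0), contig_id = character(0),
               sample_id = character(0), reference_id = character(0),
               pident = numeric(0), alen = integer(0), qcov = numeric(0),
               score = numeric(0), motif1 = character(0),
               motif2 = character(0), stringsAsFactors = FALSE)

  pps <- table(factor(unname(contig_origin[features$contig_id]),
                      levels = totals$sample_id))
  gt <- gate(candidates, thresholds,
             proteins_per_sample = setNames(as.numeric(pps), names(pps)))
  note("gate: ", nrow(gt$tier1), " tier-1, ", nrow(gt$tier2),
       " tier-2 candidates (", nrow(gt$excluded),
       " excluded by contig exclusivity)")

  res <- list(hits = hits, candidates = candidates, gate = gt,
              contig_origin = contig_origin)

  # abundance for every counted contig
  contig_lengths <- setNames(nchar(contigs), names(contigs))
  res$abundance <- compute_abundance(counts, totals, contig_lengths,
                                     contig_origin)

  # --- Tier 1: dereplicate, tree, clades, clade matrix, representatives ---
  t1 <- gt$tier1
  if (nrow(t1) > 0L) {
    derep <- dereplicate_contigs(contigs[unique(t1$contig_id)],
                                 c = derep_c, aS = derep_aS)
    res$derep <- derep
    note("dereplication: ", length(unique(t1$contig_id)), " tier-1 contigs -> ",
         length(derep$representatives), " non-redundant")
    rep_contigs <- names(derep$representatives)
    nonred <- t1[t1$contig_id %in% rep_contigs, , drop = FALSE]
    res$nonredundant_tier1 <- nonred

    if (nrow(nonred) >= 1L) {
      tree_seqs <- c(proteins[nonred$query_id], panel$proteins)
      if (length(tree_seqs) >= 3L) {
        tree <- nj_tree(pdistance_matrix(tree_seqs))
        outg <- intersect(panel_outgroup_ids(panel, outgroup_group),
                          tree$tip.label)
        tree <- root_by_outgroup(tree, outg,
                                 ignore_ids = nonred$query_id)
        res$tree <- tree
        res$clade_calls <- call_clades(tree, panel$labels)
        note("clades: ", length(unique(res$clade_calls$clade_id)),
             " clades over ", nrow(res$clade_calls), " queries")
      }
    }

    if (!is.null(res$clade_calls)) {
      # members inherit the clade of the tier-1 query on their contig's
      # dereplication representative
      rep_of <- setNames(derep$mapping$representative_id,
                         derep$mapping$member_id)
      contig_query <- setNames(nonred$query_id, nonred$contig_id)
      clade_of <- setNames(
        unname(contig_query[unname(rep_of[t1$contig_id])]), t1$query_id)
      res$clade_of <- clade_of
      res$clade_matrix <- clade_matrix(t1, res$clade_calls, res$abundance,
                                       clade_of = clade_of)

      # representative per clade: most abundant member with motif1 present
      ab <- res$abundance[res$abundance$origin_sample, ]
      member_rpkm <- setNames(
        ab$rpkm[match(t1$contig_id, ab$contig_id)], t1$query_id)
      m1 <- setNames(t1$motif1, t1$query_id)
      calls_by_query <- res$clade_calls$clade_id[
        match(unname(clade_of[t1$query_id]), res$clade_calls$query_id)]
      reps <- lapply(split(t1$query_id, calls_by_query), function(m)
        select_representative(m, member_rpkm, m1))
      res$representatives <- data.frame(
        clade_id = as.integer(names(reps)),
        representative_id = vapply(reps, `[[`, character(1),
                                   "representative_id"),
        abundance_rpkm = vapply(reps, `[[`, numeric(1), "abundance_rpkm"),
        flagged = vapply(reps, `[[`, logical(1), "flagged"),
        n_skipped = vapply(reps, function(x) nrow(x$skipped), integer(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    }

    if (do_ladder && nrow(nonred) >= 1L) {
      dxma <- character(0)
      if (!is.null(res$clade_calls)) {
        sub_of <- function(sup) {
          ids <- strsplit(sup, ";", fixed = TRUE)[[1L]]
          st <- panel$labels$subtype[match(ids, panel$labels$id)]
          names(sort(table(st), decreasing = TRUE))[1L]
        }
        subt <- vapply(res$clade_calls$supporting_reference_ids, sub_of,
                       character(1))
        dxma <- res$clade_calls$query_id[subt == "DxmA-like"]
      }
      lad_p <- identity_ladder(proteins[nonred$query_id],
                               labeled_ids = dxma, space = "protein")
      genes <- vapply(nonred$query_id, function(q) {
        f <- features[features$product_id == q, ]
        g <- substr(contigs[[f$contig_id]], f$start, f$end)
        if (f$strand == "-") revcomp(g) else g
      }, character(1))
      lad_n <- identity_ladder(genes, labeled_ids = dxma,
                               space = "nucleotide")
      lad_p$space <- "protein"; lad_n$space <- "nucleotide"
      res$ladder <- rbind(lad_p, lad_n)
    }
  }

  # --- Tier 2: dereplicate and classify on its own tree ---
  if (classify_tier2 && nrow(gt$tier2) > 0L) {
    t2 <- gt$tier2
    d2 <- dereplicate_contigs(contigs[unique(t2$contig_id)],
                              c = derep_c, aS = derep_aS)
    nonred2 <- t2[t2$contig_id %in% names(d2$representatives), ,
                  drop = FALSE]
    note("tier-2: ", nrow(t2), " candidates on ",
         length(unique(t2$contig_id)), " contigs -> ", nrow(nonred2),
         " on ", length(d2$representatives), " non-redundant contigs")
    if (nrow(nonred2) >= 1L) {
      seqs2 <- c(proteins[nonred2$query_id], panel$proteins)
      tree2 <- nj_tree(pdistance_matrix(seqs2))
      outg <- intersect(panel_outgroup_ids(panel, outgroup_group),
                        tree2$tip.label)
      tree2 <- root_by_outgroup(tree2, outg,
                                ignore_ids = nonred2$query_id)
      res$tier2_calls <- call_clades(tree2, panel$labels)
      res$tier2_derep <- d2
    }
  }

  # --- neighborhoods on tier-1 contigs; overlaps over all contigs ---
  t1_contigs <- unique(gt$tier1$contig_id)
  if (length(t1_contigs)) {
    res$itr <- do.call(rbind, lapply(t1_contigs, function(cid) {
      f <- features[features$contig_id == cid, , drop = FALSE]
      df <- find_itr(contigs[[cid]], f, min_len = min_overlap_len)
      if (nrow(df)) df$contig_id <- cid
      df
    }))
    if (!is.null(subunit_labels)) {
      res$operons <- lapply(t1_contigs, function(cid)
        check_operon_order(features[features$contig_id == cid, ,
                                    drop = FALSE], subunit_labels))
      names(res$operons) <- t1_contigs
    }
  }
  if (length(contigs) >= 2L) {
    res$overlaps <- find_terminal_overlaps(contigs,
                                           min_len = min_overlap_len)
    note("overlaps: ", nrow(res$overlaps), " terminal overlap(s) >= ",
         min_overlap_len, " bp")
  }

  res$log <- log
  if (!is.null(outdir)) .write_pipeline_outputs(res, outdir)
  res
}

.write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      .write_tsv(df, file.path(outdir, name))
    } else {
      # empty-but-valid placeholder keeps downstream consumers simple
      writeLines("", file.path(outdir, name))
    }
  }
  tiers <- rbind(res$gate$tier1, res$gate$tier2)
  w(tiers, "tiers.tsv")
  w(if (!is.null(res$derep)) res$derep$mapping, "clusters.tsv")
  w(res$clade_calls, "cladecalls.tsv")
  if (!is.null(res$clade_matrix) && length(res$clade_matrix$matrix)) {
    m <- res$clade_matrix$matrix
    df <- data.frame(clade = rownames(m),
                     group = res$clade_matrix$clade_groups[rownames(m)],
                     as.data.frame(m), check.names = FALSE)
    .write_tsv(df, file.path(outdir, "clade_matrix.tsv"))
  } else {
    writeLines("", file.path(outdir, "clade_matrix.tsv"))
  }
  w(res$ladder, "table1.tsv")
  w(res$representatives, "representatives.tsv")
  w(res$overlaps, "overlaps.tsv")
  w(res$itr, "itr.tsv")
  if (!is.null(res$tree)) {
    write_newick(res$tree, file.path(outdir, "tree.nwk"))
  }
  writeLines(res$log, file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' Run the pipeline from a config (file paths or simulation)
#'
#' The config is a list (or path to a JSON file) with either a `simulate`
#' section (passed to [simulation_config()]; plants as lists) or an
#' `inputs` section with paths `proteins`, `contigs`, `features`, `counts`,
#' `totals`, and optional `panel_fasta`/`panel_labels`, `hits`. Optional
#' `params` override tier thresholds, dereplication parameters and the
#' minimum overlap length. All inputs are validated before any stage runs;
#' the resolved config is written alongside the outputs.
#'
#' @param config list or path to JSON config.
#' @param outdir output directory.
#' @return the [sdimo_pipeline()] result, invisibly.
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  panel <- if (!is.null(config$inputs$panel_fasta)) {
    read_panel(config$inputs$panel_fasta, config$inputs$panel_labels)
  } else {
    synthetic_panel()
  }
  p <- config$params
  thresholds <- do.call(tier_thresholds, if (is.null(p$thresholds))
    list() else p$thresholds)

  if (!is.null(config$simulate)) {
    s <- config$simulate
    po <- s$planted_operons
    if (is.data.frame(po)) {       # jsonlite simplification of the list
      po <- lapply(seq_len(nrow(po)), function(i)
        Filter(Negate(is.na), as.list(po[i, ])))
    }
    s$planted_operons <- lapply(po, function(x) do.call(plant_spec, x))
    sim <- simulate_metagenome(do.call(simulation_config, s), panel,
                               outdir = file.path(outdir, "sim"))
    inputs <- list(proteins = sim$proteins, contigs = sim$contigs,
                   features = sim$features, counts = sim$counts,
                   totals = sim$totals, origin = sim$contig_origin)
    hits <- NULL
  } else {
    paths <- config$inputs
    need <- c("proteins", "contigs", "features", "counts", "totals")
    for (nm in need) {
      if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
        stop("missing input: ", nm)
      }
    }
    inputs <- list(proteins = read_fasta(paths$proteins, "protein"),
                   contigs = read_fasta(paths$contigs, "dna"),
                   features = read_features(paths$features),
                   counts = read_counts(paths$counts),
                   totals = read_totals(paths$totals),
                   origin = NULL)
    hits <- if (!is.null(paths$hits)) read_tabular_hits(paths$hits)
  }
  res <- sdimo_pipeline(
    inputs$proteins, inputs$contigs, inputs$features, inputs$counts,
    inputs$totals, panel = panel, contig_origin = inputs$origin,
    thresholds = thresholds,
    derep_c = if (is.null(p$derep_c)) 0.999 else p$derep_c,
    derep_aS = if (is.null(p$derep_aS)) 0.999 else p$derep_aS,
    hits = hits,
    min_overlap_len = if (is.null(p$min_overlap_len)) 100L
                      else as.integer(p$min_overlap_len),
    outdir = outdir)
  cfg_out <- config
  cfg_out$resolved <- list(thresholds = unclass(thresholds))
  jsonlite::write_json(cfg_out, file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(res)
}
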