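# Distance-based trees over query + panel proteins, clade calling against
# the labelled panel, group confirmation from di-iron centre flanks, and
# clade representative selection.
#
# Neighbor joining is implemented in-repo (rather than wrapping an external
# approximate-ML tool) because the tree is used only for clade membership:
# NJ is deterministic, oracle-checkable (it reconstructs additive matrices
# exactly) and adequate for monophyly calls. Tie-breaking and the handling
# of negative branch lengths are pinned for testability.

#' Pairwise p-distance matrix from global alignments
#'
#' `d(i, j) = 1 - identical columns / comparable columns` from a pairwise
#' global alignment with affine gaps; gap columns are excluded from the
#' denominator.
#'
#' @param seqs named character vector of >= 3 protein sequences.
#' @return symmetric numeric matrix with zero diagonal and the ids as
#'   dimnames.
#' @export
pdistance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  a <- .tm_space_args("protein")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    idx <- seq(i + 1L, n)
    pa <- Biostrings::pairwiseAlignment(
      a$xss(seqs[idx]), a$xs(seqs[[i]]), substitutionMatrix = a$mat,
      gapOpening = a$gap_open, gapExtension = a$gap_extend,
      type = "global")
    # comparable (non-gap) columns are exactly the matches plus mismatches
    nm <- Biostrings::nmatch(pa)
    comp <- nm + Biostrings::nmismatch(pa)
    if (any(comp == 0L)) {
      k <- which(comp == 0L)[1L]
      stop("no comparable columns between '", names(seqs)[i], "' and '",
           names(seqs)[idx[k]], "'")
    }
    d[i, idx] <- d[idx, i] <- 1 - nm / comp
  }
  d
}

.fmt_bl <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on a symmetric distance matrix.
#' Ties in the Q criterion are broken toward the smallest (i, j) index pair
#' in the current node order (input leaf order, merged nodes appended).
#' Negative branch lengths are clamped to 0 with the deficit moved to the
#' sister branch.
#'
#' @param d symmetric distance matrix with zero diagonal and ids as
#'   dimnames (see [pdistance_matrix()]).
#' @return unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) stop("d must have row/column names")
  if (max(abs(d - t(d))) > 1e-8) stop("non-symmetric distance matrix")
  if (any(!is.finite(d))) stop("non-finite distances")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")

  n0 <- nrow(d)
  size <- 2L * n0
  D <- matrix(0, size, size)
  D[seq_len(n0), seq_len(n0)] <- d
  frag <- character(size)
  frag[seq_len(n0)] <- rownames(d)
  act <- seq_len(n0)
  nxt <- n0

  clamp <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }

  while (length(act) > 3L) {
    m <- length(act)
    sub <- D[act, act]
    r <- rowSums(sub)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        q <- (m - 2) * sub[i, j] - r[i] - r[j]
        if (q < best) { best <- q; bi <- i; bj <- j }
      }
    }
    ai <- act[bi]; aj <- act[bj]
    li <- 0.5 * sub[bi, bj] + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- sub[bi, bj] - li
    bl <- clamp(li, lj)
    nxt <- nxt + 1L
    others <- act[-c(bi, bj)]
    D[nxt, others] <- D[others, nxt] <-
      0.5 * (D[ai, others] + D[aj, others] - D[ai, aj])
    frag[nxt] <- sprintf("(%s:%s,%s:%s)", frag[ai], .fmt_bl(bl[1L]),
                         frag[aj], .fmt_bl(bl[2L]))
    act <- c(others, nxt)
  }
  a <- act[1L]; b <- act[2L]; c3 <- act[3L]
  la <- max(0, (D[a, b] + D[a, c3] - D[b, c3]) / 2)
  lb <- max(0, (D[a, b] + D[b, c3] - D[a, c3]) / 2)
  lc <- max(0, (D[a, c3] + D[b, c3] - D[a, b]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], .fmt_bl(la),
                 frag[b], .fmt_bl(lb), frag[c3], .fmt_bl(lc))
  ape::read.tree(text = nwk)
}

# tips descending from every node (1..Ntip are the tips themselves)
.node_tips <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  out <- vector("list", nt + nn)
  for (i in seq_len(nt)) out[[i]] <- i
  edges <- tree$edge[order(tree$edge[, 1L], decreasing = TRUE), ,
                     drop = FALSE]
  # children have larger postorder position than parents when processed
  # from the highest node id downward (node ids of a phylo are such that
  # internal nodes are numbered from the root down, so repeat until stable)
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(edges))) {
      p <- edges[k, 1L]; ch <- edges[k, 2L]
      if (!is.null(out[[ch]])) {
        new <- union(out[[p]], out[[ch]])
        if (!identical(new, out[[p]])) { out[[p]] <- new; done <- FALSE }
      }
    }
    if (done) break
  }
  lapply(out, function(x) sort(x))
}

#' Root a tree on the edge separating an outgroup
#'
#' Places the root on the edge separating the smallest clade containing all
#' outgroup ids from the rest. If no split separates the outgroup cleanly
#' from the remaining reference leaves, the split maximizing outgroup purity
#' is used and the result is flagged (`attr(tree, "outgroup_clean")` is
#' FALSE). Leaves in `ignore_ids` (e.g. query sequences) are neutral for
#' purity.
#'
#' @param tree [ape::phylo] tree.
#' @param outgroup_ids nonempty character vector of outgroup tip labels.
#' @param ignore_ids tip labels ignored when scoring splits.
#' @return rooted [ape::phylo] with attribute `outgroup_clean`.
#' @export
root_by_outgroup <- function(tree, outgroup_ids, ignore_ids = character(0)) {
  tips <- tree$tip.label
  if (length(outgroup_ids) == 0L) stop("empty outgroup")
  unknown <- setdiff(outgroup_ids, tips)
  if (length(unknown)) stop("unknown outgroup id: ", unknown[1L])
  if (setequal(outgroup_ids, tips)) {
    stop("outgroup cannot contain all leaves")
  }
  ins <- setdiff(tips, union(outgroup_ids, ignore_ids))
  if (length(ins) == 0L) stop("no non-outgroup reference leaves to root against")
  nt <- length(tips)
  ntips <- .node_tips(tree)
  best_purity <- -1; best_side <- NULL
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    side <- tips[ntips[[ch]]]
    for (s in list(side, setdiff(tips, side))) {
      n_out_in <- sum(outgroup_ids %in% s)
      n_in_out <- sum(!(ins %in% s))
      purity <- (n_out_in + n_in_out) /
        (length(outgroup_ids) + length(ins))
      if (length(s) == 0L || length(s) == nt) next
      if (purity > best_purity) { best_purity <- purity; best_side <- s }
    }
  }
  rooted <- ape::root(tree, outgroup = best_side, resolve.root = TRUE)
  attr(rooted, "outgroup_clean") <- best_purity >= 1
  rooted
}

#' Call dioxane-degrader vs outgroup clades for query leaves
#'
#' For each query leaf, the minimal rooted clade containing the query and at
#' least one panel leaf is found. The call is `CDDP-like` when every panel
#' leaf in that clade carries documented dioxane-degradation evidence (CDDP
#' entries, or COMP entries flagged dioxane-positive), `outgroup-like` when
#' every panel leaf is an outgroup (OUT/COMPOUT), and `ambiguous` otherwise.
#' The SDIMO group is the majority group of the panel leaves in the clade
#' (ties give `"unknown"`). Queries sharing the same minimal panel set share
#' a `clade_id`.
#'
#' @param tree rooted [ape::phylo] containing query and panel leaves.
#' @param panel_labels panel label table (see [synthetic_panel()]).
#' @return data.frame with `query_id`, `call`, `group`, `clade_id`,
#'   `supporting_reference_ids` (semicolon-separated).
#' @export
call_clades <- function(tree, panel_labels) {
  tips <- tree$tip.label
  panel_ids <- intersect(tips, panel_labels$id)
  if (length(panel_ids) == 0L) stop("tree contains no panel leaves")
  queries <- setdiff(tips, panel_ids)
  if (length(queries) == 0L) {
    return(data.frame(query_id = character(0), call = character(0),
                      group = character(0), clade_id = integer(0),
                      supporting_reference_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  evid <- .panel_evidence_ids(panel_labels)
  outg <- panel_labels$id[panel_labels$dioxane_label %in%
                            c("OUT", "COMPOUT")]
  ntips <- .node_tips(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  rows <- vector("list", length(queries))
  keys <- character(length(queries))
  for (qi in seq_along(queries)) {
    tip <- match(queries[qi], tips)
    node <- tip
    repeat {
      node <- if (node == root) root else parent[node]
      clade_tips <- tips[ntips[[node]]]
      sup <- intersect(clade_tips, panel_ids)
      if (length(sup) > 0L || node == root) break
    }
    call <- if (all(sup %in% evid)) "CDDP-like"
            else if (all(sup %in% outg)) "outgroup-like"
            else "ambiguous"
    gr <- panel_labels$group[match(sup, panel_labels$id)]
    tab <- sort(table(gr), decreasing = TRUE)
    group <- if (length(tab) > 1L && tab[1L] == tab[2L]) "unknown"
             else names(tab)[1L]
    keys[qi] <- paste(sort(sup), collapse = "|")
    rows[[qi]] <- data.frame(
      query_id = queries[qi], call = call, group = group,
      supporting_reference_ids = paste(sort(sup), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$clade_id <- as.integer(factor(keys, levels = unique(keys)))
  out[, c("query_id", "call", "group", "clade_id",
          "supporting_reference_ids")]
}

.HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

#' Group-consistency score from di-iron centre flank hydrophobicity
#'
#' SDIMO group membership is reflected in the hydrophobic residues
#' surrounding the first di-iron centre. The score is the fraction of flank
#' positions (within `flank_width` of the first motif, the motif itself
#' excluded) where the query residue falls in the same hydrophobicity class
#' (hydrophobic vs other) as the reference residue. Advisory only, never a
#' gate.
#'
#' @param query,reference protein strings.
#' @param ref_anchor1 1-based start of the first DE*RH motif on the
#'   reference.
#' @param alignment optional precomputed global `tm_alignment` (query as
#'   pattern); computed if NULL.
#' @param flank_width flank width in reference residues on each side.
#' @return score in [0, 1], or NA with attribute `flagged = TRUE` when the
#'   motif region is gapped in the alignment.
#' @export
confirm_group <- function(query, reference, ref_anchor1,
                          alignment = NULL, flank_width = 5L) {
  if (is.na(ref_anchor1)) {
    out <- NA_real_; attr(out, "flagged") <- TRUE
    return(out)
  }
  if (is.null(alignment)) alignment <- align_global(query, reference)
  qc <- strsplit(alignment$q_aln, "", fixed = TRUE)[[1L]]
  rc <- strsplit(alignment$r_aln, "", fixed = TRUE)[[1L]]
  rpos <- cumsum(rc != "-") + alignment$r_start - 1L
  rpos[rc == "-"] <- NA_integer_
  motif_cols <- which(!is.na(rpos) & rpos >= ref_anchor1 &
                        rpos <= ref_anchor1 + 4L)
  if (length(motif_cols) < 5L || any(qc[motif_cols] == "-")) {
    out <- NA_real_; attr(out, "flagged") <- TRUE
    return(out)
  }
  flanks <- c(seq(ref_anchor1 - flank_width, ref_anchor1 - 1L),
              seq(ref_anchor1 + 5L, ref_anchor1 + 4L + flank_width))
  flanks <- flanks[flanks >= 1L & flanks <= alignment$ref_len]
  cols <- match(flanks, rpos)
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0L) {
    out <- NA_real_; attr(out, "flagged") <- TRUE
    return(out)
  }
  same <- (qc[cols] %in% .HYDROPHOBIC) == (rc[cols] %in% .HYDROPHOBIC) &
    qc[cols] != "-"
  sum(same) / length(flanks)
}

#' Select the clade representative by abundance and motif integrity
#'
#' Members are sorted by abundance (RPKM in the member's origin sample)
#' descending, ties broken by id ascending; the first member whose first
#' di-iron centre motif is present is chosen. Members skipped over are
#' reported with the reason. If no member has an intact first motif, the
#' most abundant member is returned flagged (represented only as a last
#' resort, never dropped).
#'
#' @param member_ids character vector of clade member ids.
#' @param abundances named numeric vector (id -> origin-sample RPKM).
#' @param motif1_states named character vector (id -> present/absent/gap).
#' @return list with `representative_id`, `abundance_rpkm`, `skipped`
#'   (data.frame id, reason), `flagged`.
#' @export
select_representative <- function(member_ids, abundances, motif1_states) {
  stopifnot(length(member_ids) >= 1L)
  if (!all(member_ids %in% names(abundances))) {
    stop("missing abundance for member")
  }
  ab <- abundances[member_ids]
  ord <- order(-ab, member_ids)
  ids <- member_ids[ord]
  st <- motif1_states[ids]
  st[is.na(st)] <- "absent"
  hit <- which(st == "present")[1L]
  if (is.na(hit)) {
    return(list(representative_id = ids[1L],
                abundance_rpkm = unname(ab[ids[1L]]),
                skipped = data.frame(id = character(0),
                                     reason = character(0)),
                flagged = TRUE))
  }
  skipped <- if (hit > 1L) {
    data.frame(id = ids[seq_len(hit - 1L)],
               reason = paste("motif1", st[seq_len(hit - 1L)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  list(representative_id = ids[hit], abundance_rpkm = unname(ab[ids[hit]]),
       skipped = skipped, flagged = FALSE)
}
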