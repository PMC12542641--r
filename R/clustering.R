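# Greedy incremental identity clustering (CD-HIT-style) for dereplication
# and identity-ladder analyses. The word-filtering heuristics of the
# original tool are deliberately omitted: at desk scale every candidate is
# aligned against the cluster representatives exactly, which keeps the
# identity definition auditable. Identity follows the CD-HIT convention:
# identical columns divided by the length of the shorter sequence, with
# `aS` the aligned coverage of the shorter sequence.

#' Pairwise identity and short-sequence coverage
#'
#' Local alignment identity in the CD-HIT convention: identical columns /
#' length of the shorter sequence; `coverage_short` is the fraction of the
#' shorter sequence covered by the alignment.
#'
#' @param a,b sequences.
#' @param space `"protein"` or `"nucleotide"`.
#' @return list with `identity` and `coverage_short` (fractions in [0, 1]).
#' @export
seq_identity <- function(a, b, space = c("protein", "nucleotide")) {
  space <- match.arg(space)
  aln <- align_local(a, b, space = if (space == "protein") "protein"
                                   else "dna")
  short <- min(nchar(a), nchar(b))
  if (nchar(aln$q_aln) == 0L) {
    return(list(identity = 0, coverage_short = 0))
  }
  q <- strsplit(aln$q_aln, "", fixed = TRUE)[[1L]]
  r <- strsplit(aln$r_aln, "", fixed = TRUE)[[1L]]
  nid <- sum(q == r & q != "-")
  span <- if (nchar(a) <= nchar(b)) aln$q_end - aln$q_start + 1L
          else aln$r_end - aln$r_start + 1L
  list(identity = nid / short, coverage_short = span / short)
}

.check_alphabet <- function(seqs, space) {
  ok <- if (space == "protein") .AA_OK else .DNA_OK
  bad <- vapply(seqs, function(s)
    length(setdiff(unique(strsplit(s, "", fixed = TRUE)[[1L]]), ok)) > 0L,
    logical(1))
  if (any(bad)) {
    stop("sequence '", names(seqs)[bad][1L], "' is not valid ", space,
         " (mixed alphabets?)")
  }
}

#' Greedy incremental identity clustering
#'
#' The published greedy-incremental scheme: sequences are sorted by length
#' (descending, ties broken by id ascending); each sequence joins the first
#' existing cluster (in founding order) whose representative it matches at
#' identity >= `c` (and coverage of the shorter sequence >= `aS`, when set),
#' otherwise it founds a new cluster. Representatives are therefore always
#' at least as long as their members, and the procedure is fully
#' deterministic.
#'
#' @param seqs named character vector of sequences (one alphabet).
#' @param c identity threshold, fraction in (0, 1].
#' @param aS optional minimum alignment coverage of the shorter sequence.
#' @param space `"protein"` or `"nucleotide"`.
#' @return object of class `tm_clusters`: list of clusters, each
#'   `list(representative_id, member_ids, member_identities)`, with the
#'   parameters in attributes.
#' @export
greedy_cluster <- function(seqs, c = 0.999, aS = NULL,
                           space = c("protein", "nucleotide")) {
  space <- match.arg(space)
  stopifnot(length(seqs) >= 1L, c > 0, c <= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  .check_alphabet(seqs, space)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  bio <- .tm_space_args(if (space == "protein") "protein" else "dna")
  clusters <- list()
  reps <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    id <- names(seqs)[i]
    joined <- FALSE
    if (length(reps)) {
      pa <- Biostrings::pairwiseAlignment(
        bio$xss(reps), bio$xs(s), substitutionMatrix = bio$mat,
        gapOpening = bio$gap_open, gapExtension = bio$gap_extend,
        type = "local")
      shorts <- pmin(nchar(reps), nchar(s))
      idents <- Biostrings::nmatch(pa) / shorts
      # span of the shorter sequence within the alignment
      rep_shorter <- nchar(reps) <= nchar(s)
      span <- ifelse(rep_shorter,
                     BiocGenerics::end(Biostrings::pattern(pa)) -
                       BiocGenerics::start(Biostrings::pattern(pa)) + 1L,
                     BiocGenerics::end(Biostrings::subject(pa)) -
                       BiocGenerics::start(Biostrings::subject(pa)) + 1L)
      covs <- span / shorts
      pass <- idents >= c
      if (!is.null(aS)) pass <- pass & covs >= aS
      j <- which(pass)[1L]
      if (!is.na(j)) {
        clusters[[j]]$member_ids <- c(clusters[[j]]$member_ids, id)
        clusters[[j]]$member_identities <-
          c(clusters[[j]]$member_identities, idents[j])
        joined <- TRUE
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <-
        list(representative_id = id, member_ids = id,
             member_identities = 1.0)
      reps <- c(reps, s)
      names(reps)[length(reps)] <- id
    }
  }
  structure(clusters, class = "tm_clusters", c = c, aS = aS, space = space)
}

#' Dereplicate contigs to a non-redundant representative set
#'
#' Greedy nucleotide clustering at the dereplication defaults (c = 0.999,
#' aS = 0.999), collapsing identical and near-identical contigs assembled
#' from multiple samples to one representative each.
#'
#' @param contigs named character vector of nucleotide contigs.
#' @param c,aS clustering parameters.
#' @return list with `representatives` (named character vector), `mapping`
#'   (data.frame member_id -> representative_id) and the `tm_clusters`
#'   object.
#' @export
dereplicate_contigs <- function(contigs, c = 0.999, aS = 0.999) {
  cl <- greedy_cluster(contigs, c = c, aS = aS, space = "nucleotide")
  mapping <- do.call(rbind, lapply(cl, function(x)
    data.frame(member_id = x$member_ids,
               representative_id = x$representative_id,
               stringsAsFactors = FALSE)))
  rownames(mapping) <- NULL
  rep_ids <- vapply(cl, `[[`, character(1), "representative_id")
  list(representatives = contigs[rep_ids], mapping = mapping, clusters = cl)
}

#' Identity ladder: cluster counts across identity thresholds
#'
#' Clusters the same sequence set at a descending ladder of identity
#' thresholds and counts total clusters and clusters containing at least one
#' labelled member (e.g. members called DxmA-like), the shape of the
#' published clustering-ladder tables.
#'
#' @param seqs named character vector.
#' @param thresholds identity thresholds (fractions).
#' @param labeled_ids ids of labelled sequences; unknown ids are dropped
#'   with a warning.
#' @param space `"protein"` or `"nucleotide"`.
#' @param aS optional coverage parameter passed through to clustering
#'   (unset by default: the ladder analyses use identity only).
#' @return data.frame with columns `c`, `n_clusters`, `n_labeled_clusters`.
#' @export
identity_ladder <- function(seqs, thresholds = c(1, 0.99, 0.97, 0.95, 0.9),
                            labeled_ids = character(0),
                            space = c("protein", "nucleotide"), aS = NULL) {
  space <- match.arg(space)
  unknown <- setdiff(labeled_ids, names(seqs))
  if (length(unknown)) {
    warning("dropping unknown labelled ids: ",
            paste(unknown, collapse = ", "))
    labeled_ids <- setdiff(labeled_ids, unknown)
  }
  rows <- lapply(thresholds, function(th) {
    cl <- greedy_cluster(seqs, c = th, aS = aS, space = space)
    lab <- vapply(cl, function(x)
      any(x$member_ids %in% labeled_ids), logical(1))
    data.frame(c = th, n_clusters = length(cl),
               n_labeled_clusters = sum(lab))
  })
  do.call(rbind, rows)
}

#' @export
print.tm_clusters <- function(x, ...) {
  cat(length(x), "clusters (c =", attr(x, "c"),
      if (!is.null(attr(x, "aS"))) paste0(", aS = ", attr(x, "aS")),
      ",", attr(x, "space"), "space)\n")
  invisible(x)
}
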