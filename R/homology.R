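# Pairwise alignment backend (Biostrings) and panel screening.
#
# Protein scoring uses BLOSUM62 with the X row/column set to 0: assemblers
# emit ambiguous codons, and X should neither reward nor punish a column.

.tm_protein_matrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.tm_env[[key]])) return(.tm_env[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]]
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  .tm_env[[key]] <- m
  m
}

# simple DNA scoring over ACGTN; N is neutral
.tm_dna_matrix <- function(match = 2L, mismatch = -3L) {
  key <- sprintf("dnamat_%d_%d", match, mismatch)
  if (!is.null(.tm_env[[key]])) return(.tm_env[[key]])
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0L
  m[, "N"] <- 0L
  .tm_env[[key]] <- m
  m
}

.tm_space_args <- function(space) {
  if (space == "protein") {
    list(mat = .tm_protein_matrix(), gap_open = 11, gap_extend = 1,
         xs = Biostrings::AAString, xss = Biostrings::AAStringSet)
  } else {
    list(mat = .tm_dna_matrix(), gap_open = 10, gap_extend = 1,
         xs = Biostrings::DNAString, xss = Biostrings::DNAStringSet)
  }
}

.as_alignment <- function(pa, i, query, reference) {
  structure(list(
    score   = Biostrings::score(pa)[i],
    q_aln   = as.character(Biostrings::alignedPattern(pa)[i]),
    r_aln   = as.character(Biostrings::alignedSubject(pa)[i]),
    q_start = BiocGenerics::start(Biostrings::pattern(pa))[i],
    q_end   = BiocGenerics::end(Biostrings::pattern(pa))[i],
    r_start = BiocGenerics::start(Biostrings::subject(pa))[i],
    r_end   = BiocGenerics::end(Biostrings::subject(pa))[i],
    query_len = nchar(query),
    ref_len = nchar(reference)
  ), class = "tm_alignment")
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' Backed by [Biostrings::pairwiseAlignment()]. For proteins the default
#' scoring is BLOSUM62 (with `X` scoring 0 against everything), gap open 11,
#' gap extend 1 -- the de facto protein-search defaults. An all-negative pair
#' yields the empty alignment with score 0.
#'
#' @param query,reference nonempty sequences (single strings).
#' @param matrix_name substitution matrix name (protein space only).
#' @param gap_open,gap_extend affine gap penalties (positive costs,
#'   `gap_open >= gap_extend >= 0`); a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param space `"protein"` or `"dna"`.
#' @return A `tm_alignment`: list with `score`, gapped aligned strings
#'   `q_aln`/`r_aln`, 1-based `q_start`/`q_end`/`r_start`/`r_end` on the
#'   original sequences, and the input lengths.
#' @export
align_local <- function(query, reference, matrix_name = "BLOSUM62",
                        gap_open = 11, gap_extend = 1,
                        space = c("protein", "dna")) {
  space <- match.arg(space)
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  if (!(gap_open >= gap_extend && gap_extend >= 0)) {
    stop("need gap_open >= gap_extend >= 0")
  }
  a <- .tm_space_args(space)
  mat <- if (space == "protein") .tm_protein_matrix(matrix_name) else a$mat
  pa <- Biostrings::pairwiseAlignment(
    a$xs(query), a$xs(reference), substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, type = "local")
  if (Biostrings::score(pa) <= 0 && Biostrings::nchar(pa) == 0L) {
    return(structure(list(score = 0, q_aln = "", r_aln = "",
                          q_start = 0L, q_end = -1L, r_start = 0L,
                          r_end = -1L, query_len = nchar(query),
                          ref_len = nchar(reference)),
                     class = "tm_alignment"))
  }
  .as_alignment(pa, 1L, query, reference)
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' Used for pairwise distances and motif-anchor mapping where end-to-end
#' correspondence is needed.
#'
#' @inheritParams align_local
#' @return A `tm_alignment` (see [align_local()]).
#' @export
align_global <- function(query, reference, matrix_name = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         space = c("protein", "dna")) {
  space <- match.arg(space)
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  a <- .tm_space_args(space)
  mat <- if (space == "protein") .tm_protein_matrix(matrix_name) else a$mat
  pa <- Biostrings::pairwiseAlignment(
    a$xs(query), a$xs(reference), substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  .as_alignment(pa, 1L, query, reference)
}

#' Alignment summary statistics for the tier gates
#'
#' `pident` is 100 x identical columns / alignment length, where gap columns
#' count toward the alignment length and never as identities. `qcov` is
#' 100 x aligned query span / query length.
#'
#' @param aln a `tm_alignment` from [align_local()] or [align_global()].
#' @param query_len query length; defaults to the length recorded in `aln`.
#' @return one-row data.frame with `pident`, `alen`, `qcov`, `score`,
#'   `n_ident`.
#' @export
hit_stats <- function(aln, query_len = aln$query_len) {
  stopifnot(inherits(aln, "tm_alignment"))
  alen <- nchar(aln$q_aln)
  if (alen == 0L) stop("empty alignment")
  span <- aln$q_end - aln$q_start + 1L
  if (query_len < span) stop("query_len (", query_len,
                             ") smaller than aligned span (", span, ")")
  q <- strsplit(aln$q_aln, "", fixed = TRUE)[[1L]]
  r <- strsplit(aln$r_aln, "", fixed = TRUE)[[1L]]
  ident <- sum(q == r & q != "-")
  data.frame(pident = 100 * ident / alen, alen = alen,
             qcov = 100 * span / query_len, score = aln$score,
             n_ident = ident)
}

#' Screen query proteins against a labelled reference panel
#'
#' In-repo mode aligns every query against every panel entry with
#' [align_local()] and retains hits whose score reaches
#' `score_floor * min(query length, reference length)` -- a score-per-column
#' floor standing in for a database e-value gate, which is tool-dependent
#' and out of scope here. When precomputed tabular hits are supplied
#' (see [read_tabular_hits()]), the e-value gate `evalue <= evalue_max`
#' applies instead and `qcov` is filled in from the recorded query spans.
#' The best hit per query (maximum score; ties broken toward the
#' lexicographically lower reference id) is flagged in column `best`.
#'
#' @param queries named character vector of query proteins.
#' @param panel a panel object (see [synthetic_panel()]) or named character
#'   vector of reference proteins.
#' @param evalue_max e-value gate for ingested tabular hits.
#' @param hits optional precomputed hits data.frame
#'   (from [read_tabular_hits()]).
#' @param score_floor score-per-column retention floor for in-repo mode.
#' @return hits data.frame with columns `query_id`, `reference_id`,
#'   `pident`, `alen`, `qcov`, `evalue`, `score`, `best`.
#' @export
screen_panel <- function(queries, panel, evalue_max = 1e-50, hits = NULL,
                         score_floor = 1.0) {
  refs <- if (is.list(panel) && !is.null(panel$proteins)) panel$proteins
          else panel
  if (length(refs) == 0L) stop("empty reference panel")
  if (!is.null(hits)) {
    keep <- !is.na(hits$evalue) & hits$evalue <= evalue_max
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits)) {
      qlen <- nchar(queries)[hits$query_id]
      hits$qcov <- 100 * (hits$qend - hits$qstart + 1L) / qlen
    }
    out <- hits[, c("query_id", "reference_id", "pident", "alen", "qcov",
                    "evalue", "score")]
    return(.flag_best(out))
  }
  if (length(queries) == 0L) return(.flag_best(.screen_empty()))
  qlens <- nchar(queries)
  rows <- vector("list", length(refs))
  a <- .tm_space_args("protein")
  qset <- a$xss(queries)
  for (j in seq_along(refs)) {
    ref <- refs[[j]]
    pa <- Biostrings::pairwiseAlignment(
      qset, a$xs(ref), substitutionMatrix = a$mat,
      gapOpening = a$gap_open, gapExtension = a$gap_extend, type = "local")
    sc <- Biostrings::score(pa)
    floor_j <- score_floor * pmin(qlens, nchar(ref))
    keep <- which(sc >= floor_j & Biostrings::nchar(pa) > 0L)
    if (!length(keep)) next
    alen <- Biostrings::nchar(pa)[keep]
    nid <- Biostrings::nmatch(pa)[keep]
    qs <- BiocGenerics::start(Biostrings::pattern(pa))[keep]
    qe <- BiocGenerics::end(Biostrings::pattern(pa))[keep]
    rows[[j]] <- data.frame(
      query_id = names(queries)[keep], reference_id = names(refs)[j],
      pident = 100 * nid / alen, alen = alen,
      qcov = 100 * (qe - qs + 1L) / qlens[keep],
      evalue = NA_real_, score = sc[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(.screen_empty())))
  .flag_best(out)
}

.screen_empty <- function() {
  data.frame(query_id = character(0), reference_id = character(0),
             pident = numeric(0), alen = integer(0), qcov = numeric(0),
             evalue = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

.flag_best <- function(hits) {
  if (nrow(hits) == 0L) {
    hits$best <- logical(0)
    return(hits)
  }
  ord <- order(hits$query_id, -hits$score, hits$reference_id)
  hits <- hits[ord, , drop = FALSE]
  hits$best <- !duplicated(hits$query_id)
  rownames(hits) <- NULL
  hits
}
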