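# Two-tier evidence gates and DE*RH di-iron centre motif validation.
#
# Tier 1: >= 90% amino-acid identity to a panel reference, >= 125 aligned
# columns, >= 60% query coverage, and at least one intact DE*RH motif.
# Tier 2: 50-90% identity (half-open window: exactly 90 is Tier 1, since
# "minimum of 90%" means the minimum is attained) with the same length and
# coverage gates and no motif requirement. Contigs carrying any Tier-1
# candidate contribute no Tier-2 candidates.

#' Tier thresholds
#'
#' @param tier1_min_pident minimum percent identity for Tier 1 (inclusive).
#' @param tier2_pident_min lower bound of the Tier-2 identity window
#'   (inclusive; the upper bound is `tier1_min_pident`, exclusive).
#' @param min_alen minimum alignment length in columns.
#' @param min_qcov minimum query coverage in percent.
#' @param evalue_max e-value gate applied to ingested tabular hits.
#' @return list of class `tm_tier_thresholds`.
#' @export
tier_thresholds <- function(tier1_min_pident = 90, tier2_pident_min = 50,
                            min_alen = 125, min_qcov = 60,
                            evalue_max = 1e-50) {
  stopifnot(tier2_pident_min < tier1_min_pident)
  structure(list(tier1_min_pident = tier1_min_pident,
                 tier2_pident_min = tier2_pident_min,
                 min_alen = min_alen, min_qcov = min_qcov,
                 evalue_max = evalue_max),
            class = "tm_tier_thresholds")
}

#' Detect DE*RH di-iron centre motifs in a query protein
#'
#' With reference anchors and a best-hit alignment available, each anchor is
#' mapped through the alignment: the motif is `present` if the pattern
#' matches the query within `window` residues of the mapped position, `gap`
#' if the anchor region falls in alignment gap columns (or outside the
#' aligned span), and `absent` otherwise. Without anchors, the whole query
#' is scanned and the first two pattern matches are recorded.
#'
#' @param query query protein string.
#' @param alignment `tm_alignment` of the query against the best-hit
#'   reference (query as pattern), or NULL for a whole-sequence scan.
#' @param anchors length-2 integer vector of 1-based motif start positions
#'   on the reference (NA when a motif is not annotated).
#' @param window tolerance, in query residues, around the mapped anchor.
#' @param pattern regular expression for the motif; the default encodes
#'   D, E, any single residue, R, H contiguously.
#' @return object of class `tm_motifs`: list with `motif1`, `motif2` (each
#'   `list(state, pos)`, state one of present/absent/gap) and `pattern`.
#' @export
detect_motifs <- function(query, alignment = NULL,
                          anchors = c(NA_integer_, NA_integer_),
                          window = 10L, pattern = "DE.RH") {
  if (window < 0L) stop("window must be >= 0")
  ok <- tryCatch({grepl(pattern, "DEARH"); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("malformed motif pattern: ", pattern)
  states <- vector("list", 2L)
  if (is.null(alignment) || all(is.na(anchors))) {
    m <- gregexpr(pattern, query)[[1L]]
    pos <- if (m[1L] == -1L) integer(0) else as.integer(m)
    for (k in 1:2) {
      states[[k]] <- if (length(pos) >= k) {
        list(state = "present", pos = pos[k])
      } else list(state = "absent", pos = NA_integer_)
    }
  } else {
    qc <- strsplit(alignment$q_aln, "", fixed = TRUE)[[1L]]
    rc <- strsplit(alignment$r_aln, "", fixed = TRUE)[[1L]]
    rpos <- cumsum(rc != "-") + alignment$r_start - 1L
    rpos[rc == "-"] <- NA_integer_
    qpos <- cumsum(qc != "-") + alignment$q_start - 1L
    for (k in 1:2) {
      a <- anchors[k]
      if (is.na(a)) {
        states[[k]] <- list(state = "absent", pos = NA_integer_)
        next
      }
      cols <- which(!is.na(rpos) & rpos >= a & rpos <= a + 4L)
      if (length(cols) < 5L || any(qc[cols] == "-")) {
        # anchor region deleted in the query or outside the aligned span
        states[[k]] <- list(state = "gap", pos = NA_integer_)
        next
      }
      q_at <- qpos[cols[1L]]
      lo <- max(1L, q_at - window)
      hi <- min(nchar(query), q_at + 4L + window)
      m <- regexpr(pattern, substr(query, lo, hi))
      states[[k]] <- if (m != -1L) {
        list(state = "present", pos = lo + as.integer(m) - 1L)
      } else list(state = "absent", pos = NA_integer_)
    }
  }
  structure(list(motif1 = states[[1L]], motif2 = states[[2L]],
                 pattern = pattern), class = "tm_motifs")
}

#' Assign the evidence tier for one candidate
#'
#' Tier 1 iff `pident >= 90`, `alen >= 125`, `qcov >= 60` and at least one
#' motif present; Tier 2 iff `50 <= pident < 90` with the same length and
#' coverage gates (no motif requirement); otherwise `"none"`.
#'
#' @param pident,alen,qcov best-hit statistics (see [hit_stats()]).
#' @param motif_states character vector of the two motif states
#'   (present/absent/gap), or a `tm_motifs` object.
#' @param thresholds a [tier_thresholds()].
#' @return `"1"`, `"2"` or `"none"`.
#' @export
assign_tier <- function(pident, alen, qcov, motif_states,
                        thresholds = tier_thresholds()) {
  if (inherits(motif_states, "tm_motifs")) {
    motif_states <- c(motif_states$motif1$state, motif_states$motif2$state)
  }
  th <- thresholds
  base <- alen >= th$min_alen && qcov >= th$min_qcov
  if (base && pident >= th$tier1_min_pident &&
      any(motif_states == "present")) {
    "1"
  } else if (base && pident >= th$tier2_pident_min &&
             pident < th$tier1_min_pident) {
    "2"
  } else {
    "none"
  }
}

#' Gate candidates into contig-exclusive tier lists
#'
#' Applies [assign_tier()] per candidate, then removes from Tier 2 every
#' candidate whose contig carries a Tier-1 candidate, so the two tiers are
#' disjoint at the contig level. Optionally reports the per-sample Tier-1
#' fraction of predicted proteins (a descriptive statistic, never a gate).
#'
#' @param candidates data.frame with columns `query_id`, `contig_id`,
#'   `pident`, `alen`, `qcov`, `motif1`, `motif2` (motif state strings) and
#'   optionally `sample_id`.
#' @param thresholds a [tier_thresholds()].
#' @param proteins_per_sample optional named vector (sample_id -> number of
#'   predicted proteins) enabling the Tier-1 fraction report.
#' @return list with data.frames `tier1`, `tier2`, `excluded` (Tier-2 calls
#'   dropped by contig exclusion) and, when requested, `tier1_fraction`
#'   (percent of predicted proteins per sample).
#' @export
gate <- function(candidates, thresholds = tier_thresholds(),
                 proteins_per_sample = NULL) {
  if (nrow(candidates) == 0L) {
    empty <- candidates
    empty$tier <- character(0)
    return(list(tier1 = empty, tier2 = empty, excluded = empty))
  }
  candidates$tier <- vapply(seq_len(nrow(candidates)), function(i)
    assign_tier(candidates$pident[i], candidates$alen[i],
                candidates$qcov[i],
                c(candidates$motif1[i], candidates$motif2[i]),
                thresholds),
    character(1))
  tier1 <- candidates[candidates$tier == "1", , drop = FALSE]
  t2 <- candidates[candidates$tier == "2", , drop = FALSE]
  excl <- t2$contig_id %in% tier1$contig_id
  out <- list(tier1 = tier1, tier2 = t2[!excl, , drop = FALSE],
              excluded = t2[excl, , drop = FALSE])
  if (!is.null(proteins_per_sample) && "sample_id" %in% names(candidates)) {
    n1 <- table(factor(tier1$sample_id,
                       levels = names(proteins_per_sample)))
    out$tier1_fraction <- data.frame(
      sample_id = names(proteins_per_sample),
      tier1_n = as.integer(n1),
      tier1_pct_of_proteins = 100 * as.integer(n1) /
        as.numeric(proteins_per_sample),
      stringsAsFactors = FALSE)
  }
  out
}
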