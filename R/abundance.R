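# Contig RPKM per sample and clade x sample aggregation.
#
# Only origin-sample abundance enters the clade matrix: a contig's
# abundance is displayed within the sample from which it was assembled.
# Cross-sample mappings are retained in the record table for reporting.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((contig_len_bp / 1000) * (total_mapped / 1e6))`.
#'
#' @param count mapped read count (>= 0).
#' @param contig_len_bp contig length in bp (> 0).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return numeric RPKM (vectorized).
#' @export
rpkm <- function(count, contig_len_bp, total_mapped) {
  if (any(contig_len_bp <= 0)) stop("contig length must be positive")
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / ((contig_len_bp / 1000) * (total_mapped / 1e6))
}

#' Per-sample contig abundance records
#'
#' @param counts data.frame (sample_id, contig_id, count).
#' @param totals data.frame (sample_id, total_mapped).
#' @param contig_lengths named integer vector (contig_id -> bp).
#' @param contig_origin named character vector (contig_id -> the sample the
#'   contig was assembled from).
#' @return data.frame with `sample_id`, `contig_id`, `rpkm`,
#'   `origin_sample` (logical).
#' @export
compute_abundance <- function(counts, totals, contig_lengths,
                              contig_origin) {
  missing_c <- setdiff(counts$contig_id, names(contig_lengths))
  if (length(missing_c)) {
    stop("counts reference unknown contig: ", missing_c[1L])
  }
  tm <- setNames(totals$total_mapped, totals$sample_id)
  if (any(!counts$sample_id %in% names(tm))) {
    stop("counts reference sample missing from totals")
  }
  data.frame(
    sample_id = counts$sample_id, contig_id = counts$contig_id,
    rpkm = rpkm(counts$count, contig_lengths[counts$contig_id],
                tm[counts$sample_id]),
    origin_sample = contig_origin[counts$contig_id] == counts$sample_id,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Clade x sample abundance matrix with group totals
#'
#' Each cell sums the origin-sample RPKM of the clade members assembled in
#' that sample; members never contribute to other samples' cells. Group
#' totals sum a group's clades over all samples. Members without a clade
#' assignment are routed to an `"unassigned"` row with a warning.
#'
#' @param members data.frame with `query_id`, `contig_id` and optionally
#'   `clade_id`, `group` (taken from `clade_calls` when absent).
#' @param clade_calls data.frame from [call_clades()] (may cover only the
#'   dereplicated representatives; members inherit the call of their
#'   representative's query via `clade_of`).
#' @param abundance data.frame from [compute_abundance()].
#' @param clade_of optional named vector mapping member query_id to the
#'   query_id whose clade call applies (dereplication mapping); default
#'   identity.
#' @return list with `matrix` (clade x sample RPKM sums), `group_totals`
#'   (named numeric), `clade_groups` (named character).
#' @export
clade_matrix <- function(members, clade_calls, abundance,
                         clade_of = NULL) {
  if (nrow(members) == 0L) {
    return(list(matrix = matrix(0, 0, 0), group_totals = numeric(0),
                clade_groups = character(0)))
  }
  key <- if (is.null(clade_of)) members$query_id
         else unname(clade_of[members$query_id])
  idx <- match(key, clade_calls$query_id)
  clade <- ifelse(is.na(idx), NA_integer_, clade_calls$clade_id[idx])
  group <- ifelse(is.na(idx), "unassigned", clade_calls$group[idx])
  if (any(is.na(clade))) {
    warning(sum(is.na(clade)), " member(s) without clade assignment",
            " routed to 'unassigned'")
  }
  clade_lab <- ifelse(is.na(clade), "unassigned",
                      paste0("clade_", clade))
  ab <- abundance[abundance$origin_sample, , drop = FALSE]
  arec <- setNames(ab$rpkm, paste(ab$contig_id, ab$sample_id))
  origin <- setNames(ab$sample_id, ab$contig_id)
  msample <- origin[members$contig_id]
  mr <- arec[paste(members$contig_id, msample)]
  if (any(is.na(mr))) stop("member without abundance record")
  samples <- sort(unique(abundance$sample_id))
  clades <- unique(clade_lab)
  mat <- matrix(0, length(clades), length(samples),
                dimnames = list(clades, samples))
  for (i in seq_len(nrow(members))) {
    mat[clade_lab[i], msample[i]] <- mat[clade_lab[i], msample[i]] + mr[i]
  }
  cg <- tapply(group, clade_lab, function(g) g[1L])
  gt <- tapply(rowSums(mat), cg[rownames(mat)], sum)
  list(matrix = mat, group_totals = setNames(as.numeric(gt), names(gt)),
       clade_groups = setNames(as.character(cg), names(cg)))
}
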