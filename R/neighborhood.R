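# Gene-neighborhood analysis of SDIMO-bearing contigs: consensus annotation
# voting over heterogeneous annotators, operon subunit-order conformance,
# inverted-terminal-repeat detection, and fixed-length terminal overlap
# (assembly-break) detection. External plasmid/virus/toxin-antitoxin/MITE
# calls are ingested as pass-through flag columns, never computed.

#' Normalize an annotation label for exact-match voting
#'
#' Lowercases, strips punctuation, collapses whitespace; "hypothetical" /
#' "unknown" / empty labels become NA (the no-vote sentinel). Annotations
#' from five heterogeneous sources cannot be compared verbatim without such
#' normalization; fuzzy matching is deliberately avoided as unauditable.
#'
#' @param x character vector of raw annotation strings.
#' @return normalized character vector with NA for non-informative labels.
#' @export
normalize_annotation <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("[[:punct:]]+", " ", y)
  y <- gsub("[[:space:]]+", " ", trimws(y))
  y[!nzchar(y) | grepl("^(hypothetical|unknown|uncharacterized)( protein)?$",
                       y)] <- NA_character_
  y[is.na(x)] <- NA_character_
  y
}

#' Consensus annotation from multi-annotator votes
#'
#' Exact-match voting on normalized labels. The homology-based source
#' (`homology_annotator`) contributes its lowest-e-value non-hypothetical
#' hit as its vote, usable both for the two-vote consensus and as the
#' fallback. Status is `consensus` when >= 2 votes agree (ties broken
#' toward the lexicographically smallest label), `putative` when there is
#' no agreement but the homology vote exists with e-value below
#' `fallback_evalue_max` (label prefixed "putative"), and `hypothetical`
#' otherwise.
#'
#' @param votes data.frame for one gene: columns `annotator`, `annotation`,
#'   `evalue` (NA except for the homology source), optionally `gene_id`.
#' @param homology_annotator annotator name of the homology-based source.
#' @param fallback_evalue_max e-value gate for the homology fallback.
#' @return list with `gene_id` (NA if absent), `label`, `status`.
#' @export
consensus_annotation <- function(votes, homology_annotator = "blastp",
                                 fallback_evalue_max = 1e-5) {
  gene_id <- if (nrow(votes) && "gene_id" %in% names(votes)) {
    votes$gene_id[1L]
  } else NA_character_
  if (nrow(votes) == 0L) {
    return(list(gene_id = gene_id, label = "hypothetical",
                status = "hypothetical"))
  }
  votes$norm <- normalize_annotation(votes$annotation)
  hom <- votes[votes$annotator == homology_annotator & !is.na(votes$norm), ,
               drop = FALSE]
  hom_vote <- NULL
  if (nrow(hom)) {
    hom <- hom[order(hom$evalue, hom$norm), , drop = FALSE]
    hom_vote <- hom[1L, ]
  }
  # one vote per non-homology annotator (first row), plus the homology vote
  oth <- votes[votes$annotator != homology_annotator, , drop = FALSE]
  oth <- oth[!duplicated(oth$annotator), , drop = FALSE]
  ballots <- c(oth$norm, if (!is.null(hom_vote)) hom_vote$norm)
  ballots <- ballots[!is.na(ballots)]
  if (length(ballots)) {
    tab <- table(ballots)
    top <- max(tab)
    if (top >= 2L) {
      winners <- sort(names(tab)[tab == top])
      return(list(gene_id = gene_id, label = winners[1L],
                  status = "consensus"))
    }
  }
  if (!is.null(hom_vote) && !is.na(hom_vote$evalue) &&
      hom_vote$evalue < fallback_evalue_max) {
    return(list(gene_id = gene_id,
                label = paste("putative", hom_vote$norm),
                status = "putative"))
  }
  list(gene_id = gene_id, label = "hypothetical", status = "hypothetical")
}

.SUBUNIT_ORDER <- c("alpha", "reductase", "beta", "coupling")

#' Check SDIMO operon subunit order on a contig
#'
#' The conserved order is alpha hydroxylase, reductase, beta subunit,
#' regulatory/coupling component, read along the operon strand (reverse-
#' strand operons are read right to left). Contigs that do not extend over
#' all four subunits report the missing subunits with `conforms = NA`
#' (not applicable). A duplicated subunit label on one contig is flagged and
#' does not conform.
#'
#' @param features feature data.frame for one contig (columns `gene_id`,
#'   `start`, `strand`).
#' @param subunit_labels named character vector gene_id -> subunit role
#'   (one of alpha/reductase/beta/coupling; other genes are ignored).
#' @return list with `contig_id`, `found_order`, `conforms` (TRUE/FALSE/NA),
#'   `missing`, `duplicated`.
#' @export
check_operon_order <- function(features, subunit_labels) {
  contig_id <- if (nrow(features)) features$contig_id[1L] else NA_character_
  roles <- unname(subunit_labels[features$gene_id])
  keep <- !is.na(roles) & roles %in% .SUBUNIT_ORDER
  f <- features[keep, , drop = FALSE]
  roles <- roles[keep]
  if (nrow(f) == 0L) {
    return(list(contig_id = contig_id, found_order = character(0),
                conforms = NA, missing = .SUBUNIT_ORDER,
                duplicated = character(0)))
  }
  ord <- order(f$start)
  roles <- roles[ord]
  strands <- f$strand[ord]
  # read along the operon strand
  neg <- sum(strands == "-") > length(strands) / 2
  if (neg) roles <- rev(roles)
  dup <- unique(roles[duplicated(roles)])
  if (length(dup)) {
    return(list(contig_id = contig_id, found_order = roles,
                conforms = FALSE, missing = character(0), duplicated = dup))
  }
  missing <- setdiff(.SUBUNIT_ORDER, roles)
  if (length(missing)) {
    return(list(contig_id = contig_id, found_order = roles, conforms = NA,
                missing = missing, duplicated = character(0)))
  }
  list(contig_id = contig_id, found_order = roles,
       conforms = identical(roles, .SUBUNIT_ORDER),
       missing = character(0), duplicated = character(0))
}

#' Detect inverted terminal repeats on a contig
#'
#' Reports (i) terminal gene pairs -- the first and last feature -- whose
#' contig subsequences are exact reverse complements (the transposase-pair
#' signature), and (ii) terminal blocks of length >= `min_len` where the
#' contig prefix equals the reverse complement of its suffix. Exact matching
#' only.
#'
#' @param contig_seq nucleotide contig string.
#' @param features feature data.frame for this contig (may be empty).
#' @param min_len minimum terminal block length.
#' @return data.frame with `type` (terminal_gene_pair / terminal_repeat),
#'   `length_bp`, `gene_a`, `gene_b`.
#' @export
find_itr <- function(contig_seq, features = NULL, min_len = 100L) {
  out <- list()
  if (!is.null(features) && nrow(features) >= 2L) {
    f <- features[order(features$start), , drop = FALSE]
    g1 <- f[1L, ]; gN <- f[nrow(f), ]
    s1 <- substr(contig_seq, g1$start, g1$end)
    sN <- substr(contig_seq, gN$start, gN$end)
    if (nchar(s1) == nchar(sN) && s1 == revcomp(sN)) {
      out[[length(out) + 1L]] <- data.frame(
        type = "terminal_gene_pair", length_bp = nchar(s1),
        gene_a = g1$gene_id, gene_b = gN$gene_id,
        stringsAsFactors = FALSE)
    }
  }
  # a terminal repeat of length k satisfies prefix_k(c) == revcomp(suffix_k(c))
  # == prefix_k(revcomp(c)), so the longest one is the longest common prefix
  # of the contig and its reverse complement
  n <- nchar(contig_seq)
  kmax <- min(floor(n / 2), 5000L)
  rc <- revcomp(contig_seq)
  x <- strsplit(substr(contig_seq, 1L, kmax), "", fixed = TRUE)[[1L]]
  y <- strsplit(substr(rc, 1L, kmax), "", fixed = TRUE)[[1L]]
  diffs <- which(x != y)
  best <- if (length(diffs)) diffs[1L] - 1L else kmax
  if (best >= min_len) {
    out[[length(out) + 1L]] <- data.frame(
      type = "terminal_repeat", length_bp = best,
      gene_a = NA_character_, gene_b = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(type = character(0), length_bp = integer(0),
               gene_a = character(0), gene_b = character(0),
               stringsAsFactors = FALSE)
}

# longest k in [min_len, kmax] with suffix_k(a) == prefix_k(b).
# Anchored probe: any such match places the first min_len characters of b
# at position na - k + 1 of a, so candidate positions are the occurrences
# of that probe in a's terminal window, scanned left to right (longest k
# first) and verified in full.
.longest_suffix_prefix <- function(a, b, min_len, kmax) {
  na <- nchar(a)
  if (kmax < min_len) return(0L)
  probe <- substr(b, 1L, min_len)
  win_start <- na - kmax + 1L
  window <- substr(a, win_start, na)
  from <- 1L
  nw <- nchar(window)
  while (from <= nw - min_len + 1L) {
    rel <- regexpr(probe, substr(window, from, nw), fixed = TRUE)
    if (rel == -1L) break
    p_win <- from + as.integer(rel) - 1L
    p <- win_start + p_win - 1L
    k <- na - p + 1L
    if (k >= min_len && substr(a, p, na) == substr(b, 1L, k)) {
      return(k)
    }
    from <- p_win + 1L
  }
  0L
}

#' Detect fixed-length terminal overlaps between contigs
#'
#' For each unordered contig pair, reports the longest exact match of
#' length >= `min_len` for each of the four end combinations: suffix of A =
#' prefix of B (3'/5'), prefix of A = suffix of B (5'/3'), suffix of A =
#' reverse complement of the suffix of B (3'/3'), and prefix of A = reverse
#' complement of the prefix of B (5'/5'). Terminal overlaps between contigs
#' assembled from the same region are the signature of an assembly break.
#' Exact matching only (`max_mismatch = 0`).
#'
#' @param contigs named character vector of >= 2 nucleotide contigs.
#' @param min_len minimum overlap length in bp.
#' @param max_len maximum overlap length searched (terminal window cap).
#' @param max_mismatch reserved; only 0 (exact) is implemented.
#' @return data.frame with `contig_a`, `contig_b`, `a_end`, `b_end`,
#'   `length_bp`, `identity`.
#' @export
find_terminal_overlaps <- function(contigs, min_len = 100L,
                                   max_len = 5000L, max_mismatch = 0L) {
  if (length(contigs) < 2L) stop("need at least 2 contigs")
  if (max_mismatch != 0L) stop("only exact matching (max_mismatch = 0) is implemented")
  ids <- names(contigs)
  out <- list()
  add <- function(a, b, a_end, b_end, len) {
    out[[length(out) + 1L]] <<- data.frame(
      contig_a = a, contig_b = b, a_end = a_end, b_end = b_end,
      length_bp = len, identity = 1.0, stringsAsFactors = FALSE)
  }
  for (i in seq_len(length(contigs) - 1L)) {
    for (j in seq(i + 1L, length(contigs))) {
      a <- contigs[[i]]; b <- contigs[[j]]
      kmax <- min(nchar(a), nchar(b), max_len)
      if (kmax < min_len) next
      k <- .longest_suffix_prefix(a, b, min_len, kmax)
      if (k >= min_len) add(ids[i], ids[j], "3'", "5'", k)
      k <- .longest_suffix_prefix(b, a, min_len, kmax)
      if (k >= min_len) add(ids[i], ids[j], "5'", "3'", k)
      rb <- revcomp(b)
      # suffix(a) == revcomp(suffix(b)): suffix of a vs prefix of revcomp(b)
      k <- .longest_suffix_prefix(a, rb, min_len, kmax)
      if (k >= min_len) add(ids[i], ids[j], "3'", "3'", k)
      # prefix(a) == revcomp(prefix(b)): suffix of revcomp(b) vs prefix of a
      k <- .longest_suffix_prefix(rb, a, min_len, kmax)
      if (k >= min_len) add(ids[i], ids[j], "5'", "5'", k)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig_a = character(0), contig_b = character(0),
               a_end = character(0), b_end = character(0),
               length_bp = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE)
}
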