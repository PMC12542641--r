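#' Read a FASTA file into a named character vector
#'
#' Headers are truncated at the first whitespace to obtain the record id;
#' the full header line is kept in the `"description"` attribute. Sequences
#' are stored uppercase. Protein records may contain the 20 standard amino
#' acids plus `X`; nucleotide records may contain `ACGTN`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return Named character vector of sequences with attributes
#'   `description` (full headers) and `alphabet`. An empty file yields an
#'   empty vector with a warning (absence of candidates in a sample is a
#'   legitimate outcome, not an error).
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    out <- character(0)
    attr(out, "description") <- character(0)
    attr(out, "alphabet") <- alphabet
    return(out)
  }
  desc <- names(set)
  ids <- sub("[ \t].*$", "", desc)
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id in ", path, ": ", dup[1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ", ids[!nzchar(seqs)][1L])
  }
  ok <- if (alphabet == "protein") .AA_OK else .DNA_OK
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
    b <- setdiff(ch, ok)
    if (length(b)) b[1L] else NA_character_
  }, character(1))
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    stop("illegal character '", bad[i], "' in record '", ids[i],
         "' (", .fasta_line_of(path, ids[i], bad[i]), ")")
  }
  attr(seqs, "description") <- desc
  attr(seqs, "alphabet") <- alphabet
  seqs
}

# locate the first file line of a record containing an offending character
.fasta_line_of <- function(path, id, ch) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  rec <- which(sub("[ \t].*$", "", sub("^>", "", lines[hdr])) == id)[1L]
  if (is.na(rec)) return("line unknown")
  from <- hdr[rec] + 1L
  to <- if (rec < length(hdr)) hdr[rec + 1L] - 1L else length(lines)
  for (i in seq(from, to)) {
    if (grepl(ch, toupper(lines[i]), fixed = TRUE)) {
      return(paste0("line ", i))
    }
  }
  paste0("record starting at line ", hdr[rec])
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (ids as names). A `description`
#'   attribute, when present and matching in length, is written as the
#'   header; otherwise the names are used.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  desc <- attr(seqs, "description")
  if (is.null(desc) || length(desc) != length(seqs)) desc <- names(seqs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", desc[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read homology hits in the 12-column tabular dialect
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. `pident` is a percentage on the 0-100 scale; query
#' coverage is left unset (it is computed later from `qstart`/`qend` and the
#' query length).
#'
#' @param path path to a tab-separated hits file (no header).
#' @return data.frame with columns `query_id`, `reference_id`, `pident`,
#'   `alen`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `score`, `qcov` (NA).
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop("line ", i, ": expected 12 tab-separated columns, got ", nf[i])
  }
  m <- do.call(rbind, parts)
  data.frame(
    query_id = m[, 1L], reference_id = m[, 2L],
    pident = as.numeric(m[, 3L]), alen = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), score = as.numeric(m[, 12L]),
    qcov = NA_real_, stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(query_id = character(0), reference_id = character(0),
             pident = numeric(0), alen = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             score = numeric(0), qcov = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read / write trees in newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] with
#' up-front bracket balancing diagnostics and branch lengths canonicalised
#' to 6 decimals on write, so that write/read/write round-trips are
#' byte-identical.
#'
#' @param path file path.
#' @return `read_newick` returns an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .check_balanced(txt)
  if (!grepl("(", txt, fixed = TRUE)) {
    # single-leaf tree "label[:length];", which ape mishandles
    m <- regmatches(txt, regexec("^\\s*([^:;,()]+)(:([0-9.eE+-]+))?;", txt))[[1L]]
    if (length(m) == 0L || !nzchar(m[2L])) {
      stop("newick parse error in ", path)
    }
    tr <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                         tip.label = m[2L], Nnode = 1L),
                    class = "phylo", order = "cladewise")
    if (nzchar(m[4L])) tr$edge.length <- as.numeric(m[4L])
    return(tr)
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  if (is.null(tr)) stop("newick parse error in ", path)
  tr
}

.check_balanced <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses at position ", i)
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth,
                        " unclosed '(' at end of input")
  invisible(TRUE)
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6L)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write gene feature tables
#'
#' Tab-separated, with header: contig_id, gene_id, start, end, strand,
#' product_id. Coordinates are 1-based inclusive (GFF convention), and are
#' kept 1-based inclusive in memory (the R/Bioconductor convention).
#'
#' @param path file path.
#' @return data.frame of features.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "gene_id", "start", "end", "strand", "product_id")
  if (!all(need %in% names(df))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 1L) || any(df$start > df$end)) {
    stop("invalid coordinates: need 1 <= start <= end")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1L])
  }
  df
}

#' @rdname read_features
#' @param features data.frame as returned by [read_features()].
#' @export
write_features <- function(features, path) {
  .write_tsv(features, path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read per-sample contig read counts and totals
#'
#' `read_counts` expects columns sample_id, contig_id, count;
#' `read_totals` expects sample_id, total_mapped. Per-sample sums of contig
#' counts are allowed to be below total_mapped (reads mapping elsewhere) and
#' are not required to be (multi-mapping).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "contig_id", "count")
  if (!all(need %in% names(df))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  }
  df$count <- as.integer(df$count)
  if (any(df$count < 0L)) stop("negative read count")
  df
}

#' @rdname read_counts
#' @export
read_totals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "total_mapped")
  if (!all(need %in% names(df))) {
    stop("totals table must have columns: ", paste(need, collapse = ", "))
  }
  df$total_mapped <- as.numeric(df$total_mapped)
  if (any(df$total_mapped <= 0)) stop("total_mapped must be positive")
  df
}

#' Read annotation vote tables
#'
#' One row per (gene, annotator) vote: gene_id, annotator, annotation,
#' evalue (may be empty/NA; populated for the homology-based source).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_votes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "annotator", "annotation")
  if (!all(need %in% names(df))) {
    stop("votes table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"evalue" %in% names(df)) df$evalue <- NA_real_
  df$evalue <- suppressWarnings(as.numeric(df$evalue))
  df
}
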