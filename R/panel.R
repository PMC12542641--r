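# Synthetic labelled reference panel of SDIMO alpha hydroxylases.
#
# The published panels of alpha-hydroxylase references are third-party data
# that cannot be redistributed here, so this module generates a SYNTHETIC
# stand-in panel with the same structure: 39 entries labelled CDDP
# (candidate dioxane-degrading protein), OUT (literature outgroup), COMP
# (composite, curated from dioxane-degrader genomes) or COMPOUT (composite
# outgroup), spread over SDIMO groups I-VI and subtypes (DxmA-like,
# PrmA*-like, TmoA-like, ...), each carrying two DE*RH di-iron centre
# motifs at known anchors -- except one dioxane-positive partial COMP entry
# that lacks both motifs.

.PANEL_LEN <- 350L
.MOTIF1_ANCHOR <- 160L
.MOTIF2_ANCHOR <- 260L
.MOTIF_FLANK <- 5L

# id, label, group, subtype, dioxane_positive
.panel_composition <- function() {
  txt <- c(
    "CDDP1    CDDP    V   DxmA-like  TRUE",
    "CDDP2    CDDP    V   DxmA-like  TRUE",
    "CDDP3    CDDP    II  TmoA-like  TRUE",
    "CDDP4    CDDP    I   TomA3-like TRUE",
    "CDDP5    CDDP    III sMMO-like  TRUE",
    "CDDP6    CDDP    VI  PrmA-like  TRUE",
    "CDDP7    CDDP    V   PrmA*-like TRUE",
    "CDDP8    CDDP    V   PrmA*-like TRUE",
    "OUT1     OUT     I   TomA3-like FALSE",
    "OUT2     OUT     II  TmoA-like  FALSE",
    "OUT3     OUT     II  TmoA-like  FALSE",
    "OUT4     OUT     III sMMO-like  FALSE",
    "OUT5     OUT     V   PrmA*-like FALSE",
    "OUT6     OUT     V   PrmA*-like FALSE",
    "OUT7     OUT     V   PrmA*-like FALSE",
    "OUT8     OUT     VI  PrmA-like  FALSE",
    "OUT9     OUT     I   TomA3-like FALSE",
    "OUT10    OUT     VI  PrmA-like  FALSE",
    "COMP1    COMP    V   DxmA-like  FALSE",
    "COMP2    COMP    V   DxmA-like  FALSE",
    "COMP3    COMP    V   DxmA-like  FALSE",
    "COMP4    COMP    II  TmoA-like  FALSE",
    "COMP5    COMP    I   TomA3-like FALSE",
    "COMP6    COMP    III sMMO-like  FALSE",
    "COMP7    COMP    V   DxmA-like  TRUE",
    "COMP8    COMP    V   DxmA-like  FALSE",
    "COMP9    COMP    V   DxmA-like  TRUE",
    "COMP10   COMP    VI  PrmA-like  FALSE",
    "COMP11   COMP    IV  EtnC-like  FALSE",
    "COMP12   COMP    IV  EtnC-like  FALSE",
    "COMP13   COMP    V   PrmA*-like FALSE",
    "COMP14   COMP    II  TmoA-like  FALSE",
    "COMP15   COMP    I   TomA3-like FALSE",
    "COMP16   COMP    V   PrmA*-like FALSE",
    "COMPOUT1 COMPOUT V   PrmA*-like FALSE",
    "COMPOUT2 COMPOUT V   PrmA*-like FALSE",
    "COMPOUT3 COMPOUT II  TmoA-like  FALSE",
    "COMPOUT4 COMPOUT I   TomA3-like FALSE",
    "COMPOUT5 COMPOUT VI  PrmA-like  FALSE")
  m <- do.call(rbind, strsplit(trimws(txt), "[ ]+"))
  data.frame(id = m[, 1L], dioxane_label = m[, 2L], group = m[, 3L],
             subtype = m[, 4L], dioxane_positive = as.logical(m[, 5L]),
             stringsAsFactors = FALSE)
}

.random_protein <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

.plant_motifs <- function(seq) {
  for (a in c(.MOTIF1_ANCHOR, .MOTIF2_ANCHOR)) {
    mid <- sample(setdiff(.AA20, c("D", "E", "R", "H")), 1L)
    substr(seq, a, a + 4L) <- paste0("DE", mid, "RH")
  }
  seq
}

# positions shielded from substitution: both motifs plus +/- flank columns
.protected_positions <- function(len, flank = .MOTIF_FLANK) {
  p <- c(seq(.MOTIF1_ANCHOR - flank, .MOTIF1_ANCHOR + 4L + flank),
         seq(.MOTIF2_ANCHOR - flank, .MOTIF2_ANCHOR + 4L + flank))
  p[p >= 1L & p <= len]
}

# substitute exactly k positions (never to the same residue), avoiding
# `protected`; `forced` positions are substituted first
.substitute_positions <- function(seq, k, protected = integer(0),
                                  forced = integer(0)) {
  len <- nchar(seq)
  k <- max(k, length(forced))
  allowed <- setdiff(seq_len(len), union(protected, forced))
  n_free <- k - length(forced)
  if (n_free > length(allowed)) {
    stop("target identity unreachable: ", n_free,
         " substitutions needed but only ", length(allowed),
         " unprotected positions available")
  }
  pos <- c(forced, if (n_free > 0L) sample(allowed, n_free))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), positions = sort(pos))
}

.mutate_fraction <- function(seq, frac, protected = integer(0)) {
  .substitute_positions(seq, round(nchar(seq) * frac), protected)$seq
}

#' Generate the synthetic labelled SDIMO reference panel
#'
#' Builds a deterministic 39-entry panel of synthetic alpha-hydroxylase
#' proteins (350 aa; one partial 220 aa entry) with hierarchical family
#' structure: a single family root, one ancestor per SDIMO group diverged
#' ~30% from the root, subtype centres diverged ~12% from their group
#' ancestor, and entries diverged ~5% from the subtype centres. The
#' resulting identities (~90% within subtype, ~75% within group, ~50%
#' between groups) mirror one enzyme family and keep pairwise distances far
#' from saturation, which distance-based tree building needs. All entries
#' carry the DE*RH motif at anchors 160 and 260 except `COMP7`, a
#' dioxane-positive partial composite that lacks both motifs. Group V
#' outgroup entries (used for re-rooting trees) descend from a dedicated
#' sub-centre so they form a clean clade.
#'
#' @param seed integer seed; the default pins the canonical panel.
#' @return object of class `tm_panel`: list with `proteins` (named character
#'   vector) and `labels` (data.frame: id, dioxane_label, group, subtype,
#'   dioxane_positive, motif1_anchor, motif2_anchor).
#' @export
synthetic_panel <- function(seed = 424242L) {
  key <- paste0("panel_", seed)
  if (!is.null(.tm_env[[key]])) return(.tm_env[[key]])
  comp <- .panel_composition()
  panel <- withr::with_seed(seed, {
    prot_all <- .protected_positions(.PANEL_LEN)
    groups <- c("I", "II", "III", "IV", "V", "VI")
    root <- .plant_motifs(.random_protein(.PANEL_LEN))
    anc <- setNames(vapply(groups, function(g)
      .mutate_fraction(root, 0.30, prot_all), character(1)), groups)
    subtypes <- unique(comp[, c("group", "subtype")])
    centre <- setNames(vector("character", nrow(subtypes)),
                       paste(subtypes$group, subtypes$subtype))
    for (i in seq_len(nrow(subtypes))) {
      centre[i] <- .mutate_fraction(anc[[subtypes$group[i]]], 0.12, prot_all)
    }
    # split the group V PrmA*-like subtype into a degrader-side and an
    # outgroup-side sub-centre so the rooting outgroup is monophyletic
    prm <- centre[["V PrmA*-like"]]
    prm_in <- .mutate_fraction(prm, 0.06, prot_all)
    prm_out <- .mutate_fraction(prm, 0.06, prot_all)
    seqs <- character(nrow(comp))
    for (i in seq_len(nrow(comp))) {
      key_i <- paste(comp$group[i], comp$subtype[i])
      base <- if (key_i == "V PrmA*-like") {
        if (comp$dioxane_label[i] %in% c("OUT", "COMPOUT")) prm_out else prm_in
      } else {
        centre[[key_i]]
      }
      seqs[i] <- .mutate_fraction(base, 0.05, prot_all)
    }
    names(seqs) <- comp$id
    # COMP7: partial, both motifs ablated (D -> A), anchors unset
    s7 <- seqs[["COMP7"]]
    substr(s7, .MOTIF1_ANCHOR, .MOTIF1_ANCHOR) <- "A"
    seqs[["COMP7"]] <- substr(s7, 1L, 220L)
    labels <- comp
    labels$motif1_anchor <- ifelse(labels$id == "COMP7", NA_integer_,
                                   .MOTIF1_ANCHOR)
    labels$motif2_anchor <- ifelse(labels$id == "COMP7", NA_integer_,
                                   .MOTIF2_ANCHOR)
    structure(list(proteins = seqs, labels = labels), class = "tm_panel")
  })
  .tm_env[[key]] <- panel
  panel
}

#' Panel entries usable as rooting outgroups
#'
#' @param panel a `tm_panel`.
#' @param group SDIMO group of the outgroup entries (default `"V"`).
#' @return character vector of entry ids with label OUT or COMPOUT in the
#'   requested group.
#' @export
panel_outgroup_ids <- function(panel, group = "V") {
  lb <- panel$labels
  lb$id[lb$group == group & lb$dioxane_label %in% c("OUT", "COMPOUT")]
}

# ids with documented dioxane-degradation evidence: CDDPs, plus COMP
# entries flagged dioxane-positive
.panel_evidence_ids <- function(labels) {
  labels$id[labels$dioxane_label == "CDDP" | labels$dioxane_positive]
}

#' Write / read panel label tables
#'
#' Tab-separated with header: id, dioxane_label, group, subtype,
#' dioxane_positive, motif1_anchor, motif2_anchor.
#'
#' @param panel a `tm_panel`.
#' @param path file path.
#' @export
write_panel_labels <- function(panel, path) {
  .write_tsv(panel$labels, path)
}

#' @rdname write_panel_labels
#' @param fasta path to the panel protein FASTA.
#' @return `read_panel` returns a `tm_panel`.
#' @export
read_panel <- function(fasta, path) {
  proteins <- read_fasta(fasta, "protein")
  labels <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "dioxane_label", "group", "subtype", "dioxane_positive")
  if (!all(need %in% names(labels))) {
    stop("panel label table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"motif1_anchor" %in% names(labels)) labels$motif1_anchor <- NA_integer_
  if (!"motif2_anchor" %in% names(labels)) labels$motif2_anchor <- NA_integer_
  if (!setequal(labels$id, names(proteins))) {
    stop("panel FASTA ids and label table ids disagree")
  }
  labels <- labels[match(names(proteins), labels$id), ]
  rownames(labels) <- NULL
  structure(list(proteins = proteins, labels = labels), class = "tm_panel")
}
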