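---
title: "Tiered discovery of SDIMO alpha-hydroxylase genes in metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered discovery of SDIMO alpha-hydroxylase genes in metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierminer)
```

## The problem

Soluble di-iron monooxygenases (SDIMOs) are multi-subunit bacterial enzymes
whose alpha-hydroxylase subunit can initiate the oxidation of recalcitrant
ethers such as 1,4-dioxane, an emerging groundwater contaminant. Six SDIMO
groups (I--VI) are distinguished by phylogeny and substrate range; dioxane
turnover can be growth-linked (direct metabolism, e.g. DxmA of
*Pseudonocardia dioxanivorans*) or co-metabolic, induced by substrates such
as tetrahydrofuran, propane or toluene (e.g. PrmA\*-like and TmoA-like
enzymes). Assessing the dioxane-degradation potential of an environmental
community from shotgun metagenomes therefore means finding alpha-hydroxylase
genes on assembled contigs, deciding how strong the evidence is for each
candidate, placing the survivors among labelled reference enzymes, and
quantifying them across samples.

tierminer implements that workflow as a tested, reusable pipeline:

1. **Screen** all predicted proteins against a labelled reference panel of
   alpha hydroxylases (Smith--Waterman local alignment, BLOSUM62, gap
   open 11 / extend 1 -- the de facto protein-search defaults, configurable
   because the original search tool's parameters are not recoverable from a
   published method section alone). Precomputed 12-column tabular hits can
   be ingested instead, with the e-value gate `evalue <= 1e-50`.
2. **Validate motifs**: the DE\*RH signature of the carboxylate di-iron
   centre is checked positionally, by mapping each reference motif anchor
   through the best-hit alignment. A motif is *present* (pattern match near
   the mapped anchor), *absent* (no match), or *gap* (the anchor region is
   deleted in the query or outside the aligned span).
3. **Tier** the candidates. Tier 1: identity >= 90%, alignment length
   >= 125 columns, query coverage >= 60%, and at least one intact DE\*RH
   motif. Tier 2: identity in [50, 90) with the same length and coverage
   gates and *no* motif requirement. Contigs carrying a Tier-1 candidate
   contribute no Tier-2 candidates.
4. **Dereplicate** carrier contigs by greedy identity clustering
   (c = 0.999, aS = 0.999, nucleotide space).
5. **Classify**: non-redundant Tier-1 proteins are placed on a
   neighbor-joining tree with the panel, the tree is re-rooted with the
   group V outgroup references, and each query is called CDDP-like
   (candidate dioxane degrader), outgroup-like, or ambiguous from the panel
   labels in its minimal enclosing clade; the SDIMO group is the clade
   majority.
6. **Quantify**: contig abundance is RPKM (reads per kilobase per million
   mapped reads); clade x sample cells sum members' origin-sample RPKM
   only.
7. **Inspect neighborhoods**: consensus annotation voting over
   heterogeneous annotators, SDIMO subunit order
   (alpha, reductase, beta, coupling), inverted terminal repeats, and
   fixed-length terminal contig overlaps (assembly-break signatures).

## Decision rules and their edge cases

**Threshold boundaries are inclusive.** "Minimum of 90%" means 90.0 is
Tier 1; the Tier-2 identity window is therefore half-open, [50, 90).

**The motif rule applies to Tier 1 only**, and either motif copy
satisfies it. This mirrors a reference panel that legitimately contains a
dioxane-positive partial protein lacking both motifs: motif absence is
evidence against a *candidate*, not against membership of the family.

**Anchored motif detection** is the default rather than a whole-sequence
regex scan, because the motif was checked in protein alignments, i.e.
positionally. The whole-sequence scan remains as the fallback when a
reference carries no anchors. The `gap` state is deliberately distinct from
`absent`: a deletion spanning the first di-iron centre disqualifies a
sequence from representing its clade but is routinely an assembly artifact,
not a biological absence.

**Consensus annotation** requires two or more of the annotation sources to
agree on the normalized label (lowercase, punctuation stripped, whitespace
collapsed; "hypothetical"/"unknown" are no-votes). With no agreement, the
homology source's lowest-e-value annotated hit is used, prefixed
"putative", provided its e-value is below 1e-05; otherwise the gene is
"hypothetical". Normalization is explicit configuration because
cross-annotator label comparison is impossible verbatim; fuzzy matching was
rejected as unauditable.

**Representative selection** within a clade prefers the most abundant
member whose *first* motif is intact (it neighbours the hydrophobic
residues that determine SDIMO group); members skipped over are reported
with reasons. When no member qualifies, the most abundant member is
returned flagged rather than dropping the clade.

**Greedy clustering** follows the published greedy-incremental contract:
length-descending scan (ties by id), each sequence joins the first cluster
whose representative matches at `c` (identity = identical columns / length
of the shorter sequence) and `aS` (aligned coverage of the shorter
sequence). The word-filter heuristics of the original tool are omitted --
at desk scale every comparison is an exact alignment, which keeps the
identity definition auditable and the procedure deterministic. Order
dependence is pinned by the sort, so results are reproducible.

**Neighbor joining replaces approximate-ML trees.** The tree is used only
for clade membership, so a deterministic, oracle-checkable method is
preferable: NJ provably reconstructs additive matrices, ties in the Q
criterion break toward the smallest index pair, and negative branch
lengths are clamped to zero with the deficit moved to the sister branch.
Distances are p-distances from global alignments with gap columns excluded
from the denominator. If the outgroup is not cleanly separable, the root
maximizes outgroup purity and the tree is flagged; query leaves are
neutral in that score, so planted queries inside an outgroup clade do not
distort rooting.

**Coordinates** are 1-based inclusive in files (GFF convention) *and* in
memory: the R ecosystem (GRanges, `substr`) is 1-based inclusive, so
converting to 0-based half-open internally would only add a translation
layer and its bugs.

**In-repo screening computes no e-values.** E-value calibration depends on
database-size statistics of a specific search tool and is out of scope; the
in-repo retention rule is a score floor of 1.0 per column of the shorter
sequence, which retains genuine family members down to ~40% identity while
rejecting composition-shuffled decoys by two orders of magnitude (verified
empirically over 100 decoys in the test suite). The 1e-50 e-value gate
applies when precomputed tabular hits are ingested.

**Query coverage orientation.** The published search ran the panel as
queries against the predicted proteins, so its "query coverage" was
panel-side; this package computes coverage of the protein being classified
(the quantity the tier gate is protecting). For full-length candidates the
two coincide; for fragmentary candidates ours is the stricter reading.

## The synthetic metagenome: what it emulates, what it does not

There is no redistributable reference panel, so `synthetic_panel()`
generates a 39-entry stand-in, labelled synthetic throughout: labels CDDP /
OUT / COMP / COMPOUT, groups I--VI, subtypes (DxmA-like, PrmA\*-like,
TmoA-like, TomA3-like, sMMO-like, EtnC-like, PrmA-like), two DE\*RH motifs
at fixed anchors, one dioxane-positive partial COMP entry lacking both
motifs, and group V outgroup entries forming a clean rooting clade. The
family is generated hierarchically -- a single root, group ancestors at
~30% divergence, subtype centres at ~12%, entries at ~5% -- giving ~90%
within-subtype, ~75% within-group and ~50% between-group identity:
the shape of one real enzyme family, and far enough from saturation that
distance-based tree building is well-posed. Sequences are 350 aa
(desk-scaled from the ~500 aa of real alpha subunits; all decision rules
depend on relative, not absolute, lengths -- the 125-column gate is still a
36% span).

`simulate_metagenome()` plants operons of known reference, target identity,
motif status and sample into multi-sample contig sets:

* **Divergence is positional substitution only** (no indels), so realized
  identity -- and therefore each plant's expected tier -- is exact by
  construction and the ground truth is closed-form.
* **Background genes are composition-shuffled panel sequences**: realistic
  residue composition with no retained homology, so the screen's decoy
  rejection is exercised on every run.
* **Counts are negative binomial** per (sample, contig) -- the standard
  overdispersed coverage model -- with mean 200 reads in the origin sample,
  5% of that elsewhere, dispersion 2, and a fixed 2e6 reads per sample
  mapping outside the simulated contig set, so contig counts always sum
  below `total_mapped` (as real multi-mapped counting guarantees in the
  other direction, the sum constraint is not assumed downstream).
* **Operons** emit the conserved subunit order alpha, reductase, beta,
  coupling; optional terminal transposase pairs are byte-identical in
  reverse complement (an inverted terminal repeat), and optional paired
  contigs share an exactly-L-bp terminal overlap (127 bp by default, the
  observed assembly-break length), with an explicit guard against the
  shared block extending by one base.

What a green test on this generator does **not** establish: robustness to
indels and fragmented gene calls, to assembly chimeras, to e-value
behaviour of heuristic search engines, or to real phylogenetic rate
heterogeneity. The generator's divergences are uniform across sites
(outside protected motif windows), so motif conservation in real families
is *better* than simulated -- the direction that makes the tier gate's
motif check conservative here.

## Numerical choices

* Protein scoring: BLOSUM62 with the `X` row and column set to 0 --
  ambiguity should neither reward nor penalize a column. A gap of length k
  costs `open + k * extend`.
* Identity in `hit_stats()` counts gap columns in the alignment length and
  never as identities; p-distances exclude gap columns from the
  denominator. These are different statistics for different jobs (a gate
  on alignment quality vs an evolutionary distance).
* All tie-breaks are lexicographic (best hit: highest score then lowest
  reference id; clustering order: length then id; NJ: smallest index
  pair), so every stage is deterministic and the full pipeline is
  idempotent under a fixed simulation seed.
* Boundary-safe testing: recovery tests plant identities >= 92 or <= 85,
  away from the 90% gate, because local-alignment end trimming can move
  measured identity ~1 point above the planted positional identity.

## Known limitations

* The greedy clustering is exact but O(n^2) alignments at desk scale; it is
  not a CD-HIT replacement for millions of sequences.
* Clade calling automates a judgment the original analysis made manually
  (seven clades cut from a tree by eye); the minimal-clade rule is the
  auditable approximation, and ambiguous calls are a first-class outcome
  rather than forced labels.
* The hydrophobic-flank group-confirmation score (`confirm_group()`) is
  advisory only -- the exact diagnostic positions are not published -- and
  is never used as a gate.
* Plasmid/virus scores, toxin-antitoxin, transposase-family and MITE calls
  are ingested as pass-through labels when provided, never computed.

## A worked example

```{r example, eval = FALSE}
panel <- synthetic_panel()
cfg <- simulation_config(
  seed = 11, n_samples = 2, n_contigs_per_sample = 2,
  planted_operons = list(
    plant_spec("CDDP1", 96),                      # Tier 1, DxmA-like
    plant_spec("CDDP3", 93),                      # Tier 1, TmoA-like
    plant_spec("OUT5", 70),                       # Tier 2, outgroup side
    plant_spec("CDDP1", 95, ablate_first_motif = TRUE,
               ablate_second_motif = TRUE),       # motif-ablated: no tier
    plant_spec("COMP9", 95, paired_overlap_len = 127)))
sim <- simulate_metagenome(cfg, panel)
res <- sdimo_pipeline(sim$proteins, sim$contigs, sim$features,
                      sim$counts, sim$totals, panel = panel,
                      contig_origin = sim$contig_origin)
res$gate$tier1        # three Tier-1 candidates, motifs present
res$clade_calls       # CDDP-like / outgroup-like calls with groups
res$overlaps          # the planted 127-bp terminal overlap
```
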