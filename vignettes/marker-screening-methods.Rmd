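---
title: "Methods: plastome structural variation and marker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structural variation and marker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and design decisions behind
`plastidscreen`, in the order a user meets them. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The screening problem

A plastome panel (several annotated chloroplast genomes of related species)
carries highly uneven variation: the two inverted-repeat copies (IRa/IRb) are
kept near-identical by concerted evolution, the large single-copy region
(LSC) varies moderately, and the small single-copy region (SSC) can be
hyper-divergent. Marker screening that ranks windows purely by nucleotide
diversity (Pi) therefore tends to pick SSC intervals whose trees conflict
with the species phylogeny. The package's strategy is to quantify variation
per region (SNPs, indels, ALS, Pi), group species by SSC similarity, and then
select *coding* markers by length, SNP count and codon-usage bias, checking
each candidate's tree against a reference topology.

## Coordinates and containers

All coordinates are 1-based and closed, matching the IRanges/GenomicRanges
convention that R users expect; human-readable reports use the same
convention, so internal and reported coordinates coincide. Genomes are stored
linearly with a declared origin (by convention inside the LSC) but treated as
circular where it matters: partition detection scans a half-rotation as well,
and junction arithmetic wraps. Sequences admit `A,C,G,T,N` only; other
ambiguity codes are rejected at read time so that variant semantics stay
crisp. Gene features carry exons, strand, kind (CDS/tRNA/rRNA) and a free-text
functional class; alignments (`msa`) carry a per-species column map from
alignment columns to ungapped genome coordinates.

## Partition detection

`detect_partition()` defines the quadripartite structure as the longest pair
of disjoint segments in which one segment matches the reverse complement of
the other at `>= min_identity` (default 0.99) over `>= min_ir_len` bp
(default 10,000; scale it down for small test genomes). Candidates are found
by chaining exact 16-mer matches between the genome and its reverse
complement along anti-diagonals, splitting chains at gaps over 500 bp, and
verifying identity over the chained span. The reported boundaries are the
matched seed span rather than a per-base greedy extension: greedy extension
would, with probability ~1/4 per junction, overrun a true repeat end by one
or more chance-complementary bases, which makes exact boundary recovery on
constructed genomes impossible. The shorter single-copy interval is the SSC;
the IR copy that follows the LSC in genome order is labeled IRb. Genomes
without a qualifying repeat raise an explicit "no IR found" error rather than
falling back to a three-region partition.

## Variant conventions

Gap and `N` handling is pairwise deletion throughout: a column contributes to
a species pair only when both members hold one of `A,C,G,T`. A column is a
SNP if it carries at least two distinct real bases across the panel;
multi-allelic columns count once globally while pairwise statistics flag each
differing pair independently, which keeps global and pairwise tallies each
internally consistent. An indel event for a pair is a maximal run of columns
gapped in exactly one member after dropping columns gapped in both; runs
touching an alignment end are discarded as artifacts of alignment trimming.
ALS for a pair and region is the number of region columns valid for the pair
divided by the pairwise SNP count there — a true per-pair average SNP spacing;
zero-SNP pairs are capped at the valid length and flagged. Matrix
normalization divides by the off-diagonal maximum (so the top entry is
exactly 1) and is idempotent.

Sliding-window Pi uses 600 bp windows and 200 bp steps by default, the
standard setting for plastome scans. Windows are laid over alignment columns
(region labels are per column, and that is what published scans do); trailing
short windows are dropped, a window is labeled by its start column, and
windows with under 10% mean valid sites are flagged undefined rather than
reported as zero. `pairwise_mean_pi()` instead slices the region's columns
first (the two IR copies are scanned separately and pooled) so that region
means are never contaminated by boundary-crossing windows. Species grouping
is single linkage under a mean-Pi threshold: the default 0.1 is deliberately
conservative and is always echoed with results; the discordant-design
analyses in this package use 0.3, which sits between the within-set
(~0.04–0.15) and between-set (~0.5+) SSC means the generator produces.

## Codon bias

RSCU is the observed codon count scaled so a uniformly used family averages
1. GC3s is the G+C fraction at third positions of sense codons excluding Met,
Trp and stops. ENC uses Wright's original composition
`2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with family homozygosity
`F = (n * sum(p^2) - 1) / (n - 1)`, clamped to `[20, 61]`; Ile is its own
three-fold term. Families observed fewer than twice, or with a non-positive
homozygosity estimate (possible at small n), are omitted from their class
average; a missing three-fold class falls back to the mean of the two- and
four-fold averages, and a missing two-, four- or six-fold class leaves ENC
undefined. This is the original formulation rather than any later corrected
variant; it is pinned here so results are reproducible to the digit. The
expected curve is `ENC(s) = 2 + s + 29/(s^2 + (1-s)^2)`; genes within 1 ENC
unit of it (the `tol` default) are classified "on" (low bias), the
marker-vetting condition. Translation uses the plastid/bacterial code (table
11), whose codon-to-amino-acid map equals the standard table; only the start
codons differ, and non-ATG table-11 starts produce a warning, not an error.
Genes under 100 codons are flagged low-confidence. A CDS with an internal
stop is an error from `codon_stats()` directly, but `marker_table()` converts
it to undefined codon statistics, because evolved or degraded copies of real
genes do acquire stops and should not abort a panel-wide table.

## Marker screening

`per_gene_stats()` reproduces the published table shape: aligned CDS length
(alignment columns), SNP count, SNP per site to six decimals, and indel
sites. "Indel sites" counts alignment columns gapped in exactly one species —
a column count, not an event count — because that convention reproduces the
magnitudes seen in published per-gene tables; it is a documented assumption,
and event counts are available from `call_indels()` if preferred. The ideal
filter uses strict inequalities (length `> 1000`, SNPs `> 30`), so a gene
with exactly 30 SNPs is excluded; on the bundled nine-species table that
screen selects exactly 15 genes. The published final marker lists in this
field additionally use per-gene tree evaluation, which is exposed separately
(`conflict_report()`) rather than folded into the numeric filter, since the
deciding tree step is a judgment about concordance, not arithmetic.

## Trees and conflict

Tree building is deliberately distance-based: p-distance with pairwise
deletion and neighbor-joining. The concordance questions the package answers
are topological, NJ answers them deterministically in milliseconds at panel
sizes, and externally computed Newick trees are accepted wherever a tree is
consumed, so users who want ML or Bayesian trees can bring them. Negative NJ
branch lengths are clamped to zero and counted on the tree object. Conflict
is operationalized as Robinson–Foulds distance strictly greater than 2
against the reference topology — one displaced bipartition is tolerated —
and the threshold is configurable because "conflict" has no unique
quantification.

## The generator and what it does (not) emulate

The simulator defines the study conditions the tests run under. Defaults: a
nine-taxon species tree whose internal branches are all at least 0.005
expected substitutions per site (so marker-based recovery is well-posed),
with one long-branch outlier taxon; a 23 kb genome (LSC 12 kb, IR 2 x 4 kb,
SSC 3 kb) — a deliberate desk-scale stand-in for a ~160 kb plastome that
preserves the region proportions' ordering LSC \> IR \> SSC; region rate
multipliers LSC 1, SSC 10, IR 0.1, reproducing the observed
IR \<\< LSC \<\< SSC variation ordering; kappa 2 with base frequencies
A/T 0.31, C/G 0.19 (38% GC, typical of plastomes); indel events at 0.02 per
site per unit branch length with geometric lengths of mean 2, sharing the
substitutions' regional profile; four planted SSR loci with slippage (one
motif unit gained or lost at 0.5 events per locus per unit branch length);
and ten genes including an IR rRNA (annotated in both copies) and a
junction-spanning CDS crossing SSC/IRa, mirroring the ycf1 arrangement of
real plastomes.

Substitutions are drawn per site with probability `branch length x regional
multiplier` (an HKY-like target choice: transition targets weighted by kappa,
all targets by base frequency). Branch lengths are therefore per-site
substitution probabilities, which matches a binomial expectation test at
small rates; at SSC-like rates multiple hits accumulate and observed
diversity saturates below the nominal multiplier — the recovered SSC/LSC
mean-Pi ratio sits near 8–9 rather than 10, inside the tested [7, 13] band,
and that is a property of any finite-rate model, not an implementation
artifact. Every event in IRa (substitution, insertion, deletion) is mirrored
into IRb, so IR copies stay exactly reverse-complementary — the concerted
evolution that keeps real IRs near-identical. Indels never split planted
CDSs by default and never cross region boundaries, keeping regions contiguous
and per-gene statistics well defined. The single-copy bases flanking both IR
junctions are pinned at construction so no chance symmetry extends the
repeat past its joints; leaf-level junctions evolve freely, so detected
(maximal) repeats may legitimately overrun a joint by a few bases, and tests
allow that.

The true alignment is assembled from per-branch event logs by progressive
merging: each subtree returns its leaf rows with every column anchored either
to a position of the subtree root's sequence or to an insertion point; merges
interleave insertion columns after their anchors, and the relative order of
independent insertions at the same anchor (an arbitrary choice in any true
alignment) follows child order deterministically. Two invariants are enforced
on every run, not just in tests: replaying the event logs from the ancestor
reproduces every leaf exactly, and ungapping every alignment row reproduces
the corresponding leaf.

The discordant-SSC preset emulates a region whose history conflicts with the
species tree: SSC non-coding sites evolve along a two-set topology
({sp1..sp5} vs {sp6..sp9}, deep inter-set branches), while all CDSs —
including the SSC gene — follow the species tree, with SSC coding sequence
held at the conserved LSC baseline rate (the empirical observation that
coding sequence escapes the SSC's hypervariability is the point of the
design). It is implemented as two substitution passes spliced by site, which
requires gap-free coordinates, so indels and slippage are disabled in this
preset.

What the generator does not emulate: codon-level selection, rearrangements
and inversions, gene loss and pseudogenization, alignment error (the true
alignment is used downstream, so tests certify the statistics given a correct
alignment, not the aligner), and rate heterogeneity within a region beyond
the three multipliers. Passing tests therefore demonstrate correctness of
the bookkeeping and the recoverability of planted signal — not robustness to
misalignment or to biological processes outside the model.

## Problem sizes and determinism

The shipped analyses use 9-leaf panels of ~23 kb genomes, 200-replicate
binomial checks on 10 kb two-leaf simulations, a 200-sequence brute-force SSR
oracle sweep at up to 5 kb, and a 20-seed rate-recovery sweep; these sizes
give stable statistics while keeping any single check in seconds. Every
stochastic path is seeded through the configuration; identical configurations
give bit-identical outputs (alignments, logs, and pipeline TSVs), and
`run_pipeline()` reruns are byte-identical, with md5 checksums recorded in
its summary.

## Known limitations

Dispersed-repeat maximality is greedy (seed and extend under the mismatch
budget), so a repeat whose mismatches cluster tightly at a seed-free end can
be reported slightly short; nested pairs are suppressed but overlapping
near-duplicates of distinct length are not merged. Partition detection
assumes the two IR copies are each internally contiguous. The GenBank writer
emits the minimal feature table the package itself consumes (gene, CDS,
tRNA, rRNA with join/complement locations); it is not a general GenBank
serializer. The pipeline's region labels come from one reference species'
partition projected across the alignment; species with structurally shifted
junctions inherit the reference's labels at orthologous columns.
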