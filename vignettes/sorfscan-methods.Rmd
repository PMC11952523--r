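---
title: "sorfscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sorfscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorfscan)
```

## The discovery problem

Short fusogens of the FAST type are single-pass membrane proteins of
roughly 60–200 residues. Their sequence conservation is too weak for
direct homology search, but their architecture is stereotyped: an
N-terminal ectodomain of about 30 residues, often opening with a glycine
myristoylation motif; a single, strongly hydrophobic transmembrane (TM)
segment; a juxtamembrane polybasic patch on the cytoplasmic side; and
amphipathic helical motifs in both domains. `sorfscan` finds candidates by
translating every ATG-initiated ORF of a nucleotide collection and testing
each translate against these hallmarks, then supports two follow-up
analyses: profile-HMM search of protein databases with models built from
the recovered families, and a permutation test for the over-representation
of a transposon group in designated 100-kb genomic tiles (the analysis
used to ask whether a piRNA master locus preferentially samples a TE
group).

## Conventions

All internal coordinates are 0-based half-open; conversion happens only at
file boundaries (GFF3 in: start − 1; TSV reports out: start + 1, labelled
1-based). A single convention everywhere eliminates off-by-one drift.
Ambiguous nucleotides (N) translate to `X`, and `X` fails every
residue-specific test and scores 0 on every hydropathy scale — degenerate
consensus positions can therefore never create evidence, only remove it.

## ORF enumeration

`find_orfs()` walks all three frames (forward strand by default, because
candidate short ORFs of LTR retrotransposons lie in the forward
orientation of the element; `both` is available for sanity checks on
genome scans). Starts are canonical ATG only — non-canonical initiation is
a known blind spot of this search strategy, accepted deliberately. An ORF
runs to the first in-frame stop; if the sequence ends first the ORF is
kept but flagged `open_ended`, since consensus sequences are often
truncated (recall over precision at the enumeration stage). Under the
default `longest_per_stop` policy the 5'-most ATG per (strand, stop) is
reported. The default length window is 50–250 aa: known insect candidates
span 63–107 aa, related viral ORFs roughly 67–115 aa, and reoviral FAST
proteins 80–200 aa, so the window brackets all observed families with
margin while keeping the search cheap. Both bounds are configurable.

## Feature detection

**Transmembrane segments.** Sliding-window mean hydropathy on the
Kyte–Doolittle scale, window 19, threshold 1.6, is the classical
dependency-free detector for single-pass TM segments, chosen because the
original analysis used an external predictor whose exact settings are not
recoverable. Maximal runs of passing window centers are expanded to the
residues those windows cover, clipped to 30 residues around the windowed
maximum, and discarded under 15 residues. The scale ships as a plain-text
table (`inst/extdata/`) and any residue→value table can be substituted
bit-exactly; code that already has TM intervals from an external predictor
can skip `detect_tm()` entirely and construct segments directly. One
consequence of window smoothing is that detected boundaries sit a few
residues off the physical span; the pipeline therefore treats boundaries
as approximate (see the decoy design below).

**Topology.** The positive-inside rule: count K+R in up to 15 residues on
each side of the segment; the more basic flank is called cytoplasmic. Ties
are `undetermined`, never guessed.

**Myristoylation.** The literal pattern M-G-x-x-x-[S/T] on the primary
translate with initiator Met retained, exactly as the motif is defined;
Met-cleavage chemistry is not modelled. Position 6 must be S or T — `X`
fails.

**Polybasic patch.** The window of at most 10 residues with the maximum
K+R count within the 15-residue juxtamembrane region of the endodomain,
reported when the count reaches 3; ties break to the earliest window.

**Amphipathicity.** The helical hydrophobic moment
μH = |Σₖ Hₖ (cos kδ, sin kδ)|/N at δ = 100°/residue on the Eisenberg
consensus scale, maximised over 11-residue windows within each domain.
The moment's magnitude is invariant to the window's phase offset, which is
what makes the cumulative-sum implementation exact. Amphipathicity and the
aromatic-belt tyrosine (a Y within 5 residues after the TM segment) are
reported but never filter by default: they were observed as shared
features of the family rather than used as search criteria.

## The composite classifier

Filters run in a fixed order — length, myristoylation, single TM segment,
topology, polybasic, ectodomain length — and the trace records every
enabled filter even after the first failure, so a negative can always be
attributed. The default configuration mirrors the published search:
length + myristoylation + exactly one TM segment. `strict = TRUE`
additionally requires N-out/C-in topology, a polybasic patch, and an
ectodomain length of 15–45 residues (motivated by the near-constant
~30-residue ectodomain of known short fusogens, suggested as a narrowing
filter). Candidates with more than one TM segment are rejected by the
single-pass assumption but remain visible in audit output
(`keep_failed = TRUE`). Overlapping passing ORFs in different frames are
all reported; deduplication happens downstream where the genome scan
counts insertions, not ORFs.

## Profile HMM

The homology search is the core computation, so the profile HMM is
self-contained rather than delegated: match/insert/delete states, global
(begin-to-end) alignment by default, with a `glocal` flag that makes the
flanking insert states free background emitters for partial-context
targets. MSA columns with gap fraction ≤ 0.5 become match states.
Emissions and transitions are maximum-posterior estimates with
pseudocount mass 1 distributed proportionally to the background (uniform
1/20 unless a frequency table is supplied): `(counts + background) /
(n + 1)`. All scoring is in log₂ space; bit scores are log-odds against
the background, so 0 bits means "no better than chance". Viterbi keeps
integer back-pointers for exact path recovery; forward uses a numerically
guarded log-sum-exp. Both are validated against exhaustive path
enumeration to 1e-9 bits on small instances, and a concentrated
single-state model reproduces the analytic log₂(20) ≈ 4.32-bit limit as
the pseudocount vanishes.

Significance is an empirical per-target shuffle null: each target is
residue-shuffled `n_shuffles` times (seeded), and
p = (1 + #{shuffle ≥ observed}) / (n_shuffles + 1), bounded below by
1/(n_shuffles+1). For short, divergent proteins at desk scale this is more
defensible than fitting an extreme-value distribution; it is also why the
default `n_shuffles = 200` bounds the smallest reportable p at ~0.005.
Whether the original database scan ran in nucleotide or protein space is
not recoverable; `sorfscan` scans protein space, which is the natural
home of the feature set. Profiles serialize to a versioned plain-text
format that round-trips scoring bit-exactly.

## Genome scan

Annotated insertions are extracted strand-aware (minus-strand insertions
reverse-complemented so each element reads 5'→3') and scanned in the
element's forward orientation. The counting unit is the insertion: an
insertion with three passing ORFs counts once, matching how prevalence is
reported at insertion level; a per-ORF count is also kept. Duplicate loci
(identical chrom/start/end) are collapsed by default; fragmented or nested
insertions are scanned independently per annotated interval — overlap
resolution is the annotation's responsibility, since no published
deduplication rule exists to implement.

## Tile enrichment

Chromosomes are cut into consecutive 100-kb tiles; a short terminal
remainder is kept but flagged and excluded from statistics. Composition
counts merge overlapping intervals of the same group before clipping at
tile boundaries (no double counting; clipped pieces sum exactly to the
merged genomic coverage). The total `te_bp` is the merged union over all
intervals, so it never exceeds the tile length; if annotations of
*different* groups overlap, per-group totals can exceed the union — TE
annotations are normally disjoint across groups, and the package does not
attempt to resolve such conflicts.

The test statistic is the group's fraction of total TE bp aggregated over
the designated target tiles. No specific named test is attached to this
analysis in the source material, so the most assumption-free reading is
used: a one-sided permutation test over tile identity. The null redraws
|targets| tiles uniformly without replacement from the background (all
non-remainder tiles with > 50% TE content) and recomputes the statistic;
p = (1 + #{null ≥ observed}) / (n + 1). When the number of distinct target
sets is at most `n_perm` the null is enumerated exhaustively, making the
test exact for small designs. The add-one smoothing makes p conservative
(super-uniform under the null), which the test suite verifies by seeded
simulation at α = 0.05 and 0.1. The statistic can be switched to per-tile
insertion counts.

## Synthetic data: what it does and does not emulate

The generators exist so that every stage has ground truth. A planted
protein realizes the canonical architecture with the package defaults as
the study conditions: 30-residue ectodomain opening M-G-x-x-x-[S/T],
21-residue TM segment drawn from {L,I,V,F,A,M}, interfacial Tyr, 6-residue
K/R patch, 20-residue tail; amphipathic character is emulated by placing a
hydrophobic residue every 3–4 positions (one helical face) in ecto and
tail. Each generated protein self-checks against `profile_features()` and
redraws if its features are not detectable — the generator's contract is
"this positive is findable", which is what makes benchmark sensitivity a
test of the scanner rather than of generation noise.

Decoys ablate exactly one feature: `tm_scrambled` rejection-samples the
membrane span from the full alphabet until no TM segment is detected;
`no_myristoylation` mutates the position-2 Gly to Ala;
`no_polybasic` strips all basic residues C-terminal of the TM and restores
two isolated lysines (keeping the topology call while no 10-residue window
can reach 3 K/R); `topology_flipped` moves the basic patch to the
N-side and strips the C-side of K/R. The latter two operate on the whole
C-terminal region rather than the planted patch alone because detected TM
boundaries are approximate (above).

Nucleotide backbones are random sequence with stop codons seeded on a
fixed lattice (offsets 0/7/14 within every 90-nt period, one per frame, so
the three frames never overwrite each other's stops), capping spurious
ORFs below the 50-aa window; an extra in-frame stop is written immediately
upstream of a planted ORF so no chance backbone ATG can absorb the plant
into a longer translate. Codon choice among synonyms is uniform — codon
usage bias is irrelevant to the filters under test. The generators do
**not** emulate evolutionary divergence between TE copies, piRNA
populations, expression, nested/fragmented insertions, or assembly gaps;
green tests therefore demonstrate correctness of the operations under
clean conditions, not performance on degraded real annotations.

Tile fixtures realize requested per-tile per-group coverages exactly and
carry an analytic expectation (including the exhaustive-mode p-value
computed by direct enumeration at generation time, independent of the
test implementation).

## Problem sizes and numerical choices

The standard verification runs use: a 300-backbone planted benchmark
(1.5-kb backbones) with 200 decoys per ablation class; 100 random
profile/sequence instances (≤ 4 match states, length ≤ 6) for the
enumeration oracle; 1000 random proteins for the feature-numeric oracles
(agreement to 1e-9); 10,000 random octamers for motif exactness; and 500
null replicates for permutation calibration on a 12-tile fixture. These
sizes give tight Monte Carlo error on every rate while keeping a full run
in a few minutes on one CPU. Ties in Viterbi tracebacks resolve in fixed
M > I > D order; ties in the polybasic search resolve to the earliest
window; tied topology flanks return `undetermined`.

## Limitations

Non-ATG starts and palmitoylated variants are invisible to the search by
design. TM detection is hydropathy-based, not an ML topology predictor;
an adapter point accepts external TM intervals. The shuffle null is
per-target and uncorrected for database size — at desk scale that is
appropriate; large-database scans should apply their own multiplicity
control. The enrichment test does not mask assembly gaps; gap handling
belongs to the annotation. Headline discovery counts from external
databases (Repbase consensus collections, curated genome assemblies, the
NCBI viral database) require those resources and are out of scope for the
offline test suite.
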