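---
title: "Mining potentially recently active Retand elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining potentially recently active Retand elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retand is a lineage of plant Ty3/gypsy LTR-retrotransposons distinguished
by an unusually long internal region: besides the canonical *gag-pol*
coding block (GAG, aspartic proteinase, reverse transcriptase, RNase H,
integrase), the region between the end of the *pol* gene and the 3'LTR
spans several kilobases and carries open reading frames oriented antisense
to *gag-pol* — most of them encoding the TRP28 (Transposase 28, PF04195)
domain — together with arrays of short tandem repeats.

Because retrotransposon copies start to diverge the moment they insert,
structural analysis is only clean on *recent* copies. The operational
class this package mines is the PRARE (Potentially Recently Active Retand
Element): an element whose two LTRs are character-identical, whose 5-bp
target-site duplications (TSDs) are identical, and whose LTR and internal
sizes are both within 2% of its cluster's consensus size. `prareminer`
implements the full discovery and annotation pipeline for this class and a
synthetic-genome generator that makes every stage testable against exact
ground truth.

## Pipeline stages and their assumptions

`run_pipeline()` composes six stages; each is exported on its own.

**1. RT-domain search** (`find_rt_hits`). A native seeded translated
search replaces a tBLASTn run: exact amino-acid 5-mers of each query are
located in all six translated frames, seed clusters become candidate loci,
and each locus is verified by a local Smith–Waterman alignment (BLOSUM62,
affine gaps, open 11 / extend 1 — the de-facto defaults of the replaced
tool; a length-$k$ gap costs $11 + k$). A hit is kept only when the
matched protein is a *complete, uninterrupted* RT domain: 157–162 aa, no
stop character, and the whole alignment within a single reading frame
(nothing is ever merged across frames, which is how frameshifted copies
are rejected). Overlapping hits to different queries collapse to the best
score. Since no analytic E-value machinery is reproduced, the score
threshold is tied to an explicit empirical null: `calibrate_min_score()`
scans i.i.d. random DNA and returns the smallest score whose null hit rate
is below a target (default 0 hits/Mb). The packaged default
(`min_score = 150`) sits far above the calibrated null maximum for
159-aa queries on megabase backgrounds and far below the score of any
planted domain. A `seqname_pattern` flag (e.g. `"chr"`) restricts the
search to chromosome-level sequences, mirroring the practice of skipping
scaffolds.

**2. Lineage assignment** (`assign_lineage`). Candidate RT proteins are
aligned together with a 62-sequence model panel (four Retand references,
seven members for each of eight other gypsy lineages, two Caulimoviridae
outgroups) by the package's progressive aligner; a neighbor-joining tree
is built from p-distances and rooted at the midpoint. A candidate is
called Retand iff it falls inside the smallest clade that contains all
Retand references and no panel member of another lineage; the analogous
rule labels other lineages, and everything else is `unassigned`. The
smallest-pure-clade rule is a documented choice — the membership rule
behind "clustered with the Retand references" is not otherwise pinned
down. p-distance (mismatches over shared ungapped columns) is used
because it is parameter-free and exactly testable.

**3. Element reconstruction** (`build_elements`). For each Retand hit the
10-kb up- and downstream windows are extracted and searched for maximal
exact same-orientation repeats with one copy on each side of the RT span —
"identical LTRs" operationalized as exact string equality and implemented
as a 21-mer anchored diagonal match (runs of consecutive anchors on one
diagonal are maximal exact matches). Accepted lengths default to 100–3,000
bp, bracketing the published 315–1,194 bp range with generous margins so
the detector does not bake in the expected answer. Among valid pairs the
longest wins; ties resolve to the outermost placement (a nested insertion
should resolve to the outermost, most recent element), then leftmost. The
implied element then must show identical 5-bp flanking repeats (the TSD;
a 4–6 bp tolerance is available via `tsd_len`). Failures carry reason
codes (`no-ltr-pair`, `no-tsd`, `edge`).

**4. Clustering and the PRARE filter** (`cluster_ltrs`, `prare_filter`).
LTR sequences — read in the element's sense orientation, so insertions on
either strand of one family cluster together — are grouped by greedy
incremental clustering at 90% identity: longest first, each sequence joins
the first cluster whose founder it matches at or above the cutoff,
otherwise it founds a new cluster. Identity is matches over total columns
of a full global alignment (exactness over speed at desk scale). The
consensus LTR and internal sizes of a cluster are member *medians* (the
lower middle value on even counts, so the consensus is always an observed
size); the median is robust to single outliers, and whether the original
procedure used mean, median or mode is unstated. An element is retained
as a PRARE iff **both** its LTR and its internal size deviate at most 2%
from the consensus — the removal rule excludes an element when either
deviates.

**5. Structural annotation** (`annotate_element`). Each element is
re-oriented so the RT strand reads forward; all labels are relative to
that direction. ORFs are ATG-initiated and maximal (first ATG after the
previous stop, through the stop codon) in all six frames, kept at ≥ 600
bp, with shorter ORFs rescued only when they carry a TRP28 hit (then
flagged `short`). Domains are scanned with position-specific scoring
matrices; a hit needs the best ungapped placement to reach the profile's
calibrated threshold, and non-overlapping multiple hits are allowed. The
POL-3'LTR region runs from just after the stop codon of the 3'-most sense
ORF carrying a pol domain (RT, RH or INT — the endpoint for two-ORF
layouts is not otherwise defined) to the base before the 3'LTR. Tandem
arrays are found per period (1–100 bp): positions equal to themselves
shifted by the period give maximal exact runs, which are extended
copy-wise while further units match the running consensus at ≥ 80%
identity. Candidates need ≥ 3 full copies and a footprint
(period × copies) of ≥ 24 bp — the footprint threshold plays the role of
the replaced tool's alignment-score threshold and keeps chance 3-bp
micro-runs out of reports. Candidates whose consensus unit is itself
periodic are discarded (they are sub-harmonics of a shorter true period);
overlaps resolve best-first by copies × period, ties to the smaller
period, so a homopolymer is reported once, as period 1. Autonomy is
`complete` iff GAG, AP, RT, RH and INT are all present among sense ORFs,
else `defective` with the missing set listed.

**6. Reporting** (`summarize_clusters`, `consensus_sequence`,
`conservation_profile`, cluster tree). Per-cluster rows mirror the
published table layout (copy number, sizes, domain flags, auxiliary
domains, tandem-array counts); summaries are exact min/max and means
rounded half-up to integer bp. Consensus sequences take the per-column
majority over non-gap residues (columns with ≥ 50% gaps are dropped from
the consensus but kept, flagged by their gap fraction, in conservation
profiles; ties go to the earlier residue in the fixed ordering
ACDEFGHIKLMNPQRSTVWY). Conservation profiles report exact per-column
frequencies binned at > 45% / > 35% / > 25% of the maximum residue. The
cluster consensus RT tree is NJ with column-resampling bootstrap
(default 1,000 replicates for the cluster tree, 100 at the mining stage),
restricted by default to clusters with ≥ 10 copies.

## Numerical and degenerate-case choices

* **Coordinates** are 1-based closed intervals throughout (IRanges /
  GFF3 convention), one convention for every module, truth record and
  report.
* **NJ** breaks Q-criterion ties lexicographically on the joined pair's
  representative labels, making the topology independent of input order;
  negative branch-length estimates are clamped to zero. On additive
  matrices the implementation recovers the generating tree exactly (a
  tree metric determines its tree uniquely), which the test suite checks
  both by path-metric identity and by exhaustive topology enumeration on
  six taxa.
* **Bootstrap** supports count bipartitions of replicate trees; splits
  absent from every replicate get 0. For an alignment of identical
  sequences the tree is metrically star-like (all branch lengths 0).
* **Progressive alignment** merges profiles with BLOSUM62 sum-of-pairs
  column scores under the same affine gap costs as the search stage; the
  left-gap DP state is computed with a running-maximum recurrence, and
  traceback re-derives moves from the stored matrices with ties preferring
  the match state.
* **Translation** uses the plain standard code table: alternative
  initiator codons are never promoted to M, and N-containing codons
  translate to X.
* **Empty inputs**: an empty genome set yields an empty report with a
  warning; a window with no qualifying repeat yields `NULL`; an element
  at a contig edge fails the TSD test with an `edge` flag rather than an
  error.

## What the synthetic generator emulates

`generate_scenario()` plants element *families* — identical copies of a
family cassette at well-separated positions on i.i.d. uniform A/C/G/T
background (the simplest null that cannot accidentally contain repeats of
LTR scale; real genomic background composition is not modeled). A cassette
is TSD + LTR + internal + LTR + TSD with: LTR lengths drawn from 315–1,194
bp; internal sizes from 7,380–12,869 bp; a codon-wise built gag-pol block
(one or two ORFs, each planted behind an in-frame stop insulator so the
planted ORF is exactly the maximal ATG-to-stop ORF); an RT domain that is
one of the panel's Retand references; a POL-3'LTR region targeted to the
published 2,933–6,566 bp span (the 5' leader absorbs the remaining
internal length) carrying antisense ORFs (TRP28 in the first), optional
pol- or LTR-adjacent tandem arrays (primitive units, guard bases at both
ends so the planted span is maximal); and per-site TSDs duplicated from
the insertion point. Elements are planted on either strand. Decoys cover
the rejection paths: diverged-LTR copies (substitutions only, so the
identity test and not a length test rejects them), solo LTRs, 5'-truncated
elements, and naked non-Retand RT coding regions from the outgroup panel.
Every planted feature has one truth row with exact coordinates, and decoys
are flagged ineligible.

Two honest gaps between simulation and real data: copies of a planted
family are byte-identical (recently active families are near-identical,
but real copies carry at least some private mutations, nested insertions
and conversion tracts — recovering *degenerate* elements is explicitly
out of scope of the PRARE definition); and the RT panel plus domain models
are synthetic stand-ins generated from a common ancestral sequence with
lineage-level divergence, not curated references (both are labeled as
such, and both entry points accept user-supplied FASTA panels and score
tables). Passing tests therefore demonstrate correctness of the machinery
under the stated element architecture, not sensitivity on diverged real
genomes.

## Problem sizes in the shipped checks

The test suite validates each operation against independent oracles
(full-DP alignment scans, a brute-force six-frame ORF walk, an exhaustive
(start, period) tandem scan, exhaustive tree-topology enumeration with
least-squares fits) on 50 random instances per suite, and runs the whole
pipeline end-to-end on a 5-Mb two-chromosome scenario with three families,
12 intact insertions and 9 decoys, requiring precision = recall = 1.0 with
exact boundaries. `scripts/acceptance.R` re-runs that scenario from
scratch at an arbitrary seed and recomputes the packaged cluster-table
summaries. These sizes were chosen as the smallest that exercise multiple
families, both strands, every decoy class and every rejection path.

## Known limitations

* The identical-LTR criterion is exact string equality; a single
  substitution in one LTR excludes an element (by design — that is the
  PRARE definition), so the pipeline is a recent-insertion detector, not
  a general annotator.
* Greedy clustering depends on the longest-first processing order, like
  the tool it mirrors; it is deterministic but not an optimal partition.
* The tandem detector's identity-based extension is seeded by at least two
  adjacent exact copies; arrays in which *every* adjacent copy pair
  differs are invisible to it.
* Domain presence is profile-based; a domain diverged far beyond its
  model scores below threshold and the element is (correctly, per the
  procedure) called defective even if a remnant is present.
* Full-DP verification at candidate loci is exact but unbanded; genomes
  far beyond desk scale (hundreds of Mb) would need a banded or compiled
  search stage.
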