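---
title: "Split-read deletion calling and breakpoint VAF quantification for UMI-tagged amplicon panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-read deletion calling and breakpoint VAF quantification for UMI-tagged amplicon panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdel)
```

## The problem

Roughly half of sporadic hepatoblastomas carry large intragenic deletions
(tens to hundreds of base pairs) in the exon 3 region of *CTNNB1*. Detecting
such deletions in circulating tumor DNA is harder than detecting point
mutations: plasma cfDNA fragments are short (~170 bp), so a deletion is seen
only through reads whose alignment splits across the deletion junction.
`ampdel` implements the computational core of a targeted
single-primer-extension (SPE) amplicon assay for this setting:

1. a **split-read deletion caller** over a single panel locus,
2. **position+UMI duplicate marking** so all evidence is counted per unique
   input molecule,
3. **breakpoint-evidence VAF quantification**, and
4. a **dilution-series evaluation layer** (limit of detection, limit of
   blank, linearity, method concordance),

together with a synthetic library generator that emulates the assay's read
structure, so every stage can be exercised and validated without external
data. The bundled locus is a randomly generated 2 kb stand-in, not a real
genomic sequence.

## Read structure of the assay

In an SPE capture, each fragment is anchored at a gene-specific primer:
read 1 starts at the primer's 5' end and reads into the target, read 2
reads back from the other end of the fragment. The simulator models
2 x 150 bp paired-end sequencing of ~110 bp inserts, so mates typically
overlap. The panel places primers on both strands: plus-strand primers
upstream of the deletion's left breakpoint and minus-strand primers
downstream of the right breakpoint, each within one insert length of its
junction (default anchor offsets 45 and 70 bp, chosen so that read 1
retains at least the 19 bp minimum overlap on its flank and read 2 can
still reach informative bases across the junction).

## Deletion calling

Aligned reads are decomposed into reference-aligned segments
(`segments_from_cigar()`): an in-read deletion gap of at least 5 bp splits
a record, and supplementary alignments contribute additional segments of
the same read, ordered along the read 5'->3'. The 5 bp absorption default
separates alignment micro-indels from panel-relevant deletions, which are
at least 10 bp (`min_del_len`); both cutoffs are configurable.

Every reference interval between consecutive segments of one read of an
unflagged pair is a candidate deletion. When sequence immediately adjacent
to the junction is identical on both sides (microhomology), several
placements of the junction produce the same mutant sequence. The package
canonicalizes by assigning ambiguous bases to the read's first (5',
primer-side) segment; expressed in reference coordinates this is the
right-most equivalent placement for a plus-strand read whose first segment
is the left flank. One global convention is applied to all candidates so
that equivalent placements observed on either strand merge into a single
canonical call; support is tallied per unique molecule *after*
canonicalization, so a molecule whose two reads show the junction at two
equivalent placements still counts once. The call with the largest
unique-molecule support is retained (ties: larger support, then smaller
left breakpoint, then smaller length, making the result independent of
input order), subject to the detection rule of at least one supporting
molecule.

## Duplicate marking

Pairs are grouped by (read 1 unclipped 5' position, read 1 strand, exact
UMI); one representative per group is left unflagged (longest total
aligned length, ties by smallest pair id). Keying on read 1 follows the
primer-anchored design: the read 1 start identifies the capture event.
UMIs are compared exactly; directional network collapse and consensus
building are deliberately out of scope — the pipeline marks duplicates, it
does not error-correct them.

## VAF quantification

For breakpoint $i \in \{1,2\}$ with $s_i$ deletion-supporting and $n_i$
non-supporting unique molecules, $t_i = s_i + n_i$ and

$$\mathrm{VAF}_i = \frac{s_i}{t_i}, \qquad
\mathrm{VAF} = w_1\,\mathrm{VAF}_1 + w_2\,\mathrm{VAF}_2, \qquad
w_i = \frac{t_i}{t_1 + t_2}.$$

A pair is informative for breakpoint $i$ when read 1 overlaps the
non-deleted flank of breakpoint $i$ by at least 19 bp (the aligner seed
length; below that an overlap could not have been mapped reliably). If
read 1 itself spans the junction, the flank containing its 5' end is used,
so each molecule informs exactly one breakpoint and the two evidence sets
are disjoint. The pair is *supporting* when read 2 contains the canonical
junction and overlaps the other breakpoint's flank by at least 19 bp;
*non-supporting* when read 2 aligns contiguously through at least 19 bp
inside the deleted region (contiguity through the deletion identifies the
wild-type allele, even when the alignment continues into the distal
flank); otherwise *uninformative*. The 19 bp rule is applied uniformly to
every overlap test. Classification keys on read 2 even when read 1 alone
proves the allele; a diagnostic counter reports such pairs. A breakpoint
with $t_i = 0$ is flagged undefined and receives weight zero; when both
are empty, the estimate is undefined rather than zero.

Counts are molecule-level (post-deduplication), consistent with treating
one UMI family as one variant copy; raw-read counts are attached for
diagnostics. `snv_pileup_vaf()` provides a minimal unique-molecule pileup
fraction at a single position as plumbing for point-variant spot checks;
small-variant calling proper is out of scope.

## The synthetic library generator

`simulate_library()` emulates, per library:

* a molecule pool of $2 \times \mathrm{GE}(\text{mass})$ allele copies,
  with $\mathrm{GE}(20\,\mathrm{ng}) = 3030$ diploid genome equivalents at
  6.6 pg per diploid genome;
* `round(vaf * pool)` variant molecules (a spiked deletion or SNV allele);
* per primer, UMI families drawn from the pool *without replacement*
  (`target_umi_depth` is the mean family count per breakpoint-informative
  position, split across the primers of that strand), so family counts can
  never exceed library complexity;
* fragment lengths ~ Normal(110, 10) truncated to [38, locus length]
  (size-selected cfDNA-like inserts; the lower bound keeps the 19 bp rule
  satisfiable on both sides of a junction);
* `1 + Poisson(duplicate_rate - 1)` read pairs per family (default mean 2,
  matching a read:UMI coverage ratio of about two);
* per-base substitution errors at `1e-3` (Illumina-like); substitutions
  never alter alignment geometry, so they cannot fabricate
  junction-spanning evidence — which grounds an expected limit of blank of
  zero. Chimeric junction artifacts can be injected explicitly
  (`chimera_rate`) to probe the blank.

Truth alignments are emitted directly: wild-type molecules align
contiguously; variant junction reads split into two segments with
ambiguous bases assigned to the read's first segment (minus-strand reads
are therefore emitted at the left-most equivalent placement, exercising
the caller's merge). Deletions of at most 50 bp are written as one SAM
record with an in-read `D` gap, longer ones as a soft-clipped primary plus
supplementary record — mirroring how short-read aligners represent this
size range — and the ingest layer treats both dialects identically.
Emitting truth alignments keeps the pipeline self-contained and the
split-segment geometry controllable; `write_fastq()`/`write_fasta()` are
provided for users who prefer to run a real aligner, and the caller
recovers the same deletion from BWA-MEM output of the simulated reads.

Determinism: every stochastic operation draws from the configured seed;
identical configurations produce byte-identical SAM output.

What the generator does **not** model: PCR and GC bias, UMI sequencing
errors and collisions, strand-specific damage, spontaneous chimera
formation, multi-locus panels, or real genome sequence. Passing tests on
simulated data therefore demonstrate correctness of the algorithms under
the stated error model, not performance on clinical libraries.

## Assay evaluation

* `genome_equivalents()`, `theoretical_lod_percent()` and
  `coverage_threshold_percent()` reproduce the analytic sensitivity
  arithmetic: 20 ng -> 3030 GE -> 0.03% theoretical floor; 1/837x -> about
  0.12% coverage-limited threshold.
* `run_dilution_series()` simulates a VAF ladder with replicate libraries,
  runs the full pipeline on each, and aggregates per level (mean of
  defined VAF estimates; a level is detected when **any** replicate yields
  at least one molecule supporting the true deletion). Replicate
  aggregation is the package's scaling device for a procedure that, in the
  laboratory, would sequence one library per level; note that under the
  any-replicate rule the smallest detectable level shrinks as replicates
  grow, because the expected number of captured variant copies per library
  (about $2 \times \text{depth} \times \text{VAF}$, here ~0.24 at 0.03%)
  is multiplied across replicates. The aggregation rule is therefore part
  of any reported LoD's definition.
* `estimate_lod()` returns the lowest nonzero level detected with
  uninterrupted detection at all higher levels; isolated detections below
  an undetected level are excluded with a warning.
* `estimate_lob()` reports the maximum spurious supporting-molecule count
  across wild-type libraries (0 under the default error model).
* `linearity()` is ordinary least squares of observed on expected VAF over
  levels with a defined estimate (undefined points are excluded, not
  zero-filled); `sensitivity_specificity()` computes concordance fractions
  against a reference method, leaving empty margins undefined.

## Problem sizes used by the test suite

The packaged checks simulate 20 ng libraries at 400 families per
breakpoint: a 10-level ladder with 10 replicates per level (100 libraries)
for LoD and linearity, 4 wild-type libraries for the blank, 20 seeds for
breakpoint truth recovery, and 100 seeded runs per spiked fraction
$v \in \{0.01, 0.05, 0.25, 0.5\}$ for binomial-bound VAF recovery
($|\hat v - v| \le 3\sqrt{v(1-v)/(t_1+t_2)}$). Brute-force equivalence of
the caller is checked exhaustively on instances of at most 50 molecules.

## Known limitations

* One deletion per sample is called; co-occurring deletions, insertions,
  inversions and translocations are out of scope.
* Single-reference panels only; no BAM index handling or mapping-quality
  modelling.
* No confidence intervals on VAF estimates.
* The LoB/LoD results inherit the simulator's idealized error model; on
  real libraries, chimera formation during library preparation can raise
  the blank above zero.
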