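---
title: "Methods: repeat-mediated recombination and structural analysis of multichromosomal plant mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated recombination and structural analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The biological problem

Many plant mitochondrial genomes are assembled as a small number of circular
chromosomes carrying abundant dispersed repeats. A repeat present in two
copies is a substrate for homologous recombination: a crossover inside the
repeat cuts both molecules and rejoins them with exchanged arms. At the
genome level this has three possible outcomes, fixed by where the copies sit
and their relative orientation:

* copies on **two different circles** → the circles **fuse** into one;
* copies on **one circle, direct relative orientation** → the circle
  **fissions** into two, each retaining one copy;
* copies on **one circle, inverted relative orientation** → one circle with
  the arc between the copies **inverted**.

Total sequence length and the number of repeat copies are conserved in every
case. A cell therefore carries a mixture of genome arrangements: a major
configuration plus minor ones reachable by recombination. `mitorecomb`
implements the analyses used to characterise such a system from a finished
assembly plus long reads, and a ground-truthed simulator so every stage can
be tested end to end at desk scale.

## Circular coordinates

All genomic coordinates are 1-based inclusive with explicit strand. An
interval crossing the circular origin carries an explicit `wraps` flag
rather than the ambiguous `start > end` encoding seen in printed coordinate
tables; the normalised form always has `start <= end` plus the flag.
Sequences are circular by default; linear mode exists for derived artifacts
(configuration references, marker regions). `N` residues take part in
extraction but never count as matches in any identity computation.

## Repeat discovery

`find_dispersed_repeats()` reports maximal exact repeated pairs (within and
between chromosomes, both orientations) by seed-and-extend with word size
equal to `min_len` (default 50 bp). Circularity is handled by scanning
doubled sequences; matches that are rotations of one another, fragments of a
wrap-crossing match, and pairs whose copies overlap on one molecule are
removed. Pairs are ranked by decreasing core length and numbered `R01`,
`R02`, .... Because matches are exact, reported identity is 1.0; a
mismatch-tolerant extension stage was considered and dropped — the
recombinogenic repeats this analysis targets are near-identical (they must
be, to recombine), and every stated contract is met by exact maximality.

`find_ssrs()` reports maximal perfect tandem runs of 1–6 bp motifs at the
conventional unit-length thresholds (10/5/4/3/3/3 copies for mono- through
hexanucleotide motifs, inclusive). Motifs are canonicalised to their
lexicographically minimal rotation; non-primitive motifs (powers of a
shorter unit) are suppressed, runs are truncated to whole units, and
overlapping candidates are resolved greedily longest-first so no two
reported SSRs overlap. Compound SSRs are not merged.

## The four-configuration test

Around a repeat with copies on (possibly) two molecules, four local
arrangements are possible. With `flank_len` bases on each side of the core
(default 1000 bp; 2000 bp is the convention when validating MTPT junctions):

* `c1` = left1 + core + right1 and `c2` = left2 + core + right2 reproduce
  the as-assembled contexts of the two copies;
* `c3` = left1 + core + right2 and `c4` = left2 + core + right1 are the two
  flank-switched arrangements that crossover products would carry.

Copy 1's plus-strand reading defines the core; for an inverted repeat the
whole copy-2 neighbourhood is reverse-complemented first (which swaps and
complements its flanks), making the switching rule orientation-safe.
Flanks are extracted circularly; copies closer than `flank_len` on one
molecule are allowed and recorded as a provenance warning, never silently
truncated.

A long read **supports** configuration `ci` when it (or its reverse
complement) aligns over the entire core and at least `min_flank_anchor`
(default 100 bp) into both flanks at `min_identity` (default 0.80), and `ci`
is the unique best-scoring qualifying reference; ties and non-spanning reads
are `unassigned`. The aligner behind this is a contract, not a tool: the
implementation seeds the core location with shared k-mers, aligns the core
and junction-anchored flank windows (default 500 bp) with Biostrings
dynamic programming, and sums the three scores. Restricting flank scoring
to a window is what makes classification fast; two flanks identical
throughout the window produce a tie and fall to `unassigned`, which only
ever loses support, never invents it.

The **recombination frequency** is pair-based: parental = c1+c2 reads,
recombinant = c3+c4 reads, and the statistic is the minority pair's share of
all classified reads, as a percentage rounded half-up to two decimals
(`round_half_up`, so 1/167 → 0.60). Unassigned reads are excluded from the
denominator. The pair-based reading (rather than the single least-supported
configuration) is the only one that reproduces all three published example
rows from their printed counts, which is why it is the implemented
definition. The value is ≤ 50 by construction and symmetric under
exchanging the pairs.

## Recombination algebra

`GenomeConfiguration` objects are multisets of segment cycles: circular,
equal up to rotation and up to reversal-with-orientation-flip (a circle read
on the other strand is the same molecule). `apply_event()` implements the
fusion/fission/inversion trichotomy above; `enumerate_products()` applies
every non-empty subset of repeats in ascending rank order (recorded in the
output, since for some repeat sets the outcome is order-dependent) and names
the products `Mic1`, `Mic2`, ... by subset size then lexicographic order.

`mac1_configuration()` encodes the published two-chromosome system
(182,239 + 165,055 bp with repeats of 13,331, 1,928 and 123 bp; R01 and R07
direct, R04 inverted, one copy per chromosome). The second R04 coordinate is
typographically corrupt in the source table, so its position is
approximated from the parseable digits; only order and orientation enter
the algebra. On this baseline the enumeration yields seven products, each
single-repeat product a single chromosome and {R01,R07} two chromosomes.
The source figure legend is self-contradictory about the {R04,R07} product
("two circular chromosomes: Mic6-1" vs. "Mic6 has one chromosome only");
the algebra yields **one** chromosome (fusion by R04, then an intramolecular
crossover between copies that end up in inverted relative orientation), and
the package reports what the algebra yields rather than hard-coding either
claim.

The algebra is verified two ways: conservation/involution properties over
random configurations, and agreement with an independent **string-surgery
oracle** that realises segments as concrete sequences, performs the
crossover by cutting both molecules at the repeat midpoint and rejoining
exchanged arms, then re-factors the product strings into cycles by pattern
matching. Repeat copies are relabelled by their repeat for the comparison,
because physical copies are indistinguishable.

## MTPT detection

Plastid-derived segments are found by a seeded local-alignment search with
word size 7 and e-value < 1e-6 — delegated to the standard NCBI `blastn`
executable (`-task blastn`, low-complexity filtering disabled for
determinism), which is the canonical tool for exactly this step. Hits
shorter than 100 bp or below 80% identity are excluded (both boundaries
inclusive; filtering is monotone in both thresholds). Surviving hits whose
mitochondrial intervals overlap or abut are merged into loci ranked by
coordinate. The summary reports the merged total and its percentage of both
genomes with explicit denominators, because the source text attaches its two
percentages to the wrong genomes relative to its own printed lengths
(28,175/347,294 = 8.11% of the mitogenome; 28,175/150,604 = 18.71% of the
plastome). A plastid gene contained in a locus is `intact` only when its
interval is fully covered by that single locus's plastid footprint.

## C-to-U RNA editing

References are CDSs (optionally with flanking sequence); pileups are
strand-resolved, so only coding-strand C→T mismatches are candidate
events. A site is called when the reference base is C, coverage ≥ 5 and T
fraction ≥ 0.1 (inclusive, and monotone in both thresholds). Codon
annotation uses the standard genetic code: a gained stop codon is
`stop_gain` (e.g. CAA→TAA, CGA→TGA), an ATG gained at codon 1 is
`start_gain`, otherwise synonymous/nonsynonymous; sites are named
`gene-position` indexing the edited base within the CDS. Genomic SNPs
called from DNA pileups at the same thresholds are removed from the editing
set. Summaries report counts and percentages over total sites
(recomputed — one published percentage is arithmetically inconsistent with
its own count and total); the hydrophilic→hydrophobic share uses the
nonsynonymous denominator, and the hydropathy class table
(`default_hydrophobic()`: A,V,L,I,P,F,M,W) is configurable because no
published scheme is stated.

## Intron markers

For each gene with ≥ 2 cis exons, the intron between consecutive exon ranks
r and r+1 is extracted as `genei{r}{r+1}` (e.g. `nad2i34`), coding-strand
orientation; trans-spliced genes are skipped with a notice. Orthologous
introns are aligned by a deterministic progressive (star) procedure: every
sequence is aligned globally to the first (match +2, mismatch −1, gap open
5, extend 1 — exposed, since the historical tool's exact parameters are
unstated) and merged on its coordinates under once-a-gap-always-a-gap.
Polymorphic loci are gap-free columns with ≥ 2 residues (SNPs; adjacent
variant columns stay separate loci) and maximal gap-containing column runs
(indels; a full gap run is the empty-string allele). Each site records the
species pairs it distinguishes. Marker target regions are sites ± 300 bp in
the reference species' intron coordinates, clamped to the intron and merged
when they overlap.

## The synthetic world

`make_genome()` builds a two-chromosome circular genome of 40 kb + 30 kb
(≈1/5 of the real assembly, so every stage runs in seconds) at 44% GC
(matching the published genome's GC content), with three cross-chromosome
repeat pairs — 2,600 bp direct, 1,000 bp inverted, 150 bp direct, mirroring
the study's 13.3 kb/1.9 kb/123 bp recombinogenic trio — two plastid-derived
insertions (800 bp at 98% identity, 1,200 bp verbatim) copied from a
generated 20 kb plastome, and multi-exon gene models with introns wide
enough to host planted polymorphisms. `simulate_long_reads()` draws reads
from a configuration mixture with normal lengths and uniform substitutions
plus insertions/deletions at jointly one quarter of the substitution rate —
a crude long-read proxy that is adequate for anchor-based spanning
classification but does not model homopolymer or quality structure.
`simulate_pileups()` plants binomial T counts at editing sites and alleles
at SNPs over a uniform background error. `make_species_trio()` derives two
species from the base by intron-only substitutions and deletions (including
one 65 bp deletion, the large diagnostic indel class seen between real
congeners), with exons held constant; substitution positions are planned
disjointly across the derived species and deletions avoid all planted
substitutions, so the truth table is recoverable site-for-site. Everything
is reproducible from its seed.

What a green test establishes, and what it does not: recovery of planted
features in this clean background demonstrates the pipeline's logic
(thresholds, orientation handling, statistics), not its performance on real
data — real mitogenomes have nested repeat families, diverged repeat
copies, chimeric reads and coverage biases that the generator deliberately
omits. Published full-data tallies (56 repeat pairs, 457 editing sites, 89
SSRs, 15 MTPT loci, ...) require the original sequencing archives and are
not reproduced at desk scale.

## Numerical choices and edge cases

* All reported percentages round half away from zero to 2 decimals.
* Threshold comparisons are inclusive (≥) with a 1e-12 floating-point
  guard on frequency/identity boundaries.
* Zero classified reads make the recombination frequency an error
  (`undefined_statistic`), not a 0.
* The editing false-negative check ("5% sites are never called") is run at
  depth 200 under a fixed seed; at depth ~20 a 5% site reaches the 10%
  threshold with probability ≈ 0.26 by binomial chance, so deep coverage is
  the only regime where that statement is meaningfully testable.
* Alignment ties in read classification are `unassigned` (conservative);
  windowed flank scoring can only lose support, never misattribute it.
* Degenerate geometries: flanks longer than a molecule are a topology
  error; repeat copies closer than a flank length are allowed and recorded.

## Known limitations

* Repeat discovery is exact-match; a diverged repeat pair (<100% identity)
  is reported as fragments rather than one mismatched pair.
* The read simulator's error model is uniform; no flowcell-realistic
  profiles or quality scores.
* Multi-event recombination products are defined by the recorded
  application order; order-dependent cases are surfaced, not resolved.
* The star alignment is exact for the three-sequence marker use case but is
  not a general-purpose MSA.
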