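---
title: "Inferring and dating paleopolyploidy with wgdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and dating paleopolyploidy with wgdkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdkit)
```

## The problem

Most flowering-plant genomes are layered palimpsests of whole-genome
duplications (WGDs).  A recent doubling leaves two co-orthologous copies of
every chromosomal region; tens of millions of years of *fractionation*
(duplicate gene loss) then erode the signal until only statistical traces
remain: collinear blocks of paralogous genes, a 1:2 depth of orthologous
regions against an unduplicated relative, and a hump in the distribution of
synonymous distances (Ks) at the age of the event.  `wgdkit` implements the
standard comparative-genomics workflow for recovering these traces in a
trio of genomes -- a slowly evolving diploid reference (tag `V`), a second
diploid (`T`), and a focal lineage suspected of an extra tetraploidy (`A`),
all sharing an ancient hexaploidy -- and for converting them into a
calibrated age for the extra event.

Every stage is exercised against a built-in genome-evolution simulator with
full ground truth, so the pipeline's statistical behaviour is measurable,
not assumed.

## Collinear block detection

Homology hits (BLAST-like tables, E-value cutoff `1e-5`, optionally thinned
to the best 5 subjects per query to stop large families flooding the
chaining) are chained in *rank coordinates*: the i-th gene on a chromosome
has rank i - 1.  A block is a chain of hit pairs strictly monotone on both
axes (co-directional or inverted) in which consecutive pairs are separated
by at most `max_gap = 50` intervening genes on either axis.  Chains are
scored by their number of pairs and extracted greedily (best chain first,
its hits removed, repeat); ties prefer the chain with less internal gap,
then the lexicographically smallest first gene id, making output
deterministic.  Blocks need `min_pairs = 4` pairs to be reported.  On
instances small enough for exhaustive chain enumeration the extractor
provably returns a maximum chain (a property the test suite re-checks on
200 random instances).  Within-genome scans drop self-pairs and report each
paralogous block once (canonical orientation).

There is no significance filter beyond block length: with a 50-gene gap and
4-pair minimum, spurious chains from random hits are rare at realistic hit
densities, and downstream statistics (modal depth, block-median Ks) are
robust to the survivors.

## Ks estimation

For each collinear pair the proteins are globally aligned (match +1,
mismatch -1, gap open 10, gap extend 0.5), the alignment is threaded back
onto codons, and gapped columns are dropped.  Equal-length CDS pairs whose
direct codon pairing already shows >= 30% amino-acid identity skip the
alignment -- no gapped alignment of full-length homologs can beat an
ungapped pairing at that identity, and the shortcut matters when scoring
tens of thousands of pairs.

Distances use the Nei-Gojobori method: per codon, each position contributes
the fraction of its three possible changes that are synonymous (changes to
stop codons count as nonsynonymous); codons differing at several positions
average their synonymous/nonsynonymous difference counts over all minimal
mutational pathways, excluding pathways through stop codons (when every
pathway is blocked -- a handful of stop-adjacent pairs -- all pathways are
used).  Proportions are Jukes-Cantor corrected,
`K = -3/4 log(1 - 4/3 p)`; `p >= 3/4` yields a saturation marker rather
than an error so that pipelines keep running.  Pathway counts for all
61 x 61 sense-codon pairs are verified against an independent recursive
enumeration in the tests.

A block's Ks is the median over its pairs, excluding saturated and failed
pairs; blocks with more than half their pairs excluded are flagged and take
no part in classification.

## Event classification and ploidy

Blocks are assigned to events by windows on the block-median Ks axis.
Windows can be given explicitly or suggested by a 1-D Gaussian mixture on
the medians (component count by BIC up to a cap; windows are mean +/- 2 sd,
truncated where adjacent component densities cross; components closer than
0.1 Ks collapse with a warning).  Blocks whose median falls between windows
stay `unassigned` -- deliberate conservatism: boundary blocks carry the
least information and are better left out of depth and fractionation
statistics than guessed.

Orthologous (speciation-window) blocks then yield a depth profile: each
reference chromosome is tiled into 100-gene windows and the number of
distinct block footprints overlapping each window is counted.  The inferred
multiplicity is the modal nonzero depth with its supporting fraction --
mode 2 over an unduplicated reference reads as one extra tetraploidy, mode
3 as a hexaploidy, mode 1 as no extra event.  The mode is deliberately
crude: it is insensitive to occasional fragmented or spurious footprints,
which is exactly what is needed from a ploidy call.

## The event-related homology table

With reference `V`, second diploid `T` and tetraploid `A` the table has 12
columns: the reference gene, its two hexaploidy paralogs, one `T` ortholog
for each of those three anchors, and two sibling `A` orthologs for each
anchor.  Cells hold gene ids or the literal dot `.` for a missing collinear
gene (lost or translocated).  Filling is by *slotting*: block views
overlapping the same reference territory must occupy different column
slots.  Views are placed largest-first; a slot is blocked by substantial
footprint overlap (a margin of 3 genes or 10% absorbs frayed chain ends);
among admissible slots the builder avoids the slot holding the view's own
duplication partners (the tetraploid's self-collinearity links), prefers
the slot continuing the same partner chromosome, and otherwise picks by a
deterministic hash of the partner chromosome -- *not* always the first
slot, so that "column 1" does not systematically collect the locally
denser sibling region.  Sibling column labels are therefore arbitrary
(only the pair is identifiable), which is how the recovery tests treat
them.  Cell conflicts resolve in favour of the longer block, then
lexicographically; a gene fills at most one cell per column, so a gene can
recur across -- never within -- a species' columns (one cell per reference
anchor).

Building the table from the second diploid as reference is supported and
places tetraploid genes whose ortholog was lost from the first reference.

## Fractionation statistics

Loss rates are dots-per-row by reference chromosome and column, plus the
row-wise "both siblings missing" rate.  Runs of consecutive dots along
reference order (never across chromosome boundaries) give the deletion
run-length spectrum; runs longer than `l_max = 15` genes are counted
separately as presumed segmental losses, not folded into the spectrum.

The spectrum is fit by least squares to the geometric family
`N p (1-p)^(l-1)` with `N` fixed at the total number of runs (including the
excluded tail, so truncation is modelled, not renormalised away) and the
extension parameter `p` free; the mean deletion run is `1/p`.  Fitting
frequencies instead of counts rescales both sides by `N` and leaves the
least-squares minimiser and R^2 unchanged, so only the counts scale is
provided.  Lack of fit is assessed by an F statistic: the residual mean
square over `l_max - 1` degrees of freedom divided by the sampling variance
expected under the fitted model (`mean(N q_l (1 - q_l))`), with the upper
tail of `F(l_max - 1, Inf)` as the p-value -- a large p-value *accepts* the
geometric model.  This construction is one reasonable choice among several;
a chi-square goodness-of-fit with a pooled tail class is emitted alongside
as a cross-check.  Note that the measured spectrum lives on the reference's
row grid: deletion runs are observed only at positions where the reference
retained a gene, so the recoverable truth for simulation comparisons is the
same statistic computed on the simulator's ideal-recovery columns
(`truth_table_columns()`), not the generative parameter itself.

## Ks peaks, rate correction, dating

Event-labelled pair Ks values are smoothed by a Gaussian KDE (Scott's rule
bandwidth unless overridden) and a single Gaussian is least-squares fit to
the density curve; the fit window is taken from the 0.5-99.5% quantiles of
the labelled values.  The shared-event (hexaploidy) peaks of the three
genomes measure their relative clocks: the slowest genome anchors the
correction, each lineage gets `lambda = mu / mu_ref`, within-genome Ks
divide by `lambda`, and cross-genome Ks divide by the mean of the two
lambdas (a Ks accrues on both branches; the arithmetic-mean branch
correction is isolated in one function so a geometric mean can be swapped
in).  After adjustment all shared-event peaks align at the reference peak
by construction.

Dating is linear: an event with adjusted peak `mu_e` against a calibration
event with adjusted peak `mu_c` and age interval `(T1, T2)` is dated
`(mu_e/mu_c) x (T1, T2)`; the default calibration is the core-eudicot
hexaploidy at 115-130 Mya.  A peak ratio above 1.5 warns that the event
would substantially predate its calibration.

## The simulator and what passing tests mean

`simulate_history()` draws an ancestral genome (2,000 genes on 4
chromosomes, 300 codons per gene by default), triples it at the hexaploidy,
splits off `V`, then `T` and `A`, doubles `A` at the tetraploidy, and
fractionates every terminal subgenome to 35% retention with
geometric-length deletion runs (extension parameter 0.4) alternating with
geometric keep runs tuned to the retention target -- so deletion run
lengths are exactly geometric by construction, and an unreachable
retention/p combination errors before generation.  Terminal rates default
to 1.0/1.23/1.50; each gene x branch length is jittered lognormally
(sd 0.25 on the log scale, mean 1), translocations move 2% of surviving
genes, and hit tables are emitted from the true genealogy with 2% dropout
and 2% spurious pairs and a bitscore that decays with true distance.
Substitutions are applied as events at synonymous/nonsynonymous sites in
the expected numbers for the target branch lengths, so the NG86 estimate
recovers the target in expectation and chains additively along branches.

Two deliberate modelling choices deserve emphasis:

* **Chronology scale.**  The default event ages keep the relative spacing
  typical of published grape/cacao-like trios (speciations at 0.69 and 0.59
  of the hexaploidy's age; tetraploidy at 0.55) but place the hexaploidy at
  Ks ~0.52 in the slow genome.  At Ks beyond ~0.8 the NG86 + Jukes-Cantor
  estimator becomes markedly biased upward (2-fold degenerate sites
  saturate faster than the site-model assumes) and increasingly censored by
  the saturation marker; truth-recovery tests run at deeper scales would
  measure estimator saturation, not pipeline correctness.  Deeper histories
  can be configured, but truth comparisons then inherit that bias.
* **Rate-shift bias in dating.**  Lineage rates change abruptly at
  speciations in the simulator, while peak-alignment correction assumes a
  lineage's rate applies along its whole path.  The truth report therefore
  exposes both the configured age ratio of tetraploidy to hexaploidy
  (0.549) and the *recoverable* adjusted-peak ratio under the correction's
  own assumptions (0.619 at default rates); the dating stage is tested
  against the latter.  The same caveat applies to real data whenever rate
  differences arose late.

The simulator does **not** model indels (alignment is exercised by unit
tests instead), inversions beyond what translocation provides, tandem
arrays, transposons, or search-tool-specific hit noise; passing tests
demonstrate recovery of block structure, depth, retention, run-length
statistics and peak positions under clean but realistically lossy
homology signal, not robustness to annotation pathology.

## Problem sizes and determinism

The test suite runs the full pipeline once on the default 2,000-gene trio
(about 6,300 diploid-equivalent genes per genome before fractionation) and
uses 500-gene bundles for module-level checks; the NG86 oracle covers all
3,721 sense-codon pairs and the chaining oracle 200 random instances.  All
randomness flows from explicit seeds; identical configs give byte-identical
bundles and summaries.

## Known limitations

* NG86 with Jukes-Cantor correction ignores transition/transversion bias
  and codon frequencies; beyond Ks ~1 it is a biased estimator and beyond
  ~2 mostly saturated.  The saturation marker keeps such pairs out of
  medians and peaks rather than pretending precision.
* The homology table forbids a target gene from filling two cells of one
  column; tandem duplicates competing for one anchor lose to the longer
  block and are only logged.
* Depth profiling counts block footprints, so heavy fragmentation of one
  orthologous region can inflate depth locally; the modal statistic, not
  the mean, is used for the ploidy call for exactly this reason.
* Dates inherit the calibration interval linearly; no uncertainty beyond
  the calibration bounds is propagated.
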