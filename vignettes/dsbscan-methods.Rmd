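---
title: "dsbscan: methods and design notes"
author: "dsbscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dsbscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbscan)
```

## The signal being modeled

When a CRISPR nuclease (Cas9 or Cas12a) cleaves genomic DNA, the repair
factor MRE11 is recruited to the double-strand break. ChIP-seq against MRE11
therefore produces paired-end fragments that accumulate around every cut
site, on- or off-target. Because MRE11 protects DNA abutting the break and
sonication plus immunoprecipitation recover fragments that end at the cut,
the per-base coverage of short paired-end reads (2 x 36 bp) shows **two
peaks flanking the cut with a dip at the cut itself**: read pairs report
only the two ends of each fragment, and fragments do not span the break.

MRE11 residence at a break is transient, and editing across a cell
population is unsynchronized, so only a fraction of alleles carry MRE11 at
any moment. Inhibiting DNA-PKcs blocks the fast nonhomologous end-joining
pathway and shifts repair toward slower MRE11-dependent pathways, prolonging
residence and multiplying the ChIP signal at every cut site while leaving
background binding unchanged. The package models this as a single
multiplicative factor (`residenceMultiplier`) on the expected number of
site-bound fragment pairs.

## The simulator

`simulateChipReads()` draws, for each planted site, a Poisson number of
fragment pairs with mean `lambda0 * efficiency * multiplier` (the multiplier
applies only under the inhibited condition; a no-nuclease sample suppresses
site fragments entirely). Each site fragment:

* lies entirely on one side of the cut (left/right equiprobable);
* has its cut-proximal end at `cut + |N(0, endSigma)|` on that side
  (half-normal, so ends abut the cut);
* has length uniform in `[fragLenMin, fragLenMax]`, extending away from the
  cut; fragments crossing a chromosome edge are resampled (hard cap of 100
  attempts).

Background fragments are uniform genome-wide. Reads report the two fragment
ends at `readLen` bases each, inward facing. PCR duplicates, low-MAPQ pairs
and orphaned mates are applied last at configurable rates, and every pair
carries a provenance tag (site index or background) so that filters and
discovery can be scored exactly against ground truth.

Background fragments and their artifact flags are drawn from an RNG stream
that depends only on the seed, never on the condition. Consequently
background reads are *identical* between the inhibited and uninhibited arms
under one seed -- the simulator's formalization of "the inhibitor adds no
DNA damage of its own" -- and `residenceMultiplier = 1` reproduces the
no-drug arm byte for byte.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `lambda0` | 50 pairs | on-target signal ~100s of pairs at multiplier 5; desk-scale |
| `residenceMultiplier` | 5 | the approximate fold-gain in site-bound signal under DNA-PKcs inhibition that the method is designed to exploit |
| `fragLenMin/Max` | 150-400 bp | typical sonicated ChIP inserts; reproduces the two-peak/dip shape at 36-bp reads |
| `endSigma` | 25 bp | cut-proximal ends cluster tightly at the break |
| `readLen` | 36 bp | short paired-end ChIP-seq layout |
| `bgPairs` | 400 | see "background depth" below |
| `dupRate/lowmapqRate/orphanRate` | 0.05/0.05/0.02 | realistic nuisance rates; exercised by the filter contract |

**Background depth.** Real ChIP libraries are orders of magnitude deeper,
but candidate detection here uses an *absolute* support cutoff (below), so
what matters scientifically is the expected number of spurious midpoint
clusters reaching that cutoff. With `n` uniform background pairs on a genome
of length `G`, clusters of two midpoints within a 500-bp window number about
`choose(n,2) * 1000/G`; each cluster is scanned over ~`2(2r+1)/16` PAM
placements with a ~3e-5 chance of a random 20-mer lying within 6 mismatches
of the guide. The default `bgPairs = 400` on the 2-Mb toy genome yields
a few tens of spurious candidate clusters per run -- enough to exercise
candidate rejection and control subtraction -- while keeping the expected
number of sequence-matched false calls well below one. Scaling `bgPairs`
and genome size together preserves this regime. Note that no absolute
support cutoff can separate weak sites from background at arbitrarily high
uniform background density; specificity in this workflow comes jointly from
the support cutoff *and* the protospacer match.

## Preprocessing contract

`filterAlignments()` applies, in order: mapping quality (pair MAPQ = min of
mates, strict `>= 25` boundary), singleton removal, then PCR-duplicate
removal by the (chrom, start1, strand1, start2, strand2) signature with the
first-seen pair kept. The order is fixed so the removal report is
reproducible; the operation is idempotent. `subsampleEqualDepth()` subsets
pairs uniformly at random, without replacement, down to the smallest
retained pair count, which leaves window RPM unbiased (checked to <2%
relative bias over 200 resamplings in the tests).

The end-to-end pipeline depth-matches the two *treated* arms (with and
without the inhibitor), because that is the comparison the equal-read rule
protects. The no-nuclease control is filtered identically but not
subsampled: its library is background-only and smaller by construction, so
using it at full depth makes its site list, and hence the subtraction,
conservative.

## Candidate detection and protospacer matching

Fragment midpoints are binned (50 bp); a sliding 500-bp window (stride one
bin) qualifies wherever it holds at least `cutoffC` midpoints (default 2, a
deliberately sensitive threshold; 3 is appropriate for pooled/merged
libraries). Overlapping qualifying windows merge; a merged region's summit
is the lower weighted median of its bin centers, and its support the total
midpoint count. The scan is defined purely on binned counts so that an
exhaustive window-enumeration oracle can verify it exactly.

`matchProtospacer()` scans both strands within `summit +/- searchRadius` for
every placement where the PAM rule holds (Cas9: NGG 3' of the protospacer,
blunt cut between positions 17 and 18; Cas12a: TTTV 5', represented by a
single cut coordinate 18 bp from the PAM-proximal end) and returns the
placement minimizing Hamming mismatches against the guide, with a fixed tie
break: mismatches, then distance of the implied cut from the summit, then +
strand, then leftmost coordinate. No bulges are considered -- sites are
annotated purely by substitution mismatch count.

**Why `searchRadius = 250`.** A fragment midpoint sits at
`cut +/- (endJitter + L/2)` with `L` in [150, 400], i.e. 75-225 bp from the
cut, and the two sides are sampled binomially. When one side dominates by
chance (likely at low support), the weighted-median summit lands 75-225 bp
from the cut, so the scan radius must cover roughly the maximum fragment
half-length plus end jitter. A radius much below ~225 bp silently misses
genuine sites whose summit fell on one flank; 250 bp covers this geometry
with margin while keeping the spurious-match rate per region small.

Calls sharing a cut position are de-duplicated (maximum support kept), RPM
annotated, and any treated call whose cut lies within 100 bp of a site
discovered in the matched no-nuclease control is removed as a presumed
false positive. Output is sorted on-target first, then RPM descending.

## Enrichment quantification

RPM in a window of 1.5 kb centered at the cut: the count of reads (each
mate separately) whose alignment start lies in `[pos - 750, pos + 750)`,
scaled by `1e6 / totalReads`. Start-containment (rather than overlap) keeps
the window count additive over disjoint windows and matches a
"number of reads per million total reads" definition; windows are clipped
silently at chromosome edges. Background enrichment is the same quantity
10 kb downstream of the cut (increasing reference coordinate; the upstream
position is used, and flagged, if the downstream window leaves the
chromosome). Coverage tracks for browser-style inspection are exact
run-length encodings of per-base read coverage via `IRanges::coverage()`.

## Amplicon indel calling

A read is classified by exact, unique matches to two 20-bp anchors located
20 bp outside the ends of the target sequence. Conventions, chosen where
the length-difference definition leaves room, all strict and tested at
their boundaries:

* forward orientation is tried first, then the reverse complement; a read
  valid in both orientations is excluded as ambiguous;
* a flank absent *or found more than once* excludes the read (`no_flank`);
* mean Phred quality over the whole read must be strictly greater than 20;
* the call is `observed inner length - reference inner length`, so
  substitutions between the flanks never change a call.

Bookkeeping is exact: no-flank exclusions + quality exclusions + histogram
counts always equal the input read count, and summaries are invariant to
read order.

## Comparison statistics

All tests are two-sided. Paired comparisons use the Wilcoxon signed-rank
test (zero differences dropped and reported; exact null for <= 25 nonzero
differences without tied magnitudes, else normal approximation with
continuity correction) or the paired t-test. Unpaired comparisons use the
rank-sum test (midranks for ties; exact when the smaller sample is <= 10
and tie-free) or the Welch t-test. The exact/approximate crossovers are
fixed constants for reproducibility. The implementations delegate to R's
`wilcox.test()`/`t.test()`; the test suite verifies the exact branches
against independent full-enumeration oracles (all `2^n` sign assignments;
all `choose(n, nx)` rank assignments) to machine precision, and calibrates
the type-I error at the 5% level over 10^4 null simulations.

Site-set overlaps use greedy nearest-coordinate matching within 100 bp on
the same chromosome, processing candidate pairs in order of increasing
distance; at tolerances far below inter-site distances this coincides with
optimal bipartite matching and is symmetric in the counts.

## End-to-end run and reproducibility

`runEndToEnd()` wires the whole workflow from one YAML-serializable config
and a single master seed, fanned out to named stages via `stageSeed()`
(polynomial string hash modulo 2^31 - 1), so stages are independently
seeded yet the full run is deterministic. The default configuration is a
2-Mb two-chromosome genome carrying one on-target site (efficiency 1) and
ten off-targets spanning 1-6 mismatches at efficiencies 0.05-0.5.

Problem sizes used by the test suite are deliberate desk-scale choices: the
default 2-Mb run for recovery checks, ten independent seeds at weak
off-target efficiencies (0.01-0.06) for the sensitivity-gain comparison,
~2000 fragment pairs for coverage-shape checks, 20000 amplicon reads for
spectrum recovery, and 10^4 simulations for test calibration.

## What passing tests do and do not show

The simulator emulates the *geometry* of the MRE11 signal (end-anchored
fragments, uniform background, residence multiplication, duplicate/MAPQ/
orphan nuisance reads) but not: sequencing errors beyond quality strings,
chromatin-driven nonuniform background, chimeric or translocated fragments,
alignment ambiguity (alignments are emitted perfect; mapping is upstream of
this package), or indel formation at ChIP sites (damage detection is kept
separate from mutagenesis readout). Recovery and specificity results on
synthetic data therefore validate the pipeline's logic and bookkeeping, not
its performance on real libraries, where background structure and
mappability dominate the difficulty. Translocations and large deletions are
invisible to the amplicon indel caller by design, and bulged protospacer
placements are not searched.
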