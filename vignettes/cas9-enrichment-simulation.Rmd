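---
title: "Modelling Cas9 targeted-excision enrichment for nanopore sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cas9 targeted-excision enrichment for nanopore sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capxcise)
```

## The workflow being modelled

Cas9 targeted-excision enrichment prepares a nanopore library for one locus
without PCR. High-molecular-weight DNA is first dephosphorylated, so that
pre-existing 5' ends can no longer ligate sequencing adapters. Cas9
ribonucleoprotein complexes programmed with guides flanking the region of
interest (ROI) then cleave, producing blunt ends with fresh 5' phosphates.
After dA-tailing, adapters ligate almost exclusively to those cut ends, and
the flow cell preferentially reads the excised molecule.

Two geometric facts drive everything downstream:

* **Cut position.** SpCas9 cleaves both strands three bases upstream of the
  NGG PAM, i.e. between protospacer positions 17 and 18. For a forward guide
  occupying `[start, end]` the blunt cut falls between `end - 6` and
  `end - 5`; for a reverse guide between `start + 5` and `start + 6`
  (`cut_site()`).
* **Directionality.** After cleavage Cas9 remains bound on the PAM-distal
  side of the cut, blocking adapter ligation there. Only the PAM-proximal
  side is freed, so reads enter the fragment from that side. A guide is
  oriented *toward* an ROI when its freed end faces it (`orientation()`);
  excision panels need all guides oriented toward the ROI, otherwise reads
  run off into flanking sequence.

`capxcise` implements this workflow as composable stages — synthetic genome,
guide design, digestion with per-end state, library simulation, QC
statistics, repeat-allele phasing — each usable on its own and chained by
`run_pipeline()` or the `capxcise` command-line tool.

## The synthetic diploid genome

`synthetic_genome_config()`/`make_genome()` build seeded diploid test
genomes: i.i.d.-nucleotide chromosomes at configured GC, a minisatellite
target locus inserted with different tandem copy numbers on the two
haplotypes, a degraded copy of the target window on another chromosome (the
paralog), optional guide-site SNPs, and planted "ligatable-end hotspots"
that give the off-target detector something to find. Everything derives
deterministically from the config seed, so FASTA bytes and truth JSON are
reproducible.

Design choices worth knowing:

* The repeat unit defaults to a random 23-mer per seed and is configurable;
  23 nt keeps the repeat arithmetic commensurate with the 23-bp guide sites
  used throughout the package. The biological exemplar (a promoter
  minisatellite present in 1 vs 6 copies, the 6-copy allele heterozygous in
  red-fleshed apple) fixes the 1/6 copy numbers used by the packaged demo,
  not the unit sequence.
* Paralog identity is imposed by independent per-base substitution at rate
  `1 - identity`, so measured identity is binomial around the configured
  value (within ±2 percentage points for loci of 1 kb and larger).
* What is *not* modelled: transposable elements, repeat families beyond the
  one target array, methylation, organellar genomes, chromatin. Tests
  passing on these fixtures therefore say nothing about repeat-rich plant
  genomes beyond the mechanisms explicitly simulated.

## Guide design and scoring

`scan_pams()` is an exhaustive NGG scan of both strands (candidates with
ambiguity codes are dropped; an N never matches). `specificity_search()`
finds all genomic sites matching a protospacer within a substitution budget
next to an NGG, and `specificity_score()` aggregates hits as
`100 * w(intended) / sum(w)` with per-site weights
`w = prod(1 - penalty[p])` over mismatched positions. The 20-entry
per-position penalty table ships as a data file
(`inst/extdata/mismatch_weights.tsv`, the widely used empirical SpCas9
mismatch weights) and can be swapped for any other 20-vector: the score is
100 exactly when the intended site is the only hit, and every secondary hit
strictly lowers it, more so for hits with few or PAM-distal mismatches.

On-target *activity* prediction (how efficiently a perfectly matched guide
cuts) is deliberately out of scope: published activity models need extended
genomic context and training data, so the packaged guide table carries the
printed activity scores as annotation only.

`snp_effect()` classifies haplotype variants at a guide site:

| class | condition | default multiplier |
|---|---|---|
| `full` | site identical | 1.0 |
| `reduced` (distal) | mismatch at protospacer positions 1–10 | 0.5 |
| `reduced` (seed) | mismatch at positions 11–20 (PAM-proximal) | 0.1 |
| `none` | PAM no longer NGG | 0.05 |

The `none` multiplier is intentionally nonzero: a PAM-disrupted guide still
digests a naked PCR amplicon detectably at high RNP excess, yet contributes
essentially no enriched genomic reads — a small residual efficiency
reproduces both observations. During digestion, `full` always cuts and the
other classes cut with probability equal to their multiplier (a seeded
draw), so a 0-or-1 multiplier behaves deterministically.

## Digestion and end states

`digest_template()` locates each guide in the template (tolerating the SNPs
above), decides cleavage, and emits fragments that tile the template
exactly. Each fragment end carries four flags — phosphorylated, blocked
(Cas9-bound), dA-tailed, adapter — plus its origin (`natural` or `cut`) and
the cutting guide. The invariant `adapter ⇒ phosphorylated ∧ dA-tailed ∧
¬blocked` holds after every stage; when a blocked end "leaks" (escapes
Cas9), it is unblocked, flagged `leaked`, and only then ligated, keeping the
invariant intact while preserving truth labels.

Two window bases are implemented side by side in `on_target_window()`
because both occur in practice: `cut_span` (inclusive interval between the
outermost predicted cuts — the excised molecule; 9,177 bp for the packaged
guide table) and `site_span` (distance between start coordinates of the
innermost flanking pair — 7,841 bp for the same table). The "innermost
flanking pair" is identified as the adjacent pair, in start order, across
the largest inter-guide gap; with flanking panels that gap is the ROI. Both
figures are recomputed from the printed coordinates, never stored.

Circular templates and single-strand nicks are unsupported.

## The read simulator and its calibration

`simulate_run()` samples read starts from three pools, with probabilities
proportional to expected ligatable-end abundance:

1. **Fragment ends with adapters** (weight 1 each): free Cas9 cut ends
   (class `cut`), leaked blocked ends (`leak`), and residual phosphorylated
   natural ends (`background`).
2. **Planted hotspots** from the genome truth (their configured density) —
   recurrent fragile sites that produce localized off-target pileups.
3. **Diffuse background** with total weight
   `2 × genome length × background_break_rate × (1 − dephosphorylation_efficiency)`:
   shear breaks along the genome whose ends survived dephosphorylation.
   Break survival is folded into the weight rather than enumerating breaks.

Reads extend from their start into the fragment; length is
`min(extent, log-normal draw, max_read_length)`. The log-normal
(`meanlog = log(1e4)`, `sdlog = 1.06`) gives a median read length near
10 kb while the length-weighted median (which is what N50 tracks) is near
31 kb — reproducing the large median-vs-N50 gap characteristic of such
runs. Per-base qualities are drawn around a per-read mean sampled from the
quality profile; the per-read probability-space mean (the quantity the Q7
pass filter thresholds) is corrected to equal the draw exactly. Two bundled
profiles, `caller_a` (median Q 9.11, spread 1.94) and `caller_b` (median Q
11.22, spread 3.24), mirror the two base callers of the reference run; the
spreads were chosen so the Q7 pass fractions land near 86% and 90%.
Errors are substitutions/insertions/deletions at configured rates (defaults
5/3/4%); homopolymer-specific inflation is off by default. Raw signal, pore
dynamics and base-caller behaviour are not modelled.

### Calibrating the ~3% on-target regime

No ligation efficiencies or break densities are available to measure, so
the `"calibrated_run"` profile *declares* them, calibrated so the packaged
demo (`enrichment_demo()`: four 2-Mb chromosomes, the 1/6-copy locus, a
four-guide panel in which one upstream guide is silenced by a PAM SNP and
the away-oriented downstream guide is weakened by a distal protospacer SNP)
reproduces an on-target read percentage near the published 3.04% at 7,000
reads. The expectation was derived by end-weight bookkeeping before any
acceptance run:

* on-target weight: 4 free cut ends delimit the excised piece (2 per
  haplotype) plus ~0.06 expected leak weight inside the window;
* off-target weight: ~1 expected free end from the weakened away-oriented
  guide, ~0.1 leak, ~0.8 residual natural chromosome ends, 1.3 planted
  hotspot weight, plus the diffuse background
  `w = 2 × 16 Mb × rate × 0.05`;
* diffuse reads overlap a window by chance with probability
  `2 × (window + E[read length]) / genome length ≈ 0.33%`.

Solving `(4.06 + 0.0033 w) / (7.2 + w) = 0.0304` gives `w ≈ 134`, i.e.
`background_break_rate ≈ 8.8e-5` per bp at dephosphorylation efficiency
0.95 — an effective ligatable-break spacing of ~13 kb, consistent with
sheared high-molecular-weight DNA. A 12-seed Monte Carlo check of the
realized mean then revealed a small extra end weight (~2.5) from rare
chance protospacer look-alikes that cleave at low efficiency; refitting the
same equation with that term gives the shipped
`background_break_rate = 8.66e-5` (realized mean within binomial noise,
`sd ≈ 0.21` percentage points at n = 7,000, of the target). These
parameters are calibrated, not measured, and live in `sim_config()` where
they can be overridden.

## QC statistics

`read_stats()` reports counts, bases, median length, N50 (largest L such
that reads ≥ L hold half the bases) and median mean-quality, for all reads
and the pass subset (mean quality ≥ 7, inclusive). `enrichment_report()`
counts a read as on-target when its best (highest mapping quality, ties
broken by target coordinate) alignment overlaps the window by ≥ 1 bp;
following the reference tables' semantics, "on-target coverage" is the
on-target read *count* (forward + reverse), with mean per-base depth over
the window reported separately. `per_base_depth()`, `bin_coverage()` (bin
size default 1,000 bp — the clustering bin width is not specified by the
source analysis, so it is a package default) and `detect_offtargets()`
implement coverage-cluster off-target detection: bins with mean depth ≥ 25
under a mapping-quality ≥ 40 filter are merged when adjacent, and regions
overlapping the on-target window are excluded. The thresholds follow the
reference analysis, where the off-target list was restricted to mapping
quality ≥ 40 and depth ≥ 25; both are arguments.

Since each haplotype is its own reference sequence, the on-target window is
located per haplotype (`target_windows()`); the haplotype carrying the
longer repeat allele has a correspondingly longer window.

## Repeat-allele phasing

Instead of assembling haplotigs (assembly, polishing and consensus are out
of scope — they are external tools' jobs, and consensus polishing is known
to collapse or truncate such arrays), `count_repeat_units()` estimates the
tandem copy number per read: approximate motif occurrences (edit distance
≤ 20% of the unit length per unit, reflecting nanopore error) are collapsed
when nearly coincident, chained when the next unit starts within half a
unit of the previous end, and the longest chain is reported.
`phase_alleles()` clusters per-read estimates: zero-copy reads are
uninformative; copy values with at least `min_support` reads are allele
candidates; neighbouring (±1 copy) sub-threshold values merge into the
better-supported candidate, ties toward the smaller copy number (so two
well-supported *adjacent* alleles, e.g. 2 and 3 copies, are kept distinct).
Two or more alleles ⇒ heterozygous, one ⇒ homozygous, none ⇒ ambiguous.

Limitations: reads that do not fully span the array undercount it (the
merge window absorbs ±1); internal unit variants (subtypes of the repeat
unit) are not distinguished; copy numbers differing by exactly 1 between
true alleles require support above the merge threshold on both sides.

## Numerical and reproducibility choices

* All public coordinates are 1-based inclusive; PAF and BED conversions
  (0-based half-open) happen only at I/O boundaries.
* One global seed fans out at fixed offsets (digestion/library `seed+1`,
  sequencing `seed+2`), so stages can be rerun in isolation; every stage
  restores the caller's RNG state.
* Deterministic tie-breaks: equal-mapq alignments resolve by target
  coordinate; equal-support allele merges resolve toward smaller copies;
  duplicate approximate repeat matches resolve by edit distance then
  position.
* Degenerate inputs fail loudly: empty hit lists, windows from a single
  guide (directed to the single-cut strategy), reverse-before-forward
  primers, out-of-bounds ROIs.
* Problem sizes: unit and property tests run on 8–60 kb fixtures with a few
  hundred reads; the packaged demonstration uses a 16 Mb diploid genome and
  7,000 reads, the scale at which the calibrated regime is defined.
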