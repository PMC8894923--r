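---
title: "Bin-based DMR calling and transgenerational methylome analysis with binmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based DMR calling and transgenerational methylome analysis with binmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`binmeth` analyses plant whole-genome bisulfite sequencing (WGBS) methylomes
at fixed 100-bp resolution. It was built for the kind of study in which a
demethylating agent such as 5-Azacytidine is applied to a population, lines
with genome-wide CG methylation loss are identified, and the fate of the
induced hypomethylated epialleles is followed across selfed generations
(eM2, eM3). The package covers the computational side of such a study:
reading per-cytosine bisulfite reports, calling differentially methylated
regions (DMRs), detecting ectopic CHG methylation, annotating DMRs against
genes and transposable elements (TEs), intersecting DMR-proximal genes with
differentially expressed gene (DEG) lists, drawing gene-body metaplots and
chromosome-scale ratio tracks, quantifying per-DMR restoration between
generations, and testing multi-set overlaps exactly. A WGBS read-count
simulator with a planted-region registry provides a known ground truth
against which every stage is validated.

Read alignment and methylation extraction are out of scope: the package
starts from the standard per-cytosine report (chromosome, 1-based position,
strand, methylated count, unmethylated count, context) that bisulfite
mappers emit.

## The methylation model

Every quantity derives from the *weighted methylation level* of a set of
cytosines: the sum of methylated read counts divided by the sum of total
read counts. This weights deeply covered sites more, which is the standard
choice because the per-site binomial noise scales with coverage. Levels are
computed per context (CG, CHG, CHH — H being A, C or T), because plant
methylation pathways differ by context, and only over sites with coverage
of at least `min_cov` reads (default 4, a conventional WGBS floor).

Cytosines are kept strand-resolved throughout: the two cytosines of a
symmetric CG dinucleotide are independent records, as in the source report.
Collapsing them would halve the site count per bin and change the meaning
of the DMC-count thresholds below, so no collapse option is offered.

Coordinates are 0-based half-open internally (the report's 1-based
positions are shifted on read and restored on write), which makes bin
arithmetic and BED export trivial and lossless.

## The DMR definition

DMRs are defined on a fixed grid of 100-bp bins anchored at position 0 of
each chromosome (the terminal short bin is kept; losing it would silently
drop sites). Comparing a treated sample against a (replicate-pooled)
control:

1. **Site screen.** A differentially methylated cytosine (DMC) is a site
   covered at least `min_cov` in *both* samples whose level difference
   reaches the context threshold.
2. **Bin screen.** A bin is a candidate if both bin levels are defined, the
   signed bin-level difference reaches the threshold in the requested
   direction, and the bin holds at least `min_dmc` DMCs of matching sign.
   Requiring sign agreement prevents a bin with antagonistic sites from
   qualifying.
3. **Merge.** Candidate bins whose edge-to-edge gap is at most 200 bp are
   merged single-linkage (so up to two empty bins may sit between merged
   candidates). Candidates that never merge are discarded: an isolated
   100-bp bin is not a region.

Default thresholds per context:

| variant      | min DMCs | min level difference | control gate |
|--------------|----------|----------------------|--------------|
| CG           | 4        | 0.40                 | —            |
| CHG          | 5        | 0.35                 | —            |
| ectopic CHG  | 3        | 0.15                 | unmethylated control bin |

The site-level DMC threshold reuses the bin threshold of its context. This
is the most parsimonious reading of a definition that names one threshold
per context, and it avoids importing a statistical test the definition does
not state; both are exposed in `dmr_params()` if a user wants them
decoupled.

**Ectopic CHG** calls target CHG methylation arising at loci unmethylated
in the control — a known consequence of CG methylation loss, mediated by
H3K9me/CMT feedback. "Unmethylated control" is deliberately not implemented
as an exact zero, which would be brittle under bisulfite conversion error:
a control bin is eligible if its weighted CHG level is at most 0.02 *and*
no single site shows 2 or more methylated reads. Both knobs are in
`dmr_params()`.

Replicates are pooled by summing counts rather than fitted with a
replicate-aware test, because the design this package targets has a single
library per treated line; pooling maximizes control coverage, and the
bin-level thresholds play the role of an effect-size filter. No
multiple-testing correction is applied across bins — the definition is a
deterministic rule, not a hypothesis test — which is why the package's
validation leans on planted-truth recall/precision and on a null
(self-resampling) control rather than on p-values.

Useful invariants, all under test: hypo DMRs of (A vs B) are exactly the
hyper DMRs of (B vs A); a self-comparison yields zero DMRs; raising any
threshold can only shrink the candidate set; calling per chromosome and
concatenating equals the whole-genome run.

## Annotation, proximity and the multi-set exact test

DMRs are classified as genic, TE or intergenic by largest base-pair overlap
(interval intersection via `GenomicRanges`), with ties broken in favour of
genes — an arbitrary but fixed and documented choice. Gene proximity for
DEG intersection uses the closest-end distance (overlap = 0), strand
ignored, with a 1-kb default window.

The significance of a k-set overlap (of DMR bin sets across lines, or of
gene sets) is computed exactly under the null that each set is an
independent uniform draw without replacement from a universe of `n`
elements. Conditional on the running intersection of the first `j` sets
having size `m`, its overlap with the next set of size `s` is
hypergeometric(`m`, `n - m`, `s`); convolving this recursion gives the
exact distribution of the k-set intersection size, from which the
upper-tail p-value `P(X >= observed)` and the expected size
`n * prod(s_i / n)` follow. For k = 2 this reduces to the classical
hypergeometric tail. The recursion costs O(k · m²) and is exact at any
desk scale; above a configurable smallest-set size a Monte-Carlo chain of
`rhyper` draws replaces it. The test suite checks the recursion against an
exhaustive enumeration of all C(6,3)³ three-set draws on a 6-element
universe and against direct tail sums and simulations.

The *universe* is a modelling choice the test cannot make for you. For
bin-overlap tests the defensible universe is the set of bins with defined
levels in every compared sample — bins uncovered in any sample could never
have been called, and counting them inflates significance. Results are
sensitive to this choice; it is a parameter, not a constant.

## Profiles

Gene-body metaplots average weighted levels in absolute 100-bp windows laid
out strand-aware around each gene: 2 kb of upstream flank, 1.5 kb walking
in from the 5' end, 1.5 kb walking out to the 3' end, 2 kb downstream
(all configurable, multiples of 100 bp). Absolute end-anchored windows are
used instead of a length-normalised body because the underlying analyses
plot fixed 100-bp intervals aligned at the gene ends. For genes shorter
than twice the body window, window pair `j` (counted from each end) is kept
only while `j * 100 <= length / 2`, so 5' and 3' windows never overlap
within a gene. Each gene contributes to a window only where it has covered
sites, and the profile value is the unweighted mean over contributing
genes — a sparse gene cannot inject undefined values.

Chromosome-scale hypomethylation tracks bin the genome at 100 kb, compute
weighted levels for two samples and report their ratio; bins where the
denominator level falls below 0.01 are undefined rather than divided by
near-zero. The DMR × sample matrix (heatmap input) pools counts over each
DMR interval per sample.

## Transgenerational restoration

For each DMR the package computes weighted levels in the control, the
progenitor (eM2) and a descendant (eM3) methylome, and summarizes recovery
as the restoration fraction

    r = (m_eM3 - m_eM2) / (m_control - m_eM2), clipped to [0, 1].

This is the unique linear interpolation with r = 0 at the progenitor level
and r = 1 at full return to control. It is undefined when the
control-to-eM2 loss is below `min_loss` (default 0.2): DMRs always lose at
least 0.4 at bin level when called, but the re-pooled interval level can
fall below, and a near-zero denominator would make `r` meaningless. A DMR
counts as *restored* when `r >= 0.8` (the threshold is a parameter),
*unrestored* when `r <= 0.2`, *partial* in between. Two sibling lines
analysed against the same DMR list are *segregating* at a DMR where their
defined statuses differ; with independent restoration at probability `p`
the expected segregating fraction is `2p(1 - p)`, which the simulator
reproduces.

## The simulator

The synthetic-data module emulates the structure of an epimutagenesis
study: an untreated control and a solvent control with two replicates each,
treated suppressor lines with strong genome-wide CG loss, non-suppressor
lines sampled from the control truth, and two eM3 sibling lines with
partial, independently drawn (hence partially segregating) restoration.

Its stages, each deterministic given the master seed:

- **Genome/annotation**: i.i.d. nucleotides at 36% GC over two 1.5-Mb
  chromosomes by default; non-overlapping genes (1.5-3.5 kb, 10 per
  100 kb) and TEs (0.5-2 kb, 5 per 100 kb) on random strands. Cytosine
  positions and contexts come from scanning the sequence on both strands.
- **True methylome**: each cytosine gets a methylation probability equal
  to its (context × compartment) base level times a multiplicative jitter
  `1 + N(0, 0.05)`, clipped to [0, 1] — multiplicative so that a base
  level of exactly 0 (needed for ectopic-CHG scenarios) stays 0. Default
  base CG levels are deliberately high in *all* compartments (gene 0.75,
  TE 0.85, intergenic 0.65). This is a stylized genome, not Arabidopsis
  euchromatin: a uniformly methylated background guarantees that a planted
  demethylation event is detectable wherever it lands, which is what makes
  unconditional recall/precision benchmarking meaningful. Consequently the
  simulation validates the *caller*, not the compartment structure of any
  real methylome.
- **Epimutagenesis**: the genome is tiled into 1-kb regions; each is hit
  independently with probability 0.1, and CG probabilities inside hit
  regions shift by -0.6 (clipped at 0). Region-level rather than site-level
  events are simulated because DMR callers detect regional signal and
  because induced hypomethylation is observed as contiguous blocks. The
  registry of hit regions is the ground truth for recall/precision.
- **Restoration**: each planted region independently reverts to its
  control probabilities with probability 0.35 (two calls with different
  seeds model siblings). Independent Bernoulli draws are the single
  mechanism behind segregation; there is no linkage between neighbouring
  regions.
- **Read counts**: per-site coverage is Poisson(20); the methylated count
  is binomial with success probability `p * (1 - 0.005)` — conversion
  error thins methylated reads, mirroring the dominant error mode of
  bisulfite chemistry — plus an optional false-methylation floor
  (default 0).

What the simulator does *not* model: read-level effects (mapping bias, PCR
duplicates, M-bias), coverage overdispersion beyond Poisson, sequence-
dependent methylation (it draws compartment means, not CG-island
structure), linked or partial restoration within a region, and dosage
response to the demethylating agent. Passing tests therefore demonstrate
that the implementation applies its rules correctly and recovers regional
signal under idealized noise — not that the default thresholds are optimal
for any particular real dataset.

## Numerical and edge-case choices

- Zero-coverage sites are retained on read (the ectopic-CHG control gate
  inspects raw counts of *all* sites) but never contribute to weighted
  levels.
- Duplicate (chromosome, position, strand) records are an error, not
  silently merged — they indicate upstream corruption.
- Bins with sites but no covered site have an undefined (`NA`) level and
  are omitted from bedGraph output; a bin must be defined in both samples
  to be screened.
- `mean_delta` of a DMR is the unweighted mean over member bins, matching
  the per-bin screening semantics; interval-pooled levels are available via
  `dmr_sample_matrix()` for heatmaps.
- Merging treats bin distance edge-to-edge; hypo and hyper candidates never
  merge with each other.
- The exact-test tail at observed = 0 is exactly 1; Monte-Carlo p-values
  use the (successes + 1)/(draws + 1) estimator so they are never 0.

## Validation scale

The test suite validates on synthetic instances sized to exercise every
rule while keeping a full run in the low minutes: a 200-kb single-
chromosome instance for exact brute-force equivalence of the caller, the
3-Mb default scenario for recall/precision (about 300 planted regions) and
for 20 null repetitions, 3-Mb and 1.2-Mb scenarios for restoration
(>= 1000 regions) and sibling segregation (>= 500 regions), and a 1-Mb
uniform-methylome instance (about 100 genes) for profile flatness. The
same computations, from scratch, are what `scripts/acceptance.R` reports.

## Limitations

- The DMR definition is deterministic; no FDR across bins is computed, and
  CHH DMRs have no calibrated defaults (the caller is context-generic, but
  sensible CHH thresholds are dataset-dependent).
- Replicate pooling discards within-group dispersion; with multi-replicate
  treated designs a beta-binomial caller would be preferable.
- The restoration fraction is a per-DMR interval summary; site-level
  definitions of a "restored locus" would differ at partially restored
  regions.
- The exact test's universe is user-supplied; conclusions can change with
  it, and no default can be defended for every design.
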