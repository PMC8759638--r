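---
title: "Fragment-size-resolved CUT&RUN analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-size-resolved CUT&RUN analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

CUT&RUN tethers micrococcal nuclease to an antibody bound in situ, so the
paired-end fragments it releases report the particles occupying the DNA near
the targeted epitope. Two fragment classes carry distinct information:

* **nucleosomal fragments** (~150-250bp) footprint intact histone octamers and
  trace the breadth of the targeted histone modification;
* **sub-nucleosomal fragments** (<120bp) footprint transcription-factor-bound
  DNA regulatory elements (or partially unwrapped nucleosomes) released
  because they sit in the immediate spatial vicinity of the modified
  nucleosomes.

Splitting one library at a strict 120bp threshold therefore yields, from a
single experiment, both a broad-domain map of the modification and a peak map
of its associated regulatory elements. Everything in this package serves that
split view: binned coverage for the all-fragment ("nucleosomal") signal,
midpoint pileups and Poisson peak calling for the short-fragment signal,
domain segmentation, border/internal classification of peaks against domains,
midpoint-versus-length (V-plot) matrices, region quantification across
knockdown-style conditions, and qPCR fold-enrichment arithmetic.

All coordinates are 0-based half-open internally and BED-dialect on disk. The
midpoint of a fragment of length $L$ at start $s$ is $s + \lfloor L/2
\rfloor$. 5' and 3' refer to genome coordinate orientation (lower/higher
coordinates), not transcript strand: the per-peak heatmaps and the
border-element vocabulary are defined without per-peak strand information.

## Short-fragment peak calling

`call_short_fragment_peaks()` is a transparent re-implementation of
local-lambda Poisson peak calling, specified completely so that an exhaustive
per-bin oracle can verify it (the test suite does exactly that):

1. midpoints of sub-nucleosomal fragments are piled into 10bp bins
   (`short_bin_bp`); no fragment-model shifting, no deduplication —
   duplicate fragments are biological signal in a nuclease-release assay;
2. each bin's expected count is $\lambda = \max(\lambda_{genome},
   \lambda_{5kb}, \lambda_{10kb})$, the local means computed over centered
   windows truncated at chromosome ends; the window pair follows the
   convention of the standard caller this replaces and is configurable;
3. a bin is significant when $P(X \ge n \mid \lambda) < 10^{-4}$ (raw
   p-value, `peak_pvalue`; no FDR correction — reproducibility filtering
   across biological replicates plays that role instead);
4. significant bins merge across gaps of at most 30bp, and merged regions
   narrower than 50bp are dropped. These two constants are not dictated by
   the upstream convention; they are chosen so that tandem footprints a few
   bp apart (such as a 14bp tandem palindrome bound by two factors) remain a
   single peak while isolated single-bin noise cannot form a peak. The
   summit is the center of the maximum-pileup bin, leftmost on ties.

`reproducible_peaks()` implements the high-confidence rule as "present in all
replicates": replicate 1's peaks are kept when they overlap (>=1bp) a peak in
every other replicate, and replicate 1's coordinates are reported. Whose
coordinates to keep is an open convention; replicate 1 is used throughout for
determinism.

## Domain segmentation

The broad-domain caller is a threshold-merge-filter segmentation with all
three constants exposed: a bin is enriched at `enrichment_factor = 2` times
the genome-wide median of nonzero bins; enriched runs merge across gaps up to
`gap_bp = 2000`; domains narrower than `domain_min_bp = 3000` (the floor of
the observed genome-wide domain size range, 3-240kb) are discarded. The
median-of-nonzero-bins background is robust both to the silent majority of
the genome and to the heavy right tail contributed by pericentric signal.

Two binning grids serve different purposes. Coverage for visualization and
per-peak profiles uses 25bp (all fragments) and 10bp (short fragments) bins,
the standard display granularity. Segmentation, however, runs on a dedicated
**500bp** grid (`domain_bin_bp` in the pipeline): at display granularity the
per-bin Poisson noise of realistic backgrounds pushes a few percent of
background bins over threshold, and the 2kb gap-merging rule then welds them
onto true domain edges, extending domains by up to 2kb; at 500bp the bin
variance shrinks enough that background exceedances are (several-sigma) rare
while edge quantization stays well below the domain size floor. The cost is
up to one 500bp bin of systematic edge uncertainty (fragment-extension smear
and the phased nucleosomes that flank border elements can carry the
edge-adjacent bin over threshold).

That uncertainty motivates the border classification slack:
`classify_peaks()` labels a summit a 5'/3' border element when it lies within
`border_slack_bp = 1000` of a segmented domain edge (inside or outside),
internal when strictly inside beyond the slack, and outside otherwise, with
the lower edge winning ties on very narrow domains. One kilobase — the same
scale as the per-peak heatmap flank — is "at the border" relative to domains
that span 3-240kb, and it absorbs the segmentation edge bias with margin;
a 500bp slack does not, and misclassifies true border elements as internal
whenever an edge extends by one segmentation bin.

Domain enrichment is summarized size-normalized: `density` is the summed
normalized per-base signal over the domain divided by its width, i.e. mean
normalized coverage, the y-axis of the width-versus-density scatter in which
an unusually dense kilobase-scale mini-domain stands out from the bulk.
Whether domains should be called per replicate or on pooled data is not
fixed by convention; the pipeline pools control replicates (peaks, by
contrast, are called per replicate and intersected).

## Quantification and normalization

`quantify_regions()` counts fragment midpoints in regions (midpoint-in-region
is additive across adjacent regions, unlike any-overlap counting), normalizes
per million fragments, and reports percent change versus a designated
control. Per-million scaling and downsampling to common depth
(`downsample_fragments()`, the pipeline default) are equivalent in
expectation; both are exposed because downsampling mirrors the conventional
processing while per-million scaling keeps unequal-depth synthetic
comparisons simple. `meta_domain_profile()` rescales each domain body to 100
bins by linear interpolation between bin midpoints and adds ±3kb native-scale
flanks at 100bp bins; domains narrower than 100bp are skipped with a warning.

`qpcr_fold_enrichment()` applies the double normalization of
CUT&RUN-qPCR: fold change relative to a whole-MNase control (free nuclease,
no antibody tethering) and relative to a reference locus depleted in the
assayed marks (default `Sas10`):
$2^{\Delta Ct_{locus}} / 2^{\Delta Ct_{ref}}$ with
$\Delta Ct = Ct_{MNase} - Ct_{CutRun}$, technical duplicates averaged on the
Ct scale. The reconstruction matches the two stated normalizations; whether
the original assay used exactly this ΔΔCt form or a percent-of-input variant
is not documented, but the two coincide up to a locus-independent factor that
the reference normalization removes.

## Motif scanning

`scan_motif()` does exact IUPAC consensus matching at every offset, on both
strands: reported hits are perfect consensus matches, so p-value-scored PWM
scanning is deliberately out of scope. Minus-strand matches are reported at
forward coordinates with strand `-`, and a palindromic motif yields
coincident +/− matches **counted separately** — the only convention under
which the 14bp tandem palindrome `TATCGATATCGATA` carries four matches of the
8bp DRE consensus `TATCGATA` (offsets 0 and 6 on each strand), and
`match_span()` of those matches is the 14bp interval whose deletion defines
the promoter-mutant transgene. A position matches when the IUPAC sets of
pattern and sequence letters intersect (for plain ACGT sequences this is
ordinary consensus matching; an `N` in the sequence matches any pattern
letter).

## The synthetic generator and what it does (not) emulate

`synthetic_spec()` and `simulate_fragments()` plant ground truth for every
downstream stage: domains of nucleosomal signal (rate per kb replaces the
background inside the domain, so condition multipliers map directly onto
percent-change readouts), elements shedding Poisson numbers of
sub-nucleosomal fragments with midpoints jittered uniformly within the
footprint, phased nucleosomal hotspots at element centers ±120bp (default
on), and uniform nucleosomal plus sub-nucleosomal background. Fragment
lengths follow truncated normals — nucleosomal mean 185, sd 25 on
[147, 250]; sub-nucleosomal mean 90, sd 20 on [50, 130] — the length
*ranges* being the observed fragment classes while the parametric form
within them is a modeling choice, fully exposed in the spec. Libraries are
reproducible from a single seed via deterministic per-library child seeds.

`dhd_fixture()` encodes the study conditions used by the tests and examples:
a 4Mb chromosome; nucleosomal background 25 fragments/kb and sub-nucleosomal
background 0.3/kb; a 5450bp mini-domain at 600/kb with exactly two border
elements (92bp and 148bp footprints, centered 151bp and 91bp inside the
edges, matching the published element spans relative to the derived edges)
and no internal elements; a 40kb control domain at 300/kb with border and
internal elements; 80 expected short fragments per element; two replicates.
The published mini-domain interval is internally inconsistent with its
stated ~5450bp width, so the fixture derives the 5' edge as (3' edge −
5450bp) and records the choice in its ground-truth notes. Domain rates are
set so that element-derived short fragments are a small minority (~3%) of
in-domain signal, as in real libraries; this matters because the in-domain
readout is an all-fragment count, and a fixture with an outsized element
share would measure a composite of the domain and element effects rather
than the planted domain effect. Condition profiles mirror the knockdown
effect regimes of the study system: −35%, −20% and −5% on domain signal,
~63% reductions of element-associated short fragments where the
corresponding factors act, a condition scaling only the mini-domain border
elements, and one raising the mini-domain by 20% while leaving elements
intact.

What passing tests on this generator do **not** show about real data: there
is no mappability or GC structure, no sequence content (no FASTQ), no
cell-type mixture (whole-tissue signal mixes germline and somatic
populations), no antibody efficiency variation between samples, and
condition effects are exactly multiplicative. Parameter-recovery results
bound estimator behavior under the model, not biological effect sizes.

## Problem sizes and numerical choices

The validation suite runs the full architecture-recovery and
parameter-recovery loops over 20 seeds each at the fixture's default depth
(~120k fragments per library), the depth at which the per-seed recovery
noise (about 1-2 percentage points on domain contrasts) is comfortably
inside the ±5-point acceptance band. Oracle-equivalence checks use 20-100kb
genomes where the exhaustive per-bin scan is affordable. Peak p-values are
computed on the log scale (`ppois(..., log.p = TRUE)`) so scores remain
finite for extreme pileups; tie-breaks (summit, classification at narrow
domains) are resolved leftmost/lower-edge-first; degenerate inputs (empty
fragment sets, all-zero tracks, zero-signal regions) return empty or flagged
results rather than errors, while contract violations (nucleosome-sized
fragments reaching the short-fragment caller, overlapping domains, target
depth exceeding library size) raise immediate errors.

## Known limitations

* Genome-wide numbers from the original tissue data (numbers of peaks and
  domains, knockdown percent changes) are properties of unreleased
  sequencing libraries and are not reproduced here; the package validates
  the *procedures* on planted ground truth and on in-text worked examples.
* Euchromatic H3K9me3 domain calling is out of scope: pericentric signal
  dominates that mark and defeats the segmentation background model; H3K9me3
  is handled only through region quantification and qPCR fold enrichment.
* The peak caller's local-lambda windows (5kb/10kb) follow the upstream
  convention rather than being estimated from the data.
* `reproducible_peaks()` privileges replicate 1's coordinates; summit-level
  consensus across replicates is not attempted.
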