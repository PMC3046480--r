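---
title: "Calling nuclear-membrane-association domains: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling nuclear-membrane-association domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmadomains)
```

# The problem

Inner-nuclear-membrane proteins of the LEM-domain family (such as LEM-2 in
*C. elegans*) contact chromatin, and ChIP against them maps which genomic
regions sit at the nuclear periphery. On a holocentric genome the picture is
distinctive: multi-megabase membrane-association domains occupy the
chromosome arms, the chromosome centers are looped away, and within each
large domain lie finer subdomains of continuous association punctuated by
gaps of various sizes that are presumed looped out. `nmadomains` implements
the complete analysis that produces this picture from raw signal —
normalization of tiling-array log-ratios or sequencing fragment counts, a
binarized sliding-window subdomain caller with a control-antibody empirical
false-discovery ratio, cross-platform validation, gap classification,
boundary metaprofiles, and the downstream enrichment statistics — together
with a synthetic-genome simulator that plants ground-truth domains so every
stage can be tested end to end without external data.

# The calling procedure

Both platforms reduce to the same calling core:

1. **Score track.** Arrays: per-probe log~2~ ratios are standardized within
   GC strata (quantile bins of the probe GC fraction; center by the bin
   median, scale by the bin MAD, with a global-MAD fallback when a bin is
   degenerate), and replicates are combined by taking the median of the
   pooled normalized values in 300-bp sliding windows. Sequencing: reads
   are extended to 300 bp in their strand direction, overlapping fragments
   are counted per base, the input library is downsampled to the ChIP's
   fragment count, subtracted, the difference is z-scored against its own
   genome-wide mean and population SD, and smoothed in 300-bp windows at
   50-bp offsets.
2. **Binarize.** Positive scores become +1, non-positive scores −1. Two tie
   rules matter. A score of exactly 0 maps to −1 (conservative toward
   non-association). For input-subtracted count tracks there is a second,
   subtler tie: count data put an atom of probability at a count difference
   of exactly zero, and after z-centering that atom sits at
   $z = -\bar d/s$, a hair above or below 0 depending only on the sampling
   sign of the genome-wide mean $\bar d$. `subtract_zscore()` therefore
   records the zero-difference point and `binarize()` bounds the positive
   class at it, so a non-positive count difference is always −1. Tracks
   whose genome mean is pulled up by genuine signal (the usual IP
   situation) are unaffected, because there the zero-difference point lies
   below $z = 0$.
3. **Window.** Binary values are averaged in 200-probe windows sliding one
   probe (arrays) or 10-kb windows at 50-bp offsets (sequencing). A
   window's genomic extent is `[first element, last element + grid step)`,
   truncated at chromosome ends; windows more than half missing are
   flagged and never called.
4. **Call and merge.** Windows whose mean is *strictly* greater than the
   threshold (0.8 array, 0.4 sequencing) are positive; positives
   overlapping by at least 1 bp are merged transitively (abutting windows
   are not merged). The same chain applied to a control-antibody track
   gives the empirical false-discovery ratio: positive control windows
   divided by positive IP windows, with ceilings of 2.5% (array) and 2.4%
   (sequencing) at the default thresholds.
5. **Cross-validate.** Regions of either platform with no overlap in the
   other are discarded as platform-specific artifacts; each connected
   overlap component is merged into one subdomain. Gaps are the
   per-chromosome complement, classified by length with left-closed
   cutoffs — S `[0, 10 kb)`, M `[10 kb, 100 kb)`, L `[100 kb, 1 Mb)`, XL
   `[1 Mb, ∞)` — and every XL gap defines a chromosome-center segment.

# The simulator

`sim_config()` holds every tunable. The defaults describe the study
conditions the test-suite exercises: two 10-Mb chromosomes, probes every
50 bp, terminal arms covering 0.3 of each chromosome end, planted domains
filling 0.5 of arm bases, association strength 0.6 array-noise-SD units at
the chromosome ends declining by 0.05 per Mb inward plus an additive 0.2
bonus within 1 Mb of a physical end, Gaussian probe noise of SD 1 with an
additive GC-linear probe bias, and Poisson sequencing fragments at a mean
depth of 3 per 300-bp extension window, with IP enrichment
$1 + (f_\mathrm{ref} - 1)\, s/s_\mathrm{end}$ so a domain at the reference
end strength is exactly doubled ($f_\mathrm{ref} = 2$).

Domain sizes are log-normal with a median that decays with distance from
the nearest chromosome end (100 kb at the end, rate 0.4 per Mb, shape 0.8),
so larger domains sit near the ends; gaps come from a three-component
log-normal mixture aligned with the S/M/L classes whose draws grow with
distance from the end (rate 0.8 per Mb, capped at 500 kb so the only XL gap
of a chromosome is its center). Within each arm the generator draws the
alternating gap/domain sequence and then rescales gaps and domains
separately so each exhausts its share of the arm exactly: realized
occupancy equals the target up to rounding and the domains span the whole
arm. The default gap-mixture weights and medians were set so the expected
gap size balances the expected domain size at the default occupancy — a
consistency requirement, since a mismatch would silently leave the inner
arms empty. Domains straddling a terminal-bonus boundary are split there,
giving the strength geography a sharp per-base edge; this is what lets the
fusion analysis recover the planted attenuation extent at window
resolution.

Annotations follow the biology the analysis is meant to detect: repeat
density is higher inside domains with family-specific contrasts (helitron
and satellite 8-fold by default, others 1.3–1.5-fold), gene density is
higher outside (180 vs 100 per Mb), a quarter of gap genes have their
translation start placed within 2 kb outside a domain edge, expression
(dcpm) is log-normal with class shifts that make small-gap genes the most
expressed and domain genes the least, early-silent genes stay silent
stage-to-stage with higher persistence inside domains (0.95 vs 0.7 per
stage), chromatin-mark tracks put H3K27me3 over domains except at active
genes and H3K4me3/RNAPII/HTZ-1 over expressed gap genes, and phenotype
labels are depleted among domain genes. Setting every effect to zero gives
a null world in which no contrast should be detectable.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: no nucleotide sequence or alignment (fragments
are coordinates), no probe cross-hybridization structure beyond a uniform
non-unique flag, no antibody-specific background structure (the control
track is a pure shared-noise null; see the FDR note below), no
cell-type mixture within a sample, and no correlation between repeat
content and signal except what is planted.

# Numerical choices

- Coordinates are 0-based half-open everywhere; conversion happens only at
  the BED/GFF3/bedGraph boundary (`rtracklayer` does the parsing, GFF3's
  1-based closed convention is converted on entry).
- The z-score uses the population (n-denominator) SD; at genome scale the
  choice is immaterial and fixing it keeps runs byte-reproducible.
- Windowed medians over bp-delimited windows on irregular probe grids are
  computed in C++ (two-pointer sweep with `nth_element`); every windowed
  operator is checked against a brute-force per-position oracle in the
  test suite.
- Missing values propagate: windows with no finite value are missing, not
  zero, and calling windows more than half missing are excluded.
- Boundary metaprofile offsets are window centers; offset 0 is the
  boundary coordinate and belongs to the subdomain side. The gap-side flank
  is limited to the gap size only when the gap is under 5 kb (gaps of 5 kb
  or more use the full ±10-kb default flank, which is a configurable
  default, not a claim about any particular dataset). Confidence intervals
  are 1.96 × SEM across boundaries or genes.
- Transcripts sharing an exact (chromosome, start, end, strand) key are
  collapsed to one before translation-start analyses.
- The fusion attenuation extent is a declared operationalization: walking
  window-by-window from the junction, windows with a difference below the
  negative threshold are attenuated, near-zero windows bridge the walk
  (gap-dominated windows dilute the per-base difference toward zero
  without interrupting the attenuated region), a clearly positive window
  ends it, and the extent reaches the far edge of the last attenuated
  window. Re-estimating GC-bin medians on a fused genome shifts the
  normalization baseline by a few hundredths of a score unit genome-wide,
  so "no difference away from the junction" holds only up to that offset.

# Design decisions that were genuinely open

- **Interfaces.** The package's functions (plus `run_pipeline()`, which
  executes the stages in dependency order and writes BED/bedGraph/TSV
  artifacts with provenance JSON) are the user interface; no shell entry
  point is provided because the intended users work in R.
- **Threshold selection.** The caller defaults to the fixed strict
  thresholds (0.8/0.4). `fdr_curve()` exposes the full threshold-ratio
  curve so a ceiling-driven choice (smallest threshold meeting the FDR
  ceiling) can be made instead; the fixed defaults are used everywhere in
  the package because they are the published operating point.
- **Strength model.** Linear decay with an additive terminal bonus is the
  simplest model producing both the end-proximal strength gradient and a
  mechanism for fusion-point attenuation; the log-normal size law and the
  decay rates are modeling conveniences, not claims about any organism.
- **Sequencing enrichment.** "Proportional to strength" and "doubled
  inside domains" are reconciled by anchoring the fold at the reference
  end strength.

# Known limitations

- **Sequencing-mode FDR under a symmetric null.** With a control track
  drawn from the same uniform Poisson null as the input, the smoothed
  binarized control has an effective sample size of only ~30 per 10-kb
  window (fragment extension plus smoothing correlate the sign process
  over roughly 450 bp), so a window mean above 0.4 is a ~2.3σ event and
  about 1% of control windows pass. With IP positives near 24% of windows
  the ratio lands around 3–7%, above the 2.4% ceiling that real data meet.
  Real control antibodies achieve lower ratios because their background is
  asymmetric (reads cluster in hotspots, depressing the z-score
  elsewhere), which the shared-null control model deliberately excludes.
  The array-mode ceiling is met comfortably because probe noise is
  independent, making the 0.8 threshold a ~4σ event.
- **Weak-domain detection edge.** Domains at ~0.45–0.55 noise-SD (the
  innermost arm, after the GC-bin median centering absorbs part of the
  planted mean) sit at the array caller's operating point; occasionally
  one platform misses such a domain entirely and cross-platform validation
  drops it. Called centers consequently extend somewhat into the weakest
  inner arms, and base-level recovery of the planted domains is high but
  not perfect.
- **Per-region rank-sum exchangeability.** Subdomains and gaps have
  different size distributions, and for sparse features (individual repeat
  families) the per-region coverage-fraction rank-sum is not calibrated
  under a zero-effect null — many small gaps have exactly zero coverage.
  Null calibration is therefore checked under permuted region labels,
  which restores exchangeability; observed contrasts should be read
  against that benchmark.

# Problem sizes

The test suite and the acceptance script run the full dual-platform caller
on two 10-Mb chromosomes (400k probes, ~400k sliding windows per
platform, ~260k sequencing fragments), recovery across 10 seeds, and unit
oracles on ≤50-kb instances; a complete dual-platform run takes a few
seconds on one core, and the whole suite minutes.
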