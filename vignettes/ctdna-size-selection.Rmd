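---
title: "Fragment-length models and in-silico size selection for ctDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-length models and in-silico size selection for ctDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnafrag)
```

## The problem

Cell-free DNA (cfDNA) in plasma is dominated by fragments released by
apoptosis of normal, mostly hematopoietic cells, with a modal length of about
167 bp — one nucleosome core plus linker. Tumor-derived cfDNA (ctDNA) is
systematically shorter: modal lengths around 134/144 bp in xenograft models
and ~145 bp in human tumors, with a pronounced ~10 bp sawtooth periodicity
attributed to nuclease cutting along the nucleosome-bound helix. Because
ctDNA is usually a small minority of total cfDNA, restricting analysis to a
fragment-length window enriched for tumor fragments can raise the mutant
allele frequency (MAF) at an assayed somatic variant severalfold — the
in-silico analogue of excising a gel slice.

`ctdnafrag` implements that analysis chain end to end: a generative cohort
simulator, a xenograft species-of-origin classifier, fragment-length
profiling, in-silico size selection with enrichment quantification, duplex
barcode collapsing, and exact-match in-silico PCR for ladder design.

## The fragment-length mixture model

The simulator draws fragment lengths from a two-component mixture defined by
`mixture_spec()`:

* **normal component** — peaks `(center, weight)`, default a single 167 bp
  peak;
* **tumor component** — default two equal teeth at 134 and 144 bp; a
  one-peak 145 bp setting models the melanoma-like case;
* each peak is a **discretized truncated Gaussian tooth** with standard
  deviation `peak_sd_bp` (default 3 bp): the probability of integer length
  $\ell$ is proportional to
  $\sum_i w_i\,[\Phi(\ell + \tfrac12; c_i, \sigma) - \Phi(\ell - \tfrac12; c_i, \sigma)]$,
  truncated and renormalized on the support $[50, 500]$ bp;
* a fragment is tumor-origin with probability $\theta$
  (`tumor_fraction`), and a tumor-origin fragment covering the assayed
  variant carries the mutant allele with probability $h$
  (`het_mutant_fraction`, default 0.5 for a heterozygous variant; raise it
  to emulate amplification).

The published observations fix only the modal lengths and the ~10 bp
period, not a parametric form; the Gaussian-tooth ladder is the simplest
shape that reproduces modes, width, and periodicity at once. `peak_sd_bp = 3`
makes the 134/144 doublet clearly resolvable while leaving realistic shoulder
overlap; `ladder_peaks()` builds longer decaying combs when an explicit
sawtooth is wanted. The relative weight of the 134 vs 144 bp teeth is not
constrained by any published value; equal weights are the neutral default.

Library preparation recovers short fragments poorly. This is modelled as an
independent logistic retention curve
$p(\ell) = \mathrm{logit}^{-1}\!\big((\ell - m)/s\big)$ with midpoint
$m = 100$ bp and scale $s = 5$ bp (`apply_library_prep()`), the simplest
monotone curve with a tunable threshold and sharpness; $s \to 0$ recovers a
hard cutoff.

### The closed-form window MAF

For a window $W$ of the length axis, with component window masses $F_t(W)$
and $F_n(W)$, the expected MAF among fragments restricted to $W$ is

$$\mathrm{MAF}(W) \;=\; \frac{h\,\theta\,F_t(W)}
{\theta\,F_t(W) + (1-\theta)\,F_n(W)}.$$

`mixture_window_maf()` evaluates this from the discretized masses and is
used throughout the tests as the quadrature oracle against which Monte-Carlo
cohorts are checked (within three binomial standard errors). The continuous
density (`mixture_density()`) integrates to 1 over the support to $10^{-6}$,
which ties the discrete and continuous views together.

## What the simulator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
two-component length mixture, heterozygous somatic variant carried only by
tumor fragments, configurable variant coverage, duplex barcodes, paired-end
101 bp SAM output (fully overlapping mates for fragments shorter than the
read length), dual-reference mapping-quality profiles with known origin, and
short-fragment library dropout. It does **not** model base-call errors,
quality-score distributions, GC or end-motif composition, nucleosome
positioning along a real genome, or PCR chimeras. Green tests therefore
demonstrate the correctness of the estimators on data satisfying the model's
assumptions, not robustness to every artifact of real libraries.

All randomness flows through R's RNG; `simulate_cohort(seed = )` seeds it
explicitly and records the seed, so truth tables and SAM output are
byte-identical across runs.

## Species-of-origin classification

In a xenograft, graft (human) ctDNA and host (rat) cfDNA are separated
bioinformatically. Each read pair is aligned against both references and
classified from the pair of mapping qualities (`classify_read_pair()`):
pairs with MQ < 30 against **both** references are discarded as low quality;
otherwise pairs with $|MQ_A - MQ_B| < 20$ are discarded as ambiguous;
otherwise the pair is assigned to the reference with the greater MQ.
Thresholds are strict as stated — a difference of exactly 20 is kept and an
MQ of exactly 30 is not low. Tumor-DNA abundance is
$n_A / (n_A + n_B)$ over assigned pairs only (`tumor_abundance()`); with no
assigned pairs it is reported undefined rather than zero.

The published rule is phrased per *read* but counted per *read pair*; this
package reconciles the two by giving a pair the **minimum** of its mates'
primary MQs against each reference (`join_dual_alignments()`), the
conservative choice: a pair is only as trustworthy as its worse mate.
Unmapped mates contribute MQ 0, so fully unmapped pairs fall into the
low-quality discard class.

## Fragment-length profiling

* `pair_fragments()` computes lengths as the distance between the outermost
  aligned bases of a proper FR pair, in 0-based half-open coordinates
  (`length = end - start`, consistent with the SAM TLEN magnitude).
  Overlapping mates are one observation. Improper pairs are excluded with
  per-reason tallies, never errors, and counts reconcile exactly:
  fragments + exclusions = input pairs.
* `modal_length()` breaks ties toward the smaller length (deterministic, and
  the shorter modes are the finding of interest); all tied modes are kept in
  an attribute.
* `estimate_periodicity()` detrends the in-band profile with a centered
  moving average (window 11 bp, one full period) and takes the lag of
  maximal autocorrelation of the residual within the search range (default
  8–12 bp). Plain autocorrelation is scale-invariant, so the reported
  amplitude is the autocorrelation multiplied by the residual's coefficient
  of variation relative to the mean band level, clipped to $[0,1]$: exactly
  0 for a flat profile and monotone in comb contrast. An autocorrelation
  estimator was chosen over a spectral fit because the phenomenon is
  reported as a period, not a spectrum, and the lag grid is the natural
  1 bp resolution of the data.
* `stratify_by_allele()` assigns each covering fragment one vote from the
  sequenced base at the variant (mates must agree; bases below Q20 and
  third alleles are excluded with tallies) and pairs votes with fragment
  lengths. `binned_allele_frequency()` bins lengths by their lower edge
  (bin 50 = 50–59 bp at width 10) and reports `mut/(mut+wt)` per bin, with
  sparse bins flagged undefined rather than dropped.

## Size selection and enrichment

`select_window()` keeps fragments with $lo \le \ell < hi$. `enrichment()`
reports the fraction-vs-library MAF fold change and the peak offset
(fraction modal length minus library modal length; negative = shorter). A
fraction equal to the whole library gives fold exactly 1, the identity that
anchors the enrichment scale. A zero library MAF makes the fold undefined
and flagged — mirroring an assay's noise floor in a negative control —
rather than infinite or silently omitted.

`scan_windows()` slides a fixed-width window (default 30 bp, matching the
width of the empirically optimal 20–50 bp-shorter region) across offsets
relative to the library peak. Windows with fewer than `min_count`
(default 20) allele-informative fragments are reported with an undefined
fold and excluded from the argmax: in a dilute cohort a nearly empty window
can contain a single mutant fragment and a spurious fold, the window-level
analogue of sparse-bin erraticism. `gel_fractions()` produces adjacent
windows tiling the support, by explicit boundaries or equal-count quantile
cuts, conserving counts across the tiling.

On a calibrated dilute simulation (tumor peak 145 bp, normal 167 bp,
library MAF ≈ 1.7%), the scan's best offset falls 20–50 bp below the
library peak, and windows above the peak dilute the mutant allele — the
qualitative shape the method predicts. Windows more than ~50 bp below the
peak lose their advantage once the logistic library-prep dropout is applied,
since sub-100 bp fragments are poorly recovered.

## Barcode collapsing and gene-level copy number

`collapse_families()` groups read pairs by duplex barcode plus alignment
key (chromosome, fragment start/end, orientation) into source-molecule
families. Singleton families are flagged and omitted from unique counts
(their error rate is relatively higher); no edit-distance barcode merging is
performed — the modelled protocol omits singletons rather than correcting
barcodes. The consensus allele is a strict majority with ties ambiguous.
Collapsing conserves pair counts, is order-invariant, and is idempotent on
its own unique observations. `copy_number_by_gene()` computes per-gene mean
unique depth via coverage vectors and flags genes whose ratio to the panel
median (or a supplied baseline) exceeds 2.0 — a free choice, as no published
threshold accompanies the amplification calls it emulates.

## In-silico PCR

`find_amplicon()` does exact matching only: the ladder primers are a fixed
worked design, not a general PCR tool. Reverse primers in protocols are
often printed 3'→5', which is ambiguous — the string may be the antiparallel
annotation of the plus strand (binding site = its base complement) or a
mislabelled 5'→3' oligo (binding site = its reverse complement). `auto` mode
tries both, keeps the interpretation yielding a unique product (preferring a
supplied expected length), and reports which was used. Product lengths are
primer-inclusive and invariant under reverse-complementing the template.

The phage-lambda genome itself is not distributed with the package;
`synthetic_ladder_template()` builds a clearly-labelled synthetic template
with the three printed ladder primer pairs planted so their products are
exactly 262, 240 and 229 bp. It validates orientation resolution and length
arithmetic; its coordinates are synthetic.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; conversion happens only at
  VCF (1-based) boundaries. `read_variant()` accepts a minimal VCF or TSV
  and rejects indels and multi-allelic records.
* Degenerate inputs are defined, not crashed: empty histograms are valid
  with total 0; the modal length of an empty distribution and a
  zero-denominator abundance are errors/undefined flags respectively;
  out-of-range lengths are tallied as under/overflow.
* Run reports (`run_report()`/`write_report()`) refuse to serialize when
  counts do not reconcile, and are written with sorted keys and no default
  timestamp so identical runs are byte-identical.
* Problem sizes in the test suite were chosen so each statistical check has
  power at three binomial standard errors: $10^4$ draws for tooth-weight
  recovery, $10^5$ fragments for window-MAF, modal-length and
  periodicity recovery, and the enrichment-profile shape.

## Worked example

```{r example, eval = FALSE}
spec <- mixture_spec(tumor_fraction = 0.034, tumor_peaks = list(c(145, 1)))
cohort <- simulate_cohort(1e5, spec, covering_fraction = 1, seed = 1)
scan <- scan_windows(cohort$observations)
scan$best_offset      # 20-50 bp below the library peak
subset(scan$profile, offset %in% c(-30, 0, 20))
```

## Known limitations

* The simulator's placement model is uniform around a single variant; it
  does not emulate capture-panel footprints or coverage waviness.
* `stratify_by_allele()` reads the base through the alignment as stacked by
  the CIGAR; it does not realign around indels (SNVs only, matching the
  variant model).
* The periodicity amplitude is a relative score for comparing profiles, not
  a calibrated physical quantity.
* Species classification consumes alignments; it performs none, and its
  accuracy inherits the aligner's behaviour on homologous regions.
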