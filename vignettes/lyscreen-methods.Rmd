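---
title: "Methods: screen scoring, simulation and colocalization statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen scoring, simulation and colocalization statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyscreen)
```

# The screening problem

A positive-selection pooled CRISPR knockout screen exposes a library of
mutant cells to a lethal agent and asks which knockouts survive. In the
design this package targets, the agent is lysenin, a cytolysin that
binds clustered sphingomyelin (SM) in the plasma membrane and kills
SM-bearing cells; cells in which SM synthesis, transport or surface
exposure is disrupted survive. The mutant library is a GeCKO-v2-style
genome-wide knockout library: six sgRNAs per gene, split three and
three across two half-libraries, A and B. Each half-library is screened
as two independent pools (A-1, A-2, B-1, B-2). Each pool has a treated
arm, exposed to a low dose of lysenin three times with regrowth in
between, and an untreated arm that is simply subcultured for the same
period. Integrated sgRNA cassettes are PCR-amplified from genomic DNA
of both arms and sequenced; the relative abundance of each guide after
versus without selection is the screen's readout.

# Scoring model

All scoring derives from three deterministic rules applied to the
guide-by-sample count table:

1. **Normalization.** For guide $g$ in sample $s$ with raw count
   $c_{gs}$,
   $$n_{gs} = \frac{c_{gs}}{\sum_{g'} c_{g's}} \times 10^7 .$$
   Every normalized column sums to $10^7$; an all-zero column is a
   hard error because the quotient is undefined.

2. **Fold enrichment.** For each pool, with treated value $t_g$ and
   untreated value $u_g$ (both normalized),
   $$\mathrm{FE}_g = \frac{t_g}{\max^{*}(u_g)}, \qquad
     \max^{*}(u_g) = \begin{cases} 1 & u_g = 0 \\ u_g & u_g > 0.\end{cases}$$
   The zero rule applies to the denominator only: a guide absent from
   the treated arm has $\mathrm{FE} = 0$, never a reformatted value.
   Because normalized values are on the $10^7$ scale, substituting 1
   for a zero denominator makes a guide that appears only after
   selection legible as strongly enriched without producing an
   infinity.

3. **Calling.** A guide is *reproducibly enriched* when
   $\mathrm{FE} > \tau$ (strictly; default $\tau = 5$, "more than
   fivefold") in **every** pool experiment of its own half-library
   (`replicate_mode = "all"`). A gene is a *candidate* when it has at
   least `min_per_half` (default 1) enriched guides in half-library A
   **and** in half-library B; genes passing in exactly one
   half-library are reported separately as *partial*. Ties are
   impossible by construction — the rule is a deterministic threshold,
   and no multiple-testing machinery is added because none is part of
   the selection rule being implemented.

Two interpretation choices here were genuinely open and are worth
recording. "Reproducibly enriched" is read as *both* replicate pools of
the guide's half-library exceeding the threshold, matching the
two-independent-experiments design; a one-of-two mode is exposed as
`replicate_mode = "any"` for sensitivity analyses. And the dual-library
gene criterion is read as at least one qualifying guide per
half-library, with the minimum exposed as `min_per_half`, because the
rule names the half-libraries but no guide count.

`run_screen()` composes the three rules and stamps the report with the
parameters used. The implementation is checked in the test suite
against a brute-force enumerator that literally loops over guides,
pools and genes applying the written rule.

# Read processing

The read-processing stage (`count_screen()`) models the amplicon as
`barcode + flank5 + spacer + flank3`:

- **Demultiplexing** assigns a read to the unique sample whose inline
  barcode is within `max_barcode_mismatch` Hamming distance of the
  read prefix (default 0). A read with no barcode in tolerance *or a
  tied best match* is unassigned — ties are never broken, trading
  yield for count integrity.
- **Spacer extraction** finds the first exact occurrence of the 5'
  flank downstream of the barcode and takes the following 20 bases; a
  non-empty 3' flank must follow immediately or the read is rejected.
  Searching (rather than a fixed offset) makes extraction robust to
  small upstream indels; a fixed `fallback_offset` is available for
  flank-damaged reads.
- **Counting** is exact-match by default. At `mismatch_tolerance = 1`
  a spacer is counted for a guide only when it matches no spacer
  exactly and exactly one within Hamming distance 1; ambiguous
  near-misses stay unmapped.

The conservation identities (reads = assigned + unassigned; assigned =
mapped + unmapped + unextractable) hold exactly and are asserted in the
tests. The defaults of 0 mismatches everywhere are the strictest
reproducible choice; real screens with noisier chemistry can relax both
tolerances by one. The barcode set, flank sequences (`CACCG`
upstream, `GTTT` downstream — the conventional U6 cloning overhang and
scaffold start for lentiviral sgRNA amplicons) and barcode-first layout
are declared conventions of this package's simulator, not a
reconstruction of any particular sequencing design; all are parameters.

# The synthetic screen

`simulate_screen()` generates screens with known ground truth so every
pipeline stage is testable without external data. The model:

- **Library**: `n_genes` genes × 6 unique random 20-nt spacers, split
  3/3 between half-libraries.
- **Baseline**: per pool, guide abundances are drawn log-normally with
  log-scale spread `baseline_sigma` and normalized to sum to one —
  the familiar skewed representation of a plasmid library after
  amplification. `baseline_sigma = 0` gives a uniform library.
- **Selection**: each round multiplies a guide's abundance by its
  survival weight $w_g = s_\mathrm{base} + e_g\,(s_\mathrm{hit} -
  s_\mathrm{base})$ for hit-gene guides of efficacy $e_g$, and
  $w_g = s_\mathrm{base}$ otherwise, then renormalizes; three rounds by
  default, mirroring the three lysenin exposures. Selection is
  computed at expectation level (deterministic), so the only
  stochasticity in the output is sequencing sampling; a finite-
  population bottleneck model is a possible extension, deliberately
  not implemented to keep closed-form expectations exact.
- **Guide efficacy**: inert with probability 1/6, otherwise
  Beta(6, 1.5) (mean 0.8) — a point mass of dead guides plus a
  high-skewed active distribution, with at least 5 of 6 guides active
  per hit gene. This reflects that most designed guides cut well but
  some fail entirely.
- **Sequencing**: a multinomial draw of `depth` reads per sample.
  The untreated arm samples the baseline abundances (the subcultured,
  never-treated control); the treated arm samples the post-selection
  abundances.

Default magnitudes — 1000 genes, 20 hit genes, $s_\mathrm{hit} = 0.5$,
$s_\mathrm{base} = 0.02$, 3 rounds, depth $10^6$, `baseline_sigma`
0.5 — are the package's declared study conditions for recovery
testing: survival fractions are not reported for the real screen, so
these are chosen to represent a low-dosage selection (a few percent of
unprotected cells survive each round, resistant knockouts survive about
half). Under these conditions an active hit guide gains roughly
$(s_\mathrm{hit}/\bar{s})^3$ in relative abundance and the screen
separates cleanly; the acceptance checks require sensitivity ≥ 0.9 and
false-discovery proportion ≤ 0.1, and observe 1.0 and 0.0.

What the simulator does **not** emulate: lentiviral multiplicity of
infection, cell-to-cell fitness variation, PCR jackpotting,
chimeric/index-hopped reads, and quality-score degradation. Passing the
recovery tests therefore demonstrates correctness of the scoring rules
under the declared generative model, not performance on an arbitrary
real screen.

`emit_fastq()` closes the loop: it writes the count table back out as
reads (with optional i.i.d. substitution errors), and at error rate 0
the FASTQ → demultiplex → extract → count path reproduces the original
table bit-exactly — asserted on an 800,000-read screen in the tests.

# Colocalization statistics

The imaging module implements the quantification used alongside such a
screen to characterize hits: where a protein sits relative to an
organelle marker, and how much signal an organelle region carries.

- **Background subtraction** is a pixelwise clamped constant,
  `max(v - b, 0)`; the constant is an explicit input because its
  determination is experiment-specific (it should be shared by all
  images of one experiment).
- **Pearson within an ROI** (`pearson_roi()`) is the standard
  correlation over the mask's pixels — e.g. protein of interest versus
  GM130 within a manually outlined cell. A channel constant over the
  mask raises an error rather than returning a silent 0.
- **Thresholded Manders** (`manders()`): M1 is the fraction of
  channel-1 intensity in pixels where channel 2 exceeds its threshold,
  and symmetrically for M2. Thresholds default to 0 (sensible after
  background subtraction) and are explicit parameters stamped on the
  result, since automatic plugin thresholding schemes vary; the strict
  `>` comparison makes zero-background pixels never count as partner
  support.
- **Marker binarization** (`binarize_marker()`) defaults to Otsu's
  threshold (between-class variance maximization on a 256-bin
  histogram, via EBImage) because the binarization used to derive
  Golgi masks from GM130 images is rarely reported; a fixed threshold
  is available. Note Otsu's maximizer is a plateau when the modes are
  well separated — any threshold in the inter-mode gap is optimal — so
  tests assert variance-maximality, not a particular value.
- **Masked mean intensity** (`masked_mean_intensity()`) is total
  signal over the mask divided by the masked area (pixel count, or
  physical area when `pixel_size` is set) — e.g. Golgi-PtdIns(4)P
  intensity normalized by Golgi area.
- **Line profiles** (`line_profile()`) sample channels along a segment
  by bilinear interpolation (pixel centers at integer coordinates,
  origin top-left), average across an odd perpendicular width, and
  normalize each channel by its own profile maximum so peaks are
  comparable on a 0–1 axis; min–max normalization is available by
  flag. Max-normalization is used because published profile figures
  conventionally run 0–1 with the peak at 1.

`synth_coloc_image()` generates ground-truthed fixtures: equal-
amplitude Gaussian blobs truncated at 4σ, placed by rejection sampling
so supports never overlap except for a designed fraction `f` of
co-positioned pairs. Truncation is what makes the ground truth exact:
with untruncated Gaussians every pixel is nonzero and zero-threshold
Manders would be 1 everywhere. By construction M1 at threshold 0
equals `f` up to discretization; the tests require the mean over 20
seeds to sit within ±0.05 of 0.5 and observe a deviation below 1e-4.

# Numerical and interface choices

- Strict inequalities throughout the calling rules (`>`, "more than
  fivefold"), so boundary values never qualify.
- Normalized columns are exact to floating point; the conservation
  test allows a relative tolerance of 1e-9.
- All randomness flows through explicit `seed` arguments; seeded
  helpers save and restore the caller's RNG state, and
  `simulate_screen()` is byte-reproducible from its config.
- Degenerate inputs fail loudly: all-zero samples (normalization),
  duplicate spacers or barcodes (load time), constant channels
  (Pearson), empty masks (intensity), zero-length lines.
- Problem sizes in the default test run are the package's choices for
  a fast, fully deterministic suite: the round-trip check uses 200
  genes at depth 1e5 (800,000 reads), recovery uses the full
  1000-gene, depth-1e6 design once, the oracle comparison runs 1000
  random small screens, and overlap recovery averages 20 seeds.

# Known limitations

- The amplicon layout (inline barcode at read start, fixed flanks) is
  a simulator convention; reads with sample indices in the FASTQ
  header, paired-end data, or staggered designs need external
  preprocessing.
- Counting tolerates at most one mismatch and no indels in the spacer;
  aligner-backed mapping is out of scope.
- The published gene list of any particular screen may reflect manual
  curation beyond the stated threshold rule; this package reproduces
  only the stated rule.
- Images are single-plane 2-D; no 3-D stacks, registration,
  deconvolution, segmentation, or Costes-style randomization tests.
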