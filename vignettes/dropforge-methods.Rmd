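---
title: "Methods: models, parameters and design choices in dropforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in dropforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropforge)
```

# The workflow this package quantifies

`dropforge` implements the quantitative analyses of a cell-free gene
construction workflow with two halves. First, phase-separated droplets formed
by an intrinsically disordered protein (a DEAD-box helicase N-terminal
region) concentrate single-stranded oligonucleotides and ligation enzymes,
so that a set of oligos annealing through short complementary overlaps can be
ligated into a full-length gene at nanomolar to sub-nanomolar concentrations.
Second, the assembled templates are distributed into an array of sealed
~50 fL microreactors at occupancies far below one molecule per reactor, so
cell-free expression gives a *digital* readout: each reactor is scored
positive or negative and the positive fraction is the measurement.

Raw data for such experiments (confocal image stacks, lifetime histograms,
sequencing reads) are large and instrument-specific, so every analysis stage
here is paired with a seeded synthetic-data generator that emulates the
corresponding raw-data modality with embedded ground truth. The test suite
and the demonstration pipeline run entirely on synthetic data.

# Condensate partitioning

## Model

The partition coefficient (PC) of a fluorescently labelled species is the
ratio of its fluorescence intensity inside a droplet to that in the dilute
phase outside. Estimation proceeds in three steps:

1. **Segmentation** (`segment_droplets`): global threshold chosen by
   between-class variance maximization (Otsu), connected-component labelling,
   then filtering by equivalent radius and circularity
   $4\pi A / P^2$ with the perimeter $P$ measured on the traced 8-connected
   contour. The circularity floor (default 0.8) rejects touching droplets
   that merge into one non-circular blob, rather than attempting to split
   them — a deliberate bias toward clean measurements over completeness.
2. **Interior mean** over the mask eroded by 2 px, to keep edge blur and
   segmentation jitter out of the average.
3. **Background**: the median intensity over all pixels at least two radii
   away from every detected droplet. The median is robust to stray bright
   specks; the two-radius exclusion keeps the halo of any droplet out of the
   background.

PC estimation is invariant to a global intensity scale, because both the
threshold (computed on the normalized image) and the final ratio are
scale-free.

## FLIM correction

An intensity ratio conflates concentration with quantum yield. When
fluorescence-lifetime imaging shows the dye's lifetime differs between
phases, the quantum yield is taken as proportional to the lifetime and the
raw PC is de-rated:

$$\mathrm{PC}_{\mathrm{corr}} = \mathrm{PC}_{\mathrm{raw}} \cdot
\frac{\tau_{\mathrm{out}}}{\tau_{\mathrm{in}}}.$$

Lifetime proportionality is the standard dynamic-quenching assumption; if a
static quenching component is known for a particular dye, the correction
factor can be replaced — the function is a single pure ratio and documented
as replaceable.

Lifetimes come from `fit_flim_lifetime`, a single-exponential *tail fit*:
bins after the histogram peak (offset by a configurable fraction of the
post-peak window, default 5%, to clear the instrument rise) are fitted by
weighted least squares of log-counts against time with weights proportional
to counts, the usual linearization under Poisson counting noise. The
Poisson reduced residual statistic is reported; values well above ~1.5 flag
decays that a single exponential does not describe (the tests construct a
bi-exponential decay and confirm it is flagged). No instrument-response
deconvolution is attempted — tail fitting is exactly the regime where that
is unnecessary.

The synthetic decay generator distributes a fixed photon budget
multinomially over bins with probabilities given by the exact per-bin
integral of $e^{-t/\tau}$ truncated to the acquisition window. Because the
binned integral of an exponential is itself exponential in the bin midpoint,
the tail fit on noiseless expected counts is exact — a useful property for
oracle tests.

## Ratiometric FRET and the gamma factor

In-droplet annealing is probed by FRET between donor-labelled and
acceptor-labelled strands. Efficiency is computed ratiometrically:

$$E = \frac{F_A}{F_A + \gamma F_D},$$

where $\gamma$ absorbs the detection-efficiency and quantum-yield imbalance
between the acceptor and donor channels. $E$ is strictly increasing in
$F_A$ and strictly decreasing in both $F_D$ and $\gamma$ (property-tested on
grids). `estimate_gamma` calibrates $\gamma$ from measurements of a
reference construct of known efficiency — in practice a zero-length,
double-labelled donor–acceptor control — by one-dimensional root finding on
the mean efficiency, which is strictly decreasing in $\gamma$, so the root
is unique. The reference efficiency is a user input: instrument vendors'
exact calibration procedures vary, and making the reference explicit keeps
the calibration auditable.

# qPCR standard-curve calculus

A TaqMan dilution series is fitted by regressing Ct on $\log_{10}$(amount)
— the instrument-software convention, so the quoted slope refers to the Ct
versus $\log_{10}$(amount) plot — and re-expressed as the exponential
calibration

$$\mathrm{amount} = A e^{-k\,\mathrm{Ct}}, \qquad
m = -\frac{\ln 10}{k}, \qquad
E_{\mathrm{amp}} = 10^{-1/m} - 1.$$

The package's reference calibration $A = 2922$, $k = 0.71$ gives
$m = -3.243$ and $E_{\mathrm{amp}} = 103.4\%$; perfect per-cycle doubling
corresponds to $m = -1/\log_{10} 2 = -3.32$ and $E_{\mathrm{amp}} = 100\%$.
Ten-fold dilutions are spaced $\ln(10)/k$ cycles apart, a closed form the
generator and tests both use.

Assembly **reaction efficiency** is the measured full-length product
concentration divided by the theoretical maximum of one product per input
oligo set, i.e. the limiting per-oligo concentration; the droplet-vs-control
**enhancement factor** is the ratio of the two efficiencies, with an
explicit distinguished outcome (rather than an infinity) when the control is
undetectable. Amounts carry whatever units the calibration carries; the
module never asserts absolute units.

# Oligo synthesis errors and assembly fidelity

## Error model

Chemically synthesized oligos carry errors at a per-base rate $q$ (default
0.151% per base, the scale measured by amplicon sequencing of synthesis
pools), split among deletions, substitutions and insertions (defaults
71.4 / 27.6 / 1.3%, renormalized to sum to one). Errors are i.i.d. uniform
across positions; real synthesis error profiles have mild position
dependence (3'-end effects), which this model omits — the closed form below
assumes uniformity anyway.

The read generator realizes indels in sequence space (read lengths change),
and the estimation path is a genuine pipeline: global Needleman–Wunsch
alignment with unit costs (so alignment cost equals Levenshtein distance,
verified against an independent dynamic-programming oracle), per-column
event extraction with gap runs merged into multi-base events, and
$\hat q$ = events / aligned reference bases with a Wilson 95% interval.
At $q \sim 10^{-3}$ adjacent errors are rare enough that event merging and
alignment ambiguity are negligible; at $q \gtrsim 10^{-1}$ the alignment
starts reinterpreting error combinations and $\hat q$ is downward biased —
the estimator is intended for synthesis-grade error rates.

## Closed-form fidelity of ligation assembly

For $n$ oligos of lengths $L_i$ tiling a product with $w$-nt overlaps at
each junction, ligation is assumed to occur only when **every base in every
overlap region is error-free** (a mismatched or shifted overlap neither
anneals correctly nor presents a ligatable nick). Terminal oligos carry one
overlap region, internal oligos two, so with five 150-nt oligos and
$w = 20$:

$$L_{\mathrm{ov}} = 8 \times 20 = 160, \qquad
L_{\mathrm{free}} = 750 - 160 = 590,$$

$$P(\mathrm{ligation}) = (1-q)^{L_{\mathrm{ov}}}, \qquad
P(\mathrm{error\text{-}free} \mid \mathrm{ligated}) = (1-q)^{L_{\mathrm{free}}}.$$

At $q = 0.00151$ the conditional probability is 41.0% — the expected
fraction of perfect clones among sequenced (hence ligated) assemblies.
A Monte-Carlo simulator (`simulate_assembly`) provides the brute-force
cross-check; because both events depend only on error *positions*, it draws
per-region error counts binomially, which simulates the events exactly while
keeping $10^6$ trials in seconds. Insertions inside an overlap abort
ligation like any other overlap error; the error-free event is blind to
error type, and the simulator is bit-identical under deletion-only and
substitution-only spectra at equal $q$ (tested).

## Clone classes

Sequenced clones are partitioned into four classes: **perfect** (no
events), **sporadic** (at most 3 events, each a substitution or a deletion
of at most 3 nt — the signature of synthesis errors), **large deletion**
(any deletion of 4 nt or more, the signature of misassembly between
truncated oligos; also the fallback for damage heavier than the sporadic
cap), and **unreadable** (mean Phred quality below 20 or clone length below
half the reference). The 4-nt boundary is the complement of the 1–3-nt
sporadic definition; the unreadable thresholds are this package's choices,
made explicit and testable — synthetic reads carry an unreadable flag
realized as low FASTQ quality.

# Digital counting in femtoliter reactor arrays

## Detection and per-reactor intensities

Reactors are found in the *fill* channel (a dye present in every chamber):
Gaussian smoothing at one third of the expected radius, Otsu threshold,
connected components, intensity-weighted (sub-pixel) centroids, and a
radius gate at ±50% of the expected radius. On synthetic 1000-reactor
lattices recall and precision are both ≥ 0.99 with mean localization error
under half a pixel. Expression intensities are disk means at the detected
radius — means, not maxima, to suppress hot pixels.

## Thresholds and the three filters

The per-channel positive threshold is fitted by iterative trimming: fit a
Gaussian mean and s.d. to all intensities, discard values above
$\mu + k\sigma$, refit to convergence; the threshold is
$\theta = \mu_{\mathrm{neg}} + k\sigma_{\mathrm{neg}}$ of the dominant
(negative) mode. The multiplier $k$ deserves care. The familiar fixed
$k = 3$ convention calls ~0.14% of true negatives positive purely from the
Gaussian tail — an order of magnitude above the pseudo-positive rates
(order $10^{-4}$) actually observed in digital expression experiments, and
enough to swamp a true signal of a few positives per field. The default is
therefore *per-field false-call control*: $k = z_{1-\alpha/n}$ for a field
of $n$ reactors with budget $\alpha = 0.05$ (about $3.5\sigma$ at
$n = 250$, a per-reactor false-call rate of about $2\times10^{-4}$ —
the observed pseudo-positive scale). This is the standard Bonferroni-style
outlier bound; a fixed $k$, including 3, can be requested explicitly and
every constant is configurable. When a second mode is resolvable, a
two-component Gaussian mixture is attached as a diagnostic; its posterior
boundary classifies a well-separated bimodal population essentially
perfectly. The residual tail is not a defect: it is the *pseudo-positive*
phenomenon, and it is why the workflow defines a detection floor (below)
instead of treating any positive reactor as signal.

Three conjunctive filters precede counting: an **intensity** validity gate
(finite, non-negative, below saturation), an **ROI comparison** (a candidate
must be a genuine fill-channel reactor, i.e. its fill intensity exceeds
$\mu_{\mathrm{fill}} - 5\sigma_{\mathrm{fill}}$ — debris bright only in an
expression channel fails here), and a **proximity** filter (nearest
neighbour at least 0.8× the lattice pitch; both members of a close pair are
dropped). Because the flags are conjunctive, filter order cannot change the
counted set.

## Counting, the pseudo-positive floor, and occupancy

The positive fraction among reactors passing all filters carries a Wilson
95% interval. The detection floor is defined from no-DNA control replicates
as mean + 3 sample s.d. of the control positive fraction (replicate-level,
matching the experimental design of 3 biological replicates — not
reactor-level). The threshold concentration of a dose series is reported as
a bracket $(c_{\mathrm{low}}, c_{\mathrm{high}}]$ around the first tested
concentration whose fraction exceeds the floor, open-ended when all or none
do. Expected per-reactor occupancy follows the Poisson model
$\lambda = c V N_A$ with $V = 50$ fL by default; at the sub-picomolar
concentrations of interest $P(\geq 1) \approx \lambda$.

# The synthetic-data generators as study conditions

The generators' defaults are the package's statement of the conditions under
which its claims are tested:

* **Droplet images**: 10 droplets per condition (the partitioning
  experiments' sample size), dilute-phase mean 25 (arbitrary units),
  additive Gaussian noise at 5% of the dilute-phase mean for recovery tests,
  flat-top droplets. True PCs span 19.1–1093, the reported range from short
  dsDNA to 80-nt ssDNA. The flat-top profile is an assumption — confocal
  sections of real droplets show edge roll-off, which the 2 px erosion is
  designed to absorb.
* **FLIM decays**: $10^6$ photons per histogram, 256 bins of 80 ps
  (a 20.5 ns window for ~3 ns lifetimes), matching the
  accumulate-until-$10^4$-counts-per-pixel acquisition style of lifetime
  imaging.
* **Reactor arrays**: lattices at pitch 12 px, radius 4 px; negative
  intensity component N(100, 10), positive N(1000, 50) — a 9:1 contrast
  typical of expressed fluorescent protein against background; fill channel
  N(500, 30); debris placed at lattice interstices with radii capped so they
  never touch a reactor disk, making filter ground truth unambiguous.
  Positive reactors are assigned by quota (`round(f N)`) so recovery tests
  have deterministic truth; a Bernoulli mode is available. Recovery and
  coverage tests use 250-reactor fields (10×25), a realistic single
  field of view.
* **Reads**: $10^4$ reads of a 150-nt reference for rate recovery — about
  $1.5 \times 10^6$ aligned bases, giving a ~10% relative standard error on
  $\hat q$ at $q = 0.151\%$.
* **qPCR**: ten 10-fold dilutions; Ct noise s.d. 0.3 for slope-recovery
  tests (the reproducibility of a well-run instrument), 0.9 for the
  fit-quality benchmark (which reproduces $R^2 \approx 0.991$ over ten
  decades).

What the generators deliberately omit: optics (no point-spread function,
no vignetting), camera noise beyond additive Gaussian, droplet coalescence,
position-dependent synthesis error profiles, and chimeric misassembly
products (the mechanism behind real large-deletion clones; the classifier
is tested on constructed large deletions instead). Passing tests therefore
demonstrate the *estimators* are correct and well-calibrated under the
stated noise models — not that the noise models exhaust real microscopy or
sequencing data.

# Numerical choices and degenerate inputs

* Randomness: every generator takes one explicit integer seed and restores
  the caller's RNG state; same (parameters, seed) is bit-reproducible.
* Wilson intervals pin the lower bound to exactly 0 at zero successes (and
  the upper to 1 at $n$), so boundary truths are never excluded by
  floating-point dust.
* Coordinates are 0-based row/col; intensities are linear (no gamma
  encoding); images are written as 32-bit-float TIFF with an affine
  scale recorded in a JSON sidecar.
* Degenerate inputs error loudly and early: blank images segment to empty
  lists (not errors), but empty eroded masks, non-positive backgrounds,
  all-zero decay tails, all-equal calibration amounts, sub-50-reactor
  threshold fits, and efficiency ratios above 1 all raise with the
  offending quantity named.
* Global alignment ties are broken deterministically by the alignment
  backend; at synthesis-grade error rates tie placement does not affect
  event counts (the cost always equals the edit distance, which is what the
  rate estimator consumes).
* The demonstration pipeline sizes (2000 reads, $2 \times 10^5$
  Monte-Carlo trials, 250–1000-reactor fields) run the full five-stage
  pipeline in tens of seconds; each size is a config key and can be scaled
  up for tighter intervals.

# Known limitations

* The FLIM-based PC correction assumes quantum yield strictly proportional
  to lifetime; dyes with static quenching inside condensates violate this.
* The gamma calibration requires an external reference efficiency; it
  cannot detect a miscalibrated reference.
* The fidelity closed form treats all overlap errors as ligation-fatal and
  all non-overlap errors as ligation-neutral; real ligases tolerate some
  distal mismatches and reject some near-nick ones, so the form brackets
  rather than resolves junction biochemistry.
* The error-rate estimator is calibrated for $q \ll 10^{-2}$; above that,
  alignment reinterpretation biases $\hat q$ low.
* Digital counting assumes co-registered channels and one global threshold
  per channel per field; illumination gradients within a field are not
  modelled or corrected.
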