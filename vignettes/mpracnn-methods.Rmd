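---
title: "Modelling and interpreting tiling-MPRA activity with mpracnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and interpreting tiling-MPRA activity with mpracnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpracnn)
```

## The problem

Massively parallel reporter assays (MPRAs) measure the transcriptional
regulatory activity of hundreds of thousands of short DNA fragments in
parallel.  In the tiling design this package targets, candidate regulatory
regions of 295 bp are each covered by 31 fragments of 145 bp spaced at 5 bp
offsets, and every fragment is assayed under four conditions (two cell
lines, K562 and HepG2, crossed with a minimal and a strong promoter).  The
scientific questions are: which sequences drive activity, which individual
nucleotides and transcription-factor (TF) motifs are responsible, and which
genetic variants are likely to change activity.

`mpracnn` addresses these with one fitted model and three layers of
interpretation:

1. a multi-task convolutional regression model mapping one-hot encoded
   fragments to per-condition activity (`mpra_cnn()`);
2. nucleotide-resolution attribution, by backpropagated contribution scores
   against dinucleotide-shuffled references (`deeplift_track()`) and by
   in-silico mutagenesis (`ism_track()`);
3. motif- and variant-level analytics built on those attributions
   (`usage_matrix()`, `motif_stats()`, `positional_profile()`,
   `variant_effect()`, `ld_adjust()`, `prioritize_variants()`).

A fully seeded simulator (`simulate_dataset()`, `simulate_variants()`)
generates tiling-MPRA benchmarks with known ground truth, so every stage
can be validated end to end without external data.

## The model

A fragment of length $L = 145$ is encoded as an $L \times 4$ indicator
matrix over the bases A, C, G, T (an `N` becomes an all-zero row).  The
regression network is

$$
\big[\mathrm{conv}(120 \times 5) \to \mathrm{BN} \to \mathrm{ReLU} \to
\mathrm{dropout}(0.1)\big] \times 3 \to \mathrm{flatten} \to
\mathrm{dense}(T)
$$

with $T = 4$ tasks.  Convolutions are "valid" (no padding), stride 1, with
no pooling and no intermediate fully connected layers, so the receptive
field of each output position is $1 + 3(5-1) = 13$ bp — short filters
suffice because the salient sequence features are TF motifs of roughly
4–20 bp.  The loss is the unweighted mean of per-task mean squared errors
on z-score–normalized activities.  Training uses Adam (learning rate
$10^{-3}$, batch 128 by default, optionally cosine-annealed and with
decoupled weight decay on the dense head — decaying pre-batchnorm
convolution weights is scale-irrelevant and numerically harmful, so it is
not offered), reverse-complement augmentation of the training partition
(each fragment's reverse complement is added with the same labels), and
early stopping on validation MSE with patience 5.  Validation and the
returned model use a Polyak (exponential moving) average of the weights,
with batch-normalization statistics recalibrated on a 2,048-example batch
(dropout off) so inference statistics match the averaged weights.  The
optimizer, learning rate, schedule, batch size and epoch budget are
conventional choices and fully configurable (`mpra_train_control()`); the
architecture is configurable through `mpra_model_spec()`.

Normalization statistics (per-task mean and population standard deviation)
are estimated on the training partition only and applied to all partitions,
avoiding leakage from held-out chromosomes.  Partitions are a pure function
of chromosome — by default chr8 fragments validate and chr18 fragments
test — so near-duplicate tiles of one region can never straddle a split.

Batch normalization uses batch statistics during training and running
statistics at inference; dropout is disabled at inference.  Prediction is
therefore a deterministic function of the parameters, which the attribution
machinery requires.

## Attribution

Two complementary scores are provided.

**Contribution tracks.**  For a fragment $x$ and a reference $r$, the
network is first folded into an affine form (batch normalization collapsed
into the preceding convolution's weights and bias).  Contribution
multipliers are then propagated backwards: the linear rule through
convolutions and the dense layer, and the rescale rule through ReLU units
(the multiplier of a unit with pre-activation difference
$\Delta a = a_x - a_r$ is $(\mathrm{ReLU}(a_x) -
\mathrm{ReLU}(a_r))/\Delta a$, falling back to the local gradient when
$|\Delta a|$ is negligible).  The per-base contributions
$m \odot (x - r)$ satisfy *summation-to-delta* exactly: they sum to
$f(x) - f(r)$ for every task.  References are dinucleotide-preserving
shuffles of the fragment itself (Altschul–Erickson Eulerian-walk
construction, exact preservation of all 16 dinucleotide counts and of the
terminal bases); scores are averaged over `n_shuffles = 10` seeded
references by default, and the per-position score is the sum over the four
base channels.  Positive scores mark activating nucleotides.  One backward
pass per reference suffices, so a track costs about as much as eleven
forward passes.

**In-silico mutagenesis (ISM).**  Every position is substituted with its
three alternative bases (3L forward passes, batched) and scored as
$\max_{\mathrm{mut}} \left[f(x) - f(x_{\mathrm{mut}})\right]$, so positions
whose disruption lowers activity score positively.  The full signed
$L \times 4$ delta matrix is retained.  ISM is the tool of choice for
allele-specific questions; the contribution track is cheaper and more
robust to redundant motifs.  The two definitions used for variants are kept
distinct: `variant_effect()` is the signed difference
$f(\mathrm{alt}) - f(\mathrm{ref})$ for a known allele pair, while
`position_ism_score()` is the allele-agnostic
$\max |f(\mathrm{mut}) - f(\mathrm{ref})|$ used when the risk allele is
unknown.

## Motif analytics

Attribution tracks are summarized at the motif level in four ways.

- **Match significance** (`motif_significance()`, `motif_stats()`): the
  mean score over each motif match (4–20 bp) is compared to
  column-shuffled-PWM control matches with a one-sided z-test using the
  control sample's mean and standard deviation as plug-in population
  values; Benjamini–Hochberg correction across motifs at FDR 0.1.
- **Positional profiles** (`positional_profile()`): strand-oriented mean
  score per position relative to match centers (halfwidth 50 bp by
  default), showing the spatial resolution of the attributions.
- **Usage scores** (`usage_score()`, `usage_matrix()`): the maximum
  Frobenius inner product between a PWM (probability matrix) and the
  per-channel attribution track across all alignments, both strands.  This
  combines motif presence with attributed importance.  Per-motif
  promoter/enhancer specificity is the ratio of mean usage over promoter
  fragments to mean usage over enhancer fragments, z-scored across motifs;
  between-motif Spearman correlations of usage columns are hierarchically
  clustered for display.  When the four tasks are combined we average the
  per-task contribution tracks within each cell type and then across cell
  types; task weights are exposed to the caller, who can restrict to one
  condition.
- **Quantile overlap** (`quantile_overlap()`): genome-positioned per-base
  scores are sorted into equal-size quantile bins (ties broken by a stable
  sort on coordinate) and the fraction of bases overlapping an annotation
  (e.g. TF binding sites) is reported per bin, with separate linear fits
  for the positive-score and negative-score regimes (threshold ±0.2,
  configurable).

Chromatin-state labels enter through `map_chromhmm_states()`, which
collapses 25-state segmentation names: Tss/PromF → promoter;
Enh/EnhF/DnaseD/DnaseU/FaireW → enhancer; Repr/ReprW/ReprD/Quies →
repressed; everything else → other.

## Variant scoring

A SNP is evaluated in its genomic context: 72 bp of flanking sequence on
each side gives a 145 bp window matching the model input
(`build_variant_context()`, with the reference allele verified against the
genome).  Scores can be aggregated over linkage-disequilibrium blocks:
each tag SNP receives the maximum ISM score over itself and its proxies at
$R^2 \ge 0.8$ (`ld_adjust()`), reflecting that the genotyped tag often
merely tags the causal variant.  `prioritize_variants()` intersects scores
with GWAS summary statistics at the conventional operating point
($|\mathrm{score}| \ge 0.45$, $p \le 5 \times 10^{-8}$, both configurable)
and emits a volcano table.  `saturation_mutagenesis()` scores every
substitution within ±25 bp of a position for mechanistic follow-up.
Indels are out of scope; multi-allelic VCF records are split into
biallelic evaluations.  All scoring is on the + strand of the supplied
genome.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws i.i.d. background sequence at GC fraction 0.41,
assigns each region a chromatin state, and plants motif instances sampled
from sharp probability matrices (12 motifs of width 6–8: a
promoter-exclusive activator, cell-type-specific enhancer activators, a
shared activator, a weak ubiquitous activator, a repressor, and six inert
decoys).  Instances are planted fully inside regions, at least 5 bp apart,
on either strand.  The true activity of a fragment is additive: a per-region
baseline (sd 0.3) plus the effects of all instances fully contained in the
fragment, each scaled by how well its sampled sequence matches the motif
consensus (geometric-mean match fraction), so imperfect instances have
proportionally weaker effects and single-base substitutions have graded,
position-dependent true allelic effects.  Two replicates per task add
Gaussian noise whose scale is calibrated by bisection so the realized
between-replicate Spearman correlation hits the configured target — 0.40
by default, the typical concordance of tiling-MPRA data; the end-to-end
recovery benchmark uses 0.8 to keep the oracle crisp.  Region chromosomes
are assigned round-robin over chr1–chr22 so the held-out-chromosome logic
is exercised.  A heteroscedastic mode scales per-fragment noise by a gamma
draw to support the error-vs-replicate-gap analysis.

`simulate_variants()` places causal variants inside planted instances (at
the motif's most informative column, substituting its least likely base;
the true allelic effect is the induced change in the additive truth) and
null variants in background sequence.  LD blocks are built so the causal
variant is always a *proxy* of a null tag — the tag never carries the
effect — and GWAS p-values are genome-wide significant for causal blocks
and null (> 0.1) otherwise.  This reproduces the qualitative situation in
which LD-adjusted scores separate significant from insignificant tags
while raw tag scores do not.

What the simulator deliberately does **not** model: barcode- or count-level
noise, biophysical TF occupancy and saturation, motif–motif interactions
(an optional saturating link is a possible extension, but the default truth
is additive), plasmid-versus-chromatin context effects, and realistic
genomic background (repeats, CpG islands).  Passing the recovery benchmarks
therefore demonstrates the correctness of the machinery — encoding, fitting,
attribution, aggregation — not that real MPRA data of a given quality will
yield equally clean recovery.

## Numerical choices and degenerate inputs

- One-hot column order is fixed to A, C, G, T everywhere; `N` encodes to a
  zero row, and fragments with more than 10% `N` should be excluded by the
  caller (the encoder accepts them; ISM flags `N` positions with score 0).
- Coordinates are 0-based half-open internally; BED is native, VCF
  positions are converted at the I/O boundary.
- Z-scoring refuses zero-variance tasks; Spearman on constant vectors
  returns `NA` with a warning rather than a silent 0.
- The rescale rule falls back to the ReLU gradient when
  $|\Delta a| < 10^{-10}$; completeness is unaffected because such units
  contribute nothing to the output difference.
- Ratio-based usage specificity shifts all scores by a common offset (and
  flags the result) when a group mean is non-positive.
- Training aborts with a diagnostic on non-finite loss; two runs with the
  same seed produce identical validation traces.
- Quantile bins differ by at most one base when the base count is not a
  multiple of the bin count; ties in score are broken by genomic
  coordinate.

## Problem sizes used in the bundled checks

The test suite trains a 24-filter model for 2 epochs on a 40-region
simulation for the attribution contracts, and a 32-filter model for 5
epochs (batch 256, cosine-annealed learning rate $6 \times 10^{-3}$,
dense-head weight decay 0.1) on a 2,000-region simulation (62,000
fragments, replicate concordance 0.8) for the end-to-end recovery and
variant benchmarks; `scripts/acceptance.R` repeats the latter from scratch
with a 6-epoch budget.  At these sizes the reduced model recovers the
planted motif structure clearly (attribution, profiles, usage rankings,
variant directions) while its held-out activity correlation, around
0.5 in Spearman's rho against labels whose replicate concordance is 0.8,
remains below the information ceiling of the labels (about 0.8–0.9): a
32-filter network trained for a handful of epochs captures the strong
planted effects but not the full graded match-quality signal.  Larger
filter budgets or longer training narrow the gap only slowly; this is a
genuine small-model limitation and is reported as such rather than tuned
around.  The full assay scale (~15,700 regions) is a straightforward, if
slower, change of `n_regions`.

## Known limitations

- The engine is a purpose-built CPU implementation (im2col + BLAS with C++
  kernels for the memory-bound steps).  It is efficient at the package's
  problem sizes but not a general deep-learning framework: only the layer
  types the architecture uses are implemented, and there is no GPU path.
- Attribution supports the rescale rule only; no RevealCancel, integrated
  gradients or SHAP variants.
- The PWM scanner used for controls and simulations is a plain log-odds
  scanner against a uniform background, adequate for planted-motif
  benchmarks but not a replacement for a dedicated motif-discovery stack.
- LD blocks are inputs; the package does not estimate LD from genotypes.
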