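# mpracnn

Convolutional modelling and interpretation of massively parallel reporter
assays (MPRAs) in R.

MPRAs measure the transcriptional regulatory activity of large libraries of
short DNA fragments. In the tiling design this package targets, 295 bp
candidate regulatory regions are each covered by 31 fragments of 145 bp at
5 bp offsets, assayed in four conditions (K562 and HepG2 cells, each with a
minimal and a strong promoter). `mpracnn` is for researchers who want to
(i) predict fragment activity from sequence, (ii) find the nucleotides and
transcription-factor motifs that drive it, and (iii) prioritize noncoding
variants by their predicted allelic effects.

At its core is a multi-task convolutional regression model

    [conv(120 x 5) -> BN -> ReLU -> dropout(0.1)] x 3 -> flatten -> dense(T)

trained with mean squared error on z-score-normalized activities, with
reverse-complement augmentation and held-out-chromosome validation (chr8)
and testing (chr18). On top of the fitted model sit two attribution methods
— backpropagated contribution scores against dinucleotide-shuffled
references (satisfying summation-to-delta: per-base scores sum to
f(x) − f(reference)) and in-silico mutagenesis (ISM, max prediction change
over the 3 substitutions per position) — and the analytics built on them:
motif-match significance against shuffled-motif controls (one-sided z-test,
Benjamini–Hochberg FDR 0.1), positional score profiles, PWM "usage" scores
(max inner product of a PWM with the attribution track), promoter/enhancer
usage specificity, score-quantile annotation overlap, and variant
prioritization with LD expansion (per-tag max over proxies at R² ≥ 0.8)
intersected with GWAS summary statistics (|score| ≥ 0.45, p ≤ 5e-8).

A seeded simulator generates tiling-MPRA benchmarks with planted,
cell-type-specific motif effects, tunable replicate concordance, and causal
variants hidden as LD proxies, so the whole pipeline is testable without
any external data.

## Worked example

A full benchmark — simulate 2,000 tiled regions (62,000 fragments, two
replicates per task calibrated to Spearman 0.8 concordance), fit a reduced
32-filter model, and evaluate on the held-out chromosome — takes about ten
minutes on one core:

```r
library(mpracnn)

sim <- simulate_dataset(sim_config(n_regions = 2000,
                                   concordance_target = 0.8, seed = 1))
ds  <- split_by_chromosome(sim$dataset)     # chr8 -> val, chr18 -> test
ds  <- zscore_normalize(ds)                 # per-task, fit on train only
ds  <- augment_with_revcomp(ds)

fit <- mpra_cnn(ds, mpra_model_spec(filters_per_layer = 32),
                mpra_train_control(epochs = 5, batch_size = 256,
                                   learning_rate = 6e-3,
                                   lr_schedule = "cosine",
                                   weight_decay = 0.1, seed = 2))
print(fit)
#> Multi-task convolutional MPRA activity model
#> CNN spec: 3 x [conv(32 filters, length 5) -> BN -> ReLU -> dropout(0.1)] -> dense(4)
#> input 145 bp; receptive field 13 bp
#> trained 5 epoch(s); best validation MSE 0.5641 at epoch 5
#> tasks: K562_minP, K562_SV40P, HepG2_minP, HepG2_SV40P

te   <- dataset_partition(ds, "test", drop_augmented = TRUE)
pred <- predict(fit, te$fragments$sequence)
round(evaluate_spearman(pred, te$labels), 2)
#>   K562_minP  K562_SV40P  HepG2_minP HepG2_SV40P
#>        0.38        0.37        0.43        0.42
```

A validation MSE well below 1 (the variance of the z-scored labels) shows
the model predicts far better than the mean; the held-out rank correlations
of ~0.4 sit below the information ceiling of the labels (~0.9 at this
concordance) — a 32-filter model trained for five epochs captures the
strong planted motif effects but not the full graded match-quality signal.
Where the model shines is nucleotide-level interpretation: contribution
scores concentrate sharply inside the planted motifs.

```r
dl  <- deeplift_track(fit, te$fragments$sequence[1], task = "K562_minP",
                      n_shuffles = 10, seed = 1)
ism <- ism_track(fit, te$fragments$sequence[1], task = "K562_minP")
attribution_concordance(dl, ism)$spearman
#> [1] 0.6
```

and the same quantities drive the motif and variant analytics
(`usage_matrix()`, `motif_stats()`, `positional_profile()`,
`variant_effect()`, `ld_adjust()`, `prioritize_variants()`). A thin
command-line launcher (`inst/cli/mpracnn`) drives the pipeline stages from
YAML configs: `simulate`, `train`, `predict`, `evaluate`, `attribute`,
`variant-score`, `ld-adjust`, `prioritize`, `saturate`.

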