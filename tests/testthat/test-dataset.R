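make_fragments <- function(n, chroms, L = 20L) {
  data.frame(fragment_id = sprintf("f%03d", seq_len(n)),
             chrom = rep_len(chroms, n), start = 0L, end = L, strand = "+",
             sequence = replicate(n, random_seq(L)),
             stringsAsFactors = FALSE)
}

test_that("z-score normalization uses training-partition population moments", {
  z <- zscore_normalize(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.vector(z$labels), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  set.seed(5)
  x <- matrix(rnorm(400), ncol = 2)
  z1 <- zscore_normalize(x)
  z2 <- zscore_normalize(z1$labels)
  expect_equal(z2$labels, z1$labels, tolerance = 1e-6)

  expect_error(zscore_normalize(matrix(rep(2, 10), ncol = 1)),
               "zero-variance")

  ## parameters are fit on train rows only, then applied everywhere
  fitrows <- 1:120
  z3 <- zscore_normalize(x, fit_idx = fitrows)
  expect_equal(colMeans(z3$labels[fitrows, ]), c(0, 0), tolerance = 1e-10)
  expect_equal(sqrt(colMeans(sweep(z3$labels[fitrows, ], 2,
                                   colMeans(z3$labels[fitrows, ]))^2)),
               c(1, 1), tolerance = 1e-10)
})

test_that("chromosome split assigns val/test/train disjointly and exhaustively", {
  fr <- make_fragments(30, c("chr1", "chr8", "chr18", "chr2", "chrX"))
  ds <- mpra_dataset(fr, matrix(rnorm(30 * 4), 30), fragment_length = 20)
  ds <- split_by_chromosome(ds)
  p <- ds$partition
  expect_true(all(p[fr$chrom == "chr8"] == "val"))
  expect_true(all(p[fr$chrom == "chr18"] == "test"))
  expect_true(all(p[fr$chrom %in% c("chr1", "chr2", "chrX")] == "train"))
  expect_false(anyNA(p))
  expect_error(split_by_chromosome(ds, val_chroms = "chr8",
                                   test_chroms = "chr8"), "disjoint")
})

test_that("reverse-complement augmentation doubles training with equal labels", {
  fr <- make_fragments(20, c("chr1", "chr8", "chr18"))
  labels <- matrix(rnorm(20 * 4), 20)
  ds <- split_by_chromosome(mpra_dataset(fr, labels, fragment_length = 20))
  n_train <- sum(ds$partition == "train")
  aug <- augment_with_revcomp(ds)
  expect_equal(sum(aug$partition == "train"), 2L * n_train)
  expect_equal(sum(aug$partition == "val"), sum(ds$partition == "val"))

  add <- aug$fragments[aug$fragments$augmented, ]
  orig_id <- sub("::rc$", "", add$fragment_id)
  orig_idx <- match(orig_id, aug$fragments$fragment_id)
  add_idx <- match(add$fragment_id, aug$fragments$fragment_id)
  expect_equal(aug$labels[add_idx, ], aug$labels[orig_idx, ])
  expect_equal(add$sequence,
               vapply(aug$fragments$sequence[orig_idx], revcomp_seq,
                      character(1), USE.NAMES = FALSE))
  expect_error(augment_with_revcomp(aug), "already augmented")
})

test_that("augmenting an empty training partition is a no-op", {
  fr <- make_fragments(4, c("chr8", "chr18"))
  ds <- split_by_chromosome(mpra_dataset(fr, matrix(rnorm(16), 4),
                                         fragment_length = 20))
  aug <- augment_with_revcomp(ds)
  expect_equal(nrow(aug$fragments), 4L)
})

test_that("ChromHMM states collapse into the four groups", {
  expect_equal(as.character(map_chromhmm_states(
    c("Tss", "PromF", "Enh", "EnhF", "DnaseD", "DnaseU", "FaireW",
      "Repr", "ReprW", "ReprD", "Quies", "Gen3", "whatever"))),
    c("promoter", "promoter", "enhancer", "enhancer", "enhancer", "enhancer",
      "enhancer", "repressed", "repressed", "repressed", "repressed",
      "other", "other"))
  expect_equal(as.character(map_chromhmm_states("10_Tss")), "promoter")
})
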