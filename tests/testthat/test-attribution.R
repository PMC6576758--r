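test_that("dinucleotide shuffle preserves pair counts, endpoints and seed", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  set.seed(77)
  for (i in 1:200) {
    s <- random_seq(sample(10:80, 1))
    sh <- dinucleotide_shuffle(s, seed = i)
    expect_equal(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)),
                 substr(s, nchar(s), nchar(s)))
  }
  s <- random_seq(60)
  expect_identical(dinucleotide_shuffle(s, seed = 5),
                   dinucleotide_shuffle(s, seed = 5))
  ## N is a fifth symbol whose pair counts are preserved too
  sn <- "ACGTNNACGTNAC"
  expect_equal(dinucleotide_counts(dinucleotide_shuffle(sn, seed = 2)),
               dinucleotide_counts(sn))
  expect_error(dinucleotide_shuffle("AC"), "length")
})

test_that("contributions of a linear model equal w * (x - x_ref) exactly", {
  set.seed(4)
  L <- 30L
  W <- matrix(rnorm(2 * 4 * L), nrow = 2)
  model <- mpracnn:::linear_mpra_model(W, c(0.5, -1), L)
  x <- random_seq(L)
  ref <- dinucleotide_shuffle(x, seed = 9)
  tr <- deeplift_track(model, x, task = 2, references = ref)
  dx <- encode_one_hot(x) - encode_one_hot(ref)
  closed_form <- matrix(W[2, ], ncol = 4, byrow = TRUE) * dx
  expect_equal(unname(tr$base_matrix), unname(closed_form), tolerance = 1e-12)
  expect_equal(tr$scores, rowSums(closed_form), tolerance = 1e-12)
})

test_that("summation-to-delta holds per reference on a trained model", {
  fit <- tiny_model()
  te <- dataset_partition(tiny_dataset(), "test", drop_augmented = TRUE)
  set.seed(2)
  for (s in sample(te$fragments$sequence, 10)) {
    all <- mpracnn:::deeplift_all_tasks(fit, s, n_shuffles = 3, seed = 1)
    delta <- sweep(-all$f_ref, 2, all$f_x, "+")
    expect_lt(max(abs(all$per_ref_sum - delta) / (abs(delta) + 1)), 1e-3)
  }
})

test_that("a fragment attributed against itself gets a zero track", {
  fit <- tiny_model()
  x <- random_seq(145)
  tr <- deeplift_track(fit, x, task = 1, references = x)
  expect_equal(max(abs(tr$scores)), 0, tolerance = 1e-12)
})

test_that("vectorized ISM equals the naive 3L-forward-pass loop", {
  fit <- tiny_model()
  x <- random_seq(145)
  tr <- ism_track(fit, x, task = 3)
  chars <- strsplit(x, "")[[1]]
  bases <- c("A", "C", "G", "T")
  f_ref <- predict(fit, x)[1, 3]
  n_mutants <- 0L
  for (i in seq(1, 145, by = 12)) {     # spot-check a grid of positions
    deltas <- c()
    for (b in setdiff(bases, chars[i])) {
      m <- chars; m[i] <- b
      deltas <- c(deltas, f_ref - predict(fit, paste(m, collapse = ""))[1, 3])
    }
    expect_equal(tr$scores[i], max(deltas), tolerance = 1e-10)
  }
  ## a 145 bp fragment requires 435 mutant evaluations
  expect_equal(sum(tr$delta != 0), 435L)
})

test_that("ISM flags N positions with zero score", {
  fit <- tiny_model()
  x <- random_seq(145)
  substr(x, 10, 10) <- "N"
  tr <- ism_track(fit, x, task = 1)
  expect_equal(tr$scores[10], 0)
  expect_equal(tr$flagged, 10L)
})

test_that("constant model yields an all-zero ISM track", {
  tr <- ism_track(constant_model(), random_seq(145), task = 1)
  expect_equal(max(abs(tr$scores)), 0)
})

test_that("track concordance is 1 against itself and -1 against its negation", {
  fit <- tiny_model()
  tr <- deeplift_track(fit, random_seq(145), task = 1, n_shuffles = 2)
  cc <- attribution_concordance(tr, tr)
  expect_equal(cc$pearson, 1)
  expect_equal(attribution_concordance(tr$scores, -tr$scores)$pearson, -1)
  expect_warning(attribution_concordance(rep(1, 5), rnorm(5)), "constant")
})

test_that("ISM and contribution tracks agree on fragments with planted motifs", {
  fit <- tiny_model()
  te <- dataset_partition(tiny_dataset(), "test", drop_augmented = TRUE)
  set.seed(14)
  rhos <- vapply(sample(te$fragments$sequence, 6), function(s) {
    dl <- deeplift_track(fit, s, task = 1, n_shuffles = 5, seed = 2)
    im <- ism_track(fit, s, task = 1)
    attribution_concordance(dl, im)$spearman
  }, numeric(1))
  expect_gt(mean(rhos), 0.5)
})
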