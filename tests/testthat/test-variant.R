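test_that("variant context windows have model length and verified alleles", {
  set.seed(71)
  genome <- c(ctg1 = random_seq(400))
  pos <- 200L
  refb <- substr(genome[["ctg1"]], pos, pos)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  ctx <- build_variant_context(genome, "ctg1", pos, refb, altb)
  expect_equal(nchar(ctx$ref_seq), 145L)   # 1 + 2 * 72
  expect_equal(nchar(ctx$alt_seq), 145L)
  expect_equal(substr(ctx$ref_seq, 73, 73), refb)
  expect_equal(substr(ctx$alt_seq, 73, 73), altb)
  diffs <- which(strsplit(ctx$ref_seq, "")[[1]] !=
                   strsplit(ctx$alt_seq, "")[[1]])
  expect_equal(diffs, 73L)

  wrong <- setdiff(c("A", "C", "G", "T"), refb)[2]
  expect_error(build_variant_context(genome, "ctg1", pos, wrong, altb),
               "mismatch")
  expect_error(build_variant_context(genome, "ctg1", 50L, "A", "C"),
               "exceeds contig")
})

test_that("ref == alt forces a zero effect", {
  fit <- tiny_model()
  s <- random_seq(145)
  expect_equal(variant_effect(fit, s, s, task = 1), 0)
})

test_that("variant effect equals the ISM signed delta at the same position", {
  fit <- tiny_model()
  s <- random_seq(145)
  tr <- ism_track(fit, s, task = 2)
  chars <- strsplit(s, "")[[1]]
  for (i in c(5L, 73L, 140L)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      alt <- s
      substr(alt, i, i) <- b
      expect_equal(variant_effect(fit, s, alt, task = 2),
                   unname(tr$delta[i, b]), tolerance = 1e-10)
    }
  }
})

test_that("position ISM score is the brute-force max |delta| and bounds effects", {
  fit <- tiny_model()
  s <- random_seq(145)
  center <- 73L
  sc <- position_ism_score(fit, s, center, task = 1)
  chars <- strsplit(s, "")[[1]]
  deltas <- vapply(setdiff(c("A", "C", "G", "T"), chars[center]), function(b) {
    alt <- s; substr(alt, center, center) <- b
    variant_effect(fit, s, alt, task = 1)
  }, numeric(1))
  expect_equal(sc, max(abs(deltas)), tolerance = 1e-10)
  expect_true(all(sc >= abs(deltas) - 1e-12))
  expect_equal(position_ism_score(constant_model(), s, 10L), 0)
})

test_that("LD adjustment takes the block maximum regardless of member order", {
  sc <- c(tag1 = 0.1, p1 = 0.9, p2 = 0.3, tag2 = 0.5)
  blocks <- data.frame(tag_id = c("tag1", "tag1", "tag2"),
                       proxy_id = c("p1", "p2", "tag2"))
  adj <- ld_adjust(sc, blocks)
  expect_equal(adj$ld_adjusted_score[adj$tag_id == "tag1"], 0.9)
  expect_equal(adj$argmax_id[adj$tag_id == "tag1"], "p1")
  expect_equal(adj$ld_adjusted_score[adj$tag_id == "tag2"], 0.5)

  shuffled <- blocks[c(3, 1, 2), ]
  adj2 <- ld_adjust(sc, shuffled)
  expect_equal(adj2[order(adj2$tag_id), -1], adj[order(adj$tag_id), -1],
               ignore_attr = TRUE)

  set.seed(81)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    ids <- paste0("v", seq_len(n))
    scores <- setNames(runif(n), ids)
    bl <- data.frame(tag_id = "v1", proxy_id = ids)
    expect_equal(ld_adjust(scores, bl)$ld_adjusted_score, max(scores))
  }
  expect_error(ld_adjust(c(a = 1), data.frame(tag_id = "t", proxy_id = "b")),
               "no scored members")
})

test_that("saturation mutagenesis covers 51 positions x 3 mutants and is consistent", {
  fit <- tiny_model()
  s <- random_seq(145)
  sat <- saturation_mutagenesis(fit, s, center = 73L, halfwidth = 25L,
                                task = 1)
  expect_equal(length(sat$positions), 51L)
  expect_equal(sum(sat$delta != 0, na.rm = TRUE), 51L * 3L)
  ## center column reproduces the single-position ISM deltas
  center_row <- which(sat$positions == 73L)
  expect_equal(max(abs(sat$delta[center_row, ])),
               position_ism_score(fit, s, 73L, task = 1), tolerance = 1e-10)
  expect_equal(unname(sat$max_abs[center_row]),
               max(abs(sat$delta[center_row, ])))
  ## constant model: all-zero table
  sat0 <- saturation_mutagenesis(constant_model(), s, 73L)
  expect_equal(max(abs(sat0$delta), na.rm = TRUE), 0)
  expect_warning(saturation_mutagenesis(fit, s, center = 5L), "clipped")
})

test_that("prioritization filters at the thresholds and is monotone", {
  set.seed(91)
  n <- 300
  scores <- data.frame(variant_id = paste0("v", 1:n),
                       score = rnorm(n, 0, 0.5))
  gwas <- data.frame(variant_id = paste0("v", 1:n),
                     p = 10^-runif(n, 0, 12))
  res <- prioritize_variants(scores, gwas)
  expect_true(all(abs(res$candidates$score) >= 0.45))
  expect_true(all(res$candidates$p <= 5e-8))
  expect_equal(res$candidates$score[order(-abs(res$candidates$score))],
               res$candidates$score)

  all_pass <- prioritize_variants(scores, gwas, score_thresh = 0,
                                  p_thresh = 1)
  expect_equal(nrow(all_pass$candidates), n)

  ## the variant at the published operating point is retained
  one <- prioritize_variants(data.frame(variant_id = "hit", score = 0.92),
                             data.frame(variant_id = "hit", p = 1e-17))
  expect_equal(nrow(one$candidates), 1L)

  ## tightening either threshold shrinks the candidate set (set inclusion)
  prev <- res$candidates$variant_id
  for (th in list(c(0.6, 5e-8), c(0.6, 1e-10), c(0.9, 1e-10))) {
    cur <- prioritize_variants(scores, gwas, th[1], th[2])$candidates$variant_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  ## unmatched ids are excluded and counted
  res2 <- prioritize_variants(rbind(scores,
                                    data.frame(variant_id = "orphan",
                                               score = 2)), gwas)
  expect_equal(res2$n_unmatched, 1L)
})

test_that("score-distribution comparison is calibrated and powered", {
  set.seed(101)
  ## null: same distribution -> p roughly uniform
  ps <- replicate(200, {
    x <- rnorm(30); y <- rnorm(30)
    compare_score_distributions(x, y)$p
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  ## shifted by one sd: overwhelming evidence
  expect_lt(compare_score_distributions(rnorm(500) + 1, rnorm(500))$p, 1e-10)
  ## wrong direction: one-sided p above 0.5
  expect_gt(compare_score_distributions(rnorm(100) - 2, rnorm(100))$p, 0.5)
  expect_error(compare_score_distributions(1:2, rnorm(10)), "at least 3")
})
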