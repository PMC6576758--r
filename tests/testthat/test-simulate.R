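test_that("tiling geometry yields 31 fragments per 295 bp region", {
  sim <- tiny_sim()
  ds <- sim$dataset
  expect_equal(nrow(ds$fragments), 40L * 31L)
  expect_equal(unname(table(ds$fragments$region_id)[1]), 31L)
  offs <- ds$fragments$tile_offset[ds$fragments$region_id == "region00001"]
  expect_equal(offs, seq(0L, 150L, by = 5L))
  expect_true(all(nchar(ds$fragments$sequence) == 145L))
  expect_error(sim_config(region_length = 296, seed = 1), "divisible")
  expect_error(sim_config(n_regions = 5), "seed")
})

test_that("simulation is byte-identical under the same config", {
  cfg <- sim_config(n_regions = 8, concordance_target = 0.6, seed = 123)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$fragments, s2$dataset$fragments)
  expect_identical(s1$dataset$labels, s2$dataset$labels)
  expect_identical(s1$truth$instances, s2$truth$instances)
})

test_that("ground truth is additive: baseline plus contained instance effects", {
  sim <- tiny_sim()
  fr <- sim$dataset$fragments
  inst <- sim$truth$instances
  tasks <- mpra_tasks()
  set.seed(2)
  for (i in sample(nrow(fr), 60)) {
    ri <- fr$region_id[i]
    contained <- inst[inst$region_id == ri &
                        inst$start >= fr$tile_offset[i] &
                        inst$end <= fr$tile_offset[i] + 145, , drop = FALSE]
    expected <- sim$truth$baseline[[ri]] +
      if (nrow(contained)) colSums(contained[, tasks, drop = FALSE]) else
        rep(0, 4)
    expect_equal(unname(sim$truth$activity[fr$fragment_id[i], ]),
                 unname(unlist(expected)), tolerance = 1e-12)
  }
})

test_that("planted instances live inside their regions with spacing", {
  inst <- tiny_sim()$truth$instances
  expect_true(all(inst$start >= 0 & inst$end <= 295))
  by_region <- split(inst, inst$region_id)
  for (b in by_region) {
    if (nrow(b) < 2) next
    b <- b[order(b$start), ]
    expect_true(all(b$start[-1] - b$end[-nrow(b)] >= 5))
  }
})

test_that("replicate noise calibration hits the concordance target", {
  cfg <- sim_config(n_regions = 330, concordance_target = 0.40, seed = 19)
  sim <- simulate_dataset(cfg)      # 10,230 fragments
  for (t in seq_len(4)) {
    rho <- cor(sim$dataset$replicates[[1]][, t],
               sim$dataset$replicates[[2]][, t], method = "spearman")
    expect_gt(rho, 0.35)
    expect_lt(rho, 0.45)
  }
})

test_that("fragment sequences really carry the planted instances", {
  sim <- tiny_sim()
  inst <- sim$truth$instances
  lib <- sim$truth$motif_library
  ids <- vapply(lib, function(m) m$pwm$motif_id, character(1))
  set.seed(3)
  for (j in sample(nrow(inst), 20)) {
    reg <- sim$truth$region_seq[[inst$region_id[j]]]
    sub <- substr(reg, inst$start[j] + 1, inst$end[j])
    fwd <- if (inst$strand[j] == "+") sub else revcomp_seq(sub)
    mf <- mpracnn:::pwm_match_frac(fwd, lib[[match(inst$motif_id[j],
                                                   ids)]]$pwm)
    expect_equal(mf, inst$match_frac[j], tolerance = 1e-12)
  }
})

test_that("simulated variants separate causal proxies from null tags in truth", {
  sim <- tiny_sim()
  vs <- simulate_variants(sim, n_blocks = 30, prop_causal = 0.5, seed = 5)
  v <- vs$variants
  expect_true(all(nchar(v$ref) == 1 & nchar(v$alt) == 1))
  expect_true(all(v$ref != v$alt))
  eff_cols <- grep("^true_effect_", names(v), value = TRUE)
  eff_any <- rowSums(abs(as.matrix(v[, eff_cols])))
  expect_true(all(eff_any[!v$is_causal] == 0))
  expect_true(all(eff_any[v$is_causal] > 0))
  ## causal variants destroy activator instances -> negative effects for
  ## positive-effect motifs (all causal candidates here have |effect| > 0)
  tags <- unique(vs$ld$tag_id)
  expect_true(all(!v$is_causal[match(tags, v$variant_id)]))
  ## every block's r2 respects the threshold
  expect_true(all(vs$ld$r2 >= 0.8))
  ## GWAS p-values: causal-block tags genome-wide significant, others null
  causal_tags <- vs$ld$tag_id[vs$ld$proxy_id %in%
                                v$variant_id[v$is_causal]]
  p <- setNames(vs$gwas$p, vs$gwas$variant_id)
  expect_true(all(p[unique(causal_tags)] < 5e-8))
  expect_true(all(p[setdiff(tags, causal_tags)] > 0.1))
  expect_error(simulate_variants(sim, n_blocks = 10, prop_causal = 0),
               "prop_causal")
  ## ref alleles match the genome
  set.seed(4)
  for (i in sample(nrow(v), 15))
    expect_equal(substr(vs$genome[[v$chrom[i]]], v$pos[i], v$pos[i]),
                 v$ref[i])
})

test_that("heteroscedastic mode produces variable per-fragment noise", {
  cfg <- sim_config(n_regions = 60, concordance_target = 0.6,
                    noise_mode = "heteroscedastic", seed = 31)
  sim <- simulate_dataset(cfg)
  gap <- abs(sim$dataset$replicates[[1]][, 1] -
               sim$dataset$replicates[[2]][, 1])
  ## perfect predictor: error correlates with replicate gap by construction
  rho <- error_vs_replicate_gap(sim$truth$activity[, 1, drop = FALSE],
                                lapply(sim$dataset$replicates, function(r)
                                  r[, 1, drop = FALSE]))
  expect_gt(rho, 0.1)
  expect_gt(sd(gap), 0)
})
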