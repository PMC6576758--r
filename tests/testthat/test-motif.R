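random_pwm <- function(id = "m", width = 7L) {
  m <- matrix(rexp(width * 4), width)
  pwm(id, m / rowSums(m))
}

test_that("match scoring is the mean over the match span", {
  expect_equal(score_motif_match(rep(3.5, 10), 2, 6), 3.5)
  expect_equal(score_motif_match(c(0, 1, 2, 3), 1, 3), 1.5)
  expect_error(score_motif_match(1:5, 3, 7), "outside")
  set.seed(6)
  for (i in 1:500) {
    tr <- rnorm(sample(20:60, 1))
    w <- sample(4:10, 1)
    s <- sample(0:(length(tr) - w), 1)
    expect_equal(score_motif_match(tr, s, s + w), mean(tr[(s + 1):(s + w)]))
  }
})

test_that("motif z-test matches the normal-tail hand computation", {
  set.seed(3)
  ctrl <- rnorm(500)
  mu0 <- mean(ctrl); sd0 <- sd(ctrl)
  n <- 25
  shifted <- rep(mu0 + 3 * sd0 / sqrt(n), n)
  st <- motif_significance(shifted, ctrl)
  expect_equal(st$z, 3, tolerance = 1e-10)
  expect_equal(st$p, pnorm(3, lower.tail = FALSE), tolerance = 1e-10)

  expect_equal(motif_significance(rep(mu0, n), ctrl)$p, 0.5, tolerance = 1e-10)
  expect_gt(motif_significance(rep(mu0 - 1, n), ctrl)$p, 0.5)
  expect_error(motif_significance(1:5, rnorm(10)), "at least 20")
  expect_error(motif_significance(1:5, rep(1, 30)), "zero variance")
})

test_that("BH step-up matches a hand-rolled reference on random p-vectors", {
  r <- bh_fdr(c(0.01, 0.02, 0.03), alpha = 0.1)
  expect_equal(r$q, c(0.03, 0.03, 0.03))
  expect_true(all(r$significant))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_true(bh_fdr(0.05, alpha = 0.1)$significant)

  step_up <- function(p) {           # independent reference implementation
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(9)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$q, step_up(p), tolerance = 1e-12)
  }
})

test_that("BH q-values dominate p-values and are monotone in p-rank", {
  set.seed(10)
  p <- runif(200)^2
  q <- bh_fdr(p)$q
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("usage score equals the exhaustive brute force over alignments", {
  brute <- function(track, pw) {
    W <- pw$width
    best <- -Inf
    for (m in list(pw$matrix, pwm_revcomp(pw)$matrix))
      for (s in 0:(nrow(track) - W))
        best <- max(best, sum(track[(s + 1):(s + W), ] * m))
    best
  }
  set.seed(17)
  for (i in 1:300) {
    track <- matrix(rnorm(sample(10:30, 1) * 4), ncol = 4)
    pw <- random_pwm(width = sample(4:8, 1))
    if (pw$width > nrow(track)) next
    expect_equal(usage_score(track, pw), brute(track, pw), tolerance = 1e-10)
  }
  ## degenerate cases
  pw <- random_pwm(width = 6)
  expect_equal(usage_score(matrix(0, 20, 4), pw), 0)
  tr6 <- matrix(rnorm(24), 6)
  expect_equal(usage_score(tr6, pw, both_strands = FALSE),
               sum(tr6 * pw$matrix))
  expect_error(usage_score(matrix(0, 4, 4), random_pwm(width = 6)), "wider")
})

test_that("usage score is invariant to zero-score flanks", {
  set.seed(23)
  track <- matrix(rnorm(40), ncol = 4)
  pw <- random_pwm(width = 5)
  padded <- rbind(matrix(0, 6, 4), track, matrix(0, 9, 4))
  expect_equal(usage_score(padded, pw), usage_score(track, pw))
})

test_that("usage correlations detect duplicated and independent motifs", {
  set.seed(29)
  u <- matrix(rnorm(1000 * 3), 1000)
  u <- cbind(u, u[, 3])                # duplicate column
  colnames(u) <- c("a", "b", "c", "c_dup")
  uc <- usage_correlation(u)
  expect_equal(uc$cor["c", "c_dup"], 1)
  expect_lt(max(abs(uc$cor["a", c("b", "c")])), 0.1)  # independent columns
})

test_that("promoter-specific usage ranks top in the ratio z-scores", {
  set.seed(33)
  n <- 200
  state <- rep(c("promoter", "enhancer"), each = n / 2)
  u <- matrix(rexp(n * 10, 2), n)      # positive baseline usage
  u[state == "promoter", 1] <- u[state == "promoter", 1] + 3
  colnames(u) <- paste0("m", 1:10)
  pe <- promoter_enhancer_ratio(u, state)
  expect_equal(pe$motif_id[which.max(pe$z)], "m1")
})

test_that("positional profiles align, orient and count matches correctly", {
  ## constant track -> flat profile
  tracks <- list(f1 = rep(2, 60))
  matches <- data.frame(fragment_id = "f1", start = 20, end = 26,
                        strand = "+")
  pr <- positional_profile(tracks, matches, halfwidth = 10)
  expect_true(all(pr$mean == 2))
  expect_equal(pr$n[pr$offset == 0], 1L)

  ## strand reversal flips the profile
  set.seed(41)
  tracks2 <- list(f1 = rnorm(80))
  m_plus <- data.frame(fragment_id = "f1", start = 30, end = 37, strand = "+")
  m_minus <- transform(m_plus, strand = "-")
  p_plus <- positional_profile(tracks2, m_plus, halfwidth = 8)
  p_minus <- positional_profile(tracks2, m_minus, halfwidth = 8)
  expect_equal(p_minus$mean, rev(p_plus$mean))

  ## counts at offset 0 equal the number of matches; edges give partials
  tracks3 <- list(a = rnorm(50), b = rnorm(50))
  m3 <- data.frame(fragment_id = c("a", "a", "b"),
                   start = c(2, 20, 44), end = c(8, 26, 50),
                   strand = c("+", "-", "+"))
  p3 <- positional_profile(tracks3, m3, halfwidth = 15)
  expect_equal(p3$n[p3$offset == 0], 3L)
  expect_lt(min(p3$n), 3L)
})

test_that("quantile overlap hits the trivial bounds and rejects tiny input", {
  set.seed(55)
  sc <- data.frame(chrom = "c1", pos = 0:199, score = rnorm(200))
  all_cov <- data.frame(chrom = "c1", start = 0, end = 200)
  qo <- quantile_overlap(sc, all_cov, n_quantiles = 10)
  expect_true(all(qo$bins$overlap_fraction == 1))
  none <- data.frame(chrom = "c2", start = 0, end = 200)
  qo0 <- quantile_overlap(sc, none, n_quantiles = 10)
  expect_true(all(qo0$bins$overlap_fraction == 0))
  expect_equal(sum(qo$bins$n), 200L)
  expect_error(quantile_overlap(sc[1:5, ], all_cov, n_quantiles = 10),
               "fewer bases")
})

test_that("high-|score| bases planted in annotations enrich the top quantile", {
  set.seed(60)
  n <- 2000
  sc <- data.frame(chrom = "c1", pos = 0:(n - 1), score = rnorm(n, 0, 0.1))
  inside <- sample(n, 200)
  sc$score[inside] <- rnorm(200, 1.2, 0.2)
  ann <- data.frame(chrom = "c1", start = sort(inside) - 1,
                    end = sort(inside))
  qo <- quantile_overlap(sc, ann, n_quantiles = 20)
  top <- qo$bins$overlap_fraction[20]
  med <- median(qo$bins$overlap_fraction[8:12])
  expect_gt(top, 2 * max(med, 0.01))
})
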