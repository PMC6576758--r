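test_that("Spearman evaluation matches a rank-then-Pearson oracle", {
  set.seed(31)
  pred <- matrix(rnorm(50 * 2), 50)
  lab <- matrix(rnorm(50 * 2), 50)
  rho <- evaluate_spearman(pred, lab)
  oracle <- vapply(1:2, function(j)
    stats::cor(rank(pred[, j]), rank(lab[, j])), numeric(1))
  expect_equal(unname(rho), oracle, tolerance = 1e-10)

  expect_equal(unname(evaluate_spearman(lab, lab)), c(1, 1))
  expect_equal(unname(evaluate_spearman(-lab, lab)), c(-1, -1))
  expect_warning(r <- evaluate_spearman(matrix(1, 10, 1),
                                        matrix(rnorm(10), 10)), "constant")
  expect_true(is.na(r))
})

test_that("state-stratified evaluation reduces to the plain one for one group", {
  set.seed(8)
  pred <- matrix(rnorm(40), ncol = 2); lab <- matrix(rnorm(40), ncol = 2)
  colnames(pred) <- colnames(lab) <- c("a", "b")
  bs <- evaluate_by_state(pred, lab, rep("enhancer", 20))
  expect_equal(nrow(bs), 1L)
  expect_equal(unlist(bs[, c("a", "b")], use.names = FALSE),
               unname(evaluate_spearman(pred, lab)))
  ## groups below 3 members are skipped with a warning
  expect_warning(bs2 <- evaluate_by_state(pred, lab,
                                          c(rep("enhancer", 18), "promoter",
                                            "promoter")), "skipped")
  expect_false("promoter" %in% bs2$state)
})

test_that("group with lower noise yields higher within-group correlation", {
  set.seed(12)
  n <- 2000
  truth <- rnorm(n)
  grp <- rep(c("promoter", "enhancer"), each = n / 2)
  noise_sd <- ifelse(grp == "promoter", 0.2, 1.5)
  lab <- matrix(truth + rnorm(n, 0, noise_sd), ncol = 1)
  pred <- matrix(truth, ncol = 1)
  colnames(lab) <- colnames(pred) <- "t"
  bs <- evaluate_by_state(pred, lab, grp)
  expect_gt(bs$t[bs$state == "promoter"], bs$t[bs$state == "enhancer"])
  expect_gt(bs$t[bs$state == "promoter"],
            evaluate_spearman(pred, lab)[["t"]])
})

test_that("error vs replicate-gap correlation behaves under the null and alternative", {
  set.seed(21)
  n <- 10000
  truth <- rnorm(n)
  ## heteroscedastic: noisy fragments have both larger gap and larger error
  sds <- sqrt(rgamma(n, 2, 2))
  r1 <- truth + rnorm(n, 0, sds); r2 <- truth + rnorm(n, 0, sds)
  pred <- matrix(truth, ncol = 1)
  rho <- error_vs_replicate_gap(pred, list(matrix(r1), matrix(r2)))
  expect_gt(rho, 0)

  ## permuting the replicate pairing destroys the association
  perm <- sample(n)
  rho0 <- error_vs_replicate_gap(pred, list(matrix(r1[perm]),
                                            matrix(r2[perm])))
  expect_lt(abs(rho0), 0.05)

  expect_warning(r <- error_vs_replicate_gap(matrix(rnorm(10)),
                                             list(matrix(1:10 / 10),
                                                  matrix(1:10 / 10))),
                 "constant")
  expect_true(is.na(r))
  expect_error(error_vs_replicate_gap(pred, list(matrix(r1))), "two replicate")
})
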