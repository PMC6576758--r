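test_that("one-hot encoding follows the A,C,G,T column convention", {
  expect_equal(unname(encode_one_hot("ACGT")),
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                     c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(unname(encode_one_hot("N")), matrix(0, 1, 4))
  expect_equal(encode_one_hot("acgt"), encode_one_hot("ACGT"))
  expect_error(encode_one_hot("ACXT"), "position 3")
})

test_that("encode/decode round-trips random N-free sequences", {
  set.seed(42)
  for (i in 1:1000) {
    s <- random_seq(sample(5:60, 1))
    expect_identical(decode_one_hot(encode_one_hot(s)), s)
  }
  expect_identical(decode_one_hot(encode_one_hot("ANGT")), "ANGT")
})

test_that("reverse_complement permutes channels and is an involution", {
  expect_equal(reverse_complement(encode_one_hot("ACGT")),
               encode_one_hot("ACGT"))
  expect_equal(reverse_complement(encode_one_hot("AAAA")),
               encode_one_hot("TTTT"))
  set.seed(7)
  for (i in 1:100) {
    m <- encode_one_hot(random_seq(sample(4:40, 1)))
    rc <- reverse_complement(m)
    expect_equal(reverse_complement(rc), m)
    expect_equal(rowSums(rc), rev(rowSums(m)))  # N rows stay N rows
  }
})

test_that("batch encoding matches per-sequence encoding", {
  set.seed(1)
  seqs <- replicate(20, random_seq(30))
  arr <- mpracnn:::encode_batch(seqs)
  for (i in seq_along(seqs))
    expect_equal(mpracnn:::engine_to_onehot(arr, i), encode_one_hot(seqs[i]))
})
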