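test_that("bank tracks forced best/worst at a pixel", {
  b <- memory_bank()
  L1 <- matrix(1, 1, 1)
  for (p in c(0.3, 0.8, 0.6)) bank_update(b, "a", matrix(p, 1, 1), L1)
  expect_equal(bank_best(b, "a")[1, 1], 0.8)
  expect_equal(bank_worst(b, "a")[1, 1], 0.3)

  L0 <- matrix(0, 1, 1)
  bank_reset(b)
  for (p in c(0.3, 0.8)) bank_update(b, "a", matrix(p, 1, 1), L0)
  expect_equal(bank_best(b, "a")[1, 1], 0.3)
  expect_equal(bank_worst(b, "a")[1, 1], 0.8)
})

test_that("empty-state and reset contracts", {
  b <- memory_bank()
  expect_error(bank_best(b, "x"), "not yet populated")
  expect_false(bank_is_populated(b, "x"))
  bank_reset(b)
  bank_reset(b)  # idempotent
  expect_error(bank_worst(b, "x"), "not yet populated")
  p <- matrix(0.4, 2, 2)
  bank_update(b, "x", p, matrix(1, 2, 2))
  expect_identical(bank_best(b, "x"), p)
  expect_identical(bank_worst(b, "x"), p)
  expect_equal(bank_n_updates(b, "x"), 1L)
  bank_reset(b)
  expect_error(bank_best(b, "x"), "not yet populated")
})

test_that("repeated reads return identical maps", {
  b <- memory_bank()
  bank_update(b, "i", rand_map(3, 3), rand_map(3, 3))
  expect_identical(bank_best(b, "i"), bank_best(b, "i"))
})

test_that("incremental bank equals brute-force stack oracle", {
  set.seed(42)
  for (trial in 1:30) {
    L <- rand_map(4, 4)
    b <- memory_bank()
    stack <- list()
    for (u in seq_len(sample(2:12, 1))) {
      p <- rand_map(4, 4)
      stack[[u]] <- p
      bank_update(b, "img", p, L)
    }
    oracle <- bank_oracle(stack, L)
    expect_identical(bank_best(b, "img"), oracle$best)
    expect_identical(bank_worst(b, "img"), oracle$worst)
    # best deviation bounded by every recorded deviation
    bd <- abs(bank_best(b, "img") - L)
    wd <- abs(bank_worst(b, "img") - L)
    expect_true(all(bd <= wd))
    for (p in stack) {
      expect_true(all(bd <= abs(p - L) + 1e-15))
      expect_true(all(abs(p - L) <= wd + 1e-15))
    }
  }
})

test_that("ties keep the earliest recorded value", {
  b <- memory_bank()
  L <- matrix(0.5, 1, 1)
  bank_update(b, "t", matrix(0.25, 1, 1), L)  # |dev| = 0.25 exactly
  bank_update(b, "t", matrix(0.75, 1, 1), L)  # |dev| = 0.25, exact tie
  expect_equal(bank_best(b, "t")[1, 1], 0.25)
  expect_equal(bank_worst(b, "t")[1, 1], 0.25)
})

test_that("bank validates shapes and a fixed within-cycle label", {
  b <- memory_bank()
  bank_update(b, "a", rand_map(2, 2), matrix(1, 2, 2))
  expect_error(bank_update(b, "a", rand_map(3, 3), matrix(1, 2, 2)), "shape")
  expect_error(bank_update(b, "a", rand_map(2, 2), matrix(0, 2, 2)),
               "mid-cycle")
  # unknown id auto-initializes
  bank_update(b, "fresh", rand_map(2, 2), matrix(1, 2, 2))
  expect_true(bank_is_populated(b, "fresh"))
})

test_that("bank storage is O(1) in epochs", {
  b <- memory_bank()
  L <- rand_map(4, 4)
  for (i in 1:40) bank_update(b, "a", rand_map(4, 4), L)
  e <- b$store[["a"]]
  expect_named(e, c("best", "worst", "best_dev", "worst_dev",
                    "n_updates", "label_digest"))
  expect_equal(e$n_updates, 40L)
})
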