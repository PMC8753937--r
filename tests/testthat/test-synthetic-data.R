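test_that("phantom generation is seeded-deterministic and well-formed", {
  a <- generate_phantom(7, size = 128, n_trees = 3)
  b <- generate_phantom(7, size = 128, n_trees = 3)
  expect_identical(a, b)
  expect_true(all(a$gold_mask %in% c(0, 1)))
  expect_gt(sum(a$gold_mask), 0)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_identical(dim(a$image), dim(a$gold_mask))
  # different seed, different phantom
  expect_false(identical(a$gold_mask, generate_phantom(8, 128, 3)$gold_mask))
  # caller's RNG stream untouched
  set.seed(99); r1 <- runif(1)
  set.seed(99); invisible(generate_phantom(1, 64)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("phantom foreground fraction stays in the configured band", {
  fr <- vapply(cached_phantom_masks(1:20, 128), mean, numeric(1))
  expect_gte(mean(fr), 0.03)
  expect_lte(mean(fr), 0.20)
})

test_that("phantom parameter validation names the offending field", {
  expect_error(generate_phantom(1, size = 16), "size")
  expect_error(generate_phantom(1, size = 64, n_trees = 0), "n_trees")
  expect_error(generate_phantom(1, thickness = c(3, 1)), "thickness")
})

test_that("contour approximation at eps = 0 is near-lossless", {
  for (s in c(3, 5)) {
    g <- generate_phantom(s, 96)$gold_mask
    expect_gte(f1_score(corrupt_contour_approx(g, 0), g), 0.99)
  }
})

test_that("corruption degrades F1 monotonically in eps", {
  masks <- cached_phantom_masks(1:10, 128)
  mean_f1 <- vapply(c(1, 2, 4), function(e)
    mean(vapply(masks, function(g)
      f1_score(corrupt_contour_approx(g, e), g), numeric(1))), numeric(1))
  expect_true(all(diff(mean_f1) <= 0))
})

test_that("a thin diagonal stroke is deleted at coarse tolerance", {
  d <- matrix(0, 32, 32)
  for (i in 5:25) d[i, i] <- 1
  expect_lt(sum(corrupt_contour_approx(d, 6)), sum(d))
})

test_that("contour corruption is mask-valued and validates input", {
  g <- cached_phantom_masks(1:10, 128)[[1]]
  out <- corrupt_contour_approx(g, 2)
  expect_true(all(out %in% c(0, 1)))
  expect_identical(dim(out), dim(g))
  expect_error(corrupt_contour_approx(g * 0.5, 1), "binary")
  expect_error(corrupt_contour_approx(g, -1), "eps")
})

test_that("noise severity levels LV1 > LV2 > LV3 strictly degrade labels", {
  masks <- cached_phantom_masks(1:10, 128)
  mean_f1 <- vapply(c("LV1", "LV2", "LV3"), function(lv) {
    eps <- noise_spec(level = lv)$eps
    mean(vapply(masks, function(g)
      f1_score(corrupt_contour_approx(g, eps), g), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_f1) < 0))
})

test_that("noise_spec resolves strictly increasing tolerances", {
  eps <- vapply(c("LV1", "LV2", "LV3"), function(lv)
    noise_spec(level = lv)$eps, numeric(1))
  expect_true(all(diff(eps) > 0))
  scaled <- noise_spec(level = "LV2", scale_ref = 565)
  expect_equal(vesselmend:::resolve_eps(scaled, 565), 3)
  expect_lt(vesselmend:::resolve_eps(scaled, 128), 3)
})

test_that("surrogate noise kinds are mask-valued and deterministic", {
  g <- cached_phantom_masks(1:10, 128)[[2]]
  de <- corrupt_dilation_erosion(g, 3, seed = 4)
  dr <- corrupt_dropout(g, 3, seed = 4)
  expect_true(all(de %in% c(0, 1)))
  expect_true(all(dr %in% c(0, 1)))
  expect_identical(de, corrupt_dilation_erosion(g, 3, seed = 4))
  expect_identical(dr, corrupt_dropout(g, 3, seed = 4))
})

test_that("make_noisy_dataset pollutes every record and reproduces", {
  d1 <- make_noisy_dataset(8, noise_spec(level = "LV2", seed = 0), seed = 0,
                           size = 64)
  expect_length(d1, 8)
  for (rec in d1)
    expect_gt(sum(rec$noisy != sample_gold(rec)), 0)
  d2 <- make_noisy_dataset(8, noise_spec(level = "LV2", seed = 0), seed = 0,
                           size = 64)
  expect_identical(d1, d2)
  expect_error(make_noisy_dataset(0, noise_spec()), "n")
})

test_that("zero-tolerance dataset keeps labels essentially clean", {
  spec <- noise_spec(level = "LV1")
  spec$eps <- 0
  d <- make_noisy_dataset(1, spec, seed = 2, size = 96)
  expect_gte(f1_score(d[[1]]$noisy, sample_gold(d[[1]])), 0.99)
})

test_that("dataset round-trips through the PNG directory layout", {
  d <- make_noisy_dataset(2, noise_spec(level = "LV2"), seed = 5, size = 64)
  dir <- withr::local_tempdir()
  write_dataset(d, dir, meta = list(level = "LV2"))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset(dir)
  expect_length(back, 2)
  expect_identical(back[[1]]$noisy, d[[1]]$noisy)
  expect_identical(sample_gold(back[[2]]), sample_gold(d[[2]]))
  expect_equal(back[[1]]$image, d[[1]]$image, tolerance = 1 / 255)
})
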