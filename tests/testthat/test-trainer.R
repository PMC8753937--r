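test_that("the default plan reproduces the reference schedule", {
  plan <- build_plan(train_config())
  expect_equal(nrow(plan), 100)
  e50 <- plan[plan$epoch == 50, ]
  expect_equal(e50$cycle, 1L)
  expect_equal(e50$phase, "warmup")
  expect_true(all(plan$phase[plan$epoch < 50] == "init"))
  expect_equal(plan$epoch[plan$correct_labels_at_end], c(59, 69, 79, 89, 99))
  expect_equal(sum(plan$correct_labels_at_end), 5)
  # corrections only at cycle-final epochs, never during init
  expect_true(all(plan$cycle[plan$correct_labels_at_end] > 0))
  # warm-up runs T epochs then the memory loss takes over
  c1 <- plan[plan$cycle == 1, ]
  expect_equal(c1$phase, c(rep("warmup", 3), rep("tml", 7)))
})

test_that("config invariants are enforced", {
  expect_error(train_config(warmup_epochs = 10), "warmup_epochs")
  expect_error(train_config(total_epochs = 99), "total_epochs")
  expect_error(train_config(sgdr_period = 5), "sgdr_period")
  # a degenerate schedule without cycles is allowed (supervised baseline)
  cfg0 <- train_config(total_epochs = 4, init_epochs = 4, n_cycles = 0,
                       epochs_per_cycle = 10, sgdr_start_epoch = 2)
  expect_equal(sum(build_plan(cfg0)$correct_labels_at_end), 0)
})

test_that("sgdr learning rate anneals with warm restarts", {
  cfg <- train_config()
  expect_equal(sgdr_lr(39, cfg), 7e-3, tolerance = 1e-9)
  expect_equal(sgdr_lr(40, cfg), 7e-3, tolerance = 1e-9)
  expect_equal(sgdr_lr(45, cfg), 3.5e-3, tolerance = 1e-9)
  expect_equal(sgdr_lr(50, cfg), 7e-3, tolerance = 1e-9)  # restart
  expect_lt(sgdr_lr(49, cfg), sgdr_lr(48, cfg))
})

test_that("flip augmentations are exact involutions", {
  set.seed(11)
  x <- rand_map(6, 4)
  for (m in c("none", "hflip", "vflip", "hvflip"))
    expect_identical(invert_prediction(flip_map(x, m), m), x)
  expect_identical(flip_map(x, "none"), x)
  expect_identical(flip_map(flip_map(x, "hflip"), "vflip"),
                   flip_map(x, "hvflip"))
  expect_identical(flip_map(flip_map(x, "vflip"), "hflip"),
                   flip_map(x, "hvflip"))
  expect_error(flip_map(x, "rot90"), "mode")
  p <- augment_pair(x, 1 - x, "hflip")
  expect_identical(p$image, flip_map(x, "hflip"))
})

test_that("one epoch of small-lr steps decreases a single image's loss", {
  data <- tiny_dataset(n = 1)
  cfg <- tiny_config()
  labels <- list(label_state(data[[1]]$noisy * 1))
  names(labels) <- data[[1]]$id
  pars <- unet_init(width = 4, seed = 2)
  before <- warmup_loss(unet_predict(pars, data[[1]]$image),
                        labels[[1]]$current)
  rec <- data.frame(epoch = 0, phase = "init", cycle = 0L, lr = 1e-4,
                    correct_labels_at_end = FALSE)
  res <- train_epoch(pars, data, rec, memory_bank(), labels, cfg)
  after <- warmup_loss(unet_predict(res$model$pars, data[[1]]$image),
                       labels[[1]]$current)
  expect_lt(after, before)
})

test_that("warm-up epochs record four views per image into the bank", {
  data <- tiny_dataset(n = 2)
  cfg <- tiny_config()
  labels <- stats::setNames(lapply(data, function(r) label_state(r$noisy * 1)),
                            vapply(data, `[[`, character(1), "id"))
  bank <- memory_bank()
  rec <- data.frame(epoch = 4, phase = "warmup", cycle = 1L, lr = 1e-3,
                    correct_labels_at_end = FALSE)
  model <- train_epoch(unet_init(width = 4, seed = 2), data, rec, bank,
                       labels, cfg)$model
  expect_equal(bank_total_updates(bank), 4L * length(data))
  for (r in data) expect_equal(bank_n_updates(bank, r$id), 4L)
  # init epochs do not record
  bank2 <- memory_bank()
  rec_init <- data.frame(epoch = 0, phase = "init", cycle = 0L, lr = 1e-3,
                         correct_labels_at_end = FALSE)
  train_epoch(unet_init(width = 4, seed = 2), data, rec_init, bank2,
              labels, cfg)
  expect_equal(bank_total_updates(bank2), 0L)
})

test_that("a frozen model records identical bank states across epochs", {
  data <- tiny_dataset(n = 1)
  cfg <- tiny_config()
  labels <- stats::setNames(list(label_state(data[[1]]$noisy * 1)),
                            data[[1]]$id)
  rec <- data.frame(epoch = 4, phase = "warmup", cycle = 1L, lr = 0,
                    correct_labels_at_end = FALSE)
  pars <- unet_init(width = 4, seed = 2)
  bank <- memory_bank()
  train_epoch(pars, data, rec, bank, labels, cfg)
  b1 <- bank_best(bank, data[[1]]$id); w1 <- bank_worst(bank, data[[1]]$id)
  train_epoch(pars, data, rec, bank, labels, cfg)
  expect_identical(bank_best(bank, data[[1]]$id), b1)
  expect_identical(bank_worst(bank, data[[1]]$id), w1)
})

test_that("gold masks are sealed against the training path", {
  rec <- tiny_dataset(n = 1)[[1]]
  withr::local_options(vesselmend.gold_locked = TRUE)
  expect_error(sample_gold(rec), "locked")
})

test_that("training never touches gold: a gold-free dataset trains fine", {
  data <- lapply(tiny_dataset(n = 2), function(r)
    sample_record(r$id, r$image, gold = NULL, noisy = r$noisy))
  fit <- run_training(tiny_config(), data)
  expect_true(all(is.na(fit$report$cycles$f1)))
  expect_equal(nrow(fit$report$cycles), 2)
  expect_false(isTRUE(getOption("vesselmend.gold_locked")))
})

test_that("full runs are reproducible and report the schedule faithfully", {
  data <- tiny_dataset(n = 2)
  cfg <- tiny_config()
  fit1 <- run_training(cfg, data, test_data = tiny_dataset(n = 2, seed = 9))
  fit2 <- run_training(cfg, data, test_data = tiny_dataset(n = 2, seed = 9))
  expect_identical(fit1$report, fit2$report)
  expect_equal(nrow(fit1$report$epochs), cfg$total_epochs)
  expect_equal(fit1$report$cycles$cycle, 1:2)
  expect_false(any(is.na(fit1$report$epochs$test_loss)))
  # corrected labels are soft maps in [0, 1]
  for (L in fit1$labels)
    expect_true(all(L >= 0 & L <= 1))
  # ablation modes run and share the schedule
  ab <- run_training(cfg, data, mode = "q_is_sbest")
  expect_equal(ab$mode, "q_is_sbest")
  expect_equal(nrow(ab$report$cycles), 2)
})

test_that("a cycle-free run is the plain supervised baseline", {
  data <- tiny_dataset(n = 1)
  cfg0 <- train_config(total_epochs = 3, init_epochs = 3, n_cycles = 0,
                       epochs_per_cycle = 10, sgdr_start_epoch = 1,
                       seed = 7, model_width = 4)
  fit <- run_training(cfg0, data)
  expect_equal(nrow(fit$report$cycles), 0)
  # labels were never corrected
  expect_identical(fit$labels[[1]], data[[1]]$noisy * 1)
})

test_that("yaml config round-trips and rejects unknown keys", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.yaml")
  writeLines(c("total_epochs: 10", "init_epochs: 4", "n_cycles: 2",
               "epochs_per_cycle: 3", "warmup_epochs: 1",
               "sgdr_start_epoch: 1", "sgdr_period: 3", "model_width: 4"),
             cfg_path)
  cfg <- vesselmend:::config_from_yaml(cfg_path)
  expect_s3_class(cfg, "train_config")
  expect_equal(cfg$n_cycles, 2)
  writeLines(c("total_epochs: 10", "bogus_key: 1"), cfg_path)
  expect_error(vesselmend:::config_from_yaml(cfg_path), "bogus_key")
})
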