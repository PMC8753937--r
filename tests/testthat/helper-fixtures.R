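# Shared fixtures and independent oracles. Everything is generated in
# code; expensive artifacts are memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

cached_phantom_masks <- function(seeds, size) {
  memo(sprintf("phantoms_%d_%s", size, paste(seeds, collapse = "_")),
       lapply(seeds, function(s) generate_phantom(s, size)$gold_mask))
}

rand_map <- function(h, w) matrix(runif(h * w, 0.01, 0.99), h, w)

# brute-force memory-bank oracle: keep the whole prediction stack and
# scan it per pixel
bank_oracle <- function(stack, L) {
  dev <- lapply(stack, function(s) abs(s - L))
  best <- stack[[1]]; worst <- stack[[1]]
  bd <- dev[[1]]; wd <- dev[[1]]
  for (u in seq_along(stack)[-1]) {
    better <- dev[[u]] < bd
    worse <- dev[[u]] > wd
    best[better] <- stack[[u]][better]; bd[better] <- dev[[u]][better]
    worst[worse] <- stack[[u]][worse]; wd[worse] <- dev[[u]][worse]
  }
  list(best = best, worst = worst)
}

# brute-force average-precision oracle: sweep every distinct threshold
pr_auc_oracle <- function(pred, gold) {
  ths <- sort(unique(c(pred)), decreasing = TRUE)
  n_pos <- sum(gold)
  prev_rec <- 0
  area <- 0
  for (t in ths) {
    p <- pred >= t
    tp <- sum(p & gold == 1)
    prec <- tp / sum(p)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# tiny training dataset used by trainer unit tests
tiny_dataset <- function(n = 2, size = 32, seed = 3) {
  memo(sprintf("tinydata_%d_%d_%d", n, size, seed),
       make_noisy_dataset(n, noise_spec(level = "LV2"), seed = seed,
                          size = size, n_trees = 1))
}

tiny_config <- function(seed = 11, width = 4) {
  train_config(total_epochs = 10, init_epochs = 4, n_cycles = 2,
               epochs_per_cycle = 3, warmup_epochs = 1,
               sgdr_start_epoch = 1, sgdr_period = 3,
               seed = seed, model_width = width)
}
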