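#' Training configuration
#'
#' Defaults follow the reference schedule: 100 epochs total, the first 50
#' as initialization, then 5 cycles of 10 epochs each; within each cycle
#' the first `warmup_epochs` train on the plain label loss while the
#' memory bank accumulates, and the rest use the temporal memory loss.
#' Cosine-annealing warm restarts start at epoch 40 with period 10 (the
#' 10-epoch offset between scheduler start and cycle start is part of the
#' schedule; when scaling down, set `sgdr_start_epoch = init_epochs -
#' epochs_per_cycle`). Optimization is Adam at `base_lr = 7e-3`, with
#' stochastic weight averaging snapshots at each restart.
#'
#' @param total_epochs total training epochs
#' @param init_epochs initialization epochs on `L^0`
#' @param n_cycles number of label-correction cycles M
#' @param epochs_per_cycle epochs per cycle E
#' @param warmup_epochs warm-up epochs T at each cycle start (the bank
#'   needs several epochs to accumulate before the memory loss is usable)
#' @param lambda_weight weight of the label term in the memory loss
#' @param base_lr Adam learning rate (also the restart peak)
#' @param sgdr_start_epoch first epoch of cosine annealing
#' @param sgdr_period restart period (must equal `epochs_per_cycle`)
#' @param swa_enabled average weight snapshots at each restart
#' @param sj_source `"swa"` (default, matching the weight-averaging
#'   practice the schedule follows) or `"online"`: which model produces
#'   the cycle-end prediction used in the compensation
#' @param seed integer seed controlling initialization
#' @param model_width first-level channel width of the segmenter
#' @return a validated `train_config`
#' @export
train_config <- function(total_epochs = 100, init_epochs = 50, n_cycles = 5,
                         epochs_per_cycle = 10, warmup_epochs = 3,
                         lambda_weight = 0.1, base_lr = 7e-3,
                         sgdr_start_epoch = 40, sgdr_period = 10,
                         swa_enabled = TRUE, sj_source = c("swa", "online"),
                         seed = 0, model_width = 8) {
  sj_source <- match.arg(sj_source)
  if (init_epochs + n_cycles * epochs_per_cycle != total_epochs)
    stop("config invariant violated: init_epochs + n_cycles * epochs_per_cycle must equal total_epochs",
         call. = FALSE)
  if (n_cycles > 0) {
    if (!(warmup_epochs >= 1 && warmup_epochs < epochs_per_cycle))
      stop("config invariant violated: 1 <= warmup_epochs < epochs_per_cycle",
           call. = FALSE)
    if (sgdr_period != epochs_per_cycle)
      stop("config invariant violated: sgdr_period must equal epochs_per_cycle",
           call. = FALSE)
  }
  structure(list(total_epochs = total_epochs, init_epochs = init_epochs,
                 n_cycles = n_cycles, epochs_per_cycle = epochs_per_cycle,
                 warmup_epochs = warmup_epochs, lambda_weight = lambda_weight,
                 base_lr = base_lr, sgdr_start_epoch = sgdr_start_epoch,
                 sgdr_period = sgdr_period, swa_enabled = swa_enabled,
                 sj_source = sj_source, seed = seed,
                 model_width = model_width),
            class = "train_config")
}

#' Cosine-annealing learning rate with warm restarts
#'
#' Before `sgdr_start_epoch` the scheduler is inactive and the rate is
#' `base_lr`; from then on `lr = base_lr / 2 * (1 + cos(pi * ((epoch -
#' start) mod period) / period))`, restarting at `base_lr` each period.
#'
#' @param epoch epoch index (0-based)
#' @param cfg a [train_config()]
#' @return learning rate
#' @export
sgdr_lr <- function(epoch, cfg) {
  if (epoch < cfg$sgdr_start_epoch) return(cfg$base_lr)
  t <- (epoch - cfg$sgdr_start_epoch) %% cfg$sgdr_period
  cfg$base_lr / 2 * (1 + cos(pi * t / cfg$sgdr_period))
}

#' Resolve the epoch-by-epoch training plan
#'
#' @param cfg a [train_config()]
#' @return data.frame with one row per epoch: `epoch` (0-based), `phase`
#'   (`init` / `warmup` / `tml`), `cycle` (0 during init), `lr`, and
#'   `correct_labels_at_end` (TRUE exactly at the last epoch of each
#'   cycle)
#' @export
build_plan <- function(cfg) {
  stopifnot(inherits(cfg, "train_config"))
  epochs <- seq_len(cfg$total_epochs) - 1L
  cyc <- ifelse(epochs < cfg$init_epochs, 0L,
                1L + (epochs - cfg$init_epochs) %/% cfg$epochs_per_cycle)
  within <- ifelse(cyc == 0L, NA_integer_,
                   (epochs - cfg$init_epochs) %% cfg$epochs_per_cycle)
  phase <- ifelse(cyc == 0L, "init",
                  ifelse(within < cfg$warmup_epochs, "warmup", "tml"))
  data.frame(epoch = epochs, phase = phase, cycle = cyc,
             lr = vapply(epochs, sgdr_lr, numeric(1), cfg = cfg),
             correct_labels_at_end =
               cyc > 0L & within == cfg$epochs_per_cycle - 1L)
}

#' Flip augmentation and its inverse
#'
#' Horizontal flip reverses columns, vertical flip reverses rows,
#' `hvflip` does both; all are exact pixel permutations and involutions,
#' so [invert_prediction()] applies the same flip again.
#'
#' @param m matrix
#' @param mode one of `"none"`, `"hflip"`, `"vflip"`, `"hvflip"`
#' @return flipped matrix
#' @export
flip_map <- function(m, mode) {
  switch(mode,
         none = m,
         hflip = m[, rev(seq_len(ncol(m))), drop = FALSE],
         vflip = m[rev(seq_len(nrow(m))), , drop = FALSE],
         hvflip = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         stop_param("mode", "must be one of none/hflip/vflip/hvflip"))
}

#' @rdname flip_map
#' @param image,label a pair to transform jointly
#' @export
augment_pair <- function(image, label, mode) {
  list(image = flip_map(image, mode), label = flip_map(label, mode))
}

#' @rdname flip_map
#' @param pred a prediction produced on the augmented view
#' @export
invert_prediction <- function(pred, mode) flip_map(pred, mode)

aug_modes <- c("none", "hflip", "vflip", "hvflip")

#' Run one training epoch
#'
#' For every image and each of the four flip views: forward pass, loss
#' according to the plan phase (`init`/`warmup`: plain label loss; `tml`:
#' temporal memory loss against the bank's historical best, falling back
#' to the warm-up loss with a warning if the bank is unpopulated), one
#' Adam step at the plan's learning rate. Views are independent batch
#' items. In warm-up and memory phases every view's prediction is
#' reversed to canonical orientation and recorded into the bank (after
#' the image's four steps), so one epoch contributes 4 updates per image.
#' Gold masks are locked for the duration of the call.
#'
#' @param model list with `pars` and `opt` (from [unet_init()] /
#'   `adam_init`); a bare parameter list is also accepted
#' @param data list of [sample_record()]s
#' @param plan_rec one row of [build_plan()]'s data.frame
#' @param bank the cycle's [memory_bank()]
#' @param labels named list of [label_state()]s keyed by record id
#' @param cfg a [train_config()]
#' @param use_tml set FALSE to ablate the memory loss (labels still
#'   corrected at cycle ends)
#' @return list: `model` (updated pars/opt), `loss` (mean over steps)
#' @export
train_epoch <- function(model, data, plan_rec, bank, labels, cfg,
                        use_tml = TRUE) {
  if (is.null(model$pars)) model <- list(pars = model, opt = adam_init(model))
  old <- options(vesselmend.gold_locked = TRUE)
  on.exit(options(old))
  lcfg <- loss_config(lambda_weight = cfg$lambda_weight)
  phase <- plan_rec$phase
  lr <- plan_rec$lr
  losses <- numeric(0)
  for (rec in data) {
    L <- labels[[rec$id]]$current
    canon_preds <- vector("list", length(aug_modes))
    for (vi in seq_along(aug_modes)) {
      mode <- aug_modes[vi]
      xv <- flip_map(rec$image, mode)
      Lv <- flip_map(L, mode)
      fwd <- unet_forward(model$pars, xv)
      S <- fwd$prob
      n <- length(S)
      if (phase == "tml" && use_tml) {
        if (bank_is_populated(bank, rec$id)) {
          bestv <- flip_map(bank_best(bank, rec$id), mode)
          loss <- temporal_memory_loss(S, bestv, Lv, lcfg)
          dz <- ((S - bestv) + cfg$lambda_weight * (S - Lv)) / n
        } else {
          warning("memory bank unpopulated in tml phase; falling back to warm-up loss")
          loss <- warmup_loss(S, Lv, lcfg)
          dz <- (S - Lv) / n
        }
      } else {
        loss <- warmup_loss(S, Lv, lcfg)
        dz <- (S - Lv) / n
      }
      grads <- unet_backward(model$pars, fwd$cache, dz)
      step <- adam_step(model$pars, grads, model$opt, lr)
      model$pars <- step$pars
      model$opt <- step$state
      losses <- c(losses, loss)
      canon_preds[[vi]] <- invert_prediction(S, mode)
    }
    if (phase %in% c("warmup", "tml")) {
      for (p in canon_preds) bank_update(bank, rec$id, p, L)
    }
  }
  list(model = model, loss = mean(losses))
}

#' Train the full framework
#'
#' Executes the resolved plan: initialization on `L^0`, then `n_cycles`
#' cycles of warm-up + temporal-memory training. At the end of cycle `j`
#' the per-image compensation `Q^j = D * best + (1 - D) * S^j` is formed
#' from the bank's best/worst maps and the cycle-end prediction, the
#' labels move to `L^{j+1} = L^0/(j+1) + Q^j * j/(j+1)`, and the bank is
#' reset for the next cycle. After the last cycle the final corrected
#' maps (`L^{M+1}`) are exported but never trained on.
#'
#' @param cfg a [train_config()]
#' @param data list of [sample_record()]s (training set; gold used only
#'   for the per-cycle correction report)
#' @param test_data optional held-out records; adds a per-epoch test loss
#'   against their gold masks (never influences training)
#' @param mode `"full"`, or an ablation: `"no_tml"` (plain label loss
#'   throughout), `"q_is_s"` (compensation replaced by the cycle-end
#'   prediction), `"q_is_sbest"` (replaced by the historical best)
#' @param verbose print per-epoch progress
#' @return list: `model`, `swa_model`, `labels` (final corrected maps),
#'   `label_states`, and `report` -- a `correction_report` with `epochs`
#'   (epoch, phase, cycle, lr, train_loss, test_loss) and `cycles`
#'   (cycle, f1, pr_auc of the freshly corrected labels vs gold)
#' @export
run_training <- function(cfg, data, test_data = NULL,
                         mode = c("full", "no_tml", "q_is_s", "q_is_sbest"),
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  mode <- match.arg(mode)
  if (length(data) == 0) stop_param("data", "dataset is empty")
  plan <- build_plan(cfg)
  ids <- vapply(data, `[[`, character(1), "id")

  with_seed(cfg$seed, {
    pars <- unet_init(width = cfg$model_width)
    model <- list(pars = pars, opt = adam_init(pars))
    bank <- memory_bank()
    labels <- stats::setNames(lapply(data, function(r) label_state(r$noisy * 1)),
                              ids)
    swa_avg <- NULL
    swa_n <- 0L
    ep_rows <- vector("list", nrow(plan))
    cy_rows <- list()

    for (i in seq_len(nrow(plan))) {
      pr <- plan[i, ]
      cycle_start <- pr$cycle > 0 &&
        (pr$epoch - cfg$init_epochs) %% cfg$epochs_per_cycle == 0
      if (cycle_start) bank_reset(bank)

      res <- train_epoch(model, data, pr, bank, labels, cfg,
                         use_tml = (mode != "no_tml"))
      model <- res$model

      test_loss <- NA_real_
      if (!is.null(test_data))
        test_loss <- mean(vapply(test_data, function(r)
          bce(unet_predict(model$pars, r$image), sample_gold(r)), numeric(1)))

      if (cfg$swa_enabled && pr$epoch >= cfg$sgdr_start_epoch &&
          (pr$epoch - cfg$sgdr_start_epoch + 1) %% cfg$sgdr_period == 0) {
        swa_avg <- swa_accumulate(swa_avg, model$pars, swa_n)
        swa_n <- swa_n + 1L
      }

      if (pr$correct_labels_at_end) {
        j <- pr$cycle
        sj_pars <- if (cfg$sj_source == "swa" && !is.null(swa_avg)) swa_avg
                   else model$pars
        f1s <- prs <- numeric(length(data))
        for (k in seq_along(data)) {
          rec <- data[[k]]
          Sj <- unet_predict(sj_pars, rec$image)
          best <- bank_best(bank, rec$id)
          worst <- bank_worst(bank, rec$id)
          Q <- switch(mode,
                      q_is_s = Sj,
                      q_is_sbest = best,
                      compensation(confidence_map(best, worst), best, Sj))
          labels[[rec$id]] <- update_labels(labels[[rec$id]], Q, j)
          gold <- sample_gold(rec)
          if (is.null(gold)) {
            f1s[k] <- NA_real_; prs[k] <- NA_real_
          } else {
            f1s[k] <- f1_score(labels[[rec$id]]$current, gold)
            prs[k] <- pr_auc(labels[[rec$id]]$current, gold)
          }
        }
        cy_rows[[length(cy_rows) + 1L]] <-
          data.frame(cycle = j, f1 = mean(f1s), pr_auc = mean(prs))
      }

      ep_rows[[i]] <- data.frame(epoch = pr$epoch, phase = pr$phase,
                                 cycle = pr$cycle, lr = pr$lr,
                                 train_loss = res$loss, test_loss = test_loss)
      if (verbose)
        message(sprintf("epoch %3d [%s c%d] lr=%.2e loss=%.4f",
                        pr$epoch, pr$phase, pr$cycle, pr$lr, res$loss))
    }

    report <- structure(
      list(epochs = do.call(rbind, ep_rows),
           cycles = if (length(cy_rows)) do.call(rbind, cy_rows)
                    else data.frame(cycle = integer(0), f1 = numeric(0),
                                    pr_auc = numeric(0)),
           mode = mode, seed = cfg$seed),
      class = "correction_report")
    list(model = model$pars, swa_model = swa_avg,
         labels = lapply(labels, `[[`, "current"),
         label_states = labels, report = report, cfg = cfg, mode = mode)
  })
}
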