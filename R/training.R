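# Optimization protocol: AdamW with cosine annealing, early stopping on
# validation loss, seeded replicate runs, and the component-ablation harness.

#' Training configuration
#'
#' @param learning_rate Initial AdamW learning rate (default 3e-4).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param max_epochs Cosine-annealing horizon and epoch cap (default 100).
#' @param batch_size Minibatch size (default 64; 128 also supported).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param min_delta Minimum validation-loss improvement that resets the
#'   patience counter (default 1e-4).
#' @param n_runs Number of seeded replicate runs (default 3).
#' @param base_seed First replicate seed; run r uses `base_seed + r - 1`.
#' @param augment List of train-time augmentation switches: `masking`
#'   (time/frequency span masking) and `mixup`.
#' @param mask_max_width,mask_n Masking span parameters.
#' @param mixup_alpha Beta(alpha, alpha) parameter for mixup draws.
#' @param ablation_flags List of component switches: `disable_AAE_weighting`,
#'   `disable_ALD_consistency`, `disable_DCA_gating`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, weight_decay = 1e-4,
                         max_epochs = 100L, batch_size = 64L, patience = 10L,
                         min_delta = 1e-4, n_runs = 3L, base_seed = 1L,
                         augment = list(masking = TRUE, mixup = FALSE),
                         mask_max_width = 4L, mask_n = 2L, mixup_alpha = 0.2,
                         ablation_flags = list(disable_AAE_weighting = FALSE,
                                               disable_ALD_consistency = FALSE,
                                               disable_DCA_gating = FALSE)) {
  stopifnot(learning_rate > 0, patience >= 1, n_runs >= 1)
  known <- c("disable_AAE_weighting", "disable_ALD_consistency", "disable_DCA_gating")
  if (!all(names(ablation_flags) %in% known)) {
    stop("unknown ablation flag: ",
         paste(setdiff(names(ablation_flags), known), collapse = ", "))
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), min_delta = min_delta,
                 n_runs = as.integer(n_runs), base_seed = as.integer(base_seed),
                 augment = augment, mask_max_width = as.integer(mask_max_width),
                 mask_n = as.integer(mask_n), mixup_alpha = mixup_alpha,
                 ablation_flags = ablation_flags),
            class = "train_config")
}

#' Cosine-annealed learning rate at an epoch
#'
#' `eta(e) = eta_min + (eta0 - eta_min)/2 * (1 + cos(pi * e / max_epochs))`
#' with `eta_min = 0`: exactly `eta0` at epoch 0 and 0 at `max_epochs`.
#'
#' @param epoch Epoch index in `0..max_epochs`.
#' @param config A [train_config()].
#' @param eta_min Floor learning rate (default 0; warm restarts are not
#'   used).
#' @return Learning rate.
#' @export
lr_at_epoch <- function(epoch, config, eta_min = 0) {
  stopifnot(epoch >= 0, epoch <= config$max_epochs)
  eta_min + (config$learning_rate - eta_min) / 2 *
    (1 + cos(pi * epoch / config$max_epochs))
}

#' Early-stopping decision
#'
#' Stops once the validation loss has failed to improve on the best value by
#' at least `min_delta` for `patience` consecutive epochs. An improvement of
#' exactly `min_delta` resets the counter.
#'
#' @param state List with `val_losses` (per-epoch validation losses so far).
#' @param config A [train_config()].
#' @return `TRUE` if training should stop.
#' @export
should_stop <- function(state, config) {
  v <- state$val_losses
  if (length(v) < 1) stop("at least one completed epoch is required")
  best <- v[1]; wait <- 0L
  for (x in v[-1]) {
    if (best - x >= config$min_delta) { best <- x; wait <- 0L } else wait <- wait + 1L
  }
  wait >= config$patience
}

# AdamW update over a named list of parameter matrices. `state` carries the
# first/second moment estimates and the step counter.
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * (mh / (sqrt(vh) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Accumulate gradient lists (by name).
acc_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  }
  total
}

# Gradients of the composite loss for one (possibly augmented) sample.
sample_grads <- function(params, X, ctx, target, config, flags, training) {
  tp <- tape_new()
  pid <- register_params(tp, params)
  out <- alht_cada_loss(tp, pid, X, ctx, target, config, flags, training)
  grads_by_id <- tp_backward(tp, out$loss)
  g <- lapply(pid, function(id) grads_by_id[[id]])
  list(grads = g, breakdown = out$breakdown,
       p_high = as.numeric(softmax_rows(tp_value(tp, out$forward$logits)))[2])
}

# Deterministic forward evaluation of a feature set: mean composite loss and
# per-window high-risk probabilities. No dropout, no augmentation.
evaluate_loss <- function(params, data, idx, config, flags) {
  tot <- c(cross_entropy = 0, consistency = 0, alignment = 0, total = 0)
  ph <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    tp <- tape_new()
    pid <- register_params(tp, params)
    target <- c(1 - data$labels[i], data$labels[i])
    out <- alht_cada_loss(tp, pid, data$features[[i]]$values, data$contexts[[i]],
                          target, config, flags, training = FALSE)
    tot <- tot + out$breakdown
    ph[k] <- as.numeric(softmax_rows(tp_value(tp, out$forward$logits)))[2]
  }
  list(breakdown = tot / length(idx), p_high = ph)
}

# Translate the configured ablation switches into forward-pass flags.
flags_from_config <- function(tc) {
  list(disable_AAE = isTRUE(tc$ablation_flags$disable_AAE_weighting),
       disable_ALD = isTRUE(tc$ablation_flags$disable_ALD_consistency),
       disable_DCA = isTRUE(tc$ablation_flags$disable_DCA_gating))
}

#' Train the screening model once
#'
#' Minibatch AdamW with cosine annealing and early stopping on validation
#' loss. Training and validation windows must come from disjoint subjects
#' (asserted). Masking and mixup augmentations apply to training batches
#' only. Fully reproducible from `seed`.
#'
#' @param model_cfg A [model_config()].
#' @param data Preprocessed cohort from [preprocess_cohort()] (`features`,
#'   `labels`, `subject_ids`, `contexts`).
#' @param train_subjects,val_subjects Disjoint subject-id vectors.
#' @param tc A [train_config()].
#' @param seed Integer seed for initialization, shuffling, dropout, and
#'   augmentation draws.
#' @param max_epochs Optional epoch cap overriding `tc$max_epochs` as the
#'   stopping bound (the cosine schedule still anneals over
#'   `tc$max_epochs`).
#' @return List with `params` (best-validation checkpoint), `history`
#'   (per-epoch train/validation loss breakdowns and learning rates),
#'   `best_epoch`, `stopped_epoch`, and `manifest`.
#' @export
train_once <- function(model_cfg, data, train_subjects, val_subjects, tc,
                       seed = tc$base_seed, max_epochs = tc$max_epochs) {
  if (length(intersect(train_subjects, val_subjects)) > 0) {
    stop("train and validation subject sets must be disjoint")
  }
  tr <- which(data$subject_ids %in% train_subjects)
  va <- which(data$subject_ids %in% val_subjects)
  if (length(tr) == 0 || length(va) == 0) stop("empty train or validation split")
  flags <- flags_from_config(tc)

  d_in <- ncol(data$features[[1]]$values)
  ctx_dim <- length(data$contexts[[1]])
  params <- init_alht_params(model_cfg, d_in, ctx_dim, seed = seed)
  opt <- list(t = 0L, m = list(), v = list())
  set.seed(seed + 5000L)

  history <- list()
  val_losses <- numeric()
  best <- list(loss = Inf, params = params, epoch = 0L)
  stopped <- max_epochs
  for (epoch in seq_len(max_epochs)) {
    lr <- lr_at_epoch(epoch - 1L, tc)
    order_idx <- sample(tr)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / tc$batch_size))
    ep_tot <- NULL
    for (b in batches) {
      gtot <- NULL
      bsum <- NULL
      for (i in b) {
        X <- data$features[[i]]$values
        y <- data$labels[i]
        target <- c(1 - y, y)
        ctx <- data$contexts[[i]]
        if (isTRUE(tc$augment$masking)) {
          X <- apply_masking(X, "time", tc$mask_max_width, tc$mask_n)
          X <- apply_masking(X, "frequency", tc$mask_max_width, tc$mask_n)
        }
        if (isTRUE(tc$augment$mixup)) {
          j <- b[sample.int(length(b), 1L)]
          lam <- stats::rbeta(1, tc$mixup_alpha, tc$mixup_alpha)
          yj <- data$labels[j]
          mixed <- mixup(X, data$features[[j]]$values, target, c(1 - yj, yj), lam)
          X <- mixed$features; target <- mixed$label
        }
        sg <- sample_grads(params, X, ctx, target, model_cfg, flags,
                           training = TRUE)
        gtot <- acc_grads(gtot, sg$grads)
        bsum <- if (is.null(bsum)) sg$breakdown else bsum + sg$breakdown
      }
      gtot <- lapply(gtot, function(g) g / length(b))
      upd <- adamw_step(params, gtot, opt, lr, tc$weight_decay)
      params <- upd$params; opt <- upd$state
      ep_tot <- if (is.null(ep_tot)) bsum / length(b) else ep_tot + bsum / length(b)
    }
    val <- evaluate_loss(params, data, va, model_cfg, flags)
    val_losses <- c(val_losses, val$breakdown[["total"]])
    history[[epoch]] <- list(epoch = epoch, lr = lr,
                             train = ep_tot / length(batches),
                             val = val$breakdown)
    if (val$breakdown[["total"]] < best$loss) {
      best <- list(loss = val$breakdown[["total"]], params = params,
                   epoch = epoch)
    }
    if (should_stop(list(val_losses = val_losses), tc)) { stopped <- epoch; break }
  }
  list(params = best$params, history = history, best_epoch = best$epoch,
       stopped_epoch = stopped,
       manifest = list(seed = seed, flags = flags,
                       train_subjects = sort(train_subjects),
                       val_subjects = sort(val_subjects),
                       augmentation = tc$augment,
                       eval_augmentation = list(masking = FALSE, mixup = FALSE),
                       optimizer = list(name = "AdamW", lr = tc$learning_rate,
                                        weight_decay = tc$weight_decay),
                       schedule = list(name = "cosine", max_epochs = tc$max_epochs)))
}

# Evaluate a checkpoint on a window index set -> metrics_report.
evaluate_checkpoint <- function(params, data, idx, model_cfg, flags = list()) {
  pred <- predict_windows(params, data$features[idx], model_cfg,
                          contexts = data$contexts[idx], flags = flags)
  confusion_metrics(data$labels[idx], pred$label, scores = pred$p_high)
}

#' Seeded replicate training runs
#'
#' Trains `n_runs` models with seeds `base_seed + 0 .. base_seed + n_runs-1`,
#' evaluates each on the validation subjects, and aggregates the metric
#' reports (mean and sample standard deviation across runs).
#'
#' @inheritParams train_once
#' @return List with `runs` (per-run checkpoint, history, and
#'   `metrics_report`) and `aggregate` (the across-run report from
#'   [aggregate_runs()]).
#' @export
run_replicates <- function(model_cfg, data, train_subjects, val_subjects, tc,
                           max_epochs = tc$max_epochs) {
  flags <- flags_from_config(tc)
  runs <- lapply(seq_len(tc$n_runs), function(r) {
    fit <- train_once(model_cfg, data, train_subjects, val_subjects, tc,
                      seed = tc$base_seed + r - 1L, max_epochs = max_epochs)
    rep <- evaluate_checkpoint(fit$params, data,
                               which(data$subject_ids %in% val_subjects),
                               model_cfg, flags)
    list(fit = fit, metrics = rep)
  })
  list(runs = runs, aggregate = aggregate_runs(lapply(runs, `[[`, "metrics")))
}

#' Component ablation suite
#'
#' Trains and evaluates the full model and the three single-component
#' removals: without dynamic frame weighting (advanced acoustic encoding),
#' without the consistency/alignment objectives (adaptive linguistic
#' decoding, `lambda2 = 0`), and without the context gate (dynamic contextual
#' adaptation, raw context used). Emits one row per variant.
#'
#' @inheritParams train_once
#' @return List with `table` (data frame: variant, accuracy, sensitivity,
#'   specificity, f1, auc, with across-run sd columns) and `reports` (the
#'   aggregated `metrics_report` per variant).
#' @export
ablation_suite <- function(model_cfg, data, train_subjects, val_subjects, tc,
                           max_epochs = tc$max_epochs) {
  variants <- list(
    full = list(),
    without_AAE = list(disable_AAE_weighting = TRUE),
    without_ALD = list(disable_ALD_consistency = TRUE),
    without_DCA = list(disable_DCA_gating = TRUE)
  )
  reports <- lapply(names(variants), function(vn) {
    tc_v <- tc
    tc_v$ablation_flags <- utils::modifyList(
      list(disable_AAE_weighting = FALSE, disable_ALD_consistency = FALSE,
           disable_DCA_gating = FALSE), variants[[vn]])
    run_replicates(model_cfg, data, train_subjects, val_subjects, tc_v,
                   max_epochs = max_epochs)$aggregate
  })
  names(reports) <- names(variants)
  tab <- do.call(rbind, lapply(names(reports), function(vn) {
    r <- reports[[vn]]
    data.frame(variant = vn,
               accuracy = r$mean[["accuracy"]], accuracy_sd = r$sd[["accuracy"]],
               sensitivity = r$mean[["sensitivity"]], specificity = r$mean[["specificity"]],
               f1 = r$mean[["f1"]], auc = r$mean[["auc"]])
  }))
  list(table = tab, reports = reports)
}

#' Stratified subject-level train/validation split
#'
#' Deterministically assigns whole subjects to splits, stratified by class so
#' both labels occur on each side. Windows from one subject never straddle
#' splits.
#'
#' @param cohort List of `labeled_recording`s.
#' @param val_fraction Fraction of subjects per class held out (default
#'   1/3).
#' @return List with `train` and `val` subject-id vectors.
#' @export
subject_split <- function(cohort, val_fraction = 1 / 3) {
  ids <- vapply(cohort, function(r) r$subject_id, "")
  labs <- vapply(cohort, function(r) r$label, 0L)
  val <- unlist(lapply(unique(labs), function(cl) {
    g <- ids[labs == cl]
    g[seq_len(max(1L, floor(length(g) * val_fraction)))]
  }))
  list(train = setdiff(ids, val), val = val)
}
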