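# Training protocol: schedule, early stopping, reproducibility, overfitting
# sanity, replicate seeding, and the ablation harness.

test_that("the cosine schedule hits its endpoints and midpoint exactly", {
  tc <- train_config()
  expect_equal(lr_at_epoch(0, tc), 3e-4)
  expect_equal(lr_at_epoch(100, tc), 0)
  expect_equal(lr_at_epoch(50, tc), 1.5e-4)
  curve <- vapply(0:100, lr_at_epoch, 0, config = tc)
  expect_true(all(diff(curve) <= 0))
  expect_error(lr_at_epoch(101, tc))
})

test_that("early stopping counts non-improving epochs correctly", {
  tc <- train_config(patience = 10L, min_delta = 1e-4)
  expect_false(should_stop(list(val_losses = seq(1, 0.1, length.out = 50)), tc))
  const <- rep(1, 11)                       # 1 baseline + 10 flat epochs
  expect_true(should_stop(list(val_losses = const), tc))
  expect_false(should_stop(list(val_losses = const[1:10]), tc))
  # improvement of exactly min_delta resets the counter (exact binary values)
  tcq <- train_config(patience = 3L, min_delta = 0.25)
  v <- c(1, 1, 1, 0.75, 0.75, 0.75)
  expect_false(should_stop(list(val_losses = v), tcq))
  expect_true(should_stop(list(val_losses = c(1, 1, 1, 1)), tcq))
  expect_error(should_stop(list(val_losses = numeric()), tc))
})

test_that("train/validation splits never share a subject", {
  dat <- small_preprocessed()
  expect_length(intersect(dat$split$train, dat$split$val), 0)
  tc <- train_config(n_runs = 1L)
  expect_error(train_once(model_config(tiny_preset = TRUE), dat$pp,
                          dat$split$train, c(dat$split$val, dat$split$train[1]),
                          tc), "disjoint")
  expect_error(train_once(model_config(tiny_preset = TRUE), dat$pp,
                          dat$split$train, "S99", tc), "empty")
})

test_that("a tiny model memorizes a small separable cohort", {
  dat <- small_preprocessed()
  mc <- model_config(tiny_preset = TRUE)
  tc <- train_config(n_runs = 1L, base_seed = 2L)
  fit <- train_once(mc, dat$pp, dat$split$train, dat$split$val, tc,
                    seed = 2L, max_epochs = 15L)
  tr_idx <- which(dat$pp$subject_ids %in% dat$split$train)
  rep <- eegrisk:::evaluate_checkpoint(fit$params, dat$pp, tr_idx, mc)
  expect_gte(rep$accuracy, 0.99)
})

test_that("the same seed reproduces training bit-identically", {
  dat <- small_preprocessed()
  mc <- model_config(tiny_preset = TRUE)
  tc <- train_config(n_runs = 1L)
  f1 <- train_once(mc, dat$pp, dat$split$train, dat$split$val, tc,
                   seed = 9L, max_epochs = 2L)
  f2 <- train_once(mc, dat$pp, dat$split$train, dat$split$val, tc,
                   seed = 9L, max_epochs = 2L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  f3 <- train_once(mc, dat$pp, dat$split$train, dat$split$val, tc,
                   seed = 10L, max_epochs = 2L)
  expect_false(identical(f1$params, f3$params))
})

test_that("the training manifest pins augmentation to the training path", {
  dat <- small_preprocessed()
  tc <- train_config(n_runs = 1L)
  fit <- train_once(model_config(tiny_preset = TRUE), dat$pp,
                    dat$split$train, dat$split$val, tc, seed = 1L,
                    max_epochs = 1L)
  expect_true(fit$manifest$augmentation$masking)
  expect_false(fit$manifest$eval_augmentation$masking)
  expect_false(fit$manifest$eval_augmentation$mixup)
})

test_that("replicates use consecutive seeds and aggregate symmetrically", {
  dat <- small_preprocessed()
  mc <- model_config(tiny_preset = TRUE)
  tc <- train_config(n_runs = 2L, base_seed = 21L)
  res <- run_replicates(mc, dat$pp, dat$split$train, dat$split$val, tc,
                        max_epochs = 2L)
  seeds <- vapply(res$runs, function(r) r$fit$manifest$seed, 0)
  expect_equal(seeds, c(21, 22))
  accs <- vapply(res$runs, function(r) r$metrics$accuracy, 0)
  expect_equal(res$aggregate$mean[["accuracy"]], mean(accs))
  # single-run aggregate equals the run itself
  tc1 <- train_config(n_runs = 1L, base_seed = 21L)
  res1 <- run_replicates(mc, dat$pp, dat$split$train, dat$split$val, tc1,
                         max_epochs = 2L)
  expect_equal(res1$aggregate$mean[["accuracy"]], res1$runs[[1]]$metrics$accuracy)
  expect_true(res1$aggregate$single_run)
})

test_that("unknown ablation flags are rejected", {
  expect_error(train_config(ablation_flags = list(disable_everything = TRUE)),
               "unknown ablation flag")
})

test_that("the ablation suite emits the four-variant table", {
  dat <- small_preprocessed()
  mc <- model_config(tiny_preset = TRUE)
  tc <- train_config(n_runs = 1L, base_seed = 5L)
  ab <- ablation_suite(mc, dat$pp, dat$split$train, dat$split$val, tc,
                       max_epochs = 2L)
  expect_equal(nrow(ab$table), 4L)
  expect_equal(ab$table$variant, c("full", "without_AAE", "without_ALD",
                                   "without_DCA"))
  expect_true(all(c("accuracy", "sensitivity", "specificity", "f1", "auc")
                  %in% names(ab$table)))
})

test_that("disabling the context gate makes training invariant to gate parameters", {
  dat <- small_preprocessed()
  mc <- model_config(tiny_preset = TRUE)
  params <- init_alht_params(mc, ncol(dat$pp$features[[1]]$values),
                             length(dat$pp$contexts[[1]]), seed = 3L)
  X <- dat$pp$features[[1]]$values
  ctx <- dat$pp$contexts[[1]]
  run <- function(p, flags) {
    tp <- tape_new()
    pid <- register_params(tp, p)
    tp_value(tp, alht_cada_forward(tp, pid, X, ctx, mc, flags)$logits)
  }
  off <- list(disable_DCA = TRUE)
  base <- run(params, off)
  pert <- params
  pert$gate_Wc <- pert$gate_Wc + 3
  pert$gate_bc <- pert$gate_bc - 7
  expect_identical(run(pert, off), base)
  # with the gate on, the same perturbation changes the output
  expect_false(identical(run(pert, list()), run(params, list())))
})
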