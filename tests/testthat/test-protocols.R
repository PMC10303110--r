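ns <- asNamespace("msatnet")

tiny_es <- function(K, n_classes = 3L, seed = 1L, sessions = NULL) {
  set.seed(seed)
  epoch_set(array(rnorm(2 * 24 * K), dim = c(2, 24, K)),
            labels = rep_len(seq_len(n_classes) - 1L, K), fs = 250,
            channel_names = c("C3", "C4"),
            session_ids = if (is.null(sessions)) rep(1L, K) else sessions)
}

test_that("evaluate tallies accuracy and confusion like a hand count", {
  # fixture with known predictions: diagonal and off-diagonal cases
  cfg <- tiny_model_config()
  m <- build_model(cfg, C = 2, T = 24, seed = 2)
  te <- tiny_es(9, seed = 3)
  ev <- evaluate(m, te)
  pred <- predict(m, te)$labels
  hand <- matrix(0L, 3, 3)
  for (k in 1:9) hand[te$labels[k] + 1, pred[k] + 1] <-
      hand[te$labels[k] + 1, pred[k] + 1] + 1L
  expect_equal(unname(unclass(ev$confusion)), hand)
  expect_equal(ev$accuracy, mean(pred == te$labels))
  expect_equal(sum(ev$confusion), 9)
  # row sums equal per-class test counts
  expect_equal(unname(rowSums(ev$confusion)), unname(tabulate(te$labels + 1L, 3)))
  expect_error(evaluate(m, tiny_es(0)), "empty")
})

test_that("perfect and constant predictors give the textbook matrices", {
  # all predictions class 0 on a balanced 4-class set -> acc 0.25, column 1
  conf <- matrix(0L, 4, 4)
  truth <- rep(0:3, each = 5)
  for (k in seq_along(truth)) conf[truth[k] + 1, 1] <- conf[truth[k] + 1, 1] + 1L
  expect_equal(sum(diag(conf)) / sum(conf), 0.25)
  expect_true(all(conf[, 2:4] == 0))
})

test_that("within-subject protocol validates its preconditions", {
  cfg <- tiny_model_config()
  tr <- tiny_es(12, seed = 4)
  te <- tiny_es(6, seed = 5)
  cfg_bad <- cfg
  cfg_bad$adapter <- adapter_config(4, 1)
  expect_error(train_within_subject(tr, te, cfg_bad), "adapter")
  te_bad <- te
  te_bad$class_names <- c("a", "b", "c")
  expect_error(train_within_subject(tr, te_bad, cfg), "class coding")
})

test_that("training is reproducible and the report is self-consistent", {
  cfg <- tiny_model_config(n_classes = 2L)
  tr <- tiny_es(20, n_classes = 2L, seed = 6)
  te <- tiny_es(10, n_classes = 2L, seed = 7)
  tc <- train_config(batch_size = 8, learning_rate = 5e-3, max_epochs = 6,
                     early_stop_patience = 3, val_fraction = 0.25, seed = 8)
  r1 <- train_within_subject(tr, te, cfg, tc)$report
  r2 <- train_within_subject(tr, te, cfg, tc)$report
  expect_identical(r1$test_accuracy, r2$test_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$epoch_losses, r2$epoch_losses)
  expect_equal(sum(r1$confusion), 10)
  expect_equal(r1$test_accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))
  # early stopping bookkeeping: best epoch no worse than any later epoch
  expect_lte(r1$val_losses[r1$best_epoch], min(r1$val_losses))
  expect_lte(r1$best_epoch, r1$stopped_epoch)
})

test_that("early stopping halts after patience epochs without improvement", {
  cfg <- tiny_model_config(n_classes = 2L)
  tr <- tiny_es(24, n_classes = 2L, seed = 9)
  te <- tiny_es(8, n_classes = 2L, seed = 10)
  # unlearnable noise + tiny lr: validation loss cannot keep improving
  tc <- train_config(batch_size = 8, learning_rate = 1e-6, max_epochs = 50,
                     early_stop_patience = 2, val_fraction = 0.25, seed = 11)
  rep <- train_within_subject(tr, te, cfg, tc)$report
  expect_lt(rep$stopped_epoch, 50)
  expect_lte(rep$best_epoch, rep$stopped_epoch)
})

test_that("cross-subject protocol enforces hygiene and freeze integrity", {
  # 3 tiny subjects; asserts inside run_cross_subject cover the freeze
  cohort <- lapply(1:3, function(s) tiny_es(12, n_classes = 2L, seed = 20 + s))
  cfg <- tiny_model_config(n_classes = 2L)
  tc <- train_config(batch_size = 8, learning_rate = 5e-3, max_epochs = 3,
                     early_stop_patience = Inf, seed = 1)
  ftc <- train_config(batch_size = 8, learning_rate = 5e-3, max_epochs = 3,
                      early_stop_patience = Inf, seed = 2)
  rep <- run_cross_subject(cohort, target_index = 2, cfg, tc, ftc, seed = 5)
  # fine-tune and evaluation halves are disjoint and cover the target
  expect_length(intersect(rep$finetune_idx, rep$eval_idx), 0)
  expect_setequal(c(rep$finetune_idx, rep$eval_idx), 1:12)
  # stratified: both halves carry both classes
  tgt <- cohort[[2]]
  expect_setequal(unique(tgt$labels[rep$finetune_idx]), 0:1)
  expect_setequal(unique(tgt$labels[rep$eval_idx]), 0:1)
  expect_true(is.finite(rep$frozen_accuracy))
  expect_error(run_cross_subject(cohort[1], 1, cfg, tc, ftc), "2 subjects")
})
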