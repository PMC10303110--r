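#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.0008, batch size 64, up to 1000 epochs with early stopping on a
#' stratified validation split of the training set, and the max-norm
#' constraint on the final dense layer applied after every optimizer step.
#'
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam learning rate (default 0.0008).
#' @param optimizer only \code{"adam"}.
#' @param max_epochs maximum training epochs (default 1000).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 50); \code{Inf} disables early stopping.
#' @param val_fraction fraction of the training set held out for validation
#'   (default 0.2, stratified by class); must be in (0, 1) when early
#'   stopping is enabled.
#' @param seed integer seed covering the split, shuffling and dropout.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 8e-4,
                         optimizer = "adam", max_epochs = 1000L,
                         early_stop_patience = 50L, val_fraction = 0.2,
                         seed = 1L) {
  assert_count(batch_size, "batch_size")
  if (!identical(optimizer, "adam"))
    stop_validation("only the adam optimizer is supported")
  assert_count(max_epochs, "max_epochs")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_validation("learning_rate must be > 0")
  if (is.finite(early_stop_patience)) {
    assert_count(early_stop_patience, "early_stop_patience", min = 1L)
    if (!is.numeric(val_fraction) || val_fraction <= 0 || val_fraction >= 1)
      stop_validation("val_fraction must lie in (0, 1) when early stopping",
                      " is enabled")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

cross_entropy <- function(probs, labels) {
  idx <- cbind(labels + 1L, seq_along(labels))
  -mean(log(pmax(probs[idx], 1e-12)))
}

stratified_indices <- function(labels, fraction) {
  picked <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n <- max(1L, round(fraction * length(idx)))
    picked <- c(picked, sample(idx, n))
  }
  sort(picked)
}

eval_loss <- function(model, x, y, batch_size = 256L) {
  K <- dim(x)[3]
  total <- 0
  for (start in seq(1L, K, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, K)
    logits <- model_forward(model, x[, , idx, drop = FALSE], training = FALSE)
    probs <- softmax_cols(logits)
    total <- total + cross_entropy(probs, y[idx]) * length(idx)
  }
  total / K
}

# Core minibatch training loop: cross-entropy + Adam + max-norm + early
# stopping with best-weight restoration. Frozen modules are skipped by the
# optimizer and keep their batch-norm statistics fixed.
fit_model <- function(model, es, tc) {
  set.seed(derive_seed(tc$seed, 41L))
  x <- es$data
  y <- es$labels
  K <- n_trials(es)
  use_es <- is.finite(tc$early_stop_patience)
  if (use_es) {
    val_idx <- stratified_indices(y, tc$val_fraction)
    tr_idx <- setdiff(seq_len(K), val_idx)
  } else {
    val_idx <- integer()
    tr_idx <- seq_len(K)
  }
  if (length(tr_idx) < 1) stop_validation("training split is empty")
  mods <- model_modules(model)
  state_holder <- c(model$stages, if (!is.null(model$adapter))
    list(adapter = model$adapter))
  dense <- model$stages$dense
  step <- 0L
  best_val <- Inf
  best_state <- NULL
  best_epoch <- 0L
  since_best <- 0L
  epoch_losses <- numeric()
  val_losses <- numeric()
  n_classes <- model$cfg$n_classes
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    for (start in seq(1L, length(ord), by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
      xb <- x[, , idx, drop = FALSE]
      yb <- y[idx]
      logits <- model_forward(model, xb, training = TRUE)
      probs <- softmax_cols(logits)
      ep_loss <- ep_loss + cross_entropy(probs, yb) * length(idx)
      onehot <- matrix(0, n_classes, length(idx))
      onehot[cbind(yb + 1L, seq_along(idx))] <- 1
      dlogits <- (probs - onehot) / length(idx)
      for (m in mods) for (p in m$param_names) m[[paste0("g_", p)]] <- NULL
      model_backward(model, dlogits)
      step <- step + 1L
      adam_step(mods, tc$learning_rate, step)
      if (!dense$frozen && !is.null(dense$max_norm))
        dense$W <- apply_max_norm(dense$W, dense$max_norm)
    }
    epoch_losses <- c(epoch_losses, ep_loss / length(tr_idx))
    if (use_es) {
      vl <- eval_loss(model, x[, , val_idx, drop = FALSE], y[val_idx])
      val_losses <- c(val_losses, vl)
      if (vl < best_val - 1e-9) {
        best_val <- vl
        best_epoch <- epoch
        best_state <- lapply(state_holder, get_state)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= tc$early_stop_patience) break
      }
    }
  }
  stopped_epoch <- length(epoch_losses)
  if (use_es && !is.null(best_state)) {
    for (nm in names(state_holder))
      set_state(state_holder[[nm]], best_state[[nm]])
  } else {
    best_epoch <- stopped_epoch
  }
  list(epoch_losses = epoch_losses, val_losses = val_losses,
       stopped_epoch = stopped_epoch, best_epoch = best_epoch)
}

fit_report <- function(model, history, acc, confusion, extra = list()) {
  audit <- parameter_audit(model)
  counts <- tapply(audit$count, sub("/.*", "", audit$module), sum)
  rep <- c(list(
    epoch_losses = history$epoch_losses,
    val_losses = history$val_losses,
    stopped_epoch = history$stopped_epoch,
    best_epoch = history$best_epoch,
    test_accuracy = acc,
    confusion = confusion,
    parameter_audit = as.list(counts),
    config_hash = hash_object(model$cfg)
  ), extra)
  class(rep) <- "fit_report"
  rep
}

#' @export
print.fit_report <- function(x, ...) {
  cat("fit_report: accuracy", sprintf("%.4f", x$test_accuracy),
      "after", x$stopped_epoch, "epochs (best", x$best_epoch, ")\n")
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Accuracy and confusion matrix on a test set
#'
#' @param model an \code{msat_model}.
#' @param test an [epoch_set()] with at least one trial.
#' @return list with \code{accuracy} (correct/total) and \code{confusion}
#'   (\code{[n_classes x n_classes]} integer matrix,
#'   \code{confusion[i, j]} = trials of true class \code{i-1} predicted as
#'   \code{j-1}).
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "msat_model"), inherits(test, "epoch_set"))
  if (n_trials(test) == 0) stop_validation("test set is empty")
  pred <- predict(model, test)
  n_cl <- model$cfg$n_classes
  confusion <- matrix(0L, n_cl, n_cl,
                      dimnames = list(truth = seq_len(n_cl) - 1L,
                                      predicted = seq_len(n_cl) - 1L))
  for (k in seq_len(n_trials(test)))
    confusion[test$labels[k] + 1L, pred$labels[k] + 1L] <-
      confusion[test$labels[k] + 1L, pred$labels[k] + 1L] + 1L
  list(accuracy = sum(diag(confusion)) / sum(confusion),
       confusion = confusion)
}

#' Within-subject training protocol
#'
#' Trains the MSFE + ATT classifier (no subject adapter) on one subject's
#' training trials with cross-entropy, Adam, the max-norm constraint and
#' early stopping on a stratified validation split, then evaluates once on
#' the held-out test trials. Fully reproducible given the configuration and
#' seed.
#'
#' @param train,test [epoch_set()]s sharing channels, samples and class
#'   coding.
#' @param model_cfg an [msat_config()] without an adapter.
#' @param tc a [train_config()].
#' @return list with \code{model} and \code{report} (a \code{fit_report}).
#' @export
train_within_subject <- function(train, test, model_cfg, tc = train_config()) {
  stopifnot(inherits(train, "epoch_set"), inherits(test, "epoch_set"),
            inherits(model_cfg, "msat_config"))
  if (!is.null(model_cfg$adapter))
    stop_validation("the within-subject protocol does not use the subject",
                    " adapter; remove it from the configuration")
  if (!identical(train$class_names, test$class_names))
    stop_validation("train and test class coding differ")
  if (!identical(dim(train$data)[1:2], dim(test$data)[1:2]))
    stop_validation("train and test shapes differ")
  model <- build_model(model_cfg, dim(train$data)[1], dim(train$data)[2],
                       seed = tc$seed)
  history <- fit_model(model, train, tc)
  ev <- evaluate(model, test)
  list(model = model,
       report = fit_report(model, history, ev$accuracy, ev$confusion))
}

#' Cross-subject pretrain / adapter fine-tune protocol
#'
#' The four-step procedure: (1) the target subject's trials are split in
#' half, class-stratified by seed — one half for fine-tuning, one for
#' evaluation; (2) the model is pretrained on all pooled source-subject
#' trials, updating all parameters; (3) a subject adapter (identity at
#' initialization) is inserted and only its parameters are fine-tuned on the
#' target fine-tuning half; (4) the adapted model is evaluated on the
#' held-out target half. Non-adapter parameters are asserted bit-identical
#' across steps 3-4.
#'
#' @param cohort list of per-subject [epoch_set()]s (>= 2 subjects).
#' @param target_index which subject is the target domain.
#' @param model_cfg an [msat_config()] without an adapter (the adapter is
#'   inserted after pretraining; \code{adapter_cfg} controls its size).
#' @param tc pretraining [train_config()].
#' @param finetune_tc fine-tuning [train_config()] (default: same learning
#'   rate, 100 epochs, patience 20).
#' @param seed seed for the target half-split and adapter initialization.
#' @param adapter_cfg optional [adapter_config()].
#' @return a \code{fit_report} with extra fields \code{frozen_accuracy}
#'   (pretrained model on the evaluation half, before fine-tuning),
#'   \code{finetune_idx} / \code{eval_idx} (disjoint target trial indices)
#'   and \code{model}.
#' @export
run_cross_subject <- function(cohort, target_index, model_cfg,
                              tc = train_config(),
                              finetune_tc = NULL, seed = 1L,
                              adapter_cfg = NULL) {
  if (!is.list(cohort) || length(cohort) < 2L)
    stop_validation("cohort must contain at least 2 subjects")
  assert_count(target_index, "target_index")
  if (target_index > length(cohort))
    stop_validation("target_index out of range")
  if (!is.null(model_cfg$adapter))
    stop_validation("configure the adapter via adapter_cfg; it is inserted",
                    " after pretraining")
  if (is.null(finetune_tc))
    finetune_tc <- train_config(batch_size = tc$batch_size,
                                learning_rate = tc$learning_rate,
                                max_epochs = 100L, early_stop_patience = 20L,
                                val_fraction = tc$val_fraction,
                                seed = derive_seed(seed, 53L))
  target <- cohort[[target_index]]
  source <- combine_epochs(cohort[-target_index])

  # (2) pretrain on the pooled source domain
  model <- build_model(model_cfg, dim(source$data)[1], dim(source$data)[2],
                       seed = tc$seed)
  history_pre <- fit_model(model, source, tc)

  # (1) class-stratified half split of the target subject
  set.seed(derive_seed(seed, 47L))
  finetune_idx <- stratified_indices(target$labels, 0.5)
  eval_idx <- setdiff(seq_len(n_trials(target)), finetune_idx)
  stopifnot(length(intersect(finetune_idx, eval_idx)) == 0)
  subset_es <- function(es, idx)
    epoch_set(es$data[, , idx, drop = FALSE], es$labels[idx], es$fs,
              es$channel_names, es$subject_id, es$session_ids[idx],
              es$class_names)
  target_fit <- subset_es(target, finetune_idx)
  target_eval <- subset_es(target, eval_idx)

  # (3) insert identity-at-init adapter, freeze everything else, fine-tune
  insert_adapters(model, adapter_cfg, seed = seed)
  frozen_eval <- evaluate(model, target_eval)
  freeze_all_but_adapters(model)
  backbone_before <- lapply(model$stages, get_state)
  history_ft <- fit_model(model, target_fit, finetune_tc)
  backbone_after <- lapply(model$stages, get_state)
  delta <- max_state_delta(backbone_before, backbone_after)
  if (delta != 0)
    stop("freeze integrity violated: non-adapter parameters moved by ", delta)

  # (4) evaluate on the held-out target half
  ev <- evaluate(model, target_eval)
  fit_report(model, history_ft, ev$accuracy, ev$confusion,
             extra = list(frozen_accuracy = frozen_eval$accuracy,
                          pretrain_epochs = history_pre$stopped_epoch,
                          finetune_idx = finetune_idx, eval_idx = eval_idx,
                          model = model))
}

max_state_delta <- function(a, b) {
  m <- 0
  for (i in seq_along(a))
    for (j in seq_along(a[[i]]))
      for (p in names(a[[i]][[j]]))
        m <- max(m, max(abs(a[[i]][[j]][[p]] - b[[i]][[j]][[p]])))
  m
}
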