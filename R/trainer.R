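# Training orchestration: the two-level adaptive early-stopping loop with
# gradual cross-entropy epoch losses. The loop talks to models through a
# tiny S3 interface (fit_batch / val_loss / predict_probs / ...) so that the
# convolutional network and scripted stub models are interchangeable; stubs
# make the stopping logic testable without optimisation noise.

#' Model interface generics
#'
#' `fit_batch` performs one optimisation step and returns
#' `list(model, loss)`; `val_loss` returns the scalar validation loss
#' (`kind` distinguishes the epoch-level "macro" check from the in-epoch
#' "micro" check, stub models may script them separately);
#' `predict_probs` returns an `N x C` probability matrix;
#' `snapshot_params`/`restore_params` support best-checkpoint restoration;
#' `model_needs_images` says whether the training loop must load pixel data
#' (stubs do not); `model_num_classes` reports the output width.
#'
#' @param model a model object (`dense_net`, `scripted_model`, ...).
#' @param xb,yb batch images `(H, W, C, n)` and 1-based labels.
#' @param x,y validation images and 1-based labels.
#' @param lr learning rate.
#' @param kind `"macro"` or `"micro"` validation check.
#' @param params a snapshot previously returned by `snapshot_params`.
#' @param ... passed to methods.
#' @name model-interface
NULL

#' @rdname model-interface
#' @export
fit_batch <- function(model, xb, yb, lr, ...) UseMethod("fit_batch")

#' @rdname model-interface
#' @export
val_loss <- function(model, x, y, kind = "macro", ...) UseMethod("val_loss")

#' @rdname model-interface
#' @export
snapshot_params <- function(model) UseMethod("snapshot_params")

#' @rdname model-interface
#' @export
restore_params <- function(model, params) UseMethod("restore_params")

#' @rdname model-interface
#' @export
model_needs_images <- function(model) UseMethod("model_needs_images")

#' @rdname model-interface
#' @export
model_num_classes <- function(model) UseMethod("model_num_classes")

#' @export
model_needs_images.default <- function(model) TRUE

#' @export
fit_batch.dense_net <- function(model, xb, yb, lr, ...) {
  train_step(model, xb, yb, lr)
}

#' @export
val_loss.dense_net <- function(model, x, y, kind = "macro", ...) {
  p <- predict_probs(model, x)
  -mean(log(pmax(p[cbind(seq_along(y), y)], .CE_PROB_FLOOR)))
}

#' @export
snapshot_params.dense_net <- function(model) model_params(model)

#' @export
restore_params.dense_net <- function(model, params) {
  model_set_params(model, params)
}

#' @export
model_num_classes.dense_net <- function(model) model$plan$num_classes

#' @rdname model-interface
#' @export
predict_probs <- function(model, x, ...) UseMethod("predict_probs")

#' @export
predict_probs.dense_net <- function(model, x, batch_size = 32L, ...) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[4]
  out <- matrix(NA_real_, N, model$plan$num_classes)
  for (start in seq(1L, N, by = batch_size)) {
    end <- min(N, start + batch_size - 1L)
    xb <- x[, , , start:end, drop = FALSE]
    out[start:end, ] <- t(model_forward(model, xb, keep = FALSE)$probs)
  }
  out
}

#' Scripted stub model
#'
#' A model whose validation losses are read from prearranged sequences
#' instead of being computed: `macro_losses[k]` is returned by the k-th
#' epoch-level check and `micro_losses[k]` by the k-th in-epoch check (each
#' sequence repeats its last value when exhausted). `fit_batch` leaves the
#' model untouched and reports `train_loss`. Used to exercise the early
#' stopping machinery deterministically.
#'
#' @param macro_losses numeric vector of epoch-level validation losses.
#' @param micro_losses numeric vector of in-epoch validation losses.
#' @param train_loss constant per-batch training loss.
#' @param num_classes output width reported to the trainer.
#' @return object of class `scripted_model`.
#' @export
scripted_model <- function(macro_losses, micro_losses = numeric(0),
                           train_loss = 1.0, num_classes = 2L) {
  env <- new.env(parent = emptyenv())
  env$macro_i <- 0L
  env$micro_i <- 0L
  structure(list(macro_losses = macro_losses, micro_losses = micro_losses,
                 train_loss = train_loss, num_classes = as.integer(num_classes),
                 env = env),
            class = "scripted_model")
}

pop_scripted <- function(vals, i) {
  if (length(vals) == 0L) stop("scripted_model: no losses scripted")
  vals[min(i, length(vals))]
}

#' @export
fit_batch.scripted_model <- function(model, xb, yb, lr, ...) {
  list(model = model, loss = model$train_loss)
}

#' @export
val_loss.scripted_model <- function(model, x, y, kind = "macro", ...) {
  if (kind == "macro") {
    model$env$macro_i <- model$env$macro_i + 1L
    pop_scripted(model$macro_losses, model$env$macro_i)
  } else {
    model$env$micro_i <- model$env$micro_i + 1L
    pop_scripted(model$micro_losses, model$env$micro_i)
  }
}

#' @export
snapshot_params.scripted_model <- function(model) NULL

#' @export
restore_params.scripted_model <- function(model, params) model

#' @export
model_needs_images.scripted_model <- function(model) FALSE

#' @export
model_num_classes.scripted_model <- function(model) model$num_classes

#' Stub predictor with fixed outputs
#'
#' Emits one-hot probabilities for a prearranged 0-based label sequence,
#' ignoring its inputs; handy for validating [evaluate()] bookkeeping
#' (a stub scripted with the true labels scores 1.0 everywhere, a
#' majority-class stub scores the majority fraction).
#'
#' @param labels 0-based labels to emit, in record order.
#' @param num_classes number of classes.
#' @return object of class `stub_predictor`.
#' @export
stub_predictor <- function(labels, num_classes) {
  structure(list(labels = as.integer(labels),
                 num_classes = as.integer(num_classes)),
            class = "stub_predictor")
}

#' @export
predict_probs.stub_predictor <- function(model, x, ...) {
  n <- if (is.null(dim(x))) as.integer(x) else dim(x)[4]
  if (n != length(model$labels)) stop("stub_predictor: length mismatch")
  p <- matrix(0, n, model$num_classes)
  p[cbind(seq_len(n), model$labels + 1L)] <- 1
  p
}

#' @export
model_needs_images.stub_predictor <- function(model) FALSE

#' @export
model_num_classes.stub_predictor <- function(model) model$num_classes

# ---------------------------------------------------------------------------

#' Training run configuration
#'
#' @param task classification task: `"five"`, `"three"` or `"two"`.
#' @param max_epochs epoch budget (the start value the stopping rule prunes).
#' @param batch_size examples per optimisation step.
#' @param micro_check_every run the in-epoch validation check every this
#'   many batches.
#' @param macro_window,micro_window consecutive stalled checks that trigger
#'   the epoch-level / in-epoch stop.
#' @param min_epochs warm-up epochs before an epoch-level stop is allowed.
#' @param learning_rate SGD step size alpha.
#' @param seed master seed for shuffling, dropout and any model updates.
#' @param micro_val_size size of the fixed held-out validation mini-batch
#'   used by the micro check.
#' @param patience_mode threshold rule passed to [init_patience()].
#' @param out_dir if set, the trace CSV is written here.
#' @param checkpoint_path if set, the restored best model is saved here.
#' @return object of class `run_config`.
#' @export
run_config <- function(task = "five", max_epochs = 50L, batch_size = 32L,
                       micro_check_every = 10L, macro_window = 3L,
                       micro_window = 3L, min_epochs = 3L,
                       learning_rate = 0.001, seed = 1L,
                       micro_val_size = 32L,
                       patience_mode = "incremental",
                       out_dir = NULL, checkpoint_path = NULL) {
  if (!(max_epochs >= min_epochs && min_epochs >= 1L)) {
    stop("need max_epochs >= min_epochs >= 1")
  }
  if (batch_size < 1L) stop("batch_size must be >= 1")
  stopifnot(micro_check_every >= 1L, macro_window >= 1L, micro_window >= 1L,
            learning_rate > 0)
  structure(list(task = match.arg(task, c("five", "three", "two")),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 micro_check_every = as.integer(micro_check_every),
                 macro_window = as.integer(macro_window),
                 micro_window = as.integer(micro_window),
                 min_epochs = as.integer(min_epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 micro_val_size = as.integer(micro_val_size),
                 patience_mode = patience_mode,
                 out_dir = out_dir, checkpoint_path = checkpoint_path),
            class = "run_config")
}

#' Train a model under two-level adaptive early stopping
#'
#' Runs at most `max_epochs` passes over the training split. Every
#' `micro_check_every` batches the loss on a fixed held-out validation
#' mini-batch feeds the in-epoch (micro) patience controller, which may
#' abort the epoch; the epoch's logged loss is then the gradual
#' cross-entropy over the `l` consumed of the `N` allocated examples
#' (delta = N/l). After every epoch the full-validation loss feeds the
#' epoch-level (macro) controller, which may stop training; the parameters
#' with the best full-validation loss are restored at the end. Each
#' observation and decision is recorded in the trace.
#'
#' @param model a model implementing the [model-interface] (a
#'   [`dense_net`][instantiate_network] or [scripted_model]).
#' @param gset a [graded_image_set] with assigned train and val splits.
#' @param config a [run_config].
#' @return object of class `training_run`: list with `model` (best
#'   parameters restored), `trace` (data.frame: epoch, batch, split,
#'   monitored_value, epsilon, threshold, stall_count, decision),
#'   `epoch_summary` (epoch, allocated, consumed, delta, epoch_loss,
#'   val_loss, micro_aborted), `epochs_run`, `stopped_early`,
#'   `total_batches`.
#' @export
train_with_adaptive_stopping <- function(model, gset, config) {
  stopifnot(inherits(gset, "graded_image_set"), inherits(config, "run_config"))
  df <- as.data.frame(gset)
  n_train <- sum(df$split == "train")
  n_val <- sum(df$split == "val")
  if (n_train == 0L || n_val == 0L) stop("dataset needs train and val splits")
  C <- task_num_classes(config$task)
  if (model_num_classes(model) != C) {
    stop(sprintf("model has %d outputs but task '%s' needs %d",
                 model_num_classes(model), config$task, C))
  }
  needs_x <- model_needs_images(model)
  if (needs_x) {
    ch <- if (inherits(model, "dense_net")) model$plan$input_size[3] else 3L
    tr <- load_images(gset, "train", channels = ch)
    va <- load_images(gset, "val", channels = ch)
    y_tr <- regroup_labels(tr$grade, config$task) + 1L
    y_va <- regroup_labels(va$grade, config$task) + 1L
  } else {
    y_tr <- regroup_labels(df$grade[df$split == "train"], config$task) + 1L
    y_va <- regroup_labels(df$grade[df$split == "val"], config$task) + 1L
    tr <- va <- NULL
  }

  trace <- list()
  summaries <- list()
  add_trace <- function(epoch, batch, split, value, eps, st, decision) {
    trace[[length(trace) + 1L]] <<- data.frame(
      epoch = epoch, batch = batch, split = split, monitored_value = value,
      epsilon = eps,
      threshold = if (is.null(st)) NA_real_ else st$patience_threshold,
      stall_count = if (is.null(st)) NA_integer_ else st$stall_count,
      decision = decision, stringsAsFactors = FALSE
    )
  }

  macro_state <- init_patience(config$patience_mode)
  best <- list(loss = Inf, params = snapshot_params(model))
  total_batches <- 0L
  stopped_early <- FALSE
  epochs_run <- 0L

  withr::with_seed(config$seed, {
    # fixed held-out mini-batch for the micro check
    mv_idx <- sample.int(n_val, min(config$micro_val_size, n_val))
    mv_x <- if (needs_x) va$x[, , , mv_idx, drop = FALSE] else NULL
    mv_y <- y_va[mv_idx]

    for (epoch in seq_len(config$max_epochs)) {
      epochs_run <- epoch
      micro_state <- init_patience(config$patience_mode)
      ord <- sample.int(n_train)
      nb <- ceiling(n_train / config$batch_size)
      consumed <- 0L
      loss_sum <- 0
      aborted <- FALSE
      prev_micro <- NA_real_
      for (b in seq_len(nb)) {
        take <- ord[((b - 1L) * config$batch_size + 1L):
                      min(b * config$batch_size, n_train)]
        xb <- if (needs_x) tr$x[, , , take, drop = FALSE] else NULL
        r <- fit_batch(model, xb, y_tr[take], config$learning_rate)
        model <- r$model
        total_batches <- total_batches + 1L
        consumed <- consumed + length(take)
        loss_sum <- loss_sum + r$loss * length(take)
        add_trace(epoch, b, "train", r$loss, NA_real_, NULL, "")
        if (b %% config$micro_check_every == 0L && b < nb) {
          mv <- val_loss(model, mv_x, mv_y, kind = "micro")
          eps <- if (is.na(prev_micro)) NA_real_ else mv - prev_micro
          prev_micro <- mv
          micro_state <- observe(micro_state, mv)
          dec <- should_stop_micro(micro_state, config$micro_window)
          add_trace(epoch, b, "val_micro", mv, eps, micro_state,
                    if (dec$stop) "micro_stop" else "")
          if (dec$stop) {
            aborted <- TRUE
            break
          }
        }
      }
      delta <- delta_coefficient(n_train, consumed)
      epoch_loss <- (delta / n_train) * loss_sum  # == mean over consumed
      vl <- val_loss(model, if (needs_x) va$x else NULL, y_va, kind = "macro")
      eps <- if (macro_state$step_index >= 1L) vl - macro_state$last_value
             else NA_real_
      macro_state <- observe(macro_state, vl)
      dec <- should_stop_macro(macro_state, config$macro_window,
                               config$min_epochs)
      add_trace(epoch, NA_integer_, "val_macro", vl, eps, macro_state,
                if (dec$stop) "macro_stop" else "")
      summaries[[epoch]] <- data.frame(
        epoch = epoch, allocated = n_train, consumed = consumed,
        delta = delta, epoch_loss = epoch_loss, val_loss = vl,
        micro_aborted = aborted, stringsAsFactors = FALSE
      )
      if (vl < best$loss) {
        best <- list(loss = vl, params = snapshot_params(model))
      }
      if (dec$stop) {
        stopped_early <- TRUE
        break
      }
    }
  })

  model <- restore_params(model, best$params)
  trace <- do.call(rbind, trace)
  run <- structure(
    list(model = model, trace = trace,
         epoch_summary = do.call(rbind, summaries),
         epochs_run = epochs_run, stopped_early = stopped_early,
         total_batches = total_batches, best_val_loss = best$loss,
         config = config),
    class = "training_run"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trace, file.path(config$out_dir, "trace.csv"),
                     row.names = FALSE)
  }
  if (!is.null(config$checkpoint_path) && inherits(model, "dense_net")) {
    save_checkpoint(model, config$checkpoint_path)
  }
  run
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf(
    "<training_run> %d epoch(s), %d batches, %s, best val loss %.4f\n",
    x$epochs_run, x$total_batches,
    if (x$stopped_early) "stopped early" else "ran full budget",
    x$best_val_loss
  ))
  invisible(x)
}

#' Evaluate a model on a dataset split
#'
#' Predicts every record of the chosen split, regroups the true grades for
#' the task, and reports the confusion matrix with micro- and
#' macro-averaged metrics.
#'
#' @param model a model implementing [model-interface].
#' @param gset a [graded_image_set].
#' @param task `"five"`, `"three"` or `"two"`.
#' @param split which split to score (default `"test"`).
#' @param out_prefix if set, metrics JSON and confusion CSV are written via
#'   [write_metrics()].
#' @return list with `confusion`, `micro`, `macro`, `n`, `task`, `split`.
#' @export
evaluate <- function(model, gset, task, split = "test", out_prefix = NULL) {
  stopifnot(inherits(gset, "graded_image_set"))
  task <- match.arg(task, c("five", "three", "two"))
  C <- task_num_classes(task)
  if (model_num_classes(model) != C) {
    stop(sprintf("model has %d outputs but task '%s' needs %d",
                 model_num_classes(model), task, C))
  }
  df <- as.data.frame(gset)
  df <- df[df$split == split, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records in split '", split, "'")
  y <- regroup_labels(df$grade, task)
  if (model_needs_images(model)) {
    ch <- if (inherits(model, "dense_net")) model$plan$input_size[3] else 3L
    x <- load_images(gset, split, channels = ch)$x
    probs <- predict_probs(model, x)
  } else {
    probs <- predict_probs(model, nrow(df))
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(y, pred, C)
  out <- list(confusion = cm, micro = micro_metrics(cm),
              macro = macro_metrics(cm), n = nrow(df), task = task,
              split = split)
  if (!is.null(out_prefix)) write_metrics(cm, task, split, out_prefix)
  out
}
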