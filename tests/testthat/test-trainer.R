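# scripted-model harness: a dataset whose images are never read
scripted_gset <- function(n_train = 10L, n_val = 4L) {
  df <- data.frame(
    path = sprintf("unused_%03d.pgm", seq_len(n_train + n_val)),
    grade = rep(c(0L, 4L), length.out = n_train + n_val),
    origin = "original",
    split = rep(c("train", "val"), c(n_train, n_val)),
    stringsAsFactors = FALSE
  )
  graded_image_set(df)
}

test_that("run_config validates its invariants", {
  expect_s3_class(run_config(), "run_config")
  expect_error(run_config(max_epochs = 2, min_epochs = 5), "max_epochs")
  expect_error(run_config(min_epochs = 0), "max_epochs|min_epochs")
  expect_error(run_config(batch_size = 0), "batch_size")
})

test_that("scripted plateau triggers a macro stop exactly window epochs in", {
  # epoch losses improve (faster than their own average, so no stalls) for
  # 5 epochs then flatten; the first flat epoch is the 6th observation, so
  # with window 3 the run stops at epoch 8
  prefix <- 100 - cumsum(cumprod(rep(1.5, 5)))
  sm <- scripted_model(macro_losses = c(prefix, rep(prefix[5], 20)))
  cfg <- run_config(task = "two", max_epochs = 30, batch_size = 5,
                    micro_check_every = 100, macro_window = 3, min_epochs = 3,
                    seed = 1)
  run <- train_with_adaptive_stopping(sm, scripted_gset(), cfg)
  expect_true(run$stopped_early)
  expect_identical(run$epochs_run, 8L)
  expect_identical(run$trace$decision[run$trace$split == "val_macro"][8],
                   "macro_stop")
})

test_that("strictly improving scripted losses run the full epoch budget", {
  # accelerating improvement: every eps beats the running average
  losses <- 100 - cumsum(cumprod(rep(1.3, 12)))
  sm <- scripted_model(macro_losses = losses)
  cfg <- run_config(task = "two", max_epochs = 12, batch_size = 5,
                    micro_check_every = 100, macro_window = 3, seed = 1)
  run <- train_with_adaptive_stopping(sm, scripted_gset(), cfg)
  expect_false(run$stopped_early)
  expect_identical(run$epochs_run, 12L)
})

test_that("micro abort logs the epoch loss as GCE over consumed examples", {
  # micro checks every batch; losses 1.0 then flat 0.5: stall on the 3rd and
  # 4th checks, micro_window 2 aborts at batch 4 of 10 (batch_size 1)
  sm <- scripted_model(macro_losses = 100 - cumsum(cumprod(rep(1.3, 8))),
                       micro_losses = c(1.0, rep(0.5, 50)),
                       train_loss = log(2))
  cfg <- run_config(task = "two", max_epochs = 2, batch_size = 1,
                    micro_check_every = 1, micro_window = 2,
                    macro_window = 5, min_epochs = 1, seed = 1)
  run <- train_with_adaptive_stopping(sm, scripted_gset(10L, 4L), cfg)
  s1 <- run$epoch_summary[1, ]
  expect_true(s1$micro_aborted)
  expect_identical(s1$consumed, 4L)
  expect_equal(s1$delta, delta_coefficient(10, 4))
  # epoch loss must equal the GCE of the consumed subset: four examples
  # with uniform 2-class predictions, in an epoch allocated 10
  oracle <- gce(loss_batch(matrix(0.5, 4, 2), rep(1, 4),
                           epoch_size = 10, consumed = 4))
  expect_equal(s1$epoch_loss, oracle, tolerance = 1e-12)
  expect_identical(sum(run$trace$decision == "micro_stop"), 2L)
  # a micro stop aborts only the epoch: training continued into epoch 2
  expect_identical(run$epochs_run, 2L)
})

test_that("early stopping saves work versus the full budget", {
  mk <- function() scripted_model(macro_losses = c(3, 2, 1, rep(1, 30)),
                                  micro_losses = c(1.0, rep(0.5, 100)))
  gs <- scripted_gset(20L, 4L)
  stop_cfg <- run_config(task = "two", max_epochs = 12, batch_size = 2,
                         micro_check_every = 2, micro_window = 2,
                         macro_window = 3, min_epochs = 3, seed = 1)
  nostop_cfg <- run_config(task = "two", max_epochs = 12, batch_size = 2,
                           micro_check_every = 100, macro_window = 100,
                           min_epochs = 3, seed = 1)
  run_stop <- train_with_adaptive_stopping(mk(), gs, stop_cfg)
  run_full <- train_with_adaptive_stopping(mk(), gs, nostop_cfg)
  expect_lt(run_stop$total_batches, run_full$total_batches)
  expect_identical(run_full$total_batches, 12L * 10L)
})

test_that("trainer rejects invalid configurations before training", {
  sm <- scripted_model(macro_losses = 1, num_classes = 3L)
  expect_error(
    train_with_adaptive_stopping(sm, scripted_gset(), run_config("two")),
    "outputs"
  )
  df <- as.data.frame(scripted_gset())
  df$split <- "train"
  expect_error(
    train_with_adaptive_stopping(
      scripted_model(1), graded_image_set(df), run_config("two")
    ),
    "train and val"
  )
})

test_that("real-model training is deterministic and writes the trace CSV", {
  fx <- small_dataset()
  df <- as.data.frame(fx$gset)
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$grade)[1:3],
                        utils::head, 6))
  sub <- df[keep, ]
  sub$split <- rep(c("train", "train", "train", "train", "val", "val"), 3)
  gs <- graded_image_set(sub)
  out <- file.path(tempdir(), "trainrun")
  mk_cfg <- function() run_config(task = "two", max_epochs = 2,
                                  batch_size = 10, micro_check_every = 1,
                                  micro_window = 10, macro_window = 3,
                                  min_epochs = 1, learning_rate = 0.1,
                                  seed = 42,
                                  micro_val_size = 5, out_dir = out)
  r1 <- train_with_adaptive_stopping(tiny_model(2, 1), gs, mk_cfg())
  r2 <- train_with_adaptive_stopping(tiny_model(2, 1), gs, mk_cfg())
  expect_equal(r1$trace$monitored_value, r2$trace$monitored_value,
               tolerance = 1e-6)
  expect_identical(r1$trace$decision, r2$trace$decision)
  trace <- utils::read.csv(file.path(out, "trace.csv"))
  expect_named(trace, c("epoch", "batch", "split", "monitored_value",
                        "epsilon", "threshold", "stall_count", "decision"))
  expect_true(all(c("train", "val_macro") %in% trace$split))
})

test_that("evaluate scores stub predictors as expected", {
  fx <- small_dataset()
  sp <- split_dataset(fx$gset, c(0.5, 0.2, 0.3), seed = 5)
  df <- as.data.frame(sp)
  test_grades <- df$grade[df$split == "test"]
  y2 <- regroup_labels(test_grades, "two")
  # perfect stub: every metric 1.0
  perfect <- evaluate(stub_predictor(y2, 2), sp, "two")
  expect_equal(unlist(perfect$micro), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unlist(perfect$macro), rep(1, 4), ignore_attr = TRUE)
  # majority stub: micro accuracy equals the majority fraction (binary)
  maj <- as.integer(names(which.max(table(y2))))
  suppressWarnings(
    res <- evaluate(stub_predictor(rep(maj, length(y2)), 2), sp, "two")
  )
  expect_equal(res$micro$accuracy, mean(y2 == maj))
  # metrics JSON round-trips
  prefix <- tempfile()
  evaluate(stub_predictor(y2, 2), sp, "two", out_prefix = prefix)
  js <- jsonlite::fromJSON(paste0(prefix, "_metrics.json"))
  expect_equal(js$accuracy[js$averaging == "micro"], 1)
  # class-count mismatch is refused
  expect_error(evaluate(stub_predictor(y2, 2), sp, "five"), "outputs")
})
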