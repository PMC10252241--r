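test_that("init_patience starts empty, deterministic, and cannot stop", {
  st <- init_patience()
  expect_s3_class(st, "patience_state")
  expect_identical(st$step_index, 0L)
  expect_identical(st$stall_count, 0L)
  expect_identical(init_patience(), init_patience())
  st <- observe(st, 1.0)
  expect_false(should_stop_macro(st, 1, 0)$stop)
  expect_false(should_stop_micro(st, 1)$stop)
})

test_that("observe tracks the running mean of successive differences", {
  st <- init_patience()
  for (v in c(1.0, 0.8, 0.7)) st <- observe(st, v)
  expect_equal(st$running_avg_diff, -0.15)  # mean(c(-0.2, -0.1))

  st <- init_patience()
  for (v in c(1.0, 0.5)) st <- observe(st, v)
  expect_equal(st$running_avg_diff, -0.5)

  st <- init_patience()
  for (v in rep(3.7, 6)) st <- observe(st, v)
  expect_equal(st$running_avg_diff, 0)

  expect_error(observe(init_patience(), NaN), "finite")
  expect_error(observe(init_patience(), Inf), "finite")
  expect_error(observe(init_patience(), c(1, 2)), "finite")
})

test_that("running_avg_diff matches brute-force mean(diff(.)) on random sequences", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(2:40, 1)
    vals <- stats::rnorm(n)
    st <- init_patience()
    for (v in vals) st <- observe(st, v)
    expect_equal(st$running_avg_diff, mean(diff(vals)), tolerance = 1e-12)
    expect_identical(st$step_index, n)
    expect_lte(st$stall_count, st$step_index)
  }
})

test_that("literal threshold mode diverges from the running mean but tracks it", {
  vals <- c(1.0, 0.9, 0.85, 0.84)
  st_inc <- init_patience("incremental")
  st_lit <- init_patience("literal")
  for (v in vals) {
    st_inc <- observe(st_inc, v)
    st_lit <- observe(st_lit, v)
  }
  # both modes agree on the true running average
  expect_equal(st_lit$running_avg_diff, st_inc$running_avg_diff)
  # literal threshold = (avg of previous diffs + current diff)/(i + 1)
  prev_avg <- mean(diff(vals)[1:2])
  expect_equal(st_lit$patience_threshold,
               (prev_avg + (0.84 - 0.85)) / (length(vals) + 1))
  expect_false(isTRUE(all.equal(st_lit$patience_threshold,
                                st_inc$patience_threshold)))
})

test_that("macro stop fires after window stalls, guarded by min_epochs", {
  # plateau after an improving prefix; the prefix improves faster than its
  # own history (accelerating decrements) so it contributes no stalls
  prefix <- 100 - cumsum(cumprod(rep(1.5, 5)))
  plateau_state <- function(n_flat) {
    st <- init_patience()
    for (v in prefix) st <- observe(st, v)
    for (i in seq_len(n_flat)) st <- observe(st, prefix[5])
    st
  }
  st <- plateau_state(3)
  expect_identical(st$stall_count, 3L)
  dec <- should_stop_macro(st, window = 3, min_epochs = 3)
  expect_true(dec$stop)
  expect_identical(dec$level, "macro")
  # window - 1 stalls: no stop
  expect_false(should_stop_macro(plateau_state(2), 3, 3)$stop)
  # warm-up guard: enough stalls but too few observations
  st2 <- init_patience()
  for (v in c(2, 1, 1, 1, 1)) st2 <- observe(st2, v)
  expect_identical(st2$stall_count, 3L)
  expect_false(should_stop_macro(st2, 3, min_epochs = 10)$stop)
  expect_true(should_stop_macro(st2, 3, min_epochs = 4)$stop)
  expect_error(should_stop_macro(st, window = 0), "window")
})

test_that("micro stop uses the same rule without the warm-up guard", {
  st <- init_patience()
  for (v in c(1, 0.5, 0.5, 0.5, 0.5)) st <- observe(st, v)
  dec <- should_stop_micro(st, window = 3)
  expect_true(dec$stop)
  expect_identical(dec$level, "micro")
  # boundary: exactly window - 1 stalls
  st2 <- init_patience()
  for (v in c(1, 0.5, 0.5, 0.5)) st2 <- observe(st2, v)
  expect_identical(st2$stall_count, 2L)
  expect_false(should_stop_micro(st2, window = 3)$stop)
  expect_error(should_stop_micro(st, window = 0), "window")
})

test_that("never-stop: eps strictly below threshold keeps stall_count at 0", {
  # accelerating improvement: each difference more negative than the
  # running average of earlier ones
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    diffs <- -cumprod(rep(1.5, n)) * stats::runif(1, 0.1, 1)
    vals <- 10 + cumsum(c(0, diffs))
    st <- init_patience()
    for (v in vals) {
      st <- observe(st, v)
      expect_identical(st$stall_count, 0L)
    }
    expect_false(should_stop_macro(st, 1, 0)$stop)
    expect_false(should_stop_micro(st, 1)$stop)
  }
})

test_that("always-stop: improving prefix then >= window flat observations", {
  set.seed(8)
  for (rep in 1:20) {
    window <- sample(1:4, 1)
    n_imp <- sample(4:10, 1)
    vals <- c(50 - cumsum(cumprod(rep(1.3, n_imp))),
              rep(0.5, window + 1))
    st <- init_patience()
    stopped <- FALSE
    for (v in vals) {
      st <- observe(st, v)
      if (should_stop_macro(st, window, min_epochs = n_imp)$stop) {
        stopped <- TRUE
        break
      }
    }
    expect_true(stopped)
  }
})

test_that("decisions are pure functions of the observation sequence", {
  vals <- c(3, 2.5, 2.5, 2.4, 2.4, 2.4)
  replay <- function() {
    st <- init_patience()
    out <- list()
    for (v in vals) {
      st <- observe(st, v)
      out[[length(out) + 1]] <- should_stop_macro(st, 2, 2)
    }
    out
  }
  expect_identical(replay(), replay())
})
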