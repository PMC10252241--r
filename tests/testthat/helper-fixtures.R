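# Shared fixtures, built in code at test time.

# a small on-disk synthetic dataset reused across pipeline/trainer tests
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 11L,
                              counts_per_grade = c(50L, 23L, 34L, 17L, 4L))
      dir <- file.path(tempdir(), "koadapt-fixture")
      cache <<- list(cfg = cfg, gset = generate_dataset(cfg, dir), dir = dir)
    }
    cache
  }
})

# reduced-plan trainable model for 64x64 inputs
tiny_model <- function(num_classes, seed = 1L) {
  plan <- build_layer_plan(c(64L, 64L, 3L), num_classes)
  instantiate_network(plan, seed, growth = 6L, init_channels = 8L,
                      block_layers = c(2L, 2L, 2L, 2L), bottleneck = FALSE)
}

# random probability matrix with rows summing to 1
random_probs <- function(n, C) {
  p <- matrix(stats::rexp(n * C), n, C)
  p / rowSums(p)
}

# brute-force per-class metric oracle computed straight from label vectors,
# independent of the confusion-matrix code path
oracle_metrics <- function(actual, predicted, C) {
  tp <- tn <- fp <- fn <- numeric(C)
  for (c in 0:(C - 1)) {
    tp[c + 1] <- sum(actual == c & predicted == c)
    fp[c + 1] <- sum(actual != c & predicted == c)
    fn[c + 1] <- sum(actual == c & predicted != c)
    tn[c + 1] <- sum(actual != c & predicted != c)
  }
  micro <- list(
    accuracy = (sum(tp) + sum(tn)) /
      (sum(tp) + sum(tn) + sum(fp) + sum(fn)),
    precision = sum(tp) / (sum(tp) + sum(fp)),
    recall = sum(tp) / (sum(tp) + sum(fn))
  )
  micro$f1 <- if (micro$precision + micro$recall == 0) 0 else
    2 * micro$precision * micro$recall / (micro$precision + micro$recall)
  pr <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  re <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  macro <- list(
    accuracy = mean((tp + tn) / length(actual)),
    precision = mean(pr), recall = mean(re)
  )
  macro$f1 <- if (macro$precision + macro$recall == 0) 0 else
    2 * macro$precision * macro$recall / (macro$precision + macro$recall)
  list(micro = micro, macro = macro)
}
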