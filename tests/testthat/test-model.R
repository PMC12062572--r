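# Window classifier: encoder determinism, prediction contracts, region
# merging, and training behaviour on a small separable synthetic set.

tiny_cfg <- function(variant = "full", seed = 9L) {
  sv_model_config(conv_channels = c(6L, 8L), kernel = 3L, input_pool = 2L,
                  pool = 4L, attention_reduction = 2L, spatial_kernel = 3L,
                  embed_dim = 16L, n_heads = 2L, n_layers = 1L, ff_dim = 24L,
                  dropout = 0.1, variant = variant, seed = seed)
}

# A window set with a planted point signal: positive submatrices get a burst
# in one channel. Built directly in memory, no BAM involved.
toy_training_set <- function(n_windows = 60L, seed = 21L) {
  set.seed(seed)
  span <- n_windows * 2000L
  counts <- matrix(rpois(span * 20L, 3), span, 20L)
  labels <- matrix(0L, n_windows, 10L)
  for (w in seq_len(n_windows)) {
    pos_subs <- which(runif(10) < 0.15)
    labels[w, pos_subs] <- 1L
    for (s in pos_subs) {
      at <- (w - 1L) * 2000L + (s - 1L) * 200L + sample(40:160, 1L)
      counts[at:(at + 30L), 2L] <- counts[at:(at + 30L), 2L] + 25L
    }
  }
  fm <- structure(list(contig = "toy", start = 0L, end = span,
                       counts = counts),
                  class = "sv_feature_matrix")
  ws <- tile_windows(fm)
  build_training_set(list(ws), list(labels), coverage = 6)
}

test_that("submatrix encoding is deterministic and shape-checked", {
  model <- sv_init_model(tiny_cfg())
  z <- matrix(0, 200L, 20L)
  e1 <- encode_submatrix(z, model)
  e2 <- encode_submatrix(z, model)
  expect_equal(length(e1), 16L)
  expect_identical(e1, e2)
  x <- matrix(rexp(4000), 200L, 20L)
  expect_identical(encode_submatrix(x, model), encode_submatrix(x, model))
  expect_error(encode_submatrix(matrix(0, 100L, 20L), model), "200")
  # re-initialising with the same seed reproduces parameters bitwise
  m2 <- sv_init_model(tiny_cfg())
  expect_identical(model$params, m2$params)
  expect_identical(encode_submatrix(x, model), encode_submatrix(x, m2))
})

test_that("window predictions are probabilities and padded submatrices score 0", {
  model <- sv_init_model(tiny_cfg())
  fm <- structure(list(contig = "c", start = 0L, end = 300L,
                       counts = matrix(rpois(300L * 20L, 2), 300L, 20L)),
                  class = "sv_feature_matrix")
  ws <- tile_windows(fm)
  wp <- predict_window(get_window_batch(ws, 1L), model, coverage = 5)
  expect_s3_class(wp, "sv_window_prediction")
  expect_true(all(wp$prob >= 0 & wp$prob <= 1))
  # submatrices 1 (full) and 2 (part-filled) carry data; 3..10 are padding
  expect_true(all(wp$prob[3:10] == 0))
  expect_true(all(wp$prob[1:2] > 0))
  # a fully padded batch scores zero everywhere
  all_pad <- list(contig = "c", start = 0L,
                  x = matrix(0, 2000L, 20L), pad_mask = rep(TRUE, 10L))
  expect_equal(predict_window(all_pad, model)$prob, numeric(10L))
  expect_equal(wp$intervals[1, ], c(start = 0L, end = 200L))
})

test_that("adjacent positive intervals merge per the min-start/max-end rule", {
  m <- merge_regions(data.frame(start = c(0L, 200L), end = c(200L, 400L)))
  expect_equal(m, data.frame(start = 0L, end = 400L))
  m2 <- merge_regions(data.frame(start = c(0L, 1000L), end = c(200L, 1200L)),
                      max_gap = 0L)
  expect_equal(nrow(m2), 2L)
  m3 <- merge_regions(data.frame(start = c(0L, 200L), end = c(600L, 400L)))
  expect_equal(m3, data.frame(start = 0L, end = 600L))
  expect_equal(nrow(merge_regions(data.frame(start = integer(0),
                                             end = integer(0)))), 0L)
})

test_that("merge_regions is idempotent, order-invariant and containing", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    starts <- sample(seq(0L, 4000L, by = 200L), n)
    iv <- data.frame(start = starts, end = starts + 200L)
    gap <- sample(c(0L, 200L, 400L), 1)
    m <- merge_regions(iv, gap)
    expect_equal(merge_regions(m, gap), m)
    expect_equal(merge_regions(iv[sample(n), , drop = FALSE], gap), m)
    within <- vapply(seq_len(n), function(i) {
      any(m$start <= iv$start[i] & m$end >= iv$end[i])
    }, TRUE)
    expect_true(all(within))
  }
})

test_that("training reduces loss on a separable toy set and early stopping works", {
  ts <- toy_training_set()
  model <- train_model(ts, tiny_cfg(), epochs = 8L, patience = 8L,
                       batch_size = 8L)
  m <- model$metrics
  expect_lte(m$train_loss[nrow(m)], m$train_loss[1L])
  expect_gt(m$val_f1[nrow(m)], 0.8)

  # early stopping: with a zero learning rate validation loss never improves
  # after the first epoch, so training halts after exactly `patience` more
  model2 <- train_model(ts, tiny_cfg(), epochs = 30L, patience = 2L,
                        batch_size = 8L, lr = 0)
  expect_equal(nrow(model2$metrics), 3L)
})

test_that("a trained model separates planted from background submatrices", {
  ts <- toy_training_set()
  model <- train_model(ts, tiny_cfg(), epochs = 8L, patience = 8L,
                       batch_size = 8L)
  held <- toy_training_set(n_windows = 30L, seed = 99L)
  probs <- svscout:::predict_window_set(held$sets[[1L]], model, coverage = 6)
  labs <- held$labels[[1L]]
  pos <- probs[labs == 1L]; neg <- probs[labs == 0L]
  set.seed(5)
  wins <- mean(sample(pos, 400L, replace = TRUE) >
                 sample(neg, 400L, replace = TRUE))
  expect_gt(wins, 0.95)
})

test_that("single-class labels warn but training proceeds; empty set errors", {
  ts <- toy_training_set(n_windows = 10L)
  ts$labels[[1L]][] <- 0L
  expect_warning(train_model(ts, tiny_cfg(), epochs = 1L, batch_size = 8L),
                 "single class")
  bad <- ts; bad$index <- bad$index[0, ]
  expect_error(train_model(bad, tiny_cfg()), "empty")
})

test_that("checkpoints round-trip through a single file", {
  ts <- toy_training_set(n_windows = 12L)
  model <- train_model(ts, tiny_cfg(), epochs = 2L, batch_size = 8L)
  path <- tempfile(fileext = ".rds")
  sv_save_model(model, path)
  back <- sv_load_model(path)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
  x <- matrix(rexp(4000), 200L, 20L)
  expect_identical(encode_submatrix(x, back), encode_submatrix(x, model))
})
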