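# Window classifier: a small 1-D CNN with channel/spatial attention encodes
# each 200 bp feature submatrix; a transformer encoder contextualises the 10
# submatrix embeddings of a 2 kb window; a linear head scores each submatrix
# for structural-variant content. Three variants are supported for ablation:
# "full" (CNN encoder + transformer), "cnn_only" (CNN encoder + head) and
# "transformer_only" (linear patch embedding + transformer).

#' Model configuration for the window classifier
#'
#' @param conv_channels Integer vector of length 2: output channels of the two
#'   1-D convolution layers applied along the position axis.
#' @param kernel Convolution kernel width (odd), in positions.
#' @param input_pool Max-pooling factor applied to the raw submatrix before
#'   the first convolution.
#' @param pool Max-pooling factor applied between the two convolutions.
#' @param attention_reduction Reduction ratio of the channel-attention MLP.
#' @param spatial_kernel Kernel width of the spatial-attention convolution.
#' @param embed_dim Embedding dimension per submatrix; must be divisible by
#'   `n_heads`.
#' @param n_heads Number of attention heads.
#' @param n_layers Number of transformer encoder layers.
#' @param ff_dim Hidden width of the transformer feed-forward sublayer.
#' @param dropout Dropout probability used during training.
#' @param positive_threshold Probability above which a submatrix is called
#'   positive; must lie strictly in (0, 1).
#' @param variant One of "full", "cnn_only", "transformer_only".
#' @param seed Integer seed controlling parameter initialisation and data
#'   shuffling during training.
#' @return A list of class `sv_model_config`.
#' @export
sv_model_config <- function(conv_channels = c(16L, 32L), kernel = 5L,
                            input_pool = 2L, pool = 4L,
                            attention_reduction = 8L,
                            spatial_kernel = 7L, embed_dim = 128L,
                            n_heads = 4L, n_layers = 2L, ff_dim = 256L,
                            dropout = 0.1, positive_threshold = 0.5,
                            variant = c("full", "cnn_only", "transformer_only"),
                            seed = 42L) {
  variant <- match.arg(variant)
  stopifnot(length(conv_channels) == 2L, kernel %% 2L == 1L,
            200L %% (input_pool * pool) == 0L, embed_dim %% n_heads == 0L,
            positive_threshold > 0, positive_threshold < 1)
  structure(list(
    conv_channels = as.integer(conv_channels), kernel = as.integer(kernel),
    input_pool = as.integer(input_pool),
    pool = as.integer(pool), attention_reduction = as.integer(attention_reduction),
    spatial_kernel = as.integer(spatial_kernel), embed_dim = as.integer(embed_dim),
    n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
    ff_dim = as.integer(ff_dim), dropout = dropout,
    positive_threshold = positive_threshold, variant = variant,
    seed = as.integer(seed)
  ), class = "sv_model_config")
}

SUB_LEN <- 200L
SUBS_PER_WINDOW <- 10L
WINDOW_LEN <- SUB_LEN * SUBS_PER_WINDOW
N_CHANNELS <- 20L

mat_rnorm <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_params <- function(cfg) {
  k <- cfg$kernel
  c1 <- cfg$conv_channels[1L]; c2 <- cfg$conv_channels[2L]
  d <- cfg$embed_dim
  p <- list()
  if (cfg$variant %in% c("full", "cnn_only")) {
    hdim <- max(1L, c2 %/% cfg$attention_reduction)
    p$cw1 <- mat_rnorm(k * N_CHANNELS, c1, sqrt(2 / (k * N_CHANNELS)))
    p$cb1 <- matrix(0, 1L, c1)
    p$cw2 <- mat_rnorm(k * c1, c2, sqrt(2 / (k * c1)))
    p$cb2 <- matrix(0, 1L, c2)
    p$ca_w1 <- mat_rnorm(c2, hdim, sqrt(2 / c2)); p$ca_b1 <- matrix(0, 1L, hdim)
    p$ca_w2 <- mat_rnorm(hdim, c2, sqrt(2 / hdim)); p$ca_b2 <- matrix(0, 1L, c2)
    p$sp_w <- mat_rnorm(2L * cfg$spatial_kernel, 1L, sqrt(1 / (2 * cfg$spatial_kernel)))
    p$sp_b <- matrix(0, 1L, 1L)
    # global pooling concatenates mean and max over positions
    p$pw <- mat_rnorm(2L * c2, d, sqrt(1 / (2 * c2))); p$pb <- matrix(0, 1L, d)
  }
  if (cfg$variant == "transformer_only") {
    p$patch_w <- mat_rnorm(SUB_LEN * N_CHANNELS, d, 0.01)
    p$patch_b <- matrix(0, 1L, d)
  }
  if (cfg$variant %in% c("full", "transformer_only")) {
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("l", l, "_")
      for (w in c("wq", "wk", "wv")) p[[paste0(pre, w)]] <- mat_rnorm(d, d, 0.02)
      for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- matrix(0, 1L, d)
      # residual-branch output projections start at zero, so the untrained
      # transformer is the identity and the encoder path dominates early
      # training; cross-submatrix context is learned on top of it
      p[[paste0(pre, "wo")]] <- matrix(0, d, d)
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1L, d); p[[paste0(pre, "ln1_b")]] <- matrix(0, 1L, d)
      p[[paste0(pre, "ln2_g")]] <- matrix(1, 1L, d); p[[paste0(pre, "ln2_b")]] <- matrix(0, 1L, d)
      p[[paste0(pre, "ff1")]] <- mat_rnorm(d, cfg$ff_dim, sqrt(2 / d))
      p[[paste0(pre, "fb1")]] <- matrix(0, 1L, cfg$ff_dim)
      p[[paste0(pre, "ff2")]] <- matrix(0, cfg$ff_dim, d)
      p[[paste0(pre, "fb2")]] <- matrix(0, 1L, d)
    }
    p$lnf_g <- matrix(1, 1L, d); p$lnf_b <- matrix(0, 1L, d)
  }
  p$hw <- mat_rnorm(d, 1L, sqrt(1 / d))
  p$hb <- matrix(0, 1L, 1L)
  p
}

# Sinusoidal positional encoding over the token slots of one window.
positional_encoding <- function(T, d) {
  pe <- matrix(0, T, d)
  pos <- seq_len(T) - 1L
  for (i in seq_len(d %/% 2L)) {
    w <- 1 / 10000^((2 * (i - 1L)) / d)
    pe[, 2L * i - 1L] <- sin(pos * w)
    pe[, 2L * i] <- cos(pos * w)
  }
  pe
}

ag_linear <- function(x, w, b) ag_add(ag_matmul(x, w), b)

# CNN encoder for a batch of submatrices: x is (S*200) x 20 with the 200
# positions of each submatrix contiguous; returns S x embed_dim embeddings.
encode_cnn <- function(lv, cfg, x, S, training) {
  k <- cfg$kernel
  # initial position pooling keeps point signals (max) while shrinking the
  # convolution workload
  if (cfg$input_pool > 1L) x <- ag_block_max(x, cfg$input_pool)
  L1 <- SUB_LEN %/% cfg$input_pool
  h <- ag_relu(ag_linear(ag_im2col(x, L1, k), lv$cw1, lv$cb1))
  h <- ag_block_max(h, cfg$pool)
  L2 <- L1 %/% cfg$pool
  h <- ag_relu(ag_linear(ag_im2col(h, L2, k), lv$cw2, lv$cb2))
  # channel attention: shared MLP over average- and max-pooled descriptors
  avg <- ag_block_mean(h, L2)
  mx <- ag_block_max(h, L2)
  mlp <- function(z) ag_linear(ag_relu(ag_linear(z, lv$ca_w1, lv$ca_b1)), lv$ca_w2, lv$ca_b2)
  catt <- ag_sigmoid(ag_add(mlp(avg), mlp(mx)))
  h <- ag_mul(h, ag_gather(catt, rep(seq_len(S), each = L2)))
  # spatial attention: 1-D convolution over [mean, max] channel descriptors
  sp_in <- ag_cbind(list(ag_rowmean(h), ag_rowmax(h)))
  sp <- ag_sigmoid(ag_linear(ag_im2col(sp_in, L2, cfg$spatial_kernel), lv$sp_w, lv$sp_b))
  h <- ag_mul(h, sp)
  pooled <- ag_cbind(list(ag_block_mean(h, L2), ag_block_max(h, L2)))
  ag_linear(pooled, lv$pw, lv$pb)
}

transformer_encode <- function(lv, cfg, e, valid, training) {
  d <- cfg$embed_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("l", l, "_")
    x1 <- ag_layernorm(e, lv[[paste0(pre, "ln1_g")]], lv[[paste0(pre, "ln1_b")]])
    q <- ag_linear(x1, lv[[paste0(pre, "wq")]], lv[[paste0(pre, "bq")]])
    k <- ag_linear(x1, lv[[paste0(pre, "wk")]], lv[[paste0(pre, "bk")]])
    v <- ag_linear(x1, lv[[paste0(pre, "wv")]], lv[[paste0(pre, "bv")]])
    heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      sl <- ((h - 1L) * dh + 1L):(h * dh)
      heads[[h]] <- ag_attention(ag_cols(q, sl), ag_cols(k, sl), ag_cols(v, sl),
                                 SUBS_PER_WINDOW, valid)
    }
    o <- ag_linear(ag_cbind(heads), lv[[paste0(pre, "wo")]], lv[[paste0(pre, "bo")]])
    if (training) o <- ag_dropout(o, cfg$dropout)
    e <- ag_add(e, o)
    x2 <- ag_layernorm(e, lv[[paste0(pre, "ln2_g")]], lv[[paste0(pre, "ln2_b")]])
    f <- ag_linear(ag_relu(ag_linear(x2, lv[[paste0(pre, "ff1")]], lv[[paste0(pre, "fb1")]])),
                   lv[[paste0(pre, "ff2")]], lv[[paste0(pre, "fb2")]])
    if (training) f <- ag_dropout(f, cfg$dropout)
    e <- ag_add(e, f)
  }
  ag_layernorm(e, lv$lnf_g, lv$lnf_b)
}

# Flatten (S*200) x 20 submatrix rows to S x 4000 patch vectors (data-side
# reshape; channel-major within a patch).
flatten_patches <- function(x, S) {
  arr <- array(x, c(SUB_LEN, S, N_CHANNELS))
  matrix(as.vector(aperm(arr, c(2L, 1L, 3L))), S, SUB_LEN * N_CHANNELS)
}

# Forward pass: returns list(logits = node, leaves = named param nodes).
model_forward <- function(params, cfg, x, valid, training = FALSE) {
  S <- nrow(x) %/% SUB_LEN
  lv <- lapply(params, ag_leaf)
  if (cfg$variant %in% c("full", "cnn_only")) {
    e <- encode_cnn(lv, cfg, ag_node(x), S, training)
  } else {
    e <- ag_linear(ag_node(flatten_patches(x, S)), lv$patch_w, lv$patch_b)
  }
  if (cfg$variant %in% c("full", "transformer_only")) {
    B <- S %/% SUBS_PER_WINDOW
    pe <- positional_encoding(SUBS_PER_WINDOW, cfg$embed_dim)
    e <- ag_add(e, ag_node(pe[rep(seq_len(SUBS_PER_WINDOW), B), , drop = FALSE]))
    if (training) e <- ag_dropout(e, cfg$dropout)
    e <- transformer_encode(lv, cfg, e, valid, training)
  }
  logits <- ag_linear(e, lv$hw, lv$hb)
  list(logits = logits, leaves = lv)
}

#' Encode one 200-position submatrix into an embedding vector
#'
#' Deterministic given the model parameters and the input block; used mainly
#' for inspection and testing of the encoder in isolation.
#'
#' @param submatrix Numeric 200 x 20 matrix of (normalised) feature counts.
#' @param model A trained or initialised model, see [sv_init_model()].
#' @return Numeric vector of length `embed_dim`.
#' @export
encode_submatrix <- function(submatrix, model) {
  if (!is.matrix(submatrix) || nrow(submatrix) != SUB_LEN ||
      ncol(submatrix) != N_CHANNELS) {
    stop("submatrix must be a ", SUB_LEN, " x ", N_CHANNELS, " matrix")
  }
  cfg <- model$config
  lv <- lapply(model$params, ag_leaf)
  if (cfg$variant == "transformer_only") {
    e <- ag_linear(ag_node(flatten_patches(submatrix, 1L)), lv$patch_w, lv$patch_b)
  } else {
    e <- encode_cnn(lv, cfg, ag_node(submatrix), 1L, training = FALSE)
  }
  as.vector(e$val)
}

#' Initialise an untrained window-classifier model
#'
#' @param config An [sv_model_config()].
#' @return A list of class `sv_model` with elements `config`, `variant`,
#'   `params` and `trained_coverage`.
#' @export
sv_init_model <- function(config = sv_model_config()) {
  set.seed(config$seed)
  structure(list(config = config, variant = config$variant,
                 params = init_params(config), trained_coverage = NA_real_,
                 metrics = NULL),
            class = "sv_model")
}

#' Save / load a model checkpoint (single file, configuration embedded)
#' @param model An `sv_model`.
#' @param path Destination file.
#' @export
sv_save_model <- function(model, path) {
  stopifnot(inherits(model, "sv_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname sv_save_model
#' @export
sv_load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sv_model")) stop("not an sv_model checkpoint: ", path)
  model
}

#' Classify the submatrices of one window
#'
#' Applies the classifier to a single `WindowBatch` as produced by
#' [get_window_batch()]. Padded submatrices are excluded from attention and
#' reported with probability 0.
#'
#' @param batch A window batch: list with `x` (2000 x 20 counts), `pad_mask`
#'   (logical length 10), `contig`, `start`.
#' @param model A trained `sv_model`.
#' @param coverage Global mean coverage used to normalise counts; defaults to
#'   the coverage the model was trained at.
#' @return List of class `sv_window_prediction` with `contig`, `start`,
#'   `intervals` (10 x 2, 0-based half-open) and `prob` (10 probabilities).
#' @export
predict_window <- function(batch, model, coverage = NULL) {
  stopifnot(inherits(model, "sv_model"))
  if (nrow(batch$x) != WINDOW_LEN || ncol(batch$x) != N_CHANNELS) {
    stop("window batch must be ", WINDOW_LEN, " x ", N_CHANNELS)
  }
  norm <- coverage %||% model$trained_coverage
  if (is.null(norm) || is.na(norm) || norm <= 0) norm <- 1
  valid <- !batch$pad_mask
  if (any(valid)) {
    fw <- model_forward(model$params, model$config, batch$x / norm,
                        valid = valid, training = FALSE)
    prob <- as.vector(1 / (1 + exp(-fw$logits$val)))
    prob[!valid] <- 0
  } else {
    prob <- numeric(SUBS_PER_WINDOW)
  }
  starts <- batch$start + (seq_len(SUBS_PER_WINDOW) - 1L) * SUB_LEN
  structure(list(contig = batch$contig, start = batch$start,
                 intervals = cbind(start = starts, end = starts + SUB_LEN),
                 prob = prob),
            class = "sv_window_prediction")
}

# Batched probability computation over a whole window set (internal).
predict_window_set <- function(ws, model, coverage, batch_size = 32L) {
  n <- nrow(ws$windows)
  probs <- matrix(0, n, SUBS_PER_WINDOW)
  if (n == 0L) return(probs)
  norm <- if (is.null(coverage) || coverage <= 0) 1 else coverage
  for (i0 in seq(1L, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1L, n)
    xb <- materialize_windows(ws, idx) / norm
    valid <- as.vector(t(!pad_mask_matrix(ws, idx)))
    fw <- model_forward(model$params, model$config, xb, valid, training = FALSE)
    p <- matrix(as.vector(1 / (1 + exp(-fw$logits$val))), length(idx),
                SUBS_PER_WINDOW, byrow = TRUE)
    p[pad_mask_matrix(ws, idx)] <- 0
    probs[idx, ] <- p
  }
  probs
}

#' Merge adjacent positive submatrix intervals into candidate regions
#'
#' Two intervals no more than `max_gap` bases apart are merged into
#' `[min(start1, start2), max(end1, end2))`, applied transitively; the result
#' is sorted and disjoint.
#'
#' @param intervals A data.frame or matrix with columns `start`, `end`
#'   (0-based half-open) on one contig.
#' @param max_gap Maximum gap (bp) across which two intervals still merge;
#'   0 merges only touching or overlapping intervals.
#' @return data.frame with columns `start`, `end`.
#' @export
merge_regions <- function(intervals, max_gap = 0L) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
  data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

# Candidate regions for a window set given submatrix probabilities.
candidate_regions <- function(ws, probs, threshold, max_gap = 0L) {
  pos <- which(probs >= threshold, arr.ind = TRUE)
  if (nrow(pos) == 0L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0)))
  }
  starts <- ws$windows$start[pos[, 1L]] + (pos[, 2L] - 1L) * SUB_LEN
  merged <- merge_regions(data.frame(start = starts, end = starts + SUB_LEN), max_gap)
  if (nrow(merged) == 0L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0)))
  }
  data.frame(contig = ws$contig, start = merged$start,
             end = pmin(merged$end, ws$end), stringsAsFactors = FALSE)
}

classification_scores <- function(prob, label, valid, threshold = 0.5) {
  pred <- prob >= threshold & valid
  lab <- label == 1 & valid
  tp <- sum(pred & lab); fp <- sum(pred & !lab); fn <- sum(!pred & lab)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

#' Train the window classifier
#'
#' Trains with Adam on weighted binary cross-entropy (positive-class weight
#' equal to the negative/positive label ratio), for at most `epochs` epochs
#' with early stopping once validation loss has not improved for `patience`
#' epochs. The parameters with the best validation loss are kept.
#'
#' @param train_set An `sv_training_set`, see [build_training_set()].
#' @param config An [sv_model_config()].
#' @param epochs Maximum number of epochs (fixed schedule length).
#' @param patience Early-stopping patience in epochs.
#' @param lr Adam learning rate.
#' @param batch_size Windows per minibatch.
#' @param val_fraction Fraction of windows held out for validation.
#' @param metrics_path Optional path for a tab-separated per-epoch metrics log.
#' @param verbose Print per-epoch metrics.
#' @return A trained `sv_model`; `$metrics` holds the per-epoch data.frame
#'   with columns epoch, train_loss, train_recall, val_loss, val_f1.
#' @export
train_model <- function(train_set, config = sv_model_config(), epochs = 20L,
                        patience = 3L, lr = 3e-3, batch_size = 32L,
                        val_fraction = 0.2, metrics_path = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(train_set, "sv_training_set"))
  n <- nrow(train_set$index)
  if (n == 0L) stop("empty training set")
  set.seed(config$seed)
  # the train/validation split is drawn before parameter initialisation so
  # that every model variant trained with the same seed sees the same split
  ord <- sample.int(n)
  params <- init_params(config)
  labs_all <- training_labels(train_set)
  valid_all <- !training_pad(train_set)
  npos <- sum(labs_all == 1 & valid_all)
  nneg <- sum(labs_all == 0 & valid_all)
  if (npos == 0L || nneg == 0L) {
    warning("training labels contain a single class; proceeding anyway")
  }
  pos_weight <- if (npos > 0L) max(1, nneg / npos) else 1
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- if (n_val < n) ord[-seq_len(n_val)] else ord
  st <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  metrics <- NULL
  for (ep in seq_len(epochs)) {
    sh <- sample(tr_idx)
    tot_loss <- 0; tot_w <- 0
    tr_prob <- c(); tr_lab <- c(); tr_val <- c()
    for (i0 in seq(1L, length(sh), by = batch_size)) {
      idx <- sh[i0:min(i0 + batch_size - 1L, length(sh))]
      bt <- training_batch(train_set, idx)
      w <- ifelse(!bt$valid, 0, ifelse(bt$y == 1, pos_weight, 1))
      ag_tape_start()
      fw <- model_forward(params, config, bt$x, bt$valid, training = TRUE)
      loss <- ag_bce_logits(fw$logits, bt$y, w)
      ag_backward(loss)
      grads <- lapply(fw$leaves, function(nd) nd$grad)
      ag_tape_stop()
      upd <- adam_step(params, grads, st, lr = lr)
      params <- upd$params; st <- upd$state
      tot_loss <- tot_loss + as.numeric(loss$val) * sum(w)
      tot_w <- tot_w + sum(w)
      pr <- as.vector(1 / (1 + exp(-fw$logits$val)))
      tr_prob <- c(tr_prob, pr); tr_lab <- c(tr_lab, bt$y); tr_val <- c(tr_val, bt$valid)
    }
    tr_sc <- classification_scores(tr_prob, tr_lab, tr_val, config$positive_threshold)
    vl <- evaluate_split(params, config, train_set, val_idx, pos_weight, batch_size)
    metrics <- rbind(metrics, data.frame(
      epoch = ep, train_loss = tot_loss / tot_w, train_recall = tr_sc[["recall"]],
      val_loss = vl$loss, val_f1 = vl$scores[["f1"]]))
    if (verbose) {
      message(sprintf("epoch %d  train_loss %.4f  train_recall %.3f  val_loss %.4f  val_f1 %.3f",
                      ep, tot_loss / tot_w, tr_sc[["recall"]], vl$loss, vl$scores[["f1"]]))
    }
    if (vl$loss < best$loss - 1e-6) {
      best <- list(loss = vl$loss, params = params, epoch = ep)
    } else if (ep - best$epoch >= patience) {
      break
    }
  }
  if (!is.null(metrics_path)) {
    utils::write.table(metrics, metrics_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  # calibrated operating point: the weighted loss makes 0.5 recall-heavy, so
  # the model's summary scores are reported at the threshold that maximises
  # F1 on the training split, evaluated on the held-out split
  tr_probs <- split_probs(best$params, config, train_set, tr_idx, batch_size)
  thrs <- seq(0.05, 0.95, by = 0.05)
  f1_tr <- vapply(thrs, function(t) {
    classification_scores(tr_probs$prob, tr_probs$lab, tr_probs$valid, t)[["f1"]]
  }, 0)
  thr_cal <- thrs[which.max(f1_tr)]
  val_probs <- split_probs(best$params, config, train_set, val_idx, batch_size)
  val_scores <- classification_scores(val_probs$prob, val_probs$lab,
                                      val_probs$valid, thr_cal)
  structure(list(config = config, variant = config$variant,
                 params = best$params, trained_coverage = train_set$coverage,
                 metrics = metrics, best_epoch = best$epoch,
                 threshold_cal = thr_cal, val_scores = val_scores),
            class = "sv_model")
}

#' Score a trained classifier on labelled window sets
#'
#' Computes submatrix-level precision/recall/F1 of a trained model on an
#' independent labelled sample (e.g. a fresh simulated genome), at the
#' model's calibrated operating threshold.
#'
#' @param model A trained `sv_model`.
#' @param window_sets List of `sv_window_set` objects.
#' @param labels List of 0/1 label matrices aligned with `window_sets`.
#' @param coverage Global mean coverage of the sample (count normaliser).
#' @param threshold Operating threshold; defaults to the model's calibrated
#'   threshold (0.5 if the model carries none).
#' @return Named vector with precision, recall, f1 and threshold.
#' @export
score_windows <- function(model, window_sets, labels, coverage,
                          threshold = NULL) {
  stopifnot(inherits(model, "sv_model"),
            length(window_sets) == length(labels))
  thr <- threshold %||% model$threshold_cal %||% 0.5
  prob <- c(); lab <- c(); valid <- c()
  for (k in seq_along(window_sets)) {
    ws <- window_sets[[k]]
    p <- predict_window_set(ws, model, coverage)
    pad <- pad_mask_matrix(ws, seq_len(nrow(ws$windows)))
    prob <- c(prob, as.vector(t(p)))
    lab <- c(lab, as.vector(t(labels[[k]])))
    valid <- c(valid, as.vector(t(!pad)))
  }
  c(classification_scores(prob, lab, valid, thr), threshold = thr)
}

split_probs <- function(params, config, train_set, idx, batch_size) {
  prob <- c(); lab <- c(); valid <- c()
  for (i0 in seq(1L, length(idx), by = batch_size)) {
    ii <- idx[i0:min(i0 + batch_size - 1L, length(idx))]
    bt <- training_batch(train_set, ii)
    fw <- model_forward(params, config, bt$x, bt$valid, training = FALSE)
    prob <- c(prob, as.vector(1 / (1 + exp(-fw$logits$val))))
    lab <- c(lab, bt$y); valid <- c(valid, bt$valid)
  }
  list(prob = prob, lab = lab, valid = valid)
}

evaluate_split <- function(params, config, train_set, idx, pos_weight,
                           batch_size) {
  tot_loss <- 0; tot_w <- 0
  prob <- c(); lab <- c(); val <- c()
  for (i0 in seq(1L, length(idx), by = batch_size)) {
    ii <- idx[i0:min(i0 + batch_size - 1L, length(idx))]
    bt <- training_batch(train_set, ii)
    w <- ifelse(!bt$valid, 0, ifelse(bt$y == 1, pos_weight, 1))
    fw <- model_forward(params, config, bt$x, bt$valid, training = FALSE)
    z <- as.vector(fw$logits$val)
    l <- pmax(z, 0) - bt$y * z + log1p(exp(-abs(z)))
    tot_loss <- tot_loss + sum(w * l); tot_w <- tot_w + sum(w)
    prob <- c(prob, 1 / (1 + exp(-z))); lab <- c(lab, bt$y); val <- c(val, bt$valid)
  }
  list(loss = tot_loss / tot_w,
       scores = classification_scores(prob, lab, val, config$positive_threshold))
}

#' @export
print.sv_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("sv_model (%s): %d parameters, embed_dim %d, %d layer(s)\n",
              x$variant, np, x$config$embed_dim, x$config$n_layers))
  if (!is.null(x$metrics)) {
    cat(sprintf("trained %d epoch(s); final val_f1 %.3f\n",
                nrow(x$metrics), x$metrics$val_f1[nrow(x$metrics)]))
  }
  invisible(x)
}
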