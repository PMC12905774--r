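## 3D densely connected convolutional classifier, implemented directly in
## vectorized R (im2col gathers + BLAS matrix products, manual
## backpropagation, AdamW with decoupled weight decay). Feature maps are
## stored as [n_voxels x channels] matrices with x-fastest voxel ordering.

#' Architecture configuration for the 3D DenseNet classifier
#'
#' @param in_channels 3 (bpMRI: t2w, adc, high_b) or 5 (bpMRI + RSI C1/C2).
#' @param init_features Channels produced by the convolutional stem.
#' @param growth_rate Channels added by each dense layer.
#' @param block_layers Four integers: layers per dense block.
#' @param compression Transition-layer channel compression in (0, 1].
#' @param out_classes Output classes (2: csPCa vs not).
#' @param scalar_fusion Concatenate the scalar RSIrs_max into the head
#'   (the "+RSI" variant).
#' @param fusion_width Width of the pre-concatenation linear layer.
#' @param preset `"paper"` (64/32/6-12-24-16: the full-scale architecture)
#'   or `"tiny"` (8/4/2-2-2-2: desk-scale, used throughout the tests).
#'   Explicit arguments override the preset.
#' @return A `densenet_config` object.
#' @export
densenet_config <- function(in_channels = 3L, init_features = NULL,
                            growth_rate = NULL, block_layers = NULL,
                            compression = 0.5, out_classes = 2L,
                            scalar_fusion = FALSE, fusion_width = 5L,
                            preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  defaults <- if (preset == "paper") {
    list(init_features = 64L, growth_rate = 32L,
         block_layers = c(6L, 12L, 24L, 16L))
  } else {
    list(init_features = 8L, growth_rate = 4L,
         block_layers = c(2L, 2L, 2L, 2L))
  }
  cfg <- structure(list(
    in_channels = as.integer(in_channels),
    init_features = as.integer(init_features %||% defaults$init_features),
    growth_rate = as.integer(growth_rate %||% defaults$growth_rate),
    block_layers = as.integer(block_layers %||% defaults$block_layers),
    compression = compression,
    out_classes = as.integer(out_classes),
    scalar_fusion = isTRUE(scalar_fusion),
    fusion_width = as.integer(fusion_width),
    preset = preset), class = "densenet_config")
  if (cfg$compression <= 0 || cfg$compression > 1)
    stop("compression must be in (0, 1]")
  if (length(cfg$block_layers) != 4)
    stop("block_layers must have 4 entries")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature-map channel counts through the network
#'
#' Returns the channel count after the stem, after each dense block, and
#' after each of the three transitions, in network order: stem adds nothing
#' beyond `init_features`, each block adds `layers * growth_rate`, each
#' transition multiplies by `compression` (floor).
#'
#' @param config A [densenet_config()].
#' @return Integer vector of length 8: (stem, block1, trans1, block2,
#'   trans2, block3, trans3, block4).
#' @export
channel_trace <- function(config) {
  c_now <- config$init_features
  trace <- c(stem = c_now)
  for (bi in 1:4) {
    c_now <- c_now + config$block_layers[bi] * config$growth_rate
    trace <- c(trace, setNames(c_now, paste0("block", bi)))
    if (bi < 4) {
      c_now <- as.integer(floor(c_now * config$compression))
      trace <- c(trace, setNames(c_now, paste0("trans", bi)))
    }
  }
  as.integer(trace) -> out
  names(out) <- names(trace)
  out
}

## ---- voxel index tables ---------------------------------------------------

## 27-neighbor table for a 3x3x3 kernel with zero padding: entry [v, o] is
## the 1-based linear index of the neighbor, or n_vox + 1 for out-of-bounds
## (which indexes a zero row appended to the feature matrix).
neighbor_table <- function(sp) {
  nv <- prod(sp)
  ix <- arrayInd(seq_len(nv), sp)
  offs <- as.matrix(expand.grid(ox = -1:1, oy = -1:1, oz = -1:1))
  tab <- matrix(nv + 1L, nv, 27L)
  for (o in seq_len(27)) {
    nb <- sweep(ix, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= sp[1] &
          nb[, 2] >= 1 & nb[, 2] <= sp[2] &
          nb[, 3] >= 1 & nb[, 3] <= sp[3]
    lin <- (nb[, 3] - 1L) * sp[1] * sp[2] + (nb[, 2] - 1L) * sp[1] + nb[, 1]
    tab[ok, o] <- lin[ok]
  }
  tab
}

## 2x2x2 average pooling (ceil mode): parent index per voxel plus counts
pool_table <- function(sp) {
  out_sp <- as.integer(ceiling(sp / 2))
  ix <- arrayInd(seq_len(prod(sp)), sp)
  px <- (ix - 1L) %/% 2L + 1L
  parent <- (px[, 3] - 1L) * out_sp[1] * out_sp[2] +
            (px[, 2] - 1L) * out_sp[1] + px[, 1]
  counts <- tabulate(parent, nbins = prod(out_sp))
  list(parent = parent, counts = counts, out_sp = out_sp, in_sp = sp)
}

.rsipipe_cache <- new.env(parent = emptyenv())

cached_tables <- function(sp) {
  key <- paste(sp, collapse = "x")
  if (is.null(.rsipipe_cache[[key]]))
    .rsipipe_cache[[key]] <- list(nb = neighbor_table(sp), pool = pool_table(sp))
  .rsipipe_cache[[key]]
}

## ---- conv / pool primitives ----------------------------------------------

im2col <- function(X, nb_tab) {
  X0 <- rbind(X, 0)
  nc <- ncol(X)
  cols <- vector("list", 27)
  for (o in seq_len(27)) cols[[o]] <- X0[nb_tab[, o], , drop = FALSE]
  do.call(cbind, cols)  # [nvox x 27*nc], offset-major blocks of nc channels
}

conv3_forward <- function(X, W, b, nb_tab) {
  P <- im2col(X, nb_tab)
  Y <- P %*% W
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, P = P)
}

conv3_backward <- function(dY, P, W, nb_tab, n_in) {
  dW <- crossprod(P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(W)
  nv <- nrow(dY)
  dX <- matrix(0, nv + 1, n_in)
  for (o in seq_len(27)) {
    blk <- dP[, ((o - 1) * n_in + 1):(o * n_in), drop = FALSE]
    idx <- nb_tab[, o]
    real <- idx <= nv
    dX[idx[real], ] <- dX[idx[real], , drop = FALSE] + blk[real, , drop = FALSE]
  }
  list(dX = dX[seq_len(nv), , drop = FALSE], dW = dW, db = db)
}

avgpool_forward <- function(X, pt) {
  S <- rowsum(X, pt$parent)
  S / pt$counts
}

avgpool_backward <- function(dY, pt) {
  dY[pt$parent, , drop = FALSE] / pt$counts[pt$parent]
}

## ---- parameter initialization --------------------------------------------

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

#' Build (initialize) a 3D DenseNet model
#'
#' Stem 3x3x3 convolution, four dense blocks (pre-activation ReLU + 3x3x3
#' convolution per layer, dense concatenation) separated by transitions
#' (ReLU + 1x1x1 channel compression + 2x average pooling), adaptive global
#' average pooling, and a classification head. With `scalar_fusion` the
#' pooled vector passes through a linear layer to `fusion_width` features,
#' is concatenated with the scalar RSIrs_max, and a final linear layer maps
#' to the class scores; otherwise a single linear layer does.
#'
#' @param config A [densenet_config()].
#' @param seed Seed for parameter initialization.
#' @return A `densenet_model` list (parameters, config, scalar
#'   normalization placeholders).
#' @export
build_model <- function(config, seed = 1L) {
  set.seed(seed)
  tr <- channel_trace(config)
  params <- list()
  params$stem_W <- he_init(27 * config$in_channels, config$init_features)
  params$stem_b <- numeric(config$init_features)
  c_now <- config$init_features
  for (bi in 1:4) {
    for (li in seq_len(config$block_layers[bi])) {
      nm <- sprintf("b%d_l%d", bi, li)
      params[[paste0(nm, "_W")]] <- he_init(27 * c_now, config$growth_rate)
      params[[paste0(nm, "_b")]] <- numeric(config$growth_rate)
      c_now <- c_now + config$growth_rate
    }
    if (bi < 4) {
      c_out <- as.integer(floor(c_now * config$compression))
      params[[sprintf("t%d_W", bi)]] <- he_init(c_now, c_out)
      params[[sprintf("t%d_b", bi)]] <- numeric(c_out)
      c_now <- c_out
    }
  }
  final_c <- c_now
  stopifnot(final_c == unname(tr["block4"]))
  if (config$scalar_fusion) {
    params$head1_W <- he_init(final_c, config$fusion_width)
    params$head1_b <- numeric(config$fusion_width)
    params$head2_W <- he_init(config$fusion_width + 1, config$out_classes)
    params$head2_b <- numeric(config$out_classes)
  } else {
    params$head_W <- he_init(final_c, config$out_classes)
    params$head_b <- numeric(config$out_classes)
  }
  structure(list(params = params, config = config, final_channels = final_c,
                 scalar_center = 0, scalar_scale = 1),
            class = "densenet_model")
}

## Forward pass for one sample. x: [nvox x in_channels] matrix; sp: spatial
## dims; scalar: standardized RSIrs_max (or NULL). Returns logits and, when
## keep_cache, everything backward needs.
net_forward <- function(model, x, sp, scalar = NULL, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  if (ncol(x) != cfg$in_channels)
    stop("input has ", ncol(x), " channels; model expects ", cfg$in_channels)
  if (cfg$scalar_fusion && is.null(scalar))
    stop("scalar_fusion model requires the rsirs_max scalar")
  if (!cfg$scalar_fusion && !is.null(scalar))
    stop("model without scalar_fusion does not accept a scalar input")
  cache <- list(sp0 = sp)
  tabs <- cached_tables(sp)
  st <- conv3_forward(x, p$stem_W, p$stem_b, tabs$nb)
  X <- st$Y
  if (keep_cache) cache$stem_P <- st$P
  for (bi in 1:4) {
    for (li in seq_len(cfg$block_layers[bi])) {
      nm <- sprintf("b%d_l%d", bi, li)
      H <- pmax(X, 0)
      cv <- conv3_forward(H, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]], tabs$nb)
      if (keep_cache) {
        cache[[paste0(nm, "_relu_in")]] <- X
        cache[[paste0(nm, "_P")]] <- cv$P
      }
      X <- cbind(X, cv$Y)
    }
    if (bi < 4) {
      H <- pmax(X, 0)
      if (keep_cache) cache[[sprintf("t%d_relu_in", bi)]] <- X
      Y <- sweep(H %*% p[[sprintf("t%d_W", bi)]], 2, p[[sprintf("t%d_b", bi)]], `+`)
      if (keep_cache) cache[[sprintf("t%d_H", bi)]] <- H
      X <- avgpool_forward(Y, tabs$pool)
      if (keep_cache) cache[[sprintf("t%d_pool", bi)]] <- tabs$pool
      sp <- tabs$pool$out_sp
      tabs <- cached_tables(sp)
    }
  }
  Hf <- pmax(X, 0)
  if (keep_cache) { cache$final_relu_in <- X; cache$final_sp <- sp }
  g <- colMeans(Hf)  # global average pool
  if (cfg$scalar_fusion) {
    h1 <- as.vector(g %*% p$head1_W) + p$head1_b
    hcat <- c(h1, scalar)
    logits <- as.vector(hcat %*% p$head2_W) + p$head2_b
    if (keep_cache) { cache$g <- g; cache$h1 <- h1; cache$hcat <- hcat }
  } else {
    logits <- as.vector(g %*% p$head_W) + p$head_b
    if (keep_cache) cache$g <- g
  }
  list(logits = logits, cache = cache)
}

## Backward pass for one sample; dlogits: gradient at the logits. Returns a
## named list of parameter gradients (same names/shapes as params).
net_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  gr <- list()
  if (cfg$scalar_fusion) {
    gr$head2_W <- outer(cache$hcat, dlogits)
    gr$head2_b <- dlogits
    dhcat <- as.vector(p$head2_W %*% dlogits)
    dh1 <- dhcat[seq_len(cfg$fusion_width)]
    gr$head1_W <- outer(cache$g, dh1)
    gr$head1_b <- dh1
    dg <- as.vector(p$head1_W %*% dh1)
  } else {
    gr$head_W <- outer(cache$g, dlogits)
    gr$head_b <- dlogits
    dg <- as.vector(p$head_W %*% dlogits)
  }
  sp <- cache$final_sp
  nv <- prod(sp)
  dHf <- matrix(dg / nv, nv, length(dg), byrow = TRUE)
  dX <- dHf * (cache$final_relu_in > 0)
  for (bi in 4:1) {
    tabs <- cached_tables(sp)
    for (li in rev(seq_len(cfg$block_layers[bi]))) {
      nm <- sprintf("b%d_l%d", bi, li)
      gw <- cfg$growth_rate
      n_before <- ncol(dX) - gw
      dY <- dX[, (n_before + 1):ncol(dX), drop = FALSE]
      dX <- dX[, seq_len(n_before), drop = FALSE]
      bk <- conv3_backward(dY, cache[[paste0(nm, "_P")]],
                           p[[paste0(nm, "_W")]], tabs$nb, n_before)
      gr[[paste0(nm, "_W")]] <- bk$dW
      gr[[paste0(nm, "_b")]] <- bk$db
      dX <- dX + bk$dX * (cache[[paste0(nm, "_relu_in")]] > 0)
    }
    if (bi > 1) {
      ti <- bi - 1
      pt <- cache[[sprintf("t%d_pool", ti)]]
      dY <- avgpool_backward(dX, pt)
      H <- cache[[sprintf("t%d_H", ti)]]
      gr[[sprintf("t%d_W", ti)]] <- crossprod(H, dY)
      gr[[sprintf("t%d_b", ti)]] <- colSums(dY)
      dH <- dY %*% t(p[[sprintf("t%d_W", ti)]])
      dX <- dH * (cache[[sprintf("t%d_relu_in", ti)]] > 0)
      sp <- pt$in_sp
    }
  }
  tabs <- cached_tables(cache$sp0)
  st <- conv3_backward(dX, cache$stem_P, p$stem_W, tabs$nb, cfg$in_channels)
  gr$stem_W <- st$dW
  gr$stem_b <- st$db
  gr
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Linear-warmup + cosine-annealing learning-rate schedule
#'
#' Ramps linearly from 0 to `lr` over `warmup_steps`, then decays along a
#' half cosine to 0 at `total_steps`.
#'
#' @param step Step index (0-based; vectorized).
#' @param warmup_steps,total_steps Schedule lengths in optimizer steps.
#' @param lr Peak learning rate.
#' @return Learning rate(s) at `step`.
#' @export
lr_schedule <- function(step, warmup_steps, total_steps, lr) {
  step <- pmin(step, total_steps)
  ifelse(step <= warmup_steps & warmup_steps > 0,
         lr * step / max(warmup_steps, 1),
         lr * 0.5 * (1 + cos(pi * (step - warmup_steps) /
                               max(total_steps - warmup_steps, 1))))
}

#' Training configuration
#'
#' @param learning_rate Peak learning rate for AdamW (default 0.001).
#' @param weight_decay Decoupled weight decay (default 0.01, the AdamW
#'   convention).
#' @param warmup_frac Fraction of total optimizer steps used for linear
#'   warm-up (default 0.1).
#' @param total_epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param internal_val_fraction Stratified fraction withheld for best-epoch
#'   selection only (default 0.10).
#' @param best_epoch_metric `"val_auc"` (maximized) or `"val_loss"`
#'   (minimized).
#' @param standardize_scalar Z-score the fused RSIrs_max scalar using
#'   training-set statistics (default TRUE).
#' @param augment Optional [augment_policy()] applied to training samples.
#' @param seed RNG seed controlling the split, shuffling, initialization and
#'   augmentation.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-2,
                         warmup_frac = 0.1, total_epochs = 10L,
                         batch_size = 8L, internal_val_fraction = 0.10,
                         best_epoch_metric = c("val_auc", "val_loss"),
                         standardize_scalar = TRUE, augment = NULL,
                         seed = 1L) {
  best_epoch_metric <- match.arg(best_epoch_metric)
  if (internal_val_fraction <= 0 || internal_val_fraction >= 1)
    stop("internal_val_fraction must be in (0, 1)")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 warmup_frac = warmup_frac,
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 internal_val_fraction = internal_val_fraction,
                 best_epoch_metric = best_epoch_metric,
                 standardize_scalar = isTRUE(standardize_scalar),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

## convert a model_input (or raw [C, x, y, z] array) into the internal
## [nvox x C] matrix plus spatial dims
input_matrix <- function(inp) {
  arr <- if (inherits(inp, "model_input")) inp$array else inp
  dm <- dim(arr)
  list(x = t(matrix(arr, nrow = dm[1])), sp = dm[2:4])
}

input_scalar <- function(inp) {
  if (inherits(inp, "model_input")) inp$rsirs_max else NULL
}

#' Stratified index split for internal validation
#' @keywords internal
stratified_split <- function(labels, fraction) {
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("both classes must be present for a stratified split")
  val <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(length(idx) * fraction))
    if (n_val >= length(idx))
      stop("class ", cl, " too small for a stratified split")
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train a 3D DenseNet classifier
#'
#' Minimizes cross-entropy over the two-way output (equivalent to binary
#' cross-entropy for two classes) with AdamW and a linear-warmup +
#' cosine-annealing schedule. A stratified `internal_val_fraction` of the
#' data is withheld for best-epoch selection only; the returned parameters
#' are those of the epoch with the best validation metric.
#'
#' @param inputs List of `model_input` tensors (or raw `[C, x, y, z]`
#'   arrays) with a common shape.
#' @param labels Binary labels (0/1) aligned with `inputs`.
#' @param net_config A [densenet_config()].
#' @param tcfg A [train_config()].
#' @param scalars Optional numeric RSIrs_max vector (required when
#'   `net_config$scalar_fusion`); overrides scalars carried on the tensors.
#' @param val_indices Optional explicit validation indices (e.g. from
#'   [loco_split()]); when given, the internal stratified draw is skipped.
#' @return A `trained_classifier`: `model`, `best_epoch`, `history`
#'   (per-epoch data.frame), `val_indices`.
#' @export
train_classifier <- function(inputs, labels, net_config, tcfg,
                             scalars = NULL, val_indices = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes")
  if (is.null(scalars))
    scalars <- vapply(inputs, function(i) input_scalar(i) %||% NA_real_, 0)
  if (net_config$scalar_fusion && anyNA(scalars))
    stop("scalar_fusion model requires an rsirs_max scalar per patient")
  set.seed(tcfg$seed)
  val_idx <- if (is.null(val_indices))
    stratified_split(labels, tcfg$internal_val_fraction) else as.integer(val_indices)
  train_idx <- setdiff(seq_along(inputs), val_idx)

  sc_center <- 0; sc_scale <- 1
  if (net_config$scalar_fusion && tcfg$standardize_scalar) {
    sc_center <- mean(scalars[train_idx])
    sc_scale <- max(sd(scalars[train_idx]), 1e-8)
  }
  zscalars <- (scalars - sc_center) / sc_scale

  model <- build_model(net_config, seed = tcfg$seed)
  model$scalar_center <- sc_center
  model$scalar_scale <- sc_scale

  mats <- lapply(inputs, input_matrix)
  n_train <- length(train_idx)
  steps_per_epoch <- ceiling(n_train / tcfg$batch_size)
  total_steps <- steps_per_epoch * tcfg$total_epochs
  warmup_steps <- max(1L, round(tcfg$warmup_frac * total_steps))

  m_state <- lapply(model$params, function(p) p * 0)
  v_state <- lapply(model$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_auc = numeric(0),
                     lr = numeric(0))
  best_val <- if (tcfg$best_epoch_metric == "val_auc") -Inf else Inf
  best_params <- model$params
  best_epoch <- 1L

  eval_set <- function(idx) {
    losses <- numeric(length(idx)); probs <- numeric(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      sc <- if (net_config$scalar_fusion) zscalars[i] else NULL
      fw <- net_forward(model, mats[[i]]$x, mats[[i]]$sp, sc)
      pr <- softmax(fw$logits)
      losses[k] <- -log(max(pr[labels[i] + 1], 1e-12))
      probs[k] <- pr[2]
    }
    list(loss = mean(losses), probs = probs)
  }

  for (ep in seq_len(tcfg$total_epochs)) {
    ord <- sample(train_idx)
    ep_losses <- numeric(0)
    for (bs in seq(1, n_train, by = tcfg$batch_size)) {
      batch <- ord[bs:min(bs + tcfg$batch_size - 1, n_train)]
      grads <- NULL
      bl <- 0
      for (i in batch) {
        xi <- mats[[i]]
        if (!is.null(tcfg$augment)) {
          aug <- augment(structure(list(array = array(t(xi$x), c(ncol(xi$x), xi$sp)),
                                        rsirs_max = NULL),
                                   class = "model_input"), tcfg$augment)
          xi <- input_matrix(aug)
        }
        sc <- if (net_config$scalar_fusion) zscalars[i] else NULL
        fw <- net_forward(model, xi$x, xi$sp, sc, keep_cache = TRUE)
        pr <- softmax(fw$logits)
        bl <- bl - log(max(pr[labels[i] + 1], 1e-12))
        dlog <- pr
        dlog[labels[i] + 1] <- dlog[labels[i] + 1] - 1
        g <- net_backward(model, fw$cache, dlog / length(batch))
        grads <- if (is.null(grads)) g else
          mapply(`+`, grads, g[names(grads)], SIMPLIFY = FALSE)
      }
      ep_losses <- c(ep_losses, bl / length(batch))
      step <- step + 1L
      lr_t <- lr_schedule(step, warmup_steps, total_steps, tcfg$learning_rate)
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
        mh <- m_state[[nm]] / (1 - beta1^step)
        vh <- v_state[[nm]] / (1 - beta2^step)
        decay <- if (grepl("_b$", nm)) 0 else tcfg$weight_decay
        model$params[[nm]] <- model$params[[nm]] -
          lr_t * (mh / (sqrt(vh) + eps) + decay * model$params[[nm]])
      }
    }
    ev <- eval_set(val_idx)
    val_auc <- if (length(unique(labels[val_idx])) == 2)
      roc_auc(ev$probs, labels[val_idx]) else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   val_loss = ev$loss, val_auc = val_auc,
                                   lr = lr_t))
    crit <- if (tcfg$best_epoch_metric == "val_auc") val_auc else ev$loss
    improved <- if (tcfg$best_epoch_metric == "val_auc")
      is.finite(crit) && crit > best_val else crit < best_val
    if (improved) {
      best_val <- crit
      best_params <- model$params
      best_epoch <- ep
    }
  }
  model$params <- best_params
  structure(list(model = model, best_epoch = best_epoch, history = hist,
                 val_indices = val_idx, train_config = tcfg),
            class = "trained_classifier")
}

#' Predict csPCa probabilities
#'
#' Softmax positive-class probability per patient, in input order.
#'
#' @param trained A `trained_classifier` (or bare `densenet_model`).
#' @param inputs List of tensors as in [train_classifier()].
#' @param scalars Optional RSIrs_max vector (standardized internally with
#'   the training statistics).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(trained, inputs, scalars = NULL) {
  model <- if (inherits(trained, "trained_classifier")) trained$model else trained
  if (is.null(scalars))
    scalars <- vapply(inputs, function(i) input_scalar(i) %||% NA_real_, 0)
  z <- (scalars - model$scalar_center) / model$scalar_scale
  vapply(seq_along(inputs), function(i) {
    mi <- input_matrix(inputs[[i]])
    sc <- if (model$config$scalar_fusion) z[i] else NULL
    softmax(net_forward(model, mi$x, mi$sp, sc)$logits)[2]
  }, 0)
}

#' Raw two-way scores (pre-softmax logits)
#' @inheritParams predict_proba
#' @return Matrix `[n x out_classes]` of logits.
#' @export
predict_logits <- function(trained, inputs, scalars = NULL) {
  model <- if (inherits(trained, "trained_classifier")) trained$model else trained
  if (is.null(scalars))
    scalars <- vapply(inputs, function(i) input_scalar(i) %||% NA_real_, 0)
  z <- (scalars - model$scalar_center) / model$scalar_scale
  t(vapply(seq_along(inputs), function(i) {
    mi <- input_matrix(inputs[[i]])
    sc <- if (model$config$scalar_fusion) z[i] else NULL
    net_forward(model, mi$x, mi$sp, sc)$logits
  }, numeric(model$config$out_classes)))
}

#' Save / load a trained classifier
#'
#' The checkpoint is self-describing: configuration snapshot, parameters,
#' scalar-normalization constants, and training history.
#'
#' @param trained A `trained_classifier`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the reloaded `trained_classifier` (load).
#' @export
save_classifier <- function(trained, path) {
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)

#' Occlusion sensitivity map
#'
#' Slides a cubic patch over the volume, replaces it (all channels) with the
#' per-channel mean of the tensor, and records the drop in predicted csPCa
#' probability; overlapping patch contributions are averaged. Large drops
#' mark regions the classifier relies on.
#'
#' @param trained A `trained_classifier`.
#' @param input A single tensor.
#' @param patch_size Cubic patch edge length, voxels.
#' @param stride Sliding stride, voxels (> 0).
#' @param scalar Optional RSIrs_max for fusion models.
#' @return Array of the input spatial shape.
#' @export
occlusion_sensitivity <- function(trained, input, patch_size = 4L,
                                  stride = 2L, scalar = NULL) {
  if (stride <= 0) stop("stride must be positive")
  model <- if (inherits(trained, "trained_classifier")) trained$model else trained
  mi <- input_matrix(input)
  sp <- mi$sp
  if (any(patch_size > sp)) stop("patch_size exceeds volume size")
  z <- if (model$config$scalar_fusion) {
    s <- scalar %||% input_scalar(input)
    if (is.null(s)) stop("fusion model requires the rsirs_max scalar")
    (s - model$scalar_center) / model$scalar_scale
  } else NULL
  base_p <- softmax(net_forward(model, mi$x, sp, z)$logits)[2]
  ch_means <- colMeans(mi$x)
  heat <- array(0, dim = sp)
  counts <- array(0, dim = sp)
  starts <- lapply(sp, function(d) {
    s <- seq(1, max(d - patch_size + 1, 1), by = stride)
    if (max(s) + patch_size - 1 < d) s <- c(s, d - patch_size + 1)
    unique(s)
  })
  lin <- array(seq_len(prod(sp)), dim = sp)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    vox <- as.vector(lin[sx:(sx + patch_size - 1),
                         sy:(sy + patch_size - 1),
                         sz:(sz + patch_size - 1)])
    xo <- mi$x
    xo[vox, ] <- matrix(ch_means, length(vox), length(ch_means), byrow = TRUE)
    p <- softmax(net_forward(model, xo, sp, z)$logits)[2]
    heat[vox] <- heat[vox] + (base_p - p)
    counts[vox] <- counts[vox] + 1
  }
  heat / pmax(counts, 1)
}
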