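# SE-ResNet-18 binary classifier, implemented directly on the compiled
# im2col/GEMM convolution kernels. Feature maps are arrays (H, W, C, N).
# Architecture: 3x3 stride-1 stem convolution + 2x2 max pool, four stages
# of two residual blocks (conv-BN-ReLU, conv-BN, SE recalibration, shortcut
# add, ReLU; stride-2 with a projection shortcut at stage transitions),
# global average pooling and a single-logit head with logistic output.
# Counting weighted layers as stem + 16 block convolutions + head gives the
# eponymous 18.

#' Model configuration
#'
#' Defaults follow the reference training protocol: canonical 18-layer
#' residual filter counts (64, 128, 256, 512), SE reduction ratio 8, Adam
#' with learning rate 1e-5, 10 epochs, binary cross-entropy. Smaller filter
#' counts and higher learning rates are useful for desk-scale synthetic
#' experiments.
#'
#' @param stage_filters integer vector of 4 per-stage filter counts.
#' @param blocks_per_stage residual blocks per stage.
#' @param se_reduction SE bottleneck reduction ratio `r`; must divide every
#'   stage filter count.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param use_se include SE recalibration (set `FALSE` for the plain
#'   residual-network ablation).
#' @param input_shape spatial input shape (rows, cols) of the spectrogram.
#' @param rng_seed seed governing initialization and batch shuffling.
#' @return an object of class `model_config`.
#' @export
model_config <- function(stage_filters = c(64L, 128L, 256L, 512L),
                         blocks_per_stage = 2L, se_reduction = 8L,
                         learning_rate = 1e-5, epochs = 10L,
                         batch_size = 16L, use_se = TRUE,
                         input_shape = c(256L, 218L), rng_seed = 1L) {
  if (length(stage_filters) != 4)
    vs_stop("stage_filters must have length 4", "vibroscrew_config_error")
  if (any(stage_filters %% se_reduction != 0))
    vs_stop("se_reduction must divide every stage filter count",
            "vibroscrew_config_error")
  if (epochs < 1)
    vs_stop("epochs must be >= 1", "vibroscrew_config_error")
  if (batch_size < 1)
    vs_stop("batch_size must be >= 1", "vibroscrew_config_error")
  structure(list(stage_filters = as.integer(stage_filters),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 kernel_size = 3L, se_reduction = as.integer(se_reduction),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), use_se = use_se,
                 input_shape = as.integer(input_shape),
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

## ---- primitive layers -------------------------------------------------

conv_fwd <- function(x, w, b, stride, pad) {
  dw <- dim(w)
  conv2d_fwd_cpp(x, dim(x), matrix(w, dw[1] * dw[2] * dw[3], dw[4]), b,
                 dw[1], dw[2], stride, pad)
}

conv_bwd <- function(x, w, dy, stride, pad) {
  dw <- dim(w)
  g <- conv2d_bwd_cpp(x, dim(x), matrix(w, dw[1] * dw[2] * dw[3], dw[4]),
                      dy, dw[1], dw[2], stride, pad)
  g$dw <- array(g$dw, dw)
  g
}

# per-channel sums/means for (H, W, C, N) arrays
channel_mean <- function(x) {
  d <- dim(x)
  rowMeans(colMeans(array(x, c(d[1] * d[2], d[3], d[4])), dims = 1))
}
channel_sum <- function(x) {
  d <- dim(x)
  rowSums(colSums(array(x, c(d[1] * d[2], d[3], d[4])), dims = 1))
}
# broadcast a per-channel vector over an (H, W, C, N) shape
bc_channel <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

bn_fwd <- function(x, gamma, beta, training, rm, rv,
                   momentum = 0.9, eps = 1e-5, relu = FALSE) {
  d <- dim(x)
  if (training) {
    st <- channel_stats_cpp(x, d)
    mu <- st$mean
    va <- st$var
    rm_new <- momentum * rm + (1 - momentum) * mu
    rv_new <- momentum * rv + (1 - momentum) * va
  } else {
    mu <- rm; va <- rv; rm_new <- rm; rv_new <- rv
  }
  invstd <- 1 / sqrt(va + eps)
  ap <- bn_apply_cpp(x, d, mu, invstd, gamma, beta, relu)
  list(y = ap$y, xhat = ap$xhat, invstd = invstd, rm = rm_new, rv = rv_new)
}

bn_bwd <- function(dy, cache, gamma) {
  g <- bn_bwd_cpp(dy, cache$xhat, dim(dy), gamma, cache$invstd)
  list(dx = g$dx, dgamma = g$dgamma, dbeta = g$dbeta)
}

se_fwd <- function(u, w1, b1, w2, b2) {
  d <- dim(u)
  z <- channel_gap_cpp(u, d) # C x N squeeze
  a1 <- w1 %*% z + b1
  h <- pmax(a1, 0)
  a2 <- w2 %*% h + b2
  s <- 1 / (1 + exp(-a2))
  list(y = scale_channels_cpp(u, d, s), z = z, h = h, s = s)
}

se_bwd <- function(dy, u, cache, w1, w2) {
  d <- dim(u)
  hw <- d[1] * d[2]
  s <- cache$s
  du <- scale_channels_cpp(dy, d, s)
  ds <- channel_gap_cpp(dy, d, u) * hw
  da2 <- ds * s * (1 - s)
  dw2 <- da2 %*% t(cache$h)
  db2 <- rowSums(da2)
  dh <- t(w2) %*% da2
  dh[cache$h <= 0] <- 0
  dw1 <- dh %*% t(cache$z)
  db1 <- rowSums(dh)
  dz <- t(w1) %*% dh
  du <- add_channel_cpp(du, d, dz / hw)
  list(du = du, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

#' Squeeze-and-Excitation recalibration of a feature map
#'
#' Channel attention: global average pooling over the spatial dimensions
#' (squeeze), a bottleneck of width `C/r` with ReLU, expansion back to `C`
#' with a logistic squashing, and channel-wise rescaling of the input. The
#' per-channel scales lie in (0, 1), so the output never exceeds the input
#' in magnitude for nonnegative inputs.
#'
#' @param feature_map array `(H, W, C)` or `(H, W, C, N)`.
#' @param r reduction ratio; must divide the channel count.
#' @param weights optional list `w1, b1, w2, b2`; initialized with
#'   `seed` when omitted.
#' @param seed seed for weight initialization when `weights` is `NULL`.
#' @return recalibrated feature map of the same shape.
#' @export
se_block <- function(feature_map, r = 8L, weights = NULL, seed = 1L) {
  d <- dim(feature_map)
  squeeze3 <- FALSE
  if (length(d) == 3) { dim(feature_map) <- c(d, 1L); squeeze3 <- TRUE }
  C <- dim(feature_map)[3]
  if (C %% r != 0)
    vs_stop(sprintf("channel count %d not divisible by reduction %d", C, r),
            "vibroscrew_config_error")
  if (is.null(weights)) {
    cr <- C %/% r
    weights <- with_seed(seed, list(
      w1 = matrix(rnorm(cr * C, 0, sqrt(2 / C)), cr, C),
      b1 = numeric(cr),
      w2 = matrix(rnorm(C * cr, 0, sqrt(2 / cr)), C, cr),
      b2 = numeric(C)))
  }
  out <- se_fwd(feature_map, weights$w1, weights$b1,
                weights$w2, weights$b2)$y
  if (squeeze3) dim(out) <- d
  out
}

## ---- model assembly ---------------------------------------------------

init_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Build an (untrained) SE-ResNet-18
#'
#' @param config a [model_config()].
#' @return an object of class `se_resnet`: parameter container, batch-norm
#'   running statistics, and the attached config. The forward pass is
#'   deterministic given fixed parameters.
#' @export
build_model <- function(config = model_config()) {
  f <- config$stage_filters
  r <- config$se_reduction
  params <- list()
  bnst <- list()
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- numeric(c)
    bnst[[paste0(name, ".mean")]] <<- numeric(c)
    bnst[[paste0(name, ".var")]] <<- rep(1, c)
  }
  with_seed(derive_seed(config$rng_seed, 11L), {
    params[["stem.w"]] <- init_conv(3, 3, 1, f[1])
    params[["stem.b"]] <- numeric(f[1])
    add_bn("stem.bn", f[1])
    cin <- f[1]
    for (si in 1:4) {
      for (bi in seq_len(config$blocks_per_stage)) {
        pre <- sprintf("s%d.b%d", si, bi)
        cout <- f[si]
        stride <- if (si > 1 && bi == 1) 2L else 1L
        params[[paste0(pre, ".conv1.w")]] <- init_conv(3, 3, cin, cout)
        params[[paste0(pre, ".conv1.b")]] <- numeric(cout)
        add_bn(paste0(pre, ".bn1"), cout)
        params[[paste0(pre, ".conv2.w")]] <- init_conv(3, 3, cout, cout)
        params[[paste0(pre, ".conv2.b")]] <- numeric(cout)
        add_bn(paste0(pre, ".bn2"), cout)
        if (config$use_se) {
          cr <- cout %/% r
          params[[paste0(pre, ".se.w1")]] <-
            matrix(rnorm(cr * cout, 0, sqrt(2 / cout)), cr, cout)
          params[[paste0(pre, ".se.b1")]] <- numeric(cr)
          params[[paste0(pre, ".se.w2")]] <-
            matrix(rnorm(cout * cr, 0, sqrt(2 / cr)), cout, cr)
          params[[paste0(pre, ".se.b2")]] <- numeric(cout)
        }
        if (stride != 1L || cin != cout) {
          params[[paste0(pre, ".proj.w")]] <- init_conv(1, 1, cin, cout)
          params[[paste0(pre, ".proj.b")]] <- numeric(cout)
          add_bn(paste0(pre, ".projbn"), cout)
        }
        cin <- cout
      }
    }
    params[["head.w"]] <- matrix(rnorm(f[4], 0, sqrt(1 / f[4])), f[4], 1)
    params[["head.b"]] <- 0
  })
  structure(list(config = config, params = params, bn_state = bnst,
                 epoch_losses = numeric(0), trained = FALSE,
                 train_digest = NA_character_),
            class = "se_resnet")
}

#' Count the weighted layers of a model
#'
#' Counts the stem convolution, the two main-path convolutions of each
#' residual block, and the classification head (projection shortcuts, SE
#' bottlenecks and normalization layers are excluded, per the usual
#' residual-network naming convention).
#'
#' @param model an `se_resnet`.
#' @return integer layer count (18 for the default configuration).
#' @export
count_weighted_layers <- function(model) {
  1L + 2L * 4L * model$config$blocks_per_stage + 1L
}

# forward through one residual block; returns output and cache
block_fwd <- function(x, p, st, pre, stride, use_se, training) {
  cache <- list(x = x)
  g <- function(n) p[[paste0(pre, ".", n)]]
  s <- function(n) st[[paste0(pre, ".", n)]]
  out1 <- conv_fwd(x, g("conv1.w"), g("conv1.b"), stride, 1L)
  bn1 <- bn_fwd(out1, g("bn1.gamma"), g("bn1.beta"), training,
                s("bn1.mean"), s("bn1.var"), relu = TRUE)
  a1 <- bn1$y
  out2 <- conv_fwd(a1, g("conv2.w"), g("conv2.b"), 1L, 1L)
  bn2 <- bn_fwd(out2, g("bn2.gamma"), g("bn2.beta"), training,
                s("bn2.mean"), s("bn2.var"))
  main <- bn2$y
  se <- NULL
  if (use_se) {
    se <- se_fwd(main, g("se.w1"), g("se.b1"), g("se.w2"), g("se.b2"))
    main <- se$y
  }
  has_proj <- !is.null(g("proj.w"))
  if (has_proj) {
    sc_conv <- conv_fwd(x, g("proj.w"), g("proj.b"), stride, 0L)
    scbn <- bn_fwd(sc_conv, g("projbn.gamma"), g("projbn.beta"), training,
                   s("projbn.mean"), s("projbn.var"))
    shortcut <- scbn$y
  } else {
    sc_conv <- NULL; scbn <- NULL
    shortcut <- x
  }
  pre_act <- main + shortcut
  y <- relu_fwd_cpp(pre_act)
  cache <- list(x = x, out1 = out1, bn1 = bn1, a1 = a1, out2 = out2,
                bn2 = bn2, se = se, bn2y = bn2$y, sc_conv = sc_conv,
                scbn = scbn, pre_act = pre_act, y = y,
                stride = stride, has_proj = has_proj)
  cache
}

block_bwd <- function(dy, cache, p, pre, use_se, grads) {
  g <- function(n) p[[paste0(pre, ".", n)]]
  put <- function(n, v) grads[[paste0(pre, ".", n)]] <<- v
  dpre <- relu_bwd_cpp(dy, cache$pre_act)
  # shortcut branch
  if (cache$has_proj) {
    scb <- bn_bwd(dpre, cache$scbn, g("projbn.gamma"))
    put("projbn.gamma", scb$dgamma); put("projbn.beta", scb$dbeta)
    cg <- conv_bwd(cache$x, g("proj.w"), scb$dx, cache$stride, 0L)
    put("proj.w", cg$dw); put("proj.b", cg$db)
    dx_short <- cg$dx
  } else {
    dx_short <- dpre
  }
  # main branch
  dmain <- dpre
  if (use_se) {
    seb <- se_bwd(dmain, cache$bn2y, cache$se, g("se.w1"), g("se.w2"))
    put("se.w1", seb$dw1); put("se.b1", seb$db1)
    put("se.w2", seb$dw2); put("se.b2", seb$db2)
    dmain <- seb$du
  }
  b2 <- bn_bwd(dmain, cache$bn2, g("bn2.gamma"))
  put("bn2.gamma", b2$dgamma); put("bn2.beta", b2$dbeta)
  c2 <- conv_bwd(cache$a1, g("conv2.w"), b2$dx, 1L, 1L)
  put("conv2.w", c2$dw); put("conv2.b", c2$db)
  da1 <- relu_bwd_cpp(c2$dx, cache$bn1$y)
  b1 <- bn_bwd(da1, cache$bn1, g("bn1.gamma"))
  put("bn1.gamma", b1$dgamma); put("bn1.beta", b1$dbeta)
  c1 <- conv_bwd(cache$x, g("conv1.w"), b1$dx, cache$stride, 1L)
  put("conv1.w", c1$dw); put("conv1.b", c1$db)
  list(dx = c1$dx + dx_short, grads = grads)
}

model_fwd <- function(model, x, training = FALSE) {
  p <- model$params
  st <- model$bn_state
  cfg <- model$config
  caches <- list()
  out <- conv_fwd(x, p[["stem.w"]], p[["stem.b"]], 1L, 1L)
  bn <- bn_fwd(out, p[["stem.bn.gamma"]], p[["stem.bn.beta"]], training,
               st[["stem.bn.mean"]], st[["stem.bn.var"]], relu = TRUE)
  a <- bn$y
  pool <- maxpool2_fwd_cpp(a, dim(a))
  caches$stem <- list(x = x, out = out, bn = bn, a = a, pool = pool,
                      adim = dim(a))
  h <- pool$y
  for (si in 1:4) {
    for (bi in seq_len(cfg$blocks_per_stage)) {
      pre <- sprintf("s%d.b%d", si, bi)
      stride <- if (si > 1 && bi == 1) 2L else 1L
      cache <- block_fwd(h, p, st, pre, stride, cfg$use_se, training)
      caches[[pre]] <- cache
      h <- cache$y
    }
  }
  d <- dim(h)
  gap <- channel_gap_cpp(h, d)
  logit <- as.vector(t(p[["head.w"]]) %*% gap + p[["head.b"]])
  prob <- 1 / (1 + exp(-logit))
  caches$final <- list(h = h, gap = gap, hdim = d)
  list(logit = logit, prob = prob, caches = caches)
}

model_bwd <- function(model, fwd, dlogit) {
  p <- model$params
  cfg <- model$config
  grads <- list()
  fin <- fwd$caches$final
  d <- fin$hdim
  hw <- d[1] * d[2]
  dlogit <- matrix(dlogit, nrow = 1)
  grads[["head.w"]] <- fin$gap %*% t(dlogit)
  grads[["head.b"]] <- sum(dlogit)
  dgap <- p[["head.w"]] %*% dlogit # C x N
  dh <- add_channel_cpp(array(0, d), d, dgap / hw)
  for (si in 4:1) {
    for (bi in rev(seq_len(cfg$blocks_per_stage))) {
      pre <- sprintf("s%d.b%d", si, bi)
      res <- block_bwd(dh, fwd$caches[[pre]], p, pre, cfg$use_se, grads)
      grads <- res$grads
      dh <- res$dx
    }
  }
  stem <- fwd$caches$stem
  dpool <- maxpool2_bwd_cpp(dh, stem$pool$idx, stem$adim)
  da <- relu_bwd_cpp(dpool, stem$bn$y)
  b <- bn_bwd(da, stem$bn, p[["stem.bn.gamma"]])
  grads[["stem.bn.gamma"]] <- b$dgamma
  grads[["stem.bn.beta"]] <- b$dbeta
  cg <- conv_bwd(stem$x, p[["stem.w"]], b$dx, 1L, 1L)
  grads[["stem.w"]] <- cg$dw
  grads[["stem.b"]] <- cg$db
  grads
}

# collect BN running-stat updates from a training forward pass
harvest_bn_state <- function(model, fwd) {
  st <- model$bn_state
  take <- function(name, bn) {
    st[[paste0(name, ".mean")]] <<- bn$rm
    st[[paste0(name, ".var")]] <<- bn$rv
  }
  take("stem.bn", fwd$caches$stem$bn)
  for (si in 1:4) {
    for (bi in seq_len(model$config$blocks_per_stage)) {
      pre <- sprintf("s%d.b%d", si, bi)
      cache <- fwd$caches[[pre]]
      take(paste0(pre, ".bn1"), cache$bn1)
      take(paste0(pre, ".bn2"), cache$bn2)
      if (cache$has_proj) take(paste0(pre, ".projbn"), cache$scbn)
    }
  }
  st
}

bce_loss <- function(logit, y) {
  # numerically stable binary cross-entropy on logits
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

#' Train the classifier
#'
#' Runs exactly `config$epochs` passes over the training set with Adam and
#' binary cross-entropy, shuffling each epoch. Fully reproducible from
#' `config$rng_seed`. `loose` is the positive class.
#'
#' @param model an `se_resnet` from [build_model()].
#' @param x training spectrograms: a list of matrices or an
#'   `(H, W, 1, N)` array (already normalized).
#' @param labels character vector (`"fixed"`/`"loose"`) or 0/1 numeric.
#' @param verbose print per-epoch loss.
#' @return the trained model, with `epoch_losses` recording the mean
#'   minibatch loss per epoch.
#' @export
train_model <- function(model, x, labels, verbose = FALSE) {
  cfg <- model$config
  x <- stack_spectrograms(x)
  y <- encode_labels(labels)
  if (length(unique(y)) < 2)
    vs_stop("training set must contain both classes",
            "vibroscrew_input_error")
  n <- dim(x)[4]
  if (length(y) != n)
    vs_stop("labels length must match sample count",
            "vibroscrew_input_error")
  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0), t = 0)
  lr <- cfg$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  losses <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$rng_seed, 23L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[idx]
        fwd <- model_fwd(model, xb, training = TRUE)
        model$bn_state <- harvest_bn_state(model, fwd)
        batch_losses <- c(batch_losses, bce_loss(fwd$logit, yb))
        dlogit <- (fwd$prob - yb) / length(yb)
        grads <- model_bwd(model, fwd, dlogit)
        adam$t <- adam$t + 1
        corr1 <- 1 - b1^adam$t
        corr2 <- 1 - b2^adam$t
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
          adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g^2
          model$params[[nm]] <- model$params[[nm]] -
            lr * (adam$m[[nm]] / corr1) /
              (sqrt(adam$v[[nm]] / corr2) + eps)
        }
      }
      losses[ep] <- mean(batch_losses)
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.5f", ep, cfg$epochs,
                        losses[ep]))
    }
  })
  model$epoch_losses <- losses
  model$trained <- TRUE
  model
}

# coerce a list of spectrogram matrices to an (H, W, 1, N) array
stack_spectrograms <- function(x) {
  if (is.array(x) && length(dim(x)) == 4) return(x)
  if (is.matrix(x)) x <- list(x)
  d <- dim(x[[1]])
  out <- array(0, c(d[1], d[2], 1, length(x)))
  for (i in seq_along(x)) {
    if (!all(dim(x[[i]]) == d))
      vs_stop("all spectrograms must share the same shape",
              "vibroscrew_input_error")
    out[, , 1, i] <- unclass(x[[i]])
  }
  out
}

encode_labels <- function(labels) {
  if (is.numeric(labels)) return(as.numeric(labels))
  as.numeric(labels == "loose")
}

#' Predict loosening probabilities
#'
#' @param object a trained `se_resnet`.
#' @param spectrograms a spectrogram matrix, list of matrices, or
#'   `(H, W, 1, N)` array; the spatial shape must match the model input.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]` that each input is
#'   loose.
#' @export
predict.se_resnet <- function(object, spectrograms, ...) {
  x <- stack_spectrograms(spectrograms)
  d <- dim(x)
  if (!all(d[1:2] == object$config$input_shape))
    vs_stop(sprintf("input shape (%d, %d) does not match model input (%d, %d)",
                    d[1], d[2], object$config$input_shape[1],
                    object$config$input_shape[2]),
            "vibroscrew_input_error")
  # predict in batches to bound memory
  n <- d[4]
  probs <- numeric(n)
  bs <- max(1L, object$config$batch_size)
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    fwd <- model_fwd(object, x[, , , idx, drop = FALSE], training = FALSE)
    probs[idx] <- fwd$prob
  }
  probs
}

#' Threshold a probability into a class label
#'
#' `loose` is the positive class; the decision is strict (`p > threshold`),
#' so a probability exactly at the threshold maps to `fixed`.
#'
#' @param p probability vector.
#' @param threshold decision threshold.
#' @return character vector of `"fixed"`/`"loose"`.
#' @export
classify <- function(p, threshold = 0.5) {
  ifelse(p > threshold, "loose", "fixed")
}
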