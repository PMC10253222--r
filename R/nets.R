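# 3D residual regression networks (ResNet3D-50 with a linear head), with
# training by mini-batch Adam on a mean-squared-error coordinate loss.
#
# The implementation is a small define-by-layer framework: each layer is a
# list with a `type`, parameters, and (for batch norm) running statistics;
# `layer_fwd()` / `layer_bwd()` implement the forward pass and the exact
# analytic gradients, with the convolution and pooling inner loops in C++
# (src/conv3d.cpp).  Gradients are verified against finite differences in
# the test suite.

# ---- layer constructors -----------------------------------------------------

new_conv <- function(cin, cout, k, s = 1L, p = (k - 1L) %/% 2L) {
  sd <- sqrt(2 / (k^3 * cin))
  list(type = "conv", k = k, s = s, p = p, cin = cin, cout = cout,
       W = matrix(rnorm(k^3 * cin * cout, sd = sd), k^3 * cin, cout),
       b = numeric(cout))
}

new_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c), momentum = 0.1, eps = 1e-5)
}

new_relu <- function() list(type = "relu")
new_maxpool <- function(k = 3L, s = 2L, p = 1L) {
  list(type = "maxpool", k = k, s = s, p = p)
}
new_gap <- function() list(type = "gap")
new_flatten <- function() list(type = "flatten")

new_dense <- function(cin, cout, sd = sqrt(1 / cin)) {
  list(type = "dense",
       W = matrix(rnorm(cin * cout, sd = sd), cin, cout),
       b = numeric(cout))
}

# bottleneck residual block: 1x1x1 -> 3x3x3 (stride) -> 1x1x1 (x4 channels)
new_block <- function(cin, mid, stride) {
  cout <- 4L * mid
  list(type = "block",
       conv1 = new_conv(cin, mid, 1L, 1L, 0L), bn1 = new_bn(mid),
       conv2 = new_conv(mid, mid, 3L, stride, 1L), bn2 = new_bn(mid),
       conv3 = new_conv(mid, cout, 1L, 1L, 0L), bn3 = new_bn(cout),
       shortcut = if (cin != cout || stride != 1L)
         list(conv = new_conv(cin, cout, 1L, stride, 0L), bn = new_bn(cout)))
}

# ---- forward / backward -----------------------------------------------------

rep_ch <- function(v, S) rep(v, each = S)  # per-channel vector across space

bn_fwd <- function(layer, x, training) {
  d <- dim(x); S <- prod(d[1:3]); N <- d[5]
  if (training) {
    m <- S * N
    mom <- cpp_channel_moments(x)
    mu <- mom$sum / m
    v <- pmax(mom$sumsq / m - mu^2, 0)
    invstd <- 1 / sqrt(v + layer$eps)
    xhat <- cpp_channel_affine(x, invstd, -mu * invstd)
    out <- cpp_channel_affine(xhat, layer$gamma, layer$beta)
    layer$rm <- (1 - layer$momentum) * layer$rm + layer$momentum * mu
    layer$rv <- (1 - layer$momentum) * layer$rv + layer$momentum * v
    list(out = out, cache = list(xhat = xhat, invstd = invstd, m = m),
         layer = layer)
  } else {
    scale <- layer$gamma / sqrt(layer$rv + layer$eps)
    out <- cpp_channel_affine(x, scale, layer$beta - scale * layer$rm)
    list(out = out, cache = NULL, layer = layer)
  }
}

bn_bwd <- function(layer, cache, dout) {
  m <- cache$m
  xhat <- cache$xhat
  ds <- cpp_channel_dots(dout, xhat)
  dgamma <- ds$dot
  dbeta <- ds$sum
  ig <- cache$invstd * layer$gamma
  # dx = ig*dout - (ig/m)*dgamma*xhat - (ig/m)*dbeta, per channel
  dx <- cpp_channel_affine2(dout, xhat, ig, -ig * dgamma / m,
                            -ig * dbeta / m)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

layer_fwd <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      out <- cpp_conv3d_fwd(x, layer$W, layer$b, layer$k, layer$s, layer$p)
      list(out = out, cache = x, layer = layer)
    },
    bn = bn_fwd(layer, x, training),
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = mask, layer = layer)
    },
    maxpool = {
      r <- cpp_maxpool3d_fwd(x, layer$k, layer$s, layer$p)
      list(out = r$out, cache = list(idx = r$idx, xdim = dim(x)),
           layer = layer)
    },
    gap = {
      d <- dim(x); S <- prod(d[1:3])
      out <- t(matrix(colMeans(matrix(x, S)), d[4], d[5]))  # N x C
      list(out = out, cache = d, layer = layer)
    },
    flatten = {
      d <- dim(x)
      list(out = t(matrix(x, prod(d[1:4]), d[5])), cache = d, layer = layer)
    },
    dense = {
      out <- x %*% layer$W
      out <- out + matrix(layer$b, nrow(out), ncol(out), byrow = TRUE)
      list(out = out, cache = x, layer = layer)
    },
    block = block_fwd(layer, x, training),
    stop("unknown layer type ", layer$type)
  )
}

layer_bwd <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      r <- cpp_conv3d_bwd(cache, layer$W, dout, layer$k, layer$s, layer$p)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    bn = bn_bwd(layer, cache, dout),
    relu = list(dx = dout * cache, grads = NULL),
    maxpool = list(dx = cpp_maxpool3d_bwd(dout, cache$idx, cache$xdim),
                   grads = NULL),
    gap = {
      d <- cache; S <- prod(d[1:3])
      v <- as.vector(t(dout)) / S
      list(dx = array(rep(v, each = S), d), grads = NULL)
    },
    flatten = list(dx = array(t(dout), cache), grads = NULL),
    dense = list(dx = dout %*% t(layer$W),
                 grads = list(W = crossprod(cache, dout),
                              b = colSums(dout))),
    block = block_bwd(layer, cache, dout),
    stop("unknown layer type ", layer$type)
  )
}

block_fwd <- function(layer, x, training) {
  cache <- list()
  h <- x
  for (nm in c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")) {
    r <- layer_fwd(layer[[nm]], h, training)
    layer[[nm]] <- r$layer
    cache[[nm]] <- r$cache
    h <- r$out
    if (nm %in% c("bn1", "bn2")) {
      cache[[paste0(nm, "_mask")]] <- h > 0
      h <- h * cache[[paste0(nm, "_mask")]]
    }
  }
  if (is.null(layer$shortcut)) {
    sc <- x
  } else {
    r1 <- layer_fwd(layer$shortcut$conv, x, training)
    layer$shortcut$conv <- r1$layer
    cache$sc_conv <- r1$cache
    r2 <- layer_fwd(layer$shortcut$bn, r1$out, training)
    layer$shortcut$bn <- r2$layer
    cache$sc_bn <- r2$cache
    sc <- r2$out
  }
  s <- h + sc
  cache$out_mask <- s > 0
  list(out = s * cache$out_mask, cache = cache, layer = layer)
}

block_bwd <- function(layer, cache, dout) {
  ds <- dout * cache$out_mask
  grads <- list()
  # main branch, reversed
  d <- ds
  for (nm in rev(c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3"))) {
    r <- layer_bwd(layer[[nm]], cache[[nm]], d)
    grads[[nm]] <- r$grads
    d <- r$dx
    # apply the mask of the relu that precedes this layer's input
    if (nm == "conv3") d <- d * cache$bn2_mask
    if (nm == "conv2") d <- d * cache$bn1_mask
  }
  dx_main <- d
  # shortcut branch
  if (is.null(layer$shortcut)) {
    dx_sc <- ds
  } else {
    r2 <- layer_bwd(layer$shortcut$bn, cache$sc_bn, ds)
    grads$sc_bn <- r2$grads
    r1 <- layer_bwd(layer$shortcut$conv, cache$sc_conv, r2$dx)
    grads$sc_conv <- r1$grads
    dx_sc <- r1$dx
  }
  list(dx = dx_main + dx_sc, grads = grads)
}

# ---- network construction ---------------------------------------------------

#' Regressor architecture specification
#'
#' A 50-layer 3D residual network (bottleneck blocks 3-4-6-3) whose final
#' activation is linear, mapping a binary voxel stack to a coordinate
#' vector: 48 outputs (16 landmarks x 3) for the whole-volume phase or 3 for
#' a per-landmark refinement phase.  `width_scale` multiplies every channel
#' count (1 = full scale) so that desk-scale experiments train in minutes.
#'
#' @param input_shape integer (W, H, D) of the input stack.
#' @param n_outputs 48 or 3.
#' @param width_scale positive channel-count multiplier.
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(input_shape, n_outputs, width_scale = 1) {
  if (length(input_shape) != 3L || any(input_shape < 1)) {
    stop("construction error: input_shape must be three positive integers")
  }
  if (!n_outputs %in% c(48L, 3L)) {
    stop("construction error: n_outputs must be 48 (phase 1) or 3 (refinement)")
  }
  if (width_scale <= 0) stop("construction error: width_scale must be > 0")
  structure(list(input_shape = as.integer(input_shape),
                 n_outputs = as.integer(n_outputs),
                 width_scale = width_scale),
            class = "regressor_spec")
}

# stage layout of the 50-layer variant: 1 stem + 3*(3+4+6+3) + 1 dense = 50
RESNET50_BLOCKS <- c(3L, 4L, 6L, 3L)

#' Build a 3D residual coordinate regressor
#'
#' @param spec a [regressor_spec()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `craniomark_model`.
#' @export
build_regressor <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "regressor_spec"))
  ws <- spec$width_scale
  chan <- function(c) max(1L, as.integer(round(c * ws)))
  shrink <- function(d, k, s, p) pmax((d + 2L * p - k) %/% s + 1L, 1L)
  with_seed(seed, {
    layers <- list(
      new_conv(1L, chan(64), 7L, 2L, 3L), new_bn(chan(64)), new_relu(),
      new_maxpool()
    )
    sp <- shrink(shrink(spec$input_shape, 7L, 2L, 3L), 3L, 2L, 1L)
    cin <- chan(64)
    base <- c(64L, 128L, 256L, 512L)
    for (st in 1:4) {
      mid <- chan(base[st])
      for (bi in seq_len(RESNET50_BLOCKS[st])) {
        # downsample at the head of stages 2-4 while the feature map can
        # still afford it, so small desk-scale inputs keep a spatial map
        # for the flattened linear head
        stride <- if (bi == 1L && st > 1L && min(sp) >= 4L) 2L else 1L
        layers[[length(layers) + 1L]] <- new_block(cin, mid, stride)
        if (stride == 2L) sp <- shrink(sp, 1L, 2L, 0L)
        cin <- 4L * mid
      }
    }
    layers[[length(layers) + 1L]] <- new_flatten()
    layers[[length(layers) + 1L]] <- new_dense(prod(sp) * cin,
                                               spec$n_outputs, sd = 0.01)
    structure(list(spec = spec, layers = layers, trained_epochs = 0L,
                   target_center = numeric(spec$n_outputs)),
              class = "craniomark_model")
  })
}

#' @export
print.craniomark_model <- function(x, ...) {
  cat("craniomark_model: 3D residual regressor, input ",
      paste(x$spec$input_shape, collapse = " x "), ", ",
      x$spec$n_outputs, " outputs, width_scale ", x$spec$width_scale,
      ", trained ", x$trained_epochs, " epochs\n", sep = "")
  invisible(x)
}

net_forward <- function(model, x5, training = FALSE) {
  caches <- vector("list", length(model$layers))
  h <- x5
  for (i in seq_along(model$layers)) {
    r <- layer_fwd(model$layers[[i]], h, training)
    model$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    h <- r$out
  }
  list(out = h, caches = caches, model = model)
}

net_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  d <- dout
  for (i in rev(seq_along(model$layers))) {
    r <- layer_bwd(model$layers[[i]], caches[[i]], d)
    grads[i] <- list(r$grads)
    d <- r$dx
  }
  grads
}

# ---- Adam optimizer over the nested layer structure ------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (is.null(ly$type)) return(NULL)
    if (ly$type == "block") {
      st <- lapply(c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3"),
                   function(nm) param_state(ly[[nm]]))
      names(st) <- c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")
      if (!is.null(ly$shortcut)) {
        st$sc_conv <- param_state(ly$shortcut$conv)
        st$sc_bn <- param_state(ly$shortcut$bn)
      }
      st
    } else {
      param_state(ly)
    }
  })
}

param_state <- function(layer) {
  nms <- param_names(layer)
  if (!length(nms)) return(NULL)
  setNames(lapply(nms, function(nm) {
    list(m = layer[[nm]] * 0, v = layer[[nm]] * 0)
  }), nms)
}

param_names <- function(layer) {
  switch(layer$type, conv = , dense = c("W", "b"),
         bn = c("gamma", "beta"), character(0))
}

adam_update_layer <- function(layer, grads, state, lr, t,
                              b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    layer[[nm]] <- layer[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(layer = layer, state = state)
}

adam_step <- function(model, grads, state, lr, t) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (ly$type == "block") {
      for (nm in c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")) {
        if (is.null(g[[nm]])) next
        u <- adam_update_layer(ly[[nm]], g[[nm]], state[[i]][[nm]], lr, t)
        ly[[nm]] <- u$layer
        state[[i]][[nm]] <- u$state
      }
      if (!is.null(ly$shortcut)) {
        u <- adam_update_layer(ly$shortcut$conv, g$sc_conv,
                               state[[i]]$sc_conv, lr, t)
        ly$shortcut$conv <- u$layer
        state[[i]]$sc_conv <- u$state
        u <- adam_update_layer(ly$shortcut$bn, g$sc_bn,
                               state[[i]]$sc_bn, lr, t)
        ly$shortcut$bn <- u$layer
        state[[i]]$sc_bn <- u$state
      }
    } else {
      u <- adam_update_layer(ly, g, state[[i]], lr, t)
      ly <- u$layer
      state[[i]] <- u$state
    }
    model$layers[[i]] <- ly
  }
  list(model = model, state = state)
}

# ---- training and inference -------------------------------------------------

stack_voxels <- function(x) {
  if (inherits(x, "binary_stack")) x$voxels else x
}

examples_to_batch <- function(examples, idx) {
  d <- dim(stack_voxels(examples[[idx[1]]]$stack))
  x5 <- array(0, c(d, 1L, length(idx)))
  for (j in seq_along(idx)) {
    x5[, , , 1L, j] <- stack_voxels(examples[[idx[j]]]$stack)
  }
  y <- t(vapply(idx, function(i) as.numeric(examples[[i]]$target),
                numeric(length(examples[[idx[1]]]$target))))
  list(x = x5, y = y)
}

#' Train a regression network
#'
#' Mini-batch Adam on the mean-squared error between predicted and target
#' coordinate vectors.  Deterministic for a fixed `seed` (shuffling and
#' initialization both derive from it).
#'
#' @param model a [build_regressor()] model.
#' @param dataset a `refinement_dataset`, or any list of examples each
#'   carrying `stack` (a [binary_stack()] or 3D array) and `target`
#'   (numeric of length `n_outputs`).
#' @param batch_size mini-batch size.
#' @param epochs number of epochs.
#' @param lr Adam step size.
#' @param seed RNG seed for shuffling.
#' @param weights_path optional path; if given, the trained weights are
#'   saved there with [save_weights()].
#' @param verbose print per-epoch loss.
#' @return A list with `model` (trained) and `history` (per-epoch mean
#'   training loss).
#' @export
train_regressor <- function(model, dataset, batch_size = 16L, epochs = 10L,
                            lr = 1e-3, seed = 0L, weights_path = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "craniomark_model"))
  examples <- if (inherits(dataset, "refinement_dataset")) dataset$examples
              else dataset
  if (!length(examples)) stop("input error: empty dataset")
  nt <- length(examples[[1]]$target)
  if (nt != model$spec$n_outputs) {
    stop("input error: target length ", nt, " does not match model outputs ",
         model$spec$n_outputs)
  }
  n <- length(examples)
  # the network regresses residuals around the training-target mean; the
  # stored centre is added back at inference
  targets <- t(vapply(examples, function(e) as.numeric(e$target), numeric(nt)))
  model$target_center <- colMeans(targets)
  state <- adam_init(model$layers)
  history <- numeric(epochs)
  t_step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        b <- examples_to_batch(examples, idx)
        fw <- net_forward(model, b$x, training = TRUE)
        model <- fw$model
        resid <- fw$out - (b$y -
          matrix(model$target_center, nrow(b$y), nt, byrow = TRUE))
        loss <- mean(resid^2)
        dout <- 2 * resid / length(resid)
        grads <- net_backward(model, fw$caches, dout)
        t_step <- t_step + 1L
        u <- adam_step(model, grads, state, lr, t_step)
        model <- u$model
        state <- u$state
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose) message("epoch ", ep, ": loss ", signif(history[ep], 5))
    }
  })
  model$trained_epochs <- model$trained_epochs + epochs
  if (!is.null(weights_path)) save_weights(model, weights_path)
  list(model = model, history = history)
}

#' Predict coordinate vectors from voxel stacks
#'
#' Runs the network in inference mode (batch-norm running statistics).
#' `model` may also be a plain R function `f(stack) -> numeric`, which lets
#' tests substitute deterministic stubs for trained networks.
#'
#' @param model a `craniomark_model` or a function.
#' @param stack a [binary_stack()], a 3D array, or a list of either.
#' @return A numeric vector (single stack) or a matrix with one row per
#'   stack.
#' @export
predict_coords <- function(model, stack) {
  UseMethod("predict_coords")
}

#' @export
predict_coords.function <- function(model, stack) {
  if (is.list(stack) && !inherits(stack, "binary_stack")) {
    return(t(vapply(stack, model, numeric(length(model(stack[[1]]))))))
  }
  model(stack)
}

#' @export
predict_coords.craniomark_model <- function(model, stack) {
  single <- !(is.list(stack) && !inherits(stack, "binary_stack"))
  stacks <- if (single) list(stack) else stack
  d <- dim(stack_voxels(stacks[[1]]))
  x5 <- array(0, c(d, 1L, length(stacks)))
  for (j in seq_along(stacks)) x5[, , , 1L, j] <- stack_voxels(stacks[[j]])
  out <- net_forward(model, x5, training = FALSE)$out
  if (!is.null(model$target_center)) {
    out <- out + matrix(model$target_center, nrow(out), ncol(out),
                        byrow = TRUE)
  }
  if (single) drop(out) else out
}

#' Persist / restore trained weights
#'
#' `load_weights()` restores a model that reproduces the saved model's
#' outputs exactly on identical input.
#'
#' @param model a `craniomark_model`.
#' @param path weights file path (conventionally `phase1.w`,
#'   `phase2_L01.w`, ..., `phase3_L16.w`).
#' @return `load_weights()`: the restored `craniomark_model`.
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "craniomark_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop("format error: no such weights file: ", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("format error: unreadable weights file: ",
                                             path, call. = FALSE))
  if (!inherits(model, "craniomark_model")) {
    stop("format error: not a craniomark model: ", path)
  }
  model
}
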