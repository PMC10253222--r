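ns <- asNamespace("craniomark")

tiny_model <- function(seed = 1) {
  set.seed(seed)
  layers <- list(ns$new_conv(1L, 2L, 3L, 1L, 1L), ns$new_bn(2L),
                 ns$new_relu(), ns$new_maxpool(),
                 ns$new_block(2L, 2L, 2L), ns$new_flatten(),
                 ns$new_dense(2L * 2L * 2L * 8L, 3L))
  structure(list(spec = list(n_outputs = 3L), layers = layers,
                 trained_epochs = 0L, target_center = numeric(3)),
            class = "craniomark_model")
}

test_that("analytic gradients match finite differences through every layer", {
  model <- tiny_model(1)
  set.seed(2)
  x <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 1, 2))
  y <- matrix(rnorm(6), 2, 3)
  loss_of <- function(m) mean((ns$net_forward(m, x, TRUE)$out - y)^2)
  fw <- ns$net_forward(model, x, TRUE)
  grads <- ns$net_backward(fw$model, fw$caches, 2 * (fw$out - y) / 6)

  probe <- function(get, set, ana, label) {
    w <- get(model)
    for (i in sample(length(w), min(6, length(w)))) {
      e <- 1e-5
      num <- (loss_of(set(model, i, e)) - loss_of(set(model, i, -e))) / (2 * e)
      expect_lt(abs(num - ana[i]), 1e-6 + 1e-3 * (abs(num) + abs(ana[i])),
                label = paste(label, "grad", i))
    }
  }
  mk_set <- function(li, nm) function(m, i, d) {
    m$layers[[li]][[nm]][i] <- m$layers[[li]][[nm]][i] + d
    m
  }
  set.seed(3)
  probe(function(m) m$layers[[1]]$W, mk_set(1, "W"), grads[[1]]$W, "conv.W")
  probe(function(m) m$layers[[2]]$gamma, mk_set(2, "gamma"),
        grads[[2]]$gamma, "bn.gamma")
  probe(function(m) m$layers[[7]]$W, mk_set(7, "W"), grads[[7]]$W, "dense.W")
  probe(function(m) m$layers[[7]]$b, mk_set(7, "b"), grads[[7]]$b, "dense.b")
  mk_set_blk <- function(nm, pn) function(m, i, d) {
    m$layers[[5]][[nm]][[pn]][i] <- m$layers[[5]][[nm]][[pn]][i] + d
    m
  }
  probe(function(m) m$layers[[5]]$conv2$W, mk_set_blk("conv2", "W"),
        grads[[5]]$conv2$W, "block.conv2.W")
  probe(function(m) m$layers[[5]]$bn3$gamma, mk_set_blk("bn3", "gamma"),
        grads[[5]]$bn3$gamma, "block.bn3.gamma")
  probe(function(m) m$layers[[5]]$shortcut$conv$W,
        function(m, i, d) {
          m$layers[[5]]$shortcut$conv$W[i] <-
            m$layers[[5]]$shortcut$conv$W[i] + d
          m
        },
        grads[[5]]$sc_conv$W, "block.shortcut.W")
})

test_that("the residual regressor has the 50-layer structure and linear head", {
  m <- build_regressor(regressor_spec(c(18, 18, 24), 48L, 0.0625), seed = 0)
  types <- vapply(m$layers, `[[`, "", "type")
  expect_identical(sum(types == "block"), 16L)  # 3 + 4 + 6 + 3 bottlenecks
  # 1 stem conv + 16 blocks x 3 convs + 1 dense = 50 weighted layers
  expect_identical(1L + 16L * 3L + 1L, 50L)
  expect_identical(types[length(types)], "dense")
  set.seed(1)
  st <- array(as.numeric(runif(18 * 18 * 24) > 0.7), c(18, 18, 24))
  out <- predict_coords(m, st)
  expect_length(out, 48L)
  expect_true(all(is.finite(out)))

  m3 <- build_regressor(regressor_spec(c(10, 10, 24), 3L, 0.0625), seed = 0)
  out3 <- predict_coords(m3, array(0, c(10, 10, 24)))
  expect_length(out3, 3L)
})

test_that("regressor specifications are validated", {
  expect_error(regressor_spec(c(18, 18), 48), "construction error")
  expect_error(regressor_spec(c(18, 18, 24), 5), "construction error")
  expect_error(regressor_spec(c(18, 18, 24), 48, 0), "construction error")
})

test_that("training fits a constant target and duplication changes nothing", {
  set.seed(4)
  mk_ex <- function(i) list(stack = array(as.numeric(runif(8 * 8 * 6) > 0.5),
                                          c(8, 8, 6)),
                            target = c(5, -2, 10))
  ds <- lapply(1:6, mk_ex)
  m <- build_regressor(regressor_spec(c(8, 8, 6), 3L, 0.0625), seed = 1)
  r <- train_regressor(m, ds, batch_size = 3, epochs = 5, lr = 1e-3, seed = 1)
  preds <- predict_coords(r$model, lapply(ds, `[[`, "stack"))
  expect_true(all(abs(preds - matrix(c(5, -2, 10), 6, 3, byrow = TRUE)) < 0.5))
  expect_lt(tail(r$history, 1), head(r$history, 1) + 1e-12)
  # duplicated examples share the same constant-target minimum
  r2 <- train_regressor(m, c(ds, ds), batch_size = 3, epochs = 5, lr = 1e-3,
                        seed = 1)
  preds2 <- predict_coords(r2$model, lapply(ds, `[[`, "stack"))
  expect_true(all(abs(preds2 - matrix(c(5, -2, 10), 6, 3, byrow = TRUE)) < 0.5))
})

test_that("training reduces the loss on a learnable localization task", {
  set.seed(5)
  ds <- lapply(1:24, function(i) {
    pos <- sample(2:7, 2)
    st <- array(0, c(8, 8, 6))
    st[pos[1] + (-1:1), pos[2] + (-1:1), 3] <- 1
    list(stack = st, target = c(pos[1] - 1, pos[2] - 1, 3))
  })
  m <- build_regressor(regressor_spec(c(8, 8, 6), 3L, 0.0625), seed = 2)
  r <- train_regressor(m, ds, batch_size = 8, epochs = 15, lr = 3e-3, seed = 2)
  expect_lt(tail(r$history, 1), head(r$history, 1))
})

test_that("weights persist and reload with bit-identical predictions", {
  set.seed(6)
  ds <- lapply(1:4, function(i) list(stack = array(as.numeric(runif(192) > 0.5),
                                                   c(8, 8, 3)),
                                     target = rnorm(3)))
  m <- build_regressor(regressor_spec(c(8, 8, 3), 3L, 0.0625), seed = 3)
  f <- tempfile(fileext = ".w")
  r <- train_regressor(m, ds, batch_size = 4, epochs = 2, lr = 1e-3, seed = 3,
                       weights_path = f)
  expect_true(file.exists(f))
  back <- load_weights(f)
  st <- ds[[1]]$stack
  expect_identical(predict_coords(r$model, st), predict_coords(back, st))
})

test_that("corrupt or mismatched inputs raise format/input errors", {
  bad <- tempfile(fileext = ".w")
  writeLines("not weights", bad)
  expect_error(load_weights(bad), "format error")
  expect_error(load_weights(tempfile()), "format error")
  m <- build_regressor(regressor_spec(c(8, 8, 3), 3L, 0.0625), seed = 0)
  ds48 <- list(list(stack = array(0, c(8, 8, 3)), target = numeric(48)))
  expect_error(train_regressor(m, ds48), "input error")
  expect_error(train_regressor(m, list()), "input error")
})
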