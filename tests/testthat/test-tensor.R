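# Finite-difference validation of the autodiff tape that all blocks run on.

grad_check <- function(build, x0, tol = 1e-6) {
  # build(tg) must return a scalar tg node
  xt <- tg_tensor(x0, requires_grad = TRUE)
  out <- build(xt)
  tg_backward(out)
  ng <- numeric_grad(function(x) tg_value(build(tg_tensor(x))), x0)
  expect_lt(max(abs(xt$grad - ng)), tol)
}

test_that("elementwise ops, reductions and softmax backpropagate correctly", {
  set.seed(1)
  x0 <- rand_arr(2, 3, 4, 4)
  y <- tg_tensor(rand_arr(2, 3, 4, 4))
  b <- tg_tensor(rand_arr(1, 3, 1, 1))
  grad_check(function(x) tg_sum(tg_mul(tg_add(x, b), y)), x0, tol = 1e-5)
  grad_check(function(x) tg_mean(tg_sigmoid(tg_scale(x, 2))), x0, tol = 1e-5)
  grad_check(function(x) tg_sum(tg_relu(x)), x0 + 0.01, tol = 1e-5)

  m0 <- rand_arr(5, 7)
  wsm <- tg_tensor(rand_arr(5, 7))
  grad_check(function(x) tg_sum(tg_mul(tg_softmax_rows(x), wsm)), m0, tol = 1e-5)
  sm <- tg_value(tg_softmax_rows(tg_tensor(m0)))
  expect_equal(rowSums(sm), rep(1, 5), tolerance = 1e-12)
})

test_that("broadcast gradients reduce over the broadcast axes", {
  set.seed(2)
  b0 <- rand_arr(1, 3, 1, 1)
  x <- tg_tensor(rand_arr(2, 3, 5, 5))
  bt <- tg_tensor(b0, requires_grad = TRUE)
  out <- tg_sum(tg_mul(x, bt))
  tg_backward(out)
  expect_equal(dim(bt$grad), c(1, 3, 1, 1))
  expect_equal(as.numeric(bt$grad),
               as.numeric(apply(tg_value(x), 2, sum)), tolerance = 1e-10)
})

test_that("matrix, batched-matrix and convolution gradients match finite differences", {
  set.seed(3)
  a0 <- rand_arr(4, 3)
  bmat <- tg_tensor(rand_arr(3, 5))
  grad_check(function(x) tg_sum(tg_matmul(x, bmat)), a0, tol = 1e-5)

  p0 <- rand_arr(3, 2, 4)
  q <- tg_tensor(rand_arr(3, 4, 2))
  grad_check(function(x) tg_sum(tg_bmm(x, q)), p0, tol = 1e-5)

  x0 <- rand_arr(2, 3, 6, 6)
  w <- tg_tensor(rand_arr(4, 3, 3, 3) * 0.3)
  bb <- tg_tensor(rnorm(4))
  wconv <- tg_tensor(rand_arr(2, 4, 6, 6))
  grad_check(function(x) tg_sum(tg_mul(tg_conv2d(x, w, bb, pad = 1L), wconv)),
             x0, tol = 1e-4)
  # and w.r.t. the kernel
  xt <- tg_tensor(x0)
  w0 <- tg_value(w)
  wt <- tg_tensor(w0, requires_grad = TRUE)
  out <- tg_sum(tg_conv2d(xt, wt, bb, pad = 1L))
  tg_backward(out)
  ng <- numeric_grad(function(wv) sum(tg_value(tg_conv2d(xt, tg_tensor(wv), bb, pad = 1L))), w0)
  expect_lt(max(abs(wt$grad - ng)), 1e-4)
})

test_that("pooling, gather, concat and slice gradients match finite differences", {
  set.seed(4)
  x0 <- rand_arr(2, 3, 4, 4)
  w1 <- tg_tensor(rand_arr(2, 3, 1, 1)); w2 <- tg_tensor(rand_arr(2, 3, 1, 1))
  w3 <- tg_tensor(rand_arr(2, 1, 4, 4)); w4 <- tg_tensor(rand_arr(2, 3, 2, 2))
  w5 <- tg_tensor(rand_arr(2, 3, 8, 8)); w6 <- tg_tensor(rand_arr(21, 1))
  w7 <- tg_tensor(rand_arr(2, 6, 4, 4))
  grad_check(function(x) tg_sum(tg_mul(tg_pool_global(x, "avg"), w1)), x0, 1e-5)
  grad_check(function(x) tg_sum(tg_mul(tg_pool_global(x, "max"), w2)), x0, 1e-5)
  grad_check(function(x) tg_sum(tg_mul(tg_reduce_channels(x, "max"), w3)), x0, 1e-5)
  grad_check(function(x) tg_sum(tg_mul(tg_avgpool2(x), w4)), x0, 1e-5)
  grad_check(function(x) tg_sum(tg_mul(tg_upsample_nearest(x, 2), w5)), x0, 1e-5)
  idx <- c(0L, sample.int(96, 20))
  grad_check(function(x) tg_sum(tg_mul(tg_gather(x, idx, c(21, 1)), w6)), x0, 1e-5)
  grad_check(function(x) tg_sum(tg_mul(tg_concat(list(x, tg_tensor(x0)), 2), w7)), x0, 1e-5)
  grad_check(function(x) tg_sum(tg_slice(x, 2, 2, 3)), x0, 1e-5)
})

test_that("grid sampling matches a scalar four-neighbour oracle and its gradients check out", {
  set.seed(5)
  x0 <- rand_arr(1, 2, 4, 4)
  gx0 <- array(runif(9, -0.8, 0.8), c(1, 3, 3))
  gy0 <- array(runif(9, -0.8, 0.8), c(1, 3, 3))
  out <- tg_value(tg_grid_sample(tg_tensor(x0), gx0, gy0))

  # independent scalar oracle: border-clamped bilinear at each position
  oracle <- function(plane, gx, gy) {
    W <- ncol(plane); H <- nrow(plane)
    ix <- min(max(((gx + 1) * W - 1) / 2, 0), W - 1)
    iy <- min(max(((gy + 1) * H - 1) / 2, 0), H - 1)
    x0i <- floor(ix); y0i <- floor(iy)
    x1i <- min(x0i + 1, W - 1); y1i <- min(y0i + 1, H - 1)
    wx <- ix - x0i; wy <- iy - y0i
    plane[y0i + 1, x0i + 1] * (1 - wx) * (1 - wy) +
      plane[y0i + 1, x1i + 1] * wx * (1 - wy) +
      plane[y1i + 1, x0i + 1] * (1 - wx) * wy +
      plane[y1i + 1, x1i + 1] * wx * wy
  }
  for (c in 1:2) for (i in 1:3) for (j in 1:3) {
    expect_equal(out[1, c, i, j],
                 oracle(x0[1, c, , ], gx0[1, i, j], gy0[1, i, j]),
                 tolerance = 1e-6)
  }

  # gradient w.r.t. features and positions (finite difference, in-range positions)
  gxt <- tg_tensor(gx0, requires_grad = TRUE)
  gyt <- tg_tensor(gy0, requires_grad = TRUE)
  xt <- tg_tensor(x0, requires_grad = TRUE)
  wgt <- rand_arr(1, 2, 3, 3)
  loss <- tg_sum(tg_mul(tg_grid_sample(xt, gxt, gyt), tg_tensor(wgt)))
  tg_backward(loss)
  f <- function(xv) sum(tg_value(tg_grid_sample(tg_tensor(xv), gx0, gy0)) * wgt)
  expect_lt(max(abs(xt$grad - numeric_grad(f, x0))), 1e-4)
  fg <- function(gv) sum(tg_value(tg_grid_sample(tg_tensor(x0), tg_tensor(gv), gy0)) * wgt)
  expect_lt(max(abs(gxt$grad - numeric_grad(fg, gx0))), 1e-3)
  fy <- function(gv) sum(tg_value(tg_grid_sample(tg_tensor(x0), gx0, tg_tensor(gv))) * wgt)
  expect_lt(max(abs(gyt$grad - numeric_grad(fy, gy0))), 1e-3)
})

test_that("loss primitives agree with direct formulas and gradients", {
  set.seed(6)
  z0 <- rand_arr(3, 4)
  tt <- array(stats::rbinom(12, 1, 0.5), c(3, 4))
  w <- array(runif(12), c(3, 4))
  l <- tg_value(tg_bce_logits(tg_tensor(z0), tt, w))
  ref <- sum(w * (-(tt * log(plogis(z0)) + (1 - tt) * log(1 - plogis(z0))))) / sum(w)
  expect_equal(as.numeric(l), ref, tolerance = 1e-10)
  grad_check(function(x) tg_bce_logits(x, tt, w), z0, tol = 1e-6)
  grad_check(function(x) tg_mse(x, tt, w), z0, tol = 1e-5)

  adam_p <- nn_param(c(0.5))
  opt <- nn_adam(list(adam_p), lr = 0.1)
  for (k in 1:50) {
    loss <- tg_mse(adam_p, 2)
    tg_backward(loss)
    nn_adam_step(opt)
  }
  expect_lt(abs(adam_p$value - 2), 0.5)
})
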