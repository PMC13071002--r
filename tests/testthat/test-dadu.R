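# Dual-adaptive dynamic upsampling block.

test_that("pixel shuffle is bijective channel-to-space rearrangement", {
  set.seed(41)
  x <- rand_arr(1, 4, 2, 2)
  y <- pixel_shuffle(x, 2)
  expect_equal(dim(y), c(1, 1, 4, 4))
  expect_equal(pixel_unshuffle(y, 2), x, tolerance = 0)
  # constant in -> constant out
  expect_true(all(pixel_shuffle(array(0.7, c(2, 8, 3, 3)), 2) == 0.7))
  expect_error(pixel_shuffle(rand_arr(1, 3, 2, 2), 2), "divisible")
})

test_that("offset branches have the receptive fields their kernels imply", {
  cfg <- dadu_config(4, scale = 2, groups = 2)
  p <- dadu_init(cfg)
  # give the branches non-zero weights
  set.seed(42)
  p$branch1$w$value[] <- rnorm(length(p$branch1$w$value), sd = 0.5)
  p$branch2$w$value[] <- rnorm(length(p$branch2$w$value), sd = 0.5)
  imp <- array(0, c(1, 4, 7, 7)); imp[1, , 4, 4] <- 1
  o1 <- predict_offsets(imp, "pointwise", p)
  expect_equal(dim(o1), c(1, 2 * 2 * 4, 7, 7))
  nz <- which(apply(o1[1, , , ] != 0, c(2, 3), any), arr.ind = TRUE)
  expect_true(all(nz[, 1] == 4 & nz[, 2] == 4))
  o2 <- predict_offsets(imp, "spatial", p)
  nz2 <- which(apply(o2[1, , , ] != 0, c(2, 3), any), arr.ind = TRUE)
  expect_true(all(abs(nz2[, 1] - 4) <= 1 & abs(nz2[, 2] - 4) <= 1))
  # zero weights -> zero offsets
  p0 <- dadu_init(cfg)
  expect_true(all(predict_offsets(imp, "pointwise", p0) == 0))
})

test_that("offset fusion is the sigmoid-weighted convex combination", {
  d1 <- array(1, c(1, 8, 3, 3)); d2 <- array(0, c(1, 8, 3, 3))
  f <- fuse_offsets(d1, d2, 0.5)
  expect_equal(as.numeric(f[1, 1, 1, 1]), plogis(0.5), tolerance = 1e-12)
  expect_equal(as.numeric(f[1, 1, 1, 1]), 0.6225, tolerance = 1e-4)
  # d1 == d2 -> result is that field for any weight
  dd <- array(rnorm(72), c(1, 8, 3, 3))
  for (a in c(-3, 0, 5)) expect_equal(fuse_offsets(dd, dd, a), dd, tolerance = 1e-12)
  # saturation limits
  expect_equal(fuse_offsets(d1, d2, 20), d1, tolerance = 1e-8)
  expect_equal(fuse_offsets(d1, d2, -20), d2, tolerance = 1e-8)
  # convexity bound
  r1 <- array(rnorm(72), c(1, 8, 3, 3)); r2 <- array(rnorm(72), c(1, 8, 3, 3))
  fr <- fuse_offsets(r1, r2, 0.3)
  expect_true(all(fr >= pmin(r1, r2) - 1e-12 & fr <= pmax(r1, r2) + 1e-12))
  expect_error(fuse_offsets(d1, array(0, c(1, 8, 2, 2)), 0), "mismatch")
})

test_that("dynamic scope contracts offsets and matches a hand evaluation", {
  cfg <- dadu_config(2, scale = 2, groups = 1, dynamic_scope = TRUE)
  p <- dadu_init(cfg)
  set.seed(43)
  x <- rand_arr(1, 2, 4, 4)
  off <- rand_arr(1, 8, 4, 4)
  # zero scope conv -> exactly half the offsets
  s0 <- apply_scope(off, x, p)
  expect_equal(s0, off * 0.5, tolerance = 1e-12)
  # hand-set 1x1 scope weights: factor = sigmoid(w . x + b) per cell
  p$scope$w$value[] <- rnorm(length(p$scope$w$value), sd = 0.3)
  p$scope$b$value[] <- 0.2
  s1 <- apply_scope(off, x, p)
  expect_true(all(abs(s1) <= abs(off) + 1e-12))
  for (ch in c(1, 5)) for (i in 1:4) for (j in 1:4) {
    fac <- plogis(sum(p$scope$w$value[ch, , 1, 1] * x[1, , i, j]) + 0.2)
    expect_equal(s1[1, ch, i, j], off[1, ch, i, j] * fac, tolerance = 1e-10)
  }
})

test_that("zero-initialised DADU reduces to base-grid bilinear resampling", {
  set.seed(44)
  cfg <- dadu_config(4, scale = 2, groups = 4)
  p <- dadu_init(cfg)
  x <- rand_arr(1, 4, 8, 8)
  out <- dadu_forward(x, cfg, p)
  expect_equal(dim(out), c(1, 4, 16, 16))

  # oracle: plain align-corners-false bilinear upsampling of each plane
  up_ref <- function(plane, s) {
    H <- nrow(plane); W <- ncol(plane)
    out <- matrix(0, H * s, W * s)
    for (i in seq_len(H * s)) for (j in seq_len(W * s)) {
      sy <- min(max(((i - 1) + 0.5) / s - 0.5, 0), H - 1)
      sx <- min(max(((j - 1) + 0.5) / s - 0.5, 0), W - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
      wy <- sy - y0; wx <- sx - x0
      out[i, j] <- plane[y0 + 1, x0 + 1] * (1 - wy) * (1 - wx) +
        plane[y0 + 1, x1 + 1] * (1 - wy) * wx +
        plane[y1 + 1, x0 + 1] * wy * (1 - wx) +
        plane[y1 + 1, x1 + 1] * wy * wx
    }
    out
  }
  for (c in 1:4) {
    expect_lt(max(abs(out[1, c, , ] - up_ref(x[1, c, , ], 2))), 1e-6)
  }

  # with zero offsets the output is independent of the fusion weight
  p$fusion$value <- array(4.7, 1)
  expect_equal(dadu_forward(x, cfg, p), out, tolerance = 1e-12)

  # constant input stays constant under any offsets (bilinear convexity)
  pc <- dadu_init(cfg)
  set.seed(45)
  pc$branch1$w$value[] <- rnorm(length(pc$branch1$w$value), sd = 1)
  pc$branch2$w$value[] <- rnorm(length(pc$branch2$w$value), sd = 1)
  cst <- array(2.5, c(1, 4, 6, 6))
  expect_lt(max(abs(dadu_forward(cst, cfg, pc) - 2.5)), 1e-10)
})

test_that("full DADU pipeline equals its stage-by-stage composition", {
  set.seed(46)
  cfg <- dadu_config(4, scale = 2, groups = 2, dynamic_scope = TRUE)
  p <- dadu_init(cfg)
  p$branch1$w$value[] <- rnorm(length(p$branch1$w$value), sd = 0.2)
  p$branch2$w$value[] <- rnorm(length(p$branch2$w$value), sd = 0.2)
  p$scope$w$value[] <- rnorm(length(p$scope$w$value), sd = 0.2)
  p$fusion$value <- array(-0.3, 1)
  x <- rand_arr(2, 4, 5, 5)
  out <- dadu_forward(x, cfg, p)
  expect_equal(dim(out), c(2, 4, 10, 10))

  d1 <- predict_offsets(x, "pointwise", p)
  d2 <- predict_offsets(x, "spatial", p)
  off <- apply_scope(fuse_offsets(d1, d2, -0.3), x, p)
  s <- 2; H <- 5; W <- 5; G <- 2
  ref <- array(0, c(2, 4, 10, 10))
  for (b in 1:2) for (g in 1:G) for (cc in 1:2) for (i in 1:10) for (j in 1:10) {
    ci <- (i - 1) %/% s + 1; cj <- (j - 1) %/% s + 1
    pp <- ((i - 1) %% s) * s + (j - 1) %% s
    ch_x <- 2 * ((g - 1) * s^2 + pp) + 1
    ch_y <- ch_x + 1
    sy <- ((i - 1) + 0.5) / s - 0.5 + off[b, ch_y, ci, cj]
    sx <- ((j - 1) + 0.5) / s - 0.5 + off[b, ch_x, ci, cj]
    sy <- min(max(sy, 0), H - 1); sx <- min(max(sx, 0), W - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
    wy <- sy - y0; wx <- sx - x0
    plane <- x[b, (g - 1) * 2 + cc, , ]
    ref[b, (g - 1) * 2 + cc, i, j] <-
      plane[y0 + 1, x0 + 1] * (1 - wy) * (1 - wx) +
      plane[y0 + 1, x1 + 1] * (1 - wy) * wx +
      plane[y1 + 1, x0 + 1] * wy * (1 - wx) +
      plane[y1 + 1, x1 + 1] * wy * wx
  }
  expect_lt(max(abs(out - ref)), 1e-6)
})

test_that("PL mode pre-expands via pixel shuffle and group permutation is consistent", {
  set.seed(47)
  cfg <- dadu_config(4, scale = 2, groups = 1, mode = "PL")
  p <- dadu_init(cfg)
  x <- rand_arr(1, 4, 8, 8)
  out <- dadu_forward(x, cfg, p)
  expect_equal(dim(out), c(1, 1, 16, 16))
  # zero offsets in PL mode with s_eff = 1: identity on the shuffled grid
  expect_equal(out, pixel_shuffle(x, 2), tolerance = 1e-10)

  # group independence: permuting channel groups permutes the output groups
  cfg2 <- dadu_config(4, scale = 2, groups = 2)
  p2 <- dadu_init(cfg2)
  p2$branch1$b$value[] <- runif(length(p2$branch1$b$value), -0.5, 0.5)
  x2 <- rand_arr(1, 4, 6, 6)
  o_a <- dadu_forward(x2, cfg2, p2)
  # swap groups (channels 1:2 <-> 3:4) and the per-group offset biases
  xs <- x2[, c(3, 4, 1, 2), , , drop = FALSE]
  p3 <- dadu_init(cfg2)
  nb <- length(p2$branch1$b$value)
  p3$branch1$b$value <- p2$branch1$b$value[c((nb / 2 + 1):nb, 1:(nb / 2))]
  o_b <- dadu_forward(xs, cfg2, p3)
  expect_equal(o_b[, c(3, 4, 1, 2), , , drop = FALSE], o_a, tolerance = 1e-10)
})

test_that("offset gradients agree with finite differences through the full block", {
  set.seed(48)
  cfg <- dadu_config(2, scale = 2, groups = 1)
  p <- dadu_init(cfg)
  x <- rand_arr(1, 2, 4, 4)
  wgt <- rand_arr(1, 2, 8, 8)
  loss_of <- function(bias_val) {
    p$branch1$b$value <- bias_val
    sum(dadu_forward(x, cfg, p) * wgt)
  }
  b0 <- array(runif(8, -0.3, 0.3), 8)
  # analytic gradient
  p$branch1$b$value <- b0
  xt <- tg_tensor(x)
  out <- dadu_forward(xt, cfg, p)
  tg_backward(tg_sum(tg_mul(out, tg_tensor(wgt))))
  ag <- p$branch1$b$grad
  ng <- numeric_grad(loss_of, b0, eps = 1e-5)
  expect_lt(max(abs(ag - ng)), 1e-3)
  # effective fusion weight stays strictly inside (0,1) after arbitrary
  # unconstrained raw-parameter updates (squashing, not clipping)
  for (raw in c(-9, -1, 0, 3, 14)) {
    eff <- tg_value(tg_sigmoid(tg_tensor(raw)))
    expect_true(eff > 0 && eff < 1)
  }
})
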