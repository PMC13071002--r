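# Condition-guided windowed attention block.

const_conditions <- function(B, H, W, o = 0.3, d = 0.7) {
  list(occlusion = array(o, c(B, 1, H, W)), density = array(d, c(B, 1, H, W)))
}

test_that("relative position index depends only on displacement", {
  idx <- relpos_index(2)
  expect_equal(dim(idx), c(4, 4))
  expect_true(all(idx >= 1 & idx <= 9))          # (2*2-1)^2 = 9 possible entries
  # zero displacement: identical index on the whole diagonal
  expect_equal(length(unique(diag(idx))), 1)
  # equal displacements share entries: tokens row-major in a 2x2 window,
  # (1 -> 2) and (3 -> 4) are both "one step right"
  expect_equal(idx[1, 2], idx[3, 4])
  expect_equal(idx[2, 1], idx[4, 3])
  expect_equal(idx[1, 3], idx[2, 4])             # one step down

  # bias materialisation: zero table -> zero bias; entries match the table
  tab <- matrix(rnorm(9 * 2), 9, 2)
  b <- relative_position_bias(tab, 2)
  expect_equal(dim(b), c(2, 4, 4))
  for (h in 1:2) for (i in 1:4) for (j in 1:4) {
    expect_equal(b[h, i, j], tab[idx[i, j], h])
  }
  expect_true(all(relative_position_bias(matrix(0, 9, 2), 2) == 0))
  # bias at zero displacement identical for all queries
  expect_equal(length(unique(diag(matrix(b[1, , ], 4, 4)))), 1)
})

test_that("window partition tiles exactly and round-trips", {
  set.seed(51)
  x <- rand_arr(1, 3, 7, 7)
  p <- partition_windows(x, 7)
  expect_equal(dim(p$windows), c(1, 49, 3))
  expect_true(all(p$pad_mask))

  x2 <- rand_arr(2, 4, 14, 14)
  p2 <- partition_windows(x2, 7)
  expect_equal(nrow(p2$windows), 2 * 4)          # (14/7)^2 windows per image
  expect_equal(merge_windows(p2$windows, p2$meta), x2, tolerance = 0)

  # padding: 5x5 grid, 4-cell windows -> 4 windows, masked outside extent
  x3 <- rand_arr(1, 2, 5, 5)
  p3 <- partition_windows(x3, 4)
  expect_equal(dim(p3$windows), c(4, 16, 2))
  expect_equal(sum(p3$pad_mask), 25)             # one valid cell per original cell
  expect_equal(merge_windows(p3$windows, p3$meta), x3, tolerance = 0)
})

test_that("window condition statistics are valid block means", {
  o <- array(0.3, c(1, 1, 8, 8)); d <- array(0.7, c(1, 1, 8, 8))
  st <- window_condition_stats(o, d, 4)
  expect_equal(dim(st), c(4, 2))
  expect_true(all(abs(st[, 1] - 0.3) < 1e-12))
  expect_true(all(abs(st[, 2] - 0.7) < 1e-12))

  # 4x4 map with value = row index / 3, 2x2 windows: hand-computed means
  m <- array(0, c(1, 1, 4, 4))
  for (i in 1:4) m[1, 1, i, ] <- (i - 1) / 3
  st2 <- window_condition_stats(m, m, 2)
  # windows ordered wy-major then wx: rows (0,1/3)->1/6 twice, (2/3,1)->5/6 twice
  expect_equal(sort(st2[, 1]), c(1 / 6, 1 / 6, 5 / 6, 5 / 6), tolerance = 1e-12)

  bin <- array(sample(0:1, 64, TRUE), c(1, 1, 8, 8))
  stb <- window_condition_stats(bin, bin, 4)
  expect_true(all(stb >= 0 & stb <= 1))
  expect_error(window_condition_stats(o, array(0.5, c(1, 1, 4, 4)), 4), "mismatch")
})

test_that("modulation factors come from the two-layer map and stay in (0,1)", {
  cfg <- cgwa_config(8, heads = 2, window_size = 2, mlp_hidden = 3)
  p <- cgwa_init(cfg)
  st <- matrix(runif(10), 5, 2)
  f <- modulation_factors(st, p)
  expect_equal(dim(f), c(5, 2))
  expect_true(all(f > 0 & f < 1))

  # zero weights/bias -> sigmoid(0) = 0.5 everywhere
  p0 <- cgwa_init(cfg)
  p0$mod1$w$value[] <- 0; p0$mod1$b$value[] <- 0
  p0$mod2$w$value[] <- 0; p0$mod2$b$value[] <- 0
  expect_true(all(modulation_factors(st, p0) == 0.5))

  # fixed-weight fixture vs direct two-layer arithmetic
  p$mod1$w$value <- matrix(c(0.5, -0.2, 0.1, 0.4, -0.3, 0.2), 2, 3)
  p$mod1$b$value <- c(0.05, -0.1, 0)
  p$mod2$w$value <- matrix(seq(-0.3, 0.2, length.out = 6), 3, 2)
  p$mod2$b$value <- c(0.1, -0.1)
  ref <- t(apply(st, 1, function(s) {
    h <- pmax(as.numeric(s %*% p$mod1$w$value) + p$mod1$b$value, 0)
    plogis(as.numeric(h %*% p$mod2$w$value) + p$mod2$b$value)
  }))
  expect_equal(unname(modulation_factors(st, p)), unname(ref), tolerance = 1e-10)
})

test_that("boundary weights respond to condition edges and stay in (0,1)", {
  set.seed(52)
  cfg <- cgwa_config(8, heads = 2, window_size = 4)
  p <- cgwa_init(cfg)
  # constant conditions -> spatially constant interior (translation invariance)
  o <- array(0.4, c(1, 1, 12, 12)); d <- array(0.6, c(1, 1, 12, 12))
  bw <- boundary_weights(o, d, p)
  expect_equal(dim(bw), c(1, 1, 12, 12))
  inner <- bw[1, 1, 3:10, 3:10]
  expect_lt(max(inner) - min(inner), 1e-12)
  expect_true(all(bw > 0 & bw < 1))

  # vertical step edge in O: mean |response - flat response| largest at the step
  o2 <- array(0, c(1, 1, 12, 12)); o2[1, 1, , 7:12] <- 1
  bw2 <- boundary_weights(o2, d, p)
  flat_left <- mean(bw2[1, 1, 3:10, 3:4])
  edge <- mean(bw2[1, 1, 3:10, 6:7])
  flat_right <- mean(bw2[1, 1, 3:10, 10:11])
  expect_gte(edge, min(flat_left, flat_right))
  expect_error(boundary_weights(o, array(0.5, c(1, 1, 6, 6)), p), "mismatch")
})

test_that("CGWA is exactly the identity at initialisation", {
  set.seed(53)
  cfg <- cgwa_config(8, heads = 2, window_size = 4)
  p <- cgwa_init(cfg)                      # zero-initialised output projection
  x <- rand_arr(2, 8, 10, 9)               # forces padding too
  cond <- const_conditions(2, 10, 9)
  out <- cgwa_forward(x, cond, cfg, p)
  expect_equal(out, x, tolerance = 0)
})

test_that("single-window CGWA with frozen modulation matches a dense attention oracle", {
  set.seed(54)
  C <- 8; heads <- 2; Hs <- 5
  cfg <- cgwa_config(C, heads = heads, window_size = Hs)
  p <- cgwa_init(cfg)
  # random projections; zero relative bias; boundary net at zero weights
  # gives a constant 0.5 per key, which cancels in the softmax
  p$qkv$w$value[] <- rnorm(length(p$qkv$w$value), sd = 0.3)
  p$qkv$b$value[] <- rnorm(length(p$qkv$b$value), sd = 0.1)
  p$proj$w$value[] <- rnorm(length(p$proj$w$value), sd = 0.3)
  p$proj$b$value[] <- rnorm(length(p$proj$b$value), sd = 0.1)
  p$bound1$w$value[] <- 0; p$bound1$b$value[] <- 0
  p$bound2$w$value[] <- 0; p$bound2$b$value[] <- 0
  m_frozen <- 0.73
  x <- rand_arr(1, C, Hs, Hs)
  cond <- const_conditions(1, Hs, Hs)
  out <- cgwa_forward(x, cond, cfg, p, freeze_modulation = m_frozen)

  # dense oracle: plain single-window multi-head attention on the 25 tokens
  T <- Hs * Hs; dh <- C / heads
  tok <- matrix(0, T, C)
  for (t in seq_len(T)) {
    ty <- (t - 1) %/% Hs + 1; tx <- (t - 1) %% Hs + 1
    tok[t, ] <- x[1, , ty, tx]
  }
  qkv <- tok %*% p$qkv$w$value + matrix(p$qkv$b$value, T, 3 * C, byrow = TRUE)
  q <- qkv[, 1:C]; k <- qkv[, (C + 1):(2 * C)]; v <- qkv[, (2 * C + 1):(3 * C)]
  ctx <- matrix(0, T, C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    logits <- m_frozen * (q[, cols] %*% t(k[, cols])) / sqrt(dh)
    a <- exp(logits - apply(logits, 1, max))
    a <- a / rowSums(a)
    ctx[, cols] <- a %*% v[, cols]
  }
  proj <- ctx %*% p$proj$w$value + matrix(p$proj$b$value, T, C, byrow = TRUE)
  ref <- x
  for (t in seq_len(T)) {
    ty <- (t - 1) %/% Hs + 1; tx <- (t - 1) %% Hs + 1
    ref[1, , ty, tx] <- ref[1, , ty, tx] + proj[t, ]
  }
  expect_lt(max(abs(out - ref)), 1e-5)
})

test_that("attention rows are normalised and padded cells carry no mass", {
  set.seed(55)
  cfg <- cgwa_config(4, heads = 2, window_size = 4)
  p <- cgwa_init(cfg)
  x <- rand_arr(1, 4, 6, 6)                 # pads 6x6 -> 8x8 with Ws=4
  cond <- const_conditions(1, 6, 6)
  res <- cgwa_forward(x, cond, cfg, p, return_attn = TRUE)
  attn <- res$attn                          # (M, T, T)
  sums <- apply(attn, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # padded keys receive ~zero attention in every window
  part <- partition_windows(x, 4)
  for (n in seq_len(nrow(part$pad_mask))) {
    invalid <- which(!part$pad_mask[n, ])
    if (length(invalid) > 0) {
      rows <- ((n - 1) * 2 + 1):(n * 2)     # slices for this window's heads
      expect_lt(max(attn[rows, , invalid]), 1e-12)
    }
  }
  # window-level statistics land between each window's min and max
  expect_true(all(res$stats >= 0 & res$stats <= 1))
})

test_that("score tensor size matches the windowed complexity bound", {
  cfg <- cgwa_config(8, heads = 4, window_size = 7)
  p <- cgwa_init(cfg)
  x <- array(0.1, c(1, 8, 56, 56))
  res <- cgwa_forward(x, const_conditions(1, 56, 56), cfg, p, return_attn = TRUE)
  ws <- 7
  expect_equal(prod(dim(res$attn)),
               ws^4 * (56 / ws) * (56 / ws) * 4)   # vs (H*W)^2 * heads dense
  expect_lt(prod(dim(res$attn)), (56 * 56)^2 * 4)
})

test_that("gradients reach the modulation network when conditions vary", {
  set.seed(56)
  cfg <- cgwa_config(4, heads = 2, window_size = 2, mlp_hidden = 4)
  p <- cgwa_init(cfg)
  # non-zero projection so attention output affects the loss
  p$proj$w$value[] <- rnorm(length(p$proj$w$value), sd = 0.3)
  x <- rand_arr(1, 4, 4, 4)
  occ <- array(0, c(1, 1, 4, 4)); occ[1, 1, , 3:4] <- 1   # varies across windows
  den <- array(runif(16), c(1, 1, 4, 4))
  out <- cgwa_forward(tg_tensor(x), list(occlusion = occ, density = den), cfg, p)
  tg_backward(tg_sum(out))
  expect_false(is.null(p$mod1$w$grad))
  expect_gt(max(abs(p$mod1$w$grad)), 0)
  expect_gt(max(abs(p$qkv$w$grad)), 0)
})
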