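# Condition-Guided Windowed Attention (CGWA).
#
# Multi-head self-attention inside non-overlapping spatial windows with a
# learned relative-position bias, conditioned on two guidance rasters: a
# per-window modulation factor alpha in (0,1) (from a small MLP over window
# mean occlusion/density) multiplies the scaled attention logits, and a
# boundary weight map beta in (0,1) (from a small conv net over the
# concatenated rasters) is added to the logits at each key position so that
# condition boundaries attract attention:
#
#     A = softmax(alpha(O,D) * (Q K^T / sqrt(d_k)) + B + beta(O,D)) V
#
# Windowing reduces the score tensor from (HW)^2 entries to
# Ws^4 * (H/Ws) * (W/Ws) per head.  The output projection is
# zero-initialised, so a freshly created block is exactly the identity
# (residual connection only) and can be inserted into a pretrained graph
# without perturbing it.

#' CGWA block configuration
#'
#' @param channels channel count C (must be divisible by `heads`).
#' @param heads number of attention heads.
#' @param window_size window edge length Ws in cells.
#' @param mlp_hidden hidden width of the modulation MLP.
#' @param dropout dropout rate of the modulation MLP (training mode only).
#' @return a `cgwa_config` list.
#' @export
cgwa_config <- function(channels, heads = 4L, window_size = 7L,
                        mlp_hidden = 16L, dropout = 0) {
  channels <- as.integer(channels); heads <- as.integer(heads)
  stopifnot(channels %% heads == 0, window_size >= 1)
  structure(list(channels = channels, heads = heads,
                 window_size = as.integer(window_size),
                 mlp_hidden = as.integer(mlp_hidden), dropout = dropout),
            class = "cgwa_config")
}

#' Relative-position index table
#'
#' For a `Ws x Ws` window, returns the `(Ws^2, Ws^2)` matrix of 1-based
#' indices into the `(2 Ws - 1)^2`-entry bias table.  The index depends only
#' on the displacement between the two positions, so equal displacements
#' share a bias entry (translation equivariance within the window).
#'
#' @param ws window size.
#' @return integer matrix `(Ws^2, Ws^2)`.
#' @export
relpos_index <- function(ws) {
  t <- ws * ws
  pos_y <- rep(seq_len(ws), each = ws)   # token order: row-major (y major)
  pos_x <- rep(seq_len(ws), times = ws)
  idx <- matrix(0L, t, t)
  for (i in seq_len(t)) {
    dy <- pos_y[i] - pos_y + (ws - 1L)
    dx <- pos_x[i] - pos_x + (ws - 1L)
    idx[i, ] <- dy * (2L * ws - 1L) + dx + 1L
  }
  idx
}

#' Materialise the relative-position bias
#'
#' `bias[h, i, j] = table[index[i, j], h]`.
#'
#' @param table bias table `((2 Ws - 1)^2, heads)` (`tg` or matrix).
#' @param ws window size.
#' @return array `(heads, Ws^2, Ws^2)`.
#' @export
relative_position_bias <- function(table, ws) {
  tv <- tg_value(table)
  heads <- ncol(tv)
  idx <- relpos_index(ws)
  t <- ws * ws
  out <- array(0, c(heads, t, t))
  for (h in seq_len(heads)) {
    out[h, , ] <- matrix(tv[idx, h], t, t)
  }
  out
}

#' Initialise CGWA parameters
#'
#' The relative-position bias table starts at zero and the output projection
#' is zero-initialised (identity block at init).  The occlusion and density
#' encoders are parallel lightweight three-layer convolutional stacks
#' (widths 8, 16, 1) that refine the condition rasters before both the
#' modulation MLP and the boundary network consume them.
#'
#' @param config a [cgwa_config()] object.
#' @return nested list of `tg` parameters.
#' @export
cgwa_init <- function(config) {
  C <- config$channels; ws <- config$window_size
  enc <- function() list(c1 = nn_conv_init(8L, 1L, 3L),
                         c2 = nn_conv_init(16L, 8L, 3L),
                         c3 = nn_conv_init(1L, 16L, 3L))
  list(
    qkv = nn_linear_init(3L * C, C),
    proj = nn_linear_init(C, C, zero = TRUE),
    bias_table = nn_param(matrix(0, (2L * ws - 1L)^2, config$heads)),
    mod1 = nn_linear_init(config$mlp_hidden, 2L),
    mod2 = nn_linear_init(config$heads, config$mlp_hidden),
    bound1 = nn_conv_init(8L, 2L, 3L),
    bound2 = nn_conv_init(1L, 8L, 3L),
    occ_enc = enc(),
    den_enc = enc()
  )
}

# three-layer condition encoder; sigmoid keeps the refined raster in (0,1)
refine_condition <- function(raster, enc) {
  z <- tg_relu(nn_conv(as_tg(raster), enc$c1))
  z <- tg_relu(nn_conv(z, enc$c2))
  tg_sigmoid(nn_conv(z, enc$c3))
}

# window geometry for an H x W grid: counts, token coordinates, validity
window_geometry <- function(B, H, W, ws) {
  od_cache(paste("wgeo", B, H, W, ws), window_geometry_impl(B, H, W, ws))
}

window_geometry_impl <- function(B, H, W, ws) {
  nh <- ceiling(H / ws); nw <- ceiling(W / ws)
  t <- ws * ws
  NW <- B * nh * nw
  # for window n (b-major, then wy, then wx) and token t (row-major in window)
  n_idx <- seq_len(NW) - 1L
  b <- n_idx %% B + 1L
  wy <- (n_idx %/% B) %% nh
  wx <- n_idx %/% (B * nh)
  tt <- seq_len(t) - 1L
  ty <- tt %/% ws; tx <- tt %% ws
  y <- outer(ty, wy * ws, `+`) + 1L     # (t, NW)
  x <- outer(tx, wx * ws, `+`) + 1L
  valid <- y <= H & x <= W
  list(nh = nh, nw = nw, t = t, NW = NW, b = matrix(rep(b, each = t), t, NW),
       y = y, x = x, valid = valid)
}

#' Partition a feature grid into attention windows
#'
#' Tiles the (zero-padded) grid with non-overlapping `Ws x Ws` windows.
#' Tokens are ordered row-major within a window; the padding mask marks
#' cells that fall outside the original extent (those receive -Inf attention
#' logits downstream).  [merge_windows()] inverts the partition exactly on
#' the unpadded cells.
#'
#' @param F `tg` tensor or array `(B, C, H, W)`.
#' @param ws window size.
#' @return list with `windows` (`(NW, Ws^2, C)`, `tg` iff the input was),
#'   `pad_mask` (logical `(NW, Ws^2)`, TRUE = real cell) and `meta`.
#' @export
partition_windows <- function(F, ws) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  geo <- window_geometry(d[1], d[3], d[4], ws)
  od <- c(geo$NW, geo$t, d[2])
  idx <- od_cache(paste("wpart", paste(d, collapse = "x"), ws), {
    gr <- expand_grid_int(od)
    yy <- geo$y[cbind(gr[[2]], gr[[1]])]
    xx <- geo$x[cbind(gr[[2]], gr[[1]])]
    yy[yy > d[3]] <- 0L; xx[xx > d[4]] <- 0L
    mark_idx(flat_index(d, list(geo$b[cbind(gr[[2]], gr[[1]])], gr[[3]], yy, xx)),
             prod(d))
  })
  win <- tg_gather(Ft, idx, od)
  list(windows = if (was_tg) win else tg_value(win),
       pad_mask = t(geo$valid),
       meta = list(dims = d, ws = ws, geo = geo))
}

#' @rdname partition_windows
#' @param windows window tensor from `partition_windows`.
#' @param meta the `meta` element returned by `partition_windows`.
#' @export
merge_windows <- function(windows, meta) {
  was_tg <- is_tg(windows)
  Wt <- as_tg(windows)
  d <- meta$dims; geo <- meta$geo
  idx <- od_cache(paste("wmerge", paste(d, collapse = "x"), meta$ws), {
    gr <- expand_grid_int(d)
    # invert: output cell (b, c, y, x) -> window n, token t
    wy <- (gr[[3]] - 1L) %/% meta$ws; wx <- (gr[[4]] - 1L) %/% meta$ws
    ty <- (gr[[3]] - 1L) %% meta$ws; tx <- (gr[[4]] - 1L) %% meta$ws
    n <- gr[[1]] + geo$NW %/% (geo$nh * geo$nw) * (wy + geo$nh * wx)
    t <- ty * meta$ws + tx + 1L
    mark_idx(flat_index(c(geo$NW, geo$t, d[2]), list(n, t, gr[[2]])),
             geo$NW * geo$t * d[2])
  })
  out <- tg_gather(Wt, idx, d)
  if (was_tg) out else tg_value(out)
}

#' Per-window condition statistics
#'
#' Mean occlusion and density over each window's valid cells, after pooling
#' the rasters to the feature resolution.
#'
#' @param O,D rasters `(B, 1, H, W)` or `(1, H, W)` at the feature grid's
#'   resolution.
#' @param ws window size.
#' @return matrix `(NW, 2)` with columns `mean_occlusion`, `mean_density`.
#' @export
window_condition_stats <- function(O, D, ws) {
  Ov <- tg_value(norm_raster(O)); Dv <- tg_value(norm_raster(D))
  if (any(dim_of(Ov) != dim_of(Dv))) stop("occlusion/density resolution mismatch")
  mo <- window_means(Ov, ws)
  md <- window_means(Dv, ws)
  cbind(mean_occlusion = mo, mean_density = md)
}

norm_raster <- function(x) {
  v <- tg_value(x)
  d <- dim_of(v)
  if (length(d) == 3) {
    if (is_tg(x)) tg_reshape(x, c(1, d)) else array(v, c(1, d))
  } else x
}

# (NW) vector of means over the valid cells of each window
window_means <- function(R, ws) {
  p <- partition_windows(R, ws)
  w <- matrix(tg_value(p$windows), dim_of(tg_value(p$windows))[1])
  rowSums(w) / pmax(rowSums(p$pad_mask), 1)
}

#' Head-specific modulation factors
#'
#' Two-layer feedforward map from `(mean_occlusion, mean_density)` to one
#' factor per head, rectified hidden layer, dropout in training mode, and a
#' sigmoid output: every factor is strictly inside (0, 1).
#'
#' @param stats matrix or `tg` tensor `(n, 2)` of window statistics.
#' @param params CGWA parameters (uses `mod1`, `mod2`).
#' @param dropout dropout rate.
#' @param training logical; enables dropout.
#' @return `(n, heads)` factors in (0, 1) (same type as `stats`).
#' @export
modulation_factors <- function(stats, params, dropout = 0, training = FALSE) {
  was_tg <- is_tg(stats)
  z <- tg_relu(nn_linear(as_tg(stats), params$mod1))
  z <- tg_dropout(z, dropout, training)
  out <- tg_sigmoid(nn_linear(z, params$mod2))
  if (was_tg) out else tg_value(out)
}

#' Boundary weight map
#'
#' Two-layer convolutional network over the concatenated occlusion/density
#' rasters with a sigmoid output: a single-channel map in (0, 1) that is
#' added to the attention logits at the corresponding key positions, so
#' cells on condition boundaries attract attention.
#'
#' @param O,D rasters `(B, 1, H, W)` or `(1, H, W)`.
#' @param params CGWA parameters (uses `bound1`, `bound2`).
#' @return raster `(B, 1, H, W)` in (0, 1) (same type as inputs).
#' @export
boundary_weights <- function(O, D, params) {
  was_tg <- is_tg(O) || is_tg(D)
  Ot <- as_tg(norm_raster(O)); Dt <- as_tg(norm_raster(D))
  if (any(dim_of(Ot$value) != dim_of(Dt$value))) stop("resolution mismatch")
  z <- tg_relu(nn_conv(tg_concat(list(Ot, Dt), 2), params$bound1))
  out <- tg_sigmoid(nn_conv(z, params$bound2))
  if (was_tg) out else tg_value(out)
}

#' CGWA forward pass
#'
#' Applies, per window and head: `softmax(alpha_h * (Q K^T / sqrt(d_k)) +
#' bias + boundary)` over valid keys, multiplies by V, concatenates heads,
#' projects and adds the residual.  Conditions must already be pooled to the
#' feature resolution (see [pool_condition()]).
#'
#' @param F `tg` tensor or array `(B, C, H, W)`.
#' @param conditions list with `occlusion` and `density` rasters
#'   (`(B, 1, H, W)` or `(1, H, W)`) at the feature resolution.
#' @param config a [cgwa_config()].
#' @param params parameters from [cgwa_init()].
#' @param training logical; enables the modulation MLP's dropout.
#' @param return_attn also return the attention tensor (heads stacked along
#'   the first axis) for inspection.
#' @param freeze_modulation optional constant in (0, 1); when given, the
#'   modulation factors are fixed at this value (used by equivalence tests).
#' @return output grid `(B, C, H, W)` (same type as input), or a list
#'   `(output, attn, stats)` when `return_attn = TRUE`.
#' @export
cgwa_forward <- function(F, conditions, config, params, training = FALSE,
                        return_attn = FALSE, freeze_modulation = NULL) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  if (d[2] != config$channels) {
    stop(sprintf("input has %d channels but config expects %d", d[2], config$channels))
  }
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  ws <- config$window_size
  heads <- config$heads
  dh <- C %/% heads
  Ot <- as_tg(norm_raster(conditions$occlusion))
  Dt <- as_tg(norm_raster(conditions$density))
  if (any(dim_of(Ot$value)[3:4] != c(H, W))) {
    stop("conditions must be pooled to the feature resolution")
  }
  # refine rasters through the lightweight encoders
  Or <- refine_condition(Ot, params$occ_enc)
  Dr <- refine_condition(Dt, params$den_enc)

  part <- partition_windows(Ft, ws)
  win <- part$windows                    # (NW, T, C)
  geo <- part$meta$geo
  NW <- geo$NW; T <- geo$t
  valid <- t(geo$valid)                  # (NW, T)

  # per-window condition statistics from the refined rasters (padded cells
  # gather as zero, so summing over all T and dividing by the valid count
  # gives the mean over valid cells)
  po <- partition_windows(Or, ws); pd <- partition_windows(Dr, ws)
  vcount <- pmax(rowSums(valid), 1)
  ones_T <- tg_tensor(array(1, c(NW, T, 1)))
  win_sum <- function(pw) {
    tg_reshape(tg_bmm(tg_aperm(pw$windows, c(1, 3, 2)), ones_T), c(NW, 1L))
  }
  inv_cnt <- tg_tensor(matrix(1 / vcount, NW, 1))
  stats <- tg_concat(list(tg_mul(win_sum(po), inv_cnt),
                          tg_mul(win_sum(pd), inv_cnt)), 2)

  # modulation factors (NW, heads) in (0,1)
  mod <- if (is.null(freeze_modulation)) {
    modulation_factors(stats, params, config$dropout, training)
  } else {
    tg_tensor(matrix(freeze_modulation, NW, heads))
  }

  # qkv projection over all window tokens
  flat <- tg_reshape(win, c(NW * T, C))  # adjacent-axis merge (NW fastest? see note)
  qkv <- nn_linear(flat, params$qkv)
  q <- tg_slice(qkv, 2, 1L, C)
  k <- tg_slice(qkv, 2, C + 1L, 2L * C)
  v <- tg_slice(qkv, 2, 2L * C + 1L, 3L * C)

  # split heads: (NW*T, C) -> (NW*heads, T, dh)
  M <- NW * heads
  hidx <- od_cache(paste("hsplit", NW, T, C, heads), {
    gr <- expand_grid_int(c(M, T, dh))
    n <- (gr[[1]] - 1L) %/% heads + 1L
    h <- (gr[[1]] - 1L) %% heads + 1L
    src_row <- n + NW * (gr[[2]] - 1L)   # row of (NW*T) flat: NW fastest
    src_col <- (h - 1L) * dh + gr[[3]]
    mark_idx(flat_index(c(NW * T, C), list(src_row, src_col)), NW * T * C)
  })
  qh <- tg_gather(q, hidx, c(M, T, dh))
  kh <- tg_gather(k, hidx, c(M, T, dh))
  vh <- tg_gather(v, hidx, c(M, T, dh))

  logits <- tg_scale(tg_bmm(qh, tg_aperm(kh, c(1, 3, 2))), 1 / sqrt(dh))

  # alpha_h multiplies the scaled logits
  m_n <- (seq_len(M) - 1L) %/% heads + 1L
  m_h <- (seq_len(M) - 1L) %% heads + 1L
  mod_m <- tg_reshape(tg_gather(mod, flat_index(c(NW, heads), list(m_n, m_h)),
                                c(M, 1L)), c(M, 1L, 1L))
  logits <- tg_mul(logits, mod_m)

  # relative position bias: (M, T, T) gathered from the table;
  # boundary-bias gather and padding mask share the same coordinate grids
  att_idx <- od_cache(paste("attidx", paste(d, collapse = "x"), ws, heads), {
    ridx <- relpos_index(ws)
    grb <- expand_grid_int(c(M, T, T))
    hb <- (grb[[1]] - 1L) %% heads + 1L
    bidx <- flat_index(dim_of(params$bias_table$value),
                       list(ridx[cbind(grb[[2]], grb[[3]])], hb))
    nb <- (grb[[1]] - 1L) %/% heads + 1L   # window index for each slice
    key_y <- geo$y[cbind(grb[[3]], nb)]
    key_x <- geo$x[cbind(grb[[3]], nb)]
    key_b <- geo$b[cbind(grb[[3]], nb)]
    key_y[key_y > H] <- 0L; key_x[key_x > W] <- 0L
    bw_idx <- mark_idx(flat_index(c(B, 1L, H, W),
                                  list(key_b, rep(1L, length(key_y)), key_y, key_x)))
    key_valid <- valid[cbind(nb, grb[[3]])]
    mask <- array(ifelse(key_valid, 0, -1e9), c(M, T, T))
    list(bidx = mark_idx(bidx), bw_idx = bw_idx, mask = mask)
  })
  logits <- tg_add(logits, tg_gather(params$bias_table, att_idx$bidx, c(M, T, T)))

  # boundary bias, broadcast over queries and heads at each key position
  bw <- boundary_weights(Or, Dr, params)
  logits <- tg_add(logits, tg_gather(bw, att_idx$bw_idx, c(M, T, T)))

  # mask padded keys
  logits <- tg_add(logits, tg_tensor(att_idx$mask))

  attn <- tg_reshape(tg_softmax_rows(tg_reshape(logits, c(M * T, T))), c(M, T, T))
  ctx <- tg_bmm(attn, vh)                # (M, T, dh)

  # merge heads back: (M, T, dh) -> (NW*T, C)
  midx <- od_cache(paste("hmerge", NW, T, C, heads), {
    gr2 <- expand_grid_int(c(NW * T, C))
    n2 <- (gr2[[1]] - 1L) %% NW + 1L
    t2 <- (gr2[[1]] - 1L) %/% NW + 1L
    h2 <- (gr2[[2]] - 1L) %/% dh + 1L
    e2 <- (gr2[[2]] - 1L) %% dh + 1L
    mark_idx(flat_index(c(M, T, dh), list((n2 - 1L) * heads + h2, t2, e2)),
             M * T * dh)
  })
  merged <- tg_gather(ctx, midx, c(NW * T, C))

  proj <- nn_linear(merged, params$proj)
  out_win <- tg_reshape(proj, c(NW, T, C))
  out <- tg_add(Ft, merge_windows(out_win, part$meta))
  if (!was_tg) out_ret <- tg_value(out) else out_ret <- out
  if (return_attn) {
    list(output = out_ret, attn = tg_value(attn), stats = tg_value(stats))
  } else {
    out_ret
  }
}
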