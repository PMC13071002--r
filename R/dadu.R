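# Dual-Adaptive Dynamic Upsampling (DADU).
#
# Content-adaptive upsampler: two parallel convolutions (1x1 pointwise and
# 3x3 spatial) each predict a field of sampling offsets; a learnable scalar,
# squashed through a sigmoid, fuses them convexly; the fused offsets displace
# a regular base grid and the output is built by group-wise bilinear grid
# sampling with border padding.  An optional pixel-shuffle pre-expansion
# ("PL" mode) performs a coarse channel-to-space upsampling first so the
# dynamic sampling only refines, and an optional dynamic-scope head shrinks
# offset magnitudes through a squashed multiplicative factor.

#' DADU block configuration
#'
#' @param channels input channel count C.
#' @param scale integer upsampling factor s (typically 2).
#' @param groups number of sampling groups G; must divide the channel count
#'   of the sampled feature (C in direct mode, C / s^2 in PL mode).
#' @param mode `"direct"` (offsets upsample the input directly) or `"PL"`
#'   (pixel-shuffle first, then refine at scale 1; requires `s^2 | C`).
#' @param dynamic_scope enable the learned offset-magnitude modulation.
#' @param fusion_init initial value of the raw (pre-sigmoid) fusion weight;
#'   the effective branch weight at initialisation is `sigmoid(0.5) ~ 0.622`.
#' @return a `dadu_config` list.
#' @export
dadu_config <- function(channels, scale = 2L, groups = 4L,
                        mode = c("direct", "PL"), dynamic_scope = FALSE,
                        fusion_init = 0.5) {
  mode <- match.arg(mode)
  channels <- as.integer(channels); scale <- as.integer(scale)
  groups <- as.integer(groups)
  stopifnot(scale >= 1)
  cs <- if (mode == "PL") {
    if (channels %% (scale^2) != 0) stop("PL mode requires channels divisible by scale^2")
    channels %/% scale^2
  } else channels
  if (cs %% groups != 0) stop("groups must divide the sampled channel count")
  structure(list(channels = channels, scale = scale, groups = groups,
                 mode = mode, dynamic_scope = dynamic_scope,
                 fusion_init = fusion_init),
            class = "dadu_config")
}

#' Initialise DADU parameters
#'
#' Offset branches are zero-initialised so the block starts as plain
#' bilinear-style base-grid resampling; the raw fusion weight starts at
#' `fusion_init`.
#'
#' @param config a [dadu_config()] object.
#' @return nested list of `tg` parameters.
#' @export
dadu_init <- function(config) {
  s_eff <- if (config$mode == "PL") 1L else config$scale
  cs <- if (config$mode == "PL") config$channels %/% config$scale^2 else config$channels
  n_off <- 2L * config$groups * s_eff^2
  p <- list(
    branch1 = nn_conv_init(n_off, cs, 1L, zero = TRUE),
    branch2 = nn_conv_init(n_off, cs, 3L, zero = TRUE),
    fusion = nn_param(config$fusion_init)
  )
  if (config$dynamic_scope) p$scope <- nn_conv_init(n_off, cs, 1L, zero = TRUE)
  p
}

#' Pixel shuffle (channel-to-space) and its inverse
#'
#' Rearranges `(B, s^2 C, H, W)` into `(B, C, sH, sW)`: each group of `s^2`
#' channels becomes an `s x s` spatial block (row-major within the block).
#' Bijective; `pixel_unshuffle` is the exact inverse.
#'
#' @param F `tg` tensor or array.
#' @param s integer scale factor.
#' @return rearranged grid (same type as input).
#' @export
pixel_shuffle <- function(F, s) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  if (d[2] %% (s * s) != 0) stop("channels not divisible by s^2")
  C <- d[2] %/% (s * s)
  od <- c(d[1], C, d[3] * s, d[4] * s)
  idx <- od_cache(paste("pshuf", paste(d, collapse = "x"), s), {
    gr <- expand_grid_int(od)
    dy <- (gr[[3]] - 1L) %% s; dx <- (gr[[4]] - 1L) %% s
    src_c <- (gr[[2]] - 1L) * s * s + dy * s + dx + 1L
    mark_idx(flat_index(d, list(gr[[1]], src_c,
                                (gr[[3]] - 1L) %/% s + 1L,
                                (gr[[4]] - 1L) %/% s + 1L)), prod(d))
  })
  out <- tg_gather(Ft, idx, od)
  if (was_tg) out else tg_value(out)
}

#' @rdname pixel_shuffle
#' @export
pixel_unshuffle <- function(F, s) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  if (d[3] %% s != 0 || d[4] %% s != 0) stop("spatial dims not divisible by s")
  od <- c(d[1], d[2] * s * s, d[3] %/% s, d[4] %/% s)
  idx <- od_cache(paste("punshuf", paste(d, collapse = "x"), s), {
    gr <- expand_grid_int(od)
    cc <- (gr[[2]] - 1L) %/% (s * s) + 1L
    p <- (gr[[2]] - 1L) %% (s * s)
    dy <- p %/% s; dx <- p %% s
    mark_idx(flat_index(d, list(gr[[1]], cc,
                                (gr[[3]] - 1L) * s + dy + 1L,
                                (gr[[4]] - 1L) * s + dx + 1L)), prod(d))
  })
  out <- tg_gather(Ft, idx, od)
  if (was_tg) out else tg_value(out)
}

#' Predict sampling offsets from one branch
#'
#' The pointwise branch is a 1x1 convolution (each cell's offsets depend only
#' on its own channel vector); the spatial branch is a same-padded 3x3
#' convolution (3x3 neighbourhood receptive field).  Offsets are expressed in
#' units of source-grid cells.
#'
#' @param F `tg` tensor or array `(B, C, H, W)`.
#' @param branch `"pointwise"` or `"spatial"`.
#' @param params DADU parameters from [dadu_init()].
#' @return offset field `(B, 2 G s^2, H, W)` (same type as input).
#' @export
predict_offsets <- function(F, branch = c("pointwise", "spatial"), params) {
  branch <- match.arg(branch)
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  out <- if (branch == "pointwise") nn_conv(Ft, params$branch1)
         else nn_conv(Ft, params$branch2)
  if (was_tg) out else tg_value(out)
}

#' Convex fusion of the two offset fields
#'
#' `fused = sigmoid(alpha) * d1 + (1 - sigmoid(alpha)) * d2` with a single
#' learnable raw weight `alpha`; the effective weight is always in (0, 1) by
#' squashing (never clipping), so the fusion is convex and the result lies
#' elementwise between the branches.
#'
#' @param d1,d2 offset fields of identical shape (`tg` or arrays).
#' @param fusion_param raw scalar weight (`tg` parameter or numeric).
#' @return fused offset field.
#' @export
fuse_offsets <- function(d1, d2, fusion_param) {
  was_tg <- is_tg(d1) || is_tg(d2) || is_tg(fusion_param)
  d1 <- as_tg(d1); d2 <- as_tg(d2)
  if (any(dim_of(d1$value) != dim_of(d2$value))) stop("offset shape mismatch")
  r <- length(dim_of(d1$value))
  a <- tg_reshape(tg_sigmoid(as_tg(fusion_param)), rep(1L, r))
  one <- tg_tensor(array(1, rep(1L, r)))
  out <- tg_add(tg_mul(a, d1), tg_mul(tg_sub(one, a), d2))
  if (was_tg) out else tg_value(out)
}

#' Dynamic-scope offset modulation
#'
#' Multiplies the offsets elementwise by a factor in (0, 1) predicted from
#' the features by an auxiliary 1x1 convolution with sigmoid squashing, so
#' offset magnitudes can only shrink.
#'
#' @param offsets offset field `(B, 2 G s^2, H, W)`.
#' @param F the feature grid the scope is predicted from.
#' @param params DADU parameters (uses `scope`).
#' @return modulated offset field.
#' @export
apply_scope <- function(offsets, F, params) {
  if (is.null(params$scope)) stop("dynamic scope head not initialised")
  was_tg <- is_tg(offsets)
  out <- tg_mul(as_tg(offsets), tg_sigmoid(nn_conv(as_tg(F), params$scope)))
  if (was_tg) out else tg_value(out)
}

#' Bilinear grid sampling of a feature grid
#'
#' Thin wrapper over the differentiable sampling primitive
#' [tg_grid_sample()]: positions are normalized to `[-1, 1]` per axis
#' (align-corners-false) and out-of-range positions replicate the border.
#'
#' @param F `tg` tensor or array `(B, C, H, W)`.
#' @param gx,gy normalized sampling coordinates `(B, Ho, Wo)`.
#' @return sampled grid `(B, C, Ho, Wo)` (same type as `F`).
#' @export
grid_sample_bilinear <- function(F, gx, gy) {
  was_tg <- is_tg(F) || is_tg(gx) || is_tg(gy)
  out <- tg_grid_sample(as_tg(F), as_tg(gx), as_tg(gy))
  if (was_tg) out else tg_value(out)
}

# Offset-channel layout: channel = 2 * (g * s^2 + p) + comp + 1, with group
# g in 0..G-1, sub-position p = dy * s + dx, comp 0 = x, 1 = y.
offset_channel <- function(g, p, comp, s_eff) {
  2L * (g * s_eff^2 + p) + comp + 1L
}

#' DADU forward pass
#'
#' Composition: optional pixel-shuffle pre-expansion, dual offset
#' prediction, sigmoid-weighted convex fusion, optional dynamic scope, then
#' per-group bilinear sampling at `base grid + offsets` (normalized to
#' `[-1, 1]`, border padding); group results are concatenated along
#' channels.  Output shape is `(B, C', sH, sW)` where `C' = C` in direct
#' mode and `C / s^2` in PL mode.
#'
#' @param X `tg` tensor or array `(B, C, H, W)`.
#' @param config a [dadu_config()].
#' @param params parameters from [dadu_init()].
#' @return upsampled grid (same type as input).
#' @export
dadu_forward <- function(X, config, params) {
  was_tg <- is_tg(X)
  Xt <- as_tg(X)
  d <- dim_of(Xt$value)
  if (d[2] != config$channels) {
    stop(sprintf("input has %d channels but config expects %d", d[2], config$channels))
  }
  s <- config$scale
  if (config$mode == "PL") {
    Xt <- pixel_shuffle(Xt, s)
    s_eff <- 1L
  } else {
    s_eff <- s
  }
  ds <- dim_of(Xt$value)
  B <- ds[1]; C <- ds[2]; H <- ds[3]; W <- ds[4]
  G <- config$groups
  cg <- C %/% G
  d1 <- predict_offsets(Xt, "pointwise", params)
  d2 <- predict_offsets(Xt, "spatial", params)
  off <- fuse_offsets(d1, d2, params$fusion)
  if (isTRUE(config$dynamic_scope)) off <- apply_scope(off, Xt, params)
  Ho <- s_eff * H; Wo <- s_eff * W
  odim <- dim_of(tg_value(off))
  geom <- od_cache(paste("dadugeo", B, Ho, Wo, s_eff, G, paste(odim, collapse = "x")), {
    # base grid, cell-center convention (align-corners-false): output pixel
    # j samples source coordinate (j + 0.5) / s - 0.5
    bx <- ((seq_len(Wo) - 1) + 0.5) / s_eff - 0.5
    by <- ((seq_len(Ho) - 1) + 0.5) / s_eff - 0.5
    base_gx <- array(rep(bx, each = B * Ho), c(B, Ho, Wo))
    base_gy <- array(rep(rep(by, each = B), times = Wo), c(B, Ho, Wo))
    grd <- expand_grid_int(c(B, Ho, Wo))
    cell_y <- (grd[[2]] - 1L) %/% s_eff + 1L
    cell_x <- (grd[[3]] - 1L) %/% s_eff + 1L
    p <- ((grd[[2]] - 1L) %% s_eff) * s_eff + (grd[[3]] - 1L) %% s_eff
    ox <- oy <- vector("list", G)
    for (g in seq_len(G)) {
      ox[[g]] <- mark_idx(flat_index(odim, list(grd[[1]], offset_channel(g - 1L, p, 0L, s_eff),
                                                cell_y, cell_x)))
      oy[[g]] <- mark_idx(flat_index(odim, list(grd[[1]], offset_channel(g - 1L, p, 1L, s_eff),
                                                cell_y, cell_x)))
    }
    list(base_gx = base_gx, base_gy = base_gy, ox = ox, oy = oy)
  })
  outs <- vector("list", G)
  for (g in seq_len(G)) {
    off_x <- tg_gather(off, geom$ox[[g]], c(B, Ho, Wo))
    off_y <- tg_gather(off, geom$oy[[g]], c(B, Ho, Wo))
    # offsets are in source-cell units; normalize: gx = (2 x + 1) / W - 1
    gx <- tg_add(tg_tensor((2 * geom$base_gx + 1) / W - 1), tg_scale(off_x, 2 / W))
    gy <- tg_add(tg_tensor((2 * geom$base_gy + 1) / H - 1), tg_scale(off_y, 2 / H))
    xg <- tg_slice(Xt, 2, (g - 1L) * cg + 1L, g * cg)
    outs[[g]] <- tg_grid_sample(xg, gx, gy)
  }
  out <- if (G == 1) outs[[1]] else tg_concat(outs, 2)
  if (was_tg) out else tg_value(out)
}
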