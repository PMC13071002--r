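# Attention-guided Space-Preserving Convolution (ASPC).
#
# Downsampling block that halves resolution without discarding values: a
# bijective space-to-depth rearrangement (2x2 spatial blocks -> four channel
# groups) followed by a 3x3 convolution and cascaded spatial-then-channel
# attention.  Unlike stride-2 convolution, which drops ~75% of spatial
# positions, the SPD stage is exactly invertible.

#' ASPC block configuration
#'
#' @param in_channels input channel count C (the convolution sees 4C).
#' @param out_channels output channel count.
#' @param spatial_kernel kernel size of the spatial-attention convolution.
#' @param channel_reduction bottleneck reduction ratio r of the
#'   channel-attention perceptron.
#' @return an `aspc_config` list.
#' @export
aspc_config <- function(in_channels, out_channels, spatial_kernel = 7L,
                        channel_reduction = 16L) {
  stopifnot(out_channels >= 1, 4 * in_channels >= channel_reduction)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 spatial_kernel = as.integer(spatial_kernel),
                 channel_reduction = as.integer(channel_reduction)),
            class = "aspc_config")
}

#' Initialise ASPC parameters
#'
#' @param config an [aspc_config()] object.
#' @return nested list of `tg` parameters.
#' @export
aspc_init <- function(config) {
  hidden <- max(1L, config$out_channels %/% config$channel_reduction)
  list(
    conv = nn_conv_init(config$out_channels, 4L * config$in_channels, 3L),
    sp_conv = nn_conv_init(1L, 2L, config$spatial_kernel),
    ch_mlp1 = nn_linear_init(hidden, config$out_channels),
    ch_mlp2 = nn_linear_init(config$out_channels, hidden)
  )
}

# index map for the space-to-depth rearrangement; group order TL, TR, BL, BR
spd_index <- function(B, C, H, W) {
  od_cache(paste("spd", B, C, H, W), {
    Ho <- (H + 1L) %/% 2L; Wo <- (W + 1L) %/% 2L
    od <- c(B, 4L * C, Ho, Wo)
    gr <- expand_grid_int(od)
    grp <- (gr[[2]] - 1L) %/% C          # 0 TL, 1 TR, 2 BL, 3 BR
    cc <- (gr[[2]] - 1L) %% C + 1L
    y <- 2L * (gr[[3]] - 1L) + 1L + grp %/% 2L
    x <- 2L * (gr[[4]] - 1L) + 1L + grp %% 2L
    y[y > H] <- 0L; x[x > W] <- 0L        # zero-pad odd extents
    idx <- mark_idx(flat_index(c(B, C, H, W), list(gr[[1]], cc, y, x)),
                    B * C * H * W)
    list(idx = idx, out_dim = od)
  })
}

#' Space-to-depth transform and its inverse
#'
#' `spd_transform` rearranges each non-overlapping 2x2 spatial block of a
#' `(B, C, H, W)` grid into four channel groups, giving `(B, 4C, ceil(H/2),
#' ceil(W/2))`.  The group order along channels is top-left, top-right,
#' bottom-left, bottom-right.  Odd extents are zero-padded on the
#' right/bottom (recorded in the `spd_hw` attribute); on the padded grid the
#' transform is bijective and `spd_inverse` reconstructs the input exactly.
#'
#' @param F `tg` tensor or array `(B, C, H, W)`.
#' @param orig_hw for `spd_inverse`: the original `(H, W)` to crop back to
#'   (defaults to the `spd_hw` attribute of plain-array inputs).
#' @return transformed grid (same type as input: `tg` in, `tg` out).
#' @export
spd_transform <- function(F) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  m <- spd_index(d[1], d[2], d[3], d[4])
  out <- tg_gather(Ft, m$idx, m$out_dim)
  if (was_tg) return(out)
  v <- tg_value(out)
  attr(v, "spd_hw") <- c(d[3], d[4])
  v
}

#' @rdname spd_transform
#' @export
spd_inverse <- function(F, orig_hw = NULL) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  stopifnot(d[2] %% 4 == 0)
  C <- d[2] %/% 4L
  if (is.null(orig_hw)) orig_hw <- attr(F, "spd_hw")
  if (is.null(orig_hw)) orig_hw <- c(2L * d[3], 2L * d[4])
  H <- orig_hw[1]; W <- orig_hw[2]
  od <- c(d[1], C, H, W)
  idx <- od_cache(paste("spdinv", paste(d, collapse = "x"), H, W), {
    gr <- expand_grid_int(od)
    grp <- ((gr[[3]] - 1L) %% 2L) * 2L + (gr[[4]] - 1L) %% 2L
    mark_idx(flat_index(d, list(
      gr[[1]], gr[[2]] + grp * C,
      (gr[[3]] - 1L) %/% 2L + 1L, (gr[[4]] - 1L) %/% 2L + 1L)), prod(d))
  })
  out <- tg_gather(Ft, idx, od)
  if (was_tg) out else tg_value(out)
}

#' Spatial attention map
#'
#' `Msp = sigmoid(Conv_kxk([channel-mean(F); channel-max(F)]))`: channel-wise
#' mean and max pooled to two planes, concatenated, convolved, squashed.
#'
#' @param F `tg` tensor or array `(B, C, H, W)`.
#' @param params ASPC parameters from [aspc_init()] (uses `sp_conv`).
#' @return `(B, 1, H, W)` map with values strictly in (0, 1).
#' @export
spatial_attention <- function(F, params) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  pooled <- tg_concat(list(tg_reduce_channels(Ft, "avg"),
                           tg_reduce_channels(Ft, "max")), 2)
  out <- tg_sigmoid(nn_conv(pooled, params$sp_conv))
  if (was_tg) out else tg_value(out)
}

#' Channel attention weights
#'
#' `Mch = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`: global average and max
#' descriptors pass a shared bottleneck perceptron (reduction r, rectified),
#' are summed and squashed.
#'
#' @inheritParams spatial_attention
#' @return `(B, C, 1, 1)` weights strictly in (0, 1).
#' @export
channel_attention <- function(F, params) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  mlp <- function(desc) {
    v <- tg_reshape(desc, c(d[1], d[2]))
    nn_linear(tg_relu(nn_linear(v, params$ch_mlp1)), params$ch_mlp2)
  }
  s <- tg_sigmoid(tg_add(mlp(tg_pool_global(Ft, "avg")),
                         mlp(tg_pool_global(Ft, "max"))))
  out <- tg_reshape(s, c(d[1], d[2], 1, 1))
  if (was_tg) out else tg_value(out)
}

#' ASPC forward pass
#'
#' `Fout = Mch * (Msp * Conv3x3(SPD(Fin)))` — spatial attention is applied
#' first, then channel attention; `Msp` broadcasts over channels and `Mch`
#' over space.  Output spatial size is `(ceil(H/2), ceil(W/2))`.
#'
#' @param F `tg` tensor or array `(B, C, H, W)` with `C = in_channels`.
#' @param config an [aspc_config()].
#' @param params parameters from [aspc_init()].
#' @return `(B, out_channels, ceil(H/2), ceil(W/2))` grid.
#' @export
aspc_forward <- function(F, config, params) {
  was_tg <- is_tg(F)
  Ft <- as_tg(F)
  d <- dim_of(Ft$value)
  if (d[2] != config$in_channels) {
    stop(sprintf("input has %d channels but config expects %d", d[2], config$in_channels))
  }
  z <- nn_conv(spd_transform(Ft), params$conv)
  # both attention maps are functions of the convolution output F
  msp <- spatial_attention(z, params)
  mch <- channel_attention(z, params)
  out <- tg_mul(mch, tg_mul(msp, z))
  if (was_tg) out else tg_value(out)
}
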