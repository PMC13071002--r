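# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# Every neural block in the package (windowed attention, space-preserving
# convolution, dynamic upsampling, the detector assembly) runs on this tape,
# so the package needs no external deep-learning framework.  Tensors are
# plain numeric arrays wrapped in an environment node; operations record
# their parents and a backward closure; `tg_backward()` walks the graph in
# reverse topological order.  Matrix products go through base BLAS.

.od_env <- new.env(parent = emptyenv())
.od_env$node_counter <- 0L
.od_env$flops_active <- FALSE
.od_env$macs <- 0
.od_env$cache <- new.env(parent = emptyenv())

#' Create a tensor node
#'
#' Wraps a numeric array as a node on the autodiff tape.  Nodes created with
#' `requires_grad = TRUE` behave as trainable parameters: [tg_backward()]
#' accumulates gradients into their `$grad` field.
#'
#' @param value numeric vector, matrix or array.
#' @param requires_grad logical; accumulate gradients into this node?
#' @return an object of class `tg`.
#' @export
tg_tensor <- function(value, requires_grad = FALSE) {
  if (is.null(dim(value))) dim(value) <- length(value)
  storage.mode(value) <- "double"
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$backward_fn <- NULL
  node$requires_grad <- requires_grad
  .od_env$node_counter <- .od_env$node_counter + 1L
  node$id <- .od_env$node_counter
  class(node) <- "tg"
  node
}

#' @export
print.tg <- function(x, ...) {
  cat("<tg tensor> dim:", paste(dim(x$value), collapse = "x"),
      if (x$requires_grad) "(param)" else "", "\n")
  invisible(x)
}

is_tg <- function(x) inherits(x, "tg")

as_tg <- function(x) if (is_tg(x)) x else tg_tensor(x)

#' Extract the value of a tensor node
#' @param x a `tg` tensor or plain array.
#' @return the underlying numeric array.
#' @export
tg_value <- function(x) if (is_tg(x)) x$value else x

tg_node <- function(value, parents, backward_fn) {
  out <- tg_tensor(value)
  out$parents <- parents
  out$backward_fn <- backward_fn
  out$requires_grad <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  out
}

dim_of <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

# Broadcast x (dims equal or 1 per axis) up to target dims td.
bc_to <- function(x, td) {
  dx <- dim_of(x)
  stopifnot(length(dx) == length(td))
  if (all(dx == td)) return(x)
  idx <- lapply(seq_along(td), function(k) {
    if (dx[k] == td[k]) seq_len(td[k]) else rep(1L, td[k])
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Reduce a gradient g (dims gd) back down to original dims od by summing
# over the broadcast axes.
rd_to <- function(g, od) {
  gd <- dim_of(g)
  if (all(gd == od)) return(g)
  keep <- which(od > 1 | gd == 1)
  s <- if (length(keep) == 0) sum(g) else apply(g, keep, sum)
  array(s, dim = od)
}

binary_dims <- function(da, db) {
  stopifnot(length(da) == length(db), all(da == db | da == 1 | db == 1))
  pmax(da, db)
}

#' Elementwise tensor arithmetic
#'
#' Addition, subtraction and multiplication with NumPy-style broadcasting
#' (axes must match or be 1; ranks must agree).  `tg_scale` multiplies by a
#' plain numeric scalar.
#'
#' @param a,b `tg` tensors or numeric arrays of equal rank.
#' @param k numeric scalar.
#' @return a `tg` tensor.
#' @export
tg_add <- function(a, b) {
  a <- as_tg(a); b <- as_tg(b)
  da <- dim_of(a$value); db <- dim_of(b$value)
  dd <- binary_dims(da, db)
  val <- bc_to(a$value, dd) + bc_to(b$value, dd)
  tg_node(val, list(a, b), function(g) list(rd_to(g, da), rd_to(g, db)))
}

#' @rdname tg_add
#' @export
tg_sub <- function(a, b) {
  a <- as_tg(a); b <- as_tg(b)
  da <- dim_of(a$value); db <- dim_of(b$value)
  dd <- binary_dims(da, db)
  val <- bc_to(a$value, dd) - bc_to(b$value, dd)
  tg_node(val, list(a, b), function(g) list(rd_to(g, da), -rd_to(g, db)))
}

#' @rdname tg_add
#' @export
tg_mul <- function(a, b) {
  a <- as_tg(a); b <- as_tg(b)
  da <- dim_of(a$value); db <- dim_of(b$value)
  dd <- binary_dims(da, db)
  av <- bc_to(a$value, dd); bv <- bc_to(b$value, dd)
  tg_node(av * bv, list(a, b),
          function(g) list(rd_to(g * bv, da), rd_to(g * av, db)))
}

#' @rdname tg_add
#' @export
tg_scale <- function(a, k) {
  a <- as_tg(a)
  tg_node(a$value * k, list(a), function(g) list(g * k))
}

#' Matrix and batched matrix product
#'
#' `tg_matmul` multiplies 2-D tensors; `tg_bmm` multiplies slice-wise over
#' the first axis of rank-3 tensors `(N, p, q) x (N, q, r) -> (N, p, r)`.
#'
#' @param a,b `tg` tensors or arrays.
#' @return a `tg` tensor.
#' @export
tg_matmul <- function(a, b) {
  a <- as_tg(a); b <- as_tg(b)
  av <- a$value; bv <- b$value
  count_macs(nrow(av) * ncol(av) * ncol(bv))
  tg_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

#' @rdname tg_matmul
#' @export
tg_bmm <- function(a, b) {
  a <- as_tg(a); b <- as_tg(b)
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3, length(db) == 3, da[1] == db[1], da[3] == db[2])
  n <- da[1]
  out <- array(0, c(n, da[2], db[3]))
  for (i in seq_len(n)) {
    out[i, , ] <- matrix(av[i, , ], da[2], da[3]) %*% matrix(bv[i, , ], db[2], db[3])
  }
  count_macs(n * da[2] * da[3] * db[3])
  tg_node(out, list(a, b), function(g) {
    ga <- array(0, da); gb <- array(0, db)
    for (i in seq_len(n)) {
      gi <- matrix(g[i, , ], da[2], db[3])
      ga[i, , ] <- gi %*% t(matrix(bv[i, , ], db[2], db[3]))
      gb[i, , ] <- crossprod(matrix(av[i, , ], da[2], da[3]), gi)
    }
    list(ga, gb)
  })
}

#' Pointwise nonlinearities
#'
#' @param x a `tg` tensor or array.
#' @return a `tg` tensor of the same shape.
#' @export
tg_sigmoid <- function(x) {
  x <- as_tg(x)
  s <- 1 / (1 + exp(-x$value))
  tg_node(s, list(x), function(g) list(g * s * (1 - s)))
}

#' @rdname tg_sigmoid
#' @export
tg_relu <- function(x) {
  x <- as_tg(x)
  m <- x$value > 0
  tg_node(x$value * m, list(x), function(g) list(g * m))
}

#' @rdname tg_sigmoid
#' @export
tg_exp <- function(x) {
  x <- as_tg(x)
  e <- exp(x$value)
  tg_node(e, list(x), function(g) list(g * e))
}

#' Row-wise softmax of a matrix
#'
#' Softmax along the second axis of a 2-D tensor (each row normalises to 1).
#'
#' @param x a `tg` tensor or matrix `(n, k)`.
#' @return a `tg` tensor `(n, k)` with rows summing to 1.
#' @export
tg_softmax_rows <- function(x) {
  x <- as_tg(x)
  v <- x$value
  m <- apply(v, 1, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  tg_node(s, list(x), function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

#' Full reductions
#'
#' @param x a `tg` tensor or array.
#' @return a scalar `tg` tensor (shape 1).
#' @export
tg_sum <- function(x) {
  x <- as_tg(x)
  d <- dim_of(x$value)
  tg_node(sum(x$value), list(x), function(g) list(array(as.numeric(g), d)))
}

#' @rdname tg_sum
#' @export
tg_mean <- function(x) {
  x <- as_tg(x)
  d <- dim_of(x$value)
  n <- prod(d)
  tg_node(mean(x$value), list(x), function(g) list(array(as.numeric(g) / n, d)))
}

#' Global spatial pooling of a feature grid
#'
#' Reduces a `(B, C, H, W)` grid over its spatial axes to `(B, C, 1, 1)` by
#' the mean or the maximum.
#'
#' @param x `tg` tensor or array `(B, C, H, W)`.
#' @param type `"avg"` or `"max"`.
#' @return a `tg` tensor `(B, C, 1, 1)`.
#' @export
tg_pool_global <- function(x, type = c("avg", "max")) {
  type <- match.arg(type)
  x <- as_tg(x)
  d <- dim(x$value)
  stopifnot(length(d) == 4)
  m <- matrix(aperm(x$value, c(3, 4, 1, 2)), d[3] * d[4], d[1] * d[2])
  if (type == "avg") {
    v <- colMeans(m)
    out <- array(v, c(d[1], d[2], 1, 1))
    tg_node(out, list(x), function(g) {
      gg <- array(rep(as.numeric(g) / (d[3] * d[4]), each = 1), c(d[1], d[2]))
      g4 <- array(0, d)
      for (i in seq_len(d[3])) for (j in seq_len(d[4])) g4[, , i, j] <- gg
      list(g4)
    })
  } else {
    am <- max.col(t(m), ties.method = "first")   # argmax per (b,c)
    v <- m[cbind(am, seq_len(ncol(m)))]
    out <- array(v, c(d[1], d[2], 1, 1))
    tg_node(out, list(x), function(g) {
      gm <- matrix(0, d[3] * d[4], d[1] * d[2])
      gm[cbind(am, seq_len(ncol(gm)))] <- as.numeric(g)
      list(aperm(array(gm, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2)))
    })
  }
}

#' Channel-wise reduction of a feature grid
#'
#' Reduces `(B, C, H, W)` over the channel axis to `(B, 1, H, W)` by the mean
#' or maximum, as used by spatial-attention pathways.
#'
#' @inheritParams tg_pool_global
#' @return a `tg` tensor `(B, 1, H, W)`.
#' @export
tg_reduce_channels <- function(x, type = c("avg", "max")) {
  type <- match.arg(type)
  x <- as_tg(x)
  d <- dim(x$value)
  stopifnot(length(d) == 4)
  if (type == "avg") {
    v <- apply(x$value, c(1, 3, 4), mean)
    out <- array(v, c(d[1], 1, d[3], d[4]))
    tg_node(out, list(x), function(g) {
      gb <- bc_to(g / d[2], d)
      list(gb)
    })
  } else {
    v <- apply(x$value, c(1, 3, 4), max)
    out <- array(v, c(d[1], 1, d[3], d[4]))
    xv <- x$value
    tg_node(out, list(x), function(g) {
      vmax <- bc_to(out, d)
      mask <- (xv == vmax)
      # split ties evenly so the gradient sums to g
      nt <- bc_to(array(apply(mask, c(1, 3, 4), sum), c(d[1], 1, d[3], d[4])), d)
      list(bc_to(g, d) * mask / nt)
    })
  }
}

#' Gather (re-index) a tensor
#'
#' Builds the output by indexing the flattened input: `out_flat[i] =
#' in_flat[idx[i]]`, with `idx == 0` meaning "fill with zero" (used for
#' padding).  The backward pass scatter-adds gradients.  All structural
#' rearrangements in the package (space-to-depth, pixel shuffle, window
#' partition, nearest upsampling) are gathers with precomputed index maps.
#'
#' @param x `tg` tensor or array.
#' @param idx integer vector of length `prod(out_dim)`, 1-based, 0 = zero.
#' @param out_dim integer vector, output dimensions.
#' @return a `tg` tensor with dimensions `out_dim`.
#' @export
tg_gather <- function(x, idx, out_dim) {
  x <- as_tg(x)
  in_dim <- dim_of(x$value)
  xv <- as.numeric(x$value)
  has_zero <- isTRUE(attr(idx, "has_zero"))
  if (is.null(attr(idx, "has_zero"))) has_zero <- any(idx == 0L)
  if (has_zero) {
    v <- xv[pmax(idx, 1L)]
    v[idx == 0L] <- 0
  } else {
    v <- xv[idx]
  }
  out <- array(v, out_dim)
  # bijective gathers (pure rearrangements) invert directly
  is_perm <- attr(idx, "is_perm")
  if (is.null(is_perm)) {
    is_perm <- !has_zero && length(idx) == prod(in_dim) && !anyDuplicated(idx)
  }
  tg_node(out, list(x), function(g) {
    gv <- as.numeric(g)
    gx <- numeric(prod(in_dim))
    if (is_perm) {
      gx[idx] <- gv
    } else {
      keep <- if (has_zero) idx > 0L else TRUE
      acc <- rowsum(gv[keep], idx[keep])
      gx[as.integer(rownames(acc))] <- acc
    }
    list(array(gx, in_dim))
  })
}

# memoised index maps: structural gathers depend only on shapes, so their
# index vectors are computed once per shape and reused across passes
od_cache <- function(key, expr) {
  hit <- .od_env$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .od_env$cache[[key]] <- val
  val
}

mark_idx <- function(idx, in_len = NULL) {
  attr(idx, "has_zero") <- any(idx == 0L)
  attr(idx, "is_perm") <- !attr(idx, "has_zero") &&
    !is.null(in_len) && length(idx) == in_len && !anyDuplicated(idx)
  idx
}

#' Reshape and transpose
#'
#' `tg_reshape` reinterprets the flat (column-major) data with new
#' dimensions; `tg_aperm` permutes axes like [base::aperm()].
#'
#' @param x `tg` tensor or array.
#' @param newdim integer vector with the same total length.
#' @param perm integer permutation of the axes.
#' @return a `tg` tensor.
#' @export
tg_reshape <- function(x, newdim) {
  x <- as_tg(x)
  od <- dim_of(x$value)
  stopifnot(prod(od) == prod(newdim))
  tg_node(array(x$value, newdim), list(x), function(g) list(array(g, od)))
}

#' @rdname tg_reshape
#' @export
tg_aperm <- function(x, perm) {
  x <- as_tg(x)
  inv <- order(perm)
  tg_node(aperm(x$value, perm), list(x), function(g) list(aperm(g, inv)))
}

#' Concatenate tensors along an axis
#'
#' @param xs list of `tg` tensors or arrays of equal rank.
#' @param axis axis index to concatenate along.
#' @return a `tg` tensor.
#' @export
tg_concat <- function(xs, axis) {
  xs <- lapply(xs, as_tg)
  dims <- lapply(xs, function(x) dim_of(x$value))
  r <- length(dims[[1]])
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  od <- dims[[1]]; od[axis] <- sum(sizes)
  out <- array(0, od)
  offs <- cumsum(c(0, sizes))
  ix_all <- lapply(od, seq_len)
  for (i in seq_along(xs)) {
    ix <- ix_all
    ix[[axis]] <- (offs[i] + 1):offs[i + 1]
    out <- do.call(`[<-`, c(list(out), ix, list(value = xs[[i]]$value)))
  }
  tg_node(out, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      ix <- ix_all
      ix[[axis]] <- (offs[i] + 1):offs[i + 1]
      do.call(`[`, c(list(g), ix, list(drop = FALSE)))
    })
  })
}

#' Slice a tensor along one axis
#'
#' @param x `tg` tensor or array.
#' @param axis axis index.
#' @param from,to 1-based inclusive bounds.
#' @return a `tg` tensor.
#' @export
tg_slice <- function(x, axis, from, to) {
  x <- as_tg(x)
  d <- dim_of(x$value)
  ix <- lapply(d, seq_len)
  ix[[axis]] <- from:to
  val <- do.call(`[`, c(list(x$value), ix, list(drop = FALSE)))
  tg_node(val, list(x), function(g) {
    gx <- array(0, d)
    gx <- do.call(`[<-`, c(list(gx), ix, list(value = g)))
    list(gx)
  })
}

#' 2-D convolution (stride 1)
#'
#' Cross-correlation of a `(B, Cin, H, W)` grid with a `(Cout, Cin, K, K)`
#' kernel, zero padding `pad` on every side.  All downsampling in the package
#' is explicit (space-to-depth or pooling), so stride is fixed at 1.
#'
#' @param x `tg` tensor or array `(B, Cin, H, W)`.
#' @param w `tg` tensor `(Cout, Cin, K, K)`.
#' @param b `tg` tensor `(Cout)` or NULL.
#' @param pad non-negative integer padding.
#' @return a `tg` tensor `(B, Cout, H', W')` with `H' = H + 2 pad - K + 1`.
#' @export
tg_conv2d <- function(x, w, b = NULL, pad = 0L) {
  x <- as_tg(x); w <- as_tg(w)
  dx <- dim(x$value); dw <- dim(w$value)
  stopifnot(length(dx) == 4, length(dw) == 4, dx[2] == dw[2])
  B <- dx[1]; Cin <- dx[2]; H <- dx[3]; W <- dx[4]
  Cout <- dw[1]; K <- dw[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- Hp - K + 1L; Wo <- Wp - K + 1L
  stopifnot(Ho >= 1, Wo >= 1)
  xp <- array(0, c(B, Cin, Hp, Wp))
  xp[, , pad + seq_len(H), pad + seq_len(W)] <- x$value
  n_out <- B * Ho * Wo
  out_mat <- matrix(0, Cout, n_out)
  tap_mat <- function(ki, kj) {
    xs <- xp[, , ki:(ki + Ho - 1L), kj:(kj + Wo - 1L), drop = FALSE]
    matrix(aperm(xs, c(2, 1, 3, 4)), Cin, n_out)
  }
  # shift-and-accumulate: one (Cout x Cin) x (Cin x B*Ho*Wo) product per tap
  for (ki in seq_len(K)) for (kj in seq_len(K)) {
    Wk <- matrix(w$value[, , ki, kj], Cout, Cin)
    out_mat <- out_mat + Wk %*% tap_mat(ki, kj)
  }
  count_macs(as.numeric(Cout) * Cin * K * K * n_out)
  bias <- if (!is.null(b)) as_tg(b) else NULL
  if (!is.null(bias)) out_mat <- out_mat + as.numeric(bias$value)
  out <- aperm(array(out_mat, c(Cout, B, Ho, Wo)), c(2, 1, 3, 4))
  parents <- if (is.null(bias)) list(x, w) else list(x, w, bias)
  wv <- w$value
  tg_node(out, parents, function(g) {
    G <- matrix(aperm(g, c(2, 1, 3, 4)), Cout, n_out)
    gw <- array(0, dw)
    gxp <- array(0, c(B, Cin, Hp, Wp))
    for (ki in seq_len(K)) for (kj in seq_len(K)) {
      M <- tap_mat(ki, kj)
      gw[, , ki, kj] <- G %*% t(M)
      Wk <- matrix(wv[, , ki, kj], Cout, Cin)
      gM <- crossprod(Wk, G)                       # Cin x n_out
      gslice <- aperm(array(gM, c(Cin, B, Ho, Wo)), c(2, 1, 3, 4))
      cur <- gxp[, , ki:(ki + Ho - 1L), kj:(kj + Wo - 1L), drop = FALSE]
      gxp[, , ki:(ki + Ho - 1L), kj:(kj + Wo - 1L)] <- cur + gslice
    }
    gx <- gxp[, , pad + seq_len(H), pad + seq_len(W), drop = FALSE]
    if (is.null(bias)) list(gx, gw) else list(gx, gw, rowSums(G))
  })
}

#' 2x2 average pooling (stride 2)
#'
#' @param x `tg` tensor or array `(B, C, H, W)` with even `H`, `W`.
#' @return a `tg` tensor `(B, C, H/2, W/2)`.
#' @export
tg_avgpool2 <- function(x) {
  x <- as_tg(x)
  d <- dim(x$value)
  stopifnot(d[3] %% 2 == 0, d[4] %% 2 == 0)
  Ho <- d[3] %/% 2L; Wo <- d[4] %/% 2L
  v <- (x$value[, , seq(1, d[3], 2), seq(1, d[4], 2), drop = FALSE] +
        x$value[, , seq(2, d[3], 2), seq(1, d[4], 2), drop = FALSE] +
        x$value[, , seq(1, d[3], 2), seq(2, d[4], 2), drop = FALSE] +
        x$value[, , seq(2, d[3], 2), seq(2, d[4], 2), drop = FALSE]) / 4
  tg_node(v, list(x), function(g) {
    gx <- array(0, d)
    for (di in 0:1) for (dj in 0:1) {
      gx[, , seq(1 + di, d[3], 2), seq(1 + dj, d[4], 2)] <- g / 4
    }
    list(gx)
  })
}

#' Nearest-neighbour upsampling by an integer factor
#'
#' @param x `tg` tensor or array `(B, C, H, W)`.
#' @param s integer scale factor.
#' @return a `tg` tensor `(B, C, sH, sW)`.
#' @export
tg_upsample_nearest <- function(x, s) {
  x <- as_tg(x)
  d <- dim(x$value)
  od <- c(d[1], d[2], d[3] * s, d[4] * s)
  src <- od_cache(paste("upnn", paste(d, collapse = "x"), s), {
    gr <- expand_grid_int(od)
    mark_idx(flat_index(d, list(gr[[1]], gr[[2]],
                                (gr[[3]] - 1L) %/% s + 1L,
                                (gr[[4]] - 1L) %/% s + 1L)))
  })
  tg_gather(x, src, od)
}

# Column-major flat index (1-based); any coordinate 0/NA -> 0 (zero fill).
flat_index <- function(dims, coords) {
  n <- length(coords[[1]])
  idx <- rep(1L, n)
  mult <- 1L
  ok <- rep(TRUE, n)
  for (k in seq_along(dims)) {
    ck <- coords[[k]]
    ok <- ok & !is.na(ck) & ck >= 1L & ck <= dims[k]
    ckc <- pmin(pmax(ck, 1L), dims[k])
    idx <- idx + (ckc - 1L) * mult
    mult <- mult * as.integer(dims[k])
  }
  idx[!ok] <- 0L
  idx
}

# All coordinate combinations of an array with dims `od`, column-major order.
expand_grid_int <- function(od) {
  n <- prod(od)
  out <- vector("list", length(od))
  rep_each <- 1L
  for (k in seq_along(od)) {
    out[[k]] <- rep(rep(seq_len(od[k]), each = rep_each), length.out = n)
    rep_each <- rep_each * as.integer(od[k])
  }
  out
}

#' Differentiable bilinear grid sampling
#'
#' Samples each channel of `x` at continuous positions given in normalized
#' coordinates (align-corners-false convention: -1 and 1 are the outer edges
#' of the corner pixels).  Out-of-range positions are clamped to the border
#' (border padding).  Differentiable in both the features and the positions.
#'
#' @param x `tg` tensor or array `(B, C, H, W)`.
#' @param gx,gy `tg` tensors or arrays `(B, Ho, Wo)` of normalized x
#'   (width-axis) and y (height-axis) coordinates in `[-1, 1]`.
#' @return a `tg` tensor `(B, C, Ho, Wo)`.
#' @export
tg_grid_sample <- function(x, gx, gy) {
  x <- as_tg(x); gx <- as_tg(gx); gy <- as_tg(gy)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  dg <- dim_of(gx$value)
  stopifnot(length(dg) == 3, dg[1] == B, all(dim_of(gy$value) == dg))
  Ho <- dg[2]; Wo <- dg[3]
  # to continuous 0-based pixel coordinates
  ix <- ((gx$value + 1) * W - 1) / 2
  iy <- ((gy$value + 1) * H - 1) / 2
  inx <- ix > 0 & ix < W - 1    # zero positional grad once border-clamped
  iny <- iy > 0 & iy < H - 1
  ixc <- pmin(pmax(ix, 0), W - 1)
  iyc <- pmin(pmax(iy, 0), H - 1)
  x0 <- floor(ixc); y0 <- floor(iyc)
  x0 <- pmin(x0, W - 1); y0 <- pmin(y0, H - 1)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  wx <- ixc - x0; wy <- iyc - y0
  n <- B * Ho * Wo
  bix <- rep(seq_len(B), times = Ho * Wo)       # batch coord per grid cell
  mk_idx <- function(xx, yy) {
    # flat index into (B, H, W) view for one channel; channel offset applied later
    flat_index(c(B, H, W), list(bix, as.integer(yy) + 1L, as.integer(xx) + 1L))
  }
  i00 <- mk_idx(x0, y0); i10 <- mk_idx(x1, y0)
  i01 <- mk_idx(x0, y1); i11 <- mk_idx(x1, y1)
  w00 <- as.numeric((1 - wx) * (1 - wy)); w10 <- as.numeric(wx * (1 - wy))
  w01 <- as.numeric((1 - wx) * wy);       w11 <- as.numeric(wx * wy)
  xv <- x$value
  out <- array(0, c(B, C, Ho, Wo))
  ch_plane <- function(c) as.numeric(xv[, c, , ])   # (B,H,W) flattened
  planes <- lapply(seq_len(C), ch_plane)
  for (c in seq_len(C)) {
    p <- planes[[c]]
    out[, c, , ] <- array(p[i00] * w00 + p[i10] * w10 + p[i01] * w01 + p[i11] * w11,
                          c(B, Ho, Wo))
  }
  dgx <- dim_of(gx$value); dgy <- dim_of(gy$value)
  tg_node(out, list(x, gx, gy), function(g) {
    gxv <- array(0, d)
    gpx <- numeric(n); gpy <- numeric(n)
    for (c in seq_len(C)) {
      gc <- as.numeric(g[, c, , ])
      gp <- numeric(B * H * W)
      acc <- rowsum(c(gc * w00, gc * w10, gc * w01, gc * w11),
                    c(i00, i10, i01, i11))
      gp[as.integer(rownames(acc))] <- acc
      gxv[, c, , ] <- array(gp, c(B, H, W))
      p <- planes[[c]]
      # d out / d wx and d wy
      gpx <- gpx + gc * ((p[i10] - p[i00]) * (1 - as.numeric(wy)) +
                         (p[i11] - p[i01]) * as.numeric(wy))
      gpy <- gpy + gc * ((p[i01] - p[i00]) * (1 - as.numeric(wx)) +
                         (p[i11] - p[i10]) * as.numeric(wx))
    }
    gpx <- gpx * as.numeric(inx) * (W / 2)   # chain through ix = ((gx+1)W-1)/2
    gpy <- gpy * as.numeric(iny) * (H / 2)
    list(gxv, array(gpx, dgx), array(gpy, dgy))
  })
}

#' Training losses
#'
#' Numerically stable binary cross-entropy on logits, weighted L1, and mean
#' squared error.  Each returns a scalar `tg`; `weight` entries of zero drop
#' the corresponding elements, and the loss is normalised by `sum(weight)`.
#'
#' @param z `tg` tensor of logits / predictions.
#' @param target numeric array of targets (constant).
#' @param weight numeric array of non-negative weights (same shape).
#' @return scalar `tg` tensor.
#' @export
tg_bce_logits <- function(z, target, weight = NULL) {
  z <- as_tg(z)
  zv <- z$value
  t <- bc_to(as.array(target), dim_of(zv))
  w <- if (is.null(weight)) array(1, dim_of(zv)) else bc_to(as.array(weight), dim_of(zv))
  denom <- max(sum(w), 1e-12)
  l <- pmax(zv, 0) - zv * t + log1p(exp(-abs(zv)))
  s <- 1 / (1 + exp(-zv))
  tg_node(sum(w * l) / denom, list(z),
          function(g) list(as.numeric(g) * w * (s - t) / denom))
}

#' @rdname tg_bce_logits
#' @export
tg_l1 <- function(z, target, weight = NULL) {
  z <- as_tg(z)
  zv <- z$value
  t <- bc_to(as.array(target), dim_of(zv))
  w <- if (is.null(weight)) array(1, dim_of(zv)) else bc_to(as.array(weight), dim_of(zv))
  denom <- max(sum(w), 1e-12)
  r <- zv - t
  tg_node(sum(w * abs(r)) / denom, list(z),
          function(g) list(as.numeric(g) * w * sign(r) / denom))
}

#' @rdname tg_bce_logits
#' @export
tg_mse <- function(z, target, weight = NULL) {
  z <- as_tg(z)
  zv <- z$value
  t <- bc_to(as.array(target), dim_of(zv))
  w <- if (is.null(weight)) array(1, dim_of(zv)) else bc_to(as.array(weight), dim_of(zv))
  denom <- max(sum(w), 1e-12)
  r <- zv - t
  tg_node(sum(w * r^2) / denom, list(z),
          function(g) list(as.numeric(g) * 2 * w * r / denom))
}

#' Dropout
#'
#' Inverted dropout: active only when `training = TRUE`, identity otherwise.
#'
#' @param x `tg` tensor.
#' @param rate drop probability in `[0, 1)`.
#' @param training logical.
#' @return a `tg` tensor.
#' @export
tg_dropout <- function(x, rate, training = FALSE) {
  x <- as_tg(x)
  if (!training || rate <= 0) return(x)
  d <- dim_of(x$value)
  mask <- array(stats::rbinom(prod(d), 1, 1 - rate), d) / (1 - rate)
  tg_mul(x, tg_tensor(mask))
}

#' Run the backward pass
#'
#' Seeds the output gradient (default: all ones) and accumulates gradients
#' into every reachable node with `requires_grad = TRUE`, in reverse
#' topological order.
#'
#' @param root scalar (or any) `tg` tensor, typically a loss.
#' @param grad optional seed gradient, same shape as `root`.
#' @export
tg_backward <- function(root, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim_of(root$value))
  # iterative topological sort
  topo <- list(); seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(fr$node$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = fr$node, stage = 2L)
      for (p in fr$node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      topo[[length(topo) + 1L]] <- fr$node
    }
  }
  grads <- new.env(parent = emptyenv())
  grads[[as.character(root$id)]] <- grad
  for (i in rev(seq_along(topo))) {
    node <- topo[[i]]
    g <- grads[[as.character(node$id)]]
    if (is.null(g)) next
    if (node$requires_grad) {
      node$grad <- if (is.null(node$grad)) g else node$grad + g
    }
    if (!is.null(node$backward_fn)) {
      pgs <- node$backward_fn(g)
      for (k in seq_along(node$parents)) {
        p <- node$parents[[k]]
        if (!p$requires_grad && is.null(p$backward_fn) && length(p$parents) == 0) next
        pk <- as.character(p$id)
        pg <- pgs[[k]]
        if (is.null(pg)) next
        cur <- grads[[pk]]
        grads[[pk]] <- if (is.null(cur)) pg else cur + pg
      }
    }
  }
  invisible(root)
}

count_macs <- function(n) {
  if (isTRUE(.od_env$flops_active)) .od_env$macs <- .od_env$macs + n
  invisible(NULL)
}
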