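# Occlusion and density condition maps.
#
# The attention block consumes two per-pixel guidance rasters in [0, 1]:
# a density map built by adaptive Gaussian kernel aggregation over annotated
# fruit centers (kernel width scales with local crowding, as in geometry-
# adaptive crowd-counting kernels), and an occlusion map estimated from the
# image itself by local contrast attenuation and edge-discontinuity analysis.

#' Adaptive density-kernel parameters
#'
#' Controls the geometry-adaptive Gaussian kernels of
#' [generate_density_map()].  Each annotated center i gets an isotropic
#' kernel with `sigma_i = clamp(beta * dbar_i, sigma_min, sigma_max)` where
#' `dbar_i` is the mean Euclidean distance (in pixels) to its `k` nearest
#' neighbouring centers; tighter clusters therefore get sharper kernels.
#'
#' @param k number of nearest neighbours (>= 1).
#' @param beta dimensionless scale on the mean neighbour distance.
#' @param sigma_min,sigma_max kernel width clamp, in pixels.
#' @return a `density_kernel_params` list.
#' @export
density_kernel_params <- function(k = 3L, beta = 0.3, sigma_min = 1, sigma_max = 15) {
  stopifnot(k >= 1, beta > 0, sigma_min > 0, sigma_max >= sigma_min)
  structure(list(k = as.integer(k), beta = beta,
                 sigma_min = sigma_min, sigma_max = sigma_max),
            class = "density_kernel_params")
}

validate_boxes <- function(boxes) {
  if (is.null(boxes) || nrow(boxes) == 0) return(invisible(boxes))
  need <- c("cx", "cy", "w", "h")
  stopifnot(all(need %in% names(boxes)))
  bad <- which(boxes$cx < 0 | boxes$cx > 1 | boxes$cy < 0 | boxes$cy > 1)
  if (length(bad) > 0) {
    stop(sprintf("box %d has center (%.4f, %.4f) outside [0,1]^2",
                 bad[1], boxes$cx[bad[1]], boxes$cy[bad[1]]))
  }
  invisible(boxes)
}

#' Generate a fruit-density map
#'
#' Places one unit-integral isotropic Gaussian kernel at each annotated box
#' center (pixel centers sit at index + 0.5; centers are given in normalized
#' [0,1] units), with the kernel width adapted to local crowding (see
#' [density_kernel_params()]).  When fewer than `k + 1` boxes exist the width
#' falls back to `sigma_min`.  The summed raster is divided by its maximum
#' plus a small guard so all values lie in `[0, 1)`.
#'
#' @param boxes data frame with columns `cx`, `cy`, `w`, `h` (normalized).
#' @param height,width output raster size in pixels.
#' @param params a [density_kernel_params()] object.
#' @return array `(1, height, width)` with values in `[0, 1)`.
#' @export
generate_density_map <- function(boxes, height, width,
                                 params = density_kernel_params()) {
  stopifnot(height >= 1, width >= 1)
  out <- matrix(0, height, width)
  if (is.null(boxes) || nrow(boxes) == 0) {
    return(array(out, c(1, height, width)))
  }
  validate_boxes(boxes)
  px <- boxes$cx * width    # continuous pixel coordinates, 0-based
  py <- boxes$cy * height
  n <- nrow(boxes)
  sigma <- adaptive_sigmas(px, py, params)
  for (i in seq_len(n)) {
    s <- sigma[i]
    r <- ceiling(4 * s)
    # pixel index ranges touched by the truncated kernel (0-based)
    x0 <- max(floor(px[i] - r), 0); x1 <- min(ceiling(px[i] + r), width - 1)
    y0 <- max(floor(py[i] - r), 0); y1 <- min(ceiling(py[i] + r), height - 1)
    xs <- x0:x1; ys <- y0:y1
    gx <- exp(-((xs + 0.5 - px[i])^2) / (2 * s^2))
    gy <- exp(-((ys + 0.5 - py[i])^2) / (2 * s^2))
    ker <- (gy %o% gx) / (2 * pi * s^2)
    out[ys + 1, xs + 1] <- out[ys + 1, xs + 1] + ker
  }
  out <- out / (max(out) + 1e-6)
  array(out, c(1, height, width))
}

#' Estimate a per-pixel occlusion map from an RGB image
#'
#' Approximates visibility degradation caused by canopy overlap by combining
#' (a) local contrast attenuation `1 - s_local / (s_global + eps)`, where
#' `s_local` is the grayscale standard deviation in a `window x window`
#' neighbourhood and `s_global` the whole-image standard deviation, and (b)
#' an edge-discontinuity term from the normalized Sobel gradient magnitude.
#' The two terms are averaged with equal weight and clipped to `[0, 1]`.
#' Both terms are ratios, so the map is invariant to global affine
#' brightness changes of the image (up to the `eps` guard).  Images with
#' near-zero global contrast return an all-zero map.
#'
#' @param image array `(H, W, 3)` of RGB values in `[0, 1]`.
#' @param window odd local-window size in pixels.
#' @param eps numerical guard.
#' @return array `(1, H, W)` with values in `[0, 1]`.
#' @export
generate_occlusion_map <- function(image, window = 7L, eps = 1e-6) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop("occlusion map requires an RGB image with 3 channels")
  }
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  H <- d[1]; W <- d[2]
  s_global <- stats::sd(as.numeric(gray))
  if (!is.finite(s_global) || s_global < eps) {
    return(array(0, c(1, H, W)))
  }
  r <- (window - 1L) %/% 2L
  cnt <- box_filter(matrix(1, H, W), r)
  mu <- box_filter(gray, r) / cnt
  mu2 <- box_filter(gray^2, r) / cnt
  s_local <- sqrt(pmax(mu2 - mu^2, 0))
  contrast <- pmin(pmax(1 - s_local / (s_global + eps), 0), 1)
  sx <- sobel(gray, "x"); sy <- sobel(gray, "y")
  mag <- sqrt(sx^2 + sy^2)
  edge <- mag / (max(mag) + eps)
  occ <- pmin(pmax(0.5 * contrast + 0.5 * edge, 0), 1)
  array(occ, c(1, H, W))
}

# Geometry-adaptive kernel widths: sigma_i = clamp(beta * mean distance to
# the k nearest neighbours, sigma_min, sigma_max); sigma_min when fewer than
# k + 1 centers exist.
adaptive_sigmas <- function(px, py, params) {
  n <- length(px)
  if (n < params$k + 1) return(rep(params$sigma_min, n))
  dm <- as.matrix(stats::dist(cbind(px, py)))
  diag(dm) <- Inf
  dbar <- apply(dm, 1, function(r) mean(sort(r)[seq_len(params$k)]))
  pmin(pmax(params$beta * dbar, params$sigma_min), params$sigma_max)
}

# Sliding-window sum with radius r via integral image; edges use the
# truncated window (pair with a box_filter of ones to get counts).
box_filter <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  ii <- matrix(0, H + 1, W + 1)
  ii[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
  y0 <- pmax(seq_len(H) - r, 1); y1 <- pmin(seq_len(H) + r, H)
  x0 <- pmax(seq_len(W) - r, 1); x1 <- pmin(seq_len(W) + r, W)
  ii[y1 + 1, x1 + 1, drop = FALSE] - ii[y0, x1 + 1, drop = FALSE] -
    ii[y1 + 1, x0, drop = FALSE] + ii[y0, x0, drop = FALSE]
}

# 3x3 Sobel response with replicate padding.
sobel <- function(x, dir = c("x", "y")) {
  dir <- match.arg(dir)
  H <- nrow(x); W <- ncol(x)
  pad <- rbind(x[1, , drop = FALSE], x, x[H, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W, drop = FALSE])
  k <- if (dir == "x") {
    matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  } else {
    matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  }
  out <- matrix(0, H, W)
  for (i in 1:3) for (j in 1:3) {
    if (k[i, j] != 0) {
      out <- out + k[i, j] * pad[i:(i + H - 1), j:(j + W - 1)]
    }
  }
  out
}

#' Area-average pooling of a condition raster
#'
#' Exact fractional area averaging: each target cell's value is the mean of
#' the source region it covers, with partially covered source cells weighted
#' by overlap.  Pooling to the source size is the identity; pooled values
#' stay within the input range.
#'
#' @param map array `(1, H, W)`, matrix `(H, W)`, or array `(B, 1, H, W)`.
#' @param target_h,target_w output size in cells (>= 1, <= source dims).
#' @return raster of the same rank as the input, spatial size
#'   `target_h x target_w`.
#' @export
pool_condition <- function(map, target_h, target_w) {
  if (target_h < 1 || target_w < 1) stop("target dimensions must be >= 1")
  d <- dim(map)
  wrap <- function(m) m
  if (length(d) == 3) {
    stopifnot(d[1] == 1)
    m <- matrix(map[1, , ], d[2], d[3])
    wrap <- function(x) array(x, c(1, target_h, target_w))
  } else if (length(d) == 4) {
    stopifnot(d[2] == 1)
    out <- array(0, c(d[1], 1, target_h, target_w))
    for (b in seq_len(d[1])) {
      out[b, 1, , ] <- pool_condition(matrix(map[b, 1, , ], d[3], d[4]),
                                      target_h, target_w)
    }
    return(out)
  } else {
    m <- map
    wrap <- identity
  }
  H <- nrow(m); W <- ncol(m)
  if (target_h > H || target_w > W) stop("target dimensions exceed source dimensions")
  wrap(overlap_weights(target_h, H) %*% m %*% t(overlap_weights(target_w, W)))
}

# (t x n) row-stochastic matrix of fractional interval overlaps between t
# equal target cells and n source cells.
overlap_weights <- function(t, n) {
  L <- matrix(0, t, n)
  step <- n / t
  for (i in seq_len(t)) {
    a <- (i - 1) * step; b <- i * step
    j0 <- floor(a); j1 <- ceiling(b) - 1
    for (j in j0:j1) {
      L[i, j + 1] <- max(0, min(b, j + 1) - max(a, j))
    }
  }
  L / rowSums(L)
}

#' Read and write YOLO-format label files
#'
#' One line per object: `class cx cy w h`, whitespace-separated, normalized
#' floats, LF line endings.  A missing or empty file reads as zero boxes.
#'
#' @param path label file path.
#' @return `read_yolo_labels`: data frame with columns `class` (integer),
#'   `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path) {
  empty <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty)
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(class = as.integer(vals[, 1]), cx = vals[, 2], cy = vals[, 3],
             w = vals[, 4], h = vals[, 5])
}

#' @rdname read_yolo_labels
#' @param boxes data frame with columns `class`, `cx`, `cy`, `w`, `h`.
#' @export
write_yolo_labels <- function(boxes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(boxes) > 0) {
    lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                     as.integer(boxes$class), boxes$cx, boxes$cy, boxes$w, boxes$h)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Build the condition pair for one image
#'
#' Convenience wrapper producing the occlusion and density rasters together,
#' validated to share spatial dimensions and lie in `[0, 1]`.
#'
#' @param image array `(H, W, 3)` RGB in `[0, 1]`.
#' @param boxes YOLO-normalized box data frame (for the density map).
#' @param params [density_kernel_params()].
#' @return list with `occlusion` and `density`, each `(1, H, W)`.
#' @export
condition_pair <- function(image, boxes, params = density_kernel_params()) {
  d <- dim(image)
  occ <- generate_occlusion_map(image)
  den <- generate_density_map(boxes, d[1], d[2], params)
  structure(list(occlusion = occ, density = den,
                 source_resolution = c(d[1], d[2])),
            class = "condition_pair")
}
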