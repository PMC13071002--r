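# Synthetic orchard scenes.
#
# Deterministic generator of orchard-like images with exact ground truth,
# standing in for field data in tests: small shaded fruit disks in three
# color-defined maturity classes (colors sampled strictly inside the
# colorimetric threshold regions so labels round-trip), clustered placement
# with controllable tightness, elliptical "leaf" occluders drawn over the
# fruits, and per-fruit occluded fractions measured exactly on pixel masks.

#' Declarative description of a synthetic orchard scene
#'
#' The defaults emulate the study regime: 640x640 scenes of small
#' (< 32x32 px) fruits, clustered so that inter-fruit center distances reach
#' below 15 px, with enough foliage occlusion that roughly 40% of fruits
#' have more than 30% of their area covered.
#'
#' @param image_size square image edge in pixels.
#' @param n_fruits number of fruits.
#' @param class_mix probability triple over (unripe, semi_ripe, ripe);
#'   must sum to 1.
#' @param radius_range fruit radius bounds in pixels.
#' @param cluster_count number of cluster centers.
#' @param cluster_spread standard deviation of fruit placement around its
#'   cluster center, in pixels.
#' @param cluster_fraction share of fruits placed in tight clusters (the
#'   rest scatter uniformly); about a third of fruits in high-density
#'   regions reproduces the study regime.
#' @param occluder_density probability in `[0, 1]` that a fruit receives a
#'   dedicated occluding leaf.
#' @param background_texture `"flat"` or `"foliage"`.
#' @param illumination_gain global multiplicative brightness factor.
#' @param seed RNG seed; equal seeds give byte-identical scenes.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = 640L, n_fruits = 30L,
                       class_mix = c(unripe = 0.2, semi_ripe = 0.3, ripe = 0.5),
                       radius_range = c(6, 14), cluster_count = 6L,
                       cluster_spread = 9, cluster_fraction = 0.45,
                       occluder_density = 0.30,
                       background_texture = c("foliage", "flat"),
                       illumination_gain = 1, seed = 1L) {
  background_texture <- match.arg(background_texture)
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, all(radius_range > 0),
            occluder_density >= 0, occluder_density <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_fruits = as.integer(n_fruits),
                 class_mix = class_mix, radius_range = radius_range,
                 cluster_count = as.integer(cluster_count),
                 cluster_spread = cluster_spread,
                 cluster_fraction = cluster_fraction,
                 occluder_density = occluder_density,
                 background_texture = background_texture,
                 illumination_gain = illumination_gain,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample a base RGB color (0-255) strictly inside a class's threshold
# region, robust to multiplicative shading down to factor `shade_min`
sample_class_color <- function(class, shade_min = 0.75) {
  for (i in 1:100) {
    if (class == "ripe") {
      h <- if (stats::runif(1) < 0.8) stats::runif(1, 2, 15) else stats::runif(1, 345, 356)
      s <- stats::runif(1, 0.70, 0.92); v <- stats::runif(1, 0.55, 0.85)
    } else if (class == "semi_ripe") {
      h <- stats::runif(1, 25, 55)
      s <- stats::runif(1, 0.5, 0.8); v <- stats::runif(1, 0.6, 0.9)
    } else {
      h <- stats::runif(1, 70, 110)
      s <- stats::runif(1, 0.45, 0.78); v <- stats::runif(1, 0.5, 0.85)
    }
    rgb <- as.numeric(grDevices::col2rgb(grDevices::hsv(h / 360, s, v)))
    ok <- TRUE
    for (f in c(1, shade_min)) {
      if (classify_rgb_pixel(round(rgb[1] * f), round(rgb[2] * f),
                             round(rgb[3] * f)) != class) ok <- FALSE
    }
    if (class == "semi_ripe" && (rgb[1] - rgb[2] > 20)) ok <- FALSE
    if (ok) return(rgb / 255)
  }
  stop("could not sample a color inside the ", class, " threshold region")
}

class_id <- function(class) match(class, maturity_classes()) - 1L

#' Render a synthetic orchard scene
#'
#' Fruits are drawn as radially shaded disks with class-conditional colors
#' sampled inside the colorimetric threshold regions (so an unoccluded
#' fruit's majority vote recovers its class); elliptical leaf occluders are
#' drawn over them with probability `occluder_density` per fruit.  The
#' occluded fraction of each fruit is measured exactly on the pixel masks as
#' the share of its disk hidden by anything drawn above it.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (array `(size, size, 3)` in `[0,1]`) and
#'   `truth`: a list with `boxes` (YOLO-style data frame, class ids
#'   0 = unripe, 1 = semi_ripe, 2 = ripe), `class` (labels),
#'   `occluded_fraction`, `radius_px` and `centers_px`.
#' @export
render_scene <- function(spec) {
  with_local_seed(spec$seed, {
    S <- spec$image_size
    n <- spec$n_fruits
    rmax <- max(spec$radius_range)
    if (n * pi * rmax^2 > 0.9 * S^2) stop("infeasible packing: too many fruits")

    img <- render_background(spec)

    if (n == 0) {
      return(list(image = img,
                  truth = list(boxes = data.frame(class = integer(0), cx = numeric(0),
                                                  cy = numeric(0), w = numeric(0),
                                                  h = numeric(0)),
                               class = character(0), occluded_fraction = numeric(0),
                               radius_px = numeric(0),
                               centers_px = matrix(0, 0, 2))))
    }

    classes <- sample(maturity_classes(), n, replace = TRUE, prob = spec$class_mix)
    radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
    margin <- radii + 2
    ccx <- stats::runif(spec$cluster_count, rmax + 2, S - rmax - 2)
    ccy <- stats::runif(spec$cluster_count, rmax + 2, S - rmax - 2)
    ci <- sample.int(spec$cluster_count, n, replace = TRUE)
    clustered <- stats::runif(n) < spec$cluster_fraction
    fx <- ifelse(clustered,
                 ccx[ci] + stats::rnorm(n, 0, spec$cluster_spread),
                 stats::runif(n, 0, S))
    fy <- ifelse(clustered,
                 ccy[ci] + stats::rnorm(n, 0, spec$cluster_spread),
                 stats::runif(n, 0, S))
    fx <- pmin(pmax(fx, margin), S - margin)
    fy <- pmin(pmax(fy, margin), S - margin)

    owner <- matrix(0L, S, S)     # last object drawn at each pixel; fruits 1..n
    disk_area <- numeric(n)

    for (i in seq_len(n)) {
      col <- sample_class_color(classes[i])
      r <- radii[i]
      x0 <- max(floor(fx[i] - r), 0); x1 <- min(ceiling(fx[i] + r), S - 1)
      y0 <- max(floor(fy[i] - r), 0); y1 <- min(ceiling(fy[i] + r), S - 1)
      xs <- x0:x1; ys <- y0:y1
      dx2 <- (xs + 0.5 - fx[i])^2
      dy2 <- (ys + 0.5 - fy[i])^2
      rho2 <- outer(dy2, dx2, `+`)
      inside <- rho2 <= r^2
      disk_area[i] <- sum(inside)
      shade <- 1 - 0.25 * pmin(rho2 / r^2, 1)
      for (ch in 1:3) {
        plane <- img[ys + 1, xs + 1, ch]
        plane[inside] <- (col[ch] * shade)[inside]
        img[ys + 1, xs + 1, ch] <- plane
      }
      sub <- owner[ys + 1, xs + 1]
      sub[inside] <- i
      owner[ys + 1, xs + 1] <- sub
    }

    # elliptical leaf occluders, one targeted per fruit with probability
    # occluder_density; coverage varies broadly so ~72% of dedicated leaves
    # cover more than 30% of their fruit
    leaf_id <- n
    for (i in seq_len(n)) {
      if (stats::runif(1) > spec$occluder_density) next
      leaf_id <- leaf_id + 1L
      r <- radii[i]
      ang <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, 0.1 * r, 1.1 * r)
      lx <- fx[i] + cos(ang) * off
      ly <- fy[i] + sin(ang) * off
      a <- r * stats::runif(1, 0.9, 1.8)          # semi-axes
      bax <- a * stats::runif(1, 0.45, 0.8)
      th <- stats::runif(1, 0, pi)
      leafcol <- as.numeric(grDevices::col2rgb(grDevices::hsv(
        stats::runif(1, 75, 105) / 360, stats::runif(1, 0.15, 0.3),
        stats::runif(1, 0.25, 0.5)))) / 255
      x0 <- max(floor(lx - a), 0); x1 <- min(ceiling(lx + a), S - 1)
      y0 <- max(floor(ly - a), 0); y1 <- min(ceiling(ly + a), S - 1)
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      ddx <- outer(rep(1, length(ys)), xs + 0.5 - lx)
      ddy <- outer(ys + 0.5 - ly, rep(1, length(xs)))
      u <- ddx * cos(th) + ddy * sin(th)
      v <- -ddx * sin(th) + ddy * cos(th)
      inside <- (u / a)^2 + (v / bax)^2 <= 1
      for (ch in 1:3) {
        plane <- img[ys + 1, xs + 1, ch]
        plane[inside] <- leafcol[ch] * (0.85 + 0.3 * (u[inside] / a))
        img[ys + 1, xs + 1, ch] <- plane
      }
      sub <- owner[ys + 1, xs + 1]
      sub[inside] <- leaf_id
      owner[ys + 1, xs + 1] <- sub
    }

    visible <- tabulate(owner[owner >= 1 & owner <= n], nbins = n)
    occluded_fraction <- ifelse(disk_area > 0, 1 - visible / disk_area, 1)

    img <- pmin(pmax(img * spec$illumination_gain, 0), 1)
    boxes <- data.frame(class = vapply(classes, class_id, integer(1)),
                        cx = fx / S, cy = fy / S,
                        w = 2 * radii / S, h = 2 * radii / S)
    list(image = img,
         truth = list(boxes = boxes, class = classes,
                      occluded_fraction = occluded_fraction,
                      radius_px = radii, centers_px = cbind(fx, fy)))
  })
}

render_background <- function(spec) {
  S <- spec$image_size
  if (spec$background_texture == "flat") {
    base <- as.numeric(grDevices::col2rgb(grDevices::hsv(100 / 360, 0.22, 0.45))) / 255
    img <- array(0, c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- base[ch]
    return(img)
  }
  # foliage: smooth low-saturation green value noise (coarse grid, bilinear)
  g <- 16L
  coarse_v <- matrix(stats::runif(g * g, 0.25, 0.55), g, g)
  coarse_h <- matrix(stats::runif(g * g, 80, 115), g, g)
  v <- upsample_matrix(coarse_v, S)
  h <- upsample_matrix(coarse_h, S)
  s <- 0.18 + 0.1 * (v - min(v)) / max(1e-9, diff(range(v)))
  img <- array(0, c(S, S, 3))
  rgbm <- grDevices::col2rgb(grDevices::hsv(as.numeric(h) / 360, as.numeric(s),
                                            as.numeric(v))) / 255
  img[, , 1] <- matrix(rgbm[1, ], S, S)
  img[, , 2] <- matrix(rgbm[2, ], S, S)
  img[, , 3] <- matrix(rgbm[3, ], S, S)
  img
}

# bilinear upsample of a small matrix to size S x S
upsample_matrix <- function(m, S) {
  g <- nrow(m)
  pos <- (seq_len(S) - 0.5) / S * (g - 1) + 1   # continuous source index
  i0 <- pmin(floor(pos), g - 1); w <- pos - i0
  rows <- m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1, , drop = FALSE] * w
  cols <- t(t(rows[, i0, drop = FALSE]) * (1 - w)) + t(t(rows[, i0 + 1, drop = FALSE]) * w)
  cols
}

#' Augmentation policy
#'
#' Parameter ranges for [augment()], defaulting to the study's augmentation
#' recipe: horizontal/vertical flips, rotation within ±15°, random cropping,
#' multi-scale resizing, brightness ±30%, contrast ±25%, hue ±10° and
#' saturation ±30%.  `identity_policy()` disables everything.
#'
#' @param hflip,vflip flip probabilities.
#' @param rotation rotation range in degrees.
#' @param crop maximum fraction of each edge removed by the random crop.
#' @param scale multi-scale resize factor range (about the center).
#' @param brightness,contrast,saturation multiplicative jitter ranges.
#' @param hue additive hue-shift range in degrees.
#' @return an `augment_policy` list.
#' @export
augment_policy <- function(hflip = 0.5, vflip = 0.5, rotation = c(-15, 15),
                           crop = 0.1, scale = c(0.9, 1.1),
                           brightness = c(-0.3, 0.3), contrast = c(-0.25, 0.25),
                           hue = c(-10, 10), saturation = c(-0.3, 0.3)) {
  structure(list(hflip = hflip, vflip = vflip, rotation = rotation, crop = crop,
                 scale = scale, brightness = brightness, contrast = contrast,
                 hue = hue, saturation = saturation),
            class = "augment_policy")
}

#' @rdname augment_policy
#' @export
identity_policy <- function() {
  augment_policy(hflip = 0, vflip = 0, rotation = c(0, 0), crop = 0,
                 scale = c(1, 1), brightness = c(0, 0), contrast = c(0, 0),
                 hue = c(0, 0), saturation = c(0, 0))
}

# 3x3 homogeneous affine helpers on normalized [0,1]^2 coordinates
aff_id <- function() diag(3)
aff_translate <- function(tx, ty) matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3)
aff_scale <- function(sx, sy) diag(c(sx, sy, 1))
aff_rotate <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
}
aff_about_center <- function(A) {
  aff_translate(0.5, 0.5) %*% A %*% aff_translate(-0.5, -0.5)
}

#' Augment an image and its boxes consistently
#'
#' Samples one transform from the policy (seeded), applies the geometric
#' part to both the image (nearest-neighbour inverse mapping, so fruit
#' colors are preserved exactly) and the boxes (transformed corner bounding
#' box, clipped to the image, dropped below 4 px² area), then applies the
#' photometric part to the image only.
#'
#' @param image array `(H, W, 3)` in `[0,1]`.
#' @param boxes YOLO-normalized box data frame.
#' @param policy an [augment_policy()].
#' @param seed RNG seed for the sampled transform.
#' @return list with `image` and `boxes`.
#' @export
augment <- function(image, boxes, policy = augment_policy(), seed = 1L) {
  with_local_seed(seed, {
    H <- dim(image)[1]; W <- dim(image)[2]
    do_h <- stats::runif(1) < policy$hflip
    do_v <- stats::runif(1) < policy$vflip
    th <- stats::runif(1, policy$rotation[1], policy$rotation[2]) * pi / 180
    sc <- stats::runif(1, policy$scale[1], policy$scale[2])
    cfrac <- if (policy$crop > 0) stats::runif(2, 0, policy$crop) else c(0, 0)
    coff <- if (policy$crop > 0) stats::runif(2, 0, 1) * cfrac else c(0, 0)

    # forward map: flip -> rotate -> scale -> crop-and-stretch
    A <- aff_id()
    if (do_h) A <- aff_about_center(aff_scale(-1, 1)) %*% A
    if (do_v) A <- aff_about_center(aff_scale(1, -1)) %*% A
    A <- aff_about_center(aff_rotate(th)) %*% A
    A <- aff_about_center(aff_scale(sc, sc)) %*% A
    cw <- 1 - cfrac[1]; chh <- 1 - cfrac[2]
    A <- aff_scale(1 / cw, 1 / chh) %*% aff_translate(-coff[1], -coff[2]) %*% A

    Ainv <- solve(A)
    # image: inverse map each output pixel center, nearest neighbour
    uo <- (rep(seq_len(W), each = H) - 0.5) / W
    vo <- (rep(seq_len(H), times = W) - 0.5) / H
    src <- Ainv %*% rbind(uo, vo, 1)
    sx <- round(src[1, ] * W + 0.5); sy <- round(src[2, ] * H + 0.5)
    ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
    out <- array(0, dim(image))
    idx <- cbind(sy[ok], sx[ok])
    tgt <- cbind(rep(seq_len(H), times = W)[ok], rep(seq_len(W), each = H)[ok])
    for (ch in 1:3) {
      plane_in <- image[, , ch]
      plane <- matrix(0, H, W)
      plane[tgt] <- plane_in[idx]
      out[, , ch] <- plane
    }

    # boxes: forward-map corners, take the axis-aligned hull, clip, filter
    new_boxes <- boxes[0, , drop = FALSE]
    if (nrow(boxes) > 0) {
      keep <- logical(nrow(boxes))
      cx <- cy <- bw <- bh <- numeric(nrow(boxes))
      for (i in seq_len(nrow(boxes))) {
        xs <- boxes$cx[i] + c(-1, 1, -1, 1) * boxes$w[i] / 2
        ys <- boxes$cy[i] + c(-1, -1, 1, 1) * boxes$h[i] / 2
        pc <- A %*% rbind(xs, ys, 1)
        x0 <- max(min(pc[1, ]), 0); x1 <- min(max(pc[1, ]), 1)
        y0 <- max(min(pc[2, ]), 0); y1 <- min(max(pc[2, ]), 1)
        if (x1 > x0 && y1 > y0 && (x1 - x0) * W * (y1 - y0) * H >= 4) {
          keep[i] <- TRUE
          cx[i] <- (x0 + x1) / 2; cy[i] <- (y0 + y1) / 2
          bw[i] <- x1 - x0; bh[i] <- y1 - y0
        }
      }
      new_boxes <- data.frame(class = boxes$class[keep], cx = cx[keep],
                              cy = cy[keep], w = bw[keep], h = bh[keep])
    }

    # photometric transforms: boxes untouched
    br <- 1 + stats::runif(1, policy$brightness[1], policy$brightness[2])
    ct <- 1 + stats::runif(1, policy$contrast[1], policy$contrast[2])
    hs <- stats::runif(1, policy$hue[1], policy$hue[2])
    sa <- 1 + stats::runif(1, policy$saturation[1], policy$saturation[2])
    if (abs(br - 1) > 0 || abs(ct - 1) > 0) {
      out <- pmin(pmax((out * br - 0.5) * ct + 0.5, 0), 1)
    }
    if (abs(hs) > 0 || abs(sa - 1) > 0) {
      hsvm <- grDevices::rgb2hsv(rbind(as.numeric(out[, , 1]),
                                       as.numeric(out[, , 2]),
                                       as.numeric(out[, , 3])), maxColorValue = 1)
      hh <- (hsvm[1, ] + hs / 360) %% 1
      ss <- pmin(pmax(hsvm[2, ] * sa, 0), 1)
      rgbm <- grDevices::col2rgb(grDevices::hsv(hh, ss, hsvm[3, ])) / 255
      for (ch in 1:3) out[, , ch] <- matrix(rgbm[ch, ], H, W)
    }
    list(image = out, boxes = new_boxes)
  })
}

#' Write a dataset of rendered scenes in YOLO layout
#'
#' Splits the scenes into train/val/test subsets (sizes within one of the
#' exact fractions), writing PNG images, YOLO label text files and
#' single-channel 32-bit float condition rasters (TIFF) whose filenames
#' mirror the image stems.
#'
#' @param scenes list of rendered scenes (see [render_scene()]).
#' @param out_dir output directory.
#' @param split length-3 fractions summing to 1 (train, val, test).
#' @param params [density_kernel_params()] for the density rasters.
#' @return manifest data frame (one row per scene: stem, split, paths).
#' @export
write_dataset <- function(scenes, out_dir, split = c(0.70, 0.15, 0.15),
                          params = density_kernel_params()) {
  if (length(scenes) == 0) stop("empty scene list")
  stopifnot(abs(sum(split) - 1) < 1e-9)
  n <- length(scenes)
  counts <- floor(split * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(split * n - counts, decreasing = TRUE)
    for (k in seq_len(rem)) {
      j <- frac_order[(k - 1) %% 3 + 1]
      counts[j] <- counts[j] + 1
    }
  }
  names(counts) <- c("train", "val", "test")
  assign_split <- rep(names(counts), counts)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- assign_split[i]
    stem <- sprintf("scene_%04d", i)
    dirs <- file.path(out_dir, c("images", "labels", "conditions"), sp)
    for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
    img_path <- file.path(dirs[1], paste0(stem, ".png"))
    lbl_path <- file.path(dirs[2], paste0(stem, ".txt"))
    occ_path <- file.path(dirs[3], paste0(stem, "_occlusion.tif"))
    den_path <- file.path(dirs[3], paste0(stem, "_density.tif"))
    sc <- scenes[[i]]
    png::writePNG(sc$image, img_path)
    write_yolo_labels(sc$truth$boxes, lbl_path)
    S <- dim(sc$image)[1]
    occ <- generate_occlusion_map(sc$image)
    den <- generate_density_map(sc$truth$boxes, S, dim(sc$image)[2], params)
    tiff::writeTIFF(matrix(occ[1, , ], S), occ_path, bits.per.sample = 32L)
    tiff::writeTIFF(matrix(den[1, , ], S), den_path, bits.per.sample = 32L)
    rows[[i]] <- data.frame(stem = stem, split = sp, image = img_path,
                            labels = lbl_path, occlusion = occ_path,
                            density = den_path, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
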