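# Small one-stage detector assembly.
#
# A reduced-width YOLO-style graph for CPU experiments: a backbone whose
# stride-2 downsamples are ASPC blocks (or plain conv + 2x2 average pooling
# in the baseline), a PAN neck whose two top-down upsamples are DADU blocks
# (or nearest-neighbour in the baseline), and condition-guided windowed
# attention applied to each of the three output scales (strides 4, 8, 16).
# Heads are anchor-free 1x1 convolutions predicting, per cell, the box
# center offset within the cell (sigmoid), log size in stride units, an
# objectness logit and per-class logits.

#' Detector configuration
#'
#' @param num_classes number of object classes.
#' @param base_channels backbone stem width; stages use multiples of it.
#' @param input_size nominal square input edge in pixels.
#' @param use_aspc,use_cgwa,use_dadu independent block toggles (all off
#'   reproduces the plain baseline graph).
#' @param window_size,heads CGWA settings at every scale.
#' @param dadu_groups sampling groups of the DADU upsamplers.
#' @param density_source where the density condition comes from at forward
#'   time: `"predicted"` (auxiliary head trained against offline
#'   ground-truth maps), `"offline_gt"` (annotation-derived maps must be
#'   supplied), or `"uniform"` (constant 0.5 ablation).
#' @return a `model_config` list.
#' @export
model_config <- function(num_classes = 3L, base_channels = 8L, input_size = 640L,
                         use_aspc = TRUE, use_cgwa = TRUE, use_dadu = TRUE,
                         window_size = 7L, heads = 2L, dadu_groups = 2L,
                         density_source = c("predicted", "offline_gt", "uniform")) {
  density_source <- match.arg(density_source)
  stopifnot(num_classes >= 1)
  structure(list(num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 input_size = as.integer(input_size),
                 use_aspc = isTRUE(use_aspc), use_cgwa = isTRUE(use_cgwa),
                 use_dadu = isTRUE(use_dadu),
                 window_size = as.integer(window_size), heads = as.integer(heads),
                 dadu_groups = as.integer(dadu_groups),
                 density_source = density_source),
            class = "model_config")
}

detector_strides <- function() c(4L, 8L, 16L)

# stage widths as multiples of the base width
stage_channels <- function(w) list(c1 = w, c2 = 2L * w, c3 = 4L * w,
                                   c4 = 6L * w, c5 = 8L * w)

#' Assemble a detector
#'
#' Builds the parameter set and module graph for the configured toggles.
#' The assembled model lists its modules (`model$modules`), which tests can
#' walk: with all toggles on the graph contains 4 ASPC downsamples, exactly
#' 2 DADU upsamplers (the two top-down PAN stages) and 3 CGWA instances
#' (one per output scale).
#'
#' @param config a [model_config()].
#' @param seed RNG seed for parameter initialisation.
#' @return an object of class `odadet_model`.
#' @export
assemble <- function(config, seed = 0L) {
  ch <- stage_channels(config$base_channels)
  modules <- character(0)
  params <- list()
  with_local_seed(seed, {
    mk_down <- function(cin, cout, tag) {
      if (config$use_aspc) {
        modules <<- c(modules, paste0("aspc:", tag))
        list(kind = "aspc", cfg = aspc_config(cin, cout, channel_reduction = 4L),
             par = aspc_init(aspc_config(cin, cout, channel_reduction = 4L)))
      } else {
        modules <<- c(modules, paste0("convdown:", tag))
        list(kind = "convdown", par = nn_conv_init(cout, cin, 3L))
      }
    }
    mk_up <- function(cin, tag) {
      if (config$use_dadu) {
        cfg <- dadu_config(cin, scale = 2L, groups = config$dadu_groups)
        modules <<- c(modules, paste0("dadu:", tag))
        list(kind = "dadu", cfg = cfg, par = dadu_init(cfg))
      } else {
        modules <<- c(modules, paste0("nearest:", tag))
        list(kind = "nearest")
      }
    }
    mk_cgwa <- function(cch, tag) {
      if (!config$use_cgwa) return(NULL)
      cfg <- cgwa_config(cch, heads = config$heads,
                         window_size = config$window_size,
                         mlp_hidden = 8L)
      modules <<- c(modules, paste0("cgwa:", tag))
      list(cfg = cfg, par = cgwa_init(cfg))
    }

    params$stem <- nn_conv_init(ch$c1, 3L, 3L)
    params$down1 <- mk_down(ch$c1, ch$c2, "backbone1")
    params$down2 <- mk_down(ch$c2, ch$c3, "backbone2")
    params$down3 <- mk_down(ch$c3, ch$c4, "backbone3")
    params$down4 <- mk_down(ch$c4, ch$c5, "backbone4")
    params$stage3 <- nn_conv_init(ch$c3, ch$c3, 3L)
    params$stage4 <- nn_conv_init(ch$c4, ch$c4, 3L)
    params$stage5 <- nn_conv_init(ch$c5, ch$c5, 3L)

    params$up5 <- mk_up(ch$c5, "pan_top")
    params$fuse4 <- nn_conv_init(ch$c4, ch$c5 + ch$c4, 3L)
    params$up4 <- mk_up(ch$c4, "pan_mid")
    params$fuse3 <- nn_conv_init(ch$c3, ch$c4 + ch$c3, 3L)
    params$pan_down3 <- nn_conv_init(ch$c4, ch$c3, 3L)   # /4 -> /8, conv+pool
    params$fuse4b <- nn_conv_init(ch$c4, ch$c4 + ch$c4, 3L)
    params$pan_down4 <- nn_conv_init(ch$c5, ch$c4, 3L)   # /8 -> /16
    params$fuse5b <- nn_conv_init(ch$c5, ch$c5 + ch$c5, 3L)

    params$cgwa3 <- mk_cgwa(ch$c3, "scale4")
    params$cgwa4 <- mk_cgwa(ch$c4, "scale8")
    params$cgwa5 <- mk_cgwa(ch$c5, "scale16")

    no <- 5L + config$num_classes
    params$head3 <- nn_conv_init(no, ch$c3, 1L)
    params$head4 <- nn_conv_init(no, ch$c4, 1L)
    params$head5 <- nn_conv_init(no, ch$c5, 1L)

    # auxiliary density head (from the /4 backbone features)
    if (config$density_source == "predicted") {
      modules <<- c(modules, "density_head")
      params$dens1 <- nn_conv_init(8L, ch$c3, 3L)
      params$dens2 <- nn_conv_init(1L, 8L, 3L)
    }
  })
  structure(list(config = config, params = params, modules = modules),
            class = "odadet_model")
}

#' @export
print.odadet_model <- function(x, ...) {
  cat("<odadet_model>", length(nn_parameters(x$params)), "parameter tensors;",
      "modules:", paste(x$modules, collapse = ", "), "\n")
  invisible(x)
}

apply_down <- function(x, blk) {
  if (blk$kind == "aspc") {
    aspc_forward(x, blk$cfg, blk$par)
  } else {
    tg_avgpool2(tg_relu(nn_conv(x, blk$par)))
  }
}

apply_up <- function(x, blk) {
  if (blk$kind == "dadu") dadu_forward(x, blk$cfg, blk$par)
  else tg_upsample_nearest(x, 2L)
}

silu_conv <- function(x, cv) tg_relu(nn_conv(x, cv))

#' Detector forward pass
#'
#' @param model an assembled detector.
#' @param images array `(B, H, W, 3)` of RGB values in `[0, 1]` (or a `tg`
#'   tensor already in `(B, 3, H, W)` layout).
#' @param conditions list with `occlusion` `(B, 1, H, W)` and (except under
#'   the `"predicted"` density source) `density` `(B, 1, H, W)` at input
#'   resolution; see [prepare_conditions()].
#' @param training logical (enables dropout paths).
#' @return list with `preds` (per scale `(B, 5 + nc, H/s, W/s)`),
#'   `density_pred` (`(B, 1, H/4, W/4)` or NULL), `features` (the three
#'   pre-head `tg` feature grids) and `strides`.
#' @export
detector_forward <- function(model, images, conditions, training = FALSE) {
  cfg <- model$config; p <- model$params
  x <- if (is_tg(images)) images else tg_tensor(to_nchw(images))
  d <- dim_of(tg_value(x))
  H <- d[3]; W <- d[4]

  s1 <- tg_relu(nn_conv(x, p$stem))
  s2 <- apply_down(s1, p$down1)                       # /2
  s3 <- silu_conv(apply_down(s2, p$down2), p$stage3)  # /4
  s4 <- silu_conv(apply_down(s3, p$down3), p$stage4)  # /8
  s5 <- silu_conv(apply_down(s4, p$down4), p$stage5)  # /16

  # density condition at /4
  dens_pred <- NULL
  den4 <- switch(cfg$density_source,
    predicted = {
      dens_pred <- tg_sigmoid(nn_conv(tg_relu(nn_conv(s3, p$dens1)), p$dens2))
      dens_pred
    },
    offline_gt = {
      if (is.null(conditions$density)) stop("offline_gt density source needs conditions$density")
      tg_tensor(pool_condition(conditions$density, dim_of(tg_value(s3))[3],
                               dim_of(tg_value(s3))[4]))
    },
    uniform = tg_tensor(array(0.5, c(d[1], 1, dim_of(tg_value(s3))[3],
                                     dim_of(tg_value(s3))[4])))
  )
  occ4 <- tg_tensor(pool_condition(conditions$occlusion,
                                   dim_of(tg_value(s3))[3], dim_of(tg_value(s3))[4]))

  # PAN top-down with DADU (or nearest) upsampling
  n4 <- silu_conv(tg_concat(list(apply_up(s5, p$up5), s4), 2), p$fuse4)
  n3 <- silu_conv(tg_concat(list(apply_up(n4, p$up4), s3), 2), p$fuse3)
  # bottom-up path
  d3 <- tg_avgpool2(tg_relu(nn_conv(n3, p$pan_down3)))
  o4 <- silu_conv(tg_concat(list(d3, n4), 2), p$fuse4b)
  d4 <- tg_avgpool2(tg_relu(nn_conv(o4, p$pan_down4)))
  o5 <- silu_conv(tg_concat(list(d4, s5), 2), p$fuse5b)
  o3 <- n3

  feats <- list(o3, o4, o5)
  if (cfg$use_cgwa) {
    cg <- list(p$cgwa3, p$cgwa4, p$cgwa5)
    for (k in 1:3) {
      dk <- dim_of(tg_value(feats[[k]]))
      ck <- list(
        occlusion = if (k == 1) occ4 else
          tg_tensor(pool_condition(tg_value(occ4), dk[3], dk[4])),
        density = if (k == 1) den4 else
          tg_tensor(pool_condition(tg_value(den4), dk[3], dk[4])))
      feats[[k]] <- cgwa_forward(feats[[k]], ck, cg[[k]]$cfg, cg[[k]]$par,
                                training = training)
    }
  }

  preds <- list(nn_conv(feats[[1]], p$head3),
                nn_conv(feats[[2]], p$head4),
                nn_conv(feats[[3]], p$head5))
  list(preds = preds, density_pred = dens_pred, features = feats,
       strides = detector_strides())
}

to_nchw <- function(images) {
  d <- dim(images)
  if (length(d) == 3) images <- array(images, c(1, d))
  aperm(images, c(1, 4, 2, 3))
}

#' Build forward-time conditions for a batch
#'
#' Occlusion maps are always computed from the images themselves (no
#' annotations needed at inference).  The density map is taken from the
#' ground-truth boxes for the `"offline_gt"` source; for `"predicted"` and
#' `"uniform"` it is supplied inside the forward pass.
#'
#' @param model assembled detector (for the density source).
#' @param images array `(B, H, W, 3)`.
#' @param boxes_list optional list of YOLO box data frames (one per image).
#' @return conditions list for [detector_forward()].
#' @export
prepare_conditions <- function(model, images, boxes_list = NULL) {
  d <- dim(images)
  if (length(d) == 3) { images <- array(images, c(1, d)); d <- dim(images) }
  B <- d[1]; H <- d[2]; W <- d[3]
  occ <- array(0, c(B, 1, H, W))
  for (b in seq_len(B)) occ[b, , , ] <- generate_occlusion_map(images[b, , , ])
  out <- list(occlusion = occ)
  if (model$config$density_source == "offline_gt") {
    den <- array(0, c(B, 1, H, W))
    for (b in seq_len(B)) {
      den[b, , , ] <- generate_density_map(boxes_list[[b]], H, W)
    }
    out$density <- den
  }
  out
}

# ---- training -------------------------------------------------------------

# per-scale target tensors for a batch of YOLO-normalized boxes
build_targets <- function(boxes_list, H, W, num_classes) {
  strides <- detector_strides()
  B <- length(boxes_list)
  lapply(strides, function(st) {
    gh <- H %/% st; gw <- W %/% st
    obj <- array(0, c(B, 1, gh, gw))
    cls <- array(0, c(B, num_classes, gh, gw))
    box <- array(0, c(B, 4, gh, gw))     # tx, ty, log w, log h targets
    msk <- array(0, c(B, 1, gh, gw))
    for (b in seq_len(B)) {
      bx <- boxes_list[[b]]
      if (is.null(bx) || nrow(bx) == 0) next
      for (i in seq_len(nrow(bx))) {
        cxp <- bx$cx[i] * W / st; cyp <- bx$cy[i] * H / st
        gx <- min(floor(cxp), gw - 1); gy <- min(floor(cyp), gh - 1)
        obj[b, 1, gy + 1, gx + 1] <- 1
        msk[b, 1, gy + 1, gx + 1] <- 1
        cls[b, bx$class[i] + 1, gy + 1, gx + 1] <- 1
        box[b, 1, gy + 1, gx + 1] <- cxp - gx
        box[b, 2, gy + 1, gx + 1] <- cyp - gy
        box[b, 3, gy + 1, gx + 1] <- log(max(bx$w[i] * W / st, 1e-3))
        box[b, 4, gy + 1, gx + 1] <- log(max(bx$h[i] * H / st, 1e-3))
      }
    }
    list(obj = obj, cls = cls, box = box, msk = msk)
  })
}

detector_loss <- function(fwd, targets, density_gt = NULL, num_classes = 3L) {
  total <- NULL
  add <- function(a, b) if (is.null(a)) b else tg_add(a, b)
  for (k in seq_along(fwd$preds)) {
    pr <- fwd$preds[[k]]; tgt <- targets[[k]]
    obj_logit <- tg_slice(pr, 2, 5L, 5L)
    l_obj <- tg_add(tg_bce_logits(obj_logit, tgt$obj, tgt$msk),
                    tg_bce_logits(obj_logit, tgt$obj, 1 - tgt$msk))
    cls_logit <- tg_slice(pr, 2, 6L, 5L + num_classes)
    wcls <- bc_to(tgt$msk, dim_of(tg_value(cls_logit)))
    l_cls <- tg_bce_logits(cls_logit, tgt$cls, wcls)
    xy <- tg_sigmoid(tg_slice(pr, 2, 1L, 2L))
    wh <- tg_slice(pr, 2, 3L, 4L)
    wbox <- bc_to(tgt$msk, dim_of(tg_value(xy)))
    l_box <- tg_add(tg_l1(xy, tgt$box[, 1:2, , , drop = FALSE], wbox),
                    tg_l1(wh, tgt$box[, 3:4, , , drop = FALSE], wbox))
    total <- add(total, tg_add(l_obj, tg_add(l_cls, tg_scale(l_box, 2))))
  }
  if (!is.null(fwd$density_pred) && !is.null(density_gt)) {
    dd <- dim_of(tg_value(fwd$density_pred))
    dgt <- pool_condition(density_gt, dd[3], dd[4])
    total <- add(total, tg_scale(tg_mse(fwd$density_pred, dgt), 0.5))
  }
  total
}

#' Train a detector on a small scene set
#'
#' Full-batch Adam on conventional one-stage losses (balanced binary
#' cross-entropy objectness, per-class BCE, L1 box regression in cell
#' units, plus an MSE auxiliary loss for the predicted density head).
#' Deterministic for a fixed seed; intended for tiny CPU-scale fixtures.
#'
#' @param model assembled detector (updated in place and returned).
#' @param scenes list of rendered scenes (see [render_scene()]) or a
#'   dataset directory created by [write_dataset()] (its `train` split).
#' @param steps number of optimiser steps.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return list with `model`, `loss_trace` and the final `loss`.
#' @export
train_tiny <- function(model, scenes, steps = 200L, lr = 5e-3, seed = 1L) {
  if (is.character(scenes)) scenes <- load_dataset_scenes(scenes, "train")
  if (length(scenes) == 0) stop("empty dataset")
  imgs <- lapply(scenes, function(s) s$image)
  d1 <- dim(imgs[[1]])
  images <- array(0, c(length(imgs), d1[1], d1[2], 3))
  for (b in seq_along(imgs)) images[b, , , ] <- imgs[[b]]
  boxes_list <- lapply(scenes, function(s) s$truth$boxes)

  conds <- prepare_conditions(model, images, boxes_list)
  H <- d1[1]; W <- d1[2]
  targets <- build_targets(boxes_list, H, W, model$config$num_classes)
  density_gt <- array(0, c(length(imgs), 1, H, W))
  for (b in seq_along(imgs)) {
    density_gt[b, , , ] <- generate_density_map(boxes_list[[b]], H, W)
  }
  xin <- tg_tensor(to_nchw(images))

  pars <- nn_parameters(model$params)
  opt <- nn_adam(pars, lr = lr)
  trace <- numeric(steps)
  with_local_seed(seed, {
    for (it in seq_len(steps)) {
      fwd <- detector_forward(model, xin, conds, training = TRUE)
      loss <- detector_loss(fwd, targets, density_gt, model$config$num_classes)
      trace[it] <- as.numeric(tg_value(loss))
      tg_backward(loss)
      nn_adam_step(opt)
    }
  })
  list(model = model, loss_trace = trace, loss = trace[length(trace)])
}

load_dataset_scenes <- function(dir, split = "train") {
  lbls <- list.files(file.path(dir, "labels", split), full.names = TRUE)
  lapply(lbls, function(lp) {
    stem <- sub("\\.txt$", "", basename(lp))
    img <- png::readPNG(file.path(dir, "images", split, paste0(stem, ".png")))
    if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
    list(image = img, truth = list(boxes = read_yolo_labels(lp)))
  })
}

#' Save and restore detector checkpoints
#'
#' A checkpoint is a single self-describing RDS file holding the config and
#' all parameter arrays; reloading reproduces predictions bit-exactly.
#'
#' @param model assembled detector.
#' @param path file path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, state = nn_state_dict(model$params),
               modules = model$modules), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- assemble(ck$config)
  nn_load_state(model$params, ck$state)
  model
}

# ---- decoding -------------------------------------------------------------

#' Decode raw predictions into scored boxes
#'
#' Applies sigmoids, keeps cells above `conf`, converts to absolute
#' `xyxy` pixel boxes and runs per-class greedy NMS (IoU 0.5; ties broken
#' by box index).
#'
#' @param fwd output of [detector_forward()].
#' @param H,W input image size in pixels.
#' @param conf confidence threshold on `objectness * class`.
#' @param iou_nms NMS IoU threshold.
#' @return list of per-image data frames `(x0, y0, x1, y1, score, class)`.
#' @export
decode_predictions <- function(fwd, H, W, conf = 0.1, iou_nms = 0.5) {
  B <- dim_of(tg_value(fwd$preds[[1]]))[1]
  out <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- list()
    for (k in seq_along(fwd$preds)) {
      pv <- tg_value(fwd$preds[[k]])
      st <- fwd$strides[k]
      gh <- dim(pv)[3]; gw <- dim(pv)[4]
      obj <- stats::plogis(pv[b, 5, , ])
      nc <- dim(pv)[2] - 5L
      for (gy in seq_len(gh)) for (gx in seq_len(gw)) {
        clp <- stats::plogis(pv[b, 6:(5 + nc), gy, gx])
        sc <- obj[gy, gx] * max(clp)
        if (sc < conf) next
        cxp <- (gx - 1 + stats::plogis(pv[b, 1, gy, gx])) * st
        cyp <- (gy - 1 + stats::plogis(pv[b, 2, gy, gx])) * st
        wp <- min(exp(pv[b, 3, gy, gx]), gw * 2) * st
        hp <- min(exp(pv[b, 4, gy, gx]), gh * 2) * st
        rows[[length(rows) + 1]] <- data.frame(
          x0 = cxp - wp / 2, y0 = cyp - hp / 2,
          x1 = cxp + wp / 2, y1 = cyp + hp / 2,
          score = sc, class = which.max(clp) - 1L)
      }
    }
    det <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                 y1 = numeric(0), score = numeric(0), class = integer(0))
    out[[b]] <- nms(det, iou_nms)
  }
  out
}

box_iou <- function(a, b) {
  # a: vector (x0,y0,x1,y1); b: matrix with columns x0,y0,x1,y1
  ix0 <- pmax(a[1], b[, 1]); iy0 <- pmax(a[2], b[, 2])
  ix1 <- pmin(a[3], b[, 3]); iy1 <- pmin(a[4], b[, 4])
  iw <- pmax(ix1 - ix0, 0); ih <- pmax(iy1 - iy0, 0)
  inter <- iw * ih
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  bb <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / pmax(aa + bb - inter, 1e-12)
}

nms <- function(det, iou_thr = 0.5) {
  if (nrow(det) <= 1) return(det)
  keep <- logical(nrow(det))
  for (cl in unique(det$class)) {
    idx <- which(det$class == cl)
    ord <- idx[order(-det$score[idx], idx)]
    taken <- integer(0)
    for (i in ord) {
      if (length(taken) > 0) {
        ious <- box_iou(as.numeric(det[i, 1:4]), as.matrix(det[taken, 1:4]))
        if (any(ious > iou_thr)) next
      }
      taken <- c(taken, i)
      keep[i] <- TRUE
    }
  }
  out <- det[keep, , drop = FALSE]
  out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
}

#' Convert YOLO-normalized boxes to absolute xyxy pixels
#'
#' @param boxes YOLO data frame (`class`, `cx`, `cy`, `w`, `h`).
#' @param H,W image size in pixels.
#' @return data frame `(x0, y0, x1, y1, class)`.
#' @export
yolo_to_xyxy <- function(boxes, H, W) {
  data.frame(x0 = (boxes$cx - boxes$w / 2) * W, y0 = (boxes$cy - boxes$h / 2) * H,
             x1 = (boxes$cx + boxes$w / 2) * W, y1 = (boxes$cy + boxes$h / 2) * H,
             class = boxes$class)
}
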