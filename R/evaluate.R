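# Detection evaluation: greedy IoU matching, all-point interpolated AP,
# precision/recall/F1, confusion matrix with a background row/column, and
# model accounting (parameters, multiply-accumulates, CAM heatmaps).

#' Evaluate detections against ground truth
#'
#' Per class, detections are sorted by descending score (ties broken by
#' image order then box index) and greedily matched to unmatched truth
#' boxes at IoU >= `iou_threshold` (highest IoU wins, ties to the lower
#' index); one match per truth box.  AP uses all-point interpolation (the
#' precision envelope), and mAP is the unweighted mean over classes present
#' in the truth.  Precision/recall/F1 are computed over detections with
#' score >= `score_threshold`.  The confusion matrix matches
#' class-agnostically and has a background row (missed truths) and column
#' (false alarms); rows are ground-truth classes, columns predictions.
#'
#' @param detections list of per-image data frames
#'   `(x0, y0, x1, y1, score, class)` in absolute pixels.
#' @param truths list of per-image data frames `(x0, y0, x1, y1, class)`.
#' @param iou_threshold IoU required for a match.
#' @param score_threshold operating point for precision/recall/F1 and the
#'   confusion matrix.
#' @param num_classes number of classes.
#' @return list with `map50`, `per_class_ap`, `precision`, `recall`, `f1`,
#'   `pr_curves` (per class recall/precision vectors) and `confusion`.
#' @export
evaluate_detections <- function(detections, truths, iou_threshold = 0.5,
                                score_threshold = 0.25, num_classes = 3L) {
  stopifnot(length(detections) == length(truths))
  classes <- 0:(num_classes - 1L)
  per_class_ap <- stats::setNames(rep(NA_real_, num_classes), classes)
  pr_curves <- list()

  for (cl in classes) {
    n_gt <- sum(vapply(truths, function(t) sum(t$class == cl), numeric(1)))
    det_rows <- list()
    for (im in seq_along(detections)) {
      d <- detections[[im]]
      d <- d[d$class == cl, , drop = FALSE]
      if (nrow(d) > 0) {
        d$image <- im; d$box_idx <- seq_len(nrow(d))
        det_rows[[length(det_rows) + 1]] <- d
      }
    }
    if (n_gt == 0) next
    if (length(det_rows) == 0) {
      per_class_ap[as.character(cl)] <- 0
      pr_curves[[as.character(cl)]] <- list(recall = 0, precision = 0)
      next
    }
    alld <- do.call(rbind, det_rows)
    alld <- alld[order(-alld$score, alld$image, alld$box_idx), , drop = FALSE]
    matched <- lapply(truths, function(t) rep(FALSE, nrow(t)))
    tp <- numeric(nrow(alld))
    for (r in seq_len(nrow(alld))) {
      im <- alld$image[r]
      gt <- truths[[im]]
      cand <- which(gt$class == cl & !matched[[im]])
      if (length(cand) > 0) {
        ious <- box_iou(as.numeric(alld[r, c("x0", "y0", "x1", "y1")]),
                        as.matrix(gt[cand, c("x0", "y0", "x1", "y1")]))
        best <- cand[which.max(ious)]          # ties: which.max takes lowest
        if (max(ious) >= iou_threshold) {
          matched[[im]][best] <- TRUE
          tp[r] <- 1
        }
      }
    }
    cum_tp <- cumsum(tp); cum_fp <- cumsum(1 - tp)
    recall <- cum_tp / n_gt
    precision <- cum_tp / pmax(cum_tp + cum_fp, 1e-12)
    per_class_ap[as.character(cl)] <- ap_interp(recall, precision)
    pr_curves[[as.character(cl)]] <- list(recall = recall, precision = precision)
  }

  present <- !is.na(per_class_ap)
  map50 <- if (any(present)) mean(per_class_ap[present]) else NA_real_

  op <- operating_point(detections, truths, iou_threshold, score_threshold,
                        num_classes)
  c(list(map50 = map50, per_class_ap = per_class_ap, pr_curves = pr_curves), op)
}

# all-point interpolated AP: area under the precision envelope
ap_interp <- function(recall, precision) {
  r <- c(0, recall)
  p <- c(0, precision)
  # envelope: running max of precision from the right
  env <- rev(cummax(rev(p)))
  sum(diff(r) * env[-1])
}

operating_point <- function(detections, truths, iou_threshold, score_threshold,
                            num_classes) {
  tp <- fp <- 0
  n_gt <- sum(vapply(truths, nrow, numeric(1)))
  confusion <- matrix(0L, num_classes + 1L, num_classes + 1L,
                      dimnames = list(truth = c(0:(num_classes - 1L), "background"),
                                      prediction = c(0:(num_classes - 1L), "background")))
  for (im in seq_along(detections)) {
    d <- detections[[im]]
    d <- d[d$score >= score_threshold, , drop = FALSE]
    gt <- truths[[im]]
    taken <- rep(FALSE, nrow(gt))
    if (nrow(d) > 0) {
      d <- d[order(-d$score, seq_len(nrow(d))), , drop = FALSE]
      for (r in seq_len(nrow(d))) {
        cand <- which(!taken)
        hit <- FALSE
        if (length(cand) > 0) {
          ious <- box_iou(as.numeric(d[r, c("x0", "y0", "x1", "y1")]),
                          as.matrix(gt[cand, c("x0", "y0", "x1", "y1")]))
          if (max(ious) >= iou_threshold) {
            g <- cand[which.max(ious)]
            taken[g] <- TRUE
            confusion[gt$class[g] + 1L, d$class[r] + 1L] <-
              confusion[gt$class[g] + 1L, d$class[r] + 1L] + 1L
            hit <- TRUE
            if (gt$class[g] == d$class[r]) tp <- tp + 1 else fp <- fp + 1
          }
        }
        if (!hit) {
          confusion[num_classes + 1L, d$class[r] + 1L] <-
            confusion[num_classes + 1L, d$class[r] + 1L] + 1L
          fp <- fp + 1
        }
      }
    }
    for (g in which(!taken)) {
      confusion[gt$class[g] + 1L, num_classes + 1L] <-
        confusion[gt$class[g] + 1L, num_classes + 1L] + 1L
    }
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (n_gt > 0) tp / n_gt else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, confusion = confusion)
}

#' Count parameters and multiply-accumulates
#'
#' Parameter count is the exact total over all trainable tensors; the MAC
#' count is measured by running one forward pass (batch 1, uniform
#' conditions) with the analytic per-op counters enabled.  Deterministic
#' and independent of batch size.
#'
#' @param model assembled detector.
#' @param input_size square input edge in pixels.
#' @return list with `params` and `macs` (and `gflops = 2 * macs / 1e9`,
#'   the convention that counts one multiply-accumulate as two floating
#'   point operations).
#' @export
count_params_flops <- function(model, input_size = NULL) {
  if (is.null(input_size)) input_size <- model$config$input_size
  n_par <- sum(vapply(nn_parameters(model$params),
                      function(p) length(p$value), numeric(1)))
  img <- array(0.5, c(1, input_size, input_size, 3))
  conds <- list(occlusion = array(0, c(1, 1, input_size, input_size)),
                density = array(0, c(1, 1, input_size, input_size)))
  res <- nn_count_macs(function() detector_forward(model, img, conds))
  list(params = n_par, macs = res$macs, gflops = 2 * res$macs / 1e9)
}

#' Gradient-weighted class-activation heatmap
#'
#' Backpropagates the summed objectness score of one output scale to that
#' scale's pre-head feature grid, weights each channel by its mean
#' gradient, rectifies the weighted sum and min-max normalises to `[0, 1]`
#' (an all-zero map becomes uniform 0.5), then resizes to the image size.
#'
#' @param model assembled (typically trained) detector.
#' @param image array `(H, W, 3)` in `[0, 1]`.
#' @param target_scale 1, 2 or 3 (strides 4, 8, 16).
#' @return matrix `(H, W)` in `[0, 1]`.
#' @export
cam_heatmap <- function(model, image, target_scale = 1L) {
  d <- dim(image)
  conds <- prepare_conditions(model, image,
                              boxes_list = list(data.frame(class = integer(0),
                                                           cx = numeric(0), cy = numeric(0),
                                                           w = numeric(0), h = numeric(0))))
  fwd <- detector_forward(model, array(image, c(1, d)), conds)
  feat <- fwd$features[[target_scale]]
  score <- tg_sum(tg_sigmoid(tg_slice(fwd$preds[[target_scale]], 2, 5L, 5L)))
  tg_backward(score)
  g <- feat$grad
  fv <- tg_value(feat)
  if (is.null(g)) g <- array(0, dim_of(fv))
  wts <- apply(g[1, , , , drop = FALSE], 2, mean)
  cam <- matrix(0, dim_of(fv)[3], dim_of(fv)[4])
  for (c in seq_along(wts)) cam <- cam + wts[c] * fv[1, c, , ]
  cam <- pmax(cam, 0)
  rng <- max(cam) - min(cam)
  cam <- if (rng < 1e-12) matrix(0.5, nrow(cam), ncol(cam)) else
    (cam - min(cam)) / rng
  upsample_matrix(cam, d[1])
}
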