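# Colorimetric ripeness classification.
#
# Coffee-cherry maturity is determined from exocarp color with fixed
# HSV/RGB thresholds: unripe = dominant green, semi-ripe = transitional
# yellow-orange, ripe = deep red.  Classification is a pure function of the
# pixel; rules are evaluated in the precedence order ripe -> semi-ripe ->
# unripe (ripe has the strictest compound condition), and hue intervals are
# half-open on the upper bound except the wrap-around red interval.

#' Default maturity color rules
#'
#' Threshold set, overridable per field:
#' \itemize{
#'   \item ripe: hue in \[0, 20) or \[340, 360) degrees, saturation > 0.6,
#'     `R > G + 15` and `R > B + 15`;
#'   \item semi-ripe: hue in \[20, 60) degrees and `R` approximately equal
#'     to `G` (`|R - G| <= rg_tol`) or slightly greater
#'     (`0 < R - G <= rg_margin`);
#'   \item unripe: hue in \[60, 120) degrees, saturation in \[0.35, 0.85\]
#'     (inclusive), `G > R` and `G > B`.
#' }
#'
#' @param rg_tol tolerance for "R approximately G" (8-bit units).
#' @param rg_margin margin for "R slightly greater than G".
#' @return a `color_rules` list.
#' @export
color_rules <- function(rg_tol = 20, rg_margin = 30) {
  structure(list(
    ripe = list(hue = list(c(0, 20), c(340, 360)), sat_min = 0.6,
                r_over_g = 15, r_over_b = 15),
    semi_ripe = list(hue = list(c(20, 60)), rg_tol = rg_tol, rg_margin = rg_margin),
    unripe = list(hue = list(c(60, 120)), sat = c(0.35, 0.85))
  ), class = "color_rules")
}

#' Classify pixels by maturity color rules
#'
#' `classify_rgb_pixel` labels 8-bit RGB values as `"ripe"`, `"semi_ripe"`,
#' `"unripe"` or `"unclassified"`.  Hue (degrees in \[0, 360)) and saturation
#' (`delta / max`) come from the standard hexagonal HSV conversion
#' ([grDevices::rgb2hsv()]).  Vectorized over pixels.
#'
#' @param r,g,b numeric vectors of 8-bit channel values (0-255).
#' @param rules a [color_rules()] object.
#' @return character vector of labels.
#' @export
classify_rgb_pixel <- function(r, g, b, rules = color_rules()) {
  stopifnot(length(r) == length(g), length(g) == length(b))
  if (length(r) == 0) return(character(0))
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  in_hue <- function(iv_list) {
    hit <- rep(FALSE, length(hue))
    for (iv in iv_list) hit <- hit | (hue >= iv[1] & hue < iv[2])
    hit
  }
  rp <- rules$ripe
  is_ripe <- in_hue(rp$hue) & sat > rp$sat_min &
    r > g + rp$r_over_g & r > b + rp$r_over_b
  sr <- rules$semi_ripe
  is_semi <- in_hue(sr$hue) &
    (abs(r - g) <= sr$rg_tol | (r - g > 0 & r - g <= sr$rg_margin))
  ur <- rules$unripe
  is_unripe <- in_hue(ur$hue) & sat >= ur$sat[1] & sat <= ur$sat[2] &
    g > r & g > b
  out <- rep("unclassified", length(r))
  out[is_unripe] <- "unripe"
  out[is_semi] <- "semi_ripe"
  out[is_ripe] <- "ripe"       # precedence: ripe > semi_ripe > unripe
  out
}

#' Maturity class labels in canonical order
#' @return character vector `c("unripe", "semi_ripe", "ripe")`.
#' @export
maturity_classes <- function() c("unripe", "semi_ripe", "ripe")

#' Classify an annotated box by majority pixel vote
#'
#' Denormalizes the box, classifies every pixel inside it and returns the
#' winning class together with its share of the classified pixels.  A box
#' containing no classifiable pixel returns `"unclassified"` with fraction 0.
#'
#' @param image array `(H, W, 3)` RGB in `[0, 1]`.
#' @param box one-row data frame (or list) with `cx`, `cy`, `w`, `h` in
#'   normalized units.
#' @param rules a [color_rules()] object.
#' @return list with `class` and `fraction`.
#' @export
classify_box <- function(image, box, rules = color_rules()) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  x0 <- max(floor((box$cx - box$w / 2) * W), 0)
  x1 <- min(ceiling((box$cx + box$w / 2) * W) - 1, W - 1)
  y0 <- max(floor((box$cy - box$h / 2) * H), 0)
  y1 <- min(ceiling((box$cy + box$h / 2) * H) - 1, H - 1)
  if (box$w <= 0 || box$h <= 0 || x1 < x0 || y1 < y0) {
    stop("degenerate (zero-area) box")
  }
  crop <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
  labels <- classify_rgb_pixel(round(as.numeric(crop[, , 1]) * 255),
                               round(as.numeric(crop[, , 2]) * 255),
                               round(as.numeric(crop[, , 3]) * 255), rules)
  labels <- labels[labels != "unclassified"]
  if (length(labels) == 0) return(list(class = "unclassified", fraction = 0))
  tab <- table(factor(labels, levels = maturity_classes()))
  win <- names(tab)[which.max(tab)]
  list(class = win, fraction = as.numeric(max(tab)) / length(labels))
}
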