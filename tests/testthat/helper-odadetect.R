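# Shared helpers: finite-difference gradient checks and small fixtures.

# Central-difference gradient of scalar-valued f at array x.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim_of_(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

dim_of_ <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

rand_arr <- function(...) array(stats::rnorm(prod(c(...))), c(...))

# A deterministic test image: textured disk on a gradient background.
fixture_image <- function(h = 48, w = 48) {
  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- outer(seq_len(h), seq_len(w), function(i, j) {
    0.3 + 0.1 * c + 0.05 * sin(i / 3) * cos(j / 4)
  })
  pmin(pmax(img, 0), 1)
}
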