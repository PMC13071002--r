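# Layer constructors and optimisation utilities on top of the autodiff tape.

#' Create trainable parameters
#'
#' `nn_param` wraps an array as a trainable tensor; `nn_conv_init` and
#' `nn_linear_init` draw Kaiming-style uniform weights (bound
#' `sqrt(6 / fan_in)`) with zero biases, using the current RNG state.
#'
#' @param value numeric array of initial values.
#' @return `nn_param`: a `tg` parameter tensor. The `*_init` helpers return a
#'   list with elements `w` and `b` (both `tg` parameters).
#' @export
nn_param <- function(value) tg_tensor(value, requires_grad = TRUE)

#' @rdname nn_param
#' @param out_ch,in_ch integer channel counts.
#' @param k odd kernel size.
#' @param zero logical; initialise weights (not just biases) to zero.
#' @export
nn_conv_init <- function(out_ch, in_ch, k, zero = FALSE) {
  fan_in <- in_ch * k * k
  bound <- sqrt(6 / fan_in)
  w <- if (zero) array(0, c(out_ch, in_ch, k, k)) else
    array(stats::runif(out_ch * in_ch * k * k, -bound, bound), c(out_ch, in_ch, k, k))
  list(w = nn_param(w), b = nn_param(numeric(out_ch)))
}

#' @rdname nn_param
#' @param n_out,n_in integer feature counts.
#' @export
nn_linear_init <- function(n_out, n_in, zero = FALSE) {
  bound <- sqrt(6 / n_in)
  w <- if (zero) matrix(0, n_in, n_out) else
    matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out)
  list(w = nn_param(w), b = nn_param(numeric(n_out)))
}

# y = x W + b for x (n, n_in), W (n_in, n_out)
nn_linear <- function(x, lin) {
  n <- dim_of(tg_value(x))[1]
  tg_add(tg_matmul(x, lin$w), tg_reshape(lin$b, c(1, length(lin$b$value))))
}

# same-padded conv y = conv(x, W) + b
nn_conv <- function(x, cv, pad = NULL) {
  k <- dim(cv$w$value)[3]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  tg_conv2d(x, cv$w, cv$b, pad = pad)
}

#' Collect trainable parameters from a nested structure
#'
#' Recursively extracts every `tg` node with `requires_grad = TRUE` from a
#' nested list of layers.
#'
#' @param x nested list containing `tg` parameter tensors.
#' @return flat named list of `tg` parameters.
#' @export
nn_parameters <- function(x) {
  out <- list()
  walk <- function(obj, prefix) {
    if (is_tg(obj)) {
      if (obj$requires_grad) out[[prefix]] <<- obj
    } else if (is.list(obj)) {
      nms <- names(obj)
      for (i in seq_along(obj)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(obj[[i]], paste0(prefix, ".", nm))
      }
    }
  }
  walk(x, "p")
  out
}

#' Adam optimiser
#'
#' `nn_adam` creates optimiser state for a flat parameter list;
#' `nn_adam_step` applies one update from the gradients currently stored in
#' the parameters and then zeroes them.
#'
#' @param params flat list of `tg` parameters (see [nn_parameters()]).
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return an optimiser state object.
#' @export
nn_adam <- function(params, lr = 5e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim_of(p$value)))
  st$v <- lapply(params, function(p) array(0, dim_of(p$value)))
  class(st) <- "nn_adam"
  st
}

#' @rdname nn_adam
#' @param st optimiser state from `nn_adam`.
#' @export
nn_adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    p$value <- p$value - st$lr * mhat / (sqrt(vhat) + st$eps)
    p$grad <- NULL
  }
  invisible(st)
}

#' Zero stored gradients
#' @param params flat list of `tg` parameters.
#' @export
nn_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

#' Count multiply-accumulate operations of a forward pass
#'
#' Runs `fn()` with the global MAC counter enabled and returns the number of
#' multiply-accumulate operations executed by convolution and matrix-product
#' ops during the call.
#'
#' @param fn zero-argument function performing a forward pass.
#' @return list with `result` (the value of `fn()`) and `macs`.
#' @export
nn_count_macs <- function(fn) {
  .od_env$flops_active <- TRUE
  .od_env$macs <- 0
  on.exit(.od_env$flops_active <- FALSE)
  res <- fn()
  list(result = res, macs = .od_env$macs)
}

# Serialise a nested parameter structure to plain arrays (for checkpoints).
nn_state_dict <- function(x) {
  if (is_tg(x)) return(x$value)
  if (is.list(x)) return(lapply(x, nn_state_dict))
  x
}

# Load plain arrays back into an existing structure of tg parameters.
nn_load_state <- function(x, state) {
  if (is_tg(x)) {
    stopifnot(all(dim_of(x$value) == dim_of(state)))
    x$value <- array(as.numeric(state), dim_of(x$value))
    return(invisible(x))
  }
  if (is.list(x)) {
    for (i in seq_along(x)) nn_load_state(x[[i]], state[[i]])
  }
  invisible(x)
}
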