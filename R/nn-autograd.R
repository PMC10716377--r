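# Minimal reverse-mode automatic differentiation for the F-VCD networks.
#
# A tensor is an environment holding a numeric array `v`, an accumulated
# gradient `g`, the list of parent tensors and a backward closure mapping the
# output gradient to per-parent gradients. Graphs are built eagerly by the
# op_* functions in nn-layers.R; `nn_backward()` runs reverse accumulation
# in topological order. Deliberately small: only what the denoiser and the
# view-to-depth reconstructor need, all in base R with BLAS matmuls.

.nn_ids <- new.env(parent = emptyenv())
.nn_ids$n <- 0

nn_tensor <- function(value, parents = list(), backward = NULL,
                      param = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$parents <- parents
  e$bw <- backward
  e$param <- param
  e$name <- name
  .nn_ids$n <- .nn_ids$n + 1
  e$id <- as.character(.nn_ids$n)
  class(e) <- "nn_tensor"
  e
}

#' Create a trainable parameter tensor
#' @param value initial numeric array.
#' @param name optional label.
#' @return an `nn_tensor` with `param = TRUE`.
#' @keywords internal
nn_param <- function(value, name = NULL) nn_tensor(value, param = TRUE, name = name)

# topological order of the graph rooted at `node` (parents before children)
nn_topo <- function(node) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  visit <- function(n) {
    id <- n$id
    if (!is.null(seen[[id]])) return(invisible(NULL))
    seen[[id]] <- TRUE
    for (p in n$parents) visit(p)
    order[[length(order) + 1]] <<- n
  }
  visit(node)
  order
}

#' Reverse-mode gradient accumulation from a scalar loss node
#' @param root scalar `nn_tensor`.
#' @keywords internal
nn_backward <- function(root) {
  stopifnot(length(root$v) == 1)
  order <- nn_topo(root)
  for (n in order) n$g <- NULL
  root$g <- 1
  for (i in rev(seq_along(order))) {
    n <- order[[i]]
    if (is.null(n$bw) || is.null(n$g)) next
    grads <- n$bw(n$g)
    for (j in seq_along(n$parents)) {
      gj <- grads[[j]]
      if (is.null(gj)) next
      p <- n$parents[[j]]
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
  }
  invisible(root)
}

# ---- Adam optimiser -------------------------------------------------------

adam_state <- function(params) {
  # zero moments with exactly the parameter's structure (plain vectors stay
  # plain: a 1-D array does not add to a column matrix in R)
  lapply(params, function(p) list(m = p$v * 0, v = p$v * 0, t = 0))
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (is.null(p$g)) next
    s <- state[[k]]
    s$t <- s$t + 1
    g <- p$g
    if (is.null(dim(s$m))) g <- as.numeric(g)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^s$t)
    vhat <- s$v / (1 - beta2^s$t)
    p$v <- p$v - lr * mhat / (sqrt(vhat) + eps)
    state[[k]] <- s
  }
  state
}
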