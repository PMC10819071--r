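# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The training stack (transformer, message passing, cross-attention, GRU,
# Set2Set, Adam) needs gradients for every trainable tensor; no autodiff
# framework is available to R in this environment, so a small tape engine is
# implemented here.  Values are plain numeric matrices wrapped in
# environments; operators record a backward closure and parent links, and
# `ag_backward()` replays the tape in reverse creation order (creation order
# is a valid topological order because parents always exist before children).
#
# Every operator is exercised by finite-difference gradient checks in the
# test suite.

.ag_state <- new.env(parent = emptyenv())
.ag_state$id <- 0

.ag_new <- function(val, parents = list(), bfn = NULL, req = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$bfn <- bfn
  e$req <- req
  .ag_state$id <- .ag_state$id + 1
  e$id <- .ag_state$id
  class(e) <- "ag"
  e
}

#' Autodiff tensors
#'
#' `ag(x)` wraps a numeric matrix (or vector, coerced to a column matrix) as
#' a constant autodiff node; `ag_param(x)` wraps it as a trainable parameter
#' that accumulates gradients.  `ag_value()` and `ag_grad()` extract the
#' forward value and the accumulated gradient.
#'
#' @param x Numeric matrix or vector.
#' @return An object of class `ag`.
#' @export
ag <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  .ag_new(x)
}

#' @rdname ag
#' @export
ag_param <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  .ag_new(x, req = TRUE)
}

#' @rdname ag
#' @param node An `ag` node.
#' @export
ag_value <- function(node) node$val

#' @rdname ag
#' @export
ag_grad <- function(node) node$grad

is_ag <- function(x) inherits(x, "ag")

.as_ag <- function(x) if (is_ag(x)) x else ag(x)

.acc <- function(node, g) {
  if (!node$req) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

.op <- function(val, parents, bfn) {
  req <- any(vapply(parents, function(p) p$req, logical(1)))
  .ag_new(val, parents = parents, bfn = if (req) bfn else NULL, req = req)
}

#' Run backpropagation from a scalar node
#'
#' Accumulates gradients into every ancestor created with `ag_param()`.
#' Gradients add up across calls; reset them with `ag_zero_grad()`.
#'
#' @param root An `ag` node holding a 1x1 value.
#' @export
ag_backward <- function(root) {
  stopifnot(is_ag(root), length(root$val) == 1L)
  # collect ancestors that require grad
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- sprintf("n%.0f", nd$id)
    if (!is.null(seen[[key]]) || !nd$req) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  root$grad <- matrix(1, 1, 1)
  for (k in ord) {
    nd <- nodes[[k]]
    if (!is.null(nd$bfn) && !is.null(nd$grad)) nd$bfn(nd$grad)
  }
  invisible(NULL)
}

#' @rdname ag_backward
#' @param params List of `ag` parameter nodes.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- arithmetic -----------------------------------------------------------

# broadcast-aware gradient reduction: g has the output shape, target the
# parent shape (same, 1x1 scalar, 1xM row, or Nx1 column)
.reduce_grad <- function(g, dim_t) {
  if (identical(dim(g), dim_t)) return(g)
  if (all(dim_t == c(1L, 1L))) return(matrix(sum(g), 1, 1))
  if (dim_t[1] == 1L) return(matrix(colSums(g), 1))
  if (dim_t[2] == 1L) return(matrix(rowSums(g), ncol = 1))
  stop("cannot reduce gradient from ", paste(dim(g), collapse = "x"),
       " to ", paste(dim_t, collapse = "x"))
}

.bcast <- function(v, d) {
  if (identical(dim(v), d)) return(v)
  if (all(dim(v) == c(1L, 1L))) return(matrix(v[1], d[1], d[2]))
  if (dim(v)[1] == 1L && dim(v)[2] == d[2])
    return(matrix(v, d[1], d[2], byrow = TRUE))
  if (dim(v)[2] == 1L && dim(v)[1] == d[1]) return(matrix(v, d[1], d[2]))
  stop("incompatible broadcast: ", paste(dim(v), collapse = "x"),
       " vs ", paste(d, collapse = "x"))
}

.bshape <- function(a, b) {
  if (prod(dim(a)) >= prod(dim(b))) dim(a) else dim(b)
}

#' Matrix product of autodiff nodes
#' @param a,b `ag` nodes or numeric matrices.
#' @return An `ag` node.
#' @export
ag_mm <- function(a, b) {
  a <- .as_ag(a); b <- .as_ag(b)
  .op(a$val %*% b$val, list(a, b), function(g) {
    .acc(a, g %*% t(b$val))
    .acc(b, t(a$val) %*% g)
  })
}

#' Elementwise arithmetic on autodiff nodes
#'
#' `ag_add`, `ag_sub`, `ag_mul`, `ag_div` broadcast a scalar, a 1-row or a
#' 1-column operand against the other operand's shape.
#'
#' @param a,b `ag` nodes or numeric matrices.
#' @return An `ag` node.
#' @export
ag_add <- function(a, b) {
  a <- .as_ag(a); b <- .as_ag(b)
  d <- .bshape(a$val, b$val)
  .op(.bcast(a$val, d) + .bcast(b$val, d), list(a, b), function(g) {
    .acc(a, .reduce_grad(g, dim(a$val)))
    .acc(b, .reduce_grad(g, dim(b$val)))
  })
}

#' @rdname ag_add
#' @export
ag_sub <- function(a, b) {
  a <- .as_ag(a); b <- .as_ag(b)
  d <- .bshape(a$val, b$val)
  .op(.bcast(a$val, d) - .bcast(b$val, d), list(a, b), function(g) {
    .acc(a, .reduce_grad(g, dim(a$val)))
    .acc(b, -.reduce_grad(g, dim(b$val)))
  })
}

#' @rdname ag_add
#' @export
ag_mul <- function(a, b) {
  a <- .as_ag(a); b <- .as_ag(b)
  d <- .bshape(a$val, b$val)
  av <- .bcast(a$val, d); bv <- .bcast(b$val, d)
  .op(av * bv, list(a, b), function(g) {
    .acc(a, .reduce_grad(g * bv, dim(a$val)))
    .acc(b, .reduce_grad(g * av, dim(b$val)))
  })
}

#' @rdname ag_add
#' @export
ag_div <- function(a, b) {
  a <- .as_ag(a); b <- .as_ag(b)
  d <- .bshape(a$val, b$val)
  av <- .bcast(a$val, d); bv <- .bcast(b$val, d)
  .op(av / bv, list(a, b), function(g) {
    .acc(a, .reduce_grad(g / bv, dim(a$val)))
    .acc(b, .reduce_grad(-g * av / bv^2, dim(b$val)))
  })
}

#' Scale an autodiff node by a constant
#' @param a An `ag` node.
#' @param s Numeric scalar constant.
#' @return An `ag` node.
#' @export
ag_scale <- function(a, s) {
  a <- .as_ag(a)
  .op(a$val * s, list(a), function(g) .acc(a, g * s))
}

# ---- elementwise nonlinearities ------------------------------------------

#' Elementwise nonlinearities for autodiff nodes
#'
#' Logistic sigmoid, tanh, (leaky) ReLU, exact GELU (`x * pnorm(x)`), exp,
#' log, square and square root.
#'
#' @param a An `ag` node or numeric matrix.
#' @param slope Negative-side slope for `ag_leakyrelu` (default 0.2).
#' @return An `ag` node.
#' @export
ag_sigmoid <- function(a) {
  a <- .as_ag(a)
  s <- 1 / (1 + exp(-a$val))
  .op(s, list(a), function(g) .acc(a, g * s * (1 - s)))
}

#' @rdname ag_sigmoid
#' @export
ag_tanh <- function(a) {
  a <- .as_ag(a)
  t <- tanh(a$val)
  .op(t, list(a), function(g) .acc(a, g * (1 - t^2)))
}

#' @rdname ag_sigmoid
#' @export
ag_relu <- function(a) {
  a <- .as_ag(a)
  .op(pmax(a$val, 0), list(a), function(g) .acc(a, g * (a$val > 0)))
}

#' @rdname ag_sigmoid
#' @export
ag_leakyrelu <- function(a, slope = 0.2) {
  a <- .as_ag(a)
  .op(ifelse(a$val > 0, a$val, slope * a$val), list(a), function(g)
    .acc(a, g * ifelse(a$val > 0, 1, slope)))
}

#' @rdname ag_sigmoid
#' @export
ag_gelu <- function(a) {
  a <- .as_ag(a)
  .op(a$val * stats::pnorm(a$val), list(a), function(g)
    .acc(a, g * (stats::pnorm(a$val) + a$val * stats::dnorm(a$val))))
}

#' @rdname ag_sigmoid
#' @export
ag_exp <- function(a) {
  a <- .as_ag(a)
  ev <- exp(a$val)
  .op(ev, list(a), function(g) .acc(a, g * ev))
}

#' @rdname ag_sigmoid
#' @export
ag_log <- function(a) {
  a <- .as_ag(a)
  .op(log(a$val), list(a), function(g) .acc(a, g / a$val))
}

#' @rdname ag_sigmoid
#' @export
ag_square <- function(a) {
  a <- .as_ag(a)
  .op(a$val^2, list(a), function(g) .acc(a, 2 * g * a$val))
}

#' @rdname ag_sigmoid
#' @export
ag_sqrt <- function(a) {
  a <- .as_ag(a)
  sv <- sqrt(a$val)
  .op(sv, list(a), function(g) .acc(a, g / (2 * sv)))
}

#' Clamp values into an interval (zero gradient outside)
#' @param a An `ag` node.
#' @param lo,hi Interval bounds.
#' @return An `ag` node.
#' @export
ag_clamp <- function(a, lo, hi) {
  a <- .as_ag(a)
  inside <- a$val >= lo & a$val <= hi
  .op(pmin(pmax(a$val, lo), hi), list(a), function(g) .acc(a, g * inside))
}

# ---- reductions and reshaping --------------------------------------------

#' Reductions over autodiff nodes
#' @param a An `ag` node.
#' @return A 1x1 `ag` node.
#' @export
ag_sum <- function(a) {
  a <- .as_ag(a)
  d <- dim(a$val)
  .op(matrix(sum(a$val), 1, 1), list(a), function(g)
    .acc(a, matrix(g[1], d[1], d[2])))
}

#' @rdname ag_sum
#' @export
ag_mean <- function(a) {
  a <- .as_ag(a)
  d <- dim(a$val); n <- prod(d)
  .op(matrix(mean(a$val), 1, 1), list(a), function(g)
    .acc(a, matrix(g[1] / n, d[1], d[2])))
}

#' Row selection (gather) with scatter-add backward
#'
#' @param a An `ag` node.
#' @param idx Integer row indices (repeats allowed).
#' @return An `ag` node with `length(idx)` rows.
#' @export
ag_rows <- function(a, idx) {
  a <- .as_ag(a)
  d <- dim(a$val)
  .op(a$val[idx, , drop = FALSE], list(a), function(g) {
    G <- matrix(0, d[1], d[2])
    rs <- rowsum(g, group = idx)
    G[as.integer(rownames(rs)), ] <- rs
    .acc(a, G)
  })
}

#' Column selection with scatter backward
#' @param a An `ag` node.
#' @param idx Integer column indices (unique).
#' @return An `ag` node.
#' @export
ag_cols <- function(a, idx) {
  a <- .as_ag(a)
  d <- dim(a$val)
  .op(a$val[, idx, drop = FALSE], list(a), function(g) {
    G <- matrix(0, d[1], d[2])
    G[, idx] <- g
    .acc(a, G)
  })
}

#' Sum rows by group (segment sum)
#'
#' Aggregates rows of `a` into `ngroups` output rows; groups absent from
#' `groups` yield zero rows.  The backward pass gathers output gradients
#' back onto the contributing rows.
#'
#' @param a An `ag` node.
#' @param groups Integer group id per row of `a` (1-based).
#' @param ngroups Number of output rows.
#' @return An `ag` node with `ngroups` rows.
#' @export
ag_rowsum_by <- function(a, groups, ngroups) {
  a <- .as_ag(a)
  out <- matrix(0, ngroups, ncol(a$val))
  if (nrow(a$val) > 0L) {
    rs <- rowsum(a$val, group = groups)
    out[as.integer(rownames(rs)), ] <- rs
  }
  .op(out, list(a), function(g) .acc(a, g[groups, , drop = FALSE]))
}

#' Concatenate autodiff nodes
#' @param lst List of `ag` nodes.
#' @return An `ag` node.
#' @export
ag_vcat <- function(lst) {
  lst <- lapply(lst, .as_ag)
  rows <- vapply(lst, function(x) nrow(x$val), integer(1))
  ends <- cumsum(rows)
  starts <- c(1L, head(ends, -1L) + 1L)
  .op(do.call(rbind, lapply(lst, ag_value)), lst, function(g) {
    for (k in seq_along(lst))
      .acc(lst[[k]], g[starts[k]:ends[k], , drop = FALSE])
  })
}

#' @rdname ag_vcat
#' @export
ag_hcat <- function(lst) {
  lst <- lapply(lst, .as_ag)
  cols <- vapply(lst, function(x) ncol(x$val), integer(1))
  ends <- cumsum(cols)
  starts <- c(1L, head(ends, -1L) + 1L)
  .op(do.call(cbind, lapply(lst, ag_value)), lst, function(g) {
    for (k in seq_along(lst))
      .acc(lst[[k]], g[, starts[k]:ends[k], drop = FALSE])
  })
}

#' Transpose an autodiff node
#' @param a An `ag` node.
#' @return An `ag` node.
#' @export
ag_t <- function(a) {
  a <- .as_ag(a)
  .op(t(a$val), list(a), function(g) .acc(a, t(g)))
}

#' Row-wise softmax with optional additive mask
#'
#' @param a An `ag` node (rows are distributions).
#' @param mask Optional logical matrix, `FALSE` entries are excluded
#'   (weight 0).
#' @return An `ag` node of the same shape; each unmasked row sums to 1.
#' @export
ag_softmax_rows <- function(a, mask = NULL) {
  a <- .as_ag(a)
  z <- a$val
  if (!is.null(mask)) z[!mask] <- -Inf
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez[is.nan(ez)] <- 0      # fully masked rows
  P <- ez / pmax(rowSums(ez), .Machine$double.eps)
  .op(P, list(a), function(g) {
    .acc(a, P * (g - rowSums(g * P)))
  })
}

#' Layer normalisation over rows
#'
#' Normalises each row to zero mean / unit variance, then applies the affine
#' transform `gamma * xhat + beta`.
#'
#' @param a An `ag` node (n x d).
#' @param gamma,beta `ag` nodes holding 1 x d parameters.
#' @param eps Variance floor.
#' @return An `ag` node, same shape as `a`.
#' @export
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- .as_ag(a); gamma <- .as_ag(gamma); beta <- .as_ag(beta)
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- .bcast(gamma$val, dim(x))
  out <- xhat * gv + .bcast(beta$val, dim(x))
  .op(out, list(a, gamma, beta), function(g) {
    .acc(gamma, matrix(colSums(g * xhat), 1))
    .acc(beta, matrix(colSums(g), 1))
    gx <- g * gv
    # d/dx of row-standardisation
    t1 <- gx
    t2 <- rowMeans(gx)
    t3 <- xhat * rowMeans(gx * xhat)
    .acc(a, inv * (t1 - t2 - t3))
  })
}

#' Inverted dropout
#'
#' @param a An `ag` node.
#' @param p Drop probability.
#' @param train Logical; when `FALSE` (or `p == 0`) this is the identity.
#' @return An `ag` node.
#' @export
ag_dropout <- function(a, p, train = TRUE) {
  a <- .as_ag(a)
  if (!train || p <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$val)), nrow(a$val)) >= p) / (1 - p)
  .op(a$val * keep, list(a), function(g) .acc(a, g * keep))
}

# ---- parameters and optimiser --------------------------------------------

#' Collect parameter nodes from a nested list
#' @param x Nested list containing `ag` parameter nodes.
#' @return Flat list of `ag` nodes.
#' @export
collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is_ag(v)) out[[length(out) + 1L]] <<- v
    else if (is.list(v)) for (e in v) walk(e)
  }
  walk(x)
  out
}

#' Adam optimiser
#'
#' `adam_init()` builds optimiser state for a flat parameter list;
#' `adam_step()` applies one update from the accumulated gradients
#' (parameters with `NULL` gradient are skipped) and then zeroes them.
#'
#' @param params Flat list of `ag` parameter nodes (see [collect_params()]).
#' @param lr Learning rate (default 1e-4, the architecture's stated default).
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return `adam_init()`: an optimiser state environment.
#' @export
adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0
  st$m <- lapply(params, function(p) p$val * 0)
  st$v <- lapply(params, function(p) p$val * 0)
  st
}

#' @rdname adam_init
#' @param st Optimiser state from `adam_init()`.
#' @export
adam_step <- function(st, params) {
  st$t <- st$t + 1
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (is.null(p$grad)) next
    st$m[[k]] <- st$b1 * st$m[[k]] + (1 - st$b1) * p$grad
    st$v[[k]] <- st$b2 * st$v[[k]] + (1 - st$b2) * p$grad^2
    p$val <- p$val - st$lr * (st$m[[k]] / bc1) /
      (sqrt(st$v[[k]] / bc2) + st$eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

#' Glorot-uniform weight initialisation
#' @param nin,nout Fan-in and fan-out.
#' @return `nin` x `nout` numeric matrix.
#' @export
glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}
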