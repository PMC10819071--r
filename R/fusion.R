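# Cross-attention fusion of sequence and graph embeddings, decoding and
# loss functions.
#
# Queries come from the sequence encoder's token states; keys and values are
# affine projections of the graph embedding, treated as a one-element memory
# (the Set2Set readout yields one vector per molecule).  Scores are scaled
# by sqrt(C/d) with C the embedding width and d the number of heads, i.e.
# the standard per-head-dimension scaling.  The attended token states are
# mean-pooled into the fused vector fed to a three-layer feed-forward
# decoder with per-task heads.

#' Default fusion configuration
#' @param model_dim Embedding width C (default 128).
#' @param n_heads Attention heads d (default 8).
#' @return Named list of settings.
#' @export
fusion_config <- function(model_dim = 128L, n_heads = 8L) {
  stopifnot(model_dim %% n_heads == 0L)
  list(model_dim = as.integer(model_dim), n_heads = as.integer(n_heads))
}

#' Initialise fusion + decoder parameters
#' @param n_tasks Number of prediction targets.
#' @param config See [fusion_config()].
#' @return Nested list of `ag` parameter nodes.
#' @export
fusion_init <- function(n_tasks, config = fusion_config()) {
  d <- config$model_dim
  h1 <- d
  h2 <- max(d %/% 2L, 8L)
  list(
    Wq = ag_param(glorot(d, d)), bq = ag_param(matrix(0, 1, d)),
    Wk = ag_param(glorot(d, d)), bk = ag_param(matrix(0, 1, d)),
    Wv = ag_param(glorot(d, d)), bv = ag_param(matrix(0, 1, d)),
    Wo = ag_param(glorot(d, d)), bo = ag_param(matrix(0, 1, d)),
    dec = list(W1 = ag_param(glorot(d, h1)), b1 = ag_param(matrix(0, 1, h1)),
               W2 = ag_param(glorot(h1, h2)), b2 = ag_param(matrix(0, 1, h2)),
               W3 = ag_param(glorot(h2, n_tasks)),
               b3 = ag_param(matrix(0, 1, n_tasks))))
}

#' Cross-attention between token states and a graph embedding
#'
#' @param params Parameters from [fusion_init()].
#' @param seq_states `ag` node, q x C token states (queries).
#' @param graph_vec `ag` node, 1 x C graph embedding, or an m x C matrix when
#'   a multi-token memory is exposed (keys and values).
#' @param config See [fusion_config()].
#' @return List: `fused` (`ag`, 1 x C mean-pooled attended states),
#'   `attended` (`ag`, q x C), `weights` (numeric q x m attention weights,
#'   averaged over heads; exactly 1 everywhere for a one-element memory).
#' @export
cross_attend <- function(params, seq_states, graph_vec,
                         config = fusion_config()) {
  d <- config$model_dim
  h <- config$n_heads
  dh <- d %/% h
  if (ncol(ag_value(seq_states)) != d || ncol(ag_value(graph_vec)) != d)
    stop("cross_attend: dimension mismatch (expected width ", d, ")")
  q <- nrow(ag_value(seq_states))
  Q <- ag_add(ag_mm(seq_states, params$Wq), params$bq)
  K <- ag_add(ag_mm(graph_vec, params$Wk), params$bk)
  V <- ag_add(ag_mm(graph_vec, params$Wv), params$bv)
  heads <- vector("list", h)
  wsum <- 0
  for (hh in seq_len(h)) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    scores <- ag_scale(ag_mm(ag_cols(Q, idx), ag_t(ag_cols(K, idx))),
                       1 / sqrt(dh))
    A <- ag_softmax_rows(scores)
    wsum <- wsum + ag_value(A)
    heads[[hh]] <- ag_mm(A, ag_cols(V, idx))
  }
  attended <- ag_add(ag_mm(ag_hcat(heads), params$Wo), params$bo)
  fused <- ag_scale(ag_mm(matrix(1, 1, q), attended), 1 / q)
  list(fused = fused, attended = attended, weights = wsum / h)
}

#' Decode a fused embedding into per-task outputs
#'
#' Three affine layers with ReLU nonlinearities; classification outputs are
#' passed through a sigmoid into (0, 1), regression outputs are unbounded.
#'
#' @param params Parameters from [fusion_init()] (uses `params$dec`).
#' @param fused `ag` node, 1 x C fused embedding.
#' @param task_type `"classification"` or `"regression"`.
#' @return `ag` node, 1 x n_tasks.
#' @export
decode <- function(params, fused, task_type = "classification") {
  p <- params$dec
  x <- ag_relu(ag_add(ag_mm(fused, p$W1), p$b1))
  x <- ag_relu(ag_add(ag_mm(x, p$W2), p$b2))
  out <- ag_add(ag_mm(x, p$W3), p$b3)
  if (task_type == "classification") ag_sigmoid(out) else out
}

#' Masked binary cross-entropy loss
#'
#' Mean BCE over unmasked entries, with predictions clamped to
#' `[eps, 1 - eps]` so the logs stay finite.  A fully masked batch yields a
#' zero loss with a warning.
#'
#' @param y Numeric matrix of labels in \{0, 1\}.
#' @param x `ag` node (or numeric matrix) of predicted probabilities,
#'   same shape.
#' @param mask Logical matrix, `TRUE` = observed (default: all observed).
#' @param eps Clamp width (default 1e-7).
#' @return 1x1 `ag` node.
#' @export
loss_classification <- function(y, x, mask = NULL, eps = 1e-7) {
  x <- .as_ag(x)
  y <- as.matrix(y)
  if (is.null(mask)) mask <- !is.na(y)
  mask <- mask & !is.na(y)
  nobs <- sum(mask)
  if (nobs == 0L) {
    warning("loss_classification: all labels masked; returning 0")
    return(ag(matrix(0, 1, 1)))
  }
  y[!mask] <- 0               # masked terms are multiplied by 0 below
  m <- as.numeric(mask)
  xc <- ag_clamp(x, eps, 1 - eps)
  terms <- ag_add(ag_mul(y, ag_log(xc)),
                  ag_mul(1 - y, ag_log(ag_sub(1, xc))))
  ag_scale(ag_sum(ag_mul(terms, matrix(m, nrow(y), ncol(y)))), -1 / nobs)
}

#' Root-mean-square-error loss
#'
#' @param y Numeric matrix/vector of targets (m >= 1).
#' @param x `ag` node (or numeric) of predictions, same shape.
#' @return 1x1 `ag` node holding `sqrt(mean((y - x)^2))`.
#' @export
loss_regression <- function(y, x) {
  x <- .as_ag(x)
  y <- as.matrix(y)
  if (length(y) == 0L) stop("loss_regression: no targets")
  ag_sqrt(ag_mean(ag_square(ag_sub(x, y))))
}
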