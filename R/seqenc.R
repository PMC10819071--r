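# Transformer encoder over FCS token sequences.
#
# Token embedding + learned positional embedding feed a stack of
# pre-activation-free ("post-norm") multi-head self-attention blocks with
# GELU feed-forward layers, producing contextual token states and a
# mean-pooled sequence vector.  One molecule is encoded at a time, so no
# padding is needed in normal operation; an optional `pad_to` argument pads
# with masked positions and is used to verify that padding never changes the
# states of real positions.

#' Default sequence-encoder configuration
#'
#' `model_dim` 128 and `n_heads` 8 are the architecture's stated defaults;
#' the number of layers is a free choice (default 4), the feed-forward width
#' is `4 * model_dim` and dropout 0.1, the usual transformer-encoder
#' settings.
#'
#' @param model_dim Embedding/state width.
#' @param n_heads Attention heads (must divide `model_dim`).
#' @param n_layers Encoder blocks.
#' @param ffn_mult Feed-forward width multiplier.
#' @param dropout Dropout probability (training only).
#' @param max_len Maximum token-sequence length; longer inputs are truncated
#'   with a warning.
#' @return Named list of settings.
#' @export
seqenc_config <- function(model_dim = 128L, n_heads = 8L, n_layers = 4L,
                          ffn_mult = 4L, dropout = 0.1, max_len = 256L) {
  stopifnot(model_dim %% n_heads == 0L)
  list(model_dim = as.integer(model_dim), n_heads = as.integer(n_heads),
       n_layers = as.integer(n_layers), ffn_mult = as.integer(ffn_mult),
       dropout = dropout, max_len = as.integer(max_len))
}

#' Initialise sequence-encoder parameters
#'
#' @param vocab_size Number of token types.
#' @param config See [seqenc_config()].
#' @return Nested list of `ag` parameter nodes.
#' @export
seqenc_init <- function(vocab_size, config = seqenc_config()) {
  d <- config$model_dim
  f <- config$ffn_mult * d
  layer <- function() list(
    Wq = ag_param(glorot(d, d)), bq = ag_param(matrix(0, 1, d)),
    Wk = ag_param(glorot(d, d)), bk = ag_param(matrix(0, 1, d)),
    Wv = ag_param(glorot(d, d)), bv = ag_param(matrix(0, 1, d)),
    Wo = ag_param(glorot(d, d)), bo = ag_param(matrix(0, 1, d)),
    ln1_g = ag_param(matrix(1, 1, d)), ln1_b = ag_param(matrix(0, 1, d)),
    W1 = ag_param(glorot(d, f)), b1 = ag_param(matrix(0, 1, f)),
    W2 = ag_param(glorot(f, d)), b2 = ag_param(matrix(0, 1, d)),
    ln2_g = ag_param(matrix(1, 1, d)), ln2_b = ag_param(matrix(0, 1, d)))
  list(embed = ag_param(matrix(stats::rnorm(vocab_size * d, sd = 0.02),
                               vocab_size, d)),
       pos = ag_param(matrix(stats::rnorm(config$max_len * d, sd = 0.02),
                             config$max_len, d)),
       layers = lapply(seq_len(config$n_layers), function(i) layer()))
}

#' Encode a token sequence
#'
#' @param params Parameters from [seqenc_init()].
#' @param token_ids Integer vector of vocabulary indices (1-based), length
#'   `q >= 1`.
#' @param config See [seqenc_config()].
#' @param train Logical; enables dropout.
#' @param pad_to Optional integer >= `q`; appends masked padding positions
#'   (verification hook, results on real positions are unchanged).
#' @return List: `token_states` (`ag`, q x model_dim), `pooled` (`ag`,
#'   1 x model_dim, mean over real positions), `attn` (list of plain
#'   per-layer, per-head attention matrices over real positions).
#' @export
encode_sequence <- function(params, token_ids, config = seqenc_config(),
                            train = FALSE, pad_to = NULL) {
  q <- length(token_ids)
  stopifnot(q >= 1L)
  if (q > config$max_len) {
    warning("token sequence longer than max_len (", q, " > ", config$max_len,
            "); truncating")
    token_ids <- token_ids[seq_len(config$max_len)]
    q <- config$max_len
  }
  d <- config$model_dim
  h <- config$n_heads
  dh <- d %/% h
  npad <- if (is.null(pad_to)) 0L else max(0L, pad_to - q)
  qp <- q + npad

  x <- ag_add(ag_rows(params$embed, token_ids),
              ag_rows(params$pos, seq_len(q)))
  if (npad > 0L) x <- ag_vcat(list(x, matrix(0, npad, d)))
  # attention mask: padding positions neither attend nor are attended to
  mask <- NULL
  if (npad > 0L) {
    mask <- matrix(FALSE, qp, qp)
    mask[seq_len(q), seq_len(q)] <- TRUE
    mask[(q + 1L):qp, ] <- TRUE          # pad rows: softmax stays finite
  }
  attn_all <- list()
  for (ly in params$layers) {
    Q <- ag_add(ag_mm(x, ly$Wq), ly$bq)
    K <- ag_add(ag_mm(x, ly$Wk), ly$bk)
    V <- ag_add(ag_mm(x, ly$Wv), ly$bv)
    heads <- vector("list", h)
    attn_layer <- vector("list", h)
    for (hh in seq_len(h)) {
      idx <- ((hh - 1L) * dh + 1L):(hh * dh)
      scores <- ag_scale(ag_mm(ag_cols(Q, idx), ag_t(ag_cols(K, idx))),
                         1 / sqrt(dh))
      A <- ag_softmax_rows(scores, mask = mask)
      attn_layer[[hh]] <- ag_value(A)[seq_len(q), seq_len(q), drop = FALSE]
      heads[[hh]] <- ag_mm(A, ag_cols(V, idx))
    }
    attn_all[[length(attn_all) + 1L]] <- attn_layer
    att <- ag_add(ag_mm(ag_hcat(heads), ly$Wo), ly$bo)
    att <- ag_dropout(att, config$dropout, train)
    x <- ag_layernorm(ag_add(x, att), ly$ln1_g, ly$ln1_b)
    ff <- ag_add(ag_mm(ag_gelu(ag_add(ag_mm(x, ly$W1), ly$b1)), ly$W2),
                 ly$b2)
    ff <- ag_dropout(ff, config$dropout, train)
    x <- ag_layernorm(ag_add(x, ff), ly$ln2_g, ly$ln2_b)
  }
  real <- ag_rows(x, seq_len(q))
  pooled <- ag_scale(ag_mm(matrix(1, 1, q), real), 1 / q)
  list(token_states = real, pooled = pooled, attn = attn_all)
}
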