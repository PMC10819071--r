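# Atom-aware message-passing network over knowledge-augmented molecular
# graphs.
#
# Two message channels encode the two kinds of incoming neighbours an atom
# has in the augmented graph: channel 1 carries messages from virtual
# property/functional-group nodes along directed knowledge edges, channel 2
# carries messages between atoms along bonds.  Each channel computes
# GAT-style attention coefficients (LeakyReLU-scored, softmax-normalised
# over the receiver's channel neighbourhood), gates a linear transform of
# the (fixed) edge state by the coefficient through a logistic sigmoid, and
# modulates it elementwise by the sender state.  Channel aggregates are
# summed (or averaged) and fed to a GRU cell that updates the node state.
# After K rounds a Set2Set readout pools the atom states into one graph
# vector.

.relation_vocab <- c("isPeriodOf", "isMetallicityOf", "isGroupOf",
                     "isRadiusOf", "isWeightOf", "hasFunctionalGroup")

#' Default graph-encoder configuration
#'
#' `hidden_dim` 128 matches the architecture's stated feature size.  K is
#' kept small (message-passing networks over-smooth beyond a few rounds);
#' default 3.  Set2Set runs 3 processing steps; aggregation is summation
#' (averaging available).
#'
#' @param hidden_dim Node/edge state width F.
#' @param rounds Message-passing rounds K.
#' @param aggregate `"sum"` or `"mean"`.
#' @param set2set_steps Set2Set processing steps.
#' @param leaky_slope Negative slope of the attention LeakyReLU.
#' @return Named list of settings.
#' @export
ampnn_config <- function(hidden_dim = 128L, rounds = 3L, aggregate = "sum",
                         set2set_steps = 3L, leaky_slope = 0.2) {
  stopifnot(aggregate %in% c("sum", "mean"), rounds >= 1L)
  list(hidden_dim = as.integer(hidden_dim), rounds = as.integer(rounds),
       aggregate = aggregate, set2set_steps = as.integer(set2set_steps),
       leaky_slope = leaky_slope)
}

#' Label vocabulary of a knowledge base
#'
#' All property-group labels an augmented graph can carry (element property
#' labels plus functional-group names), in a fixed order; virtual-node
#' embeddings are indexed by this vocabulary.
#'
#' @param kb A `knowledge_base`.
#' @return Character vector.
#' @export
kb_label_vocab <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  el <- sort(unique(unlist(lapply(kb$element_properties, unname))))
  c(el, names(kb$functional_groups))
}

#' Initialise graph-encoder parameters
#'
#' @param label_vocab Character vector from [kb_label_vocab()].
#' @param config See [ampnn_config()].
#' @param feat_dim Atom feature width (default [atom_feature_dim()]).
#' @param bond_dim Bond feature width (default 6).
#' @return Nested list of `ag` parameter nodes.
#' @export
ampnn_init <- function(label_vocab, config = ampnn_config(),
                       feat_dim = atom_feature_dim(), bond_dim = 6L) {
  f <- config$hidden_dim
  channel <- function() list(
    W_att = ag_param(glorot(f, f)),
    a_att = ag_param(matrix(stats::runif(2 * f, -0.1, 0.1), 2 * f, 1)),
    W_edge = ag_param(glorot(f, f)))
  list(
    W_in = ag_param(glorot(feat_dim, f)), b_in = ag_param(matrix(0, 1, f)),
    label_embed = ag_param(matrix(stats::rnorm(length(label_vocab) * f,
                                               sd = 0.1),
                                  length(label_vocab), f)),
    rel_embed = ag_param(matrix(stats::rnorm(length(.relation_vocab) * f,
                                             sd = 0.1),
                                length(.relation_vocab), f)),
    W_bond = ag_param(glorot(bond_dim, f)),
    ch_prop = channel(), ch_atom = channel(),
    gru = list(Wz = ag_param(glorot(f, f)), Uz = ag_param(glorot(f, f)),
               bz = ag_param(matrix(0, 1, f)),
               Wr = ag_param(glorot(f, f)), Ur = ag_param(glorot(f, f)),
               br = ag_param(matrix(0, 1, f)),
               Wh = ag_param(glorot(f, f)), Uh = ag_param(glorot(f, f)),
               bh = ag_param(matrix(0, 1, f))),
    s2s = list(W = ag_param(glorot(2 * f, 4 * f)),
               U = ag_param(glorot(f, 4 * f)),
               b = ag_param(matrix(0, 1, 4 * f))),
    W_out = ag_param(glorot(2 * f, f)), b_out = ag_param(matrix(0, 1, f)))
}

#' Index tensors of an augmented graph
#'
#' Flattens an `augmented_graph` into the arrays the encoder consumes:
#' atoms first (rows `1..n_atoms`), then virtual nodes.
#'
#' @param aug An `augmented_graph`.
#' @param label_vocab Character vector from [kb_label_vocab()].
#' @return List: `n_atoms`, `n`, `X` (atom features), `s_atom`/`r_atom`/`B`
#'   (atom-atom directed edges + bond features), `s_prop`/`r_prop`/`rel_ids`
#'   (virtual->atom edges), `label_ids` (virtual-node labels).
#' @export
augmented_tensors <- function(aug, label_vocab) {
  stopifnot(inherits(aug, "augmented_graph"))
  g <- aug$base
  n_atoms <- g$n_nodes
  nv <- nrow(aug$virtual_nodes)
  lab <- match(aug$virtual_nodes$label, label_vocab)
  if (anyNA(lab))
    stop("label(s) missing from vocabulary: ",
         paste(aug$virtual_nodes$label[is.na(lab)], collapse = ", "))
  rel <- match(aug$virtual_edges$relation, .relation_vocab)
  list(n_atoms = n_atoms, n = n_atoms + nv,
       X = atom_features(g),
       s_atom = g$edges$i, r_atom = g$edges$j, B = bond_features(g),
       s_prop = n_atoms + aug$virtual_edges$src,
       r_prop = aug$virtual_edges$dst,
       rel_ids = rel, label_ids = lab)
}

#' Attention coefficients over one receiver's neighbourhood
#'
#' Direct evaluation of the per-channel attention rule: each neighbour u of
#' receiver v is scored `LeakyReLU(a^T [W h_u || W h_v])` and the scores are
#' softmax-normalised over the neighbourhood.
#'
#' @param h_receiver Numeric vector (state of the receiving node, length F).
#' @param h_neighbors Numeric matrix (one neighbour state per row).
#' @param W Channel weight matrix (F x F, right-multiplied: `h %*% W`).
#' @param a Channel attention vector (length 2F).
#' @param slope LeakyReLU negative slope.
#' @return Numeric vector of weights summing to 1.
#' @export
attention_coefficients <- function(h_receiver, h_neighbors, W, a,
                                   slope = 0.2) {
  if (is.null(dim(h_neighbors))) h_neighbors <- matrix(h_neighbors, nrow = 1)
  stopifnot(nrow(h_neighbors) >= 1L)
  Wu <- h_neighbors %*% W
  Wv <- matrix(h_receiver, 1) %*% W
  z <- cbind(Wu, matrix(Wv, nrow(Wu), ncol(Wv), byrow = TRUE)) %*%
    matrix(a, ncol = 1)
  z <- ifelse(z > 0, z, slope * z)
  z <- z - max(z)
  e <- exp(z)
  as.numeric(e / sum(e))
}

# grouped softmax over edge scores (groups = receiver nodes)
.edge_softmax <- function(score, groups, n) {
  gmax <- rep(-Inf, n)
  sv <- ag_value(score)
  for (k in seq_along(groups)) gmax[groups[k]] <- max(gmax[groups[k]], sv[k])
  shifted <- ag_sub(score, matrix(gmax[groups], ncol = 1))
  ez <- ag_exp(shifted)
  denom <- ag_rowsum_by(ez, groups, n)
  ag_div(ez, ag_rows(denom, groups))
}

.channel_messages <- function(h, ch, he, s, r, n, cfg) {
  if (length(s) == 0L)
    return(list(agg = NULL, alpha = numeric(0)))
  Wh <- ag_mm(h, ch$W_att)
  z <- ag_mm(ag_hcat(list(ag_rows(Wh, s), ag_rows(Wh, r))), ch$a_att)
  alpha <- .edge_softmax(ag_leakyrelu(z, cfg$leaky_slope), r, n)
  msg <- ag_mul(ag_sigmoid(ag_mul(alpha, ag_mm(he, ch$W_edge))),
                ag_rows(h, s))
  agg <- ag_rowsum_by(msg, r, n)
  if (cfg$aggregate == "mean") {
    cnt <- tabulate(r, nbins = n)
    agg <- ag_mul(agg, matrix(1 / pmax(cnt, 1L), ncol = 1))
  }
  list(agg = agg, alpha = as.numeric(ag_value(alpha)))
}

#' Encode an augmented molecular graph
#'
#' Runs K rounds of dual-channel attention message passing with GRU state
#' updates, then a Set2Set readout over the atom states (virtual nodes carry
#' knowledge, not molecular identity, and are excluded from the readout).
#'
#' @param params Parameters from [ampnn_init()].
#' @param tensors Graph tensors from [augmented_tensors()].
#' @param config See [ampnn_config()].
#' @return List: `node_states` (`ag`, n x F after round K), `graph_embedding`
#'   (`ag`, 1 x F), `alpha` / `beta` (numeric attention weights of the final
#'   round, per property edge / per atom edge).
#' @export
ampnn_encode <- function(params, tensors, config = ampnn_config()) {
  tz <- tensors
  n <- tz$n
  f <- config$hidden_dim

  h_atom <- ag_add(ag_mm(ag(tz$X), params$W_in), params$b_in)
  h <- if (tz$n > tz$n_atoms) {
    ag_vcat(list(h_atom, ag_rows(params$label_embed, tz$label_ids)))
  } else h_atom

  he_atom <- if (length(tz$s_atom)) ag_mm(ag(tz$B), params$W_bond) else NULL
  he_prop <- if (length(tz$s_prop)) ag_rows(params$rel_embed, tz$rel_ids)
             else NULL

  alpha <- numeric(0); beta <- numeric(0)
  for (k in seq_len(config$rounds)) {
    c1 <- if (is.null(he_prop)) list(agg = NULL, alpha = numeric(0)) else
      .channel_messages(h, params$ch_prop, he_prop, tz$s_prop, tz$r_prop,
                        n, config)
    c2 <- if (is.null(he_atom)) list(agg = NULL, alpha = numeric(0)) else
      .channel_messages(h, params$ch_atom, he_atom, tz$s_atom, tz$r_atom,
                        n, config)
    alpha <- c1$alpha; beta <- c2$alpha
    m <- if (is.null(c1$agg) && is.null(c2$agg)) ag(matrix(0, n, f))
         else if (is.null(c1$agg)) c2$agg
         else if (is.null(c2$agg)) c1$agg
         else ag_add(c1$agg, c2$agg)
    g <- params$gru
    z <- ag_sigmoid(ag_add(ag_add(ag_mm(m, g$Wz), ag_mm(h, g$Uz)), g$bz))
    r <- ag_sigmoid(ag_add(ag_add(ag_mm(m, g$Wr), ag_mm(h, g$Ur)), g$br))
    htil <- ag_tanh(ag_add(ag_add(ag_mm(m, g$Wh),
                                  ag_mm(ag_mul(r, h), g$Uh)), g$bh))
    h <- ag_add(ag_mul(ag_sub(1, z), h), ag_mul(z, htil))
  }

  M <- ag_rows(h, seq_len(tz$n_atoms))
  qs <- set2set_readout(params$s2s, M, config$set2set_steps, f)
  emb <- ag_add(ag_mm(qs, params$W_out), params$b_out)
  list(node_states = h, graph_embedding = emb, alpha = alpha, beta = beta)
}

#' Set2Set pooling over node states
#'
#' LSTM-driven attention pooling: for T steps, an LSTM cell consumes the
#' previous query-plus-readout vector, attends over the memory rows with a
#' dot-product softmax, and appends the attention readout to the query.
#' The result is permutation-invariant in the memory rows.
#'
#' @param p Set2Set parameters (`W` 2F x 4F, `U` F x 4F, `b` 1 x 4F).
#' @param M `ag` node, n x F memory.
#' @param steps Processing steps T.
#' @param f State width F.
#' @return `ag` node, 1 x 2F.
#' @export
set2set_readout <- function(p, M, steps, f) {
  q_star <- ag(matrix(0, 1, 2 * f))
  hl <- ag(matrix(0, 1, f))
  cl <- ag(matrix(0, 1, f))
  for (t in seq_len(steps)) {
    gates <- ag_add(ag_add(ag_mm(q_star, p$W), ag_mm(hl, p$U)), p$b)
    i <- ag_sigmoid(ag_cols(gates, seq_len(f)))
    fo <- ag_sigmoid(ag_cols(gates, f + seq_len(f)))
    o <- ag_sigmoid(ag_cols(gates, 2 * f + seq_len(f)))
    gg <- ag_tanh(ag_cols(gates, 3 * f + seq_len(f)))
    cl <- ag_add(ag_mul(fo, cl), ag_mul(i, gg))
    hl <- ag_mul(o, ag_tanh(cl))
    att <- ag_softmax_rows(ag_t(ag_mm(M, ag_t(hl))))   # 1 x n
    r_t <- ag_mm(att, M)
    q_star <- ag_hcat(list(hl, r_t))
  }
  q_star
}
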