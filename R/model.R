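# Full model assembly: configuration, forward pass, ablation wiring,
# prediction and checkpoint (de)serialisation.

#' Model and training configuration
#'
#' Defaults reproduce the architecture's stated experimental setup: Adam
#' with initial learning rate 1e-4, batch size 64, feature width 128,
#' 8 attention heads, at most 100 epochs with early stopping, and 10 random
#' seeds for aggregate reporting.  The remaining knobs (encoder depth,
#' message-passing rounds, Set2Set steps, vocabulary mining thresholds,
#' split protocol) are this package's own documented choices.
#'
#' @param model_dim Shared feature width C/F (default 128).
#' @param n_heads Attention heads in transformer and fusion (default 8).
#' @param n_layers Transformer encoder layers (default 4).
#' @param rounds Message-passing rounds K (default 3).
#' @param set2set_steps Set2Set processing steps (default 3).
#' @param aggregate Channel aggregation, `"sum"` or `"mean"`.
#' @param dropout Dropout probability in the sequence encoder.
#' @param max_len Maximum token-sequence length.
#' @param ablation `"full"`, `"no_graph"` or `"no_sequence"`.
#' @param lr,batch_size,max_epochs,patience Optimisation settings.
#' @param seeds Number of random seeds for [crossmol_train()] reports.
#' @param split `"scaffold"` or `"random"`.
#' @param fractions Train/valid/test fractions (sum to 1).
#' @param min_freq,max_token_len,max_vocab FCS mining parameters.
#' @param n_bins Quantile bins for element radius/weight groups.
#' @return Named list of class `crossmol_config`.
#' @export
crossmol_config <- function(model_dim = 128L, n_heads = 8L, n_layers = 4L,
                            rounds = 3L, set2set_steps = 3L,
                            aggregate = "sum", dropout = 0.1,
                            max_len = 256L, ablation = "full",
                            lr = 1e-4, batch_size = 64L, max_epochs = 100L,
                            patience = 15L, seeds = 10L,
                            split = "scaffold",
                            fractions = c(0.8, 0.1, 0.1),
                            min_freq = 5L, max_token_len = 8L,
                            max_vocab = 1024L, n_bins = 5L) {
  stopifnot(ablation %in% c("full", "no_graph", "no_sequence"),
            split %in% c("scaffold", "random"),
            abs(sum(fractions) - 1) < 1e-8)
  structure(list(
    model_dim = as.integer(model_dim), n_heads = as.integer(n_heads),
    n_layers = as.integer(n_layers), rounds = as.integer(rounds),
    set2set_steps = as.integer(set2set_steps), aggregate = aggregate,
    dropout = dropout, max_len = as.integer(max_len), ablation = ablation,
    lr = lr, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    seeds = as.integer(seeds), split = split, fractions = fractions,
    min_freq = as.integer(min_freq),
    max_token_len = as.integer(max_token_len),
    max_vocab = as.integer(max_vocab), n_bins = as.integer(n_bins)),
    class = "crossmol_config")
}

.seq_cfg <- function(cfg) seqenc_config(cfg$model_dim, cfg$n_heads,
                                        cfg$n_layers, 4L, cfg$dropout,
                                        cfg$max_len)
.amp_cfg <- function(cfg) ampnn_config(cfg$model_dim, cfg$rounds,
                                       cfg$aggregate, cfg$set2set_steps)
.fus_cfg <- function(cfg) fusion_config(cfg$model_dim, cfg$n_heads)

#' Build a model
#'
#' @param config A `crossmol_config`.
#' @param vocab An `fcs_vocabulary` (see [mine_vocabulary()]).
#' @param kb A `knowledge_base`.
#' @param task_names Character vector of prediction targets.
#' @param task_type `"classification"` or `"regression"`.
#' @return An object of class `crossmol_model` (parameters are `ag` nodes;
#'   use [model_save()] / [model_load()] for persistence).
#' @export
build_model <- function(config, vocab, kb, task_names,
                        task_type = "classification") {
  stopifnot(inherits(config, "crossmol_config"),
            inherits(vocab, "fcs_vocabulary"),
            inherits(kb, "knowledge_base"))
  lv <- kb_label_vocab(kb)
  params <- list(seq = seqenc_init(length(vocab$tokens), .seq_cfg(config)),
                 graph = ampnn_init(lv, .amp_cfg(config)),
                 fus = fusion_init(length(task_names), .fus_cfg(config)))
  structure(list(params = params, config = config, vocab = vocab, kb = kb,
                 label_vocab = lv, task_names = task_names,
                 task_type = task_type,
                 needs_h = kb_needs_explicit_h(kb)),
            class = "crossmol_model")
}

#' @export
print.crossmol_model <- function(x, ...) {
  np <- sum(vapply(collect_params(x$params), function(p) length(p$val),
                   numeric(1)))
  cat(sprintf(paste0("<crossmol_model> %s, %d-dim, %s ablation, %d task(s),",
                     " %s parameters\n"),
              x$task_type, x$config$model_dim, x$config$ablation,
              length(x$task_names), format(np, big.mark = ",")))
  invisible(x)
}

#' Prepare a molecule for the forward pass
#'
#' Parses, augments and tokenises once; the result can be cached across
#' epochs.
#'
#' @param model A `crossmol_model`.
#' @param smiles SMILES string.
#' @return List: `token_ids`, `tensors`, `smiles`.
#' @export
prepare_molecule <- function(model, smiles) {
  g <- parse_smiles(smiles, add_hydrogens = model$needs_h)
  aug <- augment_graph(g, model$kb)
  toks <- fcs_tokenize(smiles, model$vocab)
  ids <- match(toks$tokens, model$vocab$tokens)
  list(token_ids = ids,
       tensors = augmented_tensors(aug, model$label_vocab),
       smiles = smiles)
}

#' Forward pass for one prepared molecule
#'
#' Ablation wiring: `"full"` fuses token states and graph embedding by
#' cross-attention plus a residual from the pooled token states (with a
#' one-element graph memory the attention weights are constant, so without
#' the residual the sequence branch would receive no gradient — the
#' end-to-end training contract requires every parameter group to learn);
#' `"no_graph"` decodes the mean-pooled token states; `"no_sequence"`
#' decodes the graph embedding.  Only the encoders an ablation uses are
#' executed, so gradients touch only their parameters.
#'
#' @param model A `crossmol_model`.
#' @param prep Output of [prepare_molecule()].
#' @param train Logical; enables dropout.
#' @return List: `pred` (`ag`, 1 x n_tasks), `fused` (`ag`, 1 x C).
#' @export
forward_molecule <- function(model, prep, train = FALSE) {
  cfg <- model$config
  ab <- cfg$ablation
  se <- if (ab != "no_sequence")
    encode_sequence(model$params$seq, prep$token_ids, .seq_cfg(cfg), train)
  ge <- if (ab != "no_graph")
    ampnn_encode(model$params$graph, prep$tensors, .amp_cfg(cfg))
  fused <- switch(ab,
    full = ag_add(cross_attend(model$params$fus, se$token_states,
                               ge$graph_embedding, .fus_cfg(cfg))$fused,
                  se$pooled),
    no_graph = se$pooled,
    no_sequence = ge$graph_embedding)
  list(pred = decode(model$params$fus, fused, model$task_type),
       fused = fused)
}

#' Predict properties for SMILES strings
#'
#' @param model A `crossmol_model`.
#' @param smiles Character vector.
#' @return Numeric matrix, one row per molecule, one column per task
#'   (probabilities for classification).  Unparsable molecules yield `NA`
#'   rows with a warning naming them.
#' @export
predict_molecules <- function(model, smiles) {
  out <- matrix(NA_real_, length(smiles), length(model$task_names),
                dimnames = list(NULL, model$task_names))
  for (k in seq_along(smiles)) {
    prep <- tryCatch(prepare_molecule(model, smiles[k]),
                     error = function(e) e)
    if (inherits(prep, "error")) {
      warning("prediction failed for '", smiles[k], "': ",
              conditionMessage(prep))
      next
    }
    out[k, ] <- ag_value(forward_molecule(model, prep)$pred)
  }
  out
}

#' Export fused embeddings and cosine similarities
#'
#' @param model A `crossmol_model`.
#' @param smiles Character vector.
#' @return List: `embeddings` (n x C matrix, `NA` rows for parse failures),
#'   `cosine` (n x n symmetric similarity matrix).
#' @export
export_embeddings <- function(model, smiles) {
  E <- matrix(NA_real_, length(smiles), model$config$model_dim)
  for (k in seq_along(smiles)) {
    prep <- tryCatch(prepare_molecule(model, smiles[k]),
                     error = function(e) e)
    if (inherits(prep, "error")) {
      warning("embedding failed for '", smiles[k], "': ",
              conditionMessage(prep))
      next
    }
    E[k, ] <- ag_value(forward_molecule(model, prep)$fused)
  }
  nrm <- sqrt(rowSums(E^2))
  C <- (E / nrm) %*% t(E / nrm)
  list(embeddings = E, cosine = C)
}

# recursively convert ag parameters <-> plain matrices
.params_to_plain <- function(x) {
  if (is_ag(x)) return(x$val)
  if (is.list(x)) return(lapply(x, .params_to_plain))
  x
}
.params_from_plain <- function(x) {
  if (is.matrix(x)) return(ag_param(x))
  if (is.list(x)) return(lapply(x, .params_from_plain))
  x
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files holding plain matrices plus the configuration,
#' vocabulary, knowledge base and task metadata.
#'
#' @param model A `crossmol_model`.
#' @param path Checkpoint file path.
#' @return `model_load()` returns a `crossmol_model`.
#' @export
model_save <- function(model, path) {
  stopifnot(inherits(model, "crossmol_model"))
  obj <- list(params = .params_to_plain(model$params),
              config = model$config, vocab = model$vocab, kb = model$kb,
              task_names = model$task_names, task_type = model$task_type)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  obj <- readRDS(path)
  m <- build_model(obj$config, obj$vocab, obj$kb, obj$task_names,
                   obj$task_type)
  m$params <- .params_from_plain(obj$params)
  m
}

#' Snapshot / restore parameter values in place (early stopping)
#' @keywords internal
.snapshot_params <- function(model) {
  lapply(collect_params(model$params), function(p) p$val)
}
.restore_params <- function(model, snap) {
  ps <- collect_params(model$params)
  for (k in seq_along(ps)) ps[[k]]$val <- snap[[k]]
  invisible(NULL)
}
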