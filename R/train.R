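# Training harness: metrics, Bemis-Murcko scaffold splits, minibatch Adam
# optimisation with early stopping, multi-seed evaluation reports.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midranks for ties.
#'
#' @param y Binary labels (0/1); `NA` pairs are dropped.
#' @param score Predicted scores.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when only one class is
#'   present.
#' @export
roc_auc <- function(y, score) {
  ok <- !is.na(y) & !is.na(score)
  y <- y[ok]; score <- score[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("roc_auc: only one class present; AUC undefined")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Regression error metrics
#' @param y Targets.
#' @param pred Predictions.
#' @return Scalar error.
#' @export
rmse <- function(y, pred) sqrt(mean((y - pred)^2, na.rm = TRUE))

#' @rdname rmse
#' @export
mae <- function(y, pred) mean(abs(y - pred), na.rm = TRUE)

#' Bemis-Murcko scaffold key of a molecule
#'
#' Iteratively prunes terminal (degree-1, non-ring) heavy atoms until only
#' ring systems and their linkers remain, then returns a canonical string
#' key for the remaining subgraph (element-coloured canonical permutation
#' via bliss).  Acyclic molecules return the empty scaffold `""`.
#'
#' @param smiles SMILES string.
#' @return Character scaffold key.
#' @export
scaffold_key <- function(smiles) {
  g <- parse_smiles(smiles, add_hydrogens = FALSE)
  keep <- rep(TRUE, g$n_nodes)
  e <- g$edges[g$edges$i < g$edges$j, , drop = FALSE]
  repeat {
    deg <- tabulate(c(e$i[keep[e$i] & keep[e$j]],
                      e$j[keep[e$i] & keep[e$j]]), nbins = g$n_nodes)
    drop <- keep & deg <= 1L & !g$nodes$in_ring
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  keep <- keep & g$nodes$in_ring | (keep & tabulate(
    c(e$i[keep[e$i] & keep[e$j]], e$j[keep[e$i] & keep[e$j]]),
    nbins = g$n_nodes) > 0L)
  if (!any(keep)) return("")
  idx <- which(keep)
  remap <- match(seq_len(g$n_nodes), idx)
  es <- e[keep[e$i] & keep[e$j], , drop = FALSE]
  ig <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(es))
    ig <- igraph::add_edges(ig, rbind(remap[es$i], remap[es$j]))
  colors <- as.integer(factor(g$nodes$element[idx],
                              levels = .element_symbols()))
  cp <- igraph::canonical_permutation(ig, colors = colors)$labeling
  inv <- order(cp)
  els <- g$nodes$element[idx][inv]
  if (nrow(es)) {
    a <- pmin(cp[remap[es$i]], cp[remap[es$j]])
    b <- pmax(cp[remap[es$i]], cp[remap[es$j]])
    o <- order(a, b)
    edge_str <- paste(a[o], b[o], es$order[o], sep = ":", collapse = ";")
  } else edge_str <- ""
  paste0(paste(els, collapse = ""), "|", edge_str)
}

#' Split a dataset into train/valid/test
#'
#' Scaffold splitting groups molecules by Bemis-Murcko scaffold and fills
#' the partitions largest-group-first (so test scaffolds are structurally
#' novel); random splitting shuffles records.  Partitions are disjoint and
#' exhaustive.
#'
#' @param ds A `property_dataset`.
#' @param method `"scaffold"` or `"random"`.
#' @param fractions Numeric length-3 vector summing to 1.
#' @param seed Integer seed (shuffles record order / group ties).
#' @return List of integer index vectors: `train`, `valid`, `test`.
#' @export
split_dataset <- function(ds, method = c("scaffold", "random"),
                          fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  method <- match.arg(method)
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  n <- length(ds$smiles)
  n_train <- round(fractions[1] * n)
  n_valid <- round(fractions[2] * n)
  if (method == "scaffold") {
    keys <- vapply(ds$smiles, scaffold_key, character(1), USE.NAMES = FALSE)
    groups <- split(seq_len(n), keys)
    if (length(groups) == 1L) {
      warning("all molecules share one scaffold; falling back to random split")
      method <- "random"
    } else {
      set.seed(seed)
      ord <- order(-vapply(groups, length, integer(1)),
                   stats::runif(length(groups)))
      groups <- groups[ord]
      train <- integer(0); valid <- integer(0); test <- integer(0)
      for (gset in groups) {
        if (length(train) + length(gset) <= n_train ||
            length(train) < n_train && length(valid) >= n_valid) {
          train <- c(train, gset)
        } else if (length(valid) + length(gset) <= n_valid ||
                   length(valid) < n_valid) {
          valid <- c(valid, gset)
        } else {
          test <- c(test, gset)
        }
      }
    }
  }
  if (method == "random") {
    set.seed(seed)
    ord <- sample.int(n)
    train <- ord[seq_len(n_train)]
    valid <- ord[n_train + seq_len(n_valid)]
    test <- ord[setdiff(seq_len(n), seq_len(n_train + n_valid))]
  }
  if (!length(train) || !length(valid) || !length(test))
    stop("split produced an empty partition (n = ", n, ")")
  list(train = sort(train), valid = sort(valid), test = sort(test))
}

# batch loss over prepared molecules; returns list(loss ag, preds matrix)
.batch_loss <- function(model, preps, y, mask, train = TRUE) {
  preds <- vector("list", length(preps))
  for (k in seq_along(preps))
    preds[[k]] <- forward_molecule(model, preps[[k]], train = train)$pred
  P <- ag_vcat(preds)
  loss <- if (model$task_type == "classification")
    loss_classification(y, P, mask)
  else {
    yy <- y; yy[!mask] <- ag_value(P)[!mask]  # masked cells contribute 0
    loss_regression(yy, P)
  }
  list(loss = loss, preds = ag_value(P))
}

.predict_preps <- function(model, preps) {
  out <- matrix(NA_real_, length(preps), length(model$task_names))
  for (k in seq_along(preps))
    out[k, ] <- ag_value(forward_molecule(model, preps[[k]])$pred)
  out
}

# higher-is-better validation score
.val_score <- function(model, preds, y, mask) {
  if (model$task_type == "classification") {
    aucs <- vapply(seq_len(ncol(y)), function(t) {
      suppressWarnings(roc_auc(ifelse(mask[, t], y[, t], NA), preds[, t]))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  } else {
    -rmse(ifelse(mask, y, NA), preds)
  }
}

#' Evaluate a model on a dataset
#'
#' Classification: per-task ROC-AUC over observed labels, macro-averaged
#' (single-class tasks are excluded with a warning).  Regression: RMSE and
#' MAE per task.
#'
#' @param model A `crossmol_model`.
#' @param ds A `property_dataset`.
#' @param preps Optional precomputed [prepare_molecule()] list.
#' @return List: `per_task` (named numeric), `aggregate`, `metric`,
#'   `n` (molecules evaluated), plus `mae` for regression.
#' @export
evaluate_model <- function(model, ds, preps = NULL) {
  if (is.null(preps))
    preps <- lapply(ds$smiles, function(s) prepare_molecule(model, s))
  preds <- .predict_preps(model, preps)
  y <- ds$y; mask <- ds$mask
  if (model$task_type == "classification") {
    per <- vapply(seq_len(ncol(y)), function(t) {
      yt <- ifelse(mask[, t], y[, t], NA)
      if (length(unique(stats::na.omit(yt))) < 2L) {
        warning("task '", ds$task_names[t],
                "' has a single class in this split; AUC excluded")
        return(NA_real_)
      }
      roc_auc(yt, preds[, t])
    }, numeric(1))
    names(per) <- ds$task_names
    list(metric = "roc_auc", per_task = per,
         aggregate = mean(per, na.rm = TRUE), n = nrow(y))
  } else {
    per <- vapply(seq_len(ncol(y)), function(t)
      rmse(ifelse(mask[, t], y[, t], NA), preds[, t]), numeric(1))
    perm <- vapply(seq_len(ncol(y)), function(t)
      mae(ifelse(mask[, t], y[, t], NA), preds[, t]), numeric(1))
    names(per) <- names(perm) <- ds$task_names
    list(metric = "rmse", per_task = per, aggregate = mean(per),
         mae = perm, n = nrow(y))
  }
}

.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Train one model on a fixed split
#'
#' Minibatch Adam with early stopping on the validation metric (macro
#' ROC-AUC maximised for classification, RMSE minimised for regression);
#' the best-epoch parameters are restored before returning.  A NaN loss
#' aborts training with an error (caught and logged per seed by
#' [crossmol_train()]).
#'
#' @param model A `crossmol_model`.
#' @param train_ds,valid_ds `property_dataset` splits.
#' @param verbose Print per-epoch metrics to stderr.
#' @param log_file Optional CSV path receiving per-epoch metrics.
#' @return The trained model (invisibly modified in place), with attributes
#'   `history` (data.frame epoch/loss/val) and `best_val`.
#' @export
fit_model <- function(model, train_ds, valid_ds, verbose = TRUE,
                      log_file = NULL) {
  cfg <- model$config
  tr_preps <- lapply(train_ds$smiles, function(s) prepare_molecule(model, s))
  va_keep <- va_preps <- list()
  for (s in valid_ds$smiles) {
    p <- tryCatch(prepare_molecule(model, s), error = function(e) e)
    if (inherits(p, "error")) next
    va_preps[[length(va_preps) + 1L]] <- p
    va_keep[[length(va_keep) + 1L]] <- s
  }
  if (length(va_preps) < length(valid_ds$smiles))
    warning("dropped ", length(valid_ds$smiles) - length(va_preps),
            " validation molecule(s) not covered by the vocabulary")
  va_idx <- match(unlist(va_keep), valid_ds$smiles)
  params <- collect_params(model$params)
  opt <- adam_init(params, lr = cfg$lr)
  best_val <- -Inf; best_snap <- .snapshot_params(model)
  since <- 0L
  history <- data.frame()
  n <- length(tr_preps)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      ag_zero_grad(params)
      bl <- .batch_loss(model, tr_preps[idx],
                        train_ds$y[idx, , drop = FALSE],
                        train_ds$mask[idx, , drop = FALSE])
      lv <- ag_value(bl$loss)[1]
      if (!is.finite(lv)) stop("training diverged (non-finite loss)")
      ag_backward(bl$loss)
      adam_step(opt, params)
      ep_loss <- ep_loss + lv; nb <- nb + 1L
    }
    va_pred <- .predict_preps(model, va_preps)
    val <- .val_score(model, va_pred,
                      valid_ds$y[va_idx, , drop = FALSE],
                      valid_ds$mask[va_idx, , drop = FALSE])
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / nb, val = val))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val %.4f", epoch,
                      ep_loss / nb, val))
    if (!is.null(log_file))
      utils::write.csv(history, log_file, row.names = FALSE)
    if (is.na(val)) val <- -Inf
    if (val > best_val + 1e-12) {
      best_val <- val
      best_snap <- .snapshot_params(model)
      since <- 0L
    } else {
      since <- since + 1L
      if (since > cfg$patience) break
    }
  }
  .restore_params(model, best_snap)
  attr(model, "history") <- history
  attr(model, "best_val") <- best_val
  model
}

#' End-to-end multi-seed training
#'
#' For each seed: split the dataset, mine the FCS vocabulary on the training
#' split, build the knowledge base and model, train with Adam and early
#' stopping, and evaluate on the test split.  Seeds where training diverges
#' are logged and excluded from the aggregate.
#'
#' @param dataset A `property_dataset`.
#' @param config A `crossmol_config`.
#' @param n_seeds Number of seeds (default `config$seeds`).
#' @param base_seed First seed value.
#' @param kb Optional prebuilt `knowledge_base` (default: bundled periodic
#'   table with `config$n_bins` bins and the bundled functional groups).
#' @param verbose Print progress.
#' @return Object of class `crossmol_report`: `per_seed` (data.frame with
#'   seed + aggregate metric), `per_task` (matrix), `mean`, `sd`, `metric`,
#'   `config_hash`, `model` (best-validation model across seeds),
#'   `failures` (character log of aborted seeds).
#' @export
crossmol_train <- function(dataset, config = crossmol_config(),
                           n_seeds = config$seeds, base_seed = 1L,
                           kb = NULL, verbose = TRUE) {
  stopifnot(inherits(dataset, "property_dataset"))
  if (is.null(kb)) kb <- build_knowledge_base(n_bins = config$n_bins)
  per_seed <- numeric(0)
  per_task <- NULL
  failures <- character(0)
  best_model <- NULL; best_val <- -Inf
  for (k in seq_len(n_seeds)) {
    seed <- base_seed + k - 1L
    set.seed(seed)
    res <- tryCatch({
      sp <- split_dataset(dataset, config$split, config$fractions, seed)
      tr <- dataset[sp$train]; va <- dataset[sp$valid]; te <- dataset[sp$test]
      vocab <- mine_vocabulary(tr$smiles, config$min_freq,
                               config$max_token_len, config$max_vocab)
      model <- build_model(config, vocab, kb, dataset$task_names,
                           dataset$task_type)
      model <- fit_model(model, tr, va, verbose = verbose)
      te_keep <- vapply(te$smiles, function(s)
        !inherits(tryCatch(fcs_tokenize(s, vocab), error = function(e) e),
                  "error"), logical(1), USE.NAMES = FALSE)
      ev <- evaluate_model(model, te[which(te_keep)])
      list(model = model, ev = ev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("seed %d: %s", seed,
                                      conditionMessage(res)))
      if (verbose) message("seed ", seed, " failed: ", conditionMessage(res))
      next
    }
    per_seed <- c(per_seed, stats::setNames(res$ev$aggregate,
                                            as.character(seed)))
    per_task <- rbind(per_task, res$ev$per_task)
    if (attr(res$model, "best_val") > best_val) {
      best_val <- attr(res$model, "best_val")
      best_model <- res$model
    }
    if (verbose)
      message(sprintf("seed %d: test %s = %.4f", seed, res$ev$metric,
                      res$ev$aggregate))
  }
  structure(list(
    per_seed = data.frame(seed = as.integer(names(per_seed)),
                          value = unname(per_seed)),
    per_task = per_task,
    mean = mean(per_seed), sd = stats::sd(per_seed),
    metric = if (dataset$task_type == "classification") "roc_auc" else "rmse",
    config_hash = .config_hash(config),
    model = best_model, failures = failures),
    class = "crossmol_report")
}

#' @export
print.crossmol_report <- function(x, ...) {
  cat(sprintf("<crossmol_report> %s = %.4f +/- %s over %d seed(s) [cfg %s]\n",
              x$metric, x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.4f", x$sd),
              nrow(x$per_seed), x$config_hash))
  if (length(x$failures)) cat("failures:", length(x$failures), "\n")
  invisible(x)
}
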