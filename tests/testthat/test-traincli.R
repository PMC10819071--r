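# Splits, metrics, training loop behaviour, ablations, embeddings, CLI.

test_that("ROC-AUC matches the rank-based oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)  # constant scores
  # 4-point hand example via Mann-Whitney pair counting:
  # positives (0.9, 0.2) vs negatives (0.3, 0.1): 3 of 4 pairs correct
  expect_equal(roc_auc(c(0, 1, 1, 0), c(0.3, 0.9, 0.2, 0.1)), 0.75)
  expect_warning(a <- roc_auc(c(1, 1), c(0.2, 0.4)), "one class")
  expect_true(is.na(a))
})

test_that("random splits have the documented sizes and are reproducible", {
  ds <- property_dataset(sprintf("C%sO", strrep("C", 1:10)),
                         matrix(rep(0:1, 5)), validate = FALSE)
  sp <- split_dataset(ds, "random", c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(lengths(sp), c(train = 8L, valid = 1L, test = 1L))
  expect_setequal(unlist(sp), 1:10)
  expect_identical(sp, split_dataset(ds, "random", c(0.8, 0.1, 0.1), seed = 3))
})

test_that("scaffold splits keep scaffolds together and degrade gracefully", {
  smis <- c("c1ccccc1O", "c1ccccc1N", "c1ccccc1C",       # benzene
            "C1CCCCC1O", "C1CCCCC1N",                    # cyclohexane
            "C1CCOC1O", "C1CCOC1N",                      # THF
            "CCCCO", "CCCCN", "CCCC")                    # acyclic -> ""
  ds <- property_dataset(smis, matrix(rep(0:1, 5)), validate = FALSE)
  keys <- vapply(smis, scaffold_key, character(1))
  expect_equal(length(unique(keys)), 4L)
  expect_true(all(keys[8:10] == ""))
  sp <- split_dataset(ds, "scaffold", c(0.6, 0.2, 0.2), seed = 1)
  for (key in unique(keys)) {
    members <- which(keys == key)
    where <- vapply(members, function(m)
      which(vapply(sp, function(part) m %in% part, logical(1))), integer(1))
    expect_equal(length(unique(where)), 1L, info = key)
  }
  one <- property_dataset(rep(c("c1ccccc1O", "c1ccccc1N", "c1ccccc1C"), 4),
                          matrix(rep(0:1, 6)), validate = FALSE)
  expect_warning(split_dataset(one, "scaffold", seed = 1), "one scaffold")
  expect_error(split_dataset(ds[1:2], "random", c(0.8, 0.1, 0.1), 1),
               "empty partition")
})

test_that("scaffold keys are invariant to SMILES atom order", {
  expect_identical(scaffold_key("c1ccccc1CCO"), scaffold_key("OCCc1ccccc1"))
  expect_identical(scaffold_key("C1CCNCC1C"), scaffold_key("CC1CCNCC1"))
  expect_false(scaffold_key("c1ccccc1") == scaffold_key("C1CCCCC1"))
})

test_that("patience 0 stops exactly one epoch after the first plateau", {
  set.seed(41)
  ds <- generate_fixture(fixture_spec(n_molecules = 24L, seed = 5))
  cfg <- tiny_config(max_epochs = 10L, patience = 0L, lr = 0)  # frozen model
  sp <- split_dataset(ds, "random", c(0.7, 0.15, 0.15), 1)
  vocab <- mine_vocabulary(ds$smiles, min_freq = 1)
  model <- build_model(cfg, vocab, test_kb(), ds$task_names, ds$task_type)
  model <- fit_model(model, ds[sp$train], ds[sp$valid], verbose = FALSE)
  h <- attr(model, "history")
  expect_equal(nrow(h), 2L)   # epoch 1 improves on -Inf; epoch 2 plateaus
})

test_that("multi-seed training reports one entry per seed", {
  set.seed(42)
  ds <- generate_fixture(fixture_spec(n_molecules = 40L, seed = 6))
  cfg <- tiny_config(max_epochs = 2L, patience = 2L)
  rep <- crossmol_train(ds, cfg, n_seeds = 2L, base_seed = 11L,
                        verbose = FALSE)
  expect_s3_class(rep, "crossmol_report")
  expect_equal(nrow(rep$per_seed), 2L)
  expect_equal(rep$per_seed$seed, c(11L, 12L))
  expect_true(is.finite(rep$mean))
  expect_match(rep$config_hash, "^[0-9a-f]{8}$")
  expect_s3_class(rep$model, "crossmol_model")
})

test_that("the stated experimental defaults are encoded in the config", {
  cfg <- crossmol_config()
  expect_equal(cfg$lr, 1e-4)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$max_epochs, 100L)
  expect_equal(cfg$seeds, 10L)
  expect_equal(cfg$model_dim, 128L)
  expect_equal(cfg$n_heads, 8L)
})

test_that("evaluation excludes single-class tasks with a warning", {
  set.seed(43)
  ds <- generate_fixture(fixture_spec(n_molecules = 20L, seed = 7))
  cfg <- tiny_config()
  vocab <- mine_vocabulary(ds$smiles, min_freq = 1)
  model <- build_model(cfg, vocab, test_kb(), c("a", "b"), "classification")
  ds2 <- property_dataset(ds$smiles,
                          cbind(ds$y, rep(1, 20)), c("a", "b"),
                          "classification", validate = FALSE)
  expect_warning(ev <- evaluate_model(model, ds2), "single class")
  expect_true(is.na(ev$per_task[["b"]]))
  expect_false(is.na(ev$aggregate))
})

test_that("ablation modes train only their own encoder parameters", {
  set.seed(44)
  kb <- test_kb()
  vocab <- mine_vocabulary(c("CCO", "OCCO", "CCN"), min_freq = 1)
  for (ab in c("no_graph", "no_sequence")) {
    cfg <- tiny_config(ablation = ab)
    model <- build_model(cfg, vocab, kb, "y", "classification")
    prep <- prepare_molecule(model, "CCO")
    params <- collect_params(model$params)
    ag_zero_grad(params)
    out <- forward_molecule(model, prep, train = TRUE)
    ag_backward(loss_classification(matrix(1), out$pred))
    unused <- if (ab == "no_graph") "graph" else "seq"
    used <- if (ab == "no_graph") "seq" else "graph"
    expect_true(all(vapply(collect_params(model$params[[unused]]),
                           function(p) is.null(p$grad), logical(1))))
    expect_true(any(vapply(collect_params(model$params[[used]]),
                           function(p) !is.null(p$grad), logical(1))))
  }
})

test_that("embeddings export gives a valid cosine-similarity table", {
  set.seed(45)
  cfg <- tiny_config()
  vocab <- mine_vocabulary(c("CCO", "OCCO", "CCN", "c1ccccc1"), min_freq = 1)
  model <- build_model(cfg, vocab, test_kb(), "y", "classification")
  em <- export_embeddings(model, c("CCO", "OCCO", "c1ccccc1"))
  expect_equal(dim(em$embeddings), c(3L, cfg$model_dim))
  expect_equal(diag(em$cosine), rep(1, 3), tolerance = 1e-12)
  expect_equal(em$cosine, t(em$cosine), tolerance = 1e-12)
  expect_true(all(em$cosine >= -1 - 1e-9 & em$cosine <= 1 + 1e-9))
  expect_warning(em2 <- export_embeddings(model, c("CCO", "C(")),
                 "C\\(")
  expect_true(all(is.na(em2$embeddings[2, ])))
})

test_that("checkpoints round-trip through model_save / model_load", {
  set.seed(46)
  cfg <- tiny_config()
  vocab <- mine_vocabulary(c("CCO", "OCCO"), min_freq = 1)
  model <- build_model(cfg, vocab, test_kb(), "y", "classification")
  pred1 <- predict_molecules(model, "CCO")
  tmp <- withr::local_tempfile(fileext = ".rds")
  model_save(model, tmp)
  model2 <- model_load(tmp)
  expect_equal(predict_molecules(model2, "CCO"), pred1, tolerance = 1e-12)
})

test_that("CLI subcommands run end to end", {
  dir <- withr::local_tempdir()
  out_csv <- file.path(dir, "fix.csv")
  expect_message(cli_main(c("make-fixtures", "--n", "20", "--seed", "3",
                            "--out", out_csv)), "wrote 20")
  ds <- load_dataset(out_csv, task_columns = "hydroxyl")
  expect_equal(length(ds$smiles), 20L)
  # augment prints JSON with virtual nodes
  js <- capture.output(cli_main(c("augment", "--smiles", "CCO")))
  parsed <- jsonlite::fromJSON(paste(js, collapse = ""))
  expect_true(nrow(parsed$virtual_nodes) > 0)
  # tokenize with a vocabulary mined from the fixture data
  toks <- capture.output(cli_main(c("tokenize", "--smiles", "CCO",
                                    "--data", out_csv)))
  expect_equal(gsub(" ", "", paste(toks, collapse = "")), "CCO")
})
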