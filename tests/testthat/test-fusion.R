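# Cross-attention fusion, decoder and losses.

fcfg <- fusion_config(model_dim = 8L, n_heads = 2L)

test_that("a one-element memory receives attention weight exactly 1", {
  set.seed(31)
  p <- fusion_init(1L, fcfg)
  seq_states <- ag(matrix(rnorm(3 * 8), 3, 8))
  gvec <- ag(matrix(rnorm(8), 1, 8))
  out <- cross_attend(p, seq_states, gvec, fcfg)
  expect_true(all(out$weights == 1))
  expect_equal(dim(ag_value(out$fused)), c(1L, 8L))
})

test_that("with identity output projection the fused vector is the V
           projection of the graph embedding", {
  set.seed(32)
  p <- fusion_init(1L, fcfg)
  d <- 8L
  p$Wo$val <- diag(d); p$bo$val <- matrix(0, 1, d)
  gvec <- matrix(rnorm(d), 1, d)
  # q = 1 zero sequence embedding and zero query bias: scores are 0, the
  # singleton softmax is 1, and each head emits its V slice unchanged
  p$bq$val <- matrix(0, 1, d)
  out <- cross_attend(p, ag(matrix(0, 1, d)), ag(gvec), fcfg)
  vproj <- gvec %*% ag_value(p$Wv) + ag_value(p$bv)
  expect_equal(ag_value(out$fused), vproj, tolerance = 1e-12)
})

test_that("two-query toy attention matches hand matrix arithmetic", {
  set.seed(33)
  cfg1 <- fusion_config(model_dim = 4L, n_heads = 2L)
  p <- fusion_init(1L, cfg1)
  S <- matrix(rnorm(8), 2, 4)
  G <- matrix(rnorm(8), 2, 4)    # two-row memory exercises real softmax
  out <- cross_attend(p, ag(S), ag(G), cfg1)
  v <- function(x) ag_value(x)
  Q <- S %*% v(p$Wq) + v(p$bq)[rep(1, 2), ]
  K <- G %*% v(p$Wk) + v(p$bk)[rep(1, 2), ]
  V <- G %*% v(p$Wv) + v(p$bv)[rep(1, 2), ]
  att <- NULL
  for (hh in 1:2) {
    idx <- ((hh - 1) * 2 + 1):(hh * 2)
    Z <- Q[, idx] %*% t(K[, idx]) / sqrt(2)
    A <- t(apply(Z, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
    att <- cbind(att, A %*% V[, idx])
  }
  expected <- att %*% v(p$Wo) + v(p$bo)[rep(1, 2), ]
  expect_equal(ag_value(out$attended), expected, tolerance = 1e-10)
  expect_equal(ag_value(out$fused), colMeans(expected) |> matrix(nrow = 1),
               tolerance = 1e-10)
})

test_that("cross-attention rejects mismatched widths", {
  p <- fusion_init(1L, fcfg)
  expect_error(cross_attend(p, ag(matrix(0, 2, 4)), ag(matrix(0, 1, 8)),
                            fcfg), "dimension mismatch")
})

test_that("decoder emits one bounded output per classification task", {
  set.seed(34)
  p <- fusion_init(3L, fcfg)
  fused <- ag(matrix(rnorm(8), 1, 8))
  out <- ag_value(decode(p, fused, "classification"))
  expect_equal(dim(out), c(1L, 3L))
  expect_true(all(out > 0 & out < 1))
  reg <- ag_value(decode(p, fused, "regression"))
  expect_equal(dim(reg), c(1L, 3L))
})

test_that("an identity-constructed decoder reproduces leading components", {
  d <- 8L; h2 <- 4L
  p <- fusion_init(2L, fcfg)
  p$dec$W1$val <- diag(d); p$dec$b1$val <- matrix(0, 1, d)
  p$dec$W2$val <- diag(d)[, 1:h2]; p$dec$b2$val <- matrix(0, 1, h2)
  p$dec$W3$val <- diag(h2)[, 1:2]; p$dec$b3$val <- matrix(0, 1, 2)
  x <- matrix(abs(rnorm(d)) + 0.1, 1, d)    # positive: ReLU transparent
  out <- ag_value(decode(p, ag(x), "regression"))
  expect_equal(as.numeric(out), x[1, 1:2], tolerance = 1e-12)
})

test_that("binary cross-entropy matches its closed forms", {
  expect_lt(ag_value(loss_classification(matrix(1), ag(matrix(1 - 1e-9))))[1],
            1e-6)
  # y = (1, 0), x = (0.5, 0.5): mean BCE = -ln 0.5
  L <- loss_classification(matrix(c(1, 0), 1), ag(matrix(c(0.5, 0.5), 1)))
  expect_equal(ag_value(L)[1], -log(0.5), tolerance = 1e-9)
  # clamping keeps the worst case finite
  Lw <- loss_classification(matrix(1), ag(matrix(0)))
  expect_true(is.finite(ag_value(Lw)[1]))
  # masked entries never contribute
  Lm <- loss_classification(matrix(c(1, NA), 1), ag(matrix(c(0.5, 0.9), 1)))
  expect_equal(ag_value(Lm)[1], -log(0.5), tolerance = 1e-9)
  expect_warning(L0 <- loss_classification(matrix(NA_real_), ag(matrix(0.4))),
                 "masked")
  expect_equal(ag_value(L0)[1], 0)
})

test_that("RMSE loss matches closed form and is absolutely homogeneous", {
  expect_equal(ag_value(loss_regression(c(1, 2), ag(matrix(c(1, 2)))))[1], 0)
  L <- loss_regression(c(0, 0), ag(matrix(c(3, 4))))
  expect_equal(ag_value(L)[1], sqrt((9 + 16) / 2), tolerance = 1e-9)
  expect_equal(ag_value(L)[1], 3.5355339, tolerance = 1e-6)
  y <- c(0.3, -1); x <- c(1.1, 0.4)
  l1 <- ag_value(loss_regression(y, ag(matrix(x))))[1]
  l3 <- ag_value(loss_regression(-3 * y, ag(matrix(-3 * x))))[1]
  expect_equal(l3, 3 * l1, tolerance = 1e-10)
  expect_error(loss_regression(numeric(0), ag(matrix(0, 0, 1))), "no targets")
})

test_that("one optimisation step sends gradients to every parameter group", {
  set.seed(35)
  kb <- test_kb()
  cfg <- tiny_config()
  # characters-only vocabulary keeps q > 1 so self-attention is non-trivial
  vocab <- mine_vocabulary(c("CCO", "CCN", "OCCO"), min_freq = 1,
                           max_token_len = 1)
  model <- build_model(cfg, vocab, kb, "y", "classification")
  prep <- prepare_molecule(model, "CCO")
  params <- collect_params(model$params)
  ag_zero_grad(params)
  out <- forward_molecule(model, prep, train = TRUE)
  L <- loss_classification(matrix(1), out$pred)
  ag_backward(L)
  for (group in c("seq", "graph", "fus")) {
    gp <- collect_params(model$params[[group]])
    got <- vapply(gp, function(p) !is.null(p$grad) && any(p$grad != 0),
                  logical(1))
    # the contract is per encoder/fusion group: each must receive signal
    # (individual tensors can stay at zero, e.g. the query/key projections
    # when the one-element graph memory makes attention weights constant)
    expect_true(any(got), info = group)
  }
  # the sequence trunk itself learns (embeddings, attention, feed-forward)
  seq_got <- vapply(collect_params(model$params$seq),
                    function(p) !is.null(p$grad) && any(p$grad != 0),
                    logical(1))
  expect_gt(mean(seq_got), 0.9)
})
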