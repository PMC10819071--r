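# Graph encoder: attention coefficients, dual-channel message passing, GRU
# updates, Set2Set readout.  The reference implementation below recomputes
# one round with plain per-node loops, independently of the vectorised
# encoder.

acfg <- ampnn_config(hidden_dim = 8L, rounds = 1L, set2set_steps = 2L)
# reference_message_pass() and path3_tensors() live in helper-crossmol.R
# (shared with the acceptance suite)

test_that("attention coefficients match direct softmax evaluation", {
  set.seed(21)
  f <- 4L
  W <- matrix(rnorm(f * f, sd = 0.3), f, f)
  a <- rnorm(2 * f, sd = 0.3)
  hr <- rnorm(f)
  # single neighbour: weight exactly 1
  expect_equal(attention_coefficients(hr, matrix(rnorm(f), 1), W, a), 1)
  # two identical neighbours: symmetry forces 0.5 / 0.5
  nb <- matrix(rnorm(f), 1)
  expect_equal(attention_coefficients(hr, rbind(nb, nb), W, a),
               c(0.5, 0.5), tolerance = 1e-12)
  # three random neighbours vs hand-computed scores
  nbs <- matrix(rnorm(3 * f, sd = 0.5), 3)
  got <- attention_coefficients(hr, nbs, W, a)
  scores <- sapply(1:3, function(u) {
    z <- sum(a * c(nbs[u, ] %*% W, hr %*% W))
    ifelse(z > 0, z, 0.2 * z)
  })
  expect_equal(got, exp(scores) / sum(exp(scores)), tolerance = 1e-10)
  expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("one round on a 3-node path matches the brute-force reference", {
  set.seed(22)
  kb <- test_kb()
  p <- ampnn_init(kb_label_vocab(kb), acfg)
  tz <- path3_tensors()
  enc <- ampnn_encode(p, tz, acfg)
  ref <- reference_message_pass(p, tz, acfg, rounds = 1L)
  expect_equal(ag_value(enc$node_states), ref, tolerance = 1e-10)
})

test_that("multiple rounds on an augmented graph match the reference", {
  set.seed(23)
  kb <- test_kb()
  lv <- kb_label_vocab(kb)
  cfg2 <- ampnn_config(hidden_dim = 8L, rounds = 3L, set2set_steps = 2L)
  p <- ampnn_init(lv, cfg2)
  aug <- augment_graph(parse_smiles("CC(=O)O", add_hydrogens = TRUE), kb)
  tz <- augmented_tensors(aug, lv)
  enc <- ampnn_encode(p, tz, cfg2)
  ref <- reference_message_pass(p, tz, cfg2, rounds = 3L)
  expect_equal(ag_value(enc$node_states), ref, tolerance = 1e-8)
  # mean aggregation follows the same contract
  cfgm <- ampnn_config(hidden_dim = 8L, rounds = 2L, set2set_steps = 2L,
                       aggregate = "mean")
  pm <- ampnn_init(lv, cfgm)
  expect_equal(ag_value(ampnn_encode(pm, tz, cfgm)$node_states),
               reference_message_pass(pm, tz, cfgm, rounds = 2L),
               tolerance = 1e-8)
})

test_that("attention weights normalise per receiver within each channel", {
  set.seed(24)
  kb <- test_kb()
  lv <- kb_label_vocab(kb)
  p <- ampnn_init(lv, acfg)
  aug <- augment_graph(parse_smiles("OCCO", add_hydrogens = TRUE), kb)
  tz <- augmented_tensors(aug, lv)
  enc <- ampnn_encode(p, tz, acfg)
  asum <- rowsum(enc$alpha, tz$r_prop)
  expect_true(all(abs(asum - 1) < 1e-9))
  bsum <- rowsum(enc$beta, tz$r_atom)
  expect_true(all(abs(bsum - 1) < 1e-9))
  expect_true(all(enc$alpha >= 0 & enc$alpha <= 1))
  expect_true(all(enc$beta >= 0 & enc$beta <= 1))
})

test_that("degenerate graphs stay finite and symmetric atoms stay equal", {
  set.seed(25)
  kb <- test_kb()
  p <- ampnn_init(kb_label_vocab(kb), acfg)
  # isolated single atom, no edges at all: GRU of a zero message
  tz1 <- list(n_atoms = 1L, n = 1L, X = atom_features(parse_smiles("C")),
              s_atom = integer(0), r_atom = integer(0),
              B = matrix(0, 0, 6), s_prop = integer(0), r_prop = integer(0),
              rel_ids = integer(0), label_ids = integer(0))
  enc1 <- ampnn_encode(p, tz1, acfg)
  expect_true(all(is.finite(ag_value(enc1$node_states))))
  expect_true(all(is.finite(ag_value(enc1$graph_embedding))))
  # two equivalent atoms (ethane): automorphism-equivariant states
  g2 <- parse_smiles("CC")
  tz2 <- list(n_atoms = 2L, n = 2L, X = atom_features(g2),
              s_atom = g2$edges$i, r_atom = g2$edges$j,
              B = bond_features(g2), s_prop = integer(0),
              r_prop = integer(0), rel_ids = integer(0),
              label_ids = integer(0))
  h2 <- ag_value(ampnn_encode(p, tz2, acfg)$node_states)
  expect_equal(h2[1, ], h2[2, ], tolerance = 1e-12)
})

test_that("with no virtual nodes the property channel is inert", {
  set.seed(26)
  kb <- test_kb()
  p <- ampnn_init(kb_label_vocab(kb), acfg)
  tz <- path3_tensors()
  e1 <- ag_value(ampnn_encode(p, tz, acfg)$graph_embedding)
  # perturb property-channel parameters; result must not move
  p$ch_prop$W_att$val <- p$ch_prop$W_att$val + 100
  p$ch_prop$W_edge$val <- p$ch_prop$W_edge$val - 50
  e2 <- ag_value(ampnn_encode(p, tz, acfg)$graph_embedding)
  expect_identical(e1, e2)
})

test_that("Set2Set readout matches a hand-unrolled recurrence and is
           permutation-invariant", {
  set.seed(27)
  f <- 4L
  p <- list(W = ag_param(glorot(2 * f, 4 * f)),
            U = ag_param(glorot(f, 4 * f)),
            b = ag_param(matrix(rnorm(4 * f, sd = 0.1), 1, 4 * f)))
  M <- matrix(rnorm(3 * f), 3, f)
  got <- ag_value(set2set_readout(p, ag(M), steps = 2L, f = f))
  # manual unroll, T = 2
  sig <- function(x) 1 / (1 + exp(-x))
  qs <- matrix(0, 1, 2 * f); hl <- matrix(0, 1, f); cl <- matrix(0, 1, f)
  for (t in 1:2) {
    gates <- qs %*% ag_value(p$W) + hl %*% ag_value(p$U) + ag_value(p$b)
    i <- sig(gates[, 1:f]); fo <- sig(gates[, f + 1:f])
    o <- sig(gates[, 2 * f + 1:f]); gg <- tanh(gates[, 3 * f + 1:f])
    cl <- fo * cl + i * gg
    hl <- matrix(o * tanh(cl), 1)
    sc <- as.numeric(M %*% t(hl))
    a <- exp(sc - max(sc)); a <- a / sum(a)
    qs <- cbind(hl, matrix(a, 1) %*% M)
  }
  expect_equal(got, qs, tolerance = 1e-10)
  # permutation invariance of the readout
  perm <- c(3, 1, 2)
  got_p <- ag_value(set2set_readout(p, ag(M[perm, ]), steps = 2L, f = f))
  expect_equal(got, got_p, tolerance = 1e-10)
  # single-row memory: attention weight is exactly 1 at every step, so the
  # readout half of the output equals that row
  got1 <- ag_value(set2set_readout(p, ag(M[1, , drop = FALSE]),
                                   steps = 2L, f = f))
  expect_equal(got1[1, (f + 1):(2 * f)], M[1, ], tolerance = 1e-12)
})

test_that("full-graph embedding is invariant to atom reordering", {
  set.seed(28)
  kb <- test_kb()
  lv <- kb_label_vocab(kb)
  p <- ampnn_init(lv, acfg)
  aug <- augment_graph(parse_smiles("CC(=O)O", add_hydrogens = TRUE), kb)
  tz <- augmented_tensors(aug, lv)
  e1 <- ag_value(ampnn_encode(p, tz, acfg)$graph_embedding)
  # permute atom rows and remap all edge endpoints
  na <- tz$n_atoms
  perm <- sample(na)              # new order: row k holds old atom perm[k]
  inv <- order(perm)
  tz2 <- tz
  tz2$X <- tz$X[perm, , drop = FALSE]
  remap <- function(idx) ifelse(idx <= na, inv[idx], idx)
  tz2$s_atom <- remap(tz$s_atom); tz2$r_atom <- remap(tz$r_atom)
  tz2$s_prop <- tz$s_prop; tz2$r_prop <- remap(tz$r_prop)
  e2 <- ag_value(ampnn_encode(p, tz2, acfg)$graph_embedding)
  expect_equal(e1, e2, tolerance = 1e-8)
})
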