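# Shared test utilities: scaled-down configurations (full-size defaults are
# exercised for their values, not trained), a cached knowledge base, and a
# finite-difference gradient checker.

tiny_config <- function(...) {
  base <- list(model_dim = 16L, n_heads = 2L, n_layers = 1L, rounds = 2L,
               set2set_steps = 2L, dropout = 0, lr = 1e-3,
               batch_size = 16L, max_epochs = 3L, patience = 3L,
               min_freq = 2L, max_vocab = 48L, split = "random")
  do.call(crossmol_config, utils::modifyList(base, list(...)))
}

test_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- build_knowledge_base()
    kb
  }
})

# enumerated scaffold x decoration (x alkyl prefix) corpus: deterministic,
# all strings parse, several thousand distinct molecules available
enumerate_smiles <- function(n = 200L) {
  scaffolds <- crossmol:::.fixture_scaffolds
  decos <- c("", unname(crossmol:::.fixture_decorations))
  out <- character(0)
  for (pre in c("", "C", "CC", "CCC")) {
    for (d1 in decos) for (d2 in decos) for (sc in scaffolds) {
      out <- c(out, paste0(pre, crossmol:::.instantiate(sc, c(d1, d2))))
      if (length(out) >= 4L * n) {
        u <- unique(out)
        if (length(u) >= n) return(u[seq_len(n)])
      }
    }
  }
  u <- unique(out)
  u[seq_len(min(n, length(u)))]
}

# independent brute-force reference for K rounds of message passing:
# straight per-node loops over the attention, gating, aggregation and GRU
# update rules, no autodiff machinery involved
reference_message_pass <- function(params, tz, cfg, rounds) {
  v <- function(p) ag_value(p)
  f <- cfg$hidden_dim
  h <- v(params$b_in)[rep(1, tz$n_atoms), , drop = FALSE] +
    tz$X %*% v(params$W_in)
  if (tz$n > tz$n_atoms)
    h <- rbind(h, v(params$label_embed)[tz$label_ids, , drop = FALSE])
  he_at <- if (length(tz$s_atom)) tz$B %*% v(params$W_bond)
  he_pr <- if (length(tz$s_prop))
    v(params$rel_embed)[tz$rel_ids, , drop = FALSE]
  sig <- function(x) 1 / (1 + exp(-x))
  for (k in seq_len(rounds)) {
    m <- matrix(0, tz$n, f)
    for (i in seq_len(tz$n)) {
      for (ch in c("prop", "atom")) {
        if (ch == "prop") {
          eidx <- which(tz$r_prop == i); s <- tz$s_prop[eidx]
          he <- he_pr; cp <- params$ch_prop
        } else {
          eidx <- which(tz$r_atom == i); s <- tz$s_atom[eidx]
          he <- he_at; cp <- params$ch_atom
        }
        if (!length(eidx)) next
        al <- attention_coefficients(h[i, ], h[s, , drop = FALSE],
                                     v(cp$W_att), v(cp$a_att),
                                     cfg$leaky_slope)
        agg <- numeric(f)
        for (e in seq_along(eidx)) {
          msg <- sig(al[e] * (he[eidx[e], ] %*% v(cp$W_edge))) * h[s[e], ]
          agg <- agg + msg
        }
        if (cfg$aggregate == "mean") agg <- agg / length(eidx)
        m[i, ] <- m[i, ] + agg
      }
    }
    g <- lapply(params$gru, ag_value)
    z <- sig(m %*% g$Wz + h %*% g$Uz + g$bz[rep(1, tz$n), ])
    r <- sig(m %*% g$Wr + h %*% g$Ur + g$br[rep(1, tz$n), ])
    ht <- tanh(m %*% g$Wh + (r * h) %*% g$Uh + g$bh[rep(1, tz$n), ])
    h <- (1 - z) * h + z * ht
  }
  h
}

# heavy-atom 3-node path graph (no virtual nodes)
path3_tensors <- function() {
  g <- parse_smiles("CCO")
  list(n_atoms = 3L, n = 3L, X = atom_features(g),
       s_atom = g$edges$i, r_atom = g$edges$j, B = bond_features(g),
       s_prop = integer(0), r_prop = integer(0), rel_ids = integer(0),
       label_ids = integer(0))
}

num_grad <- function(fun, params, eps = 1e-5) {
  lapply(params, function(p) {
    G <- p$val * 0
    for (k in seq_along(p$val)) {
      v0 <- p$val[k]
      p$val[k] <- v0 + eps; f1 <- fun()
      p$val[k] <- v0 - eps; f2 <- fun()
      p$val[k] <- v0
      G[k] <- (f1 - f2) / (2 * eps)
    }
    G
  })
}

expect_grad_matches <- function(loss_fn, params, tol = 1e-6) {
  ag_zero_grad(params)
  L <- loss_fn()
  ag_backward(L)
  ng <- num_grad(function() ag_value(loss_fn())[1], params)
  for (k in seq_along(params)) {
    g <- params[[k]]$grad
    if (is.null(g)) g <- 0 * ng[[k]]
    expect_lt(max(abs(g - ng[[k]])), tol)
  }
}
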