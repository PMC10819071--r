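# SMILES parsing and molecular graph construction.
#
# No cheminformatics toolkit is available to R in this stack, so the parser
# is implemented here for the common organic subset of SMILES: organic-subset
# atoms (B C N O P S F Cl Br I), aromatic lowercase atoms, bracket atoms with
# charge and explicit hydrogen counts, branches, ring closures (including
# %nn), bond symbols - = # : / \ and dot-separated components.  Isotope and
# stereo annotations inside brackets are accepted and ignored (stereochemistry
# is out of scope).  Parsed graphs were validated against RDKit on a fixture
# corpus during development; frozen oracle values live in the test suite.

.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)
# alternative valences tried in increasing order when bonds exceed the default
.alt_valences <- list(N = c(3, 5), S = c(2, 4, 6), P = c(3, 5))

.organic_subset <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into lexical tokens: atoms (organic subset,
#' two-letter halogens, aromatic lowercase, full bracket expressions),
#' bond symbols, branch parentheses, ring-closure digits and `%nn` pairs,
#' and dots.  Multi-character atoms (`Cl`, `Br`, `[...]`) are kept as single
#' tokens so downstream consumers never split an element symbol.
#'
#' @param smiles SMILES string.
#' @return Character vector of tokens.
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("SMILES parse error in '", smiles, "': unclosed bracket atom")
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[i + 1:2], collapse = "")))
        stop("SMILES parse error in '", smiles, "': bad %nn ring closure")
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        tokens <- c(tokens, two)
        i <- i + 2L
      } else {
        tokens <- c(tokens, ch)
        i <- i + 1L
      }
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

.parse_bracket_atom <- function(tok, smiles) {
  body <- sub("^\\[", "", sub("\\]$", "", tok))
  m <- regexec(
    "^([0-9]*)([A-Z][a-z]?|[bcnops]|\\*)(@{0,2})(H([0-9]*))?(\\+{1,3}|-{1,3})?([0-9]*)$",
    body)
  parts <- regmatches(body, m)[[1]]
  if (length(parts) == 0L)
    stop("SMILES parse error in '", smiles, "': cannot read bracket atom '", tok, "'")
  sym <- parts[3]
  aromatic <- sym %in% .aromatic_organic
  element <- if (aromatic) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
  if (element != "*" && !element %in% .element_symbols())
    stop("SMILES parse error in '", smiles, "': unknown element '", element,
         "' in bracket atom '", tok, "'")
  hcount <- 0L
  if (nzchar(parts[5])) hcount <- if (nzchar(parts[6])) as.integer(parts[6]) else 1L
  charge <- 0L
  cs <- parts[7]
  if (nzchar(cs)) {
    sign <- if (substr(cs, 1, 1) == "+") 1L else -1L
    mag <- if (nzchar(parts[8])) as.integer(parts[8]) else nchar(cs)
    charge <- sign * mag
  }
  list(element = element, aromatic = aromatic, hcount = hcount,
       charge = charge, h_explicit = nzchar(parts[5]))
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds an undirected molecular graph represented with directed edge
#' records: every bond appears twice, as (i, j) and (j, i), with identical
#' bond features.  Node indices are 1-based and contiguous.  Hydrogens are
#' implicit by default; with `add_hydrogens = TRUE` every implicit or
#' bracket-specified hydrogen becomes an explicit graph node (required for
#' functional-group patterns that reference H atoms).
#'
#' @param smiles SMILES string (non-empty).
#' @param add_hydrogens Logical; add explicit hydrogen nodes.
#' @return An object of class `molecular_graph`: list with `nodes`
#'   (data.frame: element, aromatic, charge, hcount, degree, in_ring, is_h),
#'   `edges` (data.frame of directed records: i, j, order, aromatic, ring,
#'   conjugated), `smiles`, `n_nodes`, `n_bonds`.
#' @export
parse_smiles <- function(smiles, add_hydrogens = FALSE) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("parse_smiles() requires a single non-empty SMILES string")
  tokens <- smiles_tokens(smiles)

  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hexp <- integer(0); hfixed <- logical(0)
  bi <- integer(0); bj <- integer(0); border <- numeric(0); barom <- logical(0)

  prev <- 0L            # index of previous atom (0 = none)
  pending_bond <- NA_character_
  stack <- integer(0)
  branch_open <- FALSE  # "(" seen with no atom yet (rejects empty branches)
  rings <- list()       # closure digit -> list(atom, bond)

  add_atom <- function(el, arom, chg, hc, hfix) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hexp[length(hexp) + 1L] <<- hc
    hfixed[length(hfixed) + 1L] <<- hfix
    length(element)
  }
  add_bond <- function(i, j, sym, arom_pair) {
    if (i == j || (length(bi) && any(bi == i & bj == j)))
      stop("SMILES parse error in '", smiles, "': duplicate or self bond")
    is_arom <- FALSE
    order <- if (is.na(sym) || sym %in% c("/", "\\")) {
      if (arom_pair) { is_arom <- TRUE; 1.5 } else 1
    } else switch(sym, "-" = 1, "=" = 2, "#" = 3,
                  ":" = { is_arom <- TRUE; 1.5 },
                  stop("SMILES parse error: bond '", sym, "'"))
    k <- length(bi) + 1L
    bi[k] <<- i; bj[k] <<- j; border[k] <<- order; barom[k] <<- is_arom
    invisible(NULL)
  }

  for (tok in tokens) {
    if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- tok
    } else if (tok == "(") {
      if (prev == 0L) stop("SMILES parse error in '", smiles, "': branch before any atom")
      stack <- c(stack, prev)
      branch_open <- TRUE
    } else if (tok == ")") {
      if (length(stack) == 0L)
        stop("SMILES parse error in '", smiles, "': unbalanced ')'")
      if (isTRUE(branch_open))
        stop("SMILES parse error in '", smiles, "': empty branch '()'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- 0L
      pending_bond <- NA_character_
    } else if (grepl("^%?[0-9]+$", tok)) {
      if (prev == 0L) stop("SMILES parse error in '", smiles, "': ring digit before atom")
      key <- sub("^%", "", tok)
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, bond = pending_bond)
      } else {
        other <- rings[[key]]
        sym <- if (!is.na(pending_bond)) pending_bond else other$bond
        add_bond(other$atom, prev, sym, aromatic[other$atom] && aromatic[prev])
        rings[[key]] <- NULL
      }
      pending_bond <- NA_character_
    } else if (grepl("^\\[", tok)) {
      a <- .parse_bracket_atom(tok, smiles)
      idx <- add_atom(a$element, a$aromatic, a$charge, a$hcount, TRUE)
      if (prev > 0L) add_bond(prev, idx, pending_bond, aromatic[prev] && a$aromatic)
      prev <- idx; pending_bond <- NA_character_; branch_open <- FALSE
    } else if (tok %in% .organic_subset || tok %in% .aromatic_organic) {
      arom <- tok %in% .aromatic_organic
      el <- if (arom) toupper(tok) else tok
      idx <- add_atom(el, arom, 0L, 0L, FALSE)
      if (prev > 0L) add_bond(prev, idx, pending_bond, aromatic[prev] && arom)
      prev <- idx; pending_bond <- NA_character_; branch_open <- FALSE
    } else {
      stop("SMILES parse error in '", smiles, "': unexpected token '", tok, "'")
    }
  }
  if (length(stack) > 0L)
    stop("SMILES parse error in '", smiles, "': unbalanced '('")
  if (length(rings) > 0L)
    stop("SMILES parse error in '", smiles, "': unclosed ring bond")
  if (length(element) == 0L)
    stop("SMILES parse error in '", smiles, "': no atoms")

  n <- length(element)
  # implicit hydrogen counts for organic-subset atoms (bracket atoms fixed)
  bondsum <- numeric(n); degree <- integer(n)
  for (k in seq_along(bi)) {
    bondsum[bi[k]] <- bondsum[bi[k]] + border[k]
    bondsum[bj[k]] <- bondsum[bj[k]] + border[k]
    degree[bi[k]] <- degree[bi[k]] + 1L
    degree[bj[k]] <- degree[bj[k]] + 1L
  }
  hcount <- hexp
  for (v in seq_len(n)) {
    if (hfixed[v]) next
    if (aromatic[v] && element[v] %in% c("N", "O", "S", "P")) {
      # aromatic heteroatom written without brackets contributes its lone
      # pair (o, s) or pyridine-type N: no implicit hydrogen (pyrrole-type
      # nitrogen must be written [nH])
      hcount[v] <- 0L
      next
    }
    vals <- .alt_valences[[element[v]]]
    if (is.null(vals)) vals <- unname(.default_valence[element[v]])
    if (length(vals) == 0L || is.na(vals[1])) { hcount[v] <- 0L; next }
    need <- ceiling(bondsum[v] - 1e-9)
    val <- vals[vals >= need][1]
    hcount[v] <- if (is.na(val)) 0L else as.integer(val - need)
  }

  ring_edge <- .ring_edges(n, bi, bj)
  conj <- .conjugated_edges(bi, bj, border, barom, ring_edge)

  if (add_hydrogens) {
    heavy_n <- n
    for (v in seq_len(heavy_n)) {
      if (hcount[v] <= 0L) next
      for (h in seq_len(hcount[v])) {
        idx <- add_atom("H", FALSE, 0L, 0L, TRUE)
        k <- length(bi) + 1L
        bi[k] <- v; bj[k] <- idx; border[k] <- 1; barom[k] <- FALSE
        ring_edge[k] <- FALSE; conj[k] <- FALSE
      }
    }
    n <- length(element)
    degree <- integer(n)
    for (k in seq_along(bi)) {
      degree[bi[k]] <- degree[bi[k]] + 1L
      degree[bj[k]] <- degree[bj[k]] + 1L
    }
    hcount <- c(rep(0L, n)) # all H now explicit
  }

  in_ring <- logical(n)
  if (any(ring_edge)) {
    in_ring[unique(c(bi[ring_edge], bj[ring_edge]))] <- TRUE
  }
  nodes <- data.frame(
    element = element, aromatic = aromatic, charge = charge,
    hcount = hcount, degree = degree, in_ring = in_ring,
    is_h = element == "H", stringsAsFactors = FALSE)

  # directed edge records, both directions with identical features
  edges <- data.frame(
    i = c(bi, bj), j = c(bj, bi),
    order = c(border, border),
    aromatic = c(barom, barom),
    ring = c(ring_edge, ring_edge),
    conjugated = c(conj, conj))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges, smiles = smiles,
                 n_nodes = n, n_bonds = length(bi)),
            class = "molecular_graph")
}

# an edge is in a ring iff it is not a bridge (endpoints stay connected
# after its removal); molecules are small, so the direct check is fine
.ring_edges <- function(n, bi, bj) {
  m <- length(bi)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bi[k]]] <- c(adj[[bi[k]]], k)
    adj[[bj[k]]] <- c(adj[[bj[k]]], k)
  }
  vapply(seq_len(m), function(k) {
    src <- bi[k]; dst <- bj[k]
    seen <- logical(n); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (bi[e] == v) bj[e] else bi[e]
        if (!seen[w]) {
          if (w == dst) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

# approximation of bond conjugation: aromatic bonds; multiple bonds adjacent
# to another multiple/aromatic bond; single bonds bridging two such bonds
.conjugated_edges <- function(bi, bj, border, barom, ring_edge) {
  m <- length(bi)
  if (m == 0L) return(logical(0))
  n <- max(c(bi, bj))
  has_multi <- logical(n)   # atom carries a bond of order >= 1.5
  for (k in seq_len(m)) {
    if (border[k] >= 1.5) has_multi[c(bi[k], bj[k])] <- TRUE
  }
  vapply(seq_len(m), function(k) {
    if (barom[k]) return(TRUE)
    if (border[k] >= 2) {
      # another multiple bond on either endpoint
      other <- (bi == bi[k] | bj == bi[k] | bi == bj[k] | bj == bj[k]) &
        seq_len(m) != k & border >= 1.5
      return(any(other))
    }
    has_multi[bi[k]] && has_multi[bj[k]]
  }, logical(1))
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d nodes, %d bonds (%d directed edges)\n",
              x$smiles, x$n_nodes, x$n_bonds, nrow(x$edges)))
  invisible(x)
}

#' Atom feature matrix
#'
#' Conventional MPNN-family atom featurisation: element one-hot over the
#' bundled periodic table (86 elements + "other"), degree one-hot (0-6),
#' formal charge (scalar), aromatic flag, and hydrogen-count one-hot (0-4,
#' clamped).  One row per node, including explicit hydrogens and, for an
#' augmented graph, zero rows for virtual nodes (their states come from
#' label embeddings instead).
#'
#' @param graph A `molecular_graph`.
#' @return Numeric matrix, `n_nodes` x `atom_feature_dim()`.
#' @export
atom_features <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  syms <- .element_symbols()
  n <- graph$n_nodes
  nd <- graph$nodes
  el_idx <- match(nd$element, syms)
  el_idx[is.na(el_idx)] <- length(syms) + 1L
  X <- matrix(0, n, atom_feature_dim())
  off <- 0L
  X[cbind(seq_len(n), el_idx)] <- 1
  off <- length(syms) + 1L
  deg <- pmin(nd$degree, 6L)
  X[cbind(seq_len(n), off + deg + 1L)] <- 1
  off <- off + 7L
  X[, off + 1L] <- nd$charge
  X[, off + 2L] <- as.numeric(nd$aromatic)
  off <- off + 2L
  hc <- pmin(nd$hcount, 4L)
  X[cbind(seq_len(n), off + hc + 1L)] <- 1
  X
}

#' @rdname atom_features
#' @export
atom_feature_dim <- function() length(.element_symbols()) + 1L + 7L + 2L + 5L

#' Bond feature matrix
#'
#' One row per directed edge record: bond-order one-hot (single, double,
#' triple, aromatic), ring membership flag, conjugation flag.
#'
#' @param graph A `molecular_graph`.
#' @return Numeric matrix, `nrow(graph$edges)` x 6.
#' @export
bond_features <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  e <- graph$edges
  m <- nrow(e)
  B <- matrix(0, m, 6L)
  if (m == 0L) return(B)
  B[e$order == 1 & !e$aromatic, 1L] <- 1
  B[e$order == 2, 2L] <- 1
  B[e$order == 3, 3L] <- 1
  B[e$aromatic, 4L] <- 1
  B[, 5L] <- as.numeric(e$ring)
  B[, 6L] <- as.numeric(e$conjugated)
  B
}

.pkg_cache <- new.env(parent = emptyenv())

.periodic_table <- function() {
  if (is.null(.pkg_cache$pt)) {
    path <- system.file("extdata", "periodic_table.csv", package = "crossmol")
    .pkg_cache$pt <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .pkg_cache$pt
}

.element_symbols <- function() .periodic_table()$symbol

#' Serialize a molecular graph to JSON
#'
#' Debugging/inspection export: nodes, directed edge list and bond features
#' as a JSON object.
#'
#' @param graph A `molecular_graph` or `augmented_graph`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
graph_to_json <- function(graph, path = NULL) {
  base <- if (inherits(graph, "augmented_graph")) graph$base else graph
  obj <- list(smiles = base$smiles, nodes = base$nodes, edges = base$edges)
  if (inherits(graph, "augmented_graph")) {
    obj$virtual_nodes <- graph$virtual_nodes
    obj$virtual_edges <- graph$virtual_edges
  }
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
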