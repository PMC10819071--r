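# Molecular knowledge base: element -> property-group triples built from the
# periodic table, functional-group substructure patterns, and augmentation of
# molecular graphs with virtual knowledge nodes.
#
# Each covered element carries exactly five discrete property labels
# (periodicity, metallicity, group, radius group, weight group); continuous
# attributes (covalent radius, atomic weight) are quantile-binned into
# discrete groups so they can act as knowledge-graph entities.  Functional
# groups are described in a restricted SMARTS-like pattern language matched
# by backtracking subgraph search (no SMARTS engine is available to R here).

.kb_categories <- c("periodicity", "metallicity", "group", "radius", "weight")
.kb_relations <- c(periodicity = "isPeriodOf", metallicity = "isMetallicityOf",
                   group = "isGroupOf", radius = "isRadiusOf",
                   weight = "isWeightOf")
.fg_relation <- "hasFunctionalGroup"

#' Build a molecular knowledge base
#'
#' Derives element -> property-group triples from a periodic-table attribute
#' table and compiles a functional-group pattern table.  Period and group
#' are taken verbatim as labels; metallicity is a three-way class; covalent
#' radius and atomic weight are quantile-binned over the supplied table into
#' `n_bins` discrete groups labelled `Radius1...`, `Weight1...`.
#'
#' @param periodic_table Data frame with columns `symbol`, `period`, `group`,
#'   `metallicity`, `radius_pm`, `weight`.  Default: the bundled table
#'   (86 elements, RDKit attribute values).
#' @param n_bins Number of quantile bins for radius and weight (>= 1;
#'   default 5).
#' @param fg_patterns Data frame with columns `name`, `pattern`, or a path to
#'   such a CSV.  Default: the bundled table (hydroxyl, amino, methyl,
#'   carboxyl, carbonyl, nitro, ester, amide, ether, thiol, halogen).
#' @return An object of class `knowledge_base` with `element_properties`
#'   (named list: element -> named character of 5 labels),
#'   `functional_groups` (compiled patterns), `n_bins`.
#' @export
build_knowledge_base <- function(periodic_table = NULL, n_bins = 5L,
                                 fg_patterns = NULL) {
  if (is.null(periodic_table)) periodic_table <- .periodic_table()
  need <- c("symbol", "period", "group", "metallicity", "radius_pm", "weight")
  miss <- setdiff(need, names(periodic_table))
  if (length(miss))
    stop("periodic table is missing columns: ", paste(miss, collapse = ", "))
  bad <- periodic_table$symbol[!stats::complete.cases(periodic_table[need])]
  if (length(bad))
    stop("periodic table has missing attributes for element(s): ",
         paste(bad, collapse = ", "))
  if (n_bins < 1L) stop("n_bins must be >= 1")

  rbin <- .quantile_bins(periodic_table$radius_pm, n_bins)
  wbin <- .quantile_bins(periodic_table$weight, n_bins)
  met <- c(metal = "Metal", metalloid = "Metalloid", nonmetal = "Nonmetal")
  props <- lapply(seq_len(nrow(periodic_table)), function(k) {
    r <- periodic_table[k, ]
    c(periodicity = paste0("Period", r$period),
      metallicity = unname(met[tolower(r$metallicity)]),
      group = paste0("Group", r$group),
      radius = paste0("Radius", rbin[k]),
      weight = paste0("Weight", wbin[k]))
  })
  names(props) <- periodic_table$symbol

  if (is.null(fg_patterns))
    fg_patterns <- system.file("extdata", "functional_groups.csv",
                               package = "crossmol")
  if (is.character(fg_patterns))
    fg_patterns <- utils::read.csv(fg_patterns, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(fg_patterns)))
    stop("functional-group table needs columns 'name' and 'pattern'")
  groups <- lapply(seq_len(nrow(fg_patterns)), function(k)
    compile_pattern(fg_patterns$name[k], fg_patterns$pattern[k]))
  names(groups) <- fg_patterns$name

  structure(list(element_properties = props, functional_groups = groups,
                 n_bins = as.integer(n_bins)),
            class = "knowledge_base")
}

.quantile_bins <- function(x, n_bins) {
  if (n_bins == 1L) return(rep(1L, length(x)))
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  as.integer(cut(x, breaks = qs, labels = FALSE, right = TRUE))
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(paste0("<knowledge_base> %d elements x 5 property categories",
                     " (%d radius/weight bins), %d functional groups\n"),
              length(x$element_properties), x$n_bins,
              length(x$functional_groups)))
  invisible(x)
}

#' Element-property triples of a knowledge base
#'
#' @param kb A `knowledge_base`.
#' @return Data frame with columns `head` (property-group label), `relation`
#'   (e.g. `"isWeightOf"`), `tail` (element symbol); 5 rows per element.
#' @export
kb_triples <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  els <- names(kb$element_properties)
  do.call(rbind, lapply(els, function(el) {
    p <- kb$element_properties[[el]]
    data.frame(head = unname(p), relation = unname(.kb_relations[names(p)]),
               tail = el, stringsAsFactors = FALSE)
  }))
}

#' Does any functional-group pattern reference explicit hydrogens?
#' @param kb A `knowledge_base`.
#' @return Logical.
#' @export
kb_needs_explicit_h <- function(kb) {
  any(vapply(kb$functional_groups, function(p)
    any(vapply(p$atoms, function(a) isTRUE(a$is_h), logical(1))), logical(1)))
}

# ---- restricted substructure pattern language ----------------------------
#
# Supported syntax: element symbols (two-letter Cl/Br recognised), branches
# (), bond symbols - = # and ~ (any bond; the default matches single or
# aromatic), [H] explicit hydrogen, and bracket atoms with comma-separated
# element alternatives, an optional heavy-degree constraint D<n> and an
# optional +/- charge, e.g. [OD1], [N+], [F,Cl,Br,I].  Bare element symbols
# match regardless of aromaticity or charge.

compile_pattern <- function(name, pattern) {
  toks <- .pattern_tokens(pattern)
  atoms <- list(); bonds <- list()
  prev <- 0L; pend <- NA_character_; stack <- integer(0)
  add_atom <- function(constr) {
    atoms[[length(atoms) + 1L]] <<- constr
    length(atoms)
  }
  for (tok in toks) {
    if (tok %in% c("-", "=", "#", "~")) {
      pend <- tok
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (!length(stack)) stop("malformed pattern '", pattern, "': unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else {
      constr <- .pattern_atom(tok, pattern)
      idx <- add_atom(constr)
      if (prev > 0L) {
        type <- switch(if (is.na(pend)) "." else pend,
                       "." = "default", "-" = "single", "=" = "double",
                       "#" = "triple", "~" = "any")
        bonds[[length(bonds) + 1L]] <- list(i = prev, j = idx, type = type)
      }
      prev <- idx; pend <- NA_character_
    }
  }
  if (length(stack)) stop("malformed pattern '", pattern, "': unbalanced '('")
  if (!length(atoms)) stop("malformed pattern '", pattern, "': no atoms")
  list(name = name, pattern = pattern, atoms = atoms, bonds = bonds)
}

.pattern_tokens <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- length(chars); i <- 1L; out <- character(0)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("malformed pattern '", pattern, "': unclosed bracket")
      out <- c(out, paste(chars[i:j], collapse = "")); i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      out <- c(out, paste0(ch, chars[i + 1L])); i <- i + 2L
    } else {
      out <- c(out, ch); i <- i + 1L
    }
  }
  out
}

.pattern_atom <- function(tok, pattern) {
  if (grepl("^\\[", tok)) {
    body <- sub("^\\[", "", sub("\\]$", "", tok))
    degree <- NA_integer_; charge <- NA_integer_
    dm <- regmatches(body, regexec("D([0-9]+)", body))[[1]]
    if (length(dm)) {
      degree <- as.integer(dm[2])
      body <- sub("D[0-9]+", "", body)
    }
    if (grepl("\\+$", body)) { charge <- 1L; body <- sub("\\+$", "", body) }
    if (grepl("-$", body)) { charge <- -1L; body <- sub("-$", "", body) }
    els <- strsplit(body, ",", fixed = TRUE)[[1]]
    if (identical(els, "H"))
      return(list(elements = "H", degree = degree, charge = charge, is_h = TRUE))
    if (!length(els) || !all(grepl("^[A-Z][a-z]?$", els)))
      stop("malformed pattern '", pattern, "': bad bracket atom '", tok, "'")
    list(elements = els, degree = degree, charge = charge, is_h = FALSE)
  } else if (tok == "X") {
    list(elements = c("F", "Cl", "Br", "I"), degree = NA_integer_,
         charge = NA_integer_, is_h = FALSE)
  } else if (tok == "A") {
    list(elements = NULL, degree = NA_integer_, charge = NA_integer_,
         is_h = FALSE)
  } else if (grepl("^[A-Z][a-z]?$", tok)) {
    list(elements = tok, degree = NA_integer_, charge = NA_integer_,
         is_h = FALSE)
  } else {
    stop("malformed pattern '", pattern, "': unexpected token '", tok, "'")
  }
}

#' Match functional-group patterns against a molecular graph
#'
#' Backtracking subgraph search of every pattern in the knowledge base.
#' All matches with distinct atom sets are kept (identical sets from
#' symmetric pattern automorphisms are deduplicated); matches are ordered
#' deterministically by their lowest atom index.  Patterns referencing
#' explicit hydrogens only match graphs parsed with `add_hydrogens = TRUE`.
#'
#' @param graph A `molecular_graph`.
#' @param kb A `knowledge_base`.
#' @return Data-frame-free list of records: `list(group, atoms)` with
#'   `atoms` an increasing integer vector of matched node indices.
#' @export
match_functional_groups <- function(graph, kb) {
  stopifnot(inherits(graph, "molecular_graph"), inherits(kb, "knowledge_base"))
  out <- list()
  for (pat in kb$functional_groups) {
    sets <- .match_pattern(graph, pat)
    for (s in sets) out[[length(out) + 1L]] <- list(group = pat$name, atoms = s)
  }
  if (length(out) > 1L) {
    key <- vapply(out, function(r) min(r$atoms), numeric(1))
    out <- out[order(key, vapply(out, function(r) r$group, character(1)))]
  }
  out
}

.match_pattern <- function(graph, pat) {
  nd <- graph$nodes
  np <- length(pat$atoms)
  n <- graph$n_nodes
  # heavy-atom degree per node
  e1 <- graph$edges
  heavy_deg <- integer(n)
  if (nrow(e1)) {
    heavy <- !nd$is_h[e1$j]
    hd <- rowsum(as.numeric(heavy), group = e1$i)
    heavy_deg[as.integer(rownames(hd))] <- as.integer(hd)
  }
  # adjacency with bond order
  adj <- vector("list", n)
  half <- e1[e1$i < e1$j, , drop = FALSE]
  for (k in seq_len(nrow(half))) {
    i <- half$i[k]; j <- half$j[k]
    adj[[i]] <- rbind(adj[[i]], c(j, half$order[k], half$aromatic[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, half$order[k], half$aromatic[k]))
  }
  bond_ok <- function(type, order, arom) {
    switch(type,
           default = (order == 1 && !arom) || arom > 0,
           single = order == 1 && !arom,
           double = order == 2,
           triple = order == 3,
           any = TRUE)
  }
  atom_ok <- function(v, constr) {
    if (constr$is_h && !nd$is_h[v]) return(FALSE)
    if (!constr$is_h && nd$is_h[v]) return(FALSE)
    if (!is.null(constr$elements) && !(nd$element[v] %in% constr$elements))
      return(FALSE)
    if (!is.na(constr$degree) && heavy_deg[v] != constr$degree) return(FALSE)
    if (!is.na(constr$charge) && nd$charge[v] != constr$charge) return(FALSE)
    TRUE
  }
  # pattern bonds incident to atom k from earlier atoms
  back_bonds <- lapply(seq_len(np), function(k)
    Filter(function(b) b$j == k && b$i < k, pat$bonds))

  sets <- list()
  assign_next <- function(k, map) {
    if (k > np) {
      sets[[length(sets) + 1L]] <<- sort(map)
      return(invisible(NULL))
    }
    constr <- pat$atoms[[k]]
    for (v in seq_len(n)) {
      if (v %in% map) next
      if (!atom_ok(v, constr)) next
      ok <- TRUE
      for (b in back_bonds[[k]]) {
        u <- map[b$i]
        a <- adj[[u]]
        row <- if (is.null(a)) integer(0) else which(a[, 1] == v)
        if (!length(row) || !bond_ok(b$type, a[row[1], 2], a[row[1], 3])) {
          ok <- FALSE
          break
        }
      }
      if (ok) assign_next(k + 1L, c(map, v))
    }
    invisible(NULL)
  }
  assign_next(1L, integer(0))
  unique(sets)
}

# ---- graph augmentation ---------------------------------------------------

#' Augment a molecular graph with knowledge virtual nodes
#'
#' Adds one virtual node per distinct element-property label present in the
#' molecule (shared across atoms with equal labels) with a directed
#' property -> atom edge per atom and category, and one virtual node per
#' functional-group match with a directed edge to each member atom.
#' Atom-atom edges are untouched; no edge ever leaves an atom toward a
#' virtual node, and dropping all virtual nodes/edges recovers the base
#' graph exactly.
#'
#' @param graph A `molecular_graph` (parse with `add_hydrogens = TRUE` when
#'   the knowledge base contains H-referencing patterns, see
#'   [kb_needs_explicit_h()]).
#' @param kb A `knowledge_base` covering every element of `graph`.
#' @return An object of class `augmented_graph`: `base` (the input),
#'   `virtual_nodes` (data.frame: id, kind, label), `virtual_edges`
#'   (data.frame: src = virtual id, dst = atom index, relation, category).
#' @export
augment_graph <- function(graph, kb) {
  if (inherits(graph, "augmented_graph"))
    stop("graph is already augmented; augmentation is applied exactly once")
  stopifnot(inherits(graph, "molecular_graph"), inherits(kb, "knowledge_base"))
  els <- unique(graph$nodes$element)
  unc <- setdiff(els, names(kb$element_properties))
  if (length(unc))
    stop("knowledge base does not cover element(s): ",
         paste(unc, collapse = ", "))

  vlabel <- character(0); vkind <- character(0)
  esrc <- integer(0); edst <- integer(0)
  erel <- character(0); ecat <- character(0)
  vid_of <- function(label, kind) {
    hit <- which(vlabel == label & vkind == kind)
    if (length(hit)) return(hit[1])
    vlabel[length(vlabel) + 1L] <<- label
    vkind[length(vkind) + 1L] <<- kind
    length(vlabel)
  }
  for (a in seq_len(graph$n_nodes)) {
    p <- kb$element_properties[[graph$nodes$element[a]]]
    for (cat in .kb_categories) {
      v <- vid_of(p[[cat]], "element-property")
      k <- length(esrc) + 1L
      esrc[k] <- v; edst[k] <- a
      erel[k] <- .kb_relations[[cat]]; ecat[k] <- cat
    }
  }
  matches <- match_functional_groups(graph, kb)
  for (m in matches) {
    # one virtual node per occurrence: two hydroxyls are two entities
    vlabel[length(vlabel) + 1L] <- m$group
    vkind[length(vkind) + 1L] <- "functional-group"
    v <- length(vlabel)
    for (a in m$atoms) {
      k <- length(esrc) + 1L
      esrc[k] <- v; edst[k] <- a
      erel[k] <- .fg_relation; ecat[k] <- "functional-group"
    }
  }
  structure(list(
    base = graph,
    virtual_nodes = data.frame(id = seq_along(vlabel), kind = vkind,
                               label = vlabel, stringsAsFactors = FALSE),
    virtual_edges = data.frame(src = esrc, dst = edst, relation = erel,
                               category = ecat, stringsAsFactors = FALSE),
    matches = matches),
    class = "augmented_graph")
}

#' @export
print.augmented_graph <- function(x, ...) {
  cat(sprintf(paste0("<augmented_graph> %s: %d atoms + %d virtual nodes,",
                     " %d property/group edges\n"),
              x$base$smiles, x$base$n_nodes, nrow(x$virtual_nodes),
              nrow(x$virtual_edges)))
  invisible(x)
}
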