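# Frequent-consecutive-subsequence (FCS) tokenisation of SMILES strings.
#
# A vocabulary of recurring substrings is mined from a training corpus by
# frequency-thresholded iterative adjacent-pair merging (BPE-style), then
# strings are segmented by greedy left-to-right longest match.  Segmentation
# is lossless: concatenating the tokens reproduces the input exactly.
# Multi-character SMILES atoms (Cl, Br, bracket atoms, %nn ring closures)
# are pre-grouped as atomic units before mining so a token never splits an
# element symbol.

#' Mine an FCS vocabulary from a SMILES corpus
#'
#' Starts from the atomic units of the corpus (every unit seen is always in
#' the vocabulary, which guarantees total segmentability) and repeatedly
#' merges the most frequent adjacent token pair whose frequency is at least
#' `min_freq` and whose merged length is at most `max_token_len` characters,
#' until `max_vocab` entries exist or no pair qualifies.  Ties are broken
#' lexicographically on the merged string, so mining is deterministic.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @param min_freq Minimum corpus frequency for a merged token (default 5).
#' @param max_token_len Maximum merged token length in characters
#'   (default 8; tokens stay medium-sized substructure fragments).
#' @param max_vocab Maximum vocabulary size (default 1024).
#' @return An object of class `fcs_vocabulary`: `tokens` (character),
#'   `freq` (integer), `min_freq`, `max_token_len`.
#' @export
mine_vocabulary <- function(corpus, min_freq = 5L, max_token_len = 8L,
                            max_vocab = 1024L) {
  if (!is.character(corpus) || length(corpus) == 0L)
    stop("mine_vocabulary() requires a non-empty SMILES corpus")
  seqs <- lapply(corpus, smiles_tokens)
  units <- unlist(seqs)
  base <- sort(unique(units))
  freq <- as.integer(table(factor(units, levels = base)))
  tokens <- base
  tok_freq <- freq

  if (max_token_len > 1L) {
    repeat {
      if (length(tokens) >= max_vocab) break
      pair_counts <- new.env(parent = emptyenv())
      for (s in seqs) {
        n <- length(s)
        if (n < 2L) next
        keys <- paste(s[-n], s[-1], sep = "\x1f")
        for (k in keys) {
          cur <- pair_counts[[k]]
          pair_counts[[k]] <- if (is.null(cur)) 1L else cur + 1L
        }
      }
      keys <- ls(pair_counts)
      if (!length(keys)) break
      counts <- vapply(keys, function(k) pair_counts[[k]], integer(1))
      merged <- gsub("\x1f", "", keys, fixed = TRUE)
      ok <- counts >= min_freq & nchar(merged) <= max_token_len &
        !(merged %in% tokens)
      if (!any(ok)) break
      cand <- which(ok)
      best <- cand[order(-counts[cand], merged[cand])][1]
      parts <- strsplit(keys[best], "\x1f", fixed = TRUE)[[1]]
      new_tok <- merged[best]
      tokens <- c(tokens, new_tok)
      tok_freq <- c(tok_freq, unname(counts[best]))
      seqs <- lapply(seqs, .merge_pair, a = parts[1], b = parts[2],
                     ab = new_tok)
    }
  }
  structure(list(tokens = tokens, freq = tok_freq,
                 min_freq = as.integer(min_freq),
                 max_token_len = as.integer(max_token_len)),
            class = "fcs_vocabulary")
}

.merge_pair <- function(s, a, b, ab) {
  n <- length(s)
  if (n < 2L) return(s)
  out <- character(0)
  k <- 1L
  while (k <= n) {
    if (k < n && s[k] == a && s[k + 1L] == b) {
      out <- c(out, ab)
      k <- k + 2L
    } else {
      out <- c(out, s[k])
      k <- k + 1L
    }
  }
  out
}

#' @export
print.fcs_vocabulary <- function(x, ...) {
  cat(sprintf(paste0("<fcs_vocabulary> %d tokens (%d multi-unit),",
                     " min_freq=%d, max_token_len=%d\n"),
              length(x$tokens), sum(nchar(x$tokens) > 1L &
                                      !grepl("^\\[|^%|^Cl$|^Br$", x$tokens)),
              x$min_freq, x$max_token_len))
  invisible(x)
}

#' Segment a SMILES string over an FCS vocabulary
#'
#' Greedy left-to-right longest-match segmentation at atomic-unit
#' granularity.  The result is lossless; every atomic unit of the input must
#' be present in the vocabulary.
#'
#' @param smiles SMILES string.
#' @param vocab An `fcs_vocabulary`.
#' @return An object of class `token_sequence`: `tokens` (character vector
#'   `d_1 ... d_q`), `source` (the input string).
#' @export
fcs_tokenize <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "fcs_vocabulary"))
  units <- smiles_tokens(smiles)
  missing <- setdiff(units, vocab$tokens)
  if (length(missing))
    stop("vocabulary does not cover unit(s): ",
         paste(unique(missing), collapse = " "), " in '", smiles, "'")
  lookup <- new.env(parent = emptyenv())
  for (tk in vocab$tokens) lookup[[tk]] <- TRUE
  maxlen <- max(nchar(vocab$tokens))
  n <- length(units)
  out <- character(0)
  k <- 1L
  while (k <= n) {
    best <- units[k]
    best_span <- 1L
    span <- 2L
    cat_ <- units[k]
    while (k + span - 1L <= n) {
      cat_ <- paste0(cat_, units[k + span - 1L])
      if (nchar(cat_) > maxlen) break
      if (!is.null(lookup[[cat_]])) {
        best <- cat_
        best_span <- span
      }
      span <- span + 1L
    }
    out <- c(out, best)
    k <- k + best_span
  }
  structure(list(tokens = out, source = smiles), class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence> %s -> [%s] (q=%d)\n", x$source,
              paste(x$tokens, collapse = " | "), length(x$tokens)))
  invisible(x)
}

#' Read/write FCS vocabulary files
#'
#' Plain-text format: one `token<TAB>frequency` line per entry, UTF-8.
#'
#' @param vocab An `fcs_vocabulary`.
#' @param path File path.
#' @return `read_vocabulary()` returns an `fcs_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "fcs_vocabulary"))
  hdr <- sprintf("#min_freq=%d\tmax_token_len=%d", vocab$min_freq,
                 vocab$max_token_len)
  writeLines(c(hdr, paste(vocab$tokens, vocab$freq, sep = "\t")), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[1]
  mf <- as.integer(sub(".*min_freq=([0-9]+).*", "\\1", hdr))
  ml <- as.integer(sub(".*max_token_len=([0-9]+).*", "\\1", hdr))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  structure(list(tokens = vapply(body, `[`, character(1), 1L),
                 freq = as.integer(vapply(body, `[`, character(1), 2L)),
                 min_freq = mf, max_token_len = ml),
            class = "fcs_vocabulary")
}
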