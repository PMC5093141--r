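# Code patterns: the compressed residue of an alignment, and decoding
# ("decompression by compression"): running the very same alignment machinery
# on a code pattern re-creates the sequence it encodes.

#' Derive the code pattern of an alignment
#'
#' Scans the alignment's columns left to right and collects every service
#' (ID) symbol that is not matched with any other symbol.  The result is a
#' compressed encoding of the New pattern: together with the grammar it
#' suffices to re-create the original sequence (see [decode()]).
#'
#' @param aln a legal `sp_alignment`.
#' @return an object of class `sp_code`: a (possibly empty) ordered symbol
#'   sequence.
#' @export
derive_code <- function(aln) {
  keep <- aln$topo[aln$col_n[aln$topo] == 1L & aln$col_has_id[aln$topo]]
  structure(list(pattern_id = "code",
                 symbols = aln$col_name[keep],
                 role = rep("CONTENTS", length(keep)),
                 frequency = 1L, provenance = "NEW"),
            class = c("sp_code", "sp_pattern"))
}

#' @export
print.sp_code <- function(x, ...) {
  cat(sprintf("<sp_code: %s>\n",
              if (length(x$symbols)) paste(x$symbols, collapse = " ")
              else "(empty)"))
  invisible(x)
}

#' Re-create a sequence from a code pattern
#'
#' The code pattern is treated as a New pattern and aligned against the same
#' grammar that produced it.  In the best alignment each code symbol resolves
#' a service symbol of some stored pattern; the original sequence is then
#' read off as, in column order, every contents symbol that is not itself a
#' resolved reference to another pattern.
#'
#' Decoding selects, among the alignments found, the one that accounts for
#' the most code symbols (a leftover code symbol is unexplained structure),
#' breaking ties by compression score: production wants the full message
#' consumed, where recognition wants the best compression of it.
#'
#' @param code an `sp_code` (or character vector of symbol names).
#' @param grammar a non-empty `sp_grammar`.
#' @param params an `sp_search_params`.
#' @return character vector: the reconstructed symbol sequence.  If no code
#'   symbol can be matched at all, a classed error
#'   (`"sp_decode_failure"`) is signalled.
#' @export
decode <- function(code, grammar, params = sp_search_params()) {
  syms <- if (inherits(code, "sp_pattern")) code$symbols else
    as.character(code)
  if (length(syms) == 0L)
    stop(decode_failure("empty code pattern"))
  if (length(grammar$patterns) == 0L)
    stop(decode_failure("empty grammar"))
  alns <- build_alignments(sp_new_pattern(syms, "code"), grammar, params)
  nm <- vapply(alns, function(a) sum(a$col_n[a$colid[[1L]]] >= 2L), 0L)
  best <- alns[[order(-nm, seq_along(alns))[1L]]]
  if (max(nm) == 0L)
    stop(decode_failure("no code symbol matches the grammar"))
  emit_terminals(best)
}

decode_failure <- function(msg) {
  structure(class = c("sp_decode_failure", "error", "condition"),
            list(message = msg, call = NULL))
}

# Contents symbols that are not consumed as references: a column is emitted
# once iff it holds at least one contents symbol of an appearance row and no
# service symbol (a contents symbol matched to an ID symbol is a resolved
# reference; row-0 symbols alone are never terminals of the grammar).
emit_terminals <- function(aln) {
  out <- character(0)
  for (k in aln$topo) {
    e <- aln$cols[aln$cols$col == k, , drop = FALSE]
    if (any(e$role == "ID")) next
    if (!any(e$row > 1L)) next
    out <- c(out, aln$col_name[k])
  }
  out
}

#' Residual redundancy of an encoding
#'
#' Compares the raw cost of the New pattern with the cost of the code the
#' best alignment leaves behind.  A ratio above 1 means the encoding
#' compresses; the residual redundancy in the code is what makes decoding
#' (a second round of compression) able to reconstruct the original.
#'
#' @param aln a scored, legal `sp_alignment` whose New row is fully matched.
#' @param model an `sp_cost_model`.
#' @return list with `b_raw` (bits of the raw New pattern), `b_code` (bits of
#'   the derived code), `ratio = b_raw / b_code`, and `compressed`
#'   (`ratio > 1`).
#' @export
residual_redundancy <- function(aln, model) {
  newsyms <- aln$rows[[1L]]$symbols
  b_raw <- sum(symbol_cost(model, newsyms))
  code <- derive_code(aln)
  b_code <- if (length(code$symbols))
    sum(symbol_cost(model, code$symbols)) else 0
  list(b_raw = b_raw, b_code = b_code,
       ratio = if (b_code > 0) b_raw / b_code else Inf,
       compressed = b_raw > b_code)
}
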