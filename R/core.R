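#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Reserved delimiter token of the pattern text dialect.
SP_DELIM <- "|"

#' Create a New (sensory) pattern
#'
#' A pattern is an ordered one-dimensional array of atomic symbols.  A symbol
#' is a bare mark: two symbols match if and only if their names are equal.
#' New patterns carry no service (ID) symbols; they are raw input.
#'
#' @param symbols character vector of symbol names (no whitespace, non-empty).
#' @param pattern_id optional identifier; defaults to `"new"`.
#' @return an object of class `sp_pattern` with provenance `"NEW"`.
#' @examples
#' sp_new_pattern(c("t", "h", "e"))
#' @export
sp_new_pattern <- function(symbols, pattern_id = "new") {
  check_symbol_names(symbols)
  structure(
    list(pattern_id = pattern_id,
         symbols = unname(as.character(symbols)),
         role = rep("CONTENTS", length(symbols)),
         frequency = 1L, provenance = "NEW"),
    class = "sp_pattern")
}

#' Create an Old (stored) pattern
#'
#' Old patterns carry system-generated ID symbols: a prefix of at least two
#' (class label plus one or more discriminators) and a single trailing
#' boundary symbol whose name is `"#"` followed by the class label.  The
#' symbols between prefix and suffix are the pattern's contents: terminal
#' marks or references to the ID symbols of other patterns.
#'
#' @param prefix character vector of ID symbols (length >= 2).
#' @param body character vector of contents symbols.
#' @param suffix single boundary symbol, name starting with `"#"`.
#' @param pattern_id unique identifier; defaults to the prefix joined by `"."`.
#' @param frequency positive integer occurrence count.
#' @return an object of class `sp_pattern` with provenance `"OLD"`.
#' @examples
#' sp_old_pattern(c("B", "1"), c("t", "h", "e"), "#B")
#' @export
sp_old_pattern <- function(prefix, body, suffix, pattern_id = NULL,
                           frequency = 1L) {
  check_symbol_names(c(prefix, body, suffix))
  if (length(prefix) < 2L)
    stop("an Old pattern needs a class label and at least one discriminator")
  if (length(suffix) != 1L || !startsWith(suffix, "#"))
    stop("an Old pattern ends with a single '#'-boundary symbol")
  if (frequency < 1L) stop("frequency must be >= 1")
  if (is.null(pattern_id)) pattern_id <- paste(prefix, collapse = ".")
  structure(
    list(pattern_id = pattern_id,
         symbols = unname(as.character(c(prefix, body, suffix))),
         role = c(rep("ID", length(prefix)), rep("CONTENTS", length(body)),
                  "ID"),
         frequency = as.integer(frequency), provenance = "OLD"),
    class = "sp_pattern")
}

check_symbol_names <- function(x) {
  if (length(x) == 0L) stop("a pattern needs at least one symbol")
  if (any(!nzchar(x)) || any(grepl("[[:space:]]", x)))
    stop("symbol names must be non-empty and contain no whitespace")
  if (any(x == SP_DELIM))
    stop("'", SP_DELIM, "' is the reserved delimiter token")
  invisible(x)
}

#' @export
print.sp_pattern <- function(x, ...) {
  cat(sprintf("<sp_pattern %s [%s] freq=%d>\n  %s\n",
              x$pattern_id, x$provenance, x$frequency, format_pattern(x)))
  invisible(x)
}

# Render in dialect form "B 1 | t h e | #B".
format_pattern <- function(p) {
  if (p$provenance == "NEW") return(paste(p$symbols, collapse = " "))
  np <- id_prefix_len(p); ns <- id_suffix_len(p)
  n <- length(p$symbols)
  paste(c(p$symbols[seq_len(np)], SP_DELIM,
          if (n - np - ns > 0) p$symbols[(np + 1L):(n - ns)], SP_DELIM,
          p$symbols[n]), collapse = " ")
}

#' Number of leading / trailing ID symbols of a pattern
#' @param p an `sp_pattern`.
#' @return integer count.
#' @export
id_prefix_len <- function(p) {
  r <- p$role != "ID"
  if (!any(r)) return(length(p$role) - 1L)  # degenerate: all ID but suffix
  which(r)[1L] - 1L
}

#' @rdname id_prefix_len
#' @export
id_suffix_len <- function(p) {
  r <- rev(p$role) != "ID"
  if (!any(r)) return(1L)
  which(r)[1L] - 1L
}

#' Contents (body) symbols of a pattern
#' @param p an `sp_pattern`.
#' @return character vector of the non-ID symbols, in order.
#' @export
pattern_body <- function(p) p$symbols[p$role == "CONTENTS"]

#' Classify raw tokens into an ID-tagged pattern
#'
#' Parses one tokenised dialect line into a pattern, assigning ID or CONTENTS
#' roles.  With explicit `|` delimiters the two delimiters partition the
#' tokens into ID prefix, body and ID suffix.  Without delimiters a fallback
#' heuristic is applied: leading tokens that look like a class label
#' (uppercase-led) or a bare discriminator (digits) are ID, and a sole
#' trailing `#`-token is ID; a warning is emitted because the heuristic can
#' misread bodies that start with such tokens.
#'
#' @param raw_tokens character vector of tokens (possibly containing `|`).
#' @param delimiters_present logical; if `NULL`, inferred from the tokens.
#' @param pattern_id,frequency passed through to the pattern.
#' @return an `sp_pattern`; provenance `"OLD"` if any ID symbols were found,
#'   else `"NEW"`.
#' @examples
#' classify_symbols(c("B", "1", "|", "t", "h", "e", "|", "#B"))
#' classify_symbols(c("t", "h", "e"))
#' @export
classify_symbols <- function(raw_tokens, delimiters_present = NULL,
                             pattern_id = NULL, frequency = 1L) {
  if (length(raw_tokens) == 0L) stop("empty token list")
  ndelim <- sum(raw_tokens == SP_DELIM)
  if (is.null(delimiters_present)) delimiters_present <- ndelim > 0L
  if (delimiters_present) {
    if (ndelim != 2L)
      stop("expected exactly two '", SP_DELIM, "' delimiters, found ", ndelim)
    at <- which(raw_tokens == SP_DELIM)
    prefix <- raw_tokens[seq_len(at[1L] - 1L)]
    body <- if (at[2L] - at[1L] > 1L)
      raw_tokens[(at[1L] + 1L):(at[2L] - 1L)] else character()
    suffix <- if (at[2L] < length(raw_tokens))
      raw_tokens[(at[2L] + 1L):length(raw_tokens)] else character()
    if (length(suffix) != 1L || !startsWith(suffix[1L], "#"))
      stop("delimited pattern must end with a single '#'-boundary symbol")
    return(sp_old_pattern(prefix, body, suffix, pattern_id = pattern_id,
                          frequency = frequency))
  }
  if (ndelim > 0L) stop("unexpected '", SP_DELIM, "' delimiter")
  looks_id <- function(tok) grepl("^[A-Z][A-Za-z0-9]*$", tok) ||
    grepl("^[0-9]+$", tok)
  np <- 0L
  while (np < length(raw_tokens) && looks_id(raw_tokens[np + 1L]))
    np <- np + 1L
  n <- length(raw_tokens)
  has_suffix <- n > np && startsWith(raw_tokens[n], "#")
  if (np == 0L && !has_suffix)
    return(sp_new_pattern(raw_tokens, pattern_id = pattern_id %||% "new"))
  if (np < 2L || !has_suffix || np >= n - 1L)
    stop("cannot classify undelimited tokens as an Old pattern")
  warning("undelimited Old pattern line; applying fallback ID heuristic",
          call. = FALSE)
  sp_old_pattern(raw_tokens[seq_len(np)], raw_tokens[(np + 1L):(n - 1L)],
                 raw_tokens[n], pattern_id = pattern_id, frequency = frequency)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Grammar: a repository of Old patterns with a symbol-frequency table.

#' Create an empty grammar
#'
#' A grammar is simply a collection of stored (Old) patterns, together with a
#' frequency table over symbol names (the multiset count of names over
#' patterns, weighted by pattern frequency) and the counter state used to
#' generate fresh ID symbols.
#'
#' @param unique_ids logical; if `TRUE`, generated discriminators are globally
#'   unique tokens rather than per-class `"1"`, `"2"`, ... (removes decode
#'   ambiguity between classes that reuse the same discriminator names).
#' @return an object of class `sp_grammar`.
#' @export
sp_grammar <- function(unique_ids = FALSE) {
  structure(
    list(patterns = list(), symbol_freq = integer(),
         id_counter = list(next_class = 1L, next_disc = integer(),
                           global_disc = 1L, unique_ids = unique_ids)),
    class = "sp_grammar")
}

#' @export
print.sp_grammar <- function(x, ...) {
  cat(sprintf("<sp_grammar: %d patterns, %d distinct symbols>\n",
              length(x$patterns), length(x$symbol_freq)))
  for (p in x$patterns)
    cat(sprintf("  %s @ %d\n", format_pattern(p), p$frequency))
  invisible(x)
}

#' Add (or re-observe) an Old pattern in a grammar
#'
#' If a stored pattern with the identical symbol sequence already exists, its
#' frequency is incremented (the repository holds one copy of any pattern);
#' otherwise the pattern is inserted.  The symbol-frequency table is updated
#' consistently in either case.
#'
#' @param grammar an `sp_grammar`.
#' @param pattern an Old `sp_pattern`.
#' @param count number of occurrences to record (default the pattern's own
#'   frequency).
#' @return the updated grammar.
#' @export
add_pattern <- function(grammar, pattern, count = pattern$frequency) {
  if (pattern$provenance != "OLD") stop("only Old patterns can be stored")
  key <- paste(pattern$symbols, collapse = "\x1f")
  keys <- vapply(grammar$patterns,
                 function(p) paste(p$symbols, collapse = "\x1f"), "")
  hit <- match(key, keys)
  if (!is.na(hit)) {
    grammar$patterns[[hit]]$frequency <-
      grammar$patterns[[hit]]$frequency + as.integer(count)
  } else {
    pattern$frequency <- as.integer(count)
    if (pattern$pattern_id %in% names(grammar$patterns))
      pattern$pattern_id <- paste0(pattern$pattern_id, ".",
                                   length(grammar$patterns) + 1L)
    grammar$patterns[[pattern$pattern_id]] <- pattern
  }
  bump <- table(rep(pattern$symbols, as.integer(count)))
  for (nm in names(bump)) {
    grammar$symbol_freq[nm] <-
      (if (nm %in% names(grammar$symbol_freq)) grammar$symbol_freq[[nm]]
       else 0L) + as.integer(bump[[nm]])
  }
  grammar
}

#' Drop a pattern from a grammar, keeping the frequency table consistent
#' @param grammar an `sp_grammar`.
#' @param pattern_id id of the stored pattern to remove.
#' @return the updated grammar.
#' @export
remove_pattern <- function(grammar, pattern_id) {
  p <- grammar$patterns[[pattern_id]]
  if (is.null(p)) return(grammar)
  drop <- table(rep(p$symbols, p$frequency))
  for (nm in names(drop))
    grammar$symbol_freq[nm] <- grammar$symbol_freq[[nm]] -
      as.integer(drop[[nm]])
  grammar$symbol_freq <- grammar$symbol_freq[grammar$symbol_freq > 0L]
  grammar$patterns[[pattern_id]] <- NULL
  grammar
}

# Recount the symbol-frequency table from scratch (test oracle).
recount_symbol_freq <- function(grammar) {
  syms <- unlist(lapply(grammar$patterns,
                        function(p) rep(p$symbols, p$frequency)))
  if (is.null(syms)) return(integer())
  tab <- table(syms)
  setNames(as.integer(tab), names(tab))
}

#' Generate fresh system ID symbols
#'
#' Class labels are drawn deterministically from the sequence A, B, C, ...,
#' Z, AA, AB, ...; discriminators are `"1"`, `"2"`, ... within each class
#' (or globally unique integers when the grammar was created with
#' `unique_ids = TRUE`); the boundary symbol is `"#"` plus the class label.
#'
#' @param grammar an `sp_grammar` (holds the counter state).
#' @param n_needed number of (class, discriminator, boundary) triples wanted.
#' @param class reuse this existing class label (new discriminators within
#'   it) instead of allocating new classes.
#' @return `list(ids = <list of lists(class, disc, suffix)>, grammar = ...)`
#'   with the counter state advanced.
#' @export
generate_ids <- function(grammar, n_needed = 1L, class = NULL) {
  stopifnot(n_needed >= 1L)
  ctr <- grammar$id_counter
  out <- vector("list", n_needed)
  for (i in seq_len(n_needed)) {
    if (is.null(class)) {
      cls <- class_label(ctr$next_class)
      ctr$next_class <- ctr$next_class + 1L
    } else cls <- class
    if (ctr$unique_ids) {
      disc <- as.character(ctr$global_disc)
      ctr$global_disc <- ctr$global_disc + 1L
    } else {
      k <- (if (cls %in% names(ctr$next_disc)) ctr$next_disc[[cls]] else 1L)
      disc <- as.character(k)
      ctr$next_disc[cls] <- k + 1L
    }
    out[[i]] <- list(class = cls, disc = disc, suffix = paste0("#", cls))
  }
  grammar$id_counter <- ctr
  list(ids = out, grammar = grammar)
}

class_label <- function(i) {
  s <- character()
  i <- i - 1L
  repeat {
    s <- c(LETTERS[(i %% 26L) + 1L], s)
    i <- i %/% 26L - 1L
    if (i < 0L) break
  }
  paste(s, collapse = "")
}

# ---------------------------------------------------------------------------
# Bit-cost model.

#' Symbol bit-cost model
#'
#' Two modes.  `"uniform"` (the default used throughout the worked examples)
#' charges every symbol `ceiling(log2(d))` bits, where `d` is the number of
#' distinct symbol names across the grammar and, optionally, a New pattern.
#' `"frequency"` charges Shannon costs `log2(total_freq / freq(name))` from
#' the grammar's symbol-frequency table, so frequent symbols are cheap; these
#' costs satisfy the Kraft equality `sum(2^-cost) == 1` by construction.
#'
#' @param grammar an `sp_grammar`.
#' @param new optional New `sp_pattern` whose symbols extend the alphabet
#'   (uniform mode only).
#' @param mode `"uniform"` or `"frequency"`.
#' @return an object of class `sp_cost_model`.
#' @export
sp_cost_model <- function(grammar, new = NULL,
                          mode = c("uniform", "frequency")) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    names_seen <- unique(c(
      unlist(lapply(grammar$patterns, `[[`, "symbols"), use.names = FALSE),
      if (!is.null(new)) new$symbols))
    d <- max(1L, length(names_seen))
    structure(list(mode = "UNIFORM",
                   bits_per_symbol = max(1, ceiling(log2(d)))),
              class = "sp_cost_model")
  } else {
    freq <- grammar$symbol_freq
    if (length(freq) == 0L) stop("frequency mode needs a non-empty grammar")
    structure(list(mode = "FREQUENCY", freq = freq,
                   total_freq = sum(freq)),
              class = "sp_cost_model")
  }
}

#' Bit cost of one symbol under a cost model
#' @param model an `sp_cost_model`.
#' @param name symbol name (or vector of names; costs are summed per name,
#'   returned as a vector).
#' @return nonnegative numeric vector of costs in bits.
#' @export
symbol_cost <- function(model, name) {
  if (model$mode == "UNIFORM")
    return(rep(model$bits_per_symbol, length(name)))
  f <- model$freq[name]
  if (anyNA(f)) stop("unknown symbol in frequency mode: ",
                     paste(name[is.na(f)], collapse = ", "))
  log2(model$total_freq / as.numeric(f))
}
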