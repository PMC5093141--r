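# Pattern text dialect, version 1.
#
#   ; sp-dialect 1
#   NEW
#   t h e b i g h o u s e
#   OLD
#   B 1 | t h e | #B @ 2
#
# One pattern per line, whitespace-separated tokens, '|' delimiting the ID
# prefix and suffix of Old patterns, an optional trailing "@ <int>" frequency,
# ';' comment lines, bare NEW / OLD section headers.

#' Read a pattern file
#'
#' @param path path to a dialect v1 file.
#' @return `list(new = <list of New sp_patterns>, grammar = <sp_grammar>)`.
#'   Duplicate Old lines are merged into one stored pattern (with a warning),
#'   incrementing its frequency.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^;\\s*sp-dialect\\s+1\\s*$", lines[1L]))
    stop("not a recognised dialect file (expected header '; sp-dialect 1'): ",
         path)
  grammar <- sp_grammar()
  new <- list()
  section <- NA_character_
  seen_old <- character()
  for (i in seq_along(lines)[-1L]) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, ";")) next
    if (line %in% c("NEW", "OLD")) { section <- line; next }
    if (is.na(section))
      stop(sprintf("%s:%d: pattern line before any NEW/OLD section header",
                   path, i))
    toks <- strsplit(line, "[[:space:]]+")[[1L]]
    freq <- 1L
    nat <- which(toks == "@")
    if (length(nat) > 1L)
      stop(sprintf("%s:%d: more than one '@' frequency marker", path, i))
    if (length(nat) == 1L) {
      if (nat != length(toks) - 1L ||
          !grepl("^[0-9]+$", toks[length(toks)]))
        stop(sprintf("%s:%d: malformed '@ <int>' frequency suffix", path, i))
      freq <- as.integer(toks[length(toks)])
      toks <- toks[seq_len(nat - 1L)]
    }
    if (section == "NEW") {
      # NEW lines are raw symbol sequences (code patterns included), never
      # reinterpreted by the ID heuristic
      if (any(toks == "|"))
        stop(sprintf("%s:%d: delimiters are not allowed in the NEW section",
                     path, i))
      p <- tryCatch(
        sp_new_pattern(toks, pattern_id = paste0("new", length(new) + 1L)),
        error = function(e)
          stop(sprintf("%s:%d: %s", path, i, conditionMessage(e)),
               call. = FALSE))
      new[[length(new) + 1L]] <- p
    } else {
      p <- tryCatch(
        classify_symbols(toks, frequency = freq),
        error = function(e)
          stop(sprintf("%s:%d: %s", path, i, conditionMessage(e)),
               call. = FALSE))
      if (p$provenance != "OLD")
        stop(sprintf("%s:%d: OLD section line has no ID symbols", path, i))
      key <- paste(p$symbols, collapse = "\x1f")
      if (key %in% seen_old)
        warning(sprintf("%s:%d: duplicate Old pattern merged", path, i),
                call. = FALSE)
      seen_old <- c(seen_old, key)
      grammar <- add_pattern(grammar, p)
    }
  }
  list(new = new, grammar = grammar)
}

#' Write patterns to a dialect file
#'
#' @param path output path.
#' @param new list of New `sp_pattern`s (may be empty).
#' @param grammar an `sp_grammar` (may be empty).
#' @return `path`, invisibly.  `read_patterns(write_patterns(...))` is the
#'   identity on symbols, roles and frequencies.
#' @export
write_patterns <- function(path, new = list(), grammar = sp_grammar()) {
  out <- "; sp-dialect 1"
  if (length(new)) {
    out <- c(out, "NEW",
             vapply(new, function(p) paste(p$symbols, collapse = " "), ""))
  }
  if (length(grammar$patterns)) {
    out <- c(out, "OLD",
             vapply(grammar$patterns, function(p) {
               line <- format_pattern(p)
               if (p$frequency != 1L)
                 line <- paste(line, "@", p$frequency)
               line
             }, ""))
  }
  writeLines(out, path)
  invisible(path)
}
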