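# Shared builders for the worked-example grammars, constructed in code so
# every test is self-contained.

letters_of <- function(s) strsplit(s, "")[[1]]

# the five-pattern phrase grammar (the/big|small/house with an abstract
# sequencing pattern)
house_grammar <- function() {
  g <- sp_grammar()
  g <- add_pattern(g, sp_old_pattern(c("B", "1"), letters_of("the"), "#B"))
  g <- add_pattern(g, sp_old_pattern(c("C", "1"), letters_of("house"), "#C"))
  g <- add_pattern(g, sp_old_pattern(c("D", "1"), letters_of("small"), "#D"))
  g <- add_pattern(g, sp_old_pattern(c("D", "2"), letters_of("big"), "#D"))
  g <- add_pattern(g, sp_old_pattern(
    c("E", "1"), c("B", "#B", "D", "#D", "C", "#C"), "#E"))
  g
}

# self-referential repetition grammar (+ empty-body terminator)
very_grammar <- function() {
  g <- sp_grammar()
  g <- add_pattern(g, sp_old_pattern(c("i", "i1"), "very", "#i"))
  g <- add_pattern(g, sp_old_pattern(
    c("ri", "ri1"), c("ri", "#ri", "i", "#i"), "#ri"))
  add_pattern(g, sp_old_pattern(c("ri", "ri2"), character(0), "#ri"))
}

# a small two-leaf hierarchy that fits inside the oracle bounds
mini_grammar <- function() {
  g <- sp_grammar()
  g <- add_pattern(g, sp_old_pattern(c("B", "1"), c("a", "b"), "#B"))
  g <- add_pattern(g, sp_old_pattern(c("C", "1"), c("c", "d"), "#C"))
  add_pattern(g, sp_old_pattern(
    c("E", "1"), c("B", "#B", "C", "#C"), "#E"))
}

new_phrase <- function(s, id = "new") sp_new_pattern(letters_of(s), id)

best_alignment <- function(new, grammar, ...) {
  build_alignments(new, grammar, ...)[[1L]]
}

# brute-force enumeration of all maximal ordered match-sets between two
# symbol sequences (independent oracle for pairwise_align)
brute_matchsets <- function(a, b) {
  cand <- list()
  for (i in seq_along(a)) for (j in seq_along(b))
    if (a[i] == b[j]) cand[[length(cand) + 1L]] <- c(i, j)
  n <- length(cand)
  out <- list()
  compat <- function(set, k) {
    for (s in set) {
      if (cand[[s]][1] == cand[[k]][1] || cand[[s]][2] == cand[[k]][2])
        return(FALSE)
      if ((cand[[s]][1] < cand[[k]][1]) != (cand[[s]][2] < cand[[k]][2]))
        return(FALSE)
    }
    TRUE
  }
  recur <- function(set, start) {
    ext <- FALSE
    for (k in seq_len(n)) {
      if (k < start || !compat(set, k)) next
      ext <- TRUE
      recur(c(set, k), k + 1L)
    }
    if (!ext && length(set)) {
      ok <- TRUE
      for (k in seq_len(n)) if (!(k %in% set) && compat(set, k)) ok <- FALSE
      if (ok) out[[length(out) + 1L]] <<- t(vapply(cand[set], identity,
                                                  c(0L, 0L)))
    }
  }
  recur(integer(0), 1L)
  out
}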