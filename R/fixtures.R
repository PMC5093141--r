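# Worked-example fixtures and the synthetic-corpus generator.  The fixtures
# are the small grammars whose behaviour is fully determined in the
# literature this engine operationalizes: the the-big/small-house learning
# example, the self-referential "very very very" grammar, and the recursive
# triangle (corner/line) grammar.  The generator samples sentences from a
# known slot-template grammar so that learning can be tested against ground
# truth without any external data.

#' Load the packaged worked-example fixtures
#'
#' Each fixture bundles a grammar, input sequences, and structured
#' expectations: `house` (one stored phrase plus the five-pattern grammar
#' that splitting it against a second phrase must produce), `very` (a
#' self-referential pattern whose best alignment must contain one appearance
#' per repetition), and `triangle` (two-level recursion: lines of points,
#' segments of corner+line, a polygon of segments; the `LN.ln2` base case
#' and the `CR.cr1` corner pattern are artifact additions that close the
#' recursion, not part of the source grammars).
#'
#' @return named list of fixtures, each
#'   `list(name, grammar, inputs, expected)`.
#' @export
make_fixtures <- function() {
  rd <- function(f) read_patterns(system.file("extdata", f,
                                              package = "icmup",
                                              mustWork = TRUE))
  house0 <- rd("house_initial.sp")
  house1 <- rd("house_learned.sp")
  very <- rd("very.sp")
  tri <- rd("triangle.sp")
  list(
    house = list(
      name = "house",
      grammar = house0$grammar,
      grammar_learned = house1$grammar,
      inputs = house0$new,
      expected = list(
        split_bodies = sort(c("t h e", "h o u s e", "s m a l l", "b i g",
                              "B #B D #D C #C")),
        appearance_classes = sort(c("B", "C", "D", "E")),
        round_trip = TRUE)),
    very = list(
      name = "very",
      grammar = very$grammar,
      inputs = very$new,
      expected = list(ri_pattern = "ri.ri1",
                      ri_appearances_equal_n = TRUE,
                      round_trip = TRUE)),
    triangle = list(
      name = "triangle",
      grammar = tri$grammar,
      inputs = tri$new,
      expected = list(sg_pattern = "SG.sg1", sg_appearances = 3L,
                      round_trip = TRUE)))
}

#' Define a slot-template grammar
#'
#' A template is an ordered list of slots, each a set of words (a word is
#' spelled out as letter symbols when sampled).  An optional recursion slot
#' repeats a bounded number of times.  Sampling always terminates and every
#' sampled sentence is parseable by the template's own pattern encoding
#' ([template_grammar()]).
#'
#' @param slots list of character vectors of words.
#' @param recursion optional `list(slot = <index>, max_repeat = <int>)`.
#' @return an object of class `sp_template`.
#' @export
sp_template <- function(slots, recursion = NULL) {
  stopifnot(length(slots) >= 1L, all(vapply(slots, length, 0L) >= 1L))
  if (!is.null(recursion))
    stopifnot(recursion$slot %in% seq_along(slots),
              recursion$max_repeat >= 1L)
  structure(list(slots = slots, recursion = recursion),
            class = "sp_template")
}

#' The default study template
#'
#' Two determiners, five adjectives and five nouns (50 sentence types).
#' Two properties matter: enough lexical diversity that shared slot
#' structure genuinely beats storing sentences whole under a two-part
#' code, and at least two alternatives in every slot -- a slot with a
#' single constant filler is not identifiable from distributional data
#' (fusing it into the neighbouring class gives a strictly shorter code),
#' so its recovery could not be demanded of any sound learner.
#' @return an `sp_template`.
#' @export
default_template <- function() {
  sp_template(list(
    c("the", "one"),
    c("big", "small", "old", "new", "fine"),
    c("house", "table", "garden", "candle", "basket")))
}

#' The template's exact pattern encoding (ground truth)
#'
#' One leaf pattern per word, one class per slot, and one abstract pattern
#' sequencing the slot classes; a recursion slot is encoded through a
#' self-referential wrapper pattern.
#'
#' @param template an `sp_template`.
#' @return an `sp_grammar`.
#' @export
template_grammar <- function(template) {
  g <- sp_grammar()
  k <- length(template$slots)
  classes <- paste0("S", seq_len(k))
  for (i in seq_len(k)) {
    for (j in seq_along(template$slots[[i]])) {
      w <- strsplit(template$slots[[i]][j], "")[[1L]]
      g <- add_pattern(g, sp_old_pattern(
        c(classes[i], as.character(j)), w, paste0("#", classes[i])))
    }
  }
  body <- character(0)
  for (i in seq_len(k)) {
    if (!is.null(template$recursion) && template$recursion$slot == i) {
      g <- add_pattern(g, sp_old_pattern(
        c("Q", "q1"),
        c("Q", "#Q", classes[i], paste0("#", classes[i])), "#Q"))
      body <- c(body, "Q", "#Q")
    } else {
      body <- c(body, classes[i], paste0("#", classes[i]))
    }
  }
  add_pattern(g, sp_old_pattern(c("R", "r1"), body, "#R"))
}

#' Sample a synthetic corpus from a template
#'
#' Reproducible given the seed; sentences are emitted as letter-level New
#' patterns.  The template's exact pattern encoding travels along as
#' attribute `"truth"`, and the word-level sentences as attribute
#' `"sentences"`.
#'
#' @param template an `sp_template`.
#' @param n number of sentences (>= 1).
#' @param seed integer seed.
#' @return list of New `sp_pattern`s.
#' @export
sample_corpus <- function(template, n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- vector("list", n)
  words <- character(n)
  for (s in seq_len(n)) {
    sent <- character(0)
    for (i in seq_along(template$slots)) {
      reps <- 1L
      if (!is.null(template$recursion) && template$recursion$slot == i)
        reps <- sample.int(template$recursion$max_repeat, 1L)
      for (r in seq_len(reps))
        sent <- c(sent, template$slots[[i]][
          sample.int(length(template$slots[[i]]), 1L)])
    }
    words[s] <- paste(sent, collapse = " ")
    out[[s]] <- sp_new_pattern(
      unlist(strsplit(sent, ""), use.names = FALSE),
      pattern_id = paste0("s", s))
  }
  attr(out, "truth") <- template_grammar(template)
  attr(out, "sentences") <- words
  out
}

#' Slot partition of a template
#'
#' The ground-truth partition of words into substitution classes, in the
#' same form as [grammar_classes()] (letter-spelled, space-joined bodies).
#'
#' @param template an `sp_template`.
#' @return list of sorted character vectors, one per slot.
#' @export
template_slot_partition <- function(template) {
  lapply(template$slots, function(w)
    sort(vapply(w, function(x)
      paste(strsplit(x, "")[[1L]], collapse = " "), "",
      USE.NAMES = FALSE)))
}

#' Does an induced grammar recover the template's slot partition?
#'
#' Compares the induced substitution classes (as sets of terminal bodies)
#' with the template's slots, ignoring class labels.
#'
#' @param grammar an induced `sp_grammar`.
#' @param template the generating `sp_template`.
#' @return logical.
#' @export
recovers_slot_partition <- function(grammar, template) {
  got <- grammar_classes(grammar)
  want <- template_slot_partition(template)
  ser <- function(x) sort(unname(vapply(x, function(v)
    paste(sort(unname(v)), collapse = "|"), "")))
  identical(ser(got), ser(want))
}
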