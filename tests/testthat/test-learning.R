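test_that("the first stored sentence is kept whole with fresh service symbols", {
  r <- assimilate(new_phrase("thebighouse", "s1"), sp_grammar())
  expect_identical(r$event$kind, "STORE_DIRECT")
  expect_length(r$grammar$patterns, 1L)
  p <- r$grammar$patterns[[1L]]
  expect_identical(p$symbols,
                   c("A", "1", letters_of("thebighouse"), "#A"))
  # one-trial storage: the sequence parses fully straight away
  b <- best_alignment(new_phrase("thebighouse"), r$grammar)
  expect_identical(sum(b$col_n[b$colid[[1L]]] >= 2L), 11L)
})

test_that("an exact repeat increments frequencies without growing the store", {
  g <- assimilate(new_phrase("thebighouse", "s1"), sp_grammar())$grammar
  r <- assimilate(new_phrase("thebighouse", "s2"), g)
  expect_identical(r$event$kind, "FREQ_INCREMENT")
  expect_length(r$grammar$patterns, 1L)
  expect_identical(r$grammar$patterns[[1L]]$frequency, 2L)
})

test_that("a partial match splits into parts, alternatives and an abstraction", {
  g <- assimilate(new_phrase("thebighouse", "s1"), sp_grammar())$grammar
  r <- assimilate(new_phrase("thesmallhouse", "s2"), g)
  expect_identical(r$event$kind, "SPLIT_AND_ABSTRACT")
  g2 <- r$grammar
  bodies <- sort(unname(vapply(g2$patterns, function(p)
    paste(pattern_body(p), collapse = ""), "")))
  expect_identical(bodies,
                   sort(c("the", "house", "small", "big", "B#BD#DC#C")))
  # canonical labelling: shared runs take B and C, the gap class is D with
  # the incoming sentence's word first
  expect_identical(paste(pattern_body(g2$patterns[["D.1"]]), collapse = ""),
                   "small")
  expect_identical(paste(pattern_body(g2$patterns[["D.2"]]), collapse = ""),
                   "big")
  # the split source is retired
  expect_false("A.1" %in% names(g2$patterns))
  # both phrases now parse fully
  for (s in c("thebighouse", "thesmallhouse")) {
    b <- best_alignment(new_phrase(s), g2)
    expect_identical(sum(b$col_n[b$colid[[1L]]] >= 2L),
                     nchar(s))
  }
})

test_that("identical bodies do not split", {
  g <- sp_grammar()
  g <- add_pattern(g, sp_old_pattern(c("A", "1"), letters_of("abc"), "#A"))
  new <- new_phrase("abc")
  ma <- best_alignment(new, g)
  res <- derive_from_alignment(ma, g)
  expect_length(res$patterns, 0L)
})

test_that("an open slot of the hierarchy is filled by a sibling pattern", {
  g <- assimilate(new_phrase("thebighouse", "s1"), sp_grammar())$grammar
  g <- assimilate(new_phrase("thesmallhouse", "s2"), g)$grammar
  r <- assimilate(new_phrase("thebigtable", "s3"), g)
  expect_identical(r$event$kind, "SPLIT_AND_ABSTRACT")
  classes <- grammar_classes(r$grammar)
  expect_true("t a b l e" %in% classes[["C"]])
  b <- best_alignment(new_phrase("thebigtable"), r$grammar)
  expect_identical(sum(b$col_n[b$colid[[1L]]] >= 2L), 11L)
})

test_that("grammar scoring decomposes into description plus encoding", {
  corpus <- list(new_phrase("thebighouse", "s1"),
                 new_phrase("thesmallhouse", "s2"))
  empty <- score_grammar(sp_grammar(), corpus)
  model <- icmup:::corpus_cost_model(sp_grammar(), corpus)
  expect_identical(empty$g_bits, 0)
  expect_identical(empty$e_bits,
                   sum(symbol_cost(model, unlist(lapply(corpus, `[[`,
                                                        "symbols")))))
  g <- house_grammar()
  sc <- score_grammar(g, corpus)
  expect_identical(sc$t_bits, sc$g_bits + sc$e_bits)
  expect_identical(sc$coverage, 1)
})

test_that("pruning removes unused patterns and never raises the score", {
  corpus <- list(new_phrase("thebighouse", "s1"),
                 new_phrase("thesmallhouse", "s2"))
  g <- house_grammar()
  g <- add_pattern(g, sp_old_pattern(c("Z", "1"), letters_of("zebra"), "#Z"))
  sc <- score_grammar(g, corpus)
  expect_identical(unname(sc$usage["Z.1"]), 0L)
  pruned <- prune(g, sc$usage)
  expect_false("Z.1" %in% names(pruned$patterns))
  expect_lte(score_grammar(pruned, corpus)$t_bits, sc$t_bits)
  # every pattern used: pruning is the identity
  g0 <- house_grammar()
  sc0 <- score_grammar(g0, corpus)
  expect_identical(names(prune(g0, sc0$usage)$patterns), names(g0$patterns))
})

test_that("replaying the event log reproduces the grammar", {
  sents <- c("thebighouse", "thebighouse", "thesmallhouse", "thebigtable")
  g <- sp_grammar()
  events <- list()
  for (i in seq_along(sents)) {
    r <- assimilate(new_phrase(sents[i], paste0("s", i)), g)
    g <- r$grammar
    events <- c(events, list(r$event))
  }
  replayed <- replay_events(events)
  expect_identical(lapply(replayed$patterns, `[[`, "symbols"),
                   lapply(g$patterns, `[[`, "symbols"))
  expect_identical(vapply(replayed$patterns, `[[`, 0L, "frequency"),
                   vapply(g$patterns, `[[`, 0L, "frequency"))
  expect_identical(replayed$symbol_freq[sort(names(replayed$symbol_freq))],
                   g$symbol_freq[sort(names(g$symbol_freq))])
})

test_that("induction on a small corpus finds shared structure", {
  sents <- rep(c("thebighouse", "thesmallhouse"), 3L)
  corpus <- lapply(seq_along(sents), function(i)
    new_phrase(sents[i], paste0("s", i)))
  cands <- induce(corpus, sp_search_params())
  best <- cands[[1L]]
  bodies <- vapply(best$grammar$patterns, function(p)
    paste(pattern_body(p), collapse = ""), "")
  expect_true("the" %in% bodies)
  expect_true("house" %in% bodies)
  expect_setequal(grammar_classes(best$grammar)[["D"]],
                  c("b i g", "s m a l l"))
  expect_identical(best$coverage, 1)
  # a single sentence is simply stored
  one <- induce(corpus[1L], sp_search_params())
  expect_length(one[[1L]]$grammar$patterns, 1L)
})

test_that("induction is reproducible for a fixed seed and order", {
  corpus <- sample_corpus(default_template(), 6L, seed = 7)
  a <- induce(corpus, sp_search_params(), seed = 3L, shuffle = TRUE)
  b <- induce(corpus, sp_search_params(), seed = 3L, shuffle = TRUE)
  expect_identical(icmup:::grammar_signature(a[[1L]]$grammar),
                   icmup:::grammar_signature(b[[1L]]$grammar))
  expect_identical(a[[1L]]$t_bits, b[[1L]]$t_bits)
})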