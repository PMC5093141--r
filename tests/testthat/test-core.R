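test_that("token classification assigns service and contents roles", {
  p <- classify_symbols(c("B", "1", "|", "t", "h", "e", "|", "#B"))
  expect_identical(p$symbols, c("B", "1", "t", "h", "e", "#B"))
  expect_identical(id_prefix_len(p), 2L)
  expect_identical(id_suffix_len(p), 1L)
  expect_identical(pattern_body(p), c("t", "h", "e"))

  n <- classify_symbols(c("t", "h", "e"))
  expect_identical(n$provenance, "NEW")
  expect_true(all(n$role == "CONTENTS"))

  # a body made of references to other patterns is still all contents
  e <- classify_symbols(c("E", "1", "|", "B", "#B", "D", "#D", "C", "#C",
                          "|", "#E"))
  expect_identical(pattern_body(e), c("B", "#B", "D", "#D", "C", "#C"))

  expect_error(classify_symbols(character(0)))
  expect_error(classify_symbols(c("B", "1", "|", "t", "|", "x", "|", "#B")))
  expect_error(classify_symbols(c("B", "1", "|", "t", "|", "t")))
  expect_warning(classify_symbols(c("B", "1", "t", "h", "e", "#B")),
                 "fallback")
})

test_that("the pattern store merges duplicates and keeps counts consistent", {
  g <- sp_grammar()
  p <- sp_old_pattern(c("A", "1"), letters_of("thebighouse"), "#A")
  g <- add_pattern(g, p)
  expect_length(g$patterns, 1L)
  g <- add_pattern(g, p)
  expect_length(g$patterns, 1L)
  expect_identical(g$patterns[[1L]]$frequency, 2L)
  g <- add_pattern(g, sp_old_pattern(c("B", "1"), letters_of("the"), "#B"))
  # brute-force recount equals the running table, and total mass equals
  # pattern length times frequency
  expect_identical(sort(names(recount_symbol_freq(g))),
                   sort(names(g$symbol_freq)))
  expect_identical(recount_symbol_freq(g)[sort(names(g$symbol_freq))],
                   g$symbol_freq[sort(names(g$symbol_freq))])
  expect_identical(sum(g$symbol_freq),
                   sum(vapply(g$patterns, function(p)
                     length(p$symbols) * p$frequency, 0L)))
  expect_error(add_pattern(g, sp_new_pattern("x")))
  g2 <- remove_pattern(g, names(g$patterns)[1L])
  expect_identical(recount_symbol_freq(g2)[sort(names(g2$symbol_freq))],
                   g2$symbol_freq[sort(names(g2$symbol_freq))])
})

test_that("generated service symbols follow the deterministic scheme", {
  g <- sp_grammar()
  r1 <- generate_ids(g, 1L)
  expect_identical(r1$ids[[1L]],
                   list(class = "A", disc = "1", suffix = "#A"))
  # two alternatives inside one class get successive discriminators
  r2 <- generate_ids(r1$grammar, 2L, class = "D")
  expect_identical(r2$ids[[1L]]$disc, "1")
  expect_identical(r2$ids[[2L]]$disc, "2")
  expect_identical(r2$ids[[2L]]$suffix, "#D")
  # determinism: same counter state, same output
  again <- generate_ids(g, 1L)
  expect_identical(again$ids, r1$ids)
  # class labels roll over past Z
  g27 <- g
  for (k in 1:27) g27 <- generate_ids(g27, 1L)$grammar
  expect_identical(generate_ids(g27, 1L)$ids[[1L]]$class, "AB")
  # globally unique discriminators on request
  gu <- sp_grammar(unique_ids = TRUE)
  u1 <- generate_ids(gu, 1L)
  u2 <- generate_ids(u1$grammar, 1L)
  expect_false(identical(u1$ids[[1L]]$disc, u2$ids[[1L]]$disc))
})

test_that("symbol costs follow the model invariants", {
  g <- sp_grammar()
  g <- add_pattern(g, sp_old_pattern(c("X", "1"), letters[1:13], "#X"))
  # 16 distinct names -> 4 bits each in uniform mode
  expect_length(g$symbol_freq, 16L)
  um <- sp_cost_model(g)
  expect_identical(symbol_cost(um, "a"), 4)

  # frequency mode: total 8 with frequency 2 costs log2(8/2) = 2 bits
  g8 <- sp_grammar()
  g8 <- add_pattern(g8, sp_old_pattern(c("P", "1"),
                                       c("a", "a", "b", "c", "d"), "#P"))
  fm <- sp_cost_model(g8, mode = "frequency")
  expect_identical(sum(g8$symbol_freq), 8L)
  expect_identical(symbol_cost(fm, "a"), 2)
  expect_error(symbol_cost(fm, "nope"))
  # Kraft equality when costs come from exact frequencies
  expect_equal(sum(2^-symbol_cost(fm, names(g8$symbol_freq))), 1)
  # a more frequent symbol is never dearer
  expect_lte(symbol_cost(fm, "a"), symbol_cost(fm, "b"))
})

test_that("dialect files round-trip patterns, roles and frequencies", {
  path <- withr::local_tempfile(fileext = ".sp")
  g <- house_grammar()
  g$patterns[["B.1"]]$frequency <- 3L
  new <- list(new_phrase("thebighouse", "s1"), sp_new_pattern("very", "s2"))
  write_patterns(path, new, g)
  back <- read_patterns(path)
  expect_length(back$new, 2L)
  expect_identical(back$new[[1L]]$symbols, new[[1L]]$symbols)
  expect_identical(lapply(back$grammar$patterns, `[[`, "symbols"),
                   lapply(g$patterns, `[[`, "symbols"))
  expect_identical(back$grammar$patterns[["B.1"]]$frequency, 3L)
  # second write of the re-read state is byte-identical (fixpoint)
  path2 <- withr::local_tempfile(fileext = ".sp")
  write_patterns(path2, back$new, back$grammar)
  expect_identical(readLines(path), readLines(path2))

  bad <- withr::local_tempfile(fileext = ".sp")
  writeLines(c("; sp-dialect 1", "OLD", "B 1 | t | h | #B"), bad)
  expect_error(read_patterns(bad), ":3:")
  writeLines(c("no header"), bad)
  expect_error(read_patterns(bad), "dialect")
  writeLines(c("; sp-dialect 1", "OLD", "B 1 | t h e | #B",
               "B 1 | t h e | #B"), bad)
  expect_warning(res <- read_patterns(bad), "duplicate")
  expect_identical(res$grammar$patterns[[1L]]$frequency, 2L)
})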