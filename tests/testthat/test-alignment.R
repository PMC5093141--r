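test_that("pairwise alignment finds order-preserving match-sets", {
  tgt <- sp_old_pattern(c("A", "1"), letters_of("thebighouse"), "#A")
  sets <- pairwise_align(letters_of("thesmallhouse"), tgt)
  best <- sets[[1L]]
  # the shared runs are "the" and "house"; "small"/"big" stay unmatched
  expect_identical(best$driving,
                   c(1L, 2L, 3L, 9L, 10L, 11L, 12L, 13L))
  expect_identical(tgt$symbols[best$target],
                   c("t", "h", "e", "h", "o", "u", "s", "e"))
  # identical sequences match completely
  idt <- pairwise_align(c("a", "b", "c"),
                        sp_old_pattern(c("X", "1"), c("a", "b", "c"), "#X"))
  expect_identical(idt[[1L]]$driving, 1:3)
  expect_identical(length(pairwise_align("z", tgt)), 0L)
})

test_that("ranked pairwise match-sets agree with brute-force enumeration", {
  cases <- list(
    list(a = c("a", "b", "a", "c"), b = c("a", "c", "a")),
    list(a = c("x", "x", "y"), b = c("x", "y", "x")),
    list(a = letters_of("abcab"), b = letters_of("bca")))
  for (cs in cases) {
    tgt <- sp_old_pattern(c("T", "1"), cs$b, "#T")
    got <- pairwise_align(cs$a, tgt, max_hits = 100L)
    # positions of cs$b inside the stored pattern are offset by the prefix
    got_sets <- lapply(got, function(s)
      paste(s$driving, s$target - 2L, collapse = ";"))
    want <- brute_matchsets(cs$a, cs$b)
    want_sets <- vapply(want, function(m)
      paste(m[order(m[, 1L]), 1L], m[order(m[, 1L]), 2L], collapse = ";"),
      "")
    expect_setequal(got_sets, want_sets)
    # and the first returned set attains the maximal size
    expect_identical(nrow(got[[1L]]),
                     max(vapply(want, nrow, 0L)))
  }
})

test_that("the phrase fixture parses into the full hierarchy", {
  g <- house_grammar()
  b <- best_alignment(new_phrase("thebighouse"), g)
  expect_identical(appearance_multiset(b),
                   sort(c("B.1", "C.1", "D.2", "E.1")))
  # every input symbol is matched
  expect_identical(b$score$b_new, 11 * 5)
  # the abstract pattern is aligned with three other patterns at once
  erow <- which(vapply(b$rows, function(r)
    identical(r$pattern_id, "E.1"), TRUE))
  partners <- unique(b$cols$row[b$cols$col %in% b$colid[[erow]] &
                                  b$cols$row != erow])
  expect_gte(length(setdiff(partners, 1L)), 3L)
})

test_that("alignments respect legality on construction", {
  g <- house_grammar()
  b <- best_alignment(new_phrase("thebighouse"), g)
  expect_silent(aln_validate(b))
  # per-row positions strictly increase along column order
  tp <- match(seq_along(b$col_n), b$topo)
  for (r in seq_along(b$rows))
    expect_true(all(diff(tp[b$colid[[r]]]) > 0))
  # column homogeneity
  for (k in seq_along(b$col_n)) {
    e <- b$cols[b$cols$col == k, , drop = FALSE]
    expect_length(unique(e$name), 1L)
    expect_lte(nrow(e), 2L)
  }
})

test_that("scoring follows the compression ledger", {
  g <- house_grammar()
  model <- sp_cost_model(g, new_phrase("thebighouse"))
  # degenerate single-row alignment explains nothing
  a0 <- score_alignment(build_alignments(new_phrase("zzz"),
                                         sp_grammar())[[1L]], model)
  expect_identical(a0$score$b_new, 0)
  expect_identical(a0$score$cs, 0)
  b <- best_alignment(new_phrase("thebighouse"), g)
  c5 <- symbol_cost(model, "t")
  # gain: 11 letters + 6 resolved references; code: E 1 1 2 1 #E
  expect_identical(b$score$b_gain, 17 * c5)
  expect_identical(b$score$b_code, 6 * c5)
  expect_identical(b$score$cs, 11 * c5)
})

test_that("rendering round-trips alignments", {
  g <- house_grammar()
  for (s in c("thebighouse", "thesmallhouse", "theighouse")) {
    new <- new_phrase(s)
    b <- best_alignment(new, g)
    txt <- render_alignment(b)
    back <- parse_alignment(txt, new, g)
    expect_identical(aln_signature(back), aln_signature(b))
  }
  cols <- render_alignment(best_alignment(new_phrase("thebighouse"), g),
                           style = "columns")
  expect_length(cols, length(best_alignment(new_phrase("thebighouse"),
                                            g)$col_n))
})

test_that("alignment JSON carries rows, columns and score", {
  b <- best_alignment(new_phrase("thebighouse"), house_grammar())
  j <- jsonlite::fromJSON(alignment_json(b), simplifyVector = FALSE)
  expect_named(j, c("rows", "columns", "score"))
  expect_length(j$rows, length(b$rows))
  expect_equal(j$score$cs, b$score$cs)
})

test_that("recursion yields one appearance per repetition", {
  g <- very_grammar()
  for (n in 1:5) {
    b <- best_alignment(sp_new_pattern(rep("very", n)), g)
    expect_identical(sum(appearance_multiset(b) == "ri.ri1"), as.integer(n))
    expect_identical(sum(appearance_multiset(b) == "i.i1"), as.integer(n))
  }
})

test_that("single-symbol corruptions leave the recognized structure intact", {
  g <- house_grammar()
  want <- sort(c("B.1", "C.1", "D.2", "E.1"))
  corrupted <- c("thebghouse",     # omission
                 "thebigxhouse",   # commission
                 "theZighouse")    # substitution
  for (s in corrupted) {
    b <- best_alignment(new_phrase(s), g)
    expect_identical(appearance_multiset(b), want)
  }
})

test_that("empty grammar yields only the degenerate alignment", {
  alns <- build_alignments(new_phrase("abc"), sp_grammar())
  expect_length(alns, 1L)
  expect_length(alns[[1L]]$rows, 1L)
  expect_lte(alns[[1L]]$score$cs, 0)
})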