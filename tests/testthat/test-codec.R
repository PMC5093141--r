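test_that("code derivation collects the unresolved service symbols in order", {
  g <- house_grammar()
  b <- best_alignment(new_phrase("thebighouse"), g)
  expect_identical(derive_code(b)$symbols, c("E", "1", "1", "2", "1", "#E"))
  # a single-row alignment of raw input leaves no code
  a0 <- build_alignments(new_phrase("abc"), sp_grammar())[[1L]]
  expect_length(derive_code(a0)$symbols, 0L)
  # recognizing an input equal to one stored body leaves only that
  # pattern's own service symbols
  g1 <- sp_grammar()
  g1 <- add_pattern(g1, sp_old_pattern(c("B", "1"), letters_of("the"), "#B"))
  b1 <- best_alignment(new_phrase("the"), g1)
  expect_identical(derive_code(b1)$symbols, c("B", "1", "#B"))
})

test_that("decoding the derived code re-creates the input", {
  g <- house_grammar()
  for (s in c("thebighouse", "thesmallhouse")) {
    new <- new_phrase(s)
    code <- derive_code(best_alignment(new, g))
    expect_identical(decode(code, g), new$symbols)
  }
  vg <- very_grammar()
  for (n in c(1L, 3L)) {
    nv <- sp_new_pattern(rep("very", n))
    code <- derive_code(best_alignment(nv, vg))
    expect_identical(decode(code, vg), nv$symbols)
  }
})

test_that("decode failures are explicit typed conditions", {
  g <- house_grammar()
  expect_error(decode(character(0), g), class = "sp_decode_failure")
  expect_error(decode(c("Q", "9"), sp_grammar()),
               class = "sp_decode_failure")
  expect_error(decode(c("Q", "9", "#Q"), g), class = "sp_decode_failure")
})

test_that("residual redundancy reports genuine compression", {
  g <- house_grammar()
  new <- new_phrase("thebighouse")
  b <- best_alignment(new, g)
  model <- sp_cost_model(g, new)
  rep <- residual_redundancy(b, model)
  # 11 letters against a 6-symbol code at equal cost
  expect_equal(rep$ratio, 11 / 6)
  expect_true(rep$compressed)
  # the ratio is invariant under uniform rescaling of symbol costs
  model2 <- model
  model2$bits_per_symbol <- model$bits_per_symbol * 3
  expect_equal(residual_redundancy(b, model2)$ratio, rep$ratio)
})

test_that("the best code is no longer than any rival's within oracle bounds", {
  m <- mini_grammar()
  nm <- sp_new_pattern(c("a", "b", "c", "d"))
  best <- best_alignment(nm, m)
  or <- enumerate_alignments_oracle(
    nm, m, bounds = list(max_symbols = 25, max_appearances = 1))
  full <- Filter(function(r) r$b_gain >= best$score$b_gain, or$alignments)
  expect_true(all(vapply(full, `[[`, 0, "b_code") >= best$score$b_code))
})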