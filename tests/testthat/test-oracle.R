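test_that("oracle count on a two-letter input matches hand enumeration", {
  g <- sp_grammar()
  g <- add_pattern(g, sp_old_pattern(c("X", "1"), "a", "#X"))
  or <- enumerate_alignments_oracle(sp_new_pattern(c("a", "a")), g)
  # by hand: the degenerate alignment; one appearance on the first or the
  # second position; two appearances covering both.  Pairing two service
  # symbols is illegal, so no other configuration exists.
  expect_identical(or$n, 4L)
  expect_identical(or$best, 0)
})

test_that("oracle refuses instances beyond its bounds", {
  g <- house_grammar()
  expect_error(
    enumerate_alignments_oracle(new_phrase("thebighouse"), g),
    "bounds")
})

test_that("heuristic best equals exhaustive best on small instances", {
  m <- mini_grammar()
  nm <- sp_new_pattern(c("a", "b", "c", "d"))
  or <- enumerate_alignments_oracle(
    nm, m, bounds = list(max_symbols = 25, max_appearances = 1))
  expect_identical(or$best, best_alignment(nm, m)$score$cs)
  expect_identical(or$best_rows$rows, sort(c("B.1", "C.1", "E.1")))

  vg <- very_grammar()
  for (n in 1:2) {
    nv <- sp_new_pattern(rep("very", n))
    orv <- enumerate_alignments_oracle(
      nv, vg, bounds = list(max_symbols = 25, max_appearances = 2))
    expect_identical(orv$best, best_alignment(nv, vg)$score$cs)
  }

  # corrupted input: optimum still matched by the heuristic
  nx <- sp_new_pattern(c("a", "x", "c", "d"))
  orx <- enumerate_alignments_oracle(
    nx, m, bounds = list(max_symbols = 25, max_appearances = 1))
  expect_identical(orx$best, best_alignment(nx, m)$score$cs)
})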