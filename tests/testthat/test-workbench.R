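test_that("packaged fixtures load and carry their expectations", {
  fx <- make_fixtures()
  expect_named(fx, c("house", "very", "triangle"))
  expect_length(fx$house$grammar$patterns, 1L)
  expect_length(fx$house$grammar_learned$patterns, 5L)
  expect_length(fx$very$grammar$patterns, 3L)
  expect_length(fx$triangle$grammar$patterns, 6L)
  # write-read identity on the packaged files
  for (f in c("house_initial.sp", "house_learned.sp", "very.sp",
              "triangle.sp")) {
    src <- system.file("extdata", f, package = "icmup", mustWork = TRUE)
    d <- read_patterns(src)
    tmp <- withr::local_tempfile(fileext = ".sp")
    write_patterns(tmp, d$new, d$grammar)
    back <- read_patterns(tmp)
    expect_identical(lapply(back$grammar$patterns, `[[`, "symbols"),
                     lapply(d$grammar$patterns, `[[`, "symbols"))
  }
})

test_that("the recursive polygon fixture parses with three segments", {
  fx <- make_fixtures()$triangle
  b <- best_alignment(fx$inputs[[1L]], fx$grammar)
  apps <- appearance_multiset(b)
  expect_identical(sum(apps == "SG.sg1"), 3L)
  expect_identical(sum(apps == "CR.cr1"), 3L)
  expect_identical(sum(apps == "TR.tr1"), 3L)
  # full round trip through its code
  expect_identical(decode(derive_code(b), fx$grammar),
                   fx$inputs[[1L]]$symbols)
})

test_that("sampled corpora are reproducible and drawn from the template", {
  tpl <- sp_template(list(c("the"), c("big", "small"),
                          c("house", "table")))
  a <- sample_corpus(tpl, 8L, seed = 1)
  b <- sample_corpus(tpl, 8L, seed = 1)
  expect_identical(lapply(a, `[[`, "symbols"), lapply(b, `[[`, "symbols"))
  expect_false(identical(lapply(a, `[[`, "symbols"),
                         lapply(sample_corpus(tpl, 8L, seed = 2), `[[`,
                                "symbols")))
  types <- paste(c("the"), rep(c("big", "small"), each = 2),
                 c("house", "table"))
  expect_true(all(attr(a, "sentences") %in% types))
  # the ground-truth encoding parses every sampled sentence fully
  truth <- attr(a, "truth")
  for (s in a[1:3]) {
    al <- best_alignment(s, truth)
    expect_identical(sum(al$col_n[al$colid[[1L]]] >= 2L),
                     length(s$symbols))
  }
})

test_that("templates with a recursion slot sample bounded repeats", {
  tpl <- sp_template(list(c("very"), c("fast")),
                     recursion = list(slot = 1L, max_repeat = 3L))
  corpus <- sample_corpus(tpl, 20L, seed = 5)
  reps <- vapply(corpus, function(s)
    sum(s$symbols %in% letters_of("very")) / 4L, 0)
  expect_true(all(reps >= 1 & reps <= 3))
})

test_that("slot recovery comparison ignores labels but not membership", {
  tpl <- sp_template(list(c("the"), c("big", "small"), c("house", "table")))
  g <- sp_grammar()
  g <- add_pattern(g, sp_old_pattern(c("Q", "1"), letters_of("the"), "#Q"))
  g <- add_pattern(g, sp_old_pattern(c("R", "1"), letters_of("big"), "#R"))
  g <- add_pattern(g, sp_old_pattern(c("R", "2"), letters_of("small"), "#R"))
  g <- add_pattern(g, sp_old_pattern(c("S", "1"), letters_of("house"), "#S"))
  g <- add_pattern(g, sp_old_pattern(c("S", "2"), letters_of("table"), "#S"))
  g <- add_pattern(g, sp_old_pattern(
    c("T", "1"), c("Q", "#Q", "R", "#R", "S", "#S"), "#T"))
  expect_true(recovers_slot_partition(g, tpl))
  g2 <- add_pattern(g, sp_old_pattern(c("R", "3"), letters_of("tiny"), "#R"))
  expect_false(recovers_slot_partition(g2, tpl))
})

test_that("the command line front end runs its subcommands", {
  tmp <- withr::local_tempfile(fileext = ".sp")
  g <- house_grammar()
  write_patterns(tmp, list(new_phrase("thebighouse")), g)
  expect_identical(suppressMessages(
    sp_cli(c("align", "--file", tmp, "--out", "json"))), 0L)
  out <- capture.output(suppressMessages(
    sp_cli(c("encode", "--file", tmp))))
  expect_identical(out, "E 1 1 2 1 #E")
  code_file <- withr::local_tempfile(fileext = ".sp")
  write_patterns(code_file,
                 list(sp_new_pattern(c("E", "1", "1", "2", "1", "#E"))), g)
  dec <- capture.output(suppressMessages(
    sp_cli(c("decode", "--file", code_file))))
  expect_identical(dec, paste(letters_of("thebighouse"), collapse = " "))
  expect_identical(suppressMessages(
    sp_cli(c("capacity", "--out", "json"))), 0L)
  # distinct failure exits: usage vs decode failure
  expect_identical(suppressMessages(sp_cli(c("bogus"))), 2L)
  empty_code <- withr::local_tempfile(fileext = ".sp")
  write_patterns(empty_code, list(sp_new_pattern("zz")), g)
  expect_identical(suppressMessages(
    sp_cli(c("decode", "--file", empty_code))), 4L)
})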