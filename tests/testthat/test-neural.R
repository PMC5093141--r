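test_that("graph compilation mirrors the grammar deterministically", {
  g <- house_grammar()
  graph <- compile_graph(g)
  expect_length(graph$assemblies, 5L)
  # node sequences equal the source patterns
  for (id in names(g$patterns))
    expect_identical(graph$assemblies[[id]]$symbols, g$patterns[[id]]$symbols)
  # receptor alphabet is the terminal vocabulary
  expect_setequal(graph$receptors, unique(letters_of("thebigsmallhouse")))
  # a receptor projects to every same-named assembly node
  t_rec <- which(graph$nodes$assembly == "receptor" & graph$nodes$name == "t")
  t_targets <- graph$edges$to[graph$edges$from == t_rec]
  expect_identical(unique(graph$nodes$assembly[t_targets]), "B.1")
  # brute-force recount of the edge construction rule
  nodes <- graph$nodes
  n_expect <- 0L
  for (i in which(nodes$role %in% c("RECEPTOR", "ID")))
    n_expect <- n_expect + sum(nodes$name == nodes$name[i] &
                                 seq_len(nrow(nodes)) != i &
                                 nodes$assembly != "receptor")
  expect_identical(nrow(graph$edges), n_expect)
  # purity: identical grammars give identical graphs
  expect_identical(compile_graph(house_grammar()), graph)
  expect_error(compile_graph(sp_grammar()))
})

test_that("lateral inhibition enhances boundaries and spares lone signals", {
  act <- rep(1, 6)
  bnd <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  post <- apply_inhibition(act, bnd, strength = 0.5)
  expect_true(all(post[bnd] > post[!bnd]))
  # a single activated node is untouched
  act1 <- c(0, 1, 0, 0)
  expect_identical(apply_inhibition(act1, rep(FALSE, 4)), act1)
  expect_true(all(apply_inhibition(rep(0, 4), rep(FALSE, 4)) == 0))
})

test_that("neural recognition agrees with the abstract engine on the phrase fixture", {
  g <- house_grammar()
  graph <- compile_graph(g)
  for (s in c("thebighouse", "thesmallhouse")) {
    new <- new_phrase(s)
    nama <- simulate_recognition(graph, new$symbols)
    rep <- nama_vs_alignment(nama, best_alignment(new, g))
    expect_true(rep$agree)
  }
})

test_that("neural recognition matches one appearance per repetition", {
  g <- very_grammar()
  graph <- compile_graph(g)
  for (n in 1:3) {
    nama <- simulate_recognition(graph, rep("very", n))
    b <- best_alignment(sp_new_pattern(rep("very", n)), g)
    expect_true(nama_vs_alignment(nama, b)$agree)
  }
})

test_that("inputs that activate nothing give an empty recognition", {
  graph <- compile_graph(house_grammar())
  nama <- simulate_recognition(graph, "g")
  expect_length(nama$winning, 0L)
  expect_length(simulate_recognition(graph, character(0))$winning, 0L)
  expect_error(simulate_recognition(graph, "Q"), "receptor")
})

test_that("a corrupted recognition is reported with a named discrepancy", {
  g <- house_grammar()
  new <- new_phrase("thebighouse")
  nama <- simulate_recognition(compile_graph(g), new$symbols)
  nama$winning <- c(nama$winning, "D.1")  # deliberate corruption
  rep <- nama_vs_alignment(nama, best_alignment(new, g))
  expect_false(rep$agree)
  expect_match(rep$first_discrepancy, "D.1")
})

test_that("the capacity arithmetic reproduces the printed chain", {
  rep <- estimate_capacity()
  expect_identical(unname(rep$raw_mb), c(1000, 10000))
  expect_identical(unname(rep$compressed_mb), c(3000, 30000))
  expect_identical(rep$knowledge_uncompressed_mb, 4000)
  expect_identical(rep$requirement_mb, 12000)
  expect_true(rep$within_capacity)
  # factor 1, one copy: the requirement is just the rounded corpus size
  triv <- estimate_capacity(compression_factor = 1, copies = 1)
  expect_identical(triv$requirement_mb, signif(1300, 1))
  expect_error(estimate_capacity(neurons_low = -1))
  # monotone nondecreasing in every numeric input over a small grid
  base <- list(neurons_low = 1e10, neurons_high = 1e11, bits_per_neuron = 1,
               compression_factor = 3, copies = 3,
               corpus_compressed_mb = 1300)
  fields <- c("raw_mb", "compressed_mb", "knowledge_uncompressed_mb",
              "requirement_mb")
  for (arg in names(base)) {
    lo <- do.call(estimate_capacity, base)
    hi_args <- base; hi_args[[arg]] <- base[[arg]] * 2
    hi <- do.call(estimate_capacity, hi_args)
    for (f in fields)
      expect_true(all(unlist(hi[f]) >= unlist(lo[f])),
                  info = paste(arg, f))
  }
})

test_that("the graph export is a readable edge list", {
  path <- withr::local_tempfile(fileext = ".txt")
  graph <- compile_graph(house_grammar())
  write_graph_edgelist(graph, path)
  lines <- readLines(path)
  expect_length(lines, nrow(graph$edges) + 1L)
})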