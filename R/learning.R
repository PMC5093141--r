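# Unsupervised learning.
#
# Sequences are absorbed one at a time.  An unseen sequence is stored
# directly (with fresh service symbols) -- one-trial storage.  A sequence the
# grammar already explains re-observes the patterns it used.  A partial match
# drives restructuring: the matching and non-matching parts become patterns
# of their own, alternatives occupying the same gap share a class, and an
# abstract pattern records the sequence of classes.  Grammars are compared by
# a two-part description length: the bits needed to write the grammar down
# (g_bits) plus the bits needed to encode the corpus with it (e_bits).

#' Assimilate one New pattern into a grammar
#'
#' @param new a New `sp_pattern`.
#' @param grammar an `sp_grammar`.
#' @param params an `sp_search_params`.
#' @param model optional `sp_cost_model` (defaults to uniform over
#'   `grammar` + `new`).
#' @param min_run minimum length of a matched run treated as structure when
#'   splitting (shorter runs are treated as accidental overlap).
#' @return `list(grammar = <updated grammar>, event = <sp_learning_event>)`.
#'   Event kinds: `STORE_DIRECT`, `FREQ_INCREMENT`, `SPLIT_AND_ABSTRACT`
#'   (which may also retire the split source pattern).
#' @export
assimilate <- function(new, grammar, params = sp_search_params(),
                       model = NULL, min_run = 2L) {
  stopifnot(new$provenance == "NEW")
  if (length(grammar$patterns) == 0L)
    return(store_direct(new, grammar))
  if (is.null(model)) model <- sp_cost_model(grammar, new)
  alns <- build_alignments(new, grammar, params, model)
  best <- alns[[1L]]
  n_new <- length(new$symbols)
  matched <- sum(best$col_n[best$colid[[1L]]] >= 2L)
  if (matched == n_new && length(best$rows) > 1L) {
    ids <- vapply(best$rows[-1L], `[[`, "", "pattern_id")
    for (id in ids) grammar <- bump_frequency(grammar, id)
    return(list(grammar = grammar,
                event = learning_event("FREQ_INCREMENT", patterns = ids)))
  }
  # prefer extending an existing class hierarchy: look for a ranked
  # alignment whose rows include an abstract sequencing pattern, and fill
  # its open slots with the unexplained stretches of the sentence
  spines <- Filter(function(a) {
    if (length(a$rows) < 2L) return(FALSE)
    if (sum(a$col_n[a$colid[[1L]]] >= 2L) < 2L) return(FALSE)
    any(vapply(a$rows[-1L], function(r)
      is_abstract_pattern(grammar$patterns[[r$pattern_id]], grammar), TRUE))
  }, alns)
  for (a in head(spines, 3L)) {
    res <- derive_siblings(a, new, grammar)
    if (!is.null(res) && length(res$patterns))
      return(list(grammar = res$grammar,
                  event = learning_event("SPLIT_AND_ABSTRACT",
                                         patterns = res$patterns,
                                         retired = character(0))))
  }
  # otherwise split against a single stored pattern -- but only while no
  # abstraction exists yet: once a class hierarchy has formed, sentences
  # it cannot yet explain are stored whole and resolved later through the
  # hierarchy, rather than founding a rival hierarchy with fused segments
  has_abstract <- any(vapply(grammar$patterns, function(p)
    is_abstract_pattern(p, grammar), TRUE))
  two <- if (has_abstract) list() else
    Filter(function(a) length(a$rows) == 2L && a$score$cs > 0 &&
             sum(a$col_n[a$colid[[1L]]] >= 2L) >= 2L, alns)
  if (length(two)) {
    res <- tryCatch(
      derive_from_alignment(two[[1L]], grammar, min_run = min_run),
      error = function(e) NULL)
    if (!is.null(res) && length(res$patterns))
      return(list(grammar = res$grammar,
                  event = learning_event("SPLIT_AND_ABSTRACT",
                                         patterns = res$patterns,
                                         retired = res$retired)))
  }
  store_direct(new, grammar)
}

store_direct <- function(new, grammar) {
  g <- generate_ids(grammar, 1L)
  id <- g$ids[[1L]]
  grammar <- g$grammar
  pat <- sp_old_pattern(c(id$class, id$disc), new$symbols, id$suffix)
  grammar <- add_pattern(grammar, pat, count = 1L)
  list(grammar = grammar,
       event = learning_event("STORE_DIRECT", patterns = list(pat)))
}

learning_event <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "sp_learning_event")
}

#' @export
print.sp_learning_event <- function(x, ...) {
  cat("<sp_learning_event ", x$kind, ">\n", sep = "")
  invisible(x)
}

bump_frequency <- function(grammar, pattern_id, by = 1L) {
  p <- grammar$patterns[[pattern_id]]
  if (is.null(p)) stop("unknown pattern: ", pattern_id)
  grammar$patterns[[pattern_id]]$frequency <- p$frequency + as.integer(by)
  for (nm in p$symbols)
    grammar$symbol_freq[nm] <- grammar$symbol_freq[[nm]] + as.integer(by)
  grammar
}

#' Create patterns from the matching and non-matching parts of a partial
#' match
#'
#' Given a two-row alignment (New pattern against one stored pattern), each
#' maximal matched run of contents symbols becomes a pattern of its own, the
#' two sides of each unmatched gap become alternative patterns sharing one
#' class (the New side takes the first discriminator), and an abstract
#' pattern records the sequence of the new classes via their service-symbol
#' pairs.  The split source pattern is retired: stored patterns are never
#' modified, only created or destroyed.
#'
#' @param ma a legal two-row `sp_alignment`.
#' @param grammar the grammar the stored row belongs to.
#' @param min_run matched runs shorter than this are treated as accidental
#'   and folded into the surrounding gap.
#' @return `list(patterns = <new sp_patterns>, retired = <pattern id>,
#'   grammar = <updated grammar with the new patterns added and the source
#'   removed>)`.
#' @export
derive_from_alignment <- function(ma, grammar, min_run = 2L) {
  if (length(ma$rows) != 2L) stop("expected exactly two rows")
  old <- ma$rows[[2L]]
  old_id <- old$pattern_id
  # per-column classification, in column order
  kind <- character(0); new_sym <- character(0); old_sym <- character(0)
  for (k in ma$topo) {
    e <- ma$cols[ma$cols$col == k, , drop = FALSE]
    if (nrow(e) == 2L) {
      kind <- c(kind, "M"); new_sym <- c(new_sym, ma$col_name[k])
      old_sym <- c(old_sym, ma$col_name[k])
    } else if (e$row == 1L) {
      kind <- c(kind, "N"); new_sym <- c(new_sym, ma$col_name[k])
      old_sym <- c(old_sym, NA)
    } else if (e$role == "CONTENTS") {
      kind <- c(kind, "O"); new_sym <- c(new_sym, NA)
      old_sym <- c(old_sym, ma$col_name[k])
    }  # old ID symbols are service scaffolding; ignored
  }
  # demote matched runs shorter than min_run
  r <- rle(kind == "M")
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] < min_run) {
      ix <- (ends[i] - r$lengths[i] + 1L):ends[i]
      kind[ix] <- "NO"  # counts on both sides of the gap
    }
  }
  if (!any(kind == "M")) stop("alignment has no matched run")
  # alternating segments
  seg_id <- cumsum(c(TRUE, (kind == "M")[-1L] != (kind == "M")[
    -length(kind)]))
  segs <- lapply(split(seq_along(kind), seg_id), function(ix)
    list(matched = kind[ix[1L]] == "M",
         new_run = new_sym[ix][!is.na(new_sym[ix])],
         old_run = old_sym[ix][!is.na(old_sym[ix])]))
  if (length(segs) == 1L && segs[[1L]]$matched)
    return(list(patterns = list(), retired = character(0),
                grammar = grammar))

  patterns <- list()
  # matched-run classes first (this reproduces the canonical labelling:
  # B = first shared run, C = second, ... then gap classes)
  freq_m <- grammar$patterns[[old_id]]$frequency
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (!s$matched) next
    g <- generate_ids(grammar, 1L); grammar <- g$grammar
    id <- g$ids[[1L]]
    segs[[i]]$class <- id$class
    patterns <- c(patterns, list(sp_old_pattern(
      c(id$class, id$disc), s$new_run, id$suffix, frequency = freq_m + 1L)))
  }
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s$matched) next
    members <- list()
    if (length(s$new_run))
      members <- c(members, list(list(body = s$new_run, freq = 1L)))
    if (length(s$old_run) &&
        !identical(s$old_run, s$new_run))
      members <- c(members, list(list(body = s$old_run, freq = freq_m)))
    cls <- NULL
    for (m in members) {
      g <- if (is.null(cls)) generate_ids(grammar, 1L) else
        generate_ids(grammar, 1L, class = cls)
      grammar <- g$grammar
      id <- g$ids[[1L]]
      cls <- id$class
      segs[[i]]$class <- cls
      patterns <- c(patterns, list(sp_old_pattern(
        c(id$class, id$disc), m$body, id$suffix, frequency = m$freq)))
    }
  }
  # the abstract sequencing pattern
  g <- generate_ids(grammar, 1L); grammar <- g$grammar
  id <- g$ids[[1L]]
  body <- unlist(lapply(segs, function(s) c(s$class, paste0("#", s$class))))
  patterns <- c(patterns, list(sp_old_pattern(
    c(id$class, id$disc), body, id$suffix, frequency = freq_m + 1L)))
  for (p in patterns) grammar <- add_pattern(grammar, p, count = p$frequency)
  grammar <- remove_pattern(grammar, old_id)
  list(patterns = patterns, retired = old_id, grammar = grammar)
}

# Does this stored pattern reference other patterns (abstract) or hold only
# terminal marks (leaf)?
is_abstract_pattern <- function(pat, grammar) {
  idnames <- unlist(lapply(grammar$patterns, function(p)
    p$symbols[p$role == "ID"]), use.names = FALSE)
  any(pattern_body(pat) %in% idnames)
}

# Multi-row generalization: a partially recognized sentence extends an
# existing class with a sibling pattern.  Each appearance directly matching
# New symbols claims the New segment up to its last matched symbol; an
# unmatched New run falling where an abstract row has exactly one unresolved
# reference pair founds a new member of that class.  Returns NULL when the
# structure is not clean enough to commit to.
derive_siblings <- function(best, new, grammar) {
  nr <- length(best$rows)
  if (nr < 2L) return(NULL)
  rows <- best$rows
  abstract <- which(vapply(seq_len(nr), function(r) r > 1L &&
    is_abstract_pattern(grammar$patterns[[rows[[r]]$pattern_id]], grammar),
    TRUE))
  if (length(abstract) != 1L) return(NULL)
  a <- abstract
  pat <- rows[[a]]

  # the spine's reference slots, with the child row resolving each (if any)
  body_ix <- which(pat$role == "CONTENTS")
  slots <- list()
  i <- 1L
  while (i <= length(body_ix)) {
    if (i == length(body_ix)) return(NULL)
    s1 <- pat$symbols[body_ix[i]]; s2 <- pat$symbols[body_ix[i + 1L]]
    if (!identical(s2, paste0("#", s1))) return(NULL)
    col1 <- best$colid[[a]][body_ix[i]]
    child <- NA_integer_
    if (best$col_n[col1] >= 2L) {
      e <- best$cols[best$cols$col == col1 & best$cols$row != a, ,
                     drop = FALSE]
      if (nrow(e) == 1L && e$pos == 1L) child <- e$row
    }
    slots[[length(slots) + 1L]] <- list(class = s1, child = child)
    i <- i + 2L
  }

  # New span directly matched by each resolved child
  n_new <- length(new$symbols)
  span <- lapply(slots, function(s) {
    if (is.na(s$child)) return(NULL)
    shared <- intersect(best$colid[[1L]], best$colid[[s$child]])
    if (!length(shared)) return(NULL)
    range(match(shared, best$colid[[1L]]))
  })
  resolved <- !vapply(span, is.null, TRUE)
  if (!any(resolved)) return(NULL)
  ord_ok <- all(diff(vapply(span[resolved], `[`, 0L, 1L)) > 0)
  if (!ord_ok) return(NULL)

  # a resolved child is a firm anchor only when its whole body is matched;
  # a partially matched child has boundaries just as uncertain as an open
  # slot, so it joins the surrounding cut region
  firm <- logical(length(slots))
  for (k in seq_along(slots)) {
    if (!resolved[k]) next
    r <- slots[[k]]$child
    cpat <- grammar$patterns[[rows[[r]]$pattern_id]]
    if (is_abstract_pattern(cpat, grammar)) return(NULL)
    nmatched <- length(intersect(best$colid[[1L]], best$colid[[r]]))
    firm[k] <- nmatched == length(pattern_body(cpat))
  }

  cursor <- 1L
  new_pats <- list()
  k <- 1L
  while (k <= length(slots)) {
    if (firm[k]) {
      last_here <- if (k == length(slots)) n_new else span[[k]][2L]
      seg <- cursor:last_here
      cursor <- last_here + 1L
      body <- new$symbols[seg]
      r <- slots[[k]]$child
      cpat <- grammar$patterns[[rows[[r]]$pattern_id]]
      if (!identical(body, pattern_body(cpat))) {
        if (!class_has_body(grammar, cpat$symbols[1L], body)) {
          g <- generate_ids(grammar, 1L, class = cpat$symbols[1L])
          grammar <- g$grammar
          id <- g$ids[[1L]]
          new_pats <- c(new_pats, list(sp_old_pattern(
            c(id$class, id$disc), body, id$suffix)))
        }
      }
      k <- k + 1L
    } else {
      # run of open or partially matched slots; cut the stretch into one
      # piece per slot, guided by similarity to each class's members
      k2 <- k
      while (k2 < length(slots) && !firm[k2 + 1L]) k2 <- k2 + 1L
      if (k2 > k) return(NULL)  # two adjacent open slots: no safe boundary
      nxt <- if (k2 < length(slots)) span[[k2 + 1L]][1L] - 1L else n_new
      if (nxt < cursor) return(NULL)
      piece <- new$symbols[cursor:nxt]
      cls <- slots[[k]]$class
      if (!class_has_body(grammar, cls, piece)) {
        g <- generate_ids(grammar, 1L, class = cls)
        grammar <- g$grammar
        id <- g$ids[[1L]]
        new_pats <- c(new_pats, list(sp_old_pattern(
          c(id$class, id$disc), piece, id$suffix)))
      }
      cursor <- nxt + 1L
      k <- k2 + 1L
    }
    if (cursor > n_new + 1L) return(NULL)
  }
  if (cursor <= n_new) return(NULL)
  if (!length(new_pats)) return(NULL)
  for (p in new_pats) grammar <- add_pattern(grammar, p, count = 1L)
  list(patterns = new_pats, grammar = grammar)
}

class_has_body <- function(grammar, class, body) {
  for (p in grammar$patterns) {
    if (p$symbols[1L] == class && !is_abstract_pattern(p, grammar) &&
        identical(pattern_body(p), body)) return(TRUE)
  }
  FALSE
}

# -- grammar scoring --------------------------------------------------------

#' Score a grammar on a corpus by two-part description length
#'
#' `g_bits` is the cost of writing the grammar down (the summed symbol costs
#' of each stored pattern, counted once).  `e_bits` is the cost of encoding
#' the corpus: for each sentence, the code its best alignment leaves behind,
#' plus any unmatched sentence symbols charged at raw cost.  `t_bits` is
#' their sum; smaller is better.
#'
#' @param grammar an `sp_grammar`.
#' @param corpus list of New `sp_pattern`s.
#' @param params an `sp_search_params`.
#' @param model an `sp_cost_model`; defaults to uniform over grammar and
#'   corpus.
#' @return an object of class `sp_grammar_candidate`:
#'   `list(grammar, g_bits, e_bits, t_bits, usage, coverage)`; `usage` maps
#'   pattern id to the number of corpus sentences whose best encoding uses
#'   it, `coverage` is the fraction of corpus symbols matched.
#' @export
score_grammar <- function(grammar, corpus, params = sp_search_params(),
                          model = NULL, cache = NULL) {
  stopifnot(length(corpus) >= 1L)
  if (is.null(model)) model <- corpus_cost_model(grammar, corpus)
  g_bits <- sum(vapply(grammar$patterns, function(p)
    sum(symbol_cost(model, p$symbols)), 0))
  e_bits <- 0
  usage <- setNames(integer(length(grammar$patterns)),
                    names(grammar$patterns))
  tot <- 0L; cov <- 0L
  gsig <- if (is.null(cache)) NULL else grammar_signature(grammar)
  for (s in corpus) {
    best <- NULL
    ckey <- NULL
    if (!is.null(cache)) {
      ckey <- paste0(gsig, "\x1e", paste(s$symbols, collapse = " "))
      best <- cache[[ckey]]
    }
    if (is.null(best)) {
      best <- build_alignments(s, grammar, params, model)[[1L]]
      if (!is.null(cache)) cache[[ckey]] <- best
    }
    unmatched <- best$col_n[best$colid[[1L]]] < 2L
    e_bits <- e_bits + best$score$b_code +
      sum(symbol_cost(model, s$symbols[unmatched]))
    for (id in unique(vapply(best$rows[-1L], `[[`, "", "pattern_id")))
      usage[id] <- usage[id] + 1L
    tot <- tot + length(s$symbols); cov <- cov + sum(!unmatched)
  }
  structure(list(grammar = grammar, g_bits = g_bits, e_bits = e_bits,
                 t_bits = g_bits + e_bits, usage = usage,
                 coverage = cov / tot),
            class = "sp_grammar_candidate")
}

#' @export
print.sp_grammar_candidate <- function(x, ...) {
  cat(sprintf(
    "<sp_grammar_candidate: %d patterns, g=%.1f + e=%.1f = t=%.1f bits, coverage %.0f%%>\n",
    length(x$grammar$patterns), x$g_bits, x$e_bits, x$t_bits,
    100 * x$coverage))
  invisible(x)
}

# One shared uniform alphabet so grammar candidates are comparable.
corpus_cost_model <- function(grammar, corpus,
                              mode = c("uniform", "frequency")) {
  mode <- match.arg(mode)
  if (mode == "frequency") return(sp_cost_model(grammar, mode = "frequency"))
  pseudo <- sp_new_pattern(
    unique(unlist(lapply(corpus, `[[`, "symbols"), use.names = FALSE)),
    "corpus")
  sp_cost_model(grammar, pseudo)
}

#' The naive grammar: one stored pattern per distinct sentence
#'
#' The baseline that grammar induction must beat: no shared structure, each
#' distinct corpus sentence stored whole with its own service symbols.
#'
#' @param corpus list of New `sp_pattern`s.
#' @return an `sp_grammar`.
#' @export
naive_grammar <- function(corpus) {
  grammar <- sp_grammar()
  for (s in corpus) {
    res <- assimilate_naive(s, grammar)
    grammar <- res
  }
  grammar
}

assimilate_naive <- function(s, grammar) {
  for (p in grammar$patterns) {
    if (identical(pattern_body(p), s$symbols))
      return(bump_frequency(grammar, p$pattern_id))
  }
  store_direct(s, grammar)$grammar
}

#' Remove unused patterns from a grammar
#'
#' Patterns that no best encoding uses are destroyed (never modified):
#' removing them cannot increase the two-part score, since `g_bits` shrinks
#' and the encodings that defined `usage` remain available.
#'
#' @param grammar an `sp_grammar`.
#' @param usage named count vector as returned in an `sp_grammar_candidate`.
#' @return the pruned grammar.
#' @export
prune <- function(grammar, usage) {
  dead <- names(usage)[usage == 0L]
  for (id in dead) grammar <- remove_pattern(grammar, id)
  grammar
}

# -- grammar search ---------------------------------------------------------

#' Induce a grammar from a corpus
#'
#' Processes the corpus sequence by sequence, maintaining a beam of grammar
#' candidates.  For every sentence each candidate branches on its
#' restructuring action and on plain direct storage; after each batch the
#' candidates are scored on the corpus seen so far, unused patterns are
#' pruned, and the best `beam_grammars` are retained.  Fully reproducible:
#' the corpus is processed in the given order unless `shuffle = TRUE`, in
#' which case `seed` fixes the permutation.
#'
#' @param corpus list of New `sp_pattern`s.
#' @param params an `sp_search_params` (`beam_grammars`, `batch_size` used
#'   here; the rest passed to alignment building).
#' @param seed integer seed (only consulted when `shuffle = TRUE`).
#' @param shuffle process the corpus in a seeded random order.
#' @param min_run passed to the splitting step.
#' @return list of `sp_grammar_candidate`s scored on the full corpus, best
#'   (smallest `t_bits`) first.  Each carries the candidate's learning-event
#'   log as attribute `"events"`.
#' @export
induce <- function(corpus, params = sp_search_params(), seed = 1L,
                   shuffle = FALSE, min_run = 2L) {
  stopifnot(length(corpus) >= 1L)
  ord <- seq_along(corpus)
  if (shuffle) {
    set.seed(seed %% .Machine$integer.max)
    ord <- sample(ord)
  }
  corpus <- corpus[ord]
  model_all <- function(g) corpus_cost_model(g, corpus)
  cands <- list(list(grammar = sp_grammar(), events = list()))
  cache <- new.env(parent = emptyenv())
  done <- 0L
  while (done < length(corpus)) {
    batch <- corpus[(done + 1L):min(done + params$batch_size,
                                    length(corpus))]
    for (s in batch) {
      nxt <- list()
      for (cand in cands) {
        res <- assimilate(s, cand$grammar, params,
                          model = model_all(cand$grammar),
                          min_run = min_run)
        nxt <- c(nxt, list(list(
          grammar = res$grammar,
          events = c(cand$events, list(res$event)))))
        if (res$event$kind != "STORE_DIRECT") {
          alt <- store_direct(s, cand$grammar)
          nxt <- c(nxt, list(list(
            grammar = alt$grammar,
            events = c(cand$events, list(alt$event)))))
        }
      }
      sigs <- vapply(nxt, function(x) grammar_signature(x$grammar), "")
      cands <- nxt[!duplicated(sigs)]
      # keep the working set bounded between scoring passes (primary
      # branches come first and are favoured)
      if (length(cands) > 2L * params$beam_grammars)
        cands <- cands[seq_len(2L * params$beam_grammars)]
    }
    done <- done + length(batch)
    # rank candidates on a recent window of the corpus (the full corpus is
    # scored once at the end); pruning uses the same pass
    lo <- max(1L, done - 2L * params$batch_size + 1L)
    seen <- corpus[lo:done]
    scored <- lapply(cands, function(cand)
      score_grammar(cand$grammar, seen, params,
                    model = model_all(cand$grammar), cache = cache))
    t <- vapply(scored, `[[`, 0, "t_bits")
    sigs <- vapply(cands, function(x) grammar_signature(x$grammar), "")
    keep <- order(t, sigs)[seq_len(min(params$beam_grammars, length(cands)))]
    cands <- cands[keep]; scored <- scored[keep]
    # destroy patterns no retained encoding uses; patterns re-observed
    # often are kept even when the recent window happens not to use them
    for (i in seq_along(cands)) {
      freq <- vapply(cands[[i]]$grammar$patterns, `[[`, 0L, "frequency")
      usage <- scored[[i]]$usage
      usage[names(freq)[freq > 2L]] <- usage[names(freq)[freq > 2L]] + 1L
      pruned <- prune(cands[[i]]$grammar, usage)
      if (length(pruned$patterns) < length(cands[[i]]$grammar$patterns)) {
        dead <- setdiff(names(cands[[i]]$grammar$patterns),
                        names(pruned$patterns))
        cands[[i]]$grammar <- pruned
        cands[[i]]$events <- c(cands[[i]]$events,
                               list(learning_event("PRUNE",
                                                   pattern_ids = dead)))
      }
    }
  }
  # rehearsal: sentences the candidate still cannot explain in full get a
  # second hearing against the mature hierarchy -- late class members fill
  # in, and whole-sentence stores made redundant by them are destroyed
  for (i in seq_len(min(2L, length(cands)))) {
    g <- cands[[i]]$grammar
    model <- model_all(g)
    for (s in corpus) {
      best <- build_alignments(s, g, params, model)[[1L]]
      if (sum(best$col_n[best$colid[[1L]]] >= 2L) == length(s$symbols))
        next
      res <- assimilate(s, g, params, model = model_all(g))
      if (res$event$kind != "FREQ_INCREMENT") {
        g <- res$grammar
        cands[[i]]$events <- c(cands[[i]]$events, list(res$event))
        model <- model_all(g)
      }
    }
    sc <- score_grammar(g, corpus, params, model = model_all(g),
                        cache = cache)
    pruned <- prune(g, sc$usage)
    if (length(pruned$patterns) < length(g$patterns)) {
      dead <- setdiff(names(g$patterns), names(pruned$patterns))
      g <- pruned
      cands[[i]]$events <- c(cands[[i]]$events,
                             list(learning_event("PRUNE",
                                                 pattern_ids = dead)))
    }
    cands[[i]]$grammar <- g
  }
  out <- lapply(cands, function(cand) {
    sc <- score_grammar(cand$grammar, corpus, params,
                        model = model_all(cand$grammar), cache = cache)
    attr(sc, "events") <- cand$events
    sc
  })
  t <- vapply(out, `[[`, 0, "t_bits")
  sigs <- vapply(out, function(x) grammar_signature(x$grammar), "")
  out[order(t, sigs)]
}

grammar_signature <- function(grammar) {
  lines <- vapply(grammar$patterns, function(p)
    paste(p$symbols, collapse = " "), "")
  paste(sort(lines), collapse = "\n")
}

#' Replay a learning-event log onto an empty grammar
#'
#' The event log is append-only; replaying it reproduces the grammar's
#' pattern store and frequency table exactly.
#'
#' @param events list of `sp_learning_event`s.
#' @return an `sp_grammar`.
#' @export
replay_events <- function(events) {
  grammar <- sp_grammar()
  for (ev in events) {
    switch(ev$kind,
      STORE_DIRECT = {
        for (p in ev$patterns) grammar <- add_pattern(grammar, p, count = 1L)
      },
      FREQ_INCREMENT = {
        for (id in ev$patterns) grammar <- bump_frequency(grammar, id)
      },
      SPLIT_AND_ABSTRACT = {
        for (p in ev$patterns)
          grammar <- add_pattern(grammar, p, count = p$frequency)
        for (id in ev$retired) grammar <- remove_pattern(grammar, id)
      },
      PRUNE = {
        for (id in ev$pattern_ids) grammar <- remove_pattern(grammar, id)
      },
      stop("unknown event kind: ", ev$kind))
  }
  grammar
}

#' Substitution classes of a grammar
#'
#' The partition of terminal bodies into classes: for every class label, the
#' set of bodies (as space-joined strings) of its leaf patterns.  Abstract
#' patterns (whose bodies reference other patterns) are skipped.
#'
#' @param grammar an `sp_grammar`.
#' @return named list: class label -> character vector of member bodies.
#' @export
grammar_classes <- function(grammar) {
  out <- list()
  for (p in grammar$patterns) {
    if (is_abstract_pattern(p, grammar)) next
    cls <- p$symbols[1L]
    out[[cls]] <- sort(c(out[[cls]],
                         paste(pattern_body(p), collapse = " ")))
  }
  out
}
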