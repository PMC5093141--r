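# Staged bottom-up composition of multiple alignments.
#
# The search works over "items": an item is one appearance of a stored
# pattern with a concrete interpretation -- each body terminal either bound
# to an input (row 0) position or left unexpressed, each reference pair
# (X ... #X) either resolved by a child item of class X or left open, and
# (for decoding) the pattern's own service symbols optionally bound to
# row-0 symbols.  Stage 1 builds items bound to the input alone; each later
# stage composes retained items into higher items; a per-(pattern, span)
# beam keeps the search narrow.  The best alignment is then an ordered,
# non-overlapping selection of top-level items (weighted-interval dynamic
# programming over the input), converted into an explicit alignment and
# rescored.  Hierarchical structure survives this search because partial
# scaffolding competes only within its own span, not against every greedy
# flat structure over the whole input.

# -- pattern metadata -------------------------------------------------------

# Body elements: TERM (one contents symbol) or REF (an adjacent pair
# "X #X" referencing class X).
pattern_meta <- function(grammar) {
  classes <- unique(vapply(grammar$patterns, function(p) p$symbols[1L], ""))
  lapply(grammar$patterns, function(p) {
    np <- id_prefix_len(p)
    n <- length(p$symbols)
    body_ix <- if (n - 1L >= np + 1L) (np + 1L):(n - 1L) else integer(0)
    elems <- list()
    i <- 1L
    while (i <= length(body_ix)) {
      s <- p$symbols[body_ix[i]]
      if (s %in% classes && i < length(body_ix) &&
          p$symbols[body_ix[i + 1L]] == paste0("#", s)) {
        elems[[length(elems) + 1L]] <- list(
          type = "REF", class = s,
          pos_open = body_ix[i], pos_close = body_ix[i + 1L])
        i <- i + 2L
      } else {
        elems[[length(elems) + 1L]] <- list(type = "TERM", sym = s,
                                            pos = body_ix[i])
        i <- i + 1L
      }
    }
    list(pattern_id = p$pattern_id, pat = p,
         idx = match(p$pattern_id, names(grammar$patterns)),
         n_pat = length(grammar$patterns),
         class = p$symbols[1L], class_pos = 1L,
         disc_pos = if (np >= 2L) 2:np else integer(0),
         boundary_pos = n, elems = elems,
         n_term = sum(vapply(elems, function(e) e$type == "TERM", TRUE)))
  })
}

# -- item chart -------------------------------------------------------------

# One composition pass for a single pattern: enumerate interpretations
# against the input and the currently live items.  Returns a list of items.
compose_pattern <- function(meta, input, live_by_class, cost, cap,
                            fresh_sigs = NULL, max_skip = 6L, q_state = 4L) {
  # Beam dynamic programme over interpretation states.  The pattern's
  # symbol slots (class, discriminators, body elements, boundary) are
  # processed in order; a partial interpretation is summarized by the state
  # (first bound input position, input high-water mark), and only the
  # `q_state` best partials per state survive each step.  This is
  # exhaustive over spans -- deep nestings cannot be starved by flat
  # enumeration -- while total work stays polynomial.
  slots <- c(list(list(kind = "ID", pos = meta$class_pos, tag = "class")),
             lapply(meta$disc_pos, function(p)
               list(kind = "ID", pos = p, tag = "disc")),
             lapply(meta$elems, function(e) c(e, list(kind = e$type))),
             list(list(kind = "ID", pos = meta$boundary_pos,
                       tag = "boundary")))
  pat_sym <- meta$pat$symbols
  # candidate children per reference slot, indexed by starting position,
  # best few per position (spanless terminator items usable anywhere)
  per_first <- 3L
  ref_cands <- lapply(seq_along(slots), function(k) {
    s <- slots[[k]]
    if (is.null(s$kind) || s$kind != "REF") return(NULL)
    ch <- Filter(function(x) x$consumable, live_by_class[[s$class]] %||%
                   list())
    if (!length(ch)) return(list())
    cs <- vapply(ch, `[[`, 0, "cs")
    nm <- vapply(ch, `[[`, 0L, "nmatch")
    sz <- vapply(ch, `[[`, 0L, "size")
    sg <- vapply(ch, `[[`, "", "sig")
    fk <- ifelse(is.na(vapply(ch, function(x) as.numeric(x$first), 0)),
                 -1, vapply(ch, function(x) as.numeric(x$first), 0))
    keep <- top_per_key(fk, order(fk, -cs, sz, sg), per_first) |
      top_per_key(fk, order(fk, -nm, -cs, sg), per_first)
    ch[keep]
  })

  counts0 <- integer(meta$n_pat)
  counts0[meta$idx] <- 1L
  p0 <- list(pos = integer(0), row0 = integer(0), kids = list(),
             gain = 0L, code = 0L, grounded = FALSE,
             kid_cs = 0, counts = counts0,
             nmatch = 0L, skips = 0L, size = 1L,
             first = NA_real_, last_hi = 0,
             class_bound = FALSE, boundary_bound = FALSE,
             fresh = is.null(fresh_sigs))
  partials <- list(p0)

  prune_states <- function(ps) {
    if (length(ps) <= 1L) return(ps)
    key <- vapply(ps, function(p)
      (if (is.na(p$first)) 0 else p$first) * 1000 + p$last_hi, 0)
    sc <- vapply(ps, function(p) (p$gain - p$code) * cost + p$kid_cs, 0)
    nm <- vapply(ps, `[[`, 0L, "nmatch")
    sz <- vapply(ps, `[[`, 0L, "size")
    # keep, per state, the best partials by compression AND by coverage:
    # production (decoding) needs the coverage-maximal interpretation even
    # where a smaller partial compresses better
    keep <- top_per_key(key, order(key, -sc, sz), q_state) |
      top_per_key(key, order(key, -nm, -sc, sz), q_state)
    ps[keep]
  }

  for (k in seq_along(slots)) {
    s <- slots[[k]]
    nxt <- list()
    push <- function(p) nxt[[length(nxt) + 1L]] <<- p
    for (p in partials) {
      if (s$kind == "ID") {
        extra <- if (s$tag == "disc") 1L else 0L
        p2 <- p; p2$code <- p$code + extra
        push(p2)
        hits <- which(input == pat_sym[s$pos])
        for (qq in hits[hits > p$last_hi]) {
          p2 <- p
          p2$pos <- c(p$pos, s$pos); p2$row0 <- c(p$row0, qq)
          p2$gain <- p$gain + 1L; p2$nmatch <- p$nmatch + 1L
          p2$last_hi <- qq; p2$grounded <- TRUE
          if (is.na(p2$first)) p2$first <- qq
          if (s$tag == "class") p2$class_bound <- TRUE
          if (s$tag == "boundary") p2$boundary_bound <- TRUE
          push(p2)
        }
      } else if (s$kind == "TERM") {
        if (p$skips < max_skip) {
          p2 <- p; p2$code <- p$code + 1L
          p2$skips <- p$skips + 1L
          push(p2)
        }
        hits <- which(input == s$sym)
        for (qq in hits[hits > p$last_hi]) {
          p2 <- p
          p2$pos <- c(p$pos, s$pos); p2$row0 <- c(p$row0, qq)
          p2$gain <- p$gain + 1L; p2$nmatch <- p$nmatch + 1L
          p2$last_hi <- qq; p2$grounded <- TRUE
          if (is.na(p2$first)) p2$first <- qq
          push(p2)
        }
      } else {  # REF
        p2 <- p; p2$code <- p$code + 2L
        push(p2)
        for (child in ref_cands[[k]]) {
          if (!is.na(child$first) && child$first <= p$last_hi) next
          cts <- p$counts + child$counts
          if (any(cts > cap)) next
          p2 <- p
          p2$kids <- c(p$kids, list(list(ref = k, item = child)))
          p2$gain <- p$gain + 2L
          p2$kid_cs <- p$kid_cs + child$cs
          p2$counts <- cts; p2$size <- sum(cts)
          p2$nmatch <- p$nmatch + child$nmatch
          if (!is.na(child$last)) p2$last_hi <- child$last
          if (is.na(p2$first)) p2$first <- child$first
          p2$fresh <- p$fresh || child$sig %in% fresh_sigs
          p2$grounded <- p$grounded || isTRUE(child$confer)
          push(p2)
        }
      }
    }
    partials <- prune_states(nxt)
  }

  out <- list()
  for (p in partials) {
    if (!length(p$pos) && !length(p$kids)) next
    if (!p$grounded) next
    if (!p$fresh) next
    span <- c(p$row0,
              unlist(lapply(p$kids, function(k)
                c(k$item$first, k$item$last)), use.names = FALSE))
    span <- span[!is.na(span)]
    sig <- paste0(meta$idx, "(",
                  paste(p$pos, p$row0, sep = ":", collapse = ","), ";",
                  paste(vapply(p$kids, function(k)
                    paste0(k$ref, ">", k$item$uid), ""), collapse = ","),
                  ")")
    out[[length(out) + 1L]] <- list(
      sig = sig, pattern_id = meta$pattern_id, class = meta$class,
      own = list(pos = p$pos, row0 = p$row0), kids = p$kids,
      first = if (length(span)) min(span) else NA_real_,
      last = if (length(span)) max(span) else NA_real_,
      counts = p$counts, size = sum(p$counts),
      cs = (p$gain - p$code) * cost + p$kid_cs,
      nmatch = p$nmatch, confer = TRUE,
      consumable = !p$class_bound && !p$boundary_bound,
      toppen = cost * (2L - p$class_bound - p$boundary_bound))
  }
  out
}

# Null items: a bodyless pattern (a recursion terminator) is satisfied
# vacuously and can be consumed anywhere.
null_item <- function(meta, cost) {
  counts0 <- integer(meta$n_pat)
  counts0[meta$idx] <- 1L
  list(sig = paste0(meta$pattern_id, "()"), pattern_id = meta$pattern_id,
       class = meta$class, own = list(pos = integer(0), row0 = integer(0)),
       kids = list(), first = NA_real_, last = NA_real_,
       counts = counts0, size = 1L,
       cs = -cost * length(meta$disc_pos), nmatch = 0L, confer = FALSE,
       consumable = TRUE, toppen = 2 * cost)
}

# -- driving the chart ------------------------------------------------------

compose_chart <- function(new, grammar, params, model) {
  input <- new$symbols
  metas <- pattern_meta(grammar)
  cost <- symbol_cost(model, if (length(input)) input[1L] else "x")[1L]
  # uniform-cost composition: under a frequency model the chart uses the
  # mean cost as its unit and the final rescoring is exact
  if (model$mode == "FREQUENCY")
    cost <- mean(symbol_cost(model, names(model$freq)))
  registry <- new.env(parent = emptyenv())
  next_uid <- 0L
  live <- list()
  for (m in metas) {
    if (m$n_term == 0L && !length(m$elems)) {
      it <- null_item(m, cost)
      next_uid <- next_uid + 1L
      it$uid <- next_uid
      assign(it$sig, it, envir = registry)
      live[[it$sig]] <- it
    }
  }
  stale <- 0L
  best_val <- c(-Inf, -Inf, -Inf)
  prev_fresh <- NULL
  for (stage in seq_len(params$max_stages)) {
    live_by_class <- split(live, vapply(live, `[[`, "", "class"))
    fresh_classes <- if (is.null(prev_fresh)) NULL else
      unique(vapply(live[vapply(live, `[[`, "", "sig") %in% prev_fresh],
                    `[[`, "", "class"))
    fresh <- list()
    for (m in metas) {
      if (m$n_term == 0L && !length(m$elems)) next
      # after stage 1 a pattern can only yield new items by consuming a
      # freshly built child
      if (!is.null(prev_fresh)) {
        refcls <- vapply(Filter(function(e) e$type == "REF", m$elems),
                         `[[`, "", "class")
        if (!length(refcls) || !any(refcls %in% fresh_classes)) next
      }
      cands <- compose_pattern(m, input, live_by_class, cost,
                               params$appearance_cap,
                               fresh_sigs = prev_fresh)
      for (it in cands) {
        if (exists(it$sig, envir = registry, inherits = FALSE)) next
        next_uid <- next_uid + 1L
        it$uid <- next_uid
        assign(it$sig, it, envir = registry)
        fresh[[it$sig]] <- it
      }
    }
    if (!length(fresh)) break
    live <- c(live, fresh)
    live <- chart_beam(live, params$max_hits)
    prev_fresh <- names(fresh)[names(fresh) %in%
                                 vapply(live, `[[`, "", "sig")]
    # stop once three successive stages fail to improve the best selection
    # (one level of hierarchy can leave the selection briefly flat)
    v <- forest_value(select_forest(live, length(input)))
    if (vgt(v, best_val)) { best_val <- v; stale <- 0L }
    else { stale <- stale + 1L; if (stale >= 3L) break }
  }
  live
}

forest_value <- function(forest) {
  if (!length(forest)) return(c(0, 0, 0))
  c(sum(vapply(forest, function(it) it$cs - it$toppen, 0)),
    sum(vapply(forest, `[[`, 0L, "nmatch")),
    -sum(vapply(forest, `[[`, 0L, "size")))
}

# Per-(pattern, span) beam: keep, for every key, the best items by
# compression and the best by input coverage.
chart_beam <- function(items, q) {
  if (!length(items)) return(items)
  key <- vapply(items, function(it)
    paste(it$pattern_id, it$first, it$last), "")
  cs <- vapply(items, `[[`, 0, "cs")
  sz <- vapply(items, `[[`, 0L, "size")
  nm <- vapply(items, `[[`, 0L, "nmatch")
  sig <- vapply(items, `[[`, "", "sig")
  keep <- top_per_key(key, order(key, -cs, -nm, sz, sig), q) |
    top_per_key(key, order(key, -nm, -cs, sz, sig), q)
  items[keep]
}

# logical vector marking, within each key group of `ord` (which must be
# sorted by key first), the first `q` elements
top_per_key <- function(key, ord, q) {
  keep <- logical(length(key))
  run <- 0L; prev <- NULL
  for (i in ord) {
    if (!identical(key[i], prev)) { prev <- key[i]; run <- 0L }
    run <- run + 1L
    keep[i] <- run <= q
  }
  keep
}

# Ordered forest selection: weighted-interval DP over the input, gaps free.
# Value of an item as a top-level structure is (cs - toppen, nmatch),
# compared lexicographically.
select_forest <- function(items, n_in) {
  items <- Filter(function(it) !is.na(it$first), items)
  if (!length(items) || n_in == 0L) return(list())
  val <- lapply(items, function(it)
    c(it$cs - it$toppen, it$nmatch, -it$size))
  lasts <- vapply(items, function(it) as.integer(ceiling(it$last)), 0L)
  firsts <- vapply(items, function(it) as.integer(floor(it$first)), 0L)
  sig <- vapply(items, `[[`, "", "sig")
  best <- vector("list", n_in + 1L)
  pick <- vector("list", n_in + 1L)
  best[[1L]] <- c(0, 0, 0)
  for (j in seq_len(n_in)) {
    best[[j + 1L]] <- best[[j]]
    pick[[j + 1L]] <- list(prev = j, item = NA_integer_)
    cand <- which(lasts == j)
    for (i in cand[order(sig[cand])]) {
      v <- best[[firsts[i]]] + val[[i]]
      if (vgt(v, best[[j + 1L]])) {
        best[[j + 1L]] <- v
        pick[[j + 1L]] <- list(prev = firsts[i] - 1L, item = i)
      }
    }
  }
  chosen <- list()
  j <- n_in
  while (j >= 1L) {
    p <- pick[[j + 1L]]
    if (is.null(p)) break
    if (!is.na(p$item)) {
      chosen <- c(list(items[[p$item]]), chosen)
      j <- p$prev
    } else j <- j - 1L
  }
  chosen
}

vgt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] != b[i]) return(a[i] > b[i])
  }
  FALSE
}

# -- item forest -> explicit alignment --------------------------------------

forest_to_alignment <- function(forest, new, grammar) {
  aln <- aln_init(new)
  for (it in forest) aln <- add_item_rows(aln, it, grammar)$aln
  aln
}

add_item_rows <- function(aln, item, grammar) {
  kid_rows <- integer(0)
  for (k in item$kids) {
    res <- add_item_rows(aln, k$item, grammar)
    aln <- res$aln
    kid_rows <- c(kid_rows, res$row)
  }
  pat <- grammar$patterns[[item$pattern_id]]
  j <- item$own$pos
  col <- item$own$row0   # row-0 columns keep their position ids
  for (i in seq_along(item$kids)) {
    k <- item$kids[[i]]
    r <- kid_rows[i]
    ref <- k$item  # child's class and boundary columns
    e <- ref_positions(k, item, grammar)
    j <- c(j, e$open, e$close)
    col <- c(col, aln$colid[[r]][1L],
             aln$colid[[r]][length(aln$colid[[r]])])
  }
  ms <- if (length(j)) data.frame(j = j, col = col) else
    data.frame(j = integer(0), col = integer(0))
  aln <- aln_add_row(aln, pat, ms)
  list(aln = aln, row = length(aln$rows))
}

# positions of the reference pair inside the parent pattern
ref_positions <- function(kid, item, grammar) {
  meta_elems <- pattern_meta_single(grammar$patterns[[item$pattern_id]],
                                    grammar)
  # kid$ref indexes the slot list: class slot + discs + elements
  np <- id_prefix_len(grammar$patterns[[item$pattern_id]])
  el <- meta_elems[[kid$ref - np]]
  list(open = el$pos_open, close = el$pos_close)
}

pattern_meta_single <- function(pat, grammar) {
  g1 <- grammar
  classes <- unique(vapply(grammar$patterns, function(p) p$symbols[1L], ""))
  np <- id_prefix_len(pat)
  n <- length(pat$symbols)
  body_ix <- if (n - 1L >= np + 1L) (np + 1L):(n - 1L) else integer(0)
  elems <- list()
  i <- 1L
  while (i <= length(body_ix)) {
    s <- pat$symbols[body_ix[i]]
    if (s %in% classes && i < length(body_ix) &&
        pat$symbols[body_ix[i + 1L]] == paste0("#", s)) {
      elems[[length(elems) + 1L]] <- list(type = "REF", class = s,
                                          pos_open = body_ix[i],
                                          pos_close = body_ix[i + 1L])
      i <- i + 2L
    } else {
      elems[[length(elems) + 1L]] <- list(type = "TERM", sym = s,
                                          pos = body_ix[i])
      i <- i + 1L
    }
  }
  elems
}
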