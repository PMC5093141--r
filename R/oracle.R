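# Exhaustive alignment enumeration.  The staged search trades completeness
# for speed ("good enough" solutions); on small instances this oracle
# enumerates every legal alignment so the heuristic's best score can be
# checked against the true optimum.  It is deliberately independent of the
# staged composition engine: an alignment is treated as a set of symbol
# pairings over a fixed universe of appearance rows, enumerated by plain
# depth-first search with incremental legality checks.

#' Enumerate all legal multiple alignments (small instances only)
#'
#' The universe is the New pattern (row 0) plus up to `max_appearances`
#' appearance rows of every stored pattern.  Candidate pairings are all
#' same-named symbol pairs whose kinds may unify (sensory with stored
#' contents, contents reference with service symbol, sensory code symbol
#' with service symbol).  The search enumerates every subset of pairings
#' that is an alignment: each symbol in at most one pair, the merged
#' left-to-right constraints acyclic, every used appearance grounded and
#' connected to row 0.  Alignments differing only by renumbering the
#' appearances of one pattern are counted once.
#'
#' @param new a New `sp_pattern`.
#' @param grammar an `sp_grammar`.
#' @param bounds `list(max_symbols, max_appearances)`: refuses instances
#'   whose total symbol count (New plus stored patterns) exceeds
#'   `max_symbols` (default 25); explores at most `max_appearances`
#'   (default 3) appearances per pattern.
#' @param model an `sp_cost_model` for scoring (default uniform).
#' @param max_states safety cap on enumerated alignments.
#' @return `list(alignments = <list of records with fields rows (active
#'   appearance pattern ids), pairs, score>, best = <highest compression
#'   score>, n = <number of distinct legal alignments>)`.
#' @export
enumerate_alignments_oracle <- function(new, grammar,
                                        bounds = list(max_symbols = 25L,
                                                      max_appearances = 3L),
                                        model = NULL,
                                        max_states = 2000000L) {
  max_symbols <- bounds$max_symbols %||% 25L
  max_app <- bounds$max_appearances %||% 3L
  total <- length(new$symbols) +
    sum(vapply(grammar$patterns, function(p) length(p$symbols), 0L))
  if (total > max_symbols)
    stop("instance exceeds oracle bounds (", total, " > ", max_symbols,
         " symbols)")
  if (is.null(model)) model <- sp_cost_model(grammar, new)

  # symbol universe: row 0, then max_app instances of every pattern
  rows <- list(list(pat = "new0", inst = 0L, symbols = new$symbols,
                    role = new$role))
  for (p in grammar$patterns)
    for (k in seq_len(max_app))
      rows[[length(rows) + 1L]] <- list(pat = p$pattern_id, inst = k,
                                        symbols = p$symbols, role = p$role)
  nr <- length(rows)
  row_of <- integer(0); pos_of <- integer(0)
  name <- character(0); kind <- character(0)
  for (r in seq_len(nr)) {
    n <- length(rows[[r]]$symbols)
    row_of <- c(row_of, rep(r, n)); pos_of <- c(pos_of, seq_len(n))
    name <- c(name, rows[[r]]$symbols)
    kind <- c(kind, if (r == 1L) rep("N", n) else
      ifelse(rows[[r]]$role == "ID", "I", "C"))
  }
  ns <- length(name)
  cost <- symbol_cost(model, name)

  ok_pair <- function(a, b) {
    name[a] == name[b] && row_of[a] != row_of[b] && kind[a] != kind[b] &&
      !(kind[a] == "N" && kind[b] == "N")
  }
  cand <- list()
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns)
    if (ok_pair(a, b)) cand[[length(cand) + 1L]] <- c(a, b)
  np <- length(cand)

  # incremental structures
  partner <- integer(ns)          # 0 = unpaired
  # acyclicity check on the current column graph
  legal_order <- function() {
    colid <- seq_len(ns)
    for (i in seq_len(ns)) if (partner[i] > 0L && partner[i] < i)
      colid[i] <- colid[partner[i]]
    colid <- match(colid, unique(colid))
    ncol <- max(colid)
    from <- integer(0); to <- integer(0)
    off <- 0L
    for (r in seq_len(nr)) {
      n <- length(rows[[r]]$symbols)
      if (n > 1L) {
        from <- c(from, colid[off + seq_len(n - 1L)])
        to <- c(to, colid[off + 2:n])
      }
      off <- off + n
    }
    indeg <- tabulate(to, nbins = ncol)
    done <- 0L
    queue <- which(indeg == 0L)
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      done <- done + 1L
      sel <- from == u
      for (v in to[sel]) {
        indeg[v] <- indeg[v] - 1L
        if (indeg[v] == 0L) queue <- c(queue, v)
      }
      from <- from[!sel]; to <- to[!sel]
    }
    done == ncol
  }

  results <- new.env(parent = emptyenv())
  n_found <- 0L
  best <- -Inf
  best_rec <- NULL
  records <- list()

  finalize_state <- function() {
    used <- sort(unique(row_of[partner > 0L]))
    active <- setdiff(used, 1L)
    # canonical instance activation (symmetry) is enforced during search;
    # grounding + connectivity checked here
    # recursive data-grounding: a row with contents must reach row 0
    # directly or through resolved references to grounded rows that
    # themselves have contents
    if (length(active)) {
      direct <- logical(nr); hasc <- logical(nr)
      kids <- lapply(seq_len(nr), function(r) integer(0))
      for (r in active) {
        ix <- which(row_of == r)
        hasc[r] <- any(rows[[r]]$role == "CONTENTS")
        prt <- partner[ix]; prt <- prt[prt > 0L]
        direct[r] <- any(row_of[prt] == 1L)
        cc <- ix[rows[[r]]$role == "CONTENTS"]
        prtc <- partner[cc]; prtc <- prtc[prtc > 0L]
        kids[[r]] <- unique(row_of[prtc][row_of[prtc] > 1L])
      }
      grounded <- direct
      repeat {
        changed <- FALSE
        for (r in active) {
          if (grounded[r]) next
          if (any(grounded[kids[[r]]] & hasc[kids[[r]]])) {
            grounded[r] <- TRUE; changed <- TRUE
          }
        }
        if (!changed) break
      }
      if (any(hasc[active] & !grounded[active])) return(invisible(NULL))
    }
    # connectivity of active rows to row 0
    if (length(active)) {
      adj <- lapply(seq_len(nr), function(r) integer(0))
      for (i in which(partner > 0L & partner > seq_len(ns))) {
        r1 <- row_of[i]; r2 <- row_of[partner[i]]
        adj[[r1]] <- c(adj[[r1]], r2); adj[[r2]] <- c(adj[[r2]], r1)
      }
      seen <- logical(nr); seen[1L] <- TRUE
      queue <- 1L
      while (length(queue)) {
        r <- queue[1L]; queue <- queue[-1L]
        for (r2 in adj[[r]]) if (!seen[r2]) { seen[r2] <- TRUE
          queue <- c(queue, r2) }
      }
      if (!all(seen[active])) return(invisible(NULL))
    }
    # canonical signature (instances of one pattern interchangeable --
    # enforced by activation order, so the pair set is already canonical)
    sig <- paste0("s", paste(which(partner > seq_len(ns)),
                             partner[partner > seq_len(ns)],
                             sep = ":", collapse = ","))
    if (exists(sig, envir = results, inherits = FALSE))
      return(invisible(NULL))
    assign(sig, TRUE, envir = results)
    gain <- sum(cost[partner > seq_len(ns)])
    code <- 0
    for (r in active) {
      ix <- which(row_of == r)
      code <- code + sum(cost[ix][partner[ix] == 0L])
    }
    cs <- gain - code
    n_found <<- n_found + 1L
    rec <- list(rows = sort(vapply(active, function(r)
      rows[[r]]$pat, "")), cs = cs, b_gain = gain, b_code = code)
    records[[length(records) + 1L]] <<- rec
    if (cs > best) { best <<- cs; best_rec <<- rec }
    invisible(NULL)
  }

  inst_active <- function(pat, k) {
    r <- which(vapply(rows, function(x)
      identical(x$pat, pat) && x$inst == k, TRUE))
    any(partner[row_of == r] > 0L)
  }

  dfs <- function(i) {
    if (n_found > max_states)
      stop("oracle state cap exceeded; instance too large")
    if (i > np) { finalize_state(); return(invisible(NULL)) }
    # exclude pair i
    dfs(i + 1L)
    a <- cand[[i]][1L]; b <- cand[[i]][2L]
    if (partner[a] == 0L && partner[b] == 0L) {
      # canonical instance activation: instance k of a pattern may only be
      # touched once instance k-1 is in use
      okk <- TRUE
      for (s in c(a, b)) {
        r <- row_of[s]
        if (r > 1L && rows[[r]]$inst > 1L &&
            !inst_active(rows[[r]]$pat, rows[[r]]$inst - 1L)) okk <- FALSE
      }
      if (okk) {
        partner[a] <<- b; partner[b] <<- a
        if (legal_order()) dfs(i + 1L)
        partner[a] <<- 0L; partner[b] <<- 0L
      }
    }
    invisible(NULL)
  }
  dfs(1L)
  list(alignments = records, best = best, n = n_found, best_rows = best_rec)
}
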