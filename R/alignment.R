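# Multiple alignments.
#
# An alignment relates one New pattern (row 0, stored first) to appearances
# of Old patterns (one row per appearance; the same stored pattern may appear
# several times, which is what makes recursion expressible).  Every symbol of
# every row belongs to exactly one column: matched symbols share a column,
# unmatched symbols sit in single-entry columns.  Column order is not stored;
# it is the (deterministic) topological order of the column DAG whose
# constraints are each row's internal left-to-right order.  Legality:
#   * order preservation: each row's positions increase along column order
#     (equivalently, the column DAG is acyclic);
#   * homogeneity: all symbols in a column have the same name;
#   * a matched column is a resolving pair: a sensory (row 0) symbol with a
#     stored contents symbol (recognition), a stored contents reference with
#     the service (ID) symbol it resolves, or a row-0 code symbol with a
#     service symbol (decoding).  Never two symbols of the same kind, and
#     never more than two: unifying two service instances, or two
#     references, would bank compression gain that no code could decode.

#' Search parameters for alignment building and grammar induction
#'
#' @param beam number of alignments retained per stage of the search.
#' @param max_stages hard cap on the number of search stages.
#' @param max_hits number of alternative match-sets considered per
#'   (alignment, stored pattern) pair in one stage.
#' @param appearance_cap maximum appearances of one stored pattern in one
#'   alignment (bounds runaway recursion on self-referential grammars).
#' @param beam_grammars number of grammar candidates retained during
#'   induction.
#' @param batch_size induction corpus batch between rescoring passes.
#' @return a list of class `sp_search_params`.
#' @export
sp_search_params <- function(beam = 20L, max_stages = 20L, max_hits = 5L,
                             appearance_cap = 10L, beam_grammars = 4L,
                             batch_size = 10L) {
  structure(list(beam = as.integer(beam), max_stages = as.integer(max_stages),
                 max_hits = as.integer(max_hits),
                 appearance_cap = as.integer(appearance_cap),
                 beam_grammars = as.integer(beam_grammars),
                 batch_size = as.integer(batch_size)),
            class = "sp_search_params")
}

# -- construction -----------------------------------------------------------

aln_init <- function(new) {
  if (new$provenance != "NEW" && !inherits(new, "sp_code"))
    stop("row 0 must be a New pattern")
  n <- length(new$symbols)
  aln <- list(
    rows = list(list(pattern_id = new$pattern_id, instance = 0L,
                     symbols = new$symbols, role = new$role, new = TRUE)),
    colid = list(seq_len(n)),
    next_col = n + 1L)
  aln_finalize(aln)
}

# Append one appearance row, sharing columns per `matchset` (data.frame with
# columns j = position in `pat`, col = existing column id).
aln_add_row <- function(aln, pat, matchset) {
  inst <- sum(vapply(aln$rows, function(r) identical(r$pattern_id,
                                                    pat$pattern_id), TRUE))
  m <- length(pat$symbols)
  cid <- integer(m)
  if (nrow(matchset)) cid[matchset$j] <- matchset$col
  un <- which(cid == 0L)
  if (length(un)) {
    cid[un] <- seq.int(aln$next_col, length.out = length(un))
    aln$next_col <- aln$next_col + length(un)
  }
  aln$rows[[length(aln$rows) + 1L]] <-
    list(pattern_id = pat$pattern_id, instance = inst,
         symbols = pat$symbols, role = pat$role, new = FALSE)
  aln$colid[[length(aln$colid) + 1L]] <- cid
  aln_finalize(aln)
}

# Validate, renumber columns densely, compute the column table, topological
# order and reachability.  Errors on any illegal structure.
aln_finalize <- function(aln) {
  rows <- rep.int(seq_along(aln$colid),
                  vapply(aln$colid, length, 0L))
  pos <- unlist(lapply(aln$colid, seq_along), use.names = FALSE)
  col_raw <- unlist(aln$colid, use.names = FALSE)
  name <- unlist(lapply(aln$rows, `[[`, "symbols"), use.names = FALSE)
  role <- unlist(lapply(aln$rows, `[[`, "role"), use.names = FALSE)
  col <- match(col_raw, unique(col_raw))
  ncol <- max(col)

  # homogeneity + resolving-pair composition per column (vectorized)
  first <- match(col, col)
  if (any(name != name[first]))
    stop("illegal alignment: column mixes symbol names")
  if (anyDuplicated(col * (max(rows) + 1L) + rows))
    stop("illegal alignment: one row twice in a column")
  if (any(tabulate(col, nbins = ncol) > 2L))
    stop("illegal alignment: column with more than two entries")
  # entry kind: sensory (row 0), stored contents, or service symbol
  ekind <- ifelse(rows == 1L, "N", ifelse(role == "ID", "I", "C"))
  if (anyDuplicated(paste0(col, ":", ekind)))
    stop("illegal alignment: column unifies two symbols of the same kind")

  # column DAG edges: consecutive positions within each row
  nr <- length(aln$colid)
  from <- integer(0); to <- integer(0)
  cstart <- c(0L, cumsum(vapply(aln$colid, length, 0L)))
  for (r in seq_len(nr)) {
    ix <- (cstart[r] + 1L):cstart[r + 1L]
    if (length(ix) > 1L) {
      from <- c(from, col[ix[-length(ix)]])
      to <- c(to, col[ix[-1L]])
    }
  }
  keep <- !duplicated(paste(from, to))
  from <- from[keep]; to <- to[keep]

  # deterministic Kahn topological sort; tie-break by the smallest
  # (row, position) entry of the candidate columns
  indeg <- tabulate(to, nbins = ncol)
  key <- rep(Inf, ncol)
  ord_ix <- order(rows, pos)
  for (i in ord_ix) if (!is.finite(key[col[i]]))
    key[col[i]] <- rows[i] * 1e6 + pos[i]
  topo <- integer(ncol)
  avail <- which(indeg == 0L)
  adj <- split(to, factor(from, levels = seq_len(ncol)))
  for (t in seq_len(ncol)) {
    if (!length(avail)) stop("illegal alignment: ordering cycle")
    pick <- avail[which.min(key[avail])]
    topo[t] <- pick
    avail <- avail[avail != pick]
    for (v in adj[[pick]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) avail <- c(avail, v)
    }
  }

  # reachability (strict): reach[u, v] TRUE iff a directed path u -> v
  reach <- matrix(FALSE, ncol, ncol)
  for (t in rev(seq_len(ncol))) {
    u <- topo[t]
    succ <- adj[[u]]
    for (v in succ) {
      reach[u, v] <- TRUE
      reach[u, ] <- reach[u, ] | reach[v, ]
    }
  }

  # renumber stored colids densely
  for (r in seq_len(nr)) {
    ix <- (cstart[r] + 1L):cstart[r + 1L]
    aln$colid[[r]] <- col[ix]
  }
  aln$next_col <- ncol + 1L
  aln$cols <- data.frame(col = col, row = rows, pos = pos,
                         name = name, role = role,
                         stringsAsFactors = FALSE)
  aln$topo <- topo
  aln$reach <- reach
  col_name <- character(ncol); col_name[col] <- name
  col_nid <- tabulate(col[role == "ID"], nbins = ncol)
  col_n <- tabulate(col, nbins = ncol)

  # data-grounding: every appearance row with contents must trace back to
  # row 0 -- directly (one of its symbols paired with a row-0 symbol) or
  # through a resolved reference to a data-grounded child that itself has
  # contents.  Free-floating towers of mutually-referencing appearances
  # would otherwise bank unification gain the input never shows.
  if (nr > 1L) {
    row0cols <- aln$colid[[1L]]
    direct <- logical(nr)
    has_contents <- logical(nr)
    kids <- vector("list", nr)
    for (r in 2:nr) {
      cid <- aln$colid[[r]]
      rrole <- aln$rows[[r]]$role
      has_contents[r] <- any(rrole == "CONTENTS")
      direct[r] <- any(cid %in% row0cols)
      cc <- cid[rrole == "CONTENTS"]
      for (r2 in 2:nr) {
        if (r2 == r) next
        idc2 <- aln$colid[[r2]][aln$rows[[r2]]$role == "ID"]
        if (any(idc2 %in% cc)) kids[[r]] <- c(kids[[r]], r2)
      }
    }
    grounded <- direct
    repeat {
      changed <- FALSE
      for (r in 2:nr) {
        if (grounded[r]) next
        if (any(grounded[kids[[r]]] & has_contents[kids[[r]]])) {
          grounded[r] <- TRUE; changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (any(has_contents[-1L] & !grounded[-1L]))
      stop("illegal alignment: ungrounded appearance row")
  }
  aln$col_name <- col_name
  aln$col_n <- col_n
  aln$col_has_id <- col_nid > 0L
  class(aln) <- "sp_alignment"
  aln
}

#' Assert the legality of a multiple alignment
#'
#' Checks order preservation (acyclic column DAG), column homogeneity,
#' single-use of every (row, position), and ID-uniqueness per column.  All
#' constructors run these checks; this is exposed for tests and for
#' alignments rebuilt from text.
#'
#' @param aln an `sp_alignment`.
#' @return `aln`, invisibly; errors if illegal.
#' @export
aln_validate <- function(aln) { aln_finalize(unclass(aln)); invisible(aln) }

#' @export
print.sp_alignment <- function(x, ...) {
  s <- x$score
  cat(sprintf("<sp_alignment: %d rows, %d columns%s>\n",
              length(x$rows), length(x$col_name),
              if (is.null(s)) "" else sprintf(", cs=%.3g", s$cs)))
  cat(render_alignment(x), sep = "\n")
  invisible(x)
}

n_appearances <- function(aln, pattern_id) {
  sum(vapply(aln$rows[-1L], function(r) r$pattern_id == pattern_id, TRUE))
}

#' Appearance multiset of an alignment
#' @param aln an `sp_alignment`.
#' @return character vector of pattern ids, one per appearance row (sorted).
#' @export
appearance_multiset <- function(aln) {
  sort(vapply(aln$rows[-1L], `[[`, "", "pattern_id"))
}

# -- scoring ----------------------------------------------------------------

#' Score an alignment by information compression
#'
#' Every unification is a compression gain: a column pairing two copies of
#' one symbol replaces two instances by one, crediting one symbol cost
#' (`b_gain`).  Against that stands everything the stored structure asserts
#' without support (`b_code`): every unmatched symbol of every appearance
#' row -- unresolved service (ID) symbols, which form the residual code,
#' and unexpressed contents symbols alike.  `cs = b_gain - b_code`;
#' unmatched sensory (row 0) symbols are simply not gained, not charged.
#' `b_new` (the cost of the New symbols matched into paired columns) is
#' also reported: the share of the gain carried by the sensory row itself.
#'
#' @param aln a legal `sp_alignment`.
#' @param model an `sp_cost_model`.
#' @return `aln` with `aln$score = list(b_new, b_gain, b_code, cs)`.
#' @export
score_alignment <- function(aln, model) {
  cost <- symbol_cost(model, aln$col_name)
  b_gain <- sum((aln$col_n - 1L) * cost)
  old_single <- tabulate(aln$cols$col[aln$cols$row > 1L],
                         nbins = length(aln$col_n)) == 1L &
    aln$col_n == 1L
  b_code <- sum(cost[old_single])
  newrow <- aln$cols$row == 1L
  matched_new <- aln$cols$col[newrow][aln$col_n[aln$cols$col[newrow]] >= 2L]
  b_new <- sum(symbol_cost(model, aln$col_name[matched_new]))
  aln$score <- list(b_new = b_new, b_gain = b_gain, b_code = b_code,
                    cs = b_gain - b_code)
  aln
}

# -- matching a pattern against an alignment --------------------------------

# Enumerate maximal legal match-sets between `pat` (a candidate appearance)
# and the columns of `aln`.  A match-set is a set of (j, col) pairs, j the
# position in `pat`, names equal, such that adding `pat` as a new row keeps
# the alignment legal: js distinct and increasing implies no column reaches
# back to an earlier one; each column used once; a column that already holds
# an ID symbol cannot take another ID symbol.  Returns up to `max_sets`
# match-sets ranked by summed matched-symbol cost (deterministic tie-break).
match_into_alignment <- function(aln, pat, model, max_sets = 10L,
                                 limit = 4000L) {
  names_t <- pat$symbols
  role_t <- pat$role
  hit <- which(outer(aln$col_name, names_t, "=="), arr.ind = TRUE)
  if (!nrow(hit)) return(list())
  cand <- data.frame(j = hit[, 2L], col = hit[, 1L])
  # only open (single-entry) columns whose kind differs from the incoming
  # symbol's kind can take a match (resolving-pair rule)
  col_kind <- col_entry_kind(aln)
  t_kind <- ifelse(role_t[cand$j] == "ID", "I", "C")
  ok <- aln$col_n[cand$col] == 1L & col_kind[cand$col] != t_kind
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(list())
  cand <- cand[order(cand$j, match(cand$col, aln$topo)), , drop = FALSE]
  n <- nrow(cand)
  reach <- aln$reach
  w <- symbol_cost(model, names_t[cand$j])

  compat <- function(i, js, cols) {
    j <- cand$j[i]; cl <- cand$col[i]
    if (j %in% js || cl %in% cols) return(FALSE)
    for (k in seq_along(js)) {
      if (js[k] < j) { if (reach[cl, cols[k]]) return(FALSE) }
      else           { if (reach[cols[k], cl]) return(FALSE) }
    }
    TRUE
  }

  res <- list()
  overflow <- FALSE
  kth <- -Inf  # weight of the max_sets-th best set found so far
  remw <- rev(cumsum(rev(w)))  # optimistic completion weight from index i
  extend <- function(js, cols, wt, start) {
    if (overflow) return()
    if (length(res) >= max_sets &&
        wt + (if (start <= n) remw[start] else 0) < kth) return()
    any_ext <- FALSE
    if (start <= n) for (i in start:n) {
      if (compat(i, js, cols)) {
        any_ext <- TRUE
        extend(c(js, cand$j[i]), c(cols, cand$col[i]), wt + w[i], i + 1L)
        if (overflow) return()
      }
    }
    if (!any_ext && length(js)) {
      # maximal iff no candidate anywhere fits
      for (i in seq_len(min(start - 1L, n)))
        if (compat(i, js, cols)) return()
      res[[length(res) + 1L]] <<- list(js = js, cols = cols, wt = wt)
      if (length(res) >= limit) overflow <<- TRUE
      wts <- sort(vapply(res, `[[`, 0, "wt"), decreasing = TRUE)
      if (length(wts) >= max_sets) kth <<- wts[max_sets]
    }
  }
  extend(integer(0), integer(0), 0, 1L)
  if (!length(res)) return(list())
  sig <- vapply(res, function(s) paste(s$js, s$cols, collapse = ";"), "")
  wt <- vapply(res, `[[`, 0, "wt")
  ord <- order(-wt, sig)
  res <- res[ord][seq_len(min(max_sets, length(res)))]
  lapply(res, function(s) data.frame(j = s$js, col = s$cols))
}

#' Pairwise alignment of a driving sequence against a stored pattern
#'
#' Finds up to `max_hits` maximal, order-preserving (non-crossing) sets of
#' symbol matches between a driving symbol sequence and one stored pattern,
#' ranked by the summed bit cost of the matched symbols.
#'
#' @param driving character vector of symbol names (or an `sp_pattern`).
#' @param target an `sp_pattern`.
#' @param model an `sp_cost_model` (defaults to a uniform model over the two
#'   sequences).
#' @param max_hits maximum number of ranked match-sets to return.
#' @return list of data.frames with columns `driving` and `target` (1-based
#'   positions), best first; empty list if nothing matches.
#' @export
pairwise_align <- function(driving, target, model = NULL, max_hits = 10L) {
  if (inherits(driving, "sp_pattern")) driving <- driving$symbols
  if (length(driving) == 0L) stop("driving sequence must be non-empty")
  if (is.null(model)) {
    g <- sp_grammar(); g <- add_pattern(g, target)
    model <- sp_cost_model(g, sp_new_pattern(driving, "drv"))
  }
  aln <- aln_init(sp_new_pattern(driving, "drv"))
  sets <- match_into_alignment(aln, target, model, max_sets = max_hits)
  lapply(sets, function(s) {
    d <- data.frame(driving = s$col, target = s$j)  # col id == position here
    d[order(d$driving), , drop = FALSE]
  })
}

# -- staged heuristic search ------------------------------------------------

# Canonical signature for duplicate detection: columns in topological order,
# each as its sorted entries "rowkey:pos", where appearance rows of the same
# pattern are ranked by the topological position of their first column.
aln_signature <- function(aln) {
  first_topo <- vapply(seq_along(aln$rows), function(r) {
    min(match(aln$colid[[r]], aln$topo))
  }, 0L)
  key <- vapply(seq_along(aln$rows), function(r) {
    if (r == 1L) return("0")
    same <- which(vapply(aln$rows, `[[`, "", "pattern_id") ==
                    aln$rows[[r]]$pattern_id)
    same <- same[same != 1L]
    paste0(aln$rows[[r]]$pattern_id, "/",
           rank(first_topo[same], ties.method = "first")[match(r, same)])
  }, "")
  lab <- paste0(key[aln$cols$row], ":", aln$cols$pos)
  grp <- match(aln$cols$col, aln$topo)
  ent <- vapply(split(lab, grp), function(e)
    paste(sort(e), collapse = ","), "")
  paste(ent[order(as.integer(names(ent)))], collapse = "|")
}

code_string <- function(aln) paste(derive_code(aln)$symbols, collapse = " ")

#' Build multiple alignments of a New pattern against a grammar
#'
#' Staged bottom-up search.  Stage 1 matches every stored pattern directly
#' against the New pattern; each later stage composes the structures
#' retained so far into larger ones, resolving the reference pairs of
#' higher patterns with the service symbols of structures built below
#' (including fresh appearances of patterns already used, which is what
#' recursion needs).  A per-(pattern, span) beam keeps `max_hits`
#' interpretations of each structure alive; after at most `max_stages`
#' stages the best ordered combination of structures over the input is
#' selected and returned as an explicit alignment, together with ranked
#' alternatives.
#'
#' @param new a New `sp_pattern`.
#' @param grammar an `sp_grammar` (may be empty).
#' @param params an `sp_search_params`.
#' @param model an `sp_cost_model`; defaults to the uniform model over
#'   `grammar` plus `new`.
#' @return list of scored `sp_alignment`s, best first (compression score
#'   descending; ties broken toward more matched input, then compact
#'   structure, then lexicographically by derived code pattern).  Always
#'   contains at least the degenerate single-row alignment.
#' @export
build_alignments <- function(new, grammar, params = sp_search_params(),
                             model = NULL) {
  if (is.null(model)) model <- sp_cost_model(grammar, new)
  a0 <- score_alignment(aln_init(new), model)
  if (!length(grammar$patterns)) return(list(a0))
  items <- compose_chart(new, grammar, params, model)
  pool <- list()
  take <- function(aln) {
    sig <- aln_signature(aln)
    if (is.null(pool[[sig]])) pool[[sig]] <<- score_alignment(aln, model)
  }
  forest <- select_forest(items, length(new$symbols))
  if (length(forest))
    take(forest_to_alignment(forest, new, grammar))
  # ranked single-structure alternatives
  spanned <- Filter(function(it) !is.na(it$first), items)
  if (length(spanned)) {
    v <- vapply(spanned, function(it) it$cs - it$toppen, 0)
    sz <- vapply(spanned, `[[`, 0L, "size")
    nm <- vapply(spanned, `[[`, 0L, "nmatch")
    sg <- vapply(spanned, `[[`, "", "sig")
    pid <- vapply(spanned, `[[`, "", "pattern_id")
    ord <- order(-v, -nm, sz, sg)
    take_ix <- union(head(ord, min(params$beam, 10L)),
                     ord[!duplicated(pid[ord])])
    for (i in take_ix) {
      aln <- tryCatch(forest_to_alignment(list(spanned[[i]]), new, grammar),
                      error = function(e) NULL)
      if (!is.null(aln)) take(aln)
    }
  }
  take(a0)
  out <- unname(pool[aln_rank(pool)])
  out[seq_len(min(length(out), params$beam))]
}

# kind of each column's entries for the pairing rule: the kind of its sole
# entry for open columns ("N" sensory, "C" stored contents, "I" service);
# closed (paired) columns are marked "X".
col_entry_kind <- function(aln) {
  k <- ifelse(aln$cols$row == 1L, "N",
              ifelse(aln$cols$role == "ID", "I", "C"))
  out <- rep("X", length(aln$col_n))
  open <- aln$col_n == 1L
  out[aln$cols$col[open[aln$cols$col]]] <- k[open[aln$cols$col]]
  out
}

aln_rank <- function(alns) {
  cs <- vapply(alns, function(a) a$score$cs, 0)
  bn <- vapply(alns, function(a) a$score$b_new, 0)
  span <- vapply(alns, aln_span_sum, 0)
  code <- vapply(alns, code_string, "")
  nr <- vapply(alns, function(a) length(a$rows), 0L)
  sig <- names(alns) %||% vapply(alns, aln_signature, "")
  # ties on compression broken toward the alignment that explains more of
  # the input, then toward compact structure, then deterministically
  order(-cs, -bn, span, code, nr, sig)
}

# total column-span of the appearance rows: compact, contiguous nestings
# beat stretched ones that reach across unrelated material
aln_span_sum <- function(aln) {
  if (length(aln$rows) < 2L) return(0)
  tp <- match(seq_along(aln$col_n), aln$topo)
  sum(vapply(aln$colid[-1L], function(cid)
    diff(range(tp[cid])), 0))
}

# -- rendering --------------------------------------------------------------

#' Render an alignment as fixed-width text
#'
#' `"rows"` style puts one pattern per line (the New pattern first, as row
#' 0), symbols placed under their columns.  `"columns"` style puts one column
#' per line.  Both are deterministic and re-parseable by
#' [parse_alignment()].
#'
#' @param aln an `sp_alignment`.
#' @param style `"rows"` or `"columns"`.
#' @return character vector of lines.
#' @export
render_alignment <- function(aln, style = c("rows", "columns")) {
  style <- match.arg(style)
  topo <- aln$topo
  if (style == "columns") {
    return(vapply(seq_along(topo), function(t) {
      k <- topo[t]
      e <- aln$cols[aln$cols$col == k, , drop = FALSE]
      paste0(aln$col_name[k], " ",
             paste(sprintf("%d@%d", e$row - 1L, e$pos), collapse = " "))
    }, ""))
  }
  width <- nchar(aln$col_name)[topo]
  off <- cumsum(c(0L, head(width + 1L, -1L)))
  nr <- length(aln$rows)
  lines <- character(nr)
  for (r in seq_len(nr)) {
    buf <- rep(" ", sum(width + 1L))
    cid <- aln$colid[[r]]
    for (p in seq_along(cid)) {
      t <- match(cid[p], topo)
      ch <- strsplit(aln$rows[[r]]$symbols[p], "")[[1L]]
      buf[off[t] + seq_along(ch)] <- ch
    }
    lines[r] <- sprintf("%*d %s ;%s", nchar(nr - 1L), r - 1L,
                        sub(" +$", "", paste(buf, collapse = "")),
                        aln$rows[[r]]$pattern_id)
  }
  lines
}

#' Rebuild an alignment from its rendered text
#'
#' @param lines character vector as produced by [render_alignment()].
#' @param new the New pattern of row 0.
#' @param grammar the grammar the appearance rows came from (source of the
#'   symbol roles).
#' @param style which rendering style the text uses.
#' @return an `sp_alignment` (unscored).
#' @export
parse_alignment <- function(lines, new, grammar,
                            style = c("rows", "columns")) {
  style <- match.arg(style)
  if (style == "columns")
    stop("parsing the columns style is not supported; use style = 'rows'")
  parts <- regmatches(lines, regexpr(";[^;]*$", lines))
  ids <- sub("^;", "", parts)
  body <- sub(" *;[^;]*$", "", lines)
  body <- sub("^ *[0-9]+ ", "", body)
  toks <- lapply(seq_along(body), function(r) {
    m <- gregexpr("[^ ]+", body[r])[[1L]]
    if (m[1L] == -1L) return(data.frame(off = integer(0), tok = character(0)))
    data.frame(off = as.integer(m),
               tok = regmatches(body[r], gregexpr("[^ ]+", body[r]))[[1L]])
  })
  offs <- sort(unique(unlist(lapply(toks, `[[`, "off"))))
  aln <- list(rows = list(), colid = list(), next_col = length(offs) + 1L)
  for (r in seq_along(lines)) {
    if (r == 1L) {
      pat <- new
    } else {
      pat <- grammar$patterns[[ids[r]]]
      if (is.null(pat)) stop("unknown pattern id in rendering: ", ids[r])
    }
    if (!identical(pat$symbols, toks[[r]]$tok))
      stop("rendered row ", r - 1L, " does not match pattern ", ids[r])
    aln$rows[[r]] <- list(pattern_id = pat$pattern_id,
                          instance = sum(ids[seq_len(r - 1L)] == ids[r]),
                          symbols = pat$symbols, role = pat$role,
                          new = r == 1L)
    aln$colid[[r]] <- match(toks[[r]]$off, offs)
  }
  aln_finalize(aln)
}

#' Serialize an alignment as JSON
#'
#' @param aln a scored `sp_alignment`.
#' @return a JSON string with fields `rows` (pattern_id, instance), `columns`
#'   (in column order, each with its entries row/pos/name/role) and `score`
#'   (`b_new`, `b_gain`, `b_code`, `cs`).
#' @export
alignment_json <- function(aln) {
  rows <- lapply(aln$rows, function(r)
    list(pattern_id = r$pattern_id, instance = r$instance))
  cols <- lapply(aln$topo, function(k) {
    e <- aln$cols[aln$cols$col == k, , drop = FALSE]
    list(name = aln$col_name[k],
         entries = lapply(seq_len(nrow(e)), function(i)
           list(row = e$row[i] - 1L, pos = e$pos[i], role = e$role[i])))
  })
  jsonlite::toJSON(list(rows = rows, columns = cols, score = aln$score),
                   auto_unbox = TRUE, digits = NA)
}
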