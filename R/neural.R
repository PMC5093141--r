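# A localist neural realization of the pattern repository: each stored
# pattern becomes a pattern assembly (an ordered array of neural symbols
# with lateral connections); a receptor array encodes sensory input; and
# directed excitatory links run from receptor and service (ID) neural
# symbols to every same-named symbol node (the labeled-line principle: a
# node's meaning is fixed by what it is connected to).  Recognition is
# staged: receptor excitation spreads into assemblies, sufficiently excited
# assemblies fire their service symbols onward, and the process repeats
# until no assembly can be newly excited.  The winning structure -- the
# neural analog of a multiple alignment (NAMA) -- should agree with the
# abstract engine's best alignment.

#' Compile a grammar into a pattern-assembly graph
#'
#' One assembly per stored pattern, one neural-symbol node per symbol
#' occurrence, a receptor node per terminal symbol name, excitatory edges
#' from every receptor or ID node to every other same-named node, and
#' lateral edges between neighbouring nodes within each assembly.
#'
#' @param grammar a non-empty `sp_grammar`.
#' @return an object of class `sp_assembly_graph`.
#' @export
compile_graph <- function(grammar) {
  if (length(grammar$patterns) == 0L) stop("grammar is empty")
  classes <- unique(vapply(grammar$patterns, function(p) p$symbols[1L], ""))
  assemblies <- lapply(grammar$patterns, function(p) {
    # adjacent contents "X ... #X" form a reference pair: both neural
    # symbols must bind signals of one and the same source assembly
    pair <- rep(NA_integer_, length(p$symbols))
    cix <- which(p$role == "CONTENTS")
    i <- 1L
    while (i < length(cix)) {
      if (p$symbols[cix[i]] %in% classes &&
          p$symbols[cix[i + 1L]] == paste0("#", p$symbols[cix[i]])) {
        pair[cix[i]] <- cix[i + 1L]
        pair[cix[i + 1L]] <- cix[i]
        i <- i + 2L
      } else i <- i + 1L
    }
    list(pattern_id = p$pattern_id, symbols = p$symbols, role = p$role,
         pair = pair,
         boundary = p$role == "ID" &
           (startsWith(p$symbols, "#") | seq_along(p$symbols) == 1L))
  })
  id_names <- unique(unlist(lapply(grammar$patterns, function(p)
    p$symbols[p$role == "ID"]), use.names = FALSE))
  term_names <- setdiff(
    unique(unlist(lapply(grammar$patterns, function(p)
      p$symbols[p$role == "CONTENTS"]), use.names = FALSE)),
    id_names)

  nodes <- do.call(rbind, c(
    list(data.frame(assembly = "receptor", idx = seq_along(term_names),
                    name = term_names, role = "RECEPTOR",
                    stringsAsFactors = FALSE)),
    lapply(assemblies, function(a)
      data.frame(assembly = a$pattern_id, idx = seq_along(a$symbols),
                 name = a$symbols, role = a$role,
                 stringsAsFactors = FALSE))))
  src <- which(nodes$role %in% c("RECEPTOR", "ID"))
  edges <- do.call(rbind, lapply(src, function(i) {
    to <- which(nodes$name == nodes$name[i] &
                  seq_len(nrow(nodes)) != i &
                  nodes$assembly != "receptor")
    if (!length(to)) return(NULL)
    data.frame(from = i, to = to)
  }))
  if (is.null(edges)) edges <- data.frame(from = integer(), to = integer())
  lateral <- do.call(rbind, lapply(assemblies, function(a) {
    n <- length(a$symbols)
    if (n < 2L) return(NULL)
    data.frame(assembly = a$pattern_id, i = 1:(n - 1L), j = 2:n,
               stringsAsFactors = FALSE)
  }))
  structure(list(assemblies = assemblies, receptors = term_names,
                 nodes = nodes, edges = edges,
                 lateral = lateral %||%
                   data.frame(assembly = character(), i = integer(),
                              j = integer())),
            class = "sp_assembly_graph")
}

#' @export
print.sp_assembly_graph <- function(x, ...) {
  cat(sprintf(
    "<sp_assembly_graph: %d assemblies, %d receptors, %d excitatory edges>\n",
    length(x$assemblies), length(x$receptors), nrow(x$edges)))
  invisible(x)
}

#' Export the assembly graph as an edge list
#' @param graph an `sp_assembly_graph`.
#' @param path output file; one `from -> to` pair per line with node labels
#'   `assembly:idx:name`.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  lab <- with(graph$nodes, paste(assembly, idx, name, sep = ":"))
  writeLines(c("# source target",
               paste(lab[graph$edges$from], lab[graph$edges$to])), path)
  invisible(path)
}

#' Lateral inhibition within one assembly
#'
#' When neighbouring signals are the same they inhibit each other; when they
#' differ they do not.  Uniform activation across a body is redundancy, and
#' suppressing it while leaving the boundary (service) nodes untouched
#' yields enhanced relative responses at the boundaries -- run-length
#' encoding in neural form.  Body activations are reduced by
#' `strength * mean(neighbour activation)` and clamped at zero; boundary
#' nodes are not inhibited.
#'
#' @param activation numeric vector, one value per node of the assembly.
#' @param is_boundary logical vector; `TRUE` for service (ID) nodes.
#' @param strength inhibition strength in `[0, 1]`.
#' @return numeric vector of post-inhibition activations.
#' @export
apply_inhibition <- function(activation, is_boundary, strength = 0.5) {
  n <- length(activation)
  stopifnot(length(is_boundary) == n, strength >= 0)
  out <- activation
  for (i in seq_len(n)) {
    if (is_boundary[i]) next
    nb <- c(if (i > 1L) activation[i - 1L], if (i < n) activation[i + 1L])
    out[i] <- max(0, activation[i] - strength * mean(nb))
  }
  out
}

#' Simulate staged recognition on the assembly graph
#'
#' Receptor nodes for the sensory symbols are clamped on; each stage, every
#' assembly tries to bind available signals (receptor excitation, or the
#' service-symbol signals of assemblies that have already fired) to its
#' contents nodes in order; assemblies whose excitation (bound signal mass
#' over contents length) reaches `theta` and that are among the `top_k`
#' most-excited assemblies of the stage fire: lateral inhibition suppresses
#' their uniformly-activated body and their service symbols signal onward.
#' Multiple disjoint bindings of one assembly fire as separate virtual
#' copies (capped), which is what recursion needs.  The process stops at a
#' fixpoint or after `max_iters` stages.
#'
#' @param graph an `sp_assembly_graph`.
#' @param sensory character vector of terminal symbol names.
#' @param theta firing threshold on the bound-contents fraction.
#' @param inhibition_strength lateral inhibition strength.
#' @param top_k number of assemblies selected per stage.
#' @param max_iters stage cap; exceeding it flags non-convergence.
#' @param appearance_cap maximum virtual copies of one assembly.
#' @return an object of class `sp_nama`: `list(winning, instances,
#'   converged, n_stages)`, where `winning` is the sorted multiset of
#'   assembly ids in the winning structure.
#' @export
simulate_recognition <- function(graph, sensory, theta = 0.4,
                                 inhibition_strength = 0.5, top_k = 2L,
                                 max_iters = 20L, appearance_cap = 10L) {
  if (length(sensory) == 0L)
    return(structure(list(winning = character(0), instances = list(),
                          converged = TRUE, n_stages = 0L),
                     class = "sp_nama"))
  unknown <- setdiff(sensory, graph$receptors)
  if (length(unknown))
    stop("sensory symbols outside the receptor alphabet: ",
         paste(unknown, collapse = ", "))
  # signals: name, lo, hi (real-valued order keys), src (instance id or
  # "receptor"), edge index within source (for same-source ordering),
  # strength, grounded (traceable to the receptor array)
  signals <- lapply(seq_along(sensory), function(p)
    list(name = sensory[p], lo = p, hi = p, src = paste0("r", p),
         edge = 1L, strength = 1, grounded = TRUE))
  instances <- list()   # fired virtual copies
  inst_sigs <- character(0)
  span_best <- list()   # values fired per (assembly, span)
  # an assembly with no contents nodes is a null expansion (a recursion
  # terminator): it is satisfied vacuously and carries no position, so a
  # single virtual copy stands ready and its signals bind anywhere
  for (a in graph$assemblies) {
    if (any(a$role == "CONTENTS")) next
    inst_id <- paste0("i", length(instances) + 1L)
    nids <- sum(a$role == "ID")
    inst <- list(id = inst_id, assembly = a$pattern_id,
                 bound_ids = character(0), consumed = character(0),
                 lo = NA_real_, hi = NA_real_,
                 excitation = 1, value = -nids, stage = 0L)
    instances <- c(instances, list(inst))
    inst_sigs <- c(inst_sigs, paste0(a$pattern_id, "|null"))
    for (i in seq_along(a$symbols))
      signals <- c(signals, list(list(
        name = a$symbols[i], lo = NA_real_, hi = NA_real_,
        src = inst_id, edge = i, strength = 1, grounded = FALSE)))
  }
  converged <- FALSE
  stage <- 0L
  new_from <- 1L
  while (stage < max_iters) {
    stage <- stage + 1L
    n_sig_now <- length(signals)
    by_id <- setNames(instances, vapply(instances, `[[`, "", "id"))
    fired <- FALSE
    for (a in graph$assemblies) {
      if (!any(a$role == "CONTENTS")) next
      n_contents <- sum(a$role == "CONTENTS")
      nids <- sum(a$role == "ID")
      src_value <- setNames(vapply(instances, `[[`, 0, "value"),
                            vapply(instances, `[[`, "", "id"))
      src_span <- setNames(vapply(instances, function(x)
        paste(x$lo, x$hi), ""), names(src_value))
      for (cand in bind_assembly(a, signals, theta, new_from = new_from,
                                 src_value = src_value,
                                 src_span = src_span)) {
        sig <- paste(a$pattern_id,
                     paste(cand$bound_ids, collapse = ","), sep = "|")
        if (sig %in% inst_sigs) next
        # a binding whose support would consume any signal twice is
        # suppressed outright (rival consumers inhibit each other)
        srcs <- sub("/.*$", "", cand$bound_ids)
        kids <- unique(srcs[srcs %in% names(by_id)])
        consumed <- c(cand$bound_ids,
                      unlist(lapply(by_id[kids], `[[`, "consumed"),
                             use.names = FALSE))
        if (anyDuplicated(consumed)) next
        # worth of the whole support: consumed minus dangling symbols --
        # the quantity that rival interpretations compete on
        value <- length(cand$bound_ids) -
          (n_contents - length(cand$bound_ids)) - nids
        for (k in kids)
          value <- value + by_id[[k]]$value + sum(srcs == k)
        # local competition: each (assembly, span) admits its `top_k`
        # most worthwhile interpretations; a stronger late arrival still
        # fires (the paper's selection of the most excited assemblies,
        # applied to rivals over the same stretch of input)
        key <- paste(a$pattern_id, cand$lo, cand$hi)
        used <- span_best[[key]] %||% numeric(0)
        if (length(used) >= top_k && value <= min(used)) next
        span_best[[key]] <- c(used, value)
        inst_id <- paste0("i", length(instances) + 1L)
        act <- numeric(length(a$symbols))
        act[a$role == "CONTENTS"] <- cand$node_strength
        act <- apply_inhibition(act, a$role == "ID", inhibition_strength)
        inst <- list(id = inst_id, assembly = a$pattern_id,
                     bound_ids = cand$bound_ids, consumed = consumed,
                     lo = cand$lo, hi = cand$hi,
                     excitation = cand$excitation, value = value,
                     stage = stage)
        instances <- c(instances, list(inst))
        by_id[[inst_id]] <- inst
        inst_sigs <- c(inst_sigs, sig)
        # the service symbols signal onward, boundary-enhanced
        idix <- which(a$role == "ID")
        for (i in idix) {
          at_end <- i > min(which(a$role == "CONTENTS"), Inf)
          signals <- c(signals, list(list(
            name = a$symbols[i],
            lo = if (at_end) cand$hi else cand$lo,
            hi = if (at_end) cand$hi else cand$lo,
            src = inst_id, edge = i,
            strength = cand$excitation / n_contents,
            grounded = TRUE)))
        }
        fired <- TRUE
      }
    }
    new_from <- n_sig_now + 1L
    if (!fired) { converged <- TRUE; break }
  }
  if (stage >= max_iters && !converged)
    warning("recognition did not converge within ", max_iters, " stages;",
            " returning partial state", call. = FALSE)
  nama_select(instances, signals, sensory, converged, stage, graph)
}

# Enumerate bindings of an assembly's contents nodes, in order, to available
# signals.  Successive bound signals must come strictly later (prev.hi <
# next.lo), except that signals emitted by one source instance may follow
# each other in their source's own node order.  Nodes may stay unbound;
# excitation = (sum of bound strengths) / (number of contents nodes).
bind_assembly <- function(a, signals, theta, cap = 400L, new_from = 1L,
                          src_value = numeric(0),
                          src_span = character(0)) {
  cix <- which(a$role == "CONTENTS")
  if (!length(cix)) return(list())
  res <- list()
  nsig <- length(signals)
  sig_name <- vapply(signals, `[[`, "", "name")
  sig_src <- vapply(signals, `[[`, "", "src")
  # for reference pairs, only the few most worthwhile child structures
  # per starting position are considered (their weaker rivals at the same
  # position are already suppressed)
  allowed_src <- NULL
  if (length(src_value)) {
    openers <- cix[!is.na(a$pair[cix]) & a$pair[cix] > cix]
    if (length(openers)) {
      cls <- unique(a$symbols[openers])
      allowed_src <- character(0)
      for (cl in cls) {
        six <- which(sig_name == cl & sig_src %in% names(src_value))
        if (!length(six)) next
        skey <- unname(src_span[sig_src[six]])
        sval <- src_value[sig_src[six]]
        keep <- top_per_key(skey, order(skey, -sval, sig_src[six]), 3L)
        allowed_src <- c(allowed_src, sig_src[six][keep])
      }
    }
  }
  recur <- function(k, last, bound, strengths, need_src) {
    if (length(res) >= cap) return()
    if (k > length(cix)) {
      # after the first stage, a binding must involve at least one signal
      # produced in the previous stage to be new
      if (length(bound) &&
          (new_from <= 1L ||
             max(unlist(bound, use.names = FALSE)) >= new_from)) {
        # firing requires a sufficient fraction of the contents nodes to
        # be driven, at least one of them by a signal grounded in the
        # receptor array (a structure fed only by vacuous terminators
        # asserts something the senses never showed); the excitation
        # itself is the total signal mass, so higher structures, fed by
        # everything below them, come to dominate the selection as
        # recognition builds up
        grounded_any <- any(vapply(bound, function(i)
          isTRUE(signals[[i]]$grounded), TRUE))
        if (grounded_any && length(bound) / length(cix) >= theta) {
          los <- vapply(bound, function(i) signals[[i]]$lo, 0)
          his <- vapply(bound, function(i) signals[[i]]$hi, 0)
          los <- los[!is.na(los)]; his <- his[!is.na(his)]
          if (!length(los)) { los <- NA_real_; his <- NA_real_ }
          ns <- numeric(length(cix))
          ns[match(names(bound), as.character(cix))] <- strengths
          res[[length(res) + 1L]] <<- list(
            bound_ids = vapply(bound, function(i) sig_id(signals[[i]]), ""),
            bound_ix = unlist(bound, use.names = FALSE),
            lo = min(los), hi = max(his),
            node_strength = ns,
            excitation = sum(strengths))
        }
      }
      return()
    }
    node <- cix[k]
    partner <- a$pair[node]
    closing <- !is.na(partner) && partner < node
    # leave unbound (forbidden for the closing half of a pair whose
    # opening half was bound: a reference pair resolves one child, whole)
    if (!closing || is.null(need_src))
      recur(k + 1L, last, bound, strengths, NULL)
    # bind a matching signal, newest signals first: combinations using
    # freshly built structure are the ones that can still be new
    for (i in rev(seq_len(nsig))) {
      if (sig_name[i] != a$symbols[node]) next
      if (closing) {
        if (is.null(need_src)) next     # pair was skipped: skip both
        if (sig_src[i] != need_src) next  # same child for both halves
      } else if (!is.na(partner) && partner > node &&
                 !is.null(allowed_src) &&
                 sig_src[i] %in% names(src_value) &&
                 !(sig_src[i] %in% allowed_src)) next
      if (!is.null(last)) {
        prev <- signals[[last]]
        cur <- signals[[i]]
        ok <- is.na(prev$hi) || is.na(cur$lo) || prev$hi < cur$lo ||
          (identical(prev$src, cur$src) && prev$edge < cur$edge)
        if (!ok) next
      }
      if (i %in% unlist(bound)) next
      b2 <- bound; b2[[as.character(node)]] <- i
      # position-free signals do not advance the ordering frontier
      newlast <- if (is.na(signals[[i]]$hi)) last else i
      recur(k + 1L, newlast, b2, c(strengths, signals[[i]]$strength),
            if (!is.na(partner) && partner > node) sig_src[i] else NULL)
    }
  }
  recur(1L, NULL, list(), numeric(0), NULL)
  res
}

sig_id <- function(s) paste0(s$src, "/", s$edge)

# Winning structure: greedily pick the instance explaining the most
# still-unexplained sensory positions (ties: higher support value, then
# compact and deterministic), pull in its whole support, and repeat;
# structures double-consuming a signal already claimed by the winning set
# are suppressed.
nama_select <- function(instances, signals, sensory, converged, n_stages,
                        graph) {
  if (!length(instances))
    return(structure(list(winning = character(0), instances = list(),
                          all_instances = instances,
                          converged = converged, n_stages = n_stages),
                     class = "sp_nama"))
  by_id <- setNames(instances, vapply(instances, `[[`, "", "id"))
  cover <- lapply(instances, function(x) {
    r <- grep("^r[0-9]+/", x$consumed, value = TRUE)
    sort(unique(as.integer(sub("^r([0-9]+)/.*$", "\\1", r))))
  })
  val <- vapply(instances, `[[`, 0, "value")
  sz <- vapply(instances, function(x) length(x$consumed), 0L)
  uncov <- seq_along(sensory)
  picked <- character(0)
  consumed_all <- character(0)
  repeat {
    gain <- vapply(cover, function(cv) length(intersect(cv, uncov)), 0L)
    if (length(consumed_all)) {
      for (i in which(gain > 0L)) {
        if (any(instances[[i]]$consumed %in% consumed_all)) gain[i] <- 0L
      }
    }
    if (!any(gain > 0L)) break
    lo <- vapply(instances, function(x) x$lo %||% Inf, 0)
    aid <- vapply(instances, `[[`, "", "assembly")
    best <- order(-gain, -val, sz, lo, aid)[1L]
    closure <- support_closure(instances[[best]], by_id)
    picked <- union(picked, closure)
    consumed_all <- c(consumed_all, instances[[best]]$consumed)
    uncov <- setdiff(uncov, cover[[best]])
  }
  win <- sort(unname(vapply(by_id[picked], `[[`, "", "assembly")))
  structure(list(winning = win, instances = by_id[picked],
                 all_instances = instances,
                 converged = converged, n_stages = n_stages),
            class = "sp_nama")
}

support_closure <- function(inst, by_id) {
  seen <- character(0)
  walk <- function(x) {
    if (x$id %in% seen) return()
    seen <<- c(seen, x$id)
    srcs <- unique(sub("/.*$", "", x$bound_ids))
    for (s in srcs) if (s %in% names(by_id)) walk(by_id[[s]])
  }
  walk(inst)
  seen
}

#' @export
print.sp_nama <- function(x, ...) {
  cat(sprintf("<sp_nama: %d winning instances%s>\n", length(x$winning),
              if (x$converged) "" else " (did not converge)"))
  if (length(x$winning))
    cat("  ", paste(x$winning, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare a neural recognition with an abstract alignment
#'
#' @param nama an `sp_nama`.
#' @param ma an `sp_alignment` built from the same grammar and input.
#' @return `list(agree = <logical>, nama = <multiset>, alignment =
#'   <multiset>, first_discrepancy = <NULL or character>)`.
#' @export
nama_vs_alignment <- function(nama, ma) {
  a <- nama$winning
  b <- appearance_multiset(ma)
  agree <- identical(a, b)
  first <- NULL
  if (!agree) {
    extra <- setdiff(union(a, b), character(0))
    for (id in sort(extra)) {
      if (sum(a == id) != sum(b == id)) {
        first <- sprintf("pattern %s: %d in NAMA vs %d in alignment",
                         id, sum(a == id), sum(b == id))
        break
      }
    }
    if (is.null(first)) first <- "multiset mismatch"
  }
  list(agree = agree, nama = a, alignment = b, first_discrepancy = first)
}

#' Brain-capacity arithmetic
#'
#' Order-of-magnitude bookkeeping: raw neural storage (neuron count times
#' bits per neuron, expressed in binary megabytes and rounded to one
#' significant figure), the same range scaled by an assumed compression
#' factor, an uncompressed-knowledge estimate from a compressed corpus size,
#' and the multi-copy storage requirement, with a flag for whether the
#' requirement falls inside the compressed-capacity range.
#'
#' @param neurons_low,neurons_high neuron-count range.
#' @param bits_per_neuron storage per neuron, bits.
#' @param compression_factor assumed overall compression factor.
#' @param copies stored copies of the knowledge base.
#' @param corpus_compressed_mb size of the compressed reference corpus, MB.
#' @return list with `raw_mb` (low/high), `compressed_mb` (low/high),
#'   `knowledge_uncompressed_mb`, `requirement_mb`, `within_capacity`.
#' @export
estimate_capacity <- function(neurons_low = 1e10, neurons_high = 1e11,
                              bits_per_neuron = 1, compression_factor = 3,
                              copies = 3, corpus_compressed_mb = 1300) {
  args <- c(neurons_low, neurons_high, bits_per_neuron, compression_factor,
            copies, corpus_compressed_mb)
  if (any(args <= 0)) stop("all capacity inputs must be positive")
  mb <- function(n) n * bits_per_neuron / 8 / 2^20
  raw <- signif(c(low = mb(neurons_low), high = mb(neurons_high)), 1)
  compressed <- signif(raw * compression_factor, 1)
  knowledge <- signif(corpus_compressed_mb * compression_factor, 1)
  requirement <- knowledge * copies
  list(raw_mb = raw, compressed_mb = compressed,
       knowledge_uncompressed_mb = knowledge,
       requirement_mb = requirement,
       within_capacity = requirement >= compressed[["low"]] &&
         requirement <= compressed[["high"]])
}
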