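#' Perspectives: extended activity networks
#'
#' A *perspective* decomposes one expected system-level behaviour into a
#' network of cellular activities. Beyond ordinary sequential edges
#' (with forks, joins, decisions and merges), three extended relationship
#' kinds capture population-level immunology that standard activity
#' notation cannot:
#'
#' * **propagating** — an active source activity spawns new tokens of
#'   execution at a target any number of times without itself moving or
#'   terminating (cellular proliferation, cytokine secretion); once the
#'   source token departs, no more spawns occur;
#' * **interrupting** — an active interrupter partially (degree in
#'   \[0,1\]) or fully (degree 1) blocks firings of a target sequential
#'   edge (regulatory killing, suppressive signalling);
#' * **contributory** — an active source shifts the branch weights of a
#'   decision node without being consumed, so one source can influence
#'   many routings (polarizing signals biasing dendritic-cell fate).
#'
#' Perspectives are typically cyclic and need not contain end nodes; they
#' must contain at least one start node so execution has somewhere to
#' begin. Swim lanes annotate the compartment in which an activity takes
#' place and are checked by [check_model()], not enforced during flow.
#'
#' @name perspectives
NULL

#' Construct an activity node
#'
#' @param name node identifier
#' @param kind one of start, action, decision, merge, fork, join, end
#' @param swim_lane optional compartment name annotation
#' @param subject optional entity-type reference (who performs it)
#' @return a `dm_activity_node`
#' @export
activity_node <- function(name,
                          kind = c("action", "start", "decision", "merge",
                                   "fork", "join", "end"),
                          swim_lane = NULL, subject = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, kind = kind, swim_lane = swim_lane,
                 subject = subject),
            class = "dm_activity_node")
}

#' Sequential, propagating, interrupting and contributory edges
#'
#' @param from,source,to,target node names (for [interrupt_edge()],
#'   `target` is a sequential-edge id `"A->B"`)
#' @param dwell optional parameter name: steps a token must dwell at
#'   `from` before the edge is eligible (default 1 step)
#' @param spawn_rate parameter name: expected spawns per active source
#'   token per step (Poisson)
#' @param degree parameter name in \[0,1\]: blocking strength
#' @param weight_shift named numeric: additive shift per branch target
#'   of the decision
#' @return edge objects used in [perspective()]
#' @name flow_edges
NULL

edge_id <- function(from, to) paste0(from, "->", to)

#' @rdname flow_edges
#' @export
sequential_edge <- function(from, to, dwell = NULL) {
  structure(list(from = from, to = to, dwell = dwell),
            class = "dm_sequential_edge")
}

#' @rdname flow_edges
#' @export
propagating_edge <- function(from, to, spawn_rate) {
  structure(list(from = from, to = to, spawn_rate = spawn_rate),
            class = "dm_propagating_edge")
}

#' @rdname flow_edges
#' @export
interrupt_edge <- function(source, target, degree) {
  structure(list(source = source, target = target, degree = degree),
            class = "dm_interrupt_edge")
}

#' @rdname flow_edges
#' @export
contributory_edge <- function(source, target, weight_shift) {
  stopifnot(is.numeric(weight_shift), !is.null(names(weight_shift)))
  structure(list(source = source, target = target,
                 weight_shift = weight_shift),
            class = "dm_contributory_edge")
}

#' Construct a perspective
#'
#' @param name perspective identifier
#' @param expands character vector of expected-behaviour names this
#'   perspective decomposes
#' @param nodes list of [activity_node()]
#' @param sequential,propagating,interrupts,contributory edge lists (see
#'   [flow_edges])
#' @return a `dm_perspective` (validate with [validate_perspective()])
#' @export
perspective <- function(name, expands, nodes, sequential = list(),
                        propagating = list(), interrupts = list(),
                        contributory = list()) {
  structure(
    list(name = name, expands = as.character(expands), nodes = nodes,
         sequential = sequential, propagating = propagating,
         interrupts = interrupts, contributory = contributory),
    class = "dm_perspective"
  )
}

perspective_node_names <- function(p) {
  vapply(p$nodes, `[[`, character(1), "name")
}

perspective_node_kinds <- function(p) {
  stats::setNames(vapply(p$nodes, `[[`, character(1), "kind"),
                  perspective_node_names(p))
}

#' Validate a perspective
#'
#' Checks the structural invariants and returns the problems found as
#' data (an empty tibble means the perspective is well-formed): at least
#' one start node; start nodes without incoming and end nodes without
#' outgoing sequential edges; decisions with at least two outgoing
#' branches; all edge endpoints resolving; interrupt targets naming an
#' existing sequential edge; contributory edges targeting a decision with
#' branch keys drawn from its outgoing edges.
#'
#' @param p a `dm_perspective`
#' @return tibble with columns `element`, `issue`
#' @export
validate_perspective <- function(p) {
  issues <- list()
  add <- function(element, issue) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(element = element,
                                                     issue = issue)
  }
  nn <- perspective_node_names(p)
  kinds <- perspective_node_kinds(p)
  if (anyDuplicated(nn)) {
    add(nn[duplicated(nn)][1L], "duplicate node name")
  }
  if (!any(kinds == "start")) {
    add(p$name, "perspective has no start node")
  }
  seq_from <- vapply(p$sequential, `[[`, character(1), "from")
  seq_to <- vapply(p$sequential, `[[`, character(1), "to")
  for (e in p$sequential) {
    for (endp in c(e$from, e$to)) {
      if (!endp %in% nn) add(edge_id(e$from, e$to),
                             paste0("unknown node '", endp, "'"))
    }
  }
  for (node in nn[kinds == "start"]) {
    if (node %in% seq_to) add(node, "start node has incoming sequential edge")
  }
  for (node in nn[kinds == "end"]) {
    if (node %in% seq_from) add(node, "end node has outgoing edge")
  }
  for (node in nn[kinds == "decision"]) {
    if (sum(seq_from == node) < 2L) {
      add(node, "decision node needs >= 2 outgoing sequential edges")
    }
  }
  seq_ids <- edge_id(seq_from, seq_to)
  for (e in p$propagating) {
    for (endp in c(e$from, e$to)) {
      if (!endp %in% nn) add(edge_id(e$from, e$to),
                             paste0("unknown node '", endp, "'"))
    }
  }
  for (e in p$interrupts) {
    if (!e$source %in% nn) add(e$source, "unknown interrupter node")
    if (!e$target %in% seq_ids) {
      add(e$target, "interrupt target is not an existing sequential edge")
    }
  }
  for (e in p$contributory) {
    if (!e$source %in% nn) add(e$source, "unknown contributory source")
    if (!e$target %in% nn) {
      add(e$target, "unknown contributory target")
    } else if (kinds[[e$target]] != "decision") {
      add(e$target, "contributory edge must target a decision node")
    } else {
      branches <- seq_to[seq_from == e$target]
      bad <- setdiff(names(e$weight_shift), branches)
      if (length(bad) > 0L) {
        add(e$target, paste0("weight_shift names non-branch(es): ",
                             paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(issues) == 0L) {
    tibble::tibble(element = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Initialize a flow state
#'
#' @param p a valid `dm_perspective`
#' @param initial_tokens named numeric vector of token counts per node;
#'   by default one token at every start node
#' @return a `dm_flow_state`: the live token multiset (with per-token age
#'   and, at join nodes, the arrival branch) plus cumulative firing
#'   counts per edge
#' @export
init_flow <- function(p, initial_tokens = NULL) {
  nn <- perspective_node_names(p)
  if (is.null(initial_tokens)) {
    kinds <- perspective_node_kinds(p)
    starts <- nn[kinds == "start"]
    initial_tokens <- stats::setNames(rep(1, length(starts)), starts)
  }
  bad <- setdiff(names(initial_tokens), nn)
  if (length(bad) > 0L) {
    stop("initial tokens placed on unknown node(s): ",
         paste(bad, collapse = ", "))
  }
  tokens <- data.frame(
    node = rep(names(initial_tokens), times = as.integer(initial_tokens)),
    age = 0L, via = NA_character_, stringsAsFactors = FALSE
  )
  seq_ids <- vapply(p$sequential, function(e) edge_id(e$from, e$to),
                    character(1))
  prop_ids <- vapply(p$propagating, function(e) edge_id(e$from, e$to),
                     character(1))
  fired <- stats::setNames(rep(0, length(seq_ids) + length(prop_ids)),
                           c(seq_ids, prop_ids))
  structure(list(tokens = tokens, fired = fired, consumed = 0),
            class = "dm_flow_state")
}

#' Token counts per node
#'
#' @param state a `dm_flow_state`
#' @return named numeric vector (all zero-count nodes omitted)
#' @export
flow_occupancy <- function(state) {
  if (nrow(state$tokens) == 0L) return(stats::setNames(numeric(), character()))
  tab <- table(state$tokens$node)
  stats::setNames(as.numeric(tab), names(tab))
}

resolve_param <- function(parameters, name, what, lo = -Inf, hi = Inf) {
  if (is.numeric(name)) return(name)  # literal rates allowed internally
  v <- parameters[[name]]
  if (is.null(v)) {
    stop("evaluation error: ", what, " parameter '", name,
         "' is not in the parameter table", call. = FALSE)
  }
  if (!is.numeric(v) || v < lo || v > hi) {
    stop("evaluation error: ", what, " parameter '", name,
         "' out of range", call. = FALSE)
  }
  v
}

#' Advance a flow by one step
#'
#' One synchronous step under a start-of-step snapshot. Token ages
#' advance, then each token old enough for an edge's dwell fires its
#' node's outgoing sequential edges (actions with several outgoing edges,
#' and fork nodes, duplicate the token; decisions route along one branch
#' sampled from baseline-1 weights additively shifted by active
#' contributory sources, floored at zero; joins consume one waiting token
#' per incoming branch and emit one). Every sequential edge's firing
#' probability is multiplied by prod(1 - degree) over its active
#' interrupters. Each token sitting at a propagating edge's source spawns
#' `Poisson(spawn_rate)` tokens at the target without moving. Tokens
#' reaching an end node are consumed.
#'
#' @param p a valid `dm_perspective`
#' @param state a `dm_flow_state`
#' @param parameters named numeric parameter table
#' @return the new `dm_flow_state`
#' @export
step_flow <- function(p, state, parameters = list()) {
  kinds <- perspective_node_kinds(p)
  tokens <- state$tokens
  fired <- state$fired
  consumed <- state$consumed
  tokens$age <- tokens$age + 1L
  snapshot <- tokens            # start-of-step view
  active <- unique(snapshot$node)

  seq_from <- vapply(p$sequential, `[[`, character(1), "from")
  seq_out <- split(p$sequential, seq_from)

  # interrupt multiplier per sequential edge id
  mult <- stats::setNames(rep(1, length(fired)), names(fired))
  for (ie in p$interrupts) {
    if (ie$source %in% active) {
      deg <- resolve_param(parameters, ie$degree, "interrupt degree", 0, 1)
      mult[[ie$target]] <- mult[[ie$target]] * (1 - deg)
    }
  }

  # decision branch weights under active contributory sources
  decision_weights <- function(node) {
    edges <- seq_out[[node]]
    branches <- vapply(edges, `[[`, character(1), "to")
    w <- stats::setNames(rep(1, length(branches)), branches)
    for (ce in p$contributory) {
      if (ce$target == node && ce$source %in% active) {
        shift <- ce$weight_shift
        w[names(shift)] <- w[names(shift)] + shift
      }
    }
    pmax(w, 0)
  }

  edge_dwell <- function(e) {
    if (is.null(e$dwell)) 1 else resolve_param(parameters, e$dwell,
                                               "dwell", 0, Inf)
  }
  passes_interrupt <- function(id) {
    m <- mult[[id]]
    if (m >= 1) TRUE else stats::runif(1) < m
  }

  keep <- rep(TRUE, nrow(snapshot))
  arrivals <- list()
  arrive <- function(node, via = NA_character_) {
    if (kinds[[node]] == "end") {
      consumed <<- consumed + 1
    } else {
      arrivals[[length(arrivals) + 1L]] <<-
        data.frame(node = node, age = 0L,
                   via = if (kinds[[node]] == "join") via else NA_character_,
                   stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(nrow(snapshot))) {
    node <- snapshot$node[i]
    age <- snapshot$age[i]
    kind <- kinds[[node]]
    edges <- seq_out[[node]]
    if (is.null(edges) || length(edges) == 0L) next
    if (kind == "decision") {
      w <- decision_weights(node)
      branches <- vapply(edges, `[[`, character(1), "to")
      eligible <- vapply(edges, function(e) age >= edge_dwell(e), logical(1))
      w[branches[!eligible]] <- 0
      if (sum(w) <= 0) next
      pick <- sample.int(length(branches), 1L, prob = w[branches])
      id <- edge_id(node, branches[pick])
      if (passes_interrupt(id)) {
        fired[[id]] <- fired[[id]] + 1
        keep[i] <- FALSE
        arrive(branches[pick], id)
      }
    } else if (kind %in% c("action", "start", "merge", "fork")) {
      moved <- FALSE
      for (e in edges) {
        if (age < edge_dwell(e)) next
        id <- edge_id(e$from, e$to)
        if (passes_interrupt(id)) {
          fired[[id]] <- fired[[id]] + 1
          moved <- TRUE
          arrive(e$to, id)
        }
      }
      if (moved) keep[i] <- FALSE
    } else if (kind == "join") {
      if (!is.na(snapshot$via[i])) next   # waiting for the other branches
      # an assembled token moves on like an action token
      moved <- FALSE
      for (e in edges) {
        if (age < edge_dwell(e)) next
        id <- edge_id(e$from, e$to)
        if (passes_interrupt(id)) {
          fired[[id]] <- fired[[id]] + 1
          moved <- TRUE
          arrive(e$to, id)
        }
      }
      if (moved) keep[i] <- FALSE
    }
  }

  # joins: consume one waiting token per incoming branch, emit one
  join_nodes <- names(kinds)[kinds == "join"]
  for (jn in join_nodes) {
    incoming <- unlist(lapply(p$sequential, function(e) {
      if (e$to == jn) edge_id(e$from, e$to) else NULL
    }))
    if (length(incoming) == 0L) next
    repeat {
      idx <- integer()
      for (br in incoming) {
        cand <- which(keep & snapshot$node == jn & snapshot$via == br &
                        !seq_len(nrow(snapshot)) %in% idx)
        if (length(cand) == 0L) break
        idx <- c(idx, cand[1L])
      }
      if (length(idx) < length(incoming)) break
      keep[idx] <- FALSE
      arrive_join <- data.frame(node = jn, age = 0L, via = NA_character_,
                                stringsAsFactors = FALSE)
      arrivals[[length(arrivals) + 1L]] <- arrive_join
    }
  }

  # propagation: per source token, Poisson spawns at target; source stays
  for (pe in p$propagating) {
    n_src <- sum(snapshot$node == pe$from)
    if (n_src == 0L) next
    rate <- resolve_param(parameters, pe$spawn_rate, "spawn rate", 0, Inf)
    spawned <- sum(stats::rpois(n_src, rate))
    if (spawned > 0L) {
      id <- edge_id(pe$from, pe$to)
      fired[[id]] <- fired[[id]] + spawned
      for (k in seq_len(spawned)) arrive(pe$to, id)
    }
  }

  remaining <- tokens[keep, , drop = FALSE]
  new_tokens <- if (length(arrivals) > 0L) {
    rbind(remaining, do.call(rbind, arrivals))
  } else {
    remaining
  }
  rownames(new_tokens) <- NULL
  structure(list(tokens = new_tokens, fired = fired, consumed = consumed),
            class = "dm_flow_state")
}

#' Run a flow for several steps
#'
#' @inheritParams step_flow
#' @param n_steps number of steps (>= 0); step 0 is the initial state
#' @param seed optional integer seed; fixing it makes the run (and its
#'   exported CSV) bit-reproducible
#' @param initial_tokens see [init_flow()]
#' @return a `dm_flow_run`: list with `occupancy` (tibble: step, node,
#'   count), `firing` (tibble: step, edge, cum_count) and `final_state`
#' @export
run_flow <- function(p, n_steps, parameters = list(), seed = NULL,
                     initial_tokens = NULL) {
  stopifnot(n_steps >= 0)
  issues <- validate_perspective(p)
  if (nrow(issues) > 0L) {
    stop("perspective '", p$name, "' is not well-formed: ",
         paste(issues$element, issues$issue, collapse = "; "))
  }
  if (!is.null(seed)) set.seed(seed)
  state <- init_flow(p, initial_tokens)
  occ <- vector("list", n_steps + 1L)
  fir <- vector("list", n_steps + 1L)
  occ[[1L]] <- flow_occupancy(state)
  fir[[1L]] <- state$fired
  for (k in seq_len(n_steps)) {
    state <- step_flow(p, state, parameters)
    occ[[k + 1L]] <- flow_occupancy(state)
    fir[[k + 1L]] <- state$fired
  }
  n_occ <- vapply(occ, length, integer(1))
  occupancy <- tibble::tibble(
    step = rep(0:n_steps, times = n_occ),
    node = as.character(unlist(lapply(occ, names))),
    count = as.numeric(unlist(occ))
  )
  n_edges <- length(state$fired)
  firing <- tibble::tibble(
    step = rep(0:n_steps, each = n_edges),
    edge = rep(names(state$fired), times = n_steps + 1L),
    cum_count = as.numeric(unlist(fir))
  )
  structure(
    list(perspective = p$name, occupancy = occupancy,
         firing = firing, final_state = state),
    class = "dm_flow_run"
  )
}

#' @export
print.dm_flow_run <- function(x, ...) {
  cat("<flow run>", x$perspective, "-",
      max(x$occupancy$step), "steps;",
      sum(x$final_state$fired), "edge firings;",
      x$final_state$consumed, "tokens consumed\n")
  invisible(x)
}

#' Total live tokens in a flow state
#'
#' @param state a `dm_flow_state`
#' @return numeric scalar
#' @export
flow_token_count <- function(state) nrow(state$tokens)
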