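#' Single-entity state machines
#'
#' The lowest modelling level describes each entity type (a cell or a
#' molecule) as a statechart: one or more orthogonal *regions*, each a set
#' of states with exactly one initial state. States may be `atomic`,
#' `composite` (containing substates with their own initial, e.g. a
#' "Lymphoid" location state decomposing into the individual lymphoid
#' organs) or `isolated` (a state with no incident transitions, used to
#' record standing capabilities such as a matured dendritic cell being
#' MHC-II capable). Transitions connect states of the same region and are
#' guarded by [parse_guard()] expressions; partial orthogonality between
#' regions is expressed by guards naming another region's active state as
#' a predicate (the interpreter values every state label of the machine's
#' own regions automatically).
#'
#' @name statecharts
NULL

#' Construct a state node
#'
#' @param name state identifier (case-sensitive, exact-match)
#' @param kind `"atomic"`, `"composite"` or `"isolated"`
#' @param substates list of `dm_state` (composite only)
#' @param initial name of the initial substate (composite only)
#' @param entry_actions,exit_actions action labels run on entry/exit
#' @param emissions action labels emitted on every step this state is active
#'   (e.g. cytokine secretion)
#' @return a `dm_state`
#' @export
state_node <- function(name, kind = c("atomic", "composite", "isolated"),
                       substates = list(), initial = NULL,
                       entry_actions = character(), exit_actions = character(),
                       emissions = character()) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "composite") {
    if (length(substates) == 0L) {
      stop("composite state '", name, "' must have at least one substate")
    }
    subnames <- vapply(substates, function(s) s$name, character(1))
    if (is.null(initial) || !initial %in% subnames) {
      stop("composite state '", name,
           "' must declare an initial substate among its substates")
    }
  } else if (length(substates) > 0L) {
    stop("only composite states may have substates ('", name, "')")
  }
  structure(
    list(name = name, kind = kind, substates = substates, initial = initial,
         entry_actions = as.character(entry_actions),
         exit_actions = as.character(exit_actions),
         emissions = as.character(emissions)),
    class = "dm_state"
  )
}

#' Construct a region of a state machine
#'
#' @param name region identifier
#' @param states list of [state_node()] objects (top level of this region)
#' @param initial name of the region's initial top-level state
#' @return a `dm_region`
#' @export
region <- function(name, states, initial) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  top <- vapply(states, function(s) s$name, character(1))
  if (length(initial) != 1L || !initial %in% top) {
    stop("region '", name, "' must declare exactly one initial state ",
         "among its top-level states")
  }
  structure(list(name = name, states = states, initial = initial),
            class = "dm_region")
}

#' Construct a guarded transition
#'
#' @param source,target state names; must lie in the same region and the
#'   source must not be an isolated state
#' @param guard guard text or a parsed `dm_guard`; empty means always-true
#' @param actions labels applied when the transition fires
#' @return a `dm_transition`
#' @export
transition <- function(source, target, guard = "", actions = character()) {
  structure(
    list(source = source, target = target, guard = parse_guard(guard),
         actions = as.character(actions)),
    class = "dm_transition"
  )
}

# flatten a region's states into an index: name -> (region, path, node)
flatten_states <- function(states, region_name, path = character()) {
  out <- list()
  for (s in states) {
    p <- c(path, s$name)
    out[[s$name]] <- list(region = region_name, path = p, node = s)
    if (s$kind == "composite") {
      out <- c(out, flatten_states(s$substates, region_name, p))
    }
  }
  out
}

#' Construct a state machine for an entity type
#'
#' Validates the structural invariants: state names unique within the
#' machine, exactly one initial per region, transition endpoints resolve
#' within one region, isolated states carry no incident transitions.
#'
#' @param entity_type name of the entity type this machine describes
#' @param regions list of [region()] objects
#' @param transitions list of [transition()] objects
#' @param death_states names of states whose occupation marks the entity
#'   as dead in simulation (e.g. an apoptotic state)
#' @return a `dm_state_machine`
#' @export
state_machine <- function(entity_type, regions, transitions = list(),
                          death_states = character()) {
  stopifnot(is.character(entity_type), length(entity_type) == 1L)
  index <- list()
  for (r in regions) {
    idx <- flatten_states(r$states, r$name)
    dup <- intersect(names(idx), names(index))
    if (length(dup) > 0L) {
      stop("state name(s) used more than once in machine '", entity_type,
           "': ", paste(dup, collapse = ", "))
    }
    index <- c(index, idx)
  }
  for (tr in transitions) {
    for (endp in c(tr$source, tr$target)) {
      if (!endp %in% names(index)) {
        stop("transition endpoint '", endp, "' does not resolve in machine '",
             entity_type, "'")
      }
    }
    if (index[[tr$source]]$region != index[[tr$target]]$region) {
      stop("transition ", tr$source, " -> ", tr$target,
           " crosses regions in machine '", entity_type, "'")
    }
    for (endp in c(tr$source, tr$target)) {
      if (index[[endp]]$node$kind == "isolated") {
        stop("isolated state '", endp, "' has an incident transition ",
             "in machine '", entity_type, "'")
      }
    }
  }
  bad_death <- setdiff(death_states, names(index))
  if (length(bad_death) > 0L) {
    stop("death state(s) not declared in machine '", entity_type, "': ",
         paste(bad_death, collapse = ", "))
  }
  trans_by_source <- split(transitions,
                           vapply(transitions, `[[`, character(1), "source"))
  structure(
    list(entity_type = entity_type, regions = regions,
         transitions = transitions, death_states = as.character(death_states),
         index = index, trans_by_source = trans_by_source),
    class = "dm_state_machine"
  )
}

#' @export
print.dm_state_machine <- function(x, ...) {
  cat("<state machine>", x$entity_type, "\n")
  for (r in x$regions) {
    cat("  region", r$name, ":",
        paste(vapply(r$states, `[[`, character(1), "name"), collapse = ", "),
        sprintf("(initial %s)", r$initial), "\n")
  }
  cat(" ", length(x$transitions), "transitions\n")
  invisible(x)
}

# descend composite initials to the active leaf; returns path top..leaf
descend_initial <- function(machine, state_name) {
  path <- machine$index[[state_name]]$path
  node <- machine$index[[state_name]]$node
  while (node$kind == "composite") {
    nxt <- node$initial
    path <- c(path, nxt)
    node <- machine$index[[nxt]]$node
  }
  path
}

#' Initial configuration of a machine
#'
#' Activates each region's initial state, descending into composite
#' initials, with all dwell counters at zero.
#'
#' @param machine a `dm_state_machine`
#' @return a `dm_config`: per region, the active leaf state and the dwell
#'   counter of every state on the active path
#' @export
initial_config <- function(machine) {
  regions <- lapply(machine$regions, function(r) {
    path <- descend_initial(machine, r$initial)
    list(leaf = path[length(path)],
         elapsed = stats::setNames(rep(0L, length(path)), path))
  })
  names(regions) <- vapply(machine$regions, `[[`, character(1), "name")
  structure(list(regions = regions), class = "dm_config")
}

#' Active state labels of a configuration
#'
#' @param config a `dm_config`
#' @return character vector of every active state (leaves and their
#'   composite ancestors, across all regions)
#' @export
active_states <- function(config) {
  unlist(lapply(config$regions, function(rc) names(rc$elapsed)),
         use.names = FALSE)
}

# value every machine state label as a predicate: TRUE iff active
own_state_env <- function(machine, config) {
  labs <- names(machine$index)
  env <- stats::setNames(as.list(labs %in% active_states(config)), labs)
  env
}

#' Force a region into a given state
#'
#' Used by the simulation engine to keep an agent's location region in
#' lock-step with the migration engine. Entering a new state resets its
#' dwell counter (and descends composite initials unless the target is a
#' leaf); re-asserting the current leaf is a no-op.
#'
#' @param machine a `dm_state_machine`
#' @param config a `dm_config`
#' @param region_name region to overwrite
#' @param state_name state to activate (leaf or composite)
#' @return updated `dm_config`
#' @export
set_region_state <- function(machine, config, region_name, state_name) {
  rc <- config$regions[[region_name]]
  if (is.null(rc)) stop("unknown region '", region_name, "'")
  info <- machine$index[[state_name]]
  if (is.null(info) || info$region != region_name) {
    stop("state '", state_name, "' is not in region '", region_name, "'")
  }
  path <- if (info$node$kind == "composite") {
    descend_initial(machine, state_name)
  } else {
    info$path
  }
  leaf <- path[length(path)]
  if (identical(leaf, rc$leaf)) return(config)
  old <- rc$elapsed
  elapsed <- stats::setNames(rep(0L, length(path)), path)
  keep <- intersect(names(old), path)  # retained ancestors keep their dwell
  elapsed[keep] <- old[keep]
  config$regions[[region_name]] <- list(leaf = leaf, elapsed = elapsed)
  config
}

#' Advance a machine by one step
#'
#' Evaluates, per region, the guards of transitions leaving the active
#' leaf or any of its composite ancestors against a start-of-step
#' snapshot (so a firing in one region never changes guard outcomes in
#' another within the same step). At most one transition fires per region;
#' ties are broken uniformly at random. Firing exits every active state
#' below the source/target least common ancestor (running exit actions,
#' innermost first), applies the transition's actions, and enters the
#' target (descending composite initials, running entry actions), with
#' the entered states' dwell counters reset to zero. Regions with no
#' enabled transition retain their state and increment dwell. The
#' emissions of every state active at the end of the step are appended.
#'
#' @param machine a `dm_state_machine`
#' @param config a valid `dm_config` for `machine`
#' @param env named logical list valuing external predicate atoms; the
#'   machine's own state labels are added automatically (active = TRUE)
#' @param parameters named numeric parameter table for `δ`/`λ` atoms
#' @param frozen character vector of region names whose transitions are
#'   not evaluated this step (dwell still advances)
#' @return list with elements `config` (the new `dm_config`), `emitted`
#'   (character vector of action labels: exit/transition/entry actions of
#'   firings plus per-step emissions of active states) and `fired`
#'   (data frame of the transitions taken: region, source, target)
#' @export
step_machine <- function(machine, config, env = list(), parameters = list(),
                         frozen = character()) {
  if (!inherits(config, "dm_config")) {
    stop("config must be a dm_config for machine '", machine$entity_type, "'")
  }
  if (!setequal(names(config$regions),
                vapply(machine$regions, `[[`, character(1), "name"))) {
    stop("config regions do not match machine '", machine$entity_type, "'")
  }
  snapshot <- config
  snap_env <- c(own_state_env(machine, snapshot), as.list(env))
  # external env may add predicates but must not mask the machine's own
  # state labels
  snap_env[names(own_state_env(machine, snapshot))] <-
    own_state_env(machine, snapshot)

  emitted <- character()
  fired <- list()

  for (rn in names(config$regions)) {
    rc_snap <- snapshot$regions[[rn]]
    active_path <- names(rc_snap$elapsed)
    if (!(rn %in% frozen)) {
      candidates <- list()
      for (src in active_path) {
        for (tr in machine$trans_by_source[[src]]) {
          candidates[[length(candidates) + 1L]] <- tr
        }
      }
      enabled <- Filter(function(tr) {
        evaluate_guard(tr$guard, snap_env,
                       elapsed = rc_snap$elapsed[[tr$source]],
                       parameters = parameters)
      }, candidates)
      if (length(enabled) > 0L) {
        tr <- enabled[[if (length(enabled) == 1L) 1L
                       else sample.int(length(enabled), 1L)]]
        src_path <- machine$index[[tr$source]]$path
        tgt_path_full <- descend_initial(machine, tr$target)
        # least common ancestor of the active path and the target's path
        lca_depth <- 0L
        while (lca_depth < min(length(active_path), length(tgt_path_full)) &&
               active_path[lca_depth + 1L] == tgt_path_full[lca_depth + 1L]) {
          lca_depth <- lca_depth + 1L
        }
        # the source itself is always exited, even when it is an ancestor
        # of the target (self/re-entry resets dwell)
        src_depth <- match(tr$source, active_path)
        exit_from <- min(lca_depth + 1L, src_depth)
        exited <- rev(active_path[seq(exit_from, length(active_path))])
        entered <- tgt_path_full[seq(exit_from, length(tgt_path_full))]
        for (sname in exited) {
          emitted <- c(emitted, machine$index[[sname]]$node$exit_actions)
        }
        emitted <- c(emitted, tr$actions)
        for (sname in entered) {
          emitted <- c(emitted, machine$index[[sname]]$node$entry_actions)
        }
        old <- config$regions[[rn]]$elapsed
        elapsed <- stats::setNames(rep(0L, length(tgt_path_full)),
                                   tgt_path_full)
        kept <- tgt_path_full[seq_len(exit_from - 1L)]
        elapsed[kept] <- old[kept] + 1L   # retained ancestors keep dwelling
        config$regions[[rn]] <- list(leaf = tgt_path_full[length(tgt_path_full)],
                                     elapsed = elapsed)
        fired[[length(fired) + 1L]] <-
          data.frame(region = rn, source = tr$source, target = tr$target,
                     stringsAsFactors = FALSE)
        next
      }
    }
    # quiescent (or frozen): retain state, advance dwell
    config$regions[[rn]]$elapsed <- config$regions[[rn]]$elapsed + 1L
  }

  for (sname in active_states(config)) {
    emitted <- c(emitted, machine$index[[sname]]$node$emissions)
  }
  fired <- if (length(fired) > 0L) do.call(rbind, fired) else
    data.frame(region = character(), source = character(),
               target = character(), stringsAsFactors = FALSE)
  list(config = config, emitted = emitted, fired = fired)
}

#' Run a machine for several steps under a fixed environment
#'
#' Convenience driver used for exploration and testing: steps the machine
#' `n_steps` times against a constant external predicate valuation and
#' records the active leaf of every region at each step.
#'
#' @inheritParams step_machine
#' @param n_steps number of steps
#' @param seed optional integer seed for the δ draws and tie-breaks
#' @return a tibble with columns `step`, `region`, `active` (leaf state),
#'   plus an attribute `"emitted"`: a list (one element per step) of the
#'   labels emitted
#' @export
run_machine <- function(machine, n_steps, env = list(), parameters = list(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- initial_config(machine)
  rows <- list()
  emitted <- vector("list", n_steps)
  snap <- function(step, config) {
    tibble::tibble(
      step = step,
      region = names(config$regions),
      active = vapply(config$regions, `[[`, character(1), "leaf")
    )
  }
  rows[[1L]] <- snap(0L, config)
  for (k in seq_len(n_steps)) {
    out <- step_machine(machine, config, env = env, parameters = parameters)
    config <- out$config
    emitted[[k]] <- out$emitted
    rows[[k + 1L]] <- snap(k, config)
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "emitted") <- emitted
  res
}
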