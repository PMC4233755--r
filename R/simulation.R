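#' Multi-agent stochastic simulation
#'
#' [run_sim()] binds a domain model's pieces into population-level runs:
#' each cell is an agent carrying a live statechart configuration inside
#' a compartment; molecules are per-compartment scalar fields. One
#' synchronous step, under a start-of-step snapshot, does in order:
#'
#' 1. *interactions* — per compartment, each eligible actor of every
#'    interaction rule fires with the rule's rate against one uniformly
#'    sampled eligible co-located partner, asserting predicates (e.g. a
#'    priming or binding signal, or the `killed` mark whose handling is
#'    left to the target's own statechart);
#' 2. *machine stepping* — every living agent's statechart advances (the
#'    location region is frozen: migration owns it), against an
#'    environment combining ambient predicates, molecule-presence
#'    predicates from the local fields and the step's asserted signals;
#' 3. *emissions* — `secrete_<molecule>` labels increment the local
#'    field; a `proliferate` label spawns exactly one daughter in the
#'    naive initial configuration with `parent_id` set;
#' 4. *deaths* — agents whose machine now occupies a declared death
#'    state stop living (dead agents never step, interact or migrate);
#' 5. *migration* — each living agent attempts one move along an allowed
#'    migration rule with its per-type migration probability, the
#'    location region being rewritten to match;
#' 6. *field decay* — each molecule field is scaled by `1 - decay`.
#'
#' Runs are deterministic given the seed. Agent iteration order is
#' shuffled each step as a safeguard against order artifacts; cells are
#' assumed well mixed within a compartment (the source domain description
#' gives no contact model).
#'
#' @name simulation
NULL

#' Declare an interaction rule
#'
#' @param name rule identifier (used for knockouts)
#' @param actor,partner lists `list(entity_type=, states=)`: the acting
#'   and target entity types with the active-state labels they must hold
#'   (empty `states` means any living agent of that type)
#' @param effect `"assert_predicate"`, `"kill"` or `"spawn"`
#' @param predicate predicate name to assert (assert_predicate only)
#' @param on `"actor"` or `"partner"`: who receives the predicate
#' @param spawn_entity entity type to create (spawn only; placed in the
#'   actor's compartment)
#' @param rate parameter name (or literal in \[0,1\]): per eligible actor
#'   per step firing probability
#' @param co_location must actor and partner share a compartment
#'   (default TRUE)
#' @return a `dm_interaction_rule`
#' @export
interaction_rule <- function(name, actor, partner,
                             effect = c("assert_predicate", "kill", "spawn"),
                             predicate = NULL, on = "partner",
                             spawn_entity = NULL, rate,
                             co_location = TRUE) {
  effect <- match.arg(effect)
  if (effect == "assert_predicate" && is.null(predicate)) {
    stop("assert_predicate rules need a predicate name")
  }
  if (effect == "spawn" && is.null(spawn_entity)) {
    stop("spawn rules need a spawn_entity")
  }
  stopifnot(on %in% c("actor", "partner"))
  structure(
    list(name = name, actor = actor, partner = partner, effect = effect,
         predicate = predicate, on = on, spawn_entity = spawn_entity,
         rate = rate, co_location = isTRUE(co_location)),
    class = "dm_interaction_rule"
  )
}

#' Simulation configuration
#'
#' @param initial_populations data frame with columns `entity_type`,
#'   `compartment`, `n` (nonnegative counts)
#' @param parameter_overrides named list merged over the model's table
#' @param n_steps number of steps (>= 0)
#' @param seed integer RNG seed
#' @param knockouts names of interaction rules or perspective edge ids to
#'   disable (see [apply_knockout()])
#' @param ambient_predicates predicates asserted true for every agent at
#'   every step (e.g. the standing antigen stimulus of an induced mouse)
#' @param force skip the strict consistency gate in [init_sim()]
#' @return a `dm_sim_config`
#' @export
sim_config <- function(initial_populations, parameter_overrides = list(),
                       n_steps = 100L, seed = 1L, knockouts = character(),
                       ambient_predicates = character(), force = FALSE) {
  initial_populations <- tibble::as_tibble(initial_populations)
  stopifnot(all(c("entity_type", "compartment", "n") %in%
                  names(initial_populations)),
            n_steps >= 0)
  if (any(initial_populations$n < 0)) {
    stop("initial populations must be nonnegative")
  }
  structure(
    list(initial_populations = initial_populations,
         parameter_overrides = parameter_overrides,
         n_steps = as.integer(n_steps), seed = as.integer(seed),
         knockouts = as.character(knockouts),
         ambient_predicates = as.character(ambient_predicates),
         force = isTRUE(force)),
    class = "dm_sim_config"
  )
}

#' Disable interaction rules or perspective edges
#'
#' Returns a configuration identical to `config` except that the listed
#' elements are disabled; names are validated against the model's
#' interaction rules and perspective edge ids when a model is supplied
#' (and always at [init_sim()]).
#'
#' @param config a `dm_sim_config`
#' @param names character vector of rule names / edge ids
#' @param model optional `dm_domain_model` for immediate validation
#' @return updated `dm_sim_config`
#' @export
apply_knockout <- function(config, names, model = NULL) {
  if (!is.null(model)) validate_knockouts(model, names)
  config$knockouts <- union(config$knockouts, as.character(names))
  config
}

knockout_universe <- function(model) {
  edge_ids <- unlist(lapply(model$perspectives, function(p) {
    c(vapply(p$sequential, function(e) edge_id(e$from, e$to), character(1)),
      vapply(p$propagating, function(e) edge_id(e$from, e$to), character(1)))
  }))
  c(names(model$interaction_rules), edge_ids)
}

validate_knockouts <- function(model, names) {
  unknown <- setdiff(names, knockout_universe(model))
  if (length(unknown) > 0L) {
    stop("unknown knockout name(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

sim_parameters <- function(model, config) {
  utils::modifyList(model$parameters, config$parameter_overrides)
}

new_agent <- function(id, entity, machine, compartment, parent_id = NA) {
  cfg <- initial_config(machine)
  list(id = id, entity_type = entity, config = cfg,
       compartment = compartment, alive = TRUE, parent_id = parent_id)
}

# place the location region (if any) at the agent's compartment
sync_location <- function(model, agent) {
  m <- model$state_machines[[agent$entity_type]]
  locr <- model$location_region
  if (is.null(machine_location_region(m, locr))) return(agent)
  if (!agent$compartment %in% names(m$index)) {
    stop("agent of type '", agent$entity_type, "' placed in compartment '",
         agent$compartment, "' absent from its location region")
  }
  agent$config <- set_region_state(m, agent$config, locr, agent$compartment)
  agent
}

#' Initialize a simulation
#'
#' Creates the initial agents (each in its machine's initial
#' configuration, location region synced to its compartment), zeroes the
#' molecule fields and seeds the RNG. Unless `config$force` is set, the
#' model must first pass [check_model()] strictly.
#'
#' @param model an assembled `dm_domain_model`
#' @param config a [sim_config()]
#' @return a `dm_sim_state`
#' @export
init_sim <- function(model, config) {
  if (!config$force) check_model(model, strict = TRUE)
  validate_knockouts(model, config$knockouts)
  comps <- model_compartment_names(model)
  cells <- model_entity_names(model)[
    vapply(model$entities, `[[`, character(1), "category") == "cell"]
  molecules <- setdiff(model_entity_names(model), cells)
  pops <- config$initial_populations
  bad_comp <- setdiff(pops$compartment, comps)
  if (length(bad_comp) > 0L) {
    stop("unknown compartment in initial populations: ",
         paste(bad_comp, collapse = ", "))
  }
  bad_ent <- setdiff(pops$entity_type, cells)
  if (length(bad_ent) > 0L) {
    stop("initial populations must name declared cell types; unknown: ",
         paste(bad_ent, collapse = ", "))
  }
  set.seed(config$seed)
  agents <- list()
  id <- 0L
  for (i in seq_len(nrow(pops))) {
    for (k in seq_len(pops$n[i])) {
      id <- id + 1L
      ag <- new_agent(id, pops$entity_type[i],
                      model$state_machines[[pops$entity_type[i]]],
                      pops$compartment[i])
      agents[[id]] <- sync_location(model, ag)
    }
  }
  fields <- matrix(0, nrow = length(molecules), ncol = length(comps),
                   dimnames = list(molecules, comps))
  init_counts <- table(factor(pops$entity_type, levels = cells))
  counts0 <- stats::setNames(rep(0L, length(cells)), cells)
  counts0[names(init_counts)] <- as.integer(
    tapply(pops$n, factor(pops$entity_type, levels = cells), sum,
           default = 0L))
  structure(
    list(model = model, config = config, step = 0L, agents = agents,
         next_id = id, fields = fields,
         initial_counts = counts0,
         births = stats::setNames(rep(0L, length(cells)), cells),
         deaths = stats::setNames(rep(0L, length(cells)), cells),
         events = list()),
    class = "dm_sim_state"
  )
}

agent_primary_state <- function(model, agent) {
  m <- model$state_machines[[agent$entity_type]]
  locr <- model$location_region
  for (r in m$regions) {
    if (r$name != locr) {
      return(agent$config$regions[[r$name]]$leaf)
    }
  }
  NA_character_
}

# predicate atoms mentioned anywhere in a machine's transition guards
machine_predicates <- function(machine) {
  unique(unlist(lapply(machine$transitions, function(tr) {
    guard_atoms(tr$guard)$predicates
  })))
}

#' Advance a simulation one step
#'
#' @param model the `dm_domain_model` being simulated
#' @param state a `dm_sim_state`
#' @return the updated `dm_sim_state`
#' @export
step_sim <- function(model, state) {
  config <- state$config
  params <- sim_parameters(model, config)
  locr <- model$location_region
  agents <- state$agents
  alive_idx <- which(vapply(agents, `[[`, logical(1), "alive"))
  threshold <- params$molecule_presence_threshold %||% 0.5

  # --- start-of-step snapshot of who is where in which states ---------
  snap <- lapply(agents[alive_idx], function(a) {
    list(id = a$id, entity_type = a$entity_type,
         compartment = a$compartment,
         labels = active_states(a$config))
  })
  preds_by_type <- lapply(model$state_machines, machine_predicates)

  # --- phase 1: interactions ------------------------------------------
  asserted <- list()   # agent id -> character vector of predicates
  assert_on <- function(id, pred) {
    key <- as.character(id)
    asserted[[key]] <<- c(asserted[[key]], pred)
  }
  rules <- model$interaction_rules
  rules <- rules[setdiff(names(rules), config$knockouts)]
  matches <- function(srec, who) {
    srec$entity_type == who$entity_type &&
      all(who$states %in% srec$labels)
  }
  for (rule in rules) {
    rate <- resolve_param(params, rule$rate, "interaction rate", 0, 1)
    actors <- Filter(function(s) matches(s, rule$actor), snap)
    if (length(actors) == 0L) next
    partners <- Filter(function(s) matches(s, rule$partner), snap)
    if (length(partners) == 0L) next
    partner_comp <- vapply(partners, `[[`, character(1), "compartment")
    for (ac in actors) {
      eligible <- partners[(!rule$co_location |
                              partner_comp == ac$compartment)]
      eligible <- Filter(function(s) s$id != ac$id, eligible)
      if (length(eligible) == 0L) next
      if (stats::runif(1) >= rate) next
      pt <- eligible[[if (length(eligible) == 1L) 1L
                      else sample.int(length(eligible), 1L)]]
      if (rule$effect == "assert_predicate") {
        target <- if (rule$on == "actor") ac$id else pt$id
        assert_on(target, rule$predicate)
      } else if (rule$effect == "kill") {
        assert_on(pt$id, "killed")
        state$events[[length(state$events) + 1L]] <-
          list(step = state$step + 1L, event = "kill", rule = rule$name,
               actor = ac$id, target = pt$id,
               compartment = ac$compartment)
      } else if (rule$effect == "spawn") {
        state$next_id <- state$next_id + 1L
        nb <- new_agent(state$next_id, rule$spawn_entity,
                        model$state_machines[[rule$spawn_entity]],
                        ac$compartment, parent_id = ac$id)
        agents[[length(agents) + 1L]] <- sync_location(model, nb)
        state$births[[rule$spawn_entity]] <-
          state$births[[rule$spawn_entity]] + 1L
        state$events[[length(state$events) + 1L]] <-
          list(step = state$step + 1L, event = "spawn", rule = rule$name,
               actor = ac$id, child = state$next_id,
               compartment = ac$compartment)
      }
    }
  }

  # --- phase 2: step every living agent's machine ---------------------
  presence <- state$fields >= threshold
  order_idx <- if (length(alive_idx) > 1L) {
    alive_idx[sample.int(length(alive_idx))]
  } else {
    alive_idx
  }
  newborns <- list()
  for (i in order_idx) {
    a <- agents[[i]]
    m <- model$state_machines[[a$entity_type]]
    preds <- preds_by_type[[a$entity_type]]
    env <- stats::setNames(as.list(rep(FALSE, length(preds))), preds)
    for (p in intersect(preds, config$ambient_predicates)) env[[p]] <- TRUE
    for (mol in rownames(presence)) {
      pp <- paste0(mol, "_present")
      if (pp %in% preds) env[[pp]] <- presence[mol, a$compartment]
    }
    got <- asserted[[as.character(a$id)]]
    for (p in intersect(preds, got)) env[[p]] <- TRUE
    frozen <- if (is.null(machine_location_region(m, locr))) character()
      else locr
    out <- step_machine(m, a$config, env = env, parameters = params,
                        frozen = frozen)
    a$config <- out$config

    # --- phase 3: emissions -------------------------------------------
    for (lab in out$emitted) {
      if (startsWith(lab, "secrete_")) {
        mol <- sub("^secrete_", "", lab)
        if (mol %in% rownames(state$fields)) {
          state$fields[mol, a$compartment] <-
            state$fields[mol, a$compartment] + 1
        }
      } else if (lab == "proliferate") {
        state$next_id <- state$next_id + 1L
        nb <- new_agent(state$next_id, a$entity_type, m, a$compartment,
                        parent_id = a$id)
        newborns[[length(newborns) + 1L]] <- sync_location(model, nb)
        state$births[[a$entity_type]] <- state$births[[a$entity_type]] + 1L
        state$events[[length(state$events) + 1L]] <-
          list(step = state$step + 1L, event = "birth", parent = a$id,
               child = state$next_id, entity_type = a$entity_type,
               compartment = a$compartment)
      }
    }

    # --- phase 4: deaths ----------------------------------------------
    if (length(m$death_states) > 0L &&
        any(active_states(a$config) %in% m$death_states)) {
      a$alive <- FALSE
      state$deaths[[a$entity_type]] <- state$deaths[[a$entity_type]] + 1L
      state$events[[length(state$events) + 1L]] <-
        list(step = state$step + 1L, event = "death", agent = a$id,
             entity_type = a$entity_type, compartment = a$compartment)
    }

    # --- phase 5: migration -------------------------------------------
    if (a$alive) {
      p_mig <- params[[paste0("p_migration_", a$entity_type)]] %||% 0
      if (p_mig > 0 && stats::runif(1) < p_mig) {
        targets <- migration_targets(model, a$entity_type, a$compartment,
                                     active_states(a$config))
        if (length(targets) > 0L) {
          dest <- targets[[if (length(targets) == 1L) 1L
                           else sample.int(length(targets), 1L)]]
          a$compartment <- dest
          a <- sync_location(model, a)
        }
      }
    }
    agents[[i]] <- a
  }
  agents <- c(agents, newborns)

  # --- phase 6: field decay -------------------------------------------
  for (mol in rownames(state$fields)) {
    decay <- params[[paste0("decay_", mol)]] %||% 0
    state$fields[mol, ] <- state$fields[mol, ] * (1 - decay)
  }

  state$agents <- agents
  state$step <- state$step + 1L
  state
}

sim_census <- function(model, state) {
  alive <- Filter(function(a) a$alive, state$agents)
  if (length(alive) == 0L) {
    return(tibble::tibble(step = state$step, entity_type = character(),
                          state = character(), compartment = character(),
                          count = integer()))
  }
  df <- tibble::tibble(
    step = state$step,
    entity_type = vapply(alive, `[[`, character(1), "entity_type"),
    state = vapply(alive, function(a) agent_primary_state(model, a),
                   character(1)),
    compartment = vapply(alive, `[[`, character(1), "compartment")
  )
  dplyr::count(df, .data$step, .data$entity_type, .data$state,
               .data$compartment, name = "count")
}

sim_bookkeeping <- function(state) {
  types <- names(state$initial_counts)
  alive <- vapply(types, function(tt) {
    sum(vapply(state$agents, function(a) a$alive && a$entity_type == tt,
               logical(1)))
  }, integer(1))
  tibble::tibble(
    step = state$step, entity_type = types,
    initial = as.integer(state$initial_counts),
    births_cum = as.integer(state$births[types]),
    deaths_cum = as.integer(state$deaths[types]),
    alive = as.integer(alive)
  )
}

#' Run a simulation
#'
#' @inheritParams init_sim
#' @return a `dm_sim_run`: `series` (tibble: step, entity_type, state,
#'   compartment, count), `bookkeeping` (tibble: per step and type,
#'   initial, cumulative births/deaths, alive — satisfying
#'   initial + births = alive + deaths at every step), `fields` (tibble:
#'   step, molecule, compartment, level), `events` (list of event
#'   records) and the `final_state`
#' @export
run_sim <- function(model, config) {
  state <- init_sim(model, config)
  series <- list(sim_census(model, state))
  book <- list(sim_bookkeeping(state))
  fields <- list(fields_tibble(state))
  for (k in seq_len(config$n_steps)) {
    state <- step_sim(model, state)
    series[[k + 1L]] <- sim_census(model, state)
    book[[k + 1L]] <- sim_bookkeeping(state)
    fields[[k + 1L]] <- fields_tibble(state)
  }
  structure(
    list(series = dplyr::bind_rows(series),
         bookkeeping = dplyr::bind_rows(book),
         fields = dplyr::bind_rows(fields),
         events = state$events,
         config = config, final_state = state),
    class = "dm_sim_run"
  )
}

fields_tibble <- function(state) {
  f <- state$fields
  if (length(f) == 0L) {
    return(tibble::tibble(step = integer(), molecule = character(),
                          compartment = character(), level = numeric()))
  }
  tibble::tibble(
    step = state$step,
    molecule = rep(rownames(f), times = ncol(f)),
    compartment = rep(colnames(f), each = nrow(f)),
    level = as.numeric(f)
  )
}

#' @export
print.dm_sim_run <- function(x, ...) {
  cat("<simulation run>", max(x$bookkeeping$step), "steps;",
      sum(x$bookkeeping$alive[x$bookkeeping$step ==
                                max(x$bookkeeping$step)]),
      "agents alive at the end\n")
  invisible(x)
}

#' Per-type population totals of a run
#'
#' @param run a `dm_sim_run`
#' @return tibble with columns `step`, `entity_type`, `total`
#' @export
sim_totals <- function(run) {
  dplyr::select(run$bookkeeping, "step", "entity_type", total = "alive")
}
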