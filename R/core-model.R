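#' Three-level domain models
#'
#' A domain model captures a cellular system at three levels: a
#' *research context* linking observed phenomena to the emergent
#' behaviours and components expected to produce them; *perspectives*
#' (activity networks, see [perspective()]) decomposing each expected
#' behaviour into cellular interactions; and *single-entity* state
#' machines (see [state_machine()]). The model also carries its spatial
#' structure — named compartments and the migration rules allowing cells
#' to move between them — and a flat, named parameter table from which
#' every `δ` probability, `λ` duration and rate is resolved, keeping
#' unknown biological rates explicit and configurable.
#'
#' @name domain_models
NULL

#' Declare a spatial compartment
#'
#' @param name compartment identifier (unique within a model, non-empty)
#' @param description free-text description
#' @return a `dm_compartment`
#' @export
compartment <- function(name, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, description = description),
            class = "dm_compartment")
}

#' Declare a migration rule
#'
#' Permits agents of one entity type to move between two distinct
#' compartments, optionally restricted to agents whose active state labels
#' satisfy a guard over predicate atoms (the `δ`/`λ` forms are not
#' allowed here: a migration condition is a property of the agent's
#' current states, e.g. `"naive | partially_activated"`).
#'
#' @param entity_type declared entity type the rule applies to
#' @param from,to distinct declared compartment names
#' @param state_condition optional guard text over active-state labels
#' @return a `dm_migration_rule`
#' @export
migration_rule <- function(entity_type, from, to, state_condition = "") {
  if (identical(from, to)) {
    stop("migration rule for '", entity_type,
         "' must connect two distinct compartments (got '", from, "')")
  }
  g <- parse_guard(state_condition)
  atoms <- guard_atoms(g)
  if (length(atoms$delta_params) > 0L || length(atoms$lambda_params) > 0L) {
    stop("migration state_condition may only use predicate atoms over ",
         "active-state labels, not δ/λ")
  }
  structure(
    list(entity_type = entity_type, from = from, to = to, state_condition = g),
    class = "dm_migration_rule"
  )
}

#' Declare an entity type
#'
#' @param name entity-type identifier
#' @param category `"cell"` (simulated as discrete agents) or
#'   `"molecule"` (simulated as per-compartment scalar fields)
#' @param description free-text description
#' @return a `dm_entity`
#' @export
entity_type <- function(name, category = c("cell", "molecule"),
                        description = "") {
  category <- match.arg(category)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, category = category, description = description),
            class = "dm_entity")
}

#' Build the system-level research context
#'
#' The research context records the real-world phenomena motivating the
#' model (each in or out of the model's scope), the emergent behaviours
#' expected to produce the in-scope phenomena, the participating
#' components (entity types), and polarized links between them:
#' `"autoimmune"` for interactions driving the autoimmune response,
#' `"regulatory"` for interactions countering it, `"neutral"` otherwise.
#' An out-of-scope phenomenon is *declared but never linked*: it records
#' the existence of a phenomenon the model does not attempt to produce.
#'
#' @param phenomena data frame / tibble with columns `name`, `in_scope`
#' @param behaviours data frame with columns `name`, `emergent`
#' @param components character vector of entity-type names
#' @param links data frame with columns `source`, `target`, `polarity`
#'   (each polarity one of autoimmune/regulatory/neutral)
#' @return a `dm_research_context`
#' @export
research_context <- function(phenomena, behaviours, components, links) {
  phenomena <- tibble::as_tibble(phenomena)
  behaviours <- tibble::as_tibble(behaviours)
  links <- tibble::as_tibble(links)
  stopifnot(all(c("name", "in_scope") %in% names(phenomena)),
            all(c("name", "emergent") %in% names(behaviours)),
            all(c("source", "target", "polarity") %in% names(links)))
  bad_pol <- setdiff(unique(links$polarity),
                     c("autoimmune", "regulatory", "neutral"))
  if (length(bad_pol) > 0L) {
    stop("unknown link polarity: ", paste(bad_pol, collapse = ", "))
  }
  declared <- c(phenomena$name, behaviours$name, components)
  for (col in c("source", "target")) {
    dangling <- setdiff(links[[col]], declared)
    if (length(dangling) > 0L) {
      stop("research-context link ", col, " does not resolve: ",
           paste(dangling, collapse = ", "))
    }
  }
  out_of_scope <- phenomena$name[!phenomena$in_scope]
  linked_out <- intersect(links$target, out_of_scope)
  if (length(linked_out) > 0L) {
    stop("out-of-scope phenomenon has incoming links: ",
         paste(linked_out, collapse = ", "))
  }
  structure(
    list(phenomena = phenomena, behaviours = behaviours,
         components = as.character(components), links = links),
    class = "dm_research_context"
  )
}

#' Assemble a domain model
#'
#' Joins the three modelling levels with the spatial structure and the
#' parameter table, enforcing referential integrity: every cross-reference
#' (migration-rule compartments and entity types, state-machine owners,
#' perspective expansion tags, swim lanes and subjects, research-context
#' components, binding-declaration partners) must resolve to a declared
#' identifier. Identifier matching is case-sensitive and exact. Any
#' dangling reference raises an assembly error naming the missing
#' identifier.
#'
#' @param context a [research_context()]
#' @param compartments list of [compartment()]
#' @param migration_rules list of [migration_rule()]
#' @param entities list of [entity_type()]
#' @param machines named list of [state_machine()], keyed (and matched)
#'   by entity type
#' @param perspectives list of [perspective()]
#' @param parameters named numeric vector/list: the flat parameter table
#' @param location_region name of the statechart region, where present,
#'   that mirrors an entity's spatial compartment (default `"location"`)
#' @param binding_declarations named list declaring structural meaning of
#'   binding predicates: each element `list(partner_entity=, partner_state=)`
#' @return an immutable `dm_domain_model`
#' @export
assemble_domain_model <- function(context, compartments = list(),
                                  migration_rules = list(), entities = list(),
                                  machines = list(), perspectives = list(),
                                  parameters = list(),
                                  location_region = "location",
                                  binding_declarations = list(),
                                  interaction_rules = list()) {
  comp_names <- vapply(compartments, `[[`, character(1), "name")
  if (anyDuplicated(comp_names)) {
    stop("assembly error: duplicate compartment name(s): ",
         paste(unique(comp_names[duplicated(comp_names)]), collapse = ", "))
  }
  ent_names <- vapply(entities, `[[`, character(1), "name")
  if (anyDuplicated(ent_names)) {
    stop("assembly error: duplicate entity name(s): ",
         paste(unique(ent_names[duplicated(ent_names)]), collapse = ", "))
  }
  need <- function(x, pool, what) {
    missing <- setdiff(x, pool)
    if (length(missing) > 0L) {
      stop("assembly error: ", what, " references undeclared identifier(s): ",
           paste(missing, collapse = ", "))
    }
  }
  for (mr in migration_rules) {
    need(mr$entity_type, ent_names, "migration rule")
    need(c(mr$from, mr$to), comp_names, "migration rule")
  }
  if (length(machines) > 0L) {
    owners <- vapply(machines, `[[`, character(1), "entity_type")
    if (!identical(unname(owners), names(machines)) &&
        !setequal(owners, names(machines))) {
      stop("assembly error: machines list must be keyed by entity type")
    }
    need(owners, ent_names, "state machine")
    names(machines) <- owners
  }
  behaviour_names <- context$behaviours$name
  for (p in perspectives) {
    need(p$expands, behaviour_names, paste0("perspective '", p$name, "'"))
  }
  need(context$components, ent_names, "research context component")
  for (bn in names(binding_declarations)) {
    bd <- binding_declarations[[bn]]
    need(bd$partner_entity, ent_names,
         paste0("binding declaration '", bn, "'"))
  }
  if (length(parameters) > 0L &&
      (is.null(names(parameters)) || any(!nzchar(names(parameters))))) {
    stop("assembly error: parameters must all be named")
  }
  for (ir in interaction_rules) {
    need(c(ir$actor$entity_type, ir$partner$entity_type), ent_names,
         paste0("interaction rule '", ir$name, "'"))
  }
  if (length(interaction_rules) > 0L) {
    names(interaction_rules) <- vapply(interaction_rules, `[[`,
                                       character(1), "name")
  }
  structure(
    list(research_context = context,
         compartments = compartments,
         migration_rules = migration_rules,
         entities = entities,
         state_machines = machines,
         perspectives = perspectives,
         parameters = as.list(parameters),
         location_region = location_region,
         binding_declarations = binding_declarations,
         interaction_rules = interaction_rules),
    class = "dm_domain_model"
  )
}

#' @export
print.dm_domain_model <- function(x, ...) {
  cat("<domain model>\n")
  cat("  compartments:",
      paste(vapply(x$compartments, `[[`, character(1), "name"),
            collapse = ", "), "\n")
  cat("  entities:    ",
      paste(vapply(x$entities, `[[`, character(1), "name"), collapse = ", "),
      "\n")
  cat("  ", length(x$migration_rules), "migration rules;",
      length(x$state_machines), "state machines;",
      length(x$perspectives), "perspectives;",
      length(x$parameters), "parameters\n")
  invisible(x)
}

model_entity_names <- function(model) {
  vapply(model$entities, `[[`, character(1), "name")
}

model_compartment_names <- function(model) {
  vapply(model$compartments, `[[`, character(1), "name")
}

#' Is a migration allowed?
#'
#' `TRUE` iff some migration rule matches the entity type and compartment
#' pair and its state condition (if any) is satisfied by the agent's
#' active state labels. Remaining in place (`from == to`) is always
#' allowed without a rule. Adding rules can only enlarge the allowed set.
#'
#' @param model a `dm_domain_model`
#' @param entity declared entity type
#' @param from,to declared compartment names
#' @param state_labels character vector of the agent's active state labels
#' @return logical scalar
#' @export
migration_allowed <- function(model, entity, from, to,
                              state_labels = character()) {
  ents <- model_entity_names(model)
  comps <- model_compartment_names(model)
  if (!entity %in% ents) stop("lookup error: undeclared entity '", entity, "'")
  for (cc in c(from, to)) {
    if (!cc %in% comps) {
      stop("lookup error: undeclared compartment '", cc, "'")
    }
  }
  if (identical(from, to)) return(TRUE)
  for (mr in model$migration_rules) {
    if (mr$entity_type == entity && mr$from == from && mr$to == to) {
      atoms <- guard_atoms(mr$state_condition)
      env <- stats::setNames(as.list(atoms$predicates %in% state_labels),
                             atoms$predicates)
      if (evaluate_guard(mr$state_condition, env)) return(TRUE)
    }
  }
  FALSE
}

#' Compartments an agent may move to in one step
#'
#' @inheritParams migration_allowed
#' @return character vector of destination compartments (excluding `from`)
#' @export
migration_targets <- function(model, entity, from,
                              state_labels = character()) {
  comps <- setdiff(model_compartment_names(model), from)
  comps[vapply(comps, function(to) {
    migration_allowed(model, entity, from, to, state_labels)
  }, logical(1))]
}
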