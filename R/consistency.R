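#' Cross-diagram consistency checking
#'
#' The three modelling levels describe one biology from different angles,
#' and the diagrams cross-reference each other: a cell's location states
#' must name real compartments, its location transitions must be backed
#' by migration rules, and a receptor-binding transition can only be
#' meaningful in compartments where the binding partner can actually be
#' present in the required state. [check_model()] runs a fixed registry
#' of such rules and reports violations as data; [list_rules()] documents
#' the registry.
#'
#' @name consistency
NULL

RULE_REGISTRY <- tibble::tibble(
  rule_id = paste0("R", 1:7),
  description = c(
    "Every state in a machine's location region names a declared compartment",
    "Every transition between location states is backed by a migration rule whose state condition is jointly satisfiable with the transition guard",
    "Binding feasibility: a transition guarded by a declared binding predicate must be unsatisfiable in every compartment reachable by its owner where no machine for the partner entity permits the required partner state to be co-located",
    "Every expected behaviour of the research context is expanded by at least one perspective",
    "Every swim-lane annotation on an activity node names a declared compartment",
    "Every activity-node subject names a declared entity type",
    "Out-of-scope phenomena have no incoming research-context links"
  )
)

#' The consistency-rule registry
#'
#' @return tibble with columns `rule_id`, `description`, in stable order
#' @export
list_rules <- function() RULE_REGISTRY

machine_location_region <- function(machine, location_region) {
  for (r in machine$regions) {
    if (r$name == location_region) return(r)
  }
  NULL
}

# leaf (non-composite) state names of a machine region, expanding composites
region_leaves <- function(machine, region_name) {
  names(Filter(function(info) {
    info$region == region_name && info$node$kind != "composite"
  }, machine$index))
}

# leaf descendants of one state (itself if not composite)
state_leaves <- function(machine, state_name) {
  node <- machine$index[[state_name]]$node
  if (node$kind != "composite") return(state_name)
  unlist(lapply(node$substates, function(s) state_leaves(machine, s$name)))
}

# compartments (location leaves) reachable from the location initial,
# following location-region transitions with guards ignored (conservative)
reachable_compartments <- function(machine, location_region) {
  reg <- machine_location_region(machine, location_region)
  if (is.null(reg)) return(NULL)
  init_path <- descend_initial(machine, reg$initial)
  start <- init_path[length(init_path)]
  leaves <- region_leaves(machine, location_region)
  adj <- stats::setNames(vector("list", length(leaves)), leaves)
  for (tr in machine$transitions) {
    if (machine$index[[tr$source]]$region != location_region) next
    from_l <- state_leaves(machine, tr$source)
    to_l <- state_leaves(machine, tr$target)
    for (f in from_l) adj[[f]] <- union(adj[[f]], to_l)
  }
  seen <- start
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# is `guard` satisfiable when the machine sits in compartment `comp`?
# location-region state labels are pinned (active along comp's path,
# inactive elsewhere); all other atoms are free
guard_satisfiable_in <- function(machine, guard, comp, location_region) {
  loc_states <- names(Filter(function(info) info$region == location_region,
                             machine$index))
  if (length(loc_states) == 0L || !comp %in% names(machine$index)) {
    return(guard_satisfiable(guard))
  }
  path <- machine$index[[comp]]$path
  fixed <- stats::setNames(as.logical(loc_states %in% path), loc_states)
  guard_satisfiable(guard, fixed)
}

#' Check a domain model for cross-diagram consistency
#'
#' Runs the rule registry of [list_rules()] over an assembled model.
#' Violations are data, not errors; under `strict = TRUE` a non-empty
#' report raises instead, for pipelines that must not proceed on a
#' questionable model.
#'
#' @param model an assembled `dm_domain_model`
#' @param strict raise an error if any violation is found
#' @return a `dm_consistency_report`: tibble of violations (`rule_id`,
#'   `locus`, `message`), a per-rule pass/fail summary and a model
#'   fingerprint
#' @export
check_model <- function(model, strict = FALSE) {
  if (!inherits(model, "dm_domain_model")) {
    stop("check_model() expects an assembled dm_domain_model")
  }
  v <- list()
  violate <- function(rule_id, locus, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(rule_id = rule_id, locus = locus,
                                           message = message)
  }
  comps <- model_compartment_names(model)
  ents <- model_entity_names(model)
  locr <- model$location_region

  for (ent in names(model$state_machines)) {
    m <- model$state_machines[[ent]]
    reg <- machine_location_region(m, locr)
    if (is.null(reg)) next

    # R1: location states name compartments
    for (s in region_leaves(m, locr)) {
      if (!s %in% comps) {
        violate("R1", paste0(ent, "/", locr, "/", s),
                paste0("location state '", s,
                       "' is not a declared compartment"))
      }
    }

    # R2: location transitions backed by migration rules
    for (tr in m$transitions) {
      if (m$index[[tr$source]]$region != locr) next
      from_l <- intersect(state_leaves(m, tr$source), comps)
      to_l <- intersect(state_leaves(m, tr$target), comps)
      for (f in from_l) for (t in setdiff(to_l, f)) {
        backed <- FALSE
        for (mr in model$migration_rules) {
          if (mr$entity_type != ent || mr$from != f || mr$to != t) next
          joint <- new_guard("and", lhs = mr$state_condition, rhs = tr$guard)
          if (guard_satisfiable(joint)) {
            backed <- TRUE
            break
          }
        }
        if (!backed) {
          violate("R2", paste0(ent, "/", tr$source, "->", tr$target),
                  paste0("no migration rule backs ", ent, " moving ", f,
                         " -> ", t))
        }
      }
    }

    # R3: binding feasibility
    owner_comps <- reachable_compartments(m, locr)
    for (tr in m$transitions) {
      atoms <- guard_atoms(tr$guard)
      bpreds <- intersect(atoms$predicates, names(model$binding_declarations))
      for (bp in bpreds) {
        bd <- model$binding_declarations[[bp]]
        pm <- model$state_machines[[bd$partner_entity]]
        partner_comps <- comps
        if (!is.null(pm)) {
          if (!bd$partner_state %in% names(pm$index)) {
            violate("R3", paste0(ent, "/", tr$source, "->", tr$target),
                    paste0("binding partner state '", bd$partner_state,
                           "' not present in machine for ",
                           bd$partner_entity))
            next
          }
          pc <- reachable_compartments(pm, locr)
          if (!is.null(pc)) partner_comps <- intersect(pc, comps)
        }
        for (cc in intersect(owner_comps, comps)) {
          if (cc %in% partner_comps) next
          if (guard_satisfiable_in(m, tr$guard, cc, locr)) {
            violate("R3", paste0(ent, "/", tr$source, "->", tr$target),
                    paste0("binding '", bp, "' (", bd$partner_entity, " in ",
                           bd$partner_state, ") is satisfiable in ", cc,
                           " where the partner cannot be co-located"))
          }
        }
      }
    }
  }

  # R4: behaviours expanded by perspectives
  expanded <- unique(unlist(lapply(model$perspectives, `[[`, "expands")))
  for (b in model$research_context$behaviours$name) {
    if (!b %in% expanded) {
      violate("R4", paste0("behaviour/", b),
              paste0("expected behaviour '", b,
                     "' is not expanded by any perspective"))
    }
  }

  # R5/R6: swim lanes and subjects
  for (p in model$perspectives) {
    for (nd in p$nodes) {
      if (!is.null(nd$swim_lane) && !nd$swim_lane %in% comps) {
        violate("R5", paste0(p$name, "/", nd$name),
                paste0("swim lane '", nd$swim_lane,
                       "' is not a declared compartment"))
      }
      if (!is.null(nd$subject) && !nd$subject %in% ents) {
        violate("R6", paste0(p$name, "/", nd$name),
                paste0("subject '", nd$subject,
                       "' is not a declared entity type"))
      }
    }
  }

  # R7: out-of-scope phenomena unlinked
  rc <- model$research_context
  oos <- rc$phenomena$name[!rc$phenomena$in_scope]
  for (ph in intersect(rc$links$target, oos)) {
    violate("R7", paste0("phenomenon/", ph),
            paste0("out-of-scope phenomenon '", ph, "' has incoming links"))
  }

  violations <- if (length(v) > 0L) dplyr::bind_rows(v) else
    tibble::tibble(rule_id = character(), locus = character(),
                   message = character())
  summary <- dplyr::left_join(
    RULE_REGISTRY,
    dplyr::count(violations, .data$rule_id, name = "n_violations"),
    by = "rule_id"
  )
  summary$n_violations[is.na(summary$n_violations)] <- 0L
  summary$pass <- summary$n_violations == 0L
  report <- structure(
    list(violations = violations, summary = summary,
         fingerprint = rlang::hash(model)),
    class = "dm_consistency_report"
  )
  if (strict && nrow(violations) > 0L) {
    stop("model failed strict consistency check: ",
         paste(violations$rule_id, violations$locus, collapse = "; "))
  }
  report
}

#' @export
print.dm_consistency_report <- function(x, ...) {
  cat("<consistency report>", "fingerprint", substr(x$fingerprint, 1, 8), "\n")
  if (nrow(x$violations) == 0L) {
    cat("  all", nrow(x$summary), "rules pass\n")
  } else {
    for (i in seq_len(nrow(x$violations))) {
      cat("  ", x$violations$rule_id[i], x$violations$locus[i], "-",
          x$violations$message[i], "\n")
    }
  }
  invisible(x)
}

#' Render a consistency report as JSON
#'
#' @param report a `dm_consistency_report`
#' @return a JSON string (machine-readable counterpart of the printed form)
#' @export
report_json <- function(report) {
  jsonlite::toJSON(
    list(fingerprint = report$fingerprint,
         pass = nrow(report$violations) == 0L,
         summary = report$summary,
         violations = report$violations),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
  )
}
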