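#' Model documents, DOT rendering and the command line
#'
#' Domain models round-trip through a versioned JSON document (YAML is
#' accepted as an equivalent surface syntax). Loading always goes through
#' [assemble_domain_model()], so referential-integrity errors surface
#' identically whether a model is built in code or read from disk. A
#' structural validator reports problems as JSON-pointer paths before
#' assembly is attempted; the shipped `model-schema.json` documents the
#' expected shape. [render_dot()] emits deterministic Graphviz DOT for
#' any machine, perspective, the research context or the compartment
#' graph.
#'
#' @name model_io
NULL

DOCUMENT_VERSION <- 1L

state_to_doc <- function(s) {
  out <- list(name = s$name, kind = s$kind)
  if (s$kind == "composite") {
    out$initial <- s$initial
    out$substates <- lapply(s$substates, state_to_doc)
  }
  if (length(s$entry_actions)) out$entry_actions <- as.list(s$entry_actions)
  if (length(s$exit_actions)) out$exit_actions <- as.list(s$exit_actions)
  if (length(s$emissions)) out$emissions <- as.list(s$emissions)
  out
}

machine_to_doc <- function(m) {
  list(
    entity_type = m$entity_type,
    regions = lapply(m$regions, function(r) {
      list(name = r$name, initial = r$initial,
           states = lapply(r$states, state_to_doc))
    }),
    transitions = lapply(m$transitions, function(tr) {
      out <- list(source = tr$source, target = tr$target,
                  guard = format_guard(tr$guard))
      if (length(tr$actions)) out$actions <- as.list(tr$actions)
      out
    }),
    death_states = as.list(m$death_states)
  )
}

perspective_to_doc <- function(p) {
  node_doc <- function(nd) {
    out <- list(name = nd$name, kind = nd$kind)
    if (!is.null(nd$swim_lane)) out$swim_lane <- nd$swim_lane
    if (!is.null(nd$subject)) out$subject <- nd$subject
    out
  }
  list(
    name = p$name, expands = as.list(p$expands),
    nodes = lapply(p$nodes, node_doc),
    sequential = lapply(p$sequential, function(e) {
      out <- list(from = e$from, to = e$to)
      if (!is.null(e$dwell)) out$dwell <- e$dwell
      out
    }),
    propagating = lapply(p$propagating, function(e) {
      list(from = e$from, to = e$to, spawn_rate = e$spawn_rate)
    }),
    interrupts = lapply(p$interrupts, function(e) {
      list(source = e$source, target = e$target, degree = e$degree)
    }),
    contributory = lapply(p$contributory, function(e) {
      list(source = e$source, target = e$target,
           weight_shift = as.list(e$weight_shift))
    })
  )
}

#' Serialize a domain model to a document
#'
#' @param model a `dm_domain_model`
#' @return `model_to_document()`: a plain nested list;
#'   `save_model()`: JSON text
#' @export
model_to_document <- function(model) {
  rc <- model$research_context
  list(
    version = DOCUMENT_VERSION,
    compartments = lapply(model$compartments, function(x) {
      list(name = x$name, description = x$description)
    }),
    migration_rules = lapply(model$migration_rules, function(x) {
      list(entity_type = x$entity_type, from = x$from, to = x$to,
           state_condition = format_guard(x$state_condition))
    }),
    entities = lapply(model$entities, function(x) {
      list(name = x$name, category = x$category,
           description = x$description)
    }),
    state_machines = lapply(model$state_machines, machine_to_doc),
    perspectives = lapply(model$perspectives, perspective_to_doc),
    research_context = list(
      phenomena = lapply(seq_len(nrow(rc$phenomena)), function(i) {
        list(name = rc$phenomena$name[i],
             in_scope = rc$phenomena$in_scope[i])
      }),
      behaviours = lapply(seq_len(nrow(rc$behaviours)), function(i) {
        list(name = rc$behaviours$name[i],
             emergent = rc$behaviours$emergent[i])
      }),
      components = as.list(rc$components),
      links = lapply(seq_len(nrow(rc$links)), function(i) {
        list(source = rc$links$source[i], target = rc$links$target[i],
             polarity = rc$links$polarity[i])
      })
    ),
    parameters = model$parameters,
    location_region = model$location_region,
    binding_declarations = model$binding_declarations,
    interaction_rules = lapply(model$interaction_rules, function(x) {
      out <- list(name = x$name,
                  actor = list(entity_type = x$actor$entity_type,
                               states = as.list(x$actor$states)),
                  partner = list(entity_type = x$partner$entity_type,
                                 states = as.list(x$partner$states)),
                  effect = x$effect, rate = x$rate,
                  co_location = x$co_location)
      if (!is.null(x$predicate)) {
        out$predicate <- x$predicate
        out$on <- x$on
      }
      if (!is.null(x$spawn_entity)) out$spawn_entity <- x$spawn_entity
      out
    })
  )
}

#' @rdname model_to_document
#' @export
save_model <- function(model) {
  as.character(jsonlite::toJSON(model_to_document(model),
                                auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"))
}

#' Write a model document to disk
#'
#' Format follows the file extension: `.json` (default) or
#' `.yaml`/`.yml`.
#'
#' @param model a `dm_domain_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(model_to_document(model), path, precision = 15L)
  } else {
    writeLines(save_model(model), path)
  }
  invisible(path)
}

chk <- function(issues, cond, pointer, issue) {
  if (!cond) {
    issues[[length(issues) + 1L]] <- tibble::tibble(pointer = pointer,
                                                    issue = issue)
  }
  issues
}

is_str <- function(x) is.character(x) && length(x) == 1L || # from YAML
  (is.vector(x) && length(x) == 1L && is.character(x[[1L]]))

#' Structurally validate a model document
#'
#' Checks a parsed document (nested list) against the shape documented
#' in `inst/extdata/model-schema.json`: required sections, record fields
#' and guard syntax. Problems are reported as data with JSON-pointer
#' paths; an empty result means the document can be assembled.
#'
#' @param doc nested list, e.g. from `jsonlite::fromJSON(txt,
#'   simplifyVector = FALSE)`
#' @return tibble with columns `pointer`, `issue`
#' @export
validate_document <- function(doc) {
  issues <- list()
  need_section <- function(name, type = "array") {
    present <- !is.null(doc[[name]])
    issues <<- chk(issues, present, paste0("/", name),
                   paste0("required section '", name, "' is missing"))
    present
  }
  guard_ok <- function(text, pointer) {
    ok <- tryCatch({
      parse_guard(text)
      TRUE
    }, error = function(e) {
      issues <<- chk(issues, FALSE, pointer, conditionMessage(e))
      FALSE
    })
    ok
  }
  each <- function(section, f) {
    for (i in seq_along(doc[[section]])) {
      f(doc[[section]][[i]], paste0("/", section, "/", i - 1L))
    }
  }
  if (need_section("compartments")) {
    each("compartments", function(x, ptr) {
      issues <<- chk(issues, is_str(x$name), paste0(ptr, "/name"),
                     "compartment needs a string name")
    })
  }
  if (need_section("entities")) {
    each("entities", function(x, ptr) {
      issues <<- chk(issues, is_str(x$name), paste0(ptr, "/name"),
                     "entity needs a string name")
      issues <<- chk(issues,
                     is_str(x$category) &&
                       x$category %in% c("cell", "molecule"),
                     paste0(ptr, "/category"),
                     "entity category must be 'cell' or 'molecule'")
    })
  }
  if (need_section("migration_rules")) {
    each("migration_rules", function(x, ptr) {
      for (f in c("entity_type", "from", "to")) {
        issues <<- chk(issues, is_str(x[[f]]), paste0(ptr, "/", f),
                       paste0("migration rule needs a string '", f, "'"))
      }
      if (!is.null(x$state_condition)) {
        guard_ok(x$state_condition, paste0(ptr, "/state_condition"))
      }
    })
  }
  if (need_section("state_machines")) {
    for (nm in names(doc$state_machines)) {
      m <- doc$state_machines[[nm]]
      ptr <- paste0("/state_machines/", nm)
      issues <- chk(issues, !is.null(m$regions) && length(m$regions) > 0L,
                    paste0(ptr, "/regions"),
                    "state machine needs at least one region")
      for (i in seq_along(m$regions)) {
        r <- m$regions[[i]]
        rptr <- paste0(ptr, "/regions/", i - 1L)
        issues <- chk(issues, is_str(r$initial), paste0(rptr, "/initial"),
                      "region needs exactly one initial state")
        issues <- chk(issues, length(r$states) > 0L, paste0(rptr, "/states"),
                      "region needs states")
      }
      for (i in seq_along(m$transitions)) {
        tr <- m$transitions[[i]]
        tptr <- paste0(ptr, "/transitions/", i - 1L)
        for (f in c("source", "target")) {
          issues <- chk(issues, is_str(tr[[f]]), paste0(tptr, "/", f),
                        paste0("transition needs a string '", f, "'"))
        }
        if (!is.null(tr$guard)) guard_ok(tr$guard, paste0(tptr, "/guard"))
      }
    }
  }
  if (need_section("perspectives")) {
    each("perspectives", function(p, ptr) {
      issues <<- chk(issues, is_str(p$name), paste0(ptr, "/name"),
                     "perspective needs a string name")
      issues <<- chk(issues, length(p$expands) > 0L, paste0(ptr, "/expands"),
                     "perspective must expand an expected behaviour")
      kinds <- vapply(p$nodes, function(nd) nd$kind %||% "", character(1))
      issues <<- chk(issues, any(kinds == "start"), paste0(ptr, "/nodes"),
                     "perspective needs at least one start node")
    })
  }
  if (need_section("research_context", "object")) {
    rc <- doc$research_context
    for (f in c("phenomena", "behaviours", "components", "links")) {
      issues <- chk(issues, !is.null(rc[[f]]),
                    paste0("/research_context/", f),
                    paste0("research context needs '", f, "'"))
    }
  }
  if (need_section("parameters", "object")) {
    ok <- all(vapply(doc$parameters, function(v) {
      is.numeric(v) || (is.vector(v) && is.numeric(v[[1L]]))
    }, logical(1)))
    issues <- chk(issues, ok, "/parameters", "parameters must be numeric")
  }
  if (length(issues) == 0L) {
    tibble::tibble(pointer = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

doc_state <- function(s) {
  state_node(
    name = s$name, kind = s$kind %||% "atomic",
    substates = lapply(s$substates %||% list(), doc_state),
    initial = s$initial,
    entry_actions = as.character(unlist(s$entry_actions)),
    exit_actions = as.character(unlist(s$exit_actions)),
    emissions = as.character(unlist(s$emissions))
  )
}

doc_machine <- function(m) {
  state_machine(
    entity_type = m$entity_type,
    regions = lapply(m$regions, function(r) {
      region(r$name, lapply(r$states, doc_state), r$initial)
    }),
    transitions = lapply(m$transitions %||% list(), function(tr) {
      transition(tr$source, tr$target, tr$guard %||% "",
                 actions = as.character(unlist(tr$actions)))
    }),
    death_states = as.character(unlist(m$death_states))
  )
}

doc_perspective <- function(p) {
  perspective(
    name = p$name, expands = as.character(unlist(p$expands)),
    nodes = lapply(p$nodes, function(nd) {
      activity_node(nd$name, nd$kind %||% "action",
                    swim_lane = nd$swim_lane, subject = nd$subject)
    }),
    sequential = lapply(p$sequential %||% list(), function(e) {
      sequential_edge(e$from, e$to, dwell = e$dwell)
    }),
    propagating = lapply(p$propagating %||% list(), function(e) {
      propagating_edge(e$from, e$to, spawn_rate = e$spawn_rate)
    }),
    interrupts = lapply(p$interrupts %||% list(), function(e) {
      interrupt_edge(e$source, e$target, degree = e$degree)
    }),
    contributory = lapply(p$contributory %||% list(), function(e) {
      contributory_edge(e$source, e$target,
                        unlist(e$weight_shift))
    })
  )
}

#' Assemble a domain model from a parsed document
#'
#' @param doc nested list (see [validate_document()])
#' @return a `dm_domain_model`
#' @export
document_to_model <- function(doc) {
  rc <- doc$research_context
  context <- research_context(
    phenomena = tibble::tibble(
      name = vapply(rc$phenomena, function(x) x$name, character(1)),
      in_scope = vapply(rc$phenomena, function(x) isTRUE(x$in_scope),
                        logical(1))
    ),
    behaviours = tibble::tibble(
      name = vapply(rc$behaviours, function(x) x$name, character(1)),
      emergent = vapply(rc$behaviours, function(x) isTRUE(x$emergent),
                        logical(1))
    ),
    components = as.character(unlist(rc$components)),
    links = tibble::tibble(
      source = vapply(rc$links, function(x) x$source, character(1)),
      target = vapply(rc$links, function(x) x$target, character(1)),
      polarity = vapply(rc$links, function(x) x$polarity, character(1))
    )
  )
  assemble_domain_model(
    context = context,
    compartments = lapply(doc$compartments, function(x) {
      compartment(x$name, x$description %||% "")
    }),
    migration_rules = lapply(doc$migration_rules, function(x) {
      migration_rule(x$entity_type, x$from, x$to, x$state_condition %||% "")
    }),
    entities = lapply(doc$entities, function(x) {
      entity_type(x$name, x$category, x$description %||% "")
    }),
    machines = lapply(doc$state_machines, doc_machine),
    perspectives = lapply(doc$perspectives, doc_perspective),
    parameters = lapply(doc$parameters, function(v) as.numeric(v[[1L]])),
    location_region = doc$location_region %||% "location",
    binding_declarations = doc$binding_declarations %||% list(),
    interaction_rules = lapply(doc$interaction_rules %||% list(),
                               function(x) {
      interaction_rule(
        name = x$name,
        actor = list(entity_type = x$actor$entity_type,
                     states = as.character(unlist(x$actor$states))),
        partner = list(entity_type = x$partner$entity_type,
                       states = as.character(unlist(x$partner$states))),
        effect = x$effect, predicate = x$predicate,
        on = x$on %||% "partner", spawn_entity = x$spawn_entity,
        rate = x$rate, co_location = x$co_location %||% TRUE
      )
    })
  )
}

#' Load a domain model
#'
#' `text` may be JSON text, YAML text, or a path to a `.json`/`.yaml`
#' file. The document is parsed, structurally validated (schema
#' violations are reported with their JSON-pointer path) and assembled.
#'
#' @param text document text or file path
#' @return a `dm_domain_model`
#' @export
load_model <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (file.exists(text) && !grepl("\n", text)) {
    raw <- paste(readLines(text, warn = FALSE), collapse = "\n")
    as_yaml <- grepl("\\.ya?ml$", text)
  } else {
    raw <- text
    as_yaml <- !grepl("^\\s*\\{", text)
  }
  doc <- if (as_yaml) {
    yaml::yaml.load(raw)
  } else {
    jsonlite::fromJSON(raw, simplifyVector = FALSE)
  }
  issues <- validate_document(doc)
  if (nrow(issues) > 0L) {
    stop("model document schema violation at ", issues$pointer[1L], ": ",
         issues$issue[1L], call. = FALSE)
  }
  document_to_model(doc)
}

dot_q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

dot_machine <- function(model, name) {
  m <- model$state_machines[[name]]
  if (is.null(m)) stop("unknown selector: no machine for '", name, "'")
  lines <- c(sprintf("digraph %s {", dot_q(paste0("machine_", name))),
             "  compound=true;", "  rankdir=LR;",
             "  node [shape=box, style=rounded];")
  emit_state <- function(s, indent) {
    pad <- strrep(" ", indent)
    if (s$kind == "composite") {
      out <- c(sprintf("%ssubgraph %s {", pad,
                       dot_q(paste0("cluster_", s$name))),
               sprintf("%s  label=%s;", pad, dot_q(s$name)))
      for (sub in s$substates) out <- c(out, emit_state(sub, indent + 2L))
      c(out, sprintf("%s}", pad))
    } else if (s$kind == "isolated") {
      sprintf("%s%s [style=\"rounded,dashed\"];", pad, dot_q(s$name))
    } else {
      sprintf("%s%s;", pad, dot_q(s$name))
    }
  }
  for (r in m$regions) {
    lines <- c(lines,
               sprintf("  subgraph %s {", dot_q(paste0("cluster_region_",
                                                       r$name))),
               sprintf("    label=%s; style=dashed;", dot_q(r$name)),
               sprintf("    %s [shape=point, width=0.12];",
                       dot_q(paste0("init_", r$name))))
    for (s in r$states) lines <- c(lines, emit_state(s, 4L))
    lines <- c(lines, sprintf("    %s -> %s;",
                              dot_q(paste0("init_", r$name)),
                              dot_q(r$initial)),
               "  }")
  }
  for (tr in m$transitions) {
    lbl <- format_guard(tr$guard)
    lines <- c(lines, sprintf("  %s -> %s%s;", dot_q(tr$source),
                              dot_q(tr$target),
                              if (nzchar(lbl)) {
                                sprintf(" [label=%s]", dot_q(lbl))
                              } else ""))
  }
  c(lines, "}")
}

dot_perspective <- function(model, name) {
  p <- NULL
  for (pp in model$perspectives) if (pp$name == name) p <- pp
  if (is.null(p)) stop("unknown selector: no perspective '", name, "'")
  shape_for <- c(start = "circle", end = "doublecircle",
                 decision = "diamond", merge = "diamond", fork = "box",
                 join = "box", action = "box")
  interrupted <- vapply(p$interrupts, `[[`, character(1), "target")
  lines <- c(sprintf("digraph %s {", dot_q(paste0("perspective_", name))),
             "  // legend: dashed+vee = propagating (spawns tokens),",
             "  // tee into point anchor = interrupting, odot = contributory",
             "  node [shape=box];")
  lanes <- unique(stats::na.omit(vapply(p$nodes, function(nd) {
    nd$swim_lane %||% NA_character_
  }, character(1))))
  node_line <- function(nd) {
    sprintf("%s [shape=%s];", dot_q(nd$name),
            shape_for[[nd$kind]])
  }
  for (lane in lanes) {
    lines <- c(lines, sprintf("  subgraph %s {",
                              dot_q(paste0("cluster_lane_", lane))),
               sprintf("    label=%s; style=dotted;", dot_q(lane)))
    for (nd in p$nodes) {
      if (identical(nd$swim_lane, lane)) {
        lines <- c(lines, paste0("    ", node_line(nd)))
      }
    }
    lines <- c(lines, "  }")
  }
  for (nd in p$nodes) {
    if (is.null(nd$swim_lane)) lines <- c(lines, paste0("  ", node_line(nd)))
  }
  for (e in p$sequential) {
    id <- edge_id(e$from, e$to)
    if (id %in% interrupted) {
      anchor <- paste0("anchor_", id)
      lines <- c(lines,
                 sprintf("  %s [shape=point, width=0.08];", dot_q(anchor)),
                 sprintf("  %s -> %s [dir=none];", dot_q(e$from),
                         dot_q(anchor)),
                 sprintf("  %s -> %s;", dot_q(anchor), dot_q(e$to)))
    } else {
      lines <- c(lines, sprintf("  %s -> %s;", dot_q(e$from), dot_q(e$to)))
    }
  }
  for (e in p$propagating) {
    lines <- c(lines,
               sprintf("  %s -> %s [style=dashed, arrowhead=vee, label=%s];",
                       dot_q(e$from), dot_q(e$to), dot_q(e$spawn_rate)))
  }
  for (e in p$interrupts) {
    lines <- c(lines,
               sprintf("  %s -> %s [arrowhead=tee, color=red, label=%s];",
                       dot_q(e$source), dot_q(paste0("anchor_", e$target)),
                       dot_q(e$degree)))
  }
  for (e in p$contributory) {
    lines <- c(lines,
               sprintf("  %s -> %s [arrowhead=odot, color=blue];",
                       dot_q(e$source), dot_q(e$target)))
  }
  c(lines, "}")
}

dot_context <- function(model) {
  rc <- model$research_context
  style_for <- c(autoimmune = "[color=red]",
                 regulatory = "[color=blue, style=dashed]",
                 neutral = "[color=grey]")
  lines <- c("digraph research_context {",
             "  // legend: red = autoimmune drive, dashed blue = regulatory,",
             "  // grey = neutral; unlinked phenomena are out of scope",
             "  rankdir=BT;")
  for (i in seq_len(nrow(rc$phenomena))) {
    lines <- c(lines, sprintf("  %s [shape=box, style=%s];",
                              dot_q(rc$phenomena$name[i]),
                              if (rc$phenomena$in_scope[i]) "solid"
                              else "dashed"))
  }
  for (b in rc$behaviours$name) {
    lines <- c(lines, sprintf("  %s [shape=octagon];", dot_q(b)))
  }
  for (cc in rc$components) {
    lines <- c(lines, sprintf("  %s [shape=ellipse];", dot_q(cc)))
  }
  for (i in seq_len(nrow(rc$links))) {
    lines <- c(lines, sprintf("  %s -> %s %s;", dot_q(rc$links$source[i]),
                              dot_q(rc$links$target[i]),
                              style_for[[rc$links$polarity[i]]]))
  }
  c(lines, "}")
}

dot_compartments <- function(model) {
  lines <- c("digraph compartments {", "  node [shape=box3d];")
  for (cc in model$compartments) {
    lines <- c(lines, sprintf("  %s;", dot_q(cc$name)))
  }
  for (mr in model$migration_rules) {
    cond <- format_guard(mr$state_condition)
    lbl <- paste0(mr$entity_type, if (nzchar(cond)) paste0(" [", cond, "]"))
    lines <- c(lines, sprintf("  %s -> %s [label=%s];", dot_q(mr$from),
                              dot_q(mr$to), dot_q(lbl)))
  }
  c(lines, "}")
}

#' Render a model element as Graphviz DOT
#'
#' @param model a `dm_domain_model`
#' @param selector `"machine:<entity>"`, `"perspective:<name>"`,
#'   `"context"` or `"compartments"`
#' @return DOT source as a single string (byte-stable for a fixed model)
#' @export
render_dot <- function(model, selector) {
  lines <- if (selector == "context") {
    dot_context(model)
  } else if (selector == "compartments") {
    dot_compartments(model)
  } else if (startsWith(selector, "machine:")) {
    dot_machine(model, sub("^machine:", "", selector))
  } else if (startsWith(selector, "perspective:")) {
    dot_perspective(model, sub("^perspective:", "", selector))
  } else {
    stop("unknown selector '", selector, "'")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

all_selectors <- function(model) {
  c("context", "compartments",
    paste0("machine:", names(model$state_machines)),
    vapply(model$perspectives, function(p) paste0("perspective:", p$name),
           character(1)))
}
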