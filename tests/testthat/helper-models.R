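# Shared fixture builders. Everything is constructed in code; the only
# on-disk artifact is the packaged EAE model document.

# -- tiny machines -----------------------------------------------------

# one region, two states, guard text on the single transition
two_state_machine <- function(guard = "", entity = "X",
                              a = "immature", b = "mature") {
  state_machine(entity, regions = list(
    region("main", list(state_node(a), state_node(b)), initial = a)
  ), transitions = list(transition(a, b, guard)))
}

# maturation + isolated capability region, mirroring a dendritic cell
dc_like_machine <- function() {
  state_machine("DC", regions = list(
    region("maturation",
           list(state_node("immature"), state_node("mature")),
           initial = "immature"),
    region("capability",
           list(state_node("MHCII_capable", kind = "isolated")),
           initial = "MHCII_capable")
  ), transitions = list(
    transition("immature", "mature", "δ(p_maturation) & stimulus")
  ))
}

# region whose initial is a composite with its own initial substate
composite_machine <- function() {
  state_machine("C", regions = list(
    region("loc", list(
      state_node("Outside"),
      state_node("Inside", "composite", initial = "A",
                 substates = list(state_node("A"), state_node("B")))
    ), initial = "Inside")
  ), transitions = list(
    transition("A", "B", "go"),
    transition("Inside", "Outside", "leave"),
    transition("Outside", "Inside", "enter")
  ))
}

# -- randomized machines for property tests ----------------------------

# random flat multi-region machine; guards draw from predicates p1..p3,
# delta/lambda over a fixed parameter table
random_machine <- function(n_regions = 2L, n_states = 3L,
                           delta_zero = FALSE) {
  mk_guard <- function() {
    pool <- c("p1", "p2", "p3",
              if (delta_zero) "δ(d0)" else "δ(d5)", "λ(t2)")
    n <- sample(1:2, 1L)
    paste(sample(pool, n), collapse = sample(c(" & ", " | "), 1L))
  }
  regions <- lapply(seq_len(n_regions), function(r) {
    states <- paste0("r", r, "s", seq_len(n_states))
    region(paste0("R", r), lapply(states, state_node), initial = states[1L])
  })
  transitions <- list()
  for (r in seq_len(n_regions)) {
    states <- paste0("r", r, "s", seq_len(n_states))
    for (k in seq_len(n_states)) {
      tgt <- sample(setdiff(states, states[k]), 1L)
      transitions[[length(transitions) + 1L]] <-
        transition(states[k], tgt, mk_guard())
    }
  }
  state_machine("rand", regions = regions, transitions = transitions)
}

random_env <- function() {
  stats::setNames(as.list(sample(c(TRUE, FALSE), 3, replace = TRUE)),
                  c("p1", "p2", "p3"))
}

machine_params <- list(d0 = 0, d5 = 0.5, t2 = 2)

# -- tiny perspectives -------------------------------------------------

chain_perspective <- function() {
  perspective("chain", "b",
    nodes = list(activity_node("s", "start"), activity_node("A"),
                 activity_node("B"), activity_node("e", "end")),
    sequential = list(sequential_edge("s", "A"), sequential_edge("A", "B"),
                      sequential_edge("B", "e")))
}

cycle_perspective <- function() {
  perspective("cycle", "b",
    nodes = list(activity_node("s", "start"), activity_node("A"),
                 activity_node("B")),
    sequential = list(sequential_edge("s", "A"), sequential_edge("A", "B"),
                      sequential_edge("B", "A")))
}

decision_perspective <- function(shift = c(X = 1)) {
  perspective("dec", "b",
    nodes = list(activity_node("s", "start"),
                 activity_node("D", "decision"),
                 activity_node("X"), activity_node("Y"),
                 activity_node("C", "start")),
    sequential = list(sequential_edge("s", "D"), sequential_edge("D", "X"),
                      sequential_edge("D", "Y"), sequential_edge("X", "D"),
                      sequential_edge("Y", "D")),
    contributory = list(contributory_edge("C", "D", shift)))
}

interrupted_perspective <- function() {
  perspective("int", "b",
    nodes = list(activity_node("s", "start"), activity_node("A"),
                 activity_node("I", "start")),
    sequential = list(sequential_edge("s", "A")),
    interrupts = list(interrupt_edge("I", "s->A", "deg")))
}

# same network without the interrupter (for the degree-0 contrast)
uninterrupted_perspective <- function() {
  perspective("noint", "b",
    nodes = list(activity_node("s", "start"), activity_node("A"),
                 activity_node("I", "start")),
    sequential = list(sequential_edge("s", "A")))
}

# -- tiny assemblable models -------------------------------------------

minimal_context <- function() {
  research_context(
    phenomena = tibble::tibble(name = "ph", in_scope = TRUE),
    behaviours = tibble::tibble(name = "b", emergent = TRUE),
    components = character(),
    links = tibble::tibble(source = character(), target = character(),
                           polarity = character())
  )
}

# random small-but-complete model for fuzzed round trips
random_model <- function() {
  n_comp <- sample(2:4, 1L)
  comps <- paste0("Comp", seq_len(n_comp))
  n_ent <- sample(1:3, 1L)
  ents <- paste0("Ent", seq_len(n_ent))
  machines <- lapply(ents, function(e) {
    state_machine(e, regions = list(
      region("main", list(state_node("s1"),
                          state_node("s2", emissions = "secrete_M")),
             initial = "s1"),
      region("location", lapply(comps, state_node), initial = comps[1L])
    ), transitions = c(
      list(transition("s1", "s2", sample(c("", "δ(p) | λ(t)", "go & δ(p)"),
                                         1L))),
      lapply(comps[-1L], function(cc) transition(comps[1L], cc, ""))
    ))
  })
  names(machines) <- ents
  rules <- unlist(lapply(ents, function(e) {
    lapply(comps[-1L], function(cc) {
      migration_rule(e, comps[1L], cc,
                     sample(c("", "s1", "s1 | s2"), 1L))
    })
  }), recursive = FALSE)
  persp <- perspective("p1", "b",
    nodes = list(activity_node("go", "start", swim_lane = comps[1L],
                               subject = ents[1L]),
                 activity_node("act")),
    sequential = list(sequential_edge("go", "act")),
    propagating = list(propagating_edge("go", "act", "r")))
  assemble_domain_model(
    context = minimal_context(),
    compartments = lapply(comps, compartment),
    migration_rules = rules,
    entities = lapply(ents, entity_type),
    machines = machines,
    perspectives = list(persp),
    parameters = list(p = stats::runif(1), t = sample(0:5, 1L),
                      r = stats::runif(1))
  )
}

# -- EAE fixture mutations (one per consistency rule) ------------------

# poke an assembled model's internals to create exactly one defect
mutate_eae <- function(rule) {
  m <- build_eae_model()
  switch(rule,
    R1 = {
      # rename a location state to an undeclared compartment
      reg_idx <- which(vapply(m$state_machines$CNSMacrophage$regions,
                              function(r) r$name == "location", logical(1)))
      mm <- eae_machine_macrophage()
      mm$regions[[reg_idx]] <- region("location",
                                      list(state_node("Thymus")),
                                      initial = "Thymus")
      mm$transitions <- mm$transitions  # unchanged
      m$state_machines$CNSMacrophage <- state_machine(
        "CNSMacrophage", mm$regions, mm$transitions)
      m
    },
    R2 = {
      # drop the migration rules backing CD8Treg CNS -> Circulation
      keep <- vapply(m$migration_rules, function(mr) {
        !(mr$entity_type == "CD8Treg" && mr$from == "CNS" &&
            mr$to == "Circulation")
      }, logical(1))
      m$migration_rules <- m$migration_rules[keep]
      m
    },
    R3 = {
      # make the receptor-binding priming transition satisfiable outside
      # the lymphoid organs (drop the location restriction)
      mach <- m$state_machines$CD8Treg
      mach$transitions[[1L]] <- transition(
        "naive", "partially_activated",
        "δ(p_cd8_priming) & Qa1_CDR1_2_binding")
      m$state_machines$CD8Treg <- state_machine(
        "CD8Treg", mach$regions, mach$transitions)
      m
    },
    R4 = {
      # orphan the behaviour expanded only by the inception perspective
      idx <- which(vapply(m$perspectives, function(p) {
        p$name == "autoimmune-inception"
      }, logical(1)))
      m$perspectives[[idx]]$expands <-
        "regulation targets encephalitogenic immune cells"
      m
    },
    R5 = {
      m$perspectives[[1L]]$nodes[[2L]]$swim_lane <- "Thymus"
      m
    },
    R6 = {
      m$perspectives[[1L]]$nodes[[2L]]$subject <- "NKCell"
      m
    },
    R7 = {
      # wire a link into the declared out-of-scope phenomenon
      rc <- m$research_context
      rc$links <- dplyr::bind_rows(rc$links, tibble::tibble(
        source = "regulation targets encephalitogenic immune cells",
        target = "protection against subsequent attempts to induce autoimmunity",
        polarity = "regulatory"))
      m$research_context <- rc
      m
    },
    stop("unknown rule ", rule)
  )
}

# locus substring expected for each seeded defect
mutation_locus <- c(
  R1 = "CNSMacrophage/location/Thymus",
  R2 = "CD8Treg/CNS->Circulation",
  R3 = "CD8Treg/naive->partially_activated",
  R4 = "behaviour/immune system harms neurons",
  R5 = "regulation/",
  R6 = "regulation/",
  R7 = "phenomenon/protection"
)

# -- DOT sanity checker ------------------------------------------------

# minimal structural check: balanced braces outside quoted strings and a
# digraph header
expect_valid_dot <- function(dot) {
  expect_match(dot, "^digraph ")
  chars <- strsplit(dot, "")[[1L]]
  depth <- 0L
  in_quote <- FALSE
  escaped <- FALSE
  for (ch in chars) {
    if (escaped) {
      escaped <- FALSE
    } else if (ch == "\\") {
      escaped <- TRUE
    } else if (ch == "\"") {
      in_quote <- !in_quote
    } else if (!in_quote && ch == "{") {
      depth <- depth + 1L
    } else if (!in_quote && ch == "}") {
      depth <- depth - 1L
      expect_gte(depth, 0L)
    }
  }
  expect_identical(depth, 0L)
  expect_false(in_quote)
}
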