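# The packaged EAE domain model

test_that("the fixture has the expected compartments and entity inventory", {
  m <- build_eae_model()
  expect_setequal(
    vapply(m$compartments, `[[`, character(1), "name"),
    c("Circulation", "CLN", "Spleen", "SLO", "CNS"))
  ents <- vapply(m$entities, `[[`, character(1), "name")
  expect_gte(length(ents), 7L)
  cats <- vapply(m$entities, `[[`, character(1), "category")
  expect_setequal(ents[cats == "molecule"],
                  c("Type1Cytokine", "Type2Cytokine"))
  expect_true(all(c("DC", "CD4Th1", "CD4Th2", "CD4Treg", "CD8Treg",
                    "CNSMacrophage", "Neuron") %in% ents))
  # every entity has a machine; every machine owner is declared
  expect_setequal(names(m$state_machines), ents)
})

test_that("effector CD8Treg cells are barred from every lymphoid compartment", {
  m <- build_eae_model()
  for (org in c("CLN", "Spleen", "SLO")) {
    expect_false(migration_allowed(m, "CD8Treg", "Circulation", org,
                                   "effector"), info = org)
    expect_true(migration_allowed(m, "CD8Treg", "Circulation", org,
                                  "naive"), info = org)
    expect_true(migration_allowed(m, "CD8Treg", "Circulation", org,
                                  "partially_activated"), info = org)
  }
  # effectors still patrol blood and CNS
  expect_true(migration_allowed(m, "CD8Treg", "Circulation", "CNS",
                                "effector"))
})

test_that("the out-of-scope protection phenomenon is declared but unlinked", {
  m <- build_eae_model()
  rc <- m$research_context
  prot <- "protection against subsequent attempts to induce autoimmunity"
  expect_true(prot %in% rc$phenomena$name)
  expect_false(rc$phenomena$in_scope[rc$phenomena$name == prot])
  expect_false(prot %in% rc$links$target)
})

test_that("the CD8Treg machine activates one maturation and one location state, with the lymphoid composite decomposed", {
  m <- build_eae_model()
  cfg <- initial_config(m$state_machines$CD8Treg)
  expect_identical(cfg$regions$maturation$leaf, "naive")
  expect_identical(cfg$regions$location$leaf, "Circulation")
  # the lymphoid organs are substates of one composite
  idx <- m$state_machines$CD8Treg$index
  for (org in c("SLO", "CLN", "Spleen")) {
    expect_identical(idx[[org]]$path, c("Lymphoid", org))
  }
})

test_that("perspectives validate cleanly and expand declared behaviours", {
  m <- build_eae_model()
  for (p in m$perspectives) {
    expect_identical(nrow(validate_perspective(p)), 0L, info = p$name)
    expect_true(all(p$expands %in% m$research_context$behaviours$name))
  }
  # the regulation perspective is cyclic with no end node
  reg <- m$perspectives[[1L]]
  kinds <- vapply(reg$nodes, `[[`, character(1), "kind")
  expect_false(any(kinds == "end"))
})

test_that("the fixture passes strict consistency", {
  expect_no_error(check_model(build_eae_model(), strict = TRUE))
})

test_that("provenance covers every state, transition, rule and edge exactly once", {
  m <- build_eae_model()
  prov <- provenance_table(m)
  expect_identical(anyDuplicated(prov$element), 0L)
  expect_true(all(prov$status %in% c("quoted", "figure-described",
                                     "inferred")))
  n_transitions <- sum(vapply(m$state_machines, function(mm) {
    length(mm$transitions)
  }, integer(1)))
  expect_identical(sum(prov$kind == "transition"), n_transitions)
  n_states <- sum(vapply(m$state_machines, function(mm) {
    length(mm$index)
  }, integer(1)))
  expect_identical(sum(prov$kind == "state"), n_states)
  expect_identical(sum(prov$kind == "migration_rule"),
                   length(m$migration_rules))
  expect_identical(sum(prov$kind == "interaction_rule"),
                   length(m$interaction_rules))
  # quoted effector exclusion and inferred type-2 cytokine entries
  expect_identical(
    unique(prov$status[grepl("^CD8Treg:Circulation->(CLN|SLO|Spleen)$",
                             prov$element)]),
    "quoted")
  expect_identical(prov$status[prov$element == "Type2Cytokine" &
                                 prov$kind == "entity"], "inferred")
  expect_error(provenance_table(random_model()), "unsupported|fixture")
})

test_that("the count of inferred elements is frozen (no silent growth)", {
  prov <- provenance_table(build_eae_model())
  counts <- table(prov$status)
  expect_identical(as.integer(counts[["inferred"]]), 152L)
  expect_identical(as.integer(counts[["quoted"]]), 42L)
  expect_identical(as.integer(counts[["figure-described"]]), 57L)
})

test_that("the fixture round-trips unchanged through the document format", {
  m <- build_eae_model()
  expect_equal(load_model(save_model(m)), m, tolerance = 1e-12)
})

test_that("the shipped model document equals the programmatic fixture", {
  path <- system.file("extdata", "eae_model.json", package = "domainsim")
  expect_true(nzchar(path))
  expect_equal(load_model(path), build_eae_model(), tolerance = 1e-12)
})
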