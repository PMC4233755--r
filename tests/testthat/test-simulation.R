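# Multi-agent simulation engine

eae_small_config <- function(n_steps = 10L, seed = 1L, ...) {
  sim_config(
    initial_populations = tibble::tribble(
      ~entity_type, ~compartment, ~n,
      "DC", "SLO", 3,
      "CD4Th1", "SLO", 6,
      "CD4Treg", "SLO", 3,
      "CD8Treg", "SLO", 3,
      "CNSMacrophage", "CNS", 2,
      "Neuron", "CNS", 4
    ),
    n_steps = n_steps, seed = seed,
    ambient_predicates = "antigen_stimulus", ...
  )
}

test_that("initialization creates agents in initial states with synced locations", {
  m <- build_eae_model()
  st <- init_sim(m, eae_small_config())
  expect_identical(length(st$agents), 21L)
  dcs <- Filter(function(a) a$entity_type == "DC", st$agents)
  expect_identical(length(dcs), 3L)
  for (a in dcs) {
    expect_identical(a$config$regions$maturation$leaf, "immature")
    expect_identical(a$config$regions$location$leaf, "SLO")
    expect_true(a$alive)
  }
  # empty populations are a valid (empty) simulation
  empty <- sim_config(tibble::tibble(entity_type = character(),
                                     compartment = character(),
                                     n = numeric()), n_steps = 3L)
  st0 <- init_sim(m, empty)
  expect_identical(length(st0$agents), 0L)
  st1 <- step_sim(m, st0)
  expect_identical(st1$step, 1L)
  expect_identical(length(st1$agents), 0L)
})

test_that("bad populations are rejected", {
  m <- build_eae_model()
  expect_error(sim_config(tibble::tibble(entity_type = "DC",
                                         compartment = "SLO", n = -1)),
               "nonnegative")
  expect_error(init_sim(m, sim_config(tibble::tibble(entity_type = "DC",
                                                     compartment = "Thymus",
                                                     n = 1))),
               "Thymus")
  expect_error(init_sim(m, sim_config(tibble::tibble(entity_type = "NKCell",
                                                     compartment = "SLO",
                                                     n = 1))),
               "NKCell")
})

test_that("a stimulated macrophage kills a co-located neuron at rate 1", {
  m <- build_eae_model()
  cfg <- sim_config(
    tibble::tibble(entity_type = c("CNSMacrophage", "Neuron"),
                   compartment = "CNS", n = c(1, 1)),
    parameter_overrides = list(rate_kill_Neuron = 1),
    n_steps = 1L, seed = 7L
  )
  st <- init_sim(m, cfg)
  # stimulate the macrophage by hand (fields are empty in this tiny run)
  mach <- m$state_machines$CNSMacrophage
  st$agents[[1L]]$config <- set_region_state(mach, st$agents[[1L]]$config,
                                             "activation", "stimulated")
  st <- step_sim(m, st)
  neuron <- Filter(function(a) a$entity_type == "Neuron", st$agents)[[1L]]
  expect_false(neuron$alive)
  expect_identical(as.integer(st$deaths[["Neuron"]]), 1L)
  # and a resting macrophage kills nothing
  st2 <- init_sim(m, cfg)
  st2 <- step_sim(m, st2)
  neuron2 <- Filter(function(a) a$entity_type == "Neuron", st2$agents)[[1L]]
  expect_true(neuron2$alive)
})

test_that("births accounting holds at every step of a 200-step run", {
  m <- build_eae_model()
  run <- run_sim(m, eae_small_config(n_steps = 200L, seed = 5L))
  bk <- run$bookkeeping
  expect_true(all(bk$initial + bk$births_cum == bk$alive + bk$deaths_cum))
  # recompute the same accounting independently from the event log
  births_from_log <- sum(vapply(run$events, function(e) {
    e$event %in% c("birth", "spawn")
  }, logical(1)))
  deaths_from_log <- sum(vapply(run$events, function(e) {
    e$event == "death"
  }, logical(1)))
  last <- bk[bk$step == 200L, ]
  expect_identical(as.integer(sum(last$births_cum)),
                   as.integer(births_from_log))
  expect_identical(as.integer(sum(last$deaths_cum)),
                   as.integer(deaths_from_log))
})

test_that("the full pipeline is deterministic per seed", {
  m <- build_eae_model()
  r1 <- run_sim(m, eae_small_config(n_steps = 40L, seed = 11L))
  r2 <- run_sim(m, eae_small_config(n_steps = 40L, seed = 11L))
  expect_identical(r1$series, r2$series)
  expect_identical(r1$bookkeeping, r2$bookkeeping)
  expect_identical(r1$fields, r2$fields)
  r3 <- run_sim(m, eae_small_config(n_steps = 0L, seed = 11L))
  expect_identical(unique(r3$series$step), 0L)
})

test_that("dead agents never step, emit, interact or migrate", {
  m <- build_eae_model()
  run <- run_sim(m, eae_small_config(n_steps = 120L, seed = 2L))
  st <- run$final_state
  dead <- Filter(function(a) !a$alive, st$agents)
  expect_gt(length(dead), 0L)   # CD8Tregs kill some CD4Th1 in 120 steps
  before <- lapply(dead, function(a) a$config)
  st2 <- step_sim(m, st)
  dead_after <- Filter(function(a) !a$alive, st2$agents)
  ids <- vapply(dead, `[[`, integer(1), "id")
  for (a in dead_after[vapply(dead_after, `[[`, integer(1),
                              "id") %in% ids]) {
    match_idx <- which(ids == a$id)
    expect_identical(a$config, before[[match_idx]])
  }
})

test_that("cytokine fields are nonnegative and decay to zero once secretion stops", {
  m <- build_eae_model()
  run <- run_sim(m, eae_small_config(n_steps = 30L, seed = 3L))
  expect_true(all(run$fields$level >= 0))
  st <- run$final_state
  # silence all secretion by emptying the agent set, then let fields decay
  st$agents <- list()
  for (k in 1:40) st <- step_sim(m, st)
  expect_true(all(st$fields < 1e-6))
})

test_that("knockouts validate names and an empty knockout is a no-op", {
  m <- build_eae_model()
  cfg <- eae_small_config()
  expect_identical(apply_knockout(cfg, character(), m), cfg)
  expect_error(apply_knockout(cfg, "no_such_rule", m), "no_such_rule")
  expect_error(init_sim(m, apply_knockout(cfg, "nope")), "nope")
  cfg2 <- apply_knockout(cfg, "CD8Treg_kills_CD4Th1", m)
  expect_identical(cfg2$knockouts, "CD8Treg_kills_CD4Th1")
  expect_identical(cfg2$initial_populations, cfg$initial_populations)
})

test_that("knocking out the killing rule removes CD4Th1 deaths", {
  m <- build_eae_model()
  base <- run_sim(m, eae_small_config(n_steps = 100L, seed = 9L))
  ko <- run_sim(m, apply_knockout(eae_small_config(n_steps = 100L,
                                                   seed = 9L),
                                  "CD8Treg_kills_CD4Th1", m))
  last <- function(run) {
    bk <- run$bookkeeping
    bk[bk$step == 100L & bk$entity_type == "CD4Th1", ]
  }
  expect_gt(last(base)$deaths_cum, 0L)
  expect_identical(as.integer(last(ko)$deaths_cum), 0L)
})

test_that("init_sim refuses inconsistent models unless forced", {
  bad <- mutate_eae("R5")
  cfg <- eae_small_config(n_steps = 1L)
  expect_error(init_sim(bad, cfg), "strict")
  cfg$force <- TRUE
  expect_no_error(init_sim(bad, cfg))
})
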