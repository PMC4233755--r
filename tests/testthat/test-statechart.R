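# Statechart construction and execution

test_that("constructors enforce the structural invariants", {
  expect_error(state_node("C", "composite"), "at least one substate")
  expect_error(state_node("C", "composite",
                          substates = list(state_node("a")),
                          initial = "zz"), "initial substate")
  expect_error(region("r", list(state_node("a")), initial = "zz"),
               "initial state")
  expect_error(
    state_machine("m",
                  regions = list(region("r", list(state_node("a"),
                                                  state_node("b")),
                                        initial = "a")),
                  transitions = list(transition("a", "zz", ""))),
    "does not resolve")
  # transitions may not cross regions or touch isolated states
  expect_error(
    state_machine("m", regions = list(
      region("r1", list(state_node("a")), initial = "a"),
      region("r2", list(state_node("b")), initial = "b")
    ), transitions = list(transition("a", "b", ""))),
    "crosses regions")
  expect_error(
    state_machine("m", regions = list(
      region("r", list(state_node("a"),
                       state_node("iso", kind = "isolated")),
             initial = "a")
    ), transitions = list(transition("a", "iso", ""))),
    "isolated")
})

test_that("initial configuration activates region initials, descending composites", {
  m <- two_state_machine()
  cfg <- initial_config(m)
  expect_identical(cfg$regions$main$leaf, "immature")
  expect_identical(unname(cfg$regions$main$elapsed), 0L)

  cm <- composite_machine()
  cfg2 <- initial_config(cm)
  expect_identical(cfg2$regions$loc$leaf, "A")
  expect_identical(names(cfg2$regions$loc$elapsed), c("Inside", "A"))

  dc <- dc_like_machine()
  cfg3 <- initial_config(dc)
  expect_setequal(active_states(cfg3), c("immature", "MHCII_capable"))
})

test_that("a quiescent step retains state, increments dwell and still emits", {
  m <- state_machine("e", regions = list(
    region("r", list(state_node("idle", emissions = "hum")), initial = "idle")
  ))
  cfg <- initial_config(m)
  out <- step_machine(m, cfg)
  expect_identical(out$config$regions$r$leaf, "idle")
  expect_identical(unname(out$config$regions$r$elapsed), 1L)
  expect_identical(out$emitted, "hum")
  expect_identical(nrow(out$fired), 0L)
})

test_that("a certain probabilistic transition fires after exactly one step and isolated states persist", {
  m <- dc_like_machine()
  cfg <- initial_config(m)
  out <- step_machine(m, cfg, env = list(stimulus = TRUE),
                      parameters = list(p_maturation = 1))
  expect_identical(out$config$regions$maturation$leaf, "mature")
  expect_true("MHCII_capable" %in% active_states(out$config))
  # and with the stimulus absent it never fires
  out2 <- step_machine(m, cfg, env = list(stimulus = FALSE),
                       parameters = list(p_maturation = 1))
  expect_identical(out2$config$regions$maturation$leaf, "immature")
})

test_that("guards may reference sibling regions' active states", {
  m <- state_machine("x", regions = list(
    region("r1", list(state_node("a"), state_node("b")), initial = "a"),
    region("r2", list(state_node("u"), state_node("v")), initial = "u")
  ), transitions = list(
    transition("a", "b", ""),
    transition("u", "v", "b")     # fires only once r1 occupies b
  ))
  cfg <- initial_config(m)
  s1 <- step_machine(m, cfg)
  # start-of-step snapshot: r1 moves to b this step, but r2 still saw a
  expect_identical(s1$config$regions$r2$leaf, "u")
  s2 <- step_machine(m, s1$config)
  expect_identical(s2$config$regions$r2$leaf, "v")
})

test_that("two enabled transitions tie-break uniformly at random", {
  m <- state_machine("t", regions = list(
    region("r", list(state_node("s"), state_node("a"), state_node("b")),
           initial = "s")
  ), transitions = list(transition("s", "a", ""), transition("s", "b", "")))
  set.seed(5)
  n <- 10000L
  to_a <- 0L
  cfg <- initial_config(m)
  for (i in seq_len(n)) {
    out <- step_machine(m, cfg)
    if (out$config$regions$r$leaf == "a") to_a <- to_a + 1L
  }
  se <- sqrt(0.25 / n)
  expect_lt(abs(to_a / n - 0.5), 3 * se)
})

test_that("exactly one active leaf per region holds across randomized runs", {
  set.seed(99)
  for (rep in 1:60) {
    m <- random_machine()
    cfg <- initial_config(m)
    env <- random_env()
    for (k in 1:18) {
      out <- step_machine(m, cfg, env = env, parameters = machine_params)
      cfg <- out$config
      for (rn in names(cfg$regions)) {
        leaf <- cfg$regions[[rn]]$leaf
        expect_identical(m$index[[leaf]]$region, rn)
        expect_identical(leaf, names(cfg$regions[[rn]]$elapsed)[
          length(cfg$regions[[rn]]$elapsed)])
      }
      expect_identical(length(active_states(cfg)),
                       length(unique(active_states(cfg))))
    }
  }
})

test_that("all-delta-zero machines are seed-invariant", {
  set.seed(1)
  machines <- replicate(10, random_machine(delta_zero = TRUE),
                        simplify = FALSE)
  envs <- replicate(10, random_env(), simplify = FALSE)
  for (i in seq_along(machines)) {
    run1 <- run_machine(machines[[i]], 25, env = envs[[i]],
                        parameters = machine_params, seed = 101)
    run2 <- run_machine(machines[[i]], 25, env = envs[[i]],
                        parameters = machine_params, seed = 20202)
    expect_identical(run1$active, run2$active)
  }
})

test_that("identical seeds give bit-identical trajectories", {
  m <- random_machine()
  env <- list(p1 = TRUE, p2 = FALSE, p3 = TRUE)
  r1 <- run_machine(m, 40, env = env, parameters = machine_params, seed = 8)
  r2 <- run_machine(m, 40, env = env, parameters = machine_params, seed = 8)
  expect_identical(r1$active, r2$active)
  expect_identical(attr(r1, "emitted"), attr(r2, "emitted"))
})

test_that("lambda enablement is monotone in dwell time", {
  m <- two_state_machine("λ(t)")
  params <- list(t = 4)
  cfg <- initial_config(m)
  fired_at <- NA
  for (k in 1:10) {
    out <- step_machine(m, cfg, parameters = params)
    if (out$config$regions$main$leaf == "mature") {
      fired_at <- k
      break
    }
    cfg <- out$config
  }
  # dwell reaches 4 after four quiescent steps; the fifth step fires
  expect_identical(fired_at, 5L)
})

test_that("entering and leaving a composite exits/enters substates and resets dwell", {
  m <- composite_machine()
  cfg <- initial_config(m)
  # move within the composite first
  out <- step_machine(m, cfg, env = list(go = TRUE, leave = FALSE,
                                         enter = FALSE))
  expect_identical(out$config$regions$loc$leaf, "B")
  expect_identical(unname(out$config$regions$loc$elapsed),
                   c(1L, 0L))  # Inside keeps dwelling, B fresh
  # leaving the composite exits its active substate
  out2 <- step_machine(m, out$config, env = list(go = FALSE, leave = TRUE,
                                                 enter = FALSE))
  expect_identical(out2$config$regions$loc$leaf, "Outside")
  expect_identical(names(out2$config$regions$loc$elapsed), "Outside")
  # re-entering descends to the composite's initial substate
  out3 <- step_machine(m, out2$config, env = list(go = FALSE, leave = FALSE,
                                                  enter = TRUE))
  expect_identical(out3$config$regions$loc$leaf, "A")
  expect_identical(names(out3$config$regions$loc$elapsed), c("Inside", "A"))
})

test_that("set_region_state forces a leaf and resets only entered states", {
  m <- composite_machine()
  cfg <- initial_config(m)
  cfg <- set_region_state(m, cfg, "loc", "B")
  expect_identical(cfg$regions$loc$leaf, "B")
  expect_error(set_region_state(m, cfg, "loc", "zz"), "not in region")
  expect_error(set_region_state(m, cfg, "zz", "B"), "unknown region")
})
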