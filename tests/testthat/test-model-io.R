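# Document round trips, schema validation, DOT rendering and the CLI

test_that("load(save(model)) is the identity on fuzzed random models", {
  set.seed(27)
  for (rep in 1:15) {
    m <- random_model()
    expect_equal(load_model(save_model(m)), m, tolerance = 1e-12)
  }
})

test_that("YAML is an equivalent surface syntax", {
  m <- random_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  expect_equal(load_model(path), m, tolerance = 1e-12)
})

test_that("the schema rejects a corpus of invalid documents with pointer paths", {
  base <- jsonlite::fromJSON(save_model(build_eae_model()),
                             simplifyVector = FALSE)
  corpus <- list(
    list(mut = function(d) { d$compartments <- NULL; d },
         ptr = "/compartments"),
    list(mut = function(d) { d$entities <- NULL; d }, ptr = "/entities"),
    list(mut = function(d) { d$migration_rules <- NULL; d },
         ptr = "/migration_rules"),
    list(mut = function(d) { d$state_machines <- NULL; d },
         ptr = "/state_machines"),
    list(mut = function(d) { d$perspectives <- NULL; d },
         ptr = "/perspectives"),
    list(mut = function(d) { d$research_context <- NULL; d },
         ptr = "/research_context"),
    list(mut = function(d) { d$parameters <- NULL; d }, ptr = "/parameters"),
    list(mut = function(d) { d$compartments[[1L]]$name <- NULL; d },
         ptr = "/compartments/0/name"),
    list(mut = function(d) { d$entities[[2L]]$category <- "tissue"; d },
         ptr = "/entities/1/category"),
    list(mut = function(d) { d$entities[[1L]]$name <- NULL; d },
         ptr = "/entities/0/name"),
    list(mut = function(d) { d$migration_rules[[1L]]$from <- NULL; d },
         ptr = "/migration_rules/0/from"),
    list(mut = function(d) { d$migration_rules[[3L]]$to <- NULL; d },
         ptr = "/migration_rules/2/to"),
    list(mut = function(d) {
      d$migration_rules[[1L]]$state_condition <- "δ(p &"; d
    }, ptr = "/migration_rules/0/state_condition"),
    list(mut = function(d) { d$state_machines$DC$regions <- NULL; d },
         ptr = "/state_machines/DC/regions"),
    list(mut = function(d) {
      d$state_machines$DC$regions[[1L]]$initial <- NULL; d
    }, ptr = "/state_machines/DC/regions/0/initial"),
    list(mut = function(d) {
      d$state_machines$DC$regions[[2L]]$states <- list(); d
    }, ptr = "/state_machines/DC/regions/1/states"),
    list(mut = function(d) {
      d$state_machines$Neuron$transitions[[1L]]$source <- NULL; d
    }, ptr = "/state_machines/Neuron/transitions/0/source"),
    list(mut = function(d) {
      d$state_machines$Neuron$transitions[[1L]]$guard <- "killed |"; d
    }, ptr = "/state_machines/Neuron/transitions/0/guard"),
    list(mut = function(d) { d$perspectives[[1L]]$name <- NULL; d },
         ptr = "/perspectives/0/name"),
    list(mut = function(d) { d$perspectives[[2L]]$expands <- list(); d },
         ptr = "/perspectives/1/expands"),
    list(mut = function(d) {
      d$perspectives[[3L]]$nodes[[1L]]$kind <- "action"; d
    }, ptr = "/perspectives/2/nodes"),
    list(mut = function(d) { d$research_context$phenomena <- NULL; d },
         ptr = "/research_context/phenomena"),
    list(mut = function(d) { d$research_context$links <- NULL; d },
         ptr = "/research_context/links"),
    list(mut = function(d) { d$parameters$p_dc_maturation <- "high"; d },
         ptr = "/parameters")
  )
  expect_gte(length(corpus), 20L)
  for (i in seq_along(corpus)) {
    doc <- corpus[[i]]$mut(base)
    issues <- validate_document(doc)
    expect_true(nrow(issues) > 0L, info = corpus[[i]]$ptr)
    expect_true(any(startsWith(issues$pointer, corpus[[i]]$ptr)),
                info = paste(i, corpus[[i]]$ptr, "got:",
                             paste(issues$pointer, collapse = ", ")))
  }
  # the clean document has no issues
  expect_identical(nrow(validate_document(base)), 0L)
})

test_that("load_model reports schema violations and guard positions", {
  doc <- jsonlite::fromJSON(save_model(build_eae_model()),
                            simplifyVector = FALSE)
  doc$compartments <- NULL
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE))
  expect_error(load_model(txt), "/compartments")
  doc2 <- jsonlite::fromJSON(save_model(build_eae_model()),
                             simplifyVector = FALSE)
  doc2$state_machines$Neuron$transitions[[1L]]$guard <- "δ(p & "
  txt2 <- as.character(jsonlite::toJSON(doc2, auto_unbox = TRUE))
  expect_error(load_model(txt2), "position")
})

test_that("DOT output is deterministic, well-formed, and shows the documented styling", {
  m <- build_eae_model()
  for (sel in all_selectors(m)) {
    dot <- render_dot(m, sel)
    expect_valid_dot(dot)
    expect_identical(render_dot(m, sel), dot)   # byte-identical on repeat
  }
  mach <- render_dot(m, "machine:CD8Treg")
  expect_match(mach, "cluster_Lymphoid")        # composite as cluster
  persp <- render_dot(m, "perspective:type-2 deviation")
  expect_match(persp, "anchor_")                # interrupt midpoint anchor
  expect_match(persp, "arrowhead=tee")
  expect_match(persp, "style=dashed, arrowhead=vee")  # propagating legend
  expect_match(persp, "arrowhead=odot")         # contributory
  expect_match(persp, "cluster_lane_CNS")       # swim lane as cluster
  expect_error(render_dot(m, "machine:NKCell"), "unknown selector")
  expect_error(render_dot(m, "bogus"), "unknown selector")
})

test_that("the CLI honours the exit-code contract on clean and defective fixtures", {
  dir <- withr::local_tempdir()
  fixture <- file.path(dir, "eae.json")
  expect_identical(dm_cli(c("fixture", "--out", fixture)), 0L)
  expect_true(file.exists(fixture))
  # validate: clean fixture exits 0
  expect_identical(dm_cli(c("validate", "--model", fixture)), 0L)
  # seeded R3 defect: exit 1 and the report cites Circulation
  bad <- mutate_eae("R3")
  bad_path <- file.path(dir, "bad.json")
  write_model(bad, bad_path)
  report_path <- file.path(dir, "report.json")
  expect_identical(dm_cli(c("validate", "--model", bad_path,
                            "--out", report_path)), 1L)
  report <- jsonlite::fromJSON(readLines(report_path))
  expect_true(any(grepl("Circulation", report$violations$message)))
  # usage errors exit 2
  expect_identical(dm_cli(character()), 2L)
  expect_identical(dm_cli("frobnicate"), 2L)
  expect_identical(dm_cli(c("knockout", "--names", "no_such_rule",
                            "--out", file.path(dir, "x"))), 2L)
})

test_that("CLI renders DOT files and simulation CSVs reproducibly", {
  dir <- withr::local_tempdir()
  expect_identical(dm_cli(c("render", "--selector", "machine:Neuron",
                            "--out", dir)), 0L)
  dot_file <- file.path(dir, "machine_Neuron.dot")
  expect_true(file.exists(dot_file))
  expect_valid_dot(paste(readLines(dot_file), collapse = "\n"))

  p1 <- file.path(dir, "runA")
  p2 <- file.path(dir, "runB")
  expect_identical(dm_cli(c("simulate", "--seed", "7", "--steps", "0",
                            "--out", p1)), 0L)
  expect_identical(dm_cli(c("simulate", "--seed", "7", "--steps", "0",
                            "--out", p2)), 0L)
  csv1 <- readLines(paste0(p1, "_series.csv"))
  expect_identical(csv1, readLines(paste0(p2, "_series.csv")))
  # step 0: exactly the initial census, one row group
  series <- readr::read_csv(paste0(p1, "_series.csv"),
                            show_col_types = FALSE)
  expect_identical(unique(series$step), 0)
  expect_true(file.exists(paste0(p1, "_meta.json")))
  expect_true(file.exists(paste0(p1, "_events.ndjson")))
})
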