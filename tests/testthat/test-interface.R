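test_that("fixture configurations materialise the documented corners", {
  td <- withr::local_tempdir()
  f <- make_fixture("baseline", file.path(td, "b.yaml"))
  cfg <- read_colony_config(f)
  expect_equal(cfg$params$b_W, 8.5)
  expect_equal(cfg$params$Z, 4)
  nm <- read_colony_config(make_fixture("no-mortality",
                                        file.path(td, "nm.yaml")))
  expect_equal(nm$params$alpha, 0)
  expect_equal(nm$params$beta, 0)
  expect_false(nm$params$oophagy)
  tiny <- read_colony_config(make_fixture("tiny", file.path(td, "t.yaml")))
  expect_equal(tiny$params$T_W, 40)
  sv <- read_colony_config(make_fixture("starvation",
                                        file.path(td, "s.yaml")))
  expect_equal(sv$scenario$forage_reduction_N, 1)
  expect_error(make_fixture("nope"))
})

test_that("unknown configuration keys are rejected by name", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.yaml")
  writeLines("parameters:\n  b_XX: 3", bad)
  expect_error(read_colony_config(bad), "b_XX")
  writeLines("mystery:\n  a: 1", bad)
  expect_error(read_colony_config(bad), "mystery")
  expect_error(read_colony_config(file.path(td, "absent.yaml")), "not found")
})

test_that("run_config writes deterministic artifacts", {
  td <- withr::local_tempdir()
  cfgf <- make_fixture("tiny", file.path(td, "tiny.yaml"))
  sim <- run_config(cfgf, file.path(td, "out1"))
  expect_true(file.exists(file.path(td, "out1", "trajectory.csv")))
  expect_true(file.exists(file.path(td, "out1", "metrics.json")))
  met <- jsonlite::read_json(file.path(td, "out1", "metrics.json"))
  expect_equal(met$reproductive_output, reproductive_output(sim))
  # byte-identical re-run
  run_config(cfgf, file.path(td, "out2"))
  expect_identical(readLines(file.path(td, "out1", "trajectory.csv")),
                   readLines(file.path(td, "out2", "trajectory.csv")))
})

test_that("the command-line interface runs a tiny season end to end", {
  cli <- system.file("exec", "bombusim", package = "bombusim")
  expect_true(file.exists(cli))
  td <- withr::local_tempdir()
  r <- system2("Rscript", c(cli, "fixture", "tiny", "--out",
                            file.path(td, "t.yaml")), stdout = TRUE,
               stderr = TRUE)
  expect_true(file.exists(file.path(td, "t.yaml")))
  r2 <- system2("Rscript", c(cli, "run", "--config", file.path(td, "t.yaml"),
                             "--out", file.path(td, "out")),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(r2, "status"), NULL)  # exit 0
  expect_true(file.exists(file.path(td, "out", "metrics.json")))
  # malformed YAML exits with status 2
  bad <- file.path(td, "bad.yaml")
  writeLines("parameters: [unclosed", bad)
  r3 <- suppressWarnings(system2("Rscript", c(cli, "run", "--config", bad),
                                 stdout = TRUE, stderr = TRUE))
  expect_equal(attr(r3, "status"), 2)
})
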