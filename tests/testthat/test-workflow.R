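popConfigFile <- function() {
  system.file("configs", "population.yaml", package = "cscsense")
}

test_that("the shipped population config resolves to the standard settings", {
  cfg <- loadConfig(popConfigFile())
  expect_equal(cfg$n, 1000L)
  expect_equal(cfg$r, 4L)
  expect_equal(cfg$grid$t_ini, 0)
  expect_equal(cfg$grid$t_end, 200)
  expect_length(cfg$grid$times, 200)
  expect_length(cfg$specs, 13)
  # every rate parameter varies +/-50%; P_sy spans [0, 1]
  nm <- vapply(cfg$specs, function(s) s$name, character(1))
  psy <- cfg$specs[[which(nm == "P_sy")]]
  expect_equal(unname(resolveInterval(psy)), c(0, 1))
  om <- cfg$specs[[which(nm == "omega_CSC")]]
  expect_equal(unname(resolveInterval(om)),
               c(0.5, 1.5) * cscParameters()[["omega_CSC"]])
})

test_that("config validation reports every problem at once", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model: csc", "n: many", "bogus_key: 1"), f)
  err <- tryCatch(loadConfig(f), error = function(e) conditionMessage(e))
  expect_match(err, "unknown key")
  expect_match(err, "'n' must be")
  expect_match(err, "seed")

  writeLines(c("model: csc", "n: 10", "seed: 1",
               "time: {t_ini: 0, t_end: 10, points: 5}",
               "parameters: {not_a_param: {min: 0, max: 1}}"), f)
  expect_error(loadConfig(f), "not_a_param")
})

test_that("the workflow runs end to end on the logistic fixture", {
  f <- withr::local_tempfile(fileext = ".yaml")
  out <- withr::local_tempdir()
  writeLines(c("model: logistic", "n: 30", "seed: 321", "var_pct: 25",
               "time: {t_ini: 0, t_end: 30, points: 16}",
               "key_parameters: [r]"), f)
  started <- Sys.time()
  res <- runWorkflow(loadConfig(f), output_dir = out)
  elapsed <- as.numeric(difftime(Sys.time(), started, units = "secs"))
  expect_lt(elapsed, 10)

  expect_true(file.exists(file.path(out, "design.csv")))
  expect_true(file.exists(file.path(out, "ensemble", "Y_N.csv")))
  expect_true(file.exists(file.path(out, "sensitivity", "prcc_long.csv")))
  expect_true(file.exists(file.path(out, "prcc_N.png")))
  expect_true(file.exists(file.path(out, "traces_r_N.png")))
  expect_true(file.exists(file.path(out, "scatter_r_N.png")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 321)
  expect_equal(manifest$n_failures, 0)

  # same seed: identical design bit-for-bit; different seed: different
  out2 <- withr::local_tempdir()
  runWorkflow(loadConfig(f), output_dir = out2)
  expect_identical(readLines(file.path(out, "design.csv")),
                   readLines(file.path(out2, "design.csv")))
  writeLines(c("model: logistic", "n: 30", "seed: 322", "var_pct: 25",
               "time: {t_ini: 0, t_end: 30, points: 16}",
               "key_parameters: [r]"), f)
  out3 <- withr::local_tempdir()
  m3 <- runWorkflow(loadConfig(f), output_dir = out3)$manifest
  expect_equal(m3$seed, 322)
  expect_false(identical(readLines(file.path(out, "design.csv")),
                         readLines(file.path(out3, "design.csv"))))
})

test_that("extinction classification uses the initial CSC count by default", {
  d <- lhsSample(cscParameterSpecs(), n = 20, seed = 55)
  Y <- simulateEnsemble("csc", d, grid = timeGrid(0, 100, points = 21))
  ext <- extinctAtEnd(Y)
  expect_equal(attr(ext, "band"), 100)
  expect_length(ext, 20)
  fin <- outputsAtTime(Y, 100)
  expect_equal(c(ext), unname(fin[, "N_CSC"] < 100))
})

test_that("the command-line interface drives the pipeline on the logistic fixture", {
  cli <- system.file("cli", "cscsense", package = "cscsense")
  f <- withr::local_tempfile(fileext = ".yaml")
  out <- withr::local_tempdir()
  writeLines(c("model: logistic", "n: 20", "seed: 11", "var_pct: 25",
               "time: {t_ini: 0, t_end: 20, points: 11}",
               "key_parameters: [r]"), f)
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  started <- Sys.time()
  status <- system2("Rscript", c(cli, "run", "--config", f, "--out", out),
                    stdout = FALSE, stderr = FALSE, env = libs)
  expect_equal(status, 0)
  expect_lt(as.numeric(difftime(Sys.time(), started, units = "secs")), 10)
  expect_true(file.exists(file.path(out, "design.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  # bifurcate subcommand on the bistable fixture
  diagf <- withr::local_tempfile(fileext = ".csv")
  status2 <- system2("Rscript", c(cli, "bifurcate", "--model", "bistable_toy",
                                  "--param", "p", "--range", "0.2:0.8",
                                  "--points", "9", "--out", diagf),
                     stdout = FALSE, stderr = FALSE, env = libs)
  expect_equal(status2, 0)
  expect_gt(nrow(read.csv(diagf)), 0)
})
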