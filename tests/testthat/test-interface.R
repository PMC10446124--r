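test_that("CSV loading assigns roles and validates content", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(y = c(1.2, 0.7, 2.2), w1 = c(1, 2, 3),
                       w2 = c(1.5, 2.5, 2.9), age = c(30, 40, 50)),
            path, row.names = FALSE)
  d <- load_study_csv(path, outcome = "y", replicates = c("w1", "w2"),
                      covariates = "age", family = "linear")
  expect_equal(n_replicates(d), 2)
  expect_equal(ncol(d$covariates), 1)
  expect_error(load_study_csv(path, "y", "nope"), "missing column")
  # logistic outcome outside {0, 1}
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(y = c(0, 1, 2), w1 = 1:3), path2, row.names = FALSE)
  expect_error(load_study_csv(path2, "y", "w1", family = "logistic"),
               "0 and 1")
  # missing values reported with rows
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(y = c(1, NA, 3), w1 = 1:3), path3, row.names = FALSE)
  expect_error(load_study_csv(path3, "y", "w1"), "rows 2")
})

test_that("the correct command produces a result JSON and a manifest", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "d.csv")
  write_study_csv(generate_linear(linear_scenario(n = 200), seed = 3), csv)
  out <- file.path(dir, "res.json")
  status <- run_cli(c("correct", "--data", csv, "--outcome", "outcome",
                      "--replicates", "w1,w2,w3", "--covariates", "age",
                      "--family", "linear", "--method", "rc",
                      "--seed", "1", "--out", out))
  expect_equal(status, 0L)
  res <- jsonlite::read_json(out)
  expect_equal(res$method, "rc")
  expect_true(is.numeric(res$estimate))
  # matches the in-R computation
  d <- load_study_csv(csv, "outcome", c("w1", "w2", "w3"), "age", "linear")
  expect_equal(res$estimate, rc_correct(d)$estimate, tolerance = 1e-10)
  manifest <- jsonlite::read_json(paste0(out, ".manifest.json"))
  expect_equal(manifest$command, "correct")
  expect_equal(manifest$options$seed, 1)
})

test_that("a user-supplied tau2 overrides the replicate estimate with a message", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "d.csv")
  write_study_csv(generate_linear(linear_scenario(n = 200), seed = 3), csv)
  out <- file.path(dir, "res.json")
  expect_message(
    run_cli(c("correct", "--data", csv, "--outcome", "outcome",
              "--replicates", "w1,w2,w3", "--covariates", "age",
              "--method", "rc", "--tau2", "48.3", "--seed", "1", "--out", out)),
    "overrides")
  res <- jsonlite::read_json(out)
  d <- load_study_csv(csv, "outcome", c("w1", "w2", "w3"), "age", "linear")
  expect_equal(res$estimate,
               rc_correct(d, error_model(48.3, "known"))$estimate,
               tolerance = 1e-10)
})

test_that("the simulate command is byte-deterministic given a seed", {
  dir <- withr::local_tempdir()
  o1 <- file.path(dir, "m1.csv"); o2 <- file.path(dir, "m2.csv")
  args <- c("simulate", "--family", "linear", "--scenario", "base",
            "--reps", "30", "--methods", "naive,rc", "--seed", "7")
  expect_equal(run_cli(c(args, "--out", o1)), 0L)
  expect_equal(run_cli(c(args, "--out", o2)), 0L)
  expect_identical(readLines(o1), readLines(o2))
  m <- read.csv(o1)
  expect_equal(sort(unique(m$method)), c("naive", "rc"))
  expect_true(file.exists(file.path(dir, "m1_summary.json")))
})

test_that("datagen and sensitivity commands run end to end", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "gen.csv")
  expect_equal(run_cli(c("datagen", "--family", "linear", "--scenario",
                         "replicates_2", "--seed", "4", "--out", csv)), 0L)
  d <- load_study_csv(csv, "outcome", c("w1", "w2"), "age", "linear")
  expect_equal(n_obs(d), 500)
  out <- file.path(dir, "sens.csv")
  status <- run_cli(c("sensitivity", "--data", csv, "--outcome", "outcome",
                      "--replicates", "w1", "--covariates", "age",
                      "--method", "rc", "--prior", "uniform:10,40",
                      "--draws", "20", "--seed", "2", "--out", out))
  expect_equal(status, 0L)
  expect_equal(nrow(read.csv(out)), 20)
})

test_that("usage errors exit nonzero without touching outputs", {
  expect_equal(run_cli(character()), 1L)
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(
    run_cli(c("datagen", "--family", "linear", "--out", "x.csv"))), 1L)
  expect_false(file.exists("x.csv"))
})
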