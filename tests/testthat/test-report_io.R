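test_that("allocation tables are written in the documented layout", {
  d <- allocate("diagwalks", 15, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_allocation_table(d, path)
  lines <- readLines(path)
  expect_identical(lines[1], "patient_id,main_pool,control_pool")
  expect_identical(lines[2], "1,1,6")
  expect_identical(lines[4], "3,1,7")

  dn <- allocate("noreplica", 7, 3)
  pn <- withr::local_tempfile(fileext = ".csv")
  write_allocation_table(dn, pn)
  expect_identical(readLines(pn)[8], "7,3,")

  # byte-identical across invocations
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_allocation_table(d, p2)
  expect_identical(readLines(p2), lines)
})

test_that("allocation tables round-trip through read_allocation_table", {
  for (alg in planner_algorithms()) {
    d <- suppressWarnings(allocate(alg, 26, 4))
    path <- withr::local_tempfile(fileext = ".csv")
    write_allocation_table(d, path)
    back <- read_allocation_table(path, alg)
    expect_same_pools(d, back)
    expect_identical(back$n_patients, d$n_patients)
    expect_identical(back$algorithm, d$algorithm)
  }
})

test_that("summaries serialize to JSON and CSV with stable formatting", {
  p <- case_study_3()
  sw <- sweep_configurations(p, "noreplica")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_summary(sw, jp, cp)
  tab <- read.csv(cp)
  expect_identical(names(tab), c("pool_size", "num_pools", "sanger_tests",
                                 "waiting", "total_cost", "optimal"))
  expect_identical(sum(tab$optimal == "true"), 1L)
  expect_identical(tab$total_cost[tab$pool_size == 3], 1626680L)
  expect_false(any(grepl("e\\+", readLines(cp))))

  cmp <- compare_algorithms(p)
  jc <- withr::local_tempfile(fileext = ".json")
  write_summary(cmp, jc)
  parsed <- jsonlite::read_json(jc, simplifyVector = TRUE)
  expect_identical(parsed$algorithms$diagwalks$breakdown$total, 201280L)
  expect_identical(parsed$algorithms$transposition$breakdown$waiting, 1901L)

  # inapplicable sweeps record the reason instead of dropping rows
  swt <- sweep_configurations(design_parameters(10, 10, 1, 1, 1),
                              "transposition")
  jt <- withr::local_tempfile(fileext = ".json")
  rep <- write_summary(swt, jt)
  inap <- Filter(function(r) !isTRUE(r$applicable), rep$configurations)
  expect_gt(length(inap), 0)
  expect_true(all(vapply(inap, function(r) nzchar(r$reason), logical(1))))
})

test_that("the CLI plans, compares and verifies end to end", {
  out <- withr::local_tempdir()
  code <- suppressMessages(run_cli(c(
    "compare", "--patients", "64", "--max-pool-size", "6",
    "--mutations", "5", "--ngs-cost", "1000", "--sanger-cost", "8",
    "--quiet", "--out-dir", out)))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out, "comparison.json")))
  tab <- read.csv(file.path(out, "comparison.csv"))
  expect_identical(tab$transposition[tab$metric == "waiting"], 56L)

  out2 <- withr::local_tempdir()
  code2 <- suppressMessages(run_cli(c(
    "plan", "--algorithm", "diagwalks", "--patients", "15",
    "--max-pool-size", "3", "--pool-size", "3", "--quiet",
    "--out-dir", out2)))
  expect_identical(code2, 0L)
  alloc <- readLines(file.path(out2, "allocation.csv"))
  expect_identical(alloc[2], "1,1,6")

  out3 <- withr::local_tempdir()
  code3 <- suppressMessages(run_cli(c(
    "verify", "--algorithm", "transposition", "--patients", "48",
    "--max-pool-size", "6", "--mutations", "2", "--trials", "20",
    "--seed", "4", "--quiet", "--out-dir", out3)))
  expect_identical(code3, 0L)
  ver <- jsonlite::read_json(file.path(out3, "verification.json"))
  expect_true(ver$ok)
})

test_that("the CLI rejects invalid input with a nonzero exit code", {
  expect_identical(
    suppressMessages(run_cli(c("plan", "--patients", "-5",
                               "--max-pool-size", "3"))), 2L)
  expect_identical(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(run_cli(character(0))), 2L)
  expect_identical(
    suppressMessages(run_cli(c("compare", "--patients", "10"))), 2L)
})

test_that("config files supply parameters and metadata passes through inert", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("patients: 64", "max-pool-size: 6", "mutations: 5",
               "ngs-cost: 1000", "sanger-cost: 8"), cfg)
  out <- withr::local_tempdir()
  code <- suppressMessages(run_cli(c("compare", "--config", cfg, "--quiet",
                                     "--out-dir", out)))
  expect_identical(code, 0L)
  parsed <- jsonlite::read_json(file.path(out, "comparison.json"),
                                simplifyVector = TRUE)
  expect_identical(parsed$params$n_patients, 64L)

  # metadata is recorded but cannot change any number
  out2 <- withr::local_tempdir()
  code2 <- suppressMessages(run_cli(c("compare", "--config", cfg, "--quiet",
                                      "--coverage", "30x",
                                      "--out-dir", out2)))
  expect_identical(code2, 0L)
  a <- jsonlite::read_json(file.path(out, "comparison.json"),
                           simplifyVector = TRUE)
  b <- jsonlite::read_json(file.path(out2, "comparison.json"),
                           simplifyVector = TRUE)
  expect_identical(a$algorithms, b$algorithms)
  expect_identical(b$metadata$coverage, "30x")
})
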