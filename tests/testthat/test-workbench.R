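test_that("plans are validated strictly", {
  d <- withr::local_tempdir()
  pf <- file.path(d, "plan.json")
  ok <- list(experiment = "exponents", seed = 3, out = file.path(d, "o"),
             L = 32, reps = 2, rho = 0, height_target = 40)
  jsonlite::write_json(ok, pf, auto_unbox = TRUE)
  plan <- load_plan(pf)
  expect_s3_class(plan, "experiment_plan")
  expect_equal(plan$n_target, 1e5)   # defaults filled
  expect_equal(plan$mu, 5e-4)

  bad <- ok; bad$rho <- 1.2
  jsonlite::write_json(bad, pf, auto_unbox = TRUE)
  expect_error(load_plan(pf), "\\[0, 1\\]")

  noseed <- ok; noseed$seed <- NULL
  jsonlite::write_json(noseed, pf, auto_unbox = TRUE)
  expect_error(load_plan(pf), "seed")

  unknown <- ok; unknown$frobnicate <- 1
  jsonlite::write_json(unknown, pf, auto_unbox = TRUE)
  expect_error(load_plan(pf), "unknown plan key")

  expect_error(load_plan(file.path(d, "missing.json")), "not found")
})

test_that("running the same plan twice is bit-reproducible", {
  d <- withr::local_tempdir()
  mk <- function(out) {
    pf <- tempfile(fileext = ".json", tmpdir = d)
    jsonlite::write_json(list(experiment = "exponents", seed = 11,
                              out = out, L = 32, reps = 2,
                              rho = 0.1, k = 0.5, height_target = 30),
                         pf, auto_unbox = TRUE)
    run_plan(pf)
  }
  m1 <- mk(file.path(d, "a"))
  m2 <- mk(file.path(d, "b"))
  sums1 <- vapply(m1$files, function(f) f$md5, character(1))
  sums2 <- vapply(m2$files, function(f) f$md5, character(1))
  expect_identical(unname(sums1), unname(sums2))
  expect_true(file.exists(file.path(d, "a", "manifest.json")))
  expect_true(file.exists(file.path(d, "a", "exponents.csv")))
})

test_that("percolation and sweep plans produce their tables", {
  d <- withr::local_tempdir()
  pf <- file.path(d, "p.json")
  jsonlite::write_json(list(experiment = "percolation", seed = 4,
                            out = file.path(d, "p"), L = 31,
                            rho_grid = seq(0.25, 0.55, by = 0.1),
                            reps = 12),
                       pf, auto_unbox = TRUE)
  run_plan(pf)
  tab <- read.csv(file.path(d, "p", "spanning.csv"))
  expect_true(all(diff(tab$p_span) <= 0.35))  # broadly decreasing
  rc <- read.csv(file.path(d, "p", "rho_c.csv"))
  expect_gt(rc$rho_c, 0.25)
  expect_lt(rc$rho_c, 0.6)

  jsonlite::write_json(list(experiment = "fmt_sweep", seed = 5,
                            out = file.path(d, "s"), n_target = 500,
                            mu = 0.01, reps = 3,
                            s_grid = c(-0.1, 0, 0.1, 0.2)),
                       file.path(d, "s.json"), auto_unbox = TRUE)
  run_plan(file.path(d, "s.json"))
  sw <- read.csv(file.path(d, "s", "sweep.csv"))
  expect_equal(nrow(sw), 4)
  ft <- read.csv(file.path(d, "s", "fits.csv"))
  expect_true(is.finite(ft$ks))
})

test_that("table-driven plans (adapt_rate, infer_mu) run end to end", {
  d <- withr::local_tempdir()
  s <- seq(-0.3, 0.3, by = 0.05)
  sweep <- rbind(data.frame(rho = 0, k = 0, s = s,
                            f_mt = 0.02 * exp(12 * s)),
                 data.frame(rho = 0.4, k = 0, s = s, f_mt = 0.02))
  write.csv(sweep, file.path(d, "sweep.csv"), row.names = FALSE)
  jsonlite::write_json(list(experiment = "adapt_rate", seed = 1,
                            out = file.path(d, "ar"),
                            data = file.path(d, "sweep.csv"),
                            s_bar = 0.03, ratio = 2),
                       file.path(d, "ar.json"), auto_unbox = TRUE)
  run_plan(file.path(d, "ar.json"))
  ar <- read.csv(file.path(d, "ar", "adaptation_rate.csv"))
  expect_equal(ar$rate_norm[ar$rho == 0], 1)
  expect_lt(ar$rate_raw[ar$rho == 0.4], 0)

  counts <- data.frame(wt_count = c(950, 1010, 980),
                       mt_count = c(12, 0, 5))
  write.csv(counts, file.path(d, "counts.csv"), row.names = FALSE)
  jsonlite::write_json(list(experiment = "infer_mu", seed = 2,
                            out = file.path(d, "mu"),
                            data = file.path(d, "counts.csv"),
                            sims_per_theta = 300),
                       file.path(d, "mu.json"), auto_unbox = TRUE)
  run_plan(file.path(d, "mu.json"))
  est <- jsonlite::read_json(file.path(d, "mu", "mu_estimate.json"))
  expect_true(est$mu_star > 0)
  expect_true(file.exists(file.path(d, "mu", "likelihood_grid.csv")))
})

test_that("fan_seed is a stable injective-enough counter scheme", {
  s <- fan_seed(1, 1, 1)
  expect_identical(s, fan_seed(1, 1, 1))
  grid <- expand.grid(i = 1:30, j = 1:50)
  seeds <- mapply(fan_seed, 123, grid$i, grid$j)
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("fixtures carry their enumerated expectations", {
  expect_error(make_fixture("nope"), "unknown fixture")
  f <- make_fixture("founder4")
  expect_equal(sum(f$expected$daughters$prob), 1)
  expect_equal(nrow(eligible_sites(f$state)), 1)
  tr <- make_fixture("two-rates")
  el <- eligible_sites(tr$state)
  expect_equal(sort(el$rate), c(1, 1.2))
})

test_that("runs round-trip through the plain-text format", {
  d <- withr::local_tempdir()
  res <- run_colony(sim_config(rho = 0.3, k = 0.2, s = 0.1, mu = 0.01,
                               L = 41, n_target = 400, seed = 77))
  write_run(res, file.path(d, "run"))
  back <- read_run(file.path(d, "run"))
  expect_identical(back$grid, res$grid)
  expect_identical(back$disorder, res$disorder)
  expect_equal(back$log$time, res$log$time)
  expect_identical(back$log$clone_id, res$log$clone_id)
  expect_identical(back$terminated_by, res$terminated_by)
  # the event log is the spec'd 0-based CSV
  ev <- read.csv(file.path(d, "run", "events.csv"))
  expect_identical(names(ev)[1:6],
                   c("index", "time", "mother_x", "mother_y",
                     "daughter_x", "daughter_y"))
  expect_equal(min(ev$daughter_x), min(res$log$daughter_x) - 1L)
  expect_true(all(ev$genotype %in% c("WT", "MT")))
})
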