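test_that("disorder generation honors density, protection and seed", {
  d0 <- generate_disorder(50, rho = 0, seed = 1)
  expect_false(any(d0$mask))

  d1 <- generate_disorder(50, rho = 1, seed = 1,
                          protected = cbind(25, 25))
  expect_false(d1$mask[25, 25])
  expect_equal(sum(!d1$mask), 1)

  # realized density within 3 binomial sd of rho at n = 10^4
  d <- generate_disorder(100, rho = 0.4, seed = 1)
  se <- sqrt(0.4 * 0.6 / 1e4)
  expect_lt(abs(d$rho_realized - 0.4), 3 * se)

  expect_identical(generate_disorder(20, rho = 0.3, seed = 7)$mask,
                   generate_disorder(20, rho = 0.3, seed = 7)$mask)
  expect_error(generate_disorder(20, rho = 1.2, seed = 1))
  expect_error(generate_disorder(20, rho = 0.5, seed = 1,
                                 protected = cbind(21, 3)),
               "out of bounds")
})

test_that("growth rates multiply transparency and selection", {
  g <- matrix(NA_integer_, 3, 3)
  g[2, 2] <- 0L  # WT
  g[1, 1] <- 1L  # MT
  d <- matrix(FALSE, 3, 3)
  d[1, 1] <- TRUE
  d[3, 3] <- TRUE
  expect_identical(growth_rate(g, d, k = 0.1, s = 0.2, c(2, 2)), 1)
  expect_equal(growth_rate(g, d, k = 0.1, s = 0.2, c(1, 1)), 0.12)
  g[3, 3] <- 0L
  expect_equal(growth_rate(g, d, k = 0, s = 0.2, c(3, 3)), 0)
  expect_error(growth_rate(g, d, k = 0, s = 0, c(2, 1)), "not occupied")
})

test_that("sim_config validates parameters and requires a seed", {
  expect_error(sim_config(rho = 1.3, seed = 1))
  expect_error(sim_config(s = -1, seed = 1))
  expect_error(sim_config(mu = 2, seed = 1))
  expect_error(sim_config(n_target = 1000, seed = NULL), "seed")
  expect_error(sim_config("radial", L = 10, n_target = 1000, seed = 1),
               "capacity")
  cfg <- sim_config(n_target = 1e4, seed = 3)
  expect_gte(cfg$L, 5 * sqrt(1e4 / pi))  # colony cannot touch the edge
})

test_that("fixture-scale stepping matches enumerated probabilities", {
  # founder with 4 free neighbours: uniform 1/4 placement
  fx <- make_fixture("founder4")
  set.seed(11)
  hits <- integer(4)
  for (i in 1:4000) {
    st <- eden_step(fx$state)
    ev <- st$log[1, ]
    j <- which(fx$expected$daughters$x == ev$daughter_x &
                 fx$expected$daughters$y == ev$daughter_y)
    expect_length(j, 1)
    hits[j] <- hits[j] + 1L
  }
  p <- hits / 4000
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(p - 0.25) < 4 * se))

  # WT vs MT(s = 0.2) mothers selected at odds 1 : 1.2
  fx2 <- make_fixture("two-rates")
  set.seed(12)
  mt <- 0
  for (i in 1:4000) {
    st <- eden_step(fx2$state)
    if (st$log$clone_id[1] > 0) mt <- mt + 1
  }
  p_mt <- mt / 4000
  se <- sqrt(prod(fx2$expected$mother_odds) / 4000)
  expect_lt(abs(p_mt - fx2$expected$mother_odds["mt"]), 4 * se)

  # founder ringed by impassable obstacles: pinned at size 1
  fx3 <- make_fixture("obstacle-ring")
  st <- eden_step(fx3$state)
  expect_true(st$pinned)
  expect_equal(sum(!is.na(st$grid)), 1)
})

test_that("compiled first-event placement matches the uniform oracle", {
  p <- first_event_frequencies(n = 8000)
  expect_length(p, 4)
  se <- sqrt(0.25 * 0.75 / 8000)
  expect_true(all(abs(p - 0.25) < 4 * se))
})

test_that("mu = 1 boundary: every wild-type daughter mutates", {
  res <- run_colony(sim_config(mu = 1, n_target = 50, seed = 5))
  # every daughter is a mutant: fresh clone from a WT mother, inherited
  # clone id otherwise
  expect_true(all(res$log$clone_id > 0))
  expect_equal(sum(res$log$mutated), res$n_clones)
  wt_mothers <- res$log$mother_x == res$config$L %/% 2 + 1 &
    res$log$mother_y == res$config$H %/% 2 + 1
  expect_identical(res$log$mutated, wt_mothers)
})

test_that("runs terminate by the documented conditions", {
  r1 <- run_colony(sim_config(rho = 0, n_target = 1000, seed = 1))
  expect_identical(r1$terminated_by, "reached_n")
  expect_equal(r1$n_occupied, 1000)

  # rho = 1 with protected founder: pinned at size 1
  r2 <- run_colony(sim_config(rho = 1, k = 0, L = 21,
                              n_target = 441, seed = 1))
  expect_identical(r2$terminated_by, "pinned")
  expect_equal(r2$n_occupied, 1)

  # k = 0 far above threshold: pinned before target in most runs
  pins <- vapply(1:20, function(s) {
    run_colony(sim_config(rho = 0.5, k = 0, L = 101, n_target = 4000,
                          seed = 100 + s))$terminated_by
  }, character(1))
  expect_gt(mean(pins == "pinned"), 0.75)

  # undersized lattice: edge flag, not silent truncation
  r3 <- run_colony(sim_config(rho = 0, L = 21, n_target = 441,
                              seed = 2))
  expect_identical(r3$terminated_by, "edge")
})

test_that("replaying the log reconstructs the final state exactly", {
  res <- small_colony()
  expect_true(replay_log(res))
  expect_equal(nrow(res$log), res$n_occupied - res$n_initial)

  lin <- run_linear(sim_config("linear", L = 24, rho = 0.2, k = 0.5,
                               mu = 0.01, height_target = 15, seed = 8))
  expect_true(replay_log(lin))
})

test_that("k = 1 disorder is neutral: bit-identical trajectories", {
  a <- run_colony(sim_config(rho = 0, k = 1, s = 0.1, mu = 0.01,
                             L = 61, n_target = 800, seed = 42))
  b <- run_colony(sim_config(rho = 0.7, k = 1, s = 0.1, mu = 0.01,
                             L = 61, n_target = 800, seed = 42))
  expect_identical(a$log, b$log)
  expect_identical(a$grid, b$grid)
  expect_identical(a$t_now, b$t_now)
})

test_that("clone areas partition the mutant population", {
  res <- small_colony()
  cl <- collect_clones(res)
  expect_equal(sum(cl$area), sum(res$grid > 0, na.rm = TRUE))
  expect_equal(sum(cl$area) / res$n_occupied, mutant_frequency(res),
               tolerance = 1e-12)
  expect_equal(max(res$grid, na.rm = TRUE), res$n_clones)
})

test_that("time advances by 1/(sum of eligible rates)", {
  # single founder, 4 free neighbours, rate 1 -> first dt = 1
  res <- run_colony(sim_config(rho = 0, n_target = 3, L = 11, seed = 1))
  expect_equal(res$log$time[1], 1)
  # after the first division: two eligible WT sites, dt = 1/2
  expect_equal(res$log$time[2] - res$log$time[1], 0.5)
})

test_that("mean time to fixed N is nondecreasing in rho at k = 0", {
  mean_t <- function(rho) {
    tt <- c()
    for (s in 1:12) {
      r <- run_colony(sim_config(rho = rho, k = 0, L = 81,
                                 n_target = 800, seed = 600 + s))
      if (r$terminated_by == "reached_n") tt <- c(tt, r$t_now)
    }
    mean(tt)
  }
  t0 <- mean_t(0); t2 <- mean_t(0.2); t35 <- mean_t(0.35)
  expect_lt(t0, t2)
  expect_lt(t2, t35)
})
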