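test_that("lineage trees cover the population and reach the root", {
  res <- run_colony(sim_config(mu = 0.01, n_target = 400, seed = 21))
  tree <- build_tree(res)
  occupied <- which(!is.na(res$grid)) - 1L  # 0-based flat indices
  expect_equal(sum(!is.na(tree$depth)), res$n_occupied)
  expect_setequal(which(!is.na(tree$depth)) - 1L, occupied)
  # every leaf walks back to the founder
  for (leaf in tree$leaves[seq_len(min(20, length(tree$leaves)))]) {
    node <- leaf
    steps <- 0
    while (tree$parent[node + 1] >= 0 && steps < 1e5) {
      # birth times decrease strictly toward the root
      expect_lt(tree$birth_time[tree$parent[node + 1] + 1],
                tree$birth_time[node + 1])
      node <- tree$parent[node + 1]
      steps <- steps + 1
    }
    expect_equal(node, tree$root)
  }
  # single-site colony: tree is the root alone
  res1 <- run_colony(sim_config(rho = 1, k = 0, L = 21, n_target = 441,
                                seed = 1))
  tr1 <- build_tree(res1)
  expect_equal(sum(!is.na(tr1$depth)), 1)
})

test_that("MRCA matches brute-force path intersection on small trees", {
  res <- run_colony(sim_config(mu = 0.02, n_target = 90, seed = 33))
  tree <- build_tree(res)
  path_to_root <- function(node) {
    out <- node
    while (tree$parent[node + 1] >= 0) {
      node <- tree$parent[node + 1]
      out <- c(out, node)
    }
    out
  }
  brute_mrca <- function(a, b) {
    pa <- path_to_root(a)
    pb <- path_to_root(b)
    common <- intersect(pa, pb)
    # the first common node along a's path is the MRCA
    pa[match(TRUE, pa %in% common)]
  }
  leaves <- tree$leaves
  tab <- pair_coalescence(tree, pair_budget = 1e9)
  # full enumeration emits pairs in nested (a, b > a) order
  expected_t2 <- c()
  for (a in seq_along(leaves)) {
    b <- seq_along(leaves)[-seq_len(a)]
    for (j in b) {
      m <- brute_mrca(leaves[a], leaves[j])
      expected_t2 <- c(expected_t2,
                       tree$t_total - tree$birth_time[m + 1])
    }
  }
  expect_equal(nrow(tab), choose(length(leaves), 2))
  expect_equal(tab$t2, expected_t2, tolerance = 1e-12)
  # global consistency: every pair's T2 is bounded by the total time
  expect_true(all(tab$t2 <= tree$t_total + 1e-12))
  expect_true(all(tab$t2 > 0))
})

test_that("straight lineages have zero transverse deviation", {
  # hand-built log: a single file of cells marching east from the founder
  L <- 21L
  cfg <- sim_config("radial", L = L, n_target = 8, seed = 1)
  grid <- matrix(NA_integer_, L, L)
  c0 <- L %/% 2 + 1L
  grid[c0, c0:(c0 + 7L)] <- 0L
  log <- data.frame(index = 1:7, time = as.numeric(1:7),
                    mother_x = c0:(c0 + 6L), mother_y = c0,
                    daughter_x = (c0 + 1L):(c0 + 7L), daughter_y = c0,
                    clone_id = 0L, mutated = FALSE)
  res <- structure(list(config = cfg, grid = grid,
                        disorder = matrix(FALSE, L, L),
                        log = log, t_now = 7, n_occupied = 8L,
                        n_initial = 1L, terminated_by = "reached_n"),
                   class = "eden_result")
  tree <- build_tree(res, front = data.frame(x = c0 + 7L, y = c0))
  b <- heterospread:::pool_lineage_bins(tree, 7L, "generations", 0L,
                                        FALSE)
  expect_true(all(b$sumsq == 0))
  expect_true(any(b$count > 0))
})

test_that("sibling pairs coalesce at the mother's division time", {
  res <- run_colony(sim_config(n_target = 60, seed = 61))
  tree <- build_tree(res)
  log <- res$log
  di <- (log$daughter_x - 1L) * tree$H + (log$daughter_y - 1L)
  # find two front leaves that share a mother
  mi <- (log$mother_x - 1L) * tree$H + (log$mother_y - 1L)
  leaf_ev <- match(tree$leaves, di)
  sib <- which(!is.na(leaf_ev))
  mothers <- mi[leaf_ev[sib]]
  dup <- mothers[duplicated(mothers)]
  skip_if(length(dup) == 0, "no sibling front pair in this colony")
  pairk <- sib[mothers == dup[1]][1:2]
  a <- tree$leaves[pairk[1]]; b <- tree$leaves[pairk[2]]
  tab <- pair_coalescence(tree, pair_budget = 1e9)
  # their MRCA is the shared mother: T2 = t_total - max(child birth)?
  # no: T2 = t_total - birth_time(mother)
  expected <- tree$t_total - tree$birth_time[dup[1] + 1]
  dxab <- sqrt((a %/% tree$H - b %/% tree$H)^2 +
                 (a %% tree$H - b %% tree$H)^2)
  expect_true(any(abs(tab$t2 - expected) < 1e-9 &
                    abs(tab$dx - dxab) < 1e-9))
})

test_that("persistence curves are proper survival functions", {
  res <- run_colony(sim_config(mu = 0.005, n_target = 2000, seed = 71))
  tree <- build_tree(res)
  tab <- pair_coalescence(tree, pair_budget = 5000)
  u <- persistence_curve(tab, dx_cutoff = 0.3)
  expect_equal(u$u[1], 1)           # U at T2 = 0
  expect_true(all(diff(u$u) <= 0))  # nonincreasing
  expect_equal(u$u[nrow(u)], 0)     # reaches 0 at the largest time
  expect_error(persistence_curve(tab, dx_cutoff = 0), "no pairs")
})

test_that("disorder shortens coalescence and lowers persistence", {
  stats_for <- function(rho, seed) {
    m <- measure_radial_ensemble(rho = rho, k = 0, n_target = 1.5e4,
                                 mu = 5e-4, n_colonies = 8, seed = seed,
                                 pair_budget = 4000)
    m
  }
  m0 <- stats_for(0, 81)
  m4 <- stats_for(0.4, 82)
  # at matched mid-range distances the mean normalized T2 is smaller
  # with obstacles: lineages from distant regions coalesce earlier
  joint <- merge(m0$t2_profile, m4$t2_profile, by = "dx_mid",
                 suffixes = c("_0", "_4"))
  joint <- joint[joint$dx_mid >= 0.1 & joint$dx_mid <= 0.6, ]
  expect_gt(mean(joint$t2_mean_0 - joint$t2_mean_4), 0)
  # and the persistence of close pairs is lower with obstacles
  mid <- seq(0.05, 0.95, by = 0.1)
  u0 <- approx(m0$persistence$t2, m0$persistence$u, xout = mid)$y
  u4 <- approx(m4$persistence$t2, m4$persistence$u, xout = mid)$y
  expect_gt(mean(u0 - u4, na.rm = TRUE), 0)
})

test_that("pooling order does not change the pooled rms curve", {
  res1 <- run_colony(sim_config(mu = 0.005, n_target = 1500, seed = 91))
  res2 <- run_colony(sim_config(mu = 0.005, n_target = 1500, seed = 92))
  t1 <- build_tree(res1); t2 <- build_tree(res2)
  pooled <- lineage_fluctuations(list(t1, t2), fit_window = c(2, 10))
  a <- lineage_fluctuations(t1, fit_window = c(2, 10))
  b <- lineage_fluctuations(t2, fit_window = c(2, 10))
  # recombine per-colony sums: rms over the union equals the pooled rms
  tmax <- min(max(a$curve$t), max(b$curve$t))
  for (t in c(2, 5, tmax)) {
    ra <- a$curve[a$curve$t == t, ]
    rb <- b$curve[b$curve$t == t, ]
    rp <- pooled$curve[pooled$curve$t == t, ]
    if (nrow(ra) && nrow(rb) && nrow(rp)) {
      manual <- sqrt((ra$l_perp^2 * ra$n + rb$l_perp^2 * rb$n) /
                       (ra$n + rb$n))
      expect_equal(rp$l_perp, manual, tolerance = 1e-12)
    }
  }
})
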