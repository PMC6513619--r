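test_that("the exponential fit is exact on noiseless tables", {
  s <- c(-0.1, -0.05, 0, 0.05, 0.1, 0.15, 0.2)
  tab <- data.frame(s = s, f_mt = 0.01 * exp(5 * s))
  ft <- fit_selection(tab)
  expect_equal(ft$f0, 0.01, tolerance = 1e-10)
  expect_equal(ft$ks, 5, tolerance = 1e-10)

  flat <- data.frame(s = s, f_mt = 0.03)
  ff <- fit_selection(flat)
  expect_equal(ff$ks, 0, tolerance = 1e-10)
  expect_equal(ff$f0, 0.03, tolerance = 1e-10)

  expect_error(fit_selection(data.frame(s = c(0, 0.1),
                                        f_mt = c(0.1, 0.2))), ">= 3")
  expect_error(fit_selection(data.frame(s = s, f_mt = -abs(s))), ">= 3")
})

test_that("fit_selection is scale-equivariant", {
  set.seed(5)
  s <- seq(-0.1, 0.2, by = 0.05)
  tab <- data.frame(s = s,
                    f_mt = 0.02 * exp(8 * s) * exp(rnorm(length(s),
                                                         0, 0.1)))
  f1 <- fit_selection(tab)
  tab2 <- tab; tab2$f_mt <- tab2$f_mt * 3.7
  f2 <- fit_selection(tab2)
  expect_equal(f2$f0, 3.7 * f1$f0, tolerance = 1e-10)
  expect_equal(f2$ks, f1$ks, tolerance = 1e-10)
})

test_that("fits recover parameters within their confidence intervals", {
  set.seed(17)
  s <- seq(-0.15, 0.2, by = 0.05)
  crit <- qt(0.975, df = length(s) - 2)  # 95% CI on few points
  hits <- replicate(60, {
    f0 <- 0.05; ks <- 12
    f_mt <- f0 * exp(ks * s) * exp(rnorm(length(s), 0, 0.15))
    ft <- fit_selection(data.frame(s = s, f_mt = f_mt),
                        weighted = FALSE)
    abs(ft$ks - ks) < crit * ft$ks_stderr
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the master-curve rescaling collapses synthetic sweeps", {
  set.seed(23)
  s <- seq(-0.1, 0.2, by = 0.05)
  tables <- lapply(1:4, function(i) {
    data.frame(rho = i / 10, k = 0.1, s = s,
               f_mt = (0.01 * i) * exp((3 * i) * s) *
                 exp(rnorm(length(s), 0, 0.05)))
  })
  rc <- rescale_master_curve(tables)
  expect_lt(rc$rms_log_dev, 0.3)
  one <- rescale_master_curve(tables[1])
  expect_equal(one$rms_log_dev,
               sqrt(mean((log(one$points$y) - one$points$x)^2)))
})

test_that("the two-sided exponential DFE is normalized and shaped", {
  for (p in list(c(0.03, 2), c(0.05, 1.25), c(0.02, 0))) {
    s_bar <- p[1]; R <- p[2]
    total <- integrate(dfe_density, -Inf, Inf, s_bar = s_bar, R = R,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
    if (R > 0) {
      neg <- integrate(dfe_density, -Inf, 0, s_bar = s_bar, R = R,
                       rel.tol = 1e-9)$value
      expect_equal(neg, R / (1 + R), tolerance = 1e-6)
    }
    # conditional mean of beneficial effects is s_bar
    m1 <- integrate(function(s) s * dfe_density(s, s_bar, R), 0, Inf,
                    rel.tol = 1e-9)$value
    mass <- 1 / (1 + R)
    expect_equal(m1 / mass, s_bar, tolerance = 1e-6)
  }
  expect_error(dfe_density(0.1, s_bar = -1, R = 2))
})

test_that("rate of adaptation obeys the analytic constant-fMT identity", {
  s <- seq(-0.3, 0.3, by = 0.01)
  for (p in list(c(0.03, 2), c(0.05, 0.5))) {
    tab <- data.frame(s = s, f_mt = 0.07)
    r <- rate_of_adaptation(tab, s_bar = p[1], R = p[2])
    expect_equal(r$rate, 0.07 * p[1] * (1 - p[2]), tolerance = 0.01)
  }
  # R = 1: beneficial and deleterious contributions cancel
  r1 <- rate_of_adaptation(data.frame(s = s, f_mt = 0.05),
                           s_bar = 0.03, R = 1)
  expect_equal(r1$rate, 0, tolerance = 1e-5)
  # linearity in f_MT
  tab1 <- data.frame(s = s, f_mt = 0.01 * exp(5 * s))
  tab2 <- tab1; tab2$f_mt <- 2 * tab1$f_mt
  expect_equal(rate_of_adaptation(tab2, 0.03, 2)$rate,
               2 * rate_of_adaptation(tab1, 0.03, 2)$rate,
               tolerance = 1e-10)
  # insufficient tabulated range for a wide DFE
  expect_error(rate_of_adaptation(data.frame(s = c(-0.02, 0, 0.02),
                                             f_mt = 0.1),
                                  s_bar = 0.05, R = 2), "mass")
})

test_that("adaptation flips sign as selection efficacy vanishes", {
  s <- seq(-0.3, 0.3, by = 0.01)
  # efficient selection (ks = 15): adaptation wins despite more
  # deleterious mutations (R = 2)
  strong <- data.frame(s = s, f_mt = 0.02 * exp(15 * s))
  weak <- data.frame(s = s, f_mt = 0.02)  # ks = 0 near the threshold
  expect_gt(rate_of_adaptation(strong, s_bar = 0.03, R = 2)$rate, 0)
  expect_lt(rate_of_adaptation(weak, s_bar = 0.03, R = 2)$rate, 0)
  sweep <- rbind(cbind(rho = 0, k = 0, strong),
                 cbind(rho = 0.4, k = 0, weak))
  out <- adaptation_sweep(sweep, s_bar = 0.03, R = 2)
  expect_equal(out$rate_norm[out$rho == 0], 1)
  expect_lt(out$rate_norm[out$rho == 0.4], 0)
})

test_that("mu = 0 sweeps yield identically zero mutant frequencies", {
  tab <- sweep_fmt(s_grid = c(0, 0.1), rho = 0, k = 0, n_target = 400,
                   mu = 0, reps = 3, seed = 9)
  expect_true(all(tab$f_mt == 0))
  expect_true(all(tab$n_reps == 3))
})
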