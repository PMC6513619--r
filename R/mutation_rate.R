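#' Simulate a replicate plating experiment
#'
#' Emulates the fluctuation-style assay behind the mutation-rate
#' inference: each replicate population starts from a Poisson number of
#' wild-type cells (zero draws are redrawn) and grows for `generations`
#' discrete doublings, so about 10 cells become about 1000 over 7
#' generations. Each wild-type division produces a mutant daughter with
#' probability `mu` (binomial per generation); mutant counts grow by the
#' expected-offspring factor `2^(1 + s)` per generation, i.e. at
#' relative rate `1 + s`. Returns the final mutant fraction of each
#' replicate.
#'
#' @param mu per-division mutation (plasmid-loss) probability.
#' @param s mutant selection coefficient (`1 + s > 0`).
#' @param n_pops number of replicate populations.
#' @param lambda0 mean initial cell number (Poisson).
#' @param generations number of growth generations.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return numeric vector of `n_pops` mutant fractions in `[0, 1]`.
#' @export
simulate_plating <- function(mu, s = 0, n_pops = 48, lambda0 = 10,
                             generations = 7, seed = NULL) {
  stopifnot(mu >= 0, mu <= 1, 1 + s > 0)
  sim <- function() {
    n0 <- rpois(n_pops, lambda0)
    while (any(n0 == 0)) n0[n0 == 0] <- rpois(sum(n0 == 0), lambda0)
    wt <- as.numeric(n0)
    mt <- numeric(n_pops)
    gf <- 2^(1 + s)
    for (g in seq_len(generations)) {
      m <- rbinom(n_pops, size = round(wt), prob = mu)
      wt <- 2 * wt - m
      mt <- mt * gf + m
    }
    mt / (mt + wt)
  }
  if (is.null(seed)) sim() else with_seed(seed, sim())
}

#' Histogram log-likelihood of observed mutant fractions
#'
#' The sampling density `f(x | theta)` is estimated from a simulated
#' ensemble at `theta` by a fixed-bin histogram on `[0, 1]`; empty bins
#' are floored at one count (add-one smoothing) so every observation
#' has finite log-density. The log-likelihood is the sum of log
#' densities of the observations.
#'
#' @param observations observed mutant fractions in `[0, 1]`.
#' @param sims simulated fractions from [simulate_plating()] at the
#'   candidate parameters.
#' @param n_bins number of equal-width histogram bins on `[0, 1]`. The
#' default 200 resolves the small mutant fractions typical of these
#' experiments; much coarser histograms visibly bias the estimate
#' upward.
#' @return the log-likelihood value.
#' @export
plating_log_likelihood <- function(observations, sims, n_bins = 200) {
  stopifnot(all(observations >= 0 & observations <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(sims, edges, rightmost.closed = TRUE),
                  nbins = n_bins)
  cnt <- pmax(cnt, 1)
  dens <- cnt / (length(sims) * (1 / n_bins))
  b <- findInterval(observations, edges, rightmost.closed = TRUE)
  sum(log(dens[b]))
}

#' Simulation-based maximum-likelihood mutation-rate inference
#'
#' Profiles the histogram log-likelihood over a grid of `(mu, s)`,
#' simulating `sims_per_theta` replicate experiments per grid point and
#' treating `s` as a free nuisance parameter. The estimate is the grid
#' maximizer; its uncertainty is the curvature rule
#' `delta_mu = 1 / sqrt(|d^2 l / d mu^2|)` applied to the profile
#' likelihood over `s` (a local quadratic fit around the maximizer,
#' robust to Monte Carlo noise). A maximizer on the `mu` grid boundary
#' is flagged (widen the grid).
#'
#' @param observations observed mutant fractions (or a data.frame with
#'   `wt_count` and `mt_count` columns, converted to fractions).
#' @param mu_grid,s_grid parameter grids; defaults are 25 log-spaced
#'   `mu` values over `10^-3.5 .. 10^-1.5` and `s` from -0.1 to 0.4 in
#'   steps of 0.05.
#' @param sims_per_theta simulated experiments per grid point.
#' @param lambda0,generations experiment shape, see
#'   [simulate_plating()].
#' @param n_bins histogram bins.
#' @param seed master seed (one derived seed per grid point).
#' @return list with `mu_star`, `s_star`, `delta_mu`, `boundary`
#'   (flag), and `grid` (data.frame `mu`, `s`, `loglik`).
#' @export
ml_infer_mu <- function(observations,
                        mu_grid = 10^seq(-3.5, -1.5, length.out = 25),
                        s_grid = seq(-0.1, 0.4, by = 0.05),
                        sims_per_theta = 5000,
                        lambda0 = 10, generations = 7,
                        n_bins = 200, seed) {
  if (is.data.frame(observations)) {
    if (!is.null(observations$mutant_fraction))
      observations <- observations$mutant_fraction
    else observations <- observations$mt_count /
        (observations$mt_count + observations$wt_count)
  }
  n_obs <- length(observations)
  grid <- expand.grid(mu = mu_grid, s = s_grid)
  grid$loglik <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sims <- simulate_plating(grid$mu[i], grid$s[i],
                             n_pops = sims_per_theta,
                             lambda0 = lambda0,
                             generations = generations,
                             seed = fan_seed(seed, i))
    grid$loglik[i] <- plating_log_likelihood(observations, sims, n_bins)
  }
  best <- which.max(grid$loglik)
  mu_star <- grid$mu[best]; s_star <- grid$s[best]
  imu <- match(mu_star, mu_grid)
  # s is a nuisance parameter; only a mu-boundary maximizer is flagged
  boundary <- imu == 1 || imu == length(mu_grid)
  # curvature of the profile likelihood along mu (s maximized out, as
  # it is a nuisance parameter): local quadratic over up to +-3 grid
  # points, robust to Monte Carlo noise
  delta_mu <- NA_real_
  if (imu > 1 && imu < length(mu_grid)) {
    l <- vapply(mu_grid, function(m)
      max(grid$loglik[grid$mu == m]), numeric(1))
    win <- max(1, imu - 3):min(length(mu_grid), imu + 3)
    qf <- lm(l[win] ~ poly(mu_grid[win], 2, raw = TRUE))
    d2 <- 2 * coef(qf)[3]
    if (is.finite(d2) && d2 < 0) delta_mu <- 1 / sqrt(abs(d2))
  }
  list(mu_star = mu_star, s_star = s_star, delta_mu = delta_mu,
       boundary = boundary, n_obs = n_obs, grid = grid)
}
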