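#' Ensemble sweep of the final mutant frequency over selection
#'
#' Runs `reps` independent seeded colonies for every value of `s` at
#' fixed `(rho, k)` and records the mean and standard error of the
#' final mutant frequency. Runs that hit the event cap or the lattice
#' border are excluded with a warning; pinned runs are kept (their
#' final state is the trapped colony).
#'
#' @param s_grid selection coefficients; the default mirrors an
#'   experimental range from +20% benefit to -15% cost.
#' @param rho,k disorder density and transparency.
#' @param n_target colony size at which runs stop.
#' @param mu mutation probability per wild-type division.
#' @param reps replicates per `s`.
#' @param seed master seed.
#' @param L optional lattice side override.
#' @return data.frame `rho`, `k`, `s`, `f_mt`, `stderr`, `n_reps`.
#' @export
sweep_fmt <- function(s_grid = c(-0.15, -0.1, -0.05, 0, 0.05, 0.1,
                                 0.15, 0.2),
                      rho = 0, k = 0, n_target = 1e5, mu = 5e-4,
                      reps = 20, seed, L = NULL) {
  rows <- lapply(seq_along(s_grid), function(i) {
    f <- rep(NA_real_, reps)
    dropped <- 0L
    for (r in seq_len(reps)) {
      cfg <- sim_config("radial", rho = rho, k = k, s = s_grid[i],
                        mu = mu, n_target = n_target, L = L,
                        seed = fan_seed(seed, i, r))
      res <- run_colony(cfg, keep_log = FALSE)
      if (res$terminated_by %in% c("max_events", "edge")) {
        dropped <- dropped + 1L
        next
      }
      f[r] <- mutant_frequency(res)
    }
    if (dropped > 0)
      warning(sprintf("s = %g: %d run(s) excluded (cap or edge)",
                      s_grid[i], dropped))
    f <- f[!is.na(f)]
    data.frame(rho = rho, k = k, s = s_grid[i],
               f_mt = mean(f),
               stderr = if (length(f) > 1) sd(f) / sqrt(length(f))
                        else NA_real_,
               n_reps = length(f))
  })
  do.call(rbind, rows)
}

#' Fit the selection-response parametrization fMT(s) = f0 * exp(ks * s)
#'
#' Exactly linear in log space, so the fit is (weighted) least squares
#' of `log(f_mt)` on `s`; weights come from the per-point standard
#' errors via the delta method (`se(log f) = se(f) / f`). `f0` is the
#' neutral diversity (mutant frequency at `s = 0`) and `ks` the
#' selection efficacy, an inverse selection scale.
#'
#' @param table a sweep table with columns `s`, `f_mt` and optionally
#'   `stderr`.
#' @param weighted use the delta-method weights (default) or ordinary
#'   least squares?
#' @return list with `f0`, `ks`, `f0_stderr`, `ks_stderr`, `cov` (2x2,
#'   on the `(log f0, ks)` scale), `fit`.
#' @export
fit_selection <- function(table, weighted = TRUE) {
  keep <- is.finite(table$f_mt) & table$f_mt > 0
  if (sum(keep) < 3) stop("need >= 3 s-points with positive mean f_mt")
  if (length(unique(table$s[keep])) < 2) stop("degenerate s grid")
  s <- table$s[keep]
  ly <- log(table$f_mt[keep])
  w <- NULL
  if (weighted && !is.null(table$stderr) &&
      all(is.finite(table$stderr[keep])) && all(table$stderr[keep] > 0))
    w <- (table$f_mt[keep] / table$stderr[keep])^2
  fit <- if (is.null(w)) lm(ly ~ s) else lm(ly ~ s, weights = w)
  cf <- coef(fit)
  V <- suppressWarnings(vcov(fit))  # exact tables fit perfectly
  list(f0 = unname(exp(cf[1])), ks = unname(cf[2]),
       f0_stderr = unname(exp(cf[1]) * sqrt(V[1, 1])),
       ks_stderr = unname(sqrt(V[2, 2])),
       cov = V, fit = fit)
}

#' Collapse sweep tables onto the exponential master curve
#'
#' Rescales every `(s, f_mt)` point by its table's fitted `(f0, ks)` to
#' `(ks * s, f_mt / f0)`; on the master curve these satisfy
#' `f_mt / f0 = exp(ks * s)`. The reported rms deviation is measured in
#' natural-log units about that curve.
#'
#' @param tables list of sweep tables (one per `(rho, k)` condition).
#' @param fits matching list of [fit_selection()] results; fitted here
#'   if omitted.
#' @return list with `points` (data.frame `x = ks*s`,
#'   `y = f_mt / f0`, `rho`, `k`) and `rms_log_dev`.
#' @export
rescale_master_curve <- function(tables, fits = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (is.null(fits)) fits <- lapply(tables, fit_selection)
  if (length(fits) != length(tables)) stop("one fit per table required")
  pts <- do.call(rbind, Map(function(tb, ft) {
    keep <- is.finite(tb$f_mt) & tb$f_mt > 0
    data.frame(x = ft$ks * tb$s[keep], y = tb$f_mt[keep] / ft$f0,
               rho = tb$rho[keep], k = tb$k[keep])
  }, tables, fits))
  list(points = pts,
       rms_log_dev = sqrt(mean((log(pts$y) - pts$x)^2)))
}

#' Two-sided exponential distribution of fitness effects
#'
#' `D(s) = exp(-s / s_bar) / (s_bar * (1 + R))` for beneficial effects
#' (`s > 0`) and `D(s) = exp(-|s| / (s_bar * R)) / (s_bar * (1 + R))`
#' for deleterious ones, so the beneficial mean is `s_bar`, the
#' deleterious mean `s_bar * R`, the density integrates to 1 and `R` is
#' the total deleterious-to-beneficial frequency ratio (mass fractions
#' `1 / (1 + R)` and `R / (1 + R)`). `R = 0` degenerates to a purely
#' beneficial exponential.
#'
#' @param s numeric vector of effects.
#' @param s_bar mean beneficial effect (> 0).
#' @param R deleterious-to-beneficial ratio (>= 0).
#' @return density values.
#' @export
dfe_density <- function(s, s_bar, R) {
  stopifnot(s_bar > 0, R >= 0)
  norm <- 1 / (s_bar * (1 + R))
  ifelse(s >= 0, norm * exp(-s / s_bar),
         if (R > 0) norm * exp(s / (s_bar * R)) else 0)
}

#' DFE-weighted rate of adaptation
#'
#' Numerically evaluates `integral D(s) * s * fMT(s) ds` from a
#' tabulated sweep: the table is linearly interpolated on a grid of
#' step `ds` and integrated by the trapezoid rule; beyond the tabulated
#' range `fMT` is held at its boundary values and the exponential tails
#' are added in closed form. Positive values mean net adaptation,
#' negative values net accumulation of deleterious mutations
#' (expansion load).
#'
#' @param table sweep table with `s` and `f_mt` (single condition).
#' @param s_bar,R DFE parameters, see [dfe_density()].
#' @param ds interpolation step.
#' @param tail_tol maximal DFE mass allowed beyond the tabulated range
#'   before an error is raised (the closed-form tail correction assumes
#'   constant `fMT` there, which is only safe for small mass).
#' @return list with `rate` and the `tail_mass` outside the table.
#' @export
rate_of_adaptation <- function(table, s_bar, R, ds = 0.005,
                               tail_tol = 0.01) {
  stopifnot(all(is.finite(table$f_mt)))
  o <- order(table$s)
  s <- table$s[o]; f <- table$f_mt[o]
  lo <- min(s); hi <- max(s)
  tail_mass <- if (R > 0) (R / (1 + R)) * exp(lo / (s_bar * R)) else 0
  tail_mass <- tail_mass + exp(-hi / s_bar) / (1 + R)
  if (tail_mass > tail_tol)
    stop(sprintf("DFE mass beyond the tabulated s-range is %.3g (> %g)",
                 tail_mass, tail_tol))
  grid <- seq(lo, hi, by = ds)
  fg <- approx(s, f, xout = grid)$y
  ig <- dfe_density(grid, s_bar, R) * grid * fg
  core <- sum((head(ig, -1) + tail(ig, -1)) / 2 * diff(grid))
  # closed-form exponential tails with fMT frozen at the edge values
  up <- f[length(f)] * (hi + s_bar) * exp(-hi / s_bar) / (1 + R)
  dn <- if (R > 0)
    -f[1] * R * (abs(lo) + s_bar * R) * exp(lo / (s_bar * R)) / (1 + R)
  else 0
  list(rate = core + up + dn, tail_mass = tail_mass)
}

#' Rate of adaptation across a heterogeneity sweep, normalized
#'
#' Applies [rate_of_adaptation()] to every `(rho, k)` condition in a
#' combined sweep table and normalizes by the value at the smallest
#' `rho` (the homogeneous maximum).
#'
#' @param tables combined sweep table (rows over `rho`, `k`, `s`).
#' @inheritParams rate_of_adaptation
#' @return data.frame `rho`, `k`, `rate_raw`, `rate_norm`.
#' @export
adaptation_sweep <- function(tables, s_bar, R, ds = 0.005) {
  key <- interaction(tables$rho, tables$k, drop = TRUE)
  rows <- lapply(split(tables, key), function(tb) {
    data.frame(rho = tb$rho[1], k = tb$k[1],
               rate_raw = rate_of_adaptation(tb, s_bar, R, ds)$rate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ref <- out$rate_raw[which.min(out$rho)]
  out$rate_norm <- out$rate_raw / ref
  out
}
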