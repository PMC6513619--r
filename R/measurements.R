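# Ensemble-level measurement protocols. These compose the module-level
# operations into the standard study conditions (linear ensembles for
# roughness exponents, radial ensembles for lineage and clone scaling)
# and are shared by the experiment plans and the reproduction script.

#' Interface growth and roughness exponents from a linear ensemble
#'
#' Runs `reps` independent linear-front simulations, records the global
#' width at log-spaced mean-height checkpoints in flight, and averages
#' `W_G^2` across runs. The growth exponent `beta` is fitted over the
#' central decade of mean height before `W_G` reaches 80% of its
#' saturation value (or of its final value if the runs stop before
#' saturating). The local roughness exponent `alpha_loc` is fitted on
#' the run-averaged local width `W_loc(l)` of the final profiles over
#' window sizes `l` in `[4, L/8]`.
#'
#' @param rho,k disorder density and transparency.
#' @param L front width (periodic).
#' @param height_target mean front height at which runs stop; default
#'   `6 * L^1.5` (well past the Family-Vicsek crossover) for `rho = 0`
#'   and `1000` otherwise (growth regime).
#' @param reps number of runs.
#' @param seed master seed.
#' @param n_checkpoints number of log-spaced width checkpoints.
#' @return list with `beta`, `beta_stderr`, `beta_window`, `alpha_loc`,
#'   `alpha_loc_stderr`, `global` (data.frame `hbar`, `w_g`), `local`
#'   (data.frame `l`, `w_loc`), `w_sat`, `n_runs`.
#' @export
measure_interface_exponents <- function(rho = 0, k = 0, L = 256,
                                        height_target = NULL,
                                        reps = 12, seed = 1,
                                        n_checkpoints = 60) {
  if (is.null(height_target))
    height_target <- if (rho == 0) 6 * L^1.5 else 1000
  cks <- unique(10^seq(0, log10(height_target * 0.999),
                       length.out = n_checkpoints))
  wsum <- numeric(length(cks)); hsum <- numeric(length(cks))
  wcnt <- numeric(length(cks))
  lsum <- NULL
  n_ok <- 0L
  for (r in seq_len(reps)) {
    cfg <- sim_config("linear", rho = rho, k = k, L = L,
                      height_target = height_target,
                      seed = fan_seed(seed, 1, r))
    res <- run_linear(cfg, keep_log = FALSE, wg_checkpoints = cks)
    wc <- res$width_curve
    n <- nrow(wc)
    if (n >= 3) {
      idx <- seq_len(n)
      wsum[idx] <- wsum[idx] + wc$w_g^2
      hsum[idx] <- hsum[idx] + wc$hbar
      wcnt[idx] <- wcnt[idx] + 1
    }
    if (res$terminated_by == "reached_n") {
      iw <- interface_widths(res)
      if (is.null(lsum)) lsum <- iw$local
      else lsum$w_loc <- lsum$w_loc + iw$local$w_loc
      n_ok <- n_ok + 1L
    }
  }
  keep <- wcnt > 0
  glob <- data.frame(hbar = hsum[keep] / wcnt[keep],
                     w_g = sqrt(wsum[keep] / wcnt[keep]),
                     n = wcnt[keep])
  # beta: central decade of hbar before W reaches 80% of saturation
  w_sat <- mean(tail(glob$w_g[glob$n == max(glob$n)], 5))
  pre <- glob[glob$w_g < 0.8 * w_sat & glob$w_g > 0 & glob$hbar > 0, ]
  if (nrow(pre) < 3) stop("no growth regime before saturation")
  m <- (log10(min(pre$hbar)) + log10(max(pre$hbar))) / 2
  bw <- 10^c(m - 0.5, m + 0.5)
  bfit <- fit_power_law(pre$hbar, pre$w_g, window = bw)
  out <- list(beta = bfit$exponent, beta_stderr = bfit$stderr,
              beta_window = bw, w_sat = w_sat, global = glob,
              n_runs = reps)
  if (!is.null(lsum) && n_ok > 0) {
    loc <- data.frame(l = lsum$l, w_loc = lsum$w_loc / n_ok)
    afit <- tryCatch(fit_power_law(loc$l, loc$w_loc,
                                   window = c(4, L / 8)),
                     error = function(e) NULL)  # L too small to fit
    out$alpha_loc <- if (is.null(afit)) NA_real_ else afit$exponent
    out$alpha_loc_stderr <- if (is.null(afit)) NA_real_ else afit$stderr
    out$local <- loc
  } else {
    out$alpha_loc <- NA_real_
    out$alpha_loc_stderr <- NA_real_
    out$local <- NULL
  }
  out
}

#' Lineage and clone statistics from a radial ensemble
#'
#' Grows radial colonies to `n_target` occupied sites (seeds whose runs
#' pin or reach the lattice border are skipped until `n_colonies`
#' complete colonies are collected), then pools over the ensemble: the
#' transverse lineage fluctuations `l_perp(t)` and their exponent `xi`,
#' the pair-coalescence table and its binned `T2(dx)` profile, the
#' persistence curve `U(T2)`, the clone table with the anisotropy
#' exponent `zeta`, and the bubble-size tail exponent.
#'
#' @param rho,k disorder density and transparency.
#' @param n_target colony size.
#' @param mu mutation probability per wild-type division.
#' @param s mutant selection coefficient.
#' @param n_colonies number of complete colonies to pool.
#' @param seed master seed.
#' @param pair_budget pairs per colony for coalescence sampling.
#' @param dx_cutoff normalized distance cutoff of the persistence
#'   curve.
#' @param abscissa,ray,bridge forward-time clock, reference-ray
#'   convention and bridge standardization for the lineage deviations,
#'   see [lineage_fluctuations()].
#' @param max_attempts give up after this many seeds (pinning near the
#'   percolation threshold discards a fraction of runs).
#' @return list with `xi` (fit list), `coalescence` (pooled pair
#'   table), `t2_profile`, `persistence`, `clones`, `zeta` (fit list or
#'   `NULL`), `bubble_tail` (fit list or `NULL`), `f_mt` (per-colony
#'   mutant frequencies), `n_colonies`, `n_attempts`.
#' @export
measure_radial_ensemble <- function(rho = 0, k = 0, n_target = 5e4,
                                    mu = 5e-4, s = 0, n_colonies = 30,
                                    seed = 1, pair_budget = 2e4,
                                    dx_cutoff = 0.05,
                                    abscissa = c("generations",
                                                 "radius"),
                                    ray = c("leaf", "lsq"),
                                    bridge = TRUE,
                                    max_attempts = 20 * n_colonies) {
  abscissa <- match.arg(abscissa)
  ray_mode <- match(match.arg(ray), c("leaf", "lsq")) - 1L
  sumsq <- numeric(0); cnt <- numeric(0)
  pairs <- vector("list", n_colonies)
  clones <- vector("list", n_colonies)
  f_mt <- numeric(n_colonies)
  done <- 0L; attempt <- 0L
  while (done < n_colonies) {
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop("too many pinned/edge runs; raise max_attempts or L")
    cfg <- sim_config("radial", rho = rho, k = k, s = s, mu = mu,
                      n_target = n_target,
                      seed = fan_seed(seed, 1, attempt))
    res <- run_colony(cfg)
    if (res$terminated_by != "reached_n") next
    done <- done + 1L
    front <- extract_front(res)
    tree <- build_tree(res, front)
    tmax <- if (abscissa == "generations") {
      max(tree$depth[tree$leaves + 1])
    } else {
      xs <- tree$leaves %/% tree$H + 1; ys <- tree$leaves %% tree$H + 1
      floor(max(sqrt((xs - tree$center[1])^2 +
                       (ys - tree$center[2])^2)))
    }
    b <- pool_lineage_bins(tree, tmax, abscissa, ray_mode, bridge)
    if (tmax > length(sumsq)) {
      length(sumsq) <- tmax; length(cnt) <- tmax
      sumsq[is.na(sumsq)] <- 0; cnt[is.na(cnt)] <- 0
    }
    idx <- seq_len(tmax)
    sumsq[idx] <- sumsq[idx] + b$sumsq
    cnt[idx] <- cnt[idx] + b$count
    pc <- pair_coalescence(tree, pair_budget)
    pairs[[done]] <- pc[, c("dx_norm", "t2_norm")]
    clones[[done]] <- collect_clones(res, front)
    f_mt[done] <- mutant_frequency(res)
  }
  keep <- cnt > 0
  curve <- data.frame(t = which(keep),
                      l_perp = sqrt(sumsq[keep] / cnt[keep]),
                      n = cnt[keep])
  xi <- lineage_curve_fit(curve)
  pooled_pairs <- do.call(rbind, pairs)
  pooled_clones <- do.call(rbind, clones)
  zeta <- tryCatch(clone_shape_anisotropy(pooled_clones),
                   error = function(e) NULL)
  bt <- tryCatch(fit_bubble_tail(pooled_clones),
                 error = function(e) NULL)
  list(xi = xi,
       coalescence = pooled_pairs,
       t2_profile = coalescence_profile(pooled_pairs),
       persistence = persistence_curve(pooled_pairs, dx_cutoff),
       clones = pooled_clones, zeta = zeta, bubble_tail = bt,
       f_mt = f_mt, n_colonies = done, n_attempts = attempt)
}

#' Lineage statistics only (thin wrapper over the radial ensemble)
#'
#' @inheritParams measure_radial_ensemble
#' @return list with `fluct` (the `xi` fit list), `t2_profile` and
#'   `persistence`.
#' @export
measure_lineage_stats <- function(rho = 0, k = 0, n_target = 5e4,
                                  mu = 5e-4, n_colonies = 30,
                                  seed = 1, ...) {
  m <- measure_radial_ensemble(rho = rho, k = k, n_target = n_target,
                               mu = mu, n_colonies = n_colonies,
                               seed = seed, ...)
  list(fluct = m$xi, t2_profile = m$t2_profile,
       persistence = m$persistence)
}
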