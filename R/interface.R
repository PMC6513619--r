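#' Extract the expansion front of a colony
#'
#' The exterior empty region is found by flood fill from the lattice
#' border (top row for linear geometry, all borders for radial);
#' impassable obstacles (`k = 0` disorder sites) act as barriers that
#' are neither exterior nor occupied. The front is the set of occupied
#' sites 4-adjacent to the exterior; boundaries of fully enclosed holes
#' are excluded. Note that front membership is independent of division
#' eligibility: a fully pinned colony can still have a nonempty front.
#'
#' @param result an `"eden_result"`, or an occupancy matrix if
#'   `disorder` and `k` are given explicitly.
#' @param disorder,k optional overrides when `result` is a bare matrix.
#' @param periodic_x wrap x (only used for bare-matrix input).
#' @return data.frame with columns `x`, `y` (1-based) of front sites.
#' @export
extract_front <- function(result, disorder = NULL, k = NULL,
                          periodic_x = FALSE) {
  if (inherits(result, "eden_result")) {
    grid <- result$grid
    disorder <- result$disorder
    k <- result$config$k
    periodic_x <- result$config$geometry == "linear"
  } else grid <- result
  H <- nrow(grid); L <- ncol(grid)
  barrier <- if (k == 0) disorder else matrix(FALSE, H, L)
  st <- grid
  st[is.na(st)] <- -1L
  ext <- cpp_exterior_mask(as.vector(st), as.vector(barrier),
                           L, H, periodic_x)
  dim(ext) <- c(H, L)
  # occupied sites adjacent to the exterior
  shift <- function(m, dx, dy) {
    out <- matrix(FALSE, H, L)
    xs <- seq_len(L) + dx; ys <- seq_len(H) + dy
    if (periodic_x) xs <- (xs - 1L) %% L + 1L
    okx <- xs >= 1L & xs <= L; oky <- ys >= 1L & ys <= H
    out[which(oky), which(okx)] <- m[ys[oky], xs[okx], drop = FALSE]
    out
  }
  near_ext <- shift(ext, 1L, 0L) | shift(ext, -1L, 0L) |
    shift(ext, 0L, 1L) | shift(ext, 0L, -1L)
  w <- which(!is.na(grid) & near_ext, arr.ind = TRUE)
  data.frame(x = as.integer(w[, 2]), y = as.integer(w[, 1]))
}

#' Per-column height profile of a linear front
#'
#' `h(x)` is the maximal occupied row in column `x` (overhangs collapsed
#' by the max rule), reported relative to the initial row, so a pristine
#' initial state has `h(x) = 0` everywhere.
#'
#' @param result an `"eden_result"` with `geometry = "linear"`.
#' @return numeric vector of length `L`.
#' @export
height_profile <- function(result) {
  if (inherits(result, "eden_result")) {
    if (result$config$geometry != "radial" &&
        !is.null(result$height_profile))
      return(result$height_profile)
    if (result$config$geometry == "radial")
      stop("height_profile is defined for linear geometry")
    grid <- result$grid
  } else grid <- result
  apply(grid, 2, function(col) {
    occ <- which(!is.na(col))
    if (length(occ) == 0) 0 else max(occ) - 1L
  })
}

#' Global and local interface widths
#'
#' The global width `W_G(t)` is the rms deviation of the height profile
#' about its spatial mean at each snapshot (Family-Vicsek observable:
#' it grows as `hbar^beta` and saturates at `L^alpha` beyond the
#' crossover). The local width `W_loc(l)` is the mean over sliding
#' windows of size `l` (periodic wrap) of the within-window rms
#' deviation, computed on the final profile.
#'
#' @param result an `"eden_result"` (linear) whose log is present, or a
#'   list with a precomputed `width_curve`.
#' @param snapshots increasing vector of mean heights at which `W_G` is
#'   evaluated (ignored if the run recorded an in-flight width curve).
#' @param window_sizes window sizes for `W_loc`; default
#'   `unique(round(2^(seq(2, log2(L / 8), by = 0.25))))`.
#' @return list with `global` (data.frame `hbar`, `w_g`) and `local`
#'   (data.frame `l`, `w_loc`).
#' @export
interface_widths <- function(result, snapshots = NULL,
                             window_sizes = NULL) {
  stopifnot(result$config$geometry == "linear")
  if (!is.null(result$width_curve) && nrow(result$width_curve) > 0) {
    glob <- result$width_curve[, c("hbar", "w_g")]
  } else {
    if (is.null(snapshots) || length(snapshots) < 2)
      stop("need at least 2 snapshot heights")
    if (is.null(result$log)) stop("run has neither width curve nor log")
    glob <- cpp_height_curve(result$log$daughter_x - 1L,
                             result$log$daughter_y - 1L,
                             result$config$L, sort(snapshots))
  }
  h <- if (!is.null(result$height_profile)) result$height_profile
       else height_profile(result)
  L <- length(h)
  if (is.null(window_sizes))
    window_sizes <- unique(round(2^(seq(2, log2(max(8, L / 8)),
                                        by = 0.25))))
  window_sizes <- window_sizes[window_sizes >= 2 & window_sizes <= L]
  wloc <- vapply(window_sizes, function(l) local_width(h, l), numeric(1))
  list(global = glob,
       local = data.frame(l = window_sizes, w_loc = wloc))
}

# mean over all periodic windows of size l of the within-window rms
local_width <- function(h, l) {
  L <- length(h)
  hh <- c(h, h[seq_len(l)])
  cs <- cumsum(c(0, hh)); cs2 <- cumsum(c(0, hh^2))
  i <- seq_len(L)
  m <- (cs[i + l] - cs[i]) / l
  v <- (cs2[i + l] - cs2[i]) / l - m^2
  mean(sqrt(pmax(v, 0)))
}

#' Least-squares power-law fit on log-log axes
#'
#' Ordinary least squares of `log(y)` on `log(x)` restricted to
#' `window`; the slope estimates the scaling exponent.
#'
#' @param x,y positive numeric vectors.
#' @param window `c(lo, hi)` range of `x` used for the fit (inclusive);
#'   default all points.
#' @return list with `exponent`, `stderr`, `intercept`, `n`, `window`.
#' @export
fit_power_law <- function(x, y, window = range(x)) {
  keep <- is.finite(x) & is.finite(y) & x >= window[1] & x <= window[2]
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points in the fit window")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive data")
  fit <- lm(log(y) ~ log(x))
  list(exponent = unname(coef(fit)[2]),
       stderr = unname(sqrt(diag(suppressWarnings(vcov(fit))))[2]),
       intercept = unname(coef(fit)[1]),
       n = length(x), window = window)
}

#' Front expansion speed
#'
#' Radial: the effective radius `R_eff(t) = sqrt(n_occupied(t) / pi)` is
#' regressed on time over the late half of the run. Linear: the mean
#' front height is regressed on time. Pinned runs report `v = 0`.
#'
#' @param results a single `"eden_result"` or a list of them (consistent
#'   geometry); speeds are estimated per run and averaged.
#' @return list with `v`, `stderr`, `per_run`.
#' @export
expansion_speed <- function(results) {
  if (inherits(results, "eden_result")) results <- list(results)
  speeds <- vapply(results, function(r) {
    if (r$terminated_by == "pinned") return(0)
    if (r$config$geometry == "radial") {
      if (is.null(r$log)) stop("radial speed needs the division log")
      tt <- r$log$time
      n <- r$n_initial + seq_along(tt)
      yy <- sqrt(n / pi)
    } else {
      wc <- r$width_curve
      if (is.null(wc) || nrow(wc) < 3) stop("linear speed needs width_curve")
      tt <- wc$time; yy <- wc$hbar
    }
    keep <- tt >= median(tt)
    if (sum(keep) < 3) stop("run too short for the speed fit window")
    unname(coef(lm(yy[keep] ~ tt[keep]))[2])
  }, numeric(1))
  list(v = mean(speeds),
       stderr = if (length(speeds) > 1) sd(speeds) / sqrt(length(speeds))
                else NA_real_,
       per_run = speeds)
}

#' Spanning probability and critical obstacle density
#'
#' For each density in `rho_grid`, `reps` radial colonies with
#' impassable obstacles (`k = 0`) are grown on an `L x L` lattice with
#' no population cap; a run spans if the colony reaches within 2 sites
#' of the border before pinning. The critical density is where the
#' fitted logistic spanning probability crosses 1/2; its uncertainty is
#' the logistic-fit width (standard error of the crossing via the delta
#' method).
#'
#' @param k transparency; must be 0 (strict pinning) for the spanning
#'   criterion to be well defined.
#' @param L lattice side.
#' @param rho_grid densities spanning the transition.
#' @param reps replicates per density.
#' @param seed master seed (fanned out per run).
#' @return list with `rho_c`, `stderr`, `table` (data.frame `rho`,
#'   `p_span`, `n`).
#' @export
estimate_critical_density <- function(k = 0, L = 128, rho_grid,
                                      reps = 100, seed) {
  stopifnot(k == 0)
  tab <- data.frame(rho = rho_grid, p_span = NA_real_, n = reps)
  span <- matrix(NA, length(rho_grid), reps)
  for (i in seq_along(rho_grid)) {
    for (r in seq_len(reps)) {
      cfg <- sim_config("radial", rho = rho_grid[i], k = 0,
                        L = L, n_target = as.numeric(L) * L,
                        seed = fan_seed(seed, i, r))
      res <- run_colony(cfg, keep_log = FALSE)
      span[i, r] <- res$terminated_by == "edge"
    }
    tab$p_span[i] <- mean(span[i, ])
  }
  ys <- rowSums(span)
  if (all(ys == reps) || all(ys == 0))
    stop("rho_grid does not bracket the spanning transition")
  fit <- glm(cbind(ys, reps - ys) ~ rho_grid, family = binomial())
  a <- coef(fit)[1]; b <- coef(fit)[2]
  rho_c <- unname(-a / b)
  V <- vcov(fit)
  g <- c(-1 / b, a / b^2)  # delta method for -a/b
  se <- sqrt(drop(t(g) %*% V %*% g))
  list(rho_c = rho_c, stderr = unname(se), table = tab)
}
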