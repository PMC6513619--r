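#' Build the lineage tree of a finished colony
#'
#' Every occupied site except the founder was born in exactly one
#' division, so the division log defines a parent map (child site ->
#' mother site) covering the whole population; the leaves of interest
#' are the sites on the final front.
#'
#' @param result an `"eden_result"` with a division log.
#' @param front optional precomputed [extract_front()].
#' @return object of class `"lineage_tree"`: list with `parent` and
#'   `depth` (flat-index vectors over the lattice, 0-based flat index
#'   `= (x - 1) * H + (y - 1)`, parent `-1` at the founder),
#'   `birth_time`, `leaves` (flat indices of front sites), `t_total`,
#'   `root`, `H`, `center`.
#' @export
build_tree <- function(result, front = NULL) {
  stopifnot(!is.null(result$log))
  cfg <- result$config
  H <- cfg$H; L <- cfg$L
  LH <- as.numeric(L) * H
  parent <- rep(-1L, LH)
  btime <- rep(NA_real_, LH)
  root <- (L %/% 2) * H + H %/% 2  # 0-based flat index of the founder
  if (cfg$geometry == "linear") stop("lineage analysis is radial-only")
  btime[root + 1] <- 0
  log <- result$log
  mi <- (log$mother_x - 1L) * H + (log$mother_y - 1L)
  di <- (log$daughter_x - 1L) * H + (log$daughter_y - 1L)
  parent[di + 1] <- mi
  btime[di + 1] <- log$time
  depth <- cpp_depths(mi, di, root, LH)
  if (is.null(front)) front <- extract_front(result)
  leaves <- (front$x - 1L) * H + (front$y - 1L)
  structure(list(parent = parent, depth = depth, birth_time = btime,
                 leaves = as.integer(leaves), t_total = result$t_now,
                 root = root, H = H,
                 center = c(L %/% 2 + 1, H %/% 2 + 1)),
            class = "lineage_tree")
}

#' Transverse lineage fluctuations and their scaling exponent
#'
#' For every front leaf the reference ray runs from the colony center
#' through that leaf and the lineage is walked from the leaf back to
#' the founder, recording at each forward-time bin `t` the
#' perpendicular distance of the lineage point from the ray.
#' Deviations are pooled over lineages and colonies and `l_perp(t)` is
#' their rms; the scaling exponent `xi` (`l_perp ~ t^xi`; 2/3 for
#' homogeneous KPZ-class colonies) is fitted over the central decade of
#' the well-populated `t` range.
#'
#' The default forward-time clock is the number of divisions along the
#' lineage (`abscissa = "generations"`, the tree depth): it is the
#' intrinsic growth time of a lineage and stays proportional to it even
#' when pinning makes the radius advance intermittently. With
#' `abscissa = "radius"` bins are unit steps of the distance from the
#' founder instead; the two agree for homogeneous colonies, but in
#' strongly disordered colonies the radius clock compresses the late
#' history of pinned lineages and inflates the apparent exponent.
#'
#' @param trees a `"lineage_tree"` or list of them (one per colony).
#' @param fit_window optional `c(lo, hi)` window on the forward-time
#'   axis; default the central decade of the bins holding at least half
#'   the pooled lineages.
#' @param abscissa forward-time clock, see Details.
#' @param ray `"leaf"` (default) uses the ray through the lineage's own
#'   front leaf; `"lsq"` anchors the reference ray at the origin with
#'   the direction that minimizes the path's squared perpendicular
#'   deviations (this absorbs the lineage's coherent angular drift and
#'   underestimates the fluctuation exponent, so it is offered for
#'   comparison only).
#' @param bridge standardize each squared deviation by the
#'   Brownian-bridge factor `1 - t / r_leaf` of its own lineage
#'   (default `TRUE`). The leaf-anchored ray forces the deviation to
#'   vanish at the leaf radius; without the standardization the pooled
#'   curve is systematically flattened at large `t`. Bins beyond
#'   `0.8 r_leaf` are dropped where the factor becomes singular.
#' @return list with `curve` (data.frame `t`, `l_perp`, `n`), `xi`,
#'   `stderr`, `fit`.
#' @export
lineage_fluctuations <- function(trees, fit_window = NULL,
                                 abscissa = c("generations", "radius"),
                                 ray = c("leaf", "lsq"),
                                 bridge = TRUE) {
  abscissa <- match.arg(abscissa)
  ray_mode <- match(match.arg(ray), c("leaf", "lsq")) - 1L
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  tmax <- max(vapply(trees, function(tr) {
    if (abscissa == "generations") max(tr$depth[tr$leaves + 1])
    else {
      xs <- tr$leaves %/% tr$H + 1; ys <- tr$leaves %% tr$H + 1
      floor(max(sqrt((xs - tr$center[1])^2 + (ys - tr$center[2])^2)))
    }
  }, numeric(1)))
  sumsq <- numeric(tmax); cnt <- numeric(tmax)
  for (tr in trees) {
    b <- pool_lineage_bins(tr, tmax, abscissa, ray_mode, bridge)
    sumsq <- sumsq + b$sumsq
    cnt <- cnt + b$count
  }
  keep <- cnt > 0
  curve <- data.frame(t = seq_len(tmax)[keep],
                      l_perp = sqrt(sumsq[keep] / cnt[keep]),
                      n = cnt[keep])
  lineage_curve_fit(curve, fit_window)
}

pool_lineage_bins <- function(tree, tmax, abscissa, ray_mode, bridge) {
  if (abscissa == "generations") {
    if (ray_mode != 0L)
      stop("the lsq ray is only implemented for the radius abscissa")
    cpp_lineage_bins_depth(tree$parent, tree$depth, tree$leaves,
                           tree$center[1] - 1, tree$center[2] - 1,
                           tree$H, as.integer(tmax), bridge)
  } else {
    cpp_lineage_bins(tree$parent, tree$leaves,
                     tree$center[1] - 1, tree$center[2] - 1,
                     tree$H, as.integer(tmax), ray_mode, bridge)
  }
}

#' Fit the lineage-fluctuation exponent from a pooled curve
#'
#' @param curve data.frame with `t`, `l_perp` and optionally `n` (as
#'   produced by [lineage_fluctuations()]).
#' @param fit_window optional `c(lo, hi)`; default the central decade
#'   of the `t` range whose bins hold at least half the pooled
#'   lineages (all of `t` if no `n` column is present), which keeps
#'   the window away from the sparsely populated deepest bins.
#' @return list with `curve`, `xi`, `stderr`, `fit`.
#' @export
lineage_curve_fit <- function(curve, fit_window = NULL) {
  if (is.null(fit_window)) {
    thalf <- if (is.null(curve$n)) max(curve$t)
             else max(curve$t[curve$n >= max(curve$n) / 2])
    m <- log10(thalf) / 2
    fit_window <- 10^c(m - 0.5, m + 0.5)
  }
  usable <- curve$l_perp > 0
  if (sum(usable & curve$t >= fit_window[1] & curve$t <= fit_window[2]) < 3)
    stop("fewer than 3 usable radius bins in the fit window")
  fit <- fit_power_law(curve$t[usable], curve$l_perp[usable],
                       window = fit_window)
  list(curve = curve, xi = fit$exponent, stderr = fit$stderr, fit = fit)
}

#' Pairwise coalescence times of front cells
#'
#' For pairs of front leaves, `dx` is their Euclidean distance and `T2`
#' the backward time to their most recent common ancestor
#' (`t_total - birth_time(MRCA)`, in wild-type generations). Normalized
#' columns divide by the maximal pairwise front distance and by
#' `t_total`. Above `pair_budget` distinct pairs, pairs are subsampled
#' at random (seed the caller's RNG for reproducibility).
#'
#' @param tree a `"lineage_tree"` with at least 2 leaves.
#' @param pair_budget maximum number of pairs evaluated.
#' @return data.frame `dx`, `t2`, `dx_norm`, `t2_norm`.
#' @export
pair_coalescence <- function(tree, pair_budget = 2e5) {
  stopifnot(inherits(tree, "lineage_tree"), length(tree$leaves) >= 2)
  tab <- cpp_pair_coalescence(tree$parent, tree$depth, tree$birth_time,
                              tree$leaves, tree$t_total, tree$H,
                              pair_budget)
  xs <- tree$leaves %/% tree$H; ys <- tree$leaves %% tree$H
  dxmax <- sqrt(diff(range(xs))^2 + diff(range(ys))^2)
  tab$dx_norm <- tab$dx / dxmax
  tab$t2_norm <- tab$t2 / tree$t_total
  tab
}

#' Binned mean coalescence time versus pair distance
#'
#' @param tables pooled [pair_coalescence()] output (one data.frame or
#'   a list to `rbind`).
#' @param breaks bin edges for `dx_norm`.
#' @return data.frame `dx_mid`, `t2_mean`, `n`.
#' @export
coalescence_profile <- function(tables,
                                breaks = seq(0, 1, by = 0.05)) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  bin <- cut(tables$dx_norm, breaks = breaks, include.lowest = TRUE)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  m <- tapply(tables$t2_norm, bin, mean)
  n <- tapply(tables$t2_norm, bin, length)
  keep <- !is.na(m)
  data.frame(dx_mid = mids[keep], t2_mean = as.numeric(m[keep]),
             n = as.numeric(n[keep]))
}

#' Persistence probability of close pairs
#'
#' `U(T2)`: the probability that a sampled pair with
#' `dx_norm < dx_cutoff` has a (normalized) coalescence time greater
#' than `T2`. `U(0) = 1` and `U` reaches 0 beyond the largest observed
#' time.
#'
#' @param tables pooled [pair_coalescence()] output.
#' @param dx_cutoff maximal normalized pair distance retained.
#' @return data.frame `t2`, `u` (right-continuous survival values at
#'   the observed times, starting from `U(0) = 1`).
#' @export
persistence_curve <- function(tables, dx_cutoff = 0.05) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  t2 <- tables$t2_norm[tables$dx_norm < dx_cutoff]
  if (length(t2) == 0) stop("no pairs below the dx cutoff")
  ts <- sort(unique(c(0, t2)))
  u <- vapply(ts, function(v) mean(t2 > v), numeric(1))
  data.frame(t2 = ts, u = u)
}
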