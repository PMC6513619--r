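#' Final mutant frequency
#'
#' Number of mutant lattice sites at the end of the run divided by the
#' total number of occupied sites.
#'
#' @param result an `"eden_result"` (or bare occupancy matrix).
#' @return a single number in `[0, 1]`.
#' @export
mutant_frequency <- function(result) {
  grid <- if (inherits(result, "eden_result")) result$grid else result
  occ <- grid[!is.na(grid)]
  if (length(occ) == 0) stop("no occupied sites")
  mean(occ > 0)
}

#' Collect mutant clones from a finished run
#'
#' A clone is the founding mutant plus all its descendants, identified
#' by descent (`clone_id`), not spatial adjacency: a clone fragmented
#' around obstacles is still one clone. A clone is a *sector* if at
#' least one of its sites lies on the final front (it kept contact with
#' the expansion), otherwise a *bubble*. Shape descriptors follow the
#' radial frame of the ray from the colony center through the clone
#' centroid: `l_par` is the extent (max - min + 1) of the site
#' projections on that ray, `l_perp` the extent on the perpendicular,
#' and `angle` the principal-axis orientation relative to the ray,
#' folded to `[0, pi/2]` (shape fields are `NA` below `min_area`).
#'
#' @param result an `"eden_result"` with final grid.
#' @param front optional precomputed [extract_front()] output.
#' @param min_area minimum clone area for shape descriptors.
#' @return data.frame with one row per clone: `clone_id`, `area`,
#'   `x_norm` (area / colony size), `is_sector`, `l_par`, `l_perp`,
#'   `angle`.
#' @export
collect_clones <- function(result, front = NULL, min_area = 5) {
  grid <- result$grid
  if (is.null(front)) front <- extract_front(result)
  front_idx <- (front$x - 1L) * nrow(grid) + front$y
  mt <- which(!is.na(grid) & grid > 0)
  n_occ <- sum(!is.na(grid))
  if (length(mt) == 0)
    return(data.frame(clone_id = integer(0), area = integer(0),
                      x_norm = numeric(0), is_sector = logical(0),
                      l_par = numeric(0), l_perp = numeric(0),
                      angle = numeric(0)))
  H <- nrow(grid)
  ids <- grid[mt]
  xs <- (mt - 1L) %/% H + 1L
  ys <- (mt - 1L) %% H + 1L
  on_front <- mt %in% front_idx
  cx <- ncol(grid) %/% 2 + 1L; cy <- H %/% 2 + 1L
  if (result$config$geometry == "linear") { cx <- NA; cy <- NA }
  by_id <- split(seq_along(ids), ids)
  rows <- lapply(by_id, function(ii) {
    x <- xs[ii]; y <- ys[ii]
    area <- length(ii)
    out <- data.frame(clone_id = ids[ii[1]], area = area,
                      x_norm = area / n_occ,
                      is_sector = any(on_front[ii]),
                      l_par = NA_real_, l_perp = NA_real_,
                      angle = NA_real_)
    if (area >= min_area && !is.na(cx)) {
      mx <- mean(x); my <- mean(y)
      u <- c(mx - cx, my - cy)
      nu <- sqrt(sum(u^2))
      if (nu > 0) {
        u <- u / nu
        pp <- (x - cx) * u[1] + (y - cy) * u[2]
        qq <- -(x - cx) * u[2] + (y - cy) * u[1]
        out$l_par <- diff(range(pp)) + 1
        out$l_perp <- diff(range(qq)) + 1
        cv <- cov(cbind(x, y))
        ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
        a <- acos(pmin(1, abs(sum(ev * u))))  # fold to [0, pi/2]
        out$angle <- a
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical clone-size survival function
#'
#' `P(X > x)`, the fraction of clones with normalized size strictly
#' greater than `x`, evaluated at the observed sizes (pooling clone
#' tables from an ensemble is the intended use).
#'
#' @param clones a clone data.frame from [collect_clones()] (or a
#'   pooled `rbind` of several), or a bare numeric vector of sizes.
#' @return data.frame with sorted unique `x` and `survival`.
#' @export
clone_size_distribution <- function(clones) {
  x <- if (is.numeric(clones)) clones else clones$x_norm
  if (length(x) == 0) stop("empty clone set")
  xs <- sort(unique(x))
  surv <- vapply(xs, function(v) mean(x > v), numeric(1))
  data.frame(x = xs, survival = surv, n_clones = length(x))
}

#' Clone anisotropy exponent
#'
#' Fits the scaling of clone transverse width with radial length,
#' `l_perp ~ l_par^zeta`. Because clone sizes are heavy tailed, clones
#' are pooled into log-spaced bins of `l_par` keeping only bins with at
#' least `min_per_bin` clones, and the median `l_perp` per bin is fit
#' against the geometric bin center. `zeta = 1` means isotropic clones,
#' smaller values mean radially elongated ones.
#'
#' By default only bubbles enter the fit: the width of a surviving
#' sector follows the deterministic wedge opening of the expansion
#' rather than boundary-fluctuation scaling, and the few large sectors
#' otherwise dominate the top bins.
#'
#' @param clones pooled clone table with `l_par`, `l_perp` (rows with
#'   `NA` shape are dropped).
#' @param min_per_bin minimum clones per log bin.
#' @param bins_per_decade number of log bins per decade of `l_par`.
#' @param include_sectors keep sector clones in the fit?
#' @param min_length smallest binned `l_par` entering the fit; extents
#'   below a few lattice sites are quantization-dominated (the median
#'   width sticks at the area cutoff's scale) and flatten the fit.
#' @return list as from [fit_power_law()] plus `binned` data.
#' @export
clone_shape_anisotropy <- function(clones, min_per_bin = 10,
                                   bins_per_decade = 6,
                                   include_sectors = FALSE,
                                   min_length = 4) {
  cl <- clones[!is.na(clones$l_par) & !is.na(clones$l_perp) &
                 clones$l_par > 0 & clones$l_perp > 0, ]
  if (!include_sectors) cl <- cl[!cl$is_sector, ]
  if (nrow(cl) == 0) stop("no clones above the shape area cutoff")
  lb <- log10(cl$l_par)
  edges <- seq(floor(min(lb) * bins_per_decade) / bins_per_decade,
               ceiling(max(lb) * bins_per_decade) / bins_per_decade +
                 1e-9, by = 1 / bins_per_decade)
  bin <- cut(lb, breaks = edges, include.lowest = TRUE)
  agg <- do.call(rbind, lapply(split(cl, bin), function(d) {
    if (nrow(d) < min_per_bin) return(NULL)
    data.frame(l_par = exp(mean(log(d$l_par))),
               l_perp = median(d$l_perp), n = nrow(d))
  }))
  if (!is.null(agg)) agg <- agg[agg$l_par >= min_length, ]
  if (is.null(agg) || nrow(agg) < 3)
    stop("too few populated bins for the anisotropy fit")
  fit <- fit_power_law(agg$l_par, agg$l_perp)
  fit$binned <- agg
  fit
}

#' Power-law tail exponent of the bubble-size distribution
#'
#' Fits the survival function of bubble sizes (sectors excluded) as
#' `P(A > a) ~ a^-lambda` over `window`; the returned `exponent` is the
#' positive magnitude `lambda` (expected `1 / (1 + z)` of the interface
#' universality class: 2/5 for KPZ, about 0.46 for QEW).
#'
#' @param sizes numeric vector of bubble sizes (absolute areas), or a
#'   clone table from which non-sector areas are taken.
#' @param window `c(lo, hi)` size range of the fit. The default
#'   `c(2, 64)` targets the small-size scaling regime: at desk-scale
#'   colony sizes the survival function steepens well before the
#'   finite-size shoulder, and the power-law regime is confined to
#'   small bubbles (it widens slowly with colony size).
#' @return list as from [fit_power_law()] with positive `exponent`.
#' @export
fit_bubble_tail <- function(sizes, window = c(2, 64)) {
  if (is.data.frame(sizes)) sizes <- sizes$area[!sizes$is_sector]
  if (length(sizes) < 10) stop("too few bubbles for a tail fit")
  d <- clone_size_distribution(sizes)
  d <- d[d$survival > 0, ]
  fit <- fit_power_law(d$x, d$survival, window = window)
  fit$exponent <- -fit$exponent
  fit
}
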