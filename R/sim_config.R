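#' Simulation configuration
#'
#' Bundles and validates all parameters of the generalized Eden model in
#' one record. Disorder sites are laid down at density `rho` and confer a
#' reduced growth rate `k` (the "transparency", `k = 0` making them
#' impassable obstacles); mutants divide at relative rate `1 + s`; each
#' wild-type division mutates the daughter with probability `mu`.
#'
#' For radial geometry the lattice side defaults to
#' `ceiling(5 * sqrt(n_target / (pi * (1 - 0.9 * rho))))`, comfortably
#' larger than the expected colony diameter so that the colony never
#' touches the border (touching the border terminates the run with
#' `terminated_by = "edge"` rather than silently truncating it). For
#' linear geometry `L` is the front width (periodic) and growth proceeds
#' upward until the mean front height reaches `height_target`.
#'
#' @param geometry `"radial"` (single founder in the center) or
#'   `"linear"` (occupied bottom row, periodic lateral boundaries).
#' @param rho disorder-site density in `[0, 1]`.
#' @param k disorder transparency in `[0, 1]`; `k = 1` is a degenerate
#'   control in which disorder has no effect.
#' @param s selection coefficient of the mutant (`1 + s > 0`).
#' @param mu mutation probability per wild-type division, in `[0, 1]`.
#' @param n_target target number of occupied sites (radial geometry).
#' @param height_target target mean front height (linear geometry).
#' @param L lattice side (radial) or front width (linear); `NULL` picks a
#'   safe default for radial geometry.
#' @param H lattice height for linear geometry; `NULL` picks
#'   `ceiling(1.6 * height_target) + 50`.
#' @param max_events hard cap on division events.
#' @param seed integer RNG seed; required for reproducibility.
#' @return an object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(rho = 0.4, k = 0, n_target = 2000, seed = 1)
#' @export
sim_config <- function(geometry = c("radial", "linear"),
                       rho = 0, k = 0, s = 0, mu = 0,
                       n_target = 1e5, height_target = 100,
                       L = NULL, H = NULL,
                       max_events = Inf, seed = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(is.numeric(rho), length(rho) == 1, rho >= 0, rho <= 1,
            is.numeric(k), length(k) == 1, k >= 0, k <= 1,
            is.numeric(mu), length(mu) == 1, mu >= 0, mu <= 1,
            is.numeric(s), length(s) == 1, 1 + s > 0)
  if (is.null(seed)) stop("a seed is required (no silent nondeterminism)")
  seed <- as.integer(seed)
  if (geometry == "radial") {
    if (is.null(L))
      L <- as.integer(ceiling(5 * sqrt(n_target / (pi * (1 - 0.9 * rho)))))
    L <- as.integer(L)
    H <- L
    if (n_target > as.numeric(L) * H)
      stop("n_target exceeds lattice capacity")
  } else {
    if (is.null(L)) L <- 256L
    L <- as.integer(L)
    if (is.null(H)) H <- as.integer(ceiling(1.6 * height_target) + 50)
    H <- as.integer(H)
    if (height_target >= H) stop("height_target must be below H")
  }
  structure(list(geometry = geometry, L = L, H = H,
                 rho = rho, k = k, s = s, mu = mu,
                 n_target = n_target, height_target = height_target,
                 max_events = max_events, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$geometry,
      sprintf(" L=%d rho=%g k=%g s=%g mu=%g seed=%d\n",
              x$L, x$rho, x$k, x$s, x$mu, x$seed))
  if (x$geometry == "radial") cat("  n_target =", x$n_target, "\n")
  else cat("  height_target =", x$height_target, " H =", x$H, "\n")
  invisible(x)
}

#' Generate a quenched disorder field
#'
#' Each non-protected site is declared a disorder site independently with
#' probability `rho`. Protected sites (the founder, or the initial row)
#' are always normal, so the expansion has a well-defined start.
#'
#' @param L lattice width (columns).
#' @param H lattice height (rows); defaults to `L`.
#' @param rho disorder density in `[0, 1]`.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   consumed (exactly `L * H` uniforms, irrespective of `rho`).
#' @param protected integer matrix or 2-column matrix of `(x, y)`
#'   1-based site coordinates forced to be normal.
#' @return a list with `mask` (H x L logical matrix, `TRUE` = disorder)
#'   and `rho_realized`.
#' @examples
#' d <- generate_disorder(50, rho = 0.4, seed = 1)
#' d$rho_realized
#' @export
generate_disorder <- function(L, H = L, rho, seed = NULL,
                              protected = NULL) {
  stopifnot(rho >= 0, rho <= 1)
  make <- function() {
    mask <- matrix(runif(as.numeric(L) * H) < rho, nrow = H, ncol = L)
    if (!is.null(protected)) {
      protected <- matrix(as.integer(protected), ncol = 2)
      if (any(protected[, 1] < 1 | protected[, 1] > L |
              protected[, 2] < 1 | protected[, 2] > H))
        stop("protected site out of bounds")
      mask[cbind(protected[, 2], protected[, 1])] <- FALSE
    }
    mask
  }
  mask <- if (is.null(seed)) make() else with_seed(seed, make())
  list(mask = mask, rho_realized = mean(mask))
}
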