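# Pure-R reference stepper. Used for enumerable fixtures and as an
# independent check of the compiled event loop: at each step it
# recomputes the eligible set from scratch and samples the mother by
# exact rate-proportional sampling, so its per-event distribution can be
# written down analytically on tiny lattices.

#' Construct an explicit colony state for fixture-scale stepping
#'
#' @param grid integer occupancy matrix (`NA` empty, `0` WT, `> 0`
#'   mutant clone id), rows = y, columns = x.
#' @param disorder logical disorder mask of the same shape (default
#'   none).
#' @param k,s,mu model parameters as in [sim_config()].
#' @param periodic_x wrap the x direction (linear geometry)?
#' @return an object of class `"eden_state"`.
#' @export
eden_state <- function(grid, disorder = NULL, k = 0, s = 0, mu = 0,
                       periodic_x = FALSE) {
  if (is.null(disorder))
    disorder <- matrix(FALSE, nrow(grid), ncol(grid))
  stopifnot(identical(dim(grid), dim(disorder)), k >= 0, k <= 1,
            mu >= 0, mu <= 1, 1 + s > 0)
  structure(list(grid = grid, disorder = disorder, k = k, s = s, mu = mu,
                 periodic_x = periodic_x, t_now = 0,
                 n_clones = max(c(0L, grid), na.rm = TRUE),
                 pinned = FALSE, log = NULL),
            class = "eden_state")
}

state_neighbours <- function(st, x, y) {
  H <- nrow(st$grid); L <- ncol(st$grid)
  nb <- rbind(c(x, y - 1L), c(x, y + 1L), c(x - 1L, y), c(x + 1L, y))
  if (st$periodic_x) nb[, 1] <- (nb[, 1] - 1L) %% L + 1L
  nb[nb[, 1] >= 1L & nb[, 1] <= L & nb[, 2] >= 1L & nb[, 2] <= H, ,
     drop = FALSE]
}

state_colonizable <- function(st, sites) {
  occ <- st$grid[cbind(sites[, 2], sites[, 1])]
  blocked <- st$k == 0 & st$disorder[cbind(sites[, 2], sites[, 1])]
  sites[is.na(occ) & !blocked, , drop = FALSE]
}

#' Eligible sites and their rates
#'
#' A site is eligible if it is occupied, its growth rate is positive and
#' it has at least one colonizable empty von-Neumann neighbour.
#'
#' @param st an [eden_state()].
#' @return data.frame with columns `x`, `y`, `rate`.
#' @export
eligible_sites <- function(st) {
  occ <- which(!is.na(st$grid), arr.ind = TRUE)  # (row=y, col=x)
  out <- data.frame(x = integer(0), y = integer(0), rate = numeric(0))
  for (i in seq_len(nrow(occ))) {
    x <- occ[i, 2]; y <- occ[i, 1]
    r <- growth_rate(st$grid, st$disorder, st$k, st$s, c(x, y))
    if (r <= 0) next
    if (nrow(state_colonizable(st, state_neighbours(st, x, y))) == 0) next
    out <- rbind(out, data.frame(x = x, y = y, rate = r))
  }
  out
}

#' Advance a fixture-scale state by one division event
#'
#' @param st an [eden_state()].
#' @return the updated state; `st$pinned` is set if no site is eligible.
#'   The last event is appended to `st$log`.
#' @export
eden_step <- function(st) {
  el <- eligible_sites(st)
  if (nrow(el) == 0) {
    st$pinned <- TRUE
    return(st)
  }
  i <- sample.int(nrow(el), 1, prob = el$rate)
  mx <- el$x[i]; my <- el$y[i]
  open <- state_colonizable(st, state_neighbours(st, mx, my))
  j <- sample.int(nrow(open), 1)
  dx <- open[j, 1]; dy <- open[j, 2]
  cl <- st$grid[my, mx]
  mutated <- FALSE
  if (cl == 0L && runif(1) < st$mu) {
    st$n_clones <- st$n_clones + 1L
    cl <- st$n_clones
    mutated <- TRUE
  }
  st$t_now <- st$t_now + 1 / sum(el$rate)
  st$grid[dy, dx] <- cl
  ev <- data.frame(time = st$t_now, mother_x = mx, mother_y = my,
                   daughter_x = dx, daughter_y = dy,
                   clone_id = cl, mutated = mutated)
  st$log <- rbind(st$log, ev)
  st
}
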