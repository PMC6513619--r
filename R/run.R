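#' Run a radial colony simulation
#'
#' Grows a colony from a single wild-type founder at the lattice center
#' until `n_target` sites are occupied, the front is pinned (no site can
#' divide), the event cap is hit, or the colony reaches the lattice
#' border (`terminated_by = "edge"`, a boundary artifact; enlarge `L`).
#'
#' In each event one eligible site (positive growth rate, at least one
#' colonizable empty von-Neumann neighbour) is chosen with probability
#' proportional to its growth rate `(k if disorder) * (1 + s if mutant)`
#' and divides into a uniformly chosen colonizable empty neighbour. The
#' daughter inherits genotype and clone id, except that a wild-type
#' mother's daughter mutates with probability `mu`, founding a new clone;
#' mutants never mutate further. Time advances by one over the sum of
#' eligible rates per event (wild-type generations). At `k = 0` disorder
#' sites can never be colonized, so trapped colonies are site-percolation
#' clusters.
#'
#' @param config a [sim_config()] with `geometry = "radial"`.
#' @param keep_log keep the full division log (needed for clone and
#'   lineage analysis)?
#' @return an object of class `"eden_result"`: a list with `config`,
#'   `grid` (H x L integer matrix: `NA` empty, `0` wild type, `> 0`
#'   mutant clone id), `disorder` (logical mask), `log` (one row per
#'   division: `time`, mother and daughter coordinates, `clone_id`,
#'   `mutated`; 1-based coordinates), `t_now`, `n_occupied`,
#'   `terminated_by`.
#' @examples
#' res <- run_colony(sim_config(n_target = 500, seed = 1))
#' res$terminated_by
#' @export
run_colony <- function(config, keep_log = TRUE) {
  stopifnot(inherits(config, "sim_config"), config$geometry == "radial")
  run_eden_impl(config, keep_log = keep_log, wg_checkpoints = numeric(0))
}

#' Run a linear (flat-front) simulation
#'
#' Starts from a fully occupied wild-type bottom row of width `L` with
#' periodic lateral boundaries and grows upward until the mean front
#' height (per-column maximum occupied row) reaches
#' `config$height_target`, pinning, or the event cap. Used to measure
#' interface roughness exponents.
#'
#' @inheritParams run_colony
#' @param config a [sim_config()] with `geometry = "linear"`.
#' @param wg_checkpoints optional increasing vector of mean front
#'   heights at which `(hbar, W_G)` is recorded in flight, returned as
#'   `$width_curve`; allows `keep_log = FALSE` for long runs.
#' @return an `"eden_result"`; additionally `height_profile` (final
#'   per-column max height) and, if requested, `width_curve`.
#' @examples
#' cfg <- sim_config("linear", L = 32, height_target = 10, seed = 1)
#' res <- run_linear(cfg)
#' @export
run_linear <- function(config, keep_log = TRUE, wg_checkpoints = NULL) {
  stopifnot(inherits(config, "sim_config"), config$geometry == "linear")
  run_eden_impl(config, keep_log = keep_log,
                wg_checkpoints = as.numeric(wg_checkpoints %||% numeric(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_eden_impl <- function(config, keep_log, wg_checkpoints) {
  radial <- config$geometry == "radial"
  L <- config$L; H <- config$H
  protected <- if (radial) {
    cbind(L %/% 2 + 1L, H %/% 2 + 1L)
  } else {
    cbind(seq_len(L), rep(1L, L))
  }
  with_seed(config$seed, {
    dis <- generate_disorder(L, H, config$rho, seed = NULL,
                             protected = protected)
    raw <- cpp_run_eden(L, H, radial, as.vector(dis$mask),
                        config$k, config$s, config$mu,
                        config$n_target, config$height_target,
                        config$max_events, 2L,
                        wg_checkpoints, keep_log)
    grid <- raw$state
    grid[grid == -1L] <- NA_integer_
    res <- list(config = config, grid = grid, disorder = dis$mask,
                rho_realized = dis$rho_realized,
                t_now = raw$t_now, n_occupied = raw$n_occupied,
                n_initial = raw$n_initial, n_clones = raw$n_clones,
                terminated_by = raw$terminated_by)
    if (keep_log) {
      log <- raw$log
      log$mother_x <- log$mother_x + 1L
      log$mother_y <- log$mother_y + 1L
      log$daughter_x <- log$daughter_x + 1L
      log$daughter_y <- log$daughter_y + 1L
      log$index <- seq_len(nrow(log))
      res$log <- log[, c("index", "time", "mother_x", "mother_y",
                         "daughter_x", "daughter_y", "clone_id",
                         "mutated")]
    }
    if (!radial) {
      res$height_profile <- raw$height_profile
      res$width_curve <- raw$width_curve
    }
    class(res) <- "eden_result"
    res
  })
}

#' @export
print.eden_result <- function(x, ...) {
  cat(sprintf(
    "<eden_result> %s rho=%g k=%g s=%g mu=%g: %d sites, t=%.1f, %s\n",
    x$config$geometry, x$config$rho, x$config$k, x$config$s, x$config$mu,
    x$n_occupied, x$t_now, x$terminated_by))
  invisible(x)
}

#' Growth rate of an occupied site
#'
#' The reference wild-type rate on a normal site is exactly 1; disorder
#' multiplies by the transparency `k` and a mutant genotype by `1 + s`.
#'
#' @param grid integer occupancy matrix (`NA` empty, `0` WT, `> 0` MT).
#' @param disorder logical disorder mask of the same shape.
#' @param k,s transparency and selection coefficient.
#' @param site `c(x, y)` 1-based coordinates (x = column, y = row).
#' @return the nonnegative division rate.
#' @export
growth_rate <- function(grid, disorder, k, s, site) {
  g <- grid[site[2], site[1]]
  if (is.na(g)) stop("site is not occupied")
  (if (disorder[site[2], site[1]]) k else 1) * (if (g > 0) 1 + s else 1)
}

#' Replay a division log against the final state
#'
#' Rebuilds the occupancy grid by replaying the log from the initial
#' condition, checking that every daughter site was empty and 4-adjacent
#' to its (occupied) mother at the time of the event, and that the
#' replayed grid equals the recorded final state. Serves as an
#' end-to-end consistency check of the event machinery.
#'
#' @param result an `"eden_result"` with a log.
#' @return invisibly `TRUE`; stops on any inconsistency.
#' @export
replay_log <- function(result) {
  cfg <- result$config
  L <- cfg$L; H <- cfg$H
  grid <- matrix(NA_integer_, H, L)
  if (cfg$geometry == "radial") {
    grid[H %/% 2 + 1L, L %/% 2 + 1L] <- 0L
  } else {
    grid[1L, ] <- 0L
  }
  log <- result$log
  periodic <- cfg$geometry == "linear"
  for (i in seq_len(nrow(log))) {
    mx <- log$mother_x[i]; my <- log$mother_y[i]
    dx <- log$daughter_x[i]; dy <- log$daughter_y[i]
    if (is.na(grid[my, mx])) stop("mother unoccupied at event ", i)
    if (!is.na(grid[dy, dx])) stop("daughter not empty at event ", i)
    ddx <- abs(mx - dx)
    if (periodic) ddx <- min(ddx, L - ddx)
    if (ddx + abs(my - dy) != 1L) stop("non-adjacent division at event ", i)
    if (log$mutated[i]) {
      if (grid[my, mx] != 0L) stop("mutation from a mutant mother at ", i)
    } else if (grid[my, mx] != log$clone_id[i]) {
      stop("clone id not inherited at event ", i)
    }
    grid[dy, dx] <- log$clone_id[i]
  }
  if (!identical(grid, result$grid)) stop("replayed grid differs")
  invisible(TRUE)
}
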