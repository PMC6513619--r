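#' Load and validate an experiment plan
#'
#' A plan is a flat JSON object with an `experiment` name (one of
#' `percolation`, `exponents`, `fmt_sweep`, `lineages`, `adapt_rate`,
#' `infer_mu`), a mandatory integer `seed`, an output directory `out`,
#' and experiment-specific parameters. Unknown keys are rejected and a
#' missing seed is an error (no silent nondeterminism). Defaults:
#' `n_target = 1e5`, `mu = 5e-4`.
#'
#' @param path path to the JSON plan file.
#' @return a validated plan (list) of class `"experiment_plan"`.
#' @export
load_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  plan <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("experiment", "seed", "out", "rho", "k", "s", "mu",
             "rho_grid", "k_grid", "s_grid", "mu_grid", "n_target",
             "height_target", "L", "reps", "n_colonies", "s_bar",
             "ratio", "data", "lambda0", "generations",
             "sims_per_theta", "wg_checkpoints")
  bad <- setdiff(names(plan), known)
  if (length(bad) > 0)
    stop("unknown plan key(s): ", paste(bad, collapse = ", "))
  experiments <- c("percolation", "exponents", "fmt_sweep", "lineages",
                   "adapt_rate", "infer_mu")
  if (is.null(plan$experiment) || !plan$experiment %in% experiments)
    stop("experiment must be one of: ",
         paste(experiments, collapse = ", "))
  if (is.null(plan$seed)) stop("plan must name an integer seed")
  if (is.null(plan$out)) stop("plan must name an output directory")
  for (f in c("rho", "k", "rho_grid", "k_grid"))
    if (!is.null(plan[[f]]) && any(plan[[f]] < 0 | plan[[f]] > 1))
      stop(f, " must lie in [0, 1]")
  if (is.null(plan$n_target)) plan$n_target <- 1e5
  if (is.null(plan$mu)) plan$mu <- 5e-4
  if (is.null(plan$reps)) plan$reps <- 20L
  structure(plan, class = "experiment_plan")
}

#' Execute an experiment plan
#'
#' Dispatches the named experiment across its parameter grid, writes
#' all output tables as headed CSV under `plan$out`, and records a JSON
#' manifest (`manifest.json`) with the plan, per-file md5 checksums and
#' timings. Rerunning the same plan reproduces all numeric outputs
#' bit for bit.
#'
#' @param plan an `"experiment_plan"` from [load_plan()], or a path.
#' @return invisibly, the manifest (list).
#' @export
run_plan <- function(plan) {
  if (is.character(plan)) plan <- load_plan(plan)
  dir.create(plan$out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- switch(
    plan$experiment,
    percolation = plan_percolation(plan),
    exponents = plan_exponents(plan),
    fmt_sweep = plan_fmt_sweep(plan),
    lineages = plan_lineages(plan),
    adapt_rate = plan_adapt_rate(plan),
    infer_mu = plan_infer_mu(plan))
  manifest <- list(
    experiment = plan$experiment, seed = plan$seed,
    plan = unclass(plan),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(plan$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

plan_out <- function(plan, name, df) {
  f <- file.path(plan$out, name)
  write.csv(df, f, row.names = FALSE)
  f
}

plan_percolation <- function(plan) {
  est <- estimate_critical_density(
    k = plan$k %||% 0, L = plan$L %||% 128,
    rho_grid = plan$rho_grid, reps = plan$reps, seed = plan$seed)
  f1 <- plan_out(plan, "spanning.csv", est$table)
  f2 <- plan_out(plan, "rho_c.csv",
                 data.frame(rho_c = est$rho_c, stderr = est$stderr))
  c(f1, f2)
}

plan_exponents <- function(plan) {
  m <- measure_interface_exponents(
    rho = plan$rho %||% 0, k = plan$k %||% 0, L = plan$L %||% 256,
    height_target = plan$height_target %||% NULL,
    reps = plan$reps, seed = plan$seed)
  c(plan_out(plan, "width_global.csv", m$global),
    plan_out(plan, "width_local.csv", m$local),
    plan_out(plan, "exponents.csv",
             data.frame(beta = m$beta, beta_stderr = m$beta_stderr,
                        alpha_loc = m$alpha_loc,
                        alpha_loc_stderr = m$alpha_loc_stderr)))
}

plan_fmt_sweep <- function(plan) {
  rhos <- plan$rho_grid %||% plan$rho %||% 0
  ks <- plan$k_grid %||% plan$k %||% 0
  sg <- plan$s_grid %||% c(-0.15, -0.1, -0.05, 0, 0.05, 0.1, 0.15, 0.2)
  combos <- expand.grid(rho = rhos, k = ks)
  tabs <- lapply(seq_len(nrow(combos)), function(i)
    sweep_fmt(s_grid = sg, rho = combos$rho[i], k = combos$k[i],
              n_target = plan$n_target, mu = plan$mu,
              reps = plan$reps, seed = fan_seed(plan$seed, i)))
  tab <- do.call(rbind, tabs)
  fits <- do.call(rbind, lapply(tabs, function(tb) {
    ft <- fit_selection(tb)
    data.frame(rho = tb$rho[1], k = tb$k[1], f0 = ft$f0, ks = ft$ks,
               f0_stderr = ft$f0_stderr, ks_stderr = ft$ks_stderr)
  }))
  c(plan_out(plan, "sweep.csv", tab),
    plan_out(plan, "fits.csv", fits))
}

plan_lineages <- function(plan) {
  m <- measure_lineage_stats(
    rho = plan$rho %||% 0, k = plan$k %||% 0,
    n_target = plan$n_target, mu = plan$mu,
    n_colonies = plan$n_colonies %||% 50, seed = plan$seed)
  c(plan_out(plan, "lineage_fluctuations.csv", m$fluct$curve),
    plan_out(plan, "t2_vs_dx.csv", m$t2_profile),
    plan_out(plan, "persistence.csv", m$persistence),
    plan_out(plan, "xi.csv",
             data.frame(xi = m$fluct$xi, stderr = m$fluct$stderr)))
}

plan_adapt_rate <- function(plan) {
  tab <- read.csv(plan$data)
  out <- adaptation_sweep(tab, s_bar = plan$s_bar,
                          R = plan$ratio)
  plan_out(plan, "adaptation_rate.csv", out)
}

plan_infer_mu <- function(plan) {
  obs <- read.csv(plan$data)
  est <- ml_infer_mu(obs,
                     sims_per_theta = plan$sims_per_theta %||% 5000,
                     lambda0 = plan$lambda0 %||% 10,
                     generations = plan$generations %||% 7,
                     seed = plan$seed)
  f1 <- plan_out(plan, "likelihood_grid.csv", est$grid)
  f2 <- file.path(plan$out, "mu_estimate.json")
  jsonlite::write_json(est[c("mu_star", "s_star", "delta_mu",
                             "boundary")],
                       f2, auto_unbox = TRUE, digits = NA)
  c(f1, f2)
}

#' Deterministic tiny fixtures with enumerated outcomes
#'
#' Hand-built lattices small enough that the first-event distribution
#' can be enumerated exactly; used by the test suite and useful for
#' exploring the update rule.
#'
#' * `"founder4"`: a lone founder with 4 free neighbours; each
#'   neighbour receives the first daughter with probability 1/4.
#' * `"obstacle-ring"`: a founder ringed by impassable obstacles;
#'   pinned at size 1.
#' * `"two-rates"`: a wild-type and a mutant (`s = 0.2`) mother side by
#'   side, selection odds 1 : 1.2.
#'
#' @param name fixture name.
#' @return list with `state` (an [eden_state()]) and `expected`
#'   (exact event probabilities or outcome).
#' @export
make_fixture <- function(name) {
  switch(
    name,
    "founder4" = {
      g <- matrix(NA_integer_, 5, 5)
      g[3, 3] <- 0L
      list(state = eden_state(g),
           expected = list(daughters = data.frame(
             x = c(3, 3, 2, 4), y = c(2, 4, 3, 3), prob = rep(1 / 4, 4))))
    },
    "obstacle-ring" = {
      g <- matrix(NA_integer_, 5, 5)
      g[3, 3] <- 0L
      d <- matrix(FALSE, 5, 5)
      d[cbind(c(2, 4, 3, 3), c(3, 3, 2, 4))] <- TRUE
      list(state = eden_state(g, d, k = 0),
           expected = list(pinned = TRUE, final_size = 1L))
    },
    "two-rates" = {
      g <- matrix(NA_integer_, 5, 7)
      g[3, 3] <- 0L  # WT mother
      g[3, 5] <- 1L  # MT mother, clone 1
      list(state = eden_state(g, s = 0.2),
           expected = list(mother_odds = c(wt = 1 / 2.2, mt = 1.2 / 2.2)))
    },
    stop("unknown fixture: ", name))
}
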