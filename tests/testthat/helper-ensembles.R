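# Small shared fixtures built in code. Heavier shared ensembles are
# built lazily and cached for the duration of the test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a small homogeneous colony with mutations, reused by several files
small_colony <- function() {
  cached("small_colony", run_colony(
    sim_config("radial", rho = 0, s = 0, mu = 0.01,
               n_target = 3000, seed = 4242)))
}

# a small disordered (k = 0) colony that pins
pinned_colony <- function() {
  cached("pinned_colony", {
    res <- NULL
    for (s in 1:50) {
      r <- run_colony(sim_config("radial", rho = 0.55, k = 0, L = 61,
                                 n_target = 61 * 61, seed = 9000 + s))
      if (r$terminated_by == "pinned" && r$n_occupied >= 30) {
        res <- r
        break
      }
    }
    stopifnot(!is.null(res))
    res
  })
}

# empirical distribution of the first daughter placement over many
# independent seeded runs of the compiled simulator
first_event_frequencies <- function(n = 2e4, rho = 0, k = 0, mu = 0,
                                    seed0 = 1e6) {
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    res <- run_colony(sim_config("radial", rho = rho, k = k, mu = mu,
                                 L = 11, n_target = 2,
                                 seed = seed0 + i))
    ev <- res$log[1, ]
    key <- paste(ev$daughter_x, ev$daughter_y)
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  out <- unlist(as.list(counts))
  out / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
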