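#' Write a finished run to a directory of plain-text files
#'
#' Emits the external representation of a run: `events.csv` (header
#' `index,time,mother_x,mother_y,daughter_x,daughter_y,genotype,clone_id,mutated`,
#' 0-based coordinates, x = column, y = row), `state.csv` (integer
#' matrix, 0 empty, 1 wild type, `clone_id + 1` for mutants),
#' `disorder.csv` (0/1 matrix) and `manifest.json` (config, seed,
#' termination, occupancy, final time).
#'
#' @param result an `"eden_result"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @export
write_run <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(result$log)) {
    log <- result$log
    ev <- data.frame(index = log$index, time = log$time,
                     mother_x = log$mother_x - 1L,
                     mother_y = log$mother_y - 1L,
                     daughter_x = log$daughter_x - 1L,
                     daughter_y = log$daughter_y - 1L,
                     genotype = ifelse(log$clone_id > 0, "MT", "WT"),
                     clone_id = log$clone_id, mutated = log$mutated)
    p <- file.path(dir, "events.csv")
    write.csv(ev, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  st <- result$grid + 1L
  st[is.na(st)] <- 0L
  p <- file.path(dir, "state.csv")
  write.table(st, p, row.names = FALSE, col.names = FALSE, sep = ",")
  paths <- c(paths, p)
  p <- file.path(dir, "disorder.csv")
  write.table(result$disorder * 1L, p, row.names = FALSE,
              col.names = FALSE, sep = ",")
  paths <- c(paths, p)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(result$config),
         terminated_by = result$terminated_by,
         n_occupied = result$n_occupied, t_now = result$t_now,
         n_clones = result$n_clones,
         rho_realized = result$rho_realized),
    p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(paths, p)
  invisible(c(paths, p))
}

#' Read a run written by [write_run()]
#'
#' @param dir the run directory.
#' @return an `"eden_result"` (without in-flight width curves).
#' @export
read_run <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- man$config
  config <- sim_config(cfg$geometry, rho = cfg$rho, k = cfg$k,
                       s = cfg$s, mu = cfg$mu, n_target = cfg$n_target,
                       height_target = cfg$height_target, L = cfg$L,
                       H = cfg$H, max_events = cfg$max_events %||% Inf,
                       seed = cfg$seed)
  st <- as.matrix(read.csv(file.path(dir, "state.csv"), header = FALSE))
  dimnames(st) <- NULL
  grid <- st - 1L
  grid[st == 0L] <- NA_integer_
  dis <- as.matrix(read.csv(file.path(dir, "disorder.csv"),
                            header = FALSE)) == 1
  dimnames(dis) <- NULL
  res <- list(config = config, grid = grid, disorder = dis,
              rho_realized = man$rho_realized, t_now = man$t_now,
              n_occupied = man$n_occupied,
              n_initial = if (cfg$geometry == "radial") 1L else cfg$L,
              n_clones = man$n_clones,
              terminated_by = man$terminated_by)
  evp <- file.path(dir, "events.csv")
  if (file.exists(evp)) {
    ev <- read.csv(evp)
    res$log <- data.frame(index = ev$index, time = ev$time,
                          mother_x = ev$mother_x + 1L,
                          mother_y = ev$mother_y + 1L,
                          daughter_x = ev$daughter_x + 1L,
                          daughter_y = ev$daughter_y + 1L,
                          clone_id = ev$clone_id,
                          mutated = as.logical(ev$mutated))
  }
  if (config$geometry == "linear")
    res$height_profile <- height_profile(grid)
  class(res) <- "eden_result"
  res
}
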