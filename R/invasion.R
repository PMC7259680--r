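#' Run a single TE invasion
#'
#' Simulates an invasion from seeding until one of: the generation limit,
#' extinction (mean fitness below the extinction threshold), TE loss (zero
#' copies left), the copy-number cap, or -- when early stopping is enabled --
#' the point where the outcome can no longer change (every individual
#' silenced and mean fitness above its running minimum for a full window).
#'
#' The trajectory records, per generation: the mean diploid copy number, the
#' mean number of cluster insertions per diploid, the mean fitness, the
#' fraction of silenced individuals (carrying at least one cluster
#' insertion) and the fraction of individuals with zero fitness. Mean
#' fitness is the mean of clamped individual fitness values (each in
#' `[0, 1]`). The lowest mean fitness reached during the invasion is the
#' "minimum fitness".
#'
#' @param config A [simulation_config()]. If `config$rng_seed` is set the
#'   run is fully reproducible.
#' @param return_population Also return the final population (off by default
#'   to keep sweeps light).
#' @return An object of class `invasion`: a list with `trajectory` (a
#'   tibble), `status` (see [classify_outcome()]), `stop_reason`,
#'   `min_fitness`, `min_fitness_generation`, `generations_run`,
#'   `final_mean_copies`, `max_mean_copies` and the `config`.
#' @examples
#' inv <- run_invasion(simulation_config(N = 250, cluster_percent = 3,
#'                                       generations = 500, rng_seed = 7))
#' inv$status
#' inv$min_fitness
#' @export
run_invasion <- function(config, return_population = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  pop <- initialize_population(config)
  res <- cpp_run_invasion(pop$individuals, engine_cfg(config), return_population)
  traj <- tibble::as_tibble(res$trajectory)
  out <- structure(
    list(
      trajectory = traj,
      stop_reason = res$stop_reason,
      min_fitness = res$min_fitness,
      min_fitness_generation = res$min_fitness_generation,
      generations_run = res$generations_run,
      final_mean_copies = res$final_mean_copies,
      max_mean_copies = max(traj$mean_copies),
      config = config,
      final_population = res$population
    ),
    class = "invasion"
  )
  out$status <- classify_outcome(out, config)
  out
}

#' @export
print.invasion <- function(x, ...) {
  cat("<invasion> status ", x$status, " after ", x$generations_run,
      " generations (", x$stop_reason, ")\n  min fitness ",
      format(x$min_fitness), " at generation ", x$min_fitness_generation,
      "; final mean copies ", format(x$final_mean_copies), "\n", sep = "")
  invisible(x)
}
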