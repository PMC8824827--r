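#' Simulation configuration for a honeybee breeding population
#'
#' Defines the breeding-scheme structure that the population simulator
#' follows. Defaults correspond to the reference study design: 20 years of
#' 500 queens, 50 dams producing 10 daughters each, matings with 12 drones
#' either freely (drone dams drawn from queens aged 1-3) or on 10 isolated
#' mating stations carrying sister groups of 8 drone-producing queens.
#'
#' @param n_years number of simulated years.
#' @param queens_per_year queens (and colonies) created per year.
#' @param n_dams breeding dams selected per year among two-year-old queens.
#' @param daughters_per_dam daughter queens per dam;
#'   `n_dams * daughters_per_dam` must equal `queens_per_year`.
#' @param n_drones_per_mating drones per mating (`n_d`).
#' @param n_stations mating stations per year (controlled mating).
#' @param dpq_per_station sister drone-producing queens per station.
#' @param p_controlled proportion of queens mated on stations, in \[0, 1\];
#'   the controlled subset has exact size
#'   `round(p_controlled * queens_per_year)` each year.
#' @param apiary_size colonies per apiary (`s_a`); must divide
#'   `queens_per_year`.
#' @param phenotype_rate probability that a colony keeps its phenotype
#'   record (`q`), in (0, 1].
#' @param trait a [trait_params()] object (true genetic parameters).
#' @param fixed_effect_sd standard deviation of the year-by-apiary fixed
#'   effects (drawn i.i.d. normal per level; estimation is invariant to it).
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   full configuration. Keep below 2^31 - 16 (phase offsets are added).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_years = 20L, queens_per_year = 500L,
                       n_dams = 50L, daughters_per_dam = 10L,
                       n_drones_per_mating = 12L,
                       n_stations = 10L, dpq_per_station = 8L,
                       p_controlled = 1, apiary_size = 50L,
                       phenotype_rate = 1,
                       trait = bee_traits()[["T1"]],
                       fixed_effect_sd = 1, seed = 1L) {
  cfg <- list(n_years = as.integer(n_years),
              queens_per_year = as.integer(queens_per_year),
              n_dams = as.integer(n_dams),
              daughters_per_dam = as.integer(daughters_per_dam),
              n_drones_per_mating = as.integer(n_drones_per_mating),
              n_stations = as.integer(n_stations),
              dpq_per_station = as.integer(dpq_per_station),
              p_controlled = p_controlled,
              apiary_size = as.integer(apiary_size),
              phenotype_rate = phenotype_rate,
              trait = trait,
              fixed_effect_sd = fixed_effect_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_years", "queens_per_year", "n_dams", "daughters_per_dam",
              "n_drones_per_mating", "n_stations", "dpq_per_station",
              "apiary_size")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("sim_config: ", f, " must be a count >= 1")
  if (cfg$n_dams * cfg$daughters_per_dam != cfg$queens_per_year)
    stop("sim_config: n_dams * daughters_per_dam must equal queens_per_year")
  if (cfg$p_controlled < 0 || cfg$p_controlled > 1)
    stop("sim_config: p_controlled must lie in [0, 1]")
  if (cfg$phenotype_rate <= 0 || cfg$phenotype_rate > 1)
    stop("sim_config: phenotype_rate must lie in (0, 1]")
  if (cfg$queens_per_year %% cfg$apiary_size != 0L)
    stop("sim_config: apiary_size must divide queens_per_year")
  if (cfg$n_dams > cfg$queens_per_year)
    stop("sim_config: fewer queens per year than dams required")
  if (!inherits(cfg$trait, "trait_params"))
    stop("sim_config: trait must be a trait_params object")
  if (cfg$fixed_effect_sd < 0)
    stop("sim_config: fixed_effect_sd must be nonnegative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d years x %d queens (%d dams x %d daughters), n_d = %d\n",
    x$n_years, x$queens_per_year, x$n_dams, x$daughters_per_dam,
    x$n_drones_per_mating))
  cat(sprintf(
    "  p_controlled = %g (%d stations x %d DPQs), s_a = %d, q = %g, seed = %d\n",
    x$p_controlled, x$n_stations, x$dpq_per_station, x$apiary_size,
    x$phenotype_rate, x$seed))
  print(x$trait)
  invisible(x)
}

# restore the caller's RNG state on exit; run expr under the given seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
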