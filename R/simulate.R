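#' Simulate a honeybee breeding population
#'
#' Runs the full breeding scheme defined by a [sim_config()]: each year a
#' cohort of queens is created (year 1 is an unrelated base cohort; later
#' cohorts descend from dams sampled among two-year-old queens), every queen
#' is mated either freely (`n_d` drones whose dams are drawn from queens
#' aged 1-3) or on one of the year's mating stations (sister groups of
#' drone-producing queens whose shared dam is a three-year-old breeding
#' queen), each queen heads one colony whose worker group inherits half the
#' queen's value plus the mean of the realized drone gametes (no Mendelian
#' sampling for the averaged worker group), colonies are randomly assigned
#' to equal-sized apiaries, and phenotypes follow the colony model
#' y = b(year, apiary) + uQ(queen) + uW(worker group) + e.
#'
#' Genetic values are drawn by the exact recursion of the relationship
#' factorization (see [build_factorization()]); the realized drone gametic
#' pairs of every mating are kept so the worker-group inheritance identity
#' holds record by record.
#'
#' The random stream is split into four phases (pedigree structure, genetic
#' values, apiaries/fixed effects/residuals, phenotype thinning) seeded at
#' `seed`, `seed + 1`, `seed + 2`, `seed + 3`, so e.g. two traits with equal
#' genetic parameters but different residual variance share their pedigree
#' and genetic draws.
#'
#' @param cfg a [sim_config()].
#' @param keep_drones keep realized drone gametic pairs per colony
#'   (matrices `2 x n_d`); needed to verify the inheritance identity.
#' @return A list of class `bee_population`: `pedigree` (data.frame),
#'   `colonies` (data.frame with `a_ww` and possibly-missing `phenotype`),
#'   `truth` (data.frame `id, uQ, uW` over relationship-matrix entities),
#'   `fact` (the factorization), `drones` (list, optional), `cfg`.
#' @export
simulate_population <- function(cfg, keep_drones = TRUE) {
  validate_sim_config(cfg)
  st  <- with_seed(cfg$seed, sim_structure(cfg))
  fact <- build_factorization(st$pedigree,
                              n_drones = cfg$n_drones_per_mating,
                              n_dpq = cfg$dpq_per_station)
  val <- with_seed(cfg$seed + 1L,
                   sim_values(fact, cfg$trait, keep_drones))
  colonies <- st$colonies
  colonies$a_ww <- unname(colony_aww(fact, colonies))
  colonies <- with_seed(cfg$seed + 2L, {
    colonies <- assign_apiaries(colonies, cfg$apiary_size)
    generate_phenotypes(colonies, val$truth, cfg$trait,
                        fixed_effect_sd = cfg$fixed_effect_sd)
  })
  if (cfg$phenotype_rate < 1)
    colonies <- with_seed(cfg$seed + 3L,
                          thin_phenotypes(colonies, cfg$phenotype_rate))
  structure(list(pedigree = st$pedigree, colonies = colonies,
                 truth = val$truth, fact = fact,
                 drones = val$drones, cfg = cfg),
            class = "bee_population")
}

#' @export
print.bee_population <- function(x, ...) {
  cat(sprintf(
    "bee_population: %d pedigree entities (%d in A), %d colonies, %d phenotyped\n",
    nrow(x$pedigree), x$fact$n, nrow(x$colonies),
    sum(!is.na(x$colonies$phenotype))))
  invisible(x)
}

# ---- structure phase -------------------------------------------------------

sample_vec <- function(x, n, replace = FALSE)
  x[sample.int(length(x), n, replace = replace)]

sim_structure <- function(cfg) {
  ny <- cfg$n_years; nq <- cfg$queens_per_year
  nd <- cfg$n_drones_per_mating
  n_ctrl <- as.integer(round(cfg$p_controlled * nq))
  cap <- ny * (2L * nq + cfg$n_stations + nq) + 8L
  kind <- character(cap); year <- integer(cap)
  dam <- integer(cap); sire <- integer(cap); fdam <- integer(cap)
  ddams <- vector("list", cap)
  cnt <- 0L
  mating <- integer(cap)          # queen -> her mating node
  is_st  <- logical(cap)          # entity is a mating station
  queens <- vector("list", ny); dams_by_year <- vector("list", ny)

  for (t in seq_len(ny)) {
    ## queens of year t
    qidx <- cnt + seq_len(nq); cnt <- cnt + nq
    kind[qidx] <- "queen"; year[qidx] <- t
    if (t > 1L) {
      prev <- queens[[t - 1L]]
      if (length(prev) < cfg$n_dams)
        stop("simulate_population: fewer two-year-old queens (",
             length(prev), ") than n_dams = ", cfg$n_dams)
      dams_t <- sample_vec(prev, cfg$n_dams)
      dvec <- rep(dams_t, each = cfg$daughters_per_dam)
      dam[qidx] <- dvec
      sire[qidx] <- mating[dvec]
      pseudo <- which(!is_st[mating[dvec]])
      for (j in pseudo)
        fdam[qidx[j]] <- sample_vec(ddams[[mating[dvec[j]]]], 1L)
      dams_by_year[[t]] <- dams_t
    }
    queens[[t]] <- qidx

    ## mating stations of year t
    st_t <- integer(0)
    if (n_ctrl > 0L) {
      poolD <- if (t >= 3L && length(dams_by_year[[t - 1L]]))
        dams_by_year[[t - 1L]] else queens[[1L]]
      if (length(poolD) < cfg$n_stations)
        stop("simulate_population: fewer eligible station dams (",
             length(poolD), ") than n_stations = ", cfg$n_stations)
      Ds <- sample_vec(poolD, cfg$n_stations)
      st_t <- cnt + seq_len(cfg$n_stations); cnt <- cnt + cfg$n_stations
      kind[st_t] <- "sire_group"; year[st_t] <- t
      dam[st_t] <- Ds; is_st[st_t] <- TRUE
      for (j in seq_along(st_t)) {
        m <- mating[Ds[j]]
        if (m > 0L && is_st[m]) sire[st_t[j]] <- m
        else if (m > 0L)
          ddams[[st_t[j]]] <- sample_vec(ddams[[m]],
                                         cfg$dpq_per_station, TRUE)
        # else: dam not yet mated (bootstrap years) -> base-sired DPQs
      }
    }

    ## matings of year t queens
    ctrl <- if (n_ctrl > 0L) sample_vec(qidx, n_ctrl) else integer(0)
    if (length(ctrl))
      mating[ctrl] <- sample_vec(st_t, length(ctrl), TRUE)
    unc <- setdiff(qidx, ctrl)
    if (length(unc)) {
      pool <- unlist(queens[max(1L, t - 2L):t], use.names = FALSE)
      u_t <- cnt + seq_along(unc); cnt <- cnt + length(unc)
      kind[u_t] <- "sire_group"; year[u_t] <- t
      for (j in seq_along(unc)) {
        p_j <- pool[pool != unc[j]]
        if (!length(p_j))
          stop("simulate_population: no eligible drone dams in year ", t)
        ddams[[u_t[j]]] <- sample_vec(p_j, nd, TRUE)
      }
      mating[unc] <- u_t
    }

    ## worker groups of year t
    widx <- cnt + seq_len(nq); cnt <- cnt + nq
    kind[widx] <- "worker_group"; year[widx] <- t
    dam[widx] <- qidx
    sire[widx] <- mating[qidx]
  }

  ## assemble ids: Q/W/S/P by kind, in creation order
  kind <- kind[seq_len(cnt)]; year <- year[seq_len(cnt)]
  dam <- dam[seq_len(cnt)]; sire <- sire[seq_len(cnt)]
  fdam <- fdam[seq_len(cnt)]; ddams <- ddams[seq_len(cnt)]
  is_st <- is_st[seq_len(cnt)]
  id <- character(cnt)
  id[kind == "queen"] <- paste0("Q", seq_len(sum(kind == "queen")))
  id[kind == "worker_group"] <- paste0("W", seq_len(sum(kind == "worker_group")))
  id[is_st] <- paste0("S", seq_len(sum(is_st)))
  pseudo <- kind == "sire_group" & !is_st
  id[pseudo] <- paste0("P", seq_len(sum(pseudo)))
  ref <- function(v) ifelse(v > 0L, id[pmax(v, 1L)], NA_character_)
  dd_str <- vapply(ddams, function(v)
    if (is.null(v)) NA_character_ else paste(id[v], collapse = ";"),
    character(1))
  ped <- data.frame(id = id, kind = kind, dam_id = ref(dam),
                    sire_group_id = ref(sire), father_dam_id = ref(fdam),
                    drone_dam_ids = dd_str, year = year,
                    stringsAsFactors = FALSE)
  wsel <- which(kind == "worker_group")
  colonies <- data.frame(colony_id = paste0("C", seq_along(wsel)),
                         queen_id = id[dam[wsel]],
                         worker_group_id = id[wsel],
                         year = year[wsel],
                         apiary = NA_integer_,
                         phenotype = NA_real_,
                         stringsAsFactors = FALSE)
  list(pedigree = ped, colonies = colonies)
}

# ---- value phase -----------------------------------------------------------

sim_values <- function(fact, trait, keep_drones = TRUE) {
  R <- chol(trait$G0)
  nA <- fact$n
  UQ <- numeric(nA); UW <- numeric(nA)
  drones <- if (keep_drones) vector("list", nA) else NULL
  biv <- function(n, v) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    s <- sqrt(pmax(v, 0))
    rbind(s * R[1, 1] * z1, s * (R[1, 2] * z1 + R[2, 2] * z2))
  }
  for (i in seq_len(nA)) {
    k2 <- fact$kind2[i]
    p <- fact$parents[[i]]; cf <- fact$coefs[[i]]
    if (k2 %in% c("base_queen", "queen", "station")) {
      e <- biv(1L, fact$d[i])
      UQ[i] <- e[1]; UW[i] <- e[2]
      if (length(p)) {
        UQ[i] <- UQ[i] + sum(cf * UQ[p])
        UW[i] <- UW[i] + sum(cf * UW[p])
      }
    } else {                      # worker group: realize the drone sample
      q <- p[1]
      if (k2 == "worker_st") {
        s <- fact$aux[[i]]$station; ndr <- fact$aux[[i]]$n_d
        g <- biv(ndr, 0.5 - fact$diag[s])
        g[1, ] <- g[1, ] + UQ[s]; g[2, ] <- g[2, ] + UW[s]
      } else if (k2 == "worker_unc") {
        dd <- fact$aux[[i]]$drone_dams
        g <- biv(length(dd), 0.5 - 0.25 * fact$diag[dd])
        g[1, ] <- g[1, ] + 0.5 * UQ[dd]; g[2, ] <- g[2, ] + 0.5 * UW[dd]
      } else {                    # anonymous base drones
        g <- biv(fact$aux[[i]]$n_d, 0.5)
      }
      UQ[i] <- 0.5 * UQ[q] + mean(g[1, ])
      UW[i] <- 0.5 * UW[q] + mean(g[2, ])
      if (keep_drones) drones[[i]] <- g
    }
  }
  truth <- data.frame(id = fact$id, uQ = UQ, uW = UW,
                      stringsAsFactors = FALSE)
  if (keep_drones) {
    wsel <- fact$kind == "worker_group"
    drones <- drones[wsel]
    names(drones) <- fact$id[wsel]
  }
  list(truth = truth, drones = drones)
}

# ---- standalone operations -------------------------------------------------

#' Assign colonies to equal-sized apiaries within years
#'
#' Within each year, colonies are partitioned uniformly at random into
#' apiaries of exactly `s_a` colonies; each (year, apiary) pair later
#' receives one fixed-effect level.
#'
#' @param colonies colony data.frame (needs `year`).
#' @param s_a apiary size; must divide each year's colony count.
#' @param seed optional seed.
#' @return The colony data.frame with an `apiary` index column.
#' @export
assign_apiaries <- function(colonies, s_a, seed = NULL) {
  run <- function() {
    for (t in unique(colonies$year)) {
      sel <- which(colonies$year == t)
      if (length(sel) %% s_a != 0L)
        stop("assign_apiaries: apiary size ", s_a,
             " does not divide the ", length(sel),
             " colonies of year ", t)
      colonies$apiary[sel] <- sample(rep(seq_len(length(sel) %/% s_a),
                                         each = s_a))
    }
    colonies
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate colony-model phenotypes
#'
#' y = b(year, apiary) + uQ(queen) + uW(worker group) + e with
#' e ~ N(0, sigma2_E) i.i.d. and one fixed-effect value b drawn per
#' (year, apiary) level from N(0, fixed_effect_sd^2). REML estimation is
#' invariant to the b values; their spread only exercises the fixed-effect
#' machinery.
#'
#' @param colonies colony data.frame with `year` and `apiary` assigned.
#' @param truth data.frame `id, uQ, uW` (e.g. from [simulate_population()]).
#' @param trait a [trait_params()] (supplies sigma2_E).
#' @param fixed_effect_sd standard deviation of the level effects.
#' @param seed optional seed.
#' @return The colony data.frame with `phenotype` filled in.
#' @export
generate_phenotypes <- function(colonies, truth, trait, fixed_effect_sd = 1,
                                seed = NULL) {
  run <- function() {
    lev <- paste(colonies$year, colonies$apiary, sep = ":")
    ulev <- sort(unique(lev))
    b <- stats::rnorm(length(ulev), sd = fixed_effect_sd)
    names(b) <- ulev
    uq <- truth$uQ[match(colonies$queen_id, truth$id)]
    uw <- truth$uW[match(colonies$worker_group_id, truth$id)]
    if (anyNA(uq) || anyNA(uw))
      stop("generate_phenotypes: colony references an entity missing from truth")
    e <- stats::rnorm(nrow(colonies), sd = sqrt(trait$sigma2_E))
    colonies$phenotype <- b[lev] + uq + uw + e
    colonies
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Randomly delete phenotype records
#'
#' Each colony independently keeps its phenotype with probability `q_rate`;
#' pedigree and colony structure are untouched.
#'
#' @param colonies colony data.frame.
#' @param q_rate retention probability in (0, 1].
#' @param seed optional seed.
#' @return The colony data.frame with deleted phenotypes set to `NA`.
#' @export
thin_phenotypes <- function(colonies, q_rate, seed = NULL) {
  stopifnot(q_rate > 0, q_rate <= 1)
  run <- function() {
    drop <- stats::runif(nrow(colonies)) >= q_rate
    colonies$phenotype[drop] <- NA_real_
    colonies
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Sample one mating
#'
#' Draws the sire side of a single mating as the breeding scheme does:
#' uncontrolled matings sample `n_d` drone dams (with replacement) from
#' queens aged 1-3 years; controlled matings pick one of the current year's
#' stations. Used by the simulator internally and exposed for inspection.
#'
#' @param queen_id id of the queen being mated.
#' @param mode `"uncontrolled"` or `"controlled"`.
#' @param population_state list with `pedigree` (current pedigree
#'   data.frame), `year` (current year), `stations` (character ids of this
#'   year's stations, for controlled mode) and `n_drones`.
#' @param seed optional seed.
#' @return List with `drone_dam_ids` (uncontrolled) or `station_id`
#'   (controlled).
#' @export
make_mating <- function(queen_id, mode = c("uncontrolled", "controlled"),
                        population_state, seed = NULL) {
  mode <- match.arg(mode)
  ped <- population_state$pedigree
  t <- population_state$year
  run <- function() {
    if (mode == "uncontrolled") {
      pool <- ped$id[ped$kind == "queen" & ped$year >= t - 2L &
                       ped$year <= t & ped$id != queen_id]
      if (!length(pool)) stop("make_mating: no eligible drone dams")
      list(drone_dam_ids = sample_vec(pool,
                                      population_state$n_drones %||% 12L,
                                      replace = TRUE))
    } else {
      st <- population_state$stations
      if (is.null(st) || !length(st))
        stop("make_mating: no mating stations available")
      list(station_id = sample_vec(st, 1L))
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single inheritance events
#'
#' Draws the genetic value pair of one offspring given parental values, on
#' the scales the breeding model uses: a worker group is exactly half its
#' queen's pair plus the mean of the realized drone gametic pairs (no
#' Mendelian sampling — individual workers' sampling terms cancel in the
#' average); a daughter queen is half her dam's pair plus the father
#' drone's full gametic pair plus a maternal gametic sampling term; a drone
#' is a single gamete of his dam (half her pair plus gametic sampling).
#' Sampling terms are bivariate normal with covariance proportional to the
#' trait's G0: a gamete from a dam with diagonal relationship `a_dd` has
#' sampling covariance (1/2 - a_dd/4) G0, so a full gamete has covariance
#' G0/2 for a non-inbred dam.
#'
#' @param offspring_kind `"worker_group"`, `"queen"` or `"drone"`.
#' @param dam_value numeric pair (uQ, uW) of the dam (the queen, for a
#'   worker group).
#' @param sire_value for a worker group: 2 x n matrix of realized drone
#'   pairs; for a queen: the father drone's pair; ignored for a drone.
#' @param trait a [trait_params()] supplying G0.
#' @param dam_diag the dam's diagonal relationship (1 if non-inbred).
#' @param seed optional seed.
#' @return Numeric pair (uQ, uW).
#' @export
inherit <- function(offspring_kind = c("worker_group", "queen", "drone"),
                    dam_value, sire_value = NULL,
                    trait = trait_params(1, 1, 0, 1), dam_diag = 1,
                    seed = NULL) {
  offspring_kind <- match.arg(offspring_kind)
  R <- chol(trait$G0)
  gam <- function() {
    z <- stats::rnorm(2)
    sqrt(max(0.5 - 0.25 * dam_diag, 0)) *
      c(R[1, 1] * z[1], R[1, 2] * z[1] + R[2, 2] * z[2])
  }
  run <- function() {
    switch(offspring_kind,
      worker_group = {
        stopifnot(is.matrix(sire_value), nrow(sire_value) == 2)
        0.5 * dam_value + rowMeans(sire_value)
      },
      queen = 0.5 * dam_value + as.numeric(sire_value) + gam(),
      drone = 0.5 * dam_value + gam())
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
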