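#' Build the honeybee relationship factorization from a pedigree
#'
#' Constructs the triangular-recursion representation of the additive
#' relationship matrix A over queens, worker groups and mating stations:
#' every entity's genetic value is a fixed linear combination of earlier
#' entities' values plus an independent term, so that
#' \eqn{A = (I-C)^{-1} D (I-C)^{-T}} with C the coefficient matrix and D the
#' diagonal of independent-term variances (unit base variance). The
#' coefficients mirror honeybee inheritance:
#' \itemize{
#'   \item a queen takes 1/2 from her dam plus a paternal gamete: the full
#'     value of one drone, represented by coefficient 1 on her dam's mating
#'     station, or 1/2 on the recorded dam of her father drone (free
#'     mating), plus gametic sampling;
#'   \item a worker group takes 1/2 from its queen plus the mean of the
#'     `n_drones` realized drone gametes: coefficient 1 on the station (plus
#'     a sample-averaging independent term), or 1/(2 n_drones) on each
#'     recorded drone dam (free mating);
#'   \item a mating station carries the mean gametic value of its sister
#'     group of drone-producing queens (DPQs): coefficient 1/4 on the DPQ
#'     dam, and for the DPQs' sires coefficient 1/2 on the dam's own mating
#'     station or 1/(4 n_dpq) on each recorded drone-dam pick.
#' }
#' Uncontrolled matings are represented in the pedigree by pseudo sire-group
#' rows (they carry the realized drone-dam lists) but do not receive rows of
#' A: the realized per-mating drone sample is an exact linear function of
#' queen values, so a matrix row for it would be degenerate (zero
#' independent-term variance); worker groups and daughter queens therefore
#' reference the drone dams directly.
#'
#' Diagonal entries (including inbreeding of later generations and the
#' worker-group diagonal `a_ww`) are accumulated exactly during a forward
#' pass. For large pedigrees the pass keeps a rolling window of recent
#' birth-year rows (all parent links in the breeding scheme reach back at
#' most 4 years); the full dense A is only formed by
#' [relationship_matrix()], which is size-guarded.
#'
#' @param pedigree data.frame with columns `id`, `kind`
#'   (queen/worker_group/sire_group), `dam_id`, `sire_group_id`,
#'   `father_dam_id`, `drone_dam_ids` (semicolon-separated), `year`.
#'   Sire-group rows with a `dam_id` are mating stations; without one they
#'   are pseudo sire groups of free matings.
#' @param n_drones drones per mating used for station-mated worker groups
#'   (free matings carry their realized drone-dam lists).
#' @param n_dpq drone-producing queens per station (used when a station's
#'   DPQ sires are another station's drones).
#' @param dense_limit above this number of parent-capable entities the
#'   forward pass switches to the rolling-window mode.
#' @param window_years years retained in rolling-window mode.
#'
#' @return An object of class `bee_factorization`: ids in topological
#'   order, per-entity parent indices and coefficients, independent-term
#'   variances `d`, diagonal relationships `diag`, and bookkeeping needed
#'   to draw genetic values.
#' @seealso [relationship_matrix()], [a_inverse()], [colony_aww()],
#'   [draw_genetic_values()]
#' @export
build_factorization <- function(pedigree, n_drones = 12L, n_dpq = 8L,
                                dense_limit = 4000L, window_years = 6L) {
  ped <- validate_pedigree(pedigree)
  kind <- ped$kind
  is_station <- kind == "sire_group" & !is.na(ped$dam_id) & ped$dam_id != ""
  is_pseudo  <- kind == "sire_group" & !is_station
  rank <- ifelse(kind == "queen", 0L, ifelse(kind == "sire_group", 1L, 2L))
  o <- order(ped$year, rank)          # stable topological order
  ped <- ped[o, , drop = FALSE]
  kind <- kind[o]; is_station <- is_station[o]; is_pseudo <- is_pseudo[o]

  row_of <- seq_len(nrow(ped)); names(row_of) <- ped$id
  in_a <- !is_pseudo
  aidx <- integer(nrow(ped)); aidx[in_a] <- seq_len(sum(in_a))
  nA <- sum(in_a)

  # resolve references to pedigree rows
  dam_r  <- match(ped$dam_id, ped$id)
  sire_r <- match(ped$sire_group_id, ped$id)
  fdam_r <- match(ped$father_dam_id, ped$id)
  dd_raw <- strsplit(ifelse(is.na(ped$drone_dam_ids), "", ped$drone_dam_ids),
                     ";", fixed = TRUE)
  dd_r <- lapply(dd_raw, function(v) {
    v <- v[v != ""]
    if (!length(v)) return(integer(0))
    m <- match(v, ped$id)
    if (anyNA(m)) stop("pedigree: unknown drone dam id(s): ",
                       paste(v[is.na(m)], collapse = ", "))
    m
  })
  bad <- which(!is.na(ped$dam_id) & ped$dam_id != "" & is.na(dam_r))
  if (length(bad)) stop("pedigree: unknown dam_id '", ped$dam_id[bad[1]],
                        "' for entity ", ped$id[bad[1]])
  bad <- which(!is.na(ped$sire_group_id) & ped$sire_group_id != "" &
                 is.na(sire_r))
  if (length(bad)) stop("pedigree: unknown sire_group_id '",
                        ped$sire_group_id[bad[1]], "' for entity ",
                        ped$id[bad[1]])
  bad <- which(!is.na(ped$father_dam_id) & ped$father_dam_id != "" &
                 is.na(fdam_r))
  if (length(bad)) stop("pedigree: unknown father_dam_id '",
                        ped$father_dam_id[bad[1]], "' for entity ",
                        ped$id[bad[1]])

  parents <- vector("list", nA)   # A-indices
  coefs   <- vector("list", nA)
  dvec    <- numeric(nA)
  dg      <- numeric(nA)          # diagonal of A
  kind2   <- character(nA)
  aux     <- vector("list", nA)   # worker drone-dam info for value drawing

  # parent-capable entities (can appear as parents): queens and stations
  pc <- (kind == "queen") | is_station
  n_pc <- sum(pc)
  use_window <- n_pc > dense_limit
  # rolling dense block of relationships among recent parent-capable rows
  slot <- integer(nA)             # A-index -> row in the window buffer
  pc_a <- integer(0)
  cur_year <- NA_integer_
  grow_step <- 512L

  # preallocate-and-grow version of the window matrix for speed
  Acap <- 0L; Aused <- 0L
  Abuf <- matrix(0, 0L, 0L)
  abuf_year <- integer(0)

  ensure_cap <- function(need) {
    if (need <= Acap) return(invisible())
    newcap <- max(need, Acap + grow_step)
    nb <- matrix(0, newcap, newcap)
    if (Aused) nb[seq_len(Aused), seq_len(Aused)] <- Abuf[seq_len(Aused),
                                                          seq_len(Aused)]
    Abuf <<- nb; Acap <<- newcap
  }

  drop_old <- function(min_year) {
    if (!Aused) return(invisible())
    keep <- which(abuf_year[seq_len(Aused)] >= min_year)
    if (length(keep) == Aused) return(invisible())
    k <- length(keep)
    Abuf[seq_len(k), seq_len(k)] <<- Abuf[keep, keep]
    # remap slots
    old_a <- pc_a
    newslot <- integer(length(slot))
    kept_a <- old_a[keep]
    newslot[kept_a] <- seq_len(k)
    slot <<- newslot
    pc_a <<- kept_a
    abuf_year[seq_len(k)] <<- abuf_year[keep]
    Aused <<- k
  }

  prow_idx <- seq_len(nrow(ped))
  for (r in prow_idx) {
    if (is_pseudo[r]) next
    ai <- aidx[r]
    yr <- ped$year[r]
    if (use_window && (is.na(cur_year) || yr != cur_year)) {
      cur_year <- yr
      drop_old(cur_year - (window_years - 1L))
    }
    k <- kind[r]
    if (k == "queen") {
      if (is.na(dam_r[r])) {                     # base queen
        kind2[ai] <- "base_queen"
        parents[[ai]] <- integer(0); coefs[[ai]] <- numeric(0)
        dvec[ai] <- 1; dg[ai] <- 1
      } else {
        dam_a <- aidx[dam_r[r]]
        p <- dam_a; cf <- 0.5
        dpat <- 0.5                               # paternal gamete, base sire
        sr <- sire_r[r]
        if (!is.na(sr)) {
          if (is_station[sr]) {
            sa <- aidx[sr]
            p <- c(p, sa); cf <- c(cf, 1)
            dpat <- 0.5 - dg[sa]
          } else if (!is.na(fdam_r[r])) {
            fa <- aidx[fdam_r[r]]
            p <- c(p, fa); cf <- c(cf, 0.5)
            dpat <- 0.5 - 0.25 * dg[fa]
          }
        }
        kind2[ai] <- "queen"
        parents[[ai]] <- p; coefs[[ai]] <- cf
        dvec[ai] <- (0.5 - 0.25 * dg[dam_a]) + dpat
      }
    } else if (is_station[r]) {
      Da <- aidx[dam_r[r]]
      p <- Da; cf <- 0.25
      dsum <- (0.5 - 0.25 * dg[Da]) / (4 * n_dpq)   # DPQ maternal gametes
      sr <- sire_r[r]
      if (!is.na(sr) && is_station[sr]) {           # DPQ sires: station drones
        sa <- aidx[sr]
        p <- c(p, sa); cf <- c(cf, 0.5)
        dsum <- dsum + (0.5 - dg[sa]) / (4 * n_dpq)
      } else if (length(dd_r[[r]])) {               # DPQ sires: recorded picks
        picks <- aidx[dd_r[[r]]]
        np <- length(picks)
        tab <- tabulate_int(picks)
        p <- c(p, tab$val); cf <- c(cf, tab$mult / (4 * np))
        dsum <- dsum + sum(0.5 - 0.25 * dg[picks]) / (4 * np^2)
      } else {                                      # DPQ sires: base gametes
        dsum <- dsum + 0.5 / (2 * n_dpq) / 2
      }
      kind2[ai] <- "station"
      parents[[ai]] <- p; coefs[[ai]] <- cf
      dvec[ai] <- dsum
    } else {                                        # worker group
      qa <- aidx[dam_r[r]]
      sr <- sire_r[r]
      if (!is.na(sr) && is_station[sr]) {
        sa <- aidx[sr]
        parents[[ai]] <- c(qa, sa); coefs[[ai]] <- c(0.5, 1)
        dvec[ai] <- (0.5 - dg[sa]) / n_drones
        kind2[ai] <- "worker_st"
        aux[[ai]] <- list(station = sa, n_d = n_drones)
      } else if (!is.na(sr) && length(dd_r[[sr]])) {
        dams <- aidx[dd_r[[sr]]]
        nd <- length(dams)
        tab <- tabulate_int(dams)
        parents[[ai]] <- c(qa, tab$val)
        coefs[[ai]] <- c(0.5, tab$mult / (2 * nd))
        dvec[ai] <- sum(0.5 - 0.25 * dg[dams]) / nd^2
        kind2[ai] <- "worker_unc"
        aux[[ai]] <- list(drone_dams = dams)
      } else {                                      # anonymous base drones
        parents[[ai]] <- qa; coefs[[ai]] <- 0.5
        dvec[ai] <- 0.5 / n_drones
        kind2[ai] <- "worker_base"
        aux[[ai]] <- list(n_d = n_drones)
      }
    }

    # diagonal and (for parent-capable entities) the relationship row
    p <- parents[[ai]]; cf <- coefs[[ai]]
    if (length(p)) {
      sl <- slot[p]
      if (any(sl == 0L))
        stop("relationship window too narrow: parent of ", ped$id[r],
             " fell outside ", window_years, " years")
      Asub <- Abuf[sl, sl, drop = FALSE]
      dg[ai] <- dvec[ai] + drop(crossprod(cf, Asub %*% cf))
    } else {
      dg[ai] <- dvec[ai]
    }
    if (pc[r]) {
      ensure_cap(Aused + 1L)
      if (length(p)) {
        sl <- slot[p]
        prow <- drop(crossprod(cf, Abuf[sl, seq_len(Aused), drop = FALSE]))
      } else prow <- numeric(Aused)
      Aused <- Aused + 1L
      if (length(prow)) {
        Abuf[Aused, seq_len(Aused - 1L)] <- prow
        Abuf[seq_len(Aused - 1L), Aused] <- prow
      }
      Abuf[Aused, Aused] <- dg[ai]
      abuf_year[Aused] <- yr
      slot[ai] <- Aused
      pc_a <- c(pc_a, ai)
    }
  }

  structure(list(
    id = ped$id[in_a], kind = kind[in_a], year = ped$year[in_a],
    parents = parents, coefs = coefs, d = dvec, diag = dg,
    kind2 = kind2, aux = aux, n = nA,
    pedigree_ids = ped$id, in_a = in_a,
    n_drones = n_drones, n_dpq = n_dpq
  ), class = "bee_factorization")
}

# multiplicity table for integer vectors, order-stable
tabulate_int <- function(x) {
  ux <- unique(x)
  list(val = ux, mult = as.numeric(tabulate(match(x, ux), length(ux))))
}

validate_pedigree <- function(ped) {
  req <- c("id", "kind", "dam_id", "sire_group_id", "year")
  miss <- setdiff(req, names(ped))
  if (length(miss)) stop("pedigree lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"father_dam_id" %in% names(ped)) ped$father_dam_id <- NA_character_
  if (!"drone_dam_ids" %in% names(ped)) ped$drone_dam_ids <- NA_character_
  if (anyDuplicated(ped$id))
    stop("pedigree: duplicate id ", ped$id[duplicated(ped$id)][1])
  badk <- !ped$kind %in% c("queen", "worker_group", "sire_group")
  if (any(badk)) stop("pedigree: unknown kind '", ped$kind[badk][1],
                      "' for entity ", ped$id[badk][1])
  for (cc in c("dam_id", "sire_group_id", "father_dam_id", "drone_dam_ids"))
    ped[[cc]][!is.na(ped[[cc]]) & ped[[cc]] == ""] <- NA_character_
  ped
}

#' @export
print.bee_factorization <- function(x, ...) {
  cat(sprintf(
    "bee_factorization: %d entities (%d queens, %d worker groups, %d stations)\n",
    x$n, sum(x$kind == "queen"), sum(x$kind == "worker_group"),
    sum(x$kind == "sire_group")))
  cat(sprintf("  mean worker-group diagonal a_ww = %.4f\n",
              mean(x$diag[x$kind == "worker_group"])))
  invisible(x)
}

#' Dense relationship matrix from a factorization
#'
#' Expands \eqn{A = (I-C)^{-1} D (I-C)^{-T}} by the forward recursion
#' \eqn{a_{i\cdot} = \sum_j c_{ij} a_{j\cdot}}, \eqn{a_{ii} = d_i + c^T A c}.
#' Intended for desk-scale pedigrees; refuses to allocate beyond
#' `max_entities`.
#'
#' @param fact a [build_factorization()] result.
#' @param max_entities guard against accidental huge dense allocations.
#' @return Dense symmetric matrix with `fact$id` dimnames.
#' @export
relationship_matrix <- function(fact, max_entities = 6000L) {
  stopifnot(inherits(fact, "bee_factorization"))
  n <- fact$n
  if (n > max_entities)
    stop("relationship_matrix: ", n, " entities exceed max_entities = ",
         max_entities, "; raise the guard explicitly if intended")
  A <- matrix(0, n, n, dimnames = list(fact$id, fact$id))
  for (i in seq_len(n)) {
    p <- fact$parents[[i]]
    if (length(p) && i > 1L) {
      pr <- drop(crossprod(fact$coefs[[i]],
                           A[p, seq_len(i - 1L), drop = FALSE]))
      A[i, seq_len(i - 1L)] <- pr
      A[seq_len(i - 1L), i] <- pr
    }
    A[i, i] <- fact$diag[i]
  }
  A
}

#' Sparse inverse of the relationship matrix
#'
#' Uses \eqn{A^{-1} = (I-C)^T D^{-1} (I-C)}; the number of stored entries
#' grows linearly with the pedigree. Errors if any independent-term
#' variance is zero (degenerate entity).
#'
#' @inheritParams relationship_matrix
#' @return A sparse symmetric `Matrix::dsCMatrix`.
#' @export
a_inverse <- function(fact) {
  stopifnot(inherits(fact, "bee_factorization"))
  n <- fact$n
  if (any(fact$d <= 0)) {
    bad <- fact$id[which(fact$d <= 0)[1]]
    stop("a_inverse: zero independent-term variance for entity ", bad,
         "; A is singular")
  }
  np <- lengths(fact$parents)
  ii <- c(seq_len(n), rep.int(seq_len(n), np))
  jj <- c(seq_len(n), unlist(fact$parents, use.names = FALSE))
  xx <- c(rep(1, n), -unlist(fact$coefs, use.names = FALSE))
  ImC <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Dinv <- Matrix::Diagonal(n, 1 / fact$d)
  Ainv <- Matrix::crossprod(ImC, Dinv %*% ImC)
  Ainv <- Matrix::forceSymmetric(Ainv)
  dimnames(Ainv) <- list(fact$id, fact$id)
  Ainv
}

#' Worker-worker relationship of a colony
#'
#' Returns the worker-group diagonal of the relationship matrix for one or
#' more colonies (or worker-group ids) — the realized average relationship
#' `a_ww` between two workers of that colony.
#'
#' @param fact a [build_factorization()] result.
#' @param colony a colony data.frame (with `worker_group_id`) or a
#'   character vector of worker-group ids.
#' @return Numeric vector of diagonal relationships.
#' @export
colony_aww <- function(fact, colony) {
  stopifnot(inherits(fact, "bee_factorization"))
  ids <- if (is.data.frame(colony)) colony$worker_group_id else colony
  m <- match(ids, fact$id)
  if (anyNA(m)) stop("colony_aww: unknown worker group ",
                     ids[is.na(m)][1])
  out <- fact$diag[m]
  names(out) <- ids
  out
}

#' Draw replicate genetic values from a factorization
#'
#' Samples bivariate (queen-effect, worker-effect) genetic values for every
#' entity by the exact generative recursion: value = sum of coefficient *
#' parent values + an independent bivariate normal with covariance
#' `d_i * G0`. With the identity G0 the sample covariance across draws
#' converges to A entrywise, which is the package's Monte-Carlo oracle for
#' the relationship construction.
#'
#' @param fact a [build_factorization()] result.
#' @param trait a [trait_params()] whose `G0` scales the values, or `NULL`
#'   for the identity (unit base variance, independent effects).
#' @param n number of independent replicate draws.
#' @param seed optional seed (caller's RNG state is preserved).
#' @return List with matrices `uQ` and `uW` (entities x draws).
#' @export
draw_genetic_values <- function(fact, trait = NULL, n = 1L, seed = NULL) {
  stopifnot(inherits(fact, "bee_factorization"))
  G0 <- if (is.null(trait)) diag(2) else trait$G0
  run <- function() {
    R <- chol(G0)
    nA <- fact$n
    UQ <- matrix(0, nA, n); UW <- matrix(0, nA, n)
    for (i in seq_len(nA)) {
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      s <- sqrt(fact$d[i])
      iq <- s * R[1, 1] * z1
      iw <- s * (R[1, 2] * z1 + R[2, 2] * z2)
      p <- fact$parents[[i]]
      if (length(p)) {
        cf <- fact$coefs[[i]]
        UQ[i, ] <- drop(crossprod(cf, UQ[p, , drop = FALSE])) + iq
        UW[i, ] <- drop(crossprod(cf, UW[p, , drop = FALSE])) + iw
      } else {
        UQ[i, ] <- iq; UW[i, ] <- iw
      }
    }
    rownames(UQ) <- rownames(UW) <- fact$id
    list(uQ = UQ, uW = UW)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
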