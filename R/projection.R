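#' Projected variances of the simplified queen model
#'
#' When colony phenotypes are generated by the colony model (queen effect +
#' averaged worker-group effect) but variance components are estimated with
#' the simplified queen model, the estimates converge not to the queen-effect
#' variance but to *projected* values. A worker group inherits half its
#' queen's worker effect, so the queen model absorbs that half into its
#' single genetic effect:
#' \deqn{\sigma^2_{A(QM)} = \sigma^2_{AQ} + \tfrac14\sigma^2_{AW} + \sigma_{AQW}}
#' \deqn{\sigma^2_{E(QM)} = (a_{ww} - \tfrac14)\,\sigma^2_{AW} + \sigma^2_E}
#' where `aww` is the average additive relationship between two workers of a
#' colony (the worker-group diagonal of the relationship matrix).
#'
#' @param trait a [trait_params()] object.
#' @param aww average worker-worker relationship, in (0, 1].
#' @return Named numeric vector `c(sigma2_A_QM, sigma2_E_QM)`.
#' @seealso [project_wm()], [phenotypic_variance()], [projection_table()]
#' @export
project_qm <- function(trait, aww) {
  stopifnot(inherits(trait, "trait_params"))
  check_aww(aww)
  c(sigma2_A_QM = trait$sigma2_AQ + trait$sigma2_AW / 4 + trait$sigma_AQW,
    sigma2_E_QM = (aww - 0.25) * trait$sigma2_AW + trait$sigma2_E)
}

#' Projected variances of the simplified worker model
#'
#' Analogue of [project_qm()] for the worker model, which attributes all
#' genetic variance to the worker group. The worker group's projected
#' contribution also carries queen-effect information through the
#' queen-worker relationship:
#' \deqn{\sigma^2_{A(WM)} = \frac{1}{4 a_{ww}^2}\sigma^2_{AQ} + \sigma^2_{AW}
#'   + \frac{1}{a_{ww}}\sigma_{AQW}}
#' \deqn{\sigma^2_{E(WM)} = \left(1 - \frac{1}{4 a_{ww}}\right)\sigma^2_{AQ}
#'   + \sigma^2_E}
#'
#' @inheritParams project_qm
#' @return Named numeric vector `c(sigma2_A_WM, sigma2_E_WM)`.
#' @export
project_wm <- function(trait, aww) {
  stopifnot(inherits(trait, "trait_params"))
  check_aww(aww)
  c(sigma2_A_WM = trait$sigma2_AQ / (4 * aww^2) + trait$sigma2_AW +
      trait$sigma_AQW / aww,
    sigma2_E_WM = (1 - 1 / (4 * aww)) * trait$sigma2_AQ + trait$sigma2_E)
}

#' Phenotypic variance of colony records
#'
#' \deqn{\sigma^2_P = \sigma^2_{AQ} + a_{ww}\sigma^2_{AW} + \sigma_{AQW}
#'   + \sigma^2_E}
#' The worker-group effect is an average over related workers, so its
#' variance enters reduced by `aww`.
#'
#' @inheritParams project_qm
#' @return The phenotypic variance (scalar).
#' @export
phenotypic_variance <- function(trait, aww) {
  stopifnot(inherits(trait, "trait_params"))
  check_aww(aww)
  trait$sigma2_AQ + aww * trait$sigma2_AW + trait$sigma_AQW + trait$sigma2_E
}

#' Projected variances for both simplified models
#'
#' Convenience wrapper returning the full set of projected components plus
#' the phenotypic variance; the two decompositions
#' `sigma2_A_QM + sigma2_E_QM` and `aww * sigma2_A_WM + sigma2_E_WM`
#' both equal `sigma2_P` by construction.
#'
#' @inheritParams project_qm
#' @return A list of class `projected_variances`.
#' @export
projected_variances <- function(trait, aww) {
  qm <- project_qm(trait, aww)
  wm <- project_wm(trait, aww)
  structure(list(
    sigma2_A_QM = unname(qm[1]), sigma2_E_QM = unname(qm[2]),
    sigma2_A_WM = unname(wm[1]), sigma2_E_WM = unname(wm[2]),
    sigma2_P    = phenotypic_variance(trait, aww),
    aww_used    = aww), class = "projected_variances")
}

#' Table of projected variances for a set of traits
#'
#' Evaluates the queen-model and worker-model projections for each trait at
#' an uncontrolled-mating and a controlled-mating value of the worker-worker
#' relationship, reproducing the layout of the study's trait table: true
#' components, derived correlation, then the 2x4 block of projected values
#' per mating regime.
#'
#' @param traits list of [trait_params()] objects (e.g. [bee_traits()]).
#' @param aww_uncontrolled worker-worker relationship under free mating;
#'   default 7/24, i.e. 1/4 + 1/(2*12) for 12 unrelated drones.
#' @param aww_controlled worker-worker relationship under station mating;
#'   default 0.37.
#' @return A data.frame with one row per trait.
#' @export
projection_table <- function(traits, aww_uncontrolled = 7 / 24,
                             aww_controlled = 0.37) {
  cols <- c("trait", "sigma2_AQ", "sigma2_AW", "sigma2_E", "sigma_AQW",
            "r_AQW",
            "sigma2_A_QM_unc", "sigma2_E_QM_unc",
            "sigma2_A_WM_unc", "sigma2_E_WM_unc",
            "sigma2_A_QM_con", "sigma2_E_QM_con",
            "sigma2_A_WM_con", "sigma2_E_WM_con")
  if (length(traits) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), length(cols) - 1L)), cols))
    return(out)
  }
  rows <- lapply(seq_along(traits), function(i) {
    tr <- traits[[i]]
    qu <- project_qm(tr, aww_uncontrolled); wu <- project_wm(tr, aww_uncontrolled)
    qc <- project_qm(tr, aww_controlled);   wc <- project_wm(tr, aww_controlled)
    data.frame(
      trait = if (!is.null(tr$name)) tr$name else
        if (!is.null(names(traits))) names(traits)[i] else as.character(i),
      sigma2_AQ = tr$sigma2_AQ, sigma2_AW = tr$sigma2_AW,
      sigma2_E = tr$sigma2_E, sigma_AQW = tr$sigma_AQW, r_AQW = tr$r_AQW,
      sigma2_A_QM_unc = unname(qu[1]), sigma2_E_QM_unc = unname(qu[2]),
      sigma2_A_WM_unc = unname(wu[1]), sigma2_E_WM_unc = unname(wu[2]),
      sigma2_A_QM_con = unname(qc[1]), sigma2_E_QM_con = unname(qc[2]),
      sigma2_A_WM_con = unname(wc[1]), sigma2_E_WM_con = unname(wc[2]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Effective worker-worker relationship under mixed mating
#'
#' With a proportion `p` of queens mated on stations and the rest mated
#' freely, the population-level worker-worker relationship is taken as the
#' weighted average of the two regime values.
#'
#' @param p proportion of controlled matings, in \[0, 1\].
#' @param aww_uncontrolled,aww_controlled regime endpoint values.
#' @return Scalar effective relationship.
#' @export
effective_aww <- function(p, aww_uncontrolled = 7 / 24, aww_controlled = 0.37) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  p * aww_controlled + (1 - p) * aww_uncontrolled
}

check_aww <- function(aww) {
  if (!is.numeric(aww) || length(aww) != 1L || aww <= 0 || aww > 1)
    stop("aww must be a single value in (0, 1]")
  invisible(aww)
}
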