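#' Trait parameters of the colony model
#'
#' Bundles the four (co)variance components of the honeybee colony model:
#' queen-effect additive variance, worker-effect additive variance, their
#' additive covariance, and the residual variance. The genetic correlation
#' between queen and worker effects is derived.
#'
#' @param sigma2_AQ queen-effect additive genetic variance (> 0).
#' @param sigma2_AW worker-effect additive genetic variance (> 0).
#' @param sigma_AQW additive genetic covariance between queen and worker
#'   effects; must satisfy |sigma_AQW| <= sqrt(sigma2_AQ * sigma2_AW).
#' @param sigma2_E residual variance (> 0).
#' @param name optional trait label.
#'
#' @return An object of class `trait_params`: a list with the four
#'   components, the derived correlation `r_AQW`, the 2x2 genetic
#'   covariance matrix `G0`, and the `name`.
#' @examples
#' t1 <- trait_params(1, 2, 0.5, 4)
#' t1$r_AQW  # 0.354
#' @export
trait_params <- function(sigma2_AQ, sigma2_AW, sigma_AQW, sigma2_E,
                         name = NULL) {
  stopifnot(is.numeric(sigma2_AQ), is.numeric(sigma2_AW),
            is.numeric(sigma_AQW), is.numeric(sigma2_E),
            length(sigma2_AQ) == 1L, length(sigma2_AW) == 1L,
            length(sigma_AQW) == 1L, length(sigma2_E) == 1L)
  if (sigma2_AQ <= 0 || sigma2_AW <= 0 || sigma2_E <= 0)
    stop("variances sigma2_AQ, sigma2_AW, sigma2_E must be positive")
  bound <- sqrt(sigma2_AQ * sigma2_AW)
  if (abs(sigma_AQW) > bound + 1e-12)
    stop("sigma_AQW violates |sigma_AQW| <= sqrt(sigma2_AQ * sigma2_AW)")
  structure(list(
    sigma2_AQ = sigma2_AQ,
    sigma2_AW = sigma2_AW,
    sigma_AQW = sigma_AQW,
    sigma2_E  = sigma2_E,
    r_AQW     = sigma_AQW / bound,
    G0        = matrix(c(sigma2_AQ, sigma_AQW, sigma_AQW, sigma2_AW), 2L, 2L,
                       dimnames = list(c("Q", "W"), c("Q", "W"))),
    name      = name
  ), class = "trait_params")
}

#' @export
print.trait_params <- function(x, ...) {
  cat("Colony-model trait parameters",
      if (!is.null(x$name)) paste0(" (", x$name, ")"), "\n", sep = "")
  cat(sprintf("  sigma2_AQ = %g, sigma2_AW = %g, sigma_AQW = %g (r = %.2f), sigma2_E = %g\n",
              x$sigma2_AQ, x$sigma2_AW, x$sigma_AQW, x$r_AQW, x$sigma2_E))
  invisible(x)
}

#' Standard simulated traits T1-T8
#'
#' The eight trait parameter sets used throughout the simulation study:
#' sigma2_AQ = 1, sigma2_AW = 2 for all traits; residual variance 4
#' (T1-T4) or 1 (T5-T8); covariance sigma_AQW cycling through
#' 0.5, 0, -0.5, -1 (correlations 0.35, 0, -0.35, -0.71).
#'
#' @param which optional subset, e.g. `"T7"` or `c("T1", "T4")`.
#' @return A named list of [trait_params()] objects.
#' @export
bee_traits <- function(which = NULL) {
  covs <- c(0.5, 0, -0.5, -1)
  out <- list()
  for (i in 1:8) {
    nm <- paste0("T", i)
    out[[nm]] <- trait_params(
      sigma2_AQ = 1, sigma2_AW = 2,
      sigma_AQW = covs[(i - 1L) %% 4L + 1L],
      sigma2_E  = if (i <= 4) 4 else 1,
      name = nm)
  }
  if (!is.null(which)) out <- out[which]
  out
}
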