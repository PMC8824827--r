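#' Plausibility rule for estimation runs
#'
#' The post-hoc filter applied to every REML run: a run fails if it did not
#' converge within the iteration cap (3000 for EM, 1000 for AI), if any
#' genetic or residual variance estimate lies outside \[0.01, 10\], or (colony
#' model only) if the estimated queen-worker correlation lies outside
#' \[-0.99, 0.99\].
#'
#' @param max_iter_em,max_iter_ai iteration caps per algorithm.
#' @param var_bounds admissible interval for variance estimates.
#' @param cor_bounds admissible interval for the CM correlation estimate.
#' @return A list of class `plausibility_rule`.
#' @export
plausibility_rule <- function(max_iter_em = 3000L, max_iter_ai = 1000L,
                              var_bounds = c(0.01, 10),
                              cor_bounds = c(-0.99, 0.99)) {
  stopifnot(var_bounds[1] < var_bounds[2], cor_bounds[1] < cor_bounds[2])
  structure(list(max_iter_em = max_iter_em, max_iter_ai = max_iter_ai,
                 var_bounds = var_bounds, cor_bounds = cor_bounds),
            class = "plausibility_rule")
}

#' Judge one estimation run
#'
#' @param fit a `reml_fit`.
#' @param rule a [plausibility_rule()].
#' @return List with `pass` (logical) and `reason` (`NA` if passed;
#'   otherwise which criterion fired first: `"not converged"`,
#'   `"variance out of bounds"`, `"correlation out of bounds"`).
#' @export
plausibility <- function(fit, rule = plausibility_rule()) {
  stopifnot(inherits(fit, "reml_fit"))
  cap <- if (fit$algorithm == "EM") rule$max_iter_em else rule$max_iter_ai
  if (!isTRUE(fit$converged) || fit$iterations > cap)
    return(list(pass = FALSE, reason = "not converged"))
  est <- fit$estimates
  vars <- est[names(est) != "sigma_AQW"]
  if (any(vars < rule$var_bounds[1] | vars > rule$var_bounds[2]))
    return(list(pass = FALSE, reason = "variance out of bounds"))
  if (fit$model == "CM") {
    r <- est["sigma_AQW"] / sqrt(est["sigma2_AQ"] * est["sigma2_AW"])
    if (!is.finite(r) || r < rule$cor_bounds[1] || r > rule$cor_bounds[2])
      return(list(pass = FALSE, reason = "correlation out of bounds"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Summarize replicate fits against reference values
#'
#' For each (model, algorithm) cell: bias = mean(estimate - reference) over
#' plausible fits, realized standard error = root mean square deviation
#' from the reference, and the mean AI-predicted standard error. For the
#' colony model the reference is the true generating parameter vector; for
#' the simplified models it is the projected-variance pair.
#'
#' @param fits list of `reml_fit` objects from replicate runs of one
#'   setting.
#' @param reference named numeric vector of reference values matching the
#'   fits' estimate names.
#' @param rule a [plausibility_rule()].
#' @return A one-row-per-component data.frame with `n_runs`, `n_plausible`,
#'   `bias`, `median_bias`, `realized_se`, `mean_predicted_se`.
#' @export
summarize_fits <- function(fits, reference, rule = plausibility_rule()) {
  stopifnot(length(fits) > 0)
  verdicts <- vapply(fits, function(f) plausibility(f, rule)$pass, logical(1))
  keep <- fits[verdicts]
  comp <- names(fits[[1]]$estimates)
  if (!all(comp %in% names(reference)))
    stop("summarize_fits: reference lacks component(s): ",
         paste(setdiff(comp, names(reference)), collapse = ", "))
  out <- data.frame(component = comp,
                    n_runs = length(fits), n_plausible = sum(verdicts),
                    reference = unname(reference[comp]),
                    bias = NA_real_, median_bias = NA_real_,
                    realized_se = NA_real_, mean_predicted_se = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(keep)) return(out)
  E <- t(vapply(keep, function(f) f$estimates[comp], numeric(length(comp))))
  dev <- sweep(E, 2, reference[comp])
  out$bias <- colMeans(dev)
  out$median_bias <- apply(dev, 2, stats::median)
  out$realized_se <- sqrt(colMeans(dev^2))
  ps <- lapply(keep, function(f) f$predicted_se)
  ps <- ps[!vapply(ps, is.null, logical(1))]
  if (length(ps)) {
    PS <- t(vapply(ps, function(v) v[comp], numeric(length(comp))))
    out$mean_predicted_se <- colMeans(PS)
  }
  out
}

#' Run a (scaled-down) simulation-estimation grid
#'
#' For every cell of the requested grid: simulate a population, fit the
#' requested models and algorithms starting from the true (CM) or projected
#' (QM/WM) parameters, apply the plausibility filter, and summarize bias
#' and standard errors against the generating truth. Reference values for
#' the simplified models are the projected variances evaluated at the
#' population's realized mean worker-group diagonal.
#'
#' @param base_cfg a [sim_config()] supplying everything the grid does not
#'   vary (population size, trait, ...).
#' @param traits named list of [trait_params()] to cycle over (default: the
#'   base config's trait).
#' @param p_values,q_values,s_a_values vectors of controlled-mating rates,
#'   phenotype completeness rates and apiary sizes.
#' @param models,algorithms subsets of CM/QM/WM and EM/AI.
#' @param replicates replicate populations per cell.
#' @param seed grid master seed; replicate r of cell c uses
#'   `seed + 1000 * c + r`.
#' @param rule a [plausibility_rule()].
#' @param verbose print one line per cell.
#' @return A tidy data.frame: one row per cell x model x algorithm x
#'   component, with the [summarize_fits()] statistics plus the cell
#'   descriptors and the failure fraction.
#' @export
run_grid <- function(base_cfg, traits = NULL, p_values = base_cfg$p_controlled,
                     q_values = base_cfg$phenotype_rate,
                     s_a_values = base_cfg$apiary_size,
                     models = c("CM", "QM", "WM"),
                     algorithms = c("EM", "AI"),
                     replicates = 5L, seed = 1L,
                     rule = plausibility_rule(), verbose = FALSE) {
  if (is.null(traits)) {
    traits <- list(base_cfg$trait)
    names(traits) <- base_cfg$trait$name %||% "trait"
  }
  cells <- expand.grid(trait = names(traits), p = p_values, q = q_values,
                       s_a = s_a_values, stringsAsFactors = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    tr <- traits[[cell$trait]]
    fits <- list()
    awws <- numeric(replicates)
    for (r in seq_len(replicates)) {
      cfg <- base_cfg
      cfg$trait <- tr
      cfg$p_controlled <- cell$p
      cfg$phenotype_rate <- cell$q
      cfg$apiary_size <- as.integer(cell$s_a)
      cfg$seed <- as.integer(seed + 1000L * ci + r)
      pop <- tryCatch(simulate_population(cfg, keep_drones = FALSE),
                      error = function(e) e)
      if (inherits(pop, "error")) {
        warning("cell ", ci, " rep ", r, " failed: ",
                conditionMessage(pop))
        next
      }
      awws[r] <- mean(pop$fact$diag[pop$fact$kind == "worker_group"])
      Afull <- relationship_matrix(pop$fact)
      for (m in models) for (alg in algorithms) {
        start <- start_values(tr, m, aww = awws[r])
        f <- tryCatch(
          fit_reml(pop, model = m, algorithm = alg, start = start,
                   A = Afull),
          error = function(e) e)
        if (inherits(f, "error")) next
        fits[[length(fits) + 1L]] <- list(fit = f, rep = r, model = m,
                                          algorithm = alg)
      }
    }
    aww_bar <- mean(awws[awws > 0])
    for (m in models) for (alg in algorithms) {
      sel <- Filter(function(z) z$model == m && z$algorithm == alg, fits)
      if (!length(sel)) next
      ref <- switch(m,
        CM = stats::setNames(c(tr$sigma2_AQ, tr$sigma_AQW, tr$sigma2_AW,
                               tr$sigma2_E),
                             c("sigma2_AQ", "sigma_AQW", "sigma2_AW",
                               "sigma2_E")),
        QM = stats::setNames(project_qm(tr, aww_bar),
                             c("sigma2_A", "sigma2_E")),
        WM = stats::setNames(project_wm(tr, aww_bar),
                             c("sigma2_A", "sigma2_E")))
      sm <- summarize_fits(lapply(sel, `[[`, "fit"), ref, rule)
      sm$trait <- cell$trait; sm$p <- cell$p; sm$q <- cell$q
      sm$s_a <- cell$s_a; sm$model <- m; sm$algorithm <- alg
      sm$mean_aww <- aww_bar
      rows[[length(rows) + 1L]] <- sm
    }
    if (verbose)
      message(sprintf("cell %d/%d done (trait %s, p=%g, q=%g, s_a=%d)",
                      ci, nrow(cells), cell$trait, cell$p, cell$q,
                      as.integer(cell$s_a)))
  }
  do.call(rbind, rows)
}
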