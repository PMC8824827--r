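#' Build the mixed-model design for a colony data set
#'
#' Assembles the response vector, the year-by-apiary fixed-effect incidence
#' and the genetic-effect links for one of the three estimation models:
#' the colony model (CM: correlated queen and worker-group effects sharing
#' one relationship matrix), the queen model (QM: one genetic effect on the
#' queen) or the worker model (WM: one genetic effect on the worker group).
#' Only colonies with a phenotype enter; the genetic effect vector spans all
#' pedigree entities, phenotyped or not.
#'
#' @param colonies colony data.frame (`queen_id`, `worker_group_id`,
#'   `year`, `apiary`, `phenotype`).
#' @param fact a [build_factorization()] of the matching pedigree.
#' @param model `"CM"`, `"QM"` or `"WM"`.
#' @return A list of class `reml_design`: `y`, dense `X` (one column per
#'   observed year-by-apiary level), per-record entity indices for each
#'   genetic effect, the number of entities `N`, and bookkeeping.
#' @export
build_design <- function(colonies, fact, model = c("CM", "QM", "WM")) {
  model <- match.arg(model)
  stopifnot(inherits(fact, "bee_factorization"))
  rec <- colonies[!is.na(colonies$phenotype), , drop = FALSE]
  if (!nrow(rec)) stop("build_design: no phenotyped colonies")
  qi <- match(rec$queen_id, fact$id)
  wi <- match(rec$worker_group_id, fact$id)
  if (anyNA(qi)) stop("build_design: unknown queen entity ",
                      rec$queen_id[is.na(qi)][1])
  if (anyNA(wi)) stop("build_design: unknown worker group ",
                      rec$worker_group_id[is.na(wi)][1])
  lev <- factor(paste(rec$year, rec$apiary, sep = ":"))
  X <- stats::model.matrix(~ 0 + lev)
  colnames(X) <- levels(lev)
  idx <- switch(model, CM = list(Q = qi, W = wi), QM = list(Q = qi),
                WM = list(W = wi))
  structure(list(y = rec$phenotype, X = X, model = model,
                 index = idx, N = fact$n, n = nrow(rec),
                 record_ids = rec$colony_id, fact = fact),
            class = "reml_design")
}

# generic design for arbitrary (y, X, Z-index, A): used by tests/oracles
new_design <- function(y, X, index, A, model = "QM") {
  structure(list(y = y, X = as.matrix(X), model = model, index = index,
                 N = nrow(A), n = length(y), A = A, fact = NULL),
            class = "reml_design")
}

# ---- preparation -----------------------------------------------------------

# reduce X to a full-rank column basis by pivoted QR
fullrank_X <- function(X) {
  qrX <- qr(X)
  r <- qrX$rank
  X[, qrX$pivot[seq_len(r)], drop = FALSE]
}

reml_prep <- function(design, A = NULL) {
  stopifnot(inherits(design, "reml_design"))
  if (is.null(A)) A <- design$A
  if (is.null(A)) {
    A <- relationship_matrix(design$fact)
  } else if (inherits(A, "bee_factorization")) {
    A <- relationship_matrix(A)
  }
  X <- fullrank_X(design$X)
  n <- design$n; p <- ncol(X)
  pp <- list(y = design$y, X = X, n = n, p = p, N = design$N,
             model = design$model)
  if (design$model == "CM") {
    qi <- design$index$Q; wi <- design$index$W
    pp$Mqq <- A[qi, qi, drop = FALSE]
    pp$Mqw <- A[qi, wi, drop = FALSE]
    pp$Mww <- A[wi, wi, drop = FALSE]
    pp$backend <- "dense"
  } else {
    ii <- design$index[[1]]
    M <- A[ii, ii, drop = FALSE]
    eg <- eigen(M, symmetric = TRUE)
    pp$lam <- pmax(eg$values, 0)
    pp$yt <- drop(crossprod(eg$vectors, design$y))
    pp$Xt <- crossprod(eg$vectors, X)
    pp$backend <- "spectral"
  }
  pp
}

# ---- per-iteration statistics ---------------------------------------------

# theta: list(G = r x r genetic covariance matrix, se = residual variance)
reml_stats <- function(theta, pp, need_ai = FALSE) {
  if (pp$backend == "dense") dense_stats(theta, pp, need_ai)
  else spectral_stats(theta, pp, need_ai)
}

dense_stats <- function(theta, pp, need_ai) {
  G <- theta$G; se <- theta$se
  n <- pp$n
  V <- G[1, 1] * pp$Mqq + G[2, 2] * pp$Mww + se * diag(n)
  if (G[1, 2] != 0) V <- V + G[1, 2] * (pp$Mqw + t(pp$Mqw))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE, reason = "V not positive definite"))
  ldV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% pp$X
  XtViX <- crossprod(pp$X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(list(ok = FALSE, reason = "singular X'V-X"))
  ldX <- 2 * sum(log(diag(chx)))
  S <- chol2inv(chx)
  P <- Vi - ViX %*% tcrossprod(S, ViX)
  pv <- drop(P %*% pp$y)
  yPy <- sum(pp$y * pv)
  logL <- -0.5 * (ldV + ldX + yPy + (n - pp$p) * log(2 * pi))
  v1 <- drop(pp$Mqq %*% pv)
  v2a <- drop(pp$Mqw %*% pv); v2b <- drop(crossprod(pp$Mqw, pv))
  v3 <- drop(pp$Mww %*% pv)
  Qm <- matrix(c(sum(pv * v1), sum(pv * v2a), sum(pv * v2a), sum(pv * v3)),
               2, 2)
  Tm <- matrix(0, 2, 2)
  Tm[1, 1] <- sum(P * pp$Mqq)
  Tm[2, 2] <- sum(P * pp$Mww)
  Tm[1, 2] <- Tm[2, 1] <- sum(P * t(pp$Mqw))
  out <- list(ok = TRUE, logL = logL, yPy = yPy, Qm = Qm, Tm = Tm,
              pp2 = sum(pv^2), trP = sum(diag(P)))
  if (need_ai) {
    # theta order: (g_QQ, g_QW, g_WW, se)
    vs <- list(v1, v2a + v2b, v3, pv)
    score <- numeric(4)
    score[1] <- -0.5 * (Tm[1, 1] - Qm[1, 1])
    score[2] <- -0.5 * (2 * Tm[1, 2] - 2 * Qm[1, 2])
    score[3] <- -0.5 * (Tm[2, 2] - Qm[2, 2])
    score[4] <- -0.5 * (out$trP - out$pp2)
    Pv <- lapply(vs, function(v) drop(P %*% v))
    AI <- matrix(0, 4, 4)
    for (a in 1:4) for (b in a:4)
      AI[a, b] <- AI[b, a] <- 0.5 * sum(vs[[a]] * Pv[[b]])
    out$score <- score; out$AI <- AI
  }
  out
}

spectral_stats <- function(theta, pp, need_ai) {
  sa <- theta$G[1, 1]; se <- theta$se
  dvec <- sa * pp$lam + se
  if (any(dvec <= 0)) return(list(ok = FALSE,
                                  reason = "V not positive definite"))
  w <- 1 / dvec
  Xw <- pp$Xt * w
  XtViX <- crossprod(pp$Xt, Xw)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(list(ok = FALSE, reason = "singular X'V-X"))
  S <- chol2inv(chx)
  bv <- crossprod(Xw, pp$yt)
  pv <- w * pp$yt - drop(Xw %*% (S %*% bv))
  yPy <- sum(pp$yt * pv)
  ldV <- sum(log(dvec))
  ldX <- 2 * sum(log(diag(chx)))
  logL <- -0.5 * (ldV + ldX + yPy + (pp$n - pp$p) * log(2 * pi))
  XwXw <- crossprod(Xw)
  trP <- sum(w) - sum(S * XwXw)
  XtMX <- crossprod(pp$Xt, pp$Xt * (w * w * pp$lam))
  trPM <- sum(w * pp$lam) - sum(S * XtMX)
  Qm <- matrix(sum(pp$lam * pv^2), 1, 1)
  Tm <- matrix(trPM, 1, 1)
  out <- list(ok = TRUE, logL = logL, yPy = yPy, Qm = Qm, Tm = Tm,
              pp2 = sum(pv^2), trP = trP)
  if (need_ai) {
    qPr <- function(a, b)
      sum(a * w * b) - drop(crossprod(crossprod(Xw, a),
                                      S %*% crossprod(Xw, b)))
    vM <- pp$lam * pv
    score <- c(-0.5 * (trPM - sum(pp$lam * pv^2)),
               -0.5 * (trP - sum(pv^2)))
    AI <- matrix(0, 2, 2)
    AI[1, 1] <- 0.5 * qPr(vM, vM)
    AI[1, 2] <- AI[2, 1] <- 0.5 * qPr(vM, pv)
    AI[2, 2] <- 0.5 * qPr(pv, pv)
    out$score <- score; out$AI <- AI
  }
  out
}

# ---- parameter vector helpers ----------------------------------------------

theta_to_vec <- function(theta, model) {
  if (model == "CM")
    c(sigma2_AQ = theta$G[1, 1], sigma_AQW = theta$G[1, 2],
      sigma2_AW = theta$G[2, 2], sigma2_E = theta$se)
  else c(sigma2_A = theta$G[1, 1], sigma2_E = theta$se)
}

vec_to_theta <- function(v, model) {
  v <- unname(v)
  if (model == "CM")
    list(G = matrix(c(v[1], v[2], v[2], v[3]), 2, 2), se = v[4])
  else list(G = matrix(v[1], 1, 1), se = v[2])
}

start_theta <- function(start, model) {
  if (inherits(start, "trait_params")) {
    if (model != "CM")
      stop("for QM/WM supply numeric start values (e.g. projected variances)")
    return(list(G = start$G0, se = start$sigma2_E))
  }
  v <- unlist(start, use.names = FALSE)
  k <- if (model == "CM") 4L else 2L
  if (length(v) != k)
    stop("start for ", model, " needs ", k, " values")
  vec_to_theta(v, model)
}

conv_measure <- function(vnew, vold) sum((vnew - vold)^2) / sum(vnew^2)

new_reml_fit <- function(model, algorithm, theta, iters, converged, cc,
                         logL, se_pred = NULL, failure = NULL,
                         trace = NULL, monotone = NA) {
  est <- theta_to_vec(theta, model)
  structure(list(model = model, algorithm = algorithm,
                 estimates = est,
                 r_AQW = if (model == "CM")
                   unname(est[2] / sqrt(abs(est[1] * est[3]))) else NA_real_,
                 iterations = iters, converged = converged,
                 conv_measure = cc, loglik = logL,
                 predicted_se = se_pred, failure = failure,
                 trace = trace, em_monotone = monotone),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit [%s, %s-REML]: %s after %d iterations (cc = %.2e)\n",
              x$model, x$algorithm,
              if (x$converged) "converged" else
                paste0("NOT converged",
                       if (!is.null(x$failure)) paste0(" (", x$failure, ")")),
              x$iterations, x$conv_measure))
  print(round(x$estimates, 5))
  if (!is.null(x$predicted_se)) {
    cat("predicted SE:\n"); print(round(x$predicted_se, 5))
  }
  invisible(x)
}

# ---- EM-REML ---------------------------------------------------------------

#' EM-REML estimation
#'
#' Classical expectation-maximization REML on the honeybee mixed model:
#' genetic (co)variances are updated from the conditional expectation of
#' the random-effect quadratic forms (equivalently
#' \eqn{G \leftarrow G + G(Q - T)G/N} with Q the quadratic forms
#' \eqn{y'P M_{rs} P y} and T the traces \eqn{tr(P M_{rs})}), the residual
#' variance from \eqn{\sigma^2_E\, y'Py/(n - rank X)}. No acceleration is
#' applied; the restricted log-likelihood is monitored and is
#' non-decreasing by construction (recorded in `em_monotone`).
#'
#' @param design a [build_design()] result (or generic design).
#' @param A relationship information: a `bee_factorization`, a dense
#'   relationship matrix, or `NULL` to use the design's own.
#' @param start starting values: a [trait_params()] (CM) or a numeric
#'   vector (CM: sigma2_AQ, sigma_AQW, sigma2_AW, sigma2_E; QM/WM:
#'   sigma2_A, sigma2_E).
#' @param max_iter iteration cap (default 3000).
#' @param tol convergence criterion on the squared relative parameter
#'   change (default 1e-12).
#' @return A `reml_fit` object; numerical failure is recorded in the
#'   object's `failure` field, not thrown.
#' @export
em_reml <- function(design, A = NULL, start, max_iter = 3000L, tol = 1e-12) {
  pp <- reml_prep(design, A)
  model <- pp$model
  theta <- start_theta(start, model)
  vold <- theta_to_vec(theta, model)
  logL_prev <- -Inf; monotone <- TRUE
  trace <- list()
  cc <- Inf; iters <- 0L; logL <- NA_real_
  for (it in seq_len(max_iter)) {
    st <- reml_stats(theta, pp, need_ai = FALSE)
    if (!st$ok)
      return(new_reml_fit(model, "EM", theta, iters, FALSE, cc, logL,
                          failure = st$reason, trace = trace,
                          monotone = monotone))
    logL <- st$logL
    if (is.finite(logL_prev) && logL < logL_prev - 1e-7 * abs(logL_prev))
      monotone <- FALSE
    logL_prev <- logL
    G <- theta$G
    Gnew <- G + G %*% (st$Qm - st$Tm) %*% G / pp$N
    senew <- theta$se * st$yPy / (pp$n - pp$p)
    theta <- list(G = (Gnew + t(Gnew)) / 2, se = senew)
    vnew <- theta_to_vec(theta, model)
    cc <- conv_measure(vnew, vold)
    vold <- vnew
    iters <- it
    trace[[it]] <- c(vnew, logL = logL)
    if (cc < tol) break
  }
  converged <- cc < tol
  new_reml_fit(model, "EM", theta, iters, converged, cc, logL,
               failure = if (!converged) "max_iter reached" else NULL,
               trace = do.call(rbind, trace), monotone = monotone)
}

# ---- AI-REML ---------------------------------------------------------------

#' AI-REML estimation
#'
#' Newton-type REML using the average-information matrix. Updates are
#' unconstrained (estimates may leave the admissible region, exactly as the
#' downstream plausibility filter expects); a step is halved when the
#' restricted log-likelihood would decrease or the implied V loses positive
#' definiteness. On convergence the predicted standard errors are the
#' square roots of the diagonal of the inverse average-information matrix.
#'
#' @inheritParams em_reml
#' @param max_iter iteration cap (default 1000).
#' @param max_halving maximum step halvings per iteration.
#' @return A `reml_fit`; failures (non-invertible AI matrix, iteration cap)
#'   are flagged, not thrown.
#' @export
ai_reml <- function(design, A = NULL, start, max_iter = 1000L, tol = 1e-12,
                    max_halving = 30L) {
  pp <- reml_prep(design, A)
  model <- pp$model
  theta <- start_theta(start, model)
  vold <- theta_to_vec(theta, model)
  k <- length(vold)
  st <- reml_stats(theta, pp, need_ai = TRUE)
  if (!st$ok)
    return(new_reml_fit(model, "AI", theta, 0L, FALSE, Inf, NA_real_,
                        failure = paste("at start:", st$reason)))
  trace <- list()
  cc <- Inf; iters <- 0L
  for (it in seq_len(max_iter)) {
    delta <- tryCatch(solve(st$AI, st$score), error = function(e) NULL)
    if (is.null(delta))
      return(new_reml_fit(model, "AI", theta, iters, FALSE, cc, st$logL,
                          failure = "AI matrix not invertible",
                          trace = do.call(rbind, trace)))
    step <- 1; ok <- FALSE
    for (h in seq_len(max_halving)) {
      vtry <- vold + step * delta
      ttry <- vec_to_theta(vtry, model)
      sttry <- reml_stats(ttry, pp, need_ai = TRUE)
      if (sttry$ok && sttry$logL >= st$logL - 1e-10 * abs(st$logL)) {
        ok <- TRUE; break
      }
      step <- step / 2
    }
    if (!ok)
      return(new_reml_fit(model, "AI", theta, iters, FALSE, cc, st$logL,
                          failure = "step-halving failed",
                          trace = do.call(rbind, trace)))
    theta <- ttry; st <- sttry
    vnew <- vtry
    cc <- conv_measure(vnew, vold)
    vold <- vnew
    iters <- it
    trace[[it]] <- c(vnew, logL = st$logL)
    if (cc < tol) break
  }
  converged <- cc < tol
  se_pred <- tryCatch({
    Ainv <- solve(st$AI)
    sp <- sqrt(pmax(diag(Ainv), 0))
    names(sp) <- names(theta_to_vec(theta, model))
    sp
  }, error = function(e) NULL)
  new_reml_fit(model, "AI", theta, iters, converged, cc, st$logL,
               se_pred = se_pred,
               failure = if (!converged) "max_iter reached" else NULL,
               trace = do.call(rbind, trace))
}

# ---- orchestrator ----------------------------------------------------------

#' Fit a model to colony data by REML
#'
#' Orchestrates design construction, relationship processing and the chosen
#' estimation algorithm for a simulated population or a
#' (colonies, pedigree) pair.
#'
#' @param colonies colony data.frame, or a `bee_population`.
#' @param pedigree pedigree data.frame or a `bee_factorization` (ignored if
#'   `colonies` is a `bee_population`).
#' @param model `"CM"`, `"QM"` or `"WM"`.
#' @param algorithm `"EM"` or `"AI"`.
#' @param start starting values (see [em_reml()]); the study design uses
#'   the true generating parameters, [start_values()] builds them.
#' @param max_iter,tol passed to the algorithm (defaults: EM 3000, AI 1000
#'   iterations; tol 1e-12).
#' @param A optional precomputed dense relationship matrix (avoids
#'   recomputation across models on the same population).
#' @return A `reml_fit`.
#' @export
fit_reml <- function(colonies, pedigree = NULL,
                     model = c("CM", "QM", "WM"),
                     algorithm = c("EM", "AI"), start,
                     max_iter = NULL, tol = 1e-12, A = NULL) {
  model <- match.arg(model); algorithm <- match.arg(algorithm)
  if (inherits(colonies, "bee_population")) {
    fact <- colonies$fact
    colonies <- colonies$colonies
  } else if (inherits(pedigree, "bee_factorization")) {
    fact <- pedigree
  } else {
    fact <- build_factorization(pedigree)
  }
  design <- build_design(colonies, fact, model)
  if (is.null(max_iter)) max_iter <- if (algorithm == "EM") 3000L else 1000L
  if (algorithm == "EM") em_reml(design, A, start, max_iter, tol)
  else ai_reml(design, A, start, max_iter, tol)
}

#' Starting values for the three models
#'
#' The estimation study starts every run at the true generating parameters:
#' for the colony model these are the trait's components; for the
#' simplified models the projected variances at the population's
#' worker-worker relationship.
#'
#' @param trait a [trait_params()].
#' @param model `"CM"`, `"QM"` or `"WM"`.
#' @param aww worker-worker relationship used for the projections.
#' @return Numeric start vector as expected by [em_reml()]/[ai_reml()].
#' @export
start_values <- function(trait, model = c("CM", "QM", "WM"), aww = 7 / 24) {
  model <- match.arg(model)
  switch(model,
    CM = c(trait$sigma2_AQ, trait$sigma_AQW, trait$sigma2_AW,
           trait$sigma2_E),
    QM = unname(project_qm(trait, aww)),
    WM = unname(project_wm(trait, aww)))
}
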