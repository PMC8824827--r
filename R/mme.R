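#' Restricted log-likelihood of the colony mixed model
#'
#' Evaluates the REML log-likelihood
#' \eqn{-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py + (n-p)\log 2\pi]}
#' for a given parameter vector, by one of two independent routes:
#' `"dense"` forms the n x n phenotypic covariance V directly;
#' `"mme"` works through Henderson's mixed-model equations and the sparse
#' inverse relationship matrix, using the determinant identities
#' \eqn{\log|V| = n\log\sigma^2_E + \log|G| + \log|C_{uu}|} and
#' \eqn{\log|X'V^{-1}X| = \log|C| - \log|C_{uu}|}. The two routes agree to
#' numerical precision, which the test suite exploits as an oracle.
#'
#' @param theta numeric parameter vector (CM: sigma2_AQ, sigma_AQW,
#'   sigma2_AW, sigma2_E; QM/WM: sigma2_A, sigma2_E).
#' @param design a [build_design()] result.
#' @param A optional relationship information (factorization or dense A).
#' @param method `"dense"` or `"mme"`.
#' @return The restricted log-likelihood (scalar); `-Inf` with a warning if
#'   the implied covariance is not positive definite.
#' @export
restricted_loglik <- function(theta, design, A = NULL,
                              method = c("dense", "mme")) {
  method <- match.arg(method)
  model <- design$model
  th <- vec_to_theta(unlist(theta, use.names = FALSE), model)
  if (th$se <= 0) stop("restricted_loglik: residual variance must be > 0")
  if (method == "dense") {
    pp <- reml_prep(design, A)
    st <- reml_stats(th, pp, need_ai = FALSE)
    if (!st$ok) { warning("non-PD V: ", st$reason); return(-Inf) }
    return(st$logL)
  }
  mme_loglik(th, design, A)
}

mme_loglik <- function(th, design, A = NULL) {
  n <- design$n
  X <- fullrank_X(design$X)
  p <- ncol(X)
  idx <- design$index
  r <- length(idx)
  N <- design$N
  fact <- design$fact

  if (!is.null(fact)) {
    Ainv <- a_inverse(fact)
    ldA <- sum(log(fact$d))
  } else {
    Afull <- if (is.null(A)) design$A else A
    cha <- chol(Afull)
    ldA <- 2 * sum(log(diag(cha)))
    Ainv <- Matrix::Matrix(chol2inv(cha), sparse = TRUE)
  }

  G0 <- th$G; se <- th$se
  chg <- tryCatch(chol(G0), error = function(e) NULL)
  if (is.null(chg)) { warning("G0 not positive definite"); return(-Inf) }
  ldG <- N * 2 * sum(log(diag(chg))) + r * ldA
  G0inv <- chol2inv(chg)
  Ginv <- kronecker(G0inv, Ainv)

  Zs <- lapply(idx, function(ii)
    Matrix::sparseMatrix(i = seq_len(n), j = ii, x = 1, dims = c(n, N)))
  Z <- do.call(cbind, Zs)
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  WtW <- Matrix::crossprod(W)
  pad <- Matrix::bdiag(Matrix::Matrix(0, p, p), Ginv)
  C <- Matrix::forceSymmetric(WtW / se + pad)
  Cuu <- Matrix::forceSymmetric(Matrix::crossprod(Z) / se + Ginv)

  ldC <- as.numeric(Matrix::determinant(C, logarithm = TRUE)$modulus)
  ldCuu <- as.numeric(Matrix::determinant(Cuu, logarithm = TRUE)$modulus)

  rhs <- Matrix::crossprod(W, design$y) / se
  sol <- Matrix::solve(C, rhs)
  yPy <- (sum(design$y^2) - sum(as.numeric(sol) *
                                  as.numeric(Matrix::crossprod(W, design$y)))) / se

  ldV <- n * log(se) + ldG + ldCuu
  ldX <- ldC - ldCuu
  -0.5 * (ldV + ldX + yPy + (n - p) * log(2 * pi))
}

#' BLUP solutions of the mixed-model equations
#'
#' Solves Henderson's equations at given variance components, returning the
#' fixed-effect estimates and the predicted genetic effects for every
#' pedigree entity (phenotyped or not).
#'
#' @inheritParams restricted_loglik
#' @return List with `fixed` (named vector) and `u` (matrix: entities x
#'   effects, e.g. columns Q and W for the colony model).
#' @export
blup_solutions <- function(theta, design, A = NULL) {
  model <- design$model
  th <- vec_to_theta(unlist(theta, use.names = FALSE), model)
  n <- design$n
  X <- fullrank_X(design$X)
  p <- ncol(X)
  idx <- design$index
  r <- length(idx)
  N <- design$N
  fact <- design$fact
  if (!is.null(fact)) {
    Ainv <- a_inverse(fact)
  } else {
    Afull <- if (is.null(A)) design$A else A
    Ainv <- Matrix::Matrix(chol2inv(chol(Afull)), sparse = TRUE)
  }
  chg <- chol(th$G)
  Ginv <- kronecker(chol2inv(chg), Ainv)
  Zs <- lapply(idx, function(ii)
    Matrix::sparseMatrix(i = seq_len(n), j = ii, x = 1, dims = c(n, N)))
  Z <- do.call(cbind, Zs)
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  C <- Matrix::forceSymmetric(Matrix::crossprod(W) / th$se +
                                Matrix::bdiag(Matrix::Matrix(0, p, p), Ginv))
  sol <- as.numeric(Matrix::solve(C, Matrix::crossprod(W, design$y) / th$se))
  u <- matrix(sol[-seq_len(p)], N, r)
  colnames(u) <- names(idx)
  if (!is.null(fact)) rownames(u) <- fact$id
  list(fixed = stats::setNames(sol[seq_len(p)], colnames(X)), u = u)
}
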