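# REML core: design construction, likelihood oracles, EM properties,
# AI behavior and cross-algorithm agreement.

test_that("design matrices have the stated structure", {
  pop <- small_mixed_pop()
  des <- build_design(pop$colonies, pop$fact, "CM")
  n <- sum(!is.na(pop$colonies$phenotype))
  expect_equal(length(des$y), n)
  # one fixed-effect column per observed year-by-apiary level, one 1 per row
  expect_equal(ncol(des$X),
               nrow(unique(pop$colonies[, c("year", "apiary")])))
  expect_true(all(rowSums(des$X) == 1))
  # CM links each record to its queen and its worker group
  expect_equal(pop$fact$id[des$index$Q], pop$colonies$queen_id)
  expect_equal(pop$fact$id[des$index$W], pop$colonies$worker_group_id)
  # thinning drops rows from the design only
  th <- thin_phenotypes(pop$colonies, 0.5, seed = 4)
  des2 <- build_design(th, pop$fact, "QM")
  expect_equal(length(des2$y), sum(!is.na(th$phenotype)))
  expect_error(build_design(transform(pop$colonies, queen_id = "nope"),
                            pop$fact, "CM"), "unknown queen")
})

test_that("MME and dense-V restricted likelihoods agree", {
  # small instance (<= 60 records) across models and parameter points
  cfg <- sim_config(n_years = 3, queens_per_year = 20, n_dams = 4,
                    daughters_per_dam = 5, n_stations = 2,
                    p_controlled = 0.5, apiary_size = 10,
                    trait = bee_traits()[["T2"]], seed = 61)
  pop <- simulate_population(cfg, keep_drones = FALSE)
  des <- build_design(pop$colonies, pop$fact, "CM")
  for (th in list(c(1, 0, 2, 4), c(0.5, -0.3, 1.5, 2), c(2, 0.8, 1, 0.7))) {
    expect_equal(restricted_loglik(th, des, method = "dense"),
                 restricted_loglik(th, des, method = "mme"),
                 tolerance = 1e-8)
  }
  for (m in c("QM", "WM")) {
    dm <- build_design(pop$colonies, pop$fact, m)
    for (th in list(c(1, 4), c(0.3, 1.2)))
      expect_equal(restricted_loglik(th, dm, method = "dense"),
                   restricted_loglik(th, dm, method = "mme"),
                   tolerance = 1e-8)
  }
})

test_that("likelihood limits and invariances hold", {
  pop <- small_mixed_pop()
  des <- build_design(pop$colonies, pop$fact, "QM")
  # vanishing genetic variance: equals the fixed-effects-only restricted
  # Gaussian likelihood computed directly
  th <- c(1e-12, 2.5)
  X <- des$X[, qr(des$X)$pivot[seq_len(qr(des$X)$rank)], drop = FALSE]
  n <- length(des$y); p <- ncol(X)
  r <- stats::lm.fit(X, des$y)$residuals
  direct <- -0.5 * (n * log(2.5) + determinant(crossprod(X) / 2.5,
                                               TRUE)$modulus[1] +
                      sum(r^2) / 2.5 + (n - p) * log(2 * pi))
  expect_equal(restricted_loglik(th, des), as.numeric(direct),
               tolerance = 1e-6)
  # a constant shift absorbed by the level-indicator X changes nothing
  des2 <- des; des2$y <- des$y + 7
  th2 <- c(0.8, 1.3)
  expect_equal(restricted_loglik(th2, des), restricted_loglik(th2, des2),
               tolerance = 1e-9)
})

test_that("EM matches closed-form ANOVA on a balanced half-sib design", {
  # s unrelated sires, k progeny each: REML equals Henderson ANOVA
  set.seed(31)
  s <- 40L; k <- 8L
  sig_s <- 0.7; sig_e <- 2.2
  u <- rnorm(s, sd = sqrt(sig_s))
  y <- rep(u, each = k) + rnorm(s * k, sd = sqrt(sig_e))
  A <- diag(s)
  des <- beereml:::new_design(y, matrix(1, s * k, 1),
                              list(S = rep(seq_len(s), each = k)), A)
  msb <- k * var(tapply(y, rep(seq_len(s), each = k), mean))
  msw <- sum((y - rep(tapply(y, rep(seq_len(s), each = k), mean),
                      each = k))^2) / (s * (k - 1))
  fit <- em_reml(des, start = c(sig_s, sig_e), max_iter = 5000)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["sigma2_E"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["sigma2_A"]), (msb - msw) / k,
               tolerance = 1e-5)
})

test_that("EM is likelihood-monotone and its fixed point is a maximum", {
  pop <- small_mixed_pop()
  des <- build_design(pop$colonies, pop$fact, "CM")
  fit <- em_reml(des, start = c(1, 0, 2, 4), max_iter = 400)
  expect_true(fit$em_monotone)
  ll <- fit$trace[, "logL"]
  expect_true(all(diff(ll) > -1e-7 * abs(ll[-length(ll)])))
  # run EM to its fixed point on a better-conditioned instance and check
  # a surrounding parameter grid never beats it
  pop2 <- small_ctrl_pop()
  des2 <- build_design(pop2$colonies, pop2$fact, "QM")
  fx <- em_reml(des2, start = c(1.5, 1.5), max_iter = 8000, tol = 1e-13)
  th0 <- unname(fx$estimates)
  l0 <- restricted_loglik(th0, des2)
  for (d1 in c(-0.05, -0.01, 0.01, 0.05)) for (d2 in c(-0.05, 0, 0.05)) {
    th <- th0 * (1 + c(d1, d2))
    expect_lt(restricted_loglik(th, des2), l0 + 1e-9)
  }
})

test_that("null-signal data drives the genetic variance to the boundary", {
  pop <- small_mixed_pop()
  col <- pop$colonies
  set.seed(12)
  col$phenotype <- rnorm(nrow(col), sd = 1.3)   # residual only
  des <- build_design(col, pop$fact, "QM")
  fit <- em_reml(des, start = c(0.5, 1), max_iter = 2000)
  expect_lt(fit$estimates["sigma2_A"], 0.05)
  # residual estimate ~ the data's own within-level variance
  lev <- paste(col$year, col$apiary)
  r <- residuals(lm(col$phenotype ~ 0 + factor(lev)))
  s2 <- sum(r^2) / (length(r) - length(unique(lev)))
  expect_equal(unname(fit$estimates["sigma2_E"]), s2, tolerance = 0.05)
})

test_that("AI-REML agrees with EM and predicts standard errors", {
  pop <- small_ctrl_pop()
  des <- build_design(pop$colonies, pop$fact, "QM")
  fe <- em_reml(des, start = c(1.5, 1.5), max_iter = 8000, tol = 1e-13)
  fa <- ai_reml(des, start = c(1.5, 1.5))
  expect_true(fa$converged && fe$converged)
  expect_equal(unname(fa$estimates), unname(fe$estimates),
               tolerance = 1e-3)
  expect_true(all(is.finite(fa$predicted_se)) && all(fa$predicted_se > 0))
  # restarting at the optimum converges immediately
  fa2 <- ai_reml(des, start = unname(fa$estimates))
  expect_lte(fa2$iterations, 2L)
  # the CM orchestrator runs end to end on the same data
  fcm <- fit_reml(pop, model = "CM", algorithm = "AI",
                  start = start_values(pop$cfg$trait, "CM"))
  expect_s3_class(fcm, "reml_fit")
  expect_named(fcm$estimates,
               c("sigma2_AQ", "sigma_AQW", "sigma2_AW", "sigma2_E"))
})

test_that("AI failures are flagged, not thrown", {
  pop <- small_mixed_pop()
  col <- pop$colonies
  col$phenotype <- 3.7            # constant phenotypes: degenerate
  des <- build_design(col, pop$fact, "WM")
  fit <- ai_reml(des, start = c(1, 1), max_iter = 50)
  expect_s3_class(fit, "reml_fit")
  expect_false(is.null(fit$failure) && fit$converged &&
                 all(fit$estimates > 0.01))
})
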