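# Relationship factorization: exact small-pedigree values, inverse
# identities, and the Monte-Carlo oracle against the generative model.

test_that("toy pedigree relationships are exact", {
  fact <- build_factorization(toy_pedigree())
  A <- relationship_matrix(fact)
  # base queens: unit diagonal, unrelated
  expect_equal(A["Q1", "Q1"], 1)
  expect_equal(A["Q1", "Q2"], 0)
  # queen to her own worker group: 1/2
  expect_equal(A["Q1", "W1"], 0.5)
  # dam-daughter: 1/2 (sire side unrelated to Q1)
  expect_equal(A["Q1", "Q3"], 0.5)
  # worker diagonal with all 12 drones from one unrelated dam:
  # 1/4 + var(mean gamete) = 1/4 + 1/24 + (11/12)(1/4)
  expect_equal(A["W1", "W1"], 0.25 + 1 / 24 + 11 / 48, tolerance = 1e-12)
  # daughter vs the worker group: shares dam (1/4) and her sire side is a
  # fresh drone of Q2, the drone dam of all W1 drones (1/2 * 1/2)
  expect_equal(A["Q3", "W1"], 0.25 + 0.25, tolerance = 1e-12)
  # daughter diagonal: non-inbred (dam and sire-dam unrelated)
  expect_equal(A["Q3", "Q3"], 1, tolerance = 1e-12)
})

test_that("worker diagonal for base uncontrolled mating equals 1/4 + 1/(2 n_d)", {
  cfg <- sim_config(n_years = 1, queens_per_year = 40, n_dams = 4,
                    daughters_per_dam = 10, p_controlled = 0,
                    apiary_size = 10, seed = 2)
  pop <- simulate_population(cfg, keep_drones = FALSE)
  f <- pop$fact
  dvals <- f$diag[f$kind == "worker_group"]
  # with-replacement draws from the 39 other base queens occasionally pick
  # a dam twice, lifting the expectation slightly above 1/4 + 1/(2 n_d)
  nd <- 12; pool <- 39
  expected <- 0.25 + (nd + nd * (nd - 1) / pool) / (4 * nd^2) + 1 / (4 * nd)
  expect_equal(mean(dvals), expected, tolerance = 0.02)
  expect_true(all(dvals >= 7 / 24 - 1e-12))
})

test_that("A times sparse inverse is the identity", {
  pop <- small_mixed_pop()
  A <- relationship_matrix(pop$fact)
  Ainv <- a_inverse(pop$fact)
  expect_lt(max(abs(as.matrix(Ainv %*% A) - diag(nrow(A)))), 1e-10)
  # sparse construction matches dense inversion
  expect_lt(max(abs(as.matrix(Ainv) - solve(A))), 1e-8)
  # stored entries grow linearly-ish: far below dense
  expect_lt(Matrix::nnzero(Ainv), 0.5 * nrow(A)^2)
})

test_that("degenerate entities are refused by the inverse", {
  fact <- build_factorization(toy_pedigree())
  fact$d[2] <- 0
  expect_error(a_inverse(fact), "Q2")
})

test_that("A is positive semi-definite with worker diagonals below one", {
  pop <- small_mixed_pop()
  A <- relationship_matrix(pop$fact)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  aww <- colony_aww(pop$fact, pop$colonies)
  expect_true(all(aww > 0.25 & aww < 1))
  expect_equal(unname(aww), pop$colonies$a_ww)
})

test_that("factorization A matches the Monte-Carlo generative covariance", {
  pop <- small_mixed_pop()
  fact <- pop$fact
  A <- relationship_matrix(fact)
  nrep <- 40000
  dr <- draw_genetic_values(fact, trait = NULL, n = nrep, seed = 99)
  # identity G0: both effect streams are independent unit-variance copies
  emp <- (tcrossprod(dr$uQ) + tcrossprod(dr$uW)) / (2 * nrep)
  se <- sqrt((outer(diag(A), diag(A)) + A^2) / (2 * nrep))
  z <- (emp - A) / se
  # entrywise 3-SE agreement up to the multiple-comparison false-positive
  # rate of the 3-sigma band itself
  expect_lt(mean(abs(z) > 3), 0.01)
  expect_lt(max(abs(z)), 6)
})

test_that("pedigree validation catches structural errors", {
  ped <- toy_pedigree()
  bad <- ped; bad$dam_id[4] <- "QX"
  expect_error(build_factorization(bad), "QX")
  bad2 <- ped; bad2$id[2] <- "Q1"
  expect_error(build_factorization(bad2), "duplicate")
  bad3 <- ped; bad3$kind[1] <- "drone"
  expect_error(build_factorization(bad3), "kind")
})

test_that("windowed and plain construction agree", {
  pop <- small_ctrl_pop()
  f1 <- pop$fact
  f2 <- build_factorization(pop$pedigree, dense_limit = 10L,
                            window_years = 4L)
  expect_equal(f1$d, f2$d, tolerance = 1e-12)
  expect_equal(f1$diag, f2$diag, tolerance = 1e-12)
})

test_that("first-year cohorts show the structural regime values 0.29 and 0.37", {
  # with base (unrelated, non-inbred) parents the mating design alone sets
  # the worker diagonal: 1/4 + 1/(2 n_d) free mating, ~0.37 station mating
  cfg_u <- sim_config(n_years = 1, queens_per_year = 200, n_dams = 20,
                      daughters_per_dam = 10, p_controlled = 0,
                      apiary_size = 10, seed = 81)
  f_u <- simulate_population(cfg_u, keep_drones = FALSE)$fact
  expect_equal(round(mean(f_u$diag[f_u$kind == "worker_group"]), 2), 0.29)
  cfg_c <- sim_config(n_years = 1, queens_per_year = 200, n_dams = 20,
                      daughters_per_dam = 10, n_stations = 4,
                      p_controlled = 1, apiary_size = 10, seed = 82)
  f_c <- simulate_population(cfg_c, keep_drones = FALSE)$fact
  expect_equal(round(mean(f_c$diag[f_c$kind == "worker_group"]), 2), 0.37)
})
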