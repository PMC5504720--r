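test_that("K = 1 collapses to the per-probe mean", {
  bm <- tiny_beta(m = 20, n = 8)
  fit <- fit_mixture(bm, 1)
  expect_equal(unname(fit$Omega[, 1]), rep(1, 8))
  expect_equal(unname(fit$Mu[, 1]), unname(rowMeans(bm)))
  expect_true(fit$converged)
})

test_that("exact factorizations are recovered to high precision", {
  fx <- exact_mixture_fixture()
  fit <- suppressWarnings(
    fit_mixture(fx$Y, 2, max_iter = 500, tol = 1e-12, seed = 1))
  mm <- match_components(fit$Omega, fx$Omega0)
  expect_lt(max(abs(fit$Omega[, mm$permutation] - fx$Omega0)), 1e-3)
})

test_that("fit invariants hold: monotone objective, bounded reconstruction,
           sample-order invariance", {
  sim <- simulate_cohort(n = 40, m = 300, K = 3, noise_sd = 0.05, seed = 21)
  fit <- suppressWarnings(fit_mixture(sim$beta, 3, seed = 2))
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  recon <- fit$Mu %*% t(fit$Omega)
  expect_true(all(recon >= -1e-6 & recon <= 1 + 1e-6))
  expect_true(all(fit$Omega >= 0))
  expect_equal(rowSums(fit$Omega), rep(1, 40), tolerance = 1e-6,
               ignore_attr = TRUE)

  # permuting samples permutes Omega rows, leaves canonical Mu unchanged
  perm <- sample(ncol(sim$beta))
  fit2 <- suppressWarnings(fit_mixture(sim$beta[, perm], 3, seed = 2))
  expect_equal(fit2$Mu, fit$Mu, tolerance = 1e-4)
  expect_equal(fit2$Omega, fit$Omega[perm, ], tolerance = 1e-4)
})

test_that("noisy mixtures are recovered with small proportion error", {
  errs <- vapply(1:3, function(s) {
    sim <- simulate_cohort(n = 60, m = 800, K = 3, noise_sd = 0.05,
                           informative_fraction = 1, seed = 30 + s)
    fit <- suppressWarnings(fit_mixture(sim$beta, 3, seed = 1))
    match_components(fit$Omega, sim$truth$Omega_true)$mean_abs_error
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("fit_mixture validates its inputs", {
  bm <- tiny_beta(m = 10, n = 4)
  expect_error(fit_mixture(bm, 0), ">= 1")
  expect_error(fit_mixture(bm, 5), "samples")
  bm[1, 1] <- NA
  expect_error(fit_mixture(bm, 2), "missing")
})

test_that("match_components finds the optimal assignment", {
  set.seed(4)
  g <- matrix(rgamma(12 * 3, 1), 12, 3)
  Om <- g / rowSums(g)
  swap <- Om[, c(2, 3, 1)]
  mm <- match_components(swap, Om)
  expect_equal(mm$permutation, c(3, 1, 2))
  expect_equal(mm$mean_abs_error, 0)

  ident <- match_components(Om, Om)
  expect_equal(ident$permutation, 1:3)

  # brute-force oracle over all 3! permutations on a random pair
  A <- matrix(runif(12), 4, 3)
  B <- matrix(runif(12), 4, 3)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  oracle <- min(vapply(perms, function(p) mean(abs(A[, p] - B)), numeric(1)))
  expect_equal(match_components(A, B)$mean_abs_error, oracle)

  expect_error(match_components(Om[, 1:2], Om), "mismatch")
})

test_that("select_k recovers structure and degenerates sensibly", {
  # singleton grid
  sim <- simulate_cohort(n = 20, m = 100, K = 2, seed = 41)
  ks <- select_k(sim$beta, 3, n_boot = 5, seed = 1)
  expect_equal(ks$chosen_K, 3L)

  # true K = 2: deviance at 2 no worse than at 1, and chosen on this fixture
  sim2 <- simulate_cohort(n = 50, m = 600, K = 2, noise_sd = 0.05,
                          informative_fraction = 1, seed = 42)
  ks2 <- select_k(sim2$beta, 1:4, n_boot = 20, top_variable = 400, seed = 2)
  expect_lte(ks2$mean_bootstrap_deviance[2], ks2$mean_bootstrap_deviance[1])
  expect_equal(ks2$chosen_K, 2L)

  # K > n skipped with a warning
  expect_warning(ks3 <- select_k(sim$beta, c(2, 50), n_boot = 5, seed = 1),
                 "skipping")
  expect_equal(ks3$k_grid, 2L)
})
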