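test_that("simulate_cohort is seed-reproducible and respects invariants", {
  a <- simulate_cohort(n = 12, m = 50, K = 3, n_age_cpgs = 5, seed = 7)
  b <- simulate_cohort(n = 12, m = 50, K = 3, n_age_cpgs = 5, seed = 7)
  expect_identical(a, b)
  c <- simulate_cohort(n = 12, m = 50, K = 3, n_age_cpgs = 5, seed = 8)
  expect_false(identical(a$beta, c$beta))

  expect_true(all(a$beta >= 0 & a$beta <= 1))
  expect_equal(unname(rowSums(a$truth$Omega_true)), rep(1, 12),
               tolerance = 1e-10)
  expect_true(all(a$truth$Mu_true >= 0 & a$truth$Mu_true <= 1))
  # slopes nonzero exactly at the planted probes
  expect_setequal(names(a$truth$slopes)[a$truth$slopes != 0],
                  a$truth$age_cpg_ids)
  expect_length(a$truth$age_cpg_ids, 5)
})

test_that("null generator has no age dependence and K=1 collapses", {
  sim <- simulate_cohort(n = 40, m = 60, K = 2, drift = 0, n_age_cpgs = 0,
                         noise_sd = 0, seed = 11)
  # with drift 0 and no planted effects, E[beta | age] is flat: regressing
  # each probe on age gives slopes indistinguishable from noise-free zero
  expect_true(all(sim$truth$slopes == 0))
  fit <- lm(t(sim$beta) ~ sim$sheet$age)
  slopes <- coef(fit)[2, ]
  # only Dirichlet composition noise remains; slopes centred on zero
  expect_lt(abs(mean(slopes)), 0.002)

  k1 <- simulate_cohort(n = 10, m = 30, K = 1, noise_sd = 0, seed = 2)
  expect_true(all(k1$truth$Omega_true == 1))
  expect_equal(unname(k1$beta[, 1]), unname(k1$truth$Mu_true[, 1]),
               tolerance = 1e-12)

  expect_error(simulate_cohort(n = 5, m = 10, K = 3, drift = 1, seed = 1),
               "simplex")
  expect_error(simulate_cohort(n = 5, m = 10, K = 2, n_age_cpgs = 20,
                               seed = 1), "n_age_cpgs")
})

test_that("simulate_region_sets plants one enriched set at the stated rates", {
  sim <- simulate_cohort(n = 10, m = 1500, K = 2, n_age_cpgs = 300, seed = 5)
  rs <- simulate_region_sets(sim$annotation, n_sets = 3,
                             planted_set_fraction = 0.4, sim$truth,
                             background_rate = 0.1, seed = 6)
  expect_equal(rs$truth$enriched_region_label, "planted_set")
  expect_length(rs$region_sets, 3)

  in_planted <- sapply(sim$annotation$probe_id, function(p) {
    i <- match(p, sim$annotation$probe_id)
    any(rs$region_sets[["planted_set"]]$intervals$chromosome ==
          sim$annotation$chromosome[i] &
        rs$region_sets[["planted_set"]]$intervals$start ==
          sim$annotation$position[i])
  })
  is_age <- sim$annotation$probe_id %in% sim$truth$age_cpg_ids
  expect_equal(mean(in_planted[is_age]), 0.4, tolerance = 0.12)
  expect_equal(mean(in_planted[!is_age]), 0.1, tolerance = 0.04)

  expect_error(simulate_region_sets(sim$annotation, 2, 1.4, sim$truth),
               "planted_set_fraction")
  expect_error(simulate_region_sets(sim$annotation, 2, 0.05, sim$truth,
                                    background_rate = 0.1), "exceed")
})

test_that("simulate_tumor_normal exaggerates only planted CpGs", {
  sim <- simulate_cohort(n = 20, m = 200, K = 2, n_age_cpgs = 40,
                         slope = 0.02, noise_sd = 0, seed = 13)
  tum <- simulate_tumor_normal(sim$beta, sim$truth, exaggeration = 3,
                               n_tumors = 30, noise_sd = 0, seed = 14)
  expect_equal(dim(tum$beta), c(200, 30))
  expect_true(all(tum$beta >= 0 & tum$beta <= 1))
  # planted CpGs shift in the direction of their age slope; others do not
  planted <- sim$truth$age_cpg_ids
  others <- setdiff(rownames(sim$beta), planted)
  dM <- rowMeans(beta_to_mvalue(tum$beta)) -
    rowMeans(beta_to_mvalue(sim$beta))
  sgn <- sign(sim$truth$slopes[planted])
  expect_gt(mean(dM[planted] * sgn), 0.4)
  expect_lt(mean(abs(dM[others])), 0.15)

  empty <- simulate_tumor_normal(sim$beta, sim$truth, exaggeration = 1,
                                 n_tumors = 0, seed = 1)
  expect_equal(ncol(empty$beta), 0)
  expect_equal(nrow(empty$sheet), 0)
  expect_error(simulate_tumor_normal(sim$beta, sim$truth,
                                     exaggeration = 0.5), ">= 1")
})

test_that("simulate_clock_cohort inverts the clock exactly at zero noise", {
  clk <- toy_clock()
  ages <- seq(25, 65, length.out = 20)
  bm <- simulate_clock_cohort(clk, ages, noise_sd = 0, seed = 3)
  pred <- dnam_age(clk, bm)
  expect_equal(unname(pred), ages, tolerance = 1e-8)

  # permuting samples permutes predictions identically
  perm <- sample(ncol(bm))
  expect_equal(unname(dnam_age(clk, bm[, perm])), ages[perm],
               tolerance = 1e-8)

  noisy <- simulate_clock_cohort(clk, ages, noise_sd = 0.01, seed = 4)
  rmse <- sqrt(mean((dnam_age(clk, noisy) - ages)^2))
  expect_lt(rmse, 1)
})
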