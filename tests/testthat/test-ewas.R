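make_sheet <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             age = runif(n, 20, 80),
             group = rbinom(n, 1, 0.5),
             stringsAsFactors = FALSE)
}

test_that("build_design drops the smallest mixture component and NA samples", {
  sheet <- make_sheet(10)
  Omega <- cbind(C1 = rep(0.5, 10), C2 = rep(0.3, 10), C3 = rep(0.2, 10))
  rownames(Omega) <- sheet$sample_id
  mix <- structure(list(Omega = Omega, K = 3L), class = "cell_mixture")
  # constant Omega columns are collinear with the intercept; jitter slightly
  Omega2 <- Omega + matrix(rnorm(30, sd = 0.01), 10)
  mix$Omega <- Omega2 / rowSums(Omega2)
  d <- build_design(sheet, "age", mixture = mix)
  expect_equal(d$dropped_component, "C3")
  expect_setequal(d$column_names, c("intercept", "age", "C1", "C2"))

  d0 <- build_design(sheet, "age")
  expect_equal(dim(d0$values), c(10, 2))

  sheet$group[4] <- NA
  expect_message(d2 <- build_design(sheet, c("age", "group")), "1 sample")
  expect_equal(nrow(d2$values), 9)
  expect_false("S04" %in% d2$sample_ids)

  sheet$dup <- sheet$age * 2
  expect_error(build_design(sheet, c("age", "dup")), "rank deficient")
})

test_that("fit_cpg_models matches exact and oracle least squares", {
  sheet <- make_sheet(8)
  d <- build_design(sheet, "age")
  M <- rbind(constant = rep(3, 8),
             linear = 2 * sheet$age,
             noisy = rnorm(8))
  colnames(M) <- sheet$sample_id
  fits <- fit_cpg_models(M, d, "age")
  expect_equal(fits$coefficient[1], 0, tolerance = 1e-12)
  expect_equal(fits$sigma2[1], 0, tolerance = 1e-12)
  expect_equal(fits$coefficient[2], 2, tolerance = 1e-10)
  expect_equal(fits$stderr[2], 0, tolerance = 1e-6)

  # hand-rolled normal-equations oracle for the noisy probe
  X <- cbind(1, sheet$age)
  beta_hat <- solve(t(X) %*% X, t(X) %*% M[3, ])
  res <- M[3, ] - X %*% beta_hat
  s2 <- sum(res^2) / (8 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(fits$coefficient[3], beta_hat[2], tolerance = 1e-10)
  expect_equal(fits$stderr[3], se, tolerance = 1e-10)

  expect_error(fit_cpg_models(M[, 1:2], build_design(make_sheet(2), "age"),
                              "age"), "more samples")
})

test_that("moderation limits recover OLS (d0=0) and coefficient ordering
           (d0=Inf)", {
  set.seed(8)
  sheet <- make_sheet(15)
  d <- build_design(sheet, "age")
  M <- matrix(rnorm(100 * 15), 100, 15,
              dimnames = list(sprintf("cg%03d", 1:100), sheet$sample_id))
  fits <- fit_cpg_models(M, d, "age")

  no_shrink <- moderate(fits, d0 = 0, s0_sq = 1)
  t_ols <- fits$coefficient / fits$stderr
  expect_equal(no_shrink$t_moderated, t_ols, tolerance = 1e-10)

  full_shrink <- moderate(fits, d0 = Inf, s0_sq = 0.8)
  expect_equal(order(abs(full_shrink$t_moderated)),
               order(abs(fits$coefficient)))

  # estimated moderation lies between: shrunken variances pull extreme
  # ordinary t-statistics toward the ensemble
  est <- moderate(fits)
  par <- attr(est, "moderation")
  expect_gt(par$d0, 0)
  expect_true(all(is.finite(est$p_value)))

  zero <- fits
  zero$sigma2 <- rep(0, nrow(zero))
  expect_error(moderate(zero), "degenerate")
})

test_that("moderated tests are calibrated on null data and probe-order
           invariant", {
  set.seed(9)
  sheet <- make_sheet(20, seed = 9)
  d <- build_design(sheet, "age")
  M <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(sprintf("cg%03d", 1:500), sheet$sample_id))
  res <- moderate(fit_cpg_models(M, d, "age"))
  typeI <- mean(res$p_value < 0.05)
  expect_gt(typeI, 0.03)
  expect_lt(typeI, 0.07)

  perm <- sample(500)
  res2 <- moderate(fit_cpg_models(M[perm, ], d, "age"))
  expect_equal(res2$p_value[order(perm)], res$p_value, tolerance = 1e-12)
})

test_that("bh_qvalues implements the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.3), 0.3)
  expect_equal(bh_qvalues(c(1, 1)), c(1, 1))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute-force oracle: q(i) = smallest alpha at which p_i is declared
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    sorted <- p[o]
    qs <- sorted * m / seq_len(m)
    qs <- rev(cummin(rev(qs)))
    q[o] <- pmin(qs, 1)
    q
  }
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_qvalues(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("delta coefficients isolate composition confounding", {
  sheet <- make_sheet(12)
  d <- build_design(sheet, "age")
  M <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("cg%03d", 1:20), sheet$sample_id))
  res <- run_ewas(M, d, "age")
  expect_equal(delta_coefficients(res, res)$delta, rep(0, 20))

  # constructed confounding: probe driven by a proportion that tracks age;
  # adjusting for the proportion removes the age coefficient, so
  # delta = unadjusted - adjusted > 0
  set.seed(11)
  omega1 <- 0.3 + 0.005 * (sheet$age - 50) + rnorm(12, sd = 0.01)
  probe <- 5 * omega1 + rnorm(12, sd = 0.01)
  M2 <- rbind(target = probe,
              M[1:10, ] + 0)  # filler probes for the moderation ensemble
  colnames(M2) <- sheet$sample_id
  Omega <- cbind(C1 = 1 - omega1 - 0.2, C2 = omega1, C3 = rep(0.2, 12))
  Omega <- Omega + matrix(rnorm(36, sd = 1e-3), 12)
  rownames(Omega) <- sheet$sample_id
  mix <- structure(list(Omega = Omega, K = 3L), class = "cell_mixture")
  adj <- run_ewas(M2, build_design(sheet, "age", mixture = mix), "age",
                  model_tag = "adjusted")
  un <- run_ewas(M2, build_design(sheet, "age"), "age")
  dd <- delta_coefficients(adj, un)
  expect_gt(dd$delta[dd$probe_id == "target"], 0.01)
  expect_gt(un$coefficient[un$probe_id == "target"],
            adj$coefficient[adj$probe_id == "target"])

  expect_error(delta_coefficients(adj[-1, ], un), "probe sets")
})

test_that("moderation agrees with the established empirical-Bayes
           implementation on heterogeneous variances", {
  skip_if_not_installed("limma")
  set.seed(34)
  n <- 18
  m <- 500
  sheet <- data.frame(sample_id = sprintf("S%02d", 1:n),
                      age = runif(n, 20, 80))
  sds <- sqrt(1 / rgamma(m, shape = 3, rate = 3))
  M <- matrix(rnorm(m * n), m, n) * sds
  dimnames(M) <- list(sprintf("cg%03d", 1:m), sheet$sample_id)
  d <- build_design(sheet, "age")
  mine <- moderate(fit_cpg_models(M, d, "age"))
  par <- attr(mine, "moderation")
  eb <- limma::eBayes(limma::lmFit(M, d$values))
  expect_equal(par$d0, unname(eb$df.prior), tolerance = 1e-10)
  expect_equal(par$s0_sq, unname(eb$s2.prior), tolerance = 1e-10)
  expect_equal(mine$t_moderated, unname(eb$t[, "age"]), tolerance = 1e-10)
  expect_equal(mine$p_value, unname(eb$p.value[, "age"]), tolerance = 1e-10)
})
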