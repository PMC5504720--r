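# Reference-free cell-mixture deconvolution.
#
# Decomposes a bulk methylation matrix Y (m probes x n samples, beta scale)
# as Y ~ Mu %*% t(Omega) with Mu in [0,1] (putative cell-type methylomes)
# and each row of Omega on the probability simplex (mixture proportions):
# a convex variant of non-negative matrix factorization. Fitting alternates
# two exact, monotone updates, so the residual sum of squares never
# increases:
#   * Omega rows: simplex-constrained least squares per sample, solved
#     exactly by enumerating support sets (K is small);
#   * Mu rows: box-constrained least squares via coordinate descent with
#     clipping to [0,1].

# Exact simplex-constrained least squares for all samples at once.
# Given MtM = t(Mu) %*% Mu (K x K), MtY = t(Mu) %*% Y (K x n), and
# yty = colSums(Y^2), returns the n x K matrix of per-sample minimisers of
# ||y - Mu w||^2 subject to w >= 0, sum(w) = 1.
# Every non-empty support set S is tried: the equality-constrained solution
# on S is closed-form (shared KKT matrix across samples), infeasible
# candidates are discarded, and the feasible candidate with the smallest
# residual wins. The optimum's own support always yields it, so the search
# is exact.
.solve_omega <- function(MtM, MtY, yty) {
  K <- nrow(MtM)
  n <- ncol(MtY)
  if (K == 1) return(matrix(1, nrow = n, ncol = 1))
  best_val <- rep(Inf, n)
  best_w <- matrix(0, nrow = K, ncol = n)
  ridge <- 1e-10 * (1 + mean(diag(MtM)))
  for (mask in seq_len(2^K - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) != 0)
    s <- length(S)
    A <- rbind(cbind(MtM[S, S, drop = FALSE] + diag(ridge, s), 1),
               c(rep(1, s), 0))
    B <- rbind(MtY[S, , drop = FALSE], rep(1, n))
    W <- tryCatch(solve(A, B), error = function(e) NULL)
    if (is.null(W)) next
    w <- W[seq_len(s), , drop = FALSE]
    feasible <- colSums(w < -1e-9) == 0
    if (!any(feasible)) next
    quad <- colSums(w * (MtM[S, S, drop = FALSE] %*% w))
    val <- yty - 2 * colSums(w * MtY[S, , drop = FALSE]) + quad
    better <- feasible & (val < best_val - 1e-12)
    if (any(better)) {
      best_val[better] <- val[better]
      best_w[, better] <- 0
      best_w[S, better] <- pmax(w[, better, drop = FALSE], 0)
    }
  }
  Omega <- t(best_w)
  Omega / rowSums(Omega)
}

# one full sweep of coordinate descent on the rows of Mu with clipping;
# each coordinate update minimises the convex quadratic exactly under the
# [0,1] box, so the objective cannot increase. With lambda > 0 a repulsion
# term -lambda * ||Mu_k - rowMeans(Mu)||^2 is added (row means held at the
# previous sweep's values): the factorisation Y ~ Mu Omega' is invariant to
# expanding the methylomes about their centroid while shrinking the
# proportions toward uniform, so least squares alone cannot resolve the
# scale; the repulsion drives Mu outward along that flat direction until
# the [0,1] box binds, which is what identifies the model.
.update_mu <- function(Y, Mu, Omega, lambda = 0) {
  OtO <- crossprod(Omega)            # K x K
  YO <- Y %*% Omega                  # m x K
  K <- ncol(Mu)
  mbar <- rowMeans(Mu)
  for (k in seq_len(K)) {
    denom <- OtO[k, k] - lambda
    if (denom <= 0) next
    num <- YO[, k] - Mu %*% OtO[, k] + Mu[, k] * OtO[k, k] - lambda * mbar
    Mu[, k] <- pmin(pmax(num / denom, 0), 1)
  }
  Mu
}

.frobenius_sq <- function(Y, Mu, Omega) {
  sum((Y - Mu %*% t(Omega))^2)
}

#' Fit a reference-free cell-mixture model
#'
#' Factorises a beta matrix into `K` putative cell-type methylomes (`Mu`,
#' entries in `[0,1]`) and per-sample mixture proportions (`Omega`, rows on
#' the simplex) by alternating constrained least squares. Components are
#' canonicalised to descending mean proportion, which makes "the component
#' with the smallest proportion" well-defined downstream.
#'
#' Because the factorisation is invariant to expanding the methylomes about
#' their centroid while shrinking the proportions toward uniform, fitting
#' runs in two phases: an exploration phase whose methylome update carries a
#' small away-from-centroid repulsion, which traverses that flat direction
#' until the `[0,1]` box binds, followed by plain alternating least squares
#' whose (non-increasing) residual sum of squares is recorded as the
#' objective trace.
#'
#' @param bm Beta matrix (probes x samples), no missing values.
#' @param K Number of putative cell types, `1 <= K <= min(m, n)`.
#' @param max_iter Maximum number of refinement iterations. Default `300`.
#' @param tol Relative objective-change convergence threshold. Default
#'   `1e-6`.
#' @param explore_iter Exploration-phase iterations. Default `40`.
#' @param expansion Repulsion strength of the exploration phase as a
#'   fraction of the smallest diagonal entry of `crossprod(Omega)`.
#'   Default `0.1`; `0` disables exploration.
#' @param seed Integer seed (controls the k-means initialisation).
#' @return An object of class `cell_mixture` with elements `Mu` (m x K),
#'   `Omega` (n x K), `K`, `objective_trace` (residual sum of squares per
#'   refinement iteration, non-increasing), and `converged`.
#' @export
fit_mixture <- function(bm, K, max_iter = 300, tol = 1e-6,
                        explore_iter = 40, expansion = 0.1, seed = 1L) {
  m <- nrow(bm)
  n <- ncol(bm)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K exceeds the number of samples", call. = FALSE)
  if (K > m) stop("K exceeds the number of probes", call. = FALSE)
  if (anyNA(bm)) stop("beta matrix contains missing values", call. = FALSE)

  if (K == 1) {
    Mu <- matrix(pmin(pmax(rowMeans(bm), 0), 1), ncol = 1,
                 dimnames = list(rownames(bm), "C1"))
    Omega <- matrix(1, nrow = n, ncol = 1,
                    dimnames = list(colnames(bm), "C1"))
    obj <- .frobenius_sq(bm, Mu, Omega)
    return(structure(list(Mu = Mu, Omega = Omega, K = 1L,
                          objective_trace = obj, converged = TRUE),
                     class = "cell_mixture"))
  }

  set.seed(seed)
  # deterministic farthest-point initialisation: start from the sample
  # farthest from the grand mean, then greedily add the sample maximising
  # the distance to the nearest chosen one. Invariant to sample order
  # (up to exact distance ties), unlike k-means.
  gm <- rowMeans(bm)
  d2 <- colSums((bm - gm)^2)
  centers <- which.max(d2)
  if (K > 1) {
    mind <- colSums((bm - bm[, centers[1]])^2)
    for (k in 2:K) {
      centers <- c(centers, which.max(mind))
      mind <- pmin(mind, colSums((bm - bm[, centers[k]])^2))
    }
  }
  Mu <- pmin(pmax(bm[, centers, drop = FALSE], 0), 1)

  yty <- colSums(bm^2)

  # exploration phase: expansion-regularised Mu updates
  if (expansion > 0) {
    for (it in seq_len(explore_iter)) {
      Omega <- .solve_omega(crossprod(Mu), crossprod(Mu, bm), yty)
      lam <- expansion * min(diag(crossprod(Omega)))
      Mu <- .update_mu(bm, Mu, Omega, lambda = lam)
    }
  }

  # refinement phase: plain monotone alternating least squares
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  Omega <- NULL
  for (it in seq_len(max_iter)) {
    Omega <- .solve_omega(crossprod(Mu), crossprod(Mu, bm), yty)
    Mu <- .update_mu(bm, Mu, Omega)
    obj <- .frobenius_sq(bm, Mu, Omega)
    trace <- c(trace, obj)
    if (is.finite(prev) && (prev - obj) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  if (!converged) {
    warning("fit_mixture did not converge in ", max_iter, " iterations")
  }

  ord <- order(-colMeans(Omega))
  Mu <- Mu[, ord, drop = FALSE]
  Omega <- Omega[, ord, drop = FALSE]
  comp_names <- sprintf("C%d", seq_len(K))
  dimnames(Mu) <- list(rownames(bm), comp_names)
  dimnames(Omega) <- list(colnames(bm), comp_names)

  structure(list(Mu = Mu, Omega = Omega, K = as.integer(K),
                 objective_trace = trace, converged = converged),
            class = "cell_mixture")
}

#' @export
print.cell_mixture <- function(x, ...) {
  cat("cell_mixture: K =", x$K, "|", nrow(x$Mu), "probes x",
      nrow(x$Omega), "samples; RSS =",
      format(utils::tail(x$objective_trace, 1), digits = 6),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Project samples onto a fitted mixture
#'
#' Solves the simplex-constrained least-squares proportions of new samples
#' against a fixed methylome matrix `Mu`.
#'
#' @param Mu m x K methylome matrix.
#' @param bm Beta matrix over the same probes.
#' @return n x K proportion matrix.
#' @export
project_mixture <- function(Mu, bm) {
  stopifnot(nrow(Mu) == nrow(bm))
  .solve_omega(crossprod(Mu), crossprod(Mu, bm), colSums(bm^2))
}

#' Choose the number of cell types by bootstrap
#'
#' Restricts to the `top_variable` most variable probes, then for each
#' bootstrap resample of specimens fits the mixture at every candidate `K`
#' and scores out-of-bag specimens against the bootstrap-fitted methylomes.
#' Scoring splits probes in half: each out-of-bag specimen's proportions are
#' projected onto the simplex span of the methylomes using one probe half,
#' and the deviance is the mean squared reconstruction error on the held-out
#' half. (Projecting and scoring on the same probes would let every extra
#' component absorb a little of the specimen's own noise, biasing selection
#' toward large K; the probe split removes that bias.) The chosen `K`
#' minimises the mean deviance, ties going to the smaller `K`.
#'
#' @param bm Beta matrix (probes x samples).
#' @param k_grid Integer vector of candidate K values.
#' @param n_boot Number of bootstrap resamples. Default `100` (increase for
#'   full-fidelity runs).
#' @param top_variable Number of most-variable probes used. Default `10000`,
#'   capped at the number of probes.
#' @param max_iter,tol Passed to [fit_mixture()]. Bootstrap scoring fits
#'   are deliberately short (a `20`-iteration expansion phase plus up to
#'   `30` refinement iterations at `tol = 2e-4`): the deviance ranking
#'   stabilises long before the fits converge fully. The expansion phase
#'   matters here: without it a fitted simplex stops short of the data
#'   extremes and surplus components pick up the uncovered signal, biasing
#'   selection upward.
#' @param seed Integer seed.
#' @return An object of class `k_selection` with `k_grid`,
#'   `mean_bootstrap_deviance`, `chosen_K`, `n_boot`, `seed`.
#' @export
select_k <- function(bm, k_grid, n_boot = 100, top_variable = 10000,
                     max_iter = 30, tol = 2e-4, seed = 1L) {
  if (length(k_grid) == 0) stop("k_grid is empty", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  n <- ncol(bm)
  bad_k <- k_grid[k_grid > n]
  if (length(bad_k) > 0) {
    warning("skipping K > n: ", paste(bad_k, collapse = ", "))
    k_grid <- k_grid[k_grid <= n]
    if (length(k_grid) == 0) stop("no admissible K in k_grid", call. = FALSE)
  }
  Y <- select_most_variable(bm, min(top_variable, nrow(bm)))

  set.seed(seed)
  m_used <- nrow(Y)
  half <- sample.int(m_used, floor(m_used / 2))
  eval_half <- setdiff(seq_len(m_used), half)
  dev <- matrix(NA_real_, nrow = n_boot, ncol = length(k_grid),
                dimnames = list(NULL, paste0("K", k_grid)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) == 0) next
    Yb <- Y[, idx, drop = FALSE]
    Yoob <- Y[, oob, drop = FALSE]
    for (j in seq_along(k_grid)) {
      K <- k_grid[j]
      fit <- suppressWarnings(
        fit_mixture(Yb, K, max_iter = max_iter, tol = tol,
                    explore_iter = 20,
                    seed = sample.int(.Machine$integer.max, 1))
      )
      W <- project_mixture(fit$Mu[half, , drop = FALSE],
                           Yoob[half, , drop = FALSE])
      dev[b, j] <- mean((Yoob[eval_half, , drop = FALSE] -
                           fit$Mu[eval_half, , drop = FALSE] %*% t(W))^2)
    }
  }
  mean_dev <- colMeans(dev, na.rm = TRUE)
  chosen <- k_grid[which.min(mean_dev)]  # which.min takes the first minimum
  structure(list(k_grid = k_grid,
                 mean_bootstrap_deviance = unname(mean_dev),
                 chosen_K = as.integer(chosen),
                 n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("k_selection over {", paste(x$k_grid, collapse = ", "), "}: chosen K =",
      x$chosen_K, "from", x$n_boot, "bootstraps\n")
  print(stats::setNames(x$mean_bootstrap_deviance, paste0("K", x$k_grid)))
  invisible(x)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Match estimated mixture components to a reference
#'
#' Finds the column permutation of `Omega_est` minimising the total absolute
#' difference to `Omega_true` (optimal assignment by exhaustive search over
#' permutations; K is small in practice).
#'
#' @param Omega_est,Omega_true n x K proportion matrices with equal K.
#' @return A list with `permutation` (column order of `Omega_est` matching
#'   `Omega_true`) and `mean_abs_error` under that matching.
#' @export
match_components <- function(Omega_est, Omega_true) {
  if (ncol(Omega_est) != ncol(Omega_true)) {
    stop("component count mismatch", call. = FALSE)
  }
  if (nrow(Omega_est) != nrow(Omega_true)) {
    stop("sample count mismatch", call. = FALSE)
  }
  K <- ncol(Omega_est)
  if (K > 8) stop("exhaustive matching supported up to K = 8", call. = FALSE)
  perms <- .permutations(K)
  costs <- apply(perms, 1, function(p) {
    mean(abs(Omega_est[, p, drop = FALSE] - Omega_true))
  })
  best <- which.min(costs)
  list(permutation = as.integer(perms[best, ]),
       mean_abs_error = costs[best])
}
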