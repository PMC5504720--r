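# Association between estimated cell-mixture proportions and subject
# covariates, made robust to the choice of K by a min-P permutation test.

# Wald p-value for the slope of a quasi-binomial (logit link) regression of
# a proportion on one covariate, with dispersion from Pearson residuals
# (floored to keep perfect-fit cases well-defined).
.qb_wald_p <- function(omega_k, x) {
  if (stats::sd(x) == 0 || stats::sd(omega_k) == 0) return(1)
  X <- cbind(1, x)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, omega_k,
                                    family = stats::quasibinomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || fit$rank < 2) return(1)
  mu <- fit$fitted.values
  w <- fit$weights
  df_res <- length(omega_k) - 2
  if (df_res <= 0) return(1)
  pearson <- sum((omega_k - mu)^2 / pmax(mu * (1 - mu), 1e-12))
  disp <- max(pearson / df_res, 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(disp * chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) return(1)
  se <- sqrt(cov[2, 2])
  if (!is.finite(se)) return(1)
  tval <- fit$coefficients[2] / se
  2 * stats::pt(-abs(tval), df = df_res)
}

#' Quasi-binomial association p-value for one mixture component
#'
#' Fits a logit-link quasi-binomial regression of the component's proportion
#' on a covariate and returns the Wald p-value of the slope, with dispersion
#' estimated from Pearson residuals. A constant proportion (or covariate)
#' yields `p = 1` by convention: no association is testable.
#'
#' @param omega_k Proportion vector in `[0, 1]`.
#' @param covariate Numeric or binary covariate vector.
#' @return A p-value.
#' @export
quasibinomial_p <- function(omega_k, covariate) {
  if (length(omega_k) != length(covariate)) {
    stop("length mismatch", call. = FALSE)
  }
  if (length(omega_k) < 5) stop("need n >= 5", call. = FALSE)
  if (any(omega_k < 0 | omega_k > 1)) {
    stop("proportions must be in [0, 1]", call. = FALSE)
  }
  ok <- !is.na(omega_k) & !is.na(covariate)
  .qb_wald_p(omega_k[ok], as.numeric(covariate[ok]))
}

#' Min-P permutation test of mixture-covariate association
#'
#' For every `K` in `k_grid`, fits the reference-free mixture, computes the
#' quasi-binomial p-value of each of the K components against the covariate,
#' and records the global minimum p over components and K. The null
#' distribution is obtained by permuting the covariate against the fixed
#' estimated proportions `B` times (the deconvolution never sees the
#' covariate, so its output is permutation-invariant) and recomputing the
#' minimum, giving
#' `p_perm = (1 + #\{perm minima <= observed\}) / (B + 1)`.
#'
#' @param bm Beta matrix (probes x samples).
#' @param sheet Sample sheet aligned to the beta columns.
#' @param covariate Covariate column name; samples with a missing value are
#'   dropped.
#' @param k_grid Candidate numbers of cell types.
#' @param B Number of permutations, `>= 19`. Default `1000`.
#' @param top_variable Probes used for the deconvolution. Default `10000`.
#' @param seed Integer seed.
#' @return An object of class `mixture_permutation` with fields
#'   `covariate_name`, `k_grid`, `observed_min_p`, `perm_min_p`, `p_perm`,
#'   `B`, `seed`.
#' @export
test_metadata_association <- function(bm, sheet, covariate, k_grid,
                                      B = 1000, top_variable = 10000,
                                      seed = 1L) {
  if (B < 19) stop("B must be >= 19", call. = FALSE)
  if (!covariate %in% names(sheet)) {
    stop("covariate '", covariate, "' not in sample sheet", call. = FALSE)
  }
  x <- sheet[[covariate]]
  if (is.character(x) || is.logical(x)) x <- as.numeric(factor(x)) - 1
  x <- as.numeric(x)
  ok <- !is.na(x)
  x <- x[ok]
  bm <- bm[, ok, drop = FALSE]
  n <- ncol(bm)

  k_grid <- sort(unique(as.integer(k_grid)))
  bad_k <- k_grid[k_grid > n]
  if (length(bad_k) > 0) {
    warning("skipping K > n: ", paste(bad_k, collapse = ", "))
    k_grid <- k_grid[k_grid <= n]
  }
  if (length(k_grid) == 0) stop("no admissible K", call. = FALSE)

  Y <- select_most_variable(bm, min(top_variable, nrow(bm)))
  set.seed(seed)
  omegas <- list()
  for (K in k_grid) {
    fit <- suppressWarnings(
      fit_mixture(Y, K, seed = sample.int(.Machine$integer.max, 1)))
    omegas[[paste0("K", K)]] <- fit$Omega
  }
  all_components <- do.call(cbind, omegas)  # n x (sum of K)

  min_p_for <- function(xv) {
    min(apply(all_components, 2, .qb_wald_p, x = xv))
  }
  observed <- min_p_for(x)
  perm_min <- vapply(seq_len(B), function(b) min_p_for(sample(x)), numeric(1))
  p_perm <- (1 + sum(perm_min <= observed)) / (B + 1)

  structure(list(covariate_name = covariate,
                 k_grid = k_grid,
                 observed_min_p = observed,
                 perm_min_p = perm_min,
                 p_perm = p_perm,
                 B = as.integer(B),
                 seed = as.integer(seed)),
            class = "mixture_permutation")
}

#' @export
print.mixture_permutation <- function(x, ...) {
  cat("mixture_permutation:", x$covariate_name,
      "| K in {", paste(x$k_grid, collapse = ", "), "}",
      "| observed min p =", format(x$observed_min_p, digits = 4),
      "| permutation p =", format(x$p_perm, digits = 4),
      "(B =", paste0(x$B, ")\n"))
  invisible(x)
}
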