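# Per-CpG association models of M values on risk factors, with optional
# cell-proportion adjustment, empirical-Bayes variance moderation, FDR
# control, and the delta-coefficient confounding diagnostic.

#' Build a per-CpG regression design matrix
#'
#' Constructs an intercept + covariate design from a sample sheet, optionally
#' appending estimated cell-mixture proportions. Because proportions sum to
#' one, all but the component with the smallest mean proportion are included,
#' avoiding multi-collinearity with the intercept. Samples with missing
#' values in any requested covariate are dropped (with a message); factors
#' are expanded to treatment-coded indicators.
#'
#' @param sheet Sample sheet `data.frame` with a `sample_id` column.
#' @param covariates Character vector of covariate column names, in order.
#' @param mixture Optional [fit_mixture()] result; its `Omega` rows must be
#'   named by sample id or aligned to `sheet`.
#' @return An object of class `ewas_design`: a list with `values` (n x p
#'   numeric matrix), `sample_ids`, `column_names`, `dropped_component`.
#' @export
build_design <- function(sheet, covariates, mixture = NULL) {
  miss <- setdiff(covariates, names(sheet))
  if (length(miss) > 0) {
    stop("covariates absent from sample sheet: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- rowSums(is.na(sheet[, covariates, drop = FALSE])) == 0
  if (any(!keep)) {
    message(sum(!keep), " sample(s) dropped for missing covariate values")
  }
  sub <- sheet[keep, , drop = FALSE]

  df <- sub[, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.character(df[[v]]) || is.logical(df[[v]])) {
      df[[v]] <- factor(df[[v]])
    }
  }
  X <- stats::model.matrix(
    stats::reformulate(covariates, intercept = TRUE), data = df)
  colnames(X)[1] <- "intercept"

  dropped_component <- NA_character_
  if (!is.null(mixture)) {
    Omega <- mixture$Omega
    if (!is.null(rownames(Omega))) {
      idx <- match(sub$sample_id, rownames(Omega))
      if (anyNA(idx)) {
        stop("mixture proportions missing for samples: ",
             paste(sub$sample_id[is.na(idx)], collapse = ", "),
             call. = FALSE)
      }
      Omega <- Omega[idx, , drop = FALSE]
    } else if (nrow(Omega) == nrow(sheet)) {
      Omega <- Omega[keep, , drop = FALSE]
    } else {
      stop("cannot align mixture proportions to the sample sheet",
           call. = FALSE)
    }
    drop_j <- which.min(colMeans(Omega))
    dropped_component <- colnames(Omega)[drop_j]
    if (is.null(dropped_component)) dropped_component <- paste0("C", drop_j)
    kept <- Omega[, -drop_j, drop = FALSE]
    if (ncol(kept) > 0) {
      if (is.null(colnames(kept))) {
        colnames(kept) <- paste0("C", seq_len(ncol(Omega))[-drop_j])
      }
      X <- cbind(X, kept)
    }
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(values = X,
                 sample_ids = sub$sample_id,
                 column_names = colnames(X),
                 dropped_component = dropped_component),
            class = "ewas_design")
}

#' Fit ordinary least squares per probe
#'
#' Fits the same linear model to every probe of an M-value matrix and
#' extracts the coefficient and standard error of one named covariate.
#'
#' @param M M-value matrix (probes x samples); columns are subset and
#'   reordered to the design's samples.
#' @param design An [build_design()] result.
#' @param covariate Name of the design column of interest (for a factor
#'   covariate, the indicator column name).
#' @return A `data.frame` with columns `probe_id`, `coefficient`, `stderr`,
#'   `sigma2` (residual variance), `df` (residual degrees of freedom), and
#'   attribute `unscaled_sd` (design-dependent scale such that
#'   `stderr = sqrt(sigma2) * unscaled_sd`).
#' @export
fit_cpg_models <- function(M, design, covariate) {
  X <- design$values
  idx <- match(design$sample_ids, colnames(M))
  if (anyNA(idx)) {
    stop("M matrix lacks samples: ",
         paste(design$sample_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  M <- M[, idx, drop = FALSE]
  n <- ncol(M)
  p <- ncol(X)
  if (n <= p) stop("need more samples than design columns", call. = FALSE)
  j <- match(covariate, colnames(X))
  if (is.na(j)) {
    stop("covariate '", covariate, "' not a design column (have: ",
         paste(colnames(X), collapse = ", "), ")", call. = FALSE)
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- M %*% X %*% XtXinv                 # m x p coefficients
  resid <- M - B %*% t(X)
  df <- n - p
  sigma2 <- rowSums(resid^2) / df
  sigma2[sigma2 < 0] <- 0
  unscaled_sd <- sqrt(XtXinv[j, j])
  out <- data.frame(probe_id = rownames(M),
                    coefficient = B[, j],
                    stderr = sqrt(sigma2) * unscaled_sd,
                    sigma2 = sigma2,
                    df = df,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "unscaled_sd") <- unscaled_sd
  attr(out, "covariate") <- covariate
  out
}

# Newton inversion of the trigamma function (solves trigamma(y) = x)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Estimate empirical-Bayes variance moderation parameters
#'
#' Moment-matching on log residual variances: the prior degrees of freedom
#' `d0` solve `trigamma(d0/2) = var(z) - trigamma(d/2)` where
#' `z = log(sigma2)`; when the observed spread is no larger than expected
#' under a common variance, `d0` is infinite and all probes share `s0_sq`.
#'
#' @param sigma2 Per-probe residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return A list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_moderation <- function(sigma2, df) {
  ok <- sigma2 > 0
  if (sum(ok) < 2) stop("need >= 2 probes with positive residual variance",
                        call. = FALSE)
  z <- log(sigma2[ok])
  e_gap <- digamma(df / 2) - log(df / 2)
  v <- stats::var(z) - trigamma(df / 2)
  if (is.na(v) || v <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(z) - e_gap)
  } else {
    d0 <- 2 * .trigamma_inverse(v)
    s0_sq <- exp(mean(z) - e_gap + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each probe's residual variance toward a prior estimated from the
#' ensemble, `s2_post = (d0 * s0_sq + df * sigma2) / (d0 + df)`, and forms
#' `t = coefficient / (sqrt(s2_post) * unscaled_sd)` with `d0 + df` degrees
#' of freedom. With `d0 = 0` this is exactly the ordinary t-statistic; with
#' `d0 = Inf` all probes share the prior variance.
#'
#' @param fits A [fit_cpg_models()] result.
#' @param d0,s0_sq Optional forced moderation parameters; by default both
#'   are estimated from the data via [estimate_moderation()].
#' @return The input `data.frame` with columns `t_moderated` and `p_value`
#'   added; the moderation parameters are attached as attribute
#'   `"moderation"`.
#' @export
moderate <- function(fits, d0 = NULL, s0_sq = NULL) {
  if (nrow(fits) < 2) stop("moderation needs >= 2 probes", call. = FALSE)
  if (all(fits$sigma2 == 0)) {
    stop("all residual variances are zero; ensemble is degenerate",
         call. = FALSE)
  }
  df <- fits$df[1]
  if (is.null(d0) || is.null(s0_sq)) {
    est <- estimate_moderation(fits$sigma2, df)
    if (is.null(d0)) d0 <- est$d0
    if (is.null(s0_sq)) s0_sq <- est$s0_sq
  }
  usd <- attr(fits, "unscaled_sd")
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, nrow(fits))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- fits$sigma2
    df_total <- df
  } else {
    s2_post <- (d0 * s0_sq + df * fits$sigma2) / (d0 + df)
    df_total <- d0 + df
  }
  t_mod <- fits$coefficient / (sqrt(s2_post) * usd)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  fits$t_moderated <- t_mod
  fits$p_value <- p
  attr(fits, "moderation") <- list(d0 = d0, s0_sq = s0_sq)
  fits
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, `p <= q <= 1`.
#' @export
bh_qvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Run a complete per-covariate EWAS
#'
#' Convenience wrapper: [fit_cpg_models()], [moderate()], [bh_qvalues()],
#' returning one tidy result table.
#'
#' @param M M-value matrix (probes x samples).
#' @param design An [build_design()] result.
#' @param covariate Design column of interest.
#' @param model_tag Label recorded in the result (e.g. `"adjusted"`).
#' @return A `data.frame` with columns `probe_id`, `coefficient`, `stderr`,
#'   `t_moderated`, `p_value`, `q_value`, `model_tag`, `covariate_name`.
#' @export
run_ewas <- function(M, design, covariate, model_tag = "unadjusted") {
  fits <- fit_cpg_models(M, design, covariate)
  fits <- moderate(fits)
  out <- data.frame(probe_id = fits$probe_id,
                    coefficient = fits$coefficient,
                    stderr = fits$stderr,
                    t_moderated = fits$t_moderated,
                    p_value = fits$p_value,
                    q_value = bh_qvalues(fits$p_value),
                    model_tag = model_tag,
                    covariate_name = covariate,
                    stringsAsFactors = FALSE)
  attr(out, "moderation") <- attr(fits, "moderation")
  out
}

#' Delta coefficients between unadjusted and adjusted models
#'
#' `delta = coefficient_unadjusted - coefficient_adjusted` per probe. A large
#' absolute delta flags a locus whose apparent association is confounded by
#' cell-composition differences.
#'
#' @param adjusted,unadjusted EWAS result tables over the same probes and
#'   covariate.
#' @return A `data.frame` with `probe_id` and `delta`.
#' @export
delta_coefficients <- function(adjusted, unadjusted) {
  if (!setequal(adjusted$probe_id, unadjusted$probe_id)) {
    stop("probe sets differ between models", call. = FALSE)
  }
  if (adjusted$covariate_name[1] != unadjusted$covariate_name[1]) {
    stop("covariates differ between models", call. = FALSE)
  }
  idx <- match(adjusted$probe_id, unadjusted$probe_id)
  data.frame(probe_id = adjusted$probe_id,
             delta = unadjusted$coefficient[idx] - adjusted$coefficient,
             stringsAsFactors = FALSE)
}
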