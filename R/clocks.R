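# Coefficient-table epigenetic clocks: DNA-methylation age prediction, age
# acceleration (residual of DNAm age on chronological age), and association
# of acceleration with risk factors. Clocks are data, not code: a named
# coefficient vector plus an invertible calibration transform.

#' Construct an epigenetic clock model
#'
#' A clock is a fixed linear predictor over CpG betas,
#' `lp = intercept + sum(w_j * beta_j)`, followed by a calibration
#' transform. Supported transforms: `"identity"`, and `"log_linear"` (the
#' adult-age breakpoint calibration used by multi-tissue age clocks:
#' `age = (1 + adult_age) * exp(lp) - 1` for `lp < 0`, else
#' `age = (1 + adult_age) * lp + adult_age`).
#'
#' @param name Clock name.
#' @param cpg_coefficients Named numeric vector: probe id -> weight per unit
#'   beta.
#' @param intercept Linear-predictor intercept. Default `0`.
#' @param transform `"identity"` or `"log_linear"`.
#' @param adult_age Breakpoint parameter of the log-linear transform.
#'   Default `20`.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, cpg_coefficients, intercept = 0,
                        transform = c("identity", "log_linear"),
                        adult_age = 20) {
  transform <- match.arg(transform)
  if (length(cpg_coefficients) == 0) {
    stop("clock must have at least one CpG", call. = FALSE)
  }
  if (is.null(names(cpg_coefficients)) ||
      any(!nzchar(names(cpg_coefficients)))) {
    stop("cpg_coefficients must be named by probe id", call. = FALSE)
  }
  structure(list(name = name,
                 cpg_coefficients = cpg_coefficients,
                 intercept = intercept,
                 transform = transform,
                 adult_age = adult_age,
                 expected_n_cpgs = length(cpg_coefficients)),
            class = "clock_model")
}

#' Construct a mitotic-rate (epiTOC-style) clock
#'
#' Scores a sample as the mean beta over a fixed CpG set (uniform weights,
#' identity transform); the score tracks cumulative cell divisions rather
#' than chronological years.
#'
#' @param cpg_ids Character vector of probe ids.
#' @return A `clock_model` with uniform weights `1/length(cpg_ids)`.
#' @export
mitotic_clock <- function(cpg_ids) {
  clock_model("mitotic",
              stats::setNames(rep(1 / length(cpg_ids), length(cpg_ids)),
                              cpg_ids),
              intercept = 0, transform = "identity")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("clock_model '", x$name, "': ", x$expected_n_cpgs, " CpGs, ",
      x$transform, " transform\n", sep = "")
  invisible(x)
}

.clock_transform <- function(clock, lp) {
  switch(clock$transform,
         identity = lp,
         log_linear = {
           aa <- clock$adult_age
           ifelse(lp < 0, (1 + aa) * exp(lp) - 1, (1 + aa) * lp + aa)
         })
}

.clock_inverse_transform <- function(clock, age) {
  switch(clock$transform,
         identity = age,
         log_linear = {
           aa <- clock$adult_age
           if (age < aa) log((age + 1) / (1 + aa)) else (age - aa) / (1 + aa)
         })
}

#' Predict DNA-methylation age
#'
#' Evaluates a clock's linear predictor over a beta matrix and applies its
#' calibration transform. Prediction is invariant to probe order and to the
#' presence of non-clock probes. Clock CpGs missing from the matrix are
#' handled per `missing_policy` provided coverage stays above
#' `min_overlap`.
#'
#' @param clock A [clock_model()].
#' @param bm Beta matrix (probes x samples).
#' @param missing_policy `"error"` (default) or `"mean_impute"` (see
#'   Details).
#' @param min_overlap Minimum fraction of clock CpGs that must be present.
#'   Default `0.95`.
#' @details Under `"mean_impute"`, a clock CpG absent from the matrix
#'   contributes `weight * 0.5` (the midpoint beta) for every sample; this
#'   keeps the predictor defined at high coverage without biasing samples
#'   relative to one another.
#' @return Named numeric vector of predicted ages (or mitotic scores), one
#'   per sample.
#' @export
dnam_age <- function(clock, bm, missing_policy = c("error", "mean_impute"),
                     min_overlap = 0.95) {
  missing_policy <- match.arg(missing_policy)
  w <- clock$cpg_coefficients
  present <- names(w) %in% rownames(bm)
  coverage <- mean(present)
  if (coverage < min_overlap) {
    stop(sprintf("clock CpG coverage %.1f%% below the %.1f%% floor",
                 100 * coverage, 100 * min_overlap), call. = FALSE)
  }
  if (any(!present) && missing_policy == "error") {
    stop("clock CpGs missing from the beta matrix: ",
         paste(utils::head(names(w)[!present], 5), collapse = ", "),
         call. = FALSE)
  }
  lp <- rep(clock$intercept, ncol(bm))
  wp <- w[present]
  lp <- lp + as.numeric(crossprod(bm[names(wp), , drop = FALSE], wp))
  if (any(!present)) {
    lp <- lp + sum(w[!present]) * 0.5
  }
  stats::setNames(.clock_transform(clock, lp), colnames(bm))
}

#' Age acceleration
#'
#' The residual of DNA-methylation age regressed on chronological age; a
#' positive value means the tissue appears epigenetically older than
#' chronology predicts. Residuals sum to zero and are orthogonal to
#' chronological age by construction.
#'
#' @param dnam Predicted DNAm ages (or mitotic scores).
#' @param chrono Chronological ages, same length, not constant.
#' @return Numeric residual vector.
#' @export
age_acceleration <- function(dnam, chrono) {
  if (length(dnam) != length(chrono)) stop("length mismatch", call. = FALSE)
  if (length(dnam) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(chrono) == 0) {
    stop("chronological age is constant", call. = FALSE)
  }
  unname(stats::residuals(stats::lm(dnam ~ chrono)))
}

#' Associate age acceleration with risk factors
#'
#' Fits one univariate OLS per covariate (`acceleration ~ covariate`) and a
#' single joint model with all covariates. Character/logical covariates are
#' expanded to treatment-coded indicators against their first level;
#' zero-variance terms are dropped with a warning.
#'
#' @param accel Acceleration residuals, aligned to `sheet` rows.
#' @param sheet Sample sheet.
#' @param covariates Covariate column names.
#' @return A list with `univariate` and `joint` coefficient tables
#'   (`term`, `estimate`, `stderr`, `p_value`, `model`).
#' @export
acceleration_associations <- function(accel, sheet, covariates) {
  miss <- setdiff(covariates, names(sheet))
  if (length(miss) > 0) {
    stop("covariates absent: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- sheet[, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.character(df[[v]]) || is.logical(df[[v]])) {
      df[[v]] <- factor(df[[v]])
    }
  }
  usable <- character(0)
  for (v in covariates) {
    vals <- df[[v]][!is.na(df[[v]])]
    if (length(unique(vals)) < 2) {
      warning("covariate '", v, "' has no variation; dropped")
    } else {
      usable <- c(usable, v)
    }
  }
  if (length(usable) == 0) stop("no usable covariates", call. = FALSE)
  df$.accel <- accel

  tidy_fit <- function(fit, model) {
    sm <- summary(fit)$coefficients
    keep <- rownames(sm) != "(Intercept)"
    data.frame(term = rownames(sm)[keep],
               estimate = sm[keep, 1],
               stderr = sm[keep, 2],
               p_value = sm[keep, 4],
               model = model,
               stringsAsFactors = FALSE, row.names = NULL)
  }

  uni <- do.call(rbind, lapply(usable, function(v) {
    fit <- stats::lm(stats::reformulate(v, ".accel"), data = df)
    tidy_fit(fit, paste0("univariate:", v))
  }))
  joint_fit <- stats::lm(stats::reformulate(usable, ".accel"), data = df)
  joint <- tidy_fit(joint_fit, "joint")
  list(univariate = uni, joint = joint)
}

#' Write a clock to a TSV + JSON pair
#'
#' The coefficient table goes to `<path>.tsv` (columns `probe_id`,
#' `weight`), the transform specification to `<path>.json`.
#'
#' @param clock A [clock_model()].
#' @param path Path stem (without extension).
#' @export
write_clock <- function(clock, path) {
  utils::write.table(
    data.frame(probe_id = names(clock$cpg_coefficients),
               weight = unname(clock$cpg_coefficients)),
    paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(name = clock$name, intercept = clock$intercept,
         transform = clock$transform, adult_age = clock$adult_age),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clock written by [write_clock()]
#' @param path Path stem (without extension).
#' @return A [clock_model()].
#' @export
read_clock <- function(path) {
  tab <- utils::read.delim(paste0(path, ".tsv"), stringsAsFactors = FALSE)
  spec <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  clock_model(spec$name,
              stats::setNames(tab$weight, tab$probe_id),
              intercept = spec$intercept,
              transform = spec$transform,
              adult_age = spec$adult_age)
}
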