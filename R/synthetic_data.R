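# Synthetic cohorts with known ground truth.
#
# The generator emulates the statistical structure a reference-free EWAS of a
# heterogeneous tissue assumes: K latent cell-type methylomes, per-subject
# mixture proportions on the simplex whose mean composition drifts with age,
# a planted set of age-associated CpGs (majority hypermethylating), and
# beta-scale measurement noise. Defaults mirror an adult breast-tissue cohort:
# ages uniform on 18-82 years, Dirichlet concentration 30, noise sd 0.03,
# 69% of planted CpGs hypermethylating.

#' Simulate a heterogeneous-tissue methylation cohort
#'
#' Generates a beta matrix from a cell-mixture model with full ground truth.
#' Cell-type methylomes `Mu_true` are bimodal (Beta-distributed) with a
#' fraction of cell-type-informative probes whose levels differ across cell
#' types; per-subject proportions `Omega_true` are Dirichlet draws whose mean
#' shifts linearly with age at rate `drift` (component 1 gains, component K
#' loses). Age effects are planted at `n_age_cpgs` probes as a linear trend of
#' `slope` M-units per year on the bulk methylome (a fraction `hyper_fraction`
#' with positive sign); truncated-Gaussian noise is added on the beta scale
#' and values are clipped to `[0, 1]`. The annotation's CpG-island relation
#' mirrors baseline methylation (islands unmethylated, open sea methylated,
#' shores/shelves intermediate), and planted CpGs are drawn from the
#' shore/shelf strata, where a linear M-scale trend is representable.
#'
#' @param n Number of subjects.
#' @param m Number of probes.
#' @param K Number of latent cell types.
#' @param age_range Length-2 numeric, years; ages drawn uniformly. Default
#'   `c(18, 82)`.
#' @param drift Per-year linear shift of the Dirichlet mean composition
#'   (component 1 up, component K down). Default `0.005`, i.e. a shift of
#'   about 0.3 across a 64-year adult age range.
#' @param n_age_cpgs Number of planted age-associated CpGs.
#' @param slope Magnitude of the planted age trend, M-units per year.
#' @param hyper_fraction Fraction of planted CpGs whose methylation increases
#'   with age. Default `0.69`.
#' @param noise_sd Beta-scale measurement noise sd. Default `0.03`.
#' @param informative_fraction Fraction of probes with cell-type-specific
#'   methylation levels (the probes that make deconvolution identifiable).
#'   Default `0.3`.
#' @param concentration Dirichlet concentration parameter. Default `30`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list with elements `beta` (m x n matrix), `sheet` (sample
#'   sheet), `annotation` (probe annotation) and `truth` (a
#'   `simulation_truth` list: `Mu_true`, `Omega_true`, `age_cpg_ids`,
#'   `slopes`, `enriched_region_label`, `seed`).
#' @export
simulate_cohort <- function(n, m, K,
                            age_range = c(18, 82),
                            drift = 0.005,
                            n_age_cpgs = 0,
                            slope = 0.02,
                            hyper_fraction = 0.69,
                            noise_sd = 0.03,
                            informative_fraction = 0.3,
                            concentration = 30,
                            seed = 1L) {
  stopifnot(K >= 1, n >= 1, m >= 1)
  if (hyper_fraction < 0 || hyper_fraction > 1) {
    stop("hyper_fraction must be in [0, 1]", call. = FALSE)
  }
  if (n_age_cpgs > m) stop("n_age_cpgs must not exceed m", call. = FALSE)
  set.seed(seed)

  probe_ids <- sprintf("cg%06d", seq_len(m))
  sample_ids <- sprintf("S%03d", seq_len(n))
  age <- stats::runif(n, age_range[1], age_range[2])
  age_mid <- mean(age_range)

  # cell-type methylomes: shared bimodal baseline; informative probes get
  # independent per-cell-type levels
  base <- stats::rbeta(m, 0.4, 0.4)
  Mu <- matrix(rep(base, K), nrow = m, ncol = K)
  n_inf <- round(informative_fraction * m)
  if (K > 1 && n_inf > 0) {
    inf_idx <- sample.int(m, n_inf)
    Mu[inf_idx, ] <- matrix(stats::rbeta(n_inf * K, 0.3, 0.3),
                            nrow = n_inf, ncol = K)
  }
  rownames(Mu) <- probe_ids

  # mixture proportions: Dirichlet with age-drifting mean
  mean0 <- rep(1 / K, K)
  Omega <- matrix(1, nrow = n, ncol = K)
  if (K > 1) {
    shift_dir <- numeric(K)
    shift_dir[1] <- 1
    shift_dir[K] <- -1
    for (i in seq_len(n)) {
      mu_i <- mean0 + drift * (age[i] - age_mid) * shift_dir
      if (any(mu_i <= 0) || any(mu_i >= 1)) {
        stop("drift pushes the Dirichlet mean outside the simplex",
             call. = FALSE)
      }
      g <- stats::rgamma(K, shape = mu_i * concentration, rate = 1)
      Omega[i, ] <- g / sum(g)
    }
  }
  rownames(Omega) <- sample_ids

  bulk <- Mu %*% t(Omega)  # m x n expected betas

  # planted age effects on the bulk methylome, linear on the M scale
  # island relation mirrors baseline methylation, as on real arrays:
  # islands are unmethylated, open sea methylated, shores/shelves in the
  # dynamic range
  island_relation <- cut(rowMeans(Mu), c(-Inf, 0.2, 0.5, 0.8, Inf),
                         labels = .island_levels)
  island_relation <- as.character(island_relation)

  # planted CpGs are drawn from the intermediate (shore/shelf) probes: a
  # linear M-scale trend is not representable at saturated probes, and
  # real age-drift CpGs concentrate at island shores. Because eligibility
  # is a union of island-relation strata, an island-matched background
  # set has the same baseline-methylation distribution as the planted set.
  slopes <- stats::setNames(numeric(m), probe_ids)
  age_idx <- integer(0)
  if (n_age_cpgs > 0) {
    eligible <- which(island_relation %in% c("shore", "shelf"))
    if (length(eligible) < n_age_cpgs) {
      stop("too few probes with intermediate methylation to plant ",
           n_age_cpgs, " age CpGs", call. = FALSE)
    }
    age_idx <- sample(eligible, n_age_cpgs)
    n_hyper <- round(hyper_fraction * n_age_cpgs)
    sgn <- rep(-1, n_age_cpgs)
    if (n_hyper > 0) sgn[seq_len(n_hyper)] <- 1
    slopes[age_idx] <- sgn * slope
    mv <- beta_to_mvalue(bulk[age_idx, , drop = FALSE])
    mv <- mv + outer(slopes[age_idx], age - age_mid)
    bulk[age_idx, ] <- mvalue_to_beta(mv)
  }

  beta <- bulk + matrix(stats::rnorm(m * n, sd = noise_sd), nrow = m)
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(probe_ids, sample_ids)

  annotation <- .simulate_annotation(probe_ids, island_relation)

  sheet <- data.frame(
    sample_id = sample_ids,
    age = age,
    bmi = round(stats::rlnorm(n, log(27), 0.2), 1),
    parous = stats::rbinom(n, 1, 0.56),
    family_history = ifelse(stats::runif(n) < 0.1, NA_integer_,
                            stats::rbinom(n, 1, 0.5)),
    race = sample(c("white", "hispanic", "african_american"), n,
                  replace = TRUE, prob = c(0.86, 0.09, 0.05)),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    Mu_true = Mu,
    Omega_true = Omega,
    age_cpg_ids = probe_ids[sort(age_idx)],
    slopes = slopes,
    enriched_region_label = NA_character_,
    seed = seed
  ), class = "simulation_truth")

  list(beta = beta, sheet = sheet, annotation = annotation, truth = truth)
}

# annotation over autosomes with unique positions per chromosome; island
# relation is supplied by the caller (tied to baseline methylation) or
# sampled uniformly
.simulate_annotation <- function(probe_ids, island_relation = NULL) {
  m <- length(probe_ids)
  chrom <- sample(paste0("chr", 1:22), m, replace = TRUE)
  position <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    position[idx] <- sort(sample.int(5e7, length(idx)))
  }
  if (is.null(island_relation)) {
    island_relation <- sample(.island_levels, m, replace = TRUE,
                              prob = c(0.30, 0.25, 0.10, 0.35))
  }
  gene_region <- sample(.gene_region_levels, m, replace = TRUE,
                        prob = c(0.25, 0.15, 0.30, 0.30))
  data.frame(
    probe_id = probe_ids,
    chromosome = chrom,
    position = position,
    island_relation = island_relation,
    gene_region = gene_region,
    gene_symbol = ifelse(gene_region == "intergenic", NA_character_,
                         paste0("GENE", seq_len(m))),
    masks = "",
    stringsAsFactors = FALSE
  )
}

#' Simulate region sets with one planted enrichment
#'
#' Builds `n_sets` labelled region sets of single-probe intervals. One set
#' (the first, labelled `"planted_set"`) covers each planted age-associated
#' CpG with probability `planted_set_fraction` and every other probe at
#' `background_rate`; the remaining sets cover all probes at
#' `background_rate`. The expected enrichment odds ratio of the planted set
#' is therefore `(f/(1-f)) / (b/(1-b))`.
#'
#' @param ann Probe annotation (supplies coordinates).
#' @param n_sets Number of region sets.
#' @param planted_set_fraction Coverage probability of planted CpGs in the
#'   planted set. Default `0.4`.
#' @param truth A `simulation_truth` (supplies `age_cpg_ids`).
#' @param background_rate Coverage probability of all other probes (and of
#'   all probes for non-planted sets). Default `0.1`.
#' @param seed Integer seed.
#' @return A list with `region_sets` (list of [region_set()]) and `truth`
#'   (input truth with `enriched_region_label` filled in).
#' @export
simulate_region_sets <- function(ann, n_sets, planted_set_fraction = 0.4,
                                 truth, background_rate = 0.1, seed = 1L) {
  if (planted_set_fraction > 1 || planted_set_fraction < 0) {
    stop("planted_set_fraction must be in [0, 1]", call. = FALSE)
  }
  if (planted_set_fraction <= background_rate) {
    stop("planted_set_fraction must exceed background_rate", call. = FALSE)
  }
  set.seed(seed)
  is_age <- ann$probe_id %in% truth$age_cpg_ids

  make_set <- function(label, p_cover) {
    covered <- stats::runif(nrow(ann)) < p_cover
    region_set(label, data.frame(
      chromosome = ann$chromosome[covered],
      start = ann$position[covered],
      end = ann$position[covered] + 1L,
      stringsAsFactors = FALSE
    ))
  }

  p_planted <- ifelse(is_age, planted_set_fraction, background_rate)
  sets <- vector("list", n_sets)
  sets[[1]] <- make_set("planted_set", p_planted)
  if (n_sets > 1) {
    for (j in 2:n_sets) {
      sets[[j]] <- make_set(sprintf("background_set_%02d", j - 1),
                            background_rate)
    }
  }
  names(sets) <- vapply(sets, `[[`, character(1), "label")
  truth$enriched_region_label <- "planted_set"
  list(region_sets = sets, truth = truth)
}

#' Simulate a tumor cohort paired with a normal generative model
#'
#' Draws `n_tumors` new subjects from the same cell-mixture generative model
#' as the normal cohort and exaggerates the planted age-direction deviations:
#' each planted CpG receives an additional M-scale offset
#' `(exaggeration - 1) * slope_j * progression_years` in the direction of its
#' age slope, emulating tumors in which age-related changes are further
#' deregulated. `exaggeration = 1` reproduces the normal model (a null).
#'
#' @param normal Beta matrix of the normal cohort (supplies probe ids and
#'   dimensions).
#' @param truth `simulation_truth` of the normal cohort.
#' @param exaggeration Multiplier (>= 1) of the planted deviations.
#' @param n_tumors Number of tumor samples; `0` yields a valid empty matrix.
#' @param noise_sd Beta-scale noise sd. Default `0.03`.
#' @param progression_years Scale of the tumor offset in equivalent years of
#'   age drift. Default `20`.
#' @param age_range,concentration As in [simulate_cohort()].
#' @param seed Integer seed.
#' @return A list with `beta` (m x n_tumors) and `sheet`.
#' @export
simulate_tumor_normal <- function(normal, truth, exaggeration = 3,
                                  n_tumors = 50, noise_sd = 0.03,
                                  progression_years = 20,
                                  age_range = c(18, 82),
                                  concentration = 30, seed = 1L) {
  if (exaggeration < 1) stop("exaggeration must be >= 1", call. = FALSE)
  set.seed(seed)
  m <- nrow(normal)
  probe_ids <- rownames(normal)
  Mu <- truth$Mu_true[probe_ids, , drop = FALSE]
  K <- ncol(Mu)
  sample_ids <- sprintf("T%03d", seq_len(n_tumors))
  age <- stats::runif(n_tumors, age_range[1], age_range[2])
  age_mid <- mean(age_range)

  if (n_tumors == 0) {
    beta <- matrix(numeric(0), nrow = m, ncol = 0,
                   dimnames = list(probe_ids, character(0)))
    sheet <- data.frame(sample_id = character(0), age = numeric(0),
                        stringsAsFactors = FALSE)
    return(list(beta = beta, sheet = sheet))
  }

  Omega <- matrix(1, nrow = n_tumors, ncol = K)
  if (K > 1) {
    for (i in seq_len(n_tumors)) {
      g <- stats::rgamma(K, shape = rep(concentration / K, K), rate = 1)
      Omega[i, ] <- g / sum(g)
    }
  }
  bulk <- Mu %*% t(Omega)

  slopes <- truth$slopes[probe_ids]
  planted <- which(slopes != 0)
  if (length(planted) > 0) {
    mv <- beta_to_mvalue(bulk[planted, , drop = FALSE])
    mv <- mv + outer(slopes[planted], age - age_mid)   # normal age trend
    mv <- mv + (exaggeration - 1) * slopes[planted] * progression_years
    bulk[planted, ] <- mvalue_to_beta(mv)
  }

  beta <- bulk + matrix(stats::rnorm(m * n_tumors, sd = noise_sd), nrow = m)
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(probe_ids, sample_ids)
  sheet <- data.frame(sample_id = sample_ids, age = age,
                      stringsAsFactors = FALSE)
  list(beta = beta, sheet = sheet)
}

#' Simulate a cohort calibrated to an epigenetic clock
#'
#' Constructs betas at the clock's CpGs so that the clock's linear predictor
#' equals the (inverse-transformed) target age for every subject, then
#' perturbs clock CpGs with Gaussian noise of sd `noise_sd` and fills
#' `n_extra` non-clock probes with noise. With `noise_sd = 0`,
#' [dnam_age()] returns the target ages exactly.
#'
#' @param clock A [clock_model()].
#' @param ages Numeric vector of target chronological ages (years).
#' @param noise_sd Beta-scale perturbation sd at clock CpGs. Default `0`.
#' @param n_extra Number of non-clock filler probes. Default `100`.
#' @param seed Integer seed.
#' @return A beta matrix ((clock CpGs + n_extra) x length(ages)).
#' @export
simulate_clock_cohort <- function(clock, ages, noise_sd = 0,
                                  n_extra = 100, seed = 1L) {
  w <- clock$cpg_coefficients
  p <- length(w)
  if (p == 0) stop("clock has no CpGs", call. = FALSE)
  set.seed(seed)
  n <- length(ages)
  target_lp <- vapply(ages, function(a) .clock_inverse_transform(clock, a),
                      numeric(1))
  base <- rep(0.5, p)
  lp0 <- clock$intercept + sum(w * base)
  # least-norm adjustment along the coefficient vector
  adj <- outer(w / sum(w^2), target_lp - lp0)
  beta_clock <- base + adj
  if (any(beta_clock < 0 | beta_clock > 1)) {
    stop("target ages are not representable with betas in [0, 1]; ",
         "use a clock with larger coefficient norm", call. = FALSE)
  }
  if (noise_sd > 0) {
    beta_clock <- beta_clock + matrix(stats::rnorm(p * n, sd = noise_sd),
                                      nrow = p)
    beta_clock <- pmin(pmax(beta_clock, 0), 1)
  }
  extra <- matrix(stats::runif(n_extra * n), nrow = n_extra)
  beta <- rbind(beta_clock, extra)
  rownames(beta) <- c(names(w), sprintf("cgX%05d", seq_len(n_extra)))
  colnames(beta) <- sprintf("S%03d", seq_len(n))
  beta
}
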