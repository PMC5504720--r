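# Region-set enrichment of significant CpGs (direction-stratified),
# matched-background resampling, two-sample KS comparison, and CpG-gene
# expression correlation.

# logical: does each universe probe fall inside any interval of rs?
# Probe positions are compared directly against the half-open intervals:
# inside iff start <= position < end.
.probe_in_set <- function(ann_sub, rs) {
  if (nrow(rs$intervals) == 0) return(rep(FALSE, nrow(ann_sub)))
  q <- GenomicRanges::GRanges(
    ann_sub$chromosome,
    IRanges::IRanges(start = ann_sub$position, width = 1))
  s <- GenomicRanges::GRanges(
    rs$intervals$chromosome,
    IRanges::IRanges(start = rs$intervals$start,
                     end = rs$intervals$end - 1L))
  IRanges::overlapsAny(q, s)
}

#' 2x2 overlap counts of a CpG query against a region set
#'
#' Counts `a` = query probes inside the set, `b` = query probes outside,
#' `c` = non-query universe probes inside, `d` = outside, so that
#' `a + b + c + d = |universe|`. The universe is the full analysis background
#' (it includes the query). Intervals are half-open: a probe at position `p`
#' is inside `[start, end)` iff `start <= p < end`.
#'
#' @param query Character vector of query probe ids (subset of universe).
#' @param universe Character vector of background probe ids.
#' @param ann Probe annotation with coordinates for every universe probe.
#' @param rs A [region_set()].
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
overlap_counts <- function(query, universe, ann, rs) {
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe", call. = FALSE)
  }
  idx <- match(universe, ann$probe_id)
  if (anyNA(idx)) {
    stop("universe probes missing coordinates: ",
         paste(utils::head(universe[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  ann_sub <- ann[idx, , drop = FALSE]
  inside <- .probe_in_set(ann_sub, rs)
  is_query <- universe %in% query
  c(a = sum(is_query & inside),
    b = sum(is_query & !inside),
    c = sum(!is_query & inside),
    d = sum(!is_query & !inside))
}

#' Fisher exact enrichment of a 2x2 table
#'
#' Two-sided Fisher exact p-value (hypergeometric), sample odds ratio
#' `(a*d)/(b*c)`, and a 95% confidence interval from the log-OR normal
#' approximation, with a 0.5 continuity correction applied only when a zero
#' cell is present.
#'
#' @param counts Numeric vector `c(a, b, c, d)` (query-in, query-out,
#'   rest-in, rest-out).
#' @return A list with `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
fisher_enrichment <- function(counts) {
  if (length(counts) != 4 || any(counts < 0)) {
    stop("counts must be 4 non-negative values", call. = FALSE)
  }
  a <- counts[[1]]; b <- counts[[2]]; c <- counts[[3]]; d <- counts[[4]]
  if (a + b == 0) stop("empty query", call. = FALSE)
  if (c + d == 0) stop("empty rest", call. = FALSE)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  if (a * d == 0 && is.nan(or)) or <- 0
  if (a == 0) or <- 0
  cc <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  a2 <- a + cc; b2 <- b + cc; c2 <- c + cc; d2 <- d + cc
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  lor <- log((a2 * d2) / (b2 * c2))
  list(odds_ratio = unname(or),
       ci_low = unname(exp(lor - 1.96 * se)),
       ci_high = unname(exp(lor + 1.96 * se)),
       p_value = unname(p))
}

#' Direction-stratified region-set enrichment
#'
#' Splits the significant CpGs (`q_value < q_threshold`) of an EWAS result
#' by coefficient sign into hypermethylated and hypomethylated strata, then
#' tests each region set for enrichment of each stratum against the full
#' probe universe with Fisher's exact test; q-values are computed across
#' sets within each direction. Empty strata produce `"skipped"` records.
#'
#' @param results EWAS result table (from [run_ewas()]).
#' @param universe Character vector of background probe ids.
#' @param ann Probe annotation.
#' @param region_sets List of [region_set()] objects.
#' @param q_threshold Significance threshold. Default `0.01`.
#' @return A `data.frame` with one row per set per direction: `set_label`,
#'   `direction`, `a`, `b`, `c`, `d`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `q_value`, `status`.
#' @export
stratified_enrichment <- function(results, universe, ann, region_sets,
                                  q_threshold = 0.01) {
  sig <- results[results$q_value < q_threshold, , drop = FALSE]
  strata <- list(hyper = sig$probe_id[sig$coefficient > 0],
                 hypo = sig$probe_id[sig$coefficient < 0])
  out <- list()
  for (dir in names(strata)) {
    q <- intersect(strata[[dir]], universe)
    if (length(q) == 0) {
      rec <- data.frame(set_label = vapply(region_sets, `[[`,
                                           character(1), "label"),
                        direction = dir, a = NA_real_, b = NA_real_,
                        c = NA_real_, d = NA_real_, odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, q_value = NA_real_,
                        status = "skipped", stringsAsFactors = FALSE)
      out[[dir]] <- rec
      next
    }
    recs <- lapply(region_sets, function(rs) {
      cnt <- overlap_counts(q, universe, ann, rs)
      fe <- fisher_enrichment(cnt)
      data.frame(set_label = rs$label, direction = dir,
                 a = cnt[["a"]], b = cnt[["b"]], c = cnt[["c"]],
                 d = cnt[["d"]], odds_ratio = fe$odds_ratio,
                 ci_low = fe$ci_low, ci_high = fe$ci_high,
                 p_value = fe$p_value, q_value = NA_real_, status = "ok",
                 stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, recs)
    rec$q_value <- bh_qvalues(rec$p_value)
    out[[dir]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample an annotation-matched background CpG set
#'
#' Draws, without replacement and disjoint from the query, a background set
#' of the same size whose per-stratum composition of `match_field` (by
#' default the CpG-island relation) equals the query's exactly.
#'
#' @param query Character vector of query probe ids.
#' @param universe Character vector of candidate probe ids (must contain the
#'   query).
#' @param ann Probe annotation.
#' @param match_field Annotation column matched on. Default
#'   `"island_relation"`.
#' @param seed Integer seed.
#' @return Character vector of background probe ids, `length(query)` long.
#' @export
sample_matched_background <- function(query, universe, ann,
                                      match_field = "island_relation",
                                      seed = 1L) {
  if (!match_field %in% names(ann)) {
    stop("annotation lacks column '", match_field, "'", call. = FALSE)
  }
  strat <- stats::setNames(ann[[match_field]], ann$probe_id)
  q_strat <- strat[query]
  pool <- setdiff(universe, query)
  pool_strat <- strat[pool]
  set.seed(seed)
  need <- table(q_strat)
  picked <- character(0)
  for (s in names(need)) {
    avail <- pool[pool_strat == s]
    if (length(avail) < need[[s]]) {
      stop("insufficient background in stratum '", s, "': need ", need[[s]],
           ", have ", length(avail), call. = FALSE)
    }
    picked <- c(picked, sample(avail, need[[s]]))
  }
  picked
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_x - ECDF_y|`; the p-value is exact (by enumeration) for
#' small samples and asymptotic otherwise, as provided by
#' [stats::ks.test()].
#'
#' @param x,y Non-empty numeric samples.
#' @return A list with `D` and `p_value`.
#' @export
ks_compare <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Spearman correlation of CpG methylation with gene expression
#'
#' For each CpG-gene pair, computes the Spearman rank correlation between
#' the probe's M values and the gene's expression over the shared samples,
#' retaining the probe's gene-region context for downstream summaries
#' (e.g. promoter vs gene-body direction dependence).
#'
#' @param M M-value matrix (probes x samples).
#' @param expr Expression matrix (genes x samples).
#' @param pairs `data.frame` with columns `probe_id` and `gene`.
#' @param ann Probe annotation (supplies `gene_region`).
#' @return A `data.frame` with `probe_id`, `gene`, `rho`, `p_value`,
#'   `gene_region`.
#' @export
cpg_expression_correlation <- function(M, expr, pairs, ann) {
  shared <- intersect(colnames(M), colnames(expr))
  if (length(shared) < 5) {
    stop("need >= 5 shared samples", call. = FALSE)
  }
  gr <- stats::setNames(ann$gene_region, ann$probe_id)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pid <- pairs$probe_id[i]
    g <- pairs$gene[i]
    if (!pid %in% rownames(M) || !g %in% rownames(expr)) {
      stop("pair ", pid, "/", g, " absent from matrices", call. = FALSE)
    }
    ct <- suppressWarnings(
      stats::cor.test(M[pid, shared], expr[g, shared], method = "spearman"))
    data.frame(probe_id = pid, gene = g,
               rho = unname(ct$estimate), p_value = ct$p.value,
               gene_region = unname(gr[pid]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
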