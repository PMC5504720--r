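test_that("overlap_counts respects the half-open interval convention", {
  ann <- tiny_annotation(paste0("cg", 1:4))
  ann$position <- c(100L, 150L, 200L, 250L)
  rs_in <- region_set("s", data.frame(chromosome = "chr1",
                                      start = 100, end = 101))
  rs_out <- region_set("s", data.frame(chromosome = "chr1",
                                       start = 101, end = 200))
  universe <- ann$probe_id
  cnt <- overlap_counts("cg1", universe, ann, rs_in)
  expect_equal(unname(cnt), c(1, 0, 0, 3))
  cnt2 <- overlap_counts("cg1", universe, ann, rs_out)
  expect_equal(cnt2[["a"]], 0)
  expect_equal(cnt2[["c"]], 1)  # cg2 at 150 inside [101, 200)

  # query = universe leaves no "rest"
  cnt3 <- overlap_counts(universe, universe, ann, rs_in)
  expect_equal(cnt3[["c"]] + cnt3[["d"]], 0)

  # empty region set
  rs0 <- region_set("empty", data.frame(chromosome = character(0),
                                        start = numeric(0),
                                        end = numeric(0)))
  cnt4 <- overlap_counts("cg1", universe, ann, rs0)
  expect_equal(cnt4[["a"]] + cnt4[["c"]], 0)

  expect_error(overlap_counts("cgZ", universe, ann, rs_in), "subset")
})

test_that("fisher_enrichment matches the hypergeometric oracle", {
  fe <- fisher_enrichment(c(20, 80, 100, 900))
  expect_equal(fe$odds_ratio, 2.25)
  expect_true(fe$ci_low < 2.25 && fe$ci_high > 2.25)

  expect_equal(fisher_enrichment(c(0, 100, 50, 850))$odds_ratio, 0)
  same <- fisher_enrichment(c(10, 90, 10, 90))
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_value, 1)

  # exact two-sided hypergeometric-sum oracle
  fisher_oracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; N <- a + b + c + d
    support <- max(0, r1 + c1 - N):min(r1, c1)
    probs <- dhyper(support, c1, N - c1, r1)
    sum(probs[probs <= dhyper(a, c1, N - c1, r1) * (1 + 1e-7)])
  }
  set.seed(12)
  for (i in 1:50) {
    tab <- rmultinom(1, sample(20:120, 1), runif(4, 0.05, 1))[, 1]
    if (tab[1] + tab[2] == 0 || tab[3] + tab[4] == 0) next
    expect_equal(fisher_enrichment(tab)$p_value,
                 fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }

  expect_error(fisher_enrichment(c(0, 0, 5, 5)), "empty query")
})

test_that("enrichment of query and complement give reciprocal odds ratios", {
  cnt <- c(30, 70, 120, 780)
  fe <- fisher_enrichment(cnt)
  flip <- fisher_enrichment(c(cnt[3], cnt[4], cnt[1], cnt[2]))
  expect_equal(flip$odds_ratio, 1 / fe$odds_ratio, tolerance = 1e-12)
})

test_that("stratified_enrichment splits by sign with exact symmetry", {
  set.seed(13)
  sim <- simulate_cohort(n = 10, m = 400, K = 2, seed = 14)
  ann <- sim$annotation
  res <- data.frame(probe_id = ann$probe_id,
                    coefficient = rnorm(400),
                    q_value = runif(400) * 0.5,
                    stringsAsFactors = FALSE)
  rs <- simulate_region_sets(ann, 2, 0.4, sim$truth, seed = 15)$region_sets
  out <- stratified_enrichment(res, ann$probe_id, ann, rs,
                               q_threshold = 0.05)
  expect_setequal(out$direction, c("hyper", "hypo"))
  expect_true(all(out$status == "ok"))

  # flipping all coefficient signs swaps the strata exactly
  res2 <- res
  res2$coefficient <- -res2$coefficient
  out2 <- stratified_enrichment(res2, ann$probe_id, ann, rs,
                                q_threshold = 0.05)
  hyper1 <- out[out$direction == "hyper", -2]
  hypo2 <- out2[out2$direction == "hypo", -2]
  rownames(hyper1) <- rownames(hypo2) <- NULL
  expect_equal(hyper1, hypo2)

  # all-positive coefficients leave the hypo stratum skipped, not dropped
  res3 <- res
  res3$coefficient <- abs(res3$coefficient)
  out3 <- stratified_enrichment(res3, ann$probe_id, ann, rs,
                                q_threshold = 0.05)
  expect_true(all(out3$status[out3$direction == "hypo"] == "skipped"))
  expect_equal(sum(out3$direction == "hypo"), length(rs))
})

test_that("sample_matched_background reproduces the query stratum profile", {
  set.seed(16)
  ann <- tiny_annotation(sprintf("cg%03d", 1:200))
  ann$island_relation <- sample(c("island", "shore", "open_sea"), 200,
                                replace = TRUE)
  universe <- ann$probe_id
  query <- sample(universe, 40)
  bg <- sample_matched_background(query, universe, ann, seed = 1)
  expect_length(bg, 40)
  expect_length(intersect(bg, query), 0)
  strat <- setNames(ann$island_relation, ann$probe_id)
  expect_equal(table(strat[bg]), table(strat[query]))

  # different seeds give different sets with identical profiles
  bg2 <- sample_matched_background(query, universe, ann, seed = 2)
  expect_false(setequal(bg, bg2))
  expect_equal(table(strat[bg2]), table(strat[query]))

  # insufficient stratum errors with the stratum name
  ann2 <- tiny_annotation(c("a", "b", "c"), island = "shelf")
  expect_error(sample_matched_background(c("a", "b"), c("a", "b", "c"),
                                         ann2, seed = 1),
               "shelf")
})

test_that("ks_compare agrees with a breakpoint-enumeration oracle", {
  expect_equal(ks_compare(1:5, 1:5)$D, 0)
  expect_equal(ks_compare(1:5, 1:5)$p_value, 1)
  expect_equal(ks_compare(1:5, 6:10)$D, 1)

  ks_oracle <- function(x, y) {
    br <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(br) - ecdf(y)(br)))
  }
  set.seed(17)
  for (i in 1:30) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    expect_equal(ks_compare(x, y)$D, ks_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
})

test_that("cpg_expression_correlation recovers monotone relations", {
  set.seed(18)
  M <- matrix(rnorm(3 * 10), 3, 10,
              dimnames = list(c("cg1", "cg2", "cg3"),
                              sprintf("S%02d", 1:10)))
  expr <- rbind(gA = exp(M[1, ]),        # monotone increasing in M
                gB = -M[2, ],            # strictly decreasing
                gC = rnorm(10))
  colnames(expr) <- colnames(M)
  ann <- tiny_annotation(rownames(M))
  pairs <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                      gene = c("gA", "gB", "gC"),
                      stringsAsFactors = FALSE)
  out <- cpg_expression_correlation(M, expr, pairs, ann)
  expect_equal(out$rho, c(1, -1, cor(M[3, ], expr[3, ],
                                     method = "spearman")))
  expect_equal(out$gene_region, rep("promoter", 3))
  expect_error(cpg_expression_correlation(M[, 1:3], expr[, 1:3], pairs, ann),
               "shared samples")
})

test_that("region sets round-trip through BED with labels preserved", {
  sets <- list(
    region_set("alpha", data.frame(chromosome = "chr1",
                                   start = c(100, 500), end = c(200, 900))),
    region_set("beta_mark", data.frame(chromosome = "chr2",
                                       start = 0, end = 50))
  )
  d <- withr::local_tempdir()
  path <- file.path(d, "marks.bed")
  write_region_sets(sets, path)
  back <- read_region_sets(path)
  expect_setequal(names(back), c("alpha", "beta_mark"))
  expect_equal(back$alpha$intervals$start, c(100, 500))
  expect_equal(back$alpha$intervals$end, c(200, 900))
  expect_equal(back$beta_mark$intervals$start, 0)
})
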