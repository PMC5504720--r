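# Small fixtures built in code, shared across test files.

# a tiny labelled beta matrix with reproducible uniform values
tiny_beta <- function(m = 10, n = 6, seed = 1) {
  set.seed(seed)
  matrix(runif(m * n), nrow = m,
         dimnames = list(sprintf("cg%03d", seq_len(m)),
                         sprintf("S%02d", seq_len(n))))
}

# minimal annotation for a set of probes, all autosomal and unmasked
tiny_annotation <- function(probe_ids, chromosome = "chr1",
                            island = "island") {
  n <- length(probe_ids)
  data.frame(probe_id = probe_ids,
             chromosome = rep_len(chromosome, n),
             position = seq(100L, by = 100L, length.out = n),
             island_relation = rep_len(island, n),
             gene_region = "promoter",
             gene_symbol = paste0("G", seq_len(n)),
             masks = "",
             stringsAsFactors = FALSE)
}

# exact mixture fixture: well-separated methylomes, proportions with
# near-vertex samples so the factorization is identifiable without noise
exact_mixture_fixture <- function(m = 400, n = 40, seed = 9) {
  set.seed(seed)
  Mu0 <- matrix(rbeta(m * 2, 0.3, 0.3), m, 2)
  Mu0[seq_len(m / 2), 1] <- 0.9
  Mu0[seq_len(m / 2), 2] <- 0.1
  g <- matrix(rgamma(n * 2, 0.5), n, 2)
  Omega0 <- g / rowSums(g)
  Y <- Mu0 %*% t(Omega0)
  dimnames(Y) <- list(sprintf("cg%03d", seq_len(m)),
                      sprintf("S%02d", seq_len(n)))
  list(Y = Y, Mu0 = Mu0, Omega0 = Omega0)
}

# synthetic identity-transform clock with enough spread to encode adult ages
toy_clock <- function(p = 200, seed = 5) {
  set.seed(seed)
  w <- rnorm(p, sd = 1.5)
  w <- w - mean(w)  # centred weights keep the base predictor at the intercept
  clock_model("toy",
              stats::setNames(w, sprintf("clk%03d", seq_len(p))),
              intercept = 45, transform = "identity")
}
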