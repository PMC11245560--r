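# shared fixture builders (everything generated in code)

# two diverged lineages plus a hybrid, small enough for fast tests
small_hybrid_sim <- function(divergence = 0.02, novel = 0, chrom_length = 50000L,
                             n_chromosomes = 1L, seed = 1L) {
  ls <- simulate_lineages(lineage_sim_config(
    n_lineages = 2L, n_chromosomes = n_chromosomes,
    chrom_length = chrom_length, divergence = divergence, seed = seed))
  hy <- make_hybrid(ls, hybrid_sim_config("L1", "L2", novel, seed = seed + 1L))
  list(lineages = ls, hybrid = hy)
}

# four lineages in two clades (within 0.005, between `between`)
clade_lineages <- function(between = 0.02, within = 0.005,
                           chrom_length = 100000L, n_chromosomes = 1L,
                           seed = 1L) {
  dv <- matrix(between, 4, 4)
  dv[1:2, 1:2] <- within
  dv[3:4, 3:4] <- within
  diag(dv) <- 0
  simulate_lineages(lineage_sim_config(
    n_lineages = 4L, n_chromosomes = n_chromosomes,
    chrom_length = chrom_length, divergence = dv, seed = seed))
}

# a deterministic toy variant table: 10 biallelic-ish sites, 4 samples
toy_variant_table <- function() {
  n <- 10L
  sites <- data.frame(chrom = "chr1", pos = seq(100L, by = 100L, length.out = n),
                      ref = rep("A", n), alt = rep("G", n),
                      qual = rep(60, n))
  sites$alt[7] <- "G,T"                     # triallelic site
  gt <- matrix("0/1", n, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  gt[3, ] <- c("0/0", "0/0", "0/0", "0/1")  # MAF = 1/8 = 0.125
  gt[5, ] <- c("0/0", "0/0", "0/0", "0/0")  # monomorphic after calls
  gt[9, ] <- c("0/0", "0/0", "0/1", "0/0")  # MAF 0.125
  ad <- matrix("10,10", n, 4, dimnames = dimnames(gt))
  dp <- matrix(20, n, 4, dimnames = dimnames(gt))
  variant_table(sites, gt, ad, dp, chrom_lengths = c(chr1 = 1000L))
}

# brute-force one-sided hypergeometric tail by pmf summation
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- seq(k, min(K, n))
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# naive second code path for the TMM trim-and-weight estimator
naive_tmm_factor <- function(obs, ref, logratio_trim = 0.3,
                             abundance_trim = 0.05) {
  No <- sum(obs); Nr <- sum(ref)
  keep <- which(obs > 0 & ref > 0)
  M <- log2((obs[keep] / No) / (ref[keep] / Nr))
  A <- 0.5 * log2((obs[keep] / No) * (ref[keep] / Nr))
  w <- (No - obs[keep]) / (No * obs[keep]) + (Nr - ref[keep]) / (Nr * ref[keep])
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  sel <- rank(M) >= loM & rank(M) <= hiM &
    rank(A) >= loA & rank(A) <= hiA
  2^(weighted.mean(M[sel], 1 / w[sel]))
}

# hand step-up BH
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- Inf
  for (i in rev(seq_len(m))) {
    run <- min(run, p[o[i]] * m / i)
    adj[o[i]] <- min(run, 1)
  }
  adj
}
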