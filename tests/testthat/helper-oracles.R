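# Independent oracles and fixture builders shared across the test files.

# Brute-force colocalization oracle: enumerate every causal configuration
# (none, each single-trait placement, every ordered pair of distinct
# placements, every shared placement) with plain sums on the natural scale.
# Kept deliberately independent of the package's log-space implementation.
brute_coloc <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(labf1)
  b1 <- exp(labf1)
  b2 <- exp(labf2)
  w0 <- 1
  w1 <- p1 * sum(b1)
  w2 <- p2 * sum(b2)
  w3 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w3 <- w3 + p1 * p2 * b1[i] * b2[j]
    }
  }
  w4 <- p12 * sum(b1 * b2)
  w <- c(w0, w1, w2, w3, w4)
  setNames(w / sum(w), c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4"))
}

# Minimal canonical summary-statistics tibble.
make_ss <- function(id, chrom = "chr1", pos = seq_along(id) * 1000,
                    a1 = "A", a2 = "G", beta = 0.1, se = 0.01,
                    p = 1e-6, maf = 0.3, info = NA_real_,
                    n_eff = NA_real_) {
  tibble::tibble(id = id, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
                 beta = beta, se = se, p = p, maf = maf, info = info,
                 n_eff = n_eff)
}

# Random validated table for harmonization property tests.
random_ss <- function(n, seed) {
  withr::with_seed(seed, {
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                   c("A", "T"), c("C", "G"))
    pick <- sample(nrow(pairs), n, replace = TRUE)
    flip <- runif(n) < 0.5
    a1 <- ifelse(flip, pairs[pick, 2], pairs[pick, 1])
    a2 <- ifelse(flip, pairs[pick, 1], pairs[pick, 2])
    make_ss(id = sprintf("rs%03d", seq_len(n)), pos = seq_len(n) * 500,
            a1 = a1, a2 = a2, beta = rnorm(n, 0, 0.05),
            se = runif(n, 0.005, 0.05), p = runif(n),
            maf = runif(n, 0.01, 0.5))
  })
}

# Lead list with a requested total count, one variant of which sits inside
# the MHC exclusion region.
make_leads <- function(n, trait, prefix, n_in_mhc = 1) {
  stopifnot(n > n_in_mhc)
  chrom <- c(rep("chr6", n_in_mhc), rep("chr1", n - n_in_mhc))
  pos <- c(rep(30e6, n_in_mhc), seq_len(n - n_in_mhc) * 1e5)
  lead_variant_set(
    tibble::tibble(id = sprintf("%s%03d", prefix, seq_len(n)),
                   chrom = chrom, pos = pos),
    trait)
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
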