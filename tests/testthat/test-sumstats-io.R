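test_that("read_sumstats loads valid rows, drops invariant violations, honours column maps", {
  header <- "id\tchrom\tpos\ta1\ta2\tbeta\tse\tp"
  rows <- c("rs1\t1\t1000\tA\tG\t0.05\t0.01\t1e-6",
            "rs2\t2\t2000\tC\tT\t-0.02\t0.02\t0.3",
            "rs3\t3\t3000\tG\tT\t0.10\t0.03\t0.01")
  f <- write_tmp_lines(c(header, rows))
  tab <- read_sumstats(f)
  expect_equal(nrow(tab), 3)
  rep <- attr(tab, "load_report")
  expect_equal(rep$n[rep$reason == "retained"], 3)
  expect_equal(tab$chrom, c("chr1", "chr2", "chr3"))

  # one row with se = 0 is dropped with the right reason
  f2 <- write_tmp_lines(c(header, rows,
                          "rs4\t4\t4000\tA\tC\t0.01\t0\t0.5"))
  tab2 <- read_sumstats(f2)
  expect_equal(nrow(tab2), 3)
  rep2 <- attr(tab2, "load_report")
  expect_equal(rep2$n[rep2$reason == "nonpositive SE"], 1)

  # column aliasing yields a table identical to canonical naming
  f3 <- write_tmp_lines(c("id\tchrom\tpos\ta1\ta2\tbeta\tse\tP-value", rows))
  tab3 <- read_sumstats(f3, column_map = c(p = "P-value"))
  expect_equal(tibble::as_tibble(tab3), tibble::as_tibble(tab))

  # missing mandatory column is a configuration error, empty file an input error
  f4 <- write_tmp_lines(c("id\tchrom\tpos\ta1\ta2\tbeta\tse", "x\t1\t1\tA\tG\t0\t1"))
  expect_error(read_sumstats(f4), class = "pleioscan_config_error")
  f5 <- write_tmp_lines(character(0))
  expect_error(read_sumstats(f5), class = "pleioscan_input_error")
})

test_that("validation keeps the smallest-p record among duplicate ids", {
  df <- make_ss(id = c("rs1", "rs1", "rs2"), pos = c(10, 10, 20),
                p = c(0.5, 1e-4, 0.1))
  out <- validate_sumstats(df)
  expect_equal(nrow(out$table), 2)
  expect_equal(out$table$p[out$table$id == "rs1"], 1e-4)
  expect_equal(out$report$n[out$report$reason == "duplicate id"], 1)
})

test_that("strand ambiguity is exactly the A/T and C/G pairs", {
  expect_true(is_strand_ambiguous("A", "T"))
  expect_true(is_strand_ambiguous("G", "C"))
  expect_false(is_strand_ambiguous("A", "G"))
  expect_false(is_strand_ambiguous("CT", "C"))  # indels are non-ambiguous
  expect_equal(is_strand_ambiguous(c("a", "c"), c("t", "g")), c(TRUE, TRUE))
})

test_that("harmonize_pair flips swapped alleles and drops ambiguous/mismatched variants", {
  a <- make_ss(id = c("rs1", "rs2", "rs3"), pos = c(100, 200, 300),
               a1 = c("A", "A", "A"), a2 = c("G", "T", "G"),
               beta = c(0.1, 0.2, 0.3))
  b <- make_ss(id = c("rs1", "rs2", "rs3"), pos = c(100, 200, 300),
               a1 = c("G", "A", "A"), a2 = c("A", "T", "C"),
               beta = c(0.2, 0.2, 0.3))
  hp <- harmonize_pair(a, b)
  expect_equal(hp$id, "rs1")
  expect_equal(hp$beta_b, -0.2)       # sign flip under allele swap
  expect_equal(hp$a1, "A")
  expect_true(hp$flipped)
  dropped <- attr(hp, "dropped")
  expect_equal(dropped$reason[dropped$id == "rs2"], "strand-ambiguous")
  expect_equal(dropped$reason[dropped$id == "rs3"], "allele mismatch")
})

test_that("harmonization is symmetric in roles and invariant to allele re-encoding", {
  for (seed in 1:4) {
    a <- random_ss(40, seed)
    b <- random_ss(40, seed + 100)
    b$chrom <- a$chrom; b$pos <- a$pos  # same sites, random allele frames
    b$a1 <- a$a1; b$a2 <- a$a2
    flip <- withr::with_seed(seed + 200, runif(40) < 0.5)
    b$a1[flip] <- a$a2[flip]; b$a2[flip] <- a$a1[flip]
    b$beta[flip] <- -b$beta[flip]

    ab <- harmonize_pair(a, b)
    ba <- harmonize_pair(b, a)
    expect_setequal(ab$id, ba$id)
    ba <- ba[match(ab$id, ba$id), ]
    # per-variant (beta, se) pairs agree after role exchange, modulo the
    # allele frame (signs flip together when the frames differ)
    expect_equal(abs(ab$beta_a), abs(ba$beta_b))
    expect_equal(ab$se_a, ba$se_b)
    expect_equal(sign(ab$beta_a * ab$beta_b), sign(ba$beta_a * ba$beta_b))

    # flipping every allele pair and beta sign of b changes nothing
    b2 <- b
    b2$a1 <- b$a2; b2$a2 <- b$a1; b2$beta <- -b$beta
    ab2 <- harmonize_pair(a, b2)
    expect_equal(ab$id, ab2$id)
    expect_equal(ab$beta_b, ab2$beta_b)
  }
})

test_that("per-variant effective sample size follows the MAF/INFO/BETA/SE formula", {
  expect_equal(neff_per_variant(0.5, beta = 0, se = 0.01), 80000)
  expect_equal(neff_per_variant(0.5, beta = 0.1, se = 0.01), 79900)
  # missing INFO treated as 1
  expect_equal(neff_per_variant(0.3, beta = 0.02, se = 0.02, info = NA),
               neff_per_variant(0.3, beta = 0.02, se = 0.02, info = 1))
  # negative values become NA with a warning
  expect_warning(out <- neff_per_variant(0.5, beta = 10, se = 0.1))
  expect_true(is.na(out))
  expect_error(neff_per_variant(1, beta = 0, se = 0.01),
               class = "pleioscan_domain_error")
  # strictly decreasing in se; minimized over maf at 0.5
  se_grid <- c(0.005, 0.01, 0.02, 0.05)
  vals <- neff_per_variant(0.2, beta = 0, se = se_grid)
  expect_true(all(diff(vals) < 0))
  maf_grid <- c(0.05, 0.2, 0.35, 0.5)
  vals2 <- neff_per_variant(maf_grid, beta = 0, se = 0.01)
  expect_true(all(vals2 >= vals2[4]))
})

test_that("count-based effective sample size is twice the harmonic mean", {
  # exact rational arithmetic: 4 * 21982 * 41944 / (21982 + 41944)
  expect_equal(neff_from_counts(21982, 41944),
               4 * 21982 * 41944 / (21982 + 41944))
  expect_equal(round(neff_from_counts(21982, 41944)), 57693)
  for (n in c(1, 10, 5000)) expect_equal(neff_from_counts(n, n), 2 * n)
  expect_equal(neff_from_counts(1, 1), 2)
  # never exceeds the total sample size
  for (seed in 1:20) {
    nc <- withr::with_seed(seed, sample.int(1e5, 2))
    expect_lte(neff_from_counts(nc[1], nc[2]), sum(nc))
  }
  expect_error(neff_from_counts(0, 10), class = "pleioscan_domain_error")
})

test_that("sumstats round-trip through the canonical writer", {
  tab <- validate_sumstats(random_ss(25, 9))$table
  f <- tempfile(fileext = ".tsv")
  write_sumstats(tab, f)
  back <- read_sumstats(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tab),
               ignore_attr = TRUE)
  rep_path <- tempfile(fileext = ".tsv")
  write_load_report(back, rep_path)
  expect_true(file.exists(rep_path))
})
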