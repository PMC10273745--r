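test_that("HLA-region exclusion removes exactly the in-region leads", {
  pd <- make_leads(90, "PD", "pd")
  als <- make_leads(15, "ALS", "als")
  expect_equal(nrow(exclude_region(pd)), 89)
  expect_equal(nrow(exclude_region(als)), 14)
  expect_equal(nrow(attr(exclude_region(pd), "excluded")), 1)
  # no region -> identity
  expect_equal(nrow(exclude_region(pd, NULL)), 90)
})

test_that("pooling is a source-annotated union", {
  adrd <- exclude_region(make_leads(84, "ADRD", "adrd"))  # 83 post-exclusion
  pd <- exclude_region(make_leads(90, "PD", "pd"))        # 89
  pooled <- pool_leads(adrd, pd)
  expect_equal(nrow(pooled), 172)
  expect_setequal(unique(pooled$lead_for), c("ADRD", "PD"))

  # a variant leading for both traits appears once, annotated "both"
  pd_shared <- pd
  pd_shared$id[5] <- adrd$id[5]
  pooled2 <- pool_leads(adrd, pd_shared)
  expect_equal(nrow(pooled2), 83 + 89 - 1)
  expect_equal(sum(pooled2$lead_for == "both"), 1)

  empty <- lead_variant_set(tibble::tibble(id = character(),
                                           chrom = character(),
                                           pos = numeric()), "PD")
  expect_equal(nrow(pool_leads(adrd, empty)), 83)
})

test_that("testability resolution reproduces a present/proxy/dropped census", {
  adrd <- exclude_region(make_leads(84, "ADRD", "adrd"))
  pd <- exclude_region(make_leads(90, "PD", "pd"))
  pooled <- pool_leads(adrd, pd)        # 172 variants
  present <- pooled$id[1:160]
  missing <- pooled$id[161:172]
  proxies <- ld_proxy_table(tibble::tibble(
    variant_a = missing[1:2], variant_b = c("px1", "px2"), r2 = c(0.9, 0.85)))
  available <- c(present, "px1", "px2")
  res <- resolve_testable(pooled, available, proxies)
  expect_equal(attr(res, "m"), 162)
  expect_equal(sum(res$status == "present"), 160)
  expect_equal(sum(res$status == "proxy"), 2)
  expect_equal(sum(res$status == "dropped"), 10)

  # everything present -> m equals the pool size
  res_all <- resolve_testable(pooled, pooled$id)
  expect_equal(attr(res_all, "m"), nrow(pooled))

  # nothing available and no proxies -> m = 0 and cross_test refuses
  res_none <- resolve_testable(pooled, character(0))
  expect_equal(attr(res_none, "m"), 0)
  expect_error(cross_test(res_none, tibble::tibble(id = character()), 0.05),
               class = "pleioscan_domain_error")
})

test_that("Bonferroni thresholds match the printed two-significant-figure values", {
  expect_equal(signif(bonferroni_threshold(162), 2), 3.1e-4)
  expect_equal(signif(bonferroni_threshold(88), 2), 5.7e-4)
  expect_equal(signif(bonferroni_threshold(98), 2), 5.1e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), class = "pleioscan_domain_error")
  # stringency is monotone in the number of tests
  ms <- c(1, 2, 10, 88, 162, 1000)
  expect_true(all(diff(bonferroni_threshold(1) / ms) < 0))
  expect_true(all(diff(vapply(ms, bonferroni_threshold, numeric(1))) < 0))
})

test_that("direction concordance classifies sign patterns", {
  expect_equal(direction_concordance(0.04, -0.02), "discordant")
  expect_equal(direction_concordance(0.05, 0.07), "concordant")
  expect_equal(direction_concordance(0, 0.1), "indeterminate")
  expect_equal(direction_concordance(c(-1, -1), c(-2, 2)),
               c("concordant", "discordant"))
})

test_that("cross_test applies a strict threshold and fills directions", {
  leads_a <- lead_variant_set(
    tibble::tibble(id = c("rsA", "rsEdge"), chrom = "chr1",
                   pos = c(1000, 2000)), "ADRD")
  leads_b <- lead_variant_set(
    tibble::tibble(id = "rs34025766", chrom = "chr4", pos = 17967188), "PD")
  pooled <- pool_leads(leads_a, leads_b)
  thr <- bonferroni_threshold(3)
  # harmonized pair: trait A = ADRD, trait B = PD
  pair <- harmonize_pair(
    make_ss(id = c("rsA", "rsEdge", "rs34025766"),
            chrom = c("chr1", "chr1", "chr4"),
            pos = c(1000, 2000, 17967188),
            beta = c(0.05, 0.05, log(1.04)),      # ADRD
            p = c(1e-6, 1e-6, 2.5e-4)),
    make_ss(id = c("rsA", "rsEdge", "rs34025766"),
            chrom = c("chr1", "chr1", "chr4"),
            pos = c(1000, 2000, 17967188),
            beta = c(0.04, 0.01, log(0.98)),      # PD
            p = c(1e-6, thr, 2.9e-10)))
  testable <- resolve_testable(pooled, pair$id)
  res <- cross_test(testable, pair, thr)
  expect_equal(nrow(res), nrow(testable))

  # ADRD lead with strong concordant PD signal
  rsa <- res[res$variant == "rsA", ]
  expect_true(rsa$significant)
  expect_equal(rsa$direction, "concordant")

  # other-trait p exactly at the threshold is NOT significant
  expect_false(res$significant[res$variant == "rsEdge"])

  # a PD lead with OR 1.04 in ADRD and 0.98 in PD: significant, discordant
  disc <- res[res$variant == "rs34025766", ]
  expect_equal(disc$source_trait, "PD")
  expect_equal(disc$target_trait, "ADRD")
  expect_true(disc$significant)
  expect_equal(disc$direction, "discordant")
  expect_equal(disc$or_source, 0.98, tolerance = 1e-12)
  expect_equal(disc$or_target, 1.04, tolerance = 1e-12)
  # OR = exp(beta) consistency
  expect_equal(res$or_target, exp(res$beta_target), tolerance = 1e-12)

  # significance decisions are invariant to variant ordering
  res_perm <- cross_test(testable[c(3, 1, 2), ], pair, thr)
  res_perm <- res_perm[match(res$variant, res_perm$variant), ]
  expect_equal(res_perm$significant, res$significant)
})

test_that("a both-trait lead is tested in both directions but counted once", {
  leads_a <- lead_variant_set(
    tibble::tibble(id = "rsBoth", chrom = "chr1", pos = 1000), "T1")
  leads_b <- lead_variant_set(
    tibble::tibble(id = "rsBoth", chrom = "chr1", pos = 1000), "T2")
  pooled <- pool_leads(leads_a, leads_b)
  pair <- harmonize_pair(make_ss("rsBoth", pos = 1000, beta = 0.1, p = 1e-9),
                         make_ss("rsBoth", pos = 1000, beta = 0.1, p = 1e-9))
  testable <- resolve_testable(pooled, pair$id)
  expect_equal(attr(testable, "m"), 1)
  res <- cross_test(testable, pair, bonferroni_threshold(1))
  expect_equal(nrow(res), 2)
  expect_setequal(res$source_trait, c("T1", "T2"))
})

test_that("the gatekeeper keeps the family-wise error rate under alpha at the global null", {
  # analytic FWER is 1 - (1 - 0.05/m)^m, equal to 0.05 at m = 1 and strictly
  # below it for every larger m
  expect_equal(1 - (1 - bonferroni_threshold(1)), 0.05)
  for (m in c(14, 88, 162, 172)) {
    expect_lt(1 - (1 - bonferroni_threshold(m))^m, 0.05)
  }
  set.seed(404)
  frac <- simulate_null_fwer(88, n_reps = 500)
  expected <- 1 - (1 - 0.05 / 88)^88
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 500))
})
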