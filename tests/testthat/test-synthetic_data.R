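test_that("copula genotypes hit target MAF and Hardy-Weinberg marginals", {
  n <- 5000
  g <- simulate_genotypes(n, one_gene(1, 0, maf_range = c(0.3, 0.3)),
                          seed = 1, missing_rate = 0)
  q <- mean(g$dosage[, 1]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * n))
  expect_lt(abs(q - 0.3), 3 * se)

  # genotype category frequencies vs (1-q)^2, 2q(1-q), q^2 at large n
  n2 <- 50000
  g2 <- simulate_genotypes(n2, one_gene(1, 0, maf_range = c(0.2, 0.2)),
                           seed = 2, missing_rate = 0)
  frq <- tabulate(g2$dosage[, 1] + 1L, 3) / n2
  exp_frq <- c(0.8^2, 2 * 0.2 * 0.8, 0.2^2)
  for (k in 1:3) {
    se_k <- sqrt(exp_frq[k] * (1 - exp_frq[k]) / n2)
    expect_lt(abs(frq[k] - exp_frq[k]), 3 * se_k)
  }
})

test_that("rho = 0 gives near-independent markers and LD rises with rho", {
  n <- 2000
  g0 <- simulate_genotypes(n, one_gene(10, 0), seed = 3, missing_rate = 0)
  r2 <- ld_r2_mean <- function(geno) {
    m <- cor(geno$dosage)^2
    mean(m[upper.tri(m)])
  }
  expect_lte(ld_r2_mean(g0), 3 / n)

  means <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    ld_r2_mean(simulate_genotypes(1500, one_gene(8, rho), seed = 4,
                                  missing_rate = 0))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("simulators are deterministic in the seed", {
  a <- simulate_genotypes(50, one_gene(5, 0.5), seed = 9)
  b <- simulate_genotypes(50, one_gene(5, 0.5), seed = 9)
  expect_identical(a, b)

  s1 <- assign_sites_and_plates(100, seed = 5)
  s2 <- assign_sites_and_plates(100, seed = 5)
  expect_identical(s1, s2)

  h1 <- simulate_hrsd(s1, seed = 6)
  h2 <- simulate_hrsd(s2, seed = 6)
  expect_identical(h1, h2)
})

test_that("site and plate assignment uses deterministic rounding", {
  s <- assign_sites_and_plates(455, seed = 1)
  expect_equal(unname(table(s$site)[c("NHRI", "TVGH")]), c(268, 187),
               ignore_attr = TRUE)
  s2 <- assign_sites_and_plates(100, plate_size = 96, seed = 1)
  expect_equal(unname(table(s2$plate)), c(96, 4), ignore_attr = TRUE)
  expect_true(all(s$age >= 18 & s$age <= 80))
})

test_that("HRSD baselines respect the minimum-14 inclusion rule", {
  s <- assign_sites_and_plates(1000, seed = 7)
  h <- simulate_hrsd(s, seed = 8)
  bl <- h[h$timepoint == "bl", sprintf("item_%02d", 1:21)]
  expect_gte(min(rowSums(bl)), 14)
  expect_true(all(h$item_01 >= 0 & h$item_01 <= 4))
})

test_that("a fixed -60% improvement with zero noise makes every subject a responder", {
  s <- assign_sites_and_plates(200, seed = 10)
  h <- simulate_hrsd(s, seed = 11, improvement_mean = -0.6,
                     improvement_sd = 0, visit_sd = 0)
  ph <- derive_phenotypes(h)
  expect_true(all(ph$response_binary == 1))
})

test_that("genetic effects shift the week-8 percentage change per allele", {
  tc <- tiny_cohort(n = 3000, seed = 20, n_variants = 1, rho = 0)
  eff <- data.frame(variant_id = colnames(tc$geno$dosage)[1],
                    outcome = "response_pct", beta = 0.15)
  h <- simulate_hrsd(tc$samples, tc$geno, eff, seed = 21,
                     improvement_sd = 0.05)
  ph <- derive_phenotypes(h)
  d <- tc$geno$dosage[ph$subject_id, 1]
  slope <- coef(lm(ph$response_pct ~ d))[2]
  expect_lt(abs(slope - 0.15), 0.02)
})

test_that("effect tables referencing unknown variants or outcomes error", {
  tc <- tiny_cohort(n = 20, seed = 30, n_variants = 2)
  expect_error(simulate_hrsd(tc$samples, tc$geno,
                             data.frame(variant_id = "nope",
                                        outcome = "response_pct", beta = 1),
                             seed = 1),
               "unknown variants")
  expect_error(simulate_hrsd(tc$samples, tc$geno,
                             data.frame(variant_id = colnames(tc$geno$dosage)[1],
                                        outcome = "banana", beta = 1),
                             seed = 1),
               "unknown outcome")
})

test_that("missingness injection follows the pattern mixture and masks only", {
  s <- assign_sites_and_plates(20000, seed = 40)
  h <- simulate_hrsd(s, seed = 41)
  mix <- default_missingness_mix()
  hm <- inject_missingness(h, mix, seed = 42)

  items <- sprintf("item_%02d", 1:21)
  # all-or-none masking; baseline untouched
  miss <- rowSums(is.na(hm[, items]))
  expect_true(all(miss %in% c(0, 21)))
  expect_true(all(miss[hm$timepoint == "bl"] == 0))

  # observed cells are unaltered
  keep <- !is.na(hm$item_01)
  expect_identical(hm[keep, items], h[keep, items])

  # fully-observed fraction near 394/428
  pt <- adpgx:::panel_totals(hm)
  p_cc <- 394 / 428
  frac <- mean(rowSums(is.na(pt$totals)) == 0)
  expect_lt(abs(frac - p_cc), 3 * sqrt(p_cc * (1 - p_cc) / 20000))

  # week-2 masking probability = 14/428
  p_w2 <- sum(mix$prob[!mix$w2])
  expect_equal(p_w2, 14 / 428)
  f_w2 <- mean(is.na(pt$totals[, "w2"]))
  expect_lt(abs(f_w2 - p_w2), 3 * sqrt(p_w2 * (1 - p_w2) / 20000))

  # identity mixture is a no-op
  id_mix <- data.frame(bl = TRUE, w2 = TRUE, w4 = TRUE, w8 = TRUE,
                       prob = 1)
  expect_identical(inject_missingness(h, id_mix, seed = 1), h)

  bad <- data.frame(bl = FALSE, w2 = TRUE, w4 = TRUE, w8 = TRUE, prob = 1)
  expect_error(inject_missingness(h, bad, seed = 1), "baseline")
})

test_that("null cohorts give uniform single-marker p-values", {
  n <- 400
  samples <- assign_sites_and_plates(n, seed = 50)
  geno <- simulate_genotypes(n, one_gene(300, 0, maf_range = c(0.1, 0.5)),
                             seed = 51, missing_rate = 0,
                             sample_ids = samples$sample_id)
  h <- simulate_hrsd(samples, seed = 52)
  ph <- derive_phenotypes(h)
  sc <- assoc_scan(geno, ph, "response_pct", samples)
  expect_gt(stats::ks.test(sc$p, "punif")$p.value, 0.01)
})
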