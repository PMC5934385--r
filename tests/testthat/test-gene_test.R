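test_that("variants map to genes with inclusive 50 kb flank boundaries", {
  genes <- data.frame(name = "G", chrom = "1", start = 200000, end = 300000)
  variants <- data.frame(variant_id = c("a", "b", "c", "d"),
                         chrom = "1",
                         pos = c(150000, 149999, 250000, 350000))
  gs <- map_variants_to_genes(variants, genes)[[1]]
  expect_setequal(gs$variant_ids, c("a", "c", "d"))  # 350000 = end + 50000
  expect_false("b" %in% gs$variant_ids)              # start - 50001 excluded
  expect_error(map_variants_to_genes(variants,
                                     data.frame(name = "G", chrom = "1",
                                                start = 10, end = 5)),
               "malformed")
})

test_that("composite LD r2 behaves on constructed and simulated pairs", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 2, 0, 2), c(0, 0, 2, 2)), 0)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero dosage variance")

  # AR(1) copula at rho = 0.8: compare against an independent Monte-Carlo
  # oracle built from raw qnorm thresholding (not the package generator)
  q <- 0.3; rho <- 0.8
  set.seed(1)
  n_or <- 100000
  z1 <- rnorm(n_or); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_or)
  t1 <- qnorm((1 - q)^2); t2 <- qnorm((1 - q)^2 + 2 * q * (1 - q))
  d1 <- (z1 > t1) + (z1 > t2); d2 <- (z2 > t1) + (z2 > t2)
  oracle_r2 <- cor(d1, d2)^2

  g <- simulate_genotypes(5000, gene_model("G", "1", 1, 100,
                                           n_variants = 2, block_rho = rho,
                                           maf_range = c(q, q)),
                          seed = 2, missing_rate = 0)
  obs <- ld_r2(g$dosage[, 1], g$dosage[, 2])
  expect_lt(abs(obs - oracle_r2), 0.04)  # ~3 se at n = 5000
})

test_that("greedy selection and pruning follows the documented rule", {
  r2 <- matrix(c(1, .6, .1,
                 .6, 1, .1,
                 .1, .1, 1), 3, 3)
  kept <- select_and_prune(c(0.01, 0.02, 0.05), r2)
  expect_equal(kept, c(1, 3))
  expect_equal(select_and_prune(c(0.2, 0.5, 0.99), r2), integer(0))
  # a duplicate (r2 = 1 with a better-ranked marker) is never retained
  r2d <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(select_and_prune(c(0.01, 0.02), r2d), 1)
})

test_that("greedy pruning matches a brute-force oracle over 3-marker grids", {
  p_grid <- c(0.01, 0.05, 0.09, 0.2)
  r_grid <- c(0.1, 0.49, 0.51, 0.9)
  for (p1 in p_grid) for (p2 in p_grid) for (p3 in p_grid)
    for (r12 in r_grid) for (r13 in r_grid) for (r23 in r_grid) {
      r2 <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
      p <- c(p1, p2, p3)
      expect_identical(sort(select_and_prune(p, r2)),
                       sort(prune_oracle(p, r2)))
    }
})

test_that("the set statistic is the order-invariant mean of squared z", {
  expect_equal(set_statistic(2), 4)
  expect_equal(set_statistic(c(1, 3)), 5)
  expect_equal(set_statistic(c(3, 1)), 5)
  expect_error(set_statistic(numeric(0)), "empty")
})

test_that("proportion significant counts strict p < 0.05 over all markers", {
  p <- c(rep(0.01, 13), rep(0.5, 153))
  expect_equal(proportion_significant(p, 166), 13 / 166)
  expect_equal(proportion_significant(rep(0.5, 10)), 0)
  expect_equal(proportion_significant(rep(0.001, 4)), 1)
  expect_equal(proportion_significant(c(0.05, 0.1)), 0)  # strict
  expect_error(proportion_significant(numeric(0)), "empty")
})

test_that("the vectorised permutation engine matches a brute-force score test", {
  set.seed(3)
  n <- 60
  tc <- tiny_cohort(n = n, seed = 4, n_variants = 3, rho = 0.3)
  G <- tc$geno$dosage
  y <- rnorm(n)
  X <- cbind(1, tc$samples$age, as.numeric(tc$samples$sex == "F"))
  nf <- adpgx:::score_null_fit(y, X, "linear")
  B <- 50
  Q <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  z2 <- adpgx:::score_z2_block(G, X, nf, Q, "linear")
  # brute force: permute (y, X) jointly, refit from scratch per permutation
  for (b in c(1, 17, 50)) {
    q <- Q[, b]
    yq <- y[q]; Xq <- X[q, ]
    fit <- lm.fit(Xq, yq)
    rq <- fit$residuals
    s2 <- sum(rq^2) / (n - ncol(Xq))
    for (m in 1:3) {
      g <- G[, m]
      U <- sum(g * rq)
      a <- crossprod(Xq, g)
      V <- s2 * (sum(g^2) - drop(t(a) %*% solve(crossprod(Xq)) %*% a))
      expect_equal(unname(z2[m, b]), U^2 / V, tolerance = 1e-10)
    }
  }
})

test_that("joint permutation preserves the covariate-outcome association", {
  set.seed(5)
  n <- 80
  X <- cbind(1, rnorm(n, 40, 10), rbinom(n, 1, 0.6))
  y <- drop(X %*% c(1, 0.05, 0.5)) + rnorm(n)
  q <- sample.int(n)
  expect_equal(unname(lm.fit(X[q, ], y[q])$coefficients),
               unname(lm.fit(X, y)$coefficients))
})

test_that("single-variant empirical p matches the asymptotic score p", {
  tc <- tiny_cohort(n = 1000, seed = 6, n_variants = 1, rho = 0)
  set.seed(777)
  d <- tc$geno$dosage[, 1]
  ph <- data.frame(subject_id = tc$samples$sample_id,
                   response_pct = rnorm(1000, -0.46, 0.2) + 0.015 * d)
  gs <- map_variants_to_genes(tc$geno$variants, one_gene(1))[[1]]
  # selection threshold lifted so the single variant is always in the set
  r <- permutation_gene_p(gs, tc$geno, ph, "response_pct", tc$samples,
                          R = 5000, seed = 8, p_threshold = 1.01)
  asym <- unname(r$marker_p[1])
  # the +1 finite-sample correction biases the empirical p up by ~1/(R+1)
  expect_lt(abs(r$empirical_p - asym),
            3 * sqrt(asym * (1 - asym) / 5000) + 1 / 5001)
})

test_that("permutation results are seed-deterministic and seed-stable", {
  tc <- tiny_cohort(n = 150, seed = 9, n_variants = 8, rho = 0.5)
  set.seed(10)
  ph <- data.frame(subject_id = tc$samples$sample_id,
                   response_pct = rnorm(150, -0.46, 0.2))
  gs <- map_variants_to_genes(tc$geno$variants, one_gene(8))[[1]]
  r1 <- permutation_gene_p(gs, tc$geno, ph, "response_pct", tc$samples,
                           R = 2000, seed = 11)
  r2 <- permutation_gene_p(gs, tc$geno, ph, "response_pct", tc$samples,
                           R = 2000, seed = 11)
  expect_identical(r1$empirical_p, r2$empirical_p)
  if (!is.na(r1$empirical_p)) {
    r3 <- permutation_gene_p(gs, tc$geno, ph, "response_pct", tc$samples,
                             R = 2000, seed = 12)
    p <- r1$empirical_p
    expect_lt(abs(r3$empirical_p - p), 3 * sqrt(p * (1 - p) / 2000) + 1e-9)
    expect_gte(r1$empirical_p, 1 / 2001)
  }
  expect_lte(r1$n_selected, r1$n_total)
})

test_that("the pruned set is maximal under the greedy order", {
  tc <- tiny_cohort(n = 200, seed = 13, n_variants = 12, rho = 0.9)
  set.seed(14)
  ph <- data.frame(subject_id = tc$samples$sample_id,
                   response_pct = rnorm(200))
  gs <- map_variants_to_genes(tc$geno$variants, one_gene(12))[[1]]
  r <- permutation_gene_p(gs, tc$geno, ph, "response_pct", tc$samples,
                          R = 10, seed = 15, p_threshold = 1.01)
  G <- apply(tc$geno$dosage, 2, as.numeric)
  r2m <- cor(G)^2
  kept <- match(r$selected, colnames(G))
  rejected <- setdiff(seq_len(ncol(G)), kept)
  expect_gt(length(rejected), 0)
  for (j in rejected)
    expect_true(any(r2m[j, kept] >= 0.5))
})
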