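make_geno <- function(dosage, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("v%03d", seq_len(m))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  structure(list(dosage = dosage,
                 variants = data.frame(variant_id = colnames(dosage),
                                       chrom = "1",
                                       pos = pos %||% seq_len(m),
                                       gene = "G1",
                                       stringsAsFactors = FALSE)),
            class = "geno_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("plate pass rate is strict at the 0.97 boundary", {
  d <- matrix(0L, 20, 100)
  plates <- rep(c("A", "B"), each = 10)
  g <- make_geno(d)
  pr <- plate_pass_rate(g, setNames(plates, rownames(d)))
  expect_equal(unname(pr$rates), c(1, 1))
  expect_length(pr$flagged_samples, 0)

  d2 <- d
  d2[11:14, 1:10] <- NA  # 40 missing of plate B's 1000 calls -> 0.96
  pr2 <- plate_pass_rate(make_geno(d2), setNames(plates, rownames(d)))
  expect_equal(unname(pr2$rates["B"]), 0.96)
  expect_equal(pr2$failed_plates, "B")
  expect_length(pr2$flagged_samples, 10)

  d3 <- d
  d3[11:13, 1:10] <- NA  # exactly 0.97 -> removed (strictly greater than)
  pr3 <- plate_pass_rate(make_geno(d3), setNames(plates, rownames(d)))
  expect_equal(unname(pr3$rates["B"]), 0.97)
  expect_equal(pr3$failed_plates, "B")
})

test_that("inbreeding coefficient matches the direct formula", {
  # 3-marker toy, frequencies implied by the column means
  d <- rbind(c(1L, 1L, 1L),   # all-heterozygous sample
             c(0L, 0L, 0L),
             c(2L, 2L, 2L),
             c(1L, 0L, 2L))
  g <- make_geno(d)
  p <- colMeans(d) / 2
  exp_h <- sum(2 * p * (1 - p))
  f <- inbreeding_coefficient(g)
  expect_equal(unname(f[1]), 1 - 3 / exp_h)
  expect_equal(unname(f[2]), 1)          # fully homozygous
  expect_equal(unname(f[3]), 1)
  expect_equal(unname(f[4]), 1 - 1 / exp_h)

  # random mating: mean F near zero
  gg <- simulate_genotypes(2000, one_gene(50, 0), seed = 1, missing_rate = 0)
  fr <- inbreeding_coefficient(gg)
  expect_lt(abs(mean(fr)), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("IBS matrix matches enumeration and flags duplicates", {
  d <- rbind(c(0L, 0L, 0L), c(2L, 2L, 2L))
  ibs <- ibs_matrix(make_geno(d))
  expect_equal(ibs[1, 2], 0)
  expect_equal(diag(ibs), c(S0001 = 1, S0002 = 1))

  # duplicated sample: IBS 1 and one of the pair removed
  g <- simulate_genotypes(30, one_gene(100, 0, maf_range = c(0.3, 0.3)),
                          seed = 2, missing_rate = 0)
  g$dosage[2, ] <- g$dosage[1, ]
  ibs2 <- ibs_matrix(g)
  expect_equal(ibs2[1, 2], 1)
  rem <- kinship_flags(ibs2, g)
  expect_equal(rem, min(rownames(g$dosage)[1:2]))

  # unrelated pair vs brute-force Hardy-Weinberg expectation (9 cells)
  q <- 0.3
  pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  exp_ibs <- 0
  for (a in 0:2) for (b in 0:2)
    exp_ibs <- exp_ibs + pg[a + 1] * pg[b + 1] * (2 - abs(a - b)) / 2
  gg <- simulate_genotypes(2, one_gene(10000, 0, maf_range = c(q, q)),
                           seed = 3, missing_rate = 0)
  obs <- ibs_matrix(gg)[1, 2]
  # per-marker IBS variance, enumerated the same way
  e2 <- 0
  for (a in 0:2) for (b in 0:2)
    e2 <- e2 + pg[a + 1] * pg[b + 1] * ((2 - abs(a - b)) / 2)^2
  se <- sqrt((e2 - exp_ibs^2) / 10000)
  expect_lt(abs(obs - exp_ibs), 3 * se)
})

test_that("MDS flags a constructed outlier and no one in a homogeneous cohort", {
  g <- simulate_genotypes(60, one_gene(500, 0.3), seed = 4, missing_rate = 0)
  ibs <- ibs_matrix(g)
  expect_length(mds_outliers(ibs, 6)$outliers, 0)

  ibs2 <- ibs
  ibs2[1, -1] <- 0.5
  ibs2[-1, 1] <- 0.5
  out <- mds_outliers(ibs2, 6)$outliers
  expect_equal(out, rownames(ibs)[1])

  bad <- ibs; bad[1, 2] <- bad[1, 2] + 0.2
  expect_error(mds_outliers(bad), "symmetric")
})

test_that("classical MDS reconstructs planar configurations", {
  set.seed(5)
  xy <- matrix(rnorm(40), 20, 2)
  dm <- as.matrix(dist(xy))
  rec <- mds_outliers(1 - dm / max(dm) / 2, 6)$coords
  # recovered distances match the (scaled) originals up to rotation
  expect_lt(max(abs(as.matrix(dist(rec)) - dm / max(dm) / 2)), 1e-8)
})

test_that("exact HWE test matches the enumeration oracle", {
  expect_equal(hwe_exact(10, 0, 0), 1)           # monomorphic
  expect_equal(hwe_exact(0, 4, 0), hwe_oracle(0, 4, 0))
  expect_equal(hwe_oracle(0, 4, 0), 0.3142857, tolerance = 1e-6)

  set.seed(6)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    aa <- sample(0:n, 1); ab <- sample(0:(n - aa), 1); bb <- n - aa - ab
    expect_equal(hwe_exact(aa, ab, bb), hwe_oracle(aa, ab, bb),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact(-1, 2, 3), "non-negative")
})

test_that("HWE conditional probabilities sum to one", {
  # reconstruct the full conditional distribution from point evaluations
  for (n in c(5, 17, 30)) for (nm in c(1, 4, 9, 2 * n %/% 2)) {
    hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
    pr <- vapply(hets, function(h) {
      haa <- (nm - h) / 2
      exp(lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) -
            lgamma(n - h - haa + 1) + h * log(2) +
            lgamma(nm + 1) + lgamma(2 * n - nm + 1) - lgamma(2 * n + 1))
    }, numeric(1))
    expect_equal(sum(pr), 1, tolerance = 1e-9)
  }
})

test_that("marker QC applies HWE, missingness and MAF rules in order", {
  set.seed(7)
  n <- 200
  good <- rbinom(n, 2, 0.3)
  d <- cbind(good,
             miss6 = replace(good, 1:12, NA),          # 6% missing
             rare = rbinom(n, 2, 0.01),                # MAF < 0.05
             hwe_bad = rep(1L, n))                     # all-het: HWE fails
  d <- matrix(as.integer(d), n, 4,
              dimnames = list(sprintf("S%04d", 1:n),
                              c("good", "miss6", "rare", "hwe_bad")))
  g <- make_geno(d)
  mq <- marker_qc(g)
  expect_equal(colnames(mq$genotypes$dosage), "good")
  expect_equal(mq$removed$reason[mq$removed$variant_id == "miss6"],
               "missingness")
  expect_equal(mq$removed$reason[mq$removed$variant_id == "rare"], "maf")
  expect_equal(mq$removed$reason[mq$removed$variant_id == "hwe_bad"], "hwe")

  # MAF exactly 0.05 is retained (strict "smaller than")
  d2 <- matrix(c(rep(1L, 10), rep(0L, 90)), 100, 1,
               dimnames = list(sprintf("S%04d", 1:100), "maf05"))
  mq2 <- marker_qc(make_geno(d2))
  expect_equal(colnames(mq2$genotypes$dosage), "maf05")

  # idempotence
  mq3 <- marker_qc(mq$genotypes)
  expect_equal(nrow(mq3$removed), 0)
})

test_that("null Hardy-Weinberg markers are essentially never removed by the HWE rule", {
  g <- simulate_genotypes(400, one_gene(1000, 0, maf_range = c(0.1, 0.5)),
                          seed = 8, missing_rate = 0)
  mq <- marker_qc(g)
  n_hwe <- sum(mq$removed$reason == "hwe")
  expect_lte(n_hwe, 2)  # exact test at 1e-4 is conservative
})

test_that("sample QC composes the three rules with one reason each", {
  tc <- tiny_cohort(n = 60, seed = 9, n_variants = 120)
  g <- tc$geno
  g$dosage[2, ] <- g$dosage[1, ]         # duplicate pair
  g$dosage[5, 1:110] <- NA               # wreck plate of sample 5? plates are size 96
  sq <- sample_qc(g, tc$samples)
  expect_true(all(table(sq$removed$sample_id) == 1))
  expect_true(any(sq$removed$reason == "kinship"))
  expect_true(all(c("plate_rates", "inbreeding_f", "mds_coords") %in%
                    names(sq$report)))
})
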