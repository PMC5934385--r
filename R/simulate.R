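#' Simulate LD-block genotypes with a Gaussian copula
#'
#' For each gene a latent multivariate-normal vector with AR(1) correlation
#' `block_rho` is drawn per sample and each coordinate is thresholded at the
#' Hardy-Weinberg genotype-probability quantiles for that marker's target
#' minor allele frequency. Marginals are therefore exactly Hardy-Weinberg at
#' the target frequency while adjacent markers are correlated, giving direct
#' control over both MAF and LD without haplotype pools. Variant positions are
#' evenly spaced over the gene span.
#'
#' @param n_samples number of diploid samples (>= 2).
#' @param genes gene models, as from [default_gene_models()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param missing_rate per-call probability of a missing genotype
#'   (default 0.001, i.e. a 99.9% call rate).
#' @param sample_ids optional character vector of sample ids.
#' @return a `geno_matrix`: list with `dosage` (samples x variants integer
#'   matrix of minor-allele counts, `NA` for missing) and `variants`
#'   (`data.frame`: variant_id, chrom, pos, gene, target_maf).
#' @export
simulate_genotypes <- function(n_samples, genes, seed, missing_rate = 0.001,
                               sample_ids = NULL) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (any(genes$block_rho < 0 | genes$block_rho >= 1))
    stop("block_rho must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))

  blocks <- vector("list", nrow(genes))
  vinfo <- vector("list", nrow(genes))
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    m <- g$n_variants
    rho <- g$block_rho
    sigma <- rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
    z <- matrix(rnorm(n_samples * m), n_samples, m)
    if (m > 1L && rho > 0) z <- z %*% chol(sigma)
    q <- runif(m, g$maf_lo, g$maf_hi)
    t1 <- qnorm((1 - q)^2)
    t2 <- qnorm((1 - q)^2 + 2 * q * (1 - q))
    dos <- matrix(0L, n_samples, m)
    for (j in seq_len(m))
      dos[, j] <- (z[, j] > t1[j]) + (z[, j] > t2[j])
    pos <- if (m == 1L) as.integer(round((g$start + g$end) / 2)) else
      as.integer(round(seq(g$start, g$end, length.out = m)))
    blocks[[k]] <- dos
    vinfo[[k]] <- data.frame(
      variant_id = sprintf("%s_%03d", g$name, seq_len(m)),
      chrom = g$chrom, pos = pos, gene = g$name, target_maf = q,
      stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, blocks)
  variants <- do.call(rbind, vinfo)
  if (missing_rate > 0) {
    miss <- matrix(runif(length(dosage)) < missing_rate,
                   nrow(dosage), ncol(dosage))
    dosage[miss] <- NA_integer_
  }
  dimnames(dosage) <- list(sample_ids, variants$variant_id)
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants (%d genes)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$gene))))
  invisible(x)
}

#' Assign site, plate, sex and age to a simulated cohort
#'
#' Sites are filled by deterministic rounding of the target fractions
#' (largest-remainder rule), plates by consecutive fill, sex by a Bernoulli
#' draw and age from a truncated normal. Defaults emulate a two-site clinical
#' cohort with a 268:187 site split, 71.3% females and mean age 43.7 years.
#'
#' @param n_samples cohort size.
#' @param site_fractions named numeric summing to 1.
#' @param plate_size samples per genotyping plate.
#' @param seed integer seed.
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param female_frac probability of female sex.
#' @return `data.frame`: sample_id, site, plate, sex ("F"/"M"), age.
#' @export
assign_sites_and_plates <- function(n_samples,
                                    site_fractions = c(NHRI = 268 / 455,
                                                       TVGH = 187 / 455),
                                    plate_size = 96L, seed = 1L,
                                    age_mean = 43.7, age_sd = 12,
                                    age_range = c(18, 80),
                                    female_frac = 0.713) {
  if (abs(sum(site_fractions) - 1) > 1e-9)
    stop("site_fractions must sum to 1", call. = FALSE)
  if (plate_size < 1) stop("plate_size must be >= 1", call. = FALSE)
  set.seed(seed)
  raw <- n_samples * site_fractions
  cnt <- floor(raw)
  rem <- n_samples - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  site <- rep(names(site_fractions), cnt)
  plate <- sprintf("P%02d", (seq_len(n_samples) - 1L) %/% plate_size + 1L)
  sex <- ifelse(runif(n_samples) < female_frac, "F", "M")
  lo <- pnorm(age_range[1], age_mean, age_sd)
  hi <- pnorm(age_range[2], age_mean, age_sd)
  age <- round(qnorm(runif(n_samples, lo, hi), age_mean, age_sd), 1)
  data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
             site = site, plate = plate, sex = sex, age = age,
             stringsAsFactors = FALSE)
}

hrsd_outcomes <- c("remitted", "response_binary", "response_pct",
                   "stem_depressed")

# Deterministically spread the part of a total not carried by item 1 over the
# remaining 20 items (each capped well below its maximum at realistic totals).
spread_items <- function(total, item1) {
  rem <- total - item1
  base <- rem %/% 20L
  extra <- rem %% 20L
  base + as.integer(seq_len(20L) <= extra)
}

#' Simulate longitudinal 21-item HRSD panels
#'
#' Each subject receives a baseline severity (total score, truncated normal,
#' minimum 14 per the usual moderate-depression inclusion rule) and a
#' subject-level linear improvement trajectory whose week-8 percentage change
#' is `improvement_mean` plus per-allele genetic effects plus Gaussian
#' subject noise; intermediate visits interpolate linearly with visit-level
#' noise. Item 1 (depressed mood, 0-4) is a monotone bin of the concurrent
#' total so the stem-depressed outcome is derivable; the remaining items
#' spread the residual total deterministically.
#'
#' @param samples sample table from [assign_sites_and_plates()].
#' @param genotypes optional `geno_matrix` supplying dosages for effects.
#' @param effects optional `data.frame(variant_id, outcome, beta)`; betas act
#'   on the week-8 percentage-change linear predictor (all four response
#'   outcomes derive from the same latent trajectory). `case_status` effects
#'   belong to [simulate_case_control()] and are rejected here.
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd baseline total model (truncated to
#'   `[14, 66]`).
#' @param improvement_mean,improvement_sd week-8 percentage change (signed
#'   fraction); defaults -0.46 (s.d. 0.20), typical of 8-week SSRI trials.
#' @param visit_sd integer-rounded Gaussian noise on intermediate totals.
#' @return an `hrsd_panel` `data.frame`: subject_id, timepoint
#'   (`bl`,`w2`,`w4`,`w8`), item_01..item_21.
#' @export
simulate_hrsd <- function(samples, genotypes = NULL, effects = NULL, seed = 1L,
                          baseline_mean = 22, baseline_sd = 5,
                          improvement_mean = -0.46, improvement_sd = 0.20,
                          visit_sd = 2) {
  stopifnot(all(c("sample_id", "age", "sex") %in% names(samples)))
  set.seed(seed)
  n <- nrow(samples)

  gshift <- rep(0, n)
  if (!is.null(effects) && nrow(effects)) {
    if (any(!effects$outcome %in% hrsd_outcomes))
      stop("unknown outcome name in effects: ",
           paste(setdiff(effects$outcome, hrsd_outcomes), collapse = ", "),
           call. = FALSE)
    if (is.null(genotypes))
      stop("effects supplied without genotypes", call. = FALSE)
    missing_v <- setdiff(effects$variant_id, colnames(genotypes$dosage))
    if (length(missing_v))
      stop("effects reference unknown variants: ",
           paste(missing_v, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(effects))) {
      d <- genotypes$dosage[samples$sample_id, effects$variant_id[i]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      gshift <- gshift + effects$beta[i] * d
    }
  }

  lo <- pnorm(14, baseline_mean, baseline_sd)
  hi <- pnorm(66, baseline_mean, baseline_sd)
  baseline <- pmax(14L, as.integer(round(
    qnorm(runif(n, lo, hi), baseline_mean, baseline_sd))))
  d8 <- improvement_mean + gshift +
    if (improvement_sd > 0) rnorm(n, 0, improvement_sd) else 0

  totals <- matrix(0L, n, 4, dimnames = list(samples$sample_id,
                                             c("bl", "w2", "w4", "w8")))
  totals[, "bl"] <- baseline
  fr <- c(w2 = 2 / 8, w4 = 4 / 8, w8 = 1)
  for (tp in names(fr)) {
    mu <- baseline * (1 + d8 * fr[[tp]])
    noise <- if (tp != "w8" && visit_sd > 0) rnorm(n, 0, visit_sd) else 0
    totals[, tp] <- pmin(66L, pmax(0L, as.integer(round(mu + noise))))
  }

  rows <- vector("list", 4)
  for (j in seq_along(colnames(totals))) {
    tp <- colnames(totals)[j]
    it1 <- item1_from_total(totals[, tp])
    items <- t(vapply(seq_len(n),
                      function(i) c(it1[i], spread_items(totals[i, tp], it1[i])),
                      integer(21)))
    colnames(items) <- sprintf("item_%02d", 1:21)
    rows[[j]] <- data.frame(subject_id = samples$sample_id, timepoint = tp,
                            items, stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(match(panel$subject_id, samples$sample_id),
                       match(panel$timepoint, c("bl", "w2", "w4", "w8"))), ]
  rownames(panel) <- NULL
  class(panel) <- c("hrsd_panel", "data.frame")
  panel
}

#' Default missing-data pattern mixture
#'
#' The eight observed/missing patterns over (baseline, week 2, week 4,
#' week 8) used by the generator, with mixture counts 394, 10, 10, 10, 1, 2,
#' 0, 1 out of 428 — the pattern mixture of the two-site SSRI cohort the
#' pipeline emulates. Baseline is always observed.
#'
#' @return `data.frame`: bl, w2, w4, w8 (logical, TRUE = observed), count,
#'   prob.
#' @export
default_missingness_mix <- function() {
  pat <- rbind(
    c(TRUE, TRUE,  TRUE,  TRUE),
    c(TRUE, FALSE, TRUE,  TRUE),
    c(TRUE, TRUE,  FALSE, TRUE),
    c(TRUE, TRUE,  TRUE,  FALSE),
    c(TRUE, FALSE, FALSE, TRUE),
    c(TRUE, FALSE, TRUE,  FALSE),
    c(TRUE, TRUE,  FALSE, FALSE),
    c(TRUE, FALSE, FALSE, FALSE))
  counts <- c(394, 10, 10, 10, 1, 2, 0, 1)
  data.frame(bl = pat[, 1], w2 = pat[, 2], w4 = pat[, 3], w8 = pat[, 4],
             count = counts, prob = counts / sum(counts))
}

#' Missing-data bookkeeping for a pattern mixture
#'
#' Per-timepoint missing-observation counts and the complete-case fraction
#' implied by a pattern mixture (or by observed pattern counts).
#'
#' @param mix pattern mixture as from [default_missingness_mix()]; must carry
#'   either `count` or `prob` plus `n_total`.
#' @param n_total cohort size; defaults to `sum(mix$count)`.
#' @return list: `n_total`, `missing_counts` (named w2/w4/w8),
#'   `missing_pct`, `complete_case_count`, `complete_case_pct`.
#' @export
missingness_bookkeeping <- function(mix = default_missingness_mix(),
                                    n_total = NULL) {
  if (is.null(mix$count)) {
    if (is.null(n_total)) stop("n_total required when mix has no counts",
                               call. = FALSE)
    mix$count <- mix$prob * n_total
  }
  n_total <- n_total %||% sum(mix$count)
  mc <- vapply(c("w2", "w4", "w8"),
               function(tp) sum(mix$count[!mix[[tp]]]), numeric(1))
  cc <- sum(mix$count[mix$w2 & mix$w4 & mix$w8])
  list(n_total = n_total, missing_counts = mc,
       missing_pct = 100 * mc / n_total,
       complete_case_count = cc,
       complete_case_pct = 100 * cc / n_total)
}

#' Inject a missing-data pattern mixture into an HRSD panel
#'
#' Each subject is assigned one pattern by a multinomial draw; at masked
#' timepoints all 21 items are set missing (the all-or-none convention:
#' a visit is missing if and only if every item is). Baseline is never
#' masked; observed values are never altered.
#'
#' @param panel an `hrsd_panel`.
#' @param mix pattern mixture (`prob` must sum to 1 within 1e-9; every
#'   pattern must observe baseline).
#' @param seed integer seed.
#' @return the panel with masked cells set to `NA`.
#' @export
inject_missingness <- function(panel, mix = default_missingness_mix(),
                               seed = 1L) {
  if (abs(sum(mix$prob) - 1) > 1e-9)
    stop("pattern probabilities must sum to 1", call. = FALSE)
  if (!all(mix$bl))
    stop("patterns masking baseline are not allowed", call. = FALSE)
  set.seed(seed)
  subjects <- unique(panel$subject_id)
  pat_id <- sample.int(nrow(mix), length(subjects), replace = TRUE,
                       prob = mix$prob)
  names(pat_id) <- subjects
  item_cols <- sprintf("item_%02d", 1:21)
  for (tp in c("w2", "w4", "w8")) {
    masked_subj <- subjects[!mix[[tp]][pat_id]]
    idx <- panel$timepoint == tp & panel$subject_id %in% masked_subj
    panel[idx, item_cols] <- NA_integer_
  }
  panel
}

#' Simulate a genotyped case-control panel
#'
#' Draws a population pool of genotypes, assigns disease status by a logistic
#' model with per-allele `case_status` effects, and returns the first
#' `n_cases` cases and `n_controls` controls. With no effects, cases and
#' controls are exchangeable draws from one population.
#'
#' @param n_cases,n_controls target counts.
#' @param genes gene models.
#' @param effects optional `data.frame(variant_id, outcome = "case_status",
#'   beta)` of log-odds per minor allele.
#' @param seed integer seed.
#' @param base_rate baseline case probability of the logistic model.
#' @return list with `geno_matrix` `genotypes` and a `samples` table carrying
#'   `status` (1 = case).
#' @export
simulate_case_control <- function(n_cases, n_controls, genes, effects = NULL,
                                  seed = 1L, base_rate = 0.3) {
  n_pool <- ceiling(3 * (n_cases + n_controls) / min(base_rate, 1 - base_rate) / 3)
  geno <- simulate_genotypes(n_pool, genes, seed = substream_seed(seed, 1))
  set.seed(substream_seed(seed, 2))
  eta <- rep(log(base_rate / (1 - base_rate)), n_pool)
  if (!is.null(effects) && nrow(effects)) {
    if (any(effects$outcome != "case_status"))
      stop("simulate_case_control only accepts case_status effects",
           call. = FALSE)
    miss <- setdiff(effects$variant_id, colnames(geno$dosage))
    if (length(miss)) stop("effects reference unknown variants: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(effects))) {
      d <- geno$dosage[, effects$variant_id[i]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      eta <- eta + effects$beta[i] * d
    }
  }
  status <- rbinom(n_pool, 1, 1 / (1 + exp(-eta)))
  keep <- c(head(which(status == 1), n_cases),
            head(which(status == 0), n_controls))
  if (length(keep) < n_cases + n_controls)
    stop("population pool too small for requested case/control counts",
         call. = FALSE)
  samples <- data.frame(sample_id = rownames(geno$dosage)[keep],
                        status = status[keep], stringsAsFactors = FALSE)
  geno$dosage <- geno$dosage[keep, , drop = FALSE]
  list(genotypes = geno, samples = samples)
}

#' Simulate a complete two-site treatment-response cohort
#'
#' Convenience wrapper tying the generators together: site/plate/sex/age
#' assignment, copula genotypes over the candidate genes, HRSD trajectories
#' with optional genetic effects, and the default missing-data pattern
#' mixture. One master seed drives per-stage substreams.
#'
#' @param n_samples cohort size (default 455, a 268:187 two-site split).
#' @param genes gene models (default [default_gene_models()]).
#' @param effects optional effect table for [simulate_hrsd()].
#' @param seed master integer seed.
#' @param mix missing-data pattern mixture.
#' @param ... further arguments to [simulate_hrsd()].
#' @return list: `samples`, `genotypes`, `hrsd` (with injected missingness).
#' @export
simulate_cohort <- function(n_samples = 455L, genes = default_gene_models(),
                            effects = NULL, seed = 1L,
                            mix = default_missingness_mix(), ...) {
  samples <- assign_sites_and_plates(n_samples, seed = substream_seed(seed, 11))
  geno <- simulate_genotypes(n_samples, genes, seed = substream_seed(seed, 12),
                             sample_ids = samples$sample_id)
  hrsd <- simulate_hrsd(samples, geno, effects,
                        seed = substream_seed(seed, 13), ...)
  hrsd <- inject_missingness(hrsd, mix, seed = substream_seed(seed, 14))
  list(samples = samples, genotypes = geno, hrsd = hrsd)
}
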