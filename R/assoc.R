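outcome_family <- function(outcome) {
  switch(outcome,
         remitted = , response_binary = , stem_depressed = ,
         case_status = "logistic",
         response_pct = "linear",
         stop("unknown outcome name: ", outcome, call. = FALSE))
}

# Design matrix for sex+age adjustment; errors on constant covariates so a
# degenerate design never proceeds silently.
covariate_matrix <- function(covariates) {
  sexf <- as.numeric(covariates$sex == "F")
  age <- as.numeric(covariates$age)
  for (nm in c("sexf", "age")) {
    v <- get(nm)
    if (length(unique(v[!is.na(v)])) < 2)
      stop("covariate '", sub("f$", "", nm),
           "' is constant; refusing to fit a degenerate adjustment",
           call. = FALSE)
  }
  cbind(intercept = 1, age = age, sexF = sexf)
}

#' Additive single-marker association fit
#'
#' Regresses the outcome on minor-allele dosage (0/1/2) with sex and age as
#' covariates: ordinary least squares for continuous outcomes, maximum
#' likelihood logistic regression for binary ones (favourable 0/1 coding, so
#' effect signs refer to the favourable outcome). The test is the 1-df Wald
#' test on the dosage coefficient. Samples with missing dosage or outcome are
#' dropped pairwise. Monomorphic markers and perfect separation are flagged
#' rather than fitted.
#'
#' @param dosage numeric dosage vector (NA allowed).
#' @param outcome numeric outcome vector (0/1 for logistic).
#' @param covariates `data.frame` with `age` and `sex` aligned to `dosage`.
#' @param family `"linear"` or `"logistic"`.
#' @param variant_id,outcome_name,site labels carried into the result.
#' @return one-row `data.frame`: variant_id, outcome, site, n, maf, effect,
#'   se, statistic, p, status ("ok", "monomorphic", "separation").
#' @export
fit_additive <- function(dosage, outcome, covariates,
                         family = c("linear", "logistic"),
                         variant_id = NA_character_,
                         outcome_name = NA_character_, site = "pooled") {
  family <- match.arg(family)
  keep <- !is.na(dosage) & !is.na(outcome)
  d <- as.numeric(dosage[keep])
  y <- as.numeric(outcome[keep])
  X <- covariate_matrix(covariates[keep, , drop = FALSE])
  res <- data.frame(variant_id = variant_id, outcome = outcome_name,
                    site = site, n = length(d), maf = dosage_maf(d),
                    effect = NA_real_, se = NA_real_, statistic = NA_real_,
                    p = NA_real_, status = "ok", stringsAsFactors = FALSE)
  if (length(unique(d)) < 2) {
    res$status <- "monomorphic"
    return(res)
  }
  if (family == "linear") {
    fit <- lm(y ~ d + X - 1)
    sm <- summary(fit)$coefficients
  } else {
    if (length(unique(y)) < 2) {
      res$status <- "monomorphic"   # constant outcome: nothing estimable
      return(res)
    }
    fit <- suppressWarnings(glm(y ~ d + X - 1, family = binomial()))
    sm <- summary(fit)$coefficients
    if (!fit$converged || abs(sm["d", "Estimate"]) > 15 ||
        sm["d", "Std. Error"] > 100) {
      res$status <- "separation"
      res$effect <- sm["d", "Estimate"]
      return(res)
    }
  }
  res$effect <- sm["d", "Estimate"]
  res$se <- sm["d", "Std. Error"]
  res$statistic <- sm["d", 3]
  res$p <- sm["d", 4]
  res
}

#' Single-marker association scan
#'
#' One additive fit per retained marker for the requested outcome,
#' optionally restricted to one site. Binary outcomes use logistic
#' regression, the continuous percentage change linear regression; all
#' models adjust for sex and age. Results are ordered by (chrom, pos).
#'
#' @param genotypes a QC'd `geno_matrix`.
#' @param phenotypes output of [derive_phenotypes()] (or a pooled equivalent).
#' @param outcome one of `"remitted"`, `"response_binary"`, `"response_pct"`,
#'   `"stem_depressed"`.
#' @param samples sample table with `sample_id`, `site`, `sex`, `age`.
#' @param site optional site label to restrict to (default all samples,
#'   labelled "pooled").
#' @return `data.frame` of per-marker results (see [fit_additive()]).
#' @export
assoc_scan <- function(genotypes, phenotypes, outcome, samples, site = NULL) {
  fam <- outcome_family(outcome)
  ids <- intersect(rownames(genotypes$dosage), phenotypes$subject_id)
  if (!is.null(site)) {
    ids <- intersect(ids, samples$sample_id[samples$site == site])
  }
  if (!length(ids)) stop("no samples left after site restriction", call. = FALSE)
  d <- genotypes$dosage[ids, , drop = FALSE]
  y <- phenotypes[[outcome]][match(ids, phenotypes$subject_id)]
  cov <- samples[match(ids, samples$sample_id), c("age", "sex")]
  ord <- order(genotypes$variants$chrom, genotypes$variants$pos)
  out <- lapply(ord, function(j)
    fit_additive(d[, j], y, cov, fam,
                 variant_id = genotypes$variants$variant_id[j],
                 outcome_name = outcome,
                 site = site %||% "pooled"))
  res <- do.call(rbind, out)
  res <- cbind(res,
               genotypes$variants[ord, c("chrom", "pos", "gene"), drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Case-control association scan
#'
#' Logistic regression of case status on dosage across the harmonised
#' variant set of a case panel and a control panel, with covariates when
#' available for every sample. Variants present in both panels must agree in
#' identity; a flipped or mismatched allele coding (detected as incompatible
#' variant metadata) is an explicit harmonisation error.
#'
#' @param case_geno,control_geno `geno_matrix` objects sharing variant ids.
#' @param covariates optional `data.frame` with `sample_id`, `age`, `sex`
#'   covering all samples; omitted from the model when absent.
#' @return `data.frame` of per-marker results, outcome `"case_status"`.
#' @export
case_control_scan <- function(case_geno, control_geno, covariates = NULL) {
  shared <- intersect(colnames(case_geno$dosage),
                      colnames(control_geno$dosage))
  if (!length(shared)) stop("no shared variants to harmonise", call. = FALSE)
  va <- case_geno$variants[match(shared, case_geno$variants$variant_id), ]
  vb <- control_geno$variants[match(shared, control_geno$variants$variant_id), ]
  if (!identical(va$chrom, vb$chrom) || !identical(va$pos, vb$pos))
    stop("allele-coding/position mismatch between case and control panels",
         call. = FALSE)
  if (!is.null(va$counted_allele) && !is.null(vb$counted_allele) &&
      any(va$counted_allele != vb$counted_allele))
    stop("allele-coding mismatch between case and control panels",
         call. = FALSE)
  d <- rbind(case_geno$dosage[, shared, drop = FALSE],
             control_geno$dosage[, shared, drop = FALSE])
  status <- c(rep(1L, nrow(case_geno$dosage)),
              rep(0L, nrow(control_geno$dosage)))
  ids <- rownames(d)
  ord <- order(va$chrom, va$pos)
  use_cov <- !is.null(covariates) && all(ids %in% covariates$sample_id)
  out <- lapply(ord, function(j) {
    dos <- d[, j]
    keep <- !is.na(dos)
    res <- data.frame(variant_id = shared[j], outcome = "case_status",
                      site = "case_control", n = sum(keep),
                      maf = dosage_maf(dos), effect = NA_real_,
                      se = NA_real_, statistic = NA_real_, p = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    if (length(unique(dos[keep])) < 2) {
      res$status <- "monomorphic"
      return(res)
    }
    if (use_cov) {
      cov <- covariates[match(ids, covariates$sample_id), c("age", "sex")]
      return(fit_additive(dos, status, cov, "logistic",
                          variant_id = shared[j],
                          outcome_name = "case_status",
                          site = "case_control"))
    }
    fit <- suppressWarnings(glm(status[keep] ~ dos[keep],
                                family = binomial()))
    sm <- summary(fit)$coefficients
    res$effect <- sm[2, 1]; res$se <- sm[2, 2]
    res$statistic <- sm[2, 3]; res$p <- sm[2, 4]
    res
  })
  res <- do.call(rbind, out)
  res <- cbind(res, va[ord, c("chrom", "pos", "gene"), drop = FALSE])
  rownames(res) <- NULL
  res
}
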