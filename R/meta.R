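#' Fisher / inverse-Gamma combination of p-values
#'
#' Combines k independent p-values with the inverse-Gamma model: each p maps
#' to the upper-tail quantile of a Gamma(alpha, 1) law and the sum is
#' referred to Gamma(k alpha, 1). With shape `alpha = 1` this is exactly
#' Fisher's method: `X = -2 sum(log p)` referred to a chi-square with 2k
#' degrees of freedom (for k = 2 the tail equals `exp(-X/2) (1 + X/2)`).
#' The combination is direction-blind; report effect-direction concordance
#' separately.
#'
#' @param p_values numeric vector of p-values in (0, 1], k >= 1.
#' @param alpha Gamma shape parameter (default 1 = Fisher).
#' @return list: `X` (combined statistic, on the chi-square scale for
#'   `alpha = 1`, otherwise the Gamma sum), `p` (meta p-value), `k`, `alpha`.
#' @export
fisher_combine <- function(p_values, alpha = 1) {
  p_values <- as.numeric(p_values)
  if (!length(p_values)) stop("at least one p-value required", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  k <- length(p_values)
  if (alpha == 1) {
    X <- -2 * sum(log(p_values))
    p <- pchisq(X, df = 2 * k, lower.tail = FALSE)
  } else {
    g <- qgamma(p_values, shape = alpha, rate = 1, lower.tail = FALSE)
    X <- sum(g)
    p <- pgamma(X, shape = k * alpha, rate = 1, lower.tail = FALSE)
  }
  list(X = X, p = p, k = k, alpha = alpha)
}

#' @importFrom stats qgamma
NULL

#' Pooled (mega) single-marker scan
#'
#' A single regression per marker on the concatenated two-site sample,
#' adjusted for sex and age. A site indicator covariate is off by default
#' and switchable.
#'
#' @inheritParams assoc_scan
#' @param include_site_covariate add a site indicator to the adjustment.
#' @return `data.frame` of per-marker results, site label `"mega"`.
#' @export
mega_scan <- function(genotypes, phenotypes, outcome, samples,
                      include_site_covariate = FALSE) {
  ids <- intersect(rownames(genotypes$dosage), phenotypes$subject_id)
  if (anyNA(samples$site[match(ids, samples$sample_id)]))
    stop("site label missing for some samples", call. = FALSE)
  if (!include_site_covariate) {
    res <- assoc_scan(genotypes, phenotypes, outcome, samples)
    res$site <- "mega"
    return(res)
  }
  fam <- outcome_family(outcome)
  d <- genotypes$dosage[ids, , drop = FALSE]
  y <- phenotypes[[outcome]][match(ids, phenotypes$subject_id)]
  sm <- samples[match(ids, samples$sample_id), ]
  site_num <- as.numeric(factor(sm$site))
  ord <- order(genotypes$variants$chrom, genotypes$variants$pos)
  out <- lapply(ord, function(j) {
    keep <- !is.na(d[, j]) & !is.na(y)
    res <- data.frame(variant_id = genotypes$variants$variant_id[j],
                      outcome = outcome, site = "mega", n = sum(keep),
                      maf = dosage_maf(d[keep, j]), effect = NA_real_,
                      se = NA_real_, statistic = NA_real_, p = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    if (length(unique(d[keep, j])) < 2) { res$status <- "monomorphic"; return(res) }
    X <- cbind(covariate_matrix(sm[keep, ]), site = site_num[keep])
    if (length(unique(site_num[keep])) < 2) X <- X[, colnames(X) != "site"]
    dat <- list(y = y[keep], dd = d[keep, j], X = X)
    fit <- if (fam == "linear") lm(y ~ dd + X - 1, data = dat)
    else suppressWarnings(glm(y ~ dd + X - 1, data = dat, family = binomial()))
    smc <- summary(fit)$coefficients
    res$effect <- smc["dd", 1]; res$se <- smc["dd", 2]
    res$statistic <- smc["dd", 3]; res$p <- smc["dd", 4]
    res
  })
  res <- do.call(rbind, out)
  res <- cbind(res, genotypes$variants[ord, c("chrom", "pos", "gene"),
                                       drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Effective number of independent tests
#'
#' Position-ordered greedy LD pruning: a marker becomes a new tag when its
#' r-squared with every existing tag is below `r2_block`. The effective test
#' count Meff is the number of tags and the LD-adjusted significance
#' threshold is `0.05 / Meff`.
#'
#' @param genotypes a QC'd `geno_matrix`.
#' @param r2_block tagging threshold (default 0.8).
#' @return list: `meff`, `threshold`, `tags` (variant ids).
#' @export
effective_tests <- function(genotypes, r2_block = 0.8) {
  d <- genotypes$dosage
  if (!ncol(d)) stop("empty marker set", call. = FALSE)
  G <- apply(d, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  ord <- order(genotypes$variants$chrom, genotypes$variants$pos)
  r2 <- ld_r2_matrix(G)
  tags <- integer(0)
  for (j in ord) {
    if (var(G[, j]) == 0) next
    if (!length(tags) || all(r2[j, tags] < r2_block)) tags <- c(tags, j)
  }
  list(meff = length(tags), threshold = 0.05 / length(tags),
       tags = colnames(d)[tags])
}

#' Two-site meta-analysis table
#'
#' Joins per-site association results by unit id, combines the per-site
#' p-values with [fisher_combine()], and records effect-direction
#' concordance across sites (the combination itself is direction-blind).
#'
#' @param site_results named list of per-site result `data.frame`s, each with
#'   an id column, `p`, and optionally `effect`.
#' @param id_col id column name (`"variant_id"` or `"gene"`).
#' @param alpha Gamma shape for the combination.
#' @return `data.frame`: id, per-site p columns, `X`, `meta_p`,
#'   `direction_concordant`.
#' @export
meta_combine <- function(site_results, id_col = "variant_id", alpha = 1) {
  stopifnot(length(site_results) >= 1, !is.null(names(site_results)))
  ids <- Reduce(intersect, lapply(site_results, function(x) x[[id_col]]))
  rows <- lapply(ids, function(id) {
    ps <- vapply(site_results,
                 function(x) x$p[match(id, x[[id_col]])], numeric(1))
    effs <- vapply(site_results, function(x) {
      if (is.null(x$effect)) NA_real_ else x$effect[match(id, x[[id_col]])]
    }, numeric(1))
    ok <- is.finite(ps) & ps > 0
    fc <- if (all(ok)) fisher_combine(ps, alpha) else list(X = NA_real_,
                                                           p = NA_real_)
    conc <- if (all(is.finite(effs))) length(unique(sign(effs[effs != 0]))) <= 1
    else NA
    out <- data.frame(id = id, t(ps), X = fc$X, meta_p = fc$p,
                      direction_concordant = conc, stringsAsFactors = FALSE)
    names(out)[1] <- id_col
    names(out)[2:(1 + length(ps))] <- paste0("p_", names(site_results))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Significance-tier classification
#'
#' Applies the fixed reporting tiers: at the variant level p < 5e-4 is
#' significant and p < 5e-3 suggestive; at the gene level p < 1e-2 is
#' significant and p < 5e-2 suggestive. Each of the meta and mega p-values
#' is classified separately; a unit is reported when either passes, and
#' `in_both` flags units below the suggestive cut in both analyses (the
#' headline criterion).
#'
#' @param meta_p,mega_p numeric vectors.
#' @param level `"variant"` or `"gene"`.
#' @return `data.frame`: tier_meta, tier_mega, reported, in_both.
#' @export
classify_significance <- function(meta_p, mega_p, level = c("variant", "gene")) {
  level <- match.arg(level)
  th <- if (level == "variant") c(sig = 5e-4, sugg = 5e-3)
  else c(sig = 1e-2, sugg = 5e-2)
  tier <- function(p) {
    if (is.na(p)) stop("missing p-value", call. = FALSE)
    if (p < th["sig"]) "significant" else if (p < th["sugg"]) "suggestive"
    else "none"
  }
  tm <- vapply(meta_p, tier, character(1))
  tg <- vapply(mega_p, tier, character(1))
  data.frame(tier_meta = tm, tier_mega = tg,
             reported = tm != "none" | tg != "none",
             in_both = meta_p < th["sugg"] & mega_p < th["sugg"],
             stringsAsFactors = FALSE)
}
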