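#' Per-plate genotyping pass rates
#'
#' The pass rate of a plate is the fraction of non-missing genotype calls
#' among its samples. Plates with a rate of 0.97 or below fail (the retention
#' rule is strictly "greater than 97%") and all their samples are flagged.
#'
#' @param genotypes a `geno_matrix`.
#' @param plates named character/factor of plate ids, one per sample (names
#'   or order matching `rownames(genotypes$dosage)`).
#' @param threshold retention threshold (default 0.97, strict).
#' @return list: `rates` (named per-plate), `failed_plates`,
#'   `flagged_samples`.
#' @export
plate_pass_rate <- function(genotypes, plates, threshold = 0.97) {
  d <- genotypes$dosage
  if (!is.null(names(plates))) plates <- plates[rownames(d)]
  if (length(plates) != nrow(d))
    stop("one plate id per sample required", call. = FALSE)
  tab <- table(plates)
  if (any(tab == 0)) stop("plate with zero samples", call. = FALSE)
  rates <- vapply(split(seq_len(nrow(d)), plates),
                  function(idx) mean(!is.na(d[idx, , drop = FALSE])),
                  numeric(1))
  failed <- names(rates)[rates <= threshold]
  list(rates = rates, failed_plates = failed,
       flagged_samples = rownames(d)[plates %in% failed])
}

#' Per-sample inbreeding coefficient
#'
#' `F = 1 - observed_het / expected_het`, where the expected heterozygosity
#' is the sum of `2 p (1 - p)` over the sample's non-missing markers, with
#' allele frequencies `p` estimated from the retained samples. Monomorphic
#' markers are excluded.
#'
#' @param genotypes a `geno_matrix`.
#' @return named numeric vector of F, one per sample.
#' @export
inbreeding_coefficient <- function(genotypes) {
  d <- genotypes$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic markers available", call. = FALSE)
  d <- d[, keep, drop = FALSE]
  exp_h <- 2 * p[keep] * (1 - p[keep])
  obs <- is_het <- d == 1L
  f <- vapply(seq_len(nrow(d)), function(i) {
    use <- !is.na(d[i, ])
    if (!any(use)) stop("sample with zero usable markers: ", rownames(d)[i],
                        call. = FALSE)
    1 - sum(is_het[i, use]) / sum(exp_h[use])
  }, numeric(1))
  setNames(f, rownames(d))
}

#' Pairwise identity-by-state similarity matrix
#'
#' `IBS(i, j)` is the mean over shared non-missing markers of
#' `(2 - |d_i - d_j|) / 2`, a similarity in [0, 1] with unit diagonal.
#'
#' @param genotypes a `geno_matrix` with at least 2 samples.
#' @return symmetric numeric matrix.
#' @export
ibs_matrix <- function(genotypes) {
  d <- genotypes$dosage
  n <- nrow(d)
  if (n < 2) stop("at least two samples required", call. = FALSE)
  obs <- !is.na(d)
  d0 <- d; d0[!obs] <- 0
  # sum over shared markers of |di - dj| via the identity
  # |a-b| = a + b - 2 min(a,b); computed with indicator cross-products.
  ge1 <- (d0 >= 1) & obs; ge2 <- (d0 >= 2) & obs
  shared <- tcrossprod(obs * 1)
  # sum of min(di,dj) over shared markers = #common(>=1) + #common(>=2)
  summin <- tcrossprod(ge1 * 1) + tcrossprod(ge2 * 1)
  sumi <- tcrossprod(d0 * obs, obs * 1)      # sum_i over shared
  sumabs <- sumi + t(sumi) - 2 * summin
  if (any(shared == 0 & row(shared) != col(shared)))
    stop("sample pair with no shared non-missing markers", call. = FALSE)
  ibs <- 1 - sumabs / (2 * shared)
  diag(ibs) <- 1
  dimnames(ibs) <- list(rownames(d), rownames(d))
  ibs
}

#' Flag kin pairs from an IBS matrix
#'
#' For each pair with similarity above the threshold, the member with the
#' lower genotype call rate is removed (ties broken by lexicographic id).
#'
#' @param ibs symmetric IBS matrix.
#' @param genotypes the `geno_matrix` the matrix came from (for call rates).
#' @param threshold IBS above which a pair is treated as kin (default 0.9).
#' @return character vector of removed sample ids.
#' @export
kinship_flags <- function(ibs, genotypes, threshold = 0.9) {
  call_rate <- rowMeans(!is.na(genotypes$dosage))
  ids <- rownames(ibs)
  removed <- character(0)
  pairs <- which(upper.tri(ibs) & ibs > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-ibs[pairs])
    for (k in ord) {
      a <- ids[pairs[k, 1]]; b <- ids[pairs[k, 2]]
      if (a %in% removed || b %in% removed) next
      drop <- if (call_rate[a] < call_rate[b]) a
      else if (call_rate[b] < call_rate[a]) b
      else min(a, b)
      removed <- c(removed, drop)
    }
  }
  removed
}

#' Multidimensional-scaling outlier detection
#'
#' Classical metric MDS (eigendecomposition of the double-centred squared
#' distance matrix, via `cmdscale`) on the IBS distance `1 - IBS`. A sample
#' is an outlier when its Euclidean distance from the centroid in the first
#' two axes exceeds `k_sd` standard deviations of those distances.
#'
#' @param ibs symmetric IBS similarity matrix.
#' @param k_sd outlier cut in standard deviations (default 6).
#' @return list: `coords` (n x 2), `outliers` (sample ids).
#' @export
mds_outliers <- function(ibs, k_sd = 6) {
  if (!isSymmetric(unname(ibs), tol = 1e-8))
    stop("IBS matrix must be symmetric", call. = FALSE)
  dmat <- 1 - ibs
  xy <- cmdscale(as.dist(dmat), k = 2)
  ctr <- colMeans(xy)
  dc <- sqrt(rowSums(sweep(xy, 2, ctr)^2))
  s <- sd(dc)
  out <- if (is.na(s) || s == 0) character(0)
  else rownames(ibs)[dc > mean(dc) + k_sd * s]
  list(coords = xy, outliers = out)
}

#' Marker-level quality control
#'
#' Removes markers failing, in order: the exact Hardy-Weinberg test at
#' p < `hwe_p` (computed in all analysed samples), genotype missing rate
#' strictly greater than `max_missing`, and minor allele frequency strictly
#' smaller than `min_maf` (MAF on non-missing calls, folded). Each removal is
#' labelled with the first failing rule. Re-running on the retained set
#' removes nothing.
#'
#' @param genotypes a `geno_matrix` (sample QC already applied).
#' @param hwe_p,max_missing,min_maf cutoffs (defaults 1e-4, 0.05, 0.05).
#' @return list: `genotypes` (filtered), `removed` (`data.frame` variant_id,
#'   reason), `stats` (`data.frame` variant_id, hwe_p, missing_rate, maf).
#' @export
marker_qc <- function(genotypes, hwe_p = 1e-4, max_missing = 0.05,
                      min_maf = 0.05) {
  d <- genotypes$dosage
  if (!ncol(d)) stop("empty genotype table", call. = FALSE)
  stats <- data.frame(variant_id = colnames(d),
                      hwe_p = NA_real_, missing_rate = NA_real_,
                      maf = NA_real_, stringsAsFactors = FALSE)
  reason <- rep(NA_character_, ncol(d))
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    obs <- x[!is.na(x)]
    stats$missing_rate[j] <- 1 - length(obs) / length(x)
    stats$maf[j] <- dosage_maf(x)
    stats$hwe_p[j] <- if (length(obs))
      hwe_exact(sum(obs == 0), sum(obs == 1), sum(obs == 2)) else NA_real_
    reason[j] <-
      if (!is.na(stats$hwe_p[j]) && stats$hwe_p[j] < hwe_p) "hwe"
      else if (stats$missing_rate[j] > max_missing) "missingness"
      else if (is.na(stats$maf[j]) || stats$maf[j] < min_maf) "maf"
      else NA_character_
  }
  drop <- !is.na(reason)
  out <- genotypes
  out$dosage <- d[, !drop, drop = FALSE]
  out$variants <- genotypes$variants[!drop, , drop = FALSE]
  list(genotypes = out,
       removed = data.frame(variant_id = colnames(d)[drop],
                            reason = reason[drop], stringsAsFactors = FALSE),
       stats = stats)
}

#' Sample-level quality control
#'
#' Applies, in order: plate pass-rate filtering (> 0.97 retained),
#' inbreeding/IBS kinship removal, and MDS outlier removal on the IBS
#' distance. Every removed sample carries exactly one primary reason (the
#' first rule it failed).
#'
#' @param genotypes a `geno_matrix`.
#' @param samples sample table with `sample_id` and `plate`.
#' @param plate_threshold,kinship_threshold,mds_k_sd cutoffs.
#' @return list: `genotypes` (filtered), `removed` (`data.frame` sample_id,
#'   reason), `report` (plate rates, inbreeding F, MDS coordinates).
#' @export
sample_qc <- function(genotypes, samples, plate_threshold = 0.97,
                      kinship_threshold = 0.9, mds_k_sd = 6) {
  plates <- setNames(samples$plate, samples$sample_id)
  pl <- plate_pass_rate(genotypes, plates, plate_threshold)
  removed <- data.frame(sample_id = pl$flagged_samples,
                        reason = rep("plate", length(pl$flagged_samples)),
                        stringsAsFactors = FALSE)
  keep <- setdiff(rownames(genotypes$dosage), removed$sample_id)
  g <- genotypes
  g$dosage <- g$dosage[keep, , drop = FALSE]

  f <- inbreeding_coefficient(g)
  ibs <- ibs_matrix(g)
  kin <- kinship_flags(ibs, g, kinship_threshold)
  if (length(kin)) {
    removed <- rbind(removed, data.frame(sample_id = kin, reason = "kinship"))
    keep <- setdiff(keep, kin)
    g$dosage <- g$dosage[keep, , drop = FALSE]
    ibs <- ibs[keep, keep, drop = FALSE]
  }

  mds <- mds_outliers(ibs, mds_k_sd)
  if (length(mds$outliers)) {
    removed <- rbind(removed, data.frame(sample_id = mds$outliers,
                                         reason = "mds_outlier"))
    keep <- setdiff(keep, mds$outliers)
    g$dosage <- g$dosage[keep, , drop = FALSE]
  }
  list(genotypes = g, removed = removed,
       report = list(plate_rates = pl$rates, inbreeding_f = f,
                     mds_coords = mds$coords))
}
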