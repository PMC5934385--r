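#' Map variants to flanked gene intervals
#'
#' A variant belongs to every gene whose interval, extended by `flank` base
#' pairs on each side, contains its position (boundaries inclusive,
#' coordinates 1-based inclusive). Multi-assignment is allowed for
#' overlapping genes.
#'
#' @param variants `data.frame` with `variant_id`, `chrom`, `pos`.
#' @param genes `data.frame` with `name`, `chrom`, `start`, `end`.
#' @param flank flank size in bp (default 50000).
#' @return named list of `gene_set` objects: `gene`, `chrom`, `start`, `end`,
#'   `flank`, `variant_ids`.
#' @export
map_variants_to_genes <- function(variants, genes, flank = 50000) {
  if (any(genes$start > genes$end))
    stop("malformed gene interval with start > end", call. = FALSE)
  sets <- lapply(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    hit <- variants$chrom == g$chrom &
      variants$pos >= g$start - flank & variants$pos <= g$end + flank
    structure(list(gene = g$name, chrom = g$chrom, start = g$start,
                   end = g$end, flank = flank,
                   variant_ids = variants$variant_id[hit]),
              class = "gene_set")
  })
  setNames(sets, genes$name)
}

#' Composite LD between two dosage vectors
#'
#' Squared Pearson correlation of unphased dosages over shared non-missing
#' samples (composite LD).
#'
#' @param dosage_a,dosage_b numeric dosage vectors of equal length.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(keep) < 2) stop("fewer than 2 shared non-missing samples",
                          call. = FALSE)
  a <- dosage_a[keep]; b <- dosage_b[keep]
  if (var(a) == 0 || var(b) == 0)
    stop("zero dosage variance", call. = FALSE)
  cor(a, b)^2
}

# Pairwise r^2 matrix of a (mean-imputed) dosage matrix.
ld_r2_matrix <- function(G) {
  r <- suppressWarnings(cor(G))
  r[is.na(r)] <- 0
  r^2
}

#' Greedy LD pruning of sub-threshold markers
#'
#' Keeps markers with single-marker p below `p_threshold`, sorts them by
#' ascending p (ties by position, then id), and greedily accepts a marker if
#' and only if its r-squared with every already-accepted marker is below
#' `r2_threshold`. An empty selection is a valid result.
#'
#' @param p single-marker p-values.
#' @param r2 pairwise r-squared matrix over the same markers.
#' @param pos marker positions (tie-break); defaults to index order.
#' @param ids marker ids (final tie-break); defaults to index order.
#' @param p_threshold,r2_threshold selection and pruning cutoffs
#'   (defaults 0.1 and 0.5).
#' @return integer indices of retained markers (in acceptance order).
#' @export
select_and_prune <- function(p, r2, pos = seq_along(p),
                             ids = as.character(seq_along(p)),
                             p_threshold = 0.1, r2_threshold = 0.5) {
  cand <- which(!is.na(p) & p < p_threshold)
  if (!length(cand)) return(integer(0))
  cand <- cand[order(p[cand], pos[cand], ids[cand])]
  kept <- integer(0)
  for (j in cand) {
    if (!length(kept) || all(r2[j, kept] < r2_threshold))
      kept <- c(kept, j)
  }
  kept
}

#' Gene set statistic
#'
#' Mean of squared single-marker z statistics over the retained
#' (selected and LD-pruned) markers.
#'
#' @param z numeric vector of retained markers' z statistics.
#' @return the statistic (undefined for an empty set: error).
#' @export
set_statistic <- function(z) {
  if (!length(z)) stop("set statistic undefined for an empty set",
                       call. = FALSE)
  mean(z^2)
}

#' Proportion of significant markers in a gene
#'
#' Number of markers with single-marker p strictly below 0.05 divided by the
#' total number of markers mapped to the gene (pre-selection, pre-pruning).
#'
#' @param p per-marker p-values for all mapped markers (NA counts as
#'   non-significant).
#' @param n_total denominator; defaults to `length(p)`.
#' @return fraction in [0, 1].
#' @export
proportion_significant <- function(p, n_total = length(p)) {
  if (!n_total) stop("empty gene", call. = FALSE)
  sum(p < 0.05, na.rm = TRUE) / n_total
}

# Null-model quantities for the 1-df score test of a marker added to
# outcome ~ covariates. Returns residuals r, weights w and the fixed
# (X'WX)^{-1}; for the linear family the score variance carries the null
# residual variance s2.
score_null_fit <- function(y, X, family) {
  if (family == "linear") {
    qx <- qr(X)
    r <- qr.resid(qx, y)
    s2 <- sum(r^2) / (length(y) - qx$rank)
    w <- rep(1, length(y))
  } else {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    mu <- fit$fitted.values
    r <- y - mu
    w <- mu * (1 - mu)
    s2 <- 1
  }
  XtWXinv <- chol2inv(chol(crossprod(X * w, X)))
  list(r = r, w = w, s2 = s2, XtWXinv = XtWXinv)
}

# Squared score z for every marker (columns of G) under a row permutation of
# the phenotype side, vectorised over a block of permutations. Qblock is an
# n x B integer matrix of permutation indices; G must be complete.
score_z2_block <- function(G, X, nf, Qblock, family) {
  n <- nrow(G); p <- ncol(X); B <- ncol(Qblock)
  Rp <- matrix(nf$r[Qblock], n, B)
  U <- crossprod(G, Rp)
  G2 <- G * G
  if (family == "linear") {
    gWg <- matrix(colSums(G2), ncol(G), B)
  } else {
    gWg <- crossprod(G2, matrix(nf$w[Qblock], n, B))
  }
  WX <- X * nf$w
  A <- lapply(seq_len(p), function(j)
    crossprod(G, matrix(WX[, j][Qblock], n, B)))
  quad <- 0
  for (j in seq_len(p)) for (k in seq_len(p)) {
    quad <- quad + nf$XtWXinv[j, k] * (A[[j]] * A[[k]])
  }
  V <- nf$s2 * (gWg - quad)
  z2 <- ifelse(V > 1e-12, U^2 / V, 0)
  z2
}

#' Gene-based permutation test
#'
#' Runs the observed pipeline — per-marker 1-df score tests of dosage added
#' to the sex/age-adjusted null model, selection at `p_threshold`, greedy LD
#' pruning at `r2_threshold`, mean squared-z set statistic — and recomputes
#' the full pipeline (including re-selection and re-pruning) under `R` joint
#' permutations of the phenotype and covariate rows against the genotype
#' rows, which preserves both the genotype LD structure and the
#' covariate-outcome association. The empirical p-value is
#' `(1 + #\{permuted statistic >= observed\}) / (R + 1)`; permutations with an
#' empty selection contribute statistic 0. Missing dosages are mean-imputed
#' within marker so the permutation statistic is well defined for every
#' shuffle.
#'
#' @param gene_set a `gene_set` from [map_variants_to_genes()].
#' @param genotypes a `geno_matrix` containing the member variants.
#' @param phenotypes output of [derive_phenotypes()].
#' @param outcome outcome name (decides linear vs logistic score test).
#' @param samples sample table with `sample_id`, `sex`, `age`.
#' @param R number of permutations (default 50000).
#' @param seed integer seed; identical seeds give identical empirical p.
#' @param p_threshold,r2_threshold selection and pruning cutoffs.
#' @param set_max optional cap on the number of retained markers
#'   (default unlimited).
#' @param chunk permutations processed per block (memory control).
#' @return list of class `gene_test_result`: `gene`, `outcome`, `n_total`,
#'   `n_selected`, `selected`, `set_stat`, `empirical_p`,
#'   `prop_significant`, `R`, `marker_p` (named per-marker score p).
#' @export
permutation_gene_p <- function(gene_set, genotypes, phenotypes, outcome,
                               samples, R = 50000L, seed = 1L,
                               p_threshold = 0.1, r2_threshold = 0.5,
                               set_max = Inf, chunk = 5000L) {
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  ids <- intersect(rownames(genotypes$dosage), phenotypes$subject_id)
  vids <- intersect(gene_set$variant_ids, colnames(genotypes$dosage))
  n_total <- length(vids)
  if (!n_total) stop("gene set has no members in the genotype table",
                     call. = FALSE)
  G <- genotypes$dosage[ids, vids, drop = FALSE]
  G <- apply(G, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  y <- phenotypes[[outcome]][match(ids, phenotypes$subject_id)]
  X <- covariate_matrix(samples[match(ids, samples$sample_id), ])
  family <- outcome_family(outcome)
  vpos <- genotypes$variants$pos[match(vids, genotypes$variants$variant_id)]

  poly <- apply(G, 2, var) > 0
  marker_p <- setNames(rep(NA_real_, n_total), vids)
  if (!any(poly)) {
    return(structure(list(gene = gene_set$gene, outcome = outcome,
                          n_total = n_total, n_selected = 0L,
                          selected = character(0), set_stat = NA_real_,
                          empirical_p = NA_real_, prop_significant = 0,
                          R = R, marker_p = marker_p),
                     class = "gene_test_result"))
  }
  Gp <- G[, poly, drop = FALSE]
  pos_p <- vpos[poly]
  nf <- score_null_fit(y, X, family)
  r2 <- ld_r2_matrix(Gp)
  n <- nrow(Gp)

  obs_z2 <- drop(score_z2_block(Gp, X, nf, matrix(seq_len(n), n, 1), family))
  obs_p <- pchisq(obs_z2, df = 1, lower.tail = FALSE)
  marker_p[colnames(Gp)] <- obs_p
  sel <- select_and_prune(obs_p, r2, pos_p, colnames(Gp),
                          p_threshold, r2_threshold)
  if (is.finite(set_max) && length(sel) > set_max)
    sel <- sel[seq_len(set_max)]
  obs_stat <- if (length(sel)) mean(obs_z2[sel]) else NA_real_

  emp_p <- NA_real_
  if (length(sel)) {
    set.seed(seed)
    n_ge <- 0L
    done <- 0L
    while (done < R) {
      B <- min(chunk, R - done)
      Q <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
      z2 <- score_z2_block(Gp, X, nf, Q, family)
      pv <- pchisq(z2, df = 1, lower.tail = FALSE)
      for (b in seq_len(B)) {
        sb <- select_and_prune(pv[, b], r2, pos_p, colnames(Gp),
                               p_threshold, r2_threshold)
        if (is.finite(set_max) && length(sb) > set_max)
          sb <- sb[seq_len(set_max)]
        stat_b <- if (length(sb)) mean(z2[sb, b]) else 0
        if (stat_b >= obs_stat) n_ge <- n_ge + 1L
      }
      done <- done + B
    }
    emp_p <- (1 + n_ge) / (R + 1)
  }
  structure(list(gene = gene_set$gene, outcome = outcome,
                 n_total = n_total, n_selected = length(sel),
                 selected = colnames(Gp)[sel], set_stat = obs_stat,
                 empirical_p = emp_p,
                 prop_significant = proportion_significant(marker_p, n_total),
                 R = R, marker_p = marker_p),
            class = "gene_test_result")
}

#' @exportS3Method base::print
print.gene_test_result <- function(x, ...) {
  cat(sprintf("<gene_test_result> %s / %s: %d/%d markers retained, stat %.3f, empirical p %s (R = %d)\n",
              x$gene, x$outcome, x$n_selected, x$n_total,
              ifelse(is.na(x$set_stat), NA, x$set_stat),
              format(x$empirical_p), x$R))
  invisible(x)
}

#' Gene-based scan over a gene panel
#'
#' Maps retained markers to flanked gene intervals and runs the permutation
#' gene test for each gene.
#'
#' @inheritParams permutation_gene_p
#' @param genes gene interval `data.frame` (`name`, `chrom`, `start`, `end`).
#' @param flank flank in bp.
#' @param site optional site restriction (with `samples$site`).
#' @return `data.frame`: gene, outcome, site, n_total, n_selected, set_stat,
#'   empirical_p, prop_significant.
#' @export
gene_scan <- function(genotypes, phenotypes, outcome, samples, genes,
                      flank = 50000, R = 50000L, seed = 1L,
                      p_threshold = 0.1, r2_threshold = 0.5, set_max = Inf,
                      site = NULL) {
  if (!is.null(site)) {
    keep <- samples$sample_id[samples$site == site]
    phenotypes <- phenotypes[phenotypes$subject_id %in% keep, , drop = FALSE]
  }
  sets <- map_variants_to_genes(genotypes$variants, genes, flank)
  sets <- Filter(function(s) length(s$variant_ids) > 0, sets)
  rows <- lapply(seq_along(sets), function(k) {
    res <- permutation_gene_p(sets[[k]], genotypes, phenotypes, outcome,
                              samples, R = R,
                              seed = substream_seed(seed, k),
                              p_threshold = p_threshold,
                              r2_threshold = r2_threshold, set_max = set_max)
    data.frame(gene = res$gene, outcome = outcome,
               site = site %||% "pooled",
               n_total = res$n_total, n_selected = res$n_selected,
               set_stat = res$set_stat, empirical_p = res$empirical_p,
               prop_significant = res$prop_significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
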