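# Shared fixtures, built in code at test time.

one_gene <- function(n_variants = 20, block_rho = 0.6,
                     maf_range = c(0.1, 0.4)) {
  gene_model("G1", "1", 1e6, 2e6, n_variants = n_variants,
             block_rho = block_rho, maf_range = maf_range)
}

# A tiny complete cohort (no genotype missingness) for association tests.
tiny_cohort <- function(n = 200, seed = 11, n_variants = 10, rho = 0.5) {
  samples <- assign_sites_and_plates(n, seed = seed)
  geno <- simulate_genotypes(n, one_gene(n_variants, rho), seed = seed + 1,
                             missing_rate = 0, sample_ids = samples$sample_id)
  list(samples = samples, geno = geno)
}

# Wrap a raw dosage matrix as a geno_matrix with sequential positions.
make_block_geno <- function(d, chrom = "1") {
  d <- as.matrix(d)
  storage.mode(d) <- "integer"
  colnames(d) <- sprintf("v%03d", seq_len(ncol(d)))
  rownames(d) <- sprintf("S%04d", seq_len(nrow(d)))
  structure(list(dosage = d,
                 variants = data.frame(variant_id = colnames(d),
                                       chrom = chrom,
                                       pos = seq_len(ncol(d)) * 1000L,
                                       gene = "G1",
                                       stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

# Direct-formula HWE enumeration oracle: conditional probability of each
# attainable heterozygote count from log-factorials, two-sided tail by
# summing probabilities <= observed. Independent of the package's recurrence.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_ref + n_het
  nb <- 2 * n - na
  nm <- min(na, nb)
  hets <- seq(nm %% 2, nm, by = 2)
  lp <- vapply(hets, function(h) {
    haa <- (na - h) / 2; hbb <- (nb - h) / 2
    lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) - lgamma(hbb + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Independent greedy-rule oracle for select_and_prune: literal restatement of
# the definition with explicit ordering and pairwise checks.
prune_oracle <- function(p, r2, p_threshold = 0.1, r2_threshold = 0.5) {
  elig <- which(!is.na(p) & p < p_threshold)
  elig <- elig[order(p[elig], elig)]
  kept <- integer(0)
  for (j in elig) {
    ok <- TRUE
    for (k in kept) if (r2[j, k] >= r2_threshold) ok <- FALSE
    if (ok) kept <- c(kept, j)
  }
  kept
}
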