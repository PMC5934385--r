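#!/usr/bin/env Rscript
# Stage 4: additive single-marker association scans, adjusted for sex and
# age, per site and on the pooled (mega) sample. Per-imputation estimates
# are pooled across the completed panels by Rubin's rules.

suppressMessages(library(adpgx))

geno <- read_genotypes("results/qc/retained_genotypes.tsv")
samples <- read_samples("results/qc/retained_samples.tsv")
ph_all <- read.delim("results/phenotypes/derived_outcomes.tsv")
outcome <- "response_pct"

rubin_scan <- function(site = NULL, mega = FALSE) {
  scans <- lapply(sort(unique(ph_all$imputation)), function(r) {
    ph <- ph_all[ph_all$imputation == r, ]
    if (mega) mega_scan(geno, ph, outcome, samples)
    else assoc_scan(geno, ph, outcome, samples, site = site)
  })
  base <- scans[[1]]
  for (i in seq_len(nrow(base))) {
    est <- vapply(scans, function(s) s$effect[i], numeric(1))
    se <- vapply(scans, function(s) s$se[i], numeric(1))
    if (any(!is.finite(est)) || any(!is.finite(se))) next
    pr <- pool_rubin(est, se)
    base[i, c("effect", "se", "statistic", "p")] <-
      pr[c("estimate", "se", "statistic", "p")]
  }
  base
}

dir.create("results/assoc", recursive = TRUE, showWarnings = FALSE)
for (site in sort(unique(samples$site))) {
  res <- rubin_scan(site = site)
  write.table(res, sprintf("results/assoc/scan_%s_%s.tsv", outcome, site),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d markers, min p = %.3g at %s\n", site, nrow(res),
              min(res$p, na.rm = TRUE),
              res$variant_id[which.min(res$p)]))
}
mega <- rubin_scan(mega = TRUE)
write.table(mega, sprintf("results/assoc/scan_%s_mega.tsv", outcome),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("mega: min p = %.3g at %s\n", min(mega$p, na.rm = TRUE),
            mega$variant_id[which.min(mega$p)]))
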