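#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with its default: QC cutoffs
#' (plate call rate > 0.97, exact HWE p < 1e-4, marker missingness <= 0.05,
#' MAF >= 0.05, kinship IBS > 0.9, MDS outliers at 6 s.d.), gene-test
#' settings (selection p < 0.1, pruning r2 < 0.5, R permutations, flank
#' 50 kb), the meta-analysis Gamma shape (1 = Fisher), multiple-imputation
#' m, and the synthetic-cohort settings. The configuration is validated here
#' (before any compute) and serialized, with its hash, into every output's
#' metadata.
#'
#' @param seed master seed.
#' @param n_samples cohort size.
#' @param genes gene models.
#' @param effects optional effect table.
#' @param outcomes outcomes to analyse.
#' @param R permutations for the gene test.
#' @param m imputations.
#' @param ... overrides for the remaining fields (see Details).
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1L, n_samples = 455L,
                       genes = default_gene_models(), effects = NULL,
                       outcomes = "response_pct", R = 2000L, m = 5L, ...) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              genes = genes, effects = effects, outcomes = outcomes,
              R = as.integer(R), m = as.integer(m),
              n_iter = 10L, flank = 50000,
              p_threshold = 0.1, r2_threshold = 0.5, set_max = Inf,
              alpha = 1, r2_block = 0.8,
              plate_threshold = 0.97, hwe_p = 1e-4, max_missing = 0.05,
              min_maf = 0.05, kinship_threshold = 0.9, mds_k_sd = 6,
              include_site_covariate = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$R < 1) stop("config error: R permutations must be >= 1",
                      call. = FALSE)
  if (cfg$m < 2) stop("config error: m imputations must be >= 2",
                      call. = FALSE)
  assert_prob(c(cfg$p_threshold, cfg$r2_threshold, cfg$plate_threshold,
                cfg$hwe_p, cfg$max_missing, cfg$min_maf,
                cfg$kinship_threshold, cfg$r2_block), "config thresholds")
  if (cfg$min_maf > 0.5) stop("config error: min_maf above 0.5", call. = FALSE)
  if (any(!cfg$outcomes %in% hrsd_outcomes))
    stop("config error: unknown outcome in config", call. = FALSE)
  invisible(cfg)
}

#' Demo configuration: two sites, ten genes, one causal VEGFA variant
#'
#' The end-to-end demonstration setup: a 455-sample two-site cohort over the
#' ten-gene panel with a single causal variant in the middle of the VEGFA
#' block (per-allele effect +0.08 on the week-8 percentage change) and
#' desk-scale gene-test permutations.
#'
#' @param seed master seed.
#' @param R gene-test permutations (default 2000).
#' @return a `run_config`.
#' @export
demo_config <- function(seed = 1L, R = 2000L) {
  run_config(seed = seed, R = R, m = 5L,
             effects = data.frame(variant_id = "VEGFA_010",
                                  outcome = "response_pct", beta = 0.08,
                                  stringsAsFactors = FALSE))
}

# Rubin-pooled single-marker scan across completed panels.
pooled_scan <- function(genotypes, imp, outcome, samples, site = NULL,
                        mega = FALSE, include_site_covariate = FALSE) {
  scans <- lapply(imp$panels, function(p) {
    ph <- derive_phenotypes(p)
    if (mega) mega_scan(genotypes, ph, outcome, samples,
                        include_site_covariate)
    else assoc_scan(genotypes, ph, outcome, samples, site = site)
  })
  base <- scans[[1]]
  for (i in seq_len(nrow(base))) {
    est <- vapply(scans, function(s) s$effect[i], numeric(1))
    se <- vapply(scans, function(s) s$se[i], numeric(1))
    if (any(!is.finite(est)) || any(!is.finite(se))) next
    pr <- pool_rubin(est, se)
    base$effect[i] <- pr$estimate
    base$se[i] <- pr$se
    base$statistic[i] <- pr$statistic
    base$p[i] <- pr$p
  }
  base
}

#' Run the full two-site analysis pipeline
#'
#' Sequences the whole study on one configuration: cohort simulation (or
#' user-provided inputs), sample QC (plates, kinship, MDS), marker QC (HWE,
#' missingness, MAF), phenotype derivation with multiple imputation and
#' Rubin pooling, per-site and pooled (mega) single-marker scans, per-site
#' and pooled gene-based permutation tests, Fisher meta-analysis of per-site
#' results, and significance-tier classification. Identical configuration
#' and seed give identical outputs. Every stage appends its in/out counts to
#' the run log.
#'
#' @param config a `run_config`.
#' @param data optional list with pre-built `samples`, `genotypes`, `hrsd`
#'   (defaults to [simulate_cohort()] under the config).
#' @param verbose emit log lines as messages.
#' @return a result bundle: config, config_hash, samples, qc, imputation,
#'   phenotypes, scans (per site/mega, Rubin-pooled), meta_variants,
#'   gene_tests, meta_genes, meff, log.
#' @export
run_pipeline <- function(config = run_config(), data = NULL, verbose = FALSE) {
  validate_config(config)
  logline <- local({
    lines <- character(0)
    function(fmt = NULL, ...) {
      if (is.null(fmt)) return(lines)
      msg <- sprintf(fmt, ...)
      if (verbose) message(msg)
      lines <<- c(lines, msg)
      invisible(NULL)
    }
  })
  hash <- config_hash(unclass(config))

  if (is.null(data))
    data <- simulate_cohort(config$n_samples, config$genes, config$effects,
                            seed = config$seed)
  samples <- data$samples
  logline("input: %d samples, %d markers", nrow(samples),
          ncol(data$genotypes$dosage))

  sq <- sample_qc(data$genotypes, samples,
                  plate_threshold = config$plate_threshold,
                  kinship_threshold = config$kinship_threshold,
                  mds_k_sd = config$mds_k_sd)
  for (rs in unique(sq$removed$reason))
    logline("sample QC: removed %d by rule '%s'",
            sum(sq$removed$reason == rs), rs)
  logline("sample QC: %d samples retained", nrow(sq$genotypes$dosage))

  mq <- marker_qc(sq$genotypes, hwe_p = config$hwe_p,
                  max_missing = config$max_missing, min_maf = config$min_maf)
  for (rs in unique(mq$removed$reason))
    logline("marker QC: removed %d by rule '%s'",
            sum(mq$removed$reason == rs), rs)
  logline("marker QC: %d markers retained", ncol(mq$genotypes$dosage))
  geno <- mq$genotypes
  kept_ids <- rownames(geno$dosage)
  samples <- samples[samples$sample_id %in% kept_ids, ]

  hrsd <- data$hrsd[data$hrsd$subject_id %in% kept_ids, ]
  pat <- panel_totals(hrsd)
  obs <- !is.na(pat$totals)
  pat_key <- apply(obs, 1, paste, collapse = "")
  for (k in sort(unique(pat_key)))
    logline("missingness pattern %s: %d subjects", k, sum(pat_key == k))

  imp <- multiple_impute(hrsd, samples, m = config$m,
                         n_iter = config$n_iter,
                         seed = substream_seed(config$seed, 21))
  phen1 <- derive_phenotypes(imp$panels[[1]])

  sites <- sort(unique(samples$site))
  scans <- list(); meta_variants <- list()
  gene_tests <- list(); meta_genes <- list()
  for (oc in config$outcomes) {
    per_site <- lapply(sites, function(s)
      pooled_scan(geno, imp, oc, samples, site = s))
    names(per_site) <- sites
    mega <- pooled_scan(geno, imp, oc, samples, mega = TRUE,
                        include_site_covariate = config$include_site_covariate)
    mv <- meta_combine(per_site, "variant_id", alpha = config$alpha)
    mv$mega_p <- mega$p[match(mv$variant_id, mega$variant_id)]
    ok <- !is.na(mv$meta_p) & !is.na(mv$mega_p)
    mv$tier_meta <- mv$tier_mega <- NA_character_
    mv$reported <- mv$in_both <- NA
    if (any(ok)) {
      cls <- classify_significance(mv$meta_p[ok], mv$mega_p[ok], "variant")
      mv[ok, c("tier_meta", "tier_mega", "reported", "in_both")] <- cls
    }
    scans[[oc]] <- c(per_site, list(mega = mega))
    meta_variants[[oc]] <- mv

    ph_site <- lapply(seq_along(sites), function(k) {
      g <- gene_scan(geno, derive_phenotypes(imp$panels[[1]]), oc, samples,
                     config$genes, flank = config$flank, R = config$R,
                     seed = substream_seed(config$seed, 30 + k),
                     p_threshold = config$p_threshold,
                     r2_threshold = config$r2_threshold,
                     set_max = config$set_max, site = sites[k])
      g$p <- g$empirical_p
      g
    })
    names(ph_site) <- sites
    g_mega <- gene_scan(geno, derive_phenotypes(imp$panels[[1]]), oc, samples,
                        config$genes, flank = config$flank, R = config$R,
                        seed = substream_seed(config$seed, 40),
                        p_threshold = config$p_threshold,
                        r2_threshold = config$r2_threshold,
                        set_max = config$set_max)
    mg <- meta_combine(ph_site, "gene", alpha = config$alpha)
    mg$mega_p <- g_mega$empirical_p[match(mg$gene, g_mega$gene)]
    okg <- !is.na(mg$meta_p) & !is.na(mg$mega_p)
    mg$tier_meta <- mg$tier_mega <- NA_character_
    mg$reported <- mg$in_both <- NA
    if (any(okg)) {
      cls <- classify_significance(mg$meta_p[okg], mg$mega_p[okg], "gene")
      mg[okg, c("tier_meta", "tier_mega", "reported", "in_both")] <- cls
    }
    gene_tests[[oc]] <- c(ph_site, list(mega = g_mega))
    meta_genes[[oc]] <- mg
    for (k in seq_len(nrow(g_mega)))
      logline("gene test (%s, pooled): %s selected %d/%d", oc,
              g_mega$gene[k], g_mega$n_selected[k], g_mega$n_total[k])
  }

  meff <- effective_tests(geno, r2_block = config$r2_block)
  logline("effective tests: Meff = %d (threshold %.3g)", meff$meff,
          meff$threshold)

  list(config = config, config_hash = hash, samples = samples,
       qc = list(samples_removed = sq$removed, markers_removed = mq$removed,
                 report = sq$report, marker_stats = mq$stats),
       imputation = imp, phenotypes = phen1, scans = scans,
       meta_variants = meta_variants, gene_tests = gene_tests,
       meta_genes = meta_genes, meff = meff, log = logline())
}

#' Write a result table with its configuration hash
#'
#' Prepends a `# adpgx_config_hash=<hash>` metadata line so outputs from
#' different configurations are detectable when mixed.
#'
#' @param df result `data.frame`.
#' @param path output TSV path.
#' @param hash configuration hash (from a pipeline bundle).
#' @export
write_result_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# adpgx_config_hash=%s", hash), con)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}
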