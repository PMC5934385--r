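#' Gene models for the synthetic cohort
#'
#' A gene model describes one candidate gene as a genomic interval carrying a
#' block of markers in linkage disequilibrium: `n_variants` markers evenly
#' spaced across `[start, end]`, with latent AR(1) correlation `block_rho`
#' and minor allele frequencies drawn uniformly from `maf_range`.
#' Coordinates are 1-based inclusive.
#'
#' @param name gene symbol.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive base-pair span; `start < end`.
#' @param n_variants number of markers in the block (>= 1).
#' @param block_rho AR(1) latent correlation between adjacent markers, in [0, 1).
#' @param maf_range length-2 numeric, target minor allele frequencies in (0, 0.5].
#' @return a one-row `data.frame` of class `gene_model` fields.
#' @export
gene_model <- function(name, chrom, start, end, n_variants = 20L,
                       block_rho = 0.8, maf_range = c(0.05, 0.5)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(start < end)) stop("gene interval must satisfy start < end", call. = FALSE)
  if (n_variants < 1) stop("n_variants must be >= 1", call. = FALSE)
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must lie in [0, 1)", call. = FALSE)
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]", call. = FALSE)
  data.frame(name = name, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             n_variants = as.integer(n_variants),
             block_rho = block_rho,
             maf_lo = maf_range[1], maf_hi = maf_range[2],
             stringsAsFactors = FALSE)
}

#' Default candidate-gene panel: ten neurotrophic-pathway genes
#'
#' The ten genes of the neurotrophic / BDNF signalling pathway that the
#' pipeline was designed around, with approximate GRCh37 spans. Marker
#' density, LD strength and allele-frequency ranges are simulation defaults
#' chosen to exercise the LD-pruning and permutation machinery at desk scale.
#'
#' @inheritParams gene_model
#' @return a `data.frame` with one row per gene (see [gene_model()]).
#' @export
default_gene_models <- function(n_variants = 20L, block_rho = 0.8,
                                maf_range = c(0.05, 0.5)) {
  g <- list(
    c("BDNF",     "11",  27676440,  27743605),
    c("NGFR",     "17",  47572655,  47592382),
    c("NTRK2",    "9",   87283466,  87638505),
    c("MTOR",     "1",   11166588,  11322614),
    c("VEGFA",    "6",   43737946,  43754224),
    c("S100A10",  "1",  151955391, 151966866),
    c("SERPINE1", "7",  100770370, 100782547),
    c("ARHGAP33", "19",  36271280,  36286425),
    c("GSK3B",    "3",  119540170, 119813264),
    c("CREB1",    "2",  208394616, 208470284)
  )
  do.call(rbind, lapply(g, function(x)
    gene_model(x[1], x[2], as.numeric(x[3]), as.numeric(x[4]),
               n_variants = n_variants, block_rho = block_rho,
               maf_range = maf_range)))
}

#' Read gene intervals from a BED file
#'
#' BED on disk is 0-based half-open; intervals are converted to the package's
#' internal 1-based inclusive convention on read (delegated to
#' `rtracklayer::import`). The name column is required.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `name`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  if (is.null(df$name) || any(is.na(df$name)) || any(!nzchar(df$name)))
    stop("every BED record must carry a name", call. = FALSE)
  out <- data.frame(name = as.character(df$name),
                    chrom = as.character(df$seqnames),
                    start = as.integer(df$start), end = as.integer(df$end),
                    stringsAsFactors = FALSE)
  bad <- out$start > out$end
  if (any(bad)) stop("malformed interval with start > end in BED", call. = FALSE)
  out
}

#' Write gene intervals to BED (0-based half-open)
#'
#' @param genes `data.frame` with `name`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param path output path.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$name)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
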