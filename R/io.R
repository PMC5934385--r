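#' Read genotypes from VCF or a dosage TSV
#'
#' VCF: diploid biallelic `GT` calls are converted to minor-allele dosage
#' (the counted allele per marker is whichever of REF/ALT is minor among the
#' read samples); `./.` becomes a missing dosage; multiallelic records are
#' rejected with record-level diagnostics; positions stay 1-based. Dosage
#' TSV: the transposed table written by [write_genotypes_tsv()] (variant
#' metadata columns then one column per sample, `.` for missing).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multiallelic records are not supported: ",
         paste(sprintf("%s:%s", fix$CHROM[multi], fix$POS[multi]),
               collapse = ", "), call. = FALSE)
  ids <- fix$ID
  if (any(duplicated(ids))) stop("duplicated variant id in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) != 2 || any(!a %in% c("0", "1")))
      stop("unsupported genotype call: ", g, call. = FALSE)
    sum(a == "1")
  })
  alt_dos <- matrix(as.integer(alt_dos), nrow(gt), ncol(gt),
                    dimnames = dimnames(gt))
  dosage <- t(alt_dos)
  counted <- fix$ALT
  q <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(q) & q > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2L - dosage[, flip]
    counted[flip] <- fix$REF[flip]
  }
  colnames(dosage) <- ids
  gene <- sub("^.*GENE=([^;]*).*$", "\\1", fix$INFO)
  gene[!grepl("GENE=", fix$INFO %||% "")] <- NA_character_
  variants <- data.frame(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         gene = gene, ref = fix$REF, alt = fix$ALT,
                         counted_allele = counted, stringsAsFactors = FALSE)
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' Write genotypes to a plain-text VCF
#'
#' Emits one biallelic record per variant with a diploid `GT` field; the
#' internal minor-allele dosage is written as the ALT-allele count (synthetic
#' alleles REF=A, ALT=G when none are recorded), so a write/read cycle is
#' lossless whenever the counted allele stays minor.
#'
#' @param genotypes a `geno_matrix`.
#' @param path output path (`.vcf`).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  d <- genotypes$dosage
  v <- genotypes$variants
  ref <- v$ref %||% rep("A", nrow(v))
  alt <- v$alt %||% rep("G", nrow(v))
  info <- if (!is.null(v$gene)) paste0("GENE=", v$gene) else rep(".", nrow(v))
  gt_map <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=adpgx",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Mapped gene\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  for (j in seq_len(ncol(d))) {
    calls <- ifelse(is.na(d[, j]), "./.", gt_map[d[, j] + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], ref[j], alt[j],
                       ".", "PASS", info[j], "GT", calls), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Write genotypes to a dosage TSV
#'
#' Variant metadata columns (`variant_id`, `chrom`, `pos`, `gene`) followed
#' by one column per sample; missing dosage is `.`.
#'
#' @param genotypes a `geno_matrix`.
#' @param path output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  v <- genotypes$variants[, c("variant_id", "chrom", "pos", "gene")]
  tab <- cbind(v, as.data.frame(t(genotypes$dosage)))
  data.table::fwrite(tab, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

read_genotypes_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t", na.strings = ".",
                           data.table = FALSE)
  meta_cols <- intersect(c("variant_id", "chrom", "pos", "gene"), names(tab))
  if (!"variant_id" %in% meta_cols)
    stop("dosage TSV must carry a variant_id column", call. = FALSE)
  if (any(duplicated(tab$variant_id)))
    stop("duplicated variant id in dosage TSV", call. = FALSE)
  sample_cols <- setdiff(names(tab), meta_cols)
  dosage <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- tab$variant_id
  variants <- tab[, meta_cols, drop = FALSE]
  variants$chrom <- as.character(variants$chrom)
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' Read and write HRSD panels as TSV
#'
#' Columns: `subject_id`, `timepoint` (`bl`, `w2`, `w4`, `w8`),
#' `item_01`..`item_21`; missing items are `.` (a visit is missing iff all
#' 21 items are).
#'
#' @param panel an `hrsd_panel`.
#' @param path file path.
#' @return `read_hrsd` returns an `hrsd_panel`.
#' @export
write_hrsd <- function(panel, path) {
  data.table::fwrite(panel, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' @rdname write_hrsd
#' @export
read_hrsd <- function(path) {
  panel <- data.table::fread(path, sep = "\t", na.strings = ".",
                             data.table = FALSE)
  need <- c("subject_id", "timepoint", item_cols)
  if (!all(need %in% names(panel)))
    stop("HRSD TSV must carry subject_id, timepoint and item_01..item_21",
         call. = FALSE)
  class(panel) <- c("hrsd_panel", "data.frame")
  panel
}

#' Read and write sample tables as TSV
#'
#' @param samples sample `data.frame`.
#' @param path file path.
#' @export
write_samples <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = ".", data.table = FALSE)
}
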