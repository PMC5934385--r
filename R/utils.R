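#' @keywords internal
"_PACKAGE"

#' @importFrom stats binomial cor glm lm lm.fit glm.fit qr.resid pchisq
#'   pgamma qgamma pnorm pt qnorm rbinom rchisq rnorm runif sd setNames var
#'   cmdscale as.dist chol2inv
#' @importFrom utils head write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-operation random seed from a master seed
#'
#' All stochastic operations in the package take an explicit integer seed.
#' Pipelines derive one substream per stage from a single master seed so a run
#' is reproducible end to end while stages stay independently re-runnable.
#' Seeds are kept within the 32-bit signed integer range.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the substream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((as.double(seed) * 1000003 + 7919 * stream) %% 2147483629)
}

# Monotone bin of an HRSD total into the 0-4 range of the depressed-mood item.
# Used by the simulator and by imputation so that the stem item is always
# consistent with the concurrent total.
item1_from_total <- function(total) {
  pmin(4L, pmax(0L, as.integer(floor(total / 5))))
}

# Fold an ALT-allele frequency to a minor allele frequency in [0, 0.5].
fold_maf <- function(q) pmin(q, 1 - q)

# Minor allele frequency of a dosage vector, non-missing calls only.
dosage_maf <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  fold_maf(mean(d) / 2)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Stable content hash of a configuration (hex md5 of its deparsed form),
# embedded in output metadata so outputs from different configs are
# distinguishable.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}
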