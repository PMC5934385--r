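#' Exact Hardy-Weinberg test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions given the
#' allele counts. The two-sided p-value sums, over every heterozygote count
#' attainable with the observed allele counts (same parity), the conditional
#' probabilities that do not exceed the probability of the observed table.
#' Probabilities are computed by the standard stable recurrence over
#' neighbouring heterozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts.
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0))
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one sample required", call. = FALSE)
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)

  hets <- seq(n_minor %% 2, n_minor, by = 2)
  pr <- numeric(length(hets))
  # start at the largest attainable heterozygote count and recurse downward:
  # P(h-2)/P(h) = h(h-1) / (4 (nA_hom+1)(nB_hom+1)) evaluated at count h.
  pr[length(hets)] <- 1
  for (i in rev(seq_along(hets))[-1]) {
    h <- hets[i + 1]
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    pr[i] <- pr[i + 1] * h * (h - 1) / (4 * (hom_min + 1) * (hom_maj + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts",
                       call. = FALSE)
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}
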