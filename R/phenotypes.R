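item_cols <- sprintf("item_%02d", 1:21)

#' Total HRSD score at one timepoint
#'
#' Arithmetic sum of the 21 item scores. A visit is either fully observed or
#' fully missing (the all-or-none convention); partially missing items are a
#' contract violation and raise an error.
#'
#' @param items numeric vector of the 21 item scores.
#' @return integer total.
#' @export
total_score <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 21) stop("exactly 21 item scores required", call. = FALSE)
  if (anyNA(items))
    stop("partially missing items at an observed timepoint", call. = FALSE)
  as.integer(sum(items))
}

# Totals matrix (subjects x timepoints) from a long panel; NA where the visit
# is missing. Errors if a visit is partially missing.
panel_totals <- function(panel) {
  tps <- c("bl", "w2", "w4", "w8")
  subjects <- unique(panel$subject_id)
  tot <- matrix(NA_integer_, length(subjects), 4,
                dimnames = list(subjects, tps))
  it1 <- tot
  m <- as.matrix(panel[, item_cols])
  n_miss <- rowSums(is.na(m))
  if (any(n_miss > 0 & n_miss < 21))
    stop("partially missing items at an observed timepoint", call. = FALSE)
  ok <- n_miss == 0
  tot[cbind(match(panel$subject_id, subjects),
            match(panel$timepoint, tps))] <-
    ifelse(ok, as.integer(rowSums(m)), NA_integer_)
  it1[cbind(match(panel$subject_id, subjects),
            match(panel$timepoint, tps))] <-
    ifelse(ok, as.integer(m[, "item_01"]), NA_integer_)
  if (anyNA(tot[, "bl"]))
    stop("baseline must be observed for every subject", call. = FALSE)
  list(totals = tot, item1 = it1)
}

#' Remission from the week-8 total
#'
#' Remission is a week-8 total of 7 or less. The historical clinical coding
#' is 1 = not remitted (total > 7), 2 = remitted; the favourable-outcome
#' recode maps remitted to 1.
#'
#' @param week8_total non-negative week-8 total score(s).
#' @return integer 0/1, 1 = remitted.
#' @export
derive_remitted <- function(week8_total) {
  if (any(week8_total < 0)) stop("negative total", call. = FALSE)
  as.integer(week8_total <= 7)
}

#' Percentage change in the HRSD total
#'
#' `(week8 - baseline) / baseline` as a signed fraction (e.g. -0.5 is a 50%
#' drop). Baseline must be positive (guaranteed by the minimum-14 inclusion
#' rule).
#'
#' @param baseline_total,week8_total total scores.
#' @return numeric signed fraction.
#' @export
percent_change <- function(baseline_total, week8_total) {
  if (any(baseline_total <= 0)) stop("zero baseline", call. = FALSE)
  (week8_total - baseline_total) / baseline_total
}

#' Treatment response from the percentage change
#'
#' A responder improves by at least 50%: percentage change of exactly -0.50
#' or lower. Clinical coding 1 = non-responder (change greater than -50%),
#' 2 = responder; favourable recode maps responder to 1.
#'
#' @param response_pct signed fraction change.
#' @return integer 0/1, 1 = responder.
#' @export
derive_response <- function(response_pct) {
  stopifnot(all(is.finite(response_pct)))
  as.integer(response_pct <= -0.5)
}

#' Stem-depressed outcome from the week-8 depressed-mood item
#'
#' Dichotomises item 1 (depressed mood, 0-4) at 3: scores of 3-4
#' (moderately severe / severe) take clinical code 1, scores of 0-2 code 2.
#' The favourable recode maps code 2 (mood no worse than moderate) to 1.
#'
#' @param item1_week8 item-1 score(s) in 0-4.
#' @return integer 0/1, 1 = favourable (item 1 below 3).
#' @export
derive_stem_depressed <- function(item1_week8) {
  if (any(item1_week8 < 0 | item1_week8 > 4))
    stop("item-1 score must lie in 0-4", call. = FALSE)
  as.integer(item1_week8 < 3)
}

#' Convert between favourable 0/1 outcomes and clinical 1/2 codes
#'
#' The clinical convention codes the favourable category as 2 and the
#' unfavourable as 1; the regression convention is favourable = 1,
#' unfavourable = 0. The two encodings round-trip losslessly.
#'
#' @param x integer vector in the source encoding.
#' @return integer vector in the target encoding.
#' @export
favourable_to_code12 <- function(x) {
  stopifnot(all(x %in% 0:1))
  as.integer(ifelse(x == 1L, 2L, 1L))
}

#' @rdname favourable_to_code12
#' @export
code12_to_favourable <- function(x) {
  stopifnot(all(x %in% 1:2))
  as.integer(x == 2L)
}

#' Derive the four treatment-response outcomes from a completed panel
#'
#' Requires a panel with no missing week-8 visit (run [multiple_impute()]
#' first when follow-ups are missing). Returns the favourable 0/1 outcomes
#' together with the clinical 1/2 codes.
#'
#' @param panel a completed `hrsd_panel`.
#' @return `data.frame`: subject_id, remitted, response_binary, response_pct,
#'   stem_depressed, plus `*_code12` columns.
#' @export
derive_phenotypes <- function(panel) {
  pt <- panel_totals(panel)
  tot <- pt$totals
  if (anyNA(tot[, "w8"]))
    stop("week-8 visit missing; impute before deriving outcomes",
         call. = FALSE)
  pct <- percent_change(tot[, "bl"], tot[, "w8"])
  out <- data.frame(
    subject_id = rownames(tot),
    remitted = derive_remitted(tot[, "w8"]),
    response_binary = derive_response(pct),
    response_pct = pct,
    stem_depressed = derive_stem_depressed(pt$item1[, "w8"]),
    stringsAsFactors = FALSE)
  out$remitted_code12 <- favourable_to_code12(out$remitted)
  out$response_code12 <- favourable_to_code12(out$response_binary)
  out$stem_code12 <- favourable_to_code12(out$stem_depressed)
  rownames(out) <- NULL
  out
}
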