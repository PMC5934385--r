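# One proper-imputation regression draw: fit y ~ X on complete rows, draw
# sigma^2 from its scaled inverse-chi-square posterior and beta from its
# normal posterior, then return predictive draws for the target rows.
draw_regression_imputes <- function(y, X, X_new) {
  fit <- lm.fit(X, y)
  df <- length(y) - fit$rank
  if (df < 1) df <- 1
  s2 <- sum(fit$residuals^2) / df
  sigma2 <- s2 * df / rchisq(1, df)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  XtXinv <- chol2inv(R)
  beta <- fit$coefficients[piv] +
    drop(crossprod(chol(sigma2 * XtXinv), rnorm(fit$rank)))
  drop(X_new[, piv, drop = FALSE] %*% beta) + rnorm(nrow(X_new), 0, sqrt(sigma2))
}

#' Multiple imputation of missing HRSD follow-ups
#'
#' Creates `m` completed panels by chained-equation regression on timepoint
#' totals: each incomplete timepoint total is regressed on the other three
#' totals plus age and sex among subjects observed at that timepoint, and
#' missing totals are replaced by proper predictive draws (posterior draws of
#' the coefficients and residual variance, plus residual noise). The chain is
#' initialised from a baseline-only model and swept `n_iter` times. Imputed
#' totals are rounded and clipped to [0, 66]; item 1 is imputed as the
#' monotone bin of the imputed total and the remaining items spread the
#' residual deterministically, so completed panels are valid panels. Observed
#' cells are identical across all `m` panels.
#'
#' @param panel an `hrsd_panel` with baseline observed for every subject.
#' @param covariates `data.frame` with `sample_id`, `age`, `sex` covering all
#'   subjects.
#' @param m number of imputed datasets (default 30).
#' @param n_iter chained-update sweeps per dataset (default 10).
#' @param seed integer seed.
#' @return an `imputation_result`: list with `panels` (list of m completed
#'   panels), `m`, `seed`, `n_iter`.
#' @export
multiple_impute <- function(panel, covariates, m = 30L, n_iter = 10L,
                            seed = 1L) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  pt <- panel_totals(panel)
  tot <- pt$totals
  subjects <- rownames(tot)
  cov <- covariates[match(subjects, covariates$sample_id), ]
  if (anyNA(cov$age) || anyNA(cov$sex))
    stop("age and sex required for every subject", call. = FALSE)
  sexf <- as.numeric(cov$sex == "F")
  age <- as.numeric(cov$age)
  tps <- c("w2", "w4", "w8")
  need <- lapply(tps, function(tp) which(is.na(tot[, tp])))
  names(need) <- tps

  panels <- vector("list", m)
  for (r in seq_len(m)) {
    set.seed(substream_seed(seed, r))
    cur <- tot
    if (all(lengths(need) == 0)) {
      panels[[r]] <- panel
      next
    }
    # initialise from baseline + covariates
    for (tp in tps) {
      idx <- need[[tp]]
      if (!length(idx)) next
      obs <- which(!is.na(tot[, tp]))
      X <- cbind(1, tot[, "bl"], age, sexf)
      cur[idx, tp] <- draw_regression_imputes(tot[obs, tp],
                                              X[obs, , drop = FALSE],
                                              X[idx, , drop = FALSE])
    }
    for (it in seq_len(n_iter)) {
      for (tp in tps) {
        idx <- need[[tp]]
        if (!length(idx)) next
        others <- setdiff(colnames(tot), tp)
        obs <- which(!is.na(tot[, tp]))
        X <- cbind(1, cur[, others, drop = FALSE], age, sexf)
        cur[idx, tp] <- draw_regression_imputes(tot[obs, tp],
                                                X[obs, , drop = FALSE],
                                                X[idx, , drop = FALSE])
      }
    }
    cur[] <- as.integer(pmin(66, pmax(0, round(cur))))
    panels[[r]] <- fill_panel(panel, cur, pt$item1)
  }
  structure(list(panels = panels, m = m, seed = seed, n_iter = n_iter),
            class = "imputation_result")
}

# Rebuild a completed long panel: observed visits are copied bit-exactly,
# imputed visits get item 1 from the monotone bin of the imputed total and a
# deterministic spread of the remainder.
fill_panel <- function(panel, totals, item1_obs) {
  out <- panel
  subjects <- rownames(totals)
  for (tp in c("w2", "w4", "w8")) {
    miss_subj <- subjects[is.na(item1_obs[, tp])]
    if (!length(miss_subj)) next
    idx <- which(out$timepoint == tp & out$subject_id %in% miss_subj)
    tt <- as.integer(totals[out$subject_id[idx], tp])
    it1 <- item1_from_total(tt)
    items <- t(vapply(seq_along(idx),
                      function(i) c(it1[i], spread_items(tt[i], it1[i])),
                      integer(21)))
    out[idx, item_cols] <- items
  }
  out
}

#' @exportS3Method base::print
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> m = %d completed panels (seed %s, %d sweeps)\n",
              x$m, format(x$seed), x$n_iter))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance. The Wald p-value uses the standard small-m
#' degrees-of-freedom adjustment `(m - 1) (1 + ubar / ((1 + 1/m) b))^2`
#' (normal reference when the between-variance is zero).
#'
#' @param estimates,ses numeric vectors of per-imputation estimates and
#'   standard errors (length m >= 2, all finite).
#' @return list: `estimate`, `se`, `statistic`, `df`, `p`, `m`,
#'   `between_var`, `within_var`.
#' @export
pool_rubin <- function(estimates, ses) {
  m <- length(estimates)
  if (m < 2) stop("at least two imputations required", call. = FALSE)
  if (any(!is.finite(estimates)) || any(!is.finite(ses)))
    stop("non-finite estimate or standard error", call. = FALSE)
  qbar <- mean(estimates)
  ubar <- mean(ses^2)
  b <- var(estimates)
  total <- ubar + (1 + 1 / m) * b
  se <- sqrt(total)
  stat <- qbar / se
  if (b > 0) {
    df <- (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2
    p <- 2 * pt(-abs(stat), df)
  } else {
    df <- Inf
    p <- 2 * pnorm(-abs(stat))
  }
  list(estimate = qbar, se = se, statistic = stat, df = df, p = p, m = m,
       between_var = b, within_var = ubar)
}
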