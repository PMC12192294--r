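#' Early-debut indicator
#'
#' 1 if and only if the event was observed before age 15. Censored records
#' are all aged 15 or more at interview, so a censored record cannot have
#' debuted before 15 and scores 0.
#'
#' @param records cohort data frame with `time_years` and `event`.
#' @param cutoff age cutoff in years (default 15).
#' @return Integer 0/1 vector.
#' @export
early_debut_indicator <- function(records, cutoff = 15) {
  as.integer(records$event == 1 & records$time_years < cutoff)
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator over distinct event times; tied events
#' are pooled at their common time and censorings at an event time remain in
#' the risk set for that event. Standard errors are Greenwood's.
#'
#' @param records data frame with `time_years` and `event`.
#' @param stratum optional label used in error messages and output.
#' @return Object of class `km_curve`: data frame with columns `time`,
#'   `at_risk`, `events`, `survival`, `se` and attribute `stratum`.
#' @export
km_estimate <- function(records, stratum = "all") {
  t <- records$time_years
  d <- records$event
  if (sum(d) < 1) stop("no events in stratum '", stratum, "'")
  et <- sort(unique(t[d == 1]))
  n_at <- vapply(et, function(u) sum(t >= u), numeric(1))
  d_at <- vapply(et, function(u) sum(t == u & d == 1), numeric(1))
  surv <- cumprod(1 - d_at / n_at)
  gw <- cumsum(d_at / (n_at * pmax(n_at - d_at, .Machine$double.eps)))
  se <- surv * sqrt(gw)
  out <- data.frame(time = et, at_risk = n_at, events = d_at,
                    survival = surv, se = se)
  attr(out, "stratum") <- stratum
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival time from a Kaplan-Meier curve
#'
#' Smallest event time at which the survival estimate drops to 0.5 or below;
#' `NA` (printed as "not reached") when the curve never crosses 0.5.
#'
#' @param curve a `km_curve`.
#' @return Numeric scalar (years), or `NA_real_` if not reached.
#' @export
survival_median <- function(curve) {
  hit <- which(curve$survival <= 0.5)
  if (length(hit) == 0L) return(NA_real_)
  curve$time[hit[1L]]
}

#' K-group log-rank test
#'
#' Classical (unweighted) log-rank: observed-minus-expected event counts per
#' group accumulated over pooled event times, with the hypergeometric
#' variance; the statistic is the quadratic form on K-1 groups and the
#' p-value comes from a chi-square with K-1 degrees of freedom.
#'
#' @param records data frame with `time_years`, `event` and the grouping
#'   column.
#' @param group name of the grouping covariate.
#' @return List of class `logrank_result`: `statistic`, `df`, `p_value`,
#'   and the per-group observed/expected table.
#' @export
logrank_test <- function(records, group) {
  g <- as.character(records[[group]])
  lev <- sort(unique(g))
  K <- length(lev)
  if (K < 2) stop("log-rank needs at least 2 groups")
  counts <- table(factor(g, levels = lev))
  if (any(counts == 0)) stop("group with zero records: ", lev[counts == 0][1])
  t <- records$time_years
  d <- records$event
  if (sum(d) < 1) stop("no events overall")
  et <- sort(unique(t[d == 1]))
  O <- stats::setNames(numeric(K), lev)
  E <- stats::setNames(numeric(K), lev)
  V <- matrix(0, K, K, dimnames = list(lev, lev))
  for (u in et) {
    at <- t >= u
    nj <- sum(at)
    dj <- sum(t == u & d == 1)
    ngj <- vapply(lev, function(l) sum(at & g == l), numeric(1))
    dgj <- vapply(lev, function(l) sum(t == u & d == 1 & g == l), numeric(1))
    O <- O + dgj
    E <- E + dj * ngj / nj
    if (nj > 1) {
      f <- dj * (nj - dj) / (nj - 1)
      pg <- ngj / nj
      V <- V + f * (diag(pg, K) - tcrossprod(pg))
    }
  }
  idx <- seq_len(K - 1L)
  ome <- (O - E)[idx]
  stat <- drop(t(ome) %*% solve(V[idx, idx, drop = FALSE], ome))
  res <- list(statistic = stat, df = K - 1L,
              p_value = stats::pchisq(stat, K - 1L, lower.tail = FALSE),
              observed = O, expected = E)
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 4),
      "on", x$df, "df, p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Early-debut prevalence table with Pearson chi-square
#'
#' Per level of a covariate: unweighted counts of early debut yes/no and
#' survey-weighted row percentages; the chi-square of independence is
#' computed on the unweighted level-by-outcome contingency table without
#' continuity correction. Weighted percentages alongside unweighted counts
#' mirror the reporting convention of weighted household surveys.
#'
#' @param records cohort data frame (needs `weight`).
#' @param covariate name of the categorical covariate.
#' @param cutoff early-debut age cutoff in years.
#' @return Data frame of class `prevalence_table` with one row per level and
#'   attributes `chi2`, `p_value`, `dropped_levels`.
#' @export
prevalence_table <- function(records, covariate, cutoff = 15) {
  if (!covariate %in% names(records)) stop("covariate not present: ", covariate)
  keep <- !is.na(records[[covariate]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " records with missing '", covariate, "' excluded")
  }
  rec <- records[keep, ]
  y <- early_debut_indicator(rec, cutoff)
  g <- rec[[covariate]]
  lev_all <- if (is.factor(g)) levels(g) else sort(unique(as.character(g)))
  g <- as.character(g)
  empty <- lev_all[!lev_all %in% g]
  if (length(empty) > 0) {
    warning("levels with zero records dropped: ", paste(empty, collapse = ", "))
  }
  lev <- setdiff(lev_all, empty)
  rows <- lapply(lev, function(l) {
    sel <- g == l
    w <- rec$weight[sel]
    yl <- y[sel]
    wy <- sum(w[yl == 1]); wn <- sum(w[yl == 0])
    data.frame(covariate = covariate, level = l, n = sum(sel),
               yes_n = sum(yl == 1), yes_pct_weighted = 100 * wy / (wy + wn),
               no_n = sum(yl == 0), no_pct_weighted = 100 * wn / (wy + wn))
  })
  out <- do.call(rbind, rows)
  tab <- table(factor(g, levels = lev), factor(y, levels = c(1, 0)))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out$chi2 <- unname(chi$statistic)
  out$p <- unname(chi$p.value)
  attr(out, "chi2") <- unname(chi$statistic)
  attr(out, "p_value") <- unname(chi$p.value)
  attr(out, "dropped_levels") <- empty
  class(out) <- c("prevalence_table", "data.frame")
  out
}
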