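#' Fit a Cox proportional-hazards model by weighted partial likelihood
#'
#' Newton-Raphson maximization of the (optionally survey-weighted) log
#' partial likelihood with Breslow handling of tied event times. Breslow
#' ties are used throughout the package because the Breslow baseline is what
#' the Poisson-offset reduction plugs in as the offset; with integer-year
#' ages ties are heavy and this choice is material.
#'
#' Survey weights are normalized to mean 1 before fitting, so fits are
#' invariant to the weights' arbitrary scale and an equal-weight fit
#' coincides exactly with the unweighted one.
#'
#' @param records data frame with `time_years`, `event`, `weight` and
#'   covariate columns.
#' @param covariates character vector of categorical covariate names
#'   (dummy-coded against `ref_levels`).
#' @param ref_levels named list of reference levels per covariate.
#' @param use_weights use the survey weights (default TRUE).
#' @param include_coords add centered `lat` and `lon` linear columns to the
#'   design, as in geoadditive reporting.
#' @param control list: `maxit` (50), `score_tol` (1e-8), `ll_tol` (1e-10).
#' @return Object of class `cox_offset_fit` with elements `beta`, `vcov`,
#'   `loglik`, `iterations`, `converged`, plus the design internals used by
#'   [breslow_cumhaz()].
#' @export
fit_cox <- function(records, covariates = character(), ref_levels = NULL,
                    use_weights = TRUE, include_coords = FALSE,
                    control = list()) {
  ctl <- utils::modifyList(list(maxit = 50L, score_tol = 1e-8,
                                ll_tol = 1e-10), control)
  t <- records$time_years
  d <- records$event
  stopifnot(all(d %in% c(0, 1)), all(t > 0))
  if (sum(d) < 1) stop("no events: cannot fit a Cox model")
  w <- if (use_weights) records$weight else rep(1, nrow(records))
  w <- w / mean(w)

  X <- dummy_design(records, covariates, ref_levels)
  centers <- NULL
  if (include_coords) {
    centers <- c(lat = mean(records$lat), lon = mean(records$lon))
    X <- cbind(X, lat = records$lat - centers["lat"],
               lon = records$lon - centers["lon"])
  }
  p <- ncol(X)
  if (p > 0) {
    qx <- qr(X)
    if (qx$rank < p) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
      stop("design matrix is rank deficient; collinear columns: ",
           paste(bad, collapse = ", "))
    }
  }

  ord <- order(t, decreasing = TRUE)
  ts <- t[ord]; ds <- d[ord]; ws <- w[ord]
  Xs <- X[ord, , drop = FALSE]
  eu <- sort(unique(ts[ds == 1]), decreasing = TRUE)
  m_u <- vapply(eu, function(u) sum(ts >= u), numeric(1))
  # weighted event sums per unique event time
  Wd <- vapply(eu, function(u) sum(ws[ts == u & ds == 1]), numeric(1))
  Sx <- t(vapply(eu, function(u) {
    sel <- ts == u & ds == 1
    if (p == 0) return(numeric(0))
    colSums(Xs[sel, , drop = FALSE] * ws[sel])
  }, numeric(p)))
  if (p == 1) Sx <- matrix(Sx, ncol = 1)

  pll <- function(beta) {
    eta <- if (p > 0) drop(Xs %*% beta) else numeric(length(ts))
    r <- ws * exp(eta)
    cr <- cumsum(r)
    ll <- sum(if (p > 0) Sx %*% beta else 0) - sum(Wd * log(cr[m_u]))
    score <- if (p > 0) {
      crx <- apply(r * Xs, 2, cumsum)
      if (p == 1) crx <- matrix(crx, ncol = 1)
      colSums(Sx) - colSums(Wd * crx[m_u, , drop = FALSE] / cr[m_u])
    } else numeric(0)
    info <- matrix(0, p, p)
    if (p > 0) {
      crx <- apply(r * Xs, 2, cumsum)
      if (p == 1) crx <- matrix(crx, ncol = 1)
      for (a in seq_len(p)) {
        for (b in a:p) {
          cab <- cumsum(r * Xs[, a] * Xs[, b])
          xbar_a <- crx[m_u, a] / cr[m_u]
          xbar_b <- crx[m_u, b] / cr[m_u]
          v <- sum(Wd * (cab[m_u] / cr[m_u] - xbar_a * xbar_b))
          info[a, b] <- v; info[b, a] <- v
        }
      }
    }
    list(ll = ll, score = score, info = info)
  }

  beta <- rep(0, p)
  obj <- pll(beta)
  iter <- 0L
  converged <- p == 0L
  trace <- numeric(0)
  while (!converged && iter < ctl$maxit) {
    iter <- iter + 1L
    step <- solve(obj$info, obj$score)
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + step / 2^h
      cobj <- pll(cand)
      if (is.finite(cobj$ll) && cobj$ll >= obj$ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) stop("partial-likelihood step failed at iteration ", iter)
    rel_ll <- abs(cobj$ll - obj$ll) / (abs(obj$ll) + 1e-12)
    beta <- cand; obj <- cobj
    trace <- c(trace, obj$ll)
    if (max(abs(obj$score)) < ctl$score_tol || rel_ll < ctl$ll_tol) {
      converged <- TRUE
    }
  }
  if (!converged) {
    stop("Cox fit did not converge in ", ctl$maxit,
         " iterations; log-likelihood trace: ",
         paste(format(trace, digits = 8), collapse = ", "))
  }
  vc <- if (p > 0) solve(obj$info) else matrix(numeric(0), 0, 0)
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, vcov = vc, loglik = obj$ll,
                 iterations = iter, converged = converged,
                 covariates = covariates, ref_levels = ref_levels,
                 include_coords = include_coords, coord_centers = centers,
                 X = X, time = t, event = d, w = w),
            class = "cox_offset_fit")
}

#' @export
print.cox_offset_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties, weighted partial likelihood)\n")
  cat("  log partial likelihood:", format(x$loglik, digits = 8),
      " iterations:", x$iterations, "\n")
  if (length(x$beta)) {
    se <- sqrt(diag(x$vcov))
    print(data.frame(beta = x$beta, se = se, HR = exp(x$beta)), digits = 4)
  }
  invisible(x)
}

#' Breslow cumulative baseline hazard
#'
#' Step-function estimate with increments (weighted) events over the
#' weighted risk-set sum of `exp(x'beta)` at each distinct event time,
#' evaluated at each record's own observed duration.
#'
#' @param fit a `cox_offset_fit`.
#' @param records optional records to evaluate at (defaults to the fit data,
#'   which must then be row-aligned with the fit internals).
#' @return List of class `breslow_cumhaz`: `time` and `cumhaz` (the step
#'   function, ascending), and `Lambda_i` per record.
#' @export
breslow_cumhaz <- function(fit, records = NULL) {
  t <- fit$time
  d <- fit$event
  w <- fit$w
  eta <- if (length(fit$beta)) drop(fit$X %*% fit$beta) else numeric(length(t))
  r <- w * exp(eta)
  eu <- sort(unique(t[d == 1]))
  inc <- vapply(eu, function(u) {
    sum(w[t == u & d == 1]) / sum(r[t >= u])
  }, numeric(1))
  cumhaz <- cumsum(inc)
  sf <- stats::stepfun(eu, c(0, cumhaz), right = FALSE)
  t_eval <- if (is.null(records)) t else records$time_years
  structure(list(time = eu, cumhaz = cumhaz, Lambda_i = sf(t_eval),
                 stepfun = sf), class = "breslow_cumhaz")
}

# Observed information of the weighted Breslow log partial likelihood for a
# design C at coefficients theta, accumulated over distinct event times with
# batched risk-set sums (rows processed in decreasing time order).
partial_info <- function(C, time, event, w, theta) {
  C <- as.matrix(C)
  q <- ncol(C)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]; ds <- event[ord]; ws <- w[ord]
  Cs <- C[ord, , drop = FALSE]
  r <- ws * exp(drop(Cs %*% theta))
  eu <- sort(unique(ts[ds == 1]), decreasing = TRUE)
  S0 <- 0; S1 <- numeric(q); S2 <- matrix(0, q, q)
  info <- matrix(0, q, q)
  pos <- 1L
  n <- length(ts)
  for (u in eu) {
    last <- pos
    while (last <= n && ts[last] >= u) last <- last + 1L
    if (last > pos) {
      idx <- pos:(last - 1L)
      Cb <- Cs[idx, , drop = FALSE]
      rb <- r[idx]
      S0 <- S0 + sum(rb)
      S1 <- S1 + colSums(Cb * rb)
      S2 <- S2 + crossprod(Cb, Cb * rb)
      pos <- last
    }
    Wd <- sum(ws[ts == u & ds == 1])
    xbar <- S1 / S0
    info <- info + Wd * (S2 / S0 - tcrossprod(xbar))
  }
  info
}

#' Reduce censored survival records to a Poisson frame with known offsets
#'
#' The counting process evaluated at the end of follow-up makes the event
#' indicator the Poisson response and the log cumulative baseline hazard the
#' known offset. Records censored before the first event time have zero
#' cumulative hazard (offset of minus infinity) and are dropped with a
#' logged count.
#'
#' @param records cohort data frame.
#' @param cumhaz a `breslow_cumhaz` evaluated for these records.
#' @return Data frame of class `poisson_frame` with columns `id`, `N`,
#'   `offset`, `weight`, `lon`, `lat`, `cluster` and the covariate columns;
#'   attribute `n_dropped` counts excluded records.
#' @export
to_poisson_frame <- function(records, cumhaz) {
  L <- cumhaz$Lambda_i
  stopifnot(length(L) == nrow(records))
  keep <- L > 0
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " records censored before the first event time dropped")
  }
  if (!any(keep)) stop("all records dropped: no positive cumulative hazard")
  out <- records[keep, , drop = FALSE]
  out$N <- out$event
  out$offset <- log(L[keep])
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("poisson_frame", "data.frame")
  out
}
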