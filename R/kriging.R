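#' Ruppert's knot-count rule
#'
#' `K = max(20, min(floor(n/4), 150))`: enough knots to resolve spatial
#' structure at small n, capped for large surveys.
#'
#' @param n number of observations (>= 1).
#' @return Integer knot count in `[20, 150]`.
#' @export
knot_count <- function(n) {
  stopifnot(n >= 1)
  as.integer(max(20, min(floor(n / 4), 150)))
}

#' Space-filling knot selection
#'
#' Greedy max-min ("coffee-house") initialization followed by pairwise swap
#' improvement of the minimum inter-knot distance until no single swap
#' improves it. Deterministic given the seed (which picks the greedy start).
#'
#' @param candidates two-column matrix of candidate locations (duplicates
#'   collapsed before selection).
#' @param K number of knots.
#' @param seed integer seed.
#' @return Object of class `knot_set`: `knots` (K x 2 matrix), `objective`
#'   (minimum inter-knot distance) and `seed`.
#' @export
select_knots <- function(candidates, K, seed = 1L) {
  cand <- unique(as.matrix(candidates)[, 1:2, drop = FALSE])
  n <- nrow(cand)
  if (n < K) stop("fewer distinct candidate locations (", n, ") than knots (", K, ")")
  if (n == K) {
    sel <- seq_len(n)
  } else {
    D <- as.matrix(stats::dist(cand))
    set.seed(seed)
    sel <- sample.int(n, 1L)
    mind <- D[, sel]
    while (length(sel) < K) {
      nxt <- which.max(mind)
      sel <- c(sel, nxt)
      mind <- pmin(mind, D[, nxt])
    }
    obj <- function(s) min(D[s, s][upper.tri(diag(length(s)))])
    cur <- obj(sel)
    repeat {
      improved <- FALSE
      out_set <- setdiff(seq_len(n), sel)
      for (i in seq_along(sel)) {
        for (j in out_set) {
          trial <- sel
          trial[i] <- j
          val <- obj(trial)
          if (val > cur + 1e-15) {
            sel <- trial
            cur <- val
            improved <- TRUE
            out_set <- setdiff(seq_len(n), sel)
          }
        }
      }
      if (!improved) break
    }
  }
  knots <- cand[sel, , drop = FALSE]
  colnames(knots) <- c("lon", "lat")
  objective <- if (K > 1) {
    min(stats::dist(knots))
  } else Inf
  structure(list(knots = knots, objective = objective, seed = seed),
            class = "knot_set")
}

#' Generalized covariance functions for low-rank kriging
#'
#' Isotropic members of the Matern family and relatives, all normalized to
#' 1 at distance zero with range parameter `tau` a length scale:
#' \describe{
#'   \item{exponential}{\eqn{e^{-h/\tau}}}
#'   \item{gaussian}{\eqn{e^{-h^2/\tau^2}}}
#'   \item{matern}{\eqn{(1 + h/\tau)e^{-h/\tau}} (smoothness 3/2)}
#'   \item{spherical}{\eqn{(1 - 1.5h/\tau + 0.5h^3/\tau^3)\,1[h<\tau]}}
#'   \item{circular}{\eqn{(2/\pi)(\arccos\vartheta - \vartheta\sqrt{1-\vartheta^2})},
#'     \eqn{\vartheta = \min(h/\tau, 1)}}
#'   \item{inverse_quadratic}{\eqn{1/(1 + h^2/\tau^2)}}
#' }
#'
#' @param family one of the six family names.
#' @param tau range parameter (> 0).
#' @param h non-negative distance(s).
#' @return Covariance value(s), vectorized over `h`.
#' @export
gcov <- function(family, tau, h) {
  family <- match.arg(family, gcov_families())
  if (!(tau > 0)) stop("range parameter tau must be positive")
  if (any(h < 0)) stop("distances must be non-negative")
  r <- h / tau
  switch(family,
    exponential = exp(-r),
    gaussian = exp(-r^2),
    matern = (1 + r) * exp(-r),
    spherical = ifelse(r < 1, 1 - 1.5 * r + 0.5 * r^3, 0),
    circular = {
      v <- pmin(r, 1)
      (2 / pi) * (acos(v) - v * sqrt(pmax(1 - v^2, 0)))
    },
    inverse_quadratic = 1 / (1 + r^2)
  )
}

#' @rdname gcov
#' @export
gcov_families <- function() {
  c("exponential", "gaussian", "matern", "spherical", "circular",
    "inverse_quadratic")
}

#' Build the low-rank kriging spline basis Z
#'
#' `Z = C(s, kappa) C(kappa, kappa)^{-1/2}` with the inverse square root
#' taken by symmetric eigendecomposition; eigenvalues below
#' `1e-10 * lambda_max` are floored and their directions contribute zero,
#' which keeps the basis finite for near-singular knot covariances (for
#' example a Gaussian family at very large range).
#'
#' @param locations n x 2 matrix of data locations.
#' @param knots a `knot_set` (or bare K x 2 matrix).
#' @param family covariance family name.
#' @param tau range parameter.
#' @return n x K numeric matrix.
#' @export
build_Z <- function(locations, knots, family, tau) {
  kap <- if (inherits(knots, "knot_set")) knots$knots else as.matrix(knots)
  Csk <- gcov(family, tau, cross_dist(as.matrix(locations)[, 1:2, drop = FALSE], kap))
  Ckk <- gcov(family, tau, cross_dist(kap, kap))
  Ckk <- (Ckk + t(Ckk)) / 2
  eg <- eigen(Ckk, symmetric = TRUE)
  lmax <- max(eg$values)
  if (lmax <= 0) {
    stop("knot covariance has no positive eigenvalues (family ", family,
         ", tau ", format(tau), ")")
  }
  keep <- eg$values > 1e-10 * lmax
  M <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / sqrt(eg$values[keep]))
  Z <- Csk %*% M
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  Z
}

#' Covariance specification
#'
#' @param family family name (see [gcov_families()]).
#' @param tau range parameter.
#' @export
cov_spec <- function(family, tau) {
  family <- match.arg(family, gcov_families())
  if (!(tau > 0)) stop("range parameter tau must be positive")
  structure(list(family = family, tau = tau), class = "cov_spec")
}

#' Assemble the geoadditive design matrices
#'
#' Fixed effects X are the dummy-coded covariates plus raw latitude and
#' longitude columns, each coordinate centered at its mean; there is no
#' intercept because the Poisson offset (the baseline hazard) already
#' carries it. Z is the low-rank kriging basis at the frame's locations.
#'
#' @param frame a `poisson_frame` (from [to_poisson_frame()]).
#' @param covariates character vector of covariate names.
#' @param ref_levels named list of reference levels.
#' @param knots a `knot_set`.
#' @param spec a `cov_spec`.
#' @return Object of class `basis_matrices`: `X`, `Z`, `y`, `offset`, `w`,
#'   `locations`, `coord_centers`, `knots`, `spec`.
#' @export
assemble_design <- function(frame, covariates, ref_levels, knots, spec) {
  Xc <- dummy_design(frame, covariates, ref_levels)
  centers <- c(lat = mean(frame$lat), lon = mean(frame$lon))
  X <- cbind(Xc, lat = frame$lat - centers["lat"],
             lon = frame$lon - centers["lon"])
  loc <- cbind(lon = frame$lon, lat = frame$lat)
  Z <- build_Z(loc, knots, spec$family, spec$tau)
  structure(list(X = X, Z = Z, y = frame$N, offset = frame$offset,
                 w = frame$weight, time = frame$time_years,
                 locations = loc, coord_centers = centers,
                 knots = knots, spec = spec,
                 covariates = covariates, ref_levels = ref_levels),
            class = "basis_matrices")
}
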