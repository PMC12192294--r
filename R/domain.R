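#' Define a rectangular study domain with an optional polygon mask
#'
#' The domain is the geographic support on which enumeration-area (cluster)
#' locations live and over which spatial surfaces are predicted. Coordinates
#' are generic planar (lon, lat) pairs; for low-latitude study areas raw
#' degrees are an adequate planar approximation.
#'
#' @param xlim,ylim numeric length-2 bounds (lon and lat axes).
#' @param mask optional two-column matrix of polygon vertices (a closed ring;
#'   the last vertex may repeat the first) lying inside the bounds.
#' @return An object of class `study_domain`.
#' @export
study_domain <- function(xlim = c(0, 1), ylim = c(0, 1), mask = NULL) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L)
  if (!(diff(xlim) > 0 && diff(ylim) > 0)) {
    stop("domain bounds are degenerate: both axes need positive extent")
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (ncol(mask) != 2L || nrow(mask) < 3L) {
      stop("mask must be a polygon with at least 3 vertices (two columns)")
    }
    if (any(mask[, 1] < xlim[1] - 1e-12) || any(mask[, 1] > xlim[2] + 1e-12) ||
        any(mask[, 2] < ylim[1] - 1e-12) || any(mask[, 2] > ylim[2] + 1e-12)) {
      stop("mask polygon must lie within the domain bounds")
    }
    # drop a repeated closing vertex; in.out expects an open ring
    if (isTRUE(all.equal(mask[1, ], mask[nrow(mask), ]))) {
      mask <- mask[-nrow(mask), , drop = FALSE]
    }
  }
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim), mask = mask),
            class = "study_domain")
}

#' Build a study domain from point locations using their convex hull
#'
#' @param points two-column matrix or data frame of (lon, lat) locations.
#' @param hull logical; use the convex hull of the points as mask.
#' @param expand fractional margin added to the bounding box.
#' @return A `study_domain`.
#' @export
domain_from_points <- function(points, hull = TRUE, expand = 0.02) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  rx <- range(p[, 1]); ry <- range(p[, 2])
  mx <- expand * max(diff(rx), diff(ry), .Machine$double.eps)
  mask <- NULL
  if (hull) mask <- p[grDevices::chull(p), , drop = FALSE]
  study_domain(xlim = rx + c(-mx, mx), ylim = ry + c(-mx, mx), mask = mask)
}

#' Test whether points fall inside the domain (bounds and mask)
#'
#' @param domain a `study_domain`.
#' @param points two-column matrix of (lon, lat).
#' @return Logical vector.
#' @export
in_domain <- function(domain, points) {
  p <- as.matrix(points)
  ok <- p[, 1] >= domain$xlim[1] & p[, 1] <= domain$xlim[2] &
    p[, 2] >= domain$ylim[1] & p[, 2] <= domain$ylim[2]
  if (!is.null(domain$mask)) {
    ok <- ok & point_in_polygon(domain$mask, p)
  }
  ok
}

# Boundary-inclusive even-odd point-in-polygon test: points on an edge (to
# within a relative tolerance) count as inside, so lattice points falling
# exactly on a mask boundary are retained.
point_in_polygon <- function(poly, pts, tol = 1e-9) {
  poly <- as.matrix(poly)
  pts <- as.matrix(pts)
  nv <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  scale <- max(abs(poly), 1)
  inside <- rep(FALSE, nrow(pts))
  on_edge <- rep(FALSE, nrow(pts))
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    # on-segment check via cross product and bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within <- px >= pmin(x1, x2) - tol * scale & px <= pmax(x1, x2) + tol * scale &
      py >= pmin(y1, y2) - tol * scale & py <= pmax(y1, y2) + tol * scale
    on_edge <- on_edge | (abs(cross) <= tol * scale^2 & within)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Sample cluster (enumeration-area) locations uniformly over the domain
#'
#' Every person assigned to a cluster later shares its point exactly,
#' mirroring surveys that geolocate at the enumeration-area level.
#'
#' @param n_clusters number of clusters (>= 1).
#' @param domain a `study_domain`.
#' @param seed integer seed.
#' @return `n_clusters` x 2 matrix with columns `lon`, `lat`.
#' @export
sample_cluster_locations <- function(n_clusters, domain, seed = 1L) {
  stopifnot(n_clusters >= 1)
  set.seed(seed)
  out <- matrix(NA_real_, n_clusters, 2, dimnames = list(NULL, c("lon", "lat")))
  filled <- 0L
  tries <- 0L
  while (filled < n_clusters) {
    m <- max(2L * (n_clusters - filled), 100L)
    cand <- cbind(stats::runif(m, domain$xlim[1], domain$xlim[2]),
                  stats::runif(m, domain$ylim[1], domain$ylim[2]))
    keep <- cand[in_domain(domain, cand), , drop = FALSE]
    if (nrow(keep) > 0) {
      k <- min(nrow(keep), n_clusters - filled)
      out[(filled + 1L):(filled + k), ] <- keep[seq_len(k), ]
      filled <- filled + k
    }
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("mask appears to have empty intersection with the domain bounds")
    }
  }
  out
}

#' Specify a smooth ground-truth spatial log-hazard field
#'
#' The field is a sum of Gaussian radial bumps,
#' \eqn{S(p) = \sum_j a_j \exp(-\|p - c_j\|^2 / (2 w_j^2))}, optionally
#' centred to mean zero over a reference grid on the domain so that the
#' baseline hazard keeps its interpretation.
#'
#' @param bumps list of bumps, each `list(center = c(x, y), amplitude, width)`.
#' @param center logical; centre the field over the reference grid.
#' @param domain `study_domain` used for the reference grid (required when
#'   `center = TRUE`).
#' @param ref_n reference-grid resolution per axis.
#' @return Object of class `field_spec`.
#' @export
field_spec <- function(bumps = list(), center = TRUE, domain = NULL,
                       ref_n = 101L) {
  for (b in bumps) {
    stopifnot(length(b$center) == 2L, is.numeric(b$amplitude))
    if (!(b$width > 0)) stop("bump widths must be positive")
  }
  spec <- structure(list(bumps = bumps, center = FALSE, offset = 0),
                    class = "field_spec")
  if (center) {
    if (is.null(domain)) stop("centering requires a domain for the reference grid")
    gx <- seq(domain$xlim[1], domain$xlim[2], length.out = ref_n)
    gy <- seq(domain$ylim[1], domain$ylim[2], length.out = ref_n)
    grid <- cbind(rep(gx, times = ref_n), rep(gy, each = ref_n))
    if (!is.null(domain$mask)) grid <- grid[in_domain(domain, grid), , drop = FALSE]
    spec$offset <- mean(evaluate_true_field(grid, spec))
    spec$center <- TRUE
  }
  spec
}

#' Evaluate the ground-truth spatial field at points
#'
#' @param points two-column matrix of (lon, lat).
#' @param spec a `field_spec`.
#' @return Numeric vector of log-hazard values.
#' @export
evaluate_true_field <- function(points, spec) {
  p <- as.matrix(points)
  if (length(p) == 0L) return(numeric(0))
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  val <- numeric(nrow(p))
  for (b in spec$bumps) {
    d2 <- (p[, 1] - b$center[1])^2 + (p[, 2] - b$center[2])^2
    val <- val + b$amplitude * exp(-d2 / (2 * b$width^2))
  }
  val - spec$offset
}
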