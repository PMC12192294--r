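#' Regular prediction lattice over a study domain
#'
#' @param domain a `study_domain`.
#' @param resolution points per axis (>= 2); a single number or length 2.
#' @return Data frame of class `prediction_grid` with columns `lon`, `lat`,
#'   `masked` (TRUE for points outside the domain mask).
#' @export
make_grid <- function(domain, resolution = 100L) {
  res <- rep(as.integer(resolution), length.out = 2L)
  if (any(res < 2)) stop("resolution must be at least 2 per axis")
  gx <- seq(domain$xlim[1], domain$xlim[2], length.out = res[1])
  gy <- seq(domain$ylim[1], domain$ylim[2], length.out = res[2])
  grid <- data.frame(lon = rep(gx, times = res[2]),
                     lat = rep(gy, each = res[1]))
  inside <- in_domain(domain, cbind(grid$lon, grid$lat))
  if (!any(inside)) stop("mask excludes every grid point")
  grid$masked <- !inside
  attr(grid, "resolution") <- res
  class(grid) <- c("prediction_grid", "data.frame")
  grid
}

#' Predict the spatial log-hazard-ratio surface
#'
#' Evaluates the fitted spatial effect — the centered-coordinate linear
#' terms plus the kriging smooth `Z(grid) u` rebuilt against the fit's own
#' knots and range — at each grid point, then mean-centers the surface over
#' the unmasked points. Only spatial contrasts are identified (the baseline
#' hazard absorbs any constant), so the map is reported on a mean-zero
#' natural-log hazard-ratio scale.
#'
#' @param fit a `geoadditive_fit` with a spatial component.
#' @param grid a `prediction_grid`.
#' @param include_linear include the linear coordinate terms (default TRUE);
#'   switch off to map the smooth alone.
#' @return Data frame of class `hazard_surface` with columns `lon`, `lat`,
#'   `log_hr`, `masked`.
#' @export
predict_log_hr <- function(fit, grid, include_linear = TRUE) {
  if (is.null(fit$knots) || fit$K == 0) {
    stop("fit has no spatial smooth to predict from")
  }
  pts <- cbind(lon = grid$lon, lat = grid$lat)
  Zg <- build_Z(pts, fit$knots, fit$family, fit$tau)
  val <- drop(Zg %*% fit$u)
  if (include_linear) {
    bs <- fit$beta[c("lat", "lon")]
    val <- val + (grid$lat - fit$coord_centers[["lat"]]) * bs[["lat"]] +
      (grid$lon - fit$coord_centers[["lon"]]) * bs[["lon"]]
  }
  val <- val - mean(val[!grid$masked])
  out <- data.frame(lon = grid$lon, lat = grid$lat, log_hr = val,
                    masked = grid$masked)
  attr(out, "resolution") <- attr(grid, "resolution")
  attr(out, "family") <- fit$family
  attr(out, "tau") <- fit$tau
  class(out) <- c("hazard_surface", "data.frame")
  out
}

#' Export a hazard surface to CSV or GeoJSON
#'
#' CSV keeps every lattice point with its masked flag; GeoJSON emits a
#' FeatureCollection of the unmasked points only, each with a `log_hr`
#' property. Numeric values are written at full precision so an
#' export/import round trip is lossless.
#'
#' @param surface a `hazard_surface`.
#' @param path output file.
#' @param format `"csv"` or `"geojson"`.
#' @export
export_surface <- function(surface, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- data.frame(lon = sprintf("%.17g", surface$lon),
                      lat = sprintf("%.17g", surface$lat),
                      log_hr = sprintf("%.17g", surface$log_hr),
                      masked = as.integer(surface$masked))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    keep <- !surface$masked
    features <- lapply(which(keep), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(surface$lon[i], surface$lat[i])),
           properties = list(log_hr = surface$log_hr[i]))
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a surface back from an exported file
#'
#' @param path file written by [export_surface()].
#' @param format `"csv"` or `"geojson"`.
#' @return A `hazard_surface` (GeoJSON imports carry only unmasked points).
#' @export
read_surface <- function(path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path)
    out <- data.frame(lon = df$lon, lat = df$lat, log_hr = df$log_hr,
                      masked = df$masked == 1)
  } else {
    j <- jsonlite::read_json(path)
    if (!identical(j$type, "FeatureCollection")) stop("not a FeatureCollection")
    out <- do.call(rbind, lapply(j$features, function(f) {
      data.frame(lon = f$geometry$coordinates[[1]],
                 lat = f$geometry$coordinates[[2]],
                 log_hr = f$properties$log_hr, masked = FALSE)
    }))
  }
  class(out) <- c("hazard_surface", "data.frame")
  out
}
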