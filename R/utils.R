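#' Derive a stage-specific random seed from a master seed
#'
#' Stage seeds are a deterministic mix of the master seed and the stage name,
#' so the pipeline needs a single user-facing seed while stages remain
#' independently reproducible.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  # all intermediates stay well below 2^53, so the modulus is exact
  as.integer((abs(master) * 1009 + h * 9176 + 17) %% 2147483629)
}

# Euclidean cross-distance matrix between two sets of points (n x 2, m x 2).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Dummy-code categorical covariates against stated reference levels.
# Returns a matrix with one indicator column per non-reference level,
# named "<covariate><level>"; no intercept.
dummy_design <- function(records, covariates, ref_levels = NULL) {
  if (length(covariates) == 0L) {
    return(matrix(numeric(0), nrow = nrow(records), ncol = 0))
  }
  cols <- list()
  for (v in covariates) {
    if (!v %in% names(records)) stop("covariate not found in records: ", v)
    x <- as.character(records[[v]])
    if (anyNA(x)) stop("missing values in covariate: ", v)
    lev <- sort(unique(x))
    if (length(lev) < 2L) {
      stop("covariate '", v, "' is constant: no information for a ",
           "hazard-ratio contrast")
    }
    ref <- if (!is.null(ref_levels) && v %in% names(ref_levels)) {
      ref_levels[[v]]
    } else {
      lev[1L]
    }
    if (!ref %in% lev) stop("reference level '", ref, "' unseen in covariate ", v)
    for (l in setdiff(lev, ref)) {
      cols[[paste0(v, l)]] <- as.numeric(x == l)
    }
  }
  do.call(cbind, cols)
}

# Significant-digit formatter used for all numeric CSV output, so that
# re-runs with the same seed are byte-identical.
fmt_sig <- function(x, digits = 12L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_numeric_csv <- function(df, path, digits = 12L) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_sig(out[[j]], digits)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
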