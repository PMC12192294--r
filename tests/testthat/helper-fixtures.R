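# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures beyond the shipped YAML example config.

unit_domain <- function() study_domain()

# Cohort with two binary covariates at hazard ratios 1.5 and 0.7 — the
# configuration used throughout the recovery and equivalence studies.
two_cov_config <- function(seed, n_clusters = 80, persons = 5,
                           rounding = FALSE, equal_weights = TRUE) {
  cohort_config(
    n_clusters = n_clusters, persons_per_cluster = persons,
    covariates = list(
      alcohol = list(levels = c("no", "yes"), probs = c(0.5, 0.5),
                     beta = c(0, log(1.5))),
      away = list(levels = c("no", "yes"), probs = c(0.5, 0.5),
                  beta = c(0, log(0.7)))),
    integer_year_rounding = rounding,
    weight_model = if (equal_weights) {
      list(dist = "uniform", min = 1, max = 1)
    } else {
      list(dist = "uniform", min = 0.2, max = 1)
    },
    seed = seed)
}

# Strong two-bump field with length scale 0.2, for spatial-recovery tests.
strong_field <- function(domain = unit_domain()) {
  field_spec(bumps = list(
    list(center = c(0.25, 0.3), amplitude = 1.0, width = 0.2),
    list(center = c(0.75, 0.7), amplitude = -1.0, width = 0.2)),
    center = TRUE, domain = domain)
}

# Tiny handmade record sets used by the hand-computed oracles.
toy_records <- function(time, event, weight = 1) {
  data.frame(id = seq_along(time), cluster = 1, lon = 0.5, lat = 0.5,
             time_years = time, event = event, weight = weight)
}

# Default calibrated cohort (seed 11, n = 5000), computed once per test run.
calibrated_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dom <- unit_domain()
      cache <<- simulate_cohort(cohort_config(seed = 11), dom,
                                default_field(dom))
    }
    cache
  }
})

# Cox-offset pipeline shorthand: records -> poisson frame + knots.
frame_and_knots <- function(records, covariates, knot_seed = 1L) {
  cf <- fit_cox(records, covariates, include_coords = TRUE)
  pf <- to_poisson_frame(records, breslow_cumhaz(cf))
  loc <- unique(cbind(pf$lon, pf$lat))
  kn <- select_knots(loc, min(knot_count(nrow(pf)), nrow(loc)),
                     seed = knot_seed)
  list(cox = cf, frame = pf, knots = kn,
       d_max = max(stats::dist(loc)))
}
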