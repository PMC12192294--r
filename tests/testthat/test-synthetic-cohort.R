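test_that("cluster locations stay in bounds and are reproducible", {
  dom <- unit_domain()
  p1 <- sample_cluster_locations(1, dom, seed = 4)
  expect_true(all(p1 >= 0 & p1 <= 1))

  a <- sample_cluster_locations(4, dom, seed = 42)
  b <- sample_cluster_locations(4, dom, seed = 42)
  expect_identical(a, b)

  big <- sample_cluster_locations(10000, dom, seed = 1)
  expect_lt(abs(mean(big[, 1]) - 0.5), 0.01)
  expect_lt(abs(mean(big[, 2]) - 0.5), 0.01)
})

test_that("masked sampling respects the polygon and rejects empty masks", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  dom <- study_domain(mask = tri)
  pts <- sample_cluster_locations(200, dom, seed = 5)
  expect_true(all(in_domain(dom, pts)))
  # a mask outside the bounds is rejected at construction
  expect_error(study_domain(xlim = c(0, 1), ylim = c(0, 1),
                            mask = rbind(c(2, 2), c(3, 2), c(2, 3))),
               "within the domain bounds")
})

test_that("true field evaluation matches the Gaussian-bump formula", {
  dom <- unit_domain()
  expect_equal(evaluate_true_field(cbind(0.3, 0.7),
                                   field_spec(center = FALSE)), 0)

  one <- field_spec(bumps = list(list(center = c(0.4, 0.6), amplitude = 1.7,
                                      width = 0.1)), center = FALSE)
  expect_equal(evaluate_true_field(cbind(0.4, 0.6), one), 1.7)

  # two symmetric bumps, centred field: direct formula evaluation as oracle
  sym <- field_spec(bumps = list(
    list(center = c(0.3, 0.3), amplitude = 0.5, width = 0.15),
    list(center = c(0.7, 0.7), amplitude = 0.5, width = 0.15)),
    center = TRUE, domain = dom)
  raw_at <- function(p) {
    0.5 * exp(-sum((p - c(0.3, 0.3))^2) / (2 * 0.15^2)) +
      0.5 * exp(-sum((p - c(0.7, 0.7))^2) / (2 * 0.15^2))
  }
  gx <- seq(0, 1, length.out = 101)
  grid <- cbind(rep(gx, times = 101), rep(gx, each = 101))
  ref_mean <- mean(0.5 * exp(-((grid[, 1] - 0.3)^2 + (grid[, 2] - 0.3)^2) / 0.045) +
                     0.5 * exp(-((grid[, 1] - 0.7)^2 + (grid[, 2] - 0.7)^2) / 0.045))
  expect_equal(evaluate_true_field(cbind(0.5, 0.5), sym),
               raw_at(c(0.5, 0.5)) - ref_mean, tolerance = 1e-10)
  # centering invariant: mean over the reference grid is zero
  expect_lt(abs(mean(evaluate_true_field(grid, sym))), 1e-10)
})

test_that("field spec rejects non-positive widths", {
  expect_error(field_spec(bumps = list(list(center = c(0, 0), amplitude = 1,
                                            width = 0)), center = FALSE),
               "widths must be positive")
})

test_that("latent debut ages follow the Weibull baseline under a null predictor", {
  dom <- unit_domain()
  cfg <- cohort_config(
    n_clusters = 100, persons_per_cluster = 100,
    covariates = list(g = list(levels = "x", probs = 1, beta = 0)),
    interview_age = c(1e6, 1e6 + 1),  # effectively no censoring
    integer_year_rounding = FALSE, seed = 7)
  coh <- simulate_cohort(cfg, dom, field_spec(center = FALSE))
  expect_true(all(coh$event == 1))
  x <- sort(coh$time_years - cfg$baseline$a0)
  # Kolmogorov-Smirnov distance against the closed-form Weibull CDF
  cdf <- pweibull(x, shape = cfg$baseline$shape, scale = cfg$baseline$scale)
  n <- length(x)
  ks <- max(pmax(abs(seq_len(n) / n - cdf), abs(cdf - (seq_len(n) - 1) / n)))
  expect_lt(ks, 0.02)
})

test_that("censoring bookkeeping is exact", {
  dom <- unit_domain()
  coh <- simulate_cohort(two_cov_config(21, rounding = FALSE), dom,
                         default_field(dom))
  lat <- attr(coh, "latent")
  expect_true(all(coh$time_years[coh$event == 1] == lat$T[coh$event == 1]))
  expect_true(all(coh$time_years[coh$event == 0] == lat$C[coh$event == 0]))
  expect_true(all(coh$time_years <= lat$C + 1e-12))
  expect_true(all(coh$time_years[coh$event == 1] >= 8))
})

test_that("integer-year rounding never flips event status", {
  dom <- unit_domain()
  a <- simulate_cohort(two_cov_config(33, rounding = FALSE), dom,
                       default_field(dom))
  b <- simulate_cohort(two_cov_config(33, rounding = TRUE), dom,
                       default_field(dom))
  expect_identical(a$event, b$event)
  expect_true(all(b$time_years == floor(b$time_years)))
  expect_true(all(b$time_years >= 1))
  expect_true(all(b$time_years <= a$time_years + 1e-12))
})

test_that("default calibrated cohort reproduces the early-debut regime", {
  coh <- calibrated_cohort()
  expect_equal(nrow(coh), 5000)
  prev <- mean(early_debut_indicator(coh))
  expect_gte(prev, 0.16)
  expect_lte(prev, 0.22)
})

test_that("proportional hazards holds in large simulations", {
  dom <- unit_domain()
  cfg <- cohort_config(
    n_clusters = 100, persons_per_cluster = 2000,
    covariates = list(g = list(levels = c("a", "b"), probs = c(0.5, 0.5),
                               beta = c(0, log(2)))),
    interview_age = c(1e6, 1e6 + 1), integer_year_rounding = FALSE,
    weight_model = list(dist = "uniform", min = 1, max = 1), seed = 19)
  coh <- simulate_cohort(cfg, dom, field_spec(center = FALSE))
  # pool events on a fine age grid, then take the log-survival cumulative
  # hazard (exact under pooled ties) per group on a common set of ages
  coh$time_years <- round(coh$time_years, 1)
  cumhaz_at <- function(sub, at) {
    km <- km_estimate(sub)
    H <- -log(pmax(km$survival, 1e-12))
    stats::stepfun(km$time, c(0, H))(at)
  }
  at <- quantile(coh$time_years, seq(0.25, 0.95, by = 0.05))
  ha <- cumhaz_at(coh[coh$g == "a", ], at)
  hb <- cumhaz_at(coh[coh$g == "b", ], at)
  # hazards are proportional in time since onset (age - a0)
  slope <- coef(lm(log(hb / ha) ~ log(at - 8)))[2]
  expect_lt(abs(slope), 0.05)
  expect_equal(mean(log(hb / ha)), log(2), tolerance = 0.05)
})

test_that("survey weights are inverse selection probabilities rescaled to mean 1", {
  rec <- toy_records(time = rep(10, 6), event = rep(1, 6))
  rec$cluster <- rep(1:2, each = 3)

  eq <- assign_survey_weights(rec, list(dist = "fixed", probs = c(0.5, 0.5)))
  expect_equal(eq$weight, rep(1, 6))

  two <- assign_survey_weights(rec, list(dist = "fixed", probs = c(0.2, 0.8)))
  # pre-rescaling weights 5 and 1.25 (ratio 4); post-rescaling mean exactly 1
  expect_equal(unique(two$weight[two$cluster == 1]) /
                 unique(two$weight[two$cluster == 2]), 4)
  expect_equal(mean(two$weight), 1)

  expect_error(assign_survey_weights(rec, list(dist = "fixed",
                                               probs = c(0, 1))),
               "must be positive")

  r1 <- assign_survey_weights(rec, list(dist = "uniform", min = 0.2, max = 1),
                              seed = 9)
  r2 <- assign_survey_weights(rec, list(dist = "uniform", min = 0.2, max = 1),
                              seed = 9)
  expect_identical(r1$weight, r2$weight)
})

test_that("config validation catches inconsistent inputs", {
  expect_error(cohort_config(baseline = list(a0 = 8, shape = -1, scale = 5)),
               "invalid Weibull")
  expect_error(cohort_config(interview_age = c(5, 10)), "after the hazard")
  expect_error(cohort_config(covariates = list(
    g = list(levels = c("a", "b"), probs = c(0.6, 0.6), beta = c(0, 0)))),
    "sum to 1")
})

test_that("the shipped YAML config round-trips to the in-code defaults", {
  path <- system.file("extdata", "default_cohort.yaml", package = "geocox")
  cfg <- read_cohort_config(path)
  ref <- cohort_config()
  expect_equal(cfg$n_clusters, ref$n_clusters)
  expect_equal(cfg$baseline$shape, ref$baseline$shape)
  expect_equal(cfg$baseline$scale, ref$baseline$scale, tolerance = 1e-8)
  expect_equal(names(cfg$covariates), names(ref$covariates))
  expect_equal(cfg$covariates$alcohol$beta, ref$covariates$alcohol$beta,
               tolerance = 1e-8)
})

test_that("cohort CSV export carries all columns with no missing values", {
  dom <- unit_domain()
  coh <- simulate_cohort(two_cov_config(3, n_clusters = 5, persons = 4), dom,
                         field_spec(center = FALSE))
  path <- tempfile(fileext = ".csv")
  write_records(coh, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(coh))
  expect_true(all(c("id", "cluster", "lat", "lon", "time_years", "event",
                    "weight", "alcohol", "away") %in% names(back)))
  expect_false(anyNA(back))
})
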