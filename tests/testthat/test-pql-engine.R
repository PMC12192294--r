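test_that("with no smooth the PQL fit is the weighted Poisson GLM", {
  coh <- simulate_cohort(two_cov_config(5, n_clusters = 60, persons = 5,
                                        equal_weights = FALSE),
                         unit_domain(), field_spec(center = FALSE))
  cf <- fit_cox(coh, c("alcohol", "away"))
  pf <- to_poisson_frame(coh, breslow_cumhaz(cf))
  X <- cbind(alcoholyes = as.numeric(pf$alcohol == "yes"),
             awayyes = as.numeric(pf$away == "yes"))
  bas <- list(X = X, Z = matrix(0, nrow(pf), 0), y = pf$N,
              offset = pf$offset, w = pf$weight)
  pq <- fit_pql(bas)
  gfit <- glm(pf$N ~ X - 1 + offset(pf$offset), family = poisson(),
              weights = pf$weight / mean(pf$weight))
  expect_lt(max(abs(pq$beta - coef(gfit))), 1e-8)
  expect_equal(pq$edf, 2)
})

test_that("PQL coefficients track the partial-likelihood estimates", {
  cfg <- cohort_config(
    n_clusters = 100, persons_per_cluster = 5,
    covariates = list(g = list(levels = c("a", "b"), probs = c(0.5, 0.5),
                               beta = c(0, log(2)))),
    weight_model = list(dist = "uniform", min = 1, max = 1), seed = 5)
  coh <- simulate_cohort(cfg, unit_domain(), field_spec(center = FALSE))
  fk <- frame_and_knots(coh, "g")
  bas <- assemble_design(fk$frame, "g", NULL, fk$knots,
                         cov_spec("spherical", fk$d_max))
  pq <- suppressWarnings(fit_pql(bas))
  expect_lt(abs(pq$beta[["gb"]] - fk$cox$beta[["gb"]]), 0.02)
})

test_that("rescaling all survey weights leaves the fit unchanged", {
  coh <- simulate_cohort(two_cov_config(7, n_clusters = 40, persons = 5,
                                        equal_weights = FALSE),
                         unit_domain(), default_field(unit_domain()))
  fk <- frame_and_knots(coh, c("alcohol", "away"))
  bas <- assemble_design(fk$frame, c("alcohol", "away"), NULL, fk$knots,
                         cov_spec("spherical", fk$d_max))
  p1 <- suppressWarnings(fit_pql(bas))
  bas$w <- bas$w * 2
  p2 <- suppressWarnings(fit_pql(bas))
  expect_identical(p1$beta, p2$beta)
  expect_identical(p1$u, p2$u)
})

test_that("information criteria reduce to the GLM limit and order correctly", {
  coh <- simulate_cohort(two_cov_config(15, n_clusters = 50, persons = 5),
                         unit_domain(), field_spec(center = FALSE))
  cf <- fit_cox(coh, c("alcohol", "away"))
  pf <- to_poisson_frame(coh, breslow_cumhaz(cf))
  X <- cbind(alcoholyes = as.numeric(pf$alcohol == "yes"),
             awayyes = as.numeric(pf$away == "yes"))
  bas <- list(X = X, Z = matrix(0, nrow(pf), 0), y = pf$N,
              offset = pf$offset, w = pf$weight)
  pq <- fit_pql(bas)
  gfit <- glm(pf$N ~ X - 1 + offset(pf$offset), family = poisson())
  # equal weights: edf = p exactly, AIC matches the closed-form GLM AIC
  expect_equal(pq$edf, 2)
  expect_equal(pq$aic, AIC(gfit), tolerance = 1e-8)
  expect_gt(pq$aicc, pq$aic)
})

test_that("effective dof shrink monotonically as the penalty tightens", {
  coh <- simulate_cohort(two_cov_config(25, n_clusters = 40, persons = 5),
                         unit_domain(), default_field(unit_domain()))
  fk <- frame_and_knots(coh, c("alcohol", "away"))
  bas <- assemble_design(fk$frame, c("alcohol", "away"), NULL, fk$knots,
                         cov_spec("gaussian", 0.3))
  edfs <- vapply(c(1, 0.1, 0.01, 1e-4, 1e-8), function(s2) {
    fit_pql(bas, sigma2_init = s2, control = list(fix_sigma2 = TRUE))$edf
  }, numeric(1))
  expect_true(all(diff(edfs) <= 1e-6))
  # sigma2 -> 0 limit: edf approaches the fixed-effect column count
  expect_equal(edfs[length(edfs)], ncol(bas$X), tolerance = 1e-3)
  expect_true(all(edfs <= ncol(bas$X) + ncol(bas$Z) + 1e-8))
})

test_that("range estimation guards degenerate location sets", {
  rec <- toy_records(time = c(9, 10, 11, 12), event = rep(1, 4))
  rec$N <- rec$event
  rec$offset <- 0
  class(rec) <- c("poisson_frame", "data.frame")
  kn <- structure(list(knots = matrix(c(0.5, 0.5), 1)), class = "knot_set")
  expect_error(estimate_tau(rec, character(), NULL, kn, "gaussian"),
               "fewer than 2 distinct locations")
})

test_that("the range profile is maximized at the returned estimate", {
  coh <- simulate_cohort(two_cov_config(13, n_clusters = 60, persons = 6),
                         unit_domain(), strong_field())
  fk <- frame_and_knots(coh, c("alcohol", "away"))
  et <- estimate_tau(fk$frame, c("alcohol", "away"), NULL, fk$knots,
                     "gaussian")
  at_hat <- et$profile$criterion[which.min(abs(et$profile$tau - et$tau))]
  expect_gte(at_hat, et$profile$criterion[1] - 1e-9)
  expect_gte(at_hat, et$profile$criterion[nrow(et$profile)] - 1e-9)
  expect_true(et$tau >= et$d_min && et$tau <= et$d_max)
})

test_that("the profiled range recovers the generating length scale", {
  # field built from Gaussian bumps of width 0.2; the Gaussian covariance
  # basis reproduces them at range 0.2 * sqrt(2) ~ 0.283. The range is
  # identifiable when the field is strong relative to the event noise
  # (amplitude well above the covariate effects); scaled-down replicate
  # study at that amplitude: at least 4 of 6 estimates within a factor of 2.
  dom <- unit_domain()
  fld <- field_spec(bumps = list(
    list(center = c(0.25, 0.3), amplitude = 1.5, width = 0.2),
    list(center = c(0.75, 0.7), amplitude = -1.5, width = 0.2)),
    center = TRUE, domain = dom)
  set.seed(9)
  seeds <- sample.int(2^31 - 1, 6)
  taus <- vapply(seeds, function(s) {
    coh <- simulate_cohort(two_cov_config(s, n_clusters = 150, persons = 7),
                           dom, fld)
    fk <- frame_and_knots(coh, c("alcohol", "away"), knot_seed = 1)
    estimate_tau(fk$frame, c("alcohol", "away"), NULL, fk$knots,
                 "gaussian")$tau
  }, numeric(1))
  target <- 0.2 * sqrt(2)
  expect_gte(sum(taus >= target / 2 & taus <= target * 2), 4)
})

test_that("covariance selection ranks families and tolerates forced choices", {
  coh <- simulate_cohort(two_cov_config(13, n_clusters = 60, persons = 6),
                         dom <- unit_domain(), strong_field())
  fk <- frame_and_knots(coh, c("alcohol", "away"))
  one <- select_covariance(fk$frame, c("alcohol", "away"), NULL, fk$knots,
                           families = "matern")
  expect_equal(one$table$family, "matern")
  expect_equal(one$best$family, "matern")

  three <- select_covariance(fk$frame, c("alcohol", "away"), NULL, fk$knots,
                             families = c("spherical", "gaussian",
                                          "exponential"))
  expect_equal(nrow(three$table), 3)
  expect_true(all(is.finite(three$table$AICc)))
  expect_true(all(is.finite(three$table$BIC)))
  expect_equal(three$table$rank, 1:3)
  expect_true(!is.unsorted(three$table$AICc))
})

test_that("smooth covariance families win on smooth-field data", {
  # data generated from a smooth Gaussian-bump field; scaled-down replicate
  # study of the family comparison
  dom <- unit_domain()
  set.seed(113)
  seeds <- sample.int(2^31 - 1, 3)
  winners <- vapply(seeds, function(s) {
    coh <- simulate_cohort(two_cov_config(s, n_clusters = 100, persons = 7),
                           dom, strong_field(dom))
    fk <- frame_and_knots(coh, c("alcohol", "away"), knot_seed = 1)
    sel <- select_covariance(fk$frame, c("alcohol", "away"), NULL, fk$knots)
    sel$table$family[1]
  }, character(1))
  smooth_set <- c("gaussian", "matern", "inverse_quadratic", "circular")
  expect_gte(sum(winners %in% smooth_set), 2)
})

test_that("hazard-ratio tables exponentiate correctly", {
  fit <- structure(list(beta = c(a = 0, b = 0.4055),
                        vcov = diag(c(0.04, 0.01))), class = "geoadditive_fit")
  hr <- hazard_ratios(fit)
  expect_equal(hr$aHR[1], 1)
  z <- qnorm(0.975)
  expect_equal(hr$aHR[2], exp(0.4055))
  expect_equal(hr$ci_low[2], exp(0.4055 - z * 0.1))
  expect_equal(hr$ci_high[2], exp(0.4055 + z * 0.1))
  expect_equal(round(hr$aHR[2], 2), 1.50)
  expect_equal(round(hr$ci_low[2], 2), 1.23)
  expect_true(all(hr$ci_low <= hr$aHR & hr$aHR <= hr$ci_high))
})

test_that("disjoint strata produce independent fits", {
  dom <- unit_domain()
  coh <- simulate_cohort(cohort_config(n_clusters = 60,
                                       persons_per_cluster = 6, seed = 29),
                         dom, default_field(dom))
  fit_stratum <- function(records, level) {
    sub <- records[records$sex == level, , drop = FALSE]
    fk <- frame_and_knots(sub, c("alcohol", "away_from_home"), knot_seed = 3)
    bas <- assemble_design(fk$frame, c("alcohol", "away_from_home"), NULL,
                           fk$knots, cov_spec("spherical", fk$d_max))
    suppressWarnings(fit_pql(bas))
  }
  f1 <- fit_stratum(coh, "female")
  # permute the other stratum's rows; the female subset keeps its order
  idx <- seq_len(nrow(coh))
  male <- which(coh$sex == "male")
  set.seed(1)
  idx[male] <- sample(male)
  f2 <- fit_stratum(coh[idx, ], "female")
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$sigma2, f2$sigma2)
})
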