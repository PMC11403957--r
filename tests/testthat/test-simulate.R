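test_that("simulation is bit-reproducible and structurally valid", {
  cfg <- sim_config(n = 300, seed = 11)
  s1 <- simulate_responses(cfg)
  s2 <- simulate_responses(cfg)
  expect_identical(unclass(s1$responses), unclass(s2$responses))
  expect_identical(s1$truth$latents, s2$truth$latents)
  expect_true(all(unclass(s1$responses) %in% 1:5))
  expect_equal(dim(s1$responses), c(300, 60))
})

test_that("config validation rejects inconsistent structure", {
  expect_error(sim_config(planted = list(QDC = c(3, 99))),
               "outside subscale QDC")
  C <- diag(9); C[1, 2] <- 0.5  # asymmetric
  dimnames(C) <- list(bc_types(), bc_types())
  expect_error(sim_config(inter_subscale_corr = C), "not a valid correlation")
  expect_error(sim_config(thresholds = c(0, 1, 1, 2)), "strictly increasing")
  expect_error(sim_config(discrimination = -1), "non-negative")
})

test_that("planted truth exposes the generating core items", {
  expect_equal(planted_truth(sim_config(planted = list(GTC = c(2, 21))))$GTC,
               c(2, 21))
  cfg0 <- sim_config(planted = setNames(list(), character(0)))
  expect_length(unlist(planted_truth(cfg0)), 0)
  def <- planted_truth(sim_config())
  expect_setequal(names(def), biased_types())
  expect_true(all(lengths(def) == 2))
})

test_that("zero discrimination yields uncorrelated items", {
  cfg <- sim_config(n = 5000, seed = 13, discrimination = 0,
                    planted_discrimination = 0)
  sim <- simulate_responses(cfg)
  R <- cor(unclass(sim$responses))
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
})

test_that("the noise-free limit is monotone in the latent trait", {
  cfg <- sim_config(n = 400, seed = 17, noise_sd = 1e-9)
  sim <- simulate_responses(cfg)
  lat <- sim$truth$latents[, "QDC"]
  r3 <- unclass(sim$responses)[, "3"]   # item 3 loads on QDC, positive key
  expect_true(all(diff(r3[order(lat)]) >= 0))
  r54 <- unclass(sim$responses)[, "54"] # reverse-keyed on GTC
  expect_true(all(diff(r54[order(sim$truth$latents[, "GTC"])]) <= 0))
})

test_that("default draws show the assumed survey structure", {
  spec <- load_spec()
  sim <- simulate_responses(sim_config(n = 5000, seed = 19))
  scores <- score_all(sim$responses, spec)
  # left-leaning biased score mass: positive sample skewness
  skew <- vapply(biased_types(), function(b)
    ccmqrapid:::sample_skewness(scores[[b]]), 0)
  expect_gte(sum(skew > 0), 6)

  # within-subscale correlations exceed between-subscale correlations
  R <- abs(cor(unclass(sim$responses)))
  diag(R) <- NA
  pm <- ccmqrapid:::default_primary_map()
  same <- matrix(FALSE, 60, 60)
  for (ids in pm) same[ids, ids] <- TRUE
  expect_gt(mean(R[same], na.rm = TRUE), mean(R[!same], na.rm = TRUE))

  # subscale reliability in the band the generator is tuned to
  alphas <- vapply(names(spec$subscales), function(nm) {
    m <- unclass(sim$responses)[, as.character(spec$subscales[[nm]])]
    rev <- spec$subscales[[nm]] %in% spec$reverse[[nm]]
    m[, rev] <- 6 - m[, rev]
    cronbach_alpha(m)
  }, 0)
  expect_true(all(alphas >= 0.6 & alphas <= 0.85))

  # classification targets are non-degenerate for every subscale
  cls <- classify_bc(scores)
  for (nm in bc_types()) {
    expect_gt(mean(cls[[nm]] == "present"), 0.02)
  }
})

test_that("prevalence calibration lands and is monotone", {
  cfg <- sim_config(n = 500, seed = 23)
  cal <- calibrate_prevalence(cfg, c(QSC = 0.5), n = 4000, tol = 0.02)
  sim <- simulate_responses(within_n(cal, 4000, 90125))
  frac <- mean(classify_bc(score_all(sim$responses, cal$spec))$QSC ==
                 "present")
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)

  # monotone: larger latent mean offset -> larger presence fraction
  lo <- cfg; lo$subscale_means["QSC"] <- -0.5
  hi <- cfg; hi$subscale_means["QSC"] <- 1.0
  frac_of <- function(c2) {
    c2$n <- 4000L; c2$seed <- 424243L
    s <- simulate_responses(c2)
    mean(classify_bc(score_all(s$responses, c2$spec))$QSC == "present")
  }
  expect_lt(frac_of(lo), frac_of(hi))

  expect_error(calibrate_prevalence(cfg, c(QSC = 0)), "strictly inside")
  expect_error(calibrate_prevalence(cfg, c(0.5)), "named by subscale")
  expect_error(calibrate_prevalence(cfg, c(QSC = 0.9999), n = 2000),
               "cannot bracket")
})
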