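test_that("reverse adjustment mirrors the Likert scale", {
  expect_equal(adjust_raw(1, TRUE), 5)
  expect_equal(adjust_raw(5, TRUE), 1)
  expect_equal(adjust_raw(3, FALSE), 3)
  expect_equal(adjust_raw(c(1, 2, 5), c(TRUE, FALSE, TRUE)), c(5, 2, 1))
  expect_error(adjust_raw(0, TRUE), "out of range")
  expect_error(adjust_raw(6, FALSE), "out of range")
})

test_that("converted score follows the published rescaling formula", {
  expect_equal(converted_score(rep(1, 7), members = 1:7), 0)
  expect_equal(converted_score(rep(5, 7), members = 1:7), 100)
  expect_equal(converted_score(rep(3, 6), members = 1:6), 50)
  # GTC: 8 items, 6 reverse; all raws 1 -> adjusted sum 2*1 + 6*5 = 32
  spec <- load_spec()
  expect_equal(converted_score(rep(1, 8), members = spec$subscales$GTC,
                               reverse = spec$reverse$GTC), 75)
  expect_error(converted_score(c(`1` = 3), members = 1:6), "missing response")
  expect_error(converted_score(rep(3, 5), members = 1:6), "one response per")
})

test_that("score_all matches per-respondent converted_score calls", {
  spec <- load_spec()
  sc <- score_all(constant_responses(spec, 3), spec)
  for (nm in biased_types()) expect_equal(sc[[nm]], rep(50, 3))
  expect_equal(nrow(score_all(constant_responses(spec, 0), spec)), 0)

  sim <- simulate_responses(sim_config(n = 10, seed = 2))
  sc <- score_all(sim$responses, spec)
  for (i in 1:10) {
    for (nm in names(spec$subscales)) {
      raws <- unclass(sim$responses)[i, as.character(spec$subscales[[nm]])]
      expect_equal(sc[[nm]][i],
                   converted_score(raws, spec$subscales[[nm]],
                                   spec$reverse[[nm]]))
    }
  }
  rs <- attr(sc, "raw_sums")
  sizes <- lengths(spec$subscales)[colnames(rs)]
  expect_true(all(t(rs) >= sizes & t(rs) <= 5 * sizes))
})

test_that("classification follows the published boundary criteria", {
  mk <- function(gtc, qdc = 10, ...) {
    s <- data.frame(respondent_id = 1, GTC = gtc, QDC = qdc, YaDC = 10,
                    YiDC = 10, PDC = 10, DHC = 10, BSC = 10, QSC = 10,
                    SDC = 10)
    extra <- list(...)
    for (nm in names(extra)) s[[nm]] <- extra[[nm]]
    s
  }
  all29 <- mk(60); all29[biased_types()] <- 29.9
  cls <- classify_bc(all29)
  expect_equal(cls$GTC, "present")
  expect_true(all(cls[biased_types()] == "absent"))

  cls <- classify_bc(mk(70, qdc = 35))
  expect_equal(cls$GTC, "absent")  # a biased score >= 30 vetoes GTC
  expect_equal(cls$QDC, "tendency")

  expect_equal(classify_bc(mk(0, qdc = 41))$QDC, "present")
  expect_equal(classify_bc(mk(0, qdc = 40))$QDC, "tendency")
  expect_equal(classify_bc(mk(0, qdc = 30))$QDC, "tendency")
  expect_equal(classify_bc(mk(0, qdc = 29.9))$QDC, "absent")
  expect_equal(classify_bc(mk(59.9))$GTC, "absent")

  expect_error(classify_bc(mk(60)[, -2]), "missing subscale")
})

test_that("prevalence summary is multi-label and reports both variants", {
  cls <- data.frame(respondent_id = 1:4,
                    GTC = c("present", "absent", "absent", "absent"),
                    QDC = c("absent", "present", "present", "present"),
                    YaDC = c("absent", "present", "present", "present"),
                    YiDC = "tendency", PDC = "absent", DHC = "absent",
                    BSC = "absent", QSC = "absent", SDC = "absent")
  pv <- prevalence_summary(cls)
  expect_equal(pv$present_pct[pv$bc == "GTC"], 25)
  expect_equal(pv$present_pct[pv$bc == "QDC"], 75)
  expect_equal(pv$present_or_tendency_pct[pv$bc == "YiDC"], 100)
  expect_equal(pv$present_pct[pv$bc == "YiDC"], 0)
  # multi-label: percentages may sum above 100
  expect_gt(sum(pv$present_pct), 100)
  expect_error(prevalence_summary(cls[0, ]), "empty")
})

test_that("converted scores are bounded, reversal-symmetric and monotone", {
  members <- 1:6
  set.seed(42)
  for (i in 1:200) {
    raws <- sample(1:5, 6, replace = TRUE)
    s <- converted_score(raws, members)
    expect_gte(s, 0); expect_lte(s, 100)
    # reversal symmetry of the formula (no reverse items)
    expect_equal(converted_score(6 - raws, members), 100 - s)
    # strict monotonicity in a non-reverse item
    j <- sample(which(raws < 5), 1)
    up <- raws; up[j] <- up[j] + 1
    expect_gt(converted_score(up, members), s)
    # strict decrease in a reverse item
    rev_s <- converted_score(raws, members, reverse = j)
    expect_gt(rev_s, converted_score(up, members, reverse = j))
  }
})
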