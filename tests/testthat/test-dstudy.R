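# Hand-derived coefficient values for fixed component sets. All reference
# numbers below were computed by hand from the closed-form expressions.

one_facet_comps <- function() {
  v <- c(p = 4, i = 0.5, "pi,e" = 1)
  attr(v, "grand_mean") <- 3.5
  v
}

test_that("scenario constructor validates replicate counts and coefficient", {
  expect_error(dstudy_scenario(n_trials = 0), ">= 1")
  expect_error(dstudy_scenario(coefficient = "XYZ"))
  sc <- dstudy_scenario(n_trials = 5, coefficient = "D")
  expect_identical(sc$coefficient, "D")
})

test_that("one-facet error variances and G/D match hand values", {
  v <- one_facet_comps()
  ev <- error_variances(v, dstudy_scenario(n_trials = 4))
  expect_equal(ev$relative, 0.25)          # 1/4
  expect_equal(ev$absolute, 0.375)         # 1/4 + 0.5/4
  g <- reliability_coefficient(v, dstudy_scenario(n_trials = 4, coefficient = "G"))
  expect_equal(g$value, 4 / 4.25)
  expect_equal(g$sem_rel, sqrt(0.25))
  expect_equal(g$sem_abs, sqrt(0.375))
  d <- reliability_coefficient(v, dstudy_scenario(n_trials = 4, coefficient = "D"))
  expect_equal(d$value, 4 / 4.375)
  expect_lte(d$value, g$value)             # absolute error >= relative error
})

test_that("two-facet coefficients reproduce the hand-derived fixture values", {
  v <- two_facet_components()   # p=2, pi=1, po=0.5, pio,e=2, i=0.4, o=0.3, oi=0.1
  sc <- function(k) dstudy_scenario(n_trials = 10, n_occasions = 2, coefficient = k)
  val <- function(k) reliability_coefficient(v, sc(k))$value
  # rel = 1/10 + 0.5/2 + 2/20 = 0.45 ; abs = rel + 0.3/2 + 0.4/10 + 0.1/20 = 0.645
  expect_equal(error_variances(v, sc("G"))$relative, 0.45)
  expect_equal(error_variances(v, sc("G"))$absolute, 0.645)
  expect_equal(val("CES_G"), 2 / 2.45)             # 0.8163265
  expect_equal(val("CES_D"), 2 / 2.645)            # 0.7561437
  expect_equal(val("CE_G"), 2.25 / 2.45)           # 0.9183673
  expect_equal(val("CS_G"), 2.1 / 2.45)            # 0.8571429
  expect_equal(val("CE_D"), 2.25 / 2.495)          # 0.9018036
  expect_equal(val("CS_D"), 2.1 / 2.605)           # 0.8061420
  expect_equal(val("G"), val("CES_G"))             # CES_G is the G coefficient
  expect_error(reliability_coefficient(v, dstudy_scenario(n_trials = 10,
                                                          coefficient = "G")),
               "n_occasions")
})

test_that("split-design error variances and coefficients match hand values", {
  v <- c(p = 1, s = 0.08, "i:s" = 0.4, ps = 0.2, "p(i:s),e" = 1.0)
  sc <- dstudy_scenario(n_splits = 4, n_trials_per_split = 5, coefficient = "G")
  ev <- error_variances(v, sc)
  expect_equal(ev$relative, 0.1)     # 0.2/4 + 1/20
  expect_equal(ev$absolute, 0.14)    # + 0.08/4 + 0.4/20
  expect_equal(reliability_coefficient(v, sc)$value, 1 / 1.1)
  sc$coefficient <- "D"
  expect_equal(reliability_coefficient(v, sc)$value, 1 / 1.14)
  expect_error(error_variances(v, dstudy_scenario(n_splits = 4, coefficient = "G")),
               "n_trials_per_split")
})

test_that("single-replicate intraclass correlations match hand values", {
  v1 <- one_facet_comps()
  expect_equal(reliability_coefficient(
    v1, dstudy_scenario(coefficient = "ICC_rel"))$value, 4 / 5)
  expect_equal(reliability_coefficient(
    v1, dstudy_scenario(coefficient = "ICC_abs"))$value, 4 / 5.5)
  v2 <- two_facet_components()
  expect_equal(reliability_coefficient(
    v2, dstudy_scenario(n_occasions = 1, coefficient = "ICC_rel"))$value, 2 / 5.5)
  expect_equal(reliability_coefficient(
    v2, dstudy_scenario(n_occasions = 1, coefficient = "ICC_abs"))$value, 2 / 6.3)
  # ICC is a single-replicate quantity: replicate counts do not change it
  expect_equal(reliability_coefficient(
    v1, dstudy_scenario(n_trials = 50, coefficient = "ICC_rel"))$value, 4 / 5)
})

test_that("cut-score dependability matches the hand value and its identities", {
  v <- one_facet_comps()   # grand mean 3.5
  sc <- dstudy_scenario(n_trials = 4, cut_score = 2.5, coefficient = "CUT")
  est <- cut_score_coefficient(v, sc)
  expect_equal(est$value, 5 / 5.375)   # (4 + 1) / (4 + 1 + 0.375) = 0.9302326
  # C at the grand mean reduces CUT to the dependability coefficient
  sc_mu <- dstudy_scenario(n_trials = 4, cut_score = 3.5, coefficient = "CUT")
  d <- reliability_coefficient(v, dstudy_scenario(n_trials = 4, coefficient = "D"))
  expect_equal(cut_score_coefficient(v, sc_mu)$value, d$value)
  # dependability grows as C moves away from the mean
  far <- cut_score_coefficient(v, dstudy_scenario(n_trials = 4, cut_score = -10,
                                                  coefficient = "CUT"))
  expect_gt(far$value, est$value)
  expect_error(reliability_coefficient(v, dstudy_scenario(n_trials = 4,
                                                          coefficient = "CUT")),
               "cut_score")
})

test_that("degenerate component sets raise undefined-coefficient errors", {
  zero <- c(p = 0, i = 0, "pi,e" = 0)
  expect_error(reliability_coefficient(zero, dstudy_scenario(coefficient = "G")),
               "undefined coefficient")
  expect_error(reliability_coefficient(zero, dstudy_scenario(coefficient = "ICC_rel")),
               "undefined coefficient")
  expect_error(error_variances(c(p = 1, q = 2), dstudy_scenario()),
               "cannot infer")
  expect_error(reliability_coefficient(c(p = 1, "pi,e" = 1),
                                       dstudy_scenario(coefficient = "G")),
               "incomplete")
  # CE/CS/CES are two-facet coefficients
  expect_error(reliability_coefficient(one_facet_comps(),
                                       dstudy_scenario(coefficient = "CE_G")),
               "two-facet")
})

test_that("projection finds the minimal replicate count or flags unreachable", {
  v <- c(p = 1, i = 0, "pi,e" = 1)
  pr <- project(v, coefficient = "G", grid = 1:20, target = 0.8)
  # G = n/(n+1) >= 0.8 first at n = 4
  expect_identical(pr$minimal_n, 4L)
  expect_false(pr$unreachable)
  expect_equal(pr$asymptote, 1, tolerance = 1e-6)
  expect_true(all(diff(pr$table$value) > 0))   # strictly increasing here

  # with occasions fixed at 1, G is capped by the person-by-occasion term
  v2 <- two_facet_components()
  base <- dstudy_scenario(n_occasions = 1, coefficient = "G")
  pr2 <- project(v2, coefficient = "G", grid = 1:1000, target = 0.9,
                 vary = "n_trials", scenario = base)
  expect_true(pr2$unreachable)
  expect_true(is.na(pr2$minimal_n))
  expect_equal(pr2$asymptote, 2 / 2.5, tolerance = 1e-6)  # p / (p + po)
  expect_lt(max(pr2$table$value), 0.9)

  expect_error(project(v, target = 1.2), "inside")
  expect_error(project(v, grid = integer(0)), "non-empty")
})

test_that("posterior summaries use per-draw coefficients and contrasts separate levels", {
  set.seed(5)
  nd <- 400
  mk <- function(p_center) {
    dr <- cbind(p = pmax(rnorm(nd, p_center, 0.1), 0.01),
                i = pmax(rnorm(nd, 0.2, 0.02), 0.001),
                "pi,e" = pmax(rnorm(nd, 1, 0.05), 0.01))
    gtrel:::new_gt_components(apply(dr, 2, median), grand_mean = 0,
                              estimator = "bayes", layout = "one_facet",
                              draws = dr, mu_draws = rep(0, nd))
  }
  hi <- mk(4); lo <- mk(1)
  sc <- dstudy_scenario(n_trials = 2, coefficient = "G")
  est_hi <- reliability_coefficient(hi, sc)
  est_lo <- reliability_coefficient(lo, sc)
  # point value is the median of per-draw coefficients
  draws_g <- hi$draws[, "p"] / (hi$draws[, "p"] + hi$draws[, "pi,e"] / 2)
  expect_equal(est_hi$value, median(draws_g))
  expect_length(est_hi$interval, 2)
  expect_true(est_hi$interval[1] <= est_hi$value &&
                est_hi$value <= est_hi$interval[2])
  ct <- contrast(list(high = est_hi, low = est_lo))
  expect_identical(nrow(ct), 1L)
  expect_gt(ct$difference, 0)
  expect_equal(ct$prob_positive, 1)
  expect_true(ct$ci_lo <= ct$difference && ct$difference <= ct$ci_hi)
  expect_error(contrast(list(est_hi)), "at least two")
  point_only <- reliability_coefficient(one_facet_comps(), sc)
  expect_error(contrast(list(a = point_only, b = point_only)), "draws")
})
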