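test_that("MCMC and prior configurations validate their inputs", {
  expect_error(gt_mcmc(), "seed is required")
  cfg <- gt_mcmc(seed = 1)
  expect_identical(cfg$chains, 4L)
  expect_identical(cfg$rhat_max, 1.01)
  pr <- gt_priors()
  expect_identical(pr$sd_scale, 2.5)
  expect_identical(pr$sd_df, 3)
})

test_that("family transforms guard their domains", {
  neg <- as_gt_table(data.frame(person = rep(c("A", "B"), each = 2),
                                trial = rep(1:2, 2), score = c(1, -1, 2, 3)))
  expect_error(estimate_bayes(neg, one_facet_design(family = "lognormal"),
                              mcmc = quick_mcmc()),
               "family error")
  expect_error(estimate_bayes(neg, one_facet_design(family = "gamma_chisq"),
                              mcmc = quick_mcmc()),
               "family error")
})

test_that("one-facet Bayesian fit agrees with EMS on balanced gaussian data", {
  sim <- simulate_gt(sim_spec(60, 15, components = c(p = 2, i = 0.3, "pi,e" = 1),
                              mu = -2, seed = 510))
  ems <- estimate_ems(sim$table, one_facet_design())
  bay <- estimate_bayes(sim$table, one_facet_design(), mcmc = quick_mcmc(seed = 1))
  expect_identical(bay$estimator, "bayes")
  expect_setequal(names(bay$components), names(ems$components))
  for (l in names(ems$components))
    expect_lt(abs(bay$components[[l]] - ems$components[[l]]), 0.4)
  expect_lt(abs(bay$grand_mean + 2), 0.5)
  # posterior draws are strictly positive and medians equal the point estimates
  expect_true(all(bay$draws > 0))
  expect_equal(unname(apply(bay$draws, 2, median)), unname(bay$components))
  expect_true(all(bay$diagnostics$rhat < quick_mcmc()$rhat_max))
})

test_that("Bayesian estimation is deterministic under its seed", {
  sim <- simulate_gt(sim_spec(25, 8, components = c(p = 1, i = 0.2, "pi,e" = 1),
                              seed = 511))
  a <- estimate_bayes(sim$table, one_facet_design(), mcmc = quick_mcmc(seed = 7))
  b <- estimate_bayes(sim$table, one_facet_design(), mcmc = quick_mcmc(seed = 7))
  expect_identical(a$components, b$components)
  expect_identical(a$draws, b$draws)
})

test_that("unbalanced tables are handled at the observation level", {
  sim <- simulate_gt(sim_spec(40, 12, components = c(p = 2, i = 0.2, "pi,e" = 1),
                              retention = 0.75, seed = 512))
  expect_false(validate_design(sim$table, one_facet_design())$balanced)
  expect_error(estimate_ems(sim$table, one_facet_design()), "balance error")
  bay <- estimate_bayes(sim$table, one_facet_design(), mcmc = quick_mcmc(seed = 2))
  expect_lt(abs(bay$components[["p"]] - 2), 1)
  expect_lt(abs(bay$components[["pi,e"]] - 1), 0.4)
})

test_that("an unreasonably strict R-hat threshold fails loudly", {
  sim <- simulate_gt(sim_spec(15, 6, components = c(p = 1, i = 0.2, "pi,e" = 1),
                              seed = 513))
  expect_error(estimate_bayes(sim$table, one_facet_design(),
                              mcmc = gt_mcmc(chains = 2, iter = 100, adapt = 100,
                                             burn = 0, seed = 3, rhat_max = 0.9)),
               "convergence error")
})

test_that("two-facet and split layouts fit and label their components", {
  s2 <- simulate_gt(sim_spec(20, 5, n_occasions = 2,
                             components = c(p = 1, i = 0.2, o = 0.2, pi = 0.3,
                                            po = 0.3, oi = 0.1, "pio,e" = 1),
                             seed = 514))
  b2 <- estimate_bayes(s2$table, two_facet_design(), mcmc = quick_mcmc(seed = 4))
  expect_setequal(names(b2$components),
                  c("p", "i", "o", "pi", "po", "oi", "pio,e"))
  # split-design components with only two split levels mix slowly: give the
  # sampler more iterations than the smoke-test default
  ss <- simulate_gt(sim_spec(30, 12, trials_per_split = 4,
                             components = c(p = 1, s = 0.1, "i:s" = 0.2,
                                            ps = 0.3, "p(i:s),e" = 1),
                             seed = 515))
  bs <- estimate_bayes(ss$table, splits_design(),
                       mcmc = gt_mcmc(chains = 3, iter = 1500, adapt = 500,
                                      burn = 500, seed = 5, rhat_max = 1.1))
  expect_setequal(names(bs$components), c("p", "s", "i:s", "ps", "p(i:s),e"))
  expect_true(all(bs$draws > 0))
})

test_that("a fixed facet yields a joint fit with per-level components", {
  we <- make_worked_example(seed = 33, n_persons = 40,
                            trial_counts = c(a = 12, b = 8),
                            components = c(p = 2, i = 0.2, "pi,e" = 2))
  design <- gt_design(gt_facet("trial", "random"), gt_facet("task", "fixed"))
  fit <- estimate_bayes(we$table, design, mcmc = quick_mcmc(seed = 6))
  expect_identical(fit$fixed_facet, "task")
  lev <- components_by_fixed_level(fit, "task")
  expect_setequal(names(lev), c("a", "b"))
  expect_true(all(lev$a$draws > 0))
  expect_match(fit$note, "average")
  # per-level reliabilities can be contrasted on their posterior draws
  sc <- dstudy_scenario(n_trials = 8, coefficient = "D")
  ct <- contrast(lapply(lev, reliability_coefficient, scenario = sc))
  expect_identical(nrow(ct), 1L)
  expect_true(ct$prob_positive >= 0 && ct$prob_positive <= 1)
})

test_that("heteroscedastic location-scale model separates residual variances", {
  spec <- sim_spec(n_persons = 60, n_trials = 20,
                   components = c(p = 1.5, i = 0.2, "pi,e" = 1), mu = 0,
                   fixed_levels = list(task = list(
                     low = list(components = c(p = 1.5, i = 0.2, "pi,e" = 0.5)),
                     high = list(components = c(p = 1.5, i = 0.2, "pi,e" = 4)))),
                   seed = 516)
  sim <- simulate_gt(spec)
  design <- gt_design(gt_facet("trial", "random"), gt_facet("task", "fixed"))
  fit <- estimate_bayes(sim$table, design,
                        mcmc = gt_mcmc(chains = 3, iter = 1500, adapt = 500,
                                       burn = 500, seed = 8, rhat_max = 1.05),
                        heteroscedastic_by = "task")
  lev <- components_by_fixed_level(fit, "task")
  expect_true(fit$diagnostics$heteroscedastic)
  # the two residual variances are recovered on the right side of each other
  expect_lt(lev$low$components[["pi,e"]], lev$high$components[["pi,e"]])
  expect_lt(abs(lev$low$components[["pi,e"]] - 0.5), 0.35)
  expect_lt(abs(lev$high$components[["pi,e"]] - 4), 1.2)
  expect_error(estimate_bayes(sim$table, design, mcmc = quick_mcmc(seed = 8),
                              heteroscedastic_by = "trial"),
               "fixed facet")
})
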