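# Shared fixtures, built in code.

# 3 persons x 2 trials with scores 1..6: a hand-checkable two-way layout
# whose ANOVA solution is sigma2_p = 4, sigma2_i = 0.5, sigma2_pi,e = 0.
toy_table <- function() {
  as_gt_table(data.frame(person = rep(c("A", "B", "C"), each = 2),
                         trial = rep(1:2, 3), score = 1:6))
}

one_facet_design <- function(...) gt_design(gt_facet("trial", "random"), ...)

two_facet_design <- function() gt_design(gt_facet("trial", "random"),
                                         gt_facet("occasion", "random"))

splits_design <- function() gt_design(gt_facet("trial", "random", nested_in = "split"),
                                      gt_facet("split", "random"))

# hand-evaluated two-facet component set used across dstudy tests
two_facet_components <- function() {
  c(p = 2, po = 0.5, pi = 1, "pio,e" = 2, o = 0.3, i = 0.4, oi = 0.1)
}

# short MCMC config for smoke tests (not for accuracy-sensitive checks)
quick_mcmc <- function(seed = 42, rhat_max = 1.2) {
  gt_mcmc(chains = 2, iter = 400, adapt = 300, burn = 100, seed = seed,
          rhat_max = rhat_max)
}

write_toy_csv <- function(path = tempfile(fileext = ".csv"), sep = ",") {
  df <- data.frame(person = rep(c("A", "B", "C"), each = 2),
                   trial = rep(1:2, 3), score = 1:6)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
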