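#' Estimate variance components by expected mean squares
#'
#' Exact random-effects ANOVA solution for fully balanced designs: the mean
#' squares of the crossed or nested layout are computed and the expected-
#' mean-squares equations solved for the component variances. This is the
#' oracle against which the Bayesian estimator is checked on balanced
#' Gaussian data. Raw negative solutions (a known artifact of the method,
#' common when a component is near zero) are reported, truncated to 0 for
#' downstream coefficients, and flagged.
#'
#' Supported balanced layouts: Persons x Trials, Persons x Trials x
#' Occasions, and Persons x (Trials:Splits). A fixed facet (e.g., task) is
#' handled by solving within each of its conditions; the global component
#' slot then holds the across-condition mean (explicitly an average over
#' fixed conditions) and [components_by_fixed_level()] returns the
#' per-condition sets.
#'
#' @param table A `gt_table`.
#' @param design A `gt_design` with `family = "gaussian"`.
#' @return A `gt_components` object (`estimator = "ems"`).
#' @seealso [estimate_bayes()] for unbalanced, non-Gaussian, or
#'   heteroscedastic data.
#' @export
estimate_ems <- function(table, design) {
  stopifnot(inherits(table, "gt_table"), inherits(design, "gt_design"))
  if (design$family != "gaussian")
    stop("estimate_ems requires family = 'gaussian'; use estimate_bayes for ",
         design$family, " scores")
  val <- validate_design(table, design)

  ff <- fixed_facets(design)
  if (length(ff) > 1L)
    stop("at most one fixed facet is supported")
  if (length(ff) == 1L) {
    lev <- sort(unique(as.character(table[[ff]])))
    sub_design <- design
    sub_design$facets[[ff]] <- NULL
    sub_design$layout <- design_layout(sub_design)
    by_level <- lapply(lev, function(l) {
      sub <- table[as.character(table[[ff]]) == l, , drop = FALSE]
      sub[[ff]] <- NULL
      estimate_ems(structure(sub, class = c("gt_table", "data.frame")), sub_design)
    })
    names(by_level) <- lev
    comp_mat <- sapply(by_level, function(b) b$components)
    pooled <- rowMeans(comp_mat)
    fit <- new_gt_components(pooled, grand_mean = mean(table$score),
                             estimator = "ems", layout = sub_design$layout,
                             raw = rowMeans(sapply(by_level, function(b) b$raw)),
                             truncation_flags = apply(sapply(by_level, function(b)
                               b$truncation_flags), 1, any),
                             by_level = by_level,
                             n = list(persons = length(unique(table$person))))
    fit$fixed_facet <- ff
    fit$note <- paste0("global components are the unweighted mean over the ",
                       length(lev), " conditions of fixed facet '", ff, "'")
    return(fit)
  }

  if (!val$balanced)
    stop("balance error: the design is unbalanced (unequal replicate counts); ",
         "expected-mean-squares estimation is exact only for balanced data -- ",
         "use estimate_bayes()")

  layout <- design$layout
  df <- as.data.frame(table)
  df$person <- factor(df$person)
  sol <- switch(layout,
    one_facet = ems_one_facet(df),
    two_facet = ems_two_facet(df),
    splits = ems_splits(df),
    stop("no closed-form expected-mean-squares table is implemented for the '",
         layout, "' layout; use estimate_bayes()"))

  raw <- sol$raw
  comps <- pmax(raw, 0)
  flags <- raw < 0
  new_gt_components(comps, grand_mean = mean(df$score), estimator = "ems",
                    layout = layout, raw = raw, truncation_flags = flags,
                    n = sol$n)
}

# Persons x Trials, one observation per cell.
# E[MS_p] = s2_pi,e + n_i s2_p ; E[MS_i] = s2_pi,e + n_p s2_i ; E[MS_pi] = s2_pi,e
ems_one_facet <- function(df) {
  df$trial <- factor(df$trial)
  np <- nlevels(df$person); ni <- nlevels(df$trial)
  ms <- anova_ms(lm(score ~ person + trial, data = df))
  mse <- ms[["Residuals"]]
  raw <- c("p" = (ms[["person"]] - mse) / ni,
           "i" = (ms[["trial"]] - mse) / np,
           "pi,e" = mse)
  list(raw = raw, n = list(persons = np, trials = ni))
}

# Persons x Trials x Occasions, one observation per cell.
ems_two_facet <- function(df) {
  df$trial <- factor(df$trial); df$occasion <- factor(df$occasion)
  np <- nlevels(df$person); ni <- nlevels(df$trial); no <- nlevels(df$occasion)
  ms <- anova_ms(lm(score ~ (person + trial + occasion)^2, data = df))
  mse <- ms[["Residuals"]]
  s_pi <- (ms[["person:trial"]] - mse) / no
  s_po <- (ms[["person:occasion"]] - mse) / ni
  s_oi <- (ms[["trial:occasion"]] - mse) / np
  raw <- c(
    "p" = (ms[["person"]] - ms[["person:trial"]] - ms[["person:occasion"]] + mse) / (ni * no),
    "i" = (ms[["trial"]] - ms[["person:trial"]] - ms[["trial:occasion"]] + mse) / (np * no),
    "o" = (ms[["occasion"]] - ms[["person:occasion"]] - ms[["trial:occasion"]] + mse) / (np * ni),
    "pi" = s_pi, "po" = s_po, "oi" = s_oi, "pio,e" = mse)
  list(raw = raw, n = list(persons = np, trials = ni, occasions = no))
}

# Persons x (Trials:Splits), one observation per cell; trials indexed by
# within-split rank so the i:s factor is the same size in every split.
ems_splits <- function(df) {
  df$split <- factor(df$split)
  # within-split trial rank (trial indices need not be contiguous)
  df <- df[order(df$person, df$split, df$trial), ]
  rk <- stats::ave(df$trial, df$person, df$split, FUN = function(x) rank(x))
  df$tin <- factor(rk)
  np <- nlevels(df$person); ns <- nlevels(df$split); nis <- nlevels(df$tin)
  ms <- anova_ms(lm(score ~ person + split + person:split + split:tin, data = df))
  mse <- ms[["Residuals"]]
  ms_ps <- ms[["person:split"]]
  ms_is <- ms[["split:tin"]]
  raw <- c(
    "p" = (ms[["person"]] - ms_ps) / (ns * nis),
    "s" = (ms[["split"]] - ms_ps - ms_is + mse) / (np * nis),
    "i:s" = (ms_is - mse) / np,
    "ps" = (ms_ps - mse) / nis,
    "p(i:s),e" = mse)
  list(raw = raw, n = list(persons = np, splits = ns, trials_per_split = nis))
}

anova_ms <- function(fit) {
  # F-tests are unused (and warn on zero-residual toys); only MS are needed
  a <- suppressWarnings(anova(fit))
  setNames(a[["Mean Sq"]], rownames(a))
}
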