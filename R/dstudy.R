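#' Specify a decision-study scenario
#'
#' A D-study scenario fixes the number of replicates the projected
#' measurement would average over (trials, occasions, splits, trials per
#' split) and the coefficient to evaluate. Replicate counts are the primed
#' n's of the coefficient formulas.
#'
#' @param n_trials Trials per replicate (`n'_i`); positive integer.
#' @param n_occasions Occasions (`n'_o`), two-facet designs.
#' @param n_splits Splits (`n'_s`), split designs.
#' @param n_trials_per_split Trials per split (`n'_i per split`), split
#'   designs. With unequal observed split lengths this is user-supplied
#'   (the harmonic mean of the observed lengths is a reasonable choice).
#' @param cut_score Cut score `C` in score units (required for
#'   `coefficient = "CUT"`).
#' @param coefficient One of `"G"` (generalizability, relative error),
#'   `"D"` (dependability, absolute error), `"ICC_rel"`, `"ICC_abs"`
#'   (single-replicate intraclass correlations), `"CE_G"`, `"CE_D"`
#'   (equivalence), `"CS_G"`, `"CS_D"` (stability), `"CES_G"`, `"CES_D"`
#'   (combined equivalence and stability; two-facet designs), `"CUT"`
#'   (cut-score dependability).
#' @return A list of class `dstudy_scenario`.
#' @export
dstudy_scenario <- function(n_trials = 1L, n_occasions = NULL, n_splits = NULL,
                            n_trials_per_split = NULL, cut_score = NULL,
                            coefficient = c("G", "D", "ICC_rel", "ICC_abs",
                                            "CE_G", "CE_D", "CS_G", "CS_D",
                                            "CES_G", "CES_D", "CUT")) {
  coefficient <- match.arg(coefficient)
  chk <- function(x, nm) {
    if (!is.null(x) && (length(x) != 1L || x < 1)) stop(nm, " must be a single value >= 1")
    x
  }
  structure(list(n_trials = chk(n_trials, "n_trials"),
                 n_occasions = chk(n_occasions, "n_occasions"),
                 n_splits = chk(n_splits, "n_splits"),
                 n_trials_per_split = chk(n_trials_per_split, "n_trials_per_split"),
                 cut_score = cut_score, coefficient = coefficient),
            class = "dstudy_scenario")
}

need <- function(vc, labels) {
  missing <- setdiff(labels, names(vc))
  if (length(missing))
    stop("component set is incomplete for this design: missing ",
         paste(missing, collapse = ", "))
}

#' Relative and absolute error variance for a scenario
#'
#' Relative error variance collects the person-by-facet interaction terms
#' (the error that perturbs relative standings); absolute error variance
#' adds the facet main-effect (mean-level) terms and underlies
#' dependability. Each term is divided by the replicate counts it is
#' averaged over. When every facet main-effect variance is zero, absolute
#' equals relative error variance.
#'
#' @param vc A `gt_components` object (or bare named numeric vector of
#'   components).
#' @param scenario A [dstudy_scenario()].
#' @return List with `relative` and `absolute` error variances.
#' @export
error_variances <- function(vc, scenario) {
  comps <- if (inherits(vc, "gt_components")) vc$components else vc
  layout <- infer_layout(comps)
  ev <- error_variance_terms(comps, scenario, layout)
  list(relative = ev$rel, absolute = ev$abs)
}

infer_layout <- function(comps) {
  nm <- names(comps)
  if ("p(i:s),e" %in% nm) {
    if ("o" %in% nm || "po" %in% nm) return("splits_occasion")
    return("splits")
  }
  if ("pio,e" %in% nm) return("two_facet")
  if ("pi,e" %in% nm) return("one_facet")
  stop("cannot infer the design layout from component labels: ",
       paste(nm, collapse = ", "))
}

# Per-layout relative/absolute error terms at the scenario's replicate
# counts. Returns rel, abs, and the pieces needed by CE/CS numerators.
error_variance_terms <- function(comps, sc, layout) {
  g <- function(l) { need(comps, l); unname(comps[l]) }
  switch(layout,
    one_facet = {
      ni <- sc$n_trials
      rel <- g("pi,e") / ni
      list(rel = rel, abs = rel + g("i") / ni)
    },
    two_facet = {
      ni <- sc$n_trials
      no <- sc$n_occasions
      if (is.null(no)) stop("two-facet scenarios need n_occasions")
      rel <- g("pi") / ni + g("po") / no + g("pio,e") / (no * ni)
      abs <- rel + g("o") / no + g("i") / ni + g("oi") / (no * ni)
      list(rel = rel, abs = abs,
           po_term = g("po") / no, pi_term = g("pi") / ni,
           o_terms = g("o") / no + g("oi") / (no * ni),
           i_terms = g("i") / ni + g("oi") / (no * ni))
    },
    splits = {
      ns <- sc$n_splits
      nis <- sc$n_trials_per_split
      if (is.null(ns) || is.null(nis))
        stop("split scenarios need n_splits and n_trials_per_split")
      rel <- g("ps") / ns + g("p(i:s),e") / (nis * ns)
      abs <- rel + g("s") / ns + g("i:s") / (nis * ns)
      list(rel = rel, abs = abs)
    },
    splits_occasion = {
      # composition of the two-facet occasion terms with the split-design
      # terms (the printed table for this layout is not machine-readable);
      # flagged experimental in the returned estimate
      ns <- sc$n_splits; nis <- sc$n_trials_per_split; no <- sc$n_occasions
      if (is.null(ns) || is.null(nis) || is.null(no))
        stop("split-by-occasion scenarios need n_splits, n_trials_per_split and n_occasions")
      rel <- g("ps") / ns + g("po") / no + g("p(i:s),e") / (nis * ns * no)
      abs <- rel + g("s") / ns + g("o") / no + g("i:s") / (nis * ns)
      list(rel = rel, abs = abs, experimental = TRUE)
    })
}

# Evaluate one coefficient for a single component vector. Returns the pieces
# (value, rel, abs) so draws can be summarized by the caller.
eval_coefficient <- function(comps, mu, sc, layout) {
  ev <- error_variance_terms(comps, sc, layout)
  p <- unname(comps["p"])
  kind <- sc$coefficient
  if (kind %in% c("CE_G", "CE_D", "CS_G", "CS_D", "CES_G", "CES_D") &&
      layout != "two_facet")
    stop("coefficient ", kind, " requires a two-facet (trials x occasions) component set")
  den_rel <- p + ev$rel
  den_abs <- p + ev$abs
  if (kind != "CUT" && den_rel <= 0)
    stop("undefined coefficient: universe-score and error variances are all zero")
  value <- switch(kind,
    G = p / den_rel,
    D = p / den_abs,
    ICC_rel = icc_value(comps, layout, absolute = FALSE),
    ICC_abs = icc_value(comps, layout, absolute = TRUE),
    CE_G = (p + ev$po_term) / den_rel,
    CE_D = (p + ev$po_term) / (p + ev$rel + ev$i_terms),
    CS_G = (p + ev$pi_term) / den_rel,
    CS_D = (p + ev$pi_term) / (p + ev$rel + ev$o_terms),
    CES_G = p / den_rel,
    CES_D = p / den_abs,
    CUT = {
      if (is.null(sc$cut_score)) stop("CUT scenarios need a cut_score")
      if (is.null(mu) || is.na(mu)) stop("CUT scenarios need a grand mean")
      dev2 <- (mu - sc$cut_score)^2
      if (p + dev2 + ev$abs <= 0)
        stop("undefined coefficient: universe-score and error variances are all zero")
      (p + dev2) / (p + dev2 + ev$abs)
    })
  list(value = value, rel = ev$rel, abs = ev$abs,
       experimental = isTRUE(ev$experimental))
}

# Single-replicate intraclass correlations (all n' = 1 in the formulas).
icc_value <- function(comps, layout, absolute) {
  g <- function(l) unname(comps[l])
  p <- g("p")
  switch(layout,
    one_facet = {
      den <- p + g("pi,e") + if (absolute) g("i") else 0
      if (den <= 0) stop("undefined coefficient: all components are zero")
      p / den
    },
    two_facet = {
      den <- p + g("po") + g("pi") + g("pio,e") +
        if (absolute) g("o") + g("i") + g("oi") else 0
      if (den <= 0) stop("undefined coefficient: all components are zero")
      p / den
    },
    splits = {
      den <- p + g("ps") + g("p(i:s),e") +
        if (absolute) g("s") + g("i:s") else 0
      if (den <= 0) stop("undefined coefficient: all components are zero")
      p / den
    },
    splits_occasion = {
      den <- p + g("ps") + g("po") + g("p(i:s),e") +
        if (absolute) g("s") + g("o") + g("i:s") else 0
      if (den <= 0) stop("undefined coefficient: all components are zero")
      p / den
    })
}

#' Evaluate a reliability coefficient for a D-study scenario
#'
#' Computes the requested coefficient from a variance-component set at the
#' scenario's replicate counts. With a Bayesian fit the coefficient is
#' evaluated per posterior draw and summarized by the median and a 95%
#' equal-tailed credible interval (the point value is the median of
#' per-draw coefficients, not the coefficient of the median components).
#'
#' @param vc A `gt_components` object.
#' @param scenario A [dstudy_scenario()].
#' @return A `gt_reliability` object: `value` (in \[0,1\]),
#'   `relative_error_variance`, `absolute_error_variance`, `sem_rel`,
#'   `sem_abs` (square roots of the error variances), `interval` (95% CrI
#'   when draws exist), `scenario`, `draws`.
#' @export
reliability_coefficient <- function(vc, scenario) {
  stopifnot(inherits(scenario, "dstudy_scenario"))
  comps <- if (inherits(vc, "gt_components")) vc$components else vc
  mu <- if (inherits(vc, "gt_components")) vc$grand_mean else attr(vc, "grand_mean")
  layout <- infer_layout(comps)
  pt <- eval_coefficient(comps, mu, scenario, layout)

  interval <- NULL; cdraws <- NULL
  if (inherits(vc, "gt_components") && !is.null(vc$draws)) {
    mu_d <- if (!is.null(vc$mu_draws)) vc$mu_draws else rep(mu, nrow(vc$draws))
    cdraws <- vapply(seq_len(nrow(vc$draws)), function(r)
      eval_coefficient(vc$draws[r, ], mu_d[r], scenario, layout)$value,
      numeric(1))
    pt$value <- median(cdraws)
    interval <- unname(quantile(cdraws, c(0.025, 0.975)))
    rel_d <- vapply(seq_len(nrow(vc$draws)), function(r)
      error_variance_terms(vc$draws[r, ], scenario, layout)$rel, numeric(1))
    abs_d <- vapply(seq_len(nrow(vc$draws)), function(r)
      error_variance_terms(vc$draws[r, ], scenario, layout)$abs, numeric(1))
    pt$rel <- median(rel_d); pt$abs <- median(abs_d)
  }

  new_gt_reliability(value = pt$value, rel = pt$rel, abs = pt$abs,
                     interval = interval, scenario = scenario, draws = cdraws,
                     experimental = pt$experimental)
}

new_gt_reliability <- function(value, rel, abs, interval = NULL, scenario,
                               draws = NULL, undefined = FALSE,
                               experimental = FALSE, notes = NULL) {
  if (!undefined) {
    stopifnot(value >= 0, value <= 1 + 1e-12)
    value <- min(value, 1)
    if (!is.null(interval)) {
      interval <- pmin(pmax(interval, 0), 1)
      stopifnot(interval[1] <= interval[2])
    }
  }
  structure(list(value = value,
                 relative_error_variance = rel, absolute_error_variance = abs,
                 sem_rel = sqrt(rel), sem_abs = sqrt(abs),
                 interval = interval, scenario = scenario, draws = draws,
                 undefined = undefined, experimental = experimental,
                 notes = notes),
            class = "gt_reliability")
}

#' @export
print.gt_reliability <- function(x, ...) {
  sc <- x$scenario
  cat("<gt_reliability>", sc$coefficient, "\n")
  if (x$undefined) {
    cat("  UNDEFINED:", x$notes, "\n")
    return(invisible(x))
  }
  cat("  value:", format(x$value, digits = 4))
  if (!is.null(x$interval))
    cat("  [95% CrI ", format(x$interval[1], digits = 4), ", ",
        format(x$interval[2], digits = 4), "]", sep = "")
  cat("\n  error variances: relative", format(x$relative_error_variance, digits = 4),
      " absolute", format(x$absolute_error_variance, digits = 4), "\n")
  cat("  SEM: relative", format(x$sem_rel, digits = 4),
      " absolute", format(x$sem_abs, digits = 4), "\n")
  if (x$experimental)
    cat("  note: split-by-occasion formulas are a composed reconstruction\n")
  invisible(x)
}

#' Cut-score dependability
#'
#' Dependability of classifications relative to a threshold `C`: the cut
#' score's squared deviation from the estimated grand mean joins the
#' universe-score variance in both numerator and denominator, so agreement
#' about standing relative to `C` is easier the farther `C` sits from the
#' mean. When `C` equals the grand mean this reduces exactly to the global
#' dependability coefficient. The estimated grand mean is used as printed,
#' with no small-sample bias correction.
#'
#' @param vc A `gt_components` object.
#' @param scenario A [dstudy_scenario()] with `cut_score` set (its
#'   `coefficient` is forced to `"CUT"`).
#' @return A `gt_reliability` object.
#' @export
cut_score_coefficient <- function(vc, scenario) {
  scenario$coefficient <- "CUT"
  reliability_coefficient(vc, scenario)
}

#' Project reliability over replicate counts
#'
#' Evaluates a coefficient over a grid of replicate counts for one facet
#' and reports the smallest count achieving a target, or flags the target
#' unreachable together with the asymptote (the coefficient's limit as the
#' varied count grows, with all non-vanishing error terms retained).
#'
#' @param vc A `gt_components` object.
#' @param coefficient Coefficient kind (see [dstudy_scenario()]).
#' @param grid Positive integer vector of replicate counts to evaluate.
#' @param target Target reliability in (0,1), or `NULL` for no search.
#' @param vary Which replicate count the grid refers to: `"n_trials"`,
#'   `"n_occasions"`, `"n_splits"`, or `"n_trials_per_split"`.
#' @param scenario Base scenario supplying the other replicate counts.
#' @return A `gt_projection`: data frame `table` (n, value), `minimal_n`
#'   (NA if unreachable), `unreachable`, `asymptote`, `target`.
#' @export
project <- function(vc, coefficient = "G", grid = 1:100, target = NULL,
                    vary = c("n_trials", "n_occasions", "n_splits",
                             "n_trials_per_split"),
                    scenario = dstudy_scenario(coefficient = coefficient)) {
  vary <- match.arg(vary)
  if (!length(grid)) stop("grid must be non-empty")
  if (!is.null(target) && (target <= 0 || target >= 1))
    stop("target must lie strictly inside (0, 1)")
  scenario$coefficient <- coefficient
  grid <- sort(unique(as.integer(grid)))
  values <- vapply(grid, function(n) {
    sc <- scenario; sc[[vary]] <- n
    reliability_coefficient(vc, sc)$value
  }, numeric(1))
  tab <- data.frame(n = grid, value = values)
  names(tab)[1] <- vary
  sc_inf <- scenario; sc_inf[[vary]] <- 1e9
  asymptote <- reliability_coefficient(vc, sc_inf)$value
  minimal <- NA_integer_; unreachable <- FALSE
  if (!is.null(target)) {
    ok <- which(values >= target)
    if (length(ok)) minimal <- grid[ok[1]] else unreachable <- TRUE
  }
  structure(list(table = tab, minimal_n = minimal, unreachable = unreachable,
                 asymptote = asymptote, target = target, vary = vary,
                 coefficient = coefficient),
            class = "gt_projection")
}

#' @export
print.gt_projection <- function(x, ...) {
  cat("<gt_projection>", x$coefficient, "varying", x$vary, "\n")
  print(head(x$table, 10), row.names = FALSE)
  if (nrow(x$table) > 10) cat("  ...", nrow(x$table), "grid points\n")
  if (!is.null(x$target)) {
    if (x$unreachable)
      cat("  target", x$target, "UNREACHABLE; asymptote =", format(x$asymptote, digits = 4), "\n")
    else cat("  minimal", x$vary, "for target", x$target, ":", x$minimal_n, "\n")
  }
  invisible(x)
}

#' Posterior contrasts between per-condition reliability estimates
#'
#' For reliability estimates carrying posterior draws (e.g., per task from
#' a fixed-facet fit), computes pairwise differences of the coefficient
#' draws with 95% credible intervals and the posterior probability that the
#' difference is positive.
#'
#' @param estimates Named list of `gt_reliability` objects with draws.
#' @return Data frame: level_a, level_b, difference (median), ci_lo, ci_hi,
#'   prob_positive.
#' @export
contrast <- function(estimates) {
  if (length(estimates) < 2L) stop("need at least two estimates to contrast")
  if (any(vapply(estimates, function(e) is.null(e$draws), logical(1))))
    stop("contrasts require posterior draws; point-only estimates were supplied")
  nms <- names(estimates)
  if (is.null(nms)) nms <- paste0("level", seq_along(estimates))
  pairs <- utils::combn(seq_along(estimates), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    nd <- min(length(estimates[[a]]$draws), length(estimates[[b]]$draws))
    d <- estimates[[a]]$draws[seq_len(nd)] - estimates[[b]]$draws[seq_len(nd)]
    ci <- quantile(d, c(0.025, 0.975))
    data.frame(level_a = nms[a], level_b = nms[b],
               difference = median(d), ci_lo = unname(ci[1]),
               ci_hi = unname(ci[2]), prob_positive = mean(d > 0))
  }))
  out
}
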