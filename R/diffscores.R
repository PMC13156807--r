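#' Bundle two measures for difference-score reliability
#'
#' Collects the variance components of each constituent measure, the
#' covariance components between them, and the replicate counts each
#' measure is averaged over. Harmonic-mean counts, used wherever a
#' covariance term is divided by a replicate count, are computed as
#' `2 / (1/nX + 1/nY)` from the per-measure counts.
#'
#' @param components_x,components_y `gt_components` (or named numeric
#'   vectors) for measures X and Y.
#' @param covariances A `gt_covariances` object, or a named numeric vector
#'   of covariance components (`p`, and error effects such as `pi,e`, `pi`,
#'   `po`, `pio,e`).
#' @param concurrent Logical; when `FALSE`, all error-level covariances are
#'   forced to exactly zero (non-concurrent measures, e.g., error vs.
#'   correct trials). Defaults to the `gt_covariances` flag when available.
#' @param n_trials_x,n_trials_y Trials averaged per measure.
#' @param n_occasions_x,n_occasions_y Occasions (two-facet designs).
#' @return A list of class `difference_pair` including harmonic means
#'   `h_trials` and `h_occasions`.
#' @export
difference_pair <- function(components_x, components_y, covariances,
                            concurrent = NULL,
                            n_trials_x, n_trials_y = n_trials_x,
                            n_occasions_x = NULL, n_occasions_y = n_occasions_x) {
  cx <- if (inherits(components_x, "gt_components")) components_x$components else components_x
  cy <- if (inherits(components_y, "gt_components")) components_y$components else components_y
  if (inherits(covariances, "gt_covariances")) {
    if (is.null(concurrent)) concurrent <- covariances$concurrent
    covs <- covariances$covariances
  } else {
    covs <- covariances
    if (is.null(concurrent)) stop("supply 'concurrent' when covariances are a bare vector")
  }
  if (!concurrent) covs[setdiff(names(covs), "p")] <- 0
  # Cauchy-Schwarz per effect, where both variance components exist
  shared <- intersect(names(covs), intersect(names(cx), names(cy)))
  bound <- sqrt(cx[shared] * cy[shared])
  bad <- abs(covs[shared]) > bound + 1e-12
  if (any(bad))
    stop("covariance component(s) violate the Cauchy-Schwarz bound: ",
         paste(shared[bad], collapse = ", "))
  hmean <- function(a, b) if (is.null(a) || is.null(b)) NULL else 2 / (1 / a + 1 / b)
  structure(list(components_x = cx, components_y = cy, covariances = covs,
                 concurrent = concurrent,
                 n_trials_x = n_trials_x, n_trials_y = n_trials_y,
                 n_occasions_x = n_occasions_x, n_occasions_y = n_occasions_y,
                 h_trials = hmean(n_trials_x, n_trials_y),
                 h_occasions = hmean(n_occasions_x, n_occasions_y)),
            class = "difference_pair")
}

#' Reliability of a difference score
#'
#' Generalizability-type reliability of `D = X - Y`. The universe-score
#' variance of the difference is
#' `sigma2_X(p) + sigma2_Y(p) - 2 sigma_XY(p)`: the person-level covariance
#' always enters the numerator, which is why highly correlated constituents
#' yield unreliable differences. Error terms enter at each measure's own
#' replicate counts; error covariances (estimable only for concurrently
#' measured signals) are divided by harmonic-mean counts and are exactly
#' zero for non-concurrent measures. For the two-facet design the base
#' coefficient is the combined equivalence-and-stability form (`CES`);
#' `CE` adds the person-by-occasion block to the numerator and `CS` the
#' person-by-trial block, mirroring the univariate coefficients.
#'
#' A numerator at or below zero is returned as a first-class *undefined*
#' state (not an error, not silently zero): between-person variance in
#' change is absent, which is diagnostic — even a perfect measure yields an
#' undefined difference-score reliability when everyone changes by the same
#' amount.
#'
#' @param pair A [difference_pair()].
#' @param design `"one_facet"` or `"two_facet"`.
#' @param coefficient `"CE"`, `"CS"`, or `"CES"` (`"CE"` is the only kind
#'   for the one-facet design; `"CS"`/`"CES"` need occasions).
#' @return A `gt_reliability`; `undefined = TRUE` with a diagnostic note
#'   when the numerator is not positive.
#' @export
difference_reliability <- function(pair, design = c("one_facet", "two_facet"),
                                   coefficient = c("CE", "CS", "CES")) {
  stopifnot(inherits(pair, "difference_pair"))
  design <- match.arg(design)
  coefficient <- match.arg(coefficient)
  cx <- pair$components_x; cy <- pair$components_y; cv <- pair$covariances
  gx <- function(l) { need(cx, l); unname(cx[l]) }
  gy <- function(l) { need(cy, l); unname(cy[l]) }
  gc_ <- function(l) if (l %in% names(cv)) unname(cv[l]) else 0

  num_base <- gx("p") + gy("p") - 2 * gc_("p")
  if (num_base <= 1e-14) {
    return(new_gt_reliability(
      value = NA_real_, rel = NA_real_, abs = NA_real_,
      scenario = dstudy_scenario(coefficient = "G"), undefined = TRUE,
      notes = paste("difference-score reliability is undefined: between-person",
                    "variance in change is absent (universe-score variance of",
                    "the difference <= 0)")))
  }

  if (design == "one_facet") {
    if (coefficient != "CE")
      stop("the one-facet difference design provides the coefficient of equivalence only")
    err <- gx("pi,e") / pair$n_trials_x + gy("pi,e") / pair$n_trials_y -
      2 * gc_("pi,e") / pair$h_trials
    num <- num_base
  } else {
    if (is.null(pair$n_occasions_x) || is.null(pair$n_occasions_y))
      stop("two-facet difference designs need occasion counts for both measures")
    nix <- pair$n_trials_x; niy <- pair$n_trials_y
    nox <- pair$n_occasions_x; noy <- pair$n_occasions_y
    pi_block <- gx("pi") / nix + gy("pi") / niy - 2 * gc_("pi") / pair$h_trials
    po_block <- gx("po") / nox + gy("po") / noy - 2 * gc_("po") / pair$h_occasions
    pio_block <- gx("pio,e") / (nix * nox) + gy("pio,e") / (niy * noy) -
      2 * gc_("pio,e") / (pair$h_trials * pair$h_occasions)
    err <- pi_block + po_block + pio_block
    num <- switch(coefficient,
      CES = num_base,
      CE = num_base + po_block,   # occasion block moves into the numerator
      CS = num_base + pi_block)   # trial block moves into the numerator
  }
  den <- num_base + err
  value <- num / den
  if (value < -1e-12 || value > 1 + 1e-12)
    stop("difference-score reliability fell outside [0, 1] (", format(value),
         "); check the covariance components")
  new_gt_reliability(value = min(max(value, 0), 1), rel = err, abs = err,
                     scenario = dstudy_scenario(coefficient = "G"))
}

#' Ceiling analysis for a difference score
#'
#' Reports each constituent's reliability, the person-level correlation
#' between constituents, and the implied difference-score reliability over
#' a sweep of that correlation from 0 toward 1 (holding variances and error
#' terms fixed). Higher positive correlations between constituent scores
#' reduce the attainable difference-score reliability; with equal variances
#' the ceiling collapses to 0 (or undefined) as the correlation approaches 1.
#'
#' @param pair A [difference_pair()] (one-facet components).
#' @param sweep Correlations to evaluate (default `seq(0, 0.99, 0.01)`).
#' @return A `gt_ceiling` list: `reliability_x`, `reliability_y`,
#'   `correlation` (the pair's own person-level correlation), and data
#'   frame `sweep` (correlation, difference_reliability).
#' @export
ceiling_analysis <- function(pair, sweep = seq(0, 0.99, by = 0.01)) {
  stopifnot(inherits(pair, "difference_pair"))
  cx <- pair$components_x; cy <- pair$components_y
  rel_x <- cx[["p"]] / (cx[["p"]] + cx[["pi,e"]] / pair$n_trials_x)
  rel_y <- cy[["p"]] / (cy[["p"]] + cy[["pi,e"]] / pair$n_trials_y)
  rho_obs <- pair$covariances[["p"]] / sqrt(cx[["p"]] * cy[["p"]])
  vals <- vapply(sweep, function(r) {
    cv <- pair$covariances
    cv["p"] <- r * sqrt(cx[["p"]] * cy[["p"]])
    pr <- difference_pair(cx, cy, cv, concurrent = pair$concurrent,
                          n_trials_x = pair$n_trials_x, n_trials_y = pair$n_trials_y)
    est <- difference_reliability(pr, "one_facet", "CE")
    if (est$undefined) NA_real_ else est$value
  }, numeric(1))
  structure(list(reliability_x = unname(rel_x), reliability_y = unname(rel_y),
                 correlation = unname(rho_obs),
                 sweep = data.frame(correlation = sweep,
                                    difference_reliability = vals)),
            class = "gt_ceiling")
}

#' @export
print.gt_ceiling <- function(x, ...) {
  cat("<gt_ceiling> constituent reliabilities:",
      format(x$reliability_x, digits = 4), "and",
      format(x$reliability_y, digits = 4), "\n")
  cat("  person-level correlation:", format(x$correlation, digits = 4), "\n")
  rng <- range(x$sweep$difference_reliability, na.rm = TRUE)
  cat("  difference reliability over the correlation sweep:",
      format(rng[1], digits = 4), "to", format(rng[2], digits = 4), "\n")
  invisible(x)
}
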