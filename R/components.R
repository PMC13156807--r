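# Container for a set of estimated variance components.
#
# `components` holds nonnegative point estimates keyed by effect label
# ("p", "i", "pi,e", ...). For Bayesian fits, `draws` is a draws x component
# matrix of strictly positive posterior samples and the point estimates are
# the per-component posterior medians; `mu_draws` carries the grand mean.
# For EMS fits, `raw` preserves the untruncated solutions and
# `truncation_flags` marks components whose raw estimate was negative.
new_gt_components <- function(components, grand_mean, estimator, layout,
                              family = "gaussian",
                              scale = c(gaussian = "identity", lognormal = "log",
                                        gamma_chisq = "sqrt")[[family]],
                              raw = NULL, truncation_flags = NULL, draws = NULL,
                              mu_draws = NULL, by_level = NULL, diagnostics = NULL,
                              n = NULL) {
  components <- unlist(components)
  if (any(components < 0)) stop("stored variance components must be nonnegative")
  if (is.null(truncation_flags))
    truncation_flags <- setNames(rep(FALSE, length(components)), names(components))
  if (!is.null(draws)) {
    if (any(draws <= 0)) stop("Bayesian draws of variance components must be strictly positive")
    med <- apply(draws, 2, median)
    components <- med[names(components)]
  }
  structure(list(components = components, grand_mean = grand_mean,
                 estimator = estimator, layout = layout, family = family,
                 scale = scale, raw = raw, truncation_flags = truncation_flags,
                 draws = draws, mu_draws = mu_draws, by_level = by_level,
                 diagnostics = diagnostics, n = n),
            class = "gt_components")
}

#' @export
print.gt_components <- function(x, ...) {
  cat("<gt_components> estimator:", x$estimator, " layout:", x$layout,
      " scale:", x$scale, "\n")
  cat("  grand mean:", format(x$grand_mean, digits = 4), "\n")
  df <- data.frame(component = names(x$components),
                   variance = round(unname(x$components), 5))
  if (!is.null(x$raw)) df$raw <- round(unname(x$raw[df$component]), 5)
  df$truncated <- unname(x$truncation_flags[df$component])
  if (!is.null(x$draws)) {
    ci <- apply(x$draws[, df$component, drop = FALSE], 2, quantile,
                probs = c(0.025, 0.975))
    df$ci_lo <- round(ci[1, ], 5); df$ci_hi <- round(ci[2, ], 5)
  }
  print(df, row.names = FALSE)
  if (!is.null(x$by_level))
    cat("  per-level fits for fixed facet:", paste(names(x$by_level), collapse = ", "), "\n")
  invisible(x)
}

#' Total variance implied by a component set
#'
#' Sum of all variance components: the model-implied variance of a single
#' observation (the "Individual Score" partition row).
#' @param vc A `gt_components` object.
#' @return Numeric scalar.
#' @export
total_variance <- function(vc) sum(vc$components)

#' Extract per-condition components for a fixed facet
#'
#' When a design includes a fixed facet (e.g., task), the estimators keep
#' person, trial, and residual components separately for each condition of
#' that facet, from a single joint model in the Bayesian path or per-level
#' solutions in the EMS path. This enables per-condition reliability and
#' post-estimation contrasts without aggregating scores.
#'
#' @param fit A `gt_components` object from [estimate_ems()] or
#'   [estimate_bayes()] on a design with a fixed facet.
#' @param fixed_facet Name of the fixed facet.
#' @return Named list (one `gt_components` per condition). A one-condition
#'   design yields a single-entry list equal to the global fit.
#' @export
components_by_fixed_level <- function(fit, fixed_facet) {
  stopifnot(inherits(fit, "gt_components"))
  if (!is.null(fit$fixed_facet)) {
    if (!identical(fit$fixed_facet, fixed_facet))
      stop("facet '", fixed_facet, "' was not a fixed facet of this fit")
    return(fit$by_level)
  }
  if (!is.null(fit$random_facets) && fixed_facet %in% fit$random_facets)
    stop("facet '", fixed_facet, "' is random in this fit, not fixed")
  # single-condition design (facet hidden/absent): one entry, the global fit
  setNames(list(fit), "all")
}

# JSON-able summary of a component set (median + 95% interval per component)
components_report <- function(vc) {
  rep <- list(estimator = vc$estimator, layout = vc$layout, family = vc$family,
              scale = vc$scale, grand_mean = vc$grand_mean,
              components = as.list(vc$components),
              truncated = as.list(vc$truncation_flags))
  if (!is.null(vc$raw)) rep$raw <- as.list(vc$raw)
  if (!is.null(vc$draws)) {
    ci <- apply(vc$draws, 2, quantile, probs = c(0.025, 0.5, 0.975))
    rep$posterior <- lapply(colnames(ci), function(cn)
      list(component = cn, median = ci[2, cn], ci95 = c(ci[1, cn], ci[3, cn])))
  }
  if (!is.null(vc$diagnostics)) rep$diagnostics <- vc$diagnostics
  rep
}
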