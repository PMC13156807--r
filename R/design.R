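#' Declare a measurement facet
#'
#' A facet is a source of measurement variation (trials, occasions, tasks),
#' analogous to an ANOVA factor. It is `random` when the observed
#' conditions are exchangeable draws from a larger universe the analysis
#' should generalize to, and `fixed` when inference is limited to the
#' observed conditions (e.g., the three tasks actually administered).
#'
#' @param name Column name in the observation table (`"trial"`,
#'   `"occasion"`, `"split"`, or any fixed-facet column such as `"task"`).
#' @param status `"random"` or `"fixed"`.
#' @param nested_in Optional name of the facet this one is nested in
#'   (e.g., trials nested in splits: `gt_facet("trial", nested_in = "split")`).
#' @return An object of class `gt_facet`.
#' @export
gt_facet <- function(name, status = c("random", "fixed"), nested_in = NULL) {
  status <- match.arg(status)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(nested_in)) stopifnot(is.character(nested_in), length(nested_in) == 1L)
  structure(list(name = name, status = status, nested_in = nested_in),
            class = "gt_facet")
}

#' Specify a measurement design
#'
#' The design names the object of measurement (whose differences the score
#' should capture, usually persons), the measurement facets with their
#' random/fixed status and nesting, the score family, and any facets that
#' are documented but observed at a single condition (hidden facets, whose
#' variance is unidentifiable).
#'
#' @param ... `gt_facet` objects (at least one random facet).
#' @param object Name of the object of measurement column. Default `"person"`.
#' @param family Score distribution family. `"gaussian"` models scores on
#'   the identity scale; `"lognormal"` models the linear decomposition of
#'   log scores (strictly positive data such as band power); `"gamma_chisq"`
#'   models the decomposition of square-root scores, appropriate for
#'   positively skewed, zero-bounded power-like scores. Components and all
#'   downstream coefficients are reported on the modeling scale.
#' @param hidden Character vector of facet names documented but not
#'   modeled (single observed condition); reliability is conditional on them.
#' @return An object of class `gt_design`.
#' @examples
#' gt_design(gt_facet("trial", "random"))
#' gt_design(gt_facet("trial", "random"), gt_facet("occasion", "random"))
#' gt_design(gt_facet("trial", "random", nested_in = "split"),
#'           gt_facet("split", "random"))
#' @export
gt_design <- function(..., object = "person",
                      family = c("gaussian", "lognormal", "gamma_chisq"),
                      hidden = character()) {
  family <- match.arg(family)
  facets <- list(...)
  if (length(facets) == 1L && is.list(facets[[1]]) && !inherits(facets[[1]], "gt_facet"))
    facets <- facets[[1]]
  if (!length(facets)) stop("a design needs at least one facet besides the object of measurement")
  if (!all(vapply(facets, inherits, logical(1), "gt_facet")))
    stop("facets must be created with gt_facet()")
  names(facets) <- vapply(facets, `[[`, character(1), "name")
  if (anyDuplicated(names(facets))) stop("duplicate facet names")
  if (object %in% names(facets)) stop("the object of measurement cannot also be a facet")

  # nesting must reference declared facets and be acyclic
  for (f in facets) {
    if (!is.null(f$nested_in)) {
      if (!f$nested_in %in% names(facets))
        stop("facet '", f$name, "' is nested in undeclared facet '", f$nested_in, "'")
      seen <- f$name; cur <- f$nested_in
      while (!is.null(cur)) {
        if (cur %in% seen) stop("cyclic nesting involving facet '", cur, "'")
        seen <- c(seen, cur); cur <- facets[[cur]]$nested_in
      }
    }
  }
  status <- vapply(facets, `[[`, character(1), "status")
  if (!any(status == "random"))
    stop("at least one random facet besides the object of measurement is required")

  d <- structure(list(facets = facets, object = object, family = family,
                      hidden = as.character(hidden)),
                 class = "gt_design")
  d$layout <- design_layout(d)
  d
}

# Classify the random-facet structure into one of the supported layouts.
design_layout <- function(design) {
  rf <- design$facets[vapply(design$facets, `[[`, character(1), "status") == "random"]
  nm <- names(rf)
  nested <- !vapply(rf, function(f) is.null(f$nested_in), logical(1))
  has_trial <- "trial" %in% nm
  has_occ <- "occasion" %in% nm
  has_split <- "split" %in% nm
  if (has_split && has_trial && identical(rf$trial$nested_in, "split")) {
    if (has_occ) return("splits_occasion")
    return("splits")
  }
  if (any(nested))
    stop("unsupported nesting structure: only trials nested in splits is supported")
  if (has_trial && has_occ) return("two_facet")
  if (has_trial) return("one_facet")
  stop("designs must include a random 'trial' facet (optionally nested in 'split', optionally crossed with 'occasion')")
}

fixed_facets <- function(design) {
  names(design$facets)[vapply(design$facets, `[[`, character(1), "status") == "fixed"]
}

random_facets <- function(design) {
  names(design$facets)[vapply(design$facets, `[[`, character(1), "status") == "random"]
}

# Component labels carried by each layout. The highest-order interaction is
# confounded with residual error and always carries the ",e" suffix.
layout_components <- function(layout) {
  switch(layout,
    one_facet = c("p", "i", "pi,e"),
    two_facet = c("p", "i", "o", "pi", "po", "oi", "pio,e"),
    splits = c("p", "s", "i:s", "ps", "p(i:s),e"),
    splits_occasion = c("p", "s", "i:s", "o", "ps", "po", "p(i:s),e"),
    stop("unknown layout: ", layout))
}

residual_label <- function(layout) {
  switch(layout, one_facet = "pi,e", two_facet = "pio,e",
         splits = , splits_occasion = "p(i:s),e")
}

#' @export
print.gt_design <- function(x, ...) {
  cat("<gt_design> layout:", x$layout, " family:", x$family, "\n")
  cat("  object of measurement:", x$object, "\n")
  for (f in x$facets)
    cat(sprintf("  facet %-10s %s%s\n", f$name, f$status,
                if (is.null(f$nested_in)) "" else paste0(" (nested in ", f$nested_in, ")")))
  if (length(x$hidden)) cat("  hidden (declared, unmodeled):", paste(x$hidden, collapse = ", "), "\n")
  invisible(x)
}
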