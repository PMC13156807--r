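#' Specify a synthetic GT dataset
#'
#' Describes data generated from the generalizability-theory linear
#' decomposition: score = grand mean + person effect + facet effects +
#' interactions + residual, each drawn independently with its stated
#' variance. Families: `gaussian` uses the linear score directly;
#' `lognormal` exponentiates it (strictly positive, right-skewed);
#' `gamma_chisq` squares it (positively skewed, zero-bounded power-like
#' scores with a noise floor, as for spectral power or EDA magnitudes).
#' Per-person unbalance emulates artifact rejection: each trial is retained
#' independently with probability `retention`, independent of score values
#' (missingness is ignorable by construction). Optional zero-inflation
#' zeroes out a trial's score with the given probability (nonresponse
#' trials in EDA).
#'
#' @param n_persons,n_trials Design size (persons, trials per person).
#' @param n_occasions Optional occasions (two-facet designs).
#' @param trials_per_split Optional split size; when set, a `split` column
#'   is generated and the split-design components (`s`, `i:s`, `ps`,
#'   `p(i:s),e`) are used.
#' @param components Named vector of true variance components for the
#'   target design, e.g. `c(p = 4, i = 0.5, "pi,e" = 1)`.
#' @param mu Grand mean (score units; on the latent linear scale for
#'   non-Gaussian families).
#' @param fixed_levels Optional named list defining one fixed facet:
#'   `list(task = list(A = list(components = ..., n_trials = ...,
#'   retention = ...), B = ...))`. Unset per-level entries inherit the
#'   global values.
#' @param family `"gaussian"`, `"lognormal"`, or `"gamma_chisq"`.
#' @param retention Per-person, per-trial retention probability in (0, 1].
#' @param zero_inflation Probability a retained trial's score is exactly 0.
#' @param covariance Optional measure-pair block for difference-score data:
#'   `list(components_y = ..., cov = c(p = ..., "pi,e" = ...),
#'   concurrent = TRUE)`. Measure X uses `components`; covariances must
#'   respect the Cauchy-Schwarz bound.
#' @param seed Integer seed; one global seed governs all draws.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_persons, n_trials, n_occasions = NULL,
                     trials_per_split = NULL,
                     components = c(p = 1, i = 0.1, "pi,e" = 1), mu = 0,
                     fixed_levels = NULL,
                     family = c("gaussian", "lognormal", "gamma_chisq"),
                     retention = 1, zero_inflation = 0, covariance = NULL,
                     seed) {
  family <- match.arg(family)
  if (missing(seed)) stop("a seed is required")
  if (any(components < 0)) stop("variance components must be nonnegative")
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  if (zero_inflation < 0 || zero_inflation > 1) stop("zero_inflation must be in [0, 1]")
  if (!is.null(covariance)) {
    cy <- covariance$components_y
    shared <- intersect(names(covariance$cov), intersect(names(components), names(cy)))
    bound <- sqrt(components[shared] * cy[shared])
    if (any(abs(covariance$cov[shared]) > bound + 1e-12))
      stop("covariance block violates the Cauchy-Schwarz bound")
  }
  structure(list(n_persons = n_persons, n_trials = n_trials,
                 n_occasions = n_occasions, trials_per_split = trials_per_split,
                 components = components, mu = mu, fixed_levels = fixed_levels,
                 family = family, retention = retention,
                 zero_inflation = zero_inflation, covariance = covariance,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate an observation table from the GT decomposition
#'
#' Draws every effect with its stated variance and assembles scores; the
#' returned truth record stores the generating components and the realized
#' design so estimators can be checked by parameter recovery. With a fixed
#' facet, effects are drawn independently per level (sub-streams are
#' derived deterministically from the global seed in level order, so adding
#' a level does not shuffle existing draws).
#'
#' @param spec A [sim_spec()].
#' @return List: `table` (a `gt_table`), `truth` (components, mu, design
#'   info, per-level truth when a fixed facet is present).
#' @export
simulate_gt <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)

  if (!is.null(spec$fixed_levels)) {
    ff <- names(spec$fixed_levels)
    if (length(ff) != 1L) stop("exactly one fixed facet is supported")
    levels <- spec$fixed_levels[[ff]]
    tabs <- list(); truths <- list()
    for (j in seq_along(levels)) {
      ov <- levels[[j]]
      sub <- spec
      sub$fixed_levels <- NULL
      for (field in intersect(names(ov), c("components", "n_trials", "retention",
                                           "mu", "zero_inflation")))
        sub[[field]] <- ov[[field]]
      sub$seed <- spec$seed + j * 10000L
      r <- simulate_gt(sub)
      r$table[[ff]] <- names(levels)[j]
      tabs[[j]] <- as.data.frame(r$table)
      truths[[names(levels)[j]]] <- r$truth
    }
    tab <- as_gt_table(do.call(rbind, tabs))
    return(list(table = tab,
                truth = list(by_level = truths, fixed_facet = ff,
                             family = spec$family, seed = spec$seed)))
  }

  if (!is.null(spec$covariance)) return(simulate_pair(spec))

  comp <- spec$components
  g <- function(l) if (l %in% names(comp)) comp[[l]] else 0
  np <- spec$n_persons; ni <- spec$n_trials
  no <- if (is.null(spec$n_occasions)) 1L else spec$n_occasions
  persons <- sprintf("P%03d", seq_len(np))

  grid <- expand.grid(person = seq_len(np), trial = seq_len(ni),
                      occasion = seq_len(no))
  # effect draws in fixed order: person, trial, occasion, interactions, residual
  e_p <- rnorm(np, 0, sqrt(g("p")))
  lin <- spec$mu + e_p[grid$person]

  if (!is.null(spec$trials_per_split)) {
    tps <- spec$trials_per_split
    if (ni %% tps != 0)
      stop("n_trials must be a multiple of trials_per_split for simulation")
    ns <- ni %/% tps
    split_of_trial <- (seq_len(ni) - 1L) %/% tps + 1L
    grid$split <- split_of_trial[grid$trial]
    e_s <- rnorm(ns, 0, sqrt(g("s")))
    e_is <- rnorm(ni, 0, sqrt(g("i:s")))          # trial-within-split effect
    e_ps <- matrix(rnorm(np * ns, 0, sqrt(g("ps"))), np, ns)
    resid <- rnorm(nrow(grid), 0, sqrt(g("p(i:s),e")))
    lin <- lin + e_s[grid$split] + e_is[grid$trial] +
      e_ps[cbind(grid$person, grid$split)] + resid
  } else if (no > 1L) {
    e_i <- rnorm(ni, 0, sqrt(g("i")))
    e_o <- rnorm(no, 0, sqrt(g("o")))
    e_pi <- matrix(rnorm(np * ni, 0, sqrt(g("pi"))), np, ni)
    e_po <- matrix(rnorm(np * no, 0, sqrt(g("po"))), np, no)
    e_oi <- matrix(rnorm(no * ni, 0, sqrt(g("oi"))), no, ni)
    resid <- rnorm(nrow(grid), 0, sqrt(g("pio,e")))
    lin <- lin + e_i[grid$trial] + e_o[grid$occasion] +
      e_pi[cbind(grid$person, grid$trial)] +
      e_po[cbind(grid$person, grid$occasion)] +
      e_oi[cbind(grid$occasion, grid$trial)] + resid
  } else {
    e_i <- rnorm(ni, 0, sqrt(g("i")))
    resid <- rnorm(nrow(grid), 0, sqrt(g("pi,e")))
    lin <- lin + e_i[grid$trial] + resid
  }

  out <- data.frame(person = persons[grid$person], trial = grid$trial)
  if (!is.null(spec$trials_per_split)) out$split <- grid$split
  if (no > 1L) out$occasion = paste0("occ", grid$occasion)
  out$score <- family_transform(lin, spec$family)

  if (spec$retention < 1) {
    kept_trials <- lapply(seq_len(np), function(p) {
      k <- which(stats::runif(ni) < spec$retention)
      if (!length(k)) k <- 1L  # never lose a person entirely
      k
    })
    keep <- mapply(function(p, t) t %in% kept_trials[[p]], grid$person, grid$trial)
    out <- out[keep, , drop = FALSE]
  }
  if (spec$zero_inflation > 0) {
    z <- stats::runif(nrow(out)) < spec$zero_inflation
    out$score[z] <- 0
  }

  list(table = as_gt_table(out),
       truth = list(components = comp, mu = spec$mu, family = spec$family,
                    n_persons = np, n_trials = ni, n_occasions = spec$n_occasions,
                    trials_per_split = spec$trials_per_split,
                    retention = spec$retention,
                    zero_inflation = spec$zero_inflation, seed = spec$seed))
}

family_transform <- function(lin, family) {
  switch(family, gaussian = lin, lognormal = exp(lin), gamma_chisq = lin^2)
}

# Two measures X and Y from the one-facet decomposition with person-level
# covariance (always) and trial-error covariance (concurrent pairs only).
# Emits long format with a 'measure' column; seed already set by the caller.
simulate_pair <- function(spec) {
  if (!is.null(spec$n_occasions) || !is.null(spec$trials_per_split))
    stop("measure-pair simulation is implemented for the Persons x Trials design")
  cb <- spec$covariance
  cx <- spec$components; cy <- cb$components_y
  gx <- function(l) if (l %in% names(cx)) cx[[l]] else 0
  gy <- function(l) if (l %in% names(cy)) cy[[l]] else 0
  gcv <- function(l) if (l %in% names(cb$cov)) cb$cov[[l]] else 0
  np <- spec$n_persons; ni <- spec$n_trials
  persons <- sprintf("P%03d", seq_len(np))

  rbvn <- function(n, v1, v2, cv) {
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- sqrt(v1) * z1
    if (v1 > 0) {
      b <- cv / v1
      y <- b * x + sqrt(max(v2 - b^2 * v1, 0)) * z2
    } else y <- sqrt(v2) * z2
    cbind(x, y)
  }
  ep <- rbvn(np, gx("p"), gy("p"), gcv("p"))
  eix <- rnorm(ni, 0, sqrt(gx("i")))
  eiy <- rnorm(ni, 0, sqrt(gy("i")))
  grid <- expand.grid(person = seq_len(np), trial = seq_len(ni))
  er <- if (isTRUE(cb$concurrent))
    rbvn(nrow(grid), gx("pi,e"), gy("pi,e"), gcv("pi,e"))
  else cbind(rnorm(nrow(grid), 0, sqrt(gx("pi,e"))),
             rnorm(nrow(grid), 0, sqrt(gy("pi,e"))))
  mu_y <- if (!is.null(cb$mu_y)) cb$mu_y else spec$mu
  lin_x <- spec$mu + ep[grid$person, 1] + eix[grid$trial] + er[, 1]
  lin_y <- mu_y + ep[grid$person, 2] + eiy[grid$trial] + er[, 2]
  out <- rbind(
    data.frame(person = persons[grid$person], trial = grid$trial, measure = "X",
               score = family_transform(lin_x, spec$family)),
    data.frame(person = persons[grid$person], trial = grid$trial, measure = "Y",
               score = family_transform(lin_y, spec$family)))
  list(table = as_gt_table(out),
       truth = list(components_x = cx, components_y = cy, cov = cb$cov,
                    concurrent = isTRUE(cb$concurrent), mu = spec$mu,
                    mu_y = mu_y, n_persons = np, n_trials = ni,
                    family = spec$family, seed = spec$seed))
}

#' Simulated three-task dataset reproducing the multi-task reliability pattern
#'
#' Generates a Persons x Trials x Tasks dataset in which the three tasks
#' share identical per-trial variance components but differ in the number
#' of retained error trials (as when task accuracy differs, so harder tasks
#' yield more usable error trials). The structural consequence: per-trial
#' intraclass correlations match across tasks while dependability at the
#' observed trial counts is ordered by retained trial count — and forcing a
#' common trial count makes the dependability differences vanish.
#'
#' @param seed Integer seed.
#' @param n_persons Persons (default 100).
#' @param trial_counts Named integer vector of retained trials per task
#'   (default `c(flanker = 88, stroop = 71, gonogo = 50)`, mirroring
#'   accuracy-driven differences in usable error trials).
#' @param components Shared per-trial components
#'   (default `c(p = 2, i = 0.2, "pi,e" = 4)`).
#' @param mu Grand mean (default -5, an ERN-like amplitude in microvolts).
#' @return List: `table` (gt_table with `task` column), `truth`.
#' @export
make_worked_example <- function(seed, n_persons = 100,
                                trial_counts = c(flanker = 88, stroop = 71,
                                                 gonogo = 50),
                                components = c(p = 2, i = 0.2, "pi,e" = 4),
                                mu = -5) {
  levels <- lapply(trial_counts, function(n)
    list(components = components, n_trials = as.integer(n)))
  spec <- sim_spec(n_persons = n_persons, n_trials = max(trial_counts),
                   components = components, mu = mu,
                   fixed_levels = list(task = levels), seed = seed)
  simulate_gt(spec)
}
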