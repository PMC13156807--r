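#' Estimate covariance components between two measures
#'
#' For difference scores (e.g., error minus correct ERN, contralateral
#' minus ipsilateral activity) the reliability of the difference depends on
#' covariance components between the two constituent measures X and Y. The
#' person-level covariance is always estimable. Error-level covariances
#' (e.g., between the trial-specific errors of X and Y) are estimable only
#' when the two measures are observed concurrently on the same trials;
#' for non-concurrent measures they are fixed at exactly zero.
#'
#' The EMS path uses the polarization identity on the raw (untruncated)
#' expected-mean-squares solutions of X+Y and X-Y for concurrent pairs
#' (cov = (VC(X+Y) - VC(X-Y)) / 4 per effect), and the sample covariance of
#' person means for non-concurrent pairs. The Bayes path fits a bivariate
#' multilevel model (one-facet designs only) with half-t SD priors and a
#' uniform prior on each correlation.
#'
#' Every covariance is constrained to the Cauchy-Schwarz bound implied by
#' the corresponding variance components; estimates beyond the bound are
#' clipped and flagged in `cs_clipped`.
#'
#' @param table A `gt_table` with a `measure` column holding exactly two
#'   labels.
#' @param design A `gt_design`.
#' @param concurrent Logical: were X and Y observed on the same trials?
#' @param estimator `"ems"` or `"bayes"`.
#' @param mcmc A [gt_mcmc()] configuration (Bayes path only).
#' @param priors A [gt_priors()] configuration (Bayes path only).
#' @return A `gt_covariances` list: `covariances` (named: `"p"` plus error
#'   effects), `concurrent`, `components_x`, `components_y`, `measures`,
#'   `cs_clipped`.
#' @export
estimate_covariances <- function(table, design, concurrent, estimator = c("ems", "bayes"),
                                 mcmc = NULL, priors = gt_priors()) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(table, "gt_table"), inherits(design, "gt_design"))
  if (!"measure" %in% names(table)) stop("table has no 'measure' column")
  meas <- sort(unique(as.character(table$measure)))
  if (length(meas) != 2L)
    stop("exactly two measure labels are required, found ", length(meas))

  split_measure <- function(m) {
    sub <- table[table$measure == m, setdiff(names(table), "measure"), drop = FALSE]
    structure(sub, class = c("gt_table", "data.frame"))
  }
  tx <- split_measure(meas[1]); ty <- split_measure(meas[2])

  if (estimator == "bayes") {
    if (is.null(mcmc)) stop("the Bayes path needs a gt_mcmc configuration")
    return(bayes_covariances(table, tx, ty, design, concurrent, meas, priors, mcmc))
  }

  vx <- estimate_ems(tx, design)
  vy <- estimate_ems(ty, design)
  labels <- names(vx$components)
  error_labels <- setdiff(labels, "p")

  if (concurrent) {
    key <- setdiff(names(tx), "score")
    merged <- merge(as.data.frame(tx), as.data.frame(ty), by = key,
                    suffixes = c("_x", "_y"))
    if (nrow(merged) != nrow(tx))
      stop("concurrent covariances need X and Y observed on the same trials")
    mk <- function(score) {
      d <- merged[key]; d$score <- score
      as_gt_table(d)
    }
    v_sum <- estimate_ems(mk(merged$score_x + merged$score_y), design)
    v_dif <- estimate_ems(mk(merged$score_x - merged$score_y), design)
    covs <- (v_sum$raw - v_dif$raw) / 4
  } else {
    pm_x <- tapply(tx$score, tx$person, mean)
    pm_y <- tapply(ty$score, ty$person, mean)
    common <- intersect(names(pm_x), names(pm_y))
    covs <- setNames(rep(0, length(labels)), labels)
    covs["p"] <- cov(pm_x[common], pm_y[common])
  }

  bound <- sqrt(vx$components[labels] * vy$components[labels])
  clipped <- abs(covs) > bound & is.finite(bound)
  covs[clipped] <- sign(covs[clipped]) * bound[clipped]
  if (!concurrent) covs[error_labels] <- 0  # exactly zero by design

  structure(list(covariances = covs, concurrent = concurrent,
                 components_x = vx, components_y = vy,
                 measures = meas, cs_clipped = clipped, estimator = estimator),
            class = "gt_covariances")
}

#' @export
print.gt_covariances <- function(x, ...) {
  cat("<gt_covariances>", x$measures[1], "vs", x$measures[2],
      if (x$concurrent) "(concurrent)" else "(non-concurrent: error covariances fixed at 0)", "\n")
  print(round(x$covariances, 5))
  if (any(x$cs_clipped))
    cat("  note: clipped to the Cauchy-Schwarz bound:",
        paste(names(x$cs_clipped)[x$cs_clipped], collapse = ", "), "\n")
  invisible(x)
}

# Bivariate one-facet multilevel model: person effects (and, when
# concurrent, trial effects and residuals) are bivariate normal across the
# two measures; separation prior (half-t SDs, uniform correlations).
bayes_covariances <- function(table, tx, ty, design, concurrent, meas, priors, mcmc) {
  if (design$layout != "one_facet")
    stop("the Bayes covariance path supports the Persons x Trials layout only; ",
         "use estimator = 'ems' for other layouts")
  persons <- sort(unique(table$person))
  pidx <- function(t) match(t$person, persons)
  sd_y <- sd(table$score); prec_s <- half_t_prec(sd_y, priors)
  dfst <- priors$sd_df

  if (concurrent) {
    key <- setdiff(names(tx), "score")
    merged <- merge(as.data.frame(tx), as.data.frame(ty), by = key,
                    suffixes = c("_x", "_y"))
    if (nrow(merged) != nrow(tx))
      stop("concurrent covariances need X and Y observed on the same trials")
    ii <- as.integer(factor(merged$trial))
    model <- paste0("model {
  for (n in 1:N) {
    z[n, 1:2] ~ dmnorm(mean_n[n, 1:2], TauE[1:2, 1:2])
    mean_n[n, 1] <- mu[1] + P[pp[n], 1] + I[ii[n], 1]
    mean_n[n, 2] <- mu[2] + P[pp[n], 2] + I[ii[n], 2]
  }
  for (j in 1:NP) { P[j, 1:2] ~ dmnorm(zero2, TauP[1:2, 1:2]) }
  for (k in 1:NI) { I[k, 1:2] ~ dmnorm(zero2, TauI[1:2, 1:2]) }
  for (m in 1:2) {
    mu[m] ~ dnorm(ybar, prec_mu)
    sdP[m] ~ dt(0, prec_s, ", dfst, ") T(0,)
    sdI[m] ~ dt(0, prec_s, ", dfst, ") T(0,)
    sdE[m] ~ dt(0, prec_s, ", dfst, ") T(0,)
  }
  rhoP ~ dunif(-1, 1); rhoI ~ dunif(-1, 1); rhoE ~ dunif(-1, 1)
  SigmaP[1,1] <- sdP[1]^2; SigmaP[2,2] <- sdP[2]^2
  SigmaP[1,2] <- rhoP * sdP[1] * sdP[2]; SigmaP[2,1] <- SigmaP[1,2]
  SigmaI[1,1] <- sdI[1]^2; SigmaI[2,2] <- sdI[2]^2
  SigmaI[1,2] <- rhoI * sdI[1] * sdI[2]; SigmaI[2,1] <- SigmaI[1,2]
  SigmaE[1,1] <- sdE[1]^2; SigmaE[2,2] <- sdE[2]^2
  SigmaE[1,2] <- rhoE * sdE[1] * sdE[2]; SigmaE[2,1] <- SigmaE[1,2]
  TauP <- inverse(SigmaP); TauI <- inverse(SigmaI); TauE <- inverse(SigmaE)
}
")
    data <- list(z = cbind(merged$score_x, merged$score_y),
                 pp = match(merged$person, persons), ii = ii,
                 N = nrow(merged), NP = length(persons), NI = max(ii),
                 zero2 = c(0, 0), prec_s = prec_s,
                 prec_mu = 1 / (10 * sd_y)^2, ybar = mean(table$score))
    res <- run_jags(model, data,
                    c("sdP", "sdI", "sdE", "rhoP", "rhoE", "mu"), mcmc)
    d <- res$draws
    cov_p <- d[, "rhoP"] * d[, "sdP[1]"] * d[, "sdP[2]"]
    cov_e <- d[, "rhoE"] * d[, "sdE[1]"] * d[, "sdE[2]"]
    covs <- c("p" = median(cov_p), "pi,e" = median(cov_e))
    mk_vc <- function(m) {
      dr <- cbind("p" = d[, paste0("sdP[", m, "]")]^2,
                  "i" = d[, paste0("sdI[", m, "]")]^2,
                  "pi,e" = d[, paste0("sdE[", m, "]")]^2)
      new_gt_components(apply(dr, 2, median),
                        grand_mean = median(d[, paste0("mu[", m, "]")]),
                        estimator = "bayes", layout = "one_facet", draws = dr,
                        mu_draws = d[, paste0("mu[", m, "]")])
    }
    vx <- mk_vc(1); vy <- mk_vc(2)
    cov_draws <- cbind(p = cov_p, `pi,e` = cov_e)
  } else {
    # non-concurrent: univariate GT model per measure, bivariate person effects
    df <- rbind(cbind(as.data.frame(tx), m = 1L), cbind(as.data.frame(ty), m = 2L))
    ii <- as.integer(factor(paste(df$m, df$trial)))
    mot <- vapply(split(df$m, ii), function(v) v[1], integer(1))
    model <- paste0("model {
  for (n in 1:N) { y[n] ~ dnorm(mu[m[n]] + P[pp[n], m[n]] + I[ii[n]], tauE[m[n]]) }
  for (j in 1:NP) { P[j, 1:2] ~ dmnorm(zero2, TauP[1:2, 1:2]) }
  for (k in 1:NI) { I[k] ~ dnorm(0, tauI[mot[k]]) }
  for (m_ in 1:2) {
    mu[m_] ~ dnorm(ybar, prec_mu)
    sdP[m_] ~ dt(0, prec_s, ", dfst, ") T(0,)
    sdI[m_] ~ dt(0, prec_s, ", dfst, ") T(0,)
    sdE[m_] ~ dt(0, prec_s, ", dfst, ") T(0,)
    tauI[m_] <- pow(sdI[m_], -2)
    tauE[m_] <- pow(sdE[m_], -2)
  }
  rhoP ~ dunif(-1, 1)
  SigmaP[1,1] <- sdP[1]^2; SigmaP[2,2] <- sdP[2]^2
  SigmaP[1,2] <- rhoP * sdP[1] * sdP[2]; SigmaP[2,1] <- SigmaP[1,2]
  TauP <- inverse(SigmaP)
}
")
    data <- list(y = df$score, pp = match(df$person, persons), m = df$m,
                 ii = ii, mot = mot, N = nrow(df), NP = length(persons),
                 NI = max(ii), zero2 = c(0, 0), prec_s = prec_s,
                 prec_mu = 1 / (10 * sd_y)^2, ybar = mean(table$score))
    res <- run_jags(model, data, c("sdP", "sdI", "sdE", "rhoP", "mu"), mcmc)
    d <- res$draws
    cov_p <- d[, "rhoP"] * d[, "sdP[1]"] * d[, "sdP[2]"]
    covs <- c("p" = median(cov_p), "pi,e" = 0)
    mk_vc <- function(m) {
      dr <- cbind("p" = d[, paste0("sdP[", m, "]")]^2,
                  "i" = d[, paste0("sdI[", m, "]")]^2,
                  "pi,e" = d[, paste0("sdE[", m, "]")]^2)
      new_gt_components(apply(dr, 2, median),
                        grand_mean = median(d[, paste0("mu[", m, "]")]),
                        estimator = "bayes", layout = "one_facet", draws = dr,
                        mu_draws = d[, paste0("mu[", m, "]")])
    }
    vx <- mk_vc(1); vy <- mk_vc(2)
    cov_draws <- cbind(p = cov_p, `pi,e` = rep(0, length(cov_p)))
  }

  labels <- names(vx$components)
  full <- setNames(rep(0, length(labels)), labels)
  full[names(covs)] <- covs
  bound <- sqrt(vx$components * vy$components)
  clipped <- abs(full) > bound & is.finite(bound)
  full[clipped] <- sign(full[clipped]) * bound[clipped]
  structure(list(covariances = full, concurrent = concurrent,
                 components_x = vx, components_y = vy, measures = meas,
                 cs_clipped = clipped, estimator = "bayes",
                 cov_draws = cov_draws),
            class = "gt_covariances")
}
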