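#' MCMC settings for the Bayesian estimator
#'
#' @param chains Number of chains (default 4).
#' @param iter Posterior draws kept per chain after warmup (default 1000).
#' @param adapt Adaptation iterations (default 500).
#' @param burn Post-adaptation burn-in iterations (default 500).
#' @param seed Integer random seed. Mandatory: there is no silent default.
#' @param rhat_max Convergence threshold on the split-chain potential scale
#'   reduction factor (default 1.01). Estimation fails loudly when any
#'   monitored parameter exceeds it.
#' @return A list of class `gt_mcmc`.
#' @export
gt_mcmc <- function(chains = 4, iter = 1000, adapt = 500, burn = 500,
                    seed, rhat_max = 1.01) {
  if (missing(seed) || is.null(seed)) stop("an MCMC seed is required (no silent default)")
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 adapt = as.integer(adapt), burn = as.integer(burn),
                 seed = as.integer(seed), rhat_max = rhat_max),
            class = "gt_mcmc")
}

#' Prior configuration for the Bayesian estimator
#'
#' Component standard deviations get weakly-informative positive
#' half-Student-t priors (df `sd_df`) with scale `sd_scale` times the
#' observed score SD on the modeling scale, which keeps all posterior
#' variance draws strictly positive while remaining diffuse relative to the
#' data. The grand mean gets a normal prior centered on the sample mean
#' with SD 10 times the observed score SD.
#'
#' @param sd_scale Multiplier of the observed score SD for the half-t scale
#'   (default 2.5).
#' @param sd_df Degrees of freedom of the half-t (default 3).
#' @param logsd_scale Half-t scale for the between-condition spread of log
#'   residual SDs in the heteroscedastic (location-scale) model (default 1,
#'   on the log-SD scale).
#' @return A list of class `gt_priors`.
#' @export
gt_priors <- function(sd_scale = 2.5, sd_df = 3, logsd_scale = 1) {
  structure(list(sd_scale = sd_scale, sd_df = sd_df, logsd_scale = logsd_scale),
            class = "gt_priors")
}

#' Estimate variance components with a Bayesian multilevel model
#'
#' Fits the generalizability-theory decomposition as a crossed
#' random-effects model in JAGS. Unlike expected-mean-squares or REML
#' estimation, the posterior draws of every variance component are strictly
#' positive by construction (half-t priors on SDs), unbalanced data are
#' handled naturally at the observation level, and the score family can be
#' non-Gaussian: `lognormal` models the linear decomposition of log scores
#' and `gamma_chisq` of square-root scores (positively skewed, zero-bounded
#' power-like data); components are reported on the modeling scale.
#'
#' When the design includes a fixed facet (e.g., task), a single joint
#' model estimates person, trial, and residual components separately for
#' each condition of that facet, enabling per-condition reliability and
#' posterior contrasts. With `heteroscedastic_by` set to that facet, the
#' per-condition residual SDs are drawn from a higher-level lognormal
#' distribution (a multilevel location-scale model); otherwise the residual
#' is shared across conditions.
#'
#' Convergence is enforced: if the split-chain potential scale reduction
#' factor of any monitored parameter exceeds `mcmc$rhat_max`, or any draw
#' is not finite, estimation fails with a convergence error.
#'
#' @param table A `gt_table`.
#' @param design A `gt_design`.
#' @param priors A [gt_priors()] configuration.
#' @param mcmc A [gt_mcmc()] configuration (seed mandatory).
#' @param heteroscedastic_by Optional name of a fixed facet whose
#'   conditions get separate residual variances under a higher-level
#'   distribution.
#' @return A `gt_components` object (`estimator = "bayes"`) with posterior
#'   `draws`; point estimates are posterior medians.
#' @export
estimate_bayes <- function(table, design, priors = gt_priors(), mcmc,
                           heteroscedastic_by = NULL) {
  stopifnot(inherits(table, "gt_table"), inherits(design, "gt_design"),
            inherits(mcmc, "gt_mcmc"), inherits(priors, "gt_priors"))
  validate_design(table, design)
  if (!is.null(heteroscedastic_by)) {
    if (!heteroscedastic_by %in% fixed_facets(design))
      stop("heteroscedastic_by must name a fixed facet of the design")
  }

  df <- as.data.frame(table)
  df$y <- transform_scores(df$score, design$family)
  layout <- design$layout
  ff <- fixed_facets(design)
  if (length(ff) > 1L) stop("at most one fixed facet is supported")

  if (length(ff) == 1L && layout != "one_facet") {
    # joint location-scale model is implemented for the Persons x Trials
    # layout; richer layouts fit one model per fixed condition (equivalent
    # component estimates, no joint contrasts)
    lev <- sort(unique(as.character(df[[ff]])))
    sub_design <- design
    sub_design$facets[[ff]] <- NULL
    sub_design$layout <- design_layout(sub_design)
    by_level <- lapply(seq_along(lev), function(j) {
      sub <- table[as.character(table[[ff]]) == lev[j], , drop = FALSE]
      sub[[ff]] <- NULL
      sub_mcmc <- mcmc; sub_mcmc$seed <- mcmc$seed + j
      estimate_bayes(structure(sub, class = c("gt_table", "data.frame")),
                     sub_design, priors, sub_mcmc)
    })
    names(by_level) <- lev
    return(pool_by_level(by_level, ff, layout = sub_design$layout))
  }

  fit <- if (length(ff) == 1L) {
    bayes_one_facet_fixed(df, ff, priors, mcmc,
                          heteroscedastic = identical(heteroscedastic_by, ff))
  } else {
    bayes_random_layout(df, layout, priors, mcmc)
  }
  fit$family <- design$family
  fit$scale <- c(gaussian = "identity", lognormal = "log", gamma_chisq = "sqrt")[[design$family]]
  if (!is.null(fit$by_level))
    for (l in names(fit$by_level)) {
      fit$by_level[[l]]$family <- design$family
      fit$by_level[[l]]$scale <- fit$scale
    }
  fit
}

transform_scores <- function(score, family) {
  switch(family,
    gaussian = score,
    lognormal = {
      if (any(score <= 0))
        stop("family error: lognormal scores must be strictly positive")
      log(score)
    },
    gamma_chisq = {
      if (any(score < 0))
        stop("family error: gamma_chisq scores must be nonnegative")
      sqrt(score)
    })
}

# ---- JAGS plumbing -------------------------------------------------------

run_jags <- function(model_string, data, monitors, mcmc) {
  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(mcmc$chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed + k))
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = mcmc$chains,
                             n.adapt = mcmc$adapt, quiet = TRUE)
  if (mcmc$burn > 0) update(model, mcmc$burn)
  samp <- rjags::coda.samples(model, monitors, n.iter = mcmc$iter)
  mat <- as.matrix(samp)
  if (!all(is.finite(mat)))
    stop("convergence error: sampler produced non-finite draws")
  rhat <- split_rhat(samp)
  if (any(rhat > mcmc$rhat_max, na.rm = TRUE)) {
    bad <- names(rhat)[which(rhat > mcmc$rhat_max)]
    stop("convergence error: split-chain R-hat above ", mcmc$rhat_max, " for ",
         paste(bad, collapse = ", "),
         " (increase iterations or reparameterize)")
  }
  list(draws = mat, rhat = rhat, chains = samp)
}

# Split-chain potential scale reduction factor (each chain halved).
split_rhat <- function(samp) {
  mats <- lapply(samp, as.matrix)
  n <- nrow(mats[[1]])
  half <- n %/% 2L
  halves <- unlist(lapply(mats, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1L):n, , drop = FALSE])), recursive = FALSE)
  vars <- colnames(mats[[1]])
  out <- vapply(vars, function(v) {
    ch <- vapply(halves, function(m) c(mean(m[, v]), var(m[, v])), numeric(2))
    W <- mean(ch[2, ])
    B <- half * var(ch[1, ])
    if (W <= 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  out
}

half_t_prec <- function(sd_y, priors) 1 / (priors$sd_scale * sd_y)^2

# ---- layouts without a fixed facet ---------------------------------------

bayes_random_layout <- function(df, layout, priors, mcmc) {
  pp <- as.integer(factor(df$person))
  np <- max(pp)
  sd_y <- sd(df$y); prec_s <- half_t_prec(sd_y, priors)
  prec_mu <- 1 / (10 * sd_y)^2
  base_data <- list(y = df$y, pp = pp, N = nrow(df), P = np,
                    prec_s = prec_s, prec_mu = prec_mu, ybar = mean(df$y))

  # each entry: component label -> list(size-constant name, index-vector name)
  spec <- switch(layout,
    one_facet = {
      ii <- as.integer(factor(df$trial))
      list(data = c(base_data, list(ii = ii, I = max(ii))),
           effects = list(i = c("I", "ii")),
           residual = "pi,e")
    },
    two_facet = {
      ii <- as.integer(factor(df$trial)); oo <- as.integer(factor(df$occasion))
      ni <- max(ii); no <- max(oo)
      list(data = c(base_data, list(
             ii = ii, I = ni, oo = oo, O = no,
             cpi = (pp - 1L) * ni + ii, CPI = np * ni,
             cpo = (pp - 1L) * no + oo, CPO = np * no,
             coi = (oo - 1L) * ni + ii, COI = ni * no)),
           effects = list(i = c("I", "ii"), o = c("O", "oo"),
                          pi = c("CPI", "cpi"), po = c("CPO", "cpo"),
                          oi = c("COI", "coi")),
           residual = "pio,e")
    },
    splits = {
      ss <- as.integer(factor(df$split)); ns <- max(ss)
      tin <- as.integer(factor(paste(df$split, df$trial)))  # trial nested in split
      list(data = c(base_data, list(ss = ss, S = ns, tin = tin, TIN = max(tin),
                                    cps = (pp - 1L) * ns + ss, CPS = np * ns)),
           effects = list(s = c("S", "ss"), `i:s` = c("TIN", "tin"),
                          ps = c("CPS", "cps")),
           residual = "p(i:s),e")
    },
    splits_occasion = {
      ss <- as.integer(factor(df$split)); ns <- max(ss)
      oo <- as.integer(factor(df$occasion)); no <- max(oo)
      tin <- as.integer(factor(paste(df$split, df$trial)))
      list(data = c(base_data, list(ss = ss, S = ns, oo = oo, O = no,
                                    tin = tin, TIN = max(tin),
                                    cps = (pp - 1L) * ns + ss, CPS = np * ns,
                                    cpo = (pp - 1L) * no + oo, CPO = np * no)),
           effects = list(s = c("S", "ss"), `i:s` = c("TIN", "tin"),
                          o = c("O", "oo"), ps = c("CPS", "cps"),
                          po = c("CPO", "cpo")),
           residual = "p(i:s),e")
    },
    stop("unsupported layout for the Bayesian estimator: ", layout))

  eff_names <- names(spec$effects)
  jid <- function(e) gsub("[^a-zA-Z]", "", e)  # "i:s" -> "is"
  terms <- paste(c("p[pp[n]]",
                   vapply(eff_names, function(e)
                     paste0(jid(e), "_[", spec$effects[[e]][2], "[n]]"),
                     character(1))),
                 collapse = " + ")
  blocks <- vapply(eff_names, function(e) {
    id <- jid(e)
    paste0("  for (j in 1:", spec$effects[[e]][1], ") { ", id,
           "_[j] ~ dnorm(0, tau_", id, ") }\n",
           "  sd_", id, " ~ dt(0, prec_s, ", priors$sd_df, ") T(0,)\n",
           "  tau_", id, " <- pow(sd_", id, ", -2)\n")
  }, character(1))
  model <- paste0(
    "model {\n",
    "  for (n in 1:N) { y[n] ~ dnorm(mu + ", terms, ", tau_e) }\n",
    "  for (j in 1:P) { p[j] ~ dnorm(0, tau_p) }\n",
    "  sd_p ~ dt(0, prec_s, ", priors$sd_df, ") T(0,)\n",
    "  tau_p <- pow(sd_p, -2)\n",
    paste(blocks, collapse = ""),
    "  sd_e ~ dt(0, prec_s, ", priors$sd_df, ") T(0,)\n",
    "  tau_e <- pow(sd_e, -2)\n",
    "  mu ~ dnorm(ybar, prec_mu)\n",
    "}\n")

  sd_monitors <- c("sd_p", paste0("sd_", vapply(eff_names, jid, character(1))), "sd_e")
  res <- run_jags(model, spec$data, c("mu", sd_monitors), mcmc)

  labels <- c("p", eff_names, spec$residual)
  sd_cols <- sd_monitors
  draws <- res$draws[, sd_cols, drop = FALSE]^2
  colnames(draws) <- labels
  comps <- apply(draws, 2, median)
  new_gt_components(comps, grand_mean = median(res$draws[, "mu"]),
                    estimator = "bayes", layout = layout,
                    draws = draws, mu_draws = res$draws[, "mu"],
                    diagnostics = list(rhat = res$rhat,
                                       chains = mcmc$chains, iter = mcmc$iter),
                    n = list(persons = np, observations = nrow(df)))
}

# ---- Persons x Trials with a fixed facet (single joint model) ------------

bayes_one_facet_fixed <- function(df, ff, priors, mcmc, heteroscedastic) {
  pp <- as.integer(factor(df$person)); np <- max(pp)
  kk <- as.integer(factor(as.character(df[[ff]])))
  lev <- levels(factor(as.character(df[[ff]])))
  K <- max(kk)
  # trial effects are specific to each fixed condition (trial 7 of task A is
  # unrelated to trial 7 of task B)
  tid <- as.integer(factor(paste(kk, df$trial)))
  task_of_trial <- vapply(split(kk, tid), function(v) v[1], integer(1))
  sd_y <- sd(df$y); prec_s <- half_t_prec(sd_y, priors)

  resid_block <- if (heteroscedastic) paste0(
    "  for (k in 1:K) {\n",
    "    log_sd_e[k] ~ dnorm(eta_e, tau_eta)\n",
    "    sd_e[k] <- exp(log_sd_e[k])\n",
    "    tau_e[k] <- pow(sd_e[k], -2)\n",
    "  }\n",
    "  eta_e ~ dnorm(log_sd_y, 0.25)\n",
    "  sd_eta ~ dt(0, ", 1 / priors$logsd_scale^2, ", ", priors$sd_df, ") T(0,)\n",
    "  tau_eta <- pow(sd_eta, -2)\n")
  else paste0(
    "  sd_e0 ~ dt(0, prec_s, ", priors$sd_df, ") T(0,)\n",
    "  for (k in 1:K) { sd_e[k] <- sd_e0 \n tau_e[k] <- pow(sd_e0, -2) }\n")

  # centered parameterization (person effects drawn around mu[k]): with many
  # observations per person the centered form mixes the per-condition means
  # far better than mu[k] + zero-centered effects. The per-condition mean
  # trial effect (ibar) is swept into the person-effect prior so that mu[k]
  # stays decoupled from the slow drift direction shared by all trial
  # effects of a condition; sweeping it in the likelihood instead would give
  # ibar every observation as a child and cripple the sampler.
  model <- paste0(
    "model {\n",
    "  for (n in 1:N) { y[n] ~ dnorm(pc[pp[n], kk[n]] + i_[tid[n]], tau_e[kk[n]]) }\n",
    "  for (j in 1:P) { for (k in 1:K) { pc[j, k] ~ dnorm(mu[k] - ibar[k], tau_p[k]) } }\n",
    "  for (t in 1:TID) { i_[t] ~ dnorm(0, tau_i[tot[t]]) }\n",
    "  for (k in 1:K) { ibar[k] <- inprod(M[k, ], i_) }\n",
    "  for (k in 1:K) {\n",
    "    sd_p[k] ~ dt(0, prec_s, ", priors$sd_df, ") T(0,)\n",
    "    tau_p[k] <- pow(sd_p[k], -2)\n",
    "    sd_i[k] ~ dt(0, prec_s, ", priors$sd_df, ") T(0,)\n",
    "    tau_i[k] <- pow(sd_i[k], -2)\n",
    "    mu[k] ~ dnorm(ybar, prec_mu)\n",
    "  }\n",
    resid_block,
    "}\n")

  TID <- max(tid)
  # M[k, t] = 1/n_k for trials of condition k, 0 otherwise (sweep weights)
  M <- t(vapply(seq_len(K), function(k)
    (task_of_trial == k) / sum(task_of_trial == k), numeric(TID)))
  data <- list(y = df$y, pp = pp, kk = kk, tid = tid, tot = task_of_trial,
               N = nrow(df), P = np, K = K, TID = TID, M = M,
               prec_s = prec_s, prec_mu = 1 / (10 * sd_y)^2, ybar = mean(df$y))
  if (heteroscedastic) data$log_sd_y <- log(sd_y)
  res <- run_jags(model, data, c("mu", "sd_p", "sd_i", "sd_e"), mcmc)

  by_level <- lapply(seq_len(K), function(k) {
    dr <- cbind("p" = res$draws[, paste0("sd_p[", k, "]")]^2,
                "i" = res$draws[, paste0("sd_i[", k, "]")]^2,
                "pi,e" = res$draws[, paste0("sd_e[", k, "]")]^2)
    new_gt_components(apply(dr, 2, median),
                      grand_mean = median(res$draws[, paste0("mu[", k, "]")]),
                      estimator = "bayes", layout = "one_facet", draws = dr,
                      mu_draws = res$draws[, paste0("mu[", k, "]")],
                      diagnostics = list(rhat = res$rhat),
                      n = list(persons = np,
                               trials = sum(task_of_trial == k)))
  })
  names(by_level) <- lev
  fit <- pool_by_level(by_level, ff, layout = "one_facet")
  fit$diagnostics <- list(rhat = res$rhat, chains = mcmc$chains, iter = mcmc$iter,
                          heteroscedastic = heteroscedastic)
  fit
}

# Global components as the unweighted per-draw mean over fixed-facet levels
# (explicitly an average over the fixed conditions; per-level sets carry the
# substantive results).
pool_by_level <- function(by_level, ff, layout) {
  labs <- names(by_level[[1]]$components)
  if (!is.null(by_level[[1]]$draws)) {
    nd <- min(vapply(by_level, function(b) nrow(b$draws), numeric(1)))
    draws <- Reduce(`+`, lapply(by_level, function(b)
      b$draws[seq_len(nd), labs, drop = FALSE])) / length(by_level)
    mu_draws <- Reduce(`+`, lapply(by_level, function(b)
      b$mu_draws[seq_len(nd)])) / length(by_level)
    fit <- new_gt_components(apply(draws, 2, median),
                             grand_mean = median(mu_draws),
                             estimator = "bayes", layout = layout,
                             draws = draws, mu_draws = mu_draws,
                             by_level = by_level)
  } else {
    comps <- rowMeans(sapply(by_level, function(b) b$components[labs]))
    fit <- new_gt_components(comps,
                             grand_mean = mean(vapply(by_level, `[[`, numeric(1), "grand_mean")),
                             estimator = by_level[[1]]$estimator, layout = layout,
                             by_level = by_level)
  }
  fit$fixed_facet <- ff
  fit$note <- paste0("global components average over the ", length(by_level),
                     " conditions of fixed facet '", ff, "'")
  fit
}
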