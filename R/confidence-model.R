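#' Slope of the hint-benefit line from its intercept and criterion
#'
#' In the negative-slope family the confidence model estimates only the
#' intercept `beta0`; the slope follows from the ask criterion fitted to
#' the choice data: `beta1 = (0.075 - beta0) / C`. On the valid range
#' `beta0 in (0.075, 1)` with `C > 0` the slope is necessarily negative.
#' Mutual inverse of [criterion_from_intercept()].
#'
#' @param beta0 Intercept in (0.075, 1).
#' @param c Positive criterion from the winning choice model.
#' @return The slope `beta1`.
#' @export
derive_beta1 <- function(beta0, c) {
  if (any(c <= 0)) stop("the criterion must be positive")
  (offload_constants()$THRESHOLD - beta0) / c
}

#' Predicted confidence rating
#'
#' Without a hint, predicted confidence is the latent recall probability
#' plus a report bias; with a hint, the subjective hint benefit is added
#' too. Predictions are clipped into the \[0, 1\] rating range.
#'
#' @param p_rec Latent recall probability.
#' @param p_hint_s Subjective hint benefit (ignored without a hint).
#' @param bias Additive report bias.
#' @param with_hint Logical: is this a confidence-with-hint trial.
#' @return Predicted confidence proportion.
#' @export
predicted_confidence <- function(p_rec, p_hint_s, bias, with_hint) {
  n <- max(length(p_rec), length(p_hint_s), length(bias),
           length(with_hint))
  wh <- rep_len(as.logical(with_hint), n)
  add <- numeric(n)
  add[wh] <- rep_len(p_hint_s, n)[wh]
  pmin(pmax(rep_len(p_rec, n) + add + rep_len(bias, n), 0), 1)
}

#' Enumerate the confidence-model lattice
#'
#' Four constraint patterns on the intercept `beta0` across the
#' 2 x 2 design (all equal; by difficulty; by saved status; all free), or
#' two difficulty-wise patterns for the all-saved variant. The first
#' experiment collects no confidence ratings.
#'
#' @param variant Experiment variant.
#' @return Data frame of confidence specs.
#' @export
enumerate_confidence_specs <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  if (variant == "exp1") stop("exp1 has no confidence ratings to model")
  patterns <- if (variant == "exp3") 1:2 else 1:4
  out <- data.frame(spec_id = sprintf("conf-b%d", patterns),
                    family = "confidence", beta0_pattern = patterns,
                    variant = variant, stringsAsFactors = FALSE)
  out$n_free <- vapply(patterns, function(p) {
    length(unique(c_group_map(variant, p))) + 2L
  }, integer(1))
  out
}

#' Plug-in inputs for the confidence model
#'
#' Extracts, from a winning slope-family choice fit, the per-free-trial
#' posterior-mean latent recall probabilities and the participant-level
#' posterior-mean criterion per cell, as point estimates to condition the
#' confidence model on.
#'
#' @param fit A `posterior_fit` of a slope-family model.
#' @return List with `p_rec_means` (per free-choice trial) and `c_means`
#'   (participants x cells matrix).
#' @export
confidence_inputs <- function(fit) {
  if (fit$spec$family == "constant") {
    stop("the constant family has no criterion to feed the confidence model")
  }
  cgrp <- fit$maps$cgrp
  dec <- fit$param_means$dec
  c_means <- dec[, cgrp, drop = FALSE]
  rownames(c_means) <- fit$data_info$ids
  list(p_rec_means = fit$p_rec_trial_means, c_means = c_means)
}

build_confidence_model <- function() {
  "model {
  for (g in 1:G0) {
    mu_b0[g] ~ dnorm(0, 0.4444)
    sig_b0[g] ~ dnorm(0, 1) T(0,)
    tau_b0[g] <- pow(sig_b0[g], -2)
  }
  mu_bias ~ dnorm(0, 0.4444)
  sig_bias ~ dnorm(0, 1) T(0,)
  tau_bias <- pow(sig_bias, -2)
  mu_ls ~ dnorm(-1.9, 0.5)
  sig_ls ~ dnorm(0, 1) T(0,)
  tau_ls <- pow(sig_ls, -2)
  for (i in 1:P) {
    for (g in 1:G0) {
      z0[i, g] ~ dnorm(mu_b0[g], tau_b0[g])
      beta0[i, g] <- 0.075 + 0.925 * ilogit(z0[i, g])
    }
    zb[i] ~ dnorm(mu_bias, tau_bias)
    bias[i] <- 2 * ilogit(zb[i]) - 1
    zs[i] ~ dnorm(mu_ls, tau_ls)
    sigma[i] <- exp(zs[i])
    tauc[i] <- pow(sigma[i], -2)
  }
  for (t in 1:N) {
    b1[t] <- (0.075 - beta0[pp[t], grp[cc[t]]]) / Cm[pp[t], cc[t]]
    phs[t] <- min(max(beta0[pp[t], grp[cc[t]]] + b1[t] * prec[t], 0), 1)
    predc[t] <- min(max(prec[t] + wh[t] * phs[t] + bias[pp[t]], 0), 1)
    conf[t] ~ dnorm(predc[t], tauc[pp[t]])
    ll[t] <- logdensity.norm(conf[t], predc[t], tauc[pp[t]])
  }
  dev <- -2 * sum(ll)
}"
}

# R-side confidence log-likelihood, used for the plug-in deviance
confidence_loglik <- function(beta0, c, prec, bias, sigma, wh, conf) {
  b1 <- derive_beta1(beta0, c)
  phs <- phint_subjective(beta0, b1, prec)
  pred <- predicted_confidence(prec, phs, bias, wh)
  sum(stats::dnorm(conf, pred, sigma, log = TRUE))
}

#' Fit a confidence-rating model
#'
#' Hierarchical fit of reported confidence on free-choice trials:
#' `confidence ~ Normal(predicted confidence, sigma_conf^2)` with the
#' subjective hint benefit `P_hint_s = clip(beta0 + beta1 * P_rec, 0, 1)`
#' and `beta1` derived per cell from `beta0` and the plugged-in criterion.
#' `beta0` lives on (0.075, 1) (sampled on a logit-rescaled support) and is
#' tied across cells per the spec's pattern; `bias` (in (-1, 1)) and
#' `sigma_conf` are per participant. The Gaussian likelihood is left
#' untruncated, as in the original model.
#'
#' @param spec One row of [enumerate_confidence_specs()].
#' @param table The `trial_table` the choice model was fitted to.
#' @param p_rec_means Posterior-mean latent recall probability for every
#'   free-choice trial of `filter_ineligible(table)` (see
#'   [confidence_inputs()]).
#' @param c_means Participants x cells matrix of positive criteria.
#' @param config An [mcmc_config()].
#' @return A `posterior_fit` (deviance trace, R-hat, DIC as for the choice
#'   models).
#' @export
fit_confidence_model <- function(spec, table, p_rec_means, c_means,
                                 config = mcmc_test_config(),
                                 quiet = TRUE) {
  spec <- as.list(spec)
  variant <- table_variant(table)
  if (variant == "exp1") stop("exp1 has no confidence ratings")
  if (!identical(spec$variant, variant)) {
    stop("table variant does not match the confidence spec")
  }
  if (any(c_means <= 0)) stop("criteria must be positive")
  tab <- filter_ineligible(table)
  free <- which(tab$test_type == "free")
  if (length(p_rec_means) != length(free)) {
    stop("p_rec_means must align with the free-choice trials of the ",
         "eligible-trial table")
  }
  has_conf <- !is.na(tab$confidence_prop[free])
  if (!any(has_conf)) stop("no confidence ratings on free-choice trials")
  rows <- free[has_conf]
  ids <- unique(tab$participant_id)
  grp <- c_group_map(variant, spec$beta0_pattern)
  pp <- match(tab$participant_id[rows], ids)
  cc <- cell_index(tab)[rows]
  P <- length(ids)
  G0 <- max(grp)
  if (is.null(rownames(c_means))) rownames(c_means) <- ids
  jdata <- list(N = length(rows), P = P, G0 = G0, grp = grp,
                pp = pp, cc = cc,
                prec = as.numeric(p_rec_means[has_conf]),
                wh = as.integer(tab$confidence_condition[rows] ==
                                  "with_hint"),
                Cm = c_means[ids, , drop = FALSE],
                conf = tab$confidence_prop[rows])
  t0 <- Sys.time()
  model <- rjags::jags.model(textConnection(build_confidence_model()),
                             data = jdata, inits = chain_inits(config),
                             n.chains = config$n_chains,
                             n.adapt = config$n_adapt, quiet = quiet)
  if (config$n_burnin > 0) {
    stats::update(model, config$n_burnin,
                  progress.bar = if (quiet) "none" else "text")
  }
  samples <- rjags::coda.samples(
    model, variable.names = c("beta0", "bias", "sigma", "mu_b0", "sig_b0",
                              "mu_bias", "mu_ls", "dev"),
    n.iter = config$n_samples, thin = config$thin,
    progress.bar = if (quiet) "none" else "text")
  draws <- as.matrix(samples)
  par_cols <- setdiff(colnames(draws), "dev")
  rhat <- rhat_columns(lapply(samples, function(s) s[, par_cols,
                                                     drop = FALSE]))
  beta0_means <- named_matrix_means(draws, "beta0", P, G0)
  bias_means <- vapply(seq_len(P), function(i) {
    mean(draws[, sprintf("bias[%d]", i)])
  }, numeric(1))
  sigma_means <- vapply(seq_len(P), function(i) {
    mean(draws[, sprintf("sigma[%d]", i)])
  }, numeric(1))
  dev_at_means <- -2 * confidence_loglik(
    beta0_means[cbind(pp, grp[cc])],
    jdata$Cm[cbind(pp, cc)], jdata$prec, bias_means[pp], sigma_means[pp],
    jdata$wh == 1L, jdata$conf)
  fit <- structure(list(
    spec = spec,
    samples = lapply(samples, function(s) s[, par_cols, drop = FALSE]),
    deviance_trace = as.numeric(draws[, "dev"]),
    dev_at_means = dev_at_means,
    rhat = rhat,
    converged = all(rhat < 1.1, na.rm = TRUE),
    param_means = list(beta0 = beta0_means, bias = bias_means,
                       sigma_conf = sigma_means),
    maps = list(grp = grp),
    data_info = list(ids = ids, rows = rows, pp = pp, cc = cc),
    config = config,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "posterior_fit")
  fit$dic <- dic(fit)
  fit
}
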