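#' MCMC configuration
#'
#' Full-scale runs mirror the original analysis: 4 chains of 100,000
#' iterations each, half discarded as burn-in. `mcmc_test_config()` is a
#' scaled-down preset used throughout the test suite and the pipeline's
#' test scale.
#'
#' @param n_chains Number of chains (>= 2 so convergence can be assessed).
#' @param n_samples Post-burn-in iterations per chain.
#' @param n_burnin Burn-in iterations per chain.
#' @param n_adapt Sampler adaptation iterations.
#' @param thin Thinning interval for stored draws, or `"auto"` to store at
#'   most ~600 draws per chain.
#' @param seed Integer seed controlling all chain RNGs.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4L, n_samples = 50000L,
                        n_burnin = 50000L, n_adapt = 1000L, thin = "auto",
                        seed = 1L) {
  stopifnot(n_chains >= 2L, n_samples >= 2L, n_burnin >= 0L)
  if (identical(thin, "auto")) thin <- max(1L, ceiling(n_samples / 600))
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_burnin = as.integer(n_burnin),
                 n_adapt = as.integer(n_adapt), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_test_config <- function(seed = 1L) {
  mcmc_config(n_chains = 3L, n_samples = 1200L, n_burnin = 600L,
              n_adapt = 300L, thin = 1L, seed = seed)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `R-hat = sqrt(V-hat / W)` where `W` is the mean within-chain variance,
#' `B = n * var(chain means)` the between-chain variance, and
#' `V-hat = ((n - 1) / n) W + B / n`. Values near 1 indicate the chains
#' have mixed; fits are screened at R-hat < 1.1.
#'
#' @param chains A list of equal-length numeric vectors (one per chain) or
#'   a matrix with one column per chain.
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  chains <- lapply(chains, as.numeric)
  m <- length(chains)
  if (m < 2L) stop("need at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 2L) stop("chains must have length >= 2")
  within <- vapply(chains, stats::var, numeric(1))
  W <- mean(within)
  if (W <= 0) stop("zero within-chain variance: degenerate chain")
  means <- vapply(chains, mean, numeric(1))
  B <- n * stats::var(means)
  v_hat <- (n - 1) / n * W + B / n
  sqrt(v_hat / W)
}

# R-hat for every column of an mcmc.list; degenerate columns give NA.
rhat_columns <- function(samples) {
  cols <- colnames(samples[[1]])
  vapply(cols, function(p) {
    ch <- lapply(samples, function(s) as.numeric(s[, p]))
    tryCatch(gelman_rubin(ch), error = function(e) NA_real_)
  }, numeric(1))
}

# ---- JAGS model assembly ------------------------------------------------

choice_indicator <- function(family) {
  switch(family,
    constant = "step(dec[pp[t], cgrp[cc[t]]] - 0.075)",
    positive_slope = "step(prec[t] - dec[pp[t], cgrp[cc[t]]])",
    negative_slope = "step(dec[pp[t], cgrp[cc[t]]] - prec[t])"
  )
}

build_choice_model <- function(family, pooling, fix_v, fix_ph) {
  dec_block <- if (pooling == "hierarchical") "
  for (g in 1:Gc) {
    mu_dec[g] ~ dnorm(0, 0.4444)
    sig_dec[g] ~ dnorm(0, 1) T(0,)
    tau_dec[g] <- pow(sig_dec[g], -2)
  }
  for (i in 1:P) { for (g in 1:Gc) {
    z_dec[i, g] ~ dnorm(mu_dec[g], tau_dec[g])
    dec[i, g] <- ilogit(z_dec[i, g])
  } }" else "
  for (i in 1:P) { for (g in 1:Gc) { dec[i, g] ~ dunif(0, 1) } }"
  ph_block <- if (fix_ph) "" else if (pooling == "hierarchical") "
  for (g in 1:Gh) {
    mu_ph[g] ~ dnorm(0, 0.4444)
    sig_ph[g] ~ dnorm(0, 1) T(0,)
    tau_ph[g] <- pow(sig_ph[g], -2)
  }
  for (i in 1:P) { for (g in 1:Gh) {
    z_ph[i, g] ~ dnorm(mu_ph[g], tau_ph[g])
    Ph[i, g] <- ilogit(z_ph[i, g])
  } }" else "
  for (i in 1:P) { for (g in 1:Gh) { Ph[i, g] ~ dunif(0, 1) } }"
  v_block <- if (fix_v) "" else if (pooling == "hierarchical") "
  for (k in 1:K) {
    mu_v[k] ~ dnorm(1.6094, 1)
    sig_v[k] ~ dnorm(0, 1) T(0,)
    tau_v[k] <- pow(sig_v[k], -2)
  }
  for (i in 1:P) { for (k in 1:K) {
    z_v[i, k] ~ dnorm(mu_v[k], tau_v[k])
    V[i, k] <- exp(z_v[i, k])
  } }" else "
  for (i in 1:P) { for (k in 1:K) { V[i, k] ~ dlnorm(1.6094, 1) } }"
  sprintf("model {%s%s%s
  for (t in 1:N) {
    prec[t] ~ dbeta(Urec[pp[t], cc[t]] * V[pp[t], cc[t]],
                    (1 - Urec[pp[t], cc[t]]) * V[pp[t], cc[t]]) T(0.001, 0.999)
    pask[t] <- 0.001 + 0.998 * %s
    ask[t] ~ dbern(pask[t])
    prr[t] <- hint[t] * min(prec[t] + Ph[pp[t], hgrp[dd[t]]], 0.999) +
              (1 - hint[t]) * prec[t]
    rec[t] ~ dbern(prr[t])
    ll[t] <- logdensity.bern(ask[t], pask[t]) +
             logdensity.bern(rec[t], prr[t])
  }
  dev <- -2 * sum(ll)
}", dec_block, ph_block, v_block, choice_indicator(family))
}

chain_inits <- function(config) {
  lapply(seq_len(config$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (config$seed * 1009 + ch * 7919) %% 2147483647L)
  })
}

# participant/cell/trial bookkeeping shared by fitting and prediction
choice_model_data <- function(table) {
  tab <- filter_ineligible(table)
  variant <- table_variant(tab)
  free <- which(tab$test_type == "free")
  if (!length(free)) stop("no free-choice trials to fit")
  ids <- unique(tab$participant_id)
  cells <- condition_cells(variant)
  cc_all <- cell_index(tab)
  list(table = tab, variant = variant, free = free, ids = ids,
       cells = cells,
       pp = match(tab$participant_id[free], ids),
       cc = cc_all[free],
       dd = ifelse(tab$difficulty[free] == "easy", 1L, 2L),
       ask = as.integer(tab$choice[free] == "ask"),
       hint = as.integer(tab$hint_shown[free]),
       rec = tab$recall[free],
       saved = tab$saved[free],
       u_rec = u_rec_matrix(tab))
}

named_matrix_means <- function(draws, node, nrow, ncol) {
  out <- matrix(NA_real_, nrow, ncol)
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    col <- sprintf("%s[%d,%d]", node, i, j)
    if (col %in% colnames(draws)) out[i, j] <- mean(draws[, col])
  }
  # JAGS reports a 1 x 1 array node without indices
  if (nrow == 1L && ncol == 1L && is.na(out[1, 1]) &&
        node %in% colnames(draws)) {
    out[1, 1] <- mean(draws[, node])
  }
  out
}

# deviance of the choice-and-recall likelihood at plugged-in values
plugin_deviance <- function(family, dec, ph, prec, ask, hint, rec) {
  pask <- choice_probability(family, dec, prec)
  prr <- recall_probability(prec, hint == 1, ph)
  -2 * sum(stats::dbinom(ask, 1, pask, log = TRUE) +
             stats::dbinom(rec, 1, prr, log = TRUE))
}

#' Fit one model of the factorial lattice
#'
#' Hierarchical MCMC fit of a choice-and-recall model: per participant and
#' condition cell, a decision parameter (criterion `C`, or `beta0` for the
#' constant family) and Beta precision `V_rec`, plus an objective hint
#' boost `P_hint_o` per difficulty, with the spec's constraint pattern
#' enforced by parameter sharing. Participant-level parameters are drawn
#' from group-level distributions (logit-normal for probabilities,
#' log-normal for `V_rec`) with weakly informative hyperpriors
#' (Normal(0, 1.5^2) locations, half-Normal(1) scales). `U_rec` is fixed
#' from forced-recall accuracy and not refit. The per-trial latent recall
#' probability is sampled explicitly (truncated to \[0.001, 0.999\] so its
#' density stays bounded when a Beta shape drops below 1).
#'
#' @param spec One row of [enumerate_model_specs()] (or an equivalent
#'   list).
#' @param table A `trial_table` matching `spec$variant`.
#' @param config An [mcmc_config()].
#' @param fixed Optional list fixing parameters instead of sampling them:
#'   `v_rec` (scalar or participants x cells matrix) and/or `p_hint_o`
#'   (scalar or participants x difficulty-groups matrix). Used for
#'   oracle-equivalence checks.
#' @param pooling `"hierarchical"` (default) or `"flat"` (independent
#'   uniform priors; used to compare against [grid_posterior()]).
#' @param u_rec Optional participants x cells matrix overriding the
#'   forced-recall-based [u_rec_matrix()] (rows in the order participants
#'   first appear). Intended for validation studies where the generating
#'   values are known.
#' @param quiet Suppress JAGS progress output.
#' @return A `posterior_fit` with stored draws, per-parameter R-hat, the
#'   deviance trace, DIC, per-trial posterior-mean latent recall
#'   probabilities and the convergence flag (all R-hat < 1.1).
#' @export
fit_model <- function(spec, table, config = mcmc_test_config(),
                      fixed = NULL, pooling = c("hierarchical", "flat"),
                      u_rec = NULL, quiet = TRUE) {
  spec <- as.list(spec)
  pooling <- match.arg(pooling)
  if (!identical(spec$variant, table_variant(table))) {
    stop("table variant does not match the model spec")
  }
  d <- choice_model_data(table)
  if (!is.null(u_rec)) {
    stopifnot(all(dim(u_rec) == dim(d$u_rec)))
    d$u_rec <- pmin(pmax(u_rec, 0.01), 0.99)
  }
  cgrp <- c_group_map(spec$variant, spec$c_pattern)
  hgrp <- phint_group_map(spec$phint_pattern)
  P <- length(d$ids); K <- nrow(d$cells)
  Gc <- max(cgrp); Gh <- max(hgrp)
  fix_v <- !is.null(fixed$v_rec)
  fix_ph <- !is.null(fixed$p_hint_o)
  jdata <- list(N = length(d$free), P = P, Gc = Gc, pp = d$pp, cc = d$cc,
                dd = d$dd, cgrp = cgrp, hgrp = hgrp, Urec = d$u_rec,
                ask = d$ask, hint = d$hint, rec = d$rec)
  if (!fix_ph) jdata$Gh <- Gh
  if (!fix_v) jdata$K <- K
  expand_fix <- function(x, ncol) {
    if (is.matrix(x)) x else matrix(x, P, ncol,
                                    byrow = length(x) == ncol)
  }
  if (fix_v) jdata$V <- expand_fix(fixed$v_rec, K)
  if (fix_ph) jdata$Ph <- expand_fix(fixed$p_hint_o, Gh)
  model_str <- build_choice_model(spec$family, pooling, fix_v, fix_ph)
  monitors <- c("dec", "dev", "prec")
  if (!fix_v) monitors <- c(monitors, "V")
  if (!fix_ph) monitors <- c(monitors, "Ph")
  if (pooling == "hierarchical") {
    monitors <- c(monitors, "mu_dec", "sig_dec")
    if (!fix_ph) monitors <- c(monitors, "mu_ph", "sig_ph")
    if (!fix_v) monitors <- c(monitors, "mu_v", "sig_v")
  }
  t0 <- Sys.time()
  model <- rjags::jags.model(textConnection(model_str), data = jdata,
                             inits = chain_inits(config),
                             n.chains = config$n_chains,
                             n.adapt = config$n_adapt, quiet = quiet)
  if (config$n_burnin > 0) {
    stats::update(model, config$n_burnin,
                  progress.bar = if (quiet) "none" else "text")
  }
  samples <- rjags::coda.samples(model, variable.names = monitors,
                                 n.iter = config$n_samples,
                                 thin = config$thin,
                                 progress.bar = if (quiet) "none" else "text")
  draws <- as.matrix(samples)
  is_latent <- grepl("^prec\\[", colnames(draws)) |
    colnames(draws) == "dev"
  par_cols <- colnames(draws)[!is_latent]
  rhat <- rhat_columns(lapply(samples, function(s) s[, par_cols,
                                                     drop = FALSE]))
  prec_means <- colMeans(draws[, sprintf("prec[%d]", seq_along(d$free)),
                               drop = FALSE])
  dec_means <- named_matrix_means(draws, "dec", P, Gc)
  ph_means <- if (fix_ph) jdata$Ph else named_matrix_means(draws, "Ph", P, Gh)
  v_means <- if (fix_v) jdata$V else named_matrix_means(draws, "V", P, K)
  dev_at_means <- plugin_deviance(
    spec$family,
    dec_means[cbind(d$pp, cgrp[d$cc])],
    ph_means[cbind(d$pp, hgrp[d$dd])],
    prec_means, d$ask, d$hint, d$rec)
  fit <- structure(list(
    spec = spec,
    samples = lapply(samples, function(s) s[, par_cols, drop = FALSE]),
    p_rec_trial_means = prec_means,
    deviance_trace = as.numeric(draws[, "dev"]),
    dev_at_means = dev_at_means,
    rhat = rhat,
    converged = all(rhat < 1.1, na.rm = TRUE),
    param_means = list(dec = dec_means, p_hint_o = ph_means,
                       v_rec = v_means),
    maps = list(cgrp = cgrp, hgrp = hgrp),
    data_info = list(ids = d$ids, cells = d$cells, free_rows = d$free,
                     pp = d$pp, cc = d$cc, dd = d$dd, saved = d$saved,
                     ask = d$ask, hint = d$hint, rec = d$rec,
                     u_rec = d$u_rec),
    config = config, pooling = pooling,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "posterior_fit")
  fit$dic <- dic(fit)
  fit
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit> %s  DIC=%.1f  converged=%s  max R-hat=%.3f\n",
              x$spec$spec_id %||% x$spec$family, x$dic, x$converged,
              suppressWarnings(max(x$rhat, na.rm = TRUE))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deviance information criterion
#'
#' `DIC = D-bar + p_D` with `D-bar` the mean deviance over stored draws and
#' `p_D = D-bar - D(theta-bar)`, where `D(theta-bar)` is the deviance with
#' every sampled quantity (per-trial latent recall probabilities included)
#' plugged in at its posterior mean. Lower is better.
#'
#' @param fit A `posterior_fit` (any list with `deviance_trace` and
#'   `dev_at_means`).
#' @return The scalar DIC.
#' @export
dic <- function(fit) {
  d_bar <- mean(fit$deviance_trace)
  if (!is.finite(fit$dev_at_means)) stop("non-finite plug-in deviance")
  p_d <- d_bar - fit$dev_at_means
  d_bar + p_d
}

#' Select the winning model
#'
#' Drops fits whose R-hat screen failed (any parameter >= 1.1), then picks
#' the converged fit with the lowest DIC. Exact DIC ties break toward
#' fewer free parameters, then lattice order.
#'
#' @param fits List of `posterior_fit` objects.
#' @param screen Apply the R-hat convergence screen (default `TRUE`).
#'   With `screen = FALSE` every fit is ranked; convergence flags are
#'   still reported.
#' @return List with `winner` (the selected fit) and `table` (ranked
#'   comparison data frame).
#' @export
select_model <- function(fits, screen = TRUE) {
  stopifnot(length(fits) >= 1L)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(spec_id = f$spec$spec_id %||% NA_character_,
               family = f$spec$family,
               c_pattern = f$spec$c_pattern %||% NA_integer_,
               phint_pattern = f$spec$phint_pattern %||% NA_integer_,
               n_free = f$spec$n_free %||% NA_integer_,
               dic = f$dic, converged = f$converged,
               max_rhat = suppressWarnings(max(f$rhat, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  lattice <- seq_along(fits)
  keep <- if (screen) which(tab$converged) else seq_along(fits)
  if (!length(keep)) stop("no model passed the R-hat < 1.1 screen")
  ord <- keep[order(tab$dic[keep], tab$n_free[keep], lattice[keep])]
  tab <- tab[c(ord, setdiff(seq_along(fits), ord)), ]
  tab$rank <- c(seq_along(ord), rep(NA_integer_,
                                    length(fits) - length(ord)))
  rownames(tab) <- NULL
  list(winner = fits[[ord[1]]], table = tab)
}

#' Posterior predictive check
#'
#' Simulates choices and recall outcomes for every free-choice trial from
#' `n_draws` stored posterior draws and compares per-cell predicted ask
#' proportions and recall accuracies (mean and central 95% interval) with
#' the empirical cell means.
#'
#' @param fit A `posterior_fit` from [fit_model()].
#' @param n_draws Number of posterior draws to simulate from.
#' @param seed Integer seed for the draw selection and the simulation.
#' @return Data frame with one row per cell x statistic: empirical value,
#'   predictive mean and 95% interval bounds.
#' @export
posterior_predictive <- function(fit, n_draws = 200L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  d <- fit$data_info
  draws <- do.call(rbind, fit$samples)
  idx <- sample.int(nrow(draws), n_draws, replace = n_draws > nrow(draws))
  K <- nrow(d$cells)
  N <- length(d$pp)
  cgrp <- fit$maps$cgrp; hgrp <- fit$maps$hgrp
  u <- d$u_rec[cbind(d$pp, d$cc)]
  get_mat <- function(row, node, fixed) {
    if (!is.null(fixed) && !any(grepl(paste0("^", node, "\\["),
                                      colnames(draws)))) {
      return(fixed)
    }
    nm <- colnames(draws)[grepl(paste0("^", node, "\\["), colnames(draws))]
    ij <- do.call(rbind, regmatches(nm, regexec(
      paste0(node, "\\[(\\d+),(\\d+)\\]"), nm)))
    out <- matrix(NA_real_, max(as.integer(ij[, 2])),
                  max(as.integer(ij[, 3])))
    out[cbind(as.integer(ij[, 2]), as.integer(ij[, 3]))] <- draws[row, nm]
    out
  }
  pred_ask <- matrix(NA_real_, n_draws, K)
  pred_rec <- matrix(NA_real_, n_draws, K)
  for (s in seq_len(n_draws)) {
    dec <- get_mat(idx[s], "dec", NULL)
    V <- get_mat(idx[s], "V", fit$param_means$v_rec)
    Ph <- get_mat(idx[s], "Ph", fit$param_means$p_hint_o)
    v <- V[cbind(d$pp, d$cc)]
    p <- stats::rbeta(N, u * v, (1 - u) * v)
    pask <- choice_probability(fit$spec$family,
                               dec[cbind(d$pp, cgrp[d$cc])], p)
    ask <- stats::runif(N) < pask
    hint <- ask & d$saved
    prr <- recall_probability(p, hint, Ph[cbind(d$pp, hgrp[d$dd])])
    rec <- stats::runif(N) < prr
    pred_ask[s, ] <- vapply(seq_len(K), function(k) {
      mean(ask[d$cc == k])
    }, numeric(1))
    pred_rec[s, ] <- vapply(seq_len(K), function(k) {
      mean(rec[d$cc == k])
    }, numeric(1))
  }
  emp_ask <- vapply(seq_len(K), function(k) mean(d$ask[d$cc == k]),
                    numeric(1))
  emp_rec <- vapply(seq_len(K), function(k) mean(d$rec[d$cc == k]),
                    numeric(1))
  summarise <- function(pred, emp, stat) {
    data.frame(d$cells, stat = stat, empirical = emp,
               predicted = colMeans(pred, na.rm = TRUE),
               lo = apply(pred, 2, stats::quantile, 0.025, na.rm = TRUE),
               hi = apply(pred, 2, stats::quantile, 0.975, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(summarise(pred_ask, emp_ask, "ask_prop"),
               summarise(pred_rec, emp_rec, "recall_acc"))
  rownames(out) <- NULL
  out
}

#' Brute-force grid posterior for one free parameter
#'
#' Independent validation oracle for [fit_model()]: for a single
#' participant with every other parameter fixed and a flat prior on the
#' free decision parameter, the posterior is evaluated directly on a
#' uniform grid as the normalised product of marginal per-trial
#' likelihoods ([trial_loglik_marginal()]).
#'
#' @param table `trial_table` of a single participant.
#' @param family Model family.
#' @param fixed List with `u_rec` (scalar or per-cell), `v_rec` (scalar)
#'   and `p_hint_o` (named by difficulty, or scalar).
#' @param grid_size Number of grid points (>= 10).
#' @return Data frame with `grid` (cell midpoints on (0, 1)) and
#'   `posterior` (summing to 1).
#' @export
grid_posterior <- function(table, family, fixed, grid_size = 101L) {
  if (grid_size < 10L) stop("grid_size must be at least 10")
  if (length(unique(table$participant_id)) > 1L) {
    stop("grid posterior is defined for a single participant")
  }
  tab <- filter_ineligible(table)
  free <- tab[tab$test_type == "free", , drop = FALSE]
  grid <- (seq_len(grid_size) - 0.5) / grid_size
  if (nrow(free) == 0L) {
    return(data.frame(grid = grid, posterior = rep(1 / grid_size,
                                                   grid_size)))
  }
  cc <- cell_index(tab)[tab$test_type == "free"]
  u_rec <- if (length(fixed$u_rec) > 1L) fixed$u_rec[cc] else {
    rep(fixed$u_rec, nrow(free))
  }
  ph <- if (!is.null(names(fixed$p_hint_o))) {
    fixed$p_hint_o[free$difficulty]
  } else rep(fixed$p_hint_o, nrow(free))
  loglik <- vapply(grid, function(g) {
    sum(vapply(seq_len(nrow(free)), function(t) {
      trial_loglik_marginal(
        list(decision = g, u_rec = u_rec[t], v_rec = fixed$v_rec,
             p_hint_o = ph[[t]]),
        family, ask = as.integer(free$choice[t] == "ask"),
        recall = free$recall[t],
        hint_shown = as.integer(free$hint_shown[t]))
    }, numeric(1)))
  }, numeric(1))
  w <- exp(loglik - max(loglik))
  data.frame(grid = grid, posterior = w / sum(w))
}

#' Serialize a fit to a directory
#'
#' Writes the posterior summary table (parameter, mean, sd, central 95%
#' interval, R-hat), and a small JSON manifest with the config, seed and
#' timing.
#'
#' @param fit A `posterior_fit`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fit_dir <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  draws <- do.call(rbind, fit$samples)
  summ <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, stats::quantile, 0.025),
    q97.5 = apply(draws, 2, stats::quantile, 0.975),
    rhat = fit$rhat[colnames(draws)],
    stringsAsFactors = FALSE)
  utils::write.csv(summ, file.path(dir, "posterior_summary.csv"),
                   row.names = FALSE)
  manifest <- list(spec = fit$spec, config = unclass(fit$config),
                   dic = fit$dic, converged = fit$converged,
                   elapsed_sec = fit$elapsed, pooling = fit$pooling)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
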