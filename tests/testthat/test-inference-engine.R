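test_that("the potential scale reduction factor matches its definition", {
  # identical chains: B = 0, W = 1, R-hat = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  # hand-computed two-chain case
  ch <- list(c(0, 1), c(2, 5))
  W <- (0.5 + 4.5) / 2
  B <- 2 * var(c(0.5, 3.5))
  expect_equal(gelman_rubin(ch), sqrt(((1 / 2) * W + B / 2) / W))
  expect_error(gelman_rubin(list(c(0, 0, 0), c(1, 1, 1))), "degenerate")
  expect_error(gelman_rubin(list(c(1, 2))), "two chains")
  expect_error(gelman_rubin(list(c(1, 2), c(1, 2, 3))), "equal length")
})

test_that("R-hat approaches 1 for long well-mixed chains and is affine-invariant", {
  set.seed(8)
  ch <- replicate(3, rnorm(10000), simplify = FALSE)
  r <- gelman_rubin(ch)
  expect_lt(abs(r - 1), 0.01)
  shifted <- lapply(ch, function(x) 7 - 3.2 * x)
  expect_equal(gelman_rubin(shifted), r, tolerance = 1e-12)
})

test_that("DIC is mean deviance plus the effective parameter count", {
  fake <- list(deviance_trace = c(10, 12), dev_at_means = 9)
  expect_equal(dic(fake), 13)
  # a point-mass posterior has no effective parameters
  fake <- list(deviance_trace = rep(42, 50), dev_at_means = 42)
  expect_equal(dic(fake), 42)
  # affine equivariance in the deviance
  base <- list(deviance_trace = rnorm(100, 100, 5), dev_at_means = 97)
  shifted <- list(deviance_trace = base$deviance_trace + 11,
                  dev_at_means = base$dev_at_means + 11)
  expect_equal(dic(shifted), dic(base) + 11)
  expect_error(dic(list(deviance_trace = 1:3, dev_at_means = NaN)),
               "non-finite")
})

fake_fit <- function(id, family, dic, converged, n_free = 8L) {
  structure(list(spec = list(spec_id = id, family = family,
                             c_pattern = 1L, phint_pattern = 1L,
                             n_free = n_free),
                 dic = dic, converged = converged,
                 deviance_trace = dic, dev_at_means = dic,
                 rhat = c(x = if (converged) 1.01 else 1.3)),
            class = "posterior_fit")
}

test_that("model selection takes the lowest-DIC converged fit", {
  fits <- list(fake_fit("a", "constant", 130, TRUE),
               fake_fit("b", "negative_slope", 125, TRUE),
               fake_fit("c", "positive_slope", 140, TRUE))
  sel <- select_model(fits)
  expect_equal(sel$winner$spec$spec_id, "b")
  expect_equal(sel$table$spec_id, c("b", "a", "c"))

  # the best DIC is excluded when its R-hat screen fails
  fits[[2]]$converged <- FALSE
  sel <- select_model(fits)
  expect_equal(sel$winner$spec$spec_id, "a")
  expect_true(is.na(sel$table$rank[sel$table$spec_id == "b"]))

  # exact ties break toward fewer free parameters
  tied <- list(fake_fit("big", "negative_slope", 100, TRUE, n_free = 10L),
               fake_fit("small", "negative_slope", 100, TRUE, n_free = 4L))
  expect_equal(select_model(tied)$winner$spec$spec_id, "small")

  none <- list(fake_fit("a", "constant", 130, FALSE))
  expect_error(select_model(none), "no model")
})

test_that("the grid posterior reduces to the prior without data and is
           monotone for all-ask all-recalled data", {
  empty <- trial_table(trial_row(item_id = "i1", test_type = "forced")[0, ],
                       "exp1")
  g <- grid_posterior(empty, "negative_slope",
                      fixed = list(u_rec = 0.5, v_rec = 2, p_hint_o = 0.2),
                      grid_size = 40)
  expect_equal(g$posterior, rep(1 / 40, 40))
  expect_error(grid_posterior(empty, "negative_slope",
                              fixed = list(u_rec = 0.5, v_rec = 2,
                                           p_hint_o = 0.2),
                              grid_size = 5), "at least 10")

  rows <- do.call(rbind, lapply(1:12, function(i) {
    trial_row(item_id = sprintf("i%02d", i), saved = TRUE, choice = "ask",
              hint_shown = TRUE, recall = 1L)
  }))
  tab <- trial_table(rows, "exp1")
  g <- grid_posterior(tab, "negative_slope",
                      fixed = list(u_rec = 0.5, v_rec = 2, p_hint_o = 0.2),
                      grid_size = 60)
  expect_true(all(diff(g$posterior) > -1e-12))
  expect_equal(sum(g$posterior), 1)
})

test_that("the grid posterior matches a Monte-Carlo likelihood estimate", {
  rows <- rbind(
    trial_row(item_id = "i1", saved = TRUE, choice = "ask",
              hint_shown = TRUE, recall = 1L),
    trial_row(item_id = "i2", saved = FALSE, choice = "self",
              recall = 0L),
    trial_row(item_id = "i3", difficulty = "difficult", saved = TRUE,
              choice = "ask", hint_shown = TRUE, recall = 0L))
  tab <- trial_table(rows, "exp1")
  fixed <- list(u_rec = 0.45, v_rec = 3,
                p_hint_o = c(easy = 0.4, difficult = 0.15))
  g <- grid_posterior(tab, "negative_slope", fixed, grid_size = 25)
  set.seed(77)
  pdraw <- rbeta(2e5, 0.45 * 3, 0.55 * 3)
  # each trial has its own latent draw: the marginal likelihood is the
  # product over trials of per-trial latent averages
  mc <- vapply(g$grid, function(C) {
    lik <- 1
    for (t in 1:3) {
      pask <- choice_probability("negative_slope", C, pdraw)
      lc <- if (tab$choice[t] == "ask") pask else 1 - pask
      ph <- fixed$p_hint_o[[tab$difficulty[t]]]
      pr <- recall_probability(pdraw, tab$hint_shown[t], ph)
      lr <- if (tab$recall[t] == 1) pr else 1 - pr
      lik <- lik * mean(lc * lr)
    }
    lik
  }, numeric(1))
  mc <- mc / sum(mc)
  expect_lt(0.5 * sum(abs(mc - g$posterior)), 0.02)
})

test_that("fits are reproducible and expose coherent posterior structure", {
  med <- fit_exp1_medium()
  fit <- med$fit
  expect_s3_class(fit, "posterior_fit")
  # per-trial latent means live strictly inside the unit interval
  expect_true(all(fit$p_rec_trial_means > 0 & fit$p_rec_trial_means < 1))
  expect_equal(length(fit$p_rec_trial_means),
               length(fit$data_info$free_rows))
  # R-hat was computed for every retained parameter column
  expect_setequal(names(fit$rhat), colnames(fit$samples[[1]]))
  expect_true(is.finite(fit$dic))
  # the deviance trace matches the stored chain length
  expect_equal(length(fit$deviance_trace),
               fit$config$n_samples / fit$config$thin * fit$config$n_chains)

  # determinism: an identical tiny fit twice
  tab <- sim_exp1_small()
  spec <- enumerate_model_specs("exp1")[18, ]
  cfg <- mcmc_config(n_chains = 2, n_samples = 200, n_burnin = 100,
                     n_adapt = 100, thin = 1, seed = 5)
  f1 <- fit_model(spec, tab, cfg)
  f2 <- fit_model(spec, tab, cfg)
  expect_identical(f1$deviance_trace, f2$deviance_trace)
  expect_identical(f1$param_means, f2$param_means)
})

test_that("posterior predictives bracket the data the model was fitted to", {
  med <- fit_exp1_medium()
  ppc <- posterior_predictive(med$fit, n_draws = 150, seed = 4)
  expect_equal(nrow(ppc), 8L)  # 4 cells x {ask, recall}
  ok <- ppc$empirical >= ppc$lo & ppc$empirical <= ppc$hi
  expect_gte(sum(ok), 7L)
  # deterministic given the seed
  ppc2 <- posterior_predictive(med$fit, n_draws = 150, seed = 4)
  expect_identical(ppc, ppc2)
})

test_that("fit directories serialize the posterior summary and manifest", {
  med <- fit_exp1_medium()
  dir <- tempfile()
  write_fit_dir(med$fit, dir)
  summ <- read.csv(file.path(dir, "posterior_summary.csv"))
  expect_true(all(c("parameter", "mean", "sd", "q2.5", "q97.5", "rhat")
                  %in% names(summ)))
  expect_true(all(summ$q2.5 <= summ$q97.5))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$spec$spec_id, med$fit$spec$spec_id)
})
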