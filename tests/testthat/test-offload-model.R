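# Closed-form marginal likelihood via incomplete-Beta identities: an
# independent oracle for the quadrature implementation.
marginal_closed_form <- function(params, family, ask, recall, hint) {
  a <- params$u_rec * params$v_rec
  b <- (1 - params$u_rec) * params$v_rec
  u <- params$u_rec
  m0 <- function(lo, hi) pbeta(hi, a, b) - pbeta(lo, a, b)
  m1 <- function(lo, hi) u * (pbeta(hi, a + 1, b) - pbeta(lo, a + 1, b))
  rec_int <- function(lo, hi) {
    if (hi <= lo) return(0)
    if (hint == 1) {
      s <- min(max(0.999 - params$p_hint_o, 0), 1)
      v <- 0
      h1 <- min(hi, s)
      if (h1 > lo) {
        pr1 <- m1(lo, h1) + params$p_hint_o * m0(lo, h1)
        v <- v + if (recall == 1) pr1 else m0(lo, h1) - pr1
      }
      l2 <- max(lo, s)
      if (hi > l2) {
        v <- v + (if (recall == 1) 0.999 else 0.001) * m0(l2, hi)
      }
      v
    } else {
      if (recall == 1) m1(lo, hi) else m0(lo, hi) - m1(lo, hi)
    }
  }
  if (family == "constant") {
    pask <- if (params$decision > 0.075) 0.999 else 0.001
    return((if (ask == 1) pask else 1 - pask) * rec_int(0, 1))
  }
  C <- min(max(params$decision, 0), 1)
  bounds <- if (family == "negative_slope") c(0, C) else c(C, 1)
  inA <- rec_int(bounds[1], bounds[2])
  outA <- rec_int(0, bounds[1]) + rec_int(bounds[2], 1)
  if (ask == 1) 0.999 * inA + 0.001 * outA else {
    0.001 * inA + 0.999 * outA
  }
}

test_that("task constants encode the payoff structure coherently", {
  k <- offload_constants()
  expect_identical(k$THRESHOLD,
                   k$HELP_COST / (k$PAYOFF_CORRECT - k$PAYOFF_WRONG))
  expect_identical(k$LAPSE_HI + k$LAPSE_LO, 1)
})

test_that("the Beta reparameterisation has the stated mean and precision", {
  expect_equal(beta_params(0.5, 2), list(a_rec = 1, b_rec = 1))
  expect_equal(beta_params(0.8, 10), list(a_rec = 8, b_rec = 2))
  for (i in 1:20) {
    u <- runif(1, 0.01, 0.99)
    v <- runif(1, 0.1, 50)
    sh <- beta_params(u, v)
    expect_equal(sh$a_rec + sh$b_rec, v)
    expect_equal(sh$a_rec / (sh$a_rec + sh$b_rec), u)
  }
  expect_error(beta_params(0, 2), "strictly")
  expect_error(beta_params(0.5, 0), "positive")
})

test_that("asking breaks even exactly at a hint benefit of 0.075", {
  expect_identical(expected_value_difference(0.075), 0)
  expect_equal(expected_value_difference(0), -3)
  expect_equal(expected_value_difference(1), 37)
  # affine with slope 40
  x <- seq(0, 1, 0.1)
  expect_equal(diff(expected_value_difference(x)) / diff(x), rep(40, 10))
})

test_that("the subjective hint benefit clips into [0, 1]", {
  expect_equal(phint_subjective(0.2, -0.5, 0.4), 0)
  expect_equal(phint_subjective(0.3, 0, 0.9), 0.3)
  expect_equal(phint_subjective(0.5, 0.8, 0.9), 1)
})

test_that("the criterion and the intercept-slope line are mutual inverses", {
  expect_equal(criterion_from_intercept(0.075, -0.5), 0)
  expect_equal(criterion_from_intercept(0.275, -0.5), 0.4)
  expect_error(criterion_from_intercept(0.2, 0), "constant")
  for (i in 1:20) {
    beta0 <- runif(1, 0.08, 0.99)
    beta1 <- runif(1, -3, -0.01)
    C <- criterion_from_intercept(beta0, beta1)
    expect_equal(derive_beta1(beta0, C), beta1, tolerance = 1e-12)
  }
})

test_that("the choice rule is near-deterministic and ties resolve to not-ask", {
  expect_equal(choice_probability("negative_slope", 0.5, 0.3), 0.999)
  expect_equal(choice_probability("negative_slope", 0.5, 0.7), 0.001)
  expect_equal(choice_probability("negative_slope", 0.5, 0.5), 0.001)
  expect_equal(choice_probability("positive_slope", 0.5, 0.7), 0.999)
  expect_equal(choice_probability("positive_slope", 0.5, 0.5), 0.001)
  expect_equal(choice_probability("constant", 0.05, runif(5)),
               rep(0.001, 5))
  expect_equal(choice_probability("constant", 0.075, 0.5), 0.001)
  expect_equal(choice_probability("constant", 0.2, 0.5), 0.999)
})

test_that("the threshold and criterion formulations of the rule agree", {
  k <- offload_constants()
  for (i in 1:200) {
    beta0 <- runif(1, -0.5, 1.5)
    beta1 <- runif(1, -3, 3)
    if (abs(beta1) < 1e-3) next
    p <- runif(1)
    via_threshold <- phint_subjective(beta0, beta1, p) > k$THRESHOLD
    C <- criterion_from_intercept(beta0, beta1)
    family <- if (beta1 > 0) "positive_slope" else "negative_slope"
    via_criterion <- choice_probability(family, C, p) == k$LAPSE_HI
    expect_identical(via_threshold, via_criterion)
  }
})

test_that("recall probability applies the capped hint boost", {
  expect_equal(recall_probability(0.8, TRUE, 0.3), 0.999)
  expect_equal(recall_probability(0.8, FALSE, 0.3), 0.8)
  expect_equal(recall_probability(0.2, TRUE, 0), 0.2)
  expect_equal(recall_probability(0.2, TRUE, 0.3), 0.5)
})

test_that("the factorial lattice has the full 24- and 12-model sizes with no duplicates", {
  for (v in c("exp1", "exp2a", "exp2b")) {
    specs <- enumerate_model_specs(v)
    expect_equal(nrow(specs), 24L)
    expect_equal(anyDuplicated(specs$spec_id), 0L)
    expect_setequal(unique(specs$family),
                    c("constant", "positive_slope", "negative_slope"))
  }
  specs3 <- enumerate_model_specs("exp3")
  expect_equal(nrow(specs3), 12L)
  expect_equal(anyDuplicated(specs3$spec_id), 0L)
})

test_that("marginal trial likelihoods match closed-form special cases", {
  # constant family: the latent integrates out of the choice term
  p <- list(decision = 0.2, u_rec = 0.6, v_rec = 4, p_hint_o = 0.3)
  ll <- trial_loglik_marginal(p, "constant", ask = 1, recall = 1,
                              hint_shown = 0)
  expect_equal(exp(ll), 0.999 * 0.6, tolerance = 1e-8)
  # negative slope under Beta(1,1) with C = 0.5: P(ask) = 0.5
  p <- list(decision = 0.5, u_rec = 0.5, v_rec = 2, p_hint_o = 0.3)
  p_ask <- exp(trial_loglik_marginal(p, "negative_slope", 1, 1, 0)) +
    exp(trial_loglik_marginal(p, "negative_slope", 1, 0, 0))
  expect_equal(p_ask, 0.999 * 0.5 + 0.001 * 0.5, tolerance = 1e-8)
})

test_that("quadrature agrees with incomplete-Beta and Monte-Carlo oracles", {
  set.seed(14)
  for (i in 1:20) {
    params <- list(decision = runif(1, 0.05, 0.95),
                   u_rec = runif(1, 0.05, 0.95),
                   v_rec = runif(1, 0.5, 20),
                   p_hint_o = runif(1))
    family <- sample(c("constant", "positive_slope", "negative_slope"), 1)
    ask <- rbinom(1, 1, 0.5)
    hint <- if (ask == 1) rbinom(1, 1, 0.5) else 0L
    recall <- rbinom(1, 1, 0.5)
    lik <- exp(trial_loglik_marginal(params, family, ask, recall, hint))
    expect_equal(lik,
                 marginal_closed_form(params, family, ask, recall, hint),
                 tolerance = 1e-7)
    # brute-force latent simulation
    pdraw <- rbeta(1e5, params$u_rec * params$v_rec,
                   (1 - params$u_rec) * params$v_rec)
    pask <- choice_probability(family, params$decision, pdraw)
    lc <- if (ask == 1) pask else 1 - pask
    pr <- recall_probability(pdraw, hint == 1, params$p_hint_o)
    lr <- if (recall == 1) pr else 1 - pr
    draws <- lc * lr
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(lik - mean(draws)), 3 * se + 1e-6)
  }
})

test_that("the marginal likelihood varies continuously in the criterion", {
  params <- list(decision = NA, u_rec = 0.5, v_rec = 5, p_hint_o = 0.2)
  grid <- seq(0.05, 0.95, by = 0.05)
  ll <- vapply(grid, function(C) {
    params$decision <- C
    trial_loglik_marginal(params, "negative_slope", 1, 1, 1)
  }, numeric(1))
  # more of the latent mass inside the ask region raises the ask likelihood
  expect_true(all(diff(ll) > 0))
  # no jump at any criterion value: shrinking steps shrink the change
  for (C in c(0.2, 0.5, 0.8)) {
    params$decision <- C
    base <- trial_loglik_marginal(params, "negative_slope", 1, 1, 1)
    params$decision <- C + 1e-7
    expect_lt(abs(trial_loglik_marginal(params, "negative_slope", 1, 1, 1)
                  - base), 1e-4)
  }
})
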