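#' Task constants
#'
#' Payoffs and numerical guards of the free-choice test: +20 points for a
#' correct answer, -20 for an incorrect one, an immediate 3-point cost for
#' asking for help, and near-deterministic Bernoulli lapse probabilities
#' (0.999/0.001) that keep the sampler away from zero-likelihood trials.
#' The decision threshold on the subjective hint benefit,
#' `THRESHOLD = HELP_COST / (PAYOFF_CORRECT - PAYOFF_WRONG) = 0.075`, is the
#' break-even point at which asking for help and answering alone have equal
#' expected value.
#'
#' @return Named list of constants.
#' @export
offload_constants <- function() {
  list(
    THRESHOLD = 0.075,
    LAPSE_HI = 0.999,
    LAPSE_LO = 0.001,
    PAYOFF_CORRECT = 20,
    PAYOFF_WRONG = -20,
    HELP_COST = 3,
    RECALL_CAP = 0.999
  )
}

MODEL_FAMILIES <- c("constant", "positive_slope", "negative_slope")

#' Beta shape parameters from mean and precision
#'
#' Reparameterises the latent recall-probability distribution
#' `P_rec ~ Beta(a_rec, b_rec)` in terms of its mean `U_rec` and a
#' precision-like scalar `V_rec`: `a_rec = U_rec * V_rec`,
#' `b_rec = (1 - U_rec) * V_rec`.
#'
#' @param u_rec Mean, strictly inside (0, 1).
#' @param v_rec Precision-like scalar, positive.
#' @return List with `a_rec` and `b_rec`.
#' @export
beta_params <- function(u_rec, v_rec) {
  if (any(u_rec <= 0 | u_rec >= 1)) {
    stop("u_rec must lie strictly inside (0, 1); clamp upstream")
  }
  if (any(v_rec <= 0)) stop("v_rec must be positive")
  list(a_rec = u_rec * v_rec, b_rec = (1 - u_rec) * v_rec)
}

#' Expected-value difference of asking for help
#'
#' `E[with hint] - E[without hint] = 40 * P_hint_s - 3` points: the payoff
#' spread (+20/-20) times the believed recall boost, minus the help cost.
#' Independent of `P_rec`, with root exactly at `P_hint_s = 0.075`.
#'
#' @param p_hint_s Subjective hint benefit, in \[0, 1\].
#' @return Expected point difference.
#' @export
expected_value_difference <- function(p_hint_s) {
  k <- offload_constants()
  (k$PAYOFF_CORRECT - k$PAYOFF_WRONG) * p_hint_s - k$HELP_COST
}

#' Subjective hint benefit as a function of memory strength
#'
#' `P_hint_s = beta0 + beta1 * P_rec`, clipped into \[0, 1\] (a hint can
#' neither hurt performance nor push recall probability above 1).
#' `beta1 = 0` reproduces the Constant family.
#'
#' @param beta0 Intercept.
#' @param beta1 Slope.
#' @param p_rec Latent recall probability, in \[0, 1\].
#' @return Clipped subjective benefit.
#' @export
phint_subjective <- function(beta0, beta1, p_rec) {
  pmin(pmax(beta0 + beta1 * p_rec, 0), 1)
}

#' Criterion on P_rec from the line parameters
#'
#' The slope families cannot separately identify `beta0` and `beta1`: the
#' ask rule `beta0 + beta1 * P_rec > 0.075` collapses to a criterion
#' `C = (0.075 - beta0) / beta1` on `P_rec` (ask when above `C` for a
#' positive slope, below `C` for a negative slope).
#'
#' @param beta0 Intercept.
#' @param beta1 Nonzero slope.
#' @return The criterion `C`.
#' @export
criterion_from_intercept <- function(beta0, beta1) {
  if (any(beta1 == 0)) stop("the constant family (beta1 = 0) has no criterion")
  (offload_constants()$THRESHOLD - beta0) / beta1
}

#' Probability of asking for help
#'
#' Near-deterministic choice rule: probability 0.999 of asking when the
#' family's condition holds (constant: `beta0 > 0.075`; positive slope:
#' `p_rec > C`; negative slope: `p_rec < C`), else 0.001. Equality at the
#' criterion resolves to not-ask.
#'
#' @param family One of `"constant"`, `"positive_slope"`,
#'   `"negative_slope"`.
#' @param decision `C` for the slope families, `beta0` for the constant
#'   family (recycled against `p_rec`).
#' @param p_rec Latent recall probability.
#' @return Probability of the ask choice.
#' @export
choice_probability <- function(family, decision, p_rec) {
  family <- match.arg(family, MODEL_FAMILIES)
  k <- offload_constants()
  ask <- switch(family,
    constant = rep(decision > k$THRESHOLD, length.out = length(p_rec)),
    positive_slope = p_rec > decision,
    negative_slope = p_rec < decision
  )
  ifelse(ask, k$LAPSE_HI, k$LAPSE_LO)
}

#' Recall probability with or without a hint
#'
#' With a hint the objective boost `P_hint_o` is added and the result is
#' capped at 0.999; without one, recall succeeds with probability `p_rec`.
#'
#' @param p_rec Latent recall probability.
#' @param hint_available Logical; was a hint delivered.
#' @param p_hint_o Objective hint boost.
#' @return Probability of successful recall.
#' @export
recall_probability <- function(p_rec, hint_available, p_hint_o) {
  n <- max(length(p_rec), length(hint_available), length(p_hint_o))
  p <- rep_len(p_rec, n)
  hint <- rep_len(as.logical(hint_available), n)
  ph <- rep_len(p_hint_o, n)
  out <- p
  out[hint] <- pmin(p[hint] + ph[hint], offload_constants()$RECALL_CAP)
  out
}

# Cell -> parameter-group maps for the factorial constraint patterns.
# Cells are ordered as in condition_cells(): exp1/2 (easy-saved,
# easy-unsaved, difficult-saved, difficult-unsaved); exp3 (easy, difficult).
c_group_map <- function(variant, c_pattern) {
  if (variant == "exp3") {
    switch(c_pattern, c(1L, 1L), c(1L, 2L),
           stop("exp3 admits c patterns 1 and 2 only"))
  } else {
    switch(c_pattern,
      c(1L, 1L, 1L, 1L),   # easy = difficult, saved = unsaved
      c(1L, 1L, 2L, 2L),   # easy != difficult, saved = unsaved
      c(1L, 2L, 1L, 2L),   # easy = difficult, saved != unsaved
      c(1L, 2L, 3L, 4L),   # easy != difficult, saved != unsaved
      stop("c_pattern must be 1..4"))
  }
}

# P_hint_o varies (at most) by difficulty: a hint is only ever delivered
# for a saved pair, so saved status is not a dimension of this parameter.
phint_group_map <- function(phint_pattern) {
  switch(phint_pattern, c(1L, 1L), c(1L, 2L),
         stop("phint_pattern must be 1 or 2"))
}

#' Enumerate the factorial model lattice
#'
#' The full lattice of choice-and-recall models: 3 families x 4 decision
#' constraint patterns x 2 hint-effect patterns = 24 models for the
#' standard design, and 3 x 2 x 2 = 12 for the all-saved variant (where
#' only difficulty-wise patterns exist). Ordering is deterministic:
#' families in (constant, positive_slope, negative_slope), then decision
#' pattern, then hint pattern.
#'
#' @param variant Experiment variant.
#' @return Data frame of model specs with columns `spec_id`, `family`,
#'   `c_pattern`, `phint_pattern`, `variant`, `n_free` (free
#'   participant-level parameters, used for DIC tie-breaking).
#' @export
enumerate_model_specs <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  n_cells <- if (variant == "exp3") 2L else 4L
  c_patterns <- if (variant == "exp3") 1:2 else 1:4
  grid <- expand.grid(phint_pattern = 1:2, c_pattern = c_patterns,
                      family = MODEL_FAMILIES, stringsAsFactors = FALSE)
  grid <- grid[, c("family", "c_pattern", "phint_pattern")]
  grid$variant <- variant
  grid$spec_id <- sprintf("%s-c%d-h%d", grid$family, grid$c_pattern,
                          grid$phint_pattern)
  grid$n_free <- vapply(seq_len(nrow(grid)), function(i) {
    length(unique(c_group_map(variant, grid$c_pattern[i]))) +
      n_cells +
      length(unique(phint_group_map(grid$phint_pattern[i])))
  }, integer(1))
  rownames(grid) <- NULL
  grid[, c("spec_id", "family", "c_pattern", "phint_pattern", "variant",
           "n_free")]
}

#' Marginal log-likelihood of one free-choice trial
#'
#' Integrates the per-trial latent recall probability out of the joint
#' choice-and-recall likelihood by adaptive quadrature:
#' `log integral Beta(p; a, b) P(choice | p) P(recall | p, hint) dp`.
#' The integrand is piecewise smooth; the integral is split at the choice
#' criterion and at the point where the hint-boosted recall probability
#' reaches its 0.999 cap.
#'
#' @param params List with `decision` (C or beta0), `v_rec`, `p_hint_o`,
#'   `u_rec`.
#' @param family Model family.
#' @param ask 1 if the participant asked for help.
#' @param recall 1 if recall succeeded.
#' @param hint_shown 1 if a hint was delivered.
#' @return Log-likelihood (scalar).
#' @export
trial_loglik_marginal <- function(params, family, ask, recall, hint_shown) {
  family <- match.arg(family, MODEL_FAMILIES)
  k <- offload_constants()
  sh <- beta_params(params$u_rec, params$v_rec)
  integrand <- function(p) {
    p_ask <- choice_probability(family, params$decision, p)
    lik_choice <- if (ask == 1) p_ask else 1 - p_ask
    p_rec <- recall_probability(p, hint_shown == 1, params$p_hint_o)
    lik_recall <- if (recall == 1) p_rec else 1 - p_rec
    stats::dbeta(p, sh$a_rec, sh$b_rec) * lik_choice * lik_recall
  }
  breaks <- c(0, 1)
  if (family != "constant") breaks <- c(breaks, params$decision)
  if (hint_shown == 1) breaks <- c(breaks, k$RECALL_CAP - params$p_hint_o)
  breaks <- sort(unique(pmin(pmax(breaks, 0), 1)))
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    if (hi - lo < 1e-12) next
    piece <- stats::integrate(integrand, lo, hi, rel.tol = 1e-10,
                              abs.tol = 1e-12, subdivisions = 400L,
                              stop.on.error = FALSE)
    if (!piece$message %in% c("OK", "roundoff error was detected")) {
      stop("quadrature failed: ", piece$message)
    }
    total <- total + piece$value
  }
  log(total)
}
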