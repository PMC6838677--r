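#' Design of a simulated experiment
#'
#' The standard task: 3 blocks of 40 word pairs (half easy, half
#' difficult), a save cap of half the list per block, and a random split of
#' test trials between forced-recall and free-choice.
#'
#' @param variant Experiment variant.
#' @param n_participants Number of simulated participants.
#' @param n_blocks Blocks per participant.
#' @param pairs_per_block Word pairs per block (even; half easy).
#' @param save_cap Maximum pairs a participant may save per block.
#' @param seed Integer seed; the whole simulated experiment is a
#'   deterministic function of the design and truth.
#' @return A `design_spec` list.
#' @export
design_spec <- function(variant, n_participants, n_blocks = 3L,
                        pairs_per_block = 40L,
                        save_cap = pairs_per_block %/% 2L, seed = 1L) {
  variant <- match.arg(variant, VARIANTS)
  stopifnot(pairs_per_block %% 2L == 0L, n_participants >= 1L,
            n_blocks >= 1L, save_cap >= 1L)
  structure(list(variant = variant,
                 n_participants = as.integer(n_participants),
                 n_blocks = as.integer(n_blocks),
                 pairs_per_block = as.integer(pairs_per_block),
                 save_cap = as.integer(save_cap),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Default generating truth for a variant
#'
#' Negative-slope truth for each task variant: condition-level criteria
#' `C`, objective hint boosts `P_hint_o`, confidence intercepts `beta0`
#' (where confidence is collected) and mean save proportions
#' representative of adult word-pair cohorts on this task. Quantities
#' those estimates do not pin down (baseline recall `U_rec` per
#' condition, Beta precision `V_rec`, between-participant spread,
#' confidence bias and noise) are fixed at values typical of cued recall;
#' see the package vignette.
#'
#' @param variant Experiment variant.
#' @return A `truth_params` list with per-cell vectors ordered as
#'   [condition_cells()].
#' @export
default_truth <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  cells <- condition_cells(variant)
  easy <- cells$difficulty == "easy"
  pick <- function(easy_val, diff_val) ifelse(easy, easy_val, diff_val)
  vals <- switch(variant,
    exp1 = list(C = c(0.611, 0.425), ph = c(0.649, 0.162),
                save = c(0.15, 0.75), b0 = c(NA, NA)),
    exp2a = list(C = c(0.649, 0.415), ph = c(0.224, 0.224),
                 save = c(0.12, 0.77), b0 = c(0.291, 0.291)),
    exp2b = list(C = c(0.695, 0.521), ph = c(0.631, 0.291),
                 save = c(0.08, 0.71), b0 = c(0.243, 0.243)),
    exp3 = list(C = c(0.620, 0.620), ph = c(0.501, 0.195),
                save = c(1, 1), b0 = c(0.221, 0.277))
  )
  u_rec <- if (variant == "exp3") {
    pick(0.70, 0.25)
  } else {
    # unsaved pairs carry somewhat stronger memory than saved ones
    ifelse(easy, ifelse(cells$saved_status == "saved", 0.60, 0.72),
           ifelse(cells$saved_status == "saved", 0.18, 0.30))
  }
  structure(list(
    variant = variant,
    family = "negative_slope",
    C = pick(vals$C[1], vals$C[2]),
    v_rec = rep(5, nrow(cells)),
    p_hint_o = c(easy = vals$ph[1], difficult = vals$ph[2]),
    u_rec = u_rec,
    save_prob = c(easy = vals$save[1], difficult = vals$save[2]),
    conf_beta0 = pick(vals$b0[1], vals$b0[2]),
    conf_bias = 0,
    sigma_conf = 0.1,
    u_sd = 0.6,    # between-participant sd of logit(U_rec)
    c_sd = 0.3,    # between-participant sd of logit(C)
    bias_sd = 0.1  # between-participant sd of the confidence bias
  ), class = "truth_params")
}

# Pseudo-random item order with no more than `max_run` consecutive items
# of the same difficulty, built sequentially with a feasibility check so
# the tail of the list can never be forced into a longer run.
order_difficulties <- function(n_easy, n_difficult, max_run = 3L) {
  left <- c(easy = n_easy, difficult = n_difficult)
  out <- character(n_easy + n_difficult)
  run_len <- 0L
  run_of <- ""
  for (i in seq_along(out)) {
    allowed <- names(left)[left > 0L]
    if (run_len >= max_run) allowed <- setdiff(allowed, run_of)
    feasible <- vapply(allowed, function(d) {
      l <- left
      l[d] <- l[d] - 1L
      o <- setdiff(names(l), d)
      r <- if (d == run_of) run_len + 1L else 1L
      # the pending run can absorb max_run - r more d's, every later o
      # opens room for max_run d's, and vice versa for o
      l[d] <= (max_run - r) + max_run * l[o] &&
        l[o] <= max_run * (l[d] + 1L)
    }, logical(1))
    allowed <- allowed[feasible]
    d <- if (length(allowed) == 1L) allowed else {
      sample(allowed, 1L, prob = left[allowed])
    }
    out[i] <- d
    left[d] <- left[d] - 1L
    if (d == run_of) run_len <- run_len + 1L else { run_of <- d; run_len <- 1L }
  }
  out
}

#' Simulate the learning phase of one block
#'
#' Items are presented in a pseudo-random order with at most three
#' consecutive pairs of the same difficulty. Each pair is saved with its
#' difficulty's save probability until the save cap is reached; later pairs
#' are marked save-ineligible. In the all-saved variant every pair is saved
#' and eligible.
#'
#' @param design A [design_spec()].
#' @param truth A `truth_params` (only `save_prob` is consulted).
#' @return Data frame with `position`, `difficulty`, `save_eligible`,
#'   `saved` for one block. Consumes the current RNG stream.
#' @export
simulate_learning_phase <- function(design, truth) {
  half <- design$pairs_per_block %/% 2L
  difficulty <- order_difficulties(half, half)
  n <- design$pairs_per_block
  if (design$variant == "exp3") {
    return(data.frame(position = seq_len(n), difficulty = difficulty,
                      save_eligible = TRUE, saved = TRUE,
                      stringsAsFactors = FALSE))
  }
  saved <- logical(n)
  eligible <- logical(n)
  n_saved <- 0L
  for (i in seq_len(n)) {
    if (n_saved >= design$save_cap) {
      eligible[i] <- FALSE
      next
    }
    eligible[i] <- TRUE
    saved[i] <- stats::runif(1) < truth$save_prob[[difficulty[i]]]
    if (saved[i]) n_saved <- n_saved + 1L
  }
  data.frame(position = seq_len(n), difficulty = difficulty,
             save_eligible = eligible, saved = saved,
             stringsAsFactors = FALSE)
}

#' Simulate one free-choice trial
#'
#' Draws the latent recall probability from its Beta distribution, applies
#' the family's near-deterministic ask rule (lapse 0.999/0.001), delivers a
#' hint only when help was requested for a saved pair, and draws recall
#' with the hint-boosted (capped) or plain recall probability.
#'
#' @param params List with `decision` (C or beta0), `u_rec`, `v_rec`,
#'   `p_hint_o`.
#' @param family Model family.
#' @param saved Was the pair saved.
#' @return List with `p_rec`, `choice` (`"ask"`/`"self"`), `hint_shown`,
#'   `recall`. Consumes the current RNG stream.
#' @export
simulate_free_choice_trial <- function(params, family, saved) {
  sh <- beta_params(params$u_rec, params$v_rec)
  p_rec <- stats::rbeta(1, sh$a_rec, sh$b_rec)
  p_ask <- choice_probability(family, params$decision, p_rec)
  ask <- stats::runif(1) < p_ask
  hint_shown <- ask && saved
  p_r <- recall_probability(p_rec, hint_shown, params$p_hint_o)
  recall <- as.integer(stats::runif(1) < p_r)
  list(p_rec = p_rec, choice = if (ask) "ask" else "self",
       hint_shown = hint_shown, recall = recall)
}

#' Simulate one confidence rating
#'
#' Predicted confidence is the latent recall probability plus (on
#' with-hint trials) the subjective hint benefit, shifted by a report bias
#' and clipped into \[0, 1\]. The observed rating adds Gaussian
#' metacognitive noise, truncated to the \[0, 1\] response scale.
#'
#' @param p_rec Latent recall probability of the trial.
#' @param p_hint_s Subjective hint benefit for the trial.
#' @param bias Additive report bias.
#' @param sigma_conf Sd of the confidence noise.
#' @param with_hint Is this a confidence-with-hint trial.
#' @return Observed confidence proportion. Consumes the RNG stream.
#' @export
simulate_confidence <- function(p_rec, p_hint_s, bias, sigma_conf,
                                with_hint) {
  pred <- predicted_confidence(p_rec, p_hint_s, bias, with_hint)
  if (sigma_conf <= 0) return(pred)
  lo <- stats::pnorm(0, pred, sigma_conf)
  hi <- stats::pnorm(1, pred, sigma_conf)
  stats::qnorm(stats::runif(1, lo, hi), pred, sigma_conf)
}

# participant-level parameters jittered around the group truth on the
# logit scale; cells whose truth values are tied share one draw, so a
# simulated participant respects the generating constraint pattern
participant_truth <- function(truth, n_cells) {
  clamp <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)
  u <- clamp(stats::plogis(stats::qlogis(truth$u_rec) +
                             stats::rnorm(n_cells, 0, truth$u_sd)))
  c_groups <- match(truth$C, unique(truth$C))
  eps_c <- stats::rnorm(max(c_groups), 0, truth$c_sd)
  C <- clamp(stats::plogis(stats::qlogis(truth$C) + eps_c[c_groups]))
  bias <- truth$conf_bias + stats::rnorm(1, 0, truth$bias_sd)
  bias <- pmin(pmax(bias, -0.95), 0.95)
  list(u_rec = u, C = C, bias = bias)
}

#' Simulate a complete experiment
#'
#' Generates a full trial table under the generative assumptions of the
#' negative-slope (or other) truth: learning-phase save decisions with the
#' cap, a random half-split of saved and of unsaved items between
#' forced-recall and free-choice tests, latent Beta-distributed recall
#' probabilities shared between the choice, recall and confidence of a
#' trial, and (outside exp1) randomly assigned with-/without-hint
#' confidence conditions with simulated ratings on the variant's native
#' scale.
#'
#' The RNG stream is seeded from `design$seed` and consumed in a fixed
#' order (participant, then block, then learning phase, test assignment
#' and test trials), so equal designs yield identical tables. The caller's
#' RNG state is restored afterwards.
#'
#' @param design A [design_spec()].
#' @param truth A `truth_params`, e.g. [default_truth()].
#' @return A [trial_table()].
#' @export
simulate_experiment <- function(design, truth) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(truth$variant) && truth$variant != design$variant) {
    stop("design and truth disagree on the variant")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(design$seed)

  variant <- design$variant
  cells <- condition_cells(variant)
  scale <- default_scale(variant)
  has_conf <- variant != "exp1"
  rows <- vector("list", design$n_participants * design$n_blocks)
  pt_draws <- vector("list", design$n_participants)
  r <- 0L
  for (i in seq_len(design$n_participants)) {
    pt <- participant_truth(truth, nrow(cells))
    pid <- sprintf("sim%03d", i)
    for (b in seq_len(design$n_blocks)) {
      learn <- simulate_learning_phase(design, truth)
      # random half-split to forced vs free within saved and within unsaved
      test_type <- character(nrow(learn))
      for (grp in unique(learn$saved)) {
        idx <- which(learn$saved == grp)
        n_forced <- floor(length(idx) / 2)
        forced_idx <- sample(idx, n_forced)
        test_type[idx] <- "free"
        test_type[forced_idx] <- "forced"
      }
      test_order <- sample.int(nrow(learn))
      block_rows <- lapply(test_order, function(j) {
        diff_j <- learn$difficulty[j]
        cell_j <- if (variant == "exp3") {
          match(diff_j, cells$difficulty)
        } else {
          match(paste(diff_j, ifelse(learn$saved[j], "saved", "unsaved")),
                paste(cells$difficulty, cells$saved_status))
        }
        params <- list(decision = pt$C[cell_j], u_rec = pt$u_rec[cell_j],
                       v_rec = truth$v_rec[cell_j],
                       p_hint_o = truth$p_hint_o[[diff_j]])
        conf_cond <- if (has_conf) {
          sample(c("with_hint", "without_hint"), 1)
        } else "absent"
        if (test_type[j] == "free") {
          tr <- simulate_free_choice_trial(params, truth$family,
                                           learn$saved[j])
        } else {
          sh <- beta_params(params$u_rec, params$v_rec)
          p_rec <- stats::rbeta(1, sh$a_rec, sh$b_rec)
          tr <- list(p_rec = p_rec, choice = "absent", hint_shown = FALSE,
                     recall = as.integer(stats::runif(1) < p_rec))
        }
        conf_raw <- NA_real_
        if (has_conf) {
          beta1 <- derive_beta1(truth$conf_beta0[cell_j], pt$C[cell_j])
          phs <- phint_subjective(truth$conf_beta0[cell_j], beta1, tr$p_rec)
          conf_prop <- simulate_confidence(tr$p_rec, phs, pt$bias,
                                           truth$sigma_conf,
                                           conf_cond == "with_hint")
          conf_raw <- scale$min + conf_prop * (scale$max - scale$min)
        }
        points <- if (tr$choice == "ask") {
          if (tr$recall == 1L) 17L else -23L
        } else {
          if (tr$recall == 1L) 20L else -20L
        }
        row <- data.frame(participant_id = pid, variant = variant, block = b,
                   item_id = sprintf("b%d_i%02d", b, j),
                   difficulty = diff_j,
                   save_eligible = learn$save_eligible[j],
                   saved = learn$saved[j], test_type = test_type[j],
                   confidence_condition = conf_cond,
                   confidence_raw = conf_raw, choice = tr$choice,
                   hint_shown = tr$hint_shown, recall = tr$recall,
                   points_delta = points, stringsAsFactors = FALSE)
        row$.p_rec <- tr$p_rec
        row
      })
      r <- r + 1L
      rows[[r]] <- do.call(rbind, block_rows)
    }
    pt_draws[[i]] <- pt
  }
  all_rows <- do.call(rbind, rows)
  out <- trial_table(all_rows[setdiff(names(all_rows), ".p_rec")],
                     variant, scale)
  # generating latents, kept for validation studies of downstream fits
  attr(out, "truth_draws") <- list(
    p_rec = all_rows$.p_rec,
    C = do.call(rbind, lapply(pt_draws, `[[`, "C")),
    u_rec = do.call(rbind, lapply(pt_draws, `[[`, "u_rec")),
    bias = vapply(pt_draws, `[[`, numeric(1), "bias"))
  out
}
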