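# Shared fixtures, built lazily and cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small simulated exp1 experiment shared by several files
sim_exp1_small <- function() {
  cached("exp1_small", function() {
    simulate_experiment(design_spec("exp1", n_participants = 8, seed = 11),
                        default_truth("exp1"))
  })
}

sim_exp2a_small <- function() {
  cached("exp2a_small", function() {
    simulate_experiment(design_spec("exp2a", n_participants = 6, seed = 3),
                        default_truth("exp2a"))
  })
}

# a medium exp1 fit of the generating spec, reused where a converged-ish
# posterior is needed without paying for a full recovery run
fit_exp1_medium <- function() {
  cached("exp1_medium_fit", function() {
    tab <- simulate_experiment(
      design_spec("exp1", n_participants = 10, seed = 21),
      default_truth("exp1"))
    specs <- enumerate_model_specs("exp1")
    spec <- specs[specs$spec_id == "negative_slope-c2-h2", ]
    cfg <- mcmc_config(n_chains = 3, n_samples = 800, n_burnin = 400,
                       n_adapt = 200, thin = 1, seed = 7)
    list(table = tab, fit = fit_model(spec, tab, cfg))
  })
}

# larger simulations shared by the pattern-reproduction and
# confidence-recovery checks
sim_exp1_large <- function() {
  cached("exp1_large", function() {
    simulate_experiment(design_spec("exp1", n_participants = 80, seed = 401),
                        default_truth("exp1"))
  })
}

sim_exp2a_medium <- function() {
  cached("exp2a_medium", function() {
    simulate_experiment(design_spec("exp2a", n_participants = 40, seed = 402),
                        default_truth("exp2a"))
  })
}

# hand-built minimal trial rows with consistent points
trial_row <- function(participant_id = "p01", variant = "exp1", block = 1L,
                      item_id, difficulty = "easy", save_eligible = TRUE,
                      saved = FALSE, test_type = "free",
                      confidence_condition = if (variant == "exp1") {
                        "absent"
                      } else "without_hint",
                      confidence_raw = NA_real_,
                      choice = if (test_type == "forced") "absent" else "self",
                      hint_shown = FALSE, recall = 1L) {
  points <- if (choice == "ask") {
    if (recall == 1L) 17L else -23L
  } else {
    if (recall == 1L) 20L else -20L
  }
  data.frame(participant_id = participant_id, variant = variant,
             block = block, item_id = item_id, difficulty = difficulty,
             save_eligible = save_eligible, saved = saved,
             test_type = test_type,
             confidence_condition = confidence_condition,
             confidence_raw = confidence_raw, choice = choice,
             hint_shown = hint_shown, recall = recall,
             points_delta = points, stringsAsFactors = FALSE)
}

demo_fixture_path <- function() {
  system.file("extdata", "demo_trials_exp1.csv", package = "offloadr")
}
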