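test_that("the packaged demo file round-trips through read and write", {
  tab <- read_trials(demo_fixture_path(), "exp1")
  expect_s3_class(tab, "trial_table")
  expect_equal(nrow(tab), 6L)
  out <- tempfile(fileext = ".csv")
  write_trials(tab, out)
  expect_identical(readLines(out), readLines(demo_fixture_path()))
  tab2 <- read_trials(out, "exp1")
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("invariant violations are rejected with the offending row", {
  rows <- rbind(
    trial_row(item_id = "i01", test_type = "forced"),
    trial_row(item_id = "i02", saved = TRUE, choice = "ask",
              hint_shown = TRUE))
  # an ask choice on a forced trial
  bad <- rows
  bad$choice[1] <- "ask"
  bad$points_delta[1] <- 17L
  expect_error(trial_table(bad, "exp1"), "row 1")
  # a hint without a save
  bad <- rows
  bad$saved[2] <- FALSE
  expect_error(trial_table(bad, "exp1"), "row 2.*saved")
  # inconsistent points
  bad <- rows
  bad$points_delta[2] <- 20L
  expect_error(trial_table(bad, "exp1"), "points_delta")
  # duplicate key
  bad <- rows
  bad$item_id[2] <- "i01"
  bad$test_type[2] <- "forced"
  bad$choice[2] <- "absent"
  bad$hint_shown[2] <- FALSE
  bad$points_delta[2] <- 20L
  expect_error(trial_table(bad, "exp1"), "duplicate")
  # exp3 requires every pair saved
  expect_error(trial_table(trial_row(variant = "exp3", item_id = "i01"),
                           "exp3"),
               "saved")
})

test_that("writing preserves missing confidence as empty, never 0", {
  rows <- rbind(
    trial_row(variant = "exp2a", item_id = "i01", confidence_raw = 3.5),
    trial_row(variant = "exp2a", item_id = "i02",
              confidence_raw = NA_real_))
  tab <- trial_table(rows, "exp2a")
  out <- tempfile(fileext = ".csv")
  write_trials(tab, out)
  lines <- readLines(out)
  expect_match(lines[2], ",3.5,")
  expect_match(lines[3], ",without_hint,,self,")
  back <- read_trials(out, "exp2a")
  expect_identical(back$confidence_raw, c(3.5, NA_real_))
  expect_identical(back$confidence_prop, c(0.5, NA_real_))
})

test_that("an empty table writes a header-only file", {
  tab <- trial_table(trial_row(item_id = "i1")[0, ], "exp1")
  out <- tempfile(fileext = ".csv")
  write_trials(tab, out)
  expect_length(readLines(out), 1L)
  expect_equal(nrow(read_trials(out, "exp1")), 0L)
})

test_that("confidence rescaling maps scales linearly onto [0, 1]", {
  pct <- confidence_scale("percent")
  sl <- confidence_scale("slider6")
  expect_equal(rescale_confidence(50, pct), 0.5)
  expect_equal(rescale_confidence(c(1, 6), sl), c(0, 1))
  expect_equal(rescale_confidence(3.5, sl), (3.5 - 1) / (6 - 1))
  # strictly increasing across the scale
  raw <- seq(1, 6, length.out = 50)
  expect_true(all(diff(rescale_confidence(raw, sl)) > 0))
  expect_error(rescale_confidence(6.5, sl), "bounds")
  expect_error(rescale_confidence(-1, pct), "bounds")
})

test_that("filtering removes exactly the save-ineligible trials", {
  tab <- sim_exp1_small()
  filtered <- filter_ineligible(tab)
  expect_equal(nrow(filtered) + sum(!tab$save_eligible), nrow(tab))
  expect_true(all(filtered$save_eligible))
  # idempotent on an already-clean table
  expect_equal(nrow(filter_ineligible(filtered)), nrow(filtered))
  # degenerate: everything ineligible
  rows <- trial_row(item_id = "i01", save_eligible = FALSE)
  all_bad <- trial_table(rows, "exp1")
  expect_warning(out <- filter_ineligible(all_bad), "ineligible")
  expect_equal(nrow(out), 0L)
})

test_that("forced-recall accuracy is a clamped stratum fraction", {
  rows <- do.call(rbind, lapply(1:10, function(i) {
    trial_row(item_id = sprintf("i%02d", i), test_type = "forced",
              recall = as.integer(i <= 7))
  }))
  tab <- trial_table(rows, "exp1")
  expect_equal(compute_u_rec(tab, "p01"), 0.7)
  # a perfect score is clamped to keep the Beta proper
  rows$recall <- 1L
  rows$points_delta <- 20L
  tab <- trial_table(rows, "exp1")
  expect_equal(compute_u_rec(tab, "p01"), 0.99)
  expect_equal(compute_u_rec(tab, "p01", clamp = FALSE), 1)
  # empty stratum instructs the fallback
  expect_error(
    compute_u_rec(tab, "p01",
                  list(difficulty = "difficult", saved_status = "saved")),
    "overall")
})

test_that("the U_rec matrix shrinks sparse cells toward the overall rate", {
  # 4 forced easy-unsaved trials, 1 forced difficult-unsaved trial
  rows <- rbind(
    do.call(rbind, lapply(1:4, function(i) {
      trial_row(item_id = sprintf("e%d", i), test_type = "forced",
                recall = as.integer(i <= 2))
    })),
    trial_row(item_id = "d1", difficulty = "difficult",
              test_type = "forced", recall = 0L))
  tab <- trial_table(rows, "exp1")
  u <- u_rec_matrix(tab, shrink = 4)
  easy_rate <- 2 / 4
  # observed cell rates pulled toward their difficulty rate by 4
  # pseudo-trials; the difficult rate here is 0/1, clamped at 0.01
  expect_equal(unname(u["p01", 2]), (2 + 4 * easy_rate) / (4 + 4))
  expect_equal(unname(u["p01", 4]), 0.01)
  expect_equal(unname(u["p01", 1]), easy_rate) # empty cell: the rate itself
  # a large cell is essentially its own raw fraction
  many <- rbind(
    do.call(rbind, lapply(1:200, function(i) {
      trial_row(item_id = sprintf("m%d", i), test_type = "forced",
                recall = as.integer(i <= 150))
    })),
    do.call(rbind, lapply(1:8, function(i) {
      trial_row(item_id = sprintf("d%d", i), difficulty = "difficult",
                test_type = "forced", recall = as.integer(i <= 2))
    })))
  u2 <- u_rec_matrix(trial_table(many, "exp1"))
  expect_lt(abs(u2["p01", 2] - 0.75), 0.005)
  # a participant with no forced trials of one difficulty is an error
  easy_only <- trial_table(trial_row(item_id = "x1", test_type = "forced"),
                           "exp1")
  expect_error(u_rec_matrix(easy_only), "difficult")
})
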