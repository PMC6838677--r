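# Column schema shared by readers, writers and the simulator.
TRIAL_COLUMNS <- c(
  "participant_id", "variant", "block", "item_id", "difficulty",
  "save_eligible", "saved", "test_type", "confidence_condition",
  "confidence_raw", "choice", "hint_shown", "recall", "points_delta"
)

VARIANTS <- c("exp1", "exp2a", "exp2b", "exp3")

#' Confidence scale descriptor
#'
#' Describes the native confidence-rating scale of an experiment variant.
#' The lab slider runs 1--6 (recorded as a continuous cursor position), the
#' online experiments use a 0--100 scale, and the first experiment collects
#' no confidence ratings at all.
#'
#' @param kind One of `"none"`, `"slider6"` (1--6 continuous) or
#'   `"percent"` (0--100).
#' @return A list with elements `kind`, `min`, `max`.
#' @export
confidence_scale <- function(kind = c("none", "slider6", "percent")) {
  kind <- match.arg(kind)
  bounds <- switch(kind,
    none = c(NA_real_, NA_real_),
    slider6 = c(1, 6),
    percent = c(0, 100)
  )
  structure(list(kind = kind, min = bounds[1], max = bounds[2]),
            class = "confidence_scale")
}

#' Default confidence scale for a variant
#'
#' @param variant Experiment variant label.
#' @return A [confidence_scale()] object.
#' @export
default_scale <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  switch(variant,
    exp1 = confidence_scale("none"),
    exp2a = confidence_scale("slider6"),
    confidence_scale("percent")
  )
}

#' Rescale a raw confidence rating to a proportion
#'
#' Maps the native scale linearly onto \[0, 1\]: the scale minimum maps to 0
#' and the maximum to 1 (so 0--100 ratings are divided by 100 and the 1--6
#' slider maps 1 to 0 and 6 to 1). Missing values pass through as `NA`.
#'
#' @param raw Numeric vector of raw ratings on the native scale.
#' @param scale A [confidence_scale()] object.
#' @return Numeric vector of proportions in \[0, 1\].
#' @export
rescale_confidence <- function(raw, scale) {
  stopifnot(inherits(scale, "confidence_scale"))
  if (scale$kind == "none") {
    if (any(!is.na(raw))) {
      stop("confidence ratings supplied but the scale declares none")
    }
    return(rep(NA_real_, length(raw)))
  }
  ok <- is.na(raw) | (raw >= scale$min & raw <= scale$max)
  if (!all(ok)) {
    stop(sprintf("confidence rating outside the declared %s bounds [%g, %g] (first offending value %g)",
                 scale$kind, scale$min, scale$max, raw[!ok][1]))
  }
  (raw - scale$min) / (scale$max - scale$min)
}

#' Construct and validate a trial table
#'
#' A trial table is a data frame with one row per trial, a `variant`
#' attribute, and a `scale_spec` attribute describing the native confidence
#' scale. Construction validates the structural invariants of the task: a
#' hint can only be shown on an ask-for-help trial for a saved pair; forced
#' trials have no choice; confidence exists exactly in the variants that
#' collect it; in the all-saved variant every pair is saved; and the point
#' outcomes are +/-20 for self answers with an extra 3-point help cost on
#' ask trials (+17/-23).
#'
#' @param records Data frame with the columns in `TRIAL_COLUMNS`
#'   (a `confidence_prop` column is recomputed, never trusted).
#' @param variant Experiment variant, one of `"exp1"`, `"exp2a"`,
#'   `"exp2b"`, `"exp3"`.
#' @param scale A [confidence_scale()] (default: the variant's scale).
#' @return A validated `trial_table`.
#' @export
trial_table <- function(records, variant, scale = default_scale(variant)) {
  variant <- match.arg(variant, VARIANTS)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[TRIAL_COLUMNS]
  for (col in c("save_eligible", "saved", "hint_shown")) {
    records[[col]] <- as.logical(records[[col]])
  }
  records$block <- as.integer(records$block)
  records$recall <- as.integer(records$recall)
  records$points_delta <- as.integer(records$points_delta)
  records$confidence_raw <- as.numeric(records$confidence_raw)
  records$confidence_prop <- rescale_confidence(records$confidence_raw, scale)
  validate_trials(records, variant)
  structure(records,
            class = c("trial_table", "data.frame"),
            variant = variant, scale_spec = scale)
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> variant=%s, %d trials, %d participants\n",
              attr(x, "variant"), nrow(x),
              length(unique(x$participant_id))))
  NextMethod()
}

#' @rdname trial_table
#' @param table Object to query.
#' @export
table_variant <- function(table) attr(table, "variant")

fail_row <- function(bad, msg) {
  if (any(bad)) stop(sprintf("row %d: %s", which(bad)[1], msg), call. = FALSE)
}

validate_trials <- function(records, variant) {
  in_set <- function(x, set) x %in% set
  fail_row(!in_set(records$difficulty, c("easy", "difficult")),
           "difficulty must be easy or difficult")
  fail_row(!in_set(records$test_type, c("forced", "free")),
           "test_type must be forced or free")
  fail_row(!in_set(records$choice, c("ask", "self", "absent")),
           "choice must be ask, self or absent")
  fail_row(!in_set(records$confidence_condition,
                   c("with_hint", "without_hint", "absent")),
           "bad confidence_condition value")
  fail_row(!in_set(records$recall, c(0L, 1L)), "recall must be 0 or 1")
  fail_row(is.na(records$block) | records$block < 1L,
           "block must be a positive integer")
  fail_row(records$hint_shown & !(records$choice == "ask" & records$saved),
           "hint_shown requires an ask choice on a saved pair")
  fail_row((records$choice == "absent") != (records$test_type == "forced"),
           "choice is absent exactly on forced trials")
  if (variant == "exp1") {
    fail_row(records$confidence_condition != "absent",
             "exp1 collects no confidence ratings")
    fail_row(!is.na(records$confidence_raw),
             "exp1 collects no confidence ratings")
  } else {
    fail_row(records$confidence_condition == "absent",
             "confidence_condition required outside exp1")
  }
  if (variant == "exp3") {
    fail_row(!records$saved, "every pair is saved in exp3")
  }
  fail_row(records$saved & !records$save_eligible,
           "a saved pair must have been save-eligible")
  expected <- ifelse(records$choice == "ask",
                     ifelse(records$recall == 1L, 17L, -23L),
                     ifelse(records$recall == 1L, 20L, -20L))
  fail_row(records$points_delta != expected,
           "points_delta inconsistent with choice and recall (+20/-20, help cost 3)")
  key <- paste(records$participant_id, records$block, records$item_id)
  fail_row(duplicated(key), "duplicate participant x block x item")
  invisible(records)
}

#' Read a trial file
#'
#' Reads comma-separated trial-level data (UTF-8, header row, booleans as
#' true/false, missing confidence as an empty cell) and returns a validated
#' [trial_table()]. Malformed headers, out-of-domain values and duplicate
#' participant x block x item keys are rejected with the offending row.
#'
#' @param path Path to a CSV file in the documented column schema.
#' @param variant Experiment variant the file contains.
#' @param scale Native confidence scale (default: the variant's).
#' @return A `trial_table`.
#' @export
read_trials <- function(path, variant, scale = default_scale(variant)) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), TRIAL_COLUMNS)) {
    stop("malformed header: expected exactly ",
         paste(TRIAL_COLUMNS, collapse = ","))
  }
  bool <- function(x) {
    out <- rep(NA, length(x))
    out[x == "true"] <- TRUE
    out[x == "false"] <- FALSE
    if (any(is.na(out))) {
      stop(sprintf("row %d: boolean fields must be true/false",
                   which(is.na(out))[1]))
    }
    out
  }
  raw$save_eligible <- bool(raw$save_eligible)
  raw$saved <- bool(raw$saved)
  raw$hint_shown <- bool(raw$hint_shown)
  raw$confidence_raw <- ifelse(raw$confidence_raw == "", NA, raw$confidence_raw)
  raw$confidence_raw <- as.numeric(raw$confidence_raw)
  raw$block <- as.integer(raw$block)
  raw$recall <- as.integer(raw$recall)
  raw$points_delta <- as.integer(raw$points_delta)
  fail_row(raw$variant != variant, paste0("variant column must be ", variant))
  trial_table(raw, variant, scale)
}

#' Write a trial table
#'
#' Inverse of [read_trials()]: writes the schema columns as CSV with
#' booleans as true/false and missing confidence as an empty cell (never 0).
#'
#' @param table A `trial_table`.
#' @param path Output file path.
#' @export
write_trials <- function(table, path) {
  out <- as.data.frame(table)[TRIAL_COLUMNS]
  for (col in c("save_eligible", "saved", "hint_shown")) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  out$confidence_raw <- ifelse(is.na(out$confidence_raw), "",
                               format(out$confidence_raw, digits = 15,
                                      trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Drop save-ineligible trials
#'
#' Removes trials on which the participant could not save the pair because
#' the per-block save cap had already been reached (around 1% of trials in
#' the real task). Record order is otherwise preserved.
#'
#' @param table A `trial_table`.
#' @return The filtered `trial_table`.
#' @export
filter_ineligible <- function(table) {
  keep <- table$save_eligible
  if (nrow(table) > 0L && !any(keep)) {
    warning("all trials were save-ineligible; empty table returned")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("variant", "scale_spec")] <-
    attributes(table)[c("variant", "scale_spec")]
  truth_draws <- attr(table, "truth_draws")
  if (!is.null(truth_draws)) {
    truth_draws$p_rec <- truth_draws$p_rec[keep]
    attr(out, "truth_draws") <- truth_draws
  }
  class(out) <- class(table)
  out
}

#' Condition cells of the design
#'
#' The 2 (easy vs difficult) x 2 (saved vs unsaved) cells of the standard
#' design, or the two difficulty-only cells of the all-saved variant where
#' saved status is collapsed.
#'
#' @param variant Experiment variant.
#' @return Data frame with columns `cell`, `difficulty`, `saved_status`.
#' @export
condition_cells <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  if (variant == "exp3") {
    data.frame(cell = 1:2, difficulty = c("easy", "difficult"),
               saved_status = "collapsed", stringsAsFactors = FALSE)
  } else {
    data.frame(cell = 1:4,
               difficulty = c("easy", "easy", "difficult", "difficult"),
               saved_status = c("saved", "unsaved", "saved", "unsaved"),
               stringsAsFactors = FALSE)
  }
}

#' Cell index of each trial
#'
#' @param table A `trial_table`.
#' @return Integer vector mapping each row to its row in
#'   [condition_cells()].
#' @export
cell_index <- function(table) {
  cells <- condition_cells(table_variant(table))
  if (table_variant(table) == "exp3") {
    match(table$difficulty, cells$difficulty)
  } else {
    status <- ifelse(table$saved, "saved", "unsaved")
    match(paste(table$difficulty, status),
          paste(cells$difficulty, cells$saved_status))
  }
}

#' Forced-recall accuracy (U_rec)
#'
#' The proportion of correct forced-recall trials for one participant,
#' either overall or within one condition cell, clamped into
#' \[0.01, 0.99\] so the Beta distribution it parameterises stays proper.
#'
#' @param table A `trial_table`.
#' @param participant Participant id.
#' @param condition `NULL` for the participant-overall value, or a row of
#'   [condition_cells()] (a list with `difficulty` and `saved_status`).
#' @param clamp Clamp into \[0.01, 0.99\] (default `TRUE`).
#' @return A proportion.
#' @export
compute_u_rec <- function(table, participant, condition = NULL, clamp = TRUE) {
  rows <- table$participant_id == participant & table$test_type == "forced"
  if (!is.null(condition)) {
    rows <- rows & table$difficulty == condition$difficulty
    if (!identical(condition$saved_status, "collapsed")) {
      rows <- rows & (table$saved == (condition$saved_status == "saved"))
    }
  }
  n <- sum(rows)
  if (n == 0L) {
    stop("no forced-recall trials in the requested stratum; ",
         "fall back to the participant-overall stratum")
  }
  u <- mean(table$recall[rows])
  if (clamp) u <- min(max(u, 0.01), 0.99)
  u
}

#' Participant-by-cell U_rec matrix
#'
#' Forced-recall accuracy per participant and condition cell, stabilised
#' by empirical-Bayes shrinkage: the cell's recall count is augmented with
#' `shrink` pseudo-trials at the participant's forced-recall rate for that
#' cell's difficulty, `(recalled + shrink * u_difficulty) / (n + shrink)`.
#' Difficulty is by far the strongest determinant of recall in this task,
#' and each difficulty stratum holds about half of a participant's forced
#' trials, so the shrinkage target is both close to the cell's own rate
#' and well estimated. Cells with many forced trials are barely moved;
#' sparse cells (a handful of trials, where a raw fraction can sit at a
#' clamped 0.01 or 0.99) are pulled toward the difficulty rate, and empty
#' cells reduce to it exactly. Values are clamped into \[0.01, 0.99\].
#'
#' @param table A `trial_table`.
#' @param shrink Pseudo-trial weight of the difficulty-level rate
#'   (default 4, comparable to the smallest cells of the design).
#' @return Matrix (participants x cells) with participant ids as row names.
#' @export
u_rec_matrix <- function(table, shrink = 4) {
  ids <- unique(table$participant_id)
  cells <- condition_cells(table_variant(table))
  out <- matrix(NA_real_, length(ids), nrow(cells),
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    for (k in seq_len(nrow(cells))) {
      cond <- cells[k, ]
      diff_rows <- table$participant_id == ids[i] &
        table$test_type == "forced" &
        table$difficulty == cond$difficulty
      if (!any(diff_rows)) {
        stop("participant ", ids[i], " has no forced-recall trials for ",
             cond$difficulty, " pairs")
      }
      target <- mean(table$recall[diff_rows])
      rows <- diff_rows
      if (cond$saved_status != "collapsed") {
        rows <- rows & (table$saved == (cond$saved_status == "saved"))
      }
      u <- (sum(table$recall[rows]) + shrink * target) /
        (sum(rows) + shrink)
      out[i, k] <- min(max(u, 0.01), 0.99)
    }
  }
  out
}
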