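#' Per-cell behavioural proportions
#'
#' For each difficulty x saved cell: the learning-phase save proportion of
#' its difficulty (computed over save-eligible trials only), the
#' ask-for-help proportion on free-choice trials, and recall accuracy
#' split by test type and, within free choice, by ask/self. Empty cells
#' are reported as `NA`, never 0.
#'
#' @param table A `trial_table`.
#' @return Data frame with one row per cell.
#' @export
condition_proportions <- function(table) {
  tab <- filter_ineligible(table)
  cells <- condition_cells(table_variant(tab))
  cc <- cell_index(tab)
  prop <- function(x) if (length(x)) mean(x) else NA_real_
  save_by_diff <- vapply(c("easy", "difficult"), function(d) {
    prop(tab$saved[tab$difficulty == d])
  }, numeric(1))
  out <- cells
  out$save_prop <- save_by_diff[cells$difficulty]
  pick <- function(k, extra) which(cc == k & extra)
  out$n_trials <- vapply(seq_len(nrow(cells)), function(k) sum(cc == k),
                         integer(1))
  out$ask_prop <- vapply(seq_len(nrow(cells)), function(k) {
    prop(tab$choice[pick(k, tab$test_type == "free")] == "ask")
  }, numeric(1))
  out$recall_forced <- vapply(seq_len(nrow(cells)), function(k) {
    prop(tab$recall[pick(k, tab$test_type == "forced")])
  }, numeric(1))
  out$recall_free <- vapply(seq_len(nrow(cells)), function(k) {
    prop(tab$recall[pick(k, tab$test_type == "free")])
  }, numeric(1))
  out$recall_free_ask <- vapply(seq_len(nrow(cells)), function(k) {
    prop(tab$recall[pick(k, tab$test_type == "free" &
                           tab$choice == "ask")])
  }, numeric(1))
  out$recall_free_self <- vapply(seq_len(nrow(cells)), function(k) {
    prop(tab$recall[pick(k, tab$test_type == "free" &
                           tab$choice == "self")])
  }, numeric(1))
  out
}

#' Per-participant summaries
#'
#' One row per participant: overall ask-for-help proportion on free-choice
#' trials, mean confidence over available free-choice ratings (with- and
#' without-hint conditions pooled), forced-recall accuracy (unclamped) and
#' the save proportion per difficulty.
#'
#' @param table A `trial_table`.
#' @return Data frame of participant summaries.
#' @export
participant_summaries <- function(table) {
  tab <- filter_ineligible(table)
  ids <- unique(tab$participant_id)
  prop <- function(x) if (length(x)) mean(x) else NA_real_
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- tab$participant_id == id
    free <- rows & tab$test_type == "free"
    conf <- tab$confidence_prop[free]
    data.frame(
      participant_id = id,
      ask_prop = prop(tab$choice[free] == "ask"),
      mean_conf = if (all(is.na(conf))) NA_real_ else {
        mean(conf, na.rm = TRUE)
      },
      forced_acc = prop(tab$recall[rows & tab$test_type == "forced"]),
      save_prop_easy = prop(tab$saved[rows & tab$difficulty == "easy"]),
      save_prop_difficult = prop(tab$saved[rows &
                                             tab$difficulty == "difficult"]),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on `z` (with intercept); equals
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param x,y,z Equal-length numeric vectors (length >= 4, none constant).
#' @return The partial correlation.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("length mismatch")
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("constant input")
  }
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# standardized OLS paths from a correlation structure:
# a (x -> m), b (m -> y | x), direct c' (x -> y | m), total c (x -> y)
mediation_paths <- function(x, m, y) {
  rxm <- stats::cor(x, m)
  rxy <- stats::cor(x, y)
  rmy <- stats::cor(m, y)
  denom <- 1 - rxm^2
  if (denom < 1e-10) {
    # x and m collinear: attribute the shared effect to the mediator
    return(list(a = rxm, b = rmy, direct = rxy - rmy * rxm, total = rxy))
  }
  list(a = rxm,
       b = (rmy - rxy * rxm) / denom,
       direct = (rxy - rmy * rxm) / denom,
       total = rxy)
}

#' Bootstrap mediation analysis
#'
#' Product-of-coefficients mediation with standardized OLS paths
#' (`m ~ x`, `y ~ x + m`): the indirect effect is `a * b`, with a
#' percentile 95% confidence interval over `n_boot` resamples of
#' participants. The exact decomposition `total = direct + a * b` holds by
#' construction.
#'
#' @param x Predictor (e.g. forced-recall accuracy).
#' @param m Mediator (e.g. mean confidence).
#' @param y Outcome (e.g. ask-for-help proportion).
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed.
#' @return A `mediation_result` list with paths, indirect effect and CI.
#' @export
bootstrap_mediation <- function(x, m, y, n_boot = 10000L, seed = 1L) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("length mismatch")
  if (n < 10L) stop("need at least 10 observations")
  if (n_boot < 1000L) stop("n_boot must be at least 1000")
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("constant input")
  }
  paths <- mediation_paths(x, m, y)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(m[idx]) == 0 ||
          stats::sd(y[idx]) == 0) {
      return(NA_real_)
    }
    p <- mediation_paths(x[idx], m[idx], y[idx])
    p$a * p$b
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE,
                        names = FALSE)
  structure(list(path_a = paths$a, path_b = paths$b,
                 total_c = paths$total, direct_c_prime = paths$direct,
                 indirect = paths$a * paths$b,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation> a=%.3f b=%.3f indirect=%.3f [%.3f, %.3f] direct=%.3f total=%.3f\n",
    x$path_a, x$path_b, x$indirect, x$ci_low, x$ci_high,
    x$direct_c_prime, x$total_c))
  invisible(x)
}
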