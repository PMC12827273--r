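# Refutation of inferred causal effects.
#
# Placebo test: the SUV column of one region is permuted across subjects
# (all other columns untouched), the backdoor-adjusted estimate is
# recomputed, and the actual effect is compared with the null distribution
# of placebo effects. Counterfactual curves apply the do-operator on the
# fitted linear structural model (or a trained prediction network).

#' Placebo (permutation) test of regional causal effects
#'
#' For each region and each of `n_permutations` permutations, shuffles that
#' region's SUV column across subjects, re-runs the backdoor-adjusted
#' estimator and records the placebo effect. A region passes when its
#' actual absolute effect exceeds the `pass_quantile` of the absolute
#' placebo effects.
#'
#' @inheritParams estimate_direct_effect
#' @param regions region columns to test.
#' @param n_permutations number of permutations (>= 1; default 100).
#' @param seed integer seed; the full run is reproducible from (data, seed).
#' @param pass_quantile quantile of |placebo| that |actual| must exceed
#'   (default 0.99).
#' @return object of class `placebo_report`: per region a list with
#'   `actual_effect`, `placebo_effects`, `placebo_mean`,
#'   `placebo_abs_quantile`, `passes`.
#' @export
placebo_test <- function(data, regions, outcome,
                         confounders = c("age", "gender"),
                         n_permutations = 100L, seed = 1L, scope = "whole",
                         pass_quantile = 0.99) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  miss <- setdiff(regions, names(data))
  if (length(miss)) stopf("unknown region(s): %s", paste(miss, collapse = ", "))
  with_seed(seed, {
    report <- list()
    for (r in regions) {
      actual <- estimate_direct_effect(data, r, outcome, confounders,
                                       scope)$effect
      shuffled <- as.data.frame(data)
      sorted_orig <- sort(as.numeric(data[[r]]))
      eff <- vapply(seq_len(n_permutations), function(i) {
        shuffled[[r]] <- sample(data[[r]])
        # shuffling must preserve the region's marginal distribution exactly
        stopifnot(identical(sort(as.numeric(shuffled[[r]])), sorted_orig))
        tryCatch(
          estimate_direct_effect(shuffled, r, outcome, confounders,
                                 scope)$effect,
          error = function(e) stopf("region '%s', permutation %d: %s",
                                    r, i, conditionMessage(e)))
      }, 0)
      q <- stats::quantile(abs(eff), pass_quantile, names = FALSE)
      report[[r]] <- list(actual_effect = actual, placebo_effects = eff,
                          placebo_mean = mean(eff),
                          placebo_abs_quantile = q,
                          passes = abs(actual) > q)
    }
    structure(report, class = "placebo_report",
              outcome = outcome, pass_quantile = pass_quantile)
  })
}

#' Summarize actual vs placebo estimates
#'
#' @param report a `placebo_report`.
#' @return data.frame (one row per region, sorted by |actual| descending)
#'   with the actual effect, the placebo mean and median absolute placebo
#'   effect, the ratio median|placebo| / |actual| and the pass flag.
#' @export
compare_actual_vs_placebo <- function(report) {
  stopifnot(inherits(report, "placebo_report"), length(report) >= 1)
  tab <- do.call(rbind, lapply(names(report), function(r) {
    x <- report[[r]]
    data.frame(region = r, actual = x$actual_effect,
               placebo_mean = x$placebo_mean,
               placebo_median_abs = stats::median(abs(x$placebo_effects)),
               ratio = stats::median(abs(x$placebo_effects)) /
                 abs(x$actual_effect),
               passes = x$passes, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-abs(tab$actual)), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Counterfactual outcome curve under SUV interventions
#'
#' Predicted outcome as a function of an intervened SUV level in one
#' region. With `mechanism = "linear_scm"` the do-operator on the fitted
#' linear structural model gives
#' `predicted(g) = mean(outcome) + effect * (g - mean(suv))` over the
#' scoped rows. With `mechanism = "trained_model"` the region column is set
#' to each grid value for all scoped subjects and the trained network's
#' predictions are averaged.
#'
#' @inheritParams estimate_direct_effect
#' @param grid increasing vector of SUV levels; default: scoped region mean
#'   +/- 2 SD, 21 points.
#' @param mechanism `"linear_scm"` (default) or `"trained_model"`.
#' @param effect optional precomputed `causal_effect` for (region, outcome,
#'   scope); fitted on the fly if omitted (linear_scm only).
#' @param model a trained `cognet_model` whose inputs include the region
#'   (trained_model only).
#' @return object of class `counterfactual_curve`: data.frame with columns
#'   `grid` and `predicted`; region, outcome, scope and mechanism recorded
#'   as attributes.
#' @export
counterfactual_curve <- function(data, region, outcome, grid = NULL,
                                 scope = "whole",
                                 mechanism = c("linear_scm", "trained_model"),
                                 confounders = c("age", "gender"),
                                 effect = NULL, model = NULL) {
  mechanism <- match.arg(mechanism)
  rows <- scope_rows(data, scope)
  suv <- data[[region]][rows]
  if (is.null(grid)) {
    grid <- seq(mean(suv) - 2 * stats::sd(suv),
                mean(suv) + 2 * stats::sd(suv), length.out = 21)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stopf("domain error: 'grid' must be strictly increasing")
  }
  if (mechanism == "linear_scm") {
    if (is.null(effect)) {
      effect <- estimate_direct_effect(data, region, outcome, confounders,
                                       scope)
    }
    stopifnot(inherits(effect, "causal_effect"))
    pred <- mean(data[[outcome]][rows]) + effect$effect * (grid - mean(suv))
  } else {
    if (is.null(model)) stopf("contract error: 'model' required")
    if (!region %in% model$features) {
      stopf("contract error: region '%s' is not a model input", region)
    }
    d <- as.data.frame(data)[rows, , drop = FALSE]
    pred <- vapply(grid, function(g) {
      d[[region]] <- g
      mean(predict(model, d))
    }, 0)
  }
  structure(data.frame(grid = grid, predicted = pred),
            class = c("counterfactual_curve", "data.frame"),
            region = region, outcome = outcome, scope = scope,
            mechanism = mechanism)
}
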