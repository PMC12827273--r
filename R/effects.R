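# Backdoor-adjusted linear estimation of each region's direct causal
# effect on an outcome. Under the assumed structural model the set
# {age, gender} blocks every backdoor path from a region's SUV to the
# outcome, so adjusting for it in an ordinary-least-squares fit identifies
# the direct effect (in score points per SUV unit).

scope_rows <- function(data, scope) {
  if (identical(scope, "whole")) return(seq_len(nrow(data)))
  if (!"group" %in% names(data)) {
    stopf("scope '%s' requires a 'group' column", scope)
  }
  which(data$group == scope)
}

# OLS with standard errors and two-sided t-test p-values via QR.
ols_fit <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stopf("rank error: collinear design matrix")
  coefs <- qr.coef(qr_x, y)
  res <- y - X %*% coefs
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(XtX_inv) * s2, 0))
  tval <- coefs / se
  list(coef = coefs, se = se, p = 2 * stats::pt(-abs(tval), df),
       df = df, sigma2 = s2)
}

#' Backdoor-adjusted direct effect of one region on an outcome
#'
#' Fits `outcome ~ intercept + suv_region + confounders` by ordinary least
#' squares on the scoped rows; the SUV coefficient is the direct causal
#' effect under the assumed model, with its standard error and two-sided
#' p-value from the usual OLS sampling formulas.
#'
#' @param data a `cohort_table` or data.frame.
#' @param region region (SUV) column name.
#' @param outcome outcome column name (`"mmse"` or `"faq"`).
#' @param confounders adjustment set (default `c("age", "gender")`); use
#'   `character()` for the unadjusted marginal slope.
#' @param scope `"whole"` (default) or a diagnostic group label.
#' @param standardize if TRUE, the SUV column is divided by its scoped SD so
#'   the effect reads as points per SUV standard deviation.
#' @return object of class `causal_effect` with fields `region`, `outcome`,
#'   `scope`, `effect`, `std_error`, `p_value`, `n`.
#' @export
estimate_direct_effect <- function(data, region, outcome,
                                   confounders = c("age", "gender"),
                                   scope = "whole", standardize = FALSE) {
  vars <- c(region, outcome, confounders)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stopf("unknown column(s): %s", paste(miss, collapse = ", "))
  rows <- scope_rows(data, scope)
  n <- length(rows)
  if (n <= length(confounders) + 4) {
    stopf("sample-size error: scope '%s' leaves n = %d", scope, n)
  }
  suv <- data[[region]][rows]
  if (standardize) suv <- suv / stats::sd(suv)
  X <- cbind(1, suv, as.matrix(as.data.frame(data)[rows, confounders,
                                                   drop = FALSE]))
  storage.mode(X) <- "double"
  fit <- ols_fit(X, as.numeric(data[[outcome]][rows]))
  structure(list(region = region, outcome = outcome, scope = scope,
                 effect = unname(fit$coef[2]), std_error = unname(fit$se[2]),
                 p_value = unname(fit$p[2]), n = n),
            class = "causal_effect")
}

#' Direct effects of every region
#'
#' Applies [estimate_direct_effect()] to each region column and returns the
#' table ranked by absolute effect (descending; ties broken by region name).
#' Per-region estimation failures are collected, not fatal.
#'
#' @inheritParams estimate_direct_effect
#' @param regions region columns (default: all regions of the table).
#' @param p_adjust `"none"` (default — the ranked tables report raw
#'   p-values) or `"BH"` for a Benjamini-Hochberg adjusted column `p_adj`.
#' @return data.frame of class `effect_table` with columns `region`,
#'   `outcome`, `scope`, `effect`, `se`, `p` (and `p_adj` when requested),
#'   `n`, `rank`; failed regions (if any) in attribute `failures`.
#' @export
estimate_all_effects <- function(data, outcome, scope = "whole",
                                 confounders = c("age", "gender"),
                                 regions = NULL, standardize = FALSE,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(regions)) regions <- cohort_regions(data)
  failures <- character()
  rows <- lapply(regions, function(r) {
    tryCatch({
      ce <- estimate_direct_effect(data, r, outcome, confounders, scope,
                                   standardize)
      data.frame(region = r, outcome = outcome, scope = scope,
                 effect = ce$effect, se = ce$std_error, p = ce$p_value,
                 n = ce$n, stringsAsFactors = FALSE)
    }, error = function(e) {
      failures[[r]] <<- conditionMessage(e)
      NULL
    })
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stopf("all regions failed for outcome '%s'", outcome)
  if (p_adjust == "BH") tab$p_adj <- stats::p.adjust(tab$p, "BH")
  ord <- order(-abs(tab$effect), tab$region)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "failures") <- failures
  class(tab) <- c("effect_table", "data.frame")
  tab
}

#' Top-k regions by absolute causal effect
#'
#' @param table an `effect_table`.
#' @param k number of regions to keep (must be positive and at most the
#'   number of rows).
#' @return character vector of the k region names, by descending |effect|
#'   (ties broken by region name ascending).
#' @export
rank_and_select <- function(table, k) {
  if (!is.numeric(k) || k <= 0) stopf("domain error: k must be > 0")
  if (k > nrow(table)) stopf("domain error: k = %d exceeds %d regions",
                             k, nrow(table))
  ord <- order(-abs(table$effect), table$region)
  table$region[ord][seq_len(k)]
}

#' Union of whole-cohort and group-wise top regions
#'
#' Takes the top `k_whole` regions of the whole-cohort table and the top
#' `k_group` of each group table and returns their union with provenance
#' (which scopes contributed each region), ordered by the maximum absolute
#' effect across contributing scopes.
#'
#' @param whole whole-cohort `effect_table`.
#' @param per_group named list of group `effect_table`s.
#' @param k_whole,k_group selection sizes (defaults 30 and 20).
#' @return data.frame of class `region_selection` with columns `region`,
#'   `max_abs_effect`, `provenance` (comma-separated scopes).
#' @export
union_selection <- function(whole, per_group, k_whole = 30L, k_group = 20L) {
  picks <- list(whole = rank_and_select(whole, min(k_whole, nrow(whole))))
  tabs <- c(list(whole = whole), per_group)
  for (g in names(per_group)) {
    picks[[g]] <- rank_and_select(per_group[[g]],
                                  min(k_group, nrow(per_group[[g]])))
  }
  regions <- unique(unlist(picks))
  prov <- lapply(regions, function(r)
    names(picks)[vapply(picks, function(p) r %in% p, TRUE)])
  max_eff <- vapply(seq_along(regions), function(i) {
    max(vapply(prov[[i]], function(sc) {
      t <- tabs[[sc]]
      abs(t$effect[t$region == regions[i]])
    }, 0))
  }, 0)
  ord <- order(-max_eff, regions)
  out <- data.frame(region = regions[ord],
                    max_abs_effect = max_eff[ord],
                    provenance = vapply(prov[ord], paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("region_selection", "data.frame")
  out
}

#' Cross-group overlap of top-ranked regions
#'
#' Partitions the union of the supplied ranked region lists into membership
#' classes (regions present in all groups, in each pair only, unique to one
#' group, ...).
#'
#' @param per_group named list (length >= 2) of character region vectors.
#' @return list with `classes` (named list of region vectors, names like
#'   `"AD&MCI"`) and `counts` (named integer vector).
#' @export
cross_group_overlap <- function(per_group) {
  if (length(per_group) < 2) stopf("need at least 2 groups")
  groups <- names(per_group)
  all_regions <- sort(unique(unlist(per_group)))
  member <- vapply(per_group, function(g) all_regions %in% g,
                   logical(length(all_regions)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(m) paste(groups[m], collapse = "&"))
  classes <- split(all_regions, key)
  list(classes = classes,
       counts = vapply(classes, length, 0L))
}
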