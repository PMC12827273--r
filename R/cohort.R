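# Synthetic ADNI-like cohort generation with known causal ground truth.
#
# The generative model is the assumed structural causal model of the
# analysis: demographics (age, gender) influence both regional SUV and the
# cognitive/functional scores; regional SUV influences the scores directly.
#
#   suv[i, r]  = base_r + a_r * age_std_i + g_r * gender_i + N(0, suv_noise_sd)
#   score[i,o] = intercept[group_i, o] + sum_r beta[r, o] * suv[i, r]
#                + gamma_age_o * age_i + gamma_gender_o * gender_i
#                + N(0, noise_sd[group_i, o])
#
# Raw scores are rounded and clipped to the group's score range; the
# pre-clipping coefficients and raw scores are kept in the ground truth.

#' Default per-group demographic and score parameters
#'
#' Group-level cohort characteristics (age range, male fraction, score
#' means/SDs and admissible integer score ranges) for the AD, MCI and NC
#' diagnostic groups, matching the demographic table of a typical ADNI-style
#' 288-subject FDG-PET cohort.
#'
#' @return named list with one entry per group (`AD`, `MCI`, `NC`).
#' @export
group_params_default <- function() {
  list(
    AD  = list(age_range = c(55, 90), gender_balance = 54 / 96,
               mmse_mean = 22.4, mmse_sd = 3.2, mmse_range = c(9, 25),
               faq_mean = 15.0, faq_sd = 6.7, faq_range = c(5, 30)),
    MCI = list(age_range = c(52, 90), gender_balance = 57 / 96,
               mmse_mean = 26.8, mmse_sd = 3.6, mmse_range = c(10, 28),
               faq_mean = 5.4, faq_sd = 6.9, faq_range = c(0, 26)),
    NC  = list(age_range = c(59, 95), gender_balance = 38 / 96,
               mmse_mean = 28.9, mmse_sd = 1.4, mmse_range = c(25, 30),
               faq_mean = 0.3, faq_sd = 1.3, faq_range = c(0, 5))
  )
}

#' Default region-level causal effects
#'
#' Ten regions carry nonzero direct effects on MMSE and FAQ (score points
#' per SUV unit). Magnitudes mirror reported whole-cohort causal-score
#' ranges for these structures (roughly -8 to +4); positive MMSE effects
#' mean higher metabolism supports cognition, negative FAQ effects mean
#' higher metabolism supports daily functioning (FAQ is reverse-scored).
#'
#' @return data.frame with columns `region`, `mmse`, `faq`.
#' @export
effect_map_default <- function() {
  data.frame(
    region = c("Angular_L", "Angular_R", "Temporal_Inf_L", "Temporal_Inf_R",
               "Temporal_Mid_L", "Hippocampus_L", "Parietal_Inf_L",
               "Supramarginal_L", "Cerebelum_3_L", "Vermis_1_2"),
    mmse   = c(3.25, 3.03, 3.68, 3.22, 2.99, 2.11, 2.40, 1.90, -2.09, -1.92),
    faq    = c(-8.26, -7.63, -4.00, -3.50, -3.00, -2.50, -5.79, -4.95,
               1.50, 1.00),
    stringsAsFactors = FALSE
  )
}

#' Default confounder loadings
#'
#' Age (standardized) and gender load on every regional SUV and on both
#' outcomes, making demographics genuine confounders of the SUV-score
#' relationship. SUV loadings are small and negative for age (metabolism
#' declines with age); score loadings are in points per year / per male.
#'
#' @param n_regions number of atlas regions.
#' @return list with `age_suv`, `gender_suv` (length `n_regions`),
#'   `age_score`, `gender_score` (named, `mmse`/`faq`).
#' @export
confounder_coeffs_default <- function(n_regions = 120L) {
  list(
    age_suv      = rep(-0.03, n_regions),
    gender_suv   = rep(0.015, n_regions),
    age_score    = c(mmse = -0.08, faq = 0.08),
    gender_score = c(mmse = 0.60, faq = -0.80)
  )
}

#' Cohort generator configuration
#'
#' Assembles and validates the full configuration of the synthetic cohort
#' generator. Defaults reproduce the stated world of the reference cohort:
#' 96 subjects per diagnostic group, 120 atlas regions, group score
#' distributions per [group_params_default()], ten causal regions per
#' [effect_map_default()] and age/gender confounding per
#' [confounder_coeffs_default()].
#'
#' @param n_per_group subjects per diagnostic group (>= 2).
#' @param n_regions number of atlas regions (default 120).
#' @param group_params per-group parameter list, see [group_params_default()].
#' @param effect_map data.frame (`region`, `mmse`, `faq`) of direct effects in
#'   score points per SUV unit; regions must be a subset of the atlas labels.
#'   Default: [effect_map_default()] restricted to the configured region set.
#' @param confounder_coeffs default [confounder_coeffs_default()] sized to
#'   `n_regions`.
#' @param noise_sd outcome residual SD: `"auto"` (default) calibrates each
#'   group/outcome residual so the total raw-score SD matches the configured
#'   group SD; or a single non-negative number used everywhere.
#' @param suv_base_mean,suv_base_sd between-region baseline SUV level and
#'   spread (unitless SUV).
#' @param suv_noise_sd subject-level SUV residual SD. The default (0.08) is
#'   deliberately small: with direct effects of up to 8 score points per SUV
#'   unit, larger inter-subject dispersion would be incompatible with the
#'   configured score SDs.
#' @param shared_factor_sd optional SD of a subject-level factor loading
#'   equally on all regions (inter-region correlation); default 0 =
#'   independent regions.
#' @param seed integer seed; (config, seed) fully determines the cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 96L,
                          n_regions = 120L,
                          group_params = group_params_default(),
                          effect_map = NULL,
                          confounder_coeffs = NULL,
                          noise_sd = "auto",
                          suv_base_mean = 5.0,
                          suv_base_sd = 0.4,
                          suv_noise_sd = 0.08,
                          shared_factor_sd = 0,
                          seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stopf("configuration error: 'n_per_group' must be >= 2")
  }
  check_number(n_regions, "n_regions", lower = 1)
  regions <- region_names(n_regions)
  if (is.null(effect_map)) {
    # default effects restricted to the regions that exist
    effect_map <- effect_map_default()
    effect_map <- effect_map[effect_map$region %in% regions, , drop = FALSE]
  }
  if (is.null(confounder_coeffs)) {
    confounder_coeffs <- confounder_coeffs_default(n_regions)
  }
  for (g in names(group_params)) {
    p <- group_params[[g]]
    for (f in c("mmse_sd", "faq_sd")) {
      if (p[[f]] < 0) stopf("configuration error: '%s' for group %s must be >= 0", f, g)
    }
    for (f in c("mmse_range", "faq_range")) {
      r <- p[[f]]
      if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 30) {
        stopf("configuration error: '%s' for group %s must lie within [0, 30]", f, g)
      }
    }
    if (p$gender_balance < 0 || p$gender_balance > 1) {
      stopf("configuration error: 'gender_balance' for group %s must be in [0, 1]", g)
    }
  }
  if (!all(c("region", "mmse", "faq") %in% names(effect_map))) {
    stopf("configuration error: 'effect_map' needs columns region, mmse, faq")
  }
  bad <- setdiff(effect_map$region, regions)
  if (length(bad)) {
    stopf("configuration error: 'effect_map' names unknown regions: %s",
          paste(bad, collapse = ", "))
  }
  for (f in c("suv_base_sd", "suv_noise_sd", "shared_factor_sd")) {
    if (get(f) < 0) stopf("configuration error: '%s' must be >= 0", f)
  }
  if (is.numeric(noise_sd)) {
    check_number(noise_sd, "noise_sd", lower = 0)
  } else if (!identical(noise_sd, "auto")) {
    stopf("configuration error: 'noise_sd' must be \"auto\" or a number >= 0")
  }
  structure(list(
    n_per_group = as.integer(n_per_group), n_regions = as.integer(n_regions),
    regions = regions, group_params = group_params, effect_map = effect_map,
    confounder_coeffs = confounder_coeffs, noise_sd = noise_sd,
    suv_base_mean = suv_base_mean, suv_base_sd = suv_base_sd,
    suv_noise_sd = suv_noise_sd, shared_factor_sd = shared_factor_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Cohort-level age mean and SD implied by the config (mixture of per-group
# uniforms with equal weights) -- used to standardize age deterministically.
age_moments <- function(config) {
  gp <- config$group_params
  mids <- vapply(gp, function(p) mean(p$age_range), 0)
  vars <- vapply(gp, function(p) diff(p$age_range)^2 / 12, 0)
  mu <- mean(mids)
  v <- mean(vars + mids^2) - mu^2
  c(mean = mu, sd = sqrt(v))
}

# Expand the effect_map data.frame to an n_regions x 2 coefficient matrix.
effect_matrix <- function(config) {
  beta <- matrix(0, config$n_regions, 2,
                 dimnames = list(config$regions, c("mmse", "faq")))
  em <- config$effect_map
  if (nrow(em)) {
    beta[em$region, "mmse"] <- em$mmse
    beta[em$region, "faq"] <- em$faq
  }
  beta
}

#' Generate a synthetic cohort with known causal ground truth
#'
#' Draws a full subject table (demographics, regional SUVs, MMSE and FAQ)
#' from the linear structural causal model described in
#' [cohort_config()]. Group score means are matched in expectation by
#' analytic intercept calibration; with `noise_sd = "auto"` the residual SD
#' is calibrated so the total raw-score SD matches the configured group SD
#' (floored at 0.5). Scores are rounded and clipped to the group's range
#' after generation; the ground truth retains the raw (pre-clipping) scores.
#'
#' @param config a [cohort_config()].
#' @return list with elements `table` (class `cohort_table`, a data.frame
#'   with columns `subject_id`, `age`, `gender` (1 = male), `group`, one SUV
#'   column per region, `mmse`, `faq`) and `truth` (class `cohort_truth`:
#'   realized coefficients, intercepts, noise SDs, baseline means, age
#'   standardization constants and raw scores).
#' @export
#' @examples
#' cc <- cohort_config(n_per_group = 5, n_regions = 8,
#'                     effect_map = effect_map_default()[1, ])
#' cohort <- generate_cohort(cc)
#' dim(cohort$table)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_params)
  n_g <- config$n_per_group
  n <- n_g * length(groups)
  regions <- config$regions
  beta <- effect_matrix(config)
  cc <- config$confounder_coeffs
  am <- age_moments(config)

  with_seed(config$seed, {
    base_r <- stats::rnorm(config$n_regions, config$suv_base_mean,
                           config$suv_base_sd)
    names(base_r) <- regions

    group <- rep(groups, each = n_g)
    age <- numeric(n); gender <- integer(n)
    for (g in groups) {
      idx <- which(group == g)
      p <- config$group_params[[g]]
      age[idx] <- stats::runif(n_g, p$age_range[1], p$age_range[2])
      n_male <- round(p$gender_balance * n_g)
      gender[idx] <- sample(rep(c(1L, 0L), c(n_male, n_g - n_male)))
    }
    age_std <- (age - am["mean"]) / am["sd"]

    suv <- matrix(stats::rnorm(n * config$n_regions, 0, config$suv_noise_sd),
                  n, config$n_regions)
    if (config$shared_factor_sd > 0) {
      suv <- suv + stats::rnorm(n, 0, config$shared_factor_sd)
    }
    suv <- suv + rep(base_r, each = n) +
      outer(age_std, cc$age_suv) + outer(as.numeric(gender), cc$gender_suv)
    if (any(suv <= 0)) {
      warning("clamping ", sum(suv <= 0), " non-positive SUV values to 0.01")
      suv[suv <= 0] <- 0.01
    }
    colnames(suv) <- regions

    # intercepts: match configured group means in expectation (analytic)
    intercepts <- noise <- matrix(0, length(groups), 2,
                                  dimnames = list(groups, c("mmse", "faq")))
    for (g in groups) {
      p <- config$group_params[[g]]
      e_age <- mean(p$age_range)
      e_age_std <- (e_age - am["mean"]) / am["sd"]
      pm <- p$gender_balance
      e_suv <- base_r + cc$age_suv * e_age_std + cc$gender_suv * pm
      v_age_std <- diff(p$age_range)^2 / 12 / am["sd"]^2
      for (o in c("mmse", "faq")) {
        target_mean <- p[[paste0(o, "_mean")]]
        target_sd <- p[[paste0(o, "_sd")]]
        intercepts[g, o] <- target_mean -
          (sum(beta[, o] * e_suv) + cc$age_score[[o]] * e_age +
             cc$gender_score[[o]] * pm)
        if (identical(config$noise_sd, "auto")) {
          c_a <- sum(beta[, o] * cc$age_suv) + cc$age_score[[o]] * am["sd"]
          c_g <- sum(beta[, o] * cc$gender_suv) + cc$gender_score[[o]]
          v_struct <- c_a^2 * v_age_std + c_g^2 * pm * (1 - pm) +
            sum(beta[, o]^2) *
              (config$suv_noise_sd^2 + config$shared_factor_sd^2)
          noise[g, o] <- sqrt(max(target_sd^2 - v_struct, 0.25))
        } else {
          noise[g, o] <- config$noise_sd
        }
      }
    }

    raw <- matrix(0, n, 2, dimnames = list(NULL, c("mmse", "faq")))
    score <- raw
    for (o in c("mmse", "faq")) {
      eps <- stats::rnorm(n, 0, noise[group, o])
      raw[, o] <- intercepts[group, o] + drop(suv %*% beta[, o]) +
        cc$age_score[[o]] * age + cc$gender_score[[o]] * gender + eps
      rng <- vapply(config$group_params,
                    function(p) p[[paste0(o, "_range")]], numeric(2))
      score[, o] <- pmin(pmax(round(raw[, o]), rng[1, group]), rng[2, group])
    }

    table <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, gender = gender, group = group,
      suv, score, check.names = FALSE, stringsAsFactors = FALSE
    )
    attr(table, "regions") <- regions
    class(table) <- c("cohort_table", "data.frame")

    truth <- structure(list(
      effect = beta, confounder_coeffs = cc, intercepts = intercepts,
      noise_sd = noise, base_means = base_r,
      age_center = unname(am["mean"]), age_scale = unname(am["sd"]),
      raw_scores = data.frame(mmse_raw = raw[, "mmse"], faq_raw = raw[, "faq"]),
      config = config
    ), class = "cohort_truth")

    list(table = table, truth = truth)
  })
}

#' Region columns of a cohort table
#' @param table a `cohort_table` (or compatible data.frame).
#' @return character vector of region column names.
#' @export
cohort_regions <- function(table) {
  attr(table, "regions") %||%
    setdiff(names(table), c("subject_id", "age", "gender", "group",
                            "mmse", "faq"))
}

#' Write / read a cohort table as delimited text
#'
#' Round-trips the subject table as comma-separated text with a header row
#' and one subject per row.
#'
#' @param table a `cohort_table`.
#' @param path output file.
#' @return `write_cohort` the path invisibly; `read_cohort` a `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  attr(tab, "regions") <- setdiff(
    names(tab), c("subject_id", "age", "gender", "group", "mmse", "faq"))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Serialize / restore a cohort configuration
#'
#' Writes the configuration as structured JSON so that a cohort is fully
#' reproducible from the file alone.
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$regions <- NULL  # implied by n_regions
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gp <- lapply(x$group_params, function(p) {
    p$age_range <- as.numeric(p$age_range)
    p$mmse_range <- as.numeric(p$mmse_range)
    p$faq_range <- as.numeric(p$faq_range)
    p
  })
  cohort_config(
    n_per_group = x$n_per_group, n_regions = x$n_regions, group_params = gp,
    effect_map = as.data.frame(x$effect_map),
    confounder_coeffs = list(
      age_suv = as.numeric(x$confounder_coeffs$age_suv),
      gender_suv = as.numeric(x$confounder_coeffs$gender_suv),
      age_score = stats::setNames(unlist(x$confounder_coeffs$age_score),
                                  c("mmse", "faq")),
      gender_score = stats::setNames(unlist(x$confounder_coeffs$gender_score),
                                     c("mmse", "faq"))),
    noise_sd = if (is.character(x$noise_sd)) x$noise_sd else as.numeric(x$noise_sd),
    suv_base_mean = x$suv_base_mean, suv_base_sd = x$suv_base_sd,
    suv_noise_sd = x$suv_noise_sd, shared_factor_sd = x$shared_factor_sd,
    seed = x$seed)
}
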