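test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  gp <- group_params_default()
  gp$AD$mmse_sd <- -1
  expect_error(cohort_config(group_params = gp), "mmse_sd")
  gp <- group_params_default()
  gp$NC$faq_range <- c(0, 40)
  expect_error(cohort_config(group_params = gp), "faq_range")
  expect_error(
    cohort_config(n_regions = 4,
                  effect_map = data.frame(region = "Nonexistent_L",
                                          mmse = 1, faq = 1),
                  confounder_coeffs = confounder_coeffs_default(4)),
    "unknown regions")
  expect_error(small_config(noise_sd = -2), "noise_sd")
})

test_that("generation is a pure function of (config, seed)", {
  cc <- small_config(seed = 42)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$intercepts, b$truth$intercepts)
  cc2 <- small_config(seed = 43)
  expect_false(identical(generate_cohort(cc2)$table$mmse, a$table$mmse))
})

test_that("degenerate linear model: raw score equals the group intercept", {
  cc <- small_config(
    n_per_group = 10,
    effects = data.frame(region = character(), mmse = numeric(),
                         faq = numeric()),
    noise_sd = 0)
  cc$confounder_coeffs$age_score[] <- 0
  cc$confounder_coeffs$gender_score[] <- 0
  gen <- generate_cohort(cc)
  for (g in c("AD", "MCI", "NC")) {
    idx <- gen$table$group == g
    expect_equal(gen$truth$raw_scores$mmse_raw[idx],
                 rep(gen$truth$intercepts[g, "mmse"], sum(idx)))
  }
})

test_that("noiseless single-effect config recovers the slope exactly", {
  regs <- region_names(8)
  cc <- small_config(
    effects = data.frame(region = regs[7], mmse = 2.0, faq = 0),
    noise_sd = 0)
  cc$confounder_coeffs$age_score[] <- 0
  cc$confounder_coeffs$gender_score[] <- 0
  gen <- generate_cohort(cc)
  d <- data.frame(y = gen$truth$raw_scores$mmse_raw,
                  x = gen$table[[regs[7]]],
                  g = gen$table$group)
  slope <- stats::coef(stats::lm(y ~ x + g, data = d))[["x"]]
  expect_equal(slope, 2.0, tolerance = 1e-10)
})

test_that("default AD group matches the configured score means", {
  # group means 22.4 (MMSE) and 15.0 (FAQ) with SDs 3.2 / 6.7 at n = 96
  gen <- generate_cohort(cohort_config(seed = 7))
  ad <- gen$table[gen$table$group == "AD", ]
  expect_equal(nrow(ad), 96)
  se_mmse <- stats::sd(ad$mmse) / sqrt(96)
  se_faq <- stats::sd(ad$faq) / sqrt(96)
  expect_lt(abs(mean(ad$mmse) - 22.4), 3 * se_mmse + 0.45)  # 0.45 = clip bias
  expect_lt(abs(mean(ad$faq) - 15.0), 3 * se_faq + 0.45)
})

test_that("raw score moments converge to configured values at n = 5000", {
  cc <- small_config(n_per_group = 5000, seed = 3)
  gen <- generate_cohort(cc)
  raw <- gen$truth$raw_scores
  for (g in c("AD", "MCI", "NC")) {
    idx <- gen$table$group == g
    p <- cc$group_params[[g]]
    expect_lt(abs(mean(raw$mmse_raw[idx]) - p$mmse_mean), 0.2)
    expect_lt(abs(stats::sd(raw$mmse_raw[idx]) - p$mmse_sd), 0.2)
    expect_lt(abs(mean(raw$faq_raw[idx]) - p$faq_mean), 0.3)
    expect_lt(abs(stats::sd(raw$faq_raw[idx]) - p$faq_sd), 0.3)
  }
})

test_that("confounding is real: marginal slope biased, adjusted slope not", {
  regs <- region_names(6)
  cc <- cohort_config(
    n_per_group = 5000, n_regions = 6,
    group_params = homogeneous_groups(),
    effect_map = data.frame(region = regs[2], mmse = 2, faq = -2),
    confounder_coeffs = confounder_coeffs_default(6), seed = 9)
  gen <- generate_cohort(cc)
  null_region <- regs[1]                  # nonzero age loading, beta = 0
  marg <- estimate_direct_effect(gen$table, null_region, "mmse",
                                 confounders = character())
  adj <- estimate_direct_effect(gen$table, null_region, "mmse")
  expect_gt(abs(marg$effect) / marg$std_error, 3)   # clearly biased
  expect_lt(abs(adj$effect), 3 * adj$std_error)     # consistent with 0
})

test_that("table invariants hold: integer scores in range, positive SUVs", {
  gen <- generate_cohort(small_config(seed = 5))
  tab <- gen$table
  expect_false(anyNA(tab))
  expect_true(all(tab$mmse == round(tab$mmse) & tab$mmse >= 0 & tab$mmse <= 30))
  expect_true(all(tab$faq == round(tab$faq) & tab$faq >= 0 & tab$faq <= 30))
  for (g in c("AD", "MCI", "NC")) {
    p <- small_config()$group_params[[g]]
    idx <- tab$group == g
    expect_true(all(tab$mmse[idx] >= p$mmse_range[1] &
                      tab$mmse[idx] <= p$mmse_range[2]))
  }
  suv <- as.matrix(tab[, cohort_regions(tab)])
  expect_true(all(suv > 0))
  expect_length(cohort_regions(tab), 8)
})

test_that("cohort table and config round-trip through text files", {
  gen <- generate_cohort(small_config(n_per_group = 5, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(gen$table, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(gen$table),
               tolerance = 1e-12)
  expect_identical(cohort_regions(back), cohort_regions(gen$table))

  cfgf <- withr::local_tempfile(fileext = ".json")
  cc <- small_config(seed = 11)
  write_cohort_config(cc, cfgf)
  cc2 <- read_cohort_config(cfgf)
  expect_identical(generate_cohort(cc2)$table, generate_cohort(cc)$table)
})
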