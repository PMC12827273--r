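test_that("a noiseless linear mechanism is recovered exactly", {
  set.seed(1)
  n <- 60
  d <- data.frame(age = runif(n, 55, 90), gender = rbinom(n, 1, 0.5),
                  suv = runif(n, 4, 6))
  d$mmse <- 2 * d$suv + 0.5 * d$age
  ce <- estimate_direct_effect(d, "suv", "mmse")
  expect_equal(ce$effect, 2.0, tolerance = 1e-12)
  expect_equal(ce$n, n)
})

test_that("backdoor estimate equals the Frisch-Waugh partialled estimate", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 150
    d <- data.frame(age = rnorm(n, 70, 8), gender = rbinom(n, 1, 0.5))
    d$suv <- 5 - 0.05 * d$age + 0.2 * d$gender + rnorm(n, 0, 0.5)
    d$mmse <- 20 + 1.5 * d$suv - 0.1 * d$age + rnorm(n)
    ce <- estimate_direct_effect(d, "suv", "mmse")
    rx <- stats::resid(stats::lm(suv ~ age + gender, data = d))
    ry <- stats::resid(stats::lm(mmse ~ age + gender, data = d))
    fw <- stats::coef(stats::lm(ry ~ rx))[["rx"]]
    expect_equal(ce$effect, fw, tolerance = 1e-10)
  }
})

test_that("adjustment removes confounding bias on null regions", {
  regs <- region_names(4)
  cc <- cohort_config(
    n_per_group = 5000 %/% 3 + 1, n_regions = 4,
    group_params = homogeneous_groups(),
    effect_map = data.frame(region = regs[2], mmse = 2, faq = 0),
    confounder_coeffs = confounder_coeffs_default(4), seed = 13)
  tab <- generate_cohort(cc)$table
  unadj <- estimate_direct_effect(tab, regs[1], "mmse",
                                  confounders = character())
  adj <- estimate_direct_effect(tab, regs[1], "mmse")
  expect_gt(abs(unadj$effect), 3 * abs(adj$effect))
  expect_lt(abs(adj$effect), 3 * adj$std_error)
})

test_that("estimator error contracts: collinearity and small samples", {
  d <- data.frame(age = rnorm(30), gender = rbinom(30, 1, 0.5))
  d$suv <- d$age                          # collinear with the confounder
  d$mmse <- rnorm(30)
  expect_error(estimate_direct_effect(d, "suv", "mmse"), "rank error")
  d2 <- d[1:5, ]
  expect_error(estimate_direct_effect(d2, "suv", "mmse"),
               "sample-size error")
  expect_error(estimate_direct_effect(d, "nope", "mmse"), "unknown column")
})

test_that("the effect table covers all regions, ranked, scope-filtered", {
  gen <- generate_cohort(small_config(n_per_group = 96, n_regions = 10))
  tab <- estimate_all_effects(gen$table, "mmse")
  expect_s3_class(tab, "effect_table")
  expect_equal(nrow(tab), 10)
  expect_identical(tab$rank, 1:10)
  expect_true(all(diff(abs(tab$effect)) <= 1e-12))
  expect_true(all(tab$n == 288))
  ad <- estimate_all_effects(gen$table, "mmse", scope = "AD")
  expect_true(all(ad$n == 96))
  # whole-cohort n equals the sum of group ns
  ns <- vapply(c("AD", "MCI", "NC"), function(g)
    estimate_all_effects(gen$table, "mmse", scope = g)$n[1], 0)
  expect_equal(sum(ns), tab$n[1])
})

test_that("optional BH adjustment adds a monotone p_adj column", {
  gen <- generate_cohort(small_config(n_per_group = 40, n_regions = 6))
  et <- estimate_all_effects(gen$table, "mmse", p_adjust = "BH")
  expect_true("p_adj" %in% names(et))
  expect_equal(et$p_adj, stats::p.adjust(et$p, "BH"))
  expect_true(all(et$p_adj >= et$p - 1e-15))
})

test_that("per-region failures are collected, not fatal", {
  gen <- generate_cohort(small_config(n_per_group = 30, n_regions = 5))
  tab <- gen$table
  tab[[region_names(5)[2]]] <- tab$age     # force a rank error
  et <- estimate_all_effects(tab, "mmse")
  expect_equal(nrow(et), 4)
  fails <- attr(et, "failures")
  expect_named(fails, region_names(5)[2])
  expect_match(fails[[1]], "rank error")
})

test_that("selection ranks by absolute effect with name tie-breaks", {
  tab <- data.frame(region = c("ITG_L", "Angular_L", "Caudate_L"),
                    effect = c(3.68, 3.25, 1.73))
  expect_identical(rank_and_select(tab, 2), c("ITG_L", "Angular_L"))
  tab2 <- data.frame(region = c("A", "B"), effect = c(-8.26, 4.0))
  expect_identical(rank_and_select(tab2, 1), "A")
  tab3 <- data.frame(region = c("C", "A", "B"), effect = c(2, 2, 2))
  expect_identical(rank_and_select(tab3, 2), c("A", "B"))
  expect_error(rank_and_select(tab, 0), "domain error")
  expect_error(rank_and_select(tab, 9), "domain error")
})

test_that("union selection merges scopes with provenance", {
  mk <- function(regions, effects) {
    structure(data.frame(region = regions, effect = effects),
              class = c("effect_table", "data.frame"))
  }
  whole <- mk(c("R1", "R2", "R3"), c(3, 2, 1))
  same <- list(AD = whole, MCI = whole, NC = whole)
  u <- union_selection(whole, same, k_whole = 2, k_group = 2)
  expect_equal(nrow(u), 2)                 # identical lists: union size = k
  expect_identical(u$region, c("R1", "R2"))
  expect_identical(u$provenance[1], "whole,AD,MCI,NC")

  dis <- list(AD = mk(c("A1", "A2", "A3"), c(5, 4, 3)),
              MCI = mk(c("M1", "M2", "M3"), c(7, 6, 5)),
              NC = mk(c("N1", "N2", "N3"), c(2, 1.5, 1)))
  u2 <- union_selection(mk(c("W1", "W2", "W3"), c(9, 8, 7)), dis,
                        k_whole = 3, k_group = 3)
  expect_equal(nrow(u2), 12)
  expect_true(all(!grepl(",", u2$provenance)))   # singleton provenance
  expect_identical(u2$region[1], "W1")           # ordered by max |effect|
  expect_identical(u2$region[3], "M1")           # tie at 7 broken by name
})

test_that("cross-group overlap partitions match brute-force set arithmetic", {
  ov <- cross_group_overlap(list(AD = c("A", "B"), MCI = c("B", "C"),
                                 NC = c("C", "A")))
  expect_identical(ov$classes[["AD&MCI"]], "B")
  expect_identical(ov$classes[["MCI&NC"]], "C")
  expect_identical(ov$classes[["AD&NC"]], "A")
  expect_false("AD&MCI&NC" %in% names(ov$classes))

  same <- cross_group_overlap(list(AD = c("X", "Y"), MCI = c("X", "Y"),
                                   NC = c("Y", "X")))
  expect_setequal(same$classes[["AD&MCI&NC"]], c("X", "Y"))

  set.seed(9)
  pool <- paste0("R", 1:30)
  lists <- list(AD = sample(pool, 12), MCI = sample(pool, 12),
                NC = sample(pool, 12))
  ov2 <- cross_group_overlap(lists)
  expect_setequal(unlist(ov2$classes), unique(unlist(lists)))
  triple <- Reduce(intersect, lists)
  if (length(triple)) {
    expect_setequal(ov2$classes[["AD&MCI&NC"]], triple)
  }
  expect_error(cross_group_overlap(list(A = "x")), "at least 2")
})
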