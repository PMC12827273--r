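test_that("SUV conversion implements the dose-per-weight normalization", {
  expect_equal(compute_suv(0, 370, 74), 0)
  # activity equal to dose/weight in consistent units gives SUV 1:
  # 370 MBq / 74 kg = 5 kBq/mL under unit density
  expect_equal(compute_suv(5, injected_dose = 370, body_weight = 74), 1.0)
  expect_equal(compute_suv(c(1, 2), 100, 50), c(0.5, 1.0))
  expect_error(compute_suv(1, 0, 70), "injected_dose")
  expect_error(compute_suv(1, 370, -1), "body_weight")
  expect_error(compute_suv(-1, 370, 74), "activity")
})

test_that("SUV is homogeneous in activity and inverse in dose", {
  a <- matrix(runif(20, 1, 10), 4, 5)
  s <- compute_suv(a, 300, 70)
  expect_equal(compute_suv(3 * a, 300, 70), 3 * s)
  expect_equal(compute_suv(a, 2 * 300, 70), s / 2)
  expect_equal(compute_suv(a, 300, 2 * 70), 2 * s)
})

test_that("region means are exact voxel averages, background excluded", {
  atlas <- array(0L, c(3, 3, 1))
  atlas[1, 1:2, 1] <- 1L
  atlas[2, 1, 1] <- 2L
  vol <- array(0, c(3, 3, 1))
  vol[1, 1, 1] <- 1; vol[1, 2, 1] <- 3   # region 1: mean 2
  vol[2, 1, 1] <- 7                      # region 2: constant 7
  vol[3, 3, 1] <- 99                     # background, must not leak
  m <- extract_region_means(vol, atlas)
  expect_equal(unname(m), c(2, 7))
  expect_named(m, c("1", "2"))
})

test_that("extraction equals a brute-force voxel loop on random volumes", {
  set.seed(4)
  atlas <- array(sample(0:5, 16^3, replace = TRUE), c(16, 16, 16))
  vol <- array(rnorm(16^3), c(16, 16, 16))
  m <- extract_region_means(vol, atlas)
  for (l in 1:5) {
    acc <- 0; cnt <- 0
    for (i in seq_len(16^3)) {
      if (atlas[i] == l) { acc <- acc + vol[i]; cnt <- cnt + 1 }
    }
    expect_equal(unname(m[as.character(l)]), acc / cnt)
  }
})

test_that("extraction errors are explicit", {
  atlas <- array(1L, c(2, 2, 2))
  expect_error(extract_region_means(array(0, c(2, 2, 3)), atlas),
               "alignment error")
  expect_error(extract_region_means(array(0, c(2, 2, 2)), atlas, labels = 5),
               "empty-region error.*5")
  vol <- array(1, c(2, 2, 2)); vol[1] <- NaN
  expect_message(m <- extract_region_means(vol, atlas), "1 NaN")
  expect_equal(unname(m), 1)
})

test_that("frame averaging is the unweighted arithmetic mean", {
  m <- matrix(c(1, 5, 3, 7), 2, 2)       # regions x frames
  expect_equal(unname(average_frames(m)), c(2, 6))
  one <- matrix(c(1, 5), 2, 1)
  expect_equal(average_frames(cbind(one, one, one)), average_frames(one))
  expect_error(average_frames(matrix(0, 2, 0)), "at least one frame")
  expect_error(average_frames(matrix(c(1, NA), 1, 2)), "missing")
  set.seed(1)
  r <- matrix(rnorm(6 * 4), 4, 6)
  brute <- apply(r, 1, function(x) sum(x) / length(x))
  expect_equal(unname(average_frames(r)), unname(brute))
})

test_that("fixtures are deterministic with exactly recorded region means", {
  fx <- generate_pet_fixture(c(8, 8, 8), n_regions = 4, n_frames = 3,
                             seed = 7)
  expect_identical(fx, generate_pet_fixture(c(8, 8, 8), 4, 3, seed = 7))
  expect_setequal(unique(as.vector(fx$atlas)), 0:4)
  # zero noise: every voxel of region r equals the stored per-frame mean
  for (t in 1:3) {
    frame <- array(fx$volume[, , , t], dim = c(8, 8, 8))
    for (r in 1:4) {
      expect_true(all(frame[fx$atlas == r] == fx$true_region_means[r, t]))
    }
    expect_equal(unname(extract_region_means(frame, fx$atlas)),
                 unname(fx$true_region_means[, t]))
  }
  expect_error(generate_pet_fixture(c(2, 2, 1), n_regions = 50),
               "sizing error")
})

test_that("feature table equals the hand-chained pipeline of the three ops", {
  fx <- generate_pet_fixture(c(8, 8, 8), n_regions = 4, n_frames = 3,
                             seed = 3)
  fx$subject_id <- "sub1"
  tab <- build_feature_table(list(fx))
  expect_equal(tab$subject_id, "sub1")
  # hand chain: voxelwise SUV -> per-frame region means -> frame average
  per_frame <- sapply(1:3, function(t) {
    suv <- compute_suv(array(fx$volume[, , , t], c(8, 8, 8)),
                       fx$injected_dose, fx$body_weight)
    extract_region_means(suv, fx$atlas)
  })
  expect_equal(unname(unlist(tab[1, -1])), unname(average_frames(per_frame)))
  # zero-noise fixture: table equals SUV-converted true means exactly
  expect_equal(unname(unlist(tab[1, -1])),
               unname(compute_suv(rowMeans(fx$true_region_means),
                                  fx$injected_dose, fx$body_weight)))
})

test_that("identical volumes with different weights scale by weight ratio", {
  fx <- generate_pet_fixture(c(6, 6, 6), n_regions = 2, n_frames = 2,
                             seed = 5)
  s1 <- fx; s1$subject_id <- "a"
  s2 <- fx; s2$subject_id <- "b"; s2$body_weight <- fx$body_weight * 2
  tab <- build_feature_table(list(s1, s2))
  expect_equal(unname(unlist(tab[2, -1])), 2 * unname(unlist(tab[1, -1])))
})

test_that("subject errors carry the subject id and label context", {
  fx <- generate_pet_fixture(c(6, 6, 6), n_regions = 3, n_frames = 1,
                             seed = 1)
  fx$subject_id <- "bad_subject"
  expect_error(build_feature_table(list(fx), labels = 1:5),
               "bad_subject.*empty-region error.*4, 5")
})

test_that("frame and region averaging commute", {
  fx <- generate_pet_fixture(c(8, 8, 8), n_regions = 3, n_frames = 4,
                             seed = 11, noise_sd = 0.5)
  per_frame <- sapply(1:4, function(t)
    extract_region_means(array(fx$volume[, , , t], c(8, 8, 8)), fx$atlas))
  order1 <- average_frames(per_frame)
  mean_vol <- array(apply(fx$volume, 1:3, mean), c(8, 8, 8))
  order2 <- extract_region_means(mean_vol, fx$atlas)
  expect_equal(order1, order2)
})
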