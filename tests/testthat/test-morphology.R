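test_that("kink detection applies the visibility threshold and signs", {
  straight <- rbind(c(0, 0), c(100, 0), c(200, 0))
  expect_equal(nrow(detect_kinks(straight, 20)), 0L)

  # single 90-degree left bend: sign -1, +1 after reversing traversal
  left <- rbind(c(0, 0), c(100, 0), c(100, 100))
  k <- detect_kinks(left, 20)
  expect_equal(k$index, 2L)
  expect_equal(k$angle, 90)
  expect_equal(k$sign, -1)
  expect_equal(detect_kinks(left[3:1, ], 20)$sign, 1)

  # of turning angles (10, 30) only the second clears a 20 degree threshold
  fc <- build_polyline(c(100, 100, 100), c(10, 30), c(1L, 1L))
  k2 <- detect_kinks(fc, 20)
  expect_equal(nrow(k2), 1L)
  expect_equal(k2$angle, 30, tolerance = 1e-9)

  expect_equal(nrow(detect_kinks(rbind(c(0, 0), c(1, 1)), 20)), 0L)
  expect_error(detect_kinks(left, -3), "non-negative")
})

test_that("radius of gyration matches the rod limit and contracts on folding", {
  rod <- rbind(c(0, 0), c(600, 0))
  expect_equal(rg_norm_sq(rod, resample_step = 0.25), 1 / 12,
               tolerance = 1e-3)
  # discretization bias shrinks with the step
  expect_lt(abs(rg_norm_sq(rod, resample_step = 0.25) - 1 / 12),
            abs(rg_norm_sq(rod, resample_step = 5) - 1 / 12))
  bent <- build_polyline(c(300, 300), 90, 1L)
  expect_lt(rg_norm_sq(bent), 1 / 12)
  # value depends only on shape, not pose
  fc <- zigzag_chain()
  moved <- transform_chain(fc, angle = 1.1, center = c(5, 5),
                           shift = c(-40, 12))
  expect_equal(rg_norm_sq(moved), rg_norm_sq(fc), tolerance = 1e-12)
  # and not on traversal direction
  expect_equal(rg_norm_sq(reverse_chain(fc)), rg_norm_sq(fc),
               tolerance = 1e-12)
  expect_error(rg_norm_sq(rod, resample_step = 0), "positive")
})

test_that("rg decreases monotonically as a single kink deepens", {
  vals <- vapply(seq(5, 175, by = 10), function(a)
    rg_norm_sq(build_polyline(c(300, 300), a, 1L), resample_step = 1),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("orientation statistics recover alignment and isotropy", {
  rods_par <- lapply(1:30, function(i) straight_rod(100, heading = 0,
                                                    origin = c(0, i)))
  expect_equal(orientation_statistics(rods_par)$s2d, 1)
  rods_perp <- lapply(1:30, function(i) straight_rod(100, heading = pi / 2,
                                                     origin = c(i, 0)))
  expect_equal(orientation_statistics(rods_perp)$s2d, -1)

  set.seed(301)
  rods_iso <- lapply(1:20000, function(i)
    straight_rod(100, heading = runif(1, 0, pi)))
  o <- orientation_statistics(rods_iso)
  expect_lt(abs(o$s2d), 3 / sqrt(20000) * sqrt(0.5) + 0.005)
  # histogram is a density over the 180-degree range
  expect_equal(sum(o$od$density) * (180 / nrow(o$od)), 1, tolerance = 1e-9)
  # director measured relative: rotating the director recovers alignment
  expect_equal(orientation_statistics(rods_perp, director = pi / 2)$s2d, 1)
  expect_error(orientation_statistics(list()), "empty")
})

test_that("segment weighting makes long segments dominate the OD", {
  long_axial <- build_polyline(c(900, 100), 90, 1L)    # 900 nm along x
  o <- orientation_statistics(list(long_axial))
  expect_equal(o$s2d, (900 * 1 + 100 * (-1)) / 1000)
})

test_that("conformation summary reports the per-population descriptors", {
  # identical one-kink fibrils: every statistic is the single fibril's value
  one <- build_polyline(c(300, 300), 65, 1L)
  s <- conformation_summary(rep(list(one), 10), kinks = "annotated")
  expect_equal(s$mean_L, 600)
  expect_equal(s$mean_nk, 1)
  expect_equal(s$mean_kink_angle, 65)
  expect_equal(s$mean_inverse_kink_density, 600)
  expect_equal(s$mean_segment_length, 300)
  expect_equal(unname(s$mean_kink_angle_by_nk["1"]), 65)

  # kink-free population: density undefined, segment length = contour length
  rods <- lapply(c(500, 700), straight_rod)
  s0 <- conformation_summary(rods)
  expect_true(is.na(s0$mean_inverse_kink_density))
  expect_equal(s0$mean_segment_length, s0$mean_L)
  expect_true(is.na(s0$mean_kink_angle))
  expect_null(s0$sign_product)

  # detection route equals annotation route when all kinks are deep
  set.seed(302)
  pop <- sample_population(fibril_model(), 400)
  sd1 <- conformation_summary(pop, kinks = "detect")
  sd2 <- conformation_summary(pop, kinks = "annotated")
  expect_equal(sd1$mean_nk, sd2$mean_nk)
  expect_equal(sd1$mean_kink_angle, sd2$mean_kink_angle, tolerance = 1e-9)
})

test_that("summary statistics are invariant under rigid motion and reversal", {
  set.seed(303)
  pop <- sample_population(fibril_model(), 300)
  moved <- lapply(pop, function(f)
    transform_chain(f, angle = 0.4, shift = c(100, -50)))
  resum <- function(fs) conformation_summary(fs, kinks = "annotated")
  a <- resum(pop)
  b <- resum(moved)
  expect_equal(b$mean_rg_norm_sq, a$mean_rg_norm_sq, tolerance = 1e-10)
  expect_equal(b$mean_kink_angle, a$mean_kink_angle, tolerance = 1e-10)
  expect_equal(b$mean_segment_length, a$mean_segment_length)
  rev <- resum(lapply(pop, reverse_chain))
  expect_equal(rev$mean_rg_norm_sq, a$mean_rg_norm_sq, tolerance = 1e-10)
  expect_equal(rev$mean_kink_angle, a$mean_kink_angle, tolerance = 1e-10)
  # |sum of signs| per class survives the global sign flip
  for (cl in names(a$sign_sum_abs_by_nk))
    expect_equal(rev$sign_sum_abs_by_nk[[cl]]$mean,
                 a$sign_sum_abs_by_nk[[cl]]$mean)
})

test_that("sign product statistics invert to the persistence probability", {
  expect_equal(p_from_sign_product(0.30), 0.65)
  expect_equal(sign_product_variance(0.30), 0.91)
  expect_equal(sign_product_theory(0.65), 0.30)
  expect_error(p_from_sign_product(1.2), "\\[-1, 1\\]")

  # perfectly alternating two-kink population
  alt <- sign_product_stats(rep(list(c(1L, -1L)), 50), n_boot = 0)
  expect_equal(alt$mean, -1)
  expect_equal(alt$p_hat, 0)
  expect_equal(alt$variance, 0)

  set.seed(304)
  st <- sign_product_stats(sign_population(20000, 2, 0.65), n_boot = 200)
  expect_lt(abs(st$mean - 0.30), 3 * sqrt(0.91 / 20000))
  expect_equal(st$variance, 1 - st$mean^2, tolerance = 1e-12)
  expect_lt(abs(st$p_hat - 0.65), 1.5 * sqrt(0.91 / 20000))
  expect_error(sign_product_stats(list()), "no two-kink")
  expect_error(sign_product_stats(list(c(1L, 1L, 1L))), "two-kink class")
})

test_that("sign-sum theory closed forms equal sequence enumeration", {
  for (p in seq(0, 1, by = 0.1)) {
    expect_equal(sign_sum_theory(2, p), markov_sign_sum_oracle(2, p),
                 tolerance = 1e-12)
    expect_equal(sign_sum_theory(3, p), markov_sign_sum_oracle(3, p),
                 tolerance = 1e-12)
    expect_equal(sign_sum_theory(4, p), markov_sign_sum_oracle(4, p),
                 tolerance = 1e-12)
    expect_equal(sign_sum_theory(6, p), markov_sign_sum_oracle(6, p),
                 tolerance = 1e-12)
    expect_equal(sign_sum_theory(4, p, method = "enumeration"),
                 sign_sum_theory(4, p, method = "closed_form"),
                 tolerance = 1e-12)
  }
  expect_equal(sign_sum_theory(3, 1), 3)
  expect_equal(sign_sum_theory(2, 0.65), 1.30)
  expect_equal(sign_sum_theory(4, 0.65), 2.0085)
  expect_error(sign_sum_theory(1, 0.5), "at least 2")
})

test_that("simulated sign sums match theory and flips preserve them", {
  set.seed(305)
  for (nk in 2:4) {
    pop <- sign_population(20000, nk, 0.65)
    ss <- sign_sum_abs(pop, n_boot = 200)
    expect_lt(abs(ss$mean - sign_sum_theory(nk, 0.65)), 3 * ss$se)
    flipped <- lapply(pop, function(s) -s)
    expect_equal(sign_sum_abs(flipped, n_boot = 0)$mean, ss$mean)
  }
  expect_equal(sign_sum_abs(rep(list(c(1L, 1L, 1L)), 5), n_boot = 0)$mean, 3)
  expect_error(sign_sum_abs(list()), "empty")
  expect_error(sign_sum_abs(list(c(1L, 1L), c(1L, 1L, -1L))), "same kink")
})

test_that("excluded area of thin rods follows the Onsager 2D result", {
  expect_equal(excluded_area_rod(600), 2 * 600^2 / pi)
  expect_false(interaction_flag(1e6, 600))
  expect_true(interaction_flag(2e5, 600))
  expect_error(excluded_area_rod(-1), "positive")
  set.seed(306)
  expect_equal(mc_excluded_area(600, n = 2e5), 2 * 600^2 / pi,
               tolerance = 0.02)
})

test_that("percentile bootstrap is deterministic and scales as 1/sqrt(n)", {
  expect_error(bootstrap_ci(3), "at least 2")
  expect_error(bootstrap_ci(1:10, n_boot = 10), "at least 100")
  const <- bootstrap_ci(rep(2.5, 40), mean, n_boot = 200)
  expect_equal(const$lower, const$upper)
  expect_equal(const$estimate, 2.5)

  set.seed(307)
  x <- sample(c(-1, 1), 500, replace = TRUE, prob = c(0.35, 0.65))
  set.seed(308); ci1 <- bootstrap_ci(x, mean, n_boot = 500)
  set.seed(308); ci2 <- bootstrap_ci(x, mean, n_boot = 500)
  expect_identical(ci1, ci2)
  # binomial-theory width 2 * 1.96 * sqrt((1 - m^2) / n)
  m <- mean(x)
  expect_equal(ci1$upper - ci1$lower, 2 * 1.96 * sqrt((1 - m^2) / 500),
               tolerance = 0.15)
})

test_that("p_hat recovery: bootstrap CI covers the true p in most runs", {
  set.seed(309)
  cover <- vapply(1:20, function(i) {
    st <- sign_product_stats(sign_population(400, 2, 0.65), n_boot = 300)
    st$p_ci[1] <= 0.65 && 0.65 <= st$p_ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
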