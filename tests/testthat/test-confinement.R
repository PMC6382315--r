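test_that("random placement is a rigid motion with uniform transverse COM", {
  sl <- slit(750)
  fc <- zigzag_chain()
  set.seed(201)
  for (i in 1:10) {
    placed <- place_random(fc, sl)
    expect_equal(placed$L, fc$L)
    expect_equal(placed$kink_angles, fc$kink_angles)
    expect_equal(placed$signs, fc$signs)
    expect_equal(turning_angles(placed$vertices)$angle,
                 turning_angles(fc$vertices)$angle, tolerance = 1e-9)
  }
  # near-point-like fibril: transverse COM uniform on [0, w]
  dot <- straight_rod(1e-6)
  ys <- replicate(3000, place_random(dot, sl)$vertices[1, 2])
  ks <- suppressWarnings(stats::ks.test(ys, "punif", 0, 750))
  expect_gt(ks$p.value, 1e-4)
})

test_that("fits is decided by vertex containment", {
  sl <- slit(750)
  up <- build_polyline(600, heading = pi / 2, origin = c(0, 75))
  expect_true(fits(up, sl))                     # transverse rod, L < w, fits
  expect_false(fits(build_polyline(800, heading = pi / 2, origin = c(0, 0)),
                    sl))                        # transverse rod longer than w
  expect_true(fits(build_polyline(5000, heading = 0, origin = c(0, 10)),
                   sl))                         # axial rod of any length
})

test_that("vertex check agrees with dense 1 nm resampling (convexity)", {
  sl <- slit(400)
  set.seed(202)
  for (i in 1:30) {
    f <- place_random(sample_fibril(fibril_model()), sl)
    v <- f$vertices
    s <- c(0, cumsum(vertex_segment_lengths(v)))
    t <- seq(0, f$L, by = 1)
    dense_ok <- all(stats::approx(s, v[, 2], xout = t)$y >= 0 &
                      stats::approx(s, v[, 2], xout = t)$y <= sl$width)
    expect_identical(fits(f, sl), dense_ok)
  }
})

test_that("accept/reject simulator records counts and preserves geometry", {
  m <- fibril_model()
  ens <- simulate_confined(m, slit(750), n_accept_target = 500, seed = 203)
  expect_s3_class(ens, "confined_ensemble")
  expect_equal(ens$n_accepted, 500L)
  expect_equal(ens$acceptance_fraction, ens$n_accepted / ens$n_proposed)
  for (f in ens$fibrils[1:20]) {
    expect_true(all(f$vertices[, 2] >= 0 & f$vertices[, 2] <= 750))
    expect_true(all(f$kink_angles == 65))
    expect_true(f$L >= 550 && f$L <= 650)
  }
  # over-tight slit fails loudly
  expect_error(
    simulate_confined(m, slit(1), n_accept_target = 5, max_proposals = 200),
    "too tight")
})

test_that("a very wide slit accepts the unconfined population unchanged", {
  ens <- simulate_confined(fibril_model(), slit(1e6),
                           n_accept_target = 5000, seed = 204)
  # only a fibril hanging over a wall is rejected: ~ extent / w ~ 6e-4
  expect_gte(ens$acceptance_fraction, 0.998)
  nk <- vapply(ens$fibrils, n_kinks, integer(1))
  expect_equal(mean(nk), 1.24, tolerance = 0.04)
})

test_that("acceptance fraction is non-decreasing in slit width", {
  fracs <- vapply(c(700, 1000, 1500, 2500, 6000), function(w) {
    simulate_confined(fibril_model(), slit(w), n_accept_target = 800,
                      seed = 205)$acceptance_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("the slit filter enriches kinked fibrils (selectivity bound)", {
  ens <- simulate_confined(fibril_model(), slit(750),
                           n_accept_target = 5000, seed = 206)
  accepted_nk <- mean(vapply(ens$fibrils, n_kinks, integer(1)))
  expect_gte(accepted_nk, expected_kink_count(fibril_model()$kink_pmf) - 0.03)
})

test_that("rod order parameter closed form matches its quadrature", {
  expect_error(rod_s2d_closed_form(-1, 10), "positive")
  expect_error(rod_s2d_closed_form(10, 0), "positive")
  # isotropic limit
  expect_lt(abs(rod_s2d_closed_form(1, 1e6)), 1e-5)
  # L = w endpoint
  expect_equal(rod_s2d_closed_form(750, 750), 1 / (3 * (pi / 2 - 1)))
  for (r in c(0.063, 0.27, 0.40, 0.80, 1.0)) {
    expect_equal(rod_s2d_closed_form(600, 600 / r),
                 rod_s2d_quadrature(600, 600 / r), tolerance = 1e-8)
  }
  # beyond the weak branch the quadrature takes over and stays in [0, 1]
  s_over <- rod_s2d_closed_form(900, 750)
  expect_true(s_over > 0 && s_over < 1)
})

test_that("kink-free rod simulation matches the analytic acceptance", {
  m0 <- fibril_model(kink_pmf = 1,
                     length_law = list(type = "fixed", value = 600))
  ens <- simulate_confined(m0, slit(750), n_accept_target = 8000, seed = 207)
  p_acc <- rod_acceptance(600, 750)
  se <- sqrt(p_acc * (1 - p_acc) / ens$n_proposed)
  expect_lt(abs(ens$acceptance_fraction - p_acc), 4 * se)
})

test_that("length-weighted S2D combiner handles mass and errors", {
  unif <- list(type = "uniform", min = 0, max = 4)
  # single ratio passes through
  expect_equal(s2d_weighted(0.5, 0.37, unif, 1), 0.37)
  # equal masses average
  expect_equal(s2d_weighted(c(1, 3), c(0.2, 0.4), unif, 1), 0.3)
  # unequal masses weight accordingly: bins (0,2] and (2,Inf) on uniform(0,3)
  expect_equal(s2d_weighted(c(1, 3), c(0.2, 0.4),
                            list(type = "uniform", min = 0, max = 3), 1),
               (2 / 3 * 0.2 + 1 / 3 * 0.4))
  expect_error(s2d_weighted(c(1, 3), c(0.2, 0.4),
                            list(type = "uniform", min = 10, max = 11), 1e-9),
               "no mass")
  expect_error(s2d_weighted(numeric(), numeric(), unif, 1), "non-empty")
})

test_that("weighted combination of simulated and closed-form S2D agree", {
  # two routes to the population S2D under log-normal lengths: per-ratio
  # Monte Carlo estimates vs per-ratio closed forms, combined with the same
  # length-mass weights
  law <- list(type = "lognormal", meanlog = log(500), sdlog = 0.25)
  w <- 1200
  ratios <- c(0.2, 0.4, 0.6, 0.9)
  set.seed(208)
  mc <- numeric(length(ratios))
  ses <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    m <- fibril_model(kink_pmf = 1,
                      length_law = list(type = "fixed",
                                        value = ratios[i] * w))
    ens <- simulate_confined(m, slit(w), n_accept_target = 6000)
    th <- vapply(ens$fibrils, function(f) {
      d <- diff(f$vertices)
      atan2(d[2], d[1])
    }, numeric(1))
    mc[i] <- mean(cos(2 * th))
    ses[i] <- stats::sd(cos(2 * th)) / sqrt(length(th))
  }
  cf <- vapply(ratios, function(r) rod_s2d_closed_form(r * w, w), numeric(1))
  expect_lt(abs(s2d_weighted(ratios, mc, law, w) -
                  s2d_weighted(ratios, cf, law, w)), 3 * max(ses))
})
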