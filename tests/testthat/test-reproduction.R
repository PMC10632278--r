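TI1 <- ti_exponential(1)

test_that("R_star reduces correctly in the three classical regimes", {
  d <- hh_dist(c(0.5, 0.2, 0.3))
  sb <- size_bias(d)
  # lambda_L = Inf: R_* = lambda_G E[T_I] mu_Htilde
  expect_equal(R_star(d, 1.3, Inf, TI1), 1.3 * sb$mu, tolerance = 1e-12)
  # all size 1 and lambda_L = 0: R_* = lambda_G E[T_I]
  expect_equal(R_star(hh_common(1), 2.2, 5, TI1), 2.2)
  expect_equal(R_star(d, 2.2, 0, TI1), 2.2)
  # scales with the mean infectious period
  expect_equal(R_star(d, 1.3, 1, ti_exponential(0.5)),
               2 * R_star(d, 1.3, 2, TI1), tolerance = 1e-12)
})

test_that("rank-generation means match hand enumeration and brute force", {
  # lambda_L = Inf: (1, n-1, 0, ...)
  g <- rank_generation_means(4, Inf, TI1)$means
  expect_equal(g, c(1, 3, 0, 0))
  # n = 2: (1, 1 - phi(lambda_L))
  expect_equal(rank_generation_means(2, 1.7, TI1)$means,
               c(1, 1 - TI1$phi(1.7)))
  # n = 3 hand enumeration: mu_1 = 2 p_L, mu_2 = 2(phi - phi2)(1 - phi)
  lamL <- 1.698
  ph <- TI1$phi(lamL); ph2 <- TI1$phi(2 * lamL)
  g3 <- rank_generation_means(3, lamL, TI1)$means
  expect_equal(g3[2], 2 * (1 - ph), tolerance = 1e-12)
  expect_equal(g3[3], 2 * (ph - ph2) * (1 - ph), tolerance = 1e-12)

  # full brute-force digraph enumeration for n <= 3, several laws
  for (law in list(TI1, ti_fixed(1), ti_erlang(2, 2))) {
    for (lamL in c(0.4, 1, 2.5)) {
      for (n in 2:3) {
        expect_equal(rank_generation_means(n, lamL, law)$means,
                     oracle_rank_generations(n, lamL, law),
                     tolerance = 1e-12)
      }
    }
  }

  # generations partition the household final size: sum_i mu_i = mu_n
  for (n in c(2, 4, 6, 9)) {
    for (lamL in c(0.3, 1, 4)) {
      expect_equal(sum(rank_generation_means(n, lamL, TI1)$means),
                   single_household_mean_size(n, lamL, TI1),
                   tolerance = 1e-10)
    }
  }
})

test_that("rank-generation R0 solves its defining equation", {
  # lambda_L = 0: R0 = lambda_G E[T_I]
  expect_equal(R0(hh_dist(c(0.5, 0.5)), 1.7, 0, TI1), 1.7,
               tolerance = 1e-9)
  # common size 2 closed form: lambda^2 = lambda_G E (lambda + p_L)
  lg <- 1.9; lamL <- 1.1
  pL <- 1 - TI1$phi(lamL)
  lam_closed <- (lg + sqrt(lg^2 + 4 * lg * pL)) / 2
  expect_equal(R0(hh_common(2), lg, lamL, TI1), lam_closed,
               tolerance = 1e-10)
  # highly locally and maximally separated: common n with
  # lambda_G = 4 / ((1+n) E[T_I]) gives R0 = 2
  for (n in c(2, 4, 6)) {
    expect_equal(R0(hh_common(n), 4 / (1 + n), Inf, TI1), 2,
                 tolerance = 1e-9)
  }
})

test_that("post-vaccination threshold parameter interpolates R_* to zero and decreases", {
  d <- hh_dist(c(0.4, 0.3, 0.3))
  expect_equal(R_U_hat(d, 1.5, 1.2, TI1, 0),
               R_star(d, 1.5, 1.2, TI1), tolerance = 1e-12)
  expect_equal(R_U_hat(d, 1.5, 1.2, TI1, 1), 0)
  grid <- seq(0, 1, by = 0.05)
  vals <- R_U_hat(d, 1.5, 1.2, TI1, grid)
  expect_true(all(diff(vals) < 0))
  # highly locally infectious closed form:
  # lambda_G E [c(1-c) + mu (1-c)^2]
  sb <- size_bias(d)
  for (cc in c(0.2, 0.5, 0.8)) {
    expect_equal(R_U_hat(d, 1.5, Inf, TI1, cc),
                 1.5 * (cc * (1 - cc) + sb$mu * (1 - cc)^2),
                 tolerance = 1e-12)
  }
})

test_that("residual threshold parameter from outcomes has the right extremes", {
  d <- hh_dist(c(0.4, 0.3, 0.3))
  none <- lapply(1:3, function(n) c(1, numeric(n)))
  all_inf <- lapply(1:3, function(n) c(numeric(n), 1))
  expect_equal(R_DI_from_outcome(d, 1.5, 1.2, TI1, none),
               R_star(d, 1.5, 1.2, TI1), tolerance = 1e-12)
  expect_equal(R_DI_from_outcome(d, 1.5, 1.2, TI1, all_inf), 0)
  # highly locally infectious outcome: sum_n n alpha_tilde_n pi^n lamG E
  pi <- 0.55
  sb <- size_bias(d)
  out_inf <- lapply(1:3, function(n) {
    v <- numeric(n + 1); v[1] <- pi^n; v[n + 1] <- 1 - pi^n; v
  })
  expect_equal(R_DI_from_outcome(d, 1.5, Inf, TI1, out_inf),
               1.5 * sum((1:3) * sb$probs * pi^(1:3)), tolerance = 1e-12)
})

test_that("growth rate solves the household Lotka-Euler equation", {
  # homogeneous SIR: r = lambda_G - gamma
  expect_equal(growth_rate(hh_common(1), 2, 0, 1), 1, tolerance = 1e-9)
  expect_equal(growth_rate(hh_common(1), 0.4, 0, 1), -0.6,
               tolerance = 1e-9)
  # homogeneous SEIR consistency with (1 + r/delta)(1 + r/gamma) = lamG/gamma
  gam <- 1 / 4; del <- 1 / 3
  lg <- gam * (1 + (1 / 6) / del) * (1 + (1 / 6) / gam)
  expect_equal(growth_rate(hh_common(1), lg, 0, gam, del), 1 / 6,
               tolerance = 1e-9)
  # r = 0 exactly at R_* = 1
  d <- hh_dist(c(0.5, 0.5))
  lg_crit <- 1 / sum(size_bias(d)$probs *
                       single_household_mean_size(1:2, 0.8, TI1))
  expect_equal(growth_rate(d, lg_crit, 0.8, 1), 0, tolerance = 1e-8)
  expect_error(growth_rate(d, 1, Inf, 1), "finite")
})

test_that("R0-to-growth-rate conversion and calibration round-trip", {
  expect_equal(r_from_R0BBT(1, 1 / 4, 1 / 3), 0)
  expect_equal(r_from_R0BBT(2.5, 1 / 4, 1 / 3), 1 / 6, tolerance = 1e-12)
  for (r in c(0.05, 0.2, 0.8)) {
    R0b <- (1 + r / (1 / 3)) * (1 + r / (1 / 4))
    expect_equal(r_from_R0BBT(R0b, 1 / 4, 1 / 3), r, tolerance = 1e-12)
  }

  # homogeneous SIR: r_target = 1, gamma = 1 -> lambda_G = 2
  expect_equal(calibrate_lambda_G(hh_common(1), 0, 1, NULL, 1), 2,
               tolerance = 1e-10)
  # round trip on a household structure, SIR and SEIR
  d <- hh_dist(c(0.3, 0.4, 0.3))
  for (del in list(NULL, 1 / 3)) {
    lg <- calibrate_lambda_G(d, 1.1, 1 / 4, del, r_target = 0.15)
    expect_equal(growth_rate(d, lg, 1.1, 1 / 4, del), 0.15,
                 tolerance = 1e-8)
  }
  # holding r fixed, a larger local rate needs a smaller global rate
  lgs <- vapply(c(0.2, 0.8, 2, 5),
                function(l) calibrate_lambda_G(d, l, 1, NULL, 0.5),
                numeric(1))
  expect_true(all(diff(lgs) < 0))
})

test_that("threshold quantities agree in sign across parameter draws", {
  set.seed(7)
  for (k in 1:12) {
    w <- stats::runif(4)
    d <- hh_dist(w / sum(w))
    lg <- stats::runif(1, 0.2, 2.5)
    lamL <- stats::runif(1, 0, 3)
    s_rstar <- sign(R_star(d, lg, lamL, TI1) - 1)
    s_r0 <- sign(R0(d, lg, lamL, TI1) - 1)
    r <- growth_rate(d, lg, lamL, 1)
    expect_equal(s_rstar, s_r0)
    if (abs(r) > 1e-8) expect_equal(s_rstar, sign(r))
  }
})
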