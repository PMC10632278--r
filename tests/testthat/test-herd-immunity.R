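TI1 <- ti_exponential(1)

test_that("vaccine-induced level matches closed forms in all three regimes", {
  # homogeneous: lambda_G E = 2.5 -> 0.6
  expect_equal(h_C(hh_common(1), 2.5, 0, TI1)$level, 0.6,
               tolerance = 1e-10)
  # lambda_L = 0 on any structure: 1 - 1/(lambda_G E)
  d <- hh_dist(c(0.4, 0.3, 0.3))
  expect_equal(h_C(d, 2, 0, TI1)$level, 0.5, tolerance = 1e-10)
  # lambda_L = Inf: bisection agrees with the quadratic closed form
  for (lg in c(0.8, 1.5, 3)) {
    expect_equal(h_C(d, lg, Inf, TI1)$level,
                 h_C_highly_local(d, lg, TI1), tolerance = 1e-10)
  }
  # common n = 2, lambda_G = E = 1: 1 - (sqrt(5) - 1)/2
  expect_equal(h_C_highly_local(hh_common(2), 1, TI1),
               1 - (sqrt(5) - 1) / 2, tolerance = 1e-12)
  # mu_Htilde -> 1 limit collapses to the homogeneous formula
  expect_equal(h_C_highly_local(hh_common(1), 2.5, TI1), 0.6)
  # subcritical: flagged level zero / error for the closed form
  sub <- h_C(d, 0.2, 1, TI1)
  expect_true(sub$already_immune)
  expect_equal(sub$level, 0)
  expect_error(h_C_highly_local(d, 0.1, TI1), "subcritical")
  # residual threshold parameter is one at the solution
  res <- h_C(d, 1.8, 0.9, TI1)
  expect_equal(res$residual_R, 1, tolerance = 1e-8)
})

test_that("final-size disease-induced level matches its dedicated limit branches", {
  d <- hh_dist(c(0.4, 0.3, 0.3))
  # lambda_L = 0: 1 - 1/(lambda_G E)
  expect_equal(h_tilde_D(d, 2, 0, TI1)$level, 0.5, tolerance = 1e-8)
  # common n, lambda_L = Inf: 1 - 1/(n lambda_G E)
  for (n in 2:4) {
    expect_equal(h_tilde_D(hh_common(n), 1.1, Inf, TI1)$level,
                 1 - 1 / (n * 1.1), tolerance = 1e-8)
    expect_equal(h_tilde_D_highly_local(hh_common(n), 1.1, TI1)$level,
                 1 - 1 / (n * 1.1), tolerance = 1e-10)
  }
  # general solver with the Inf flag equals the pgf branch
  for (lg in c(0.9, 1.6)) {
    expect_equal(h_tilde_D(d, lg, Inf, TI1)$level,
                 h_tilde_D_highly_local(d, lg, TI1)$level,
                 tolerance = 1e-8)
  }
  # the residual epidemic is exactly critical at the solution
  res <- h_tilde_D(d, 1.7, 1.3, TI1)
  expect_equal(res$residual_R, 1, tolerance = 1e-8)
  expect_equal(res$pi, exp(-res$kappa_hat * 1.7 * res$z),
               tolerance = 1e-10)
  # geometric size-biased structure: equality with h_C across lambda_G
  dg <- geometric_size_biased(2.2, n_max = 60)
  for (lg in c(0.6, 1, 2.4)) {
    expect_equal(h_tilde_D_highly_local(dg, lg, TI1)$level,
                 h_C_highly_local(dg, lg, TI1), tolerance = 1e-6)
  }
})

test_that("common household sizes give a strictly larger disease-induced level", {
  # highly locally infectious, closed forms, n = 2..6
  for (n in 2:6) {
    for (lg in c(0.51 * 4 / n, 1, 4, 9) / 1) {
      if (n * lg <= 1) next
      expect_gt(h_tilde_D_highly_local(hh_common(n), lg, TI1)$level,
                h_C_highly_local(hh_common(n), lg, TI1))
    }
  }
  # finite local rates, n = 2 and 3, general solvers
  for (n in 2:3) {
    for (lamL in c(0.25, 1, 8)) {
      for (Rtar in c(1.5, 4, 10)) {
        lg <- Rtar / (sum(size_bias(hh_common(n))$probs *
                            single_household_mean_size(n, lamL, TI1)))
        expect_gt(h_tilde_D(hh_common(n), lg, lamL, TI1)$level,
                  h_C(hh_common(n), lg, lamL, TI1)$level)
      }
    }
  }
})

test_that("two-size crossover rate matches the sign change of the level difference", {
  # n = 2 and the p <= (n-2)/(2(n-1)) region admit no crossover
  expect_null(lambda_G_star_two_sizes(2, 0.5))
  expect_null(lambda_G_star_two_sizes(3, 0.25))
  expect_null(lambda_G_star_two_sizes(5, 0.3))

  # n = 4, p = 0.5: pi_hat solves pi^3 - 2 pi + 1 = 0 -> (sqrt(5) - 1)/2
  cross <- lambda_G_star_two_sizes(4, 0.5)
  expect_equal(cross$pi_hat, (sqrt(5) - 1) / 2, tolerance = 1e-10)
  expect_equal(cross$lambda_G_star,
               1 / (cross$pi_hat * (0.5 + 4 * 0.5 * cross$pi_hat^3)),
               tolerance = 1e-10)

  # the level difference changes sign across lambda_G_star
  d <- hh_mixture_1n(4, 0.5)
  lgs <- cross$lambda_G_star
  below <- h_tilde_D_highly_local(d, 0.9 * lgs, TI1)$level -
    h_C_highly_local(d, 0.9 * lgs, TI1)
  above <- h_tilde_D_highly_local(d, 1.1 * lgs, TI1)$level -
    h_C_highly_local(d, 1.1 * lgs, TI1)
  at <- h_tilde_D_highly_local(d, lgs, TI1)$level -
    h_C_highly_local(d, lgs, TI1)
  expect_gt(below, 0)
  expect_lt(above, 0)
  expect_lt(abs(at), 1e-8)
})

test_that("ordering classifiers reproduce the moment and pmf criteria", {
  # common size n > 1: var = 0 < E[H]E[H-1] -> larger disease-induced level
  v <- ordering_just_supercritical(size_bias(hh_common(4)))
  expect_equal(v$verdict, "h_tilde_D > h_C")
  expect_equal(v$witness_index, 2L)

  # geometric: equality in both regimes
  sbg <- size_bias(geometric_size_biased(2.5, n_max = 30))
  expect_equal(ordering_just_supercritical(sbg)$verdict,
               "equality/geometric")
  expect_equal(ordering_high_global(sbg)$verdict, "equality/geometric")

  # alpha_tilde_1 = alpha_tilde_7 = 0.5: var = 9 < 12 = E[H]E[H-1]
  d17 <- hh_mixture_1n(7, 0.5)
  expect_equal(ordering_just_supercritical(size_bias(d17))$verdict,
               "h_tilde_D > h_C")

  # two-point with high variability flips the verdict
  # (size-biased weights 0.9 on size 1, 0.1 on size 20)
  sbv <- size_bias(hh_mixture_1n(20, 0.1))
  expect_gt(sbv$var, sbv$mu * (sbv$mu - 1))
  expect_equal(ordering_just_supercritical(sbv)$verdict,
               "h_tilde_D < h_C")

  # high-global regime: common size -> G^(n*)(0) = n!(1-n) < 0
  vg <- ordering_high_global(size_bias(hh_common(3)))
  expect_equal(vg$verdict, "h_tilde_D > h_C")
  expect_equal(vg$witness_index, 3L)
})

test_that("ordering verdicts agree with direct numerics near their regimes", {
  TIe <- TI1
  # just supercritical, highly locally infectious: verdict vs closed forms
  for (d in list(hh_common(3), hh_mixture_1n(7, 0.5))) {
    sb <- size_bias(d)
    v <- ordering_just_supercritical(sb)
    lg <- 1.02 / sb$mu          # R_* = 1.02
    diff <- h_tilde_D_highly_local(d, lg, TIe)$level -
      h_C_highly_local(d, lg, TIe)
    expect_equal(v$verdict,
                 if (diff > 0) "h_tilde_D > h_C" else "h_tilde_D < h_C")
  }
  # weakly locally infectious: sign of E[H-1] - var vs numerics
  d_pos <- hh_common(3)                      # var 0 < E[H-1] = 2
  d_neg <- hh_mixture_1n(7, 0.5)             # var 9 > E[H-1] = 3
  for (case in list(list(d = d_pos, sgn = 1), list(d = d_neg, sgn = -1))) {
    diff <- h_tilde_D(case$d, 1.5, 0.05, TIe)$level -
      h_C(case$d, 1.5, 0.05, TIe)$level
    expect_equal(sign(diff), case$sgn)
    expect_equal(sign(weak_local_difference(size_bias(case$d), 1.5, 0.05)),
                 case$sgn)
  }
})

test_that("weak-local expansion has the right leading term and maximiser", {
  # var(Htilde) = E[Htilde - 1] gives a vanishing leading term
  # (two-point {1, n} with (n-1)^2 p (1-p) = (n-1) p: p = 1 - 1/(n-1))
  sb_eq <- size_bias(hh_mixture_1n(4, 2 / 3))
  expect_equal(sb_eq$var, sb_eq$mu - 1, tolerance = 1e-12)
  expect_equal(weak_local_difference(sb_eq, 2, 0.1), 0, tolerance = 1e-14)

  # common size: positive coefficient
  expect_gt(weak_local_difference(size_bias(hh_common(3)), 2, 0.1), 0)
  expect_error(weak_local_difference(size_bias(hh_common(3)), 0.9, 0.1))

  # prefactor maximised at lambda_G = 1.5 (pi_0 = 2/3)
  opt <- stats::optimize(
    function(lg) weak_local_difference(size_bias(hh_common(3)), lg, 0.1),
    c(1 + 1e-9, 20), maximum = TRUE, tol = 1e-12)
  expect_equal(opt$maximum, 1.5, tolerance = 1e-6)
})

test_that("the leading term approximates the level difference to o(lambda_L^2)", {
  d <- hh_common(3)
  sb <- size_bias(d)
  lamLs <- c(0.1, 0.05, 0.025)
  rem_over_lamL2 <- vapply(lamLs, function(l) {
    diff <- h_tilde_D(d, 1.5, l, TI1)$level - h_C(d, 1.5, l, TI1)$level
    abs(diff - weak_local_difference(sb, 1.5, l)) / l^2
  }, numeric(1))
  # remainder / lambda_L^2 must itself vanish as lambda_L halves
  expect_true(all(diff(rem_over_lamL2) < 0))
  expect_lt(rem_over_lamL2[3], 0.55 * rem_over_lamL2[2])
})

test_that("gap maximiser recovers the closed-form rate and R0 = 2 when highly local", {
  for (n in c(3, 5)) {
    am <- argmax_difference_over_lambda_G(hh_common(n), Inf, TI1)
    expect_equal(am$lambda_G_hat, 4 / (1 + n), tolerance = 1e-6)
    expect_equal(am$R0, 2, tolerance = 1e-6)
    expect_gt(am$difference, 0)
  }
  expect_error(argmax_difference_over_lambda_G(hh_common(3), 0, TI1),
               "flat objective")
  # small lambda_L: maximising R0 approaches 1.5
  am_small <- argmax_difference_over_lambda_G(hh_common(3), 0.05, TI1,
                                              upper = 6)
  expect_equal(am_small$R0, 1.5, tolerance = 0.05)
})
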