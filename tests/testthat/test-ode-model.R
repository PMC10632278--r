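TI1 <- ti_exponential(1)

test_that("state space enumeration has the right size and ordering", {
  expect_equal(nrow(build_state_space(1, "SIR")), 3)
  expect_equal(nrow(build_state_space(2, "SIR")), 9)
  expect_equal(nrow(build_state_space(2, "SEIR")), 14)
  # general counts: sum_n C(n+2, 2) (SIR) and C(n+3, 3) (SEIR)
  for (nm in 3:5) {
    expect_equal(nrow(build_state_space(nm, "SIR")),
                 sum(choose((1:nm) + 2, 2)))
    expect_equal(nrow(build_state_space(nm, "SEIR")),
                 sum(choose((1:nm) + 3, 3)))
  }
  # deterministic ordering
  expect_identical(build_state_space(3, "SIR"), build_state_space(3, "SIR"))
})

test_that("initial condition seeds the largest size class and conserves mass", {
  d <- hh_dist(c(0.4, 0.3, 0.3))
  states <- build_state_space(3, "SEIR")
  h <- initial_condition(d, 1e-5, "SEIR")
  # seeded state (n_max - 1, 0, 1, 0)
  seeded <- states$s == 2 & states$e == 0 & states$i == 1 & states$r == 0
  expect_equal(h[seeded], 1e-5)
  # per-size mass conservation
  for (n in 1:3) {
    expect_equal(sum(h[states$n == n]), d$probs[n], tolerance = 1e-15)
  }
  # epsilon = 0: fully susceptible
  h0 <- initial_condition(d, 0, "SIR")
  st0 <- build_state_space(3, "SIR")
  expect_equal(sum(h0[st0$s == st0$n]), 1)
  expect_error(initial_condition(d, 0.5, "SIR"), "alpha")
})

test_that("the generator conserves per-size mass and collapses to homogeneous dynamics", {
  d <- hh_dist(c(0.4, 0.3, 0.3))
  states <- build_state_space(3, "SEIR")
  sys <- hhimmunity:::build_ode_system(states, 1.4, 0.9, 1, 0.7,
                                       kappa = 1, mu_H = d$mu)
  h <- initial_condition(d, 1e-3, "SEIR")
  ibar <- sum(states$i * h)
  dh <- as.vector(sys$A %*% h + ibar * (sys$B %*% h))
  for (n in 1:3) {
    expect_equal(sum(dh[states$n == n]), 0, tolerance = 1e-16)
  }
  # fully susceptible density: zero derivative
  h0 <- initial_condition(d, 0, "SEIR")
  dh0 <- as.vector(sys$A %*% h0 + sum(states$i * h0) * (sys$B %*% h0))
  expect_equal(max(abs(dh0)), 0)

  # all households of size 1: reduces to the homogeneous SIR equations
  st1 <- build_state_space(1, "SIR")
  sys1 <- hhimmunity:::build_ode_system(st1, 2, 0, 1, 0, 1, mu_H = 1)
  hS <- as.numeric(st1$s == 1)
  hI <- as.numeric(st1$i == 1)
  y <- 0.8 * hS + 0.15 * hI          # S = 0.8, I = 0.15
  dy <- as.vector(sys1$A %*% y + sum(st1$i * y) * (sys1$B %*% y))
  expect_equal(sum(dy * st1$s), -2 * 0.15 * 0.8, tolerance = 1e-12)
  expect_equal(sum(dy * st1$i), 2 * 0.15 * 0.8 - 1 * 0.15,
               tolerance = 1e-12)
})

test_that("residual threshold parameter interpolates R_* to zero along immunisation", {
  d <- hh_dist(c(0.4, 0.3, 0.3))
  states <- build_state_space(3, "SIR")
  h_sus <- initial_condition(d, 0, "SIR")
  expect_equal(R_V(h_sus, states, d, 1.4, 0.9, TI1),
               R_star(d, 1.4, 0.9, TI1), tolerance = 1e-12)
  # fully recovered population
  idx <- hhimmunity:::state_index(states)
  h_rec <- numeric(nrow(states))
  for (n in 1:3) h_rec[idx[[paste(0, 0, n)]]] <- d$probs[n]
  expect_equal(R_V(h_rec, states, d, 1.4, 0.9, TI1), 0)
  # highly local two-point states match the pgf-route residual parameter
  pi <- 0.7
  h_two <- numeric(nrow(states))
  for (n in 1:3) {
    h_two[idx[[paste(n, 0, 0)]]] <- d$probs[n] * pi^n
    h_two[idx[[paste(0, 0, n)]]] <- d$probs[n] * (1 - pi^n)
  }
  sb <- size_bias(d)
  expect_equal(R_V(h_two, states, d, 1.4, Inf, TI1),
               1.4 * sum((1:3) * sb$probs * pi^(1:3)), tolerance = 1e-12)
})

test_that("the integrated trajectory conserves mass and reproduces the analytic final size", {
  d <- hh_common(3)
  tr <- integrate_households(d, 2, 1, 1, epsilon = 1e-7)
  # per-size mass conserved along the trajectory
  drift <- apply(tr$h, 1, function(h) abs(sum(h) - 1))
  expect_lt(max(drift), 1e-8)
  # S and R_V non-increasing
  expect_true(all(diff(tr$S) <= 1e-10))
  expect_true(all(diff(tr$R_V) <= 1e-8))
  # final size matches the fixed point as epsilon -> 0 (SIR and SEIR)
  z <- final_size(d, 2, 1, TI1)$z
  expect_lt(abs((1 - tr$S[length(tr$S)]) - z), 1e-4)
  trL <- integrate_households(d, 2, 1, 1, delta = 1, epsilon = 1e-7)
  expect_lt(abs((1 - trL$S[length(trL$S)]) - z), 1e-4)
  # subcritical: essentially nothing happens
  tr0 <- integrate_households(d, 0.1, 1, 1, epsilon = 1e-7)
  expect_lt(1 - tr0$S[length(tr0$S)], 1e-5)
})

test_that("trajectory-based herd immunity levels match their limit identities", {
  # lambda_L ~ 0: h_D equals the homogeneous value 1 - 1/(lambda_G E)
  expect_equal(h_D(hh_common(2), 2, 1e-8, 1)$level, 0.5,
               tolerance = 1e-3)
  # h_D is below the epidemic's final size
  d <- hh_common(3)
  res <- h_D(d, 2, 1, 1)
  tr <- integrate_households(d, 2, 1, 1)
  expect_lt(res$level, 1 - tr$S[length(tr$S)])
  expect_equal(res$residual_R, 1, tolerance = 1e-6)
  # epsilon-robustness: 1e-5 vs 1e-6 changes the level by < 1e-3
  expect_lt(abs(h_D(d, 2, 1, 1, epsilon = 1e-6)$level - res$level), 1e-3)
  # subcritical: flagged
  expect_true(h_D(d, 0.1, 1, 1)$already_immune)
})

test_that("latency shifts the trajectory level and vanishes in the fast-latency limit", {
  d <- hh_common(2)
  hd <- h_D(d, 3.109, 2.547, 1)$level
  # delta -> Inf recovers the SIR level
  expect_equal(h_D_L(d, 3.109, 2.547, 1, 1000)$level, hd,
               tolerance = 1e-3)
  # strong local infection: latency lowers the disease-induced level
  lamL_hi <- lambda_L_from_p_L(0.95, TI1)
  lg <- lambda_G_for_R0(d, lamL_hi, TI1, 2)
  expect_gt(h_D(d, lg, lamL_hi, 1)$level,
            h_D_L(d, lg, lamL_hi, 1, 1)$level)
})

test_that("restricted first epidemics interpolate between the two disease-induced levels", {
  d <- hh_common(3)
  lg <- 2; lamL <- 1
  hd <- h_D(d, lg, lamL, 1)$level
  htd <- h_tilde_D(d, lg, lamL, TI1)
  kap_hat <- htd$kappa_hat
  # kappa = 1 is the unrestricted level
  expect_equal(h_hat_D(d, lg, lamL, 1, kappa = 1)$level, hd,
               tolerance = 1e-10)
  # decreasing in kappa, approaching the final-size approximation near
  # the critical restriction
  kaps <- c(kap_hat * 1.01, 0.75, 0.9, 1)
  levels <- vapply(kaps, function(k) {
    h_hat_D(d, lg, lamL, 1, kappa = k)$level
  }, numeric(1))
  expect_true(all(diff(levels) < 0))
  expect_equal(levels[1], htd$level, tolerance = 5e-3)
  # kappa at or below kappa_hat: the crossing never happens
  expect_error(h_hat_D(d, lg, lamL, 1, kappa = kap_hat * 0.9),
               "kappa")
})

test_that("susceptible profiles at herd immunity show the expected clumping", {
  # p_L = 0, common n = 4, R0 = 2: Bin(4, 1/2) susceptibles per household
  d <- hh_common(4)
  lg <- lambda_G_for_R0(d, 0, TI1, 2)
  expect_equal(lg, 2, tolerance = 1e-9)
  tr <- integrate_households(d, lg, 0, 1)
  prof <- susceptible_household_profile(tr$h_at_T_star, tr$states,
                                        size = 4)
  expect_equal(sum(prof), 1, tolerance = 1e-10)
  expect_equal(unname(prof), stats::dbinom(0:4, 4, 0.5),
               tolerance = 5e-3)
  # the final-size construction at the same point has more mass at the
  # extremes 0 and n (clumping)
  htd <- h_tilde_D(d, lg, 1, TI1)
  P <- final_size(d, lg, 1, TI1, kappa = htd$kappa_hat)$outcome[[4]]
  prof_traj <- susceptible_household_profile(
    integrate_households(d, lg, 1, 1)$h_at_T_star,
    build_state_space(4, "SIR"), size = 4)
  # P is over infected v; susceptibles = 4 - v
  prof_fs <- rev(P)
  expect_gt(prof_fs[1] + prof_fs[5], prof_traj[[1]] + prof_traj[[5]])
})
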