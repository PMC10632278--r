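#' Household state space of the deterministic limit
#'
#' Enumerates the household configurations \eqn{(s, e, i, r)} with
#' \eqn{1 \le s + e + i + r \le n_{max}} (the SIR model uses the
#' \eqn{e \equiv 0} slice, recorded as \eqn{(s, i, r)}). The ordering is
#' deterministic: by household size, then lexicographically in
#' \eqn{(s, e, i)}.
#'
#' @param n_max largest household size.
#' @param model \code{"SIR"} or \code{"SEIR"}.
#' @return A data frame with one row per state: columns \code{s},
#'   (\code{e},) \code{i}, \code{r} and \code{n} (household size).
#' @export
build_state_space <- function(n_max, model = c("SIR", "SEIR")) {
  model <- match.arg(model)
  stopifnot(n_max >= 1, n_max == round(n_max))
  if (model == "SIR") {
    st <- expand.grid(r = 0:n_max, i = 0:n_max, s = 0:n_max)
    st <- st[, c("s", "i", "r")]
    st$n <- st$s + st$i + st$r
  } else {
    st <- expand.grid(r = 0:n_max, i = 0:n_max, e = 0:n_max, s = 0:n_max)
    st <- st[, c("s", "e", "i", "r")]
    st$n <- st$s + st$e + st$i + st$r
  }
  st <- st[st$n >= 1 & st$n <= n_max, , drop = FALSE]
  ord <- if (model == "SIR") {
    order(st$n, st$s, st$i, st$r)
  } else {
    order(st$n, st$s, st$e, st$i, st$r)
  }
  st <- st[ord, , drop = FALSE]
  rownames(st) <- NULL
  st
}

# index lookup table: key string -> row index
state_index <- function(states) {
  keys <- if ("e" %in% names(states)) {
    paste(states$s, states$e, states$i, states$r)
  } else {
    paste(states$s, states$i, states$r)
  }
  stats::setNames(seq_len(nrow(states)), keys)
}

#' Initial household state density
#'
#' A fraction \code{epsilon} of all households — taken from the largest
#' size class — starts with one infectious member and the rest susceptible
#' (state \eqn{(n_{max} - 1, 0, 1, 0)}); every other household is fully
#' susceptible. Mass within each size class is conserved.
#'
#' @param dist a \code{hh_dist}.
#' @param epsilon seeded fraction of households, \eqn{0 \le \epsilon <
#'   \alpha_{n_{max}}}.
#' @param model \code{"SIR"} or \code{"SEIR"}.
#' @return Numeric density vector over [build_state_space()] rows.
#' @export
initial_condition <- function(dist, epsilon, model = c("SIR", "SEIR")) {
  model <- match.arg(model)
  dist <- as_hh_dist(dist)
  if (epsilon < 0 || epsilon >= dist$probs[dist$n_max]) {
    stop("epsilon must lie in [0, alpha_{n_max})")
  }
  states <- build_state_space(dist$n_max, model)
  idx <- state_index(states)
  h <- numeric(nrow(states))
  for (n in seq_len(dist$n_max)) {
    if (dist$probs[n] == 0) next
    key <- if (model == "SIR") paste(n, 0, 0) else paste(n, 0, 0, 0)
    h[idx[[key]]] <- dist$probs[n]
  }
  if (epsilon > 0) {
    n <- dist$n_max
    seed_key <- if (model == "SIR") paste(n - 1, 1, 0) else paste(n - 1, 0, 1, 0)
    full_key <- if (model == "SIR") paste(n, 0, 0) else paste(n, 0, 0, 0)
    h[idx[[seed_key]]] <- epsilon
    h[idx[[full_key]]] <- h[idx[[full_key]]] - epsilon
  }
  h
}

# Assemble the linear structure of the deterministic limit:
#   dh/dt = A h + ibar(t) * (B h),    ibar = sum(i * h)
# A carries latency, recovery and local infection; B carries global
# infection. Densities are per household, so the per-susceptible global
# force is kappa * lambda_G * (m ibar) / N = kappa * lambda_G * ibar / mu_H.
build_ode_system <- function(states, lambda_G, lambda_L, gamma, delta,
                             kappa = 1, mu_H = 1) {
  K <- nrow(states)
  seir <- "e" %in% names(states)
  idx <- state_index(states)
  key_of <- function(s, e, i, r) {
    if (seir) paste(s, e, i, r) else paste(s, i, r)
  }
  A <- matrix(0, K, K)
  B <- matrix(0, K, K)
  add <- function(M, from, to, rate) {
    M[from, from] <- M[from, from] - rate
    M[to, from] <- M[to, from] + rate
    M
  }
  for (j in seq_len(K)) {
    s <- states$s[j]
    e <- if (seir) states$e[j] else 0
    i <- states$i[j]
    r <- states$r[j]
    if (seir && e > 0) {                       # latency progression
      A <- add(A, j, idx[[key_of(s, e - 1, i + 1, r)]], delta * e)
    }
    if (i > 0) {                               # recovery
      A <- add(A, j, idx[[key_of(s, e, i - 1, r + 1)]], gamma * i)
    }
    if (s > 0) {
      to <- if (seir) idx[[paste(s - 1, e + 1, i, r)]]
            else idx[[paste(s - 1, i + 1, r)]]
      if (i > 0 && is.finite(lambda_L)) {      # local infection
        A <- add(A, j, to, lambda_L * s * i)
      }
      # global infection at force kappa * lambda_G * ibar / mu_H
      B <- add(B, j, to, kappa * lambda_G * s / mu_H)
    }
  }
  list(A = A, B = B, ivec = states$i, svec = states$s,
       nvec = states$n, K = K)
}

#' Integrate the deterministic household epidemic
#'
#' Integrates the ODE limit of the household SIR/SEIR process from the
#' \code{epsilon}-seeded initial condition, with the global rate scaled by
#' \code{kappa}, until the exposed-plus-infective mass falls below
#' \code{1e-12} or the horizon is reached. Records the susceptible
#' fraction \eqn{S(t)}, the infective density \eqn{\bar i(t)} and the
#' residual threshold parameter \eqn{R_V(t)} (always at the unreduced
#' global rate).
#'
#' @param dist a \code{hh_dist}.
#' @param lambda_G global rate; \code{lambda_L} finite local rate;
#'   \code{gamma} recovery rate; \code{delta} latency rate or \code{NULL}
#'   for SIR.
#' @param lambda_L,gamma,delta epidemic rates (see above).
#' @param epsilon initially seeded fraction of households.
#' @param kappa restriction factor on the global rate, in \eqn{(0, 1]}.
#' @param times output time grid (default: 400 points to the stopping
#'   time, found adaptively).
#' @param horizon latest time considered.
#' @return Object of class \code{hh_trajectory}: list with \code{times},
#'   \code{states} (data frame), \code{h} (densities, one row per time),
#'   \code{S}, \code{ibar}, \code{R_V}, \code{T_star} (first time
#'   \eqn{R_V \le 1}, or \code{NA}) and \code{h_at_T_star}.
#' @export
integrate_households <- function(dist, lambda_G, lambda_L, gamma,
                                 delta = NULL, epsilon = 1e-5, kappa = 1,
                                 times = NULL, horizon = 1e4) {
  dist <- as_hh_dist(dist)
  stopifnot(is.finite(lambda_L), lambda_L >= 0, gamma > 0,
            is.null(delta) || delta > 0, kappa > 0, kappa <= 1)
  model <- if (is.null(delta)) "SIR" else "SEIR"
  states <- build_state_space(dist$n_max, model)
  sys <- build_ode_system(states, lambda_G, lambda_L, gamma,
                          if (is.null(delta)) 0 else delta, kappa,
                          mu_H = dist$mu)
  h0 <- initial_condition(dist, epsilon, model)
  T_I <- ti_exponential(gamma)
  mu_by_s <- single_household_mean_size(0:dist$n_max, lambda_L, T_I)
  mu_H <- dist$mu
  eimass <- if (model == "SEIR") states$e + states$i else states$i

  rv <- function(h) {
    lambda_G * T_I$mean * sum(h * sys$svec * mu_by_s[sys$svec + 1]) / mu_H
  }
  deriv <- function(t, h, parms) {
    ibar <- sum(sys$ivec * h)
    list(as.vector(sys$A %*% h + ibar * (sys$B %*% h)))
  }
  roots <- function(t, h, parms) {
    c(rv(h) - 1, sum(eimass * h) - 1e-12)
  }

  # root-stopping pass: find T_star and the extinction time
  out <- deSolve::lsodar(
    y = h0, times = c(0, horizon), func = deriv,
    rootfunc = roots, rtol = 1e-10, atol = 1e-12)
  t_stop <- out[nrow(out), 1]
  h_stop <- out[nrow(out), -1]
  # which root fired? a genuine herd-immunity time has R_V = 1 there;
  # the extinction root leaves R_V strictly away from 1
  T_star <- if (abs(rv(h_stop) - 1) < 1e-6) t_stop else NA_real_
  h_at_T_star <- if (!is.na(T_star)) h_stop else NULL

  if (!is.na(T_star)) {
    # continue to extinction for the full trajectory span
    out2 <- deSolve::lsodar(
      y = h_stop, times = c(t_stop, horizon), func = deriv,
      rootfunc = function(t, h, p) sum(eimass * h) - 1e-12,
      rtol = 1e-10, atol = 1e-12)
    t_end <- out2[nrow(out2), 1]
  } else {
    t_end <- t_stop
  }

  if (is.null(times)) times <- seq(0, t_end, length.out = 400L)
  traj <- deSolve::lsoda(y = h0, times = times, func = deriv,
                         rtol = 1e-10, atol = 1e-12)
  H <- traj[, -1, drop = FALSE]
  S <- as.vector(H %*% sys$svec) / mu_H
  ibar <- as.vector(H %*% sys$ivec)
  R_V <- apply(H, 1, rv)

  structure(
    list(times = times, states = states, h = H, S = S, ibar = ibar,
         R_V = R_V, T_star = T_star, h_at_T_star = h_at_T_star,
         model = model, kappa = kappa, dist = dist,
         lambda_G = lambda_G, lambda_L = lambda_L,
         gamma = gamma, delta = delta),
    class = "hh_trajectory"
  )
}

#' @export
print.hh_trajectory <- function(x, ...) {
  cat(sprintf(
    "Deterministic household %s trajectory (kappa = %.4g): %d states, t in [0, %.4g]\n",
    x$model, x$kappa, nrow(x$states), max(x$times)))
  if (!is.na(x$T_star)) {
    cat(sprintf("  R_V crosses 1 at T* = %.6g\n", x$T_star))
  }
  cat(sprintf("  final susceptible fraction %.6g\n", x$S[length(x$S)]))
  invisible(x)
}

#' Residual threshold parameter of a household state density
#'
#' The threshold parameter \eqn{R_V} of a new epidemic started in a
#' population frozen in household state density \code{h}: exposed,
#' infective and recovered members count as non-susceptible, and a global
#' contact landing on a susceptible in a household with \eqn{s}
#' susceptibles triggers a local epidemic of mean size
#' \eqn{\mu_s(\lambda_L)}, so
#' \deqn{R_V = \frac{\lambda_G E[T_I]}{\mu_H} \sum_{(s,e,i,r)}
#'   h_{s,e,i,r}\; s\; \mu_s(\lambda_L).}
#'
#' @param h density vector over the rows of \code{states}.
#' @param states state space from [build_state_space()].
#' @param dist the household size distribution.
#' @param lambda_G unreduced global rate.
#' @param lambda_L local rate.
#' @param T_I infectious period law.
#' @export
R_V <- function(h, states, dist, lambda_G, lambda_L, T_I) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  mu_by_s <- single_household_mean_size(0:dist$n_max, lambda_L, T_I)
  lambda_G * T_I$mean * sum(h * states$s * mu_by_s[states$s + 1]) / dist$mu
}

h_from_trajectory <- function(dist, lambda_G, lambda_L, gamma, delta,
                              epsilon, kappa, kind) {
  traj <- integrate_households(dist, lambda_G, lambda_L, gamma, delta,
                               epsilon = epsilon, kappa = kappa)
  if (is.na(traj$T_star)) {
    stop(paste(
      "residual threshold parameter never reached 1 before extinction;",
      if (kappa < 1) "kappa is at or below the critical restriction kappa_hat"
      else "the epidemic is too weak for disease-induced herd immunity"))
  }
  mu_H <- traj$dist$mu
  S_star <- sum(traj$h_at_T_star * traj$states$s) / mu_H
  new_herd_immunity_result(
    1 - S_star, kind,
    T_star = traj$T_star, kappa = kappa,
    residual_R = R_V(traj$h_at_T_star, traj$states, dist, lambda_G,
                     lambda_L, ti_exponential(gamma)),
    S_at_T_star = S_star)
}

#' Disease-induced herd immunity level along the SIR trajectory
#'
#' Integrates the deterministic household SIR system (no restrictions,
#' \eqn{\kappa = 1}), locates the first time \eqn{T_*} at which the
#' residual threshold parameter \eqn{R_V(t)} reaches one, and returns
#' \eqn{h_D = 1 - S(T_*)}, the fraction no longer susceptible.
#'
#' @inheritParams integrate_households
#' @export
h_D <- function(dist, lambda_G, lambda_L, gamma, epsilon = 1e-5) {
  dist <- as_hh_dist(dist)
  Rs <- R_star(dist, lambda_G, lambda_L, ti_exponential(gamma))
  if (Rs <= 1) {
    return(new_herd_immunity_result(0, "h_D", R_star = Rs,
                                    already_immune = TRUE))
  }
  h_from_trajectory(dist, lambda_G, lambda_L, gamma, NULL, epsilon, 1,
                    "h_D")
}

#' Disease-induced herd immunity level with a latent period (SEIR)
#'
#' As [h_D()] but for the SEIR system with latency rate \code{delta}.
#'
#' @inheritParams integrate_households
#' @export
h_D_L <- function(dist, lambda_G, lambda_L, gamma, delta, epsilon = 1e-5) {
  dist <- as_hh_dist(dist)
  Rs <- R_star(dist, lambda_G, lambda_L, ti_exponential(gamma))
  if (Rs <= 1) {
    return(new_herd_immunity_result(0, "h_D_L", R_star = Rs,
                                    already_immune = TRUE))
  }
  h_from_trajectory(dist, lambda_G, lambda_L, gamma, delta, epsilon, 1,
                    "h_D_L")
}

#' Disease-induced herd immunity level under global restrictions
#'
#' The first epidemic runs with global rate \eqn{\kappa \lambda_G}
#' (\eqn{\kappa \in (\hat\kappa, 1]}); \eqn{T_*} is located from the
#' residual threshold parameter computed at the unreduced \eqn{\lambda_G},
#' and \eqn{\hat h_D = 1 - S(T_*)}. For \eqn{\kappa \le \hat\kappa} the
#' second epidemic stays supercritical throughout the first and an error
#' is signalled.
#'
#' @inheritParams integrate_households
#' @export
h_hat_D <- function(dist, lambda_G, lambda_L, gamma, delta = NULL,
                    kappa, epsilon = 1e-5) {
  dist <- as_hh_dist(dist)
  Rs <- R_star(dist, lambda_G, lambda_L, ti_exponential(gamma))
  if (Rs <= 1) {
    return(new_herd_immunity_result(0, "h_hat_D", R_star = Rs,
                                    already_immune = TRUE))
  }
  h_from_trajectory(dist, lambda_G, lambda_L, gamma, delta, epsilon,
                    kappa, "h_hat_D")
}

#' Distribution of susceptibles per household in a state density
#'
#' Marginal distribution of the number of susceptible members of a
#' household drawn from the density \code{h} (optionally conditioned on
#' household size). Used to compare the clumping of susceptibles when herd
#' immunity is reached along the trajectory versus under the final-size
#' approximation.
#'
#' @inheritParams R_V
#' @param size optional household size to condition on.
#' @return Named numeric vector: probabilities over s = 0, 1, ....
#' @export
susceptible_household_profile <- function(h, states, size = NULL) {
  keep <- if (is.null(size)) rep(TRUE, nrow(states)) else states$n == size
  w <- h[keep]
  s <- states$s[keep]
  tot <- sum(w)
  if (tot <= 0) stop("no household mass in the requested stratum")
  smax <- max(states$n)
  p <- vapply(0:smax, function(v) sum(w[s == v]) / tot, numeric(1))
  stats::setNames(p, 0:smax)
}
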