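#' Early exponential growth rate of the household epidemic
#'
#' For Markovian laws (\eqn{T_I \sim Exp(\gamma)}, optionally
#' \eqn{T_E \sim Exp(\delta)}), the early phase of the epidemic is a
#' branching process of single-household epidemics linked by global
#' contacts. Its Malthusian parameter \eqn{r} solves the household
#' Lotka-Euler equation
#' \deqn{\lambda_G \sum_n \tilde\alpha_n \int_0^\infty e^{-rt}
#'   E[I_n(t)]\, dt = 1,}
#' where \eqn{E[I_n(t)]} is the expected number of infectives at time
#' \eqn{t} in a size-\eqn{n} single-household epidemic started by one newly
#' (globally) infected member. The Laplace transform is obtained by a
#' linear solve against the within-household Markov generator. \eqn{r > 0}
#' iff \eqn{R_* > 1}.
#'
#' @param dist a \code{hh_dist}.
#' @param lambda_G global contact rate.
#' @param lambda_L finite local contact rate.
#' @param gamma recovery rate (so \eqn{T_I \sim Exp(\gamma)}).
#' @param delta latency rate \eqn{\delta}, or \code{NULL} for the SIR model
#'   (no latent period).
#' @return The growth rate \code{r} (negative when subcritical).
#' @export
growth_rate <- function(dist, lambda_G, lambda_L, gamma, delta = NULL) {
  dist <- as_hh_dist(dist)
  stopifnot(lambda_G > 0, gamma > 0, is.null(delta) || delta > 0)
  if (is.infinite(lambda_L)) {
    stop("growth_rate requires a finite local rate (Markovian dynamics)")
  }
  L <- household_infective_transform(dist, lambda_L, gamma, delta)
  f <- function(r) lambda_G * L(r) - 1
  # decreasing in r; F(0) = R_* - 1
  r_floor <- -0.999 * min(gamma, if (is.null(delta)) Inf else delta)
  if (f(0) > 0) {
    hi <- 1
    while (f(hi) > 0) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  } else {
    lo <- r_floor / 2
    while (f(lo) < 0 && lo > r_floor * 0.9999) {
      lo <- (lo + r_floor) / 2
    }
    if (f(lo) < 0) return(lo)   # decay-rate bound reached
    stats::uniroot(f, c(lo, 0), tol = 1e-12)$root
  }
}

# Laplace transform of the expected infectives in a single household,
# averaged over the size-biased household size:
#   L(r) = sum_n alpha_tilde_n  integral e^{-rt} E[I_n(t)] dt,
# computed as i' (rI - Q')^{-1} p0 on the within-household transient states.
# Independent of lambda_G. Returns a function of r.
household_infective_transform <- function(dist, lambda_L, gamma, delta) {
  sb <- size_bias(dist)
  per_n <- lapply(seq_len(dist$n_max), function(n) {
    if (sb$probs[n] == 0) return(NULL)
    if (is.null(delta)) {
      st <- expand.grid(s = 0:n, i = 0:n)
      st <- st[st$s + st$i <= n & st$i > 0, , drop = FALSE]
      key <- function(s, i) paste(s, i)
      idx <- stats::setNames(seq_len(nrow(st)), key(st$s, st$i))
      K <- nrow(st)
      Q <- matrix(0, K, K)
      for (j in seq_len(K)) {
        s <- st$s[j]; i <- st$i[j]
        out <- 0
        # recovery i -> i-1 (leaves transient space when i = 1)
        rr <- gamma * i
        out <- out + rr
        if (i > 1) Q[j, idx[[key(s, i - 1)]]] <- Q[j, idx[[key(s, i - 1)]]] + rr
        # local infection s -> s-1, i -> i+1
        if (s > 0) {
          rl <- lambda_L * s * i
          out <- out + rl
          Q[j, idx[[key(s - 1, i + 1)]]] <- Q[j, idx[[key(s - 1, i + 1)]]] + rl
        }
        Q[j, j] <- Q[j, j] - out
      }
      p0 <- numeric(K); p0[idx[[key(n - 1, 1)]]] <- 1
      list(Q = Q, p0 = p0, ivec = st$i)
    } else {
      st <- expand.grid(s = 0:n, e = 0:n, i = 0:n)
      st <- st[st$s + st$e + st$i <= n & st$e + st$i > 0, , drop = FALSE]
      key <- function(s, e, i) paste(s, e, i)
      idx <- stats::setNames(seq_len(nrow(st)), key(st$s, st$e, st$i))
      K <- nrow(st)
      Q <- matrix(0, K, K)
      for (j in seq_len(K)) {
        s <- st$s[j]; e <- st$e[j]; i <- st$i[j]
        out <- 0
        if (e > 0) {                     # latency e -> e-1, i -> i+1
          rl <- delta * e
          out <- out + rl
          Q[j, idx[[key(s, e - 1, i + 1)]]] <-
            Q[j, idx[[key(s, e - 1, i + 1)]]] + rl
        }
        if (i > 0) {                     # recovery
          rr <- gamma * i
          out <- out + rr
          if (e + i > 1) {
            Q[j, idx[[key(s, e, i - 1)]]] <-
              Q[j, idx[[key(s, e, i - 1)]]] + rr
          }
        }
        if (s > 0 && i > 0) {            # local infection s -> s-1, e -> e+1
          rl <- lambda_L * s * i
          out <- out + rl
          Q[j, idx[[key(s - 1, e + 1, i)]]] <-
            Q[j, idx[[key(s - 1, e + 1, i)]]] + rl
        }
        Q[j, j] <- Q[j, j] - out
      }
      p0 <- numeric(K); p0[idx[[key(n - 1, 1, 0)]]] <- 1
      list(Q = Q, p0 = p0, ivec = st$i)
    }
  })
  function(r) {
    tot <- 0
    for (n in seq_len(dist$n_max)) {
      sys <- per_n[[n]]
      if (is.null(sys)) next
      x <- solve(r * diag(nrow(sys$Q)) - t(sys$Q), sys$p0)
      tot <- tot + sb$probs[n] * sum(sys$ivec * x)
    }
    tot
  }
}

#' Growth rate implied by a next-generation-matrix R0 in a Markov SEIR model
#'
#' For homogeneously mixing (and, more generally, multitype) Markov SEIR
#' models with latency rate \eqn{\delta} and recovery rate \eqn{\gamma},
#' the basic reproduction number and the exponential growth rate are linked
#' by
#' \deqn{R_0 = (1 + r/\delta)(1 + r/\gamma).}
#' This returns the root \eqn{r > -\min(\gamma, \delta)} of the quadratic;
#' it is positive iff \code{R0BBT > 1}.
#'
#' @param R0BBT reference reproduction number (> 0).
#' @param gamma recovery rate.
#' @param delta latency rate.
#' @export
r_from_R0BBT <- function(R0BBT, gamma, delta) {
  stopifnot(R0BBT > 0, gamma > 0, delta > 0)
  (-(gamma + delta) + sqrt((gamma - delta)^2 + 4 * gamma * delta * R0BBT)) / 2
}

#' Calibrate the global rate to a target growth rate
#'
#' Chooses \eqn{\lambda_G} so that the early exponential growth rate of the
#' household SEIR (or SIR when \code{delta} is \code{NULL}) model equals
#' \code{r_target}. Since the within-household dynamics do not involve
#' \eqn{\lambda_G}, the Lotka-Euler equation gives it in closed form:
#' \eqn{\lambda_G = 1 / \sum_n \tilde\alpha_n L_n(r)}.
#'
#' @inheritParams growth_rate
#' @param r_target desired growth rate (> 0).
#' @export
calibrate_lambda_G <- function(dist, lambda_L, gamma, delta = NULL,
                               r_target) {
  dist <- as_hh_dist(dist)
  stopifnot(r_target > 0, gamma > 0, is.null(delta) || delta > 0)
  if (is.infinite(lambda_L)) {
    stop("calibrate_lambda_G requires a finite local rate")
  }
  L <- household_infective_transform(dist, lambda_L, gamma, delta)
  1 / L(r_target)
}
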