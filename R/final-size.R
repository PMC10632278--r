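#' Escape-probability coefficients for single-household final-size algebra
#'
#' Computes the coefficients \eqn{\beta_1, \dots, \beta_{k_{max}}} defined
#' recursively by
#' \deqn{\sum_{i=1}^{k} \binom{k}{i} \beta_i(\lambda_L)
#'   \phi(i \lambda_L)^{k-i} = k, \qquad k = 1, 2, \dots,}
#' where \eqn{\phi} is the Laplace transform of the infectious period. The
#' system is unit-triangular in \eqn{\beta_k} and is solved by forward
#' substitution. These coefficients underlie the mean final size of a
#' within-household epidemic.
#'
#' @param lambda_L local (within-household) infection rate; may be \code{0}
#'   or \code{Inf}.
#' @param T_I infectious period law (a \code{ti_law}).
#' @param k_max number of coefficients required.
#' @return Numeric vector \code{beta[1:k_max]}.
#' @export
beta_coefficients <- function(lambda_L, T_I, k_max) {
  stopifnot(k_max >= 1, k_max == round(k_max), lambda_L >= 0)
  T_I <- as_ti_law(T_I)
  phi <- T_I$phi(seq_len(k_max) * lambda_L)
  beta <- numeric(k_max)
  for (k in seq_len(k_max)) {
    i <- seq_len(k - 1)
    acc <- if (k > 1) sum(choose(k, i) * beta[i] * phi[i]^(k - i)) else 0
    beta[k] <- k - acc
  }
  beta
}

#' Mean final size of a single-household epidemic
#'
#' Mean number ultimately infected (including the initial case) in a
#' household of size \code{n} with one initial infective and local rate
#' \eqn{\lambda_L}:
#' \deqn{\mu_n(\lambda_L) = n - \sum_{k=1}^{n-1} \binom{n-1}{k}
#'   \beta_k(\lambda_L) \phi(k\lambda_L)^{n-k}.}
#' By convention \eqn{\mu_0 = 0}. Satisfies \eqn{1 \le \mu_n \le n}, with
#' \eqn{\mu_n = 1} when \eqn{\lambda_L = 0} and \eqn{\mu_n = n} when
#' \eqn{\lambda_L = \infty}.
#'
#' @param n household size(s); vectorised, \code{n = 0} allowed.
#' @inheritParams beta_coefficients
#' @export
single_household_mean_size <- function(n, lambda_L, T_I) {
  stopifnot(all(n >= 0), all(n == round(n)), lambda_L >= 0)
  T_I <- as_ti_law(T_I)
  n_top <- max(n)
  if (n_top == 0) return(rep(0, length(n)))
  if (is.infinite(lambda_L)) return(as.numeric(n))
  beta <- beta_coefficients(lambda_L, T_I, n_top)
  phi <- T_I$phi(seq_len(n_top) * lambda_L)
  vapply(n, function(nn) {
    if (nn == 0) return(0)
    if (nn == 1) return(1)
    k <- seq_len(nn - 1)
    nn - sum(choose(nn - 1, k) * beta[k] * phi[k]^(nn - k))
  }, numeric(1))
}

#' Mean final size with binomially many global introductions
#'
#' Mean number ultimately infected in a household of size \code{n} in which
#' each member independently avoids global infection with probability
#' \eqn{\pi} (so there are \eqn{Bin(n, 1-\pi)} initial infectives):
#' \deqn{\tilde\mu_n(\lambda_L, \pi) = n - \sum_{k=1}^{n} \binom{n}{k}
#'   \phi(k\lambda_L)^{n-k} \pi^k \beta_k(\lambda_L).}
#' Boundary values: \eqn{\tilde\mu_n(\cdot, 1) = 0} and
#' \eqn{\tilde\mu_n(\cdot, 0) = n}.
#'
#' @inheritParams single_household_mean_size
#' @param pi probability of avoiding global infection, in \eqn{[0, 1]}.
#' @export
mixed_initial_mean_size <- function(n, lambda_L, T_I, pi) {
  stopifnot(all(n >= 0), all(n == round(n)), lambda_L >= 0,
            pi >= 0, pi <= 1)
  T_I <- as_ti_law(T_I)
  n_top <- max(n)
  if (n_top == 0) return(rep(0, length(n)))
  if (is.infinite(lambda_L)) return(n * (1 - pi^n))
  beta <- beta_coefficients(lambda_L, T_I, n_top)
  phi <- T_I$phi(seq_len(n_top) * lambda_L)
  vapply(n, function(nn) {
    if (nn == 0) return(0)
    k <- seq_len(nn)
    nn - sum(choose(nn, k) * phi[k]^(nn - k) * pi^k * beta[k])
  }, numeric(1))
}

#' Final-outcome distribution of a household exposed to a major outbreak
#'
#' Solves the triangular system, for \eqn{v = 0, 1, \dots, n},
#' \deqn{\sum_{i=0}^{v} \binom{n-i}{v-i}
#'   \frac{P_{n,i}}{\phi((n-v)\lambda_L)^i\, \pi^{n-v}} = \binom{n}{v}}
#' for the proportions \eqn{P_{n,v}} of households of size \eqn{n} with
#' \eqn{v} members ultimately infected, when each member independently
#' avoids global infection with probability \eqn{\pi}. Entries are clipped
#' to \eqn{[0, 1]} within a negativity tolerance of \code{1e-9}; the vector
#' sums to one and has mean \eqn{\tilde\mu_n(\lambda_L, \pi)}.
#'
#' In the highly locally infectious case (\eqn{\lambda_L = \infty}) the
#' outcome is two-point: \eqn{P_{n,0} = \pi^n}, \eqn{P_{n,n} = 1 - \pi^n}.
#'
#' @inheritParams mixed_initial_mean_size
#' @param n single household size.
#' @return Numeric vector of length \code{n + 1}, entries
#'   \eqn{P_{n,0}, \dots, P_{n,n}}.
#' @export
household_outcome_distribution <- function(n, lambda_L, T_I, pi) {
  stopifnot(n >= 1, n == round(n), lambda_L >= 0, pi >= 0, pi <= 1)
  T_I <- as_ti_law(T_I)
  if (pi == 0) {                      # everyone infected globally
    P <- numeric(n + 1); P[n + 1] <- 1
    return(P)
  }
  if (is.infinite(lambda_L)) {
    P <- numeric(n + 1)
    P[1] <- pi^n
    P[n + 1] <- 1 - pi^n
    return(P)
  }
  phi <- T_I$phi((0:n) * lambda_L)    # phi[j+1] = phi(j * lambda_L)
  P <- numeric(n + 1)
  for (v in 0:n) {
    ph <- phi[n - v + 1]              # phi((n - v) lambda_L); phi(0) = 1
    i <- seq_len(v) - 1               # 0 .. v-1
    acc <- if (v > 0) {
      sum(choose(n - i, v - i) * P[i + 1] / (ph^i * pi^(n - v)))
    } else 0
    P[v + 1] <- (choose(n, v) - acc) * ph^v * pi^(n - v)
  }
  if (any(P < -1e-9)) {
    stop(sprintf(
      "household outcome distribution ill-conditioned (n = %d): entry %.3g",
      n, min(P)))
  }
  P <- pmin(pmax(P, 0), 1)
  P / sum(P)
}

#' Population final size of the household epidemic
#'
#' Solves the final-size fixed point
#' \deqn{z = \sum_n \tilde\alpha_n\, \tilde\mu_n(\lambda_L, \pi(z)) / n,
#'   \qquad \pi(z) = \exp(-\kappa \lambda_G E[T_I] z),}
#' returning the largest root \eqn{z \in [0, 1)}; \eqn{z > 0} iff the
#' (effective) household threshold parameter exceeds one. The factor
#' \code{kappa} scales the global rate only, as when restrictions act on
#' between-household mixing.
#'
#' @param dist a \code{hh_dist} (or probability vector).
#' @param lambda_G global contact rate.
#' @param lambda_L local contact rate (may be \code{0} or \code{Inf}).
#' @param T_I infectious period law.
#' @param kappa multiplier on the global rate in \eqn{(0, 1]}.
#'
#' @return An object of class \code{final_size_solution}: list with the
#'   infected fraction \code{z}, the global escape probability \code{pi},
#'   per-size outcome distributions \code{outcome} (list indexed by size),
#'   \code{kappa} and the effective threshold parameter \code{R_star_eff}.
#' @export
final_size <- function(dist, lambda_G, lambda_L, T_I, kappa = 1) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  stopifnot(lambda_G >= 0, lambda_L >= 0, kappa > 0, kappa <= 1)
  sb <- size_bias(dist)
  n <- seq_len(dist$n_max)
  rate <- kappa * lambda_G * T_I$mean
  R_eff <- R_star(dist, kappa * lambda_G, lambda_L, T_I)

  g <- function(z) {
    z - sum(sb$probs * mixed_initial_mean_size(n, lambda_L, T_I,
                                               exp(-rate * z)) / n)
  }
  if (R_eff <= 1) {
    z <- 0
  } else {
    lo <- 1e-12
    if (g(lo) >= 0) {
      z <- 0
    } else {
      z <- stats::uniroot(g, c(lo, 1), tol = 1e-14)$root
    }
  }
  pi <- exp(-rate * z)
  outcome <- lapply(n, function(nn) {
    if (dist$probs[nn] > 0) {
      household_outcome_distribution(nn, lambda_L, T_I, pi)
    } else NULL
  })
  structure(
    list(z = z, pi = pi, outcome = outcome, kappa = kappa,
         R_star_eff = R_eff),
    class = "final_size_solution"
  )
}

#' @export
print.final_size_solution <- function(x, ...) {
  cat(sprintf(
    "Household epidemic final size: z = %.6g (pi = %.6g, kappa = %.4g, effective R* = %.4g)\n",
    x$z, x$pi, x$kappa, x$R_star_eff))
  invisible(x)
}
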