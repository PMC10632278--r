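#' Household threshold parameter R*
#'
#' The mean number of global contacts emanating from a typical newly
#' infected household,
#' \deqn{R_* = \sum_n \tilde\alpha_n\, \mu_n(\lambda_L)\,
#'   \lambda_G E[T_I].}
#' A major outbreak is possible iff \eqn{R_* > 1}. In the highly locally
#' infectious case this reduces to
#' \eqn{R_* = \lambda_G E[T_I] \mu_{\tilde H}}.
#'
#' @param dist a \code{hh_dist} (or probability vector).
#' @param lambda_G global contact rate.
#' @param lambda_L local contact rate (\code{0} to \code{Inf}).
#' @param T_I infectious period law.
#' @export
R_star <- function(dist, lambda_G, lambda_L, T_I) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  sb <- size_bias(dist)
  n <- seq_len(dist$n_max)
  mu_n <- single_household_mean_size(n, lambda_L, T_I)
  lambda_G * T_I$mean * sum(sb$probs * mu_n)
}

#' Mean rank-generation sizes of a single-household epidemic
#'
#' In the within-household directed random graph, each individual —
#' conditional on its infectious period \eqn{T} — contacts each housemate
#' independently with probability \eqn{1 - e^{-\lambda_L T}}; an
#' individual's rank generation is its shortest-path distance from the
#' initial case. Generation sizes form a Markov chain on (frontier size
#' \eqn{f}, unreached count \eqn{u}): conditional on the sum of the
#' frontier's infectious periods, unreached members are reached
#' independently, so
#' \deqn{P(k \text{ new} \mid f, u) = \binom{u}{k} \sum_{j=0}^{k}
#'   \binom{k}{j} (-1)^j \phi((j + u - k)\lambda_L)^f.}
#' The mean generation sizes \eqn{\mu_i^{(n)}} follow exactly for any
#' \eqn{n}, and satisfy \eqn{\mu_0^{(n)} = 1} and
#' \eqn{\sum_i \mu_i^{(n)} = \mu_n(\lambda_L)}.
#'
#' @param n household size.
#' @inheritParams R_star
#' @return Object of class \code{rank_generation_profile}: list with
#'   \code{n} and \code{means} = \eqn{(\mu_0^{(n)}, \dots,
#'   \mu_{n-1}^{(n)})}.
#' @export
rank_generation_means <- function(n, lambda_L, T_I) {
  stopifnot(n >= 1, n == round(n), lambda_L >= 0)
  T_I <- as_ti_law(T_I)
  means <- numeric(n)
  means[1] <- 1
  if (n > 1) {
    if (is.infinite(lambda_L)) {
      means[2] <- n - 1            # whole household in generation 1
    } else {
      phi <- T_I$phi((0:(n - 1)) * lambda_L)   # phi[j+1] = phi(j lambda_L)
      # state distribution over (f, u); start at f = 1, u = n - 1
      # represent as matrix p[f+1, u+1]
      p <- matrix(0, n + 1, n)
      p[2, n] <- 1
      for (gen in 1:(n - 1)) {
        q <- matrix(0, n + 1, n)
        for (f in 1:n) for (u in 0:(n - 1)) {
          pr <- p[f + 1, u + 1]
          if (pr <= 0) next
          if (u == 0) next                     # chain ends
          for (k in 0:u) {
            j <- 0:k
            pk <- choose(u, k) *
              sum(choose(k, j) * (-1)^j * phi[j + u - k + 1]^f)
            q[k + 1, u - k + 1] <- q[k + 1, u - k + 1] + pr * pk
          }
        }
        p <- q
        f_sizes <- 0:n
        means[gen + 1] <- sum(rowSums(p) * f_sizes)
        if (means[gen + 1] < 1e-300) break
      }
    }
  }
  structure(list(n = n, means = means), class = "rank_generation_profile")
}

#' @export
print.rank_generation_profile <- function(x, ...) {
  cat(sprintf("Mean rank-generation sizes, household of size %d:\n", x$n))
  print(stats::setNames(round(x$means, 6), seq_along(x$means) - 1))
  invisible(x)
}

#' Rank-generation basic reproduction number R0
#'
#' The basic reproduction number of the household model defined as the
#' asymptotic geometric growth rate of mean rank-generation sizes: the
#' unique positive root \eqn{\lambda} of
#' \deqn{1 - \lambda_G E[T_I] \sum_{i \ge 0} \mu_i / \lambda^{i+1} = 0,
#'   \qquad \mu_i = \sum_n \tilde\alpha_n\, \mu_i^{(n)}.}
#' The series is finite (\eqn{\mu_i^{(n)} = 0} for \eqn{i \ge n}).
#' Satisfies \eqn{R_0 > 1} iff \eqn{R_* > 1}.
#'
#' @inheritParams R_star
#' @export
R0 <- function(dist, lambda_G, lambda_L, T_I) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  stopifnot(lambda_G > 0)
  sb <- size_bias(dist)
  n_max <- dist$n_max
  mu_i <- numeric(n_max)               # mu_i[i+1] = mean generation-i size
  for (nn in seq_len(n_max)) {
    if (sb$probs[nn] == 0) next
    g <- rank_generation_means(nn, lambda_L, T_I)$means
    mu_i[seq_along(g)] <- mu_i[seq_along(g)] + sb$probs[nn] * g
  }
  a <- lambda_G * T_I$mean
  f <- function(lam) 1 - a * sum(mu_i / lam^(seq_along(mu_i)))
  hi <- a * sum(mu_i) + 1
  stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

#' Post-vaccination threshold parameter
#'
#' Threshold parameter for an epidemic after a fraction \code{c} of the
#' population is vaccinated uniformly at random with a perfect vaccine:
#' \deqn{\hat R_U(c) = \sum_n \tilde\alpha_n \sum_{v=0}^{n} \binom{n}{v}
#'   c^v (1-c)^{n-v} \frac{n-v}{n}\, \mu_{n-v}(\lambda_L)\,
#'   \lambda_G E[T_I].}
#' Continuous and strictly decreasing with \eqn{\hat R_U(0) = R_*} and
#' \eqn{\hat R_U(1) = 0}.
#'
#' @inheritParams R_star
#' @param c vaccinated fraction in \eqn{[0, 1]} (vectorised).
#' @export
R_U_hat <- function(dist, lambda_G, lambda_L, T_I, c) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  stopifnot(all(c >= 0), all(c <= 1))
  sb <- size_bias(dist)
  n_max <- dist$n_max
  mu <- single_household_mean_size(0:n_max, lambda_L, T_I)  # mu[j+1]=mu_j
  vapply(c, function(cc) {
    tot <- 0
    for (nn in seq_len(n_max)) {
      if (sb$probs[nn] == 0) next
      v <- 0:nn
      bin <- stats::dbinom(v, nn, cc)
      tot <- tot + sb$probs[nn] *
        sum(bin * ((nn - v) / nn) * mu[nn - v + 1])
    }
    tot * lambda_G * T_I$mean
  }, numeric(1))
}

#' Residual threshold parameter given household outcome distributions
#'
#' Threshold parameter \eqn{\hat R_{DI}} for a second epidemic (at the full
#' global rate) among the susceptibles left by a first epidemic whose
#' per-household outcomes are \code{outcome}:
#' \deqn{\hat R_{DI} = \lambda_G E[T_I] \sum_n \tilde\alpha_n
#'   \sum_{v=0}^n P_{n,v} \left(1 - \frac{v}{n}\right)
#'   \mu_{n-v}(\lambda_L).}
#'
#' @inheritParams R_star
#' @param outcome list indexed by household size; element \code{n} is the
#'   outcome vector \eqn{(P_{n,0}, \dots, P_{n,n})} (as produced by
#'   [final_size()]).
#' @export
R_DI_from_outcome <- function(dist, lambda_G, lambda_L, T_I, outcome) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  sb <- size_bias(dist)
  n_max <- dist$n_max
  mu <- single_household_mean_size(0:n_max, lambda_L, T_I)
  tot <- 0
  for (nn in seq_len(n_max)) {
    if (sb$probs[nn] == 0) next
    P <- outcome[[nn]]
    if (is.null(P)) stop(sprintf("missing outcome distribution for size %d", nn))
    stopifnot(length(P) == nn + 1)
    v <- 0:nn
    tot <- tot + sb$probs[nn] * sum(P * (1 - v / nn) * mu[nn - v + 1])
  }
  tot * lambda_G * T_I$mean
}
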