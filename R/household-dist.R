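#' Household size distributions
#'
#' A household size distribution assigns probability \eqn{\alpha_n} to a
#' household (chosen uniformly at random among households) having size
#' \eqn{n}, for \eqn{n = 1, \dots, n_{max}} with finite \eqn{n_{max}}.
#' The mean household size is \eqn{\mu_H = \sum_n n \alpha_n}.
#'
#' @param probs numeric vector of probabilities, either of length
#'   \code{max(sizes)} indexed by size, or parallel to \code{sizes}.
#'   Non-negative; normalised to sum to one (a warning is issued if the
#'   input sums to something farther than \code{1e-6} from one).
#' @param sizes optional integer vector of sizes matching \code{probs}.
#'
#' @return An object of class \code{hh_dist}: a list with \code{probs}
#'   (full vector over sizes \code{1:n_max}), \code{n_max} and the mean
#'   household size \code{mu}.
#'
#' @examples
#' hh_dist(c(0.8, 0, 0, 0.2))          # sizes 1 and 4
#' hh_dist(c(0.8, 0.2), sizes = c(1, 4))
#' hh_common(3)                         # all households of size 3
#' @export
hh_dist <- function(probs, sizes = NULL) {
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == length(probs), all(sizes == round(sizes)),
              all(sizes >= 1), !anyDuplicated(sizes))
    full <- numeric(max(sizes))
    full[sizes] <- probs
    probs <- full
  }
  stopifnot(is.numeric(probs), length(probs) >= 1L)
  if (any(probs < 0)) stop("household size probabilities must be non-negative")
  s <- sum(probs)
  if (s <= 0) stop("empty household size distribution")
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("probabilities sum to %.8g; renormalising", s))
  }
  probs <- probs / s
  n_max <- max(which(probs > 0))
  probs <- probs[seq_len(n_max)]
  structure(
    list(probs = probs, n_max = n_max,
         mu = sum(seq_len(n_max) * probs)),
    class = "hh_dist"
  )
}

#' @rdname hh_dist
#' @param n common household size.
#' @export
hh_common <- function(n) {
  stopifnot(n == round(n), n >= 1)
  hh_dist(1, sizes = n)
}

#' Two household sizes, 1 and n, parametrised by the size-biased weight
#'
#' Builds the distribution in which a fraction \code{p} of *individuals*
#' live in households of size \code{n} and the rest in households of size 1
#' (so the size-biased probabilities are \eqn{\tilde\alpha_n = p},
#' \eqn{\tilde\alpha_1 = 1 - p}).
#'
#' @param n the larger household size (> 1).
#' @param p fraction of individuals in households of size \code{n}.
#' @export
hh_mixture_1n <- function(n, p) {
  stopifnot(n == round(n), n > 1, p > 0, p < 1)
  # alpha_n proportional to alpha_tilde_n / n
  w <- c(1 - p, p / n)
  hh_dist(w / sum(w), sizes = c(1L, as.integer(n)))
}

#' @export
print.hh_dist <- function(x, ...) {
  cat(sprintf("Household size distribution on 1..%d (mean size %.4g)\n",
              x$n_max, x$mu))
  sup <- which(x$probs > 0)
  print(stats::setNames(round(x$probs[sup], 6), sup))
  invisible(x)
}

as_hh_dist <- function(x) {
  if (inherits(x, "hh_dist")) return(x)
  if (is.numeric(x)) return(hh_dist(x))
  stop("expected a 'hh_dist' object")
}

#' Size-biased household size distribution
#'
#' The size-biased distribution \eqn{\tilde H} describes the household size
#' of an individual chosen uniformly at random from the population:
#' \eqn{\tilde\alpha_n = n \alpha_n / \mu_H}. Its mean
#' \eqn{\mu_{\tilde H}}, variance and factorial moments govern the herd
#' immunity orderings in the highly and weakly locally infectious limits.
#'
#' @param dist a \code{hh_dist} object.
#'
#' @return An object of class \code{hh_sizebiased}: list with \code{probs}
#'   (\eqn{\tilde\alpha_n} over \code{1:n_max}), \code{n_max}, \code{mu}
#'   (\eqn{\mu_{\tilde H}}), \code{var}, \code{mu_H} (mean of the
#'   unbiased distribution).
#'
#' @examples
#' sb <- size_bias(hh_dist(c(0.8, 0, 0, 0.2)))
#' sb$probs   # 0.5 on sizes 1 and 4
#' @export
size_bias <- function(dist) {
  dist <- as_hh_dist(dist)
  n <- seq_len(dist$n_max)
  probs <- n * dist$probs / dist$mu
  mu <- sum(n * probs)
  structure(
    list(probs = probs, n_max = dist$n_max, mu = mu,
         var = sum(n^2 * probs) - mu^2, mu_H = dist$mu),
    class = "hh_sizebiased"
  )
}

#' @export
print.hh_sizebiased <- function(x, ...) {
  cat(sprintf(
    "Size-biased household size distribution on 1..%d (mean %.4g, var %.4g)\n",
    x$n_max, x$mu, x$var))
  sup <- which(x$probs > 0)
  print(stats::setNames(round(x$probs[sup], 6), sup))
  invisible(x)
}

as_sizebiased <- function(x) {
  if (inherits(x, "hh_sizebiased")) return(x)
  if (inherits(x, "hh_dist")) return(size_bias(x))
  stop("expected a 'hh_sizebiased' or 'hh_dist' object")
}

#' Recover the household distribution from its size-biased version
#'
#' Inverts [size_bias()]: \eqn{\alpha_n \propto \tilde\alpha_n / n}.
#'
#' @param sb a \code{hh_sizebiased} object (or \code{hh_dist}, returned
#'   unchanged after a round trip).
#' @export
unbias <- function(sb) {
  sb <- as_sizebiased(sb)
  n <- seq_len(sb$n_max)
  w <- sb$probs / n
  hh_dist(w / sum(w))
}

#' Probability-generating function of the size-biased distribution
#'
#' \eqn{f_{\tilde H}(x) = \sum_n \tilde\alpha_n x^n} and its derivatives.
#'
#' @param sb a \code{hh_sizebiased} object.
#' @param x evaluation points in \eqn{[0, 1]} (vectorised).
#' @param deriv non-negative integer derivative order.
#' @export
sb_pgf <- function(sb, x, deriv = 0L) {
  sb <- as_sizebiased(sb)
  stopifnot(deriv >= 0, deriv == round(deriv))
  n <- seq_len(sb$n_max)
  # d^k/dx^k x^n = n (n-1) ... (n-k+1) x^(n-k)
  fall <- vapply(n, function(nn) prod(nn - seq_len(deriv) + 1), numeric(1))
  if (deriv == 0L) fall <- rep(1, sb$n_max)
  pow <- n - deriv
  vapply(x, function(xx) {
    xp <- ifelse(pow < 0, 0, xx^pmax(pow, 0))
    sum(sb$probs * fall * xp)
  }, numeric(1))
}

#' Factorial moments of the size-biased household size
#'
#' Returns \eqn{\mu_{\tilde H}^{[i]} = E[\tilde H (\tilde H - 1) \cdots
#' (\tilde H - i + 1)]}, with \eqn{\mu^{[0]} = 1} and
#' \eqn{\mu^{[1]} = \mu_{\tilde H}}.
#'
#' @param sb a \code{hh_sizebiased} object.
#' @param i non-negative integer order (vectorised).
#' @export
factorial_moment <- function(sb, i) {
  sb <- as_sizebiased(sb)
  stopifnot(all(i >= 0), all(i == round(i)))
  n <- seq_len(sb$n_max)
  vapply(i, function(k) {
    if (k == 0) return(1)
    fall <- vapply(n, function(nn) prod(nn - seq_len(k) + 1), numeric(1))
    fall[n < k] <- 0
    sum(sb$probs * fall)
  }, numeric(1))
}

#' Geometric reference factorial moments
#'
#' The \eqn{i}th factorial moment of a geometric distribution on
#' \eqn{\{1, 2, \dots\}} with success probability \eqn{1/\mu}:
#' \eqn{\hat\mu^{[i]} = i!\, \mu (\mu - 1)^{i-1}}. Equality of the size-biased
#' factorial moments with this reference characterises the logarithmic
#' household size distribution for which the disease-induced and
#' vaccine-induced levels coincide in the highly locally infectious case.
#'
#' @param mu mean of the geometric distribution (\eqn{\ge 1}).
#' @param i non-negative integer order (vectorised).
#' @export
geometric_factorial_moment <- function(mu, i) {
  stopifnot(mu >= 1, all(i >= 0), all(i == round(i)))
  vapply(i, function(k) {
    if (k == 0) return(1)
    factorial(k) * mu * (mu - 1)^(k - 1)
  }, numeric(1))
}

#' Household distribution whose size-biased version is geometric
#'
#' Constructs the (logarithmic) household size distribution \eqn{H} whose
#' size-biased version \eqn{\tilde H} is geometric on \eqn{\{1, 2, \dots\}}
#' with mean \code{mu}, truncated at \code{n_max} and renormalised. This is
#' the unique household structure for which the final-size approximation to
#' the disease-induced herd immunity level equals the vaccine-induced level
#' for every supercritical global rate in the highly locally infectious
#' case.
#'
#' @param mu target mean of the size-biased distribution (\eqn{\ge 1}).
#' @param n_max truncation point (default 30).
#'
#' @return A \code{hh_dist}; attribute \code{truncated_mass} reports the
#'   size-biased mass beyond \code{n_max} that was discarded.
#' @export
geometric_size_biased <- function(mu, n_max = 30L) {
  stopifnot(is.numeric(mu), length(mu) == 1L)
  if (mu < 1) stop("mu must be at least 1")
  stopifnot(n_max >= 1, n_max == round(n_max))
  if (mu == 1) {
    out <- hh_common(1)
    attr(out, "truncated_mass") <- 0
    return(out)
  }
  theta <- 1 / mu
  n <- seq_len(n_max)
  tilde <- theta * (1 - theta)^(n - 1)
  trunc_mass <- (1 - theta)^n_max
  tilde <- tilde / sum(tilde)
  w <- tilde / n              # alpha_n proportional to alpha_tilde_n / n
  out <- hh_dist(w / sum(w))
  attr(out, "truncated_mass") <- trunc_mass
  out
}

#' Synthetic household size distributions with prescribed size-biased moments
#'
#' Generates a random household size distribution on \code{1:n_max} whose
#' size-biased mean and variance match the targets. A Dirichlet draw over
#' the support is exponentially tilted in \eqn{(n, n^2)} by a damped Newton
#' iteration until both moments match to within \code{tol}; boundary targets
#' (zero variance at an integer mean, or the maximal variance
#' \eqn{(\mu - 1)(n_{max} - \mu)}) are returned as the unique two-point or
#' point-mass solutions. Deterministic given \code{seed}.
#'
#' @param seed integer seed.
#' @param n_max support upper bound.
#' @param target_mean_tilde desired \eqn{\mu_{\tilde H}}.
#' @param target_var_tilde desired \eqn{var(\tilde H)}.
#' @param tol moment-matching tolerance (default \code{1e-6}; the Newton
#'   solve typically lands near machine precision).
#' @return A \code{hh_dist} object.
#' @export
random_household_distribution <- function(seed, n_max, target_mean_tilde,
                                          target_var_tilde, tol = 1e-6) {
  stopifnot(n_max >= 1, n_max == round(n_max))
  m <- target_mean_tilde
  v <- target_var_tilde
  if (m < 1 || m > n_max) {
    stop(sprintf("infeasible size-biased mean %.4g: must lie in [1, %d]",
                 m, n_max))
  }
  v_max <- (m - 1) * (n_max - m)
  fr <- m - floor(m)
  v_min <- fr * (1 - fr)   # two-point on {floor(m), ceiling(m)}
  if (v < v_min - tol || v > v_max + tol) {
    stop(sprintf(
      "infeasible size-biased variance %.4g for mean %.4g on {1..%d}: feasible range is [%.4g, %.4g]",
      v, m, n_max, v_min, v_max))
  }
  n <- seq_len(n_max)

  make <- function(tilde) {
    tilde <- pmax(tilde, 0)
    tilde <- tilde / sum(tilde)
    w <- tilde / n
    out <- hh_dist(w / sum(w))
    sb <- size_bias(out)
    if (abs(sb$mu - m) > tol || abs(sb$var - v) > tol) {
      stop("internal: synthetic generator missed its moment targets")
    }
    out
  }

  # boundary cases have a unique solution
  if (v <= v_min + 1e-12) {
    if (fr < 1e-12) {
      tilde <- numeric(n_max); tilde[round(m)] <- 1
      return(make(tilde))
    }
    tilde <- numeric(n_max)
    tilde[floor(m)] <- 1 - fr
    tilde[ceiling(m)] <- fr
    return(make(tilde))
  }
  if (v >= v_max - 1e-12) {
    p <- (m - 1) / (n_max - 1)
    tilde <- numeric(n_max)
    tilde[1] <- 1 - p; tilde[n_max] <- p
    return(make(tilde))
  }

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  target <- c(m, v + m^2)
  for (attempt in seq_len(200L)) {
    d <- stats::rexp(n_max)
    d <- d / sum(d)
    th <- c(0, 0)
    ok <- FALSE
    for (it in seq_len(200L)) {
      w <- d * exp(th[1] * n + th[2] * n^2)
      if (!all(is.finite(w)) || sum(w) <= 0) break
      q <- w / sum(w)
      m1 <- sum(q * n); m2 <- sum(q * n^2)
      g <- c(m1, m2) - target
      if (max(abs(g)) < 1e-12) { ok <- TRUE; break }
      # Jacobian: covariance of (n, n^2) under q
      c11 <- m2 - m1^2
      c12 <- sum(q * n^3) - m1 * m2
      c22 <- sum(q * n^4) - m2^2
      J <- matrix(c(c11, c12, c12, c22), 2, 2)
      step <- tryCatch(solve(J, g), error = function(e) NULL)
      if (is.null(step)) break
      # damped step
      lam <- 1
      repeat {
        th_new <- th - lam * step
        w_new <- d * exp(th_new[1] * n + th_new[2] * n^2)
        if (all(is.finite(w_new)) && sum(w_new) > 0) {
          q_new <- w_new / sum(w_new)
          g_new <- c(sum(q_new * n), sum(q_new * n^2)) - target
          if (sum(g_new^2) < sum(g^2) || lam < 1e-6) { th <- th_new; break }
        }
        lam <- lam / 2
        if (lam < 1e-8) { th <- th - 1e-8 * step; break }
      }
    }
    if (ok) {
      w <- d * exp(th[1] * n + th[2] * n^2)
      return(make(w / sum(w)))
    }
  }
  stop("synthetic generator failed to reach moment targets; try other seed")
}

#' Read and write household size distributions as CSV
#'
#' Two-column CSV with a header: \code{size} plus either \code{probability}
#' or \code{count} (counts are normalised on load).
#'
#' @param path file path.
#' @param dist a \code{hh_dist} object (for writing).
#' @export
read_hh_dist <- function(path) {
  df <- utils::read.csv(path)
  if (!"size" %in% names(df)) stop("CSV must have a 'size' column")
  wcol <- intersect(c("probability", "count"), names(df))
  if (length(wcol) == 0) {
    stop("CSV must have a 'probability' or 'count' column")
  }
  w <- df[[wcol[1]]]
  hh_dist(w / sum(w), sizes = df$size)
}

#' @rdname read_hh_dist
#' @export
write_hh_dist <- function(dist, path) {
  dist <- as_hh_dist(dist)
  sup <- which(dist$probs > 0)
  utils::write.csv(
    data.frame(size = sup, probability = dist$probs[sup]),
    path, row.names = FALSE)
  invisible(path)
}
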