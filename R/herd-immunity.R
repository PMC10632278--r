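new_herd_immunity_result <- function(level, kind, ...) {
  structure(
    c(list(level = level, kind = kind), list(...)),
    class = "herd_immunity_result"
  )
}

#' @export
print.herd_immunity_result <- function(x, ...) {
  cat(sprintf("Herd immunity level (%s): %.6g\n", x$kind, x$level))
  extra <- setdiff(names(x), c("level", "kind"))
  for (nm in extra) {
    val <- x[[nm]]
    if (is.numeric(val) && length(val) == 1) {
      cat(sprintf("  %s = %.6g\n", nm, val))
    }
  }
  invisible(x)
}

#' Vaccine-induced herd immunity level
#'
#' The critical uniform vaccination coverage \eqn{h_C}: the unique
#' \eqn{c \in (0, 1)} with \eqn{\hat R_U(c) = 1} (see [R_U_hat()]). When
#' \eqn{R_* \le 1} herd immunity already holds and level 0 is returned with
#' a flag.
#'
#' @inheritParams R_star
#' @return A \code{herd_immunity_result} with the level, the residual
#'   threshold parameter at the solution, and \code{already_immune}.
#' @export
h_C <- function(dist, lambda_G, lambda_L, T_I) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  Rs <- R_star(dist, lambda_G, lambda_L, T_I)
  if (Rs <= 1) {
    return(new_herd_immunity_result(
      0, "h_C", R_star = Rs, residual_R = Rs, already_immune = TRUE))
  }
  root <- stats::uniroot(
    function(cc) R_U_hat(dist, lambda_G, lambda_L, T_I, cc) - 1,
    c(0, 1), tol = 1e-12)$root
  new_herd_immunity_result(
    root, "h_C", R_star = Rs,
    residual_R = R_U_hat(dist, lambda_G, lambda_L, T_I, root),
    already_immune = FALSE)
}

#' Vaccine-induced level in the highly locally infectious case
#'
#' Closed form for \eqn{\lambda_L = \infty}: \eqn{h_C} solves the quadratic
#' \eqn{c(1-c) + \mu_{\tilde H}(1-c)^2 = 1/(\lambda_G E[T_I])}, giving
#' \deqn{h_C = 1 - \frac{\sqrt{1 + 4(\mu_{\tilde H} - 1) /
#'   (\lambda_G E[T_I])} - 1}{2(\mu_{\tilde H} - 1)}.}
#' The degenerate case \eqn{\mu_{\tilde H} = 1} (all households of size 1)
#' reduces to the homogeneous \eqn{1 - 1/(\lambda_G E[T_I])}.
#'
#' @inheritParams R_star
#' @export
h_C_highly_local <- function(dist, lambda_G, T_I) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  mu <- size_bias(dist)$mu
  x <- 1 / (lambda_G * T_I$mean)
  if (lambda_G * T_I$mean * mu <= 1) {
    stop("subcritical: R_* <= 1 in the highly locally infectious case")
  }
  if (abs(mu - 1) < 1e-14) return(1 - x)
  1 - (sqrt(1 + 4 * (mu - 1) * x) - 1) / (2 * (mu - 1))
}

#' Final-size approximation to the disease-induced herd immunity level
#'
#' Computes \eqn{\tilde h_D}: the first epidemic is run with global rate
#' \eqn{\kappa \lambda_G} (local rate unchanged) to its final outcome; the
#' residual threshold parameter \eqn{\hat R_{DI}(\kappa)} of a second
#' epidemic at the full global rate among remaining susceptibles is then
#' computed from the per-household outcome distributions. The critical
#' scaling \eqn{\hat\kappa} solves \eqn{\hat R_{DI}(\hat\kappa) = 1} and
#' \eqn{\tilde h_D = z(\hat\kappa)}, the infected fraction in the first
#' epidemic.
#'
#' @inheritParams R_star
#' @return A \code{herd_immunity_result} with diagnostics
#'   \code{kappa_hat}, \code{pi}, \code{z} and \code{residual_R}.
#' @export
h_tilde_D <- function(dist, lambda_G, lambda_L, T_I) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  Rs <- R_star(dist, lambda_G, lambda_L, T_I)
  if (Rs <= 1) {
    return(new_herd_immunity_result(
      0, "h_tilde_D", R_star = Rs, residual_R = Rs, already_immune = TRUE))
  }
  # degenerate: all households of size one
  if (dist$n_max == 1) {
    lev <- 1 - 1 / (lambda_G * T_I$mean)
    return(new_herd_immunity_result(
      lev, "h_tilde_D", kappa_hat = 1 / (lambda_G * T_I$mean),
      pi = 1 - lev, z = lev, residual_R = 1, already_immune = FALSE))
  }
  resid <- function(kappa) {
    fs <- final_size(dist, lambda_G, lambda_L, T_I, kappa = kappa)
    R_DI_from_outcome(dist, lambda_G, lambda_L, T_I, fs$outcome) - 1
  }
  lo <- (1 + 1e-9) / Rs
  hi <- 1
  if (resid(hi) > 0) {
    stop("residual epidemic still supercritical after an unrestricted first wave")
  }
  kap <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  fs <- final_size(dist, lambda_G, lambda_L, T_I, kappa = kap)
  new_herd_immunity_result(
    fs$z, "h_tilde_D", kappa_hat = kap, pi = fs$pi, z = fs$z,
    residual_R = R_DI_from_outcome(dist, lambda_G, lambda_L, T_I,
                                   fs$outcome),
    already_immune = FALSE)
}

#' Disease-induced level approximation in the highly locally infectious case
#'
#' For \eqn{\lambda_L = \infty} the scaled-epidemic construction reduces to
#' solving \eqn{\pi f'_{\tilde H}(\pi) = 1 / (\lambda_G E[T_I])} for the
#' escape probability \eqn{\pi \in (0, 1)} and returning
#' \eqn{\tilde h_D = 1 - f_{\tilde H}(\pi)}, with \eqn{f_{\tilde H}} the
#' probability-generating function of the size-biased household size.
#'
#' @inheritParams R_star
#' @export
h_tilde_D_highly_local <- function(dist, lambda_G, T_I) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  sb <- size_bias(dist)
  target <- 1 / (lambda_G * T_I$mean)
  if (sb$mu <= target) {
    stop("subcritical: R_* <= 1 in the highly locally infectious case")
  }
  g <- function(p) p * sb_pgf(sb, p, deriv = 1L) - target
  pi <- stats::uniroot(g, c(1e-14, 1), tol = 1e-14)$root
  lev <- 1 - sb_pgf(sb, pi)
  new_herd_immunity_result(
    lev, "h_tilde_D", pi = pi, z = lev,
    kappa_hat = -log(pi) / (lambda_G * T_I$mean * lev),
    residual_R = 1, already_immune = FALSE)
}

#' Crossover global rate for populations with household sizes 1 and n
#'
#' In the highly locally infectious case with size-biased weights
#' \eqn{\tilde\alpha_n = p = 1 - \tilde\alpha_1}, the ordering of
#' \eqn{\tilde h_D} and \eqn{h_C} can flip as \eqn{\lambda_G} grows. For
#' \eqn{n = 2}, or for \eqn{p \le (n-2) / (2(n-1))}, there is no sign
#' change (\code{NULL} is returned). Otherwise the crossover is
#' \deqn{\lambda_G^*(n, p) = \left[E[T_I]\, \hat\pi_n(p) \left(1 - p +
#'   n p\, \hat\pi_n(p)^{n-1}\right)\right]^{-1},}
#' where \eqn{\hat\pi_n(p)} is the unique root in \eqn{(0, 1)} of
#' \eqn{\pi^{n/2-1} - p \pi^{n-1} - (1-p) = 0}.
#'
#' @param n the larger household size (> 1).
#' @param p size-biased weight of size-\code{n} households, in (0, 1).
#' @param mean_TI mean infectious period.
#' @return \code{NULL} when no crossover exists, otherwise a list with
#'   \code{lambda_G_star} and the root \code{pi_hat}.
#' @export
lambda_G_star_two_sizes <- function(n, p, mean_TI = 1) {
  stopifnot(n == round(n), n > 1, p > 0, p < 1, mean_TI > 0)
  if (n == 2 || p <= (n - 2) / (2 * (n - 1)) + 1e-15) return(NULL)
  g <- function(pi) pi^(n / 2 - 1) - p * pi^(n - 1) - (1 - p)
  pi_hat <- stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  list(
    lambda_G_star = 1 / (mean_TI * pi_hat *
                           (1 - p + n * p * pi_hat^(n - 1))),
    pi_hat = pi_hat
  )
}

new_ordering_verdict <- function(verdict, witness_index, witness, regime) {
  structure(
    list(verdict = verdict, witness_index = witness_index,
         witness = witness, regime = regime),
    class = "ordering_verdict"
  )
}

#' @export
print.ordering_verdict <- function(x, ...) {
  cat(sprintf("Ordering of h_tilde_D and h_C (%s regime): %s\n",
              x$regime, x$verdict))
  if (!is.na(x$witness_index)) {
    cat(sprintf("  witness index %d: %s\n", x$witness_index,
                paste(sprintf("%.6g", x$witness), collapse = " vs ")))
  }
  invisible(x)
}

#' Ordering of the herd immunity levels for just supercritical epidemics
#'
#' In the highly locally infectious case with \eqn{R_*} just above one, the
#' ordering of \eqn{\tilde h_D} and \eqn{h_C} is decided by the first
#' factorial moment of \eqn{\tilde H} that departs from the geometric
#' reference \eqn{\hat\mu^{[k]} = k!\,\mu(\mu-1)^{k-1}}: with
#' \eqn{l^* = \inf\{k \ge 2 : \mu^{[k]} \ne \hat\mu^{[k]}\}},
#' \eqn{\tilde h_D > h_C} iff \eqn{\mu^{[l^*]} < \hat\mu^{[l^*]}}. If all
#' moments up to \code{2 * n_max} match (relative tolerance \code{1e-9}),
#' the geometric/equality verdict is returned; a truncated geometric
#' support is flagged inconclusive.
#'
#' @param sb a \code{hh_sizebiased} (or \code{hh_dist}).
#' @export
ordering_just_supercritical <- function(sb) {
  sb <- as_sizebiased(sb)
  mu <- sb$mu
  if (mu <= 1) {
    return(new_ordering_verdict("inconclusive", NA_integer_, NA_real_,
                                "just-supercritical"))
  }
  geo <- geometric_pmf_check(sb)
  if (geo$is_geometric) {
    # truncated geometric pmf: the infinite-support completion gives exact
    # equality; report it (with the truncated mass recorded), rather than
    # the spurious high-order moment witness caused by truncation alone
    return(new_ordering_verdict("equality/geometric", NA_integer_,
                                geo$truncated_mass, "just-supercritical"))
  }
  for (k in 2:sb$n_max) {
    mk <- factorial_moment(sb, k)
    ref <- geometric_factorial_moment(mu, k)
    if (abs(mk - ref) > 1e-9 * max(1, abs(ref))) {
      verdict <- if (mk < ref) "h_tilde_D > h_C" else "h_tilde_D < h_C"
      return(new_ordering_verdict(verdict, k, c(mk, ref),
                                  "just-supercritical"))
    }
  }
  new_ordering_verdict("inconclusive", NA_integer_, NA_real_,
                       "just-supercritical")
}

# does the size-biased pmf have the constant-ratio (geometric) form?
geometric_pmf_check <- function(sb, tol = 1e-9) {
  p <- sb$probs
  if (sb$n_max == 1) {
    return(list(is_geometric = TRUE, ratio = 0, truncated_mass = 0))
  }
  if (any(p <= 0)) {
    return(list(is_geometric = FALSE, ratio = NA_real_,
                truncated_mass = NA_real_))
  }
  ratios <- p[-1] / p[-sb$n_max]
  r <- ratios[1]
  if (any(abs(ratios - r) > tol * max(1, r))) {
    return(list(is_geometric = FALSE, ratio = NA_real_,
                truncated_mass = NA_real_))
  }
  list(is_geometric = TRUE, ratio = r, truncated_mass = r^sb$n_max)
}

#' Ordering for highly locally and highly globally infectious epidemics
#'
#' As the escape probability \eqn{\pi \downarrow 0}, the ordering is
#' decided by the first non-zero derivative at zero of
#' \deqn{G^{(n)}(0) = n!\left((1-n)\tilde\alpha_n + (\mu_{\tilde H}-1)
#'   \sum_{k=1}^{n-1} \tilde\alpha_{n-k} \tilde\alpha_k\right):}
#' \eqn{G^{(n^*)}(0) < 0} gives \eqn{\tilde h_D > h_C};
#' \eqn{G^{(n^*)}(0) > 0} gives \eqn{\tilde h_D < h_C}. All derivatives
#' vanish exactly for the geometric size-biased distribution
#' (\eqn{\tilde\alpha_n = \tilde\alpha_1^n (\mu_{\tilde H}-1)^{n-1}}).
#'
#' @param sb a \code{hh_sizebiased} (or \code{hh_dist}).
#' @export
ordering_high_global <- function(sb) {
  sb <- as_sizebiased(sb)
  mu <- sb$mu
  geo <- geometric_pmf_check(sb)
  if (geo$is_geometric) {
    return(new_ordering_verdict("equality/geometric", NA_integer_,
                                geo$truncated_mass, "high-global"))
  }
  a <- c(sb$probs, numeric(sb$n_max))  # pad so a[n-k] is defined
  for (n in 2:(2 * sb$n_max)) {
    an <- if (n <= sb$n_max) sb$probs[n] else 0
    k <- seq_len(n - 1)
    conv <- sum(a[n - k] * a[k])
    Gn0 <- factorial(n) * ((1 - n) * an + (mu - 1) * conv)
    if (abs(Gn0) > 1e-12 * factorial(n)) {
      verdict <- if (Gn0 < 0) "h_tilde_D > h_C" else "h_tilde_D < h_C"
      geo_ref <- if (sb$probs[1] > 0) {
        sb$probs[1]^n * (mu - 1)^(n - 1)
      } else NA_real_
      return(new_ordering_verdict(verdict, n, c(an, geo_ref, Gn0),
                                  "high-global"))
    }
  }
  new_ordering_verdict("inconclusive", NA_integer_, NA_real_,
                       "high-global")
}

#' Leading-order herd immunity difference for weak local infection
#'
#' For small \eqn{\lambda_L} (with \eqn{E[T_I] = 1} so the model at
#' \eqn{\lambda_L = 0} is homogeneous with \eqn{R_0 = \lambda_G}), the
#' difference expands as
#' \deqn{\tilde h_D(\lambda_L) - h_C(\lambda_L) = 2\lambda_L^2 \pi_0^2
#'   (1-\pi_0)\left[E[\tilde H - 1] - var(\tilde H)\right] +
#'   o(\lambda_L^2), \quad \pi_0 = 1/\lambda_G.}
#' This returns the leading term. Its prefactor
#' \eqn{\pi_0^2 (1 - \pi_0)} is maximised at \eqn{\pi_0 = 2/3}, i.e. at
#' \eqn{\lambda_G = 1.5}.
#'
#' @param sb a \code{hh_sizebiased} (or \code{hh_dist}).
#' @param lambda_G global rate (> 1 so the model is supercritical).
#' @param lambda_L small local rate.
#' @export
weak_local_difference <- function(sb, lambda_G, lambda_L) {
  sb <- as_sizebiased(sb)
  if (lambda_G <= 1) stop("requires lambda_G > 1 (supercritical at lambda_L = 0)")
  pi0 <- 1 / lambda_G
  2 * lambda_L^2 * pi0^2 * (1 - pi0) * ((sb$mu - 1) - sb$var)
}

#' Global rate maximising the gap between the herd immunity levels
#'
#' Numerically maximises \eqn{\tilde h_D(\lambda_G) - h_C(\lambda_G)} over
#' the supercritical range of \eqn{\lambda_G} and reports the maximiser
#' together with the rank-generation \eqn{R_0} evaluated there. In the
#' highly locally infectious case the closed forms are used (for a common
#' household size the maximiser is \eqn{4 / ((1+n) E[T_I])} and the
#' corresponding \eqn{R_0} equals 2). At \eqn{\lambda_L = 0} the two
#' levels coincide for every \eqn{\lambda_G}, so the maximiser is not
#' well-defined and an error is signalled.
#'
#' @inheritParams R_star
#' @param upper upper end of the search range for \eqn{\lambda_G}
#'   (default: the rate at which \eqn{R_* = 50}).
#' @return List with \code{lambda_G_hat}, \code{R0}, and the attained
#'   \code{difference}.
#' @export
argmax_difference_over_lambda_G <- function(dist, lambda_L, T_I,
                                            upper = NULL) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  if (lambda_L == 0) {
    stop("flat objective: h_tilde_D = h_C for every lambda_G when lambda_L = 0")
  }
  crit <- 1 / (T_I$mean *
                 sum(size_bias(dist)$probs *
                       single_household_mean_size(seq_len(dist$n_max),
                                                  lambda_L, T_I)))
  if (is.null(upper)) upper <- 50 * crit
  obj <- if (is.infinite(lambda_L)) {
    function(lg) {
      h_tilde_D_highly_local(dist, lg, T_I)$level -
        h_C_highly_local(dist, lg, T_I)
    }
  } else {
    function(lg) {
      h_tilde_D(dist, lg, lambda_L, T_I)$level -
        h_C(dist, lg, lambda_L, T_I)$level
    }
  }
  opt <- stats::optimize(obj, c(crit * (1 + 1e-6), upper), maximum = TRUE,
                         tol = 1e-10)
  list(
    lambda_G_hat = opt$maximum,
    R0 = R0(dist, opt$maximum, lambda_L, T_I),
    difference = opt$objective
  )
}
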